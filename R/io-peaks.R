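#' Construct a peak set
#'
#' Peaks are held as a `GRanges` (1-based, closed intervals, the Bioconductor
#' convention; BED-style half-open coordinates are converted on read/write)
#' with metadata columns `name`, `score`, `summit` (absolute 1-based position
#' of the point of highest enrichment) and `fold_enrichment`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds (BED convention), as in
#'   the on-disk formats.
#' @param name peak identifiers.
#' @param score numeric score column (e.g. -10*log10 q from MACS2).
#' @param strand strand characters; "." is stored as "*".
#' @param summit absolute 0-based summit coordinate; defaults to the interval
#'   midpoint (rounded down).
#' @param fold_enrichment non-negative fold enrichment at the summit.
#' @return a `GRanges` of peaks.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0, strand = "*",
                     summit = NULL, fold_enrichment = 0) {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L || length(end) == 0L) n <- 0L
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  if (any(!nzchar(chrom))) stop_validation("chromosome names must be non-empty")
  if (any(start < 0) || any(start >= end))
    stop_validation("peak intervals require 0 <= start < end")
  if (is.null(name)) name <- if (n) paste0("peak_", seq_len(n)) else character()
  name <- rep_len(as.character(name), n)
  if (is.null(summit)) summit <- (start + end) %/% 2L
  if (any(summit < start | summit >= end))
    stop_validation("summit must lie within its peak interval")
  if (any(fold_enrichment < 0))
    stop_validation("fold_enrichment must be non-negative")
  strand <- rep_len(ifelse(strand == ".", "*", strand), n)
  gr <- GRanges(chrom, IRanges(start + 1L, end),
                strand = if (n) strand else character())
  mcols(gr)$name <- as.character(name)
  mcols(gr)$score <- as.numeric(rep_len(score, n))
  mcols(gr)$summit <- as.integer(summit + 1L)
  mcols(gr)$fold_enrichment <- as.numeric(rep_len(fold_enrichment, n))
  gr
}

#' Read a peak file (BED6 or ENCODE narrowPeak)
#'
#' narrowPeak carries the summit as an offset in column 10 and fold
#' enrichment in column 7; BED6 has neither, so the summit defaults to the
#' interval midpoint and fold enrichment to 0.
#'
#' @param path file path.
#' @param format `"narrowpeak"` or `"bed6"`.
#' @return a `GRanges` of peaks (see [peak_set()]).
#' @export
read_peaks <- function(path, format = c("narrowpeak", "bed6")) {
  format <- match.arg(format)
  ncol_req <- if (format == "narrowpeak") 10L else 6L
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(peak_set(character(), integer(), integer()))
  fields <- strsplit(lines[keep], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < ncol_req)) {
    bad <- which(keep)[which(nf < ncol_req)[1L]]
    stop_validation("parse error at line %d of %s: expected >= %d columns, found %d",
                    bad, path, ncol_req, nf[which(nf < ncol_req)[1L]])
  }
  m <- t(vapply(fields, function(f) f[seq_len(ncol_req)], character(ncol_req)))
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(keep)[which(is.na(start) | is.na(end))[1L]]
    stop_validation("parse error at line %d of %s: non-numeric coordinates", bad, path)
  }
  if (any(start >= end)) {
    bad <- which(keep)[which(start >= end)[1L]]
    stop_validation("invalid interval at line %d of %s: start >= end", bad, path)
  }
  if (format == "narrowpeak") {
    offset <- as.integer(m[, 10L])
    summit <- ifelse(offset >= 0L, start + offset, (start + end) %/% 2L)
    fold <- as.numeric(m[, 7L])
  } else {
    summit <- (start + end) %/% 2L
    fold <- 0
  }
  peak_set(m[, 1L], start, end, name = m[, 4L],
           score = suppressWarnings(as.numeric(m[, 5L])), strand = m[, 6L],
           summit = summit, fold_enrichment = fold)
}

#' Write peaks to BED6 or narrowPeak
#'
#' Inverse of [read_peaks()]: coordinates are emitted 0-based half-open and
#' the narrowPeak summit as an offset from the start, so a read/write
#' round-trip reproduces every semantic field.
#'
#' @param peaks a peak `GRanges`.
#' @param path output path.
#' @param format `"narrowpeak"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowpeak", "bed6")) {
  format <- match.arg(format)
  start0 <- start(peaks) - 1L
  strand_chr <- as.character(strand(peaks))
  strand_chr[strand_chr == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)), start = start0,
                   end = end(peaks), name = mcols(peaks)$name,
                   score = mcols(peaks)$score, strand = strand_chr)
  if (format == "narrowpeak") {
    df$signalValue <- mcols(peaks)$fold_enrichment
    df$pValue <- -1
    df$qValue <- -1
    df$peak <- mcols(peaks)$summit - start(peaks)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
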