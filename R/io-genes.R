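#' Construct a gene model set
#'
#' One row per transcript. A gene may appear several times (alternative
#' transcripts); de-duplication is caller policy. CDS bounds and exon
#' structure are optional and only needed for genomic-feature classification
#' (UTRs, coding exons, introns).
#'
#' @param gene_id gene identifiers (character).
#' @param chrom chromosome names.
#' @param strand "+" or "-" (a gene must be stranded: the TSS depends on it).
#' @param tx_start,tx_end transcript bounds, 0-based half-open.
#' @param cds_start,cds_end coding-sequence bounds, 0-based half-open;
#'   `NA` (or `cds_start == cds_end`) for non-coding transcripts.
#' @param exons optional `IRangesList` (one element per transcript) of
#'   absolute 1-based exon intervals.
#' @return a `GRanges` of transcripts with metadata columns `gene_id`,
#'   `cds_start`, `cds_end` (1-based closed, `NA` if non-coding) and `exons`.
#' @export
gene_set <- function(gene_id, chrom, strand, tx_start, tx_end,
                     cds_start = NA_integer_, cds_end = NA_integer_,
                     exons = NULL) {
  n <- length(gene_id)
  if (!all(strand %in% c("+", "-")))
    stop_validation("gene strand must be '+' or '-'")
  if (any(tx_start >= tx_end))
    stop_validation("gene models require tx_start < tx_end")
  cds_start <- rep_len(as.integer(cds_start), n)
  cds_end <- rep_len(as.integer(cds_end), n)
  noncoding <- is.na(cds_start) | is.na(cds_end) | cds_start >= cds_end
  gr <- GRanges(chrom, IRanges(tx_start + 1L, tx_end), strand = strand)
  mcols(gr)$gene_id <- as.character(gene_id)
  mcols(gr)$cds_start <- ifelse(noncoding, NA_integer_, cds_start + 1L)
  mcols(gr)$cds_end <- ifelse(noncoding, NA_integer_, cds_end)
  if (is.null(exons))
    exons <- IRanges::IRangesList(lapply(seq_len(n), function(i)
      IRanges(tx_start[i] + 1L, tx_end[i])))
  mcols(gr)$exons <- as(exons, "CompressedIRangesList")
  gr
}

#' Read gene annotation (refFlat or BED12)
#'
#' refFlat rows are `geneName transcript chrom strand txStart txEnd cdsStart
#' cdsEnd exonCount exonStarts exonEnds` (UCSC, 0-based half-open); BED12 is
#' parsed through rtracklayer with blocks as exons and the thick range as
#' CDS. Header lines starting with `#` are skipped. Duplicate gene ids
#' (alternative transcripts) are retained.
#'
#' @param path file path.
#' @param format `"refflat"` or `"bed12"`.
#' @return a `GRanges` of transcripts (see [gene_set()]).
#' @export
read_gene_annotation <- function(path, format = c("refflat", "bed12")) {
  format <- match.arg(format)
  if (format == "refflat") {
    tab <- read.table(path, sep = "\t", comment.char = "#",
                      colClasses = "character", quote = "")
    if (ncol(tab) < 11L)
      stop_validation("refFlat requires 11 columns, found %d in %s", ncol(tab), path)
    if (!all(tab[[4L]] %in% c("+", "-")))
      stop_validation("unknown strand symbol in %s: %s", path,
                      paste(setdiff(unique(tab[[4L]]), c("+", "-")), collapse = ","))
    exon_starts <- lapply(strsplit(tab[[10L]], ","), as.integer)
    exon_ends <- lapply(strsplit(tab[[11L]], ","), as.integer)
    exons <- IRanges::IRangesList(mapply(function(s, e) IRanges(s + 1L, e),
                                         exon_starts, exon_ends,
                                         SIMPLIFY = FALSE))
    gene_set(tab[[1L]], tab[[3L]], tab[[4L]],
             as.integer(tab[[5L]]), as.integer(tab[[6L]]),
             as.integer(tab[[7L]]), as.integer(tab[[8L]]), exons = exons)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    strand_chr <- as.character(strand(gr))
    if (any(strand_chr == "*"))
      stop_validation("unknown strand symbol in %s: BED12 gene models must be stranded", path)
    blocks <- ranges(gr)  # fallback: whole transcript
    if (!is.null(mcols(gr)$blocks))
      blocks <- IRanges::IRangesList(mapply(function(b, s) shift(b, s - 1L),
                                            mcols(gr)$blocks, start(gr),
                                            SIMPLIFY = FALSE))
    thick <- mcols(gr)$thick
    has_cds <- !is.null(thick) & width(thick) > 0L
    gene_set(mcols(gr)$name, as.character(seqnames(gr)), strand_chr,
             start(gr) - 1L, end(gr),
             ifelse(has_cds, start(thick) - 1L, NA_integer_),
             ifelse(has_cds, end(thick), NA_integer_),
             exons = if (is(blocks, "IRangesList")) blocks else NULL)
  }
}

#' Write gene models as refFlat
#'
#' @param genes a gene `GRanges` from [gene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  exons <- mcols(genes)$exons
  starts <- vapply(exons, function(e) paste0(paste(start(e) - 1L, collapse = ","), ","), "")
  ends <- vapply(exons, function(e) paste0(paste(end(e), collapse = ","), ","), "")
  cds_start <- mcols(genes)$cds_start
  cds_end <- mcols(genes)$cds_end
  # refFlat encodes "no CDS" as cdsStart == cdsEnd == txEnd
  no_cds <- is.na(cds_start)
  df <- data.frame(geneName = mcols(genes)$gene_id,
                   name = mcols(genes)$gene_id,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   txStart = start(genes) - 1L, txEnd = end(genes),
                   cdsStart = ifelse(no_cds, end(genes), cds_start - 1L),
                   cdsEnd = ifelse(no_cds, end(genes), cds_end),
                   exonCount = lengths(exons),
                   exonStarts = starts, exonEnds = ends)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
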