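#' Read a coverage track (bedGraph or fixedStep WIG)
#'
#' The track is stored as a per-chromosome run-length encoded vector
#' (`RleList`); any position not covered by a record has value 0.
#'
#' @param path file path.
#' @param format `"bedgraph"` or `"fixedstep_wig"`.
#' @param seqlengths optional named integer vector of chromosome lengths; the
#'   track is padded with zeros to these lengths.
#' @return a named `RleList` of non-negative coverage values.
#' @export
read_coverage <- function(path, format = c("bedgraph", "fixedstep_wig"),
                          seqlengths = NULL) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = if (format == "bedgraph") "bedGraph" else "wig")
  coverage_from_runs(gr, seqlengths = seqlengths)
}

#' Build a coverage track from scored runs
#'
#' @param gr a `GRanges` with a numeric `score` column; runs within a
#'   chromosome must not overlap.
#' @param seqlengths optional named chromosome lengths used to pad with zeros.
#' @return an `RleList` coverage track.
#' @export
coverage_from_runs <- function(gr, seqlengths = NULL) {
  if (any(mcols(gr)$score < 0))
    stop_validation("coverage values must be non-negative")
  if (!all(IRanges::isDisjoint(GenomicRanges::split(ranges(gr), seqnames(gr)))))
    stop_validation("overlapping coverage records within a chromosome")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), names(seqlengths))
    seqlengths(gr)[names(seqlengths)] <- seqlengths
  }
  coverage(gr, weight = "score")
}

#' Query a coverage track at single positions
#'
#' Total over the genome: positions beyond the stored runs (including
#' chromosomes absent from the track) return 0.
#'
#' @param track an `RleList` from [read_coverage()].
#' @param chrom chromosome name (scalar or vector recycled against `pos`).
#' @param pos 1-based position(s).
#' @return numeric vector of coverage values.
#' @export
coverage_at <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  vapply(seq_len(n), function(i) {
    if (!chrom[i] %in% names(track)) return(0)
    r <- track[[chrom[i]]]
    if (pos[i] < 1L || pos[i] > length(r)) return(0)
    as.numeric(r[pos[i]])
  }, numeric(1))
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted, so re-reading reproduces the track.
#'
#' @param track an `RleList`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  rows <- lapply(names(track), function(chr) {
    r <- track[[chr]]
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)  # 0-based
    keep <- runValue(r) != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chr, start = starts[keep], end = ends[keep],
               value = runValue(r)[keep])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), value = numeric())
  write.table(format(df, scientific = FALSE, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
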