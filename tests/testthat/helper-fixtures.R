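# shared fixture builders; everything is generated in code at test time

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a tab-joined narrowPeak/BED line from space-separated fields
np_line <- function(...) paste(c(...), collapse = "\t")

# tiny refFlat row (0-based half-open, UCSC column order)
refflat_row <- function(gene, chrom, strand, tx_start, tx_end,
                        cds_start = tx_start, cds_end = tx_end,
                        exon_starts = tx_start, exon_ends = tx_end) {
  paste(gene, gene, chrom, strand, tx_start, tx_end, cds_start, cds_end,
        length(exon_starts),
        paste0(paste(exon_starts, collapse = ","), ","),
        paste0(paste(exon_ends, collapse = ","), ","), sep = "\t")
}

# coverage track from parallel vectors of runs (1-based closed intervals)
make_track <- function(chrom, start, end, value, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  GenomicRanges::mcols(gr)$score <- value
  coverage_from_runs(gr, seqlengths = seqlengths)
}

# small expression matrix fixture
make_expr <- function(values, n_control, n_knockdown, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  samples <- c(paste0("c", seq_len(n_control)), paste0("k", seq_len(n_knockdown)))
  dimnames(values) <- list(gene_ids, samples)
  expression_matrix(values, setNames(rep(c("control", "knockdown"),
                                         c(n_control, n_knockdown)), samples))
}

# independent hypergeometric upper-tail oracle by explicit enumeration
hyper_tail_oracle <- function(N, a, b, k) {
  i <- k:min(a, b)
  sum(choose(a, i) * choose(N - a, b - i)) / choose(N, b)
}

# exact one-sided Fisher tail by enumeration over 2x2 tables with fixed margins
fisher_tail_oracle <- function(a, b, c, d) {
  n_fg <- a + b; n_bg <- c + d; hits <- a + c; N <- n_fg + n_bg
  i <- a:min(n_fg, hits)
  sum(choose(hits, i) * choose(N - hits, n_fg - i)) / choose(N, n_fg)
}

# random DNA string
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# overwrite part of a sequence string (plant a motif)
splice_motif <- function(seq, at, motif) {
  substr(seq, at, at + nchar(motif) - 1L) <- motif
  seq
}

rest_consensus <- "TTCAGCACCACGGACAGCGCC"
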