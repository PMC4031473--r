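# brute-force all-pairs oracle for target assignment
brute_force_targets <- function(peaks, genes, window) {
  summit <- S4Vectors::mcols(peaks)$summit
  pchr <- as.character(GenomicRanges::seqnames(peaks))
  tss_pos <- tss(genes)
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gid <- S4Vectors::mcols(genes)$gene_id
  hits <- character(0)
  for (i in seq_along(genes))
    for (j in seq_along(peaks))
      if (gchr[i] == pchr[j] && abs(summit[j] - tss_pos[i]) <= window)
        hits <- c(hits, gid[i])
  sort(unique(hits))
}

test_that("TSS is strand aware", {
  g <- gene_set(c("G1", "G2"), "chr1", c("+", "-"), c(1000L, 1000L),
                c(5000L, 5000L))
  expect_equal(tss(g), c(1001L, 5000L))  # 0-based 1000 and 4999
})

test_that("target assignment respects the window boundary and sign convention", {
  g <- gene_set("G1", "chr1", "+", 10000L, 15000L)  # TSS at 0-based 10,000
  near <- peak_set("chr1", 8050L, 8450L, name = "p", summit = 8250L)
  tm <- assign_targets(near, g, window = 3000)
  expect_equal(tm$gene_id, "G1")
  expect_equal(tm$distance, -1750)

  # strict inclusive boundary: 3,000 in, 3,001 out
  at_edge <- peak_set("chr1", 12800L, 13200L, name = "p", summit = 13000L)
  expect_equal(assign_targets(at_edge, g, 3000)$distance, 3000)
  beyond <- peak_set("chr1", 12801L, 13201L, name = "p", summit = 13001L)
  expect_equal(nrow(assign_targets(beyond, g, 3000)), 0L)

  # minus-strand gene: downstream flips sign
  gm <- gene_set("G2", "chr1", "-", 5000L, 10000L)  # TSS 0-based 9,999
  tm2 <- assign_targets(peak_set("chr1", 8800L, 9200L, summit = 8999L), gm, 3000)
  expect_equal(tm2$distance, 1000)  # 1 kb downstream in gene orientation
})

test_that("toy four-gene example matches the brute-force oracle", {
  g <- gene_set(paste0("G", 1:4), "chr1", "+",
                c(1000L, 10000L, 20000L, 30000L) - 0L,
                c(1000L, 10000L, 20000L, 30000L) + 5000L)
  p <- peak_set("chr1", c(1300L, 21800L, 49800L), c(1700L, 22200L, 50200L),
                summit = c(1500L, 22000L, 50000L))
  tm <- assign_targets(p, g, 3000)
  expect_setequal(target_genes(tm), c("G1", "G3"))
  expect_equal(target_genes(tm), intersect(target_genes(tm),
                                           brute_force_targets(p, g, 3000)))
  expect_length(target_genes(tm), 2L)
})

test_that("no peaks or empty genes behave as specified", {
  g <- gene_set(paste0("G", 1:5), "chr1", "+", (1:5) * 10000L, (1:5) * 10000L + 2000L)
  empty <- peak_set(character(), integer(), integer())
  expect_equal(nrow(assign_targets(empty, g, 3000)), 0L)
  p <- peak_set("chr1", 100L, 200L)
  expect_error(assign_targets(p, GenomicRanges::GRanges(), 3000), "empty")
})

test_that("assignment equals brute force on random fixtures and obeys window monotonicity and translation invariance", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n_g <- 40L; n_p <- 60L
      g <- gene_set(paste0("G", seq_len(n_g)),
                    sample(c("chr1", "chr2"), n_g, TRUE),
                    sample(c("+", "-"), n_g, TRUE),
                    tx_start <- sample.int(2e5, n_g), tx_start + 5000L)
      s <- sample.int(2e5, n_p)
      p <- peak_set(sample(c("chr1", "chr2"), n_p, TRUE), s - 100L, s + 100L,
                    summit = s)
      tm3 <- assign_targets(p, g, 3000)
      expect_equal(sort(target_genes(tm3)), brute_force_targets(p, g, 3000))
      # window monotonicity
      expect_true(all(target_genes(tm3) %in%
                        target_genes(assign_targets(p, g, 10000))))
      # translation invariance
      shift <- 1234L
      g2 <- gene_set(S4Vectors::mcols(g)$gene_id,
                     as.character(GenomicRanges::seqnames(g)),
                     as.character(GenomicRanges::strand(g)),
                     GenomicRanges::start(g) - 1L + shift,
                     GenomicRanges::end(g) + shift)
      p2 <- peak_set(as.character(GenomicRanges::seqnames(p)),
                     GenomicRanges::start(p) - 1L + shift,
                     GenomicRanges::end(p) + shift,
                     summit = S4Vectors::mcols(p)$summit - 1L + shift)
      tm_shift <- assign_targets(p2, g2, 3000)
      expect_equal(tm_shift$gene_id, tm3$gene_id)
      expect_equal(tm_shift$distance, tm3$distance)
    }
  })
})

test_that("multi-transcript genes report the minimal-|distance| transcript", {
  g <- gene_set(c("G1", "G1"), "chr1", "+", c(10000L, 12000L), c(20000L, 20000L))
  p <- peak_set("chr1", 11300L, 11700L, summit = 11500L)
  tm <- assign_targets(p, g, 3000)
  expect_equal(nrow(tm), 1L)
  expect_equal(tm$distance, -500)  # nearer to the 12,000 TSS than the 10,000 one
})

test_that("peak locations are classified with promoter precedence", {
  g <- gene_set("G1", "chr1", "+", 10000L, 30000L, 12000L, 28000L,
                exons = IRanges::IRangesList(IRanges::IRanges(
                  c(10001L, 15001L, 25001L), c(13000L, 16000L, 30000L))))
  pk <- function(s) peak_set("chr1", s - 50L, s + 50L, summit = s)
  frac <- function(fd, cat) fd$fraction[fd$category == cat]
  # summit 500 bp upstream of the TSS -> promoter
  expect_equal(frac(classify_peak_locations(pk(9500L), g, 3000), "promoter"), 1)
  # inside the first intron, > 3 kb from the TSS -> intron
  expect_equal(frac(classify_peak_locations(pk(14000L), g, 3000), "intron"), 1)
  # inside a coding exon beyond the promoter window
  expect_equal(frac(classify_peak_locations(pk(15500L), g, 3000), "coding exon"), 1)
  # 3'UTR: exonic, past cds_end
  expect_equal(frac(classify_peak_locations(pk(29000L), g, 3000), "3'UTR"), 1)
  # chromosome without genes -> intergenic
  lonely <- peak_set("chrM", 100L, 300L)
  expect_equal(frac(classify_peak_locations(lonely, g, 3000), "intergenic"), 1)
})

test_that("feature fractions sum to one and count every peak once", {
  withr::with_seed(5, {
    ds <- generate_synthetic(synthetic_config(n_chroms = 1L, chrom_length = 900000L,
                                              n_genes = 40L, n_peaks = 40L,
                                              seed = 5),
                             sequence = FALSE, coverage = FALSE)
    fd <- classify_peak_locations(ds$peaks$A, ds$genes, 3000)
    expect_equal(sum(fd$count), length(ds$peaks$A))
    expect_equal(sum(fd$fraction), 1, tolerance = 1e-9)
  })
})

test_that("expressed genes are thresholded on the control mean", {
  e <- make_expr(rbind(c(5, 6, 0, 0), c(1, 2, 9, 9)), 2, 2)
  expect_equal(expressed_genes(e, 4), "g1")
  expect_setequal(expressed_genes(e, -Inf), c("g1", "g2"))
  expect_length(expressed_genes(e, 100), 0L)
  g <- gene_set("g1", "chr1", "+", 0L, 10L)
  expect_warning(expressed_genes(e, -Inf, annotation = g), "absent")
})
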