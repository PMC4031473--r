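test_that("summit windows are centred, fixed width and truncated at bounds", {
  p <- peak_set("chr1", 900L, 1100L, summit = 1000L)  # 0-based summit 1,000
  w <- summit_windows(p, 600L)
  expect_equal(GenomicRanges::start(w), 701L)  # 0-based [700, 1300)
  expect_equal(GenomicRanges::end(w), 1300L)
  near_start <- peak_set("chr1", 50L, 150L, summit = 100L)
  wt <- summit_windows(near_start, 600L, seqlengths = c(chr1 = 10000L))
  expect_equal(GenomicRanges::start(wt), 1L)
  expect_equal(GenomicRanges::end(wt), 400L)  # 0-based [0, 400)
  twin <- peak_set("chr1", c(900L, 950L), c(1100L, 1150L), summit = c(1000L, 1000L))
  ww <- summit_windows(twin, 600L)
  expect_equal(GenomicRanges::start(ww), c(701L, 701L))
  expect_error(summit_windows(p, 601L), "even")
})

test_that("log-odds scoring matches hand values and strand symmetry", {
  # 2-position consensus PWM (probability 1, no pseudocount), uniform bg
  m <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 1; m["C", 2] <- 1
  cons <- pwm(m, pseudocount = 0)
  expect_equal(logodds_score("AC", cons, 1, "+"), 4)  # 2 * log2(4)
  expect_equal(cons$max_score, 4)
  # reverse complement of AC is GT: scoring GT on - strand gives the same
  expect_equal(logodds_score("GT", cons, 1, "-"), 4)
  # background-distributed PWM scores 0 everywhere
  flat <- pwm(matrix(0.25, 4, 2), pseudocount = 0)
  expect_equal(logodds_score("GT", flat, 1, "+"), 0)
  expect_equal(logodds_score("AA", flat, 1, "+"), 0)
  # N positions contribute zero
  expect_equal(logodds_score("NC", cons, 1, "+"), 2)
  expect_error(logodds_score("AC", cons, 2, "+"), "out of range")
})

test_that("JASPAR-style matrices load with pseudocount normalization", {
  path <- write_lines_tmp(c(">toy_motif", "A [ 10 0 ]", "C [ 0 10 ]",
                            "G [ 0 0 ]", "T [ 0 0 ]"))
  m <- read_pwm(path, pseudocount = 0.5)
  expect_s3_class(m, "pwm")
  expect_equal(colSums(m$prob), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(m$prob["A", 1]), 10.5 / 12)
  rest <- read_pwm(bundled_pwm_path("rest"))
  expect_equal(ncol(rest$prob), 21L)
  e2f <- read_pwm(bundled_pwm_path("e2f1"))
  expect_equal(ncol(e2f$prob), 8L)
})

test_that("window scanning finds planted sites and respects thresholds", {
  motif <- rest_consensus
  seq1 <- splice_motif(random_dna(400, seed = 61), 150, motif)
  genome <- Biostrings::DNAStringSet(c(chr1 = seq1))
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300))
  names(w) <- "w1"
  m <- read_pwm(bundled_pwm_path("rest"))
  res <- scan_windows(w, genome, m, score_threshold = m$max_score)
  expect_true(res$window_hit[["w1"]])
  expect_true(any(res$hits$offset == 50 & res$hits$strand == "+"))
  # +Inf threshold -> nothing; all-N window -> nothing
  expect_false(any(scan_windows(w, genome, m, Inf)$window_hit))
  gn <- Biostrings::DNAStringSet(c(chr1 = strrep("N", 400)))
  expect_false(any(scan_windows(w, gn, m, 0.8 * m$max_score)$window_hit))
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 500))
  expect_error(scan_windows(wide, genome, m), "beyond")
})

test_that("enrichment is invariant under reverse-complementing the genome", {
  m <- read_pwm(bundled_pwm_path("rest"))
  L <- 2000L
  seq1 <- random_dna(L, seed = 77)
  seq1 <- splice_motif(seq1, 400, rest_consensus)
  seq1 <- splice_motif(seq1, 1200, rest_consensus)
  genome <- Biostrings::DNAStringSet(c(chr1 = seq1))
  starts <- c(301, 701, 1101, 1501)
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 200))
  names(w) <- paste0("w", seq_along(starts))
  fwd <- scan_windows(w, genome, m, 0.8 * m$max_score)
  rc_genome <- Biostrings::DNAStringSet(Biostrings::reverseComplement(genome[[1]]))
  names(rc_genome) <- "chr1"
  w_rc <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(L - (starts + 199) + 1, width = 200))
  names(w_rc) <- names(w)
  rev <- scan_windows(w_rc, rc_genome, m, 0.8 * m$max_score)
  expect_equal(rev$window_hit, fwd$window_hit)
})

test_that("Fisher enrichment matches enumeration and handles edge tables", {
  # 8/10 foreground vs 2/10 background hits
  L <- 12000L
  seq1 <- random_dna(L, seed = 55)
  fg_starts <- seq(101, by = 600, length.out = 10)
  bg_starts <- seq(6101, by = 500, length.out = 10)
  for (s in fg_starts[1:8]) seq1 <- splice_motif(seq1, s + 90, rest_consensus)
  for (s in bg_starts[1:2]) seq1 <- splice_motif(seq1, s + 90, rest_consensus)
  genome <- Biostrings::DNAStringSet(c(chr1 = seq1))
  fg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(fg_starts, width = 200))
  bg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(bg_starts, width = 200))
  m <- read_pwm(bundled_pwm_path("rest"))
  res <- motif_enrichment_test(fg, bg, genome, m)
  expect_equal(res$fg_hits, 8L)
  expect_equal(res$bg_hits, 2L)
  expect_lt(res$p, 0.05)
  expect_equal(res$p, fisher_tail_oracle(8, 2, 2, 8), tolerance = 1e-9)

  # equal rates -> p >= 0.5 (scan the same windows against themselves)
  eq <- motif_enrichment_test(fg, fg, genome, m)
  expect_gte(eq$p, 0.5)

  # zero background hits -> Haldane-corrected finite odds ratio
  clean <- GenomicRanges::GRanges("chr1", IRanges::IRanges(bg_starts[3:6] + 250,
                                                           width = 100))
  res0 <- motif_enrichment_test(fg, clean, genome, m)
  expect_true(is.finite(res0$odds_ratio))
  expect_error(motif_enrichment_test(fg[0], bg, genome, m), "non-empty")
})

test_that("enrichment p equals table enumeration across random margins <= 40", {
  m <- read_pwm(bundled_pwm_path("rest"))
  make_windows <- function(n, n_hit, region_start, seq1) {
    starts <- seq(region_start, by = 400, length.out = n)
    for (s in starts[seq_len(n_hit)])
      seq1 <- splice_motif(seq1, s + 50, rest_consensus)
    list(w = GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 200)),
         seq = seq1)
  }
  withr::with_seed(19, {
    for (i in 1:6) {
      n_fg <- sample(3:15, 1); n_bg <- sample(3:15, 1)
      a <- sample(0:n_fg, 1); c <- sample(0:n_bg, 1)
      seq1 <- random_dna(20000)
      fgw <- make_windows(n_fg, a, 101, seq1)
      bgw <- make_windows(n_bg, c, 10001, fgw$seq)
      genome <- Biostrings::DNAStringSet(c(chr1 = bgw$seq))
      res <- motif_enrichment_test(fgw$w, bgw$w, genome, m)
      expect_equal(res$fg_hits, a)
      expect_equal(res$bg_hits, c)
      expect_equal(res$p, fisher_tail_oracle(a, n_fg - a, c, n_bg - c),
                   tolerance = 1e-9)
    }
  })
})
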