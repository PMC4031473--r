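test_that("narrowPeak fields map to peaks (summit offset, fold enrichment)", {
  path <- write_lines_tmp(np_line("chr1", 100, 200, "p1", 50, ".", 12.5, 30, 25, 40),
                          ".narrowPeak")
  pk <- read_peaks(path, "narrowpeak")
  expect_length(pk, 1L)
  expect_equal(GenomicRanges::start(pk), 101L)   # 0-based 100
  expect_equal(GenomicRanges::end(pk), 200L)
  expect_equal(S4Vectors::mcols(pk)$summit, 141L)  # 0-based 140 = 100 + 40
  expect_equal(S4Vectors::mcols(pk)$fold_enrichment, 12.5)
  expect_equal(S4Vectors::mcols(pk)$name, "p1")
})

test_that("BED6 peaks take the interval midpoint as summit", {
  path <- write_lines_tmp(np_line("chr1", 100, 200, "p1", 0, "."), ".bed")
  pk <- read_peaks(path, "bed6")
  expect_equal(S4Vectors::mcols(pk)$summit, 151L)  # 0-based 150
  expect_equal(S4Vectors::mcols(pk)$fold_enrichment, 0)
})

test_that("peak reading validates input and reports line numbers", {
  expect_length(read_peaks(write_lines_tmp(character(), ".bed"), "bed6"), 0L)
  bad <- write_lines_tmp(c(np_line("chr1", 1, 10, "a", 0, "."),
                           np_line("chr1", 5)), ".bed")
  expect_error(read_peaks(bad, "bed6"), "line 2")
  inverted <- write_lines_tmp(np_line("chr1", 200, 100, "a", 0, "."), ".bed")
  expect_error(read_peaks(inverted, "bed6"), "start >= end")
})

test_that("peak write/read round-trip preserves all semantic fields", {
  pk <- peak_set(c("chr1", "chr2"), c(100L, 5000L), c(600L, 5400L),
                 name = c("a", "b"), score = c(50, 75), strand = c("+", "."),
                 summit = c(180L, 5200L), fold_enrichment = c(12.5, 31.25))
  path <- tempfile(fileext = ".narrowPeak")
  write_peaks(pk, path, "narrowpeak")
  back <- read_peaks(path, "narrowpeak")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(pk))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(pk))
  expect_equal(S4Vectors::mcols(back)$summit, S4Vectors::mcols(pk)$summit)
  expect_equal(S4Vectors::mcols(back)$fold_enrichment,
               S4Vectors::mcols(pk)$fold_enrichment)
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(pk)$name)
})

test_that("peak reading is independent of record order", {
  lines <- c(np_line("chr2", 50, 90, "b", 0, "."),
             np_line("chr1", 10, 30, "a", 0, "."),
             np_line("chr1", 100, 130, "c", 0, "."))
  p1 <- read_peaks(write_lines_tmp(lines, ".bed"), "bed6")
  p2 <- read_peaks(write_lines_tmp(rev(lines), ".bed"), "bed6")
  o1 <- order(S4Vectors::mcols(p1)$name)
  o2 <- order(S4Vectors::mcols(p2)$name)
  expect_equal(GenomicRanges::start(p1)[o1], GenomicRanges::start(p2)[o2])
  expect_equal(S4Vectors::mcols(p1)$summit[o1], S4Vectors::mcols(p2)$summit[o2])
})

test_that("refFlat parsing keeps strand, coordinates and skips headers", {
  path <- write_lines_tmp(c("#geneName\tname\tchrom...",
                            refflat_row("G1", "chr1", "+", 1000, 5000),
                            refflat_row("G2", "chr1", "-", 8000, 9000)))
  g <- read_gene_annotation(path, "refflat")
  expect_length(g, 2L)
  expect_equal(GenomicRanges::start(g)[1L], 1001L)  # 0-based 1000
  expect_equal(GenomicRanges::end(g)[1L], 5000L)
  expect_equal(as.character(GenomicRanges::strand(g)), c("+", "-"))
  bad <- write_lines_tmp(refflat_row("G1", "chr1", "?", 0, 10))
  expect_error(read_gene_annotation(bad, "refflat"), "strand")
})

test_that("BED12 gene models preserve strand, blocks and thick range", {
  line <- np_line("chr1", 1000, 5000, "G1", 0, "-", 1200, 4800, "0",
                  3, "300,400,500", "0,2000,3500")
  g <- read_gene_annotation(write_lines_tmp(line, ".bed"), "bed12")
  expect_equal(as.character(GenomicRanges::strand(g)), "-")
  expect_equal(S4Vectors::mcols(g)$cds_start, 1201L)
  expect_equal(S4Vectors::mcols(g)$cds_end, 4800L)
  exons <- S4Vectors::mcols(g)$exons[[1L]]
  expect_equal(IRanges::start(exons), c(1001L, 3001L, 4501L))
  expect_equal(IRanges::width(exons), c(300L, 400L, 500L))
  unstranded <- np_line("chr1", 0, 10, "G1", 0, ".")
  expect_error(read_gene_annotation(write_lines_tmp(unstranded, ".bed"), "bed12"),
               "strand")
})

test_that("gene annotation round-trips through refFlat", {
  g <- gene_set(c("G1", "G2"), "chr1", c("+", "-"), c(100L, 900L), c(700L, 1500L),
                c(150L, 950L), c(650L, 1450L))
  path <- tempfile()
  write_gene_annotation(g, path)
  back <- read_gene_annotation(path, "refflat")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(g))
  expect_equal(S4Vectors::mcols(back)$cds_start, S4Vectors::mcols(g)$cds_start)
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(g)))
})

test_that("bedGraph coverage is total: covered runs and zero elsewhere", {
  path <- write_lines_tmp(np_line("chr1", 0, 10, 2.0), ".bedGraph")
  track <- read_coverage(path, "bedgraph")
  expect_equal(coverage_at(track, "chr1", 5), 2.0)
  expect_equal(coverage_at(track, "chr1", 15), 0)
  expect_equal(coverage_at(track, "chrX", 5), 0)
})

test_that("coverage validation rejects negatives and overlapping records", {
  neg <- write_lines_tmp(np_line("chr1", 0, 10, -1), ".bedGraph")
  expect_error(read_coverage(neg, "bedgraph"), "non-negative")
  ovl <- write_lines_tmp(c(np_line("chr1", 0, 10, 1), np_line("chr1", 5, 15, 2)),
                         ".bedGraph")
  expect_error(read_coverage(ovl, "bedgraph"), "overlapping")
})

test_that("adjacent equal-value runs and fixedStep WIG query identically", {
  adj <- write_lines_tmp(c(np_line("chr1", 0, 10, 3), np_line("chr1", 10, 20, 3)),
                         ".bedGraph")
  track <- read_coverage(adj, "bedgraph")
  expect_equal(coverage_at(track, "chr1", c(10, 11)), c(3, 3))
  wig <- write_lines_tmp(c("fixedStep chrom=chr2 start=1 step=5 span=5", "1", "2"),
                         ".wig")
  tw <- read_coverage(wig, "fixedstep_wig")
  expect_equal(coverage_at(tw, "chr2", c(3, 8, 11)), c(1, 2, 0))
})

test_that("coverage round-trips through bedGraph", {
  track <- make_track("chr1", c(1, 51), c(20, 60), c(2.5, 7))
  path <- tempfile(fileext = ".bedGraph")
  write_coverage(track, path)
  back <- read_coverage(path, "bedgraph")
  expect_equal(coverage_at(back, "chr1", 1:60), coverage_at(track, "chr1", 1:60))
})

test_that("expression TSV + condition map load into a validated matrix", {
  mat <- write_lines_tmp(c("gene_id\ts1\ts2\ts3\ts4",
                           "g1\t1\t2\t3\t4", "g2\t5\t6\t7\t8", "g3\t1\t1\t2\t2"))
  cmap <- write_lines_tmp(c("s1\tcontrol", "s2\tcontrol",
                            "s3\tknockdown", "s4\tknockdown"))
  e <- read_expression(mat, cmap)
  expect_equal(dim(e$values), c(3L, 4L))
  expect_equal(unname(e$condition),
               c("control", "control", "knockdown", "knockdown"))

  na_mat <- write_lines_tmp(c("gene_id\ts1\ts2\ts3\ts4",
                              "g1\t1\t2\t3\t4", "gNA\t5\tNA\t7\t8"))
  expect_error(read_expression(na_mat, cmap), "gNA")

  bad_map <- write_lines_tmp(c("s1\tcontrol", "s2\tcontrol",
                               "s3\ttreated", "s4\tknockdown"))
  expect_error(read_expression(mat, bad_map), "treated")

  short_map <- write_lines_tmp(c("s1\tcontrol", "s2\tknockdown"))
  expect_error(read_expression(mat, short_map), "missing")
})

test_that("expression matrices round-trip with a YAML condition map", {
  e <- make_expr(matrix(rnorm(12), 3), 2, 2)
  mat <- tempfile(fileext = ".tsv")
  cmap <- tempfile(fileext = ".yaml")
  write_expression(e, mat, cmap)
  back <- read_expression(mat, cmap)
  expect_equal(back$values, e$values, tolerance = 1e-9)
  expect_equal(back$condition, e$condition)
})

test_that("FASTA records are uppercased, name-trimmed and validated", {
  path <- write_lines_tmp(c(">chr1 some description", "acgt", "ACGT"))
  s <- read_fasta(path)
  expect_equal(names(s), "chr1")
  expect_equal(as.character(s[["chr1"]]), "ACGTACGT")
  dup <- write_lines_tmp(c(">chr1", "AC", ">chr1", "GT"))
  expect_error(read_fasta(dup), "duplicate")
  empty <- write_lines_tmp(c(">chr1", "AC", ">chr2"))
  expect_error(read_fasta(empty), "empty")
})
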