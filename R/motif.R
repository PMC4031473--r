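#' Construct a position weight matrix
#'
#' @param counts 4 x L numeric matrix of base counts or probabilities, rows
#'   A, C, G, T.
#' @param name motif name.
#' @param background base composition (length 4, sums to 1); uniform by
#'   default.
#' @param pseudocount added to every cell before column normalization
#'   (default 0.5; use 0 for an exact consensus matrix).
#' @return an object of class `pwm` with elements `name`, `prob` (4 x L
#'   column-stochastic), `background`, `pseudocount`, `log_odds`
#'   (log2(p/bg), bits) and `max_score`.
#' @export
pwm <- function(counts, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.5) {
  if (!is.matrix(counts) || nrow(counts) != 4L)
    stop_validation("'counts' must be a 4 x L matrix (rows A, C, G, T)")
  if (abs(sum(background) - 1) > 1e-9)
    stop_validation("'background' must sum to 1")
  prob <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  rownames(prob) <- c("A", "C", "G", "T")
  lo <- log2(prob / background)
  structure(list(name = name, prob = prob, background = background,
                 pseudocount = pseudocount, log_odds = lo,
                 max_score = sum(apply(lo, 2L, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, max score %.2f bits, consensus %s\n",
              x$name, ncol(x$prob), x$max_score,
              paste(rownames(x$prob)[apply(x$prob, 2L, which.max)], collapse = "")))
  invisible(x)
}

#' Read a JASPAR-style count matrix
#'
#' Expects a `>` header line (id and optional name) followed by four rows
#' `A [ n1 n2 ... ]` (brackets optional) in A, C, G, T order.
#'
#' @param path file path.
#' @param background,pseudocount passed to [pwm()].
#' @return a `pwm` object.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 0.5) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!startsWith(lines[1L], ">"))
    stop_validation("JASPAR matrix must start with a '>' header: %s", path)
  name <- sub("^>\\s*", "", lines[1L])
  rows <- lapply(lines[2:5], function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(l, "\\s+")[[1L]]
    as.numeric(parts[-1L])
  })
  base_order <- toupper(substr(lines[2:5], 1L, 1L))
  if (!identical(sort(base_order), c("A", "C", "G", "T")))
    stop_validation("JASPAR matrix rows must be labelled A, C, G, T: %s", path)
  counts <- do.call(rbind, rows)[match(c("A", "C", "G", "T"), base_order), ]
  pwm(counts, name = name, background = background, pseudocount = pseudocount)
}

#' Summit-centred windows around peaks
#'
#' Each window spans `width` bp centred on the peak summit (peaks are
#' trimmed or extended to the common width), truncated at chromosome bounds
#' when lengths are known.
#'
#' @param peaks a peak `GRanges`.
#' @param width window width in bp (even, > 0); default 600.
#' @param seqlengths optional named chromosome lengths for truncation.
#' @return a `GRanges` of windows named after the peaks.
#' @export
summit_windows <- function(peaks, width = 600L, seqlengths = NULL) {
  if (width <= 0 || width %% 2 != 0)
    stop_validation("'width' must be a positive even number of bp")
  s <- mcols(peaks)$summit
  start <- pmax(s - width %/% 2L, 1L)
  end <- s + width %/% 2L - 1L
  chr <- as.character(seqnames(peaks))
  if (!is.null(seqlengths))
    end <- pmin(end, seqlengths[chr])
  gr <- GRanges(chr, IRanges(start, end))
  names(gr) <- mcols(peaks)$name
  gr
}

#' Random background windows
#'
#' Same-width windows placed uniformly on the given chromosomes (the
#' "random located peaks" control for motif enrichment), reproducible for a
#' fixed seed.
#'
#' @param n number of windows.
#' @param width window width in bp.
#' @param seqlengths named chromosome lengths.
#' @param seed integer seed.
#' @return a `GRanges` of `n` windows named `bg_1..bg_n`.
#' @export
sample_background_windows <- function(n, width, seqlengths, seed) {
  withr::with_seed(seed, {
    chr <- sample(names(seqlengths), n, replace = TRUE,
                  prob = seqlengths / sum(seqlengths))
    start <- vapply(chr, function(c)
      sample.int(seqlengths[[c]] - width + 1L, 1L), integer(1))
    gr <- GRanges(chr, IRanges(start, width = width))
    names(gr) <- paste0("bg_", seq_len(n))
    gr
  })
}

seq_to_codes <- function(s) {
  match(strsplit(as.character(s), "")[[1L]], c("A", "C", "G", "T"))
}

score_codes <- function(codes, lo, offset) {
  L <- ncol(lo)
  idx <- codes[offset:(offset + L - 1L)]
  sum(lo[cbind(idx, seq_len(L))[!is.na(idx), , drop = FALSE]])
}

#' PWM log-odds score at a window offset
#'
#' `sum_j log2(p_j(base) / bg(base))` in bits; positions with an `N` (or any
#' non-ACGT base) contribute 0. On the `-` strand the reverse complement of
#' the motif-length stretch starting at `offset` is scored.
#'
#' @param window_seq character or `DNAString` window sequence.
#' @param pwm a `pwm` object.
#' @param offset 1-based start of the scored stretch within the window.
#' @param strand `"+"` or `"-"`.
#' @return log-odds score in bits.
#' @export
logodds_score <- function(window_seq, pwm, offset, strand = "+") {
  codes <- seq_to_codes(window_seq)
  L <- ncol(pwm$log_odds)
  if (offset < 1L || offset + L - 1L > length(codes))
    stop_validation("offset %d out of range for a %d-bp window and %d-bp motif",
                    offset, length(codes), L)
  stretch <- codes[offset:(offset + L - 1L)]
  if (strand == "-") stretch <- rev(5L - stretch)  # reverse complement codes
  keep <- !is.na(stretch)
  sum(pwm$log_odds[cbind(stretch[keep], seq_len(L)[keep])])
}

#' Scan windows for PWM hits
#'
#' Scores every offset of every window on both strands and flags windows
#' containing at least one hit at or above the threshold.
#'
#' @param windows a `GRanges` of windows (names used as window ids).
#' @param genome a named `DNAStringSet` covering all window chromosomes.
#' @param pwm a `pwm` object.
#' @param score_threshold hit threshold in bits; default 80% of the PWM's
#'   maximum achievable score.
#' @return list with `hits` (data.frame `window_id`, `offset`, `strand`,
#'   `score`) and `window_hit` (named logical per window).
#' @export
scan_windows <- function(windows, genome, pwm,
                         score_threshold = 0.8 * pwm$max_score) {
  chrs <- as.character(seqnames(windows))
  missing <- setdiff(unique(chrs), names(genome))
  if (length(missing))
    stop_validation("genome lacks chromosome(s): %s", paste(missing, collapse = ", "))
  ids <- if (is.null(names(windows))) as.character(seq_along(windows)) else names(windows)
  L <- ncol(pwm$log_odds)
  hit_rows <- list()
  window_hit <- setNames(logical(length(windows)), ids)
  for (i in seq_along(windows)) {
    if (end(windows)[i] > length(genome[[chrs[i]]]))
      stop_validation("window %s extends beyond chromosome %s", ids[i], chrs[i])
    s <- Biostrings::subseq(genome[[chrs[i]]], start(windows)[i], end(windows)[i])
    codes <- seq_to_codes(s)
    W <- length(codes)
    if (W < L) next
    for (o in seq_len(W - L + 1L)) {
      fwd <- score_codes(codes, pwm$log_odds, o)
      stretch <- codes[o:(o + L - 1L)]
      rc <- rev(5L - stretch)
      keep <- !is.na(rc)
      rev_score <- sum(pwm$log_odds[cbind(rc[keep], seq_len(L)[keep])])
      for (sc in list(c(score = fwd, strand = 1), c(score = rev_score, strand = 2))) {
        if (sc[["score"]] >= score_threshold) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            window_id = ids[i], offset = o,
            strand = c("+", "-")[sc[["strand"]]], score = sc[["score"]])
          window_hit[ids[i]] <- TRUE
        }
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(window_id = character(), offset = integer(),
               strand = character(), score = numeric())
  list(hits = hits, window_hit = window_hit)
}

#' Motif enrichment of foreground vs background windows
#'
#' Builds the 2x2 table of windows with/without a PWM hit in the foreground
#' and background sets and tests foreground enrichment with a one-sided
#' Fisher exact test. The odds ratio uses the Haldane correction (+0.5 per
#' cell) when any cell is zero.
#'
#' @param fg_windows,bg_windows window `GRanges` (non-empty).
#' @param genome a named `DNAStringSet`.
#' @param pwm a `pwm` object.
#' @param score_threshold hit threshold in bits (default 80% of maximum).
#' @return list of class `motif_enrichment`: `n_fg`, `n_bg`, `fg_hits`,
#'   `bg_hits`, `odds_ratio`, `p`.
#' @export
motif_enrichment_test <- function(fg_windows, bg_windows, genome, pwm,
                                  score_threshold = 0.8 * pwm$max_score) {
  if (length(fg_windows) == 0L || length(bg_windows) == 0L)
    stop_validation("both window sets must be non-empty")
  fg <- scan_windows(fg_windows, genome, pwm, score_threshold)
  bg <- scan_windows(bg_windows, genome, pwm, score_threshold)
  a <- sum(fg$window_hit); b <- length(fg$window_hit) - a
  c <- sum(bg$window_hit); d <- length(bg$window_hit) - c
  tab <- matrix(c(a, b, c, d), 2L,
                dimnames = list(hit = c("yes", "no"), set = c("fg", "bg")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  or <- if (any(tab == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  structure(list(n_fg = a + b, n_bg = c + d, fg_hits = a, bg_hits = c,
                 odds_ratio = or, p = p, table = tab,
                 score_threshold = score_threshold),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("motif_enrichment: %d/%d fg vs %d/%d bg windows hit; OR = %.2f, one-sided Fisher p = %.3g\n",
              x$fg_hits, x$n_fg, x$bg_hits, x$n_bg, x$odds_ratio, x$p))
  invisible(x)
}

#' Bundled consensus-derived PWMs
#'
#' Returns the path to one of the consensus-derived matrices shipped with
#' the package (synthetic matrices built from the published consensus
#' sequences, in JASPAR-style text): `"rest"` (the 21-bp NRSE element
#' recognized by REST/NRSF) or `"e2f1"` (the 8-bp E2F consensus).
#'
#' @param motif `"rest"` or `"e2f1"`.
#' @return file path.
#' @export
bundled_pwm_path <- function(motif = c("rest", "e2f1")) {
  motif <- match.arg(motif)
  system.file("extdata",
              paste0(motif, "_consensus_synthetic.jaspar"),
              package = "chipcoop", mustWork = TRUE)
}
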