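#' Filter peaks by fold enrichment
#'
#' Keeps peaks whose fold enrichment strictly exceeds `min_fold` (the
#' conventional "fold change greater than N" filter), preserving order.
#'
#' @param peaks a peak `GRanges`.
#' @param min_fold minimum fold enrichment (exclusive).
#' @return the filtered `GRanges`.
#' @export
filter_by_fold <- function(peaks, min_fold) {
  assert_scalar_number(min_fold, "min_fold")
  peaks[mcols(peaks)$fold_enrichment > min_fold]
}

#' Pairs of overlapping peaks between two sets
#'
#' @param peaks_a,peaks_b peak `GRanges`.
#' @param min_bp minimum overlap length in bp (>= 1).
#' @return a `data.frame` with columns `index_a`, `index_b`, one row per
#'   overlapping pair (same chromosome, overlap >= `min_bp`).
#' @export
interval_overlaps <- function(peaks_a, peaks_b, min_bp = 1L) {
  if (min_bp < 1L) stop_validation("'min_bp' must be >= 1")
  # disjoint seqlevel sets are an expected no-overlap case, not a warning
  hits <- suppressWarnings(findOverlaps(peaks_a, peaks_b, minoverlap = min_bp,
                                        ignore.strand = TRUE))
  data.frame(index_a = queryHits(hits), index_b = subjectHits(hits))
}

#' Partition peaks into solo and ensemble groups
#'
#' A peak of the primary factor is "ensemble" when it overlaps (>= `min_bp`
#' bp) at least one peak of the partner factor, "solo" otherwise. The two
#' groups are disjoint and exhaustive.
#'
#' @param peaks_a primary-factor peak `GRanges`.
#' @param peaks_b partner-factor peak `GRanges`.
#' @param partner label for the partner factor, kept in the result.
#' @param min_bp minimum overlap in bp.
#' @return a list of class `peak_partition` with elements `ensemble`, `solo`
#'   (both `GRanges`) and `partner`.
#' @export
partition_solo_ensemble <- function(peaks_a, peaks_b, partner = "partner",
                                    min_bp = 1L) {
  ov <- interval_overlaps(peaks_a, peaks_b, min_bp = min_bp)
  is_ens <- seq_along(peaks_a) %in% ov$index_a
  out <- structure(list(ensemble = peaks_a[is_ens], solo = peaks_a[!is_ens],
                        partner = partner),
                   class = "peak_partition")
  stopifnot(length(out$ensemble) + length(out$solo) == length(peaks_a))
  out
}

#' @export
print.peak_partition <- function(x, ...) {
  cat(sprintf("peak_partition vs %s: %d ensemble, %d solo\n",
              x$partner, length(x$ensemble), length(x$solo)))
  invisible(x)
}

#' Randomly sample peaks without replacement
#'
#' Used to size-match a solo set to an ensemble set before profile
#' comparison. Reproducible for a fixed seed; the global RNG state is left
#' untouched.
#'
#' @param peaks a peak `GRanges`.
#' @param n sample size (must not exceed the number of peaks).
#' @param seed integer seed.
#' @return a `GRanges` of `n` sampled peaks.
#' @export
sample_peaks <- function(peaks, n, seed) {
  if (n > length(peaks))
    stop_validation("cannot sample %d peaks from %d", n, length(peaks))
  idx <- withr::with_seed(seed, sample.int(length(peaks), n))
  peaks[idx]
}

#' Hypergeometric significance of a target-set overlap
#'
#' Upper-tail hypergeometric probability of observing at least the measured
#' overlap between two gene sets drawn from a common universe (the observed
#' overlap is included in the tail).
#'
#' @param set_a,set_b character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector, the gene universe.
#' @return a list of class `overlap_result` with `n_a`, `n_b`, `n_universe`,
#'   `overlap` and `p`.
#' @export
target_overlap_significance <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop_validation("gene sets must be subsets of the universe")
  n <- length(universe)
  a <- length(set_a); b <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1L, a, n - a, b, lower.tail = FALSE)
  structure(list(n_a = a, n_b = b, n_universe = n, overlap = k,
                 p = min(max(p, 0), 1)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of |A|=%d, |B|=%d, N=%d: hypergeometric p = %.3g\n",
              x$overlap, x$n_a, x$n_b, x$n_universe, x$p))
  invisible(x)
}

#' Venn region counts for two or three gene sets
#'
#' @param sets a named list of 2 or 3 character vectors.
#' @return named integer vector of disjoint region counts; names are
#'   combinations of set names joined by `&`. Counts sum to the size of the
#'   union.
#' @export
venn_counts <- function(sets) {
  if (!length(sets) %in% c(2L, 3L))
    stop_validation("venn_counts takes 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 0L)
    member <- matrix(logical(), 0L, length(sets), dimnames = list(NULL, names(sets)))
  n <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  counts <- apply(combos, 1L, function(cmb) {
    sum(apply(member, 1L, function(row) all(row == cmb)))
  })
  names(counts) <- apply(combos, 1L, function(cmb)
    paste(names(sets)[as.logical(cmb)], collapse = "&"))
  counts
}
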