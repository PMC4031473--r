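#' Anchor-centred signal profile matrix
#'
#' Bins the coverage around each anchor (a TSS or a peak summit) into
#' `nbins` equal-width bins spanning `[-halfwindow, +halfwindow)` and
#' records the mean coverage per bin. Anchors on the `-` strand have their
#' bins reversed so that bin order always reads 5' to 3' in anchor
#' orientation. Windows truncated at chromosome ends take signal 0 outside
#' the track (coverage is total: every position has exactly one value).
#'
#' @param track an `RleList` coverage track.
#' @param anchors a `data.frame` with columns `id`, `chrom`, `pos` (1-based
#'   anchor position) and optionally `strand` (`+`, `-`; default `+`).
#' @param halfwindow half-width of the window in bp.
#' @param nbins number of bins; `2 * halfwindow` must be divisible by it.
#' @return a numeric matrix (anchors x bins) of class `profile_matrix`,
#'   rownames = anchor ids, with attributes `bin_offsets` (bp offset of each
#'   bin start relative to the anchor) and `bin_width`.
#' @export
profile_matrix <- function(track, anchors, halfwindow, nbins) {
  if (!is.numeric(nbins) || nbins <= 0)
    stop_validation("'nbins' must be a positive integer")
  assert_scalar_number(halfwindow, "halfwindow", positive = TRUE)
  if ((2 * halfwindow) %% nbins != 0)
    stop_validation("2*halfwindow (%d) must be divisible by nbins (%d)",
                    2 * halfwindow, nbins)
  if (is.null(anchors$strand)) anchors$strand <- "+"
  w <- as.integer(2 * halfwindow / nbins)
  m <- matrix(0, nrow(anchors), nbins,
              dimnames = list(as.character(anchors$id), NULL))
  for (i in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[i]
    s <- anchors$pos[i] - halfwindow
    vals <- numeric(2 * halfwindow)
    if (chr %in% names(track)) {
      r <- track[[chr]]
      s2 <- max(s, 1L); e2 <- min(s + 2 * halfwindow - 1L, length(r))
      if (s2 <= e2)
        vals[(s2 - s + 1L):(e2 - s + 1L)] <- as.numeric(r[s2:e2])
    }
    bins <- colMeans(matrix(vals, nrow = w))
    if (anchors$strand[i] == "-") bins <- rev(bins)
    m[i, ] <- bins
  }
  structure(m, bin_offsets = seq(-halfwindow, halfwindow - w, by = w),
            bin_width = w, class = c("profile_matrix", class(m)))
}

#' Average signal profile over anchors
#'
#' @param matrix a `profile_matrix`.
#' @return numeric vector of per-bin means (length = number of bins).
#' @export
average_profile <- function(matrix) {
  if (nrow(matrix) == 0L)
    stop_validation("cannot average an empty profile matrix")
  colMeans(matrix)
}

#' Order anchors by central signal
#'
#' The conventional heatmap row order: anchors sorted by decreasing mean
#' signal in the central `2 * center_halfwidth_bins` bins, ties broken by
#' anchor id (lexicographic).
#'
#' @param matrix a `profile_matrix`.
#' @param center_halfwidth_bins number of bins on each side of the window
#'   centre to average; at most `nbins / 2`.
#' @return character vector: the anchor ids in display order.
#' @export
order_anchors_by_signal <- function(matrix, center_halfwidth_bins) {
  nb <- ncol(matrix)
  if (center_halfwidth_bins > nb / 2)
    stop_validation("'center_halfwidth_bins' exceeds half the bin count")
  centre <- (nb / 2 - center_halfwidth_bins + 1):(nb / 2 + center_halfwidth_bins)
  key <- rowMeans(matrix[, centre, drop = FALSE])
  ids <- rownames(matrix)
  ids[order(-key, ids)]
}

#' Sliding-window average smoother
#'
#' "Valid"-mode moving average: element `i` of the output is the mean of
#' `values[i .. i + window - 1]`; the output has `length(values) - window +
#' 1` elements when `step = 1`. A `step > 1` moves the window by that many
#' positions between outputs.
#'
#' @param values numeric vector.
#' @param window window length (>= 1 and <= `length(values)`).
#' @param step stride between successive windows (default 1).
#' @return numeric vector of window means.
#' @export
sliding_window_smooth <- function(values, window, step = 1L) {
  n <- length(values)
  if (window < 1L || window != round(window))
    stop_validation("'window' must be a positive integer")
  if (window > n)
    stop_validation("window (%d) exceeds sequence length (%d)", window, n)
  cs <- c(0, cumsum(values))
  starts <- seq.int(1L, n - window + 1L, by = step)
  (cs[starts + window] - cs[starts]) / window
}
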