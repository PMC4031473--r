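#' Background-correct intensities ("half" rule)
#'
#' Subtracts the background and floors the result at 0.5 so all corrected
#' intensities stay positive (the standard "half" background-correction rule
#' for two-channel/one-channel array intensities; delegated to limma).
#'
#' @param signal,background numeric matrices of identical shape; background
#'   must be non-negative.
#' @return corrected matrix, elementwise `max(signal - background, 0.5)`.
#' @export
background_correct_half <- function(signal, background) {
  if (!identical(dim(signal), dim(background)))
    stop_validation("signal and background matrices must have the same shape")
  if (any(background < 0))
    stop_validation("background intensities must be non-negative")
  out <- limma::backgroundCorrect.matrix(signal, background, method = "half",
                                         verbose = FALSE)
  dimnames(out) <- dimnames(signal)
  out
}

#' Quantile normalization between arrays
#'
#' Forces every column (array) to share a common value distribution: the
#' sorted values of each column are replaced by the row means of the
#' column-wise sorted matrix, ties receiving the mean of the quantile values
#' they span (limma's quantile method).
#'
#' @param x numeric matrix with >= 2 columns and no missing values.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2L)
    stop_validation("quantile normalization needs at least 2 columns")
  if (anyNA(x))
    stop_validation("missing values are not allowed in quantile normalization")
  if (nrow(x) == 1L) {
    out <- matrix(mean(x), 1L, ncol(x))  # single quantile: the row mean
  } else {
    out <- limma::normalizeQuantiles(x, ties = TRUE)
  }
  dimnames(out) <- dimnames(x)
  out
}

# vectorized pooled-variance Student t over matrix rows
row_t_test <- function(values, condition) {
  ctrl <- values[, condition == "control", drop = FALSE]
  kd <- values[, condition == "knockdown", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(kd)
  if (n1 < 2L || n2 < 2L)
    stop_validation("each condition needs >= 2 samples (found %d control, %d knockdown)",
                    n1, n2)
  m1 <- rowMeans(ctrl); m2 <- rowMeans(kd)
  ss1 <- rowSums((ctrl - m1)^2); ss2 <- rowSums((kd - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  # degenerate rows: zero pooled variance
  degen <- se == 0
  t[degen] <- ifelse(m1[degen] == m2[degen], 0, sign(m1 - m2)[degen] * Inf)
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  data.frame(gene_id = rownames(values), mean_control = m1,
             mean_knockdown = m2, delta = m2 - m1, t_stat = t, p = p,
             row.names = NULL)
}

#' Two-sample Student t-test for one gene
#'
#' Pooled-variance two-sided t-test of control vs knockdown samples
#' (`n1 + n2 - 2` degrees of freedom). The statistic is
#' `(mean_control - mean_knockdown) / se`; a constant gene (zero pooled
#' variance, equal means) yields `t = 0, p = 1`.
#'
#' @param expr an [expression_matrix()].
#' @param gene_id row to test.
#' @return list with `t` and `p`.
#' @export
gene_t_test <- function(expr, gene_id) {
  if (!gene_id %in% rownames(expr$values))
    stop_validation("gene '%s' not in the expression matrix", gene_id)
  res <- row_t_test(expr$values[gene_id, , drop = FALSE], expr$condition)
  list(t = res$t_stat, p = res$p)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up by default (`min_{j >= i} m p_(j) / j`,
#' clipped at 1, returned in input order); Bonferroni available.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop_validation("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = method)
}

#' Collapse probe-level values to gene level
#'
#' @param values numeric matrix with probe rownames.
#' @param probe_map named character vector mapping probe id to gene id;
#'   probes without a mapping are dropped.
#' @return matrix with one row per gene: the per-column median over its
#'   probes.
#' @export
collapse_probes <- function(values, probe_map) {
  keep <- rownames(values) %in% names(probe_map)
  values <- values[keep, , drop = FALSE]
  genes <- probe_map[rownames(values)]
  out <- t(vapply(split(seq_len(nrow(values)), genes), function(idx)
    apply(values[idx, , drop = FALSE], 2L, stats::median),
    numeric(ncol(values))))
  colnames(out) <- colnames(values)
  out
}

#' Knockdown differential expression
#'
#' Per-gene pooled-variance Student t-tests of knockdown vs control with
#' multiple-testing adjustment and direction calls. Input values are assumed
#' already preprocessed (background-corrected / normalized / log scale);
#' see [background_correct_half()], [quantile_normalize()] and
#' [collapse_probes()] for those stages.
#'
#' @param expr an [expression_matrix()].
#' @param alpha significance threshold on the adjusted p (default 0.001).
#' @param adjust multiple-testing method passed to [bh_adjust()].
#' @return a `data.frame` of class `de_result`: one row per gene with
#'   `gene_id`, `mean_control`, `mean_knockdown`, `delta`
#'   (knockdown - control), `t_stat`, `p`, `p_adj` and `direction`
#'   (`decreased` / `increased` / `ns`).
#' @export
run_differential_expression <- function(expr, alpha = 0.001,
                                        adjust = c("BH", "bonferroni")) {
  if (alpha <= 0 || alpha >= 1) stop_validation("'alpha' must be in (0, 1)")
  res <- row_t_test(expr$values, expr$condition)
  res$p_adj <- bh_adjust(res$p, method = match.arg(adjust))
  res$direction <- ifelse(res$p_adj < alpha & res$delta < 0, "decreased",
                          ifelse(res$p_adj < alpha & res$delta > 0,
                                 "increased", "ns"))
  structure(res, class = c("de_result", "data.frame"), alpha = alpha)
}

#' Split differential-expression results into direction sets
#'
#' @param results a `de_result` from [run_differential_expression()].
#' @param alpha threshold on the adjusted p.
#' @return list with character vectors `decreased` (adjusted p < alpha and
#'   delta < 0, i.e. lower after knockdown) and `increased`; always
#'   disjoint.
#' @export
de_sets <- function(results, alpha) {
  if (alpha <= 0 || alpha >= 1) stop_validation("'alpha' must be in (0, 1)")
  sig <- results$p_adj < alpha
  list(decreased = results$gene_id[sig & results$delta < 0],
       increased = results$gene_id[sig & results$delta > 0])
}
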