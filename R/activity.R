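#' Nearest peak-summit distance per gene
#'
#' For every gene the minimum over same-chromosome peaks of the absolute
#' distance between its TSS and a peak summit (over all transcripts of the
#' gene). Genes with no peak on their chromosome get `Inf`.
#'
#' @param genes a gene `GRanges`.
#' @param peaks a peak `GRanges`.
#' @return named numeric vector: gene id -> distance in bp (or `Inf`); every
#'   gene of the annotation appears exactly once.
#' @export
nearest_peak_distance <- function(genes, peaks) {
  gene_ids <- unique(mcols(genes)$gene_id)
  out <- setNames(rep(Inf, length(gene_ids)), gene_ids)
  if (length(peaks) == 0L || length(genes) == 0L) return(out)
  by_chr <- split(mcols(peaks)$summit, as.character(seqnames(peaks)))
  tss_pos <- tss(genes)
  chr <- as.character(seqnames(genes))
  d_tx <- vapply(seq_along(genes), function(i) {
    s <- by_chr[[chr[i]]]
    if (is.null(s)) Inf else min(abs(s - tss_pos[i]))
  }, numeric(1))
  d_gene <- tapply(d_tx, mcols(genes)$gene_id, min)
  out[names(d_gene)] <- as.numeric(d_gene)
  out
}

#' Empirical CDF of a distance set
#'
#' Built on the finite distances only; the number of `Inf` sentinels (genes
#' with no peak on their chromosome) is reported in attribute `n_infinite`
#' rather than imputed.
#'
#' @param distances non-negative numeric vector, possibly containing `Inf`.
#' @return a step function `F(x) = #(finite values <= x) / n_finite` with
#'   attributes `n_finite` and `n_infinite`.
#' @export
distance_ecdf <- function(distances) {
  finite <- distances[is.finite(distances)]
  if (length(finite) == 0L)
    stop_validation("no finite distances: cannot build an ECDF")
  if (any(finite < 0)) stop_validation("distances must be non-negative")
  f <- stats::ecdf(finite)
  attr(f, "n_finite") <- length(finite)
  attr(f, "n_infinite") <- sum(!is.finite(distances))
  f
}

# sup_x [F_x(x) - F_y(x)] over the pooled sample points (both ECDFs are
# right-continuous step functions, so the supremum is attained there)
dplus_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  fx <- findInterval(v, sort(x)) / length(x)
  fy <- findInterval(v, sort(y)) / length(y)
  max(0, fx - fy)
}

#' One-sided Kolmogorov-Smirnov comparison of TSS-distance distributions
#'
#' Tests whether a gene set's peak-to-TSS distances are stochastically
#' *smaller* (the set lies closer to the factor's binding sites) than a
#' background set's. The statistic is `D+ = sup_x [F_set(x) - F_bg(x)]` and
#' the asymptotic p-value `exp(-2 n_eff D+^2)` with
#' `n_eff = m n / (m + n)`, clipped to `[0, 1]`. A permutation p-value
#' (label reshuffling) is computed when `n_permutations > 0`.
#'
#' Infinite distances are excluded (and counted) before testing.
#'
#' @param set_distances distances of the gene set under test.
#' @param background_distances distances of the background genes.
#' @param set_label label stored in the result.
#' @param claim_threshold p below which the set is claimed
#'   `closer_than_background`.
#' @param n_permutations if > 0, also estimate the p-value from this many
#'   label permutations.
#' @param seed seed for the permutation null.
#' @return a list of class `activity_call`: `set_label`, `n_set`,
#'   `n_background`, `n_infinite_dropped`, `D_plus`, `p`, `p_permutation`
#'   (or `NA`), `direction_claim`.
#' @export
ks_one_sided <- function(set_distances, background_distances,
                         set_label = "custom", claim_threshold = 0.05,
                         n_permutations = 0L, seed = 1L) {
  n_inf <- sum(!is.finite(set_distances)) + sum(!is.finite(background_distances))
  x <- set_distances[is.finite(set_distances)]
  y <- background_distances[is.finite(background_distances)]
  if (length(x) == 0L || length(y) == 0L)
    stop_validation("both samples need at least one finite distance")
  D <- dplus_statistic(x, y)
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- min(1, max(0, exp(-2 * n_eff * D^2)))
  p_perm <- NA_real_
  if (n_permutations > 0L) {
    pooled <- c(x, y)
    m <- length(x)
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_permutations), function(b) {
        idx <- sample.int(length(pooled), m)
        dplus_statistic(pooled[idx], pooled[-idx]) >= D
      }, logical(1)))
    })
    p_perm <- (1 + exceed) / (n_permutations + 1)
  }
  structure(list(set_label = set_label, n_set = length(x),
                 n_background = length(y), n_infinite_dropped = n_inf,
                 D_plus = D, p = p, p_permutation = p_perm,
                 direction_claim = if (p < claim_threshold)
                   "closer_than_background" else "not_closer"),
            class = "activity_call")
}

#' @export
print.activity_call <- function(x, ...) {
  cat(sprintf("activity_call [%s]: n=%d vs background n=%d, D+ = %.4f, p = %.3g (%s)\n",
              x$set_label, x$n_set, x$n_background, x$D_plus, x$p,
              x$direction_claim))
  invisible(x)
}

#' Regulatory-potential score per gene
#'
#' Aggregates a factor's peaks around each gene's TSS with a weight that
#' decays exponentially in distance: `RP = sum_i exp(-(0.5 + 4 d_i /
#' decay_distance))` over peaks with `d_i <= horizon`. Strictly decreasing
#' in each peak's distance, additive over peaks, and 0 iff no peak lies
#' within the horizon.
#'
#' @param genes a gene `GRanges`.
#' @param peaks a peak `GRanges`.
#' @param decay_distance decay scale in bp (default 100000).
#' @param horizon maximum distance considered, bp (default 100000).
#' @return named numeric vector gene id -> RP score.
#' @export
regulatory_potential <- function(genes, peaks, decay_distance = 1e5,
                                 horizon = 1e5) {
  assert_scalar_number(decay_distance, "decay_distance", positive = TRUE)
  gene_ids <- unique(mcols(genes)$gene_id)
  out <- setNames(numeric(length(gene_ids)), gene_ids)
  if (length(peaks) == 0L) return(out)
  by_chr <- split(mcols(peaks)$summit, as.character(seqnames(peaks)))
  tss_pos <- tss(genes)
  chr <- as.character(seqnames(genes))
  rp_tx <- vapply(seq_along(genes), function(i) {
    s <- by_chr[[chr[i]]]
    if (is.null(s)) return(0)
    d <- abs(s - tss_pos[i])
    d <- d[d <= horizon]
    sum(exp(-(0.5 + 4 * d / decay_distance)))
  }, numeric(1))
  rp_gene <- tapply(rp_tx, mcols(genes)$gene_id, max)
  out[names(rp_gene)] <- as.numeric(rp_gene)
  out
}

#' Select top regulated targets by DE significance and regulatory potential
#'
#' Within each response direction, genes are ranked by the product of their
#' DE-significance rank (ascending adjusted p) and their RP rank (descending
#' score); the `n` smallest rank products are returned. Genes that decreased
#' after knockdown are the factor's candidate *activated* ("active")
#' targets; genes that increased are candidate *repressed* ("repressive")
#' targets.
#'
#' @param de_results a `de_result` from [run_differential_expression()].
#' @param rp_scores named numeric vector from [regulatory_potential()].
#' @param n number of genes per direction.
#' @return list with `active`, `repressive` (character vectors, each of
#'   length `min(n, available)`) and `shortfall` (named integer vector of
#'   how many genes were missing per direction).
#' @export
select_top_regulated <- function(de_results, rp_scores, n) {
  if (n < 1L) stop_validation("'n' must be >= 1")
  pick <- function(delta_sign) {
    sub <- de_results[sign(de_results$delta) == delta_sign, , drop = FALSE]
    sub <- sub[order(sub$gene_id), , drop = FALSE]  # input-order invariance
    if (nrow(sub) == 0L) return(character())
    rp <- rp_scores[sub$gene_id]
    rp[is.na(rp)] <- 0
    r_de <- rank(sub$p_adj, ties.method = "min")
    r_rp <- rank(-rp, ties.method = "min")
    score <- r_de * r_rp
    sub$gene_id[order(score, sub$gene_id)][seq_len(min(n, nrow(sub)))]
  }
  active <- pick(-1)
  repressive <- pick(+1)
  list(active = active, repressive = repressive,
       shortfall = c(active = n - length(active),
                     repressive = n - length(repressive)))
}

#' Activator/repressor evidence for a factor
#'
#' Runs the one-sided KS distance test for the decreased-after-knockdown and
#' increased-after-knockdown gene sets against background genes. Evidence
#' that the decreased set sits closer to the factor's peaks than background
#' supports an activator role; the increased set, a repressor role. Both can
#' hold. An empty (or all-`Inf`) gene set yields no evidence for that role.
#'
#' @param de_direction_sets list with `decreased` and `increased` gene-id
#'   vectors (see [de_sets()]).
#' @param distances named distance vector from [nearest_peak_distance()].
#' @param background_genes gene ids of the background universe (typically
#'   the expressed genes not in either DE set).
#' @param threshold KS p-value below which evidence is called (default 0.05).
#' @return a list of class `factor_direction_call` with logical
#'   `activator_evidence`, `repressor_evidence` and the two `activity_call`
#'   objects (`NULL` where the set was empty).
#' @export
call_factor_direction <- function(de_direction_sets, distances,
                                  background_genes, threshold = 0.05) {
  bg <- distances[intersect(background_genes, names(distances))]
  run_set <- function(ids, label) {
    d <- distances[intersect(ids, names(distances))]
    if (sum(is.finite(d)) == 0L || sum(is.finite(bg)) == 0L) return(NULL)
    ks_one_sided(d, bg, set_label = label, claim_threshold = threshold)
  }
  ks_dec <- run_set(de_direction_sets$decreased, "decreased_after_kd")
  ks_inc <- run_set(de_direction_sets$increased, "increased_after_kd")
  structure(list(
    activator_evidence = !is.null(ks_dec) && ks_dec$p < threshold,
    repressor_evidence = !is.null(ks_inc) && ks_inc$p < threshold,
    ks_decreased = ks_dec, ks_increased = ks_inc,
    threshold = threshold), class = "factor_direction_call")
}

#' @export
print.factor_direction_call <- function(x, ...) {
  cat(sprintf("factor_direction_call: activator evidence = %s, repressor evidence = %s (KS p threshold %g)\n",
              x$activator_evidence, x$repressor_evidence, x$threshold))
  invisible(x)
}
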