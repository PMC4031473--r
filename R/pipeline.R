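#' Pipeline configuration
#'
#' All thresholds of the analysis in one object. Defaults are the
#' full-scale constants of the workflow: a 3 kb TSS window for target
#' assignment, fold-enrichment filter > 10, 6 kb profile window in 120
#' bins, 600 bp motif windows, adjusted-p threshold 0.001 for differential
#' expression, expression smoothing window 100, top 1000 regulated targets
#' per direction and a 100 kb regulatory-potential decay/horizon.
#'
#' @param tss_window TSS window half-width, bp.
#' @param fold_threshold fold-enrichment filter (exclusive).
#' @param heatmap_halfwindow profile half-window, bp.
#' @param profile_bins number of profile bins.
#' @param motif_window motif window width, bp.
#' @param de_alpha adjusted-p threshold for differential expression.
#' @param direction_alpha KS p threshold for activator/repressor evidence.
#' @param smooth_window expression smoothing window (genes).
#' @param top_n regulated targets selected per direction.
#' @param rp_decay_distance regulatory-potential decay scale, bp.
#' @param rp_horizon regulatory-potential horizon, bp.
#' @param expression_threshold mean-control threshold for "expressed".
#' @param rng_seed seed for the pipeline's random choices (solo peak
#'   sampling, background windows).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(tss_window = 3000, fold_threshold = 10,
                            heatmap_halfwindow = 3000, profile_bins = 120,
                            motif_window = 600, de_alpha = 0.001,
                            direction_alpha = 0.05, smooth_window = 100,
                            top_n = 1000, rp_decay_distance = 1e5,
                            rp_horizon = 1e5, expression_threshold = 6,
                            rng_seed = 1L) {
  cfg <- list(tss_window = tss_window, fold_threshold = fold_threshold,
              heatmap_halfwindow = heatmap_halfwindow,
              profile_bins = profile_bins, motif_window = motif_window,
              de_alpha = de_alpha, direction_alpha = direction_alpha,
              smooth_window = smooth_window, top_n = top_n,
              rp_decay_distance = rp_decay_distance, rp_horizon = rp_horizon,
              expression_threshold = expression_threshold,
              rng_seed = as.integer(rng_seed))
  for (f in c("tss_window", "heatmap_halfwindow", "profile_bins",
              "motif_window", "smooth_window", "top_n", "rp_decay_distance"))
    if (cfg[[f]] <= 0)
      stop_validation("'%s' must be positive", f)
  if (cfg$de_alpha <= 0 || cfg$de_alpha >= 1)
    stop_validation("'de_alpha' must be in (0, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full co-occupancy / knockdown-response pipeline
#'
#' Executes the stages in dependency order: peak filtering, target
#' assignment and feature classification, target-set overlap (Venn +
#' hypergeometric), solo/ensemble partition with matched solo sampling,
#' signal profiles, differential expression, activator/repressor inference,
#' regulatory-potential ranking, and (when a genome is supplied) motif
#' enrichment in ensemble summit windows against seeded random windows.
#'
#' @param inputs a named list of file paths: `peaks` (named character
#'   vector, first element the knocked-down primary factor), `genes`
#'   (refFlat), `expression`, `conditions`, and optionally `coverage`
#'   (named, matching `peaks`), `genome` (FASTA) and `pwm` (JASPAR text;
#'   defaults to the bundled REST consensus matrix).
#' @param config a [pipeline_config()].
#' @return a list of class `run_report` with per-stage results and a
#'   `stats` element collecting the headline numbers.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  required <- c("peaks", "genes", "expression", "conditions")
  for (r in required)
    if (is.null(inputs[[r]]))
      stop_validation("missing input '%s'", r)
  paths <- c(inputs$peaks, inputs$genes, inputs$expression, inputs$conditions,
             inputs$coverage, inputs$genome, inputs$pwm)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_validation("input file(s) not found: %s", paste(missing, collapse = ", "))

  factors <- names(inputs$peaks)
  if (is.null(factors)) factors <- LETTERS[seq_along(inputs$peaks)]
  primary <- factors[1L]

  genes <- read_gene_annotation(inputs$genes, format = "refflat")
  peaks <- lapply(inputs$peaks, read_peaks, format = "narrowpeak")
  names(peaks) <- factors
  expr <- read_expression(inputs$expression, inputs$conditions)

  # stage: fold filtering + target assignment
  peaks_f <- lapply(peaks, filter_by_fold, min_fold = config$fold_threshold)
  targets <- lapply(peaks_f, assign_targets, genes = genes,
                    window = config$tss_window)
  target_sets <- lapply(targets, target_genes)
  features <- classify_peak_locations(peaks_f[[primary]], genes,
                                      promoter_window = config$tss_window)
  expressed <- expressed_genes(expr, config$expression_threshold)

  # stage: co-occupancy
  universe <- unique(mcols(genes)$gene_id)
  overlap <- if (length(target_sets) >= 2L)
    target_overlap_significance(target_sets[[1L]], target_sets[[2L]], universe)
  venn <- if (length(target_sets) >= 2L)
    venn_counts(target_sets[seq_len(min(3L, length(target_sets)))])
  partition <- if (length(peaks_f) >= 2L)
    partition_solo_ensemble(peaks_f[[1L]], peaks_f[[2L]],
                            partner = factors[2L])
  solo_matched <- if (!is.null(partition) &&
                      length(partition$ensemble) > 0L &&
                      length(partition$solo) >= length(partition$ensemble))
    sample_peaks(partition$solo, length(partition$ensemble),
                 seed = config$rng_seed)

  # stage: signal profiles (primary factor around its expressed targets)
  profiles <- NULL
  if (!is.null(inputs$coverage)) {
    track <- read_coverage(inputs$coverage[[1L]], format = "bedgraph")
    tgt <- intersect(target_sets[[primary]], expressed)
    idx <- match(tgt, mcols(genes)$gene_id)
    anchors <- data.frame(id = tgt, chrom = as.character(seqnames(genes))[idx],
                          pos = tss(genes)[idx],
                          strand = as.character(strand(genes))[idx])
    pm <- profile_matrix(track, anchors, config$heatmap_halfwindow,
                         config$profile_bins)
    ord <- order_anchors_by_signal(pm, center_halfwidth_bins =
                                     max(1L, round(500 / attr(pm, "bin_width"))))
    expr_ctrl <- rowMeans(expr$values[, expr$condition == "control",
                                      drop = FALSE])
    ordered_expr <- expr_ctrl[ord]
    smooth <- if (length(ordered_expr) >= config$smooth_window)
      sliding_window_smooth(ordered_expr, config$smooth_window)
    prof_ens <- prof_solo <- NULL
    if (!is.null(partition) && length(partition$ensemble) > 0L &&
        !is.null(solo_matched)) {
      mk_anchor <- function(p) data.frame(
        id = mcols(p)$name, chrom = as.character(seqnames(p)),
        pos = mcols(p)$summit, strand = "+")
      prof_ens <- average_profile(profile_matrix(track, mk_anchor(partition$ensemble),
                                                 config$heatmap_halfwindow,
                                                 config$profile_bins))
      prof_solo <- average_profile(profile_matrix(track, mk_anchor(solo_matched),
                                                  config$heatmap_halfwindow,
                                                  config$profile_bins))
    }
    profiles <- list(matrix = pm, order = ord, smoothed_expression = smooth,
                     ensemble_mean = prof_ens, solo_mean = prof_solo)
  }

  # stage: differential expression
  de <- run_differential_expression(expr, alpha = config$de_alpha)
  sets <- de_sets(de, config$de_alpha)

  # stage: activator/repressor inference
  distances <- nearest_peak_distance(genes, peaks_f[[primary]])
  background <- setdiff(expressed, c(sets$decreased, sets$increased))
  direction <- call_factor_direction(sets, distances, background,
                                     threshold = config$direction_alpha)
  rp <- regulatory_potential(genes, peaks_f[[primary]],
                             decay_distance = config$rp_decay_distance,
                             horizon = config$rp_horizon)
  top <- select_top_regulated(de, rp, n = config$top_n)

  # stage: motif enrichment (ensemble summit windows vs random windows)
  motif <- NULL
  if (!is.null(inputs$genome) && !is.null(partition) &&
      length(partition$ensemble) > 0L) {
    genome <- read_fasta(inputs$genome)
    sl <- setNames(lengths(genome), names(genome))
    pwm_path <- if (!is.null(inputs$pwm)) inputs$pwm else bundled_pwm_path("rest")
    mot <- read_pwm(pwm_path)
    fg <- summit_windows(partition$ensemble, width = config$motif_window,
                         seqlengths = sl)
    bg <- sample_background_windows(length(fg), config$motif_window, sl,
                                    seed = config$rng_seed)
    motif <- motif_enrichment_test(fg, bg, genome, mot)
  }

  stats <- list(
    n_genes = length(universe),
    n_peaks = setNames(lapply(peaks, length), factors),
    n_peaks_filtered = setNames(lapply(peaks_f, length), factors),
    n_targets = setNames(lapply(target_sets, length), factors),
    n_expressed = length(expressed),
    n_expressed_primary_targets = length(intersect(target_sets[[primary]],
                                                   expressed)),
    overlap_p = if (!is.null(overlap)) overlap$p,
    venn = venn,
    n_ensemble = if (!is.null(partition)) length(partition$ensemble),
    n_solo = if (!is.null(partition)) length(partition$solo),
    n_decreased = length(sets$decreased),
    n_increased = length(sets$increased),
    ks_decreased_p = if (!is.null(direction$ks_decreased)) direction$ks_decreased$p,
    ks_increased_p = if (!is.null(direction$ks_increased)) direction$ks_increased$p,
    activator_evidence = direction$activator_evidence,
    repressor_evidence = direction$repressor_evidence,
    motif_p = if (!is.null(motif)) motif$p,
    motif_odds_ratio = if (!is.null(motif)) motif$odds_ratio)

  structure(list(config = config, factors = factors, targets = targets,
                 features = features, expressed = expressed,
                 overlap = overlap, venn = venn, partition = partition,
                 solo_matched = solo_matched, profiles = profiles, de = de,
                 de_direction_sets = sets, distances = distances,
                 direction = direction, regulatory_potential = rp,
                 top_regulated = top, motif = motif, stats = stats),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$stats
  cat("run_report\n")
  cat(sprintf("  genes: %d; expressed: %d\n", s$n_genes, s$n_expressed))
  for (f in x$factors)
    cat(sprintf("  factor %s: %d peaks (%d after fold filter), %d target genes\n",
                f, s$n_peaks[[f]], s$n_peaks_filtered[[f]], s$n_targets[[f]]))
  if (!is.null(s$overlap_p))
    cat(sprintf("  target overlap %s vs %s: hypergeometric p = %.3g\n",
                x$factors[1], x$factors[2], s$overlap_p))
  if (!is.null(s$n_ensemble))
    cat(sprintf("  partition: %d ensemble / %d solo\n", s$n_ensemble, s$n_solo))
  cat(sprintf("  DE: %d decreased, %d increased (alpha %g)\n",
              s$n_decreased, s$n_increased, x$config$de_alpha))
  if (!is.null(s$ks_decreased_p))
    cat(sprintf("  KS decreased-set p = %.3g\n", s$ks_decreased_p))
  if (!is.null(s$ks_increased_p))
    cat(sprintf("  KS increased-set p = %.3g\n", s$ks_increased_p))
  cat(sprintf("  activator evidence: %s; repressor evidence: %s\n",
              s$activator_evidence, s$repressor_evidence))
  if (!is.null(s$motif_p))
    cat(sprintf("  motif enrichment: OR = %.2f, p = %.3g\n",
                s$motif_odds_ratio, s$motif_p))
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' @param report a `run_report`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report$stats, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
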