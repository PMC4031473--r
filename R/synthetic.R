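#' Configuration for the synthetic-data generator
#'
#' Defaults describe the desk-scale study the package is validated on:
#' a 2 x 5 Mb toy genome, 500 genes, three factors with 300 peaks each
#' (factor A is the knocked-down primary factor, B its co-binding partner,
#' C an independent promoter-enriched factor), a controlled co-binding
#' fraction, and a 4 + 4 sample knockdown expression matrix in which A-bound
#' genes respond with an effect decaying exponentially in peak-to-TSS
#' distance. All fractions are exact (`round(fraction * n)` items), so the
#' planted structure is controlled rather than merely expected.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_genes total number of genes.
#' @param n_peaks peaks per factor.
#' @param cobinding_fraction fraction of factor-A peaks co-located with a
#'   factor-B peak (summit jitter +/- 100 bp).
#' @param promoter_binding_fraction fraction of each factor's peaks placed
#'   with summit within +/- 3 kb of a TSS.
#' @param activator_effect log2 expression decrease after knockdown at
#'   distance 0 for genes the factor activates.
#' @param repressor_effect log2 increase at distance 0 for genes it
#'   represses (0 for an activator-only factor).
#' @param activated_fraction fraction of A-bound genes assigned the
#'   activated role; the remainder get the repressed role.
#' @param effect_decay_bp exponential decay scale of the effect in bp.
#' @param expression_noise_sd per-sample iid Gaussian noise sd (log2 scale).
#' @param motif_plant_rate_fg,motif_plant_rate_bg fraction of ensemble-peak
#'   windows / background windows carrying a planted REST consensus.
#' @param n_control,n_knockdown samples per condition.
#' @param peak_width peak interval width in bp.
#' @param kernel_halfwidth half-width of the triangular coverage kernel, bp.
#' @param seed integer seed driving all randomness.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 2L, chrom_length = 5e6L,
                             n_genes = 500L, n_peaks = 300L,
                             cobinding_fraction = 0.3,
                             promoter_binding_fraction = 0.6,
                             activator_effect = 2.0, repressor_effect = 2.0,
                             activated_fraction = 0.5,
                             effect_decay_bp = 2000,
                             expression_noise_sd = 0.5,
                             motif_plant_rate_fg = 0.8,
                             motif_plant_rate_bg = 0.1,
                             n_control = 4L, n_knockdown = 4L,
                             peak_width = 400L, kernel_halfwidth = 300L,
                             seed = 1L) {
  cfg <- list(n_chroms = n_chroms, chrom_length = as.integer(chrom_length),
              n_genes = n_genes, n_peaks = n_peaks,
              cobinding_fraction = cobinding_fraction,
              promoter_binding_fraction = promoter_binding_fraction,
              activator_effect = activator_effect,
              repressor_effect = repressor_effect,
              activated_fraction = activated_fraction,
              effect_decay_bp = effect_decay_bp,
              expression_noise_sd = expression_noise_sd,
              motif_plant_rate_fg = motif_plant_rate_fg,
              motif_plant_rate_bg = motif_plant_rate_bg,
              n_control = n_control, n_knockdown = n_knockdown,
              peak_width = as.integer(peak_width),
              kernel_halfwidth = as.integer(kernel_halfwidth),
              seed = as.integer(seed))
  fracs <- c("cobinding_fraction", "promoter_binding_fraction",
             "activated_fraction", "motif_plant_rate_fg", "motif_plant_rate_bg")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_validation("'%s' must lie in [0, 1]", f)
  if (cfg$expression_noise_sd < 0)
    stop_validation("'expression_noise_sd' must be >= 0")
  structure(cfg, class = "synthetic_config")
}

# genes on an even grid with jitter; spacing >= 10 kb guaranteed
place_genes <- function(cfg) {
  margin <- 50000L
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1L)))
  rows <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    span <- cfg$chrom_length - 2L * margin
    slot <- span %/% k
    max_len <- 8000L
    if (slot < max_len + 10000L)
      stop_validation("genome capacity exceeded: %d genes do not fit chromosome %d at 10 kb spacing",
                      k, ci)
    len <- sample(2000:max_len, k, replace = TRUE)
    jitter <- vapply(slot - len - 10000L, function(m) sample.int(m + 1L, 1L) - 1L,
                     integer(1))
    tx_start <- margin + (seq_len(k) - 1L) * slot + jitter
    rows[[ci]] <- data.frame(chrom = paste0("chr", ci), tx_start = tx_start,
                             tx_end = tx_start + len,
                             strand = sample(c("+", "-"), k, replace = TRUE))
  }
  genes <- do.call(rbind, rows)
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes
}

# three exons with an intron between each; CDS from mid-exon1 to mid-exon3
gene_structures <- function(genes) {
  n <- nrow(genes)
  len <- genes$tx_end - genes$tx_start
  b <- vapply(len, function(l) round(l * c(.2, .15, .3, .15)), numeric(4))
  e1_end <- genes$tx_start + b[1, ]
  e2_start <- e1_end + b[2, ]
  e2_end <- e2_start + b[3, ]
  e3_start <- e2_end + b[4, ]
  exons <- IRanges::IRangesList(lapply(seq_len(n), function(i)
    IRanges(c(genes$tx_start[i], e2_start[i], e3_start[i]) + 1L,
            c(e1_end[i], e2_end[i], genes$tx_end[i]))))
  list(exons = exons,
       cds_start = genes$tx_start + round(b[1, ] / 2),
       cds_end = e3_start + round((genes$tx_end - e3_start) / 2))
}

make_factor_peaks <- function(prefix, cfg, genes, tss_pos,
                              avoid_summits = NULL) {
  n_prom <- round(cfg$promoter_binding_fraction * cfg$n_peaks)
  n_inter <- cfg$n_peaks - n_prom
  if (nrow(genes) < n_prom)
    stop_validation("genome capacity exceeded: %d promoter peaks requested, %d genes",
                    n_prom, nrow(genes))
  bound_idx <- sample.int(nrow(genes), n_prom)
  draw_d <- function() pmax(pmin(round(rnorm(n_prom, 0, 1200)), 2999L), -2999L)
  d_raw <- draw_d()
  prom_summit <- tss_pos[bound_idx] + d_raw
  if (!is.null(avoid_summits)) {
    # keep >= 1 kb from the avoided factor's summits so the only physical
    # overlaps between the two factors are the planted co-bound pairs
    for (guard in 1:100) {
      clash <- vapply(seq_len(n_prom), function(i) {
        av <- avoid_summits[[genes$chrom[bound_idx[i]]]]
        !is.null(av) && any(abs(prom_summit[i] - av) <= 1000L)
      }, logical(1))
      if (!any(clash)) break
      redraw <- draw_d()
      d_raw[clash] <- redraw[clash]
      prom_summit <- tss_pos[bound_idx] + d_raw
      if (guard == 100L)
        stop_validation("genome capacity exceeded: cannot place promoter peaks clear of the avoided factor")
    }
  }
  chroms <- sort(unique(genes$chrom))
  n_i_per <- diff(round(seq(0, n_inter, length.out = length(chroms) + 1L)))
  rows <- lapply(seq_along(chroms), function(ci) {
    chr <- chroms[ci]
    on_chr <- which(genes$chrom == chr)
    forb_tss <- tss_pos[on_chr]
    forb_avoid <- avoid_summits[[chr]]
    # spacing from the factor's own peaks keeps planted overlaps the only ones
    self <- prom_summit[genes$chrom[bound_idx] == chr]
    n_i <- n_i_per[ci]
    pos <- integer(0)
    guard <- 0L
    while (length(pos) < n_i) {
      guard <- guard + 1L
      if (guard > 200L)
        stop_validation("genome capacity exceeded: cannot place %d intergenic peaks", n_i)
      p <- sample.int(cfg$chrom_length - 100000L, n_i - length(pos)) + 50000L
      for (x in p) {
        if (all(abs(x - forb_tss) > 4000L) &&
            (is.null(forb_avoid) || all(abs(x - forb_avoid) > 1500L)) &&
            (length(self) == 0L || all(abs(x - self) > 1000L))) {
          pos <- c(pos, x)
          self <- c(self, x)
        }
      }
    }
    data.frame(chrom = rep(chr, length(pos)), summit = pos)
  })
  inter <- do.call(rbind, rows)
  df <- rbind(data.frame(chrom = genes$chrom[bound_idx], summit = prom_summit,
                         gene_idx = bound_idx, planted_distance = abs(d_raw)),
              data.frame(chrom = inter$chrom, summit = inter$summit,
                         gene_idx = rep(NA_integer_, nrow(inter)),
                         planted_distance = rep(NA_real_, nrow(inter))))
  df$name <- sprintf("%s_%04d", prefix, seq_len(nrow(df)))
  df$fold <- exp(rnorm(nrow(df), log(20), 0.4))
  df
}

peaks_df_to_granges <- function(df, cfg) {
  hw <- cfg$peak_width %/% 2L
  s0 <- df$summit - 1L  # generator coordinates are 1-based; peak_set takes 0-based
  peak_set(df$chrom, s0 - hw, s0 + hw, name = df$name,
           score = round(df$fold * 10), strand = ".",
           summit = s0, fold_enrichment = df$fold)
}

triangular_coverage <- function(df, cfg) {
  hw <- cfg$kernel_halfwidth
  kern_off <- seq(-(hw - 1L), hw - 1L)
  kern_w <- 1 - abs(kern_off) / hw
  tracks <- lapply(sort(unique(df$chrom)), function(chr) {
    v <- numeric(cfg$chrom_length)
    sub <- df[df$chrom == chr, ]
    for (i in seq_len(nrow(sub))) {
      idx <- sub$summit[i] + kern_off
      v[idx] <- v[idx] + sub$fold[i] * kern_w
    }
    Rle(v)
  })
  names(tracks) <- sort(unique(df$chrom))
  methods::as(tracks, "SimpleRleList")
}

random_chrom_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

plant_motif <- function(seqs, chrom, pos, motif) {
  for (i in seq_along(chrom)) {
    s <- seqs[[chrom[i]]]
    substr(s, pos[i], pos[i] + nchar(motif) - 1L) <- motif
    seqs[[chrom[i]]] <- s
  }
  seqs
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Builds a toy genome, gene annotation, three factors' peak sets with a
#' controlled co-binding fraction, triangular-kernel coverage tracks,
#' a knockdown expression matrix with planted distance-decaying effects,
#' and (optionally) genome sequence with REST-consensus motifs planted
#' under ensemble peaks. All randomness derives from `config$seed`;
#' the same seed reproduces the dataset (and its files) exactly.
#'
#' @param config a [synthetic_config()].
#' @param outdir if non-`NULL`, write all files (FASTA, refFlat, narrowPeak
#'   per factor, bedGraph per factor, expression TSV, condition-map YAML,
#'   ground-truth JSON) into this directory.
#' @param sequence generate genome sequence and plant motifs (needed for
#'   motif enrichment; skipping it makes replicate studies much faster).
#' @param coverage generate coverage tracks.
#' @return a list of class `synthetic_dataset`: `config`, `seqlengths`,
#'   `genes` (GRanges), `peaks` (list `A`, `B`, `C`), `coverage` (list of
#'   `RleList` or `NULL`), `genome` (`DNAStringSet` or `NULL`), `expr`
#'   ([expression_matrix()]), `bg_windows` (background windows used for
#'   motif planting, or `NULL`) and `truth` (per-gene and per-peak ground
#'   truth data frames).
#' @export
generate_synthetic <- function(config = synthetic_config(), outdir = NULL,
                               sequence = TRUE, coverage = TRUE) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    genes_df <- place_genes(cfg)
    struct <- gene_structures(genes_df)
    tss_pos <- ifelse(genes_df$strand == "+", genes_df$tx_start + 1L,
                      genes_df$tx_end)
    genes <- gene_set(genes_df$gene_id, genes_df$chrom, genes_df$strand,
                      genes_df$tx_start, genes_df$tx_end,
                      struct$cds_start, struct$cds_end, exons = struct$exons)

    # factor A (primary, knocked down)
    a_df <- make_factor_peaks("peakA", cfg, genes_df, tss_pos)

    # factor B: an exact fraction of A's peaks co-located, rest independent
    n_cob <- round(cfg$cobinding_fraction * nrow(a_df))
    cob_idx <- sort(sample.int(nrow(a_df), n_cob))
    b_cob <- data.frame(chrom = a_df$chrom[cob_idx],
                        summit = a_df$summit[cob_idx] +
                          sample(-100:100, n_cob, replace = TRUE),
                        gene_idx = a_df$gene_idx[cob_idx],
                        planted_distance = NA_real_)
    avoid <- split(a_df$summit, a_df$chrom)
    cfg_b <- cfg
    cfg_b$n_peaks <- cfg$n_peaks - n_cob
    b_rest <- make_factor_peaks("tmp", cfg_b, genes_df, tss_pos,
                                avoid_summits = avoid)
    b_df <- rbind(b_cob[c("chrom", "summit", "gene_idx", "planted_distance")],
                  b_rest[c("chrom", "summit", "gene_idx", "planted_distance")])
    b_df$name <- sprintf("peakB_%04d", seq_len(nrow(b_df)))
    b_df$fold <- exp(rnorm(nrow(b_df), log(20), 0.4))

    # factor C: independent promoter-enriched factor
    c_df <- make_factor_peaks("peakC", cfg, genes_df, tss_pos)

    peaks <- list(A = peaks_df_to_granges(a_df, cfg),
                  B = peaks_df_to_granges(b_df, cfg),
                  C = peaks_df_to_granges(c_df, cfg))

    # planted expression effects on A-bound genes
    bound_a <- !is.na(a_df$gene_idx)
    bound_gene_idx <- a_df$gene_idx[bound_a]
    bound_dist <- a_df$planted_distance[bound_a]
    role <- rep("unbound", nrow(genes_df))
    delta <- numeric(nrow(genes_df))
    n_act <- round(cfg$activated_fraction * length(bound_gene_idx))
    act_pick <- seq_along(bound_gene_idx) <= n_act
    decay <- exp(-bound_dist / cfg$effect_decay_bp)
    role[bound_gene_idx[act_pick]] <- "activated"
    delta[bound_gene_idx[act_pick]] <- -cfg$activator_effect * decay[act_pick]
    role[bound_gene_idx[!act_pick]] <- "repressed"
    delta[bound_gene_idx[!act_pick]] <- cfg$repressor_effect * decay[!act_pick]

    mu <- rnorm(nrow(genes_df), 8, 1)
    n_s <- cfg$n_control + cfg$n_knockdown
    sample_ids <- c(sprintf("ctrl_%d", seq_len(cfg$n_control)),
                    sprintf("kd_%d", seq_len(cfg$n_knockdown)))
    cond <- setNames(rep(c("control", "knockdown"),
                         c(cfg$n_control, cfg$n_knockdown)), sample_ids)
    means <- outer(mu, rep(1, n_s)) +
      outer(delta, c(rep(0, cfg$n_control), rep(1, cfg$n_knockdown)))
    values <- means + matrix(rnorm(nrow(genes_df) * n_s, 0, cfg$expression_noise_sd),
                             nrow(genes_df))
    dimnames(values) <- list(genes_df$gene_id, sample_ids)
    expr <- expression_matrix(values, cond)

    cov <- NULL
    if (coverage)
      cov <- list(A = triangular_coverage(a_df, cfg),
                  B = triangular_coverage(b_df, cfg),
                  C = triangular_coverage(c_df, cfg))

    is_ensemble <- seq_len(nrow(a_df)) %in% cob_idx
    genome <- NULL
    bg_windows <- NULL
    motif_flag <- rep(NA, nrow(a_df))
    bg_flag <- logical(0)
    if (sequence) {
      seqs <- setNames(lapply(seq_len(cfg$n_chroms),
                              function(i) random_chrom_seq(cfg$chrom_length)),
                       paste0("chr", seq_len(cfg$n_chroms)))
      consensus <- "TTCAGCACCACGGACAGCGCC"
      ens_idx <- which(is_ensemble)
      n_fg <- round(cfg$motif_plant_rate_fg * length(ens_idx))
      fg_pick <- if (length(ens_idx)) sort(sample(ens_idx, n_fg)) else integer(0)
      motif_flag <- seq_len(nrow(a_df)) %in% fg_pick
      motif_flag[!is_ensemble] <- NA
      if (length(fg_pick))
        seqs <- plant_motif(seqs, a_df$chrom[fg_pick],
                            a_df$summit[fg_pick] - 10L, consensus)
      sl <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                     paste0("chr", seq_len(cfg$n_chroms)))
      n_bgw <- max(length(ens_idx), 1L)
      bg_windows <- sample_background_windows(n_bgw, 600L, sl,
                                              seed = sample.int(1e6, 1L))
      n_bg <- round(cfg$motif_plant_rate_bg * n_bgw)
      bg_flag <- seq_len(n_bgw) %in% sample.int(n_bgw, n_bg)
      if (any(bg_flag))
        seqs <- plant_motif(seqs, as.character(seqnames(bg_windows))[bg_flag],
                            start(bg_windows)[bg_flag] + 290L, consensus)
      genome <- DNAStringSet(unlist(seqs))
    }

    truth_genes <- data.frame(
      gene_id = genes_df$gene_id,
      bound_A = seq_len(nrow(genes_df)) %in% bound_gene_idx,
      planted_distance = NA_real_, role = role, planted_delta = delta)
    truth_genes$planted_distance[bound_gene_idx] <- bound_dist
    truth_peaks_a <- data.frame(name = a_df$name, is_ensemble = is_ensemble,
                                has_planted_motif = motif_flag)

    out <- structure(list(
      config = cfg,
      seqlengths = setNames(rep(cfg$chrom_length, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms))),
      genes = genes, peaks = peaks, coverage = cov, genome = genome,
      expr = expr, bg_windows = bg_windows,
      truth = list(genes = truth_genes, peaks_A = truth_peaks_a,
                   bg_window_planted = bg_flag)),
      class = "synthetic_dataset")
  })
  if (!is.null(outdir)) write_synthetic(out, outdir)
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d chroms x %d bp, %d genes, %d peaks/factor, seed %d\n",
              x$config$n_chroms, x$config$chrom_length,
              length(unique(mcols(x$genes)$gene_id)),
              length(x$peaks$A), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: `genome.fa`,
#' `genes.refflat`, `peaks_<F>.narrowPeak` and `coverage_<F>.bedGraph` per
#' factor, `expression.tsv`, `conditions.yaml` and `truth.json`.
#'
#' @param dataset a `synthetic_dataset`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  if (!is.null(dataset$genome)) write_fasta(dataset$genome, p("genome.fa"))
  write_gene_annotation(dataset$genes, p("genes.refflat"))
  for (f in names(dataset$peaks))
    write_peaks(dataset$peaks[[f]], p(sprintf("peaks_%s.narrowPeak", f)))
  if (!is.null(dataset$coverage))
    for (f in names(dataset$coverage))
      write_coverage(dataset$coverage[[f]], p(sprintf("coverage_%s.bedGraph", f)))
  write_expression(dataset$expr, p("expression.tsv"), p("conditions.yaml"))
  jsonlite::write_json(dataset$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

#' Recovery metrics of pipeline outputs against the planted truth
#'
#' @param dataset a `synthetic_dataset`.
#' @param target_map optional `target_map` of factor A (see
#'   [assign_targets()]).
#' @param partition optional `peak_partition` of factor A vs B.
#' @param direction_call optional `factor_direction_call`.
#' @param window TSS window used for target calls, bp.
#' @return list of confusion-matrix metrics per supplied stage:
#'   `target_sensitivity`, `target_specificity`, `ensemble_accuracy`,
#'   `activator_correct`, `repressor_correct` (entries `NULL` when the
#'   corresponding output was not supplied).
#' @export
truth_report <- function(dataset, target_map = NULL, partition = NULL,
                         direction_call = NULL, window = 3000) {
  tg <- dataset$truth$genes
  out <- list()
  if (!is.null(target_map)) {
    called <- tg$gene_id %in% target_genes(target_map)
    truly <- tg$bound_A & !is.na(tg$planted_distance) &
      tg$planted_distance <= window
    out$target_sensitivity <- if (any(truly)) mean(called[truly]) else NA_real_
    out$target_specificity <- if (any(!tg$bound_A)) mean(!called[!tg$bound_A]) else NA_real_
  }
  if (!is.null(partition)) {
    tp <- dataset$truth$peaks_A
    part_names <- c(mcols(partition$ensemble)$name, mcols(partition$solo)$name)
    if (!all(part_names %in% tp$name))
      stop_validation("partition peak names do not match the dataset")
    # scored over the peaks the partition saw (e.g. after fold filtering)
    tp <- tp[tp$name %in% part_names, , drop = FALSE]
    called_ens <- tp$name %in% mcols(partition$ensemble)$name
    out$ensemble_accuracy <- mean(called_ens == tp$is_ensemble)
  }
  if (!is.null(direction_call)) {
    planted_act <- any(tg$role == "activated" & tg$planted_delta < 0)
    planted_rep <- any(tg$role == "repressed" & tg$planted_delta > 0)
    out$activator_correct <- direction_call$activator_evidence == planted_act
    out$repressor_correct <- direction_call$repressor_evidence == planted_rep
  }
  out
}
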