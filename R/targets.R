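#' Transcription start sites of gene models
#'
#' Strand aware: the TSS of a `+` transcript is its leftmost base, of a `-`
#' transcript its rightmost base (1-based coordinates).
#'
#' @param genes a gene `GRanges` from [gene_set()].
#' @return integer vector of TSS positions, one per transcript.
#' @export
tss <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' Assign peaks to target genes by a TSS window
#'
#' A gene is a target of a factor when at least one peak summit lies within
#' `window` bp of one of its transcripts' TSS (inclusive boundary). The
#' distance reported is summit minus TSS, sign-flipped for `-` strand genes
#' so that positive means downstream of the TSS in gene orientation; for a
#' gene with several transcripts the minimal-|distance| transcript defines
#' the distance of each qualifying peak.
#'
#' @param peaks a peak `GRanges`.
#' @param genes a gene `GRanges`; must be non-empty.
#' @param window half-width of the TSS window in bp (default 3000).
#' @return a `data.frame` of class `target_map` with columns `gene_id`,
#'   `peak_name`, `distance`, one row per qualifying gene/peak pair, sorted
#'   by gene id then peak name. The window is kept in attribute `window`.
#' @export
assign_targets <- function(peaks, genes, window = 3000) {
  assert_scalar_number(window, "window", positive = TRUE)
  if (length(genes) == 0L)
    stop_validation("gene list is empty: target assignment needs an annotation")
  empty <- data.frame(gene_id = character(), peak_name = character(),
                      distance = numeric())
  if (length(peaks) == 0L)
    return(structure(empty, class = c("target_map", "data.frame"), window = window))
  tss_pos <- tss(genes)
  tss_win <- GRanges(seqnames(genes),
                     IRanges(pmax(tss_pos - window, 1L), tss_pos + window))
  summits <- GRanges(seqnames(peaks), IRanges(mcols(peaks)$summit,
                                              mcols(peaks)$summit))
  hits <- suppressWarnings(findOverlaps(summits, tss_win, ignore.strand = TRUE))
  if (length(hits) == 0L)
    return(structure(empty, class = c("target_map", "data.frame"), window = window))
  pk <- queryHits(hits)
  tx <- subjectHits(hits)
  d <- mcols(peaks)$summit[pk] - tss_pos[tx]
  d <- ifelse(as.character(strand(genes))[tx] == "-", -d, d)
  df <- data.frame(gene_id = mcols(genes)$gene_id[tx],
                   peak_name = mcols(peaks)$name[pk], distance = d)
  # minimal |distance| transcript per (gene, peak); deterministic tie-break
  df <- df[order(df$gene_id, df$peak_name, abs(df$distance), df$distance), ]
  df <- df[!duplicated(df[c("gene_id", "peak_name")]), ]
  rownames(df) <- NULL
  structure(df, class = c("target_map", "data.frame"), window = window)
}

#' Target gene ids of a target map
#'
#' @param tm a `target_map` from [assign_targets()].
#' @return character vector of unique target gene ids.
#' @export
target_genes <- function(tm) unique(tm$gene_id)

#' Write a target map or feature distribution as TSV
#'
#' @param x a `target_map` or `feature_distribution` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

feature_categories <- c("promoter", "5'UTR", "3'UTR", "coding exon",
                        "intron", "intergenic")

classify_one <- function(pos, tx_strand, tx_exons, cds_start, cds_end) {
  in_exon <- any(pos >= start(tx_exons) & pos <= end(tx_exons))
  if (!in_exon) return("intron")
  if (is.na(cds_start)) return("intron")  # non-coding transcript body, no finer call
  if (pos >= cds_start && pos <= cds_end) return("coding exon")
  five_side <- if (tx_strand == "+") pos < cds_start else pos > cds_end
  if (five_side) "5'UTR" else "3'UTR"
}

#' Classify peak locations into genomic features
#'
#' Each peak is assigned exactly one category from its summit position, with
#' precedence promoter > 5'UTR > 3'UTR > coding exon > intron > intergenic
#' (a summit within `promoter_window` of any TSS is a promoter peak no
#' matter what else it overlaps).
#'
#' @param peaks a peak `GRanges`.
#' @param genes a gene `GRanges` carrying CDS bounds and exons.
#' @param promoter_window promoter half-width around the TSS in bp.
#' @return a `data.frame` of class `feature_distribution` with columns
#'   `category`, `count`, `fraction` over the six categories.
#' @export
classify_peak_locations <- function(peaks, genes, promoter_window = 3000) {
  n <- length(peaks)
  rank_of <- setNames(seq_along(feature_categories), feature_categories)
  cat_rank <- rep.int(rank_of[["intergenic"]], n)
  if (n > 0L && length(genes) > 0L) {
    summit <- mcols(peaks)$summit
    summits <- GRanges(seqnames(peaks), IRanges(summit, summit))
    tss_pos <- tss(genes)
    tss_win <- GRanges(seqnames(genes),
                       IRanges(pmax(tss_pos - promoter_window, 1L),
                               tss_pos + promoter_window))
    prom <- unique(queryHits(suppressWarnings(findOverlaps(summits, tss_win, ignore.strand = TRUE))))
    cat_rank[prom] <- rank_of[["promoter"]]
    hits <- suppressWarnings(findOverlaps(summits, genes, ignore.strand = TRUE))
    exons <- mcols(genes)$exons
    strands <- as.character(strand(genes))
    for (i in seq_along(hits)) {
      pk <- queryHits(hits)[i]
      tx <- subjectHits(hits)[i]
      cat <- classify_one(summit[pk], strands[tx], exons[[tx]],
                          mcols(genes)$cds_start[tx], mcols(genes)$cds_end[tx])
      cat_rank[pk] <- min(cat_rank[pk], rank_of[[cat]])
    }
  }
  counts <- tabulate(cat_rank, nbins = length(feature_categories))
  structure(data.frame(category = feature_categories, count = counts,
                       fraction = if (n > 0L) counts / n else rep(0, length(counts))),
            class = c("feature_distribution", "data.frame"))
}

#' Expressed genes by mean control-condition signal
#'
#' @param expr an [expression_matrix()].
#' @param threshold genes whose mean expression across control samples is at
#'   least this value are called expressed.
#' @param annotation optional gene `GRanges`; ids present in the expression
#'   matrix but absent from the annotation trigger a warning and are kept.
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(expr, threshold, annotation = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop_validation("'threshold' must be a single number")
  ctrl <- expr$values[, expr$condition == "control", drop = FALSE]
  ids <- rownames(ctrl)[rowMeans(ctrl) >= threshold]
  if (!is.null(annotation)) {
    unknown <- setdiff(ids, mcols(annotation)$gene_id)
    if (length(unknown))
      warning(sprintf("%d expressed ids absent from annotation (kept), e.g. %s",
                      length(unknown), unknown[1L]))
  }
  ids
}
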