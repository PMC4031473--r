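#' Construct an expression matrix with a condition map
#'
#' @param values numeric matrix, rows = genes/probes, columns = samples; must
#'   have row and column names and only finite values.
#' @param condition named character vector mapping every sample id to
#'   `"control"` or `"knockdown"`.
#' @return an object of class `expression_matrix` (a list with `values` and
#'   `condition`).
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("'values' must carry row and column names")
  bad <- rownames(values)[!stats::complete.cases(values) |
                            apply(values, 1L, function(r) any(!is.finite(r)))]
  if (length(bad))
    stop_validation("non-finite expression values in rows: %s",
                    paste(head(bad, 5L), collapse = ", "))
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing))
    stop_validation("samples missing from condition map: %s",
                    paste(missing, collapse = ", "))
  condition <- condition[colnames(values)]
  if (!all(condition %in% c("control", "knockdown")))
    stop_validation("unknown condition label(s): %s",
                    paste(setdiff(unique(condition), c("control", "knockdown")),
                          collapse = ", "))
  structure(list(values = values, condition = condition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d control, %d knockdown)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "control"), sum(x$condition == "knockdown")))
  invisible(x)
}

#' Read an expression matrix and its sample-condition map
#'
#' The matrix is a TSV with a header of sample ids and gene/probe ids in the
#' first column. The condition map is either a YAML mapping
#' (`sample: condition`) or a two-column TSV; labels must be `control` or
#' `knockdown`. Rows containing any non-numeric cell are rejected with the
#' offending row ids.
#'
#' @param path matrix TSV path.
#' @param condition_map_path condition map path (`.yaml`/`.yml` or TSV).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, condition_map_path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  ids <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                    dimnames = list(ids, colnames(raw))))
  bad <- ids[apply(values, 1L, function(r) any(!is.finite(r)))]
  if (length(bad))
    stop_validation("non-numeric expression values in rows: %s",
                    paste(head(bad, 5L), collapse = ", "))
  if (grepl("\\.ya?ml$", condition_map_path)) {
    cm <- yaml::read_yaml(condition_map_path)
    condition <- unlist(cm)
  } else {
    cm <- read.table(condition_map_path, sep = "\t", colClasses = "character")
    condition <- setNames(cm[[2L]], cm[[1L]])
  }
  expression_matrix(values, condition)
}

#' Write an expression matrix and condition map
#'
#' @param expr an [expression_matrix()].
#' @param path matrix TSV path.
#' @param condition_map_path condition map path; written as YAML when the
#'   extension is `.yaml`/`.yml`, TSV otherwise.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, condition_map_path = NULL) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(condition_map_path)) {
    if (grepl("\\.ya?ml$", condition_map_path)) {
      yaml::write_yaml(as.list(expr$condition), condition_map_path)
    } else {
      write.table(data.frame(names(expr$condition), expr$condition),
                  condition_map_path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}
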