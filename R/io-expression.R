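#' Expression matrix with a two-condition design
#'
#' Container for a genes-by-samples real matrix (missing values allowed)
#' plus a design assigning each sample to exactly one of two conditions.
#' Two-channel (R/G spot intensity) data for LOWESS normalization is carried
#' in the optional `channels` slot as a list of matrices `R` and `G` of the
#' same dimensions.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample labels).
#' @param design data.frame with columns `sample` and `condition`; exactly
#'   two condition levels.
#' @param channels optional list with matrices `R` and `G`.
#' @param log2_scale logical or `NA`; whether `values` are on the log2
#'   scale.  `NA` requests the load-time heuristic (99th percentile < 30).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, design, channels = NULL,
                              log2_scale = NA) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  design <- data.frame(sample = as.character(design$sample),
                       condition = as.character(design$condition),
                       stringsAsFactors = FALSE)
  if (!setequal(design$sample, colnames(values)) ||
      anyDuplicated(design$sample))
    stop_mssnet("design samples must match matrix columns one-to-one")
  conds <- unique(design$condition)
  if (length(conds) != 2)
    stop_mssnet("design must have exactly 2 conditions, found %d",
                length(conds))
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  if (is.na(log2_scale))
    log2_scale <- stats::quantile(values, 0.99, na.rm = TRUE) < 30
  structure(list(values = values, design = design, channels = channels,
                 log2_scale = isTRUE(log2_scale)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$design$condition)
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (%s), %s scale, %d missing\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    if (x$log2_scale) "log2" else "linear", sum(is.na(x$values))))
  invisible(x)
}

#' Condition levels of an expression matrix, in first-appearance order
#' @param x an `expression_matrix`.
#' @return character vector of length 2.
#' @export
conditions <- function(x) unique(x$design$condition)

#' Read an expression matrix and its design file
#'
#' The expression TSV has gene ids in the first column and a header row of
#' sample labels; empty fields, `NA` and `NaN` all parse as missing.  The
#' design TSV has two columns, `sample` and `condition` (header optional).
#'
#' @param expr_path expression TSV path.
#' @param design_path design TSV path.
#' @param log2_scale logical or `NA` (auto-detect).
#' @return an [expression_matrix].
#' @export
read_expression_matrix <- function(expr_path, design_path, log2_scale = NA) {
  tab <- utils::read.delim(expr_path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#",
                           na.strings = c("", "NA", "NaN"))
  genes <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  des <- utils::read.delim(design_path, header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(as.character(des[1, 1])), "sample"))
    des <- des[-1, , drop = FALSE]
  design <- data.frame(sample = as.character(des[[1]]),
                       condition = as.character(des[[2]]))
  expression_matrix(vals, design, log2_scale = log2_scale)
}

#' Write an expression matrix to TSV
#' @param x an `expression_matrix`.
#' @param expr_path,design_path output paths (design skipped when `NULL`).
#' @return `expr_path`, invisibly.
#' @export
write_expression_matrix <- function(x, expr_path, design_path = NULL) {
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(expr_path)
}
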