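#' K-nearest-neighbour imputation of missing expression values
#'
#' For each missing cell, the `k` gene rows nearest to the target row are
#' found by root-mean-square Euclidean distance over mutually observed
#' columns (so rows with different missingness patterns are comparable),
#' restricted to rows observed in the target column; the imputed value is
#' the unweighted mean of those neighbours' values in that column.
#' Observed entries are never modified.
#'
#' @param x an [expression_matrix] (or a plain numeric matrix).
#' @param k positive integer number of neighbours (default 10).
#' @return an object of the same type with no missing entries.
#' @export
knn_impute <- function(x, k = 10) {
  mat <- if (inherits(x, "expression_matrix")) x$values else x
  stopifnot(is.matrix(mat), k >= 1)
  miss <- is.na(mat)
  if (!any(miss)) return(x)
  all_missing <- rownames(mat)[rowSums(!miss) == 0]
  if (length(all_missing) > 0)
    stop_mssnet("gene(s) with zero observed entries: %s",
                paste(all_missing, collapse = ", "))
  out <- mat
  need <- which(rowSums(miss) > 0)
  for (g in need) {
    target <- mat[g, ]
    obs_t <- !miss[g, ]
    # squared diffs over mutually observed columns, root-mean-squared
    diffs <- sweep(mat[, obs_t, drop = FALSE], 2, target[obs_t], "-")
    shared <- rowSums(!is.na(diffs))
    d <- sqrt(rowSums(diffs^2, na.rm = TRUE) / shared)
    d[g] <- Inf
    d[shared == 0] <- Inf
    for (j in which(miss[g, ])) {
      cand <- which(!miss[, j] & is.finite(d))
      if (length(cand) == 0)
        stop_mssnet("no neighbour with an observed value in column '%s'",
                    colnames(mat)[j])
      if (length(cand) < k)
        warn_mssnet("only %d neighbour(s) available for gene '%s', column '%s'",
                    length(cand), rownames(mat)[g], colnames(mat)[j])
      ord <- cand[order(d[cand], cand)]
      nn <- utils::head(ord, k)
      out[g, j] <- mean(mat[nn, j])
    }
  }
  if (inherits(x, "expression_matrix")) { x$values <- out; x } else out
}

#' Within-array LOWESS (intensity-dependent) normalization
#'
#' Classic two-channel M-A normalization: per array, `M = log2(R/G)` and
#' `A = 0.5 * log2(R * G)`; a LOWESS curve of M on A estimates the
#' intensity-dependent dye bias, and the corrected value is
#' `M' = M - lowess(A)`.  Non-positive intensities are floored at half the
#' smallest positive intensity on that array.
#'
#' @param x an [expression_matrix] whose `channels` slot holds `R` and `G`
#'   intensity matrices (spots x arrays).
#' @param span LOWESS smoother span (fraction of spots; default 0.4).
#' @return the [expression_matrix] with `values` replaced by normalized M
#'   (log2 scale) and `channels` dropped.
#' @export
lowess_normalize <- function(x, span = 0.4) {
  stopifnot(inherits(x, "expression_matrix"))
  if (is.null(x$channels) || is.null(x$channels$R) || is.null(x$channels$G))
    stop_mssnet("lowess_normalize requires two-channel R/G intensities")
  R <- x$channels$R; G <- x$channels$G
  stopifnot(identical(dim(R), dim(G)))
  if (nrow(R) < 10)
    stop_mssnet("fewer than 10 spots per array; lowess is underdetermined")
  Mn <- matrix(NA_real_, nrow(R), ncol(R), dimnames = dimnames(R))
  for (j in seq_len(ncol(R))) {
    r <- R[, j]; g <- G[, j]
    pos <- c(r[r > 0 & !is.na(r)], g[g > 0 & !is.na(g)])
    floor_val <- min(pos) / 2
    r <- pmax(r, floor_val); g <- pmax(g, floor_val)
    M <- log2(r / g); A <- 0.5 * log2(r * g)
    ok <- is.finite(M) & is.finite(A)
    fit <- stats::lowess(A[ok], M[ok], f = span)
    trend <- stats::approx(fit$x, fit$y, xout = A[ok], rule = 2,
                           ties = mean)$y
    Mn[ok, j] <- M[ok] - trend
  }
  x$values <- Mn
  x$channels <- NULL
  x$log2_scale <- TRUE
  x
}

#' Per-gene two-sided two-class Welch t-test with fold change
#'
#' Tests each gene for a difference between the two design conditions with
#' Welch's unequal-variance t statistic,
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` (unbiased variance
#' estimators), two-sided p via the Welch-Satterthwaite degrees of freedom.
#' Fold change is `mean(condition2) / mean(condition1)` on the linear
#' scale; log2 input (per the matrix's `log2_scale` flag) is exponentiated
#' first.
#'
#' Degenerate genes (zero variance in both groups): equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` and `degenerate = TRUE`.
#'
#' @param x an [expression_matrix] with >= 2 samples per condition and no
#'   missing values (run [knn_impute()] first).
#' @return data.frame: `gene`, `fold_change`, `t`, `raw_p`, `degenerate`.
#' @export
two_class_ttest <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (anyNA(x$values))
    stop_mssnet("expression matrix has missing values; impute first")
  conds <- conditions(x)
  i1 <- x$design$condition == conds[1]
  i2 <- x$design$condition == conds[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2)
    stop_mssnet("each condition needs >= 2 samples (found %d and %d)", n1, n2)
  g1 <- x$values[, i1, drop = FALSE]
  g2 <- x$values[, i2, drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- v1 == 0 & v2 == 0
  t[degen & m1 == m2] <- 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  lin1 <- if (x$log2_scale) 2^g1 else g1
  lin2 <- if (x$log2_scale) 2^g2 else g2
  fc <- rowMeans(lin2) / rowMeans(lin1)
  data.frame(gene = rownames(x$values), fold_change = unname(fc),
             t = unname(t), raw_p = unname(p),
             degenerate = unname(degen & m1 != m2),
             stringsAsFactors = FALSE)
}

#' Holm step-down adjustment of p-values
#'
#' Bonferroni-Holm step-down correction (controls the family-wise error
#' rate), returned in the input order.  Output is monotone nondecreasing in
#' sorted order and never smaller than the raw p.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_adjust <- function(p) {
  if (length(p) < 1) stop_mssnet("need at least one p-value")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_mssnet("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg step-up adjustment of p-values
#'
#' Step-up FDR correction with monotonicity enforcement, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (length(p) < 1) stop_mssnet("need at least one p-value")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_mssnet("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call up- and down-regulated genes
#'
#' A gene is up-regulated when `adjusted_p < alpha` and
#' `fold_change > up_threshold`, down-regulated when `adjusted_p < alpha`
#' and `fold_change < down_threshold`; the two gates are independent, so
#' their order does not matter.  Defaults follow the conventional
#' 1.5-fold / 0.67-fold gates with alpha 0.05.
#'
#' @param stats data.frame from [two_class_ttest()].
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param up_threshold,down_threshold linear fold-change gates (1.5, 0.67).
#' @param adjust `"holm"` (default) or `"bh"`.
#' @return object of class `de_gene_sets`: list with `up`, `down`
#'   (character vectors) and `table` (per-gene stats with `adjusted_p` and
#'   `call`).
#' @export
call_de_genes <- function(stats, alpha = 0.05, up_threshold = 1.5,
                          down_threshold = 0.67,
                          adjust = c("holm", "bh")) {
  adjust <- match.arg(adjust)
  adj <- if (adjust == "holm") holm_adjust(stats$raw_p)
         else bh_adjust(stats$raw_p)
  call <- rep("ns", nrow(stats))
  call[adj < alpha & stats$fold_change > up_threshold] <- "up"
  call[adj < alpha & stats$fold_change < down_threshold] <- "down"
  tab <- data.frame(gene = stats$gene, fold_change = stats$fold_change,
                    raw_p = stats$raw_p, adjusted_p = adj, call = call,
                    stringsAsFactors = FALSE)
  structure(list(up = tab$gene[call == "up"], down = tab$gene[call == "down"],
                 table = tab, alpha = alpha,
                 up_threshold = up_threshold,
                 down_threshold = down_threshold, adjust = adjust),
            class = "de_gene_sets")
}

#' @export
print.de_gene_sets <- function(x, ...) {
  cat(sprintf("de_gene_sets: %d up, %d down of %d genes (%s, alpha %g)\n",
              length(x$up), length(x$down), nrow(x$table), x$adjust, x$alpha))
  invisible(x)
}
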