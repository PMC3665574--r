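#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that a draw of
#' `n` genes from a universe of `N` containing `K` category members hits
#' the category at least `k` times.  Evaluated through the log-space
#' routines of the stats distribution functions for numerical stability.
#'
#' @param k observed category members in the drawn set.
#' @param n drawn set size.
#' @param K category size in the universe.
#' @param N universe size.
#' @return the upper-tail probability (1 when `k = 0`).
#' @examples
#' hypergeom_tail(5, 5, 5, 20)  # 1 / choose(20, 5)
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K))
    stop_mssnet("hypergeom_tail: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(n, K)")
  if (k == 0) return(1)
  # P(X >= k) = P(X > k - 1); log.p guards against underflow for deep tails
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Category overrepresentation in one subnetwork
#'
#' Hypergeometric overrepresentation test of every annotation category in
#' the genes of one MSSN (seed included, per its membership of the
#' subnetwork), with Benjamini-Hochberg correction across the subnetwork's
#' own term family.  The universe is the annotation map's universe;
#' subnetwork genes outside the universe are ignored (their count is
#' reported).
#'
#' @param mssn an [build_mssn()] result, or a plain character vector of
#'   gene ids.
#' @param ann an [annotation_map].
#' @param alpha significance level used for the `significant` flag
#'   (default 0.05).
#' @param min_term_size smallest universe category tested (default 2).
#' @return data.frame sorted by `adjusted_p` (ties: larger `k` first, then
#'   term id): `term`, `k`, `n`, `K`, `N`, `raw_p`, `adjusted_p`,
#'   `significant`; attribute `n_outside_universe`.
#' @export
enrich_subnetwork <- function(mssn, ann, alpha = 0.05, min_term_size = 2) {
  genes <- if (inherits(mssn, "mssn")) mssn$nodes else as.character(mssn)
  inside <- intersect(genes, ann$universe)
  n_outside <- length(setdiff(genes, ann$universe))
  if (length(inside) == 0) {
    warn_mssnet("no subnetwork gene lies in the annotation universe")
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), raw_p = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0))
    attr(out, "n_outside_universe") <- n_outside
    return(out)
  }
  N <- length(ann$universe)
  n <- length(inside)
  sizes <- table(ann$gene2term$term)
  terms <- names(sizes)[sizes >= min_term_size]
  if (length(terms) == 0) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), raw_p = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0))
    attr(out, "n_outside_universe") <- n_outside
    return(out)
  }
  g2t <- ann$gene2term[ann$gene2term$term %in% terms, , drop = FALSE]
  hit <- g2t$gene %in% inside
  k <- vapply(terms, function(tm) sum(hit[g2t$term == tm]), 0L)
  K <- as.integer(sizes[terms])
  raw_p <- mapply(hypergeom_tail, k = k, n = n, K = K, N = N)
  adj <- bh_adjust(raw_p)
  out <- data.frame(term = terms, k = as.integer(k), n = n, K = K, N = N,
                    raw_p = raw_p, adjusted_p = adj,
                    significant = adj < alpha, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(out$adjusted_p, -out$k, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outside_universe") <- n_outside
  out
}

#' Core-pathway profile across a collection of MSSNs
#'
#' Counts, for every annotation term, in how many of the supplied MSSN
#' enrichment results it is significant (`adjusted_p < alpha`).  The terms
#' most frequently overrepresented across subnetworks are the candidate
#' core pathways.  An optional permutation null reshuffles the gene-to-term
#' labels and recounts, giving a per-term frequency p-value.
#'
#' @param all_results named list of [enrich_subnetwork()] data.frames, one
#'   per MSSN.
#' @param alpha per-MSSN significance level (default 0.05).
#' @param n_permutations 0 (default) disables the permutation null.
#' @param ann annotation map (required when `n_permutations > 0`).
#' @param mssn_genes list of per-MSSN gene vectors (required with
#'   permutations).
#' @param rng_seed seed for the permutation null.
#' @return object of class `core_pathway_profile`: data.frame `profile`
#'   (`term`, `n_significant`, `n_mssn`, `frequency`, `mean_adjusted_p`,
#'   optional `perm_p`), ranked by frequency (ties: smaller mean adjusted
#'   p, then term id), plus `alpha` and `n_mssn`.
#' @export
core_pathways <- function(all_results, alpha = 0.05, n_permutations = 0,
                          ann = NULL, mssn_genes = NULL, rng_seed = NULL) {
  if (length(all_results) < 1)
    stop_mssnet("core_pathways needs at least one MSSN result")
  n_mssn <- length(all_results)
  count_sig <- function(results) {
    sig_terms <- unlist(lapply(results, function(df)
      df$term[df$adjusted_p < alpha]))
    table(sig_terms)
  }
  cnt <- count_sig(all_results)
  if (length(cnt) == 0) {
    prof <- data.frame(term = character(0), n_significant = integer(0),
                       n_mssn = integer(0), frequency = numeric(0),
                       mean_adjusted_p = numeric(0))
    return(structure(list(profile = prof, alpha = alpha, n_mssn = n_mssn),
                     class = "core_pathway_profile"))
  }
  terms <- names(cnt)
  meanp <- vapply(terms, function(tm) {
    ps <- unlist(lapply(all_results, function(df) df$adjusted_p[df$term == tm]))
    if (length(ps) == 0) NA_real_ else mean(ps)
  }, 0)
  prof <- data.frame(term = terms, n_significant = as.integer(cnt),
                     n_mssn = n_mssn,
                     frequency = as.integer(cnt) / n_mssn,
                     mean_adjusted_p = unname(meanp),
                     stringsAsFactors = FALSE)
  if (n_permutations > 0) {
    if (is.null(ann) || is.null(mssn_genes))
      stop_mssnet("permutation null needs `ann` and `mssn_genes`")
    exceed <- stats::setNames(integer(length(terms)), terms)
    with_seed(rng_seed, {
      for (b in seq_len(n_permutations)) {
        perm_ann <- ann
        perm_ann$gene2term$gene <- sample(perm_ann$gene2term$gene)
        perm_res <- lapply(mssn_genes, function(gs)
          suppressWarnings(enrich_subnetwork(gs, perm_ann, alpha = alpha)))
        pc <- count_sig(perm_res)
        for (tm in terms)
          if (!is.na(pc[tm]) && pc[tm] >= cnt[tm])
            exceed[tm] <- exceed[tm] + 1L
      }
    })
    prof$perm_p <- (exceed[prof$term] + 1) / (n_permutations + 1)
  }
  prof <- prof[order(-prof$frequency, prof$mean_adjusted_p, prof$term), ,
               drop = FALSE]
  rownames(prof) <- NULL
  structure(list(profile = prof, alpha = alpha, n_mssn = n_mssn),
            class = "core_pathway_profile")
}

#' @export
print.core_pathway_profile <- function(x, ...) {
  cat(sprintf("core_pathway_profile: %d term(s) over %d MSSNs (alpha %g)\n",
              nrow(x$profile), x$n_mssn, x$alpha))
  print(utils::head(x$profile, 10))
  invisible(x)
}
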