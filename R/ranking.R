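#' Designate the core-pathway set
#'
#' Selects the terms treated as core pathways by [rank_drivers()]:
#' the top `k` of the frequency-ranked profile, all terms at or above a
#' frequency threshold, or an explicit externally validated list (the
#' typical use when a core pathway has been confirmed by experiment).
#'
#' @param core a [core_pathways()] profile (may be `NULL` for
#'   `explicit_list`).
#' @param mode `"top_k"`, `"frequency_threshold"` or `"explicit_list"`.
#' @param k number of terms for `top_k` (default 4).
#' @param threshold minimum frequency for `frequency_threshold`.
#' @param terms character vector for `explicit_list`.
#' @param ann optional [annotation_map]; explicit terms absent from it
#'   trigger a warning but are kept.
#' @return character vector of designated core terms.
#' @export
designate_core <- function(core = NULL,
                           mode = c("top_k", "frequency_threshold",
                                    "explicit_list"),
                           k = 4, threshold = 0.5, terms = NULL,
                           ann = NULL) {
  mode <- match.arg(mode)
  if (mode == "explicit_list") {
    if (is.null(terms)) stop_mssnet("explicit_list mode needs `terms`")
    if (!is.null(ann)) {
      missing <- setdiff(terms, unique(ann$gene2term$term))
      if (length(missing) > 0)
        warn_mssnet("explicit core term(s) absent from the annotation map: %s",
                    paste(missing, collapse = ", "))
    }
    return(as.character(terms))
  }
  if (is.null(core) || nrow(core$profile) == 0) {
    if (mode == "top_k")
      stop_mssnet("core-pathway profile is empty; cannot take top_k")
    return(character(0))
  }
  prof <- core$profile
  if (mode == "top_k") return(utils::head(prof$term, k))
  prof$term[prof$frequency >= threshold]
}

#' Rank candidate driver mutations
#'
#' Combines the two evidence channels into a tiered ranking:
#' tier 1 seeds pass both criteria — at least one of their MSSNs is
#' enriched (`adjusted_p < alpha`) for a designated core pathway, and at
#' least one direction has path significance (`empirical_p < alpha`);
#' tier 2 seeds pass exactly one criterion; tier 3 neither.  Within a tier,
#' seeds sort by their best Welch t (max over directions) descending, with
#' a deterministic tie-break on gene id.  Seeds missing from either input
#' are emitted flagged in tier 3.
#'
#' @param stats data.frame with one row per seed x direction: columns
#'   `seed`, `direction`, `t`, `z`, `empirical_p` (as produced by
#'   [run_pipeline()] or assembled from [mssn_statistics()] results; `NA`
#'   rows allowed for flagged/degenerate MSSNs).
#' @param enrich named list: for each seed, a named list of
#'   [enrich_subnetwork()] data.frames keyed by direction.
#' @param core_terms character vector from [designate_core()].
#' @param mutations optional data.frame from [read_gene_list()]; its
#'   substitutions are carried into the output.
#' @param alpha significance level for both criteria (default 0.05).
#' @return object of class `driver_ranking`: data.frame with columns
#'   `rank`, `gene`, `mutations`, `tier`, `t_up`, `t_down`, `z_up`,
#'   `z_down`, `empirical_p_up`, `empirical_p_down`, `core_enriched`
#'   (best core-term adjusted p), `pass_path`, `pass_enrichment`,
#'   `missing_data`.
#' @export
rank_drivers <- function(stats, enrich, core_terms, mutations = NULL,
                         alpha = 0.05) {
  seeds <- sort(union(unique(stats$seed), names(enrich)))
  get_stat <- function(seed, direction, field) {
    i <- which(stats$seed == seed & stats$direction == direction)
    if (length(i) == 0) return(NA_real_)
    as.numeric(stats[[field]][i[1]])
  }
  rows <- lapply(seeds, function(sd) {
    t_up <- get_stat(sd, "up", "t"); t_dn <- get_stat(sd, "down", "t")
    z_up <- get_stat(sd, "up", "z"); z_dn <- get_stat(sd, "down", "z")
    p_up <- get_stat(sd, "up", "empirical_p")
    p_dn <- get_stat(sd, "down", "empirical_p")
    core_p <- NA_real_
    if (!is.null(enrich[[sd]])) {
      ps <- unlist(lapply(enrich[[sd]], function(df) {
        hit <- df$term %in% core_terms
        if (any(hit)) min(df$adjusted_p[hit]) else NA_real_
      }))
      ps <- ps[!is.na(ps)]
      if (length(ps) > 0) core_p <- min(ps)
    }
    missing_data <- !(sd %in% stats$seed) || is.null(enrich[[sd]])
    pe <- c(p_up, p_dn)
    pe <- pe[!is.na(pe)]
    pass_path <- length(pe) > 0 && min(pe) < alpha
    pass_enr <- isTRUE(core_p < alpha)
    tier <- if (missing_data) 3L
            else 3L - sum(pass_path, pass_enr)
    data.frame(gene = sd, tier = tier, t_up = t_up, t_down = t_dn,
               z_up = z_up, z_down = z_dn, empirical_p_up = p_up,
               empirical_p_down = p_dn, core_enriched = core_p,
               pass_path = pass_path, pass_enrichment = pass_enr,
               missing_data = missing_data, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  best_t <- suppressWarnings(pmax(out$t_up, out$t_down, na.rm = TRUE))
  best_t[!is.finite(best_t)] <- -Inf
  out <- out[order(out$tier, -best_t, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  muts <- rep(NA_character_, nrow(out))
  if (!is.null(mutations)) {
    muts <- vapply(out$gene, function(g) {
      s <- mutations$substitution[mutations$gene == g]
      s <- s[!is.na(s)]
      if (length(s) == 0) NA_character_ else paste(s, collapse = ",")
    }, "")
  }
  out <- cbind(rank = out$rank, gene = out$gene, mutations = muts,
               out[, setdiff(names(out), c("rank", "gene")), drop = FALSE])
  rownames(out) <- NULL
  structure(out, class = c("driver_ranking", "data.frame"))
}

#' @export
print.driver_ranking <- function(x, ...) {
  cat(sprintf("driver_ranking: %d seeds (%d in tier 1)\n",
              nrow(x), sum(x$tier == 1)))
  print.data.frame(utils::head(x, 15), digits = 4)
  invisible(x)
}
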