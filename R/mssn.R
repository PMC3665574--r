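#' Single-source shortest-path distances
#'
#' Exact Dijkstra distances from one source gene to a set of destination
#' genes on the weighted PPI network.  Unreachable destinations are
#' reported as `Inf`, never as an error.
#'
#' @param network a [ppi_network].
#' @param source source gene id (must be a network node).
#' @param destinations character vector of destination gene ids (ids absent
#'   from the network are dropped).
#' @return named numeric vector of distances (`Inf` = unreachable).
#' @export
shortest_distances <- function(network, source, destinations) {
  nodes <- network_nodes(network)
  if (!(source %in% nodes))
    stop_mssnet("source gene '%s' is not a node of the network", source)
  dest <- intersect(destinations, nodes)
  if (length(dest) == 0) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(network$graph, v = source, to = dest,
                         weights = igraph::E(network$graph)$weight,
                         algorithm = "dijkstra")
  stats::setNames(as.numeric(d[1, ]), colnames(d))
}

#' Build a mutation-seeded subnetwork (MSSN)
#'
#' The MSSN of a mutated gene (the seed) for one DE direction is the union
#' of shortest paths from the seed to each reachable differentially
#' expressed target.  When several equal-cost shortest paths exist for a
#' target, the path whose node-id sequence is lexicographically smallest is
#' retained, which makes the subnetwork deterministic.  The distance sample
#' used downstream contains one distance per reachable target; unreachable
#' targets are counted but excluded from the sample.
#'
#' @param network a [ppi_network].
#' @param seed seed gene id (must be a network node).
#' @param de_set character vector of DE gene ids for the given direction.
#' @param direction `"up"` or `"down"` (label carried into outputs).
#' @return object of class `mssn`: list with `seed`, `direction`,
#'   `targets` (in-network targets, seed excluded), `distances` (named,
#'   reachable targets only), `n_unreachable`, `nodes`, `edges`
#'   (two-column character matrix) and `n_targets_dropped` (targets absent
#'   from the network).
#' @export
build_mssn <- function(network, seed, de_set, direction = c("up", "down")) {
  direction <- match.arg(direction)
  nodes <- network_nodes(network)
  if (!(seed %in% nodes))
    stop_mssnet("seed gene '%s' is not a node of the network", seed)
  de_set <- unique(as.character(de_set))
  targets <- intersect(de_set, nodes)
  n_dropped <- length(de_set) - length(targets)
  targets <- setdiff(targets, seed)
  if (length(targets) == 0)
    stop_mssnet("no %s-regulated target overlaps the network for seed '%s'",
                direction, seed)
  g <- network$graph
  w <- igraph::E(g)$weight
  d <- shortest_distances(network, seed, targets)
  reach <- names(d)[is.finite(d)]
  sub_nodes <- character(0)
  edge_from <- character(0); edge_to <- character(0)
  if (length(reach) > 0) {
    asp <- igraph::all_shortest_paths(g, from = seed, to = reach, weights = w)
    paths <- lapply(asp$vpaths, function(p) igraph::V(g)$name[as.integer(p)])
    endpoints <- vapply(paths, function(p) p[length(p)], "")
    for (tg in reach) {
      cand <- paths[endpoints == tg]
      best <- cand[[1]]
      if (length(cand) > 1) {
        for (p in cand[-1]) if (lex_less(p, best)) best <- p
      }
      sub_nodes <- union(sub_nodes, best)
      if (length(best) > 1) {
        edge_from <- c(edge_from, best[-length(best)])
        edge_to <- c(edge_to, best[-1])
      }
    }
  }
  a <- pmin(edge_from, edge_to); b <- pmax(edge_from, edge_to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(from = a[keep], to = b[keep])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(seed = seed, direction = direction, targets = targets,
                 distances = d[is.finite(d)],
                 n_unreachable = sum(!is.finite(d)),
                 nodes = sort(sub_nodes), edges = edges,
                 n_targets_dropped = n_dropped),
            class = "mssn")
}

#' @export
print.mssn <- function(x, ...) {
  cat(sprintf(
    "mssn: seed %s (%s), %d/%d targets reachable, %d nodes, %d edges\n",
    x$seed, x$direction, length(x$distances), length(x$targets),
    length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Background shortest-path distance samples
#'
#' Emulates random "background networks": each replicate draws one random
#' source gene and `n_targets` distinct random destination genes (uniform,
#' without replacement, source excluded) and collects the reachable
#' shortest-path distances.  The pooled distances form the background
#' sample for the Welch t; the per-replicate mean distances form the
#' empirical null for the z-score and empirical p.
#'
#' @param network a [ppi_network].
#' @param n_targets destinations per replicate (matched to the observed
#'   target-set size).
#' @param n_replicates number of replicates (>= 2).
#' @param rng_seed integer seed for reproducibility (or `NULL`).
#' @param dist_matrix optional precomputed all-pairs distance matrix
#'   (rownames/colnames = node ids) to avoid repeated Dijkstra runs on
#'   small networks.
#' @return list with `pooled` (numeric vector) and `replicate_means`
#'   (length `n_replicates`, `NA` for replicates with no reachable
#'   destination).
#' @export
background_distances <- function(network, n_targets, n_replicates = 1000,
                                 rng_seed = NULL, dist_matrix = NULL) {
  if (n_replicates < 2) stop_mssnet("n_replicates must be >= 2")
  nodes <- network_nodes(network)
  if (length(nodes) <= n_targets + 1)
    stop_mssnet("network must have more than n_targets + 1 nodes")
  with_seed(rng_seed, {
    sources <- sample(nodes, n_replicates, replace = TRUE)
    if (is.null(dist_matrix)) {
      usrc <- unique(sources)
      dist_matrix <- igraph::distances(
        network$graph, v = usrc,
        weights = igraph::E(network$graph)$weight, algorithm = "dijkstra")
    }
    pooled <- vector("list", n_replicates)
    rep_means <- rep(NA_real_, n_replicates)
    for (r in seq_len(n_replicates)) {
      src <- sources[r]
      dest <- sample(setdiff(nodes, src), n_targets)
      d <- dist_matrix[src, dest]
      d <- d[is.finite(d)]
      pooled[[r]] <- d
      if (length(d) > 0) rep_means[r] <- mean(d)
    }
    list(pooled = unname(unlist(pooled)), replicate_means = rep_means)
  })
}

#' Welch t statistic for MSSN vs background path lengths
#'
#' Computes `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with unbiased
#' variance estimators, where sample 1 is the background distances and
#' sample 2 the MSSN distances: a positive t means the subnetwork's paths
#' are shorter than random background paths.  When per-replicate background
#' means are supplied, two further quantities are derived: an empirical p
#' (fraction of background replicate means at or below the observed MSSN
#' mean) and a z-score of the observed mean against the replicate-mean
#' distribution.
#'
#' @param sample1 numeric vector of background distances (n >= 2).
#' @param sample2 numeric vector of MSSN distances (n >= 2).
#' @param replicate_means optional numeric vector of per-replicate
#'   background mean distances.
#' @return object of class `path_statistics`: list with `t`, `mean_bg`
#'   (m1), `mean_mssn` (m2), `var_bg`, `var_mssn`, `n_bg`, `n_mssn`,
#'   `empirical_p` and `z` (the latter two `NA` without replicate means).
#' @examples
#' welch_t(c(4, 5, 6), c(1, 2, 3))$t  # +3.674: subnetwork paths shorter
#' @export
welch_t <- function(sample1, sample2, replicate_means = NULL) {
  sample1 <- sample1[is.finite(sample1)]
  sample2 <- sample2[is.finite(sample2)]
  if (length(sample1) < 2 || length(sample2) < 2)
    stop_mssnet("both samples need >= 2 finite values (got %d and %d)",
                length(sample1), length(sample2))
  n1 <- length(sample1); n2 <- length(sample2)
  m1 <- mean(sample1); m2 <- mean(sample2)
  v1 <- stats::var(sample1); v2 <- stats::var(sample2)
  t <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  emp <- NA_real_; z <- NA_real_
  if (!is.null(replicate_means)) {
    rm_ok <- replicate_means[!is.na(replicate_means)]
    emp <- mean(rm_ok <= m2)
    z <- (m1 - m2) / stats::sd(rm_ok)
  }
  structure(list(t = t, mean_bg = m1, mean_mssn = m2, var_bg = v1,
                 var_mssn = v2, n_bg = n1, n_mssn = n2,
                 empirical_p = emp, z = z),
            class = "path_statistics")
}

#' @export
print.path_statistics <- function(x, ...) {
  cat(sprintf(
    "path_statistics: t = %.3f (bg %.3f +/- %.3f, n=%d; mssn %.3f +/- %.3f, n=%d)",
    x$t, x$mean_bg, sqrt(x$var_bg), x$n_bg, x$mean_mssn, sqrt(x$var_mssn),
    x$n_mssn))
  if (!is.na(x$empirical_p))
    cat(sprintf("; z = %.3f, empirical p = %.4g", x$z, x$empirical_p))
  cat("\n")
  invisible(x)
}

#' Score one seed's MSSN against a random background
#'
#' Convenience wrapper: builds the MSSN, draws a matched background
#' (destination-set size equal to the observed in-network target count) and
#' returns both the subnetwork and its path statistics.
#'
#' @inheritParams build_mssn
#' @param n_replicates background replicates (default 1000).
#' @param rng_seed integer master seed; a per-seed substream is derived
#'   from it and the seed gene id, so backgrounds are redrawn per seed.
#' @param dist_matrix optional precomputed all-pairs distance matrix.
#' @return list with elements `mssn` and `stats` (`stats` is `NA` when the
#'   distance sample has fewer than 2 reachable targets; the record is
#'   flagged via `mssn$n_unreachable`).
#' @export
mssn_statistics <- function(network, seed, de_set,
                            direction = c("up", "down"),
                            n_replicates = 1000, rng_seed = NULL,
                            dist_matrix = NULL) {
  direction <- match.arg(direction)
  m <- build_mssn(network, seed, de_set, direction)
  stats <- NA
  if (length(m$distances) >= 2) {
    bg <- background_distances(
      network, n_targets = length(m$targets), n_replicates = n_replicates,
      rng_seed = derive_seed(rng_seed, paste0(seed, ":", direction)),
      dist_matrix = dist_matrix)
    stats <- welch_t(bg$pooled, m$distances, bg$replicate_means)
  }
  list(mssn = m, stats = stats)
}
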