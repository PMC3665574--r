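#' Protein-protein interaction network container
#'
#' A `ppi_network` wraps an undirected [igraph::igraph] with positive edge
#' weights plus source metadata.  Node names are gene identifiers after a
#' single normalization pass (optional alias table) at load time; comparisons
#' are case-sensitive thereafter.  Invariants: no self-loops, no multi-edges,
#' weights strictly positive.
#'
#' @param graph an undirected igraph object with a `weight` edge attribute.
#' @param metadata character description of the source.
#' @return an object of class `ppi_network`.
#' @export
ppi_network <- function(graph, metadata = "") {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph))
    graph <- igraph::as_undirected(graph, mode = "collapse")
  w <- igraph::E(graph)$weight
  if (is.null(w)) igraph::E(graph)$weight <- 1
  else if (any(w <= 0)) stop_mssnet("edge weights must be strictly positive")
  if (any(igraph::which_loop(graph)))
    graph <- igraph::simplify(graph, remove.multiple = FALSE)
  structure(list(graph = graph, metadata = metadata), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (nzchar(x$metadata)) x$metadata else "unspecified source"))
  invisible(x)
}

#' Nodes of a PPI network
#' @param network a `ppi_network`.
#' @return character vector of gene ids.
#' @export
network_nodes <- function(network) {
  igraph::V(network$graph)$name
}

#' Read a STRING-style protein-links file
#'
#' Parses a whitespace-delimited file with columns
#' `protein1 protein2 combined_score` (an optional header line is detected
#' and skipped).  Edges below `score_threshold` are dropped; duplicate and
#' reciprocal lines are merged keeping the maximum score; self-loops are
#' discarded with a warning.
#'
#' @param path file path.
#' @param score_threshold integer in `[0, 1000]`; STRING combined scores
#'   below it are discarded.  Default 400 (STRING "medium confidence").
#' @param weight_scheme `"unit"` gives every kept edge weight 1 (distances
#'   are hop counts, the default reading of a shortest-path search on
#'   STRING); `"string_confidence"` assigns `1000 / combined_score`, so
#'   higher-confidence interactions are shorter.
#' @param aliases optional two-column data.frame or TSV path (`from`, `to`)
#'   applied to protein ids at load; unmatched ids are kept as-is.
#' @return a [ppi_network].
#' @examples
#' tf <- tempfile()
#' writeLines(c("a b 900", "b a 900", "b c 400"), tf)
#' net <- read_string_links(tf, score_threshold = 500)
#' network_nodes(net)
#' @export
read_string_links <- function(path, score_threshold = 400,
                              weight_scheme = c("unit", "string_confidence"),
                              aliases = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  if (score_threshold < 0 || score_threshold > 1000)
    stop_mssnet("score_threshold must be in [0, 1000]")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    warn_mssnet("empty protein-links file '%s'; returning empty network", path)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(ppi_network(g, metadata = basename(path)))
  }
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  start <- 1L
  if (length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3]))))
    start <- 2L  # header line
  body <- lines[seq(start, length.out = length(lines) - start + 1L)]
  toks <- strsplit(trimws(body), "[ \t]+")
  nl <- lengths(toks)
  if (any(nl < 3))
    stop_mssnet("malformed protein-links line %d in '%s'",
                which(nl < 3)[1] + start - 1L, path)
  p1 <- vapply(toks, `[`, "", 1L)
  p2 <- vapply(toks, `[`, "", 2L)
  sc <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
  if (anyNA(sc))
    stop_mssnet("malformed combined_score on line %d in '%s'",
                which(is.na(sc))[1] + start - 1L, path)
  if (any(sc < 0 | sc > 1000))
    stop_mssnet("combined_score outside [0, 1000] on line %d",
                which(sc < 0 | sc > 1000)[1] + start - 1L)
  if (!is.null(aliases)) {
    al <- read_alias_table(aliases)
    p1 <- apply_aliases(p1, al)
    p2 <- apply_aliases(p2, al)
  }
  self <- p1 == p2
  if (any(self)) {
    warn_mssnet("dropping %d self-loop line(s)", sum(self))
    p1 <- p1[!self]; p2 <- p2[!self]; sc <- sc[!self]
  }
  keep <- sc >= score_threshold
  p1 <- p1[keep]; p2 <- p2[keep]; sc <- sc[keep]
  if (length(p1) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(ppi_network(g, metadata = basename(path)))
  }
  # canonical unordered pair; keep max score across duplicates/reciprocals
  a <- pmin(p1, p2); b <- pmax(p1, p2)
  key <- paste(a, b, sep = "\r")
  best <- tapply(sc, key, max)
  pair <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  w <- switch(weight_scheme, unit = rep(1, length(best)),
              string_confidence = 1000 / as.numeric(best))
  el <- data.frame(from = pair[, 1], to = pair[, 2], weight = w,
                   combined_score = as.numeric(best),
                   stringsAsFactors = FALSE)
  ord <- order(el$from, el$to)
  el <- el[ord, , drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  ppi_network(g, metadata = sprintf("%s (threshold %d, %s weights)",
                                    basename(path), as.integer(score_threshold),
                                    weight_scheme))
}

#' Write a PPI network to the canonical protein-links TSV
#'
#' Writes `protein1 protein2 combined_score` with a header, round-trippable
#' through [read_string_links()] at threshold 0.  When the network has no
#' stored combined score, weight-1 edges are written with score 1000.
#'
#' @param network a [ppi_network].
#' @param path output path.
#' @param config_hash,rng_seed provenance strings for the commented header.
#' @return the path, invisibly.
#' @export
write_network_tsv <- function(network, path, config_hash = "none",
                              rng_seed = "none") {
  g <- network$graph
  el <- igraph::as_data_frame(g, what = "edges")
  score <- el$combined_score
  if (is.null(score)) score <- round(1000 * pmin(1, 1 / el$weight))
  df <- data.frame(protein1 = pmin(el$from, el$to),
                   protein2 = pmax(el$from, el$to),
                   combined_score = as.integer(score))
  df <- df[order(df$protein1, df$protein2), , drop = FALSE]
  write_tsv_provenance(df, path, config_hash, rng_seed)
}

#' Read an identifier alias table
#'
#' @param x a two-column data.frame (`from`, `to`) or a TSV path.
#' @return a named character vector mapping raw ids to normalized ids.
#' @export
read_alias_table <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.delim(x, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  }
  stats::setNames(as.character(x[[2]]), as.character(x[[1]]))
}

apply_aliases <- function(ids, aliases) {
  hit <- ids %in% names(aliases)
  if (any(!hit) && any(hit)) {
    # unmatched ids are kept under their raw id, never dropped
    miss <- unique(ids[!hit])
    if (length(miss) > 0)
      message(sprintf("alias table: %d id(s) kept unmapped (e.g. %s)",
                      length(miss), miss[1]))
  }
  ids[hit] <- unname(aliases[ids[hit]])
  ids
}
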