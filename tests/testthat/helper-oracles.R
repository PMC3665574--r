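# Independent oracles used by the test suite.  These deliberately avoid the
# package's own code paths (and igraph), so they can cross-check them.

# Floyd-Warshall all-pairs shortest paths on an edge list (plain matrix
# dynamic programming; O(n^3)).
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes); j <- match(edges$to[r], nodes)
    w <- edges$weight[r]
    if (w < D[i, j]) { D[i, j] <- w; D[j, i] <- w }
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# Random connected weighted graph as an edge list (spanning tree + extras).
random_connected_graph <- function(n, extra = n, weight_range = c(0.5, 3)) {
  nodes <- sprintf("n%02d", seq_len(n))
  from <- integer(0); to <- integer(0)
  for (v in 2:n) {  # random spanning tree: attach each node to an earlier one
    from <- c(from, sample(v - 1, 1)); to <- c(to, v)
  }
  for (e in seq_len(extra)) {
    pair <- sample(n, 2)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b))
  data.frame(from = nodes[a[keep]], to = nodes[b[keep]],
             weight = round(runif(sum(keep), weight_range[1],
                                  weight_range[2]), 3))
}

edges_to_ppi <- function(nodes, edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  ppi_network(g)
}

# Reference Welch t via the textbook formula written independently (checked
# once against stats::t.test in the suite).
ref_welch_t <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(sum((x - mean(x))^2) / (length(x) - 1) / length(x) +
           sum((y - mean(y))^2) / (length(y) - 1) / length(y))
}

# Exhaustive hypergeometric tail: enumerate all subsets of size n from a
# universe of N with the first K elements marked, count overlap >= k.
enum_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}

# Brute-force coevolution scores from raw symbols (independent of the
# package's encoded-matrix fast paths).
brute_mi <- function(chars, i, j) {
  a <- chars[, i]; b <- chars[, j]
  ok <- a != "-" & b != "-"
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  s <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0)
      s <- s + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  s
}

brute_omes <- function(chars, i, j) {
  a <- chars[, i]; b <- chars[, j]
  ok <- a != "-" & b != "-"
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  s <- 0
  for (x in unique(a)) for (y in unique(b)) {
    obs <- sum(a == x & b == y)
    exp <- sum(a == x) * sum(b == y) / n
    s <- s + (obs - exp)^2
  }
  # cells with zero observed but nonzero expected still contribute; the
  # loop above misses (x, y) combos absent from both columns' observed
  # pairs only when obs = 0 AND exp = 0, which contribute 0 anyway -- but
  # combos where x occurs and y occurs are covered by unique() products.
  s / n
}

brute_conservation <- function(chars, col) {
  a <- chars[, col]
  a <- a[a != "-"]
  f <- table(a) / length(a)
  1 - (-sum(f * log(f))) / log(20)
}

# Random small MSA as a character matrix (for brute-force comparisons).
random_msa_chars <- function(n_seqs, n_cols, alphabet = c("A", "C", "D", "E"),
                             gap_prob = 0) {
  m <- matrix(sample(alphabet, n_seqs * n_cols, replace = TRUE),
              n_seqs, n_cols)
  if (gap_prob > 0)
    m[matrix(runif(n_seqs * n_cols) < gap_prob, n_seqs)] <- "-"
  m
}

chars_to_msa <- function(chars) {
  seqs <- apply(chars, 1, paste, collapse = "")
  names(seqs) <- sprintf("s%03d", seq_len(nrow(chars)))
  msa(seqs)
}
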