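# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' perturb the caller's RNG stream.  A `NULL` seed evaluates in the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label,
# so per-seed-gene background draws come from independent substreams.
derive_seed <- function(master, label) {
  if (is.null(master)) return(NULL)
  h <- 0
  for (ch in utf8ToInt(paste0(label))) h <- (h * 31 + ch) %% 2147480000
  as.integer((as.numeric(master) * 7919 + h) %% 2147480000) + 1L
}

# Largest-remainder (Hamilton) apportionment of `total` into categories with
# target quotas proportional to `weights`, honouring per-category caps.
largest_remainder <- function(weights, total, cap = Inf) {
  k <- length(weights)
  cap <- rep_len(cap, k)
  if (total == 0 || sum(weights) == 0) return(integer(k))
  quota <- total * weights / sum(weights)
  alloc <- pmin(floor(quota), cap)
  frac <- quota - floor(quota)
  # distribute the remainder by descending fractional part, skipping
  # saturated categories; ties broken by category index for determinism
  ord <- order(-frac, seq_len(k))
  rem <- total - sum(alloc)
  pass <- 0
  while (rem > 0 && pass < k + 1) {
    for (j in ord) {
      if (rem == 0) break
      if (alloc[j] < cap[j]) {
        alloc[j] <- alloc[j] + 1
        rem <- rem - 1
      }
    }
    pass <- pass + 1
  }
  as.integer(alloc)
}

# Lexicographic comparison of two character vectors (element-wise, then
# length).  Returns TRUE if a < b.
lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# Provenance header lines (tab-delimited outputs).  Deliberately free of
# timestamps so identical runs are byte-identical.
provenance_header <- function(config_hash = "none", rng_seed = "none") {
  c(sprintf("# mssnet %s", as.character(utils::packageVersion("mssnet"))),
    sprintf("# config_hash: %s", config_hash),
    sprintf("# rng_seed: %s", rng_seed))
}

# Write a data.frame as TSV with provenance header comments.
write_tsv_provenance <- function(df, path, config_hash = "none",
                                 rng_seed = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config_hash, rng_seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stop_mssnet <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_mssnet <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
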