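#' Multiple sequence alignment container
#'
#' Holds aligned amino-acid sequences as a character matrix over the 20
#' standard residues plus the gap symbol `-` (dots and unknown codes are
#' normalized to gaps at load), a designated reference sequence, and the
#' mapping from alignment columns to reference residue numbers.
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths).
#' @param reference id of the reference sequence (default: first).
#' @return object of class `msa`: list with `ids`, `matrix` (sequences x
#'   columns, characters), `encoded` (integer matrix, 1..20 for residues,
#'   0 for gap), `reference`, `ncol`, and `ref_map` (named integer vector:
#'   alignment column -> reference residue number for non-gap reference
#'   columns).
#' @export
msa <- function(sequences, reference = NULL) {
  if (length(sequences) < 1) stop_mssnet("empty alignment")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop_mssnet("sequences must be named")
  L <- unique(nchar(sequences))
  if (length(L) != 1)
    stop_mssnet("aligned sequences must all have the same length")
  if (is.null(reference)) reference <- names(sequences)[1]
  if (!(reference %in% names(sequences)))
    stop_mssnet("reference sequence '%s' not present", reference)
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  mat[mat == "."] <- "-"
  mat[!(mat %in% c(AA_ALPHABET, "-"))] <- "-"
  enc <- matrix(match(mat, AA_ALPHABET, nomatch = 0L), nrow(mat), ncol(mat),
                dimnames = dimnames(mat))
  refrow <- mat[reference, ]
  nz <- which(refrow != "-")
  structure(list(ids = names(sequences), matrix = mat, encoded = enc,
                 reference = reference, ncol = L,
                 ref_map = stats::setNames(seq_along(nz), as.character(nz))),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (reference %s)\n",
              length(x$ids), x$ncol, x$reference))
  invisible(x)
}

#' Read an MSA from aligned FASTA
#'
#' @param path FASTA path (aligned amino-acid sequences).
#' @param reference reference sequence id (default: first record).
#' @return an [msa].
#' @export
read_msa <- function(path, reference = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(aa),
                          sub("\\s.*$", "", names(aa)))
  msa(seqs, reference = reference)
}

#' Write an MSA to FASTA
#' @param x an [msa].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_msa <- function(x, path) {
  seqs <- apply(x$matrix, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Map a reference residue number to its alignment column
#'
#' @param x an [msa].
#' @param position residue number in the ungapped reference sequence.
#' @param ref_aa optional expected residue; a mismatch with the reference
#'   sequence is a hard error (it means the mutation and the alignment
#'   disagree).
#' @return alignment column index (1-based).
#' @export
reference_column <- function(x, position, ref_aa = NULL) {
  cols <- as.integer(names(x$ref_map))
  hit <- cols[x$ref_map == position]
  if (length(hit) != 1)
    stop_mssnet("reference position %d not covered by the alignment",
                position)
  if (!is.null(ref_aa)) {
    found <- x$matrix[x$reference, hit]
    if (found != toupper(ref_aa))
      stop_mssnet(
        "reference residue mismatch at position %d: alignment has %s, mutation says %s",
        position, found, ref_aa)
  }
  hit
}

#' Greedy redundancy removal at a sequence-identity threshold
#'
#' Longest-first greedy clustering (CD-HIT-style): sequences are visited in
#' decreasing ungapped length (the reference first, so it is always
#' retained); a sequence joins the first existing cluster whose
#' representative it matches at or above the identity threshold, otherwise
#' it founds a new cluster.  Pairwise identity is matches divided by
#' aligned columns where both sequences are non-gapped.
#'
#' @param x an [msa].
#' @param identity_threshold default 0.90.
#' @return an [msa] containing the cluster representatives.
#' @export
remove_redundancy <- function(x, identity_threshold = 0.90) {
  stopifnot(inherits(x, "msa"))
  n <- length(x$ids)
  if (n == 1) return(x)
  ungapped <- rowSums(x$matrix != "-")
  ord <- order(-ungapped, seq_len(n))
  ord <- c(which(x$ids == x$reference), setdiff(ord, which(x$ids == x$reference)))
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      both <- x$matrix[i, ] != "-" & x$matrix[r, ] != "-"
      ident <- if (any(both))
        sum(x$matrix[i, both] == x$matrix[r, both]) / sum(both) else 0
      if (ident >= identity_threshold) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, i)
  }
  reps <- sort(reps)
  seqs <- apply(x$matrix[reps, , drop = FALSE], 1, paste, collapse = "")
  msa(stats::setNames(seqs, x$ids[reps]), reference = x$reference)
}

#' Column gap mask
#'
#' @param x an [msa].
#' @param max_gap_fraction columns with a larger gap fraction are masked
#'   (default 0.5).
#' @return logical vector, `TRUE` = column usable.
#' @export
gap_mask <- function(x, max_gap_fraction = 0.5) {
  colMeans(x$encoded == 0L) <= max_gap_fraction
}

# Joint residue counts for a column pair, restricted to sequences
# non-gapped at both columns.  Returns a 20x20 count matrix (rows = column
# i's residue, cols = column j's) plus the marginal counts.
pair_counts <- function(x, i, j) {
  ci <- x$encoded[, i]; cj <- x$encoded[, j]
  ok <- ci > 0L & cj > 0L
  ci <- ci[ok]; cj <- cj[ok]
  joint <- matrix(tabulate((ci - 1L) * 20L + cj, nbins = 400L), 20, 20,
                  byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  list(joint = joint, ni = rowSums(joint), nj = colSums(joint),
       n = length(ci))
}

#' Mutual information between two alignment columns
#'
#' `MI = sum p(x,y) ln[p(x,y) / (p(x) p(y))]` in nats, with frequencies
#' from the sequences non-gapped at both columns.  Zero for a constant
#' column; symmetric in `(i, j)`.
#'
#' @param x an [msa].
#' @param i,j column indices.
#' @return MI in nats, or `NA` when fewer than 2 usable sequences remain.
#' @export
mutual_information <- function(x, i, j) {
  pc <- pair_counts(x, i, j)
  if (pc$n < 2) return(NA_real_)
  pj <- pc$joint / pc$n
  pi_ <- pc$ni / pc$n
  pj_ <- pc$nj / pc$n
  nz <- which(pj > 0, arr.ind = TRUE)
  sum(pj[nz] * log(pj[nz] / (pi_[nz[, 1]] * pj_[nz[, 2]])))
}

#' Observed-minus-expected-squared covariation (OMES)
#'
#' `OMES = (1/N) sum_xy (N_obs(x,y) - N_exp(x,y))^2` with
#' `N_exp(x,y) = N_i(x) N_j(y) / N`, over the sequences non-gapped at both
#' columns.
#'
#' @inheritParams mutual_information
#' @return the OMES score, or `NA` when fewer than 2 usable sequences.
#' @export
omes <- function(x, i, j) {
  pc <- pair_counts(x, i, j)
  if (pc$n < 2) return(NA_real_)
  expected <- outer(pc$ni, pc$nj) / pc$n
  sum((pc$joint - expected)^2) / pc$n
}

#' Column conservation score and the ConservationSum pair score
#'
#' Per-column conservation is `c = 1 - H / ln 20` with `H` the Shannon
#' entropy (nats) of the column's residue frequencies, gaps excluded; the
#' pair score is simply `c(i) + c(j)`, so highly conserved column pairs
#' score high regardless of their joint distribution.
#'
#' @inheritParams mutual_information
#' @return the pair score `c(i) + c(j)`, or `NA` when either column has
#'   fewer than 2 residues.
#' @export
conservation_sum <- function(x, i, j) {
  ci <- column_conservation(x, i)
  cj <- column_conservation(x, j)
  if (is.na(ci) || is.na(cj)) return(NA_real_)
  ci + cj
}

#' @rdname conservation_sum
#' @param col column index.
#' @export
column_conservation <- function(x, col) {
  cnt <- tabulate(x$encoded[, col][x$encoded[, col] > 0L], nbins = 20L)
  n <- sum(cnt)
  if (n < 2) return(NA_real_)
  f <- cnt[cnt > 0] / n
  1 - (-sum(f * log(f))) / log(20)
}

# Sequences carrying the most frequent residue at column i (the
# perturbation subalignment of SCA/ELSC).  Ties on the top count break
# alphabetically.  Returns NULL when the subalignment is degenerate
# (fully conserved column, or below min_subset).
perturbation_subset <- function(x, i, min_subset = 5) {
  col <- x$encoded[, i]
  cnt <- tabulate(col[col > 0L], nbins = 20L)
  if (sum(cnt) == 0) return(NULL)
  top <- which(cnt == max(cnt))[1]  # alphabetical tie-break (encoded order)
  rows <- which(col == top)
  if (length(rows) < min_subset) return(NULL)
  if (length(rows) == nrow(x$encoded)) return(NULL)  # no perturbation
  if (length(rows) == sum(col > 0L) && all(col > 0L)) return(NULL)
  rows
}

#' Statistical coupling analysis (SCA) perturbation score
#'
#' Perturbation-style SCA: the subalignment keeps the sequences carrying
#' the most frequent residue at column `i`; the score is the
#' root-sum-square over residue types of the regularized log-ratio
#' `kT* ln((f_sub(x) + 1) / (f_full(x) + 1))` at column `j`, with `f` the
#' residue frequency and `kT* = 1` (the statistical-energy unit).  The
#' unit pseudocount on the frequencies keeps every term finite and, being
#' sample-size free, makes the score exactly zero whenever column `j` has
#' identical composition in the subalignment and the full alignment;
#' masked (`NA`) when column `i` is fully conserved or the subalignment is
#' smaller than `min_subset`.
#'
#' @inheritParams mutual_information
#' @param min_subset smallest allowed subalignment (default 5).
#' @param kT statistical-energy scale constant (default 1).
#' @return the SCA score for perturbation at `i` observed at `j`, or `NA`.
#' @export
sca_perturbation <- function(x, i, j, min_subset = 5, kT = 1) {
  rows <- perturbation_subset(x, i, min_subset)
  if (is.null(rows)) return(NA_real_)
  cj <- x$encoded[, j]
  full <- cj[cj > 0L]
  sub <- cj[rows][cj[rows] > 0L]
  if (length(sub) < 1 || length(full) < 1) return(NA_real_)
  f_full <- tabulate(full, nbins = 20L) / length(full)
  f_sub <- tabulate(sub, nbins = 20L) / length(sub)
  sqrt(sum((kT * log((f_sub + 1) / (f_full + 1)))^2))
}

#' Explicit likelihood of subset covariation (ELSC)
#'
#' Uses the same perturbation subalignment as [sca_perturbation()].  With
#' `N_y` the count of residue `y` at column `j` in the full alignment and
#' `n_y` its count in the subalignment, the score is
#' `-ln prod_y [ C(N_y, n_y) / C(N_y, m_y) ]`, where `m_y` is the
#' composition an unbiased draw of the same subset size would give
#' (largest-remainder rounding of the proportional allocation, capped at
#' `N_y`).  Zero when the subset composition is exactly proportional;
#' larger scores mean the observed subset composition is less likely under
#' unbiased sampling.
#'
#' @inheritParams sca_perturbation
#' @return the ELSC score, or `NA` when masked.
#' @export
elsc <- function(x, i, j, min_subset = 5) {
  rows <- perturbation_subset(x, i, min_subset)
  if (is.null(rows)) return(NA_real_)
  cj <- x$encoded[, j]
  full_ok <- cj > 0L
  Ny <- tabulate(cj[full_ok], nbins = 20L)
  sub_ok <- intersect(rows, which(full_ok))
  ny <- tabulate(cj[sub_ok], nbins = 20L)
  n_sub <- sum(ny)
  if (n_sub < 1) return(NA_real_)
  my <- largest_remainder(Ny, n_sub, cap = Ny)
  sum(lchoose(Ny, my) - lchoose(Ny, ny))
}

#' Compute one method's full coupling matrix
#'
#' Scores every unordered pair of unmasked columns with one of the five
#' covariation methods and returns a symmetric matrix.  The perturbation
#' methods (SCA, ELSC) are directional; their matrix entry is the mean of
#' the two directed scores (or the single defined one), which preserves
#' the symmetry contract of the container.
#'
#' @param x an [msa].
#' @param method one of `"MI"`, `"OMES"`, `"SCA"`, `"ELSC"`,
#'   `"ConservationSum"`.
#' @param max_gap_fraction column gap mask threshold (default 0.5).
#' @param min_subset SCA/ELSC smallest subalignment (default 5).
#' @return object of class `coupling_matrix`: list with `method`, `scores`
#'   (L x L symmetric, `NA` diagonal and masked entries) and `mask`
#'   (logical, usable columns).
#' @export
coupling_matrix <- function(x, method = c("MI", "OMES", "SCA", "ELSC",
                                          "ConservationSum"),
                            max_gap_fraction = 0.5, min_subset = 5) {
  method <- match.arg(method)
  L <- x$ncol
  mask <- gap_mask(x, max_gap_fraction)
  S <- matrix(NA_real_, L, L)
  cols <- which(mask)
  if (method == "ConservationSum") {
    cons <- rep(NA_real_, L)
    cons[cols] <- vapply(cols, function(cc) column_conservation(x, cc), 0)
    for (a in seq_along(cols)) for (b in seq_len(a - 1)) {
      i <- cols[a]; j <- cols[b]
      v <- if (is.na(cons[i]) || is.na(cons[j])) NA_real_ else cons[i] + cons[j]
      S[i, j] <- v; S[j, i] <- v
    }
  } else if (method %in% c("MI", "OMES")) {
    fun <- if (method == "MI") mutual_information else omes
    for (a in seq_along(cols)) for (b in seq_len(a - 1)) {
      i <- cols[a]; j <- cols[b]
      v <- fun(x, i, j)
      S[i, j] <- v; S[j, i] <- v
    }
  } else {
    fun <- if (method == "SCA") {
      function(i, j) sca_perturbation(x, i, j, min_subset = min_subset)
    } else {
      function(i, j) elsc(x, i, j, min_subset = min_subset)
    }
    subsets <- lapply(seq_len(L), function(i)
      if (mask[i]) perturbation_subset(x, i, min_subset) else NULL)
    for (a in seq_along(cols)) for (b in seq_len(a - 1)) {
      i <- cols[a]; j <- cols[b]
      sij <- if (!is.null(subsets[[i]])) fun(i, j) else NA_real_
      sji <- if (!is.null(subsets[[j]])) fun(j, i) else NA_real_
      v <- mean(c(sij, sji), na.rm = TRUE)
      if (is.nan(v)) v <- NA_real_
      S[i, j] <- v; S[j, i] <- v
    }
  }
  structure(list(method = method, scores = S, mask = mask),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: %s, %d columns (%d masked)\n",
              x$method, ncol(x$scores), sum(!x$mask)))
  invisible(x)
}

#' Consensus coevolution calls at a mutated column
#'
#' Per method, a partner column `j` is flagged for the mutated column when
#' its score is at or above the method's `flag_quantile` over all valid
#' column pairs (each method is thresholded on its own score
#' distribution).  The consensus keeps the columns flagged by at least two
#' distinct methods.
#'
#' @param matrices list of [coupling_matrix] objects from the same MSA.
#' @param mutated_column alignment column index of the mutation.
#' @param flag_quantile per-method flagging quantile (default 0.95).
#' @param msa_obj optional [msa]; when given, reference residue numbers
#'   are attached.
#' @return object of class `consensus_couplings`: data.frame `couplings`
#'   (`column`, `ref_residue`, `n_methods`, `methods`), plus
#'   `mutated_column`, `flag_quantile` and per-method thresholds.
#' @export
consensus_couplings <- function(matrices, mutated_column,
                                flag_quantile = 0.95, msa_obj = NULL) {
  stopifnot(length(matrices) >= 2)
  L <- ncol(matrices[[1]]$scores)
  for (m in matrices) {
    if (ncol(m$scores) != L)
      stop_mssnet("coupling matrices disagree on column count")
    if (!m$mask[mutated_column])
      stop_mssnet("mutated column %d is masked for method %s (gap content)",
                  mutated_column, m$method)
  }
  methods <- vapply(matrices, function(m) m$method, "")
  flags <- matrix(FALSE, L, length(matrices),
                  dimnames = list(NULL, methods))
  thresholds <- stats::setNames(numeric(length(matrices)), methods)
  for (k in seq_along(matrices)) {
    S <- matrices[[k]]$scores
    vals <- S[upper.tri(S)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) next
    thr <- stats::quantile(vals, flag_quantile, names = FALSE, type = 7)
    thresholds[k] <- thr
    row <- S[mutated_column, ]
    flags[, k] <- !is.na(row) & row >= thr
  }
  n_methods <- rowSums(flags)
  hit <- which(n_methods >= 2)
  support <- vapply(hit, function(j)
    paste(methods[flags[j, ]], collapse = ","), "")
  ref_res <- rep(NA_integer_, length(hit))
  if (!is.null(msa_obj)) {
    rm_cols <- as.integer(names(msa_obj$ref_map))
    idx <- match(hit, rm_cols)
    ref_res <- ifelse(is.na(idx), NA_integer_,
                      as.integer(msa_obj$ref_map[idx]))
  }
  df <- data.frame(column = hit, ref_residue = ref_res,
                   n_methods = as.integer(n_methods[hit]),
                   methods = support, stringsAsFactors = FALSE,
                   row.names = NULL)
  structure(list(couplings = df, mutated_column = mutated_column,
                 flag_quantile = flag_quantile, thresholds = thresholds),
            class = "consensus_couplings")
}

#' @export
print.consensus_couplings <- function(x, ...) {
  cat(sprintf(
    "consensus_couplings: column %d, %d partner(s) supported by >= 2 of %d methods\n",
    x$mutated_column, nrow(x$couplings), length(x$thresholds)))
  if (nrow(x$couplings) > 0) print(x$couplings)
  invisible(x)
}

#' Full coevolution consensus for one mutation
#'
#' End-to-end molecular-scale analysis: removes redundant sequences at the
#' identity threshold, computes all five coupling matrices, maps the
#' mutation to its alignment column (validating the reference residue) and
#' returns the >= 2-method consensus.
#'
#' @param msa_obj an [msa].
#' @param substitution substitution token, e.g. `"S55N"` (numbering on the
#'   ungapped reference sequence).
#' @param identity_threshold redundancy-removal identity (default 0.90).
#' @param flag_quantile per-method flagging quantile (default 0.95).
#' @param max_gap_fraction column gap mask (default 0.5).
#' @return list with `consensus` ([consensus_couplings]), `matrices` (the
#'   five [coupling_matrix] objects), `msa` (the filtered alignment) and
#'   `mutated_column`.
#' @export
coevolve <- function(msa_obj, substitution, identity_threshold = 0.90,
                     flag_quantile = 0.95, max_gap_fraction = 0.5) {
  sub <- parse_substitution(substitution)
  filtered <- remove_redundancy(msa_obj, identity_threshold)
  col <- reference_column(filtered, sub$pos, ref_aa = sub$ref)
  mats <- lapply(c("MI", "OMES", "SCA", "ELSC", "ConservationSum"),
                 function(m) coupling_matrix(filtered, m,
                                             max_gap_fraction = max_gap_fraction))
  cons <- consensus_couplings(mats, col, flag_quantile, msa_obj = filtered)
  list(consensus = cons, matrices = mats, msa = filtered,
       mutated_column = col)
}
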