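#' Synthetic PPI network with planted modules
#'
#' Scale-free backbone by preferential attachment (the first
#' `attachment_m` nodes form a clique; each later node attaches to
#' `attachment_m` distinct existing nodes with probability proportional to
#' degree), guaranteeing a connected graph with exactly
#' `m (n - m) + choose(m, 2)` backbone edges.  Dense modules are overlaid
#' by connecting each within-module pair with the module's
#' `internal_edge_prob`.  All edges have unit weight.
#'
#' @param n_nodes number of genes.
#' @param attachment_m edges per new node (>= 1).
#' @param modules list of module specs, each a list/vector with `size` and
#'   `internal_edge_prob` (optionally `members`, a fixed id vector);
#'   members are sampled disjointly when not given.
#' @param rng_seed integer seed.
#' @return list with `network` (a [ppi_network]) and `truth` (module
#'   memberships and generator parameters).
#' @export
generate_network <- function(n_nodes, attachment_m = 2, modules = list(),
                             rng_seed = 1) {
  if (attachment_m < 1)
    stop_mssnet("attachment_m must be >= 1 (backbone would be disconnected)")
  if (n_nodes <= attachment_m) stop_mssnet("n_nodes must exceed attachment_m")
  sizes <- vapply(modules, function(m) as.integer(m$size), 0L)
  if (sum(sizes) > n_nodes)
    stop_mssnet("module sizes exceed n_nodes")
  with_seed(rng_seed, {
    ids <- sprintf("g%04d", seq_len(n_nodes))
    deg <- integer(n_nodes)
    from <- integer(0); to <- integer(0)
    m <- attachment_m
    if (m > 1) {
      clique <- utils::combn(seq_len(m), 2)
      from <- clique[1, ]; to <- clique[2, ]
      deg[seq_len(m)] <- m - 1
    }
    for (v in seq(m + 1, n_nodes)) {
      existing <- seq_len(v - 1)
      prob <- deg[existing]
      if (all(prob == 0)) prob <- rep(1, length(existing))
      att <- sample(existing, m, prob = prob)
      from <- c(from, att); to <- c(to, rep(v, m))
      deg[att] <- deg[att] + 1L
      deg[v] <- m
    }
    # overlay planted dense modules
    taken <- character(0)
    module_members <- list()
    for (k in seq_along(modules)) {
      spec <- modules[[k]]
      if (!is.null(spec$members)) {
        mem <- as.character(spec$members)
      } else {
        mem <- sample(setdiff(ids, taken), spec$size)
      }
      taken <- c(taken, mem)
      module_members[[k]] <- sort(mem)
      idx <- match(mem, ids)
      prs <- utils::combn(sort(idx), 2)
      add <- stats::runif(ncol(prs)) < spec$internal_edge_prob
      from <- c(from, prs[1, add]); to <- c(to, prs[2, add])
    }
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(paste(a, b))
    el <- data.frame(from = ids[a[keep]], to = ids[b[keep]], weight = 1)
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = data.frame(name = ids))
    net <- ppi_network(g, metadata = sprintf(
      "synthetic preferential-attachment network (n=%d, m=%d, seed %s)",
      n_nodes, attachment_m, format(rng_seed)))
    truth <- list(kind = "network", n_nodes = n_nodes,
                  attachment_m = attachment_m,
                  modules = module_members,
                  internal_edge_prob = vapply(modules, function(x)
                    as.numeric(x$internal_edge_prob), 0),
                  rng_seed = rng_seed)
    list(network = net, truth = truth)
  })
}

#' Synthetic two-condition expression matrix with planted DE genes
#'
#' Log2 expression values are Normal(mu_gene, sigma) in each arm, with the
#' second arm's mean shifted by `log2(fold_change)` for planted DE genes.
#' Gene baselines mimic microarray log2 intensities (Normal(8, 1.5)).
#' Missing entries are introduced uniformly at random.
#'
#' @param n_genes gene count (ignored when `gene_ids` is given).
#' @param n_per_arm samples per condition.
#' @param de_genes data.frame with columns `gene` and `fold_change`
#'   (linear scale, > 0), or `NULL` for a global null.
#' @param sigma per-arm log2 standard deviation.
#' @param missing_rate fraction of entries set missing (in `[0, 0.5)`).
#' @param rng_seed integer seed.
#' @param gene_ids optional explicit gene ids.
#' @return list with `expression` (an [expression_matrix], log2 scale) and
#'   `truth`.
#' @export
generate_expression <- function(n_genes, n_per_arm, de_genes = NULL,
                                sigma = 0.25, missing_rate = 0,
                                rng_seed = 1, gene_ids = NULL) {
  if (!is.null(de_genes) && any(de_genes$fold_change <= 0))
    stop_mssnet("planted fold changes must be positive")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop_mssnet("missing_rate must be in [0, 0.5)")
  with_seed(rng_seed, {
    if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
    n_genes <- length(gene_ids)
    mu <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
    shift <- rep(0, n_genes)
    if (!is.null(de_genes)) {
      idx <- match(as.character(de_genes$gene), gene_ids)
      if (anyNA(idx)) stop_mssnet("planted DE gene absent from gene_ids")
      shift[idx] <- log2(de_genes$fold_change)
    }
    samples <- c(sprintf("c1_%02d", seq_len(n_per_arm)),
                 sprintf("c2_%02d", seq_len(n_per_arm)))
    vals <- cbind(
      matrix(stats::rnorm(n_genes * n_per_arm, mu, sigma), n_genes),
      matrix(stats::rnorm(n_genes * n_per_arm, mu + shift, sigma), n_genes))
    dimnames(vals) <- list(gene_ids, samples)
    if (missing_rate > 0) {
      drop <- stats::runif(length(vals)) < missing_rate
      # never blank out a full row
      for (r in which(rowSums(matrix(drop, n_genes)) >= ncol(vals)))
        drop[r] <- FALSE
      vals[matrix(drop, n_genes)] <- NA_real_
    }
    design <- data.frame(sample = samples,
                         condition = rep(c("condition1", "condition2"),
                                         each = n_per_arm))
    em <- expression_matrix(vals, design, log2_scale = TRUE)
    truth <- list(kind = "expression", de_genes = de_genes, sigma = sigma,
                  n_per_arm = n_per_arm, missing_rate = missing_rate,
                  rng_seed = rng_seed)
    list(expression = em, truth = truth)
  })
}

#' Synthetic MSA with planted covarying column pairs
#'
#' Background columns are drawn independently per sequence from per-column
#' residue profiles sampled from a symmetric Dirichlet
#' (`profile_concentration` per residue; small values give conserved,
#' low-entropy columns).  For each planted pair `(i, j, coupling)` the
#' residue at `j` is, with probability `coupling`, a deterministic
#' function of the residue at `i` (a fixed alphabet rotation), otherwise
#' drawn from `j`'s own profile.  The first sequence is the gap-free
#' reference.  Several pairs may share a source column `i`; sharing a
#' dependent column `j` (or using one column as both source and dependent)
#' is an error because the plantings would overwrite each other.
#'
#' @param n_seqs,n_cols alignment dimensions.
#' @param planted_pairs data.frame with columns `i`, `j`, `coupling`
#'   (`[0, 1]`), or `NULL`.
#' @param profile_concentration Dirichlet concentration per residue
#'   (default 0.5).
#' @param rng_seed integer seed.
#' @return list with `msa` (an [msa]) and `truth`.
#' @export
generate_msa <- function(n_seqs, n_cols, planted_pairs = NULL,
                         profile_concentration = 0.5, rng_seed = 1) {
  if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
    if (any(planted_pairs$i == planted_pairs$j) ||
        any(planted_pairs$i < 1 | planted_pairs$j < 1 |
            planted_pairs$i > n_cols | planted_pairs$j > n_cols))
      stop_mssnet("planted pairs must have distinct in-range columns")
    if (any(planted_pairs$coupling < 0 | planted_pairs$coupling > 1))
      stop_mssnet("coupling must lie in [0, 1]")
    if (anyDuplicated(planted_pairs$j) ||
        length(intersect(planted_pairs$i, planted_pairs$j)) > 0)
      stop_mssnet("planted pairs may not share a dependent column")
  }
  with_seed(rng_seed, {
    profiles <- matrix(stats::rgamma(20 * n_cols,
                                     shape = profile_concentration), 20)
    profiles <- sweep(profiles, 2, colSums(profiles), "/")
    enc <- matrix(0L, n_seqs, n_cols)
    for (cc in seq_len(n_cols))
      enc[, cc] <- sample.int(20, n_seqs, replace = TRUE,
                              prob = profiles[, cc])
    if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
      for (r in seq_len(nrow(planted_pairs))) {
        i <- planted_pairs$i[r]; j <- planted_pairs$j[r]
        cp <- planted_pairs$coupling[r]
        dep <- stats::runif(n_seqs) < cp
        enc[dep, j] <- (enc[dep, i] %% 20L) + 1L  # fixed alphabet rotation
      }
    }
    chars <- matrix(AA_ALPHABET[enc], n_seqs, n_cols)
    seqs <- apply(chars, 1, paste, collapse = "")
    names(seqs) <- c("reference",
                     sprintf("seq%03d", seq_len(n_seqs - 1)))
    truth <- list(kind = "msa", n_seqs = n_seqs, n_cols = n_cols,
                  planted_pairs = planted_pairs,
                  profile_concentration = profile_concentration,
                  rng_seed = rng_seed)
    list(msa = msa(seqs, reference = "reference"), truth = truth)
  })
}

#' Generate a coherent small benchmark study with planted truth
#'
#' One call builds every input the pipeline consumes, wired so the planted
#' signal propagates end to end:
#' a preferential-attachment network with two planted modules; five driver
#' seed genes, each attached by direct edges to most members of its
#' module; planted DE genes inside the modules (module 1 up-regulated,
#' module 2 down-regulated) realized as a two-arm expression matrix; an
#' annotation map in which each module is one category (plus background
#' categories covering every gene); mutation records for the seeds; and
#' one MSA with planted covarying pairs at the mutated column of the first
#' seed.  Control analyses can draw random non-seed genes.
#'
#' Module members and driver seeds are drawn from peripheral, minimum-degree
#' backbone nodes, and module densities are modest.  This encodes two
#' assumptions: pathway genes are rarely network hubs, and — critically for
#' the statistics — the planted extra edges then restore the targets'
#' centrality to about the network average instead of exceeding it, so the
#' random-source/random-destination background sampling stays calibrated
#' (non-driver genes show "significantly short" paths at about the nominal
#' rate).  The drivers' signal comes solely from their direct wiring to
#' their module's targets.
#'
#' @param rng_seed integer master seed.
#' @param n_nodes network size (default 500).
#' @param module_size genes per module (default 20).
#' @param internal_edge_prob within-module edge probability (default 0.05).
#' @param n_seeds planted driver count (default 5).
#' @param seed_attach_prob probability of a direct seed-to-member edge
#'   (default 0.5).
#' @param n_per_arm expression samples per condition (default 6).
#' @param sigma log2 expression noise sd (default 0.15).
#' @param missing_rate expression missingness (default 0.02).
#' @param fc_up,fc_down planted linear fold changes (2.0, 0.5).
#' @param msa_seqs,msa_cols MSA dimensions (60 x 40).
#' @param msa_coupling planted coupling strength (default 0.9).
#' @return object of class `toy_study`: list with `network`, `expression`,
#'   `annotation`, `mutations`, `msa`, `mutated_column` and `truth`.
#' @export
make_toy_study <- function(rng_seed = 1, n_nodes = 500, module_size = 20,
                           internal_edge_prob = 0.05, n_seeds = 5,
                           seed_attach_prob = 0.5, n_per_arm = 6,
                           sigma = 0.15, missing_rate = 0.02, fc_up = 2,
                           fc_down = 0.5, msa_seqs = 60, msa_cols = 40,
                           msa_coupling = 0.9) {
  gn <- generate_network(n_nodes, attachment_m = 2, modules = list(),
                         rng_seed = derive_seed(rng_seed, "network"))
  net <- gn$network
  with_seed(derive_seed(rng_seed, "wiring"), {
    ids <- network_nodes(net)
    deg <- igraph::degree(net$graph)
    # peripheral pool: minimum-degree nodes from the later 70% of the
    # attachment order (never re-attached to, hence non-hub by construction)
    pool <- ids[deg == 2 & seq_along(ids) > round(0.3 * n_nodes)]
    need <- 2 * module_size + n_seeds
    if (length(pool) < need) pool <- ids[order(deg)][seq_len(need * 2)]
    picked <- sample(pool, need)
    mods <- list(sort(picked[seq_len(module_size)]),
                 sort(picked[module_size + seq_len(module_size)]))
    seeds <- sort(picked[2 * module_size + seq_len(n_seeds)])
    seed_module <- rep(c(1L, 2L), length.out = n_seeds)
    g <- net$graph
    for (mem in mods) {
      prs <- utils::combn(mem, 2)
      add <- stats::runif(ncol(prs)) < internal_edge_prob
      if (any(add))
        g <- igraph::add_edges(g,
                               as.vector(rbind(prs[1, add], prs[2, add])),
                               attr = list(weight = 1))
    }
    for (k in seq_len(n_seeds)) {
      mem <- mods[[seed_module[k]]]
      att <- mem[stats::runif(length(mem)) < seed_attach_prob]
      if (length(att) == 0) att <- mem[1]
      g <- igraph::add_edges(g, as.vector(rbind(seeds[k], att)),
                             attr = list(weight = 1))
    }
    g <- igraph::simplify(g, edge.attr.comb = "first")
    net <- ppi_network(g, metadata = net$metadata)
  })
  de_truth <- data.frame(
    gene = c(mods[[1]], mods[[2]]),
    fold_change = c(rep(fc_up, length(mods[[1]])),
                    rep(fc_down, length(mods[[2]]))))
  ge <- generate_expression(length(network_nodes(net)), n_per_arm,
                            de_genes = de_truth, sigma = sigma,
                            missing_rate = missing_rate,
                            rng_seed = derive_seed(rng_seed, "expression"),
                            gene_ids = network_nodes(net))
  ann <- with_seed(derive_seed(rng_seed, "annotation"), {
    ids <- network_nodes(net)
    bg_terms <- sprintf("BG%02d", 1:8)
    pairs <- data.frame(gene = c(mods[[1]], mods[[2]], ids),
                        term = c(rep("MODULE1", length(mods[[1]])),
                                 rep("MODULE2", length(mods[[2]])),
                                 sample(bg_terms, length(ids),
                                        replace = TRUE)))
    extra <- data.frame(gene = sample(ids, length(ids) %/% 2),
                        term = sample(bg_terms, length(ids) %/% 2,
                                      replace = TRUE))
    annotation_map(rbind(pairs, extra), universe = ids)
  })
  gm <- with_seed(derive_seed(rng_seed, "msa-pairs"), {
    i0 <- sample(5:(msa_cols - 5), 1)
    partners <- sample(setdiff(seq_len(msa_cols), i0), 3)
    generate_msa(msa_seqs, msa_cols,
                 planted_pairs = data.frame(i = i0, j = partners,
                                            coupling = msa_coupling),
                 rng_seed = derive_seed(rng_seed, "msa"))
  })
  i0 <- gm$truth$planted_pairs$i[1]
  ref_aa <- gm$msa$matrix[gm$msa$reference, i0]
  alt <- setdiff(AA_ALPHABET, ref_aa)[1]
  mutations <- data.frame(
    gene = seeds,
    substitution = c(sprintf("%s%d%s", ref_aa, i0, alt),
                     vapply(seq_len(n_seeds - 1), function(k) {
                       sprintf("%s%d%s", AA_ALPHABET[k], k + 10,
                               AA_ALPHABET[k + 1])
                     }, "")),
    accession = NA_character_, stringsAsFactors = FALSE)
  truth <- list(kind = "toy_study", rng_seed = rng_seed,
                seeds = seeds, seed_module = seed_module,
                modules = mods, de_genes = de_truth,
                planted_pairs = gm$truth$planted_pairs,
                params = list(n_nodes = n_nodes, module_size = module_size,
                              internal_edge_prob = internal_edge_prob,
                              seed_attach_prob = seed_attach_prob,
                              n_per_arm = n_per_arm, sigma = sigma,
                              missing_rate = missing_rate, fc_up = fc_up,
                              fc_down = fc_down, msa_seqs = msa_seqs,
                              msa_cols = msa_cols,
                              msa_coupling = msa_coupling))
  structure(list(network = net, expression = ge$expression,
                 annotation = ann, mutations = mutations, msa = gm$msa,
                 mutated_column = i0, truth = truth),
            class = "toy_study")
}

#' @export
print.toy_study <- function(x, ...) {
  cat(sprintf(
    "toy_study: %d-node network, %d planted seeds, %d planted DE genes, MSA %d x %d\n",
    length(network_nodes(x$network)), length(x$truth$seeds),
    nrow(x$truth$de_genes), length(x$msa$ids), x$msa$ncol))
  invisible(x)
}

#' Write a toy study to disk in the pipeline's input formats
#'
#' Emits `network.tsv` (STRING protein-links format, score 900),
#' `expression.tsv` + `design.tsv`, `mutations.tsv`, `annotation.tsv`
#' (tsv2col), `msa.fasta` and `truth.json`.  Every file parses back
#' through the package's readers.
#'
#' @param study a [make_toy_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- igraph::as_data_frame(study$network$graph, what = "edges")
  df <- data.frame(protein1 = pmin(el$from, el$to),
                   protein2 = pmax(el$from, el$to),
                   combined_score = 900L)
  df <- df[order(df$protein1, df$protein2), ]
  utils::write.table(df, file.path(dir, "network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_matrix(study$expression, file.path(dir, "expression.tsv"),
                          file.path(dir, "design.tsv"))
  utils::write.table(study$mutations[, c("gene", "substitution")],
                     file.path(dir, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     na = "")
  utils::write.table(study$annotation$gene2term,
                     file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_msa(study$msa, file.path(dir, "msa.fasta"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a serialized toy-study truth file
#' @param path `truth.json` path.
#' @return the truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
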