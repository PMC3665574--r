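test_that("preferential-attachment backbone has the exact predicted edge count", {
  gn <- generate_network(100, attachment_m = 2, rng_seed = 4)
  g <- gn$network$graph
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::ecount(g), 2 * (100 - 2) + choose(2, 2))  # 197
  expect_true(igraph::is_connected(g))
  expect_error(generate_network(100, attachment_m = 0), "disconnected")
})

test_that("planted modules at probability one induce cliques", {
  gn <- generate_network(60, 2,
                         modules = list(list(size = 10,
                                             internal_edge_prob = 1.0)),
                         rng_seed = 9)
  mem <- gn$truth$modules[[1]]
  sub <- igraph::induced_subgraph(gn$network$graph, mem)
  expect_equal(igraph::ecount(sub), choose(10, 2))
})

test_that("generators are pure functions of their seed", {
  e1 <- igraph::as_data_frame(generate_network(80, 2, rng_seed = 5)$network$graph)
  e2 <- igraph::as_data_frame(generate_network(80, 2, rng_seed = 5)$network$graph)
  expect_identical(e1, e2)
  e3 <- igraph::as_data_frame(generate_network(80, 2, rng_seed = 6)$network$graph)
  expect_false(identical(e1, e3))

  x1 <- generate_expression(50, 4, rng_seed = 3)$expression$values
  x2 <- generate_expression(50, 4, rng_seed = 3)$expression$values
  expect_identical(x1, x2)

  m1 <- generate_msa(20, 10, rng_seed = 8)$msa$matrix
  m2 <- generate_msa(20, 10, rng_seed = 8)$msa$matrix
  expect_identical(m1, m2)

  s1 <- make_toy_study(rng_seed = 2)
  s2 <- make_toy_study(rng_seed = 2)
  expect_identical(igraph::as_data_frame(s1$network$graph),
                   igraph::as_data_frame(s2$network$graph))
  expect_identical(s1$truth$seeds, s2$truth$seeds)
})

test_that("noiseless planted fold changes are realized exactly", {
  de <- data.frame(gene = c("g0001", "g0002"), fold_change = c(2, 0.5))
  ge <- generate_expression(10, 3, de_genes = de, sigma = 1e-12, rng_seed = 1)
  em <- ge$expression
  i1 <- em$design$condition == "condition1"
  fc <- rowMeans(2^em$values[, !i1]) / rowMeans(2^em$values[, i1])
  expect_equal(unname(fc[1:2]), c(2, 0.5), tolerance = 1e-6)
  expect_equal(unname(fc[3]), 1, tolerance = 1e-6)
  expect_false(anyNA(generate_expression(10, 3, missing_rate = 0,
                                         rng_seed = 1)$expression$values))
})

test_that("planted DE detection tracks the Welch-power oracle", {
  # Monte-Carlo power oracle at fc 1.5, sigma 0.25, n 6/arm, Holm over 200
  # genes with 10 planted; compared to the dge module's realized recall
  set.seed(77)
  n_rep <- 60; n_genes <- 200; n_plant <- 10
  oracle_hits <- 0
  for (b in seq_len(n_rep)) {
    p <- vapply(seq_len(n_genes), function(g) {
      eff <- if (g <= n_plant) log2(1.5) else 0
      t.test(rnorm(6, 0, 0.25), rnorm(6, eff, 0.25))$p.value
    }, 0)
    oracle_hits <- oracle_hits + sum(p.adjust(p, "holm")[1:n_plant] < 0.05)
  }
  oracle_power <- oracle_hits / (n_rep * n_plant)

  pkg_hits <- 0
  for (b in seq_len(n_rep)) {
    de_truth <- data.frame(gene = sprintf("g%04d", 1:n_plant),
                           fold_change = 1.5)
    ge <- generate_expression(n_genes, 6, de_genes = de_truth, sigma = 0.25,
                              rng_seed = 5000 + b)
    de <- call_de_genes(two_class_ttest(ge$expression))
    pkg_hits <- pkg_hits + sum(de_truth$gene %in% de$up)
  }
  pkg_power <- pkg_hits / (n_rep * n_plant)
  se <- sqrt(oracle_power * (1 - oracle_power) / (n_rep * n_plant))
  expect_lt(abs(pkg_power - oracle_power), 3 * se + 1e-9)
})

test_that("planted MSA pairs hit closed-form MI at full coupling and vanish at zero", {
  pp <- data.frame(i = 3, j = 8, coupling = 1.0)
  gm <- generate_msa(150, 10, planted_pairs = pp, rng_seed = 12)
  m <- gm$msa
  # deterministic dependence: MI equals the entropy of column i's realized
  # distribution (direct count)
  cnt <- table(m$matrix[, 3])
  f <- cnt / sum(cnt)
  expect_equal(mutual_information(m, 3, 8), -sum(f * log(f)),
               tolerance = 1e-10)

  # coupling 0: planted pair MI within the background range
  bg_mi <- c(); planted_mi <- c()
  for (b in 1:20) {
    gm0 <- generate_msa(80, 10, planted_pairs = transform(pp, coupling = 0),
                        rng_seed = 100 + b)
    planted_mi <- c(planted_mi, mutual_information(gm0$msa, 3, 8))
    bg_mi <- c(bg_mi, mutual_information(gm0$msa, 2, 6))
  }
  expect_lt(max(planted_mi), quantile(bg_mi, 0.99) + diff(range(bg_mi)))
  expect_error(generate_msa(10, 8,
                            data.frame(i = c(1, 2), j = c(4, 4),
                                       coupling = 0.5)),
               "dependent column")
})

test_that("toy study files parse back cleanly and truth round-trips", {
  study <- make_toy_study(rng_seed = 3)
  dir <- withr::local_tempdir()
  expect_no_warning(write_toy_study(study, dir))
  expect_no_warning({
    net <- read_string_links(file.path(dir, "network.tsv"))
    em <- read_expression_matrix(file.path(dir, "expression.tsv"),
                                 file.path(dir, "design.tsv"))
    muts <- read_gene_list(file.path(dir, "mutations.tsv"))
    ann <- read_annotation_map(file.path(dir, "annotation.tsv"))
    m <- read_msa(file.path(dir, "msa.fasta"))
  })
  expect_setequal(network_nodes(net), network_nodes(study$network))
  expect_equal(igraph::ecount(net$graph), igraph::ecount(study$network$graph))
  expect_equal(muts$gene, study$mutations$gene)
  expect_identical(m$matrix, study$msa$matrix)
  truth <- read_truth(file.path(dir, "truth.json"))
  expect_equal(truth$seeds, study$truth$seeds)
  expect_equal(truth$de_genes$gene, study$truth$de_genes$gene)
})
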