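test_that("shortest distances follow weights, not hop counts", {
  edges <- data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                      weight = c(1, 1, 3))
  net <- edges_to_ppi(c("a", "b", "c"), edges)
  d <- shortest_distances(net, "a", c("b", "c"))
  expect_equal(unname(d["c"]), 2)  # via b, cheaper than the direct 3-edge

  path <- data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 1))
  net <- edges_to_ppi(c("a", "b", "c"), path)
  expect_equal(unname(shortest_distances(net, "a", "c")["c"]), 2)

  two_comp <- data.frame(from = "a", to = "b", weight = 1)
  net <- edges_to_ppi(c("a", "b", "x"), two_comp)
  expect_equal(unname(shortest_distances(net, "a", "x")["x"]), Inf)
  expect_error(shortest_distances(net, "zz", "a"), "zz")
})

test_that("Dijkstra agrees exactly with Floyd-Warshall on random graphs", {
  set.seed(101)
  for (g in 1:100) {
    n <- sample(5:50, 1)
    edges <- random_connected_graph(n)
    nodes <- sprintf("n%02d", seq_len(n))
    net <- edges_to_ppi(nodes, edges)
    ref <- fw_distances(nodes, edges)
    src <- sample(nodes, 1)
    d <- shortest_distances(net, src, nodes)
    expect_equal(d[nodes], ref[src, nodes], tolerance = 1e-12)
  }
})

test_that("MSSN construction retains deterministic lexicographic shortest paths", {
  # star: seed adjacent to all three targets
  edges <- data.frame(from = "s", to = c("t1", "t2", "t3"), weight = 1)
  net <- edges_to_ppi(c("s", "t1", "t2", "t3"), edges)
  m <- build_mssn(net, "s", c("t1", "t2", "t3"), "up")
  expect_equal(unname(sort(m$distances)), c(1, 1, 1))
  expect_setequal(m$nodes, c("s", "t1", "t2", "t3"))
  expect_equal(nrow(m$edges), 3)

  # 8-node fixture: one 2-hop target (via a tie) and one 3-hop target;
  # hand-traced union given the lexicographic tie-break s-a-t1 over s-b-t1
  edges <- data.frame(
    from = c("s", "s", "a", "b", "s", "c", "d", "x"),
    to   = c("a", "b", "t1", "t1", "c", "d", "t2", "t2"),
    weight = 1)
  net <- edges_to_ppi(c("s", "a", "b", "c", "d", "t1", "t2", "x"), edges)
  m <- build_mssn(net, "s", c("t1", "t2"), "down")
  expect_equal(unname(m$distances[c("t1", "t2")]), c(2, 3))
  expect_setequal(m$nodes, c("s", "a", "t1", "c", "d", "t2"))
  expect_false("b" %in% m$nodes)  # lexicographic tie-break picked a

  expect_error(build_mssn(net, "s", c("zz1", "zz2"), "up"), "up")
})

test_that("unreachable targets are flagged, not fatal", {
  edges <- data.frame(from = "s", to = "t1", weight = 1)
  net <- edges_to_ppi(c("s", "t1", "island"), edges)
  m <- build_mssn(net, "s", c("t1", "island"))
  expect_equal(m$n_unreachable, 1)
  expect_equal(names(m$distances), "t1")
})

test_that("background sampling matches the exact all-pairs expectation", {
  # complete graph: every background distance is 1
  k5 <- utils::combn(sprintf("v%d", 1:5), 2)
  edges <- data.frame(from = k5[1, ], to = k5[2, ], weight = 1)
  net <- edges_to_ppi(sprintf("v%d", 1:5), edges)
  bg <- background_distances(net, n_targets = 2, n_replicates = 10,
                             rng_seed = 1)
  expect_true(all(bg$pooled == 1))

  # determinism under a fixed seed
  bg2 <- background_distances(net, n_targets = 2, n_replicates = 10,
                              rng_seed = 1)
  expect_identical(bg, bg2)

  # path graph of 5 nodes: mean pooled distance approaches the average of
  # d(u, v) over all ordered pairs (exact oracle), within 3 SE
  nodes <- sprintf("p%d", 1:5)
  edges <- data.frame(from = nodes[1:4], to = nodes[2:5], weight = 1)
  net <- edges_to_ppi(nodes, edges)
  D <- fw_distances(nodes, edges)
  exact <- mean(D[row(D) != col(D)])
  bg <- background_distances(net, n_targets = 1, n_replicates = 1e4,
                             rng_seed = 7)
  se <- sd(bg$pooled) / sqrt(length(bg$pooled))
  expect_lt(abs(mean(bg$pooled) - exact), 3 * se)

  expect_error(background_distances(net, 1, n_replicates = 1), ">= 2")
})

test_that("welch_t reproduces the printed formula with the shorter-is-positive sign", {
  st <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(st$t, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$n_bg, 3); expect_equal(st$n_mssn, 3)
  expect_equal(st$var_bg, 1); expect_equal(st$var_mssn, 1)

  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # antisymmetry under sample swap
  expect_equal(welch_t(c(1, 2, 3), c(4, 5, 6))$t, -st$t)
  expect_error(welch_t(c(1, 2), 3), ">= 2")
})

test_that("welch_t matches an independent reference on 1000 random pairs", {
  set.seed(202)
  for (i in 1:1000) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    t_pkg <- welch_t(x, y)$t
    expect_equal(t_pkg, ref_welch_t(x, y), tolerance = 1e-10)
  }
  # the hand formula itself agrees with stats::t.test once
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(ref_welch_t(x, y),
               unname(t.test(x, y, var.equal = FALSE)$statistic),
               tolerance = 1e-12)
})

test_that("empirical p and z derive from the replicate-mean null", {
  rm <- c(2, 3, 4, 5, 6)
  st <- welch_t(c(3, 4, 5, 6), c(2.2, 2.4), replicate_means = rm)
  expect_equal(st$empirical_p, mean(rm <= mean(c(2.2, 2.4))))
  expect_equal(st$z, (st$mean_bg - st$mean_mssn) / sd(rm))
})
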