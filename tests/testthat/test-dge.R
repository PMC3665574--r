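make_em <- function(values, n1 = NULL, log2_scale = FALSE) {
  if (is.null(n1)) n1 <- ncol(values) / 2
  n2 <- ncol(values) - n1
  colnames(values) <- c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  design <- data.frame(sample = colnames(values),
                       condition = rep(c("c1", "c2"), c(n1, n2)))
  expression_matrix(values, design, log2_scale = log2_scale)
}

test_that("knn imputation reproduces brute-force nearest-row means", {
  m <- matrix(rnorm(20), 5, 4)
  em <- make_em(m)
  expect_identical(knn_impute(em), em)  # complete matrix untouched

  # k = 1: imputed value equals the single nearest row's value, verified by
  # brute-force nearest-row search on the 5 x 4 fixture
  set.seed(7)
  m <- matrix(rnorm(20), 5, 4)
  m[2, 3] <- NA
  imp <- knn_impute(make_em(m), k = 1)$values
  d <- apply(m[-2, c(1, 2, 4)], 1, function(r)
    sqrt(mean((r - m[2, c(1, 2, 4)])^2)))
  nearest_idx <- setdiff(1:5, 2)[which.min(d)]
  expect_equal(imp[2, 3], m[nearest_idx, 3])

  # k = 3 with three equidistant-enough neighbours all valued 5.0
  m <- rbind(c(1, 1, 5), c(1.01, 1, 5), c(0.99, 1, 5), c(1, 1.01, 5),
             c(1, 1, NA))
  imp <- knn_impute(make_em(m, n1 = 1), k = 3)$values
  expect_equal(imp[5, 3], 5)

  m[5, ] <- NA
  expect_error(knn_impute(make_em(m, n1 = 1)), "zero observed")
})

test_that("knn imputation with k = all rows equals column mean of other rows", {
  set.seed(11)
  m <- matrix(rnorm(40), 8, 5)
  m[3, 2] <- NA
  imp <- knn_impute(make_em(m, n1 = 2), k = 7)$values
  expect_equal(imp[3, 2], mean(m[-3, 2]))
})

test_that("lowess normalization removes constant and simulated dye trends", {
  set.seed(3)
  n <- 1000
  G <- 2^runif(n, 4, 12)
  make_two_channel <- function(R, G) {
    vals <- matrix(0, n, 1, dimnames = list(sprintf("s%04d", 1:n), "arr1"))
    vals2 <- cbind(vals, vals); colnames(vals2) <- c("arr1", "arr2")
    em <- expression_matrix(vals2,
                            data.frame(sample = c("arr1", "arr2"),
                                       condition = c("c1", "c2")),
                            log2_scale = TRUE)
    em$channels <- list(R = cbind(arr1 = R, arr2 = R),
                        G = cbind(arr1 = G, arr2 = G))
    em
  }
  # M identically zero stays zero
  em0 <- make_two_channel(G, G)
  out <- lowess_normalize(em0)
  expect_true(all(abs(out$values) < 1e-12))

  # constant offset M = c is removed
  emc <- make_two_channel(G * 2^0.7, G)
  out <- lowess_normalize(emc, span = 0.4)
  expect_true(all(abs(out$values) < 1e-6))

  # simulated intensity-dependent bias: M = 0.5 A + noise (with R ~ G the
  # abscissa A is ~ log2 G)
  R <- G * 2^(0.5 * log2(G) + rnorm(n, 0, 0.01))
  emb <- make_two_channel(R, G)
  out <- lowess_normalize(emb, span = 0.4)
  Mp <- out$values[, 1]
  Ap <- 0.5 * log2(R * G)
  expect_lt(abs(mean(Mp)), 0.01)
  expect_lt(abs(coef(lm(Mp ~ Ap))[2]), 0.02)

  small <- make_two_channel(G, G)
  small$channels$R <- small$channels$R[1:5, , drop = FALSE]
  small$channels$G <- small$channels$G[1:5, , drop = FALSE]
  expect_error(lowess_normalize(small), "fewer than 10")
})

test_that("welch t-test per gene matches the hand formula and handles degeneracy", {
  m <- rbind(c(1, 2, 3, 4, 5, 6))
  em <- make_em(m, n1 = 3, log2_scale = FALSE)
  res <- two_class_ttest(em)
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$raw_p, ref$p.value, tolerance = 1e-12)

  # fold change of linear group means 4 vs 2 is 2.0
  m <- rbind(c(2, 2, 2.0001, 4, 4, 3.9999))
  res <- two_class_ttest(make_em(m, n1 = 3))
  expect_equal(res$fold_change, 2, tolerance = 1e-4)

  # identical groups: t = 0, p = 1 (zero-variance convention)
  m <- rbind(c(5, 5, 5, 5), c(5, 5, 7, 7))
  res <- two_class_ttest(make_em(m, n1 = 2))
  expect_equal(res$t[1], 0)
  expect_equal(res$raw_p[1], 1)
  expect_equal(res$raw_p[2], 0)       # zero variance, unequal means
  expect_true(res$degenerate[2])
})

test_that("holm and BH adjustments reproduce hand-worked examples", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.3, 0.3)), c(0.6, 0.6))
  expect_equal(holm_adjust(0.07), 0.07)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("adjusted p-values dominate raw ones and respect permutations", {
  set.seed(5)
  p <- runif(50)
  for (f in list(holm_adjust, bh_adjust)) {
    adj <- f(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    perm <- sample(50)
    expect_equal(f(p[perm]), adj[perm])
  }
})

test_that("DE calls apply independent alpha and fold-change gates", {
  stats <- data.frame(gene = c("a", "b", "c", "d"),
                      fold_change = c(1.6, 0.5, 1.6, 1.0),
                      raw_p = c(0.001, 0.001, 0.2, 0.001))
  # single-test family: adjusted == raw here via per-gene Holm on one value
  de <- call_de_genes(data.frame(gene = "a", fold_change = 1.6,
                                 raw_p = 0.01))
  expect_equal(de$up, "a")
  de <- call_de_genes(data.frame(gene = "b", fold_change = 0.5,
                                 raw_p = 0.01))
  expect_equal(de$down, "b")
  de <- call_de_genes(data.frame(gene = "c", fold_change = 1.6,
                                 raw_p = 0.2))
  expect_equal(de$table$call, "ns")
  # up and down sets are disjoint by construction of the gates
  de <- call_de_genes(stats)
  expect_length(intersect(de$up, de$down), 0)
})
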