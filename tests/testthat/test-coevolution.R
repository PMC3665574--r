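two_col_msa <- function(col_i, col_j) {
  chars_to_msa(cbind(col_i, col_j))
}

aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

test_that("mutual information reproduces closed forms", {
  # perfectly correlated 50/50 columns: MI = ln 2
  m <- two_col_msa(rep(c("A", "C"), each = 10), rep(c("A", "C"), each = 10))
  expect_equal(mutual_information(m, 1, 2), log(2), tolerance = 1e-12)
  # a constant column has zero entropy, hence MI = 0
  m <- two_col_msa(rep("A", 20), sample(c("A", "C", "D"), 20, replace = TRUE))
  expect_equal(mutual_information(m, 1, 2), 0, tolerance = 1e-12)
})

test_that("OMES matches the hand-counted 2x2 tables", {
  # factorized counts: AA, AC, CA, CC -> observed == expected -> 0
  m <- two_col_msa(c("A", "A", "C", "C"), c("A", "C", "A", "C"))
  expect_equal(omes(m, 1, 2), 0, tolerance = 1e-12)
  # (A,A) x2 and (C,C) x2: each of 4 cells deviates by 1 from expected 1
  m <- two_col_msa(c("A", "A", "C", "C"), c("A", "A", "C", "C"))
  expect_equal(omes(m, 1, 2), 1, tolerance = 1e-12)
  # doubling every sequence: deviations 2^2 over 4 cells / 8 = 2
  m <- two_col_msa(rep(c("A", "A", "C", "C"), 2), rep(c("A", "A", "C", "C"), 2))
  expect_equal(omes(m, 1, 2), 2, tolerance = 1e-12)
})

test_that("conservation sum reproduces entropy closed forms", {
  m <- two_col_msa(rep("A", 10), rep("C", 10))
  expect_equal(conservation_sum(m, 1, 2), 2, tolerance = 1e-12)
  m <- two_col_msa(rep(c("A", "C"), 5), rep("W", 10))
  expect_equal(column_conservation(m, 1), 1 - log(2) / log(20),
               tolerance = 1e-12)
  # a column uniform over all 20 residues contributes 0
  m <- two_col_msa(aa_letters, rep("A", 20))
  expect_equal(column_conservation(m, 1), 0, tolerance = 1e-12)
})

test_that("SCA perturbation scores behave per contract", {
  # column j identical in subalignment and full alignment -> 0
  col_i <- rep(c("A", "C"), each = 8)
  col_j <- rep(c("D", "E"), 8)  # independent of i, same composition in subsets
  m <- two_col_msa(col_i, col_j)
  # composition of j among A-carriers: alternating D/E = same as full
  expect_equal(sca_perturbation(m, 1, 2), 0, tolerance = 1e-12)
  # fully conserved column i is masked
  m <- two_col_msa(rep("A", 16), col_j)
  expect_true(is.na(sca_perturbation(m, 1, 2)))
  # invariant to sequence order shuffling
  set.seed(9)
  ci <- sample(c("A", "C", "D"), 30, replace = TRUE)
  cj <- sample(c("K", "L"), 30, replace = TRUE)
  m1 <- two_col_msa(ci, cj)
  perm <- sample(30)
  m2 <- two_col_msa(ci[perm], cj[perm])
  expect_equal(sca_perturbation(m1, 1, 2), sca_perturbation(m2, 1, 2),
               tolerance = 1e-12)
})

test_that("ELSC is zero for proportional subsets and nonnegative in general", {
  # subset composition exactly proportional to the full column
  col_i <- rep(c("A", "C"), each = 10)
  col_j <- rep(c("D", "E"), 10)
  m <- two_col_msa(col_i, col_j)
  expect_equal(elsc(m, 1, 2), 0, tolerance = 1e-12)
  set.seed(21)
  for (rep in 1:25) {
    ci <- sample(c("A", "C", "D", "E"), 40, replace = TRUE)
    cj <- sample(c("K", "L", "M"), 40, replace = TRUE)
    m <- two_col_msa(ci, cj)
    v <- elsc(m, 1, 2)
    if (!is.na(v)) expect_gte(v, -1e-12)
  }
})

test_that("MI, OMES and ConservationSum match brute-force counting oracles", {
  set.seed(55)
  for (rep in 1:50) {
    chars <- random_msa_chars(sample(5:20, 1), sample(4:10, 1),
                              gap_prob = ifelse(rep %% 3 == 0, 0.1, 0))
    m <- chars_to_msa(chars)
    cols <- sample(ncol(chars), 2)
    i <- cols[1]; j <- cols[2]
    ok <- chars[, i] != "-" & chars[, j] != "-"
    if (sum(ok) < 2) next
    expect_equal(mutual_information(m, i, j), brute_mi(chars, i, j),
                 tolerance = 1e-10)
    expect_equal(omes(m, i, j), brute_omes(chars, i, j), tolerance = 1e-10)
    ci <- chars[, i][chars[, i] != "-"]
    cj <- chars[, j][chars[, j] != "-"]
    if (length(ci) >= 2 && length(cj) >= 2)
      expect_equal(conservation_sum(m, i, j),
                   brute_conservation(chars, i) + brute_conservation(chars, j),
                   tolerance = 1e-10)
  }
})

test_that("all five coupling matrices are exactly symmetric", {
  gm <- generate_msa(40, 12, rng_seed = 5)
  for (method in c("MI", "OMES", "SCA", "ELSC", "ConservationSum")) {
    cm <- coupling_matrix(gm$msa, method)
    expect_identical(cm$scores, t(cm$scores))
  }
})

test_that("redundancy removal keeps cluster representatives and the reference", {
  base <- paste(rep("ACDEFGHIKL", 3), collapse = "")
  mutate_seq <- function(s, positions, to = "Y") {
    v <- strsplit(s, "")[[1]]; v[positions] <- to
    paste(v, collapse = "")
  }
  # two identical sequences collapse to one
  m <- msa(c(a = base, b = base))
  expect_equal(length(remove_redundancy(m)$ids), 1)
  # pairwise < 90% identical sequences are all retained (>3 of 30 differ)
  m <- msa(c(a = base, b = mutate_seq(base, 1:5), c = mutate_seq(base, 10:14, "W")))
  expect_equal(length(remove_redundancy(m)$ids), 3)
  # 3 planted clusters at ~97% within (1/30 mismatch), 50% between
  scramble <- function(s, shift) {
    v <- strsplit(s, "")[[1]]
    v[seq(1, 30, 2)] <- aa_letters[(seq(1, 30, 2) + shift) %% 20 + 1]
    paste(v, collapse = "")
  }
  centers <- c(base, scramble(base, 3), scramble(base, 7))
  seqs <- unlist(lapply(seq_along(centers), function(k)
    vapply(0:2, function(d) mutate_seq(centers[k], 15 + d, "M"), "")))
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  filt <- remove_redundancy(msa(seqs), 0.90)
  expect_equal(length(filt$ids), 3)
  expect_true(filt$reference %in% filt$ids)
})

test_that("consensus requires support from at least two methods", {
  fake_cm <- function(method, hot) {
    # graded background keeps the 95% threshold above every row-1 entry
    S <- outer(1:10, 1:10, function(i, j) (i + j) / 100)
    diag(S) <- NA
    S[1, hot] <- 5; S[hot, 1] <- 5
    structure(list(method = method, scores = S, mask = rep(TRUE, 10)),
              class = "coupling_matrix")
  }
  mats <- list(fake_cm("MI", 4), fake_cm("OMES", c(4, 7)),
               fake_cm("SCA", 9), fake_cm("ELSC", integer(0)),
               fake_cm("ConservationSum", integer(0)))
  cons <- consensus_couplings(mats, 1, flag_quantile = 0.95)
  expect_equal(cons$couplings$column, 4)   # MI + OMES agree on 4 only
  expect_equal(cons$couplings$methods, "MI,OMES")
  # a column flagged by exactly one method (7, 9) is excluded
  expect_false(any(c(7, 9) %in% cons$couplings$column))

  masked <- fake_cm("MI", 4); masked$mask[1] <- FALSE
  expect_error(consensus_couplings(list(masked, fake_cm("OMES", 4)), 1),
               "masked")
})

test_that("mutation-to-column mapping validates the reference residue", {
  gm <- generate_msa(10, 15, rng_seed = 3)
  ref_res <- gm$msa$matrix["reference", 6]
  expect_equal(reference_column(gm$msa, 6, ref_aa = ref_res), 6)
  wrong <- setdiff(c("A", "C"), ref_res)[1]
  expect_error(reference_column(gm$msa, 6, ref_aa = wrong), "mismatch")
})
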