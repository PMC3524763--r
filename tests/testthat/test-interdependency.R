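test_that("joint entropy matches closed forms and brute-force enumeration", {
  expect_equal(joint_entropy(c("A", "A", "C", "C"), c("D", "D", "E", "E")),
               log(2))
  expect_equal(joint_entropy(rep("A", 6), rep("C", 6)), 0)
  x <- c("A", "A", "A", "C")
  y <- c("D", "D", "E", "E")
  expect_equal(joint_entropy(x, y), oracle_joint_entropy(x, y),
               tolerance = 1e-12)
  expect_error(joint_entropy(c("A", "C"), c("A")), "same length")
})

test_that("mutual information obeys I = H_i + H_j - H_ij and known cases", {
  expect_equal(mutual_information(c("A", "A", "C", "C"),
                                  c("D", "D", "E", "E")), log(2))
  expect_equal(mutual_information(c("A", "A", "C", "C"),
                                  c("D", "E", "D", "E")), 0)
  x <- c("A", "A", "A", "C")
  y <- c("D", "D", "E", "E")
  hi <- oracle_joint_entropy(x, x)
  hj <- oracle_joint_entropy(y, y)
  expect_equal(mutual_information(x, y), hi + hj - oracle_joint_entropy(x, y),
               tolerance = 1e-12)
  expect_equal(mutual_information(x, y), oracle_mutual_information(x, y),
               tolerance = 1e-12)
})

test_that("redundancy hits its extremes and the brute-force ratio", {
  expect_equal(redundancy(c("A", "A", "C", "C"), c("D", "D", "E", "E")), 1)
  expect_equal(redundancy(c("A", "A", "C", "C"), c("D", "E", "D", "E")), 0)
  x <- c("A", "A", "A", "C")
  y <- c("D", "D", "E", "E")
  expect_equal(redundancy(x, y), oracle_redundancy(x, y), tolerance = 1e-12)
  # bijective relabelling => exactly 1
  x2 <- c("A", "C", "D", "A", "C")
  y2 <- c("Q", "W", "E", "Q", "W")
  expect_equal(redundancy(x2, y2), 1)
  # both constant: uninformative pair scores 0
  expect_equal(redundancy(rep("A", 4), rep("A", 4)), 0)
})

test_that("redundancy is invariant to the logarithm base of the oracle", {
  set.seed(11)
  for (rep in 1:20) {
    x <- random_column(30)
    y <- random_column(30)
    expect_equal(redundancy(x, y), oracle_redundancy(x, y, base = 2),
                 tolerance = 1e-12)
  }
})

test_that("redundancy_matrix agrees with the pairwise brute-force loop", {
  set.seed(7)
  mat <- matrix(sample(c("A", "C", "D", "E", "-"), 50 * 6, replace = TRUE),
                nrow = 50)
  aln <- msa(apply(mat, 1, paste, collapse = ""))
  rm <- redundancy_matrix(aln)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(rm$R[i, j], oracle_redundancy(mat[, i], mat[, j]),
                   tolerance = 1e-12)
      expect_equal(rm$H[i, j], oracle_joint_entropy(mat[, i], mat[, j]),
                   tolerance = 1e-12)
      expect_equal(rm$I[i, j], oracle_mutual_information(mat[, i], mat[, j]),
                   tolerance = 1e-12)
    }
  }
  expect_true(isSymmetric(rm$R))
  expect_equal(diag(rm$H),
               sapply(1:6, function(j) oracle_joint_entropy(mat[, j],
                                                            mat[, j])),
               tolerance = 1e-12, ignore_attr = TRUE)
  # joint entropy dominates the marginals
  for (i in 1:6) for (j in 1:6) {
    expect_gte(rm$H[i, j] + 1e-12, max(rm$H[i, i], rm$H[j, j]))
  }
})

test_that("duplicated columns give R = 1 and two-column alignments one pair", {
  aln <- msa(c("AA", "CC", "DD", "EE", "FF"))
  rm <- redundancy_matrix(aln)
  expect_equal(rm$R[1, 2], 1)
  aln2 <- msa(c("AC", "AD", "CC", "CD", "EC"))
  rm2 <- redundancy_matrix(aln2)
  expect_equal(rm2$R[1, 2], redundancy(as.matrix(aln2)[, 1],
                                       as.matrix(aln2)[, 2]))
})

test_that("row permutation and within-column relabelling leave R unchanged", {
  set.seed(12)
  sim <- simulate_msa(60, 5, blocks = list(1:3), rho = 0.7, seed = 12)
  rm <- redundancy_matrix(sim$aln)
  perm <- sample(60)
  aln_p <- msa(apply(as.matrix(sim$aln)[perm, ], 1, paste, collapse = ""))
  expect_equal(redundancy_matrix(aln_p)$R, rm$R, tolerance = 1e-12)
  # bijective relabelling of one column's symbols
  mat <- as.matrix(sim$aln)
  from <- unique(mat[, 2])
  to <- rev(from)
  mat[, 2] <- to[match(mat[, 2], from)]
  aln_r <- msa(apply(mat, 1, paste, collapse = ""))
  expect_equal(redundancy_matrix(aln_r)$R, rm$R, tolerance = 1e-12)
})

test_that("dependency test matches the closed-form chi-square comparison", {
  # n = 4 perfectly dependent binary pair: 2nI = 8 log 2 vs chisq_1(0.95)
  aln <- msa(c("AC", "AC", "CD", "CD"))
  rm <- suppressWarnings(redundancy_matrix(aln))
  out <- dependency_test(rm, alpha = 0.05)
  expect_equal(out$statistic, 8 * log(2), tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_true(out$dependent)
  expect_gte(out$statistic, qchisq(0.95, 1))
  # exactly factorising pair: I = 0, never dependent
  aln0 <- msa(c("AC", "AD", "CC", "CD"))
  out0 <- dependency_test(suppressWarnings(redundancy_matrix(aln0)))
  expect_false(out0$dependent)
  # constant column: df = 0, not testable
  alnc <- msa(c("AC", "AD", "AC", "AD"))
  outc <- dependency_test(suppressWarnings(redundancy_matrix(alnc)))
  expect_false(outc$testable)
  expect_false(outc$dependent)
})

test_that("decisions via R * 2nH and via 2nI agree on random pairs", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    mat <- cbind(random_column(n), random_column(n, c("A", "C", "D")))
    aln <- msa(apply(mat, 1, paste, collapse = ""))
    rm <- suppressWarnings(redundancy_matrix(aln))
    out <- dependency_test(rm, alpha = 0.05)
    if (!out$testable) next
    q <- qchisq(0.95, out$df)
    via_R <- out$R * 2 * rm$n * out$H >= q - 1e-9
    via_I <- 2 * rm$n * out$I >= q - 1e-9
    expect_identical(out$dependent, via_R)
    expect_identical(via_R, via_I)
  }
})

test_that("the full-alphabet df option is more conservative", {
  set.seed(3)
  mat <- cbind(random_column(30), random_column(30))
  aln <- msa(apply(mat, 1, paste, collapse = ""))
  rm <- redundancy_matrix(aln)
  obs <- dependency_test(rm, df_alphabet = "observed")
  full <- dependency_test(rm, df_alphabet = "full")
  expect_gte(full$df, obs$df)
  expect_gte(full$threshold, obs$threshold)
})

test_that("sr_sum adds redundancies over a site set", {
  R <- diag(5)
  R[1, 2] <- R[2, 1] <- 0.4
  R[1, 3] <- R[3, 1] <- 0.3
  R[2, 3] <- R[3, 2] <- 0.2
  rm <- rmat_from_R(R)
  expect_equal(sr_sum(rm, 1, c(1)), 0)
  expect_equal(sr_sum(rm, 1, c(1, 2, 3)), 0.7)
  set.seed(5)
  Rr <- matrix(runif(25), 5, 5)
  Rr <- (Rr + t(Rr)) / 2
  diag(Rr) <- 1
  rmr <- rmat_from_R(Rr)
  s <- c(1, 3, 4, 5)
  expect_equal(sr_sum(rmr, 3, s), sum(Rr[3, c(1, 4, 5)]))
  expect_error(sr_sum(rmr, 9, s), "Unknown site")
})
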