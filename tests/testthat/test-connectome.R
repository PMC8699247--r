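test_that("covariance uses frames as observations and flags degeneracy", {
  z <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  sig <- covarianceMatrix(spk(z, "smoothed"))
  expect_equal(sig, matrix(var(c(1, 2, 3, 4)), 2, 2))   # rank-deficient

  one <- covarianceMatrix(matrix(c(2, 4, 6), 1))
  expect_equal(as.numeric(one), var(c(2, 4, 6)))

  flat <- covarianceMatrix(rbind(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(attr(flat, "zero_variance"), 1L)
  expect_error(covarianceMatrix(matrix(1, 3, 1)), "at least 2 frames")

  set.seed(51)
  big <- matrix(rnorm(2 * 1e5), 2)
  sig2 <- covarianceMatrix(big)
  expect_lt(abs(sig2[1, 2]), 3 / sqrt(1e5))   # independent rows: cov ~ 0
})

test_that("precision matrix inverts well-conditioned covariances exactly", {
  expect_equal(unname(precisionMatrix(diag(3))[, ]), diag(3),
               ignore_attr = TRUE)
  phi <- precisionMatrix(diag(c(2, 4)))
  expect_equal(unname(phi[, ]), diag(c(0.5, 0.25)), ignore_attr = TRUE)
  expect_equal(attr(phi, "ridge_used"), 0)

  set.seed(52)
  A <- matrix(rnorm(36), 6)
  sigma <- crossprod(A) + diag(6)
  phi6 <- precisionMatrix(sigma)
  # independent oracle: solve each column of the identity
  oracle <- sapply(seq_len(6), function(j) solve(sigma, diag(6)[, j]))
  expect_equal(unname(phi6[, ]), oracle, tolerance = 1e-8)
  expect_lt(max(abs(phi6 %*% sigma - diag(6))), 1e-8)
})

test_that("singular covariances trigger ridge escalation, not failure", {
  z <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 1, 3, 2))
  sigma <- covarianceMatrix(z)
  expect_message(phi <- precisionMatrix(sigma), "ridge escalated")
  expect_gt(attr(phi, "ridge_used"), 0)
  expect_true(all(is.finite(phi)))

  flat <- rbind(c(1, 1, 1, 1), c(1, 2, 0, 3))
  expect_error(precisionMatrix(covarianceMatrix(flat)), "non-positive diagonal")
  expect_error(precisionMatrix(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("partial correlations match the worked equicorrelated value", {
  sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
  conn <- partialCorrelations(precisionMatrix(sigma))
  p <- pcorMatrix(conn)
  expect_equal(p[1, 2], 1/3, tolerance = 1e-10)
  expect_equal(p[1, 3], 1/3, tolerance = 1e-10)
  expect_equal(diag(p), rep(0, 3))
  # closed form for three variables: (r12 - r13 r23) / sqrt((1-r13^2)(1-r23^2))
  expect_equal(p[1, 2], (0.5 - 0.25) / (1 - 0.25), tolerance = 1e-12)

  expect_true(all(pcorMatrix(partialCorrelations(diag(4))) == 0))
  expect_error(partialCorrelations(matrix(c(-1, 0, 0, 1), 2)), "non-positive")
})

test_that("precision-based partial correlations equal the residual oracle", {
  set.seed(53)
  for (k in 1:10) {
    n <- sample(3:8, 1)
    z <- matrix(rnorm(n * 60), n)
    conn <- partialCorrelations(precisionMatrix(covarianceMatrix(z)))
    p <- pcorMatrix(conn)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      expect_equal(p[i, j], pcor_residual_oracle(z, i, j), tolerance = 1e-8)
  }
})

test_that("two-neuron partial correlation reduces to Pearson correlation", {
  set.seed(54)
  z <- matrix(rnorm(2 * 200), 2)
  p <- pcorMatrix(partialCorrelations(precisionMatrix(covarianceMatrix(z))))
  expect_equal(p[1, 2], cor(z[1, ], z[2, ]), tolerance = 1e-10)
})

test_that("partial correlations are scale-invariant per neuron", {
  set.seed(55)
  z <- matrix(rnorm(5 * 100), 5)
  z2 <- z; z2[3, ] <- 7.5 * z2[3, ]
  p1 <- pcorMatrix(partialCorrelations(precisionMatrix(covarianceMatrix(z))))
  p2 <- pcorMatrix(partialCorrelations(precisionMatrix(covarianceMatrix(z2))))
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("edge ranking orders by magnitude with lexicographic ties", {
  p <- matrix(0, 3, 3)
  p[1, 2] <- p[2, 1] <- 0.5
  p[1, 3] <- p[3, 1] <- -0.8
  p[2, 3] <- p[3, 2] <- 0.1
  conn <- new("Connectome", partial_corr = p, neuron_ids = 0:2)
  r <- rankEdges(conn)
  expect_equal(nrow(r), 3)
  expect_equal(r$neuron_i, c(0, 0, 1))
  expect_equal(r$neuron_j, c(2, 1, 2))
  expect_equal(r$score, c(0.8, 0.5, 0.1))
  expect_equal(r$pcor[1], -0.8)

  # all-tied scores fall back to lexicographic order; n = 4 gives 6 rows
  pt <- matrix(0.4, 4, 4); diag(pt) <- 0
  rt <- rankEdges(new("Connectome", partial_corr = pt, neuron_ids = 0:3))
  expect_equal(nrow(rt), 6)
  expect_equal(rt$neuron_i, c(0, 0, 0, 1, 1, 2))
  expect_equal(rt$neuron_j, c(1, 2, 3, 2, 3, 3))
})

test_that("full inference recovers a simulated connectome", {
  ds <- bench60()
  conn <- inferConnectome(ds$traces)
  res <- scoreRanking(rankEdges(conn), symmetrizeTruth(ds$network))
  expect_gt(auroc(res), 0.7)
})

test_that("silent neurons are excluded and reported, pairs zeroed", {
  ds <- simulateDataset(simConfig(8, 120, seed = 61), density = 0.15)
  v <- as.matrix(ds$traces)
  v[3, ] <- 0   # flat trace: no activity at all
  conn <- suppressMessages(suppressWarnings(inferConnectome(flt(v))))
  expect_true(3L %in% silentNeurons(conn))
  expect_true(all(pcorMatrix(conn)[3, ] == 0))
  expect_true(all(pcorMatrix(conn)[, 3] == 0))

  # fewer than two active neurons is an error
  dead <- flt(matrix(0, 2, 150))
  expect_error(suppressMessages(suppressWarnings(inferConnectome(dead))),
               "fewer than 2 active")
})

test_that("inference is equivariant under neuron permutation", {
  ds <- simulateDataset(simConfig(10, 120, seed = 63), density = 0.15)
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  p_full <- pcorMatrix(inferConnectome(ds$traces))
  v <- as.matrix(ds$traces)
  p_perm <- pcorMatrix(inferConnectome(flt(v[perm, ])))
  expect_equal(p_perm, p_full[perm, perm], tolerance = 1e-9)
})
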