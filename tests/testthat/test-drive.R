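test_that("poisson trains have the right counts and no cross-correlation", {
  set.seed(3)
  expect_equal(nrow(poisson_trains(0, 5, 1000)), 0)
  tr <- poisson_trains(16, 20, 1000)
  # total count within the 99% Poisson interval around 320 (oracle: qpois)
  expect_gte(nrow(tr), qpois(0.005, 320))
  expect_lte(nrow(tr), qpois(0.995, 320))
  expect_true(all(tr$time_ms >= 0 & tr$time_ms <= 1000))
  expect_error(poisson_trains(-1, 5, 100), class = "spikevar_bad_rate")

  # pairwise spike-count correlations across 100 trains are near zero
  set.seed(4)
  counts <- replicate(100, {
    t1 <- poisson_trains(20, 1, 2000)
    hist(t1$time_ms, breaks = seq(0, 2000, 100), plot = FALSE)$counts
  })
  cm <- cor(counts)
  offdiag <- cm[upper.tri(cm)]
  expect_lt(abs(mean(offdiag)), 0.02)
})

test_that("evoked rates add modulations and guard non-negativity", {
  spec <- input_spec()
  expect_equal(unname(evoked_rates(spec)), c(16, 90, 9.3, 12))
  # boundary: modulation down to exactly zero is accepted
  r <- evoked_rates(spec, c(PC = -16))
  expect_equal(unname(r[["PC"]]), 0)
  expect_error(evoked_rates(spec, c(PC = -17)), class = "spikevar_negative_rate")
  # the VIP channel is pinned at zero modulation
  r2 <- evoked_rates(spec, c(VIP = 100))
  expect_equal(unname(r2[["VIP"]]), 12)
  # channel naming (E/P/S) is accepted by the engine-facing normalizer
  expect_equal(unname(evoked_rates(spec, spikevar:::normalize_delta(c(E = 2)))[["PC"]]),
               18)
})

test_that("covariance builder accepts PSD matrices and rejects the rest", {
  m <- build_covariance(variances = c(1.8, 0.6, 0.6))
  expect_equal(diag(m), c(E = 1.8, P = 0.6, S = 0.6))
  expect_true(isSymmetric(m))
  # Cauchy-Schwarz violation is not PSD
  expect_null(build_covariance(variances = c(1, 1, 1),
                               covariances = c(EP = 1.2, ES = 0, PS = 0)))
  # symmetric output with uniform off-diagonals
  m2 <- build_covariance(variances = c(1.8, 0.6, 0.6),
                         covariances = c(EP = 0.5, ES = 0.5, PS = 0.5))
  expect_true(isSymmetric(m2))

  # rejection decision agrees with a direct eigenvalue oracle across
  # random symmetric matrices
  set.seed(11)
  for (i in 1:200) {
    v <- runif(3, 0, 2)
    cv <- runif(3, -1.5, 1.5)
    m3 <- build_covariance(variances = v,
                           covariances = c(EP = cv[1], ES = cv[2], PS = cv[3]))
    mm <- matrix(c(v[1], cv[1], cv[2], cv[1], v[2], cv[3], cv[2], cv[3], v[3]), 3)
    ok <- min(eigen(mm, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
    expect_equal(!is.null(m3), ok)
  }
})

test_that("balance factors carry variance ratios with correlation signs", {
  m <- build_covariance(variances = c(1.8, 0.6, 0.9),
                        covariances = c(EP = 0.3, ES = -0.2, PS = 0))
  b <- balance_factors(m)
  expect_equal(unname(b[["EP"]]), 1.8 / 0.6)
  expect_equal(unname(b[["ES"]]), -(1.8 / 0.9))
  # flipping an off-diagonal sign flips exactly that balance sign
  m2 <- build_covariance(variances = c(1.8, 0.6, 0.9),
                         covariances = c(EP = -0.3, ES = -0.2, PS = 0))
  b2 <- balance_factors(m2)
  expect_equal(unname(b2[["EP"]]), -unname(b[["EP"]]))
  expect_equal(unname(b2[["ES"]]), unname(b[["ES"]]))
})

test_that("balance-mode construction splits a fixed total variance", {
  tot <- 3
  m <- build_covariance(total_var = tot, balance = c(EP = 3, ES = 3),
                        covariances = c(EP = 0.5, ES = 0.5, PS = 0.5))
  expect_equal(sum(diag(m)), tot)
  expect_equal(m["E", "E"] / m["P", "P"], 3)
  expect_equal(m["E", "E"] / m["S", "S"], 3)
  # negative balance flips the corresponding covariance sign
  mn <- build_covariance(total_var = tot, balance = c(EP = -3, ES = 3),
                         covariances = c(EP = 0.5, ES = 0.5, PS = 0.5))
  if (!is.null(mn)) expect_lt(mn["E", "P"], 0)
})

test_that("sampled clouds recover the distribution and are reproducible", {
  # zero covariance: every point is the mean
  d0 <- input_distribution(mean = c(E = 1, P = 2, S = 3),
                           sigma = matrix(0, 3, 3))
  c0 <- sample_cloud(d0, 10, seed = 1)
  expect_true(all(c0$dlambda_E == 1 & c0$dlambda_P == 2 & c0$dlambda_S == 3))

  # entrywise 3% recovery of sigma at n = 1e5 (law of large numbers)
  sg <- build_covariance(variances = c(1.8, 0.6, 0.6),
                         covariances = c(EP = 0.5, ES = 0.2, PS = 0.1))
  d <- input_distribution(sigma = sg)
  cl <- sample_cloud(d, 1e5, seed = 2)
  emp <- cov(as.matrix(cl[, -1]))
  expect_lt(max(abs(emp - sg)) / max(abs(sg)), 0.03)

  # deterministic given (dist, n, seed)
  expect_identical(sample_cloud(d, 50, seed = 9), sample_cloud(d, 50, seed = 9))
  expect_false(identical(sample_cloud(d, 50, seed = 9),
                         sample_cloud(d, 50, seed = 10)))
})

test_that("input distributions insist on accepted covariances", {
  expect_error(input_distribution(sigma = NULL), class = "spikevar_bad_covariance")
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(input_distribution(sigma = bad), class = "spikevar_bad_covariance")
})
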