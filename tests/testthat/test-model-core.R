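test_that("differencing matrix has the boundary-to-interval structure", {
  expect_equal(differencing_matrix(2), matrix(c(1, -1), 2, 1))
  expect_equal(differencing_matrix(3),
               matrix(c(1, -1, 0, 0, 1, -1), 3, 2))
  for (K in c(4, 7, 12)) {
    Tm <- differencing_matrix(K)
    expect_equal(dim(Tm), c(K, K - 1))
    # each jitter moves one boundary, conserving total sequence length
    expect_equal(colSums(Tm), rep(0, K - 1))
    expect_equal(diag(Tm[seq_len(K - 1), , drop = FALSE]), rep(1, K - 1))
  }
  expect_error(differencing_matrix(1), "integer >= 2")
})

test_that("model covariance assembles the three components", {
  K <- 4
  m_id <- timing_model(matrix(0, K, 1), rep(1, K), rep(0, K - 1))
  expect_equal(model_covariance(m_id), diag(K))

  m_shared <- timing_model(rep(1, 3), rep(0, 3), rep(0, 2))
  expect_equal(model_covariance(m_shared), matrix(1, 3, 3))

  # adjacent covariance = sum_m w_k w_{k+1} - jitter at the shared boundary
  m <- timing_model(c(1, 2, 3), c(1, 1, 1), c(0.5, 0.25))
  S <- model_covariance(m)
  expect_equal(S[1, 2], 1 * 2 - 0.5)
  expect_equal(S[2, 3], 2 * 3 - 0.25)
  expect_equal(S[1, 3], 1 * 3)
  expect_equal(diag(S), c(1 + 1 + 0.5, 4 + 1 + 0.75, 9 + 1 + 0.25))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
})

test_that("model covariance matches the empirical covariance of simulation", {
  m <- timing_model(c(1, 2, 3), c(1, 1, 1), c(0.5, 0.25),
                    means = c(100, 50, 120))
  sim <- simulate_intervals(m, 2e5, seed = 42)
  Shat <- cov(sim$data$durations)
  S <- model_covariance(m)
  expect_lt(norm(Shat - S, "F") / norm(S, "F"), 0.02)
})

test_that("log-likelihood equals the exact Gaussian density", {
  K <- 4
  m <- random_instance(K, 2, seed = 7)
  sim <- simulate_intervals(m, 40, seed = 8)
  Y <- sim$data$durations
  Yc <- sweep(Y, 2, colMeans(Y))
  oracle <- mvn_logpdf_rows(Yc, rep(0, K), model_covariance(m))
  expect_equal(model_loglik(m, Y), oracle, tolerance = 1e-10)

  # mean-subtraction invariance: shifting a column changes nothing
  Y2 <- Y
  Y2[, 2] <- Y2[, 2] + 17.3
  expect_equal(model_loglik(m, Y2), model_loglik(m, Y))

  # constant data under identity covariance: zero quadratic form
  m_id <- timing_model(matrix(0, K, 1), rep(1, K), rep(0, K - 1))
  Yconst <- matrix(rep(c(100, 50, 120, 60), each = 10), 10, K)
  expect_equal(model_loglik(m_id, Yconst), -(10 * K / 2) * log(2 * pi))

  # singular covariance: non-finite likelihood with a warning, not a crash
  m_sing <- timing_model(matrix(0, K, 1), rep(0, K), rep(0, K - 1))
  expect_warning(ll <- model_loglik(m_sing, Y), "singular")
  expect_identical(ll, -Inf)
})

test_that("simulation is exact in the noise-free limit and reproducible", {
  mu <- c(100, 50, 120)
  m0 <- timing_model(matrix(0, 3, 1), rep(0, 3), rep(0, 2), means = mu)
  sim <- simulate_intervals(m0, 5, seed = 1)
  expect_equal(sim$data$durations,
               matrix(rep(mu, each = 5), 5, 3,
                      dimnames = list(NULL, colnames(sim$data$durations))))
  s1 <- simulate_intervals(random_instance(5, 1, seed = 3), 20, seed = 99)
  s2 <- simulate_intervals(random_instance(5, 1, seed = 3), 20, seed = 99)
  expect_identical(s1$data$durations, s2$data$durations)
  expect_identical(s1$z, s2$z)
})

test_that("boundary jitter never changes total sequence length", {
  base <- timing_model(c(1, 1, 1, 1), rep(1, 4), rep(0, 3))
  jittery <- timing_model(c(1, 1, 1, 1), rep(1, 4), c(2, 3, 1))
  n <- 2e5
  v0 <- var(rowSums(simulate_intervals(base, n, seed = 5)$data$durations))
  v1 <- var(rowSums(simulate_intervals(jittery, n, seed = 6)$data$durations))
  analytic <- sum(c(1, 1, 1, 1))^2 + 4   # (sum w)^2 + sum psi_e
  expect_equal(v0 / analytic, 1, tolerance = 0.05)
  expect_equal(v1 / analytic, 1, tolerance = 0.05)
})

test_that("dataset validation enforces shape and finiteness", {
  expect_error(interval_dataset(matrix(1, 4, 2)), "K >= 3")
  expect_error(interval_dataset(matrix(c(1, NA, rep(1, 10)), 4, 3)),
               "finite")
  expect_error(interval_dataset(matrix(c(-1, rep(1, 11)), 4, 3)), "> 0")
  d <- interval_dataset(matrix(runif(12, 50, 60), 4, 3),
                        labels = c("syllable", "gap_within", "syllable"),
                        meta = data.frame(day = 1:4))
  expect_s3_class(d, "interval_dataset")
  expect_equal(dim(d), c(4L, 3L))
})
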