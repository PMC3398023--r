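test_that("initialization respects the data-driven uniform ranges", {
  set.seed(1)
  Y <- simulate_intervals(fixture_model_for_tests(), 200, seed = 2)$data
  sds <- apply(Y$durations, 2, sd)
  vars <- sds^2
  set.seed(3)
  for (i in 1:200) {
    init <- initialize_parameters(Y, 1)
    expect_true(all(init$global_weights >= 0 & init$global_weights <= sds))
    expect_true(all(init$independent_vars <= vars))
    expect_true(all(init$jitter_vars <= mean(vars) / 2))
  }
  set.seed(11)
  a <- initialize_parameters(Y, 2)
  set.seed(11)
  b <- initialize_parameters(Y, 2)
  expect_identical(a$global_weights, b$global_weights)

  # constant column: zero variability bounds collapse to zero
  Yc <- Y$durations
  Yc[, 2] <- 55
  init <- initialize_parameters(Yc, 1)
  expect_equal(init$global_weights[2, 1], 0)
  expect_equal(init$independent_vars[2], 0)
})

test_that("E step matches brute-force joint-Gaussian conditioning", {
  set.seed(21)
  for (i in 1:12) {
    K <- sample(3:6, 1)
    M <- sample(1:3, 1)
    m <- random_instance(K, M)
    Y <- simulate_intervals(m, 30)$data$durations
    post <- e_step(m, Y)
    oracle <- conditioning_oracle(m, Y)
    expect_lt(max(abs(post$post_cov - oracle$post_cov)), 1e-10)
    expect_lt(max(abs(post$post_mean - oracle$post_mean)), 1e-10)
    # second moment identity
    expect_equal(post$second_moment,
                 post$post_cov +
                   crossprod(post$post_mean) / nrow(Y), tolerance = 1e-12)
  }
})

test_that("E step reduces to the prior when the likelihood is uninformative", {
  m <- timing_model(c(1, 1.2, 0.8, 1), rep(1e8, 4), c(0.5, 0.4, 0.6),
                    means = c(100, 50, 120, 60))
  Y <- simulate_intervals(timing_model(c(1, 1.2, 0.8, 1), rep(1, 4),
                                       c(0.5, 0.4, 0.6)),
                          50, seed = 4)$data$durations
  post <- e_step(m, Y)
  C <- diag(c(1, 0.5, 0.4, 0.6))
  expect_lt(max(abs(post$post_cov - C)), 1e-3)
  expect_lt(max(abs(post$post_mean)), 1e-3)
})

test_that("true parameters are a fixed point of one EM cycle on their own
           covariance", {
  for (seed in c(5, 17)) {
    m <- random_instance(6, 2, seed = seed)
    S <- model_covariance(m)
    mom <- timefactor:::e_step_moments(m, S)
    m2 <- timefactor:::m_step_moments(mom, S, m, 1e-12)
    expect_lt(max(abs(m2$global_weights - m$global_weights)), 1e-8)
    expect_lt(max(abs(m2$independent_vars - m$independent_vars)), 1e-8)
    expect_lt(max(abs(m2$jitter_vars - m$jitter_vars)), 1e-8)
  }
})

test_that("closed-form M step agrees with numerical maximization of the
           expected complete-data log-likelihood", {
  m_true <- timing_model(c(1, 1.2, 0.9), c(1, 0.8, 1.1), c(0.5, 0.4))
  Y <- simulate_intervals(m_true, 400, seed = 9)$data$durations
  set.seed(10)
  cur <- initialize_parameters(Y, 1)
  post <- e_step(cur, Y)
  closed <- m_step(post, Y, cur)
  negQ <- expected_negQ_factory(cur, Y)
  start <- c(cur$global_weights,
             log(cur$independent_vars + 0.1), log(cur$jitter_vars + 0.1))
  opt <- optim(start, negQ, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  K <- 3
  W_num <- opt$par[1:K]
  pe_num <- exp(opt$par[(K + 1):(2 * K)])
  px_num <- exp(opt$par[(2 * K + 1):(3 * K - 1)])
  expect_equal(unname(drop(closed$global_weights)), W_num,
               tolerance = 1e-4)
  expect_equal(closed$independent_vars, pe_num, tolerance = 1e-4)
  expect_equal(closed$jitter_vars, px_num, tolerance = 1e-4)
})

test_that("every EM update increases the log-likelihood", {
  set.seed(31)
  for (i in 1:25) {
    K <- sample(3:5, 1)
    m_true <- random_instance(K, 1)
    Y <- simulate_intervals(m_true, 60)$data$durations
    init <- initialize_parameters(Y, 1)
    res <- run_em(Y, 1, init, tol = 1e-8, max_iter = 40)
    expect_true(all(diff(res$loglik_trace) > -1e-9))
  }
})

test_that("run_em is deterministic and beats the truth's likelihood on the
           sample", {
  m_true <- fixture_model_for_tests()
  Y <- simulate_intervals(m_true, 2000, seed = 12)$data$durations
  set.seed(13)
  init <- initialize_parameters(Y, 1)
  r1 <- run_em(Y, 1, init, tol = 1e-7)
  r2 <- run_em(Y, 1, init, tol = 1e-7)
  expect_identical(r1$loglik_trace, r2$loglik_trace)
  # maximum likelihood dominates the generating parameters on the sample
  expect_gte(r1$loglik, model_loglik(m_true, Y) - 1e-6)
})

test_that("the fit protocol keeps the best restart and validates inputs", {
  fx <- cached("fit_small", {
    m <- fixture_model_for_tests()
    sim <- simulate_intervals(m, 300, seed = 14)
    fit <- fit_timing_model(sim$data, 1,
                            fit_config(n_restarts = 6, n_keep = 2,
                                       seed = 15))
    list(model = m, sim = sim, fit = fit)
  })
  fit <- fx$fit
  expect_gte(fit$loglik, max(fit$restart_logliks) - 1e-6)
  expect_true(all(vapply(fit$loglik_trace,
                         function(tr) all(diff(tr) > -1e-9), logical(1))))
  expect_true(fit$converged)
  expect_equal(fit$loglik, model_loglik(fit$model, fx$sim$data$durations))
  expect_error(fit_timing_model(fx$sim$data, 0), "M must be")
  expect_error(fit_timing_model(fx$sim$data$durations[1:5, ], 1),
               "N >= K \\+ 1")
})

test_that("latent estimates satisfy the reconstruction identity and pool
           tempo information", {
  fx <- cached("fit_small", stop("populated by the previous block"))
  fit <- fx$fit
  lat <- estimate_latents(fit)
  K <- fit$model$n_intervals
  Z <- as.matrix(lat[, grep("^z", names(lat)), drop = FALSE])
  X <- as.matrix(lat[, grep("^x", names(lat)), drop = FALSE])
  E <- as.matrix(lat[, grep("^e", names(lat)), drop = FALSE])
  recon <- sweep(Z %*% t(fit$model$global_weights) +
                   X %*% t(fit$model$differencing) + E,
                 2, fit$model$means, "+")
  expect_equal(unname(recon), unname(fx$sim$data$durations),
               tolerance = 1e-12)
  # tempo pools information across all K intervals, so its latent is
  # recovered better than any single boundary or interval latent
  al <- timefactor:::align_estimate(fit$model, fx$model, Z_est = Z,
                                    Z_true = fx$sim$z)
  tempo_cor <- cor(al$Z_est[, 1], al$Z_true[, 1])
  x_cors <- vapply(seq_len(ncol(X)),
                   function(j) cor(X[, j], fx$sim$x[, j]), numeric(1))
  e_cors <- vapply(seq_len(ncol(E)),
                   function(j) cor(E[, j], fx$sim$e[, j]), numeric(1))
  expect_true(all(tempo_cor > x_cors))
  expect_true(all(tempo_cor > e_cors))
})
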