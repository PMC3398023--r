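# Independent oracles and shared fixtures for the test suite.

# random well-conditioned model instance
random_instance <- function(K, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  timing_model(
    global_weights = matrix(rnorm(K * M, sd = 1), K, M),
    independent_vars = runif(K, 0.3, 2),
    jitter_vars = runif(K - 1, 0.1, 1),
    means = runif(K, 40, 200))
}

# generic multivariate-normal log density, independent of the package's
# likelihood path (direct solve of the covariance, row by row)
mvn_logpdf_rows <- function(Y, mu, S) {
  K <- ncol(Y)
  Sinv <- solve(S)
  ld <- determinant(S, logarithm = TRUE)$modulus
  sum(apply(Y, 1, function(y) {
    d <- y - mu
    -0.5 * (K * log(2 * pi) + ld + drop(t(d) %*% Sinv %*% d))
  }))
}

# brute-force joint-Gaussian conditioning oracle for the E step: assemble
# the joint covariance of (u, y) and condition by Schur complement
conditioning_oracle <- function(model, Y) {
  A <- cbind(model$global_weights, model$differencing)
  C <- diag(c(rep(1, model$n_global), model$jitter_vars))
  S <- A %*% C %*% t(A) + diag(model$independent_vars)
  CovUY <- C %*% t(A)
  Yc <- sweep(Y, 2, colMeans(Y))
  list(post_cov = C - CovUY %*% solve(S) %*% t(CovUY),
       post_mean = Yc %*% solve(S) %*% t(CovUY))
}

# expected complete-data negative log-likelihood (up to constants), the
# objective the M step must maximize; parameterized by log-variances
expected_negQ_factory <- function(model, Y) {
  post <- e_step(model, Y)
  K <- model$n_intervals
  M <- model$n_global
  Tm <- model$differencing
  Yc <- sweep(Y, 2, colMeans(Y))
  N <- nrow(Yc)
  Shat <- crossprod(Yc) / N
  M2 <- post$second_moment
  Cyu <- crossprod(Yc, post$post_mean) / N
  xi <- (M + 1):(M + K - 1)
  function(par) {
    W <- matrix(par[seq_len(K * M)], K, M)
    pe <- exp(par[(K * M + 1):(K * M + K)])
    px <- exp(par[(K * M + K + 1):(K * M + 2 * K - 1)])
    A <- cbind(W, Tm)
    quad <- Shat - A %*% t(Cyu) - Cyu %*% t(A) + A %*% M2 %*% t(A)
    0.5 * (sum(log(pe)) + sum(diag(quad) / pe) +
             sum(log(px)) + sum(diag(M2)[xi] / px))
  }
}

draw_latent_matrix_for_tests <- function(spec, n, L)
  timefactor:::draw_latent_matrix(spec, n, L)

# K = 7 single-factor model with song-scale parameters (weights and
# component SDs near 1 msec), the recovery benchmark truth
fixture_model_for_tests <- function() make_fixture("k7", n = 10)$model

# session-level cache so the expensive Monte Carlo runs are shared between
# related test blocks
.tf_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tf_cache)) {
    assign(key, force(expr), envir = .tf_cache)
  }
  get(key, envir = .tf_cache)
}
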