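#' EM fitting configuration
#'
#' Controls the multi-restart, two-stage fitting protocol.  Stage 1 runs EM
#' from \code{n_restarts} random initializations until the log-likelihood
#' increment per iteration falls below \code{tol_loose}; the \code{n_keep}
#' restarts with the highest log-likelihoods are then continued (stage 2)
#' until the maximum relative change of the global weights and jitter
#' variances falls below \code{tol_strict} (the independent variances
#' converge faster and are not monitored).  All variances are floored at
#' \code{variance_floor} after every M step to keep the E step well-posed
#' and to prevent Heywood-style collapse.
#'
#' @param n_restarts number of random EM restarts (default 100).
#' @param n_keep number of top restarts continued to strict convergence
#'   (default 5).
#' @param tol_loose stage-1 absolute log-likelihood increment threshold.
#' @param tol_strict stage-2 relative parameter-change threshold on the
#'   global weights and jitter variances.
#' @param max_iter iteration cap per EM run (default 10000).
#' @param variance_floor lower bound applied to all variances, msec^2.
#' @param seed optional master seed; restart r draws its initialization from
#'   a sub-seed derived from it, so any single restart is reproducible.
#' @return a list of class \code{"fit_config"}.
#' @export
fit_config <- function(n_restarts = 100L, n_keep = 5L, tol_loose = 1e-6,
                       tol_strict = 1e-5, max_iter = 10000L,
                       variance_floor = 1e-12, seed = NULL) {
  n_restarts <- as.integer(n_restarts)
  n_keep <- as.integer(n_keep)
  if (n_restarts < 1L || n_keep < 1L || n_keep > n_restarts)
    stop("need 1 <= n_keep <= n_restarts", call. = FALSE)
  if (tol_loose <= 0 || tol_strict <= 0 || variance_floor <= 0)
    stop("tolerances and variance_floor must be > 0", call. = FALSE)
  structure(list(n_restarts = n_restarts, n_keep = n_keep,
                 tol_loose = tol_loose, tol_strict = tol_strict,
                 max_iter = as.integer(max_iter),
                 variance_floor = variance_floor, seed = seed),
            class = "fit_config")
}

#' Random initialization of model parameters
#'
#' Draws each starting parameter from a uniform distribution whose upper
#' bound is set by the variability of the corresponding interval: global
#' weights from U(0, sd of the interval), independent variances from
#' U(0, sample variance of the interval), and each jitter variance from
#' U(0, half the average interval variance) — jitter parameters are not tied
#' to a unique interval and contribute variance to two intervals at once.
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param data an [interval_dataset()] or duration matrix.
#' @param M number of global factors.
#' @return a [timing_model()] with means set to the column means.
#' @export
initialize_parameters <- function(data, M) {
  Y <- dataset_matrix(data)
  K <- ncol(Y)
  sds <- apply(Y, 2L, sd)
  vars <- sds^2
  W <- matrix(runif(K * M, 0, rep(sds, M)), K, M)
  psi_e <- runif(K, 0, vars)
  psi_x <- runif(K - 1L, 0, mean(vars) / 2)
  timing_model(W, psi_e, psi_x, means = colMeans(Y),
               labels = if (inherits(data, "interval_dataset")) data$labels)
}

## Block-diagonal prior covariance C of the concatenated latent u = [z | x]:
## identity for the M unit-variance global factors, diag(jitter_vars) for
## the K-1 boundary jitters.  Off-diagonal blocks are exactly zero.
prior_cov <- function(model) {
  M <- model$n_global
  L <- M + model$n_intervals - 1L
  C <- diag(c(rep(1, M), model$jitter_vars), L)
  C
}

## E step from sufficient statistics.  Posterior of u_n = [z_n | x_n] given
## y_n is Gaussian with shared covariance
##   Sigma = (C^-1 + A' Psi_e^-1 A)^-1  =  C - C A' S^-1 A C   (Woodbury)
## and mean <u_n> = y_n Psi_e^-1 A Sigma = y_n S^-1 A C.  The Woodbury form
## needs no inverse of C and stays well-posed at the variance floor.
## Returns Sigma, the coefficient matrix B (K x L, post_mean = Yc B), the
## average second moment M2 = Sigma + B' Shat B, and Cyu = Shat B.
e_step_moments <- function(model, Shat) {
  A <- cbind(model$global_weights, model$differencing)
  C <- prior_cov(model)
  S <- model_covariance(model)
  ch <- tryCatch(chol(S), error = function(e)
    stop("model covariance is singular in the E step", call. = FALSE))
  Sinv_AC <- chol2inv(ch) %*% (A %*% C)       # K x L
  Sigma <- C - crossprod(A %*% C, Sinv_AC)
  Sigma <- (Sigma + t(Sigma)) / 2
  B <- Sinv_AC
  M2 <- Sigma + crossprod(B, Shat %*% B)
  M2 <- (M2 + t(M2)) / 2
  list(Sigma = Sigma, B = B, M2 = M2, Cyu = Shat %*% B, A = A)
}

#' E step: posterior moments of the latent variables
#'
#' Computes the Gaussian posterior of the concatenated latent vector
#' u = [z | x] for every trial under the current parameters.  The posterior
#' covariance is shared across trials (the model is homoscedastic); only the
#' means vary with the data.  The average second moment retains the z-x
#' cross-moments: although the latents are independent a priori, they are
#' not independent under the posterior.
#'
#' @param model a [timing_model()].
#' @param data an [interval_dataset()] or duration matrix.
#' @return an object of class \code{"latent_posterior"}: \code{post_cov}
#'   (L x L shared posterior covariance, L = M + K - 1), \code{post_mean}
#'   (N x L), \code{second_moment} (L x L average
#'   \eqn{(1/N)\sum_n \langle u_n' u_n\rangle}), and index vectors
#'   \code{z_idx}, \code{x_idx} for the two blocks.
#' @export
e_step <- function(model, data) {
  Y <- dataset_matrix(data)
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  Shat <- crossprod(Yc) / nrow(Yc)
  mom <- e_step_moments(model, Shat)
  M <- model$n_global
  L <- M + model$n_intervals - 1L
  structure(list(post_cov = mom$Sigma, post_mean = Yc %*% mom$B,
                 second_moment = mom$M2, z_idx = seq_len(M),
                 x_idx = (M + 1L):L),
            class = "latent_posterior")
}

## M step from E-step moments; returns an updated timing_model.
## Updates (T held fixed throughout):
##   Psi_x <- diagonal of the x-block of M2 (z-block pinned to identity)
##   W     <- [Cyz - T M2_xz] M2_zz^-1
##   Psi_e <- diag(Shat - A Cyu' - Cyu A' + A M2 A')  with A_new = [W_new | T]
## The Psi_e update keeps the full expected quadratic: the factor-analysis
## shortcut diag(Shat - Cyu A') needs A M2 = Cyu, which the fixed
## differencing block does not satisfy away from a fixed point.  The full
## form is the exact maximizer of the expected complete-data log-likelihood
## (verified against a numerical optimizer) and preserves EM monotonicity.
m_step_moments <- function(mom, Shat, model, floor) {
  M <- model$n_global
  K <- model$n_intervals
  zi <- seq_len(M)
  xi <- (M + 1L):(M + K - 1L)
  Tm <- model$differencing
  M2 <- mom$M2
  psi_x <- pmax(diag(M2[xi, xi, drop = FALSE]), floor)
  Czz <- M2[zi, zi, drop = FALSE]
  W_new <- tryCatch(
    (mom$Cyu[, zi, drop = FALSE] - Tm %*% M2[xi, zi, drop = FALSE]) %*%
      solve(Czz),
    error = function(e)
      stop("collapsed global factor: <z'z> moment is singular",
           call. = FALSE))
  A_new <- cbind(W_new, Tm)
  quad_diag <- diag(Shat) - 2 * rowSums(A_new * mom$Cyu) +
    rowSums((A_new %*% M2) * A_new)
  psi_e <- pmax(quad_diag, floor)
  timing_model(W_new, psi_e, psi_x, means = model$means,
               labels = model$labels)
}

#' M step: closed-form parameter update
#'
#' Maximizes the expected complete-data log-likelihood under the posterior
#' from [e_step()], with the differencing matrix held fixed and the global
#' latent covariance pinned to the identity.  All variances are floored.
#'
#' @param posterior a \code{"latent_posterior"} from [e_step()] computed
#'   under \code{model}.
#' @param data the same data the posterior was computed from.
#' @param model the current [timing_model()].
#' @param variance_floor lower bound for the updated variances.
#' @return the updated [timing_model()].
#' @export
m_step <- function(posterior, data, model, variance_floor = 1e-12) {
  stopifnot(inherits(posterior, "latent_posterior"))
  Y <- dataset_matrix(data)
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  N <- nrow(Yc)
  Shat <- crossprod(Yc) / N
  mom <- list(M2 = posterior$second_moment,
              Cyu = crossprod(Yc, posterior$post_mean) / N)
  m_step_moments(mom, Shat, model, variance_floor)
}

#' Run EM from one initialization
#'
#' Alternates E and M steps from \code{init} until the convergence criterion
#' is met or \code{max_iter} is reached.  With \code{criterion = "loglik"}
#' the run stops when the log-likelihood increment falls below \code{tol};
#' with \code{criterion = "param"} it stops when the maximum relative change
#' of the global weights and jitter variances falls below \code{tol}.
#'
#' @param data an [interval_dataset()] or duration matrix.
#' @param M number of global factors (>= 1).
#' @param init a [timing_model()] giving the starting parameters.
#' @param tol convergence threshold (see \code{criterion}).
#' @param max_iter iteration cap.
#' @param criterion \code{"loglik"} or \code{"param"}.
#' @param variance_floor variance lower bound applied each M step.
#' @return a list with \code{model}, \code{loglik}, non-decreasing
#'   \code{loglik_trace} (one entry per iteration), \code{converged} and
#'   \code{n_iter}.
#' @export
run_em <- function(data, M, init, tol = 1e-6, max_iter = 10000L,
                   criterion = c("loglik", "param"),
                   variance_floor = 1e-12) {
  criterion <- match.arg(criterion)
  Y <- dataset_matrix(data)
  Shat <- cov_mle(Y)
  run_em_cov(Shat, nrow(Y), init, tol, max_iter, criterion, variance_floor)
}

## EM on sufficient statistics: exact, and per-iteration cost independent
## of N.  The loop works on raw parameter arrays; the validated
## timing_model object is rebuilt only on exit.
run_em_cov <- function(Shat, N, init, tol, max_iter, criterion,
                       variance_floor) {
  K <- init$n_intervals
  M <- init$n_global
  Tm <- init$differencing
  zi <- seq_len(M)
  xi <- (M + 1L):(M + K - 1L)
  W <- init$global_weights
  psi_e <- pmax(init$independent_vars, variance_floor)
  psi_x <- pmax(init$jitter_vars, variance_floor)
  trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  const <- K * log(2 * pi)
  ## factorization of the current model covariance, reused across the E
  ## step and the likelihood evaluation of the previous M step
  A <- cbind(W, Tm)
  cdiag <- c(rep(1, M), psi_x)
  AC <- A * rep(cdiag, each = K)
  S <- AC %*% t(A) + diag(psi_e, K)
  ch <- tryCatch(chol(S), error = function(e)
    stop("model covariance is singular in the E step", call. = FALSE))
  Sinv <- chol2inv(ch)
  repeat {
    it <- it + 1L
    ## E step (Woodbury): Sigma = C - CA'S^-1AC, B = S^-1 A C
    B <- Sinv %*% AC
    Sigma <- diag(cdiag, M + K - 1L) - crossprod(AC, B)
    ShB <- Shat %*% B
    M2 <- Sigma + crossprod(B, ShB)
    ## M step
    psi_x_new <- pmax(diag(M2)[xi], variance_floor)
    Czz <- M2[zi, zi, drop = FALSE]
    W_new <- tryCatch(
      (ShB[, zi, drop = FALSE] - Tm %*% M2[xi, zi, drop = FALSE]) %*%
        solve(Czz),
      error = function(e)
        stop("collapsed global factor: <z'z> moment is singular",
             call. = FALSE))
    A_new <- cbind(W_new, Tm)
    quad_diag <- diag(Shat) - 2 * rowSums(A_new * ShB) +
      rowSums((A_new %*% M2) * A_new)
    psi_e_new <- pmax(quad_diag, variance_floor)
    ## log-likelihood of the updated parameters (factorization reused by
    ## the next E step)
    cdiag <- c(rep(1, M), psi_x_new)
    AC <- A_new * rep(cdiag, each = K)
    S <- AC %*% t(A_new) + diag(psi_e_new, K)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("updated model covariance is singular",
                          call. = FALSE)
    Sinv <- chol2inv(ch)
    ll <- -(N / 2) * (const + 2 * sum(log(diag(ch))) + sum(Sinv * Shat))
    trace[it] <- ll
    done <- if (criterion == "loglik") {
      is.finite(ll_old) && ll - ll_old < tol
    } else {
      max(rel_change(W_new, W), rel_change(psi_x_new, psi_x)) < tol
    }
    W <- W_new
    psi_e <- psi_e_new
    psi_x <- psi_x_new
    if (done) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
  }
  model <- timing_model(W, psi_e, psi_x, means = init$means,
                        labels = init$labels)
  list(model = model, loglik = trace[it], loglik_trace = trace[seq_len(it)],
       converged = converged, n_iter = it)
}

## relative parameter change, with the denominator floored at a small
## fraction of the block's largest magnitude: parameters indistinguishable
## from zero (e.g. a collapsed surplus factor) would otherwise never
## satisfy a purely relative criterion
rel_change <- function(new, old) {
  scale <- pmax(abs(old), 1e-3 * max(abs(old)), 1e-8)
  max(abs(new - old) / scale)
}

#' Fit the timing variability model by constrained EM
#'
#' Maximum-likelihood estimation with the multi-restart, two-stage protocol
#' of [fit_config()]: \code{n_restarts} randomly initialized EM runs to a
#' loose log-likelihood criterion, then the top \code{n_keep} continued
#' until the global weights and jitter variances stabilize, returning the
#' highest-likelihood result (ties broken toward the lowest restart index).
#' Trial-wise latent posteriors are computed from a final E step under the
#' selected parameters.
#'
#' @param data an [interval_dataset()] or numeric N x K duration matrix with
#'   N >= K + 1.
#' @param M number of global factors (>= 1).
#' @param config a [fit_config()].
#' @return an object of class \code{"timing_fit"} with elements
#'   \code{model}, \code{loglik}, \code{loglik_trace} (kept restarts),
#'   \code{converged}, \code{restart_logliks}, \code{latents}
#'   (a \code{"latent_posterior"}), \code{data_cov}, \code{model_cov},
#'   \code{srmr}, \code{n_trials} and \code{data}.
#' @export
fit_timing_model <- function(data, M = 1L, config = fit_config()) {
  if (!inherits(config, "fit_config")) stop("config must be a fit_config()",
                                            call. = FALSE)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("M must be a single integer >= 1", call. = FALSE)
  M <- as.integer(M)
  Y <- dataset_matrix(data)
  N <- nrow(Y)
  K <- ncol(Y)
  if (N < K + 1L)
    stop("need N >= K + 1 trials for a generically full-rank data ",
         "covariance; got N = ", N, ", K = ", K, call. = FALSE)
  mu <- colMeans(Y)
  Shat <- cov_mle(Y)
  if (!is.null(config$seed)) set.seed(config$seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, config$n_restarts)

  stage1 <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    set.seed(restart_seeds[r])
    init <- initialize_parameters(Y, M)
    if (inherits(data, "interval_dataset")) init$labels <- data$labels
    stage1[[r]] <- tryCatch(
      run_em_cov(Shat, N, init, config$tol_loose, config$max_iter,
                 "loglik", config$variance_floor),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "em_failure"))
  }
  ok <- !vapply(stage1, inherits, logical(1), "em_failure")
  if (!any(ok)) {
    msgs <- vapply(stage1, function(s) s$error %||% "", character(1))
    stop("all EM restarts failed:\n", paste(unique(msgs), collapse = "\n"),
         call. = FALSE)
  }
  lls <- rep(-Inf, config$n_restarts)
  lls[ok] <- vapply(stage1[ok], `[[`, numeric(1), "loglik")
  keep <- order(-lls, seq_along(lls))[seq_len(min(config$n_keep, sum(ok)))]

  stage2 <- lapply(keep, function(r)
    tryCatch(
      run_em_cov(Shat, N, stage1[[r]]$model, config$tol_strict,
                 config$max_iter, "param", config$variance_floor),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "em_failure")))
  ok2 <- !vapply(stage2, inherits, logical(1), "em_failure")
  if (!any(ok2))
    stop("all stage-2 EM continuations failed", call. = FALSE)
  lls2 <- rep(-Inf, length(stage2))
  lls2[ok2] <- vapply(stage2[ok2], `[[`, numeric(1), "loglik")
  best <- order(-lls2, seq_along(lls2))[1L]

  model <- stage2[[best]]$model
  model$means <- mu
  fit_data <- if (inherits(data, "interval_dataset")) data else
    interval_dataset(Y, check_positive = FALSE)
  model$labels <- fit_data$labels
  latents <- e_step(model, fit_data)
  S <- model_covariance(model)
  traces <- lapply(seq_along(keep), function(i)
    if (ok2[i]) c(stage1[[keep[i]]]$loglik_trace, stage2[[i]]$loglik_trace)
    else stage1[[keep[i]]]$loglik_trace)
  structure(
    list(model = model, loglik = lls2[best],
         loglik_trace = traces, best_restart = keep[best],
         converged = stage2[[best]]$converged &&
           stage1[[keep[best]]]$converged,
         restart_logliks = lls, kept_restarts = keep,
         latents = latents, data_cov = Shat, model_cov = S,
         srmr = srmr(Shat, S), n_trials = N, M = M, config = config,
         data = fit_data),
    class = "timing_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.timing_fit <- function(x, ...) {
  cat("Timing variability model fit\n")
  cat("  N =", x$n_trials, "trials, K =", x$model$n_intervals,
      "intervals, M =", x$M, "global factor(s)\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " SRMR:", format(x$srmr, digits = 4), "\n")
  cat("  restarts:", length(x$restart_logliks),
      " kept:", length(x$kept_restarts),
      " converged:", x$converged, "\n")
  print(x$model)
  invisible(x)
}

#' @export
logLik.timing_fit <- function(object, ...) {
  K <- object$model$n_intervals
  M <- object$M
  structure(object$loglik, df = count_parameters(K, M),
            nobs = object$n_trials, class = "logLik")
}

#' Trial-wise latent variable estimates
#'
#' Extracts maximum-likelihood (posterior mean = posterior mode) estimates
#' of the latent variables for every trial: global factors \code{z}, boundary
#' jitters \code{x}, and independent deviations
#' \code{e = y - means - z W' - x T'} (so the reconstruction identity holds
#' exactly).  Trial metadata is carried along so downstream analyses
#' (circadian modulation, day-to-day drift) can be run on the estimates.
#'
#' @param fit a \code{"timing_fit"} from [fit_timing_model()].
#' @return a data.frame with one row per trial: \code{trial}, any metadata
#'   columns, \code{z1..zM}, \code{x1..x(K-1)}, \code{e1..eK}.
#' @export
estimate_latents <- function(fit) {
  stopifnot(inherits(fit, "timing_fit"))
  model <- fit$model
  Y <- fit$data$durations
  U <- fit$latents$post_mean
  Z <- U[, fit$latents$z_idx, drop = FALSE]
  X <- U[, fit$latents$x_idx, drop = FALSE]
  E <- sweep(Y, 2L, model$means, "-") - Z %*% t(model$global_weights) -
    X %*% t(model$differencing)
  out <- data.frame(trial = seq_len(nrow(Y)))
  if (!is.null(fit$data$meta)) out <- cbind(out, fit$data$meta)
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(E) <- paste0("e", seq_len(ncol(E)))
  cbind(out, Z, X, E)
}
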