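#' Differencing matrix mapping boundary jitter to interval deviations
#'
#' Builds the fixed K x (K-1) matrix \code{T} with \code{T[k, k] = +1}
#' (jitter at boundary k shifts the offset of interval k) and
#' \code{T[k + 1, k] = -1} (the same jitter shifts the onset of interval
#' k + 1).  Boundary k is the internal boundary between interval k and
#' interval k + 1.  Every column sums to zero: moving a boundary never
#' changes the total sequence length.
#'
#' @param K number of consecutive intervals (K >= 2).
#' @return a K x (K-1) matrix of 0 / +1 / -1.
#' @examples
#' differencing_matrix(3)
#' @export
differencing_matrix <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K != round(K) || K < 2)
    stop("K must be a single integer >= 2", call. = FALSE)
  K <- as.integer(K)
  Tm <- matrix(0, K, K - 1L)
  idx <- seq_len(K - 1L)
  Tm[cbind(idx, idx)] <- 1
  Tm[cbind(idx + 1L, idx)] <- -1
  Tm
}

#' Timing variability model
#'
#' Container for the parameters of the timing variability model of one
#' sequence template: a K x M matrix of global factor weights (msec per unit
#' latent; each global latent has unit variance by convention), per-interval
#' independent variances (msec^2), jitter variances at the K-1 internal
#' boundaries (msec^2), and mean interval durations (msec).  Jitter at the
#' first onset and last offset of the sequence cannot be separated from
#' independent noise (there is no adjacent interval on the far side to show
#' the tell-tale negative covariance) and is absorbed into the independent
#' variance of the edge intervals; diagnostics flag those intervals.
#'
#' @param global_weights numeric K-vector or K x M matrix W of global factor
#'   weights, msec.
#' @param independent_vars numeric K-vector of independent variances, msec^2,
#'   all >= 0.
#' @param jitter_vars numeric (K-1)-vector of boundary jitter variances,
#'   msec^2, all >= 0; element k belongs to the boundary between interval k
#'   and interval k + 1.
#' @param means numeric K-vector of mean interval durations, msec; defaults
#'   to zeros (a mean-centred model).
#' @param labels optional character K-vector of interval types, each one of
#'   \code{"syllable"}, \code{"gap_within"}, \code{"gap_between"}.
#' @return an object of class \code{"timing_model"}.
#' @seealso [model_covariance()], [simulate_intervals()], [fit_timing_model()]
#' @export
timing_model <- function(global_weights, independent_vars, jitter_vars,
                         means = NULL, labels = NULL) {
  W <- unname(as.matrix(global_weights))
  if (!is.numeric(W)) stop("global_weights must be numeric", call. = FALSE)
  K <- nrow(W)
  M <- ncol(W)
  if (K < 2L || M < 1L)
    stop("global_weights must be a K x M matrix with K >= 2, M >= 1",
         call. = FALSE)
  independent_vars <- as.numeric(independent_vars)
  jitter_vars <- as.numeric(jitter_vars)
  if (length(independent_vars) != K)
    stop("independent_vars must have length K = ", K, call. = FALSE)
  if (length(jitter_vars) != K - 1L)
    stop("jitter_vars must have length K - 1 = ", K - 1L, call. = FALSE)
  if (any(!is.finite(W)) || any(!is.finite(independent_vars)) ||
      any(!is.finite(jitter_vars)))
    stop("model parameters must be finite", call. = FALSE)
  if (any(independent_vars < 0)) stop("independent_vars must be >= 0",
                                      call. = FALSE)
  if (any(jitter_vars < 0)) stop("jitter_vars must be >= 0", call. = FALSE)
  if (is.null(means)) means <- numeric(K)
  means <- as.numeric(means)
  if (length(means) != K) stop("means must have length K", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != K) stop("labels must have length K", call. = FALSE)
    ok <- labels %in% c("syllable", "gap_within", "gap_between")
    if (!all(ok))
      stop("labels must be 'syllable', 'gap_within' or 'gap_between'",
           call. = FALSE)
  }
  structure(
    list(n_intervals = K, n_global = M, global_weights = W,
         independent_vars = independent_vars, jitter_vars = jitter_vars,
         means = means, labels = labels,
         differencing = differencing_matrix(K)),
    class = "timing_model")
}

#' @export
print.timing_model <- function(x, ...) {
  cat("Timing variability model: K =", x$n_intervals,
      "intervals, M =", x$n_global, "global factor(s)\n")
  cat("  tempo weights (factor 1, msec): ",
      paste(signif(x$global_weights[, 1L], 3), collapse = " "), "\n")
  cat("  independent SDs (msec): ",
      paste(signif(sqrt(x$independent_vars), 3), collapse = " "), "\n")
  cat("  jitter SDs (msec): ",
      paste(signif(sqrt(x$jitter_vars), 3), collapse = " "), "\n")
  invisible(x)
}

#' Model-implied covariance of interval durations
#'
#' Assembles the K x K covariance matrix implied by the model,
#' \deqn{S = W W' + T \,\mathrm{diag}(\Psi_x)\, T' + \mathrm{diag}(\Psi_e),}
#' the sum of the global, jitter and independent covariance components.
#' Jitter at boundary k contributes \code{-jitter_vars[k]} to the covariance
#' of intervals k and k + 1.
#'
#' @param model a [timing_model()].
#' @return a symmetric K x K covariance matrix, msec^2.
#' @export
model_covariance <- function(model) {
  stopifnot(inherits(model, "timing_model"))
  W <- model$global_weights
  Tm <- model$differencing
  S <- tcrossprod(W) + Tm %*% (model$jitter_vars * t(Tm)) +
    diag(model$independent_vars, model$n_intervals)
  (S + t(S)) / 2
}

#' Exact Gaussian log-likelihood of an interval dataset
#'
#' Evaluates the zero-mean multivariate Gaussian log density of the
#' mean-subtracted duration rows under the model-implied covariance S:
#' \deqn{\ell = -\tfrac{N}{2}\left[K \log 2\pi + \log\det S
#'   + \mathrm{tr}(S^{-1} \hat S)\right],}
#' where \eqn{\hat S} is the data covariance with 1/N normalization.
#' Column means are removed internally, so adding a constant to a column of
#' the data leaves the value unchanged.
#'
#' @param model a [timing_model()].
#' @param data an [interval_dataset()] or numeric N x K matrix of durations.
#' @return scalar log-likelihood in nats; \code{-Inf} (with a warning) when
#'   the model covariance is singular.
#' @export
model_loglik <- function(model, data) {
  Y <- dataset_matrix(data)
  K <- model$n_intervals
  if (ncol(Y) != K) stop("data has ", ncol(Y), " columns but model has K = ",
                         K, call. = FALSE)
  N <- nrow(Y)
  Shat <- cov_mle(Y)
  loglik_from_cov(model_covariance(model), Shat, N)
}

## log-likelihood from sufficient statistics (Shat with 1/N normalization)
loglik_from_cov <- function(S, Shat, N) {
  K <- nrow(S)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    warning("model covariance is singular; log-likelihood is -Inf",
            call. = FALSE)
    return(-Inf)
  }
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  -(N / 2) * (K * log(2 * pi) + logdet + sum(Sinv * Shat))
}

## ML (1/N) covariance of the columns of Y after removing column means
cov_mle <- function(Y) {
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  crossprod(Yc) / nrow(Y)
}

#' Simulate interval durations from a timing model
#'
#' Runs the model in generative mode: for each of \code{n} trials it draws
#' the global latents z (unit variance), boundary jitters x and independent
#' deviations e (scaled by the model's standard deviations) and combines
#' them as \code{y = means + z W' + x T' + e}.  The true latent draws are
#' returned alongside the data so that recovery of both parameters and
#' trial-wise latents can be scored.
#'
#' @param model a [timing_model()].
#' @param n number of trials to simulate (n >= 1).
#' @param latents a [latent_spec()] giving the (standardized) latent
#'   distribution family, or a family name; default Gaussian.
#' @param seed optional integer seed for reproducibility.
#' @return a list of class \code{"interval_sim"} with elements \code{data}
#'   (an [interval_dataset()]), and the true latent draws \code{z}
#'   (n x M), \code{x} (n x (K-1)) and \code{e} (n x K).
#' @export
simulate_intervals <- function(model, n, latents = latent_spec("gaussian"),
                               seed = NULL) {
  stopifnot(inherits(model, "timing_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (is.character(latents)) latents <- latent_spec(latents)
  if (!inherits(latents, "latent_spec"))
    stop("latents must be a latent_spec or family name", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  K <- model$n_intervals
  M <- model$n_global
  Z <- draw_latent_matrix(latents, n, M)
  X <- draw_latent_matrix(latents, n, K - 1L)
  E <- draw_latent_matrix(latents, n, K)
  X <- sweep(X, 2L, sqrt(model$jitter_vars), "*")
  E <- sweep(E, 2L, sqrt(model$independent_vars), "*")
  Y <- Z %*% t(model$global_weights) + X %*% t(model$differencing) + E
  Y <- sweep(Y, 2L, model$means, "+")
  data <- interval_dataset(Y, labels = model$labels, check_positive = FALSE)
  structure(list(data = data, z = Z, x = X, e = E, seed = seed),
            class = "interval_sim")
}
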