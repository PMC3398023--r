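#' Number of free parameters of the timing model
#'
#' K x M global weights, K independent variances and K - 1 jitter variances:
#' \code{p = K*M + K + (K - 1)}.
#'
#' @param K number of intervals (>= 3).
#' @param M number of global factors (>= 1).
#' @return integer parameter count.
#' @export
count_parameters <- function(K, M) {
  stopifnot(K >= 3, M >= 1)
  as.integer(K * M + K + (K - 1))
}

#' Bayesian Information Criterion for a timing model fit
#'
#' \code{BIC = -2 * loglik + p * log(N)} with p from [count_parameters()].
#'
#' @param loglik maximized log-likelihood.
#' @param K,M model dimensions.
#' @param N number of trials (>= 2).
#' @return scalar BIC (lower is better).
#' @export
bic_score <- function(loglik, K, M, N) {
  stopifnot(N >= 2)
  -2 * loglik + count_parameters(K, M) * log(N)
}

#' Choose the number of global factors by BIC
#'
#' Runs the full fitting protocol (including all restarts) once per
#' candidate dimensionality and picks the M with the lowest BIC; ties are
#' broken toward the smaller (more parsimonious) M.  Every candidate uses
#' an identical [fit_config()], so restart budgets are equalized across M.
#'
#' @param data an [interval_dataset()] or duration matrix.
#' @param config a [fit_config()].
#' @param M_range candidate factor counts (default 1:4).
#' @return an object of class \code{"dimension_selection"}: a data.frame
#'   \code{table} with columns \code{m, loglik, p, bic}, the
#'   \code{chosen_m}, and the list of \code{fits} indexed by as.character(m).
#' @export
select_global_dimension <- function(data, config = fit_config(),
                                    M_range = 1:4) {
  stopifnot(all(M_range >= 1))
  fits <- list()
  rows <- list()
  N <- nrow(dataset_matrix(data))
  K <- ncol(dataset_matrix(data))
  for (m in M_range) {
    f <- tryCatch(fit_timing_model(data, M = m, config = config),
                  error = function(e) {
                    warning("fit failed for M = ", m, ": ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(f)) next
    fits[[as.character(m)]] <- f
    rows[[as.character(m)]] <- data.frame(
      m = m, loglik = f$loglik, p = count_parameters(K, m),
      bic = bic_score(f$loglik, K, m, N))
  }
  if (length(rows) == 0L)
    stop("model fitting failed for every candidate M", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  chosen <- tab$m[order(tab$bic, tab$m)][1L]
  structure(list(table = tab, chosen_m = chosen, fits = fits,
                 n_trials = N),
            class = "dimension_selection")
}

#' @export
print.dimension_selection <- function(x, ...) {
  cat("Global-factor dimensionality selection (BIC)\n")
  print(x$table, row.names = FALSE)
  cat("chosen M =", x$chosen_m, "\n")
  invisible(x)
}

#' Rotate the global weight matrix to the tempo basis
#'
#' The fitted weight matrix W is only identified up to an orthonormal
#' rotation of latent space.  This rotation confines all global
#' sequence-length (tempo) variance to the first factor: the first latent
#' direction is \eqn{v_1 = W'1 / \|W'1\|}, and the remaining columns are the
#' principal axes of the deflated global covariance
#' \eqn{B = W (I - v_1 v_1') W'}, in descending eigenvalue order.  Every
#' rotated column j >= 2 is sequence-length neutral
#' (\eqn{1'(WR)_j = 0}) and \eqn{(WR)(WR)' = WW'} exactly.
#'
#' @param W numeric K x M global weight matrix (or a K-vector for M = 1).
#' @return an object of class \code{"tempo_rotation"}: the orthonormal
#'   \code{R}, \code{rotated} = W R, \code{v1}, and the \code{eigenvalues}
#'   and \code{eigenvectors} of the deflated matrix B.
#' @export
rotate_to_tempo_basis <- function(W) {
  W <- as.matrix(W)
  K <- nrow(W)
  M <- ncol(W)
  w1 <- colSums(W)                      # W' 1
  nv <- sqrt(sum(w1^2))
  if (nv < 1e-10 * max(1, max(abs(W))))
    stop("no tempo direction: W'1 is (numerically) zero, the global ",
         "factors carry no net sequence-length sensitivity", call. = FALSE)
  v1 <- w1 / nv
  if (M == 1L) {
    R <- matrix(1, 1, 1)
    return(structure(list(R = R, rotated = W, v1 = v1,
                          eigenvalues = numeric(0),
                          eigenvectors = matrix(0, K, 0)),
                     class = "tempo_rotation"))
  }
  P <- diag(M) - tcrossprod(v1)
  B <- W %*% P %*% t(W)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > 1e-12 * max(1, eig$values[1L]))
  pos <- pos[seq_len(min(length(pos), M - 1L))]
  cols <- lapply(pos, function(j)
    P %*% crossprod(W, eig$vectors[, j]) / sqrt(eig$values[j]))
  R <- cbind(v1, do.call(cbind, c(cols, list(matrix(0, M, 0)))))
  if (ncol(R) < M) {
    ## deflated matrix is rank deficient: complete with an orthonormal
    ## basis of the remaining latent null space
    null_basis <- qr.Q(qr(cbind(R, diag(M))))[, (ncol(R) + 1L):M,
                                              drop = FALSE]
    R <- cbind(R, null_basis)
  }
  colnames(R) <- NULL
  structure(list(R = R, rotated = W %*% R, v1 = v1,
                 eigenvalues = eig$values[pos],
                 eigenvectors = eig$vectors[, pos, drop = FALSE]),
            class = "tempo_rotation")
}

#' Resolve the sign indeterminacy of rotated factor columns
#'
#' Each factor column is only identified up to sign.  Factor 1 (tempo) is
#' flipped so the sum of its weights is positive (nearly all tempo weights
#' are positive in song data); factors j >= 2 are flipped so the sum of
#' their weights over syllable-labelled intervals is positive.  A column
#' whose deciding sum is exactly zero is left unchanged with a warning.
#'
#' @param WR rotated K x M weight matrix (from [rotate_to_tempo_basis()]).
#' @param interval_labels character K-vector of interval types; needed for
#'   columns beyond the first.
#' @return the sign-normalized weight matrix.
#' @export
apply_sign_convention <- function(WR, interval_labels = NULL) {
  WR <- as.matrix(WR)
  s1 <- sum(WR[, 1L])
  if (s1 < 0) WR[, 1L] <- -WR[, 1L]
  else if (s1 == 0)
    warning("factor 1 weight sum is exactly zero; sign left unchanged",
            call. = FALSE)
  if (ncol(WR) > 1L) {
    if (is.null(interval_labels))
      stop("interval_labels are required to sign-normalize factors >= 2",
           call. = FALSE)
    syl <- interval_labels == "syllable"
    for (j in 2:ncol(WR)) {
      sj <- sum(WR[syl, j])
      if (sj < 0) WR[, j] <- -WR[, j]
      else if (sj == 0)
        warning("factor ", j, " syllable weight sum is exactly zero; ",
                "sign left unchanged", call. = FALSE)
    }
  }
  WR
}
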