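## Align a fitted model (and optionally its latent estimates) to the truth
## before scoring recovery error.  Factor columns are only identified up to
## an orthonormal rotation, so for M > 1 both truth and estimate are rotated
## to the tempo basis (which canonicalizes factor 1), and the residual
## factors are matched greedily by maximal absolute weight-column
## correlation with sign fixing.  For M = 1 only the sign is resolved, by
## the inner product with the true weights.  None of this changes WW'.
align_estimate <- function(est_model, true_model,
                           Z_est = NULL, Z_true = NULL) {
  We <- est_model$global_weights
  Wt <- true_model$global_weights
  M <- ncol(Wt)
  if (M == 1L) {
    s <- if (sum(We * Wt) < 0) -1 else 1
    return(list(W_est = We * s, W_true = Wt,
                Z_est = if (!is.null(Z_est)) Z_est * s,
                Z_true = Z_true))
  }
  rot_t <- rotate_to_tempo_basis(Wt)
  rot_e <- rotate_to_tempo_basis(We)
  Wt_r <- rot_t$rotated
  We_r <- rot_e$rotated
  Zt_r <- if (!is.null(Z_true)) Z_true %*% rot_t$R
  Ze_r <- if (!is.null(Z_est)) Z_est %*% rot_e$R
  perm <- integer(M)
  sgn <- numeric(M)
  perm[1L] <- 1L
  sgn[1L] <- 1
  avail <- 2:M
  for (j in 2:M) {
    cors <- vapply(avail, function(a)
      suppressWarnings(cor(We_r[, a], Wt_r[, j])), numeric(1))
    cors[is.na(cors)] <- 0
    best <- which.max(abs(cors))
    perm[j] <- avail[best]
    sgn[j] <- if (cors[best] < 0) -1 else 1
    avail <- avail[-best]
  }
  We_al <- sweep(We_r[, perm, drop = FALSE], 2L, sgn, "*")
  Ze_al <- if (!is.null(Ze_r))
    sweep(Ze_r[, perm, drop = FALSE], 2L, sgn, "*")
  list(W_est = We_al, W_true = Wt_r, Z_est = Ze_al, Z_true = Zt_r)
}

#' Monte Carlo parameter and latent recovery experiment
#'
#' Repeatedly simulates data from a known model, refits the model (same
#' number of global factors), aligns the estimate to the truth, and
#' accumulates recovery error.  Error is reported as the median absolute
#' deviation of estimates from the true values (MAD), on the msec / SD
#' scale, per parameter class: tempo weights (factor 1), higher global
#' factors (if any), independent SDs and jitter SDs.  Latent recovery is
#' scored as the Pearson correlation between each true latent draw and its
#' trial-wise posterior-mean estimate, summarized by the per-class median.
#'
#' @param true_model the generating [timing_model()].
#' @param N trials per replicate.
#' @param reps number of replicates (>= 2).
#' @param spec a [latent_spec()] for the latent distributions.
#' @param config a [fit_config()] (its seed field is overridden per
#'   replicate by a sub-seed of \code{seed}).
#' @param seed master seed; every replicate derives simulation and fitting
#'   sub-seeds from it, so the whole report is reproducible.
#' @return an object of class \code{"mc_report"}: per-class \code{mad}
#'   (named vector), per-class median latent correlations
#'   \code{latent_cor}, pooled error and correlation vectors, the SRMR
#'   median and MAD across replicates, per-replicate summaries, seeds and
#'   the failed-replicate count.
#' @export
recovery_experiment <- function(true_model, N, reps,
                                spec = latent_spec("gaussian"),
                                config = fit_config(n_restarts = 8L,
                                                    n_keep = 2L),
                                seed = 1L) {
  stopifnot(inherits(true_model, "timing_model"), reps >= 2)
  if (is.character(spec)) spec <- latent_spec(spec)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  M <- true_model$n_global
  err <- list(tempo = numeric(0), higher_global = numeric(0),
              independent = numeric(0), jitter = numeric(0))
  cors <- list(tempo = numeric(0), higher_global = numeric(0),
               independent = numeric(0), jitter = numeric(0))
  srmrs <- numeric(0)
  per_rep <- list()
  n_failed <- 0L
  for (i in seq_len(reps)) {
    sim <- simulate_intervals(true_model, N, latents = spec,
                              seed = rep_seeds[i])
    cfg <- config
    cfg$seed <- rep_seeds[i]
    fit <- tryCatch(fit_timing_model(sim$data, M = M, config = cfg),
                    error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    Z_est <- fit$latents$post_mean[, fit$latents$z_idx, drop = FALSE]
    al <- align_estimate(fit$model, true_model, Z_est = Z_est,
                         Z_true = sim$z)
    e_tempo <- abs(al$W_est[, 1L] - al$W_true[, 1L])
    e_higher <- if (M > 1L)
      abs(al$W_est[, -1L, drop = FALSE] - al$W_true[, -1L, drop = FALSE])
    e_ind <- abs(sqrt(fit$model$independent_vars) -
                   sqrt(true_model$independent_vars))
    e_jit <- abs(sqrt(fit$model$jitter_vars) -
                   sqrt(true_model$jitter_vars))
    err$tempo <- c(err$tempo, e_tempo)
    if (M > 1L) err$higher_global <- c(err$higher_global, as.numeric(e_higher))
    err$independent <- c(err$independent, e_ind)
    err$jitter <- c(err$jitter, e_jit)

    X_est <- fit$latents$post_mean[, fit$latents$x_idx, drop = FALSE]
    lat <- estimate_latents(fit)
    E_est <- as.matrix(lat[, grep("^e[0-9]+$", names(lat)), drop = FALSE])
    c_tempo <- cor(al$Z_est[, 1L], al$Z_true[, 1L])
    c_higher <- if (M > 1L)
      vapply(2:M, function(j) cor(al$Z_est[, j], al$Z_true[, j]), numeric(1))
    c_x <- vapply(seq_len(ncol(X_est)),
                  function(j) cor(X_est[, j], sim$x[, j]), numeric(1))
    c_e <- vapply(seq_len(ncol(E_est)),
                  function(j) cor(E_est[, j], sim$e[, j]), numeric(1))
    cors$tempo <- c(cors$tempo, c_tempo)
    if (M > 1L) cors$higher_global <- c(cors$higher_global, c_higher)
    cors$independent <- c(cors$independent, c_e)
    cors$jitter <- c(cors$jitter, c_x)
    srmrs <- c(srmrs, fit$srmr)
    per_rep[[i]] <- data.frame(
      rep = i, seed = rep_seeds[i], srmr = fit$srmr, loglik = fit$loglik,
      tempo_err = median(e_tempo), independent_err = median(e_ind),
      jitter_err = median(e_jit), tempo_cor = c_tempo,
      independent_cor = median(c_e), jitter_cor = median(c_x))
  }
  if (length(srmrs) == 0L)
    stop("every Monte Carlo replicate failed to fit", call. = FALSE)
  mads <- vapply(err, function(v) if (length(v)) median(v) else NA_real_,
                 numeric(1))
  lat_cor <- vapply(cors, function(v) if (length(v)) median(v) else NA_real_,
                    numeric(1))
  structure(
    list(mad = mads, latent_cor = lat_cor, errors = err,
         correlations = cors, srmr_median = median(srmrs),
         srmr_mad = median(abs(srmrs - median(srmrs))), srmr = srmrs,
         per_rep = do.call(rbind, per_rep), n = N, reps = reps,
         family = spec$family, seed = seed, rep_seeds = rep_seeds,
         n_failed = n_failed),
    class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  cat("Monte Carlo recovery report: N =", x$n, ", reps =", x$reps,
      ", latents =", x$family, "\n")
  cat("  parameter MAD (msec, SD scale):\n")
  print(signif(x$mad, 3))
  cat("  median latent correlations:\n")
  print(signif(x$latent_cor, 3))
  cat("  SRMR:", signif(x$srmr_median, 3), "+/-", signif(x$srmr_mad, 3),
      " failed replicates:", x$n_failed, "\n")
  invisible(x)
}

#' Sample-size sweep of recovery error
#'
#' Runs [recovery_experiment()] at several sample sizes and regresses the
#' pooled parameter error on \eqn{1/\sqrt{N}} (error = a + b/sqrt(N)),
#' reporting the goodness of that square-root law, the analogous SRMR
#' scaling, and the ceiling behaviour of the latent correlations (the
#' change in tempo-latent correlation between the two largest N).
#'
#' @param true_model generating [timing_model()].
#' @param N_list at least 3 distinct sample sizes.
#' @param reps replicates per sample size.
#' @param spec a [latent_spec()].
#' @param config a [fit_config()].
#' @param seed master seed.
#' @return an object of class \code{"mc_sweep"}: the per-N \code{table},
#'   the \code{scaling} lm fit and its \code{r_squared}, SRMR scaling
#'   \code{r_squared_srmr}, \code{ceiling_delta}, and the individual
#'   \code{reports}.
#' @export
sample_size_sweep <- function(true_model, N_list, reps,
                              spec = latent_spec("gaussian"),
                              config = fit_config(n_restarts = 8L,
                                                  n_keep = 2L),
                              seed = 1L) {
  N_list <- sort(unique(as.integer(N_list)))
  stopifnot(length(N_list) >= 3L)
  set.seed(seed)
  sweep_seeds <- sample.int(.Machine$integer.max - 1L, length(N_list))
  reports <- list()
  rows <- list()
  for (i in seq_along(N_list)) {
    rep_i <- recovery_experiment(true_model, N_list[i], reps, spec = spec,
                                 config = config, seed = sweep_seeds[i])
    reports[[as.character(N_list[i])]] <- rep_i
    pooled <- unlist(rep_i$errors, use.names = FALSE)
    rows[[i]] <- data.frame(
      n = N_list[i], overall_mad = median(pooled),
      tempo_mad = rep_i$mad[["tempo"]],
      independent_mad = rep_i$mad[["independent"]],
      jitter_mad = rep_i$mad[["jitter"]],
      srmr = rep_i$srmr_median,
      tempo_cor = rep_i$latent_cor[["tempo"]],
      independent_cor = rep_i$latent_cor[["independent"]],
      jitter_cor = rep_i$latent_cor[["jitter"]])
  }
  tab <- do.call(rbind, rows)
  fit_mad <- lm(overall_mad ~ I(1 / sqrt(n)), data = tab)
  fit_srmr <- lm(srmr ~ I(1 / sqrt(n)), data = tab)
  r2 <- function(f) summary(f)$r.squared
  k <- nrow(tab)
  structure(
    list(table = tab, scaling = fit_mad, r_squared = r2(fit_mad),
         r_squared_srmr = r2(fit_srmr),
         ceiling_delta = abs(tab$tempo_cor[k] - tab$tempo_cor[k - 1L]),
         reports = reports, seed = seed),
    class = "mc_sweep")
}

#' @export
print.mc_sweep <- function(x, ...) {
  cat("Sample-size sweep of Monte Carlo recovery error\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  cat("error = a + b/sqrt(N):  R^2 =", signif(x$r_squared, 4),
      "  (SRMR scaling R^2 =", signif(x$r_squared_srmr, 4), ")\n")
  cat("tempo-correlation change between two largest N:",
      signif(x$ceiling_delta, 3), "\n")
  invisible(x)
}
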