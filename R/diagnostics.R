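#' Standardized root-mean-square residual (SRMR)
#'
#' Goodness-of-fit between the data and model-implied covariance matrices
#' after standardizing both by the data standard deviations: the residual
#' correlation is
#' \eqn{r_{jk} = \hat S_{jk}/(s_j s_k) - S_{jk}/(s_j s_k)} with
#' \eqn{s_j = \sqrt{\hat S_{jj}}}, and SRMR is the root-mean-square of
#' \eqn{r_{jk}} over the lower triangle, counting each unordered pair once
#' and including the diagonal (the conventional summation set; set
#' \code{include_diagonal = FALSE} for a sensitivity check).  As a factor
#' analysis rule of thumb, SRMR below about 0.08 indicates an adequate fit
#' and below 0.05 an excellent one.
#'
#' @param data_cov K x K data covariance matrix.
#' @param model_cov K x K model-implied covariance matrix.
#' @param include_diagonal include the diagonal residuals (default TRUE).
#' @return scalar SRMR >= 0.
#' @export
srmr <- function(data_cov, model_cov, include_diagonal = TRUE) {
  data_cov <- as.matrix(data_cov)
  model_cov <- as.matrix(model_cov)
  stopifnot(nrow(data_cov) == ncol(data_cov),
            all(dim(data_cov) == dim(model_cov)))
  s <- sqrt(diag(data_cov))
  if (any(s <= 0))
    stop("zero data variance for interval(s) ",
         paste(which(s <= 0), collapse = ", "), call. = FALSE)
  D <- tcrossprod(s)
  r <- data_cov / D - model_cov / D
  idx <- lower.tri(r, diag = include_diagonal)
  sqrt(mean(r[idx]^2))
}

#' Per-interval variance decomposition
#'
#' Splits the model-implied covariance into its three additive component
#' matrices — global \eqn{WW'}, jitter \eqn{T\,\mathrm{diag}(\Psi_x)\,T'}
#' and independent \eqn{\mathrm{diag}(\Psi_e)} — and summarizes each
#' interval: mean duration; global SD (row norm of W, equal to |w_k| for
#' M = 1) and, for M > 1, the tempo-rotated factor-1 weight; independent
#' SD; jitter SD (square root of the sum of the jitter variances at the two
#' flanking boundaries, edge boundaries contributing 0); tempo elasticity
#' (tempo weight / mean, a partial CV with respect to tempo); independent
#' CV; and total model SD.  Estimates for the first and last interval are
#' inherently less accurate (their outer-edge jitter is unidentifiable) and
#' those intervals are excluded from the summary table by default.
#'
#' @param model a fitted [timing_model()] (or a \code{"timing_fit"}).
#' @param keep_edges keep the first and last interval in the summary table
#'   (they are always flagged via the \code{edge} column).
#' @return a list of class \code{"interval_decomposition"}:
#'   \code{components} (list of the three K x K matrices, which sum to the
#'   model covariance exactly) and \code{summary} (data.frame, one row per
#'   reported interval).
#' @export
interval_variance_decomposition <- function(model, keep_edges = FALSE) {
  if (inherits(model, "timing_fit")) model <- model$model
  stopifnot(inherits(model, "timing_model"))
  K <- model$n_intervals
  W <- model$global_weights
  Tm <- model$differencing
  comp <- list(global = tcrossprod(W),
               jitter = Tm %*% (model$jitter_vars * t(Tm)),
               independent = diag(model$independent_vars, K))
  psi_x_padded <- c(0, model$jitter_vars, 0)
  tempo_w <- if (model$n_global == 1L) W[, 1L] else
    rotate_to_tempo_basis(W)$rotated[, 1L]
  mu <- model$means
  cv_ok <- all(mu > 0)
  if (!cv_ok)
    warning("non-positive mean durations: CV-type measures set to NA",
            call. = FALSE)
  summ <- data.frame(
    interval = seq_len(K),
    label = if (is.null(model$labels)) NA_character_ else model$labels,
    mean = mu,
    tempo_weight = tempo_w,
    global_sd = sqrt(rowSums(W^2)),
    independent_sd = sqrt(model$independent_vars),
    jitter_sd = sqrt(psi_x_padded[seq_len(K)] + psi_x_padded[2:(K + 1)]),
    total_sd = sqrt(diag(comp$global) + diag(comp$jitter) +
                      model$independent_vars),
    tempo_elasticity = if (cv_ok) tempo_w / mu else NA_real_,
    independent_cv = if (cv_ok) sqrt(model$independent_vars) / mu
                     else NA_real_,
    edge = seq_len(K) %in% c(1L, K))
  if (!keep_edges) summ <- summ[!summ$edge, , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(components = comp, summary = summ),
            class = "interval_decomposition")
}

#' @export
print.interval_decomposition <- function(x, ...) {
  cat("Per-interval variance decomposition (msec / msec-SD units)\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Sequence-length (motif-length) variance decomposition
#'
#' Because the global factors are shared by every interval, their
#' contributions accumulate coherently in the total sequence length:
#' \code{global_var = ||1'W||^2} (for M = 1 this is \eqn{(\sum_k w_k)^2}),
#' whereas independent noise adds incoherently,
#' \code{independent_var = sum(independent_vars)}.  Boundary jitter
#' contributes nothing at all (each jitter lengthens one interval exactly
#' as it shortens its neighbour, \eqn{1'T = 0}).
#'
#' @param model a [timing_model()] (or a \code{"timing_fit"}).
#' @return a list with \code{global_var}, \code{independent_var} (msec^2)
#'   and \code{global_fraction} = global / (global + independent).
#' @export
sequence_length_decomposition <- function(model) {
  if (inherits(model, "timing_fit")) model <- model$model
  stopifnot(inherits(model, "timing_model"))
  g <- sum(colSums(model$global_weights)^2)
  ind <- sum(model$independent_vars)
  list(global_var = g, independent_var = ind,
       global_fraction = g / (g + ind))
}

#' Compare variability measures across interval types
#'
#' Rank-based comparison of the per-interval summary measures between
#' interval groups (for example syllables vs silent gaps): per-group
#' medians with raw median absolute deviations (no consistency factor),
#' pairwise Wilcoxon rank-sum tests, and Spearman correlations of each
#' measure against mean interval duration (the length-scaling analysis).
#'
#' @param summary the \code{summary} data.frame of an
#'   [interval_variance_decomposition()] (or the decomposition itself),
#'   possibly pooled over several sequences/birds.
#' @param measures columns to compare.
#' @param group_col grouping column (default \code{"label"}).
#' @return a list of class \code{"group_comparison"} with data.frames
#'   \code{group_stats} (median, mad, n per group and measure),
#'   \code{wilcoxon} (pairwise rank-sum p-values; absent with one group)
#'   and \code{spearman} (rho and p of each measure vs mean duration).
#' @export
group_compare <- function(summary,
                          measures = c("tempo_elasticity", "independent_cv",
                                       "global_sd", "independent_sd",
                                       "jitter_sd"),
                          group_col = "label") {
  if (inherits(summary, "interval_decomposition")) summary <- summary$summary
  stopifnot(is.data.frame(summary))
  measures <- intersect(measures, names(summary))
  groups <- unique(stats::na.omit(summary[[group_col]]))
  stats_rows <- list()
  wilcox_rows <- list()
  spearman_rows <- list()
  for (m in measures) {
    x <- summary[[m]]
    for (g in groups) {
      xg <- x[summary[[group_col]] == g]
      stats_rows[[paste(m, g)]] <- data.frame(
        measure = m, group = g, n = length(xg),
        median = median(xg), mad = median(abs(xg - median(xg))))
    }
    if (length(groups) >= 2L) {
      pairs <- utils::combn(as.character(groups), 2L, simplify = FALSE)
      for (p in pairs) {
        xa <- x[summary[[group_col]] == p[1L]]
        xb <- x[summary[[group_col]] == p[2L]]
        pv <- if (length(xa) >= 1L && length(xb) >= 1L)
          suppressWarnings(wilcox.test(xa, xb)$p.value) else NA_real_
        wilcox_rows[[paste(m, p[1L], p[2L])]] <- data.frame(
          measure = m, group_a = p[1L], group_b = p[2L], p_value = pv)
      }
    }
    if ("mean" %in% names(summary) && length(unique(x)) > 1L) {
      ct <- suppressWarnings(cor.test(x, summary$mean, method = "spearman"))
      spearman_rows[[m]] <- data.frame(measure = m, rho = unname(ct$estimate),
                                       p_value = ct$p.value)
    }
  }
  out <- list(group_stats = do.call(rbind, stats_rows))
  if (length(wilcox_rows)) out$wilcoxon <- do.call(rbind, wilcox_rows)
  if (length(spearman_rows)) out$spearman <- do.call(rbind, spearman_rows)
  for (nm in names(out)) rownames(out[[nm]]) <- NULL
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of interval variability measures\n")
  print(format(x$group_stats, digits = 3), row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("\nWilcoxon rank-sum tests\n")
    print(format(x$wilcoxon, digits = 3), row.names = FALSE)
  }
  if (!is.null(x$spearman)) {
    cat("\nSpearman correlation with mean duration\n")
    print(format(x$spearman, digits = 3), row.names = FALSE)
  }
  invisible(x)
}
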