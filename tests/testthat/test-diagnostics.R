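test_that("SRMR of a perfect fit is zero and the hand-worked case matches", {
  S <- matrix(c(2, 0.3, 0.3, 1.5), 2, 2)
  expect_equal(srmr(S, S), 0)
  Shat <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  Smod <- matrix(c(1, 0.2, 0.2, 1), 2, 2)
  # residuals over the lower triangle incl. diagonal: {0, 0.3, 0}
  expect_equal(srmr(Shat, Smod), sqrt(0.09 / 3))
  expect_equal(srmr(Shat, Smod, include_diagonal = FALSE), 0.3)
  # common rescaling of both matrices cancels in the standardization
  expect_equal(srmr(3.7 * Shat, 3.7 * Smod), srmr(Shat, Smod))
  Sz <- Shat
  Sz[1, 1] <- 0
  expect_error(srmr(Sz, Smod), "zero data variance.*1")
})

test_that("variance decomposition components sum to the model covariance", {
  m <- make_fixture("zf_song", n = 10)$model
  dec <- interval_variance_decomposition(m, keep_edges = TRUE)
  S <- model_covariance(m)
  expect_lt(max(abs(dec$components$global + dec$components$jitter +
                      dec$components$independent - S)), 1e-12)
  expect_equal(dec$summary$total_sd, sqrt(diag(S)))
  # interior interval with unit components: total SD sqrt(1+1+0.5+0.5)
  m3 <- timing_model(c(1, 1, 1), c(1, 1, 1), c(0.5, 0.5),
                     means = c(100, 50, 120))
  d3 <- interval_variance_decomposition(m3, keep_edges = TRUE)
  expect_equal(d3$summary$total_sd[2], sqrt(3))
  expect_equal(d3$summary$jitter_sd, c(sqrt(0.5), 1, sqrt(0.5)))
  # no jitter: jitter column identically zero
  m0 <- timing_model(c(1, 1, 1), c(1, 1, 1), c(0, 0),
                     means = c(100, 50, 120))
  expect_equal(interval_variance_decomposition(m0,
                 keep_edges = TRUE)$summary$jitter_sd, rep(0, 3))
  # edges flagged and excluded by default
  dec_def <- interval_variance_decomposition(m)
  expect_false(any(dec_def$summary$edge))
  expect_equal(nrow(dec_def$summary), m$n_intervals - 2)
})

test_that("sequence-length variance is dominated by coherent tempo and is
           jitter-free", {
  m <- timing_model(rep(1, 7), rep(1, 7), rep(0.8, 6))
  sl <- sequence_length_decomposition(m)
  expect_equal(sl$global_var, 49)
  expect_equal(sl$independent_var, 7)
  expect_equal(sl$global_fraction, 0.875)
  # simulation oracle: jitter drops out of row sums
  sim <- simulate_intervals(m, 2e5, seed = 81)
  expect_equal(var(rowSums(sim$data$durations)) /
                 (sl$global_var + sl$independent_var), 1, tolerance = 0.05)
  # after tempo rotation, factor 1 alone carries all of global_var
  m2 <- make_fixture("two_factor", n = 10)$model
  WR <- rotate_to_tempo_basis(m2$global_weights)$rotated
  expect_equal(sum(colSums(m2$global_weights)^2), sum(WR[, 1])^2,
               tolerance = 1e-10)
})

test_that("group comparison recovers constructed syllable/gap contrasts", {
  # constructed truth: gap elasticity exactly twice syllable elasticity
  n_per <- 50
  set.seed(91)
  mu <- c(runif(n_per, 80, 200), runif(n_per, 30, 90))
  elast <- c(rep(0.008, n_per) * exp(rnorm(n_per, 0, 0.1)),
             rep(0.016, n_per) * exp(rnorm(n_per, 0, 0.1)))
  tab <- data.frame(label = rep(c("syllable", "gap_within"), each = n_per),
                    mean = mu, tempo_elasticity = elast,
                    tempo_weight = elast * mu)
  cmp <- group_compare(tab, measures = c("tempo_elasticity", "tempo_weight"))
  gs <- cmp$group_stats
  med_syl <- gs$median[gs$group == "syllable" &
                         gs$measure == "tempo_elasticity"]
  med_gap <- gs$median[gs$group == "gap_within" &
                         gs$measure == "tempo_elasticity"]
  expect_equal(med_gap / med_syl, 2, tolerance = 0.2)
  expect_lt(cmp$wilcoxon$p_value[cmp$wilcoxon$measure == "tempo_elasticity"],
            1e-6)
  # identical groups: no detectable difference
  tab_same <- tab
  tab_same$tempo_elasticity <- rep(elast[1:n_per], 2)
  cmp_same <- group_compare(tab_same, measures = "tempo_elasticity")
  expect_gt(cmp_same$wilcoxon$p_value[1], 0.9)
  # perfect proportionality w = c * mu gives Spearman rho = 1
  tab_prop <- data.frame(label = "syllable", mean = mu,
                         tempo_weight = 0.01 * mu)
  cmp_prop <- group_compare(tab_prop, measures = "tempo_weight")
  expect_equal(cmp_prop$spearman$rho[1], 1)
})
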