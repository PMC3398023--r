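#' Built-in song-scale model fixtures
#'
#' Constructs a [timing_model()] with realistic zebra finch song timing
#' parameters plus one simulated dataset.  Syllable means span roughly
#' 50-200 msec with silent gaps about half as long; per-interval total SDs
#' land in the 1.5-3.5 msec range; tempo weights are all positive; and gaps
#' are more tempo-elastic (larger weight / mean ratio) than syllables.
#' Component SDs sit inside the observed per-bird ranges (global about
#' 0.55-1.46 msec, independent 0.56-2.35 msec, jitter 0.64-1.72 msec).
#'
#' Presets:
#' \describe{
#'   \item{zf_small}{K = 5 alternating syllable/gap sequence (default
#'     N = 300).}
#'   \item{zf_song}{K = 11 alternating sequence ending in an inter-motif
#'     gap and the first syllable of the next motif (default N = 500).}
#'   \item{two_factor}{zf_song plus a second, syllable/gap-antagonistic
#'     global factor with weights +0.5 msec (syllables) and -0.5 msec
#'     (gaps) (default N = 800).}
#'   \item{k7}{K = 7, M = 1 recovery benchmark with all weights and
#'     component SDs near 1 msec (default N = 500).}
#' }
#'
#' @param preset one of \code{"zf_small"}, \code{"zf_song"},
#'   \code{"two_factor"}, \code{"k7"}.
#' @param seed seed for the simulated dataset.
#' @param n number of simulated trials; preset default if NULL.
#' @return a list with \code{model} (the generating [timing_model()]),
#'   \code{data} (an [interval_dataset()]) and \code{sim} (the full
#'   simulation including true latent draws).
#' @export
make_fixture <- function(preset = c("zf_small", "zf_song", "two_factor",
                                    "k7"),
                         seed = 1L, n = NULL) {
  preset <- match.arg(preset)
  model <- fixture_model(preset)
  defaults <- c(zf_small = 300L, zf_song = 500L, two_factor = 800L,
                k7 = 500L)
  if (is.null(n)) n <- defaults[[preset]]
  sim <- simulate_intervals(model, n, seed = seed)
  list(model = model, data = sim$data, sim = sim, preset = preset,
       seed = seed)
}

fixture_model <- function(preset) {
  switch(preset,
    zf_small = timing_model(
      global_weights = c(1.0, 0.9, 0.8, 0.95, 1.2),
      independent_vars = c(1.1, 0.9, 1.2, 0.85, 1.3)^2,
      jitter_vars = c(0.9, 1.0, 0.85, 1.1)^2,
      means = c(120, 55, 90, 60, 150),
      labels = c("syllable", "gap_within", "syllable", "gap_within",
                 "syllable")),
    zf_song = timing_model(
      global_weights = c(1.1, 0.85, 1.25, 0.9, 1.35, 0.8, 0.95, 1.0,
                         1.2, 1.05, 1.05),
      independent_vars = c(1.2, 0.9, 1.3, 1.0, 1.4, 0.85, 1.1, 1.05,
                           1.25, 1.9, 1.15)^2,
      jitter_vars = c(0.9, 1.1, 0.8, 1.0, 1.2, 0.95, 0.85, 1.05, 1.15,
                      0.9)^2,
      means = c(95, 45, 120, 55, 160, 40, 75, 65, 140, 70, 110),
      labels = c("syllable", "gap_within", "syllable", "gap_within",
                 "syllable", "gap_within", "syllable", "gap_within",
                 "syllable", "gap_between", "syllable")),
    two_factor = {
      base <- fixture_model("zf_song")
      syl <- base$labels == "syllable"
      W2 <- ifelse(syl, 0.5, -0.5)
      timing_model(cbind(base$global_weights, W2),
                   base$independent_vars, base$jitter_vars,
                   means = base$means, labels = base$labels)
    },
    k7 = timing_model(
      global_weights = c(1.0, 0.9, 1.1, 0.95, 1.05, 0.85, 1.0),
      independent_vars = c(1.0, 0.9, 1.1, 0.95, 1.05, 1.0, 0.9)^2,
      jitter_vars = c(0.9, 1.0, 0.95, 1.05, 0.9, 1.0)^2,
      means = c(100, 50, 130, 60, 150, 45, 110),
      labels = c("syllable", "gap_within", "syllable", "gap_within",
                 "syllable", "gap_within", "syllable")),
    stop("unknown preset: ", preset, call. = FALSE))
}
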