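# timefactor

Decomposes trial-to-trial variability in the timing of repeated action
sequences into three latent sources.  The motivating data are zebra finch
song motifs — a stereotyped string of syllables and silent gaps whose
durations vary by only a few milliseconds across renditions — but the model
applies to any behavior that can be segmented into the same K consecutive
intervals on every trial.

For an N × K table of interval durations (msec), the model explains the
deviation of trial *n* from the mean durations μ as

    y_n = μ + z_n W' + x_n T' + e_n

* **global (tempo) factors** `z` — M shared latent variables (unit
  variance) whose K × M weight matrix W spreads correlated speeding/slowing
  across the whole sequence;
* **boundary jitter** `x` — noise at each of the K−1 internal boundaries;
  the fixed differencing matrix T (+1/−1 on its two diagonals) makes each
  jitter lengthen one interval exactly as it shortens its neighbour, so
  jitter induces *negative* adjacent covariance (the Wing–Kristofferson
  signature of downstream/measurement noise) and never changes total
  sequence length;
* **independent variability** `e` — per-interval noise, diagonal
  covariance.

The implied covariance `S = W W' + T diag(Ψx) T' + diag(Ψe)` is fitted by
maximum likelihood with a structurally constrained EM algorithm
(multi-restart, two-stage convergence).  The number of global factors is
chosen by BIC (`−2·loglik + p·ln N`, `p = K·M + K + (K−1)`), the weight
matrix is rotated so factor 1 carries all sequence-length variance, and
goodness of fit is summarized by the standardized root-mean-square residual
(SRMR).  The fit also yields trial-wise posterior estimates of every latent
variable, ready for downstream circadian/drift analyses.

## Worked example

```r
library(timefactor)

## a song-scale generating model (K = 11 syllables/gaps) and one dataset
fx  <- make_fixture("zf_song", seed = 1, n = 500)
fit <- fit_timing_model(fx$data, M = 1,
                        config = fit_config(n_restarts = 20, n_keep = 5,
                                            seed = 7))
fit
#> Timing variability model fit
#>   N = 500 trials, K = 11 intervals, M = 1 global factor(s)
#>   log-likelihood: -11282.562  SRMR: 0.03102
#>   restarts: 20  kept: 5  converged: TRUE
#> Timing variability model: K = 11 intervals, M = 1 global factor(s)
#>   tempo weights (factor 1, msec):  1.05 0.894 1.33 0.882 1.27 0.908 0.94 1.06 1.21 1.08 1.11
#>   independent SDs (msec):  1.26 1.14 1.16 0.989 1.47 0.906 0.945 1.04 1.1 1.77 1.02
#>   jitter SDs (msec):  0.88 1.08 0.907 1.02 1.22 1.02 0.964 0.977 1.17 0.893

## how much of the motif-length variance is tempo?
sequence_length_decomposition(fit$model)
#> $global_var
#> [1] 137.6447
#> $independent_var
#> [1] 15.57543
#> $global_fraction
#> [1] 0.8983461
```

The fitted tempo weights sit within ~0.11 msec of the generating values
(compare `fx$model`), and although per-interval tempo SDs (~1 msec) are
comparable to the independent and jitter SDs, tempo accounts for ~90% of
total motif-length variance: shared variation accumulates coherently
across the K intervals (as `(Σ w_k)²`) while independent noise adds up
incoherently (as `Σ σ²`), and jitter cancels entirely.

`interval_variance_decomposition(fit)` tabulates per-interval means, SDs
and partial CVs (edge intervals flagged and excluded by default);
`estimate_latents(fit)` returns the trial-by-trial latent estimates;
`select_global_dimension(data, config)` runs the full BIC sweep over
M = 1…4; `recovery_experiment()` / `sample_size_sweep()` run the Monte
Carlo parameter- and latent-recovery experiments, including skewed-Weibull
and exponential latent distributions.

A command-line interface wrapping the same functions is installed at
`inst/scripts/timefactor`:

```sh
Rscript inst/scripts/timefactor fixture --preset zf_song --seed 1 \
    --out data.csv --model-out truth.json
Rscript inst/scripts/timefactor fit --data data.csv --m 1 --seed 7 \
    --out fit.json --latents-out latents.csv
```

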