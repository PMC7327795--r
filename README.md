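# moveloc — movement-assisted localization for acoustic telemetry

`moveloc` estimates the locations of acoustic transmitters from
detection/non-detection records at fixed receiver arrays.  It is aimed at
movement ecologists working with acoustic telemetry (fish, reptiles,
marine mammals) who want to use *all* of their encounter data — including
signals detected at only one or two receivers, the "observed zeros" at
non-detecting receivers, and even occasions with no detections at all —
instead of discarding everything below three simultaneous detections.

## The model

Localization is cast as a hierarchical spatial capture-recapture (SCR)
problem.  For tag *i* and signal occasion *t* with latent source location
**u**_t:

* detection at receiver *j* (coordinates **x**_j) is Bernoulli with the
  half-normal detection function
  p_j = p0 · exp(−‖**u**_t − **x**_j‖² / (2σ²_det));
* successive locations follow Brownian motion,
  **u**_t | **u**_{t−1} ~ Normal(**u**_{t−1}, σ²_u · Δ_t),
  where Δ_t is the elapsed time between signals;
* transmission intervals follow the tag's programmed random schedule,
  Δ_t ~ Uniform(a, b).

Four estimators are provided, from the classical baseline to the fully
latent-schedule model:

| function | schedule information | localizes |
|---|---|---|
| `fit_independent()` | none (each signal alone) | detected signals |
| `fit_movement("detection_only")` | elapsed time between detections | detected signals |
| `fit_movement("known_interval")` | full emission schedule known | every signal, incl. zero-detection |
| `fit_unknown_interval()` | only (a, b) known; missed-signal counts latent | detected signals + per-gap missed-signal posteriors |

All are fitted by custom Metropolis-within-Gibbs samplers (C++ cores);
the unknown-interval model uses trans-dimensional moves for the number of
signals missed within each inter-detection gap, with a
normal-approximation signal-rate likelihood
Δ_obs ~ Normal(k(a+b)/2, k(b−a)²/12) for a gap tiled by k intervals.
See the methods vignette
(`vignettes/movement-assisted-localization.Rmd`) for the full model,
sampler, and design-choice documentation.

## Worked example

Simulate a benchmark-style system (10 tags on a 10 × 10 unit-spaced
receiver grid for 75 time units; half-normal detection with p0 = 0.562,
σ_det = 0.75; σ_u = 0.25; intervals Uniform(1, 2)) and fit the
known-interval and unknown-interval models:

```r
library(moveloc)

sim <- simulate_dataset(sim_config(n_individuals = 10, duration = 75, seed = 101))
sp  <- state_space(sim$receivers, buffer = 5 * 0.75)
st  <- mcmc_settings(n_chains = 3, n_iter = 4000, n_burn = 1500, thin = 2, seed = 11)

fk <- fit_movement(sim$detections, sim$receivers, "known_interval",
                   schedule = sim_schedule(sim), space = sp, settings = st)
tidy(fk)
#> # A tibble: 3 × 6
#>   term      estimate std.error conf.low conf.high  rhat
#>   <chr>        <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#> 1 p0           0.566    0.0400    0.488     0.645  1.02
#> 2 sigma_det    0.770    0.0288    0.718     0.828  1.05
#> 3 sigma_u      0.222    0.0191    0.190     0.260  1.12
```

The detection parameters (truth 0.562 / 0.75) and the movement scale
(truth 0.25) are recovered from the encounter histories alone — no range
testing.  The unknown-interval model additionally estimates how many
signals were missed in each gap between detections:

```r
fu <- fit_unknown_interval(sim$detections, sim$receivers, a = 1, b = 2,
                           space = sp, settings = st)
missed_signal_summary(fu, sim$truth)
#> # A tibble: 7 × 4
#>   tag_id n_gaps est_missed true_missed
#>   <chr>   <int>      <dbl>       <dbl>
#> 1 tag01       9      23.9           24
#> 2 tag03      36      13.2           13
#> 3 tag04      33      17.4           17
#> 4 tag06      42       6.02           6
#> 5 tag07      32       8.53           8
#> 6 tag08      20      29.7           31
#> 7 tag09       7      40.3           41
```

Per-signal localizations with their uncertainty come from `localize(fit)`
(posterior means and SDs), full posterior clouds from
`trajectory_draws(fit)`, and `autoplot(fit)` draws the array, the draw
clouds, and the posterior mean tracks.  Against simulation truth,
`localization_metrics(fit, sim$truth)` tabulates RMSE, precision, and 95%
HPD coverage by detection count — on data like the above, the movement
model roughly halves the localization RMSE of signals detected at one or
two receivers relative to `fit_independent()`.

Field data come in through `read_receivers()` / `read_detections()`
(plain CSV: `receiver_id,x,y` and `tag_id,receiver_id,time`), with
near-simultaneous detections grouped into per-signal encounter vectors by
`build_encounters()`.  A command-line wrapper with `simulate`, `fit`, and
`evaluate` subcommands is installed at `inst/cli/moveloc.R`.

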