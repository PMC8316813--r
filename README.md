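# troopmove

Tools for studying how animal groups whose members differ in locomotor
capacity stay together while travelling, built around simultaneous
biologging of most of a group: 1 Hz GPS and 12 Hz tri-axial accelerometry
per individual, plus morphometrics (front-leg length). The motivating
system is a wild olive-baboon troop, where leg lengths span 31–51 cm and an
individual's preferred ("characteristic") stride frequency falls with leg
length while its preferred travel speed rises with it — so cohesion forces
everyone to compromise.

The package covers the full analysis chain:

* **Synthetic biologging** (`make_troop()`, `simulate_day()`,
  `synth_accel()`, `inject_artifacts()`): seeded troops, GPS days with
  stationary periods, solo-movement windows and collective travel,
  footfall-structured heave-axis accelerometry, GPS jitter, collar spikes
  and dropouts — with full ground-truth labels, so every estimator can be
  validated by parameter recovery.
* **Gait and energetics from accelerometry** (`hampel_filter()`,
  `estimate_stride_frequency()`, `compute_vedba()`,
  `classify_activity()`): despiking, stride frequency from heave-axis peak
  timing, vectorial dynamic body acceleration (VeDBA, the standard proxy
  for movement energetics), and moving/stationary classification.
* **Group state** (`compute_centroid()`, `detect_bouts()`,
  `filter_bouts()`, `front_back_positions()`, `group_spread()`): travel
  bouts by change-point detection (PELT) on centroid speed; positions
  rotated into the heading frame with front–back coordinate `d`, ranks and
  a rescaled position `p ∈ [−1, 1]` (+1 = front); spread as the
  front–back extent.
* **Individual movement metrics** (`daily_travel_distance()` at 5-m
  discretisation, `daily_max_displacement()`,
  `characteristic_stride_frequency()`, `stride_deviation()`,
  `move_pause_ratio()`, `nn_size_difference()`, `separation_profile()`).
* **A 1D collective-movement simulator** (`simulate_bout_1d()`,
  `simulate_bouts()`) comparing three speed-modulation decision rules —
  (I) characteristic speed, (II) speed modulated by signed distance from
  the centroid, `v_i − g·d_i`, and (III) rule I until the group spread
  exceeds a threshold `T`, rule II beyond it — fitted to observed spread
  distributions by simulated likelihood and ranked by AIC
  (`compare_scenarios()`), with emergent size segregation summarised by
  `simulated_segregation()`.
* **Mixed models** (`fit_lmm()` with AR1 residuals, `fit_beta_glmm()` for
  move:pause proportions with a logit-link beta family), with
  broom-style `tidy()`/`glance()` methods throughout.

See `vignettes/troopmove-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

Generate a troop, simulate part of a tracking day, segment the travel
bouts, and ask which decision rule explains a set of observed group
spreads:

```r
library(troopmove)

troop <- make_troop(troop_config(seed = 1))
pearson_corr(troop, "f_char_true_hz", "leg_length_cm")
#> # A tibble: 1 × 5
#>        r p.value     n conf.low conf.high
#>    <dbl>   <dbl> <int>    <dbl>     <dbl>
#> 1 -0.614 0.00109    25   -0.812    -0.289

sched <- make_day_schedule(n_travel = 3, total_duration = 4 * 3600, seed = 1)
day   <- simulate_day(troop, sched, motion_params(), seed = 1)

cen   <- compute_centroid(day$gps, coverage_threshold = 13)
filter_bouts(detect_bouts(cen))
#> # A tibble: 3 × 7
#>   bout_id t_start t_end duration_s state          mean_speed_ms coverage
#>     <int>   <dbl> <dbl>      <dbl> <chr>                  <dbl>    <dbl>
#> 1       2   25461 26274        814 non-stationary         0.874       25
#> 2       4   29373 30780       1408 non-stationary         0.871       25
#> 3       6   33793 34499        707 non-stationary         0.871       25

obs <- simulate_bouts(troop, "III",
                      sim_params(g = 0.05, T_spread = 80, noise_sd = 0.3,
                                 duration = 300, init_spread_sd = 5),
                      n_bouts = 20, durations = rep(300, 20), seed = 2)
cmp <- compare_scenarios(obs$spread_samples, troop, durations = rep(300, 20),
                         params = sim_params(noise_sd = 0.3, duration = 300,
                                             init_spread_sd = 5),
                         g_grid = c(0.005, 0.02, 0.05, 0.2),
                         T_grid = seq(20, 160, by = 10),
                         n_sim = 40, seed = 3)
tidy(cmp)
#> # A tibble: 3 × 7
#>   scenario     k      g T_spread logLik   AIC   dAIC
#>   <chr>    <int>  <dbl>    <dbl>  <dbl> <dbl>  <dbl>
#> 1 III          2  0.02        80 -2521. 5046.    0
#> 2 I            0 NA           NA -2564. 5128.   82.1
#> 3 II           1  0.005       NA -3741. 7484. 2438.
```

Reading the output: the generated stride-frequency/leg-length correlation
(−0.61 here; the generator targets −0.53 on average) confirms that
longer-legged animals stride more slowly. The three scheduled travel bouts
are recovered from noisy GPS with their boundaries within seconds, each
with ~0.87 m/s centroid speed and full 25-individual coverage. The rule
comparison identifies the threshold-gated rule (III) as the best
explanation of spreads that were in fact generated under it, recovers the
80 m threshold exactly, and charges rules I and II the AIC cost of their
poorer predictive densities. `autoplot(cmp)` draws the observed-vs-fitted
spread CDFs.

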