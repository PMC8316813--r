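---
title: "Methods: synthetic biologging, cohesion metrics and decision-rule inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic biologging, cohesion metrics and decision-rule inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troopmove)
```

## The scientific problem

Members of a travelling animal group rarely share the same locomotor
capacity. In a baboon troop, front-leg lengths span roughly 31--51 cm, and
since preferred stride frequency falls with limb length while travel speed
rises with it, group-mates differ in the speed they would choose on their
own. A cohesive group must reconcile those differences: somebody strides
faster than they would like, somebody pauses and waits. `troopmove`
implements the full analysis chain used to study this problem with
high-resolution biologgers -- 1 Hz GPS and 12 Hz tri-axial accelerometry on
most members of a group -- together with a one-dimensional simulator for
comparing candidate speed-coordination rules by AIC.

Because the original field data are not public, the package ships a
first-class synthetic-data module. Every downstream stage (gait extraction,
bout segmentation, spatial metrics, mixed models, rule inference) is
validated by parameter recovery against the generator's ground truth.

## The synthetic troop and day

`make_troop()` draws individuals with leg lengths from a scaled Beta
distribution on the configured range (default 31--51 cm, mean 38 cm) and
characteristic stride frequencies from

\[ f_i = a + b\,L_i + \varepsilon_i,\qquad \varepsilon_i \sim N(0,\sigma^2), \]

truncated to (0.5, 4) Hz. The slope is `freq_leg_slope = -0.02` Hz/cm, and
by default \(\sigma\) is derived from the target correlation \(r = -0.53\)
via \(\sigma = |b|\,\mathrm{sd}(L)\sqrt{1/r^2 - 1}\), so the generated
stride-frequency/leg-length correlation matches the target at large *n*
without further tuning. The slope was chosen so that characteristic
*speed*, \(v_i = \kappa f_i L_i/100\) with \(\kappa = 1.3\), still increases
clearly with body size (correlation about +0.7): longer-legged animals
stride more slowly but cover more ground per stride, which is the regime
the collective-movement predictions assume. With these defaults a 2 Hz
stride at the mean leg length gives about 1 m/s, so hours-long travel bouts
cover the km-scale daily distances reported for wild troops.

`simulate_day()` alternates stationary periods and collective travel.
Stationary periods are bounded random walks about an anchor (burst steps of
SD 0.3 m per axis with probability 0.05 per second, plus a weak tether),
with scheduled *solo-movement windows* -- one per individual per day by
default -- during which the focal walks at its characteristic speed while
all group-mates hold still. These windows exist because the characteristic
stride frequency is *defined* as the gait chosen during independent
movement; without them it would not be estimable. Travel segments embed the
1D cohesion engine (below) along the segment heading, so speed modulation,
position-dependent pausing and spread dynamics during travel are exactly
the dynamics the inference stage later fits. GPS noise is isotropic
Gaussian with SD 1 m (no field error model is available; 1 m is typical of
modern wildlife collars). True per-second labels (moving/stationary, group
state, instantaneous stride frequency, solo windows) are returned alongside
the tracks.

Travel-segment durations in `make_day_schedule()` are lognormal with mean
26 min and a broad SD (truncated to 2--90 min), matching the scale of
observed collective travel bouts.

What the generator does *not* emulate: terrain and habitat structure,
foraging decisions, GPS error autocorrelation, collar-orientation drift,
and any social structure beyond the position-dependent movement rules.
Passing recovery tests therefore demonstrate that the estimators are
correct and well-calibrated under the stated noise model -- not that they
are robust to every pathology of field data.

## Accelerometry synthesis and gait extraction

While an individual moves at speed \(v\), its heave (dorsal--ventral) axis
carries a periodic footfall waveform at the instantaneous stride frequency
\(f = v/(\kappa L)\):

\[ h(t) = g_0 + A\left(\tfrac{1 + \cos 2\pi u(t)}{2}\right)^{p} + \eta(t), \]

with cycle phase \(u\), amplitude `footfall_amp = 3` m/s², shape exponent
`pulse_shape = 1` and white sensor noise of SD 0.15 m/s². The default shape
is a sinusoidal oscillation rather than a narrow impact spike for a reason
worth recording: at 12 Hz sampling a pulse much narrower than ~0.3 s
occupies one or two samples, and a rolling-median despiking filter --
correctly -- treats such samples as outliers. Gait energy concentrated in a
broad waveform survives despiking at all cadences between 1 and 3 Hz while
still yielding one unambiguous peak per stride.

`hampel_filter()` is the classic despiker: a sample deviating from the
centred rolling median by more than `n_mad = 3` robust SDs (1.4826 times
the rolling MAD) is replaced by that median. The default window is
`half_window = 36` samples (6.1 s). A narrow window (say 0.5 s) makes the
rolling MAD of pure sensor noise so variable that roughly 2--3% of clean
samples get replaced by chance; at 6.1 s the false-replacement rate stays
around 0.6--0.7% with margin to spare, while isolated collar-strike spikes
(~10 signal SDs) are still removed essentially completely.

`estimate_stride_frequency()` detects heave peaks per 10 s window: strict
local maxima above the window median plus `prominence_mult = 0.4` robust
SDs, separated by at least 0.25 s (capping detectable strides at 4 Hz),
with peak times refined by a local quadratic fit -- at 12 Hz the raw sample
grid quantises inter-peak intervals to 1/12 s, which alone would break
0.1 Hz accuracy at e.g. 2.25 Hz. The stride frequency is the reciprocal of
the *median* inter-peak interval, defined only when at least 3 peaks are
found *and* the intervals are gait-regular (coefficient of variation at
most 0.35). The regularity gate is what lets the prominence threshold sit
low enough to catch broad sinusoidal crests without reporting a "stride"
for the chance maxima of stationary noise; a flat signal still yields no
peaks at all.

`compute_vedba()` follows the standard dynamic-body-acceleration recipe:
static component = centred 2 s rolling mean per axis, dynamic = residual,
sample VeDBA = Euclidean norm of the three dynamic components, reported
per second as the mean of sample values (rate-like, so gap patterns do not
change the scale). The closed-form check in the test-suite uses a 1.92 Hz
sine: at that frequency the 25-sample boxcar has an exact spectral zero and
the 12 Hz grid sweeps the phase uniformly, so the discrete mean of
\(|A\sin|\) matches \(2A/\pi\) to better than 1%; at frequencies
commensurate with the grid (e.g. 2.0 Hz) the sampled mean of \(|\sin|\) is
biased for *any* estimator and would make the oracle itself wrong.

Activity classification uses a linear SVM on three per-second features
(mean VeDBA, footfall-peak count, dominant-frequency power), trained on
generator labels, with a documented fallback (moving iff VeDBA >
0.5 m/s²) that needs no training. On labelled synthetic days the SVM
exceeds 95% per-second accuracy when trained on a few individuals and
tested on the rest.

## Group state and spatial position

The group centroid is the unweighted mean of available fixes per second
(undefined below a coverage threshold), its displacement speed is measured
over a centred 10 s window, and the heading is that displacement
normalised, undefined below 0.1 m/s where it is noise-dominated. Travel
bouts are found by penalised change-point segmentation (PELT with an L2
mean cost, written in vectorised R; no change-point package is assumed)
with a BIC-style default penalty \(2\hat\sigma^2\log n\), \(\hat\sigma\)
robustly estimated from first differences. Segments are labelled stationary
below 0.1 m/s and merged; analyses retain non-stationary bouts of at least
120 s with data for at least 16 individuals (closed bounds).

Within a bout, each fix is re-expressed in the centroid frame rotated to
the heading: the signed front--back coordinate \(d\), ranks ordered by
\(d\) (rank 1 = backmost, ties broken by individual id), and the rank-based
rescaled position \(p = 2(\mathrm{rank}-1)/(N-1) - 1\), so +1 is the front
and -1 the back regardless of spread. *Group spread* is defined as the
front--back extent \(d_{\max} - d_{\min}\): it is the quantity the 1D
simulator produces natively and the quantity a threshold rule in metres can
act on; the mean distance to the centroid is kept as a secondary
dispersion statistic. All outputs are invariant to global translation and
rotation, which the test-suite asserts directly.

## The 1D cohesion engine and rule inference

Agents move along a line with per-step displacement
\(\Delta x_i = \max(v_i^{\mathrm{rule}} + \varepsilon, 0)\,\Delta t\)
(clipped at zero: agents pause rather than reverse), where

* rule I: \(v^{\mathrm{rule}}_i = v_i\) (characteristic speed);
* rule II: \(v^{\mathrm{rule}}_i = v_i - g\,d_i\), with \(d_i\) the signed
  metric distance from the centroid -- additive metric modulation was chosen
  over rank-based alternatives because it gives the closed-form two-agent
  equilibrium spread \(\Delta v/g\) and the bounded-spread behaviour a
  threshold in metres requires;
* rule III: rule I while the spread is at most \(T\), rule II beyond it.

Because \(\sum_i d_i = 0\), rule II redistributes speed without changing
the centroid's pace. The engine consumes its random-number stream
identically under every rule, so rules II and III with \(g = 0\) reproduce
rule I trajectories exactly under a shared seed -- a property the tests pin
at 1e-9. An optional move/pause layer thins steps with probability
\(\mathrm{logit}^{-1}(b_0 + b_{\mathrm{leg}} z_i + s_f\,[sep_i > c_f] +
s_b\,[sep_i < c_b])\): baseline moving probability 0.9, smaller individuals
pausing less (\(b_{\mathrm{leg}} = -0.35\) per SD of leg length), a strong
pause response once an agent is more than \(c_f = 20\) m ahead of the rest
of the group, and a catch-up response once more than \(|c_b| = 40\) m
behind. This layer drives the day generator's travel segments and the
separation-profile analyses.

Rule comparison uses a simulated predictive likelihood, since no
closed-form spread density exists: for each candidate parameter value,
replicate bouts are simulated (durations resampled from the observed
bout-duration distribution), pooled spread samples are binned into a 5 m
histogram with pseudocount 0.5, and the observed spreads are scored against
that density; \(AIC = 2k - 2\ln L\) with \(k \in \{0, 1, 2\}\) free
parameters. Common random numbers across grid points keep the likelihood
surface smooth. Grid search replaces continuous optimisation because the
objective is stochastic and the parameter count small.

Emergent size segregation is summarised per bout as the difference in mean
front--back rank between large and small individuals (median split on leg
length) plus a pooled regression of rank on leg length. In the validation
design, the "no coordination" world is rule I with neither speed nor pause
modulation -- there faster, predominantly larger, agents pile up at the
front -- while the "full rule set" world is rule III with strong gain plus
the position-dependent pause layer, where ranks decouple from size. The
contrast is between behavioural repertoires, not merely between values of
\(g\).

## Statistical stage

`fit_lmm()` fits the window-record regressions with random intercepts and
an AR1 residual component. The default engine is `nlme::lme` with nested
intercepts (individual, bout within individual) and `corAR1` on the
within-series order -- a fast, classical approximation of the crossed
design; `glmmTMB` is available as an alternative engine with genuinely
crossed intercepts and an `ar1()` covariance. `fit_beta_glmm()` fits
move:pause proportions with a logit-link beta family and crossed random
intercepts; boundary proportions must first be shrunk by
\((p(n-1) + 0.5)/n\). Calibration is checked by simulation: 95% CI coverage
of a known slope under AR1 residuals stays above 90% over 50 replicates,
and the Wald type-I error at nominal 0.05 stays at or below 0.07 over 200
null replicates. No multiple-comparison correction is applied anywhere;
tests are reported raw.

The separation profile estimates where the moving probability steps: on
each side of zero separation, a single-breakpoint two-level binomial model
is fitted over 5 m bin edges and accepted only when it beats the flat model
by BIC -- so position-independent pausing yields a curve but no breakpoint.
Move/pause outcomes are paired with the separation at the *start* of the
step (decision time); pairing with post-step positions blurs the threshold
by one step length.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which each recovery is statistically clean: a full synthetic day uses 25
individuals for 12 h (1 Hz GPS; 12 Hz accelerometry processed per
individual); gait-size correlation recovery uses 20 seeded troops with
solo-window accelerometry; rule identification uses troops of 10, twenty
300 s observed bouts, 40 simulated bouts per grid point, a four-point gain
grid and a 10 m threshold grid; segregation and separation-profile analyses
use 50 and 10 bouts of 600--900 s. Ties in ranks are broken by individual
id in empirical frames (documented, deterministic) and by averaging in
simulator output (so identical agents show zero rank difference). Missing
data are never interpolated in signal paths; the change-point stage alone
linearly interpolates gaps in centroid speed before segmentation.

## Known limitations

* The generator's noise model is white; real collars show autocorrelated
  GPS error and orientation-dependent accelerometer offsets.
* The 1D engine has no lateral dimension, so nearest-neighbour analyses on
  simulated data use front--back separation only.
* The simulated-likelihood AIC compares rules at fixed noise and duration
  distributions; it does not propagate uncertainty in those nuisances.
* `nlme`'s nested approximation of crossed random effects is slightly
  conservative when bout effects are truly crossed; use the `glmmTMB`
  engine when that distinction matters.
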