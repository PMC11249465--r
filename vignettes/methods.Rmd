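---
title: "Methods: from irregular satellite fixes to behavioural time budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from irregular satellite fixes to behavioural time budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`polarmove` turns raw satellite-tag telemetry from polar bears ashore in
Hudson Bay into behavioural time budgets. This vignette is the package's
account of the statistical machinery: the models, their assumptions, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## 1. The data and their pathologies

A deployment produces a sequence of fixes: timestamp, longitude/latitude,
and error metadata. Argos-linked tags (pentagon and tribrush fur tags, ear
tags) are duty-cycled at 4 h and each Doppler-derived position carries one
of six location classes — 3, 2, 1, 0, A, B in decreasing accuracy, with
nominal horizontal errors < 250 m (class 3), < 500 m (2), < 1500 m (1),
> 1500 m (0) and no estimate for A and B, which derive from fewer than four
satellite messages. GPS/Iridium SeaTrkr tags are duty-cycled at 2 h and
report a per-fix horizontal error in metres (typically ~11 m). Fix attempts
fail sporadically; tags detach (fur tags especially) or exhaust batteries.

Four pre-processing rules clean this record, applied per deployment in
order:

* **Post-capture truncation** (`truncate_post_capture`, default 3 days):
  movement immediately after chemical immobilization is not representative.
  A fix exactly at the 72-h boundary is retained.
* **Speed filtering** (`speed_filter`, default threshold 40 km/h): bears
  sprint at up to ~40 km/h only briefly, so sustained implied speeds at or
  above that are position errors. We use the McConnell root-mean-square
  construction: each interior fix's RMS speed over the legs to its two
  preceding and two following retained neighbours; while any fix is at or
  over the threshold the worst offender is removed (ties to the earliest)
  and speeds recomputed. Endpoints are never removed — they lack two-sided
  neighbours. Only the speed criterion is applied; the companion
  angle/spike tests found in some filter implementations are deliberately
  left out, since speed is the stated exclusion rule for these data. A
  successive-pair mode (`speed_mode = "pairwise"`) is available for
  sensitivity checks.
  The filter is idempotent and only ever deletes rows.
* **Terrestrial selection** (`terrestrial_filter`, default `max_foray`
  50): the analysis concerns bears ashore. Marine fixes are kept only as
  *forays*: maximal marine runs shorter than 50 fixes bounded by land
  fixes of the same deployment on both sides. Leading/trailing marine runs
  (the bear left for the ice and never returned within the record) are
  dropped. Land status comes from a per-fix flag or, failing that, a
  user-supplied point-in-polygon landmask function.
* **Segmentation** (`segment_tracks`, defaults: gap 24 h, minimum length
  100): interpolating across long dropout gaps would manufacture
  positions, so tracks are split strictly after any gap > 24 h (exactly
  24 h does not split) and segments under 100 fixes are discarded — too
  short to inform state-transition estimates.

Every stage reports counts; `run_study_pipeline` asserts that input =
removed + retained throughout.

## 2. CTCRW regularization

Hidden Markov models need positions on a fixed grid. We standardize every
segment to exact 4-h spacing with a continuous-time correlated random walk:
per planar axis, velocity `v` is Ornstein–Uhlenbeck with autocorrelation
rate `beta_vel` (1/h) and noise scale `sigma_vel`, position is its
integral, and fix `y_t` observes position with isotropic Gaussian error.
The discrete-time transition and innovation covariance over a step `dt`
have closed forms in `(beta_vel, sigma_vel)`, so the exact likelihood comes
from the Kalman filter; both parameters are estimated by Nelder–Mead on the
log scale, and positions at grid times by the RTS smoother with grid times
inserted as missing observations.

Numerical and design choices:

* Segments are projected to a local azimuthal-equidistant plane centred on
  the segment centroid (working units km). The projection is exact in
  distance and bearing from the centre; round-trip error is far below 1 m
  within 500 km, ample for coastal segments.
* Measurement SDs are fixed, not estimated: defaults 0.25, 0.5, 1.5, 5, 8,
  15 km for classes 3, 2, 1, 0, A, B and 0.02 km for GPS, overridable via
  `pipeline_config(error_sd_by_class=, gps_sd_km=)`. The estimable classes
  follow the nominal class bounds; A and B, which carry no estimate, get
  deliberately conservative values. Errors are isotropic with independent
  axes — the standard simplification absent per-fix error ellipses.
* Both axes share the same measurement SD and dynamics, so one covariance
  recursion serves both axes; only the means differ. This halves the
  filter cost.
* The grid is anchored at each segment's first fix time and never extends
  beyond its last fix: the smoother interpolates, it does not extrapolate.
  Grid points with no observed fix within 1 h are flagged `interpolated`.
* The filter is initialized at the first observation with variance
  `4·tau² + 1 km²` in position and the stationary velocity variance
  `sigma²/(2·beta)` in velocity — proper but weakly informative.
* If a segment's CTCRW fit fails to converge, the pipeline falls back to
  piecewise-linear interpolation onto the same grid and records the
  segment in the report (`ctcrw_fallback`), keeping results auditable.

## 3. The movement HMM

From each regular track we take step lengths (great-circle km between
successive grid points) and turn angles (change of bearing, wrapped to
(−π, π] with −π mapped to +π). The first turn of each segment is undefined
and contributes only its step density. Segments are independent time series
sharing one parameter set; their log-likelihoods add.

Emissions are gamma (parameterized by mean and SD, internally converted to
shape = mean²/sd², rate = mean/sd²) for steps and von Mises for turns.
Exact zero steps are incompatible with a continuous gamma density with no
zero mass; they are replaced by half the minimum positive step
(`treat_zero_steps`). This keeps the parameter count at 2 per state per
stream — no zero-inflation parameters — matching the 11/13/15 counts of
the three transition models.

Transitions follow a multinomial logit in ambient temperature: for each
off-diagonal `i -> j`, `eta_ij = beta0 + beta1·x (+ beta2·x²)`, rows
normalized. The covariate of step `t` is the temperature at the step's
start position, obtained from the hourly series of the station nearest
(great-circle) to the segment centroid — matching "nearest permanent
weather station" in the simplest deterministic way. Temperature is matched
by linear interpolation between the bracketing hourly records when both
are within `max_temp_gap_h` (default 6 h), by the single in-range record
otherwise, and flagged missing beyond that; covariate-missing steps are
dropped from the HMM input rather than imputed (no defensible imputation
rule exists for a 6-h+ hole). Whether to interpolate or take the nearest
hour was genuinely open; interpolation was chosen as hourly series are
smooth at this scale and the midpoint case is then exact.

The likelihood is the scaled forward algorithm (Rcpp, O(T·N²)), with the
initial distribution `delta` estimated freely and shared across segments
(N−1 free parameters). `n` in the AICc correction is the total number of
step observations.

**Optimization.** The likelihood is multimodal; in particular there is a
family of degenerate modes in which one state's SD diverges. Each restart
therefore runs a Nelder–Mead phase (600 iterations, escapes these modes
reliably), a BFGS phase, then a Newton-type `nlm` polish whose
scaled-gradient criterion (`gradtol = 1e-6` on the transformed scale) is
the convergence test; restarts that fail it are logged, not fatal, and the
best converged restart wins. Parameters are optimized unconstrained: logs
for positive quantities, identity for logit coefficients and angle means
(wrapped on unpacking), multinomial-logit for `delta`. Temperature is
z-scored internally for conditioning; coefficients are reported on both
scales. Restart draws: state step means log-uniform between the 5th and
95th step percentiles (ordered), SDs equal to means, angle means from
{0, π}, concentrations log-uniform on [0.1, 5], dwell probabilities
uniform on [0.7, 0.99], covariate coefficients 0. The default is 50
restarts (`n_restarts`), deterministic given `seed`; at the study sizes
used in the tests the optimum is reached from essentially every start, so
the test harnesses use 2–3 restarts to keep runtimes in minutes.

After fitting, states are relabelled so state 1 has the smaller step mean
("resting") — resolving label switching — and all parameter blocks,
including transition coefficients, are permuted accordingly. Viterbi
decoding runs per segment in log space with ties broken toward the lower
state index; forward–backward posteriors are computed alongside. Stationary
curves solve `pi %*% Gamma(x) = pi` by linear solve at each temperature;
under the logit link all entries are strictly positive, so failures can
only be numerical underflow, which is raised as an error.

## 4. Tag performance

Tags enter inactivity mode after ≥ 12 h without movement; a run of more
than 3 consecutive inactivity-flagged fixes (i.e. ≥ 4) is read as
detachment, dated at the run's first fix. Otherwise the tag "stopped"
(malfunction or battery) at its last transmission. Functional duration is
the event time minus attachment, in real-valued days (display rounding is
left to the caller; whether the field durations were day-truncated before
averaging is not stated anywhere authoritative, so we keep real values).
Group summaries report mean, range and SE = sd(n−1)/√n, the SE being
undefined for singleton groups. Error-class tables give per-design
proportions over Argos fixes only; GPS fixes are summarized separately by
their metric horizontal error.

## 5. The synthetic-study generator

`simulate_study` generates what the pipeline consumes, with the statistical
structure the analysis assumes:

* **Temperature**: hourly series = linear autumn cooling trend (start mean
  10 °C, −0.25 °C/day) + diel sinusoid (amplitude 3 °C) + AR(1) noise
  (coefficient 0.8, innovation SD 1.5 °C), started from the AR stationary
  distribution. The defaults emulate September–November on the western
  Hudson Bay coast, where daily means drift from ~10 °C toward well below
  freezing.
* **Movement**: the two-state chain is simulated at the 4-h step scale
  with the logit-linear temperature transition model; steps are gamma,
  headings accumulate von Mises turns; positions build on a local plane
  and map to lon/lat near the coast. Defaults: resting steps mean 0.02 km
  (SD 0.02), traveling 0.74 km (SD 0.5) per 4 h — i.e. ~0.19 km/h
  traveling; turn means π (resting) and 0 (traveling) with concentrations
  0.7 and 1.5; transition intercepts give dwell probabilities 0.965
  (resting) and 0.92 (traveling) at the reference temperature — both
  "about 0.95" — chosen so the long-run resting occupancy sits near 70%,
  the budget typical of bears ashore; the temperature coefficient on
  resting→traveling is negative (−0.06/°C): bears travel more as autumn
  cools. The 1-h "truth" grid linearly subdivides each 4-h step; it exists
  so duty cycles of 2 and 4 h can both be thinned from one truth.
* **Observation**: thinning to the design's duty cycle (4 h Argos, 2 h
  GPS), independent fix failures (success 0.9), Argos classes drawn from
  the ear-tag mix 6/14/14/13/18/36% (renormalized — these rounded
  percentages sum to 101) with isotropic Gaussian positional
  error at the class SDs above, GPS noise 0.011 km with lognormal ~11 m
  reported errors. Detachment is exponential with design-specific means
  (pentagon 22, seatrkr 58, tribrush 47 days; ear tags effectively never —
  they fail by battery); after detachment the tag sits still, flags
  inactivity 12 h later, transmits a handful of inactive fixes and goes
  silent.
* **Coastline**: a latitude half-plane (marine above 58.85°N) — the
  minimum geometry that exercises the foray rule without GIS data.

What it does **not** emulate — and what passing recovery tests therefore do
not establish about field data: heavy-tailed or anisotropic Argos errors
(a mixture flag exists but is off by default), spatially varying
temperature, tidal flats that complicate the land/sea boundary, individual
heterogeneity in movement parameters, more than two behavioural states,
and any sea-ice dynamics. Parameter-recovery claims (emission means within
10%, decoded budgets within 3 points) are made on the generator's true
step series; pushing class-structured Argos noise with 8–15 km SDs through
regularization necessarily inflates a 0.02-km resting step mean, which is
why the noisy pipeline is checked for structural properties (counts,
spacing, model ranking) rather than sub-10% recovery.

## 6. Problem sizes and reproducibility

The recovery harnesses use the default study — 10 tracks × 500 four-hour
steps (≈ 83 days) — for single-study checks, and 20 replicated studies of
the same size for sign-recovery and model-preference rates; the CTCRW
check uses 500 hourly positions. These sizes give Monte-Carlo error
comfortably inside the stated tolerances while keeping the full suite in
the tens of minutes on one CPU. All generators and fitters are
deterministic given their `seed` arguments, and `simulate_study` writes a
`config_echo.txt` provenance file beside every emitted dataset.

## 7. Known limitations

* The CTCRW assumes the movement process it regularizes; applying it to
  gamma/von Mises switching tracks (as the generator produces) is the same
  model misspecification real analyses accept when regularizing bear
  tracks, and it slightly smooths genuine resting jitter.
* Fixed Argos SDs are a declared convention, not estimates; if per-fix
  error ellipses are available they cannot currently be used.
* Dropping covariate-missing steps (rather than splitting segments there)
  lets a transition span the hole under the same parameters; with the
  default 6-h window and complete hourly series this path is rarely taken.
* Only N = 2 states is exercised; the code generalizes in N but with these
  duty cycles finer behavioural distinctions are not identifiable.
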