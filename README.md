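# polarmove

Movement and behaviour analysis for satellite-tagged polar bears.

During the Hudson Bay ice-free season, subadult and adult male polar bears —
which cannot safely carry radio collars — can be tracked with small fur- and
ear-mounted Argos and GPS/Iridium tags. The resulting telemetry is short,
irregular and noisy: fixes arrive on 4-h (Argos) or 2-h (GPS) duty cycles
with missed attempts, Argos positions carry class-structured errors of
hundreds of metres to tens of kilometres, and tags detach or exhaust their
batteries within weeks to months. `polarmove` implements the full analysis
chain such data need, for movement ecologists working with short-duty-cycle
tag deployments:

1. **Filtering** — post-capture truncation (3 days), iterative
   McConnell-style root-mean-square speed filtering (threshold 40 km/h),
   terrestrial selection that keeps short marine forays (< 50 consecutive
   fixes bounded by land), and segmentation at temporal gaps > 24 h with a
   100-fix minimum segment length.
2. **Regularization** — a continuous-time correlated random walk (CTCRW)
   state-space model with integrated Ornstein–Uhlenbeck velocity, fitted by
   Kalman filtering with per-class Argos measurement SDs, then smoothed onto
   an exact 4-h grid (interpolating sparse Argos tracks, rarefying 2-h GPS
   tracks).
3. **Behavioural inference** — a two-state hidden Markov model of step
   lengths (gamma) and turn angles (von Mises), with state transition
   probabilities a multinomial-logit function of ambient temperature
   (intercept-only, linear, or quadratic), 50 random restarts, AICc model
   selection, Viterbi decoding, stationary-state curves and time budgets.
4. **Tag performance** — functional-duration summaries per tag design,
   detachment detection from inactivity signals (≥ 4 consecutive inactive
   fixes), and Argos error-class composition tables.
5. **Synthetic studies** — a generator that emulates the whole observation
   process (Markov-switching movement, cooling autumn temperatures, duty
   cycles, class-structured error, missed fixes, detachment), so every
   stage is testable without field data.

## The model

Let `l_t` be the step length and `phi_t` the turn angle between consecutive
4-h grid positions. Conditional on a latent behavioural state
`S_t ∈ {1 = resting, 2 = traveling}`:

    l_t   | S_t = s  ~  Gamma(mean mu_s, sd sigma_s)
    phi_t | S_t = s  ~  von Mises(theta_s, kappa_s)

The state sequence is Markov with transition matrix `Γ(x_t)` whose
off-diagonal entries follow a logit-linear model in ambient temperature
`x_t`:

    logit Pr(S_t = j | S_{t-1} = i) = beta0_ij + beta1_ij x_t (+ beta2_ij x_t^2)

Model selection over the three transition formulations uses
`AICc = −2·logL + 2K + 2K(K+1)/(n−K−1)` with `K = 11, 13, 15` parameters
respectively (2 states). Long-run behaviour at a fixed temperature is the
stationary distribution solving `π Γ(x) = π`.

Track regularization uses the CTCRW: velocity is an Ornstein–Uhlenbeck
process with autocorrelation rate `beta_vel` (1/h) and noise scale
`sigma_vel`, position its integral, observed with isotropic Gaussian error
fixed per Argos class (defaults 0.25/0.5/1.5/5/8/15 km for classes
3/2/1/0/A/B; 0.02 km for GPS). Fitting maximizes the Kalman-filter
likelihood on a local azimuthal-equidistant plane; prediction uses the
Kalman (RTS) smoother.

## Worked example

```r
library(polarmove)

cfg    <- sim_config(n_bears = 3, n_steps = 200,
                     designs = c("seatrkr", "ear", "ear"), seed = 7)
study  <- simulate_study(cfg)
report <- run_study_pipeline(study$fixes, study$deployments, study$temperature,
                             pipeline_config(n_restarts = 3, seed = 7))
print(report)
```

```
Telemetry study report
======================
Fixes in: 724 | removed: truncation 64, speed 0, terrestrial 0, short segments 0 | retained: 660
Track segments analysed: 3

Functional duration by design:
  design n mean_days min_days max_days se_days
     ear 2  33.33333 33.33333 33.33333       0
 seatrkr 1  33.25000 33.25000 33.25000      NA

Argos error-class proportions:
 design class_3 class_2 class_1 class_0 class_A class_B
    ear  0.0443   0.141    0.13   0.119   0.208   0.357

Model selection (AICc):
          model  K     aicc delta_aicc  loglik
 intercept_only 11 -95.0561    0.00000 58.7757
           temp 13 -93.9000    1.15610 60.2928
          temp2 15 -91.3145    3.74163 61.1109

Time budget (decoded): state1 65.5%, state2 34.5%
```

Reading the output: of 724 generated fixes, 64 fall in the 3-day
post-capture window; nothing is fast enough to trip the 40 km/h filter and
no bear leaves land, so 660 fixes in 3 segments reach the HMM. All three
tags transmit until the end of the 33-day study. The error-class
proportions recover the generator's ear-tag class mix. At this small desk
scale the temperature effect on switching is not always detectable — here
the intercept-only model wins AICc by 1.2 — and the decoded budget is about
two-thirds resting. At the default study size (10 bears × 500 steps) the
linear-temperature model is preferred and the budget approaches the 70/30
resting/traveling split typical of bears ashore.

Individual stages are exported too: `read_fixes()`, `speed_filter()`,
`fit_ctcrw()`, `regularize_segment()`, `steps_and_turns()`, `fit_hmm()`
(returns an `hmm_fit` with `print`, `summary`, `coef`, `logLik`, `predict`,
`plot`, `simulate` methods), `viterbi_decode()`, `stationary_probs()`,
`time_budget()`, `detect_detachment()`, `summarize_durations()`,
`error_class_table()`.

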