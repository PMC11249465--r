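test_that("forward log-likelihood matches exhaustive enumeration on short series", {
  for (seed in 1:5) {
    ser <- random_series(8, seed)
    par <- random_params(seed + 100)
    expect_equal(hmm_loglik(ser, par), oracle_loglik(ser, par),
                 tolerance = 1e-10)
  }
  # multiple segments: additivity over independent segments
  ser <- random_series(6, 42)
  par <- random_params(7)
  two <- rbind(ser, transform(ser, segment_id = "s2"))
  expect_equal(hmm_loglik(two, par), 2 * hmm_loglik(ser, par), tolerance = 1e-10)
})

test_that("a single-observation segment reduces to the delta-weighted mixture", {
  par <- random_params(9)
  one <- data.frame(step_km = 0.4, turn_rad = NA_real_, temp = 2,
                    segment_id = "s1")
  sh <- par$gamma_mean^2 / par$gamma_sd^2
  ra <- par$gamma_mean / par$gamma_sd^2
  manual <- log(sum(par$delta * dgamma(0.4, shape = sh, rate = ra)))
  expect_equal(hmm_loglik(one, par), manual, tolerance = 1e-12)
})

test_that("zero steps without pre-treatment raise an interval-naming error", {
  par <- random_params(1)
  ser <- random_series(5, 2)
  ser$step_km[3] <- 0
  expect_error(hmm_loglik(ser, par), "interval 3")
  fixed <- treat_zero_steps(ser$step_km)
  expect_equal(fixed[3], min(ser$step_km[-3]) / 2)
  expect_equal(fixed[-3], ser$step_km[-3])
})

test_that("parameter counts follow the N-state formula", {
  expect_equal(count_parameters(2, "intercept_only"), 11)
  expect_equal(count_parameters(2, "temp"), 13)
  expect_equal(count_parameters(2, "temp2"), 15)
  expect_equal(count_parameters(3, "temp"), 26)   # 12 + 6*2 + 2
  expect_error(count_parameters(2, "cubic"), "model_label")
})

test_that("AICc ranking reproduces the closed form and the large-n limit", {
  mkfit <- function(ll, K, n, label) {
    structure(list(loglik = ll, K = K, n_obs = n,
                   aicc = -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1),
                   model_label = label, data_hash = c(n = 1, s = 1, t = 1)),
              class = "hmm_fit")
  }
  f <- mkfit(-100, 3, 50, "intercept_only")
  expect_equal(f$aicc, 206 + 24 / 46)
  # printed AICc values 2327.796 and 2338.155 differ by 10.359
  a <- mkfit(-1164.898, 13, 2460, "temp"); a$aicc <- 2327.796
  b <- mkfit(-1170.078, 11, 2460, "intercept_only"); b$aicc <- 2338.155
  tab <- model_selection(list(a, b))
  expect_equal(tab$model, c("temp", "intercept_only"))
  expect_equal(tab$delta_aicc, c(0, 10.359), tolerance = 1e-9)
  # correction vanishes as n grows
  g1 <- mkfit(-100, 3, 1e9, "temp")
  expect_equal(g1$aicc, -2 * -100 + 2 * 3, tolerance = 1e-6)
  # differing data refused
  c2 <- mkfit(-90, 3, 50, "temp"); c2$data_hash <- c(n = 2, s = 1, t = 1)
  expect_error(model_selection(list(f, c2)), "differing data")
})

test_that("Viterbi agrees with brute-force path enumeration", {
  for (seed in 1:4) {
    ser <- random_series(9, seed + 20)
    par <- random_params(seed + 200)
    fit <- structure(list(params = par, n_states = 2, model_label = "temp"),
                     class = "hmm_fit")
    dec <- viterbi_decode(ser, fit)
    expect_equal(dec$state, oracle_viterbi(ser, par))
    # posterior rows sum to one
    expect_equal(dec$p_state1 + dec$p_state2, rep(1, nrow(ser)),
                 tolerance = 1e-10)
  }
})

test_that("fully symmetric models decode to state 1 by the tie convention", {
  par <- list(gamma_mean = c(0.5, 0.5), gamma_sd = c(0.5, 0.5),
              vm_mean = c(0, 0), vm_conc = c(1, 1),
              beta = matrix(c(0, 0), 2, 1), delta = c(0.5, 0.5))
  ser <- random_series(10, 77)
  fit <- structure(list(params = par, n_states = 2,
                        model_label = "intercept_only"), class = "hmm_fit")
  expect_true(all(viterbi_decode(ser, fit)$state == 1))
})

test_that("non-overlapping emission regimes are decoded exactly", {
  # state 1 steps ~0.01 km, state 2 steps ~10 km: supports effectively disjoint
  par <- list(gamma_mean = c(0.01, 10), gamma_sd = c(0.005, 2),
              vm_mean = c(0, 0), vm_conc = c(0.5, 0.5),
              beta = matrix(log(c(0.3 / 0.7, 0.3 / 0.7)), 2, 1),
              delta = c(0.5, 0.5))
  truth <- rep(c(1L, 2L), times = c(6, 6))
  ser <- data.frame(step_km = ifelse(truth == 1, 0.01, 10),
                    turn_rad = c(NA, runif(11, -1, 1)),
                    temp = 0, segment_id = "s1")
  fit <- structure(list(params = par, n_states = 2,
                        model_label = "intercept_only"), class = "hmm_fit")
  expect_equal(viterbi_decode(ser, fit)$state, truth)
})

test_that("transition rows and stationary solutions behave across the grid", {
  par <- random_params(31)
  X <- polarmove:::.hmm_design(seq(-20, 15, length.out = 40), 1)
  tpm <- polarmove:::.hmm_tpm(par$beta, X, 2)
  expect_equal(tpm[, 1] + tpm[, 2], rep(1, 40), tolerance = 1e-12)
  expect_equal(tpm[, 3] + tpm[, 4], rep(1, 40), tolerance = 1e-12)

  expect_equal(stationary_dist(matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)),
               c(5 / 6, 1 / 6), tolerance = 1e-12)
  expect_equal(stationary_dist(matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE)),
               c(0.5, 0.5))
  expect_error(stationary_dist(diag(2)), "reducible")

  # negative temp coefficient on 1->2: traveling occupancy falls as it warms
  par$beta <- matrix(c(-2.9, -0.08, -2.4, 0.05), 2, 2, byrow = TRUE)
  cur <- stationary_probs(list(gamma_mean = c(0.02, 0.74), gamma_sd = c(0.02, 0.5),
                               vm_mean = c(pi, 0), vm_conc = c(0.7, 1.5),
                               beta = par$beta, delta = c(0.5, 0.5)),
                          seq(-25, 15, by = 1))
  expect_true(all(diff(cur$state2) < 0))
  expect_equal(cur$state1 + cur$state2, rep(1, nrow(cur)), tolerance = 1e-10)
})

test_that("time budgets are simple occupancy proportions", {
  dec <- structure(data.frame(state = rep(c(1L, 2L), c(7, 3))),
                   class = c("hmm_decoding", "data.frame"))
  expect_equal(unname(time_budget(dec)), c(0.7, 0.3))
  one <- structure(data.frame(state = rep(1L, 5)),
                   class = c("hmm_decoding", "data.frame"))
  expect_equal(unname(time_budget(one, n_states = 2)), c(1, 0))
  expect_error(time_budget(dec[0, , drop = FALSE]), "empty")
})

test_that("fitting is deterministic under a seed and beats the generating truth", {
  cfg <- sim_config(n_bears = 2, n_steps = 150, seed = 3)
  ser <- truth_series(cfg, 2)
  f1 <- fit_hmm(ser, "intercept_only", n_restarts = 2, seed = 11)
  f2 <- fit_hmm(ser, "intercept_only", n_restarts = 2, seed = 11)
  f1$series <- f2$series <- NULL
  expect_identical(f1, f2)

  f3 <- fit_hmm(ser, "temp", n_restarts = 2, seed = 11)
  truth_par <- cfg$params
  expect_gte(f3$loglik, hmm_loglik(ser, truth_par))
  # AICc identity holds on real fits
  expect_equal(f3$aicc,
               -2 * f3$loglik + 2 * f3$K + 2 * f3$K * (f3$K + 1) / (f3$n_obs - f3$K - 1))
  expect_equal(f3$K, 13)
  # states labelled so the resting state has the smaller step mean
  expect_lt(f3$params$gamma_mean[1], f3$params$gamma_mean[2])
})

test_that("fit methods expose coefficients, likelihood, prediction and simulation", {
  cfg <- sim_config(n_bears = 2, n_steps = 150, seed = 4)
  ser <- truth_series(cfg, 2)
  fit <- fit_hmm(ser, "temp", n_restarts = 2, seed = 5)
  expect_named(coef(fit))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(attr(logLik(fit), "df"), 13)
  pred <- predict(fit, newdata = data.frame(temp = c(-10, 0, 10)))
  expect_equal(pred$state1 + pred$state2, rep(1, 3), tolerance = 1e-10)
  sim <- simulate(fit, nsim = 200, seed = 1, temp = 0)
  expect_equal(nrow(sim), 200)
  expect_true(all(sim$state %in% 1:2))
  expect_output(print(fit), "movement HMM")
  expect_output(print(summary(fit)), "AICc")
})
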