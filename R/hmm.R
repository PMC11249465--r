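#' von Mises density and random deviates
#'
#' Density of the von Mises distribution on (-pi, pi] with mean direction
#' `mu` and concentration `kappa` (kappa = 0 is the circular uniform).
#' `rvonmises` uses the Best & Fisher (1979) rejection sampler.
#'
#' @param x Angle(s) in radians.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, >= 0.
#' @return `dvonmises`: density values; `rvonmises`: `n` angles in
#'   (-pi, pi].
#' @export
dvonmises <- function(x, mu, kappa) {
  exp(kappa * (cos(x - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname dvonmises
#' @param n Number of deviates.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- seq_len(min(sum(ok), m))
    out[got + take] <- th[take]
    got <- got + length(take)
  }
  wrap_angle(out + mu)
}

#' Replace exact zero steps before HMM fitting
#'
#' Exact zeros are incompatible with a gamma step-length model with no
#' point mass at zero; they are replaced by half the minimum positive
#' observed step.
#'
#' @param step_km Numeric vector of step lengths.
#' @return The vector with zeros replaced.
#' @export
treat_zero_steps <- function(step_km) {
  z <- step_km == 0
  if (any(z, na.rm = TRUE)) {
    pos <- step_km[!z & !is.na(step_km)]
    if (!length(pos)) stop("all steps are zero; cannot fit a gamma model",
                           call. = FALSE)
    step_km[which(z)] <- min(pos) / 2
  }
  step_km
}

.hmm_model_labels <- c("intercept_only", "temp", "temp2")

.model_p <- function(model_label) {
  switch(model_label, intercept_only = 0L, temp = 1L, temp2 = 2L,
         stop("unknown model_label: ", model_label, call. = FALSE))
}

#' Number of estimated parameters of an N-state movement HMM
#'
#' K = 2N (gamma mean, sd) + 2N (von Mises mean, concentration) +
#' N(N-1)(1+p) transition coefficients (p covariate terms) + (N-1) free
#' initial-distribution parameters. For two states this gives K = 11, 13
#' and 15 for the intercept-only, linear-temperature and quadratic-
#' temperature transition models.
#'
#' @param n_states Number of behavioural states (default 2).
#' @param model_label One of `"intercept_only"`, `"temp"`, `"temp2"`.
#' @return Integer parameter count K.
#' @export
count_parameters <- function(n_states = 2, model_label = "intercept_only") {
  p <- .model_p(model_label)
  n <- as.integer(n_states)
  4L * n + n * (n - 1L) * (1L + p) + (n - 1L)
}

# design matrix for the transition model: columns 1, z, z^2 as needed
.hmm_design <- function(z, p) {
  T <- length(z)
  X <- matrix(1, T, 1 + p)
  if (p >= 1) X[, 2] <- z
  if (p >= 2) X[, 3] <- z^2
  X
}

# T x (N*N) row-major transition probabilities under the multinomial-logit
# link; beta has one row per off-diagonal (i->j), ordered by i then j.
.hmm_tpm <- function(beta, X, n_states) {
  N <- n_states
  T <- nrow(X)
  eta <- X %*% t(beta)                 # T x N(N-1)
  out <- matrix(0, T, N * N)
  k <- 0L
  expeta <- exp(eta)
  for (i in seq_len(N)) {
    denom <- rep(1, T)
    cols <- integer(0)
    for (j in seq_len(N)) {
      if (i == j) next
      k <- k + 1L
      denom <- denom + expeta[, k]
      cols <- c(cols, k)
      out[, (i - 1L) * N + j] <- expeta[, k]
    }
    out[, (i - 1L) * N + i] <- 1
    for (j in seq_len(N)) {
      out[, (i - 1L) * N + j] <- out[, (i - 1L) * N + j] / denom
    }
  }
  out
}

# T x N matrix of state-dependent densities; undefined turns (NA)
# contribute the step density only.
.hmm_emissions <- function(step, turn, params) {
  N <- length(params$gamma_mean)
  T <- length(step)
  if (any(!is.finite(step)) || any(step <= 0)) {
    bad <- which(!is.finite(step) | step <= 0)[1]
    stop(sprintf("non-positive or non-finite step at interval %d; apply treat_zero_steps() first",
                 bad), call. = FALSE)
  }
  emis <- matrix(NA_real_, T, N)
  na_turn <- is.na(turn)
  turn0 <- turn
  turn0[na_turn] <- 0
  for (s in seq_len(N)) {
    shape <- params$gamma_mean[s]^2 / params$gamma_sd[s]^2
    rate <- params$gamma_mean[s] / params$gamma_sd[s]^2
    dens <- suppressWarnings(stats::dgamma(step, shape = shape, rate = rate))
    vm <- dvonmises(turn0, params$vm_mean[s], params$vm_conc[s])
    vm[na_turn] <- 1
    emis[, s] <- dens * vm
  }
  if (any(!is.finite(emis))) {
    bad <- which(!is.finite(rowSums(emis)))[1]
    stop(sprintf("non-finite emission density at interval %d", bad), call. = FALSE)
  }
  emis
}

.newseg <- function(segment_id) {
  c(TRUE, segment_id[-1] != segment_id[-length(segment_id)])
}

#' Forward-algorithm log-likelihood of a movement HMM
#'
#' Sum over track segments of the scaled forward-algorithm log-likelihood.
#' The emission density is gamma(step; mean, sd reparameterized to
#' shape/rate) x von Mises(turn; mean, kappa); the undefined first turn of
#' each segment contributes the step density only. The transition matrix at
#' interval `t` is the multinomial-logit function of the covariates at `t`
#' (on whatever scale `params$beta` is expressed).
#'
#' @param series Step series: data.frame with `step_km`, `turn_rad`,
#'   `temp`, `segment_id`.
#' @param params List with `gamma_mean`, `gamma_sd`, `vm_mean`, `vm_conc`
#'   (length-N vectors), `beta` (N(N-1) x (1+p) matrix), `delta` (length-N
#'   initial distribution).
#' @return Log-likelihood (scalar).
#' @export
hmm_loglik <- function(series, params) {
  N <- length(params$gamma_mean)
  p <- ncol(params$beta) - 1L
  if (p > 0 && anyNA(series$temp)) {
    stop("covariate model but temp missing for some steps", call. = FALSE)
  }
  emis <- .hmm_emissions(series$step_km, series$turn_rad, params)
  X <- .hmm_design(series$temp, p)
  X[is.na(X)] <- 0
  tpm <- .hmm_tpm(params$beta, X, N)
  hmm_forward_cpp(emis, tpm, params$delta, .newseg(series$segment_id))
}

# ---- working-scale parameter packing -------------------------------------

.pack <- function(params) {
  c(log(params$gamma_mean), log(params$gamma_sd),
    params$vm_mean, log(params$vm_conc),
    as.vector(t(params$beta)),
    log(params$delta[-1] / params$delta[1]))
}

.unpack <- function(w, n_states, p) {
  N <- n_states
  i <- 0
  take <- function(k) { out <- w[(i + 1):(i + k)]; i <<- i + k; out }
  gm <- exp(take(N)); gs <- exp(take(N))
  vmm <- wrap_angle(take(N)); vk <- exp(take(N))
  beta <- matrix(take(N * (N - 1L) * (1L + p)), nrow = N * (N - 1L),
                 ncol = 1L + p, byrow = TRUE)
  ed <- take(N - 1L)
  delta <- c(1, exp(ed)); delta <- delta / sum(delta)
  list(gamma_mean = gm, gamma_sd = gs, vm_mean = vmm, vm_conc = vk,
       beta = beta, delta = delta)
}

# starting values: state step means log-uniform between the 5th and 95th
# step percentiles (ordered), sds equal to means, angle means from {0, pi},
# concentrations log-uniform on [0.1, 5], dwell probabilities uniform on
# [0.7, 0.99], covariate coefficients 0, initial distribution uniform.
.draw_start <- function(step, n_states, p) {
  N <- n_states
  q <- stats::quantile(step, c(0.05, 0.95), names = FALSE)
  q[q <= 0] <- min(step[step > 0])
  gm <- sort(exp(stats::runif(N, log(q[1]), log(q[2]))))
  vmm <- sample(c(0, pi), N, replace = TRUE)
  vk <- exp(stats::runif(N, log(0.1), log(5)))
  dwell <- stats::runif(N, 0.7, 0.99)
  beta <- matrix(0, N * (N - 1L), 1L + p)
  k <- 0L
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    k <- k + 1L
    beta[k, 1] <- log((1 - dwell[i]) / (N - 1)) - log(dwell[i])
  }
  list(gamma_mean = gm, gamma_sd = gm, vm_mean = vmm, vm_conc = vk,
       beta = beta, delta = rep(1 / N, N))
}

# reorder states so state 1 has the smaller step mean ("resting"), applying
# the permutation to every parameter block including transitions
.relabel <- function(params) {
  ord <- order(params$gamma_mean)
  N <- length(ord)
  if (all(ord == seq_len(N))) return(params)
  idx_of <- function(i, j) {
    # row index of transition i->j in the beta matrix
    (i - 1L) * (N - 1L) + j - (j > i)
  }
  # new state s corresponds to old state ord[s], so the new (i -> j)
  # coefficients are the old (ord[i] -> ord[j]) ones
  beta_new2 <- params$beta
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    beta_new2[idx_of(i, j), ] <- params$beta[idx_of(ord[i], ord[j]), ]
  }
  list(gamma_mean = params$gamma_mean[ord], gamma_sd = params$gamma_sd[ord],
       vm_mean = params$vm_mean[ord], vm_conc = params$vm_conc[ord],
       beta = beta_new2, delta = params$delta[ord])
}

# transition coefficients on the standardized covariate scale -> raw scale
# eta = b0 + b1 z + b2 z^2, z = (x - mu)/sd
.beta_to_raw <- function(beta, center, scale) {
  p <- ncol(beta) - 1L
  if (p == 0L || is.null(center)) return(beta)
  out <- beta
  if (p == 1L) {
    out[, 1] <- beta[, 1] - beta[, 2] * center / scale
    out[, 2] <- beta[, 2] / scale
  } else {
    out[, 1] <- beta[, 1] - beta[, 2] * center / scale +
      beta[, 3] * center^2 / scale^2
    out[, 2] <- beta[, 2] / scale - 2 * beta[, 3] * center / scale^2
    out[, 3] <- beta[, 3] / scale^2
  }
  out
}

#' Fit a movement hidden Markov model
#'
#' Maximizes the forward-algorithm likelihood of an N-state HMM of step
#' lengths (gamma) and turn angles (von Mises) with transition
#' probabilities a multinomial-logit function of ambient temperature
#' (intercept-only, linear, or linear+quadratic). Because the likelihood is
#' multimodal, the optimization is restarted `n_restarts` times from random
#' starting values for the state step means and SDs, turn-angle means and
#' concentrations; the best converged restart is returned. Deterministic
#' given `seed`. Temperature is standardized internally for optimization;
#' transition coefficients are reported on both scales.
#'
#' @param series Step series (see [hmm_loglik()]); exact zero steps are
#'   replaced via [treat_zero_steps()].
#' @param model_label `"intercept_only"`, `"temp"`, or `"temp2"`.
#' @param n_states Number of states (default 2).
#' @param n_restarts Number of random restarts (default 50).
#' @param seed Integer seed controlling the restart draws.
#' @param maxit Maximum BFGS iterations per restart.
#' @return Object of class `hmm_fit`: `params` (raw temperature scale),
#'   `params_std` (standardized scale, with `temp_center`/`temp_scale`),
#'   `loglik`, `K`, `n_obs`, `aicc`, `model_label`,
#'   `n_restarts_converged`, `delta`, and the fitted series.
#' @export
fit_hmm <- function(series, model_label = "intercept_only", n_states = 2,
                    n_restarts = 50, seed = NULL, maxit = 300) {
  model_label <- match.arg(model_label, .hmm_model_labels)
  p <- .model_p(model_label)
  if (nrow(series) == 0) stop("empty step series", call. = FALSE)
  if (p > 0 && anyNA(series$temp)) {
    stop("temperature covariate required but missing for some steps",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(n_states)

  work <- series
  work$step_km <- treat_zero_steps(work$step_km)
  ctr <- scl <- NULL
  if (p > 0) {
    ctr <- mean(work$temp); scl <- stats::sd(work$temp)
    if (!is.finite(scl) || scl == 0) scl <- 1
    work$temp <- (work$temp - ctr) / scl
  }
  newseg <- .newseg(work$segment_id)
  X <- .hmm_design(if (p > 0) work$temp else rep(0, nrow(work)), p)

  nll <- function(w) {
    pr <- .unpack(w, N, p)
    emis <- tryCatch(.hmm_emissions(work$step_km, work$turn_rad, pr),
                     error = function(e) NULL)
    if (is.null(emis)) return(1e10)
    tpm <- .hmm_tpm(pr$beta, X, N)
    if (any(!is.finite(tpm))) return(1e10)
    v <- -hmm_forward_cpp(emis, tpm, pr$delta, newseg)
    if (!is.finite(v)) 1e10 else v
  }

  best <- NULL
  n_conv <- 0L
  diag_log <- character(0)
  for (r in seq_len(n_restarts)) {
    w0 <- .pack(.draw_start(work$step_km, N, p))
    # a simplex phase first: the likelihood has degenerate local modes
    # (state-collapse) in which gradient methods started far away get stuck
    opt <- tryCatch({
      pre <- stats::optim(w0, nll, method = "Nelder-Mead",
                          control = list(maxit = 600))
      mid <- stats::optim(pre$par, nll, method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-9))
      # Newton-type polish; its scaled-gradient criterion (gradtol) is the
      # convergence test
      fin <- suppressWarnings(stats::nlm(nll, mid$par, iterlim = 100,
                                         gradtol = 1e-6))
      list(par = fin$estimate, value = fin$minimum, code = fin$code,
           grad = fin$gradient)
    }, error = function(e) NULL)
    if (is.null(opt)) { diag_log <- c(diag_log, sprintf("restart %d: optim error", r)); next }
    converged <- opt$code %in% c(1, 2) && is.finite(opt$value) && opt$value < 1e9
    if (!converged) {
      diag_log <- c(diag_log,
                    sprintf("restart %d: nlm code %d, |grad|=%.3g, nll=%.4f",
                            r, opt$code, max(abs(opt$grad)), opt$value))
      next
    }
    n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop(paste(c("no HMM restart converged:", diag_log), collapse = "\n  "),
         call. = FALSE)
  }

  params_std <- .relabel(.unpack(best$par, N, p))
  params <- params_std
  params$beta <- .beta_to_raw(params_std$beta, ctr, scl)
  rownames(params$beta) <- rownames(params_std$beta) <- .trans_labels(N)
  colnames(params$beta) <- colnames(params_std$beta) <-
    c("(Intercept)", "temp", "temp2")[seq_len(1 + p)]

  ll <- -best$value
  n_obs <- nrow(work)
  K <- count_parameters(N, model_label)
  structure(list(
    params = params,
    params_std = c(params_std, list(temp_center = ctr, temp_scale = scl)),
    loglik = ll,
    K = K,
    n_obs = n_obs,
    aicc = -2 * ll + 2 * K + 2 * K * (K + 1) / (n_obs - K - 1),
    model_label = model_label,
    n_states = N,
    n_restarts_converged = n_conv,
    data_hash = .series_hash(series),
    series = series
  ), class = "hmm_fit")
}

.trans_labels <- function(N) {
  lab <- character(0)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i != j) lab <- c(lab, sprintf("%d->%d", i, j))
  }
  lab
}

.series_hash <- function(series) {
  c(n = nrow(series), s = sum(series$step_km),
    t = sum(series$turn_rad, na.rm = TRUE))
}

#' Rank fitted HMMs by small-sample-corrected AIC
#'
#' AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1), with n the total number of
#' step observations. Delta AICc is relative to the best (smallest) value.
#'
#' @param fits List of `hmm_fit` objects fitted to the identical series.
#' @return data.frame sorted by ascending AICc with columns `model`, `K`,
#'   `aicc`, `delta_aicc`, `loglik`.
#' @export
model_selection <- function(fits) {
  h <- lapply(fits, function(f) f$data_hash)
  if (length(fits) > 1) {
    for (k in 2:length(fits)) {
      if (!isTRUE(all.equal(h[[1]], h[[k]]))) {
        stop("model_selection: fits were made on differing data", call. = FALSE)
      }
    }
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$model_label, character(1)),
    K = vapply(fits, function(f) f$K, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1))
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tab <- tab[order(tab$aicc), c("model", "K", "aicc", "delta_aicc", "loglik")]
  rownames(tab) <- NULL
  tab
}

#' Decode the most likely behavioural state sequence
#'
#' Per-segment Viterbi decoding in log space (ties broken toward the lower
#' state index) plus forward-backward posterior state probabilities.
#'
#' @param series Step series the model was fitted to (zero steps are
#'   treated as in fitting).
#' @param fit An `hmm_fit`.
#' @return Object of class `hmm_decoding`: data.frame with `segment_id`,
#'   `state` (Viterbi), and posterior columns `p_state1..p_stateN`.
#' @export
viterbi_decode <- function(series, fit) {
  params <- fit$params
  N <- fit$n_states
  p <- .model_p(fit$model_label)
  step <- treat_zero_steps(series$step_km)
  emis <- .hmm_emissions(step, series$turn_rad, params)
  X <- .hmm_design(if (p > 0) series$temp else rep(0, nrow(series)), p)
  tpm <- .hmm_tpm(params$beta, X, N)
  newseg <- .newseg(series$segment_id)
  T <- nrow(series)
  lemis <- log(emis)
  ldelta <- log(fit$params$delta)

  state <- integer(T)
  post <- matrix(NA_real_, T, N)
  seg_starts <- which(newseg)
  seg_ends <- c(seg_starts[-1] - 1L, T)
  for (k in seq_along(seg_starts)) {
    rng <- seg_starts[k]:seg_ends[k]
    Ts <- length(rng)
    ltpm <- log(array(t(tpm[rng, , drop = FALSE]), c(N, N, Ts)))
    # ltpm[j, i, t] after transpose of row-major rows: entry (i->j) at
    # position i*N+j means tpm row is (i1j1,i1j2,i2j1,i2j2); t() gives
    # column vectors; reshape to N x N with first index j
    dp <- matrix(-Inf, Ts, N)
    bk <- matrix(1L, Ts, N)
    dp[1, ] <- ldelta + lemis[rng[1], ]
    if (Ts > 1) for (t in 2:Ts) {
      for (j in seq_len(N)) {
        cand <- dp[t - 1, ] + ltpm[j, , t]
        best_i <- which.max(cand)          # first max: lower index on ties
        dp[t, j] <- cand[best_i] + lemis[rng[t], j]
        bk[t, j] <- best_i
      }
    }
    s <- integer(Ts)
    s[Ts] <- which.max(dp[Ts, ])
    if (Ts > 1) for (t in (Ts - 1):1) s[t] <- bk[t + 1, s[t + 1]]
    state[rng] <- s

    # forward-backward with scaling
    al <- matrix(0, Ts, N); be <- matrix(0, Ts, N)
    al[1, ] <- fit$params$delta * emis[rng[1], ]
    al[1, ] <- al[1, ] / sum(al[1, ])
    if (Ts > 1) for (t in 2:Ts) {
      G <- matrix(tpm[rng[t], ], N, N, byrow = TRUE)
      a <- (al[t - 1, ] %*% G) * emis[rng[t], ]
      al[t, ] <- a / sum(a)
    }
    be[Ts, ] <- 1
    if (Ts > 1) for (t in (Ts - 1):1) {
      G <- matrix(tpm[rng[t + 1], ], N, N, byrow = TRUE)
      b <- G %*% (be[t + 1, ] * emis[rng[t + 1], ])
      be[t, ] <- b / max(b)
    }
    pp <- al * be
    post[rng, ] <- pp / rowSums(pp)
  }
  out <- data.frame(segment_id = series$segment_id, state = state)
  for (s in seq_len(N)) out[[paste0("p_state", s)]] <- post[, s]
  class(out) <- c("hmm_decoding", "data.frame")
  out
}

#' Stationary state probabilities along a temperature gradient
#'
#' For each temperature, solves pi Gamma(temp) = pi, sum(pi) = 1, for the
#' fitted (raw-scale) transition model. Under the logit link all transition
#' probabilities are strictly positive, so the chain is irreducible unless
#' probabilities underflow numerically, which raises an error at that grid
#' value.
#'
#' @param fit An `hmm_fit` (or a params list with a `beta` matrix).
#' @param temp_grid Temperatures (degrees C) at which to evaluate.
#' @return data.frame with `temp` and one stationary-probability column per
#'   state; rows sum to 1.
#' @export
stationary_probs <- function(fit, temp_grid) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  N <- length(params$delta)
  p <- ncol(params$beta) - 1L
  X <- .hmm_design(temp_grid, p)
  tpm <- .hmm_tpm(params$beta, X, N)
  out <- matrix(NA_real_, length(temp_grid), N)
  for (t in seq_along(temp_grid)) {
    G <- matrix(tpm[t, ], N, N, byrow = TRUE)
    out[t, ] <- stationary_dist(G)
  }
  res <- data.frame(temp = temp_grid)
  for (s in seq_len(N)) res[[paste0("state", s)]] <- out[, s]
  res
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi G = pi with sum(pi) = 1 by a linear solve.
#'
#' @param G Row-stochastic N x N matrix.
#' @return Stationary probability vector.
#' @export
stationary_dist <- function(G) {
  N <- nrow(G)
  if (any(G < 0) || any(abs(rowSums(G) - 1) > 1e-8)) {
    stop("G is not row-stochastic", call. = FALSE)
  }
  # absorbing/reducible chains have no unique interior solution
  A <- t(diag(N) - G)
  A <- rbind(A, rep(1, N))
  pi_hat <- tryCatch(stats::lm.fit(A, c(rep(0, N), 1))$coefficients,
                     error = function(e) NULL)
  if (is.null(pi_hat) || anyNA(pi_hat) || any(pi_hat < -1e-10)) {
    stop("transition matrix is reducible or absorbing; no unique stationary distribution",
         call. = FALSE)
  }
  as.numeric(pi_hat / sum(pi_hat))
}

#' Behavioural time budget from a decoded state sequence
#'
#' @param decoding An `hmm_decoding` (or any data.frame with a `state`
#'   column) plus the number of states via attribute or maximum state.
#' @param n_states Number of states (default: max observed).
#' @return Named numeric vector of per-state proportions summing to 1.
#' @export
time_budget <- function(decoding, n_states = NULL) {
  if (nrow(decoding) == 0) stop("empty decoding", call. = FALSE)
  N <- n_states %||% max(decoding$state)
  prop <- tabulate(decoding$state, nbins = N) / nrow(decoding)
  names(prop) <- paste0("state", seq_len(N))
  prop
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("%d-state movement HMM (transition model: %s)\n",
              x$n_states, x$model_label))
  cat(sprintf("  log-likelihood %.3f, K = %d, AICc = %.3f (n = %d steps)\n",
              x$loglik, x$K, x$aicc, x$n_obs))
  cat(sprintf("  converged restarts: %d\n", x$n_restarts_converged))
  cat("\nStep length (gamma):\n")
  print(round(data.frame(mean_km = x$params$gamma_mean,
                         sd_km = x$params$gamma_sd,
                         row.names = paste("state", seq_len(x$n_states))), 4))
  cat("\nTurn angle (von Mises):\n")
  print(round(data.frame(mean_rad = x$params$vm_mean,
                         concentration = x$params$vm_conc,
                         row.names = paste("state", seq_len(x$n_states))), 4))
  cat("\nTransition coefficients (ambient temperature scale):\n")
  print(round(x$params$beta, 5))
  invisible(x)
}

#' @export
summary.hmm_fit <- function(object, ...) {
  out <- list(
    model = object$model_label,
    n_states = object$n_states,
    loglik = object$loglik,
    K = object$K,
    n_obs = object$n_obs,
    aicc = object$aicc,
    step = data.frame(mean_km = object$params$gamma_mean,
                      sd_km = object$params$gamma_sd),
    turn = data.frame(mean_rad = object$params$vm_mean,
                      concentration = object$params$vm_conc),
    beta = object$params$beta,
    delta = object$params$delta
  )
  class(out) <- "summary.hmm_fit"
  out
}

#' @export
print.summary.hmm_fit <- function(x, ...) {
  cat(sprintf("Movement HMM summary: %d states, model %s\n", x$n_states, x$model))
  cat(sprintf("logLik %.3f  K %d  AICc %.3f  n %d\n", x$loglik, x$K, x$aicc, x$n_obs))
  cat("\nStep length:\n"); print(round(x$step, 4))
  cat("\nTurn angle:\n"); print(round(x$turn, 4))
  cat("\nTransitions:\n"); print(round(x$beta, 5))
  cat("\nInitial distribution:", round(x$delta, 4), "\n")
  invisible(x)
}

#' @export
coef.hmm_fit <- function(object, ...) {
  p <- object$params
  c(stats::setNames(p$gamma_mean, paste0("gamma_mean", seq_along(p$gamma_mean))),
    stats::setNames(p$gamma_sd, paste0("gamma_sd", seq_along(p$gamma_sd))),
    stats::setNames(p$vm_mean, paste0("vm_mean", seq_along(p$vm_mean))),
    stats::setNames(p$vm_conc, paste0("vm_conc", seq_along(p$vm_conc))),
    stats::setNames(as.vector(t(p$beta)),
                    paste0("beta_", rep(rownames(p$beta), each = ncol(p$beta)),
                           "_", rep(colnames(p$beta), nrow(p$beta)))),
    stats::setNames(p$delta, paste0("delta", seq_along(p$delta))))
}

#' @export
logLik.hmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n_obs,
            class = "logLik")
}

#' Predict stationary state probabilities from a fitted HMM
#'
#' @param object An `hmm_fit`.
#' @param newdata data.frame with a `temp` column (or a numeric temperature
#'   vector). Defaults to the fitted series' temperature range.
#' @param ... Unused.
#' @return See [stationary_probs()].
#' @export
predict.hmm_fit <- function(object, newdata = NULL, ...) {
  temps <- if (is.null(newdata)) {
    if (all(is.na(object$series$temp))) 0 else
      seq(min(object$series$temp, na.rm = TRUE),
          max(object$series$temp, na.rm = TRUE), length.out = 50)
  } else if (is.data.frame(newdata)) newdata$temp else as.numeric(newdata)
  stationary_probs(object, temps)
}

#' Plot fitted state-dependent distributions
#'
#' Step-length and turn-angle histograms of the fitted series overlaid with
#' the per-state gamma and von Mises densities weighted by the decoded time
#' budget.
#'
#' @param x An `hmm_fit`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.hmm_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  step <- treat_zero_steps(x$series$step_km)
  w <- time_budget(viterbi_decode(x$series, x), x$n_states)
  graphics::hist(step, breaks = 40, freq = FALSE, main = "Step length",
                 xlab = "step (km)", ...)
  xs <- seq(1e-4, max(step), length.out = 400)
  for (s in seq_len(x$n_states)) {
    shape <- x$params$gamma_mean[s]^2 / x$params$gamma_sd[s]^2
    rate <- x$params$gamma_mean[s] / x$params$gamma_sd[s]^2
    graphics::lines(xs, w[s] * stats::dgamma(xs, shape, rate), col = s + 1, lwd = 2)
  }
  turn <- x$series$turn_rad[!is.na(x$series$turn_rad)]
  graphics::hist(turn, breaks = 40, freq = FALSE, main = "Turn angle",
                 xlab = "turn (rad)", ...)
  ts_ <- seq(-pi, pi, length.out = 400)
  for (s in seq_len(x$n_states)) {
    graphics::lines(ts_, w[s] * dvonmises(ts_, x$params$vm_mean[s], x$params$vm_conc[s]),
                    col = s + 1, lwd = 2)
  }
  invisible(x)
}

#' Simulate a step series from a fitted HMM
#'
#' Draws a latent state chain under the fitted transition model at the
#' supplied temperatures, then gamma steps and von Mises turns from the
#' fitted state-dependent distributions.
#'
#' @param object An `hmm_fit` (or a params list).
#' @param nsim Number of steps to simulate.
#' @param seed Optional RNG seed.
#' @param temp Temperature per step (recycled; default 0).
#' @param ... Unused.
#' @return data.frame with `step_km`, `turn_rad`, `temp`, `segment_id`,
#'   `state`.
#' @export
simulate.hmm_fit <- function(object, nsim = 1, seed = NULL, temp = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  params <- if (inherits(object, "hmm_fit")) object$params else object
  N <- length(params$delta)
  p <- ncol(params$beta) - 1L
  temp <- rep_len(temp, nsim)
  X <- .hmm_design(temp, p)
  tpm <- .hmm_tpm(params$beta, X, N)
  state <- integer(nsim)
  state[1] <- sample.int(N, 1, prob = params$delta)
  for (t in seq_len(nsim)[-1]) {
    G <- matrix(tpm[t, ], N, N, byrow = TRUE)
    state[t] <- sample.int(N, 1, prob = G[state[t - 1], ])
  }
  shape <- params$gamma_mean^2 / params$gamma_sd^2
  rate <- params$gamma_mean / params$gamma_sd^2
  step <- stats::rgamma(nsim, shape[state], rate[state])
  turn <- vapply(seq_len(nsim), function(t) {
    rvonmises(1, params$vm_mean[state[t]], params$vm_conc[state[t]])
  }, numeric(1))
  turn[1] <- NA_real_
  data.frame(step_km = step, turn_rad = turn, temp = temp,
             segment_id = "sim", state = state)
}
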