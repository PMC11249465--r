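# Independent oracles and fixture builders shared across tests.

utc <- function(x) as.POSIXct(x, tz = "UTC")
t0_utc <- utc("2021-09-05 00:00:00")

# exhaustive-enumeration log-likelihood for a two-state HMM; written
# independently of the package's forward implementation (direct sum over
# all state paths, densities from first principles)
oracle_loglik <- function(series, params) {
  seg_f <- factor(series$segment_id, levels = unique(series$segment_id))
  total <- 0
  for (idx in split(seq_len(nrow(series)), seg_f)) {
    Ts <- length(idx)
    step <- series$step_km[idx]; turn <- series$turn_rad[idx]
    temp <- series$temp[idx]
    dens <- function(t, s) {
      sh <- params$gamma_mean[s]^2 / params$gamma_sd[s]^2
      ra <- params$gamma_mean[s] / params$gamma_sd[s]^2
      d <- dgamma(step[t], shape = sh, rate = ra)
      if (!is.na(turn[t])) {
        k <- params$vm_conc[s]
        d <- d * exp(k * cos(turn[t] - params$vm_mean[s])) /
          (2 * pi * besselI(k, 0, expon.scaled = TRUE) * exp(k))
      }
      d
    }
    trans <- function(t, i, j) {
      # multinomial logit, two states, covariates at the arrival step t
      x <- c(1, temp[t], temp[t]^2)[seq_len(ncol(params$beta))]
      e12 <- exp(sum(params$beta[1, ] * x))
      e21 <- exp(sum(params$beta[2, ] * x))
      G <- rbind(c(1, e12) / (1 + e12), c(e21, 1) / (1 + e21))
      G[i, j]
    }
    tot <- 0
    paths <- as.matrix(expand.grid(rep(list(1:2), Ts)))
    for (r in seq_len(nrow(paths))) {
      s <- paths[r, ]
      p <- params$delta[s[1]] * dens(1, s[1])
      if (Ts > 1) for (t in 2:Ts) p <- p * trans(t, s[t - 1], s[t]) * dens(t, s[t])
      tot <- tot + p
    }
    total <- total + log(tot)
  }
  total
}

# brute-force most-likely path (ties toward the lexicographically smallest,
# i.e. lower state indices first)
oracle_viterbi <- function(series, params) {
  seg_f <- factor(series$segment_id, levels = unique(series$segment_id))
  out <- integer(nrow(series))
  for (idx in split(seq_len(nrow(series)), seg_f)) {
    Ts <- length(idx)
    sub <- series[idx, , drop = FALSE]
    # used with continuous random parameters, where the argmax path is
    # unique almost surely, so tie order does not matter
    grid <- as.matrix(expand.grid(rep(list(1:2), Ts)))
    best <- -Inf; best_path <- NULL
    for (r in seq_len(nrow(grid))) {
      s <- grid[r, ]
      lp <- log(params$delta[s[1]])
      for (t in seq_len(Ts)) {
        sh <- params$gamma_mean[s[t]]^2 / params$gamma_sd[s[t]]^2
        ra <- params$gamma_mean[s[t]] / params$gamma_sd[s[t]]^2
        lp <- lp + dgamma(sub$step_km[t], shape = sh, rate = ra, log = TRUE)
        if (!is.na(sub$turn_rad[t])) {
          k <- params$vm_conc[s[t]]
          lp <- lp + k * (cos(sub$turn_rad[t] - params$vm_mean[s[t]]) - 1) -
            log(2 * pi * besselI(k, 0, expon.scaled = TRUE))
        }
        if (t > 1) {
          x <- c(1, sub$temp[t], sub$temp[t]^2)[seq_len(ncol(params$beta))]
          e12 <- exp(sum(params$beta[1, ] * x))
          e21 <- exp(sum(params$beta[2, ] * x))
          G <- rbind(c(1, e12) / (1 + e12), c(e21, 1) / (1 + e21))
          lp <- lp + log(G[s[t - 1], s[t]])
        }
      }
      if (lp > best) { best <- lp; best_path <- s }
    }
    out[idx] <- best_path
  }
  out
}

# small random step series for oracle comparisons
random_series <- function(T, seed, model_p = 1) {
  set.seed(seed)
  data.frame(
    step_km = rgamma(T, 2, 4),
    turn_rad = c(NA, runif(T - 1, -pi, pi)),
    temp = round(runif(T, -10, 10), 1),
    segment_id = "s1"
  )
}

random_params <- function(seed, p = 1) {
  set.seed(seed)
  list(
    gamma_mean = sort(runif(2, 0.05, 1.5)),
    gamma_sd = runif(2, 0.05, 1),
    vm_mean = runif(2, -pi, pi),
    vm_conc = runif(2, 0.2, 3),
    beta = matrix(c(rnorm(2, -2, 0.5), rnorm(2 * p, 0, 0.05)), nrow = 2),
    delta = c(0.6, 0.4)
  )
}

# fixture: a simple fix table on a straight northward line, 4-h spacing
make_line_fixes <- function(n, tag_id = "T01", start = t0_utc,
                            speed_kmh = 2, interval_h = 4,
                            source = "argos", on_land = TRUE) {
  dlat <- speed_kmh * interval_h / 111.1949
  data.frame(
    tag_id = rep(tag_id, n), bear_id = rep("B01", n),
    time = start + (seq_len(n) - 1) * interval_h * 3600,
    lon = rep(-93.5, n), lat = 58 + (seq_len(n) - 1) * dlat,
    source = rep(source, n),
    loc_class = rep(if (source == "argos") "1" else NA_character_, n),
    h_error_m = rep(if (source == "gps") 10 else NA_real_, n),
    activity = rep("active", n), on_land = rep(on_land, n)
  )
}

# simulate positions from the exact discrete-time integrated-OU system --
# an independent generator, not the package's Kalman code
sim_ctcrw_xy <- function(n, beta, sigma, dt_h = 1, seed = 1) {
  set.seed(seed)
  e1 <- exp(-beta * dt_h); e2 <- exp(-2 * beta * dt_h)
  Tm <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
  Q <- matrix(c(
    sigma^2 / beta^2 * (dt_h - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta)),
    sigma^2 / (2 * beta^2) * (1 - e1)^2,
    sigma^2 / (2 * beta^2) * (1 - e1)^2,
    sigma^2 / (2 * beta) * (1 - e2)), 2, 2)
  L <- t(chol(Q))
  one_axis <- function() {
    out <- numeric(n)
    st <- c(0, rnorm(1, 0, sigma / sqrt(2 * beta)))
    for (i in seq_len(n)) {
      st <- as.numeric(Tm %*% st + L %*% rnorm(2))
      out[i] <- st[1]
    }
    out
  }
  list(x = one_axis(), y = one_axis())
}

ctcrw_segment <- function(n, beta, sigma, tau, dt_h = 1, seed = 1,
                          ctr = c(-93.5, 58)) {
  p <- sim_ctcrw_xy(n, beta, sigma, dt_h, seed)
  ll <- polarmove::unproject_aeq(p$x + rnorm(n, 0, tau),
                                 p$y + rnorm(n, 0, tau), ctr[1], ctr[2])
  data.frame(tag_id = "T01", time = t0_utc + (1:n) * dt_h * 3600,
             lon = ll$lon, lat = ll$lat,
             source = "gps", loc_class = NA_character_,
             truth_x = p$x, truth_y = p$y)
}

# truth-level step series for one synthetic study (no observation layer)
truth_series <- function(cfg, n_tracks = NULL) {
  n_tracks <- n_tracks %||% cfg$n_bears
  temperature <- polarmove::simulate_temperature(cfg, cfg$n_steps * 4 + 48)
  occ <- c(0, 0)
  ser <- vector("list", n_tracks)
  for (b in seq_len(n_tracks)) {
    tr <- polarmove::simulate_track(cfg, temperature)
    s <- tr$steps
    occ <- occ + tabulate(s$state, 2)
    s$segment_id <- paste0("seg", b)
    ser[[b]] <- s[, c("step_km", "turn_rad", "temp", "segment_id", "time")]
  }
  structure(do.call(rbind, ser), occupancy = occ / sum(occ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
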