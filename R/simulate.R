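#' Configuration for a synthetic telemetry study
#'
#' Defines the generating conditions of a synthetic study: a two-state
#' Markov-switching movement process (gamma step lengths, von Mises turns)
#' whose transition probabilities depend on ambient temperature on the
#' logit scale, an autumn cooling temperature series, design-specific duty
#' cycles, class-structured Argos positional error, missed fixes, and tag
#' detachment/battery failure. Defaults emulate subadult/adult male polar
#' bears ashore on the Hudson Bay coast during the ice-free season:
#' resting steps averaging 0.02 km and traveling steps 0.74 km per 4 h,
#' dwell probabilities near 0.95 with long-run resting occupancy near 70%,
#' a negative temperature effect on the resting-to-traveling transition
#' (bears travel more as autumn cools), and the ear-tag Argos class mix
#' (6/14/14/13/18/36% for classes 3/2/1/0/A/B).
#'
#' @param n_bears Number of tagged bears (default 10).
#' @param n_steps Number of 4-h behavioural steps per bear (default 500).
#' @param designs Tag design per bear, recycled (default 6 seatrkr + 4 ear).
#' @param gamma_mean,gamma_sd Step-length mean/SD per state, km per 4-h step.
#' @param vm_mean,vm_conc Turn-angle mean (rad) and concentration per state.
#' @param beta Transition coefficient matrix, rows `1->2` and `2->1`,
#'   columns intercept and temperature (degrees C).
#' @param delta Initial state distribution.
#' @param temp_mean0 Season-start mean temperature, degrees C.
#' @param cooling_per_day Linear temperature trend, degrees C per day
#'   (negative = cooling).
#' @param diel_amp Amplitude of the diel temperature sinusoid, degrees C.
#' @param temp_ar1,temp_innov_sd AR(1) coefficient and innovation SD of the
#'   hourly temperature noise.
#' @param fix_success Probability a scheduled fix is obtained.
#' @param class_mix Argos location-class probabilities (3,2,1,0,A,B).
#' @param class_sd_km Positional error SD per Argos class, km.
#' @param gps_sd_km GPS positional error SD, km.
#' @param mean_retention_days Mean of the exponential detachment time per
#'   design (`Inf` disables detachment).
#' @param battery_days Battery lifetime per design, days.
#' @param coast_lat Latitude of the half-plane coastline: points at or above
#'   it are marine.
#' @param start_lon,start_lat Deployment area center.
#' @param start_jitter_km Uniform jitter of each bear's start point, km.
#' @param season_start UTC timestamp of the study start.
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(
    n_bears = 10,
    n_steps = 500,
    designs = c(rep("seatrkr", 6), rep("ear", 4)),
    gamma_mean = c(0.02, 0.74),
    gamma_sd = c(0.02, 0.5),
    vm_mean = c(pi, 0),
    vm_conc = c(0.7, 1.5),
    beta = matrix(c(stats::qlogis(0.035), -0.06,
                    stats::qlogis(0.08), 0.04),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("1->2", "2->1"), c("(Intercept)", "temp"))),
    delta = c(0.7, 0.3),
    temp_mean0 = 10,
    cooling_per_day = -0.25,
    diel_amp = 3,
    temp_ar1 = 0.8,
    temp_innov_sd = 1.5,
    fix_success = 0.9,
    class_mix = c(`3` = 0.06, `2` = 0.14, `1` = 0.14, `0` = 0.13,
                  A = 0.18, B = 0.36),
    class_sd_km = default_error_sd_km,
    gps_sd_km = 0.011,
    mean_retention_days = c(pentagon = 22, seatrkr = 58, tribrush = 47,
                            ear = 2000),
    battery_days = c(pentagon = 165, seatrkr = 330, tribrush = 165, ear = 165),
    coast_lat = 58.85,
    start_lon = -93.5, start_lat = 58.0,
    start_jitter_km = 30,
    season_start = as.POSIXct("2021-09-01 00:00:00", tz = "UTC"),
    seed = 1L) {
  # class percentages quoted as rounded integers may not sum exactly to
  # 100; renormalize within a small tolerance
  if (abs(sum(class_mix) - 1) > 0.05) {
    stop("class_mix must sum to ~1", call. = FALSE)
  }
  class_mix <- class_mix / sum(class_mix)
  stopifnot(all(class_mix >= 0), fix_success >= 0, fix_success <= 1,
            all(delta >= 0), abs(sum(delta) - 1) < 1e-9,
            all(mean_retention_days > 0))
  cfg <- list(
    n_bears = n_bears, n_steps = n_steps, designs = designs,
    params = list(gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                  vm_mean = vm_mean, vm_conc = vm_conc,
                  beta = beta, delta = delta),
    temp_mean0 = temp_mean0, cooling_per_day = cooling_per_day,
    diel_amp = diel_amp, temp_ar1 = temp_ar1, temp_innov_sd = temp_innov_sd,
    fix_success = fix_success, class_mix = class_mix,
    class_sd_km = class_sd_km, gps_sd_km = gps_sd_km,
    mean_retention_days = mean_retention_days, battery_days = battery_days,
    coast_lat = coast_lat, start_lon = start_lon, start_lat = start_lat,
    start_jitter_km = start_jitter_km, season_start = season_start,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' A noise- and failure-free variant of a study configuration
#'
#' Convenience wrapper: perfect fix success, zero positional error, no
#' detachment or battery failure. Useful for oracle-style pipeline checks
#' (with no observation noise no implausible speeds exist, so the speed
#' filter must remove nothing).
#'
#' @param ... Passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_noise_free <- function(...) {
  cfg <- sim_config(...)
  cfg$fix_success <- 1
  cfg$class_sd_km[] <- 0
  cfg$gps_sd_km <- 0
  cfg$mean_retention_days[] <- Inf
  cfg$battery_days[] <- Inf
  cfg
}

#' Simulate an hourly station temperature series
#'
#' Hourly temperature = seasonal linear trend + diel sinusoid + AR(1)
#' noise, started from the stationary distribution of the AR process.
#'
#' @param config A `sim_config`.
#' @param duration_h Series length in hours.
#' @param start_time Series start (default `config$season_start`).
#' @return Temperature data.frame in the format of [read_temperature()].
#' @export
simulate_temperature <- function(config, duration_h,
                                 start_time = config$season_start) {
  stopifnot(duration_h > 0)
  h <- 0:ceiling(duration_h)
  trend <- config$temp_mean0 + config$cooling_per_day * h / 24
  diel <- config$diel_amp * sin(2 * pi * (h %% 24) / 24)
  n <- length(h)
  phi <- config$temp_ar1
  e <- numeric(n)
  sd0 <- if (abs(phi) < 1) config$temp_innov_sd / sqrt(1 - phi^2) else
    config$temp_innov_sd
  e[1] <- stats::rnorm(1, 0, sd0)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, config$temp_innov_sd)
    for (t in 2:n) e[t] <- phi * e[t - 1] + innov[t - 1]
  }
  data.frame(
    station_id = "SIM1", station_lon = -94.07, station_lat = 58.74,
    time = start_time + h * 3600,
    temp = trend + diel + e
  )
}

#' Simulate one bear's true movement track
#'
#' Simulates the latent two-state chain with temperature-dependent
#' transition probabilities on the 4-h step grid, draws gamma steps and von
#' Mises turns, accumulates positions on a local plane centred on the
#' bear's start point, and maps them to lon/lat near the Hudson Bay coast.
#' True positions are also provided on a 1-h grid (linear within each 4-h
#' step); each 1-h point carries the state of its step and an `on_land`
#' flag from the half-plane coastline model.
#'
#' @param config A `sim_config`.
#' @param temperature Hourly temperature series covering the track span.
#' @param start_lon,start_lat Track origin (default: config center).
#' @param start_time Track start (default `config$season_start`).
#' @return List with `hourly` (time, lon, lat, state, on_land on the 1-h
#'   grid) and `steps` (time, step_km, turn_rad, temp, state on the 4-h
#'   grid).
#' @export
simulate_track <- function(config, temperature,
                           start_lon = config$start_lon,
                           start_lat = config$start_lat,
                           start_time = config$season_start) {
  pars <- config$params
  n <- config$n_steps
  step_h <- 4
  t4 <- start_time + (0:n) * step_h * 3600
  if (max(as.numeric(t4)) > max(as.numeric(temperature$time)) ||
      min(as.numeric(t4)) < min(as.numeric(temperature$time))) {
    stop("temperature series does not cover the track span", call. = FALSE)
  }
  # temperature at each step's start
  tmp <- attach_temperature(data.frame(time = t4[1:n]), temperature,
                            max_gap_h = 2)$temp

  N <- length(pars$delta)
  X <- .hmm_design(tmp, ncol(pars$beta) - 1L)
  tpm <- .hmm_tpm(pars$beta, X, N)
  state <- integer(n)
  state[1] <- sample.int(N, 1, prob = pars$delta)
  for (t in 2:n) {
    G <- matrix(tpm[t, ], N, N, byrow = TRUE)
    state[t] <- sample.int(N, 1, prob = G[state[t - 1], ])
  }
  shape <- pars$gamma_mean^2 / pars$gamma_sd^2
  rate <- pars$gamma_mean / pars$gamma_sd^2
  step <- stats::rgamma(n, shape[state], rate[state])
  turn <- numeric(n)
  for (t in seq_len(n)) turn[t] <- rvonmises(1, pars$vm_mean[state[t]],
                                             pars$vm_conc[state[t]])
  heading <- cumsum(c(stats::runif(1, -pi, pi), turn[-1]))
  x <- cumsum(c(0, step * sin(heading)))
  y <- cumsum(c(0, step * cos(heading)))

  # 1-h grid: linear interpolation of the planar path within each step
  h_frac <- seq(0, n * step_h) / step_h
  hx <- stats::approx(0:n, x, xout = h_frac)$y
  hy <- stats::approx(0:n, y, xout = h_frac)$y
  ll <- unproject_aeq(hx, hy, start_lon, start_lat)
  hstate <- state[pmin(floor(h_frac) + 1, n)]
  hourly <- data.frame(
    time = start_time + seq(0, n * step_h) * 3600,
    lon = ll$lon, lat = ll$lat, state = hstate,
    on_land = ll$lat < config$coast_lat
  )
  steps <- data.frame(
    time = t4[1:n], step_km = step,
    turn_rad = c(NA_real_, turn[-1]),
    temp = tmp, state = state
  )
  list(hourly = hourly, steps = steps)
}

#' Simulate the observation process over a true track
#'
#' Thins the 1-h truth to the design's duty cycle, drops scheduled fixes
#' independently with probability `1 - fix_success`, assigns Argos location
#' classes by the configured mix and perturbs positions with isotropic
#' Gaussian noise at the class SD (GPS fixes get the GPS SD and an emitted
#' `h_error_m`), and applies detachment/battery failure. After detachment
#' the tag sits still at the detachment point; fixes more than 12 h after
#' detachment are flagged inactive and the tag falls silent after a handful
#' of inactivity transmissions.
#'
#' @param track Output of [simulate_track()].
#' @param config A `sim_config`.
#' @param design Tag design (sets the duty cycle, error model, and failure
#'   rates).
#' @param tag_id,bear_id Identifiers for the emitted fixes.
#' @return List with `fixes` (a valid fix table) and `truth` (detach_time,
#'   inactivity_start, battery_end; NA where not applicable).
#' @export
simulate_observation <- function(track, config, design,
                                 tag_id = "T01", bear_id = "B01") {
  hourly <- track$hourly
  t0 <- hourly$time[1]
  interval_h <- if (design == "seatrkr") 2 else 4
  source <- if (design == "seatrkr") "gps" else "argos"
  span_h <- as.numeric(difftime(hourly$time[nrow(hourly)], t0, units = "hours"))
  duty_h <- seq(0, span_h, by = interval_h)

  mean_ret <- config$mean_retention_days[[design]]
  detach_time <- if (is.finite(mean_ret)) {
    t0 + stats::rexp(1, 1 / mean_ret) * 86400
  } else as.POSIXct(NA)
  battery_end <- if (is.finite(config$battery_days[[design]])) {
    t0 + config$battery_days[[design]] * 86400
  } else as.POSIXct(NA)

  times <- t0 + duty_h * 3600
  detached <- !is.na(detach_time) & times > detach_time
  inactivity_start <- if (any(detached)) detach_time + 12 * 3600 else as.POSIXct(NA)
  inactive <- !is.na(inactivity_start) & times >= inactivity_start
  # at most 6 inactivity transmissions, then silence
  if (any(inactive)) {
    idx <- which(inactive)
    keep_until <- idx[min(6, length(idx))]
    drop_tail <- seq_along(times) > keep_until
  } else drop_tail <- rep(FALSE, length(times))
  if (!is.na(battery_end)) drop_tail <- drop_tail | times > battery_end

  sel <- !drop_tail & stats::runif(length(times)) < config$fix_success
  times <- times[sel]; detached <- detached[sel]; inactive <- inactive[sel]
  n <- length(times)
  if (n == 0) {
    return(list(fixes = NULL,
                truth = list(detach_time = detach_time,
                             inactivity_start = inactivity_start,
                             battery_end = battery_end)))
  }

  # true position: frozen at the detachment point once detached
  hidx <- round(as.numeric(difftime(times, t0, units = "hours"))) + 1L
  lon <- hourly$lon[hidx]; lat <- hourly$lat[hidx]
  if (any(detached)) {
    didx <- max(which(hourly$time <= detach_time))
    lon[detached] <- hourly$lon[didx]
    lat[detached] <- hourly$lat[didx]
  }

  if (source == "argos") {
    loc_class <- sample(names(config$class_mix), n, replace = TRUE,
                        prob = config$class_mix)
    sd_km <- unname(config$class_sd_km[loc_class])
    h_error <- rep(NA_real_, n)
  } else {
    loc_class <- rep(NA_character_, n)
    sd_km <- rep(config$gps_sd_km, n)
    h_error <- pmax(stats::rlnorm(n, log(10), 0.5), 1)
  }
  # isotropic error on the local plane around each true point
  dx <- stats::rnorm(n, 0, sd_km); dy <- stats::rnorm(n, 0, sd_km)
  obs <- unproject_aeq(dx, dy, lon, lat)

  fixes <- data.frame(
    tag_id = tag_id, bear_id = bear_id, time = times,
    lon = obs$lon, lat = obs$lat, source = source,
    loc_class = loc_class, h_error_m = h_error,
    activity = ifelse(inactive, "inactive", "active"),
    on_land = obs$lat < config$coast_lat
  )
  list(fixes = fixes,
       truth = list(detach_time = detach_time,
                    inactivity_start = inactivity_start,
                    battery_end = battery_end))
}

#' Simulate a complete synthetic telemetry study
#'
#' Generates, deterministically under `config$seed`, a full study: one
#' hourly station temperature series, one true track per bear, and the
#' observed fix and deployment tables, together with the generating truth
#' (latent states, true positions, generating parameters, failure times).
#' When `out_dir` is given, writes `fixes.csv`, `deployments.csv`,
#' `temperature.csv` and a `config_echo.txt` provenance file readable back
#' with the package readers.
#'
#' @param config A `sim_config`.
#' @param out_dir Optional output directory.
#' @return List with `fixes`, `deployments`, `temperature` (data.frames)
#'   and `truth` (per-bear list: `steps`, `hourly`, failure times; plus
#'   `params` and the `config` echo).
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  span_h <- config$n_steps * 4 + 48
  temperature <- simulate_temperature(config, span_h)
  designs <- rep_len(config$designs, config$n_bears)

  fixes_list <- list(); truth <- list(); dep_rows <- list()
  for (b in seq_len(config$n_bears)) {
    tag_id <- sprintf("T%02d", b)
    bear_id <- sprintf("B%02d", b)
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, config$start_jitter_km)
    origin <- unproject_aeq(rad * sin(ang), rad * cos(ang),
                            config$start_lon, config$start_lat)
    tr <- simulate_track(config, temperature,
                         start_lon = origin$lon, start_lat = origin$lat)
    ob <- simulate_observation(tr, config, designs[b], tag_id, bear_id)
    fixes_list[[b]] <- ob$fixes
    truth[[tag_id]] <- list(steps = tr$steps, hourly = tr$hourly,
                            detach_time = ob$truth$detach_time,
                            inactivity_start = ob$truth$inactivity_start,
                            battery_end = ob$truth$battery_end)
    dep_rows[[b]] <- data.frame(
      tag_id = tag_id, bear_id = bear_id, design = designs[b],
      attach_time = config$season_start, season = "fall",
      adhesive = designs[b] == "tribrush",
      fix_interval_h = if (designs[b] == "seatrkr") 2 else 4,
      end_time = NA_character_, end_cause = NA_character_
    )
  }
  fixes <- do.call(rbind, fixes_list[!vapply(fixes_list, is.null, logical(1))])
  fixes <- fixes[order(fixes$tag_id, fixes$time), , drop = FALSE]
  rownames(fixes) <- NULL
  deployments <- do.call(rbind, dep_rows)
  deployments$attach_time <- as.POSIXct(deployments$attach_time, tz = "UTC")

  out <- list(fixes = fixes, deployments = deployments,
              temperature = temperature,
              truth = c(truth, list(params = config$params, config = config)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fixes(fixes, file.path(out_dir, "fixes.csv"))
    write_deployments(deployments, file.path(out_dir, "deployments.csv"))
    tmp <- temperature
    tmp$time <- format(tmp$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    utils::write.csv(tmp, file.path(out_dir, "temperature.csv"),
                     row.names = FALSE)
    dput(config[setdiff(names(config), "season_start")],
         file.path(out_dir, "config_echo.txt"))
  }
  out
}
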