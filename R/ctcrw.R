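#' Default Argos class and GPS measurement error SDs (km)
#'
#' Per-class standard deviations of isotropic positional error supplied to
#' the CTCRW state-space model. The estimable classes follow the nominal
#' bound structure (class 3 < 250 m, 2 < 500 m, 1 < 1500 m, 0 > 1500 m);
#' classes A and B, whose error is not estimable from satellite messages,
#' get conservative values. All values are config-overridable.
#'
#' @export
default_error_sd_km <- c(`3` = 0.25, `2` = 0.5, `1` = 1.5, `0` = 5,
                         A = 8, B = 15)

#' @rdname default_error_sd_km
#' @export
default_gps_sd_km <- 0.02

.fix_error_sd <- function(fixes, error_sd_by_class, gps_sd_km) {
  tau <- ifelse(fixes$source == "gps", gps_sd_km,
                unname(error_sd_by_class[as.character(fixes$loc_class)]))
  if (anyNA(tau)) stop("missing error SD for some fixes", call. = FALSE)
  tau
}

# Discrete-time transition and innovation covariance of the integrated
# Ornstein-Uhlenbeck velocity process over a step of dt hours.
.ou_system <- function(beta, sigma, dt) {
  e1 <- exp(-beta * dt)
  e2 <- exp(-2 * beta * dt)
  s2 <- sigma^2
  Tm <- matrix(c(1, 0, (1 - e1) / beta, e1), 2, 2)
  q_xx <- s2 / beta^2 * (dt - 2 * (1 - e1) / beta + (1 - e2) / (2 * beta))
  q_xv <- s2 / (2 * beta^2) * (1 - e1)^2
  q_vv <- s2 / (2 * beta) * (1 - e2)
  Q <- matrix(c(q_xx, q_xv, q_xv, q_vv), 2, 2)
  list(T = Tm, Q = Q)
}

# Kalman filter (and optional RTS smoother) for the CTCRW model on one
# planar axis pair. y is an n x 2 matrix of planar coordinates (km) with NA
# rows at pure prediction times; tau is the per-row measurement SD (km).
# Because the error SD is common to both axes, one covariance recursion is
# shared; only the means differ by axis.
.ctcrw_kalman <- function(times_h, y, tau, beta, sigma, smooth = FALSE) {
  n <- length(times_h)
  obs <- !is.na(y[, 1])
  H <- matrix(c(1, 0), 1, 2)

  m <- matrix(0, 2, 2)    # columns: axis x, axis y; rows: position, velocity
  i1 <- which(obs)[1]
  m[1, ] <- y[i1, ]       # anchor at the first observation
  P <- diag(c(tau[i1]^2 * 4 + 1, sigma^2 / (2 * beta)))

  ll <- 0
  if (smooth) {
    mf <- array(NA_real_, c(2, 2, n)); Pf <- array(NA_real_, c(2, 2, n))
    mp <- array(NA_real_, c(2, 2, n)); Pp <- array(NA_real_, c(2, 2, n))
    Tms <- vector("list", n)
  }
  for (t in seq_len(n)) {
    if (t > 1) {
      dt <- times_h[t] - times_h[t - 1]
      sys <- .ou_system(beta, sigma, dt)
      m <- sys$T %*% m
      P <- sys$T %*% P %*% t(sys$T) + sys$Q
      if (smooth) Tms[[t]] <- sys$T
    }
    if (smooth) { mp[, , t] <- m; Pp[, , t] <- P }
    if (obs[t]) {
      S <- P[1, 1] + tau[t]^2
      e <- y[t, ] - m[1, ]
      K <- P[, 1] / S
      m <- m + K %*% t(e)          # 2x2: gain applied per axis
      P <- P - tcrossprod(K) * S
      ll <- ll - 0.5 * sum(log(2 * pi * S) + e^2 / S)
    }
    if (smooth) { mf[, , t] <- m; Pf[, , t] <- P }
  }
  out <- list(loglik = ll)
  if (smooth) {
    ms <- mf; Ps <- Pf
    for (t in rev(seq_len(n - 1L))) {
      G <- Pf[, , t] %*% t(Tms[[t + 1]]) %*% solve(Pp[, , t + 1])
      ms[, , t] <- mf[, , t] + G %*% (ms[, , t + 1] - mp[, , t + 1])
      Ps[, , t] <- Pf[, , t] + G %*% (Ps[, , t + 1] - Pp[, , t + 1]) %*% t(G)
    }
    out$pos <- t(ms[1, , ])        # n x 2 smoothed positions
    out$pos_var <- Ps[1, 1, ]      # smoothed position variance per time
    out$prior_var <- Pp[1, 1, ]    # one-step-ahead position variance
  }
  out
}

#' Fit a continuous-time correlated random walk to a track segment
#'
#' Maximizes the Kalman-filter likelihood of the integrated
#' Ornstein-Uhlenbeck velocity model over the velocity autocorrelation rate
#' `beta_vel` (1/h) and the velocity noise scale `sigma_vel`, with per-fix
#' measurement SDs fixed by Argos class (or the GPS SD). Coordinates are
#' projected to a local azimuthal-equidistant plane centred on the segment
#' centroid; working units are km.
#'
#' @param segment data.frame of at least 10 time-ordered fixes with `lon`,
#'   `lat`, `time`, `source`, `loc_class`.
#' @param error_sd_by_class Named vector of per-class error SDs in km
#'   (default [default_error_sd_km]).
#' @param gps_sd_km Measurement SD for GPS fixes, km (default
#'   [default_gps_sd_km]).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @param tol Relative convergence tolerance of the optimizer
#'   (default 1e-10).
#' @return Object of class `ctcrw_fit` with elements `beta_vel`, `sigma_vel`,
#'   `error_sd_by_class`, `gps_sd_km`, `loglik`, `projection` (center
#'   lon/lat), and the planar data used.
#' @export
fit_ctcrw <- function(segment, error_sd_by_class = default_error_sd_km,
                      gps_sd_km = default_gps_sd_km,
                      max_iter = 500, tol = 1e-10) {
  if (nrow(segment) < 10) stop("segment too short for CTCRW fit (< 10 fixes)",
                               call. = FALSE)
  ctr <- c(mean(segment$lon), mean(segment$lat))
  xy <- project_aeq(segment$lon, segment$lat, ctr[1], ctr[2])
  tau <- .fix_error_sd(segment, error_sd_by_class, gps_sd_km)
  th <- as.numeric(segment$time) / 3600
  th <- th - th[1]
  y <- as.matrix(xy)

  # moment-based starting values: beta ~ 1/h, sigma matched to the observed
  # mean speed via the stationary velocity SD sqrt(sigma^2 / (2 beta))
  v_obs <- great_circle_km(segment$lon[-nrow(segment)], segment$lat[-nrow(segment)],
                           segment$lon[-1], segment$lat[-1]) / pmax(diff(th), 1e-6)
  b0 <- 1
  s0 <- max(mean(v_obs), 0.05) * sqrt(2 * b0)
  nll <- function(w) {
    v <- -.ctcrw_kalman(th, y, tau, exp(w[1]), exp(w[2]))$loglik
    if (!is.finite(v)) 1e10 else v
  }
  opt <- stats::optim(log(c(b0, s0)), nll, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = tol))
  if (opt$convergence != 0) {
    g <- .num_grad(nll, opt$par)
    stop(sprintf(
      "CTCRW optimizer failed to converge (code %d) at log(beta)=%.4f, log(sigma)=%.4f, |grad|=%.3g",
      opt$convergence, opt$par[1], opt$par[2], sqrt(sum(g^2))), call. = FALSE)
  }
  structure(list(
    beta_vel = exp(opt$par[1]),
    sigma_vel = exp(opt$par[2]),
    error_sd_by_class = error_sd_by_class,
    gps_sd_km = gps_sd_km,
    loglik = -opt$value,
    projection = list(center_lon = ctr[1], center_lat = ctr[2]),
    times_h = th,
    y = y,
    tau = tau,
    segment = segment
  ), class = "ctcrw_fit")
}

.num_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, eps)
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

#' @export
print.ctcrw_fit <- function(x, ...) {
  cat("Continuous-time correlated random walk fit\n")
  cat(sprintf("  beta (velocity autocorrelation): %.4f /h\n", x$beta_vel))
  cat(sprintf("  sigma (velocity noise scale):    %.4f\n", x$sigma_vel))
  cat(sprintf("  log-likelihood: %.3f on %d fixes\n", x$loglik, nrow(x$y)))
  invisible(x)
}

#' @export
coef.ctcrw_fit <- function(object, ...) {
  c(beta_vel = object$beta_vel, sigma_vel = object$sigma_vel)
}

#' @export
logLik.ctcrw_fit <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' Predict smoothed positions at arbitrary times
#'
#' @param object A `ctcrw_fit`.
#' @param newdata Optional vector of POSIXct times (default: observation
#'   times).
#' @param ... Unused.
#' @return data.frame with `time`, `lon`, `lat`, and smoothed position
#'   variance `pos_var_km2`.
#' @export
predict.ctcrw_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$segment$time else newdata
  th <- (as.numeric(times) - as.numeric(object$segment$time[1])) / 3600
  sm <- .ctcrw_smooth_at(object, th)
  ll <- unproject_aeq(sm$pos[, 1], sm$pos[, 2],
                      object$projection$center_lon, object$projection$center_lat)
  data.frame(time = times, lon = ll$lon, lat = ll$lat, pos_var_km2 = sm$pos_var)
}

# Smooth the fitted model at extra times (hours from segment start). Times
# within 1 s of an observation reuse the observation's time point.
.ctcrw_smooth_at <- function(fit, extra_h) {
  obs_h <- fit$times_h
  tol <- 1 / 3600
  is_new <- vapply(extra_h, function(t) min(abs(obs_h - t)) > tol, logical(1))
  all_h <- c(obs_h, extra_h[is_new])
  ord <- order(all_h)
  all_h <- all_h[ord]
  n <- length(all_h)
  y <- matrix(NA_real_, n, 2)
  tau <- rep(1, n)
  src <- c(seq_along(obs_h), rep(NA_integer_, sum(is_new)))[ord]
  y[!is.na(src), ] <- fit$y[src[!is.na(src)], ]
  tau[!is.na(src)] <- fit$tau[src[!is.na(src)]]
  sm <- .ctcrw_kalman(all_h, y, tau, fit$beta_vel, fit$sigma_vel, smooth = TRUE)
  # map each requested time to its row (coincident times -> observation row)
  row_of <- vapply(extra_h, function(t) which.min(abs(all_h - t)), integer(1))
  list(pos = sm$pos[row_of, , drop = FALSE], pos_var = sm$pos_var[row_of],
       all_h = all_h, full = sm)
}

#' Regularize a track segment onto a fixed time grid
#'
#' Predicts the Kalman-smoothed position at `t0, t0 + interval_h, ...` up to
#' the last observed fix (never beyond: no extrapolation), where `t0` is the
#' segment's first fix time. Grid points with no observed fix within one
#' hour are marked `interpolated`.
#'
#' @param segment The segment the fit was obtained on.
#' @param fit `ctcrw_fit` for that segment.
#' @param interval_h Grid spacing in hours (default 4).
#' @return data.frame of class `regular_track` with columns `time`, `lon`,
#'   `lat`, `interpolated`, and attributes `tag_id` and `segment_index`
#'   carried over from the segment.
#' @export
regularize_segment <- function(segment, fit, interval_h = 4) {
  if (interval_h <= 0) stop("interval_h must be > 0", call. = FALSE)
  t0 <- as.numeric(segment$time[1])
  t_end <- as.numeric(segment$time[nrow(segment)])
  grid_s <- seq(t0, t_end, by = interval_h * 3600)
  grid_h <- (grid_s - t0) / 3600
  sm <- .ctcrw_smooth_at(fit, grid_h)
  ll <- unproject_aeq(sm$pos[, 1], sm$pos[, 2],
                      fit$projection$center_lon, fit$projection$center_lat)
  obs_s <- as.numeric(segment$time)
  interp <- vapply(grid_s, function(t) min(abs(obs_s - t)) > 3600, logical(1))
  out <- data.frame(
    time = as.POSIXct(grid_s, origin = "1970-01-01", tz = "UTC"),
    lon = ll$lon, lat = ll$lat, interpolated = interp
  )
  attr(out, "tag_id") <- attr(segment, "tag_id") %||% segment$tag_id[1]
  attr(out, "segment_index") <- attr(segment, "segment_index") %||% 0L
  class(out) <- c("regular_track", "data.frame")
  out
}

#' Piecewise-linear regularization fallback
#'
#' Linear interpolation of planar coordinates onto the same grid as
#' [regularize_segment()], used when the CTCRW fit fails for a segment.
#' Flagged in the pipeline report so results remain auditable.
#'
#' @inheritParams regularize_segment
#' @return A `regular_track` data.frame (see [regularize_segment()]).
#' @export
regularize_linear <- function(segment, interval_h = 4) {
  if (interval_h <= 0) stop("interval_h must be > 0", call. = FALSE)
  ctr <- c(mean(segment$lon), mean(segment$lat))
  xy <- project_aeq(segment$lon, segment$lat, ctr[1], ctr[2])
  t0 <- as.numeric(segment$time[1])
  obs_s <- as.numeric(segment$time)
  grid_s <- seq(t0, obs_s[length(obs_s)], by = interval_h * 3600)
  px <- stats::approx(obs_s, xy$x, xout = grid_s)$y
  py <- stats::approx(obs_s, xy$y, xout = grid_s)$y
  ll <- unproject_aeq(px, py, ctr[1], ctr[2])
  interp <- vapply(grid_s, function(t) min(abs(obs_s - t)) > 3600, logical(1))
  out <- data.frame(
    time = as.POSIXct(grid_s, origin = "1970-01-01", tz = "UTC"),
    lon = ll$lon, lat = ll$lat, interpolated = interp
  )
  attr(out, "tag_id") <- attr(segment, "tag_id") %||% segment$tag_id[1]
  attr(out, "segment_index") <- attr(segment, "segment_index") %||% 0L
  class(out) <- c("regular_track", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
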