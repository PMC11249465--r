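#' Step lengths and turn angles from a regular track
#'
#' Step `t` is the great-circle distance between grid points `t` and `t+1`;
#' turn `t` is the change in bearing between step `t-1` and step `t`,
#' wrapped to (-pi, pi] (so an exact reversal is +pi). The first step of a
#' segment has an undefined turn (`NA`). The temperature covariate of a step
#' is the temperature at the step's start point, when the track carries a
#' `temp` column.
#'
#' @param track A `regular_track` (or any data.frame with `time`, `lon`,
#'   `lat` and optionally `temp`/`temp_missing`), at least 3 points.
#' @return data.frame with one row per step: `step_km`, `turn_rad`, `temp`
#'   (NA if the track has none), `segment_id`, `time` (step start).
#' @export
steps_and_turns <- function(track) {
  n <- nrow(track)
  if (n < 3) stop("track must have at least 3 points", call. = FALSE)
  i <- seq_len(n - 1)
  step <- great_circle_km(track$lon[i], track$lat[i],
                          track$lon[i + 1], track$lat[i + 1])
  brg <- initial_bearing_rad(track$lon[i], track$lat[i],
                             track$lon[i + 1], track$lat[i + 1])
  turn <- c(NA_real_, wrap_angle(diff(brg)))
  seg_id <- attr(track, "tag_id") %||% track$tag_id[1] %||% "seg"
  idx <- attr(track, "segment_index")
  if (!is.null(idx)) seg_id <- paste0(seg_id, ":", idx)
  data.frame(
    step_km = step,
    turn_rad = turn,
    temp = if ("temp" %in% names(track)) track$temp[i] else NA_real_,
    segment_id = seg_id,
    time = track$time[i]
  )
}

#' Concatenate per-segment step series
#'
#' Stacks step series from several segments into one series in which each
#' segment is treated as an independent time series under shared parameters.
#' Steps whose covariate is missing are dropped when `drop_missing_temp` is
#' set (the default for covariate models).
#'
#' @param series_list List of data.frames from [steps_and_turns()].
#' @param drop_missing_temp Drop steps with `NA` temperature (default FALSE).
#' @return A single stacked step-series data.frame.
#' @export
bind_step_series <- function(series_list, drop_missing_temp = FALSE) {
  out <- do.call(rbind, series_list)
  if (drop_missing_temp) out <- out[!is.na(out$temp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
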