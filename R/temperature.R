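#' Attach ambient temperature to track positions
#'
#' Matches each position to the hourly station series: the temperature is
#' linearly interpolated between the bracketing records when both lie within
#' `max_gap_h` hours; if only one record is within reach, that record's value
#' is used; positions with no record within `max_gap_h` are flagged
#' covariate-missing (`temp = NA`). The series is never extrapolated beyond
#' `max_gap_h`.
#'
#' @param track data.frame with a POSIXct `time` column.
#' @param series Temperature records for one station: data.frame with `time`
#'   (POSIXct, strictly increasing) and `temp` (degrees C).
#' @param max_gap_h Maximum distance in hours to the nearest record
#'   (default 6).
#' @return `track` with columns `temp` (degrees C, `NA` where missing) and
#'   `temp_missing` (logical) appended.
#' @export
attach_temperature <- function(track, series, max_gap_h = 6) {
  if (is.null(series) || nrow(series) == 0) {
    stop("empty temperature series", call. = FALSE)
  }
  st <- as.numeric(series$time)
  sv <- series$temp
  tt <- as.numeric(track$time)
  gap_s <- max_gap_h * 3600

  # index of nearest record and of bracketing records
  lo <- findInterval(tt, st)                       # last record <= t (0 if none)
  hi <- pmin(lo + 1L, length(st))
  lo_ok <- lo >= 1L & (tt - st[pmax(lo, 1L)]) <= gap_s
  hi_ok <- lo < length(st) & (st[hi] - tt) <= gap_s

  temp <- rep(NA_real_, length(tt))
  both <- lo_ok & hi_ok
  if (any(both)) {
    l <- lo[both]; h <- hi[both]
    w <- (tt[both] - st[l]) / (st[h] - st[l])
    temp[both] <- (1 - w) * sv[l] + w * sv[h]
  }
  only_lo <- lo_ok & !hi_ok
  temp[only_lo] <- sv[lo[only_lo]]
  only_hi <- hi_ok & !lo_ok
  temp[only_hi] <- sv[hi[only_hi]]
  # exact hits fall in `both` with w = 0 or in the one-sided branches

  track$temp <- temp
  track$temp_missing <- is.na(temp)
  track
}
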