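#' Nominal Argos location-class error bounds
#'
#' Horizontal-error bounds (metres) associated with the six Argos location
#' classes, in order of decreasing accuracy. Classes A and B are derived from
#' fewer than four satellite messages and carry no error estimate.
#'
#' @format Named list with elements `classes` (character vector, best to
#'   worst), `bound_m` (named numeric upper bounds in metres; `Inf` for
#'   class 0) and `estimable` (named logical).
#' @export
argos_error_classes <- list(
  classes   = c("3", "2", "1", "0", "A", "B"),
  bound_m   = c(`3` = 250, `2` = 500, `1` = 1500, `0` = Inf,
                A = NA_real_, B = NA_real_),
  estimable = c(`3` = TRUE, `2` = TRUE, `1` = TRUE, `0` = TRUE,
                A = FALSE, B = FALSE)
)

.tag_designs <- c("pentagon", "seatrkr", "tribrush", "ear")

.parse_utc <- function(x, what, rows) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  need <- !is.na(x) & x != ""
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(need & is.na(out))
    if (!length(idx)) break
    p <- strptime(x[idx], fmt, tz = "UTC")
    ok <- !is.na(p)
    out[idx[ok]] <- as.POSIXct(p[ok], tz = "UTC")
  }
  bad <- which(need & is.na(out))
  if (length(bad)) {
    stop(sprintf("unparseable %s timestamp at row %d: '%s'",
                 what, rows[bad[1]], x[bad[1]]), call. = FALSE)
  }
  out
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read telemetry fixes from a CSV file
#'
#' Expects columns `tag_id, bear_id, time, lon, lat, source, loc_class,
#' h_error_m, activity, on_land` (the last four may be empty per row). Rows
#' are sorted by tag and time; duplicate `(tag_id, time)` rows are collapsed
#' to the first occurrence with a warning.
#'
#' @param path Path to a comma-delimited file with a header row.
#' @return data.frame of fixes with `time` as POSIXct (UTC), `on_land`
#'   logical, other metadata columns character/numeric, `NA` where absent.
#' @export
read_fixes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("tag_id", "bear_id", "time", "lon", "lat", "source"),
                "fixes")
  for (opt in c("loc_class", "h_error_m", "activity", "on_land")) {
    if (!opt %in% names(df)) df[[opt]] <- rep(NA, nrow(df))
  }
  df$loc_class <- as.character(df$loc_class)
  df$time <- .parse_utc(as.character(df$time), "fix", seq_len(nrow(df)))
  df$loc_class[!is.na(df$loc_class) & df$loc_class == ""] <- NA
  df$activity[!is.na(df$activity) & df$activity == ""] <- NA
  df$on_land <- as.logical(df$on_land)
  df$h_error_m <- as.numeric(df$h_error_m)
  validate_fixes(df)
  df <- df[order(df$tag_id, df$time), , drop = FALSE]
  dup <- duplicated(df[, c("tag_id", "time")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate (tag_id, time) fix row(s), keeping first",
                    sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Validate a fix table against the data-model invariants
#'
#' Checks coordinate ranges, that Argos fixes carry a location class and no
#' GPS error, and that GPS fixes carry a positive horizontal error and no
#' class.
#'
#' @param fixes data.frame of fixes.
#' @return `fixes`, invisibly, on success; otherwise an error naming the
#'   first offending row.
#' @export
validate_fixes <- function(fixes) {
  bad_lat <- which(fixes$lat < -90 | fixes$lat > 90)
  if (length(bad_lat)) stop("lat out of [-90, 90] at row ", bad_lat[1], call. = FALSE)
  bad_lon <- which(fixes$lon < -180 | fixes$lon > 180)
  if (length(bad_lon)) stop("lon out of [-180, 180] at row ", bad_lon[1], call. = FALSE)
  bad_src <- which(!fixes$source %in% c("argos", "gps"))
  if (length(bad_src)) stop("unknown source at row ", bad_src[1], call. = FALSE)
  is_argos <- fixes$source == "argos"
  bad_lc <- which(is_argos & (is.na(fixes$loc_class) |
                              !fixes$loc_class %in% argos_error_classes$classes))
  if (length(bad_lc)) {
    stop("argos fix with missing/unknown loc_class at row ", bad_lc[1], call. = FALSE)
  }
  bad_lc2 <- which(!is_argos & !is.na(fixes$loc_class))
  if (length(bad_lc2)) stop("gps fix with a loc_class at row ", bad_lc2[1], call. = FALSE)
  bad_he <- which(!is_argos & (is.na(fixes$h_error_m) | fixes$h_error_m <= 0))
  if (length(bad_he)) {
    stop("gps fix with missing or non-positive h_error_m at row ", bad_he[1],
         call. = FALSE)
  }
  bad_he2 <- which(is_argos & !is.na(fixes$h_error_m))
  if (length(bad_he2)) stop("argos fix with h_error_m at row ", bad_he2[1], call. = FALSE)
  invisible(fixes)
}

#' Write a fix table to CSV
#'
#' Inverse of [read_fixes()]: `write_fixes` then `read_fixes` is the identity
#' on all fields.
#'
#' @param fixes data.frame of fixes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read tag deployment records from a CSV file
#'
#' Expects columns `tag_id, bear_id, design, attach_time, season, adhesive,
#' fix_interval_h` and optionally `end_time, end_cause`. The same `bear_id`
#' may appear under several `tag_id`s (bears retagged after a tag failed).
#'
#' @param path Path to a comma-delimited file with a header row.
#' @return data.frame of deployments, one row per tag deployment.
#' @export
read_deployments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("tag_id", "bear_id", "design", "attach_time",
                      "season", "fix_interval_h"), "deployments")
  bad <- which(!df$design %in% .tag_designs)
  if (length(bad)) {
    stop(sprintf("unknown tag design '%s' at row %d", df$design[bad[1]], bad[1]),
         call. = FALSE)
  }
  if (!"adhesive" %in% names(df)) df$adhesive <- rep(NA, nrow(df))
  if (!"end_time" %in% names(df)) df$end_time <- rep(NA_character_, nrow(df))
  if (!"end_cause" %in% names(df)) df$end_cause <- rep(NA_character_, nrow(df))
  df$attach_time <- .parse_utc(as.character(df$attach_time), "deployment",
                               seq_len(nrow(df)))
  df$end_time <- .parse_utc(as.character(df$end_time), "deployment",
                            seq_len(nrow(df)))
  df$adhesive <- as.logical(df$adhesive)
  df$end_cause[!is.na(df$end_cause) & df$end_cause == ""] <- NA_character_
  if (any(df$fix_interval_h <= 0)) stop("fix_interval_h must be > 0", call. = FALSE)
  bad_end <- which(!is.na(df$end_time) & df$end_time < df$attach_time)
  if (length(bad_end)) stop("end_time before attach_time at row ", bad_end[1],
                            call. = FALSE)
  rownames(df) <- NULL
  df
}

#' @rdname read_deployments
#' @param deployments data.frame of deployments.
#' @param path Output path.
#' @export
write_deployments <- function(deployments, path) {
  out <- deployments
  out$attach_time <- format(out$attach_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (inherits(out$end_time, "POSIXct")) {
    out$end_time <- format(out$end_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an hourly weather-station temperature series
#'
#' Expects columns `station_id, station_lon, station_lat, time, temp`.
#' Several stations may share one file; use [nearest_station()] to pick the
#' station serving a given track segment.
#'
#' @param path Path to a comma-delimited file with a header row.
#' @return data.frame with `time` as POSIXct (UTC), sorted by station then
#'   time; timestamps must be strictly increasing within a station.
#' @export
read_temperature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("station_id", "station_lon", "station_lat", "time", "temp"),
                "temperature")
  df$time <- .parse_utc(as.character(df$time), "temperature", seq_len(nrow(df)))
  df <- df[order(df$station_id, df$time), , drop = FALSE]
  for (sid in unique(df$station_id)) {
    tt <- df$time[df$station_id == sid]
    if (any(diff(as.numeric(tt)) <= 0)) {
      stop("temperature timestamps not strictly increasing for station ", sid,
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Pick the temperature station nearest a track segment
#'
#' Great-circle distance from each station to the segment centroid (mean
#' lon/lat of its fixes).
#'
#' @param segment data.frame with `lon`, `lat` columns.
#' @param temperature Temperature table as returned by [read_temperature()].
#' @return The rows of `temperature` belonging to the nearest station.
#' @export
nearest_station <- function(segment, temperature) {
  st <- unique(temperature[, c("station_id", "station_lon", "station_lat")])
  if (nrow(st) == 0) stop("empty temperature series", call. = FALSE)
  d <- great_circle_km(st$station_lon, st$station_lat,
                       mean(segment$lon), mean(segment$lat))
  sid <- st$station_id[which.min(d)]
  temperature[temperature$station_id == sid, , drop = FALSE]
}
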