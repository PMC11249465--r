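#' Drop the post-capture acclimation period
#'
#' Removes fixes recorded during the first `days` days after tag attachment,
#' the period over which movement may still be affected by chemical
#' immobilization. A fix exactly at the boundary is retained.
#'
#' @param fixes Time-ordered fixes for one deployment.
#' @param deployment One-row deployment record (uses `attach_time`).
#' @param days Truncation window in days (default 3).
#' @return The retained fixes.
#' @export
truncate_post_capture <- function(fixes, deployment, days = 3) {
  cutoff <- deployment$attach_time[1] + days * 86400
  fixes[fixes$time >= cutoff, , drop = FALSE]
}

.rms_speeds <- function(lon, lat, tt) {
  # RMS speed of each fix over the (up to) four speeds to its two preceding
  # and two following neighbours, McConnell-style
  n <- length(tt)
  ssum <- numeric(n)
  cnt <- numeric(n)
  for (off in c(-2L, -1L, 1L, 2L)) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1L & j <= n
    i <- i[ok]; j <- j[ok]
    d <- great_circle_km(lon[i], lat[i], lon[j], lat[j])
    dt <- abs(tt[j] - tt[i]) / 3600
    v2 <- (d / dt)^2
    v2[dt == 0] <- Inf
    ssum[i] <- ssum[i] + v2
    cnt[i] <- cnt[i] + 1
  }
  sqrt(ssum / cnt)
}

#' Remove biologically implausible fixes by RMS speed
#'
#' Iterative McConnell-style speed filter: while any interior fix has a
#' root-mean-square speed of at least `vmax_kmh` — computed from great-circle
#' distances to its two preceding and two following *retained* neighbours —
#' the fix with the largest RMS speed is removed (ties broken by earliest
#' time) and speeds are recomputed. The first and last fixes are never
#' removed. The filter is idempotent and order-preserving, and only ever
#' removes rows.
#'
#' A simple successive-pair mode (`mode = "pairwise"`) is available for
#' sensitivity checks: it removes, iteratively, the later fix of any
#' consecutive pair implying a speed of at least `vmax_kmh`.
#'
#' @param fixes Time-ordered fixes (one tag).
#' @param vmax_kmh Speed threshold in km/h (default 40).
#' @param mode `"rms"` (default) or `"pairwise"`.
#' @return List with elements `retained` and `removed` (both data.frames).
#' @export
speed_filter <- function(fixes, vmax_kmh = 40, mode = c("rms", "pairwise")) {
  mode <- match.arg(mode)
  n0 <- nrow(fixes)
  if (n0 < 2) return(list(retained = fixes, removed = fixes[0, , drop = FALSE]))
  keep <- rep(TRUE, n0)
  tt <- as.numeric(fixes$time)

  if (mode == "pairwise") {
    repeat {
      idx <- which(keep)
      if (length(idx) < 2) break
      d <- great_circle_km(fixes$lon[idx[-length(idx)]], fixes$lat[idx[-length(idx)]],
                           fixes$lon[idx[-1]], fixes$lat[idx[-1]])
      v <- d / (diff(tt[idx]) / 3600)
      bad <- which(v >= vmax_kmh)
      if (!length(bad)) break
      keep[idx[bad[1] + 1]] <- FALSE
    }
  } else {
    repeat {
      idx <- which(keep)
      if (length(idx) < 3) break
      v <- .rms_speeds(fixes$lon[idx], fixes$lat[idx], tt[idx])
      v[c(1, length(idx))] <- 0   # endpoints are never removed
      worst <- which(v >= vmax_kmh)
      if (!length(worst)) break
      # largest RMS speed; ties broken by earliest time (which.max is
      # first-wins on ties and idx is time-ordered)
      keep[idx[which.max(v)]] <- FALSE
    }
  }
  list(retained = fixes[keep, , drop = FALSE],
       removed  = fixes[!keep, , drop = FALSE])
}

#' Keep terrestrial fixes and short marine forays
#'
#' Land fixes are always retained. A maximal run of consecutive marine fixes
#' is retained only when it is shorter than `max_foray` fixes *and* bounded
#' by land fixes of the same deployment on both sides (the bear returned to
#' land). Leading/trailing marine runs, and runs of `max_foray` or more
#' fixes, are removed — the latter correspond to departure onto the sea ice.
#'
#' @param fixes Time-ordered fixes for one tag with `on_land` resolved.
#' @param max_foray Marine runs of this many fixes or more are removed
#'   (default 50).
#' @param landmask Optional function `(lon, lat) -> logical` used to resolve
#'   `on_land` where the flag is missing (e.g. a point-in-polygon test).
#' @return The retained fixes.
#' @export
terrestrial_filter <- function(fixes, max_foray = 50, landmask = NULL) {
  if (nrow(fixes) == 0) return(fixes)
  land <- fixes$on_land
  if (anyNA(land)) {
    if (is.null(landmask)) {
      stop("fixes with unresolved on_land and no landmask supplied", call. = FALSE)
    }
    miss <- is.na(land)
    land[miss] <- as.logical(landmask(fixes$lon[miss], fixes$lat[miss]))
    if (anyNA(land)) stop("landmask returned NA", call. = FALSE)
  }
  r <- rle(land)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- rep(TRUE, nrow(fixes))
  for (k in seq_along(r$values)) {
    if (r$values[k]) next                       # land run
    bounded <- k > 1L && k < length(r$values)   # land on both sides
    if (!(bounded && r$lengths[k] < max_foray)) {
      keep[starts[k]:ends[k]] <- FALSE
    }
  }
  fixes[keep, , drop = FALSE]
}

#' Build a land/sea test from a polygon
#'
#' Returns a landmask function `(lon, lat) -> logical` testing whether
#' points fall inside a land polygon (even-odd ray casting in lon/lat,
#' adequate for the coastal scales involved). Points on an edge count as
#' inside.
#'
#' @param polygon data.frame with `lon`, `lat` vertex columns (closed or
#'   open ring), or the path of a CSV file with those columns.
#' @return Function usable as the `landmask` argument of
#'   [terrestrial_filter()] and [pipeline_config()].
#' @export
make_polygon_landmask <- function(polygon) {
  if (is.character(polygon)) {
    polygon <- utils::read.csv(polygon, stringsAsFactors = FALSE)
  }
  .require_cols(polygon, c("lon", "lat"), "landmask polygon")
  px <- polygon$lon; py <- polygon$lat
  n <- length(px)
  if (n >= 2 && px[1] == px[n] && py[1] == py[n]) {  # drop closing vertex
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  if (n < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  function(lon, lat) {
    vapply(seq_along(lon), function(k) {
      x <- lon[k]; y <- lat[k]
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        on_seg <- (py[i] - y) * (px[j] - x) == (py[j] - y) * (px[i] - x) &&
          min(px[i], px[j]) <= x && x <= max(px[i], px[j]) &&
          min(py[i], py[j]) <= y && y <= max(py[i], py[j])
        if (on_seg) return(TRUE)
        if ((py[i] > y) != (py[j] > y)) {
          xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
          if (x < xint) inside <- !inside
        }
        j <- i
      }
      inside
    }, logical(1))
  }
}

#' Split tracks at long temporal gaps
#'
#' Splits each tag's fixes strictly after any gap greater than `gap_h` hours
#' (a gap of exactly `gap_h` does not split), then discards segments with
#' fewer than `min_len` fixes, which carry little information about state
#' transitions.
#'
#' @param fixes Time-ordered fixes (may span several tags).
#' @param gap_h Gap threshold in hours (default 24).
#' @param min_len Minimum segment length in fixes (default 100).
#' @return List with `segments` (list of data.frames, each with attributes
#'   `tag_id` and `segment_index`) and `discarded` (data.frame of fixes in
#'   segments that were too short).
#' @export
segment_tracks <- function(fixes, gap_h = 24, min_len = 100) {
  segments <- list()
  discarded <- fixes[0, , drop = FALSE]
  for (tid in unique(fixes$tag_id)) {
    f <- fixes[fixes$tag_id == tid, , drop = FALSE]
    gaps <- diff(as.numeric(f$time)) / 3600
    grp <- cumsum(c(0, gaps > gap_h))
    si <- 0L
    for (g in unique(grp)) {
      seg <- f[grp == g, , drop = FALSE]
      if (nrow(seg) < min_len) {
        discarded <- rbind(discarded, seg)
      } else {
        attr(seg, "tag_id") <- tid
        attr(seg, "segment_index") <- si
        segments[[length(segments) + 1L]] <- seg
        si <- si + 1L
      }
    }
  }
  list(segments = segments, discarded = discarded)
}
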