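#' Detect tag detachment from inactivity signals
#'
#' Tags enter inactivity mode after at least 12 h without movement; a run of
#' more than 3 consecutive fixes flagged inactive (i.e. 4 or more) indicates
#' the tag has detached from the bear. The event time is the first fix of
#' that run. With no such run the tag is considered to have stopped
#' (malfunction or battery exhaustion) at its last transmission.
#'
#' @param fixes Time-ordered fixes for one tag with an `activity` column
#'   (`"active"`/`"inactive"`, `NA` where not transmitted).
#' @return List with `status` (`"detached"` or `"stopped"`) and
#'   `event_time` (POSIXct; `NA` if there are no fixes).
#' @export
detect_detachment <- function(fixes) {
  if (nrow(fixes) == 0) {
    return(list(status = "stopped", event_time = as.POSIXct(NA)))
  }
  inact <- !is.na(fixes$activity) & fixes$activity == "inactive"
  r <- rle(inact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= 4)
  if (length(hit)) {
    list(status = "detached", event_time = fixes$time[starts[hit[1]]])
  } else {
    list(status = "stopped", event_time = fixes$time[nrow(fixes)])
  }
}

#' Functional duration of one tag deployment
#'
#' Days the tag remained active while attached: the detachment event time
#' (see [detect_detachment()]) or, failing that, the last transmission,
#' minus the attachment time. Real-valued days.
#'
#' @param deployment One-row deployment record.
#' @param fixes The deployment's fixes, time-ordered.
#' @return Duration in days (0 with a warning if there are no fixes).
#' @export
functional_duration <- function(deployment, fixes) {
  if (nrow(fixes) == 0) {
    warning("no fixes for tag ", deployment$tag_id[1], "; duration 0",
            call. = FALSE)
    return(0)
  }
  det <- detect_detachment(fixes)
  as.numeric(difftime(det$event_time, deployment$attach_time[1], units = "days"))
}

#' Summarize functional durations by tag design
#'
#' Mean, range and standard error (sample SD with the n-1 divisor over
#' sqrt(n); absent for singleton groups) of per-tag functional durations.
#'
#' @param durations Numeric vector of durations in days.
#' @param design Character vector of tag designs, same length.
#' @return data.frame with one row per design: `design`, `n`, `mean_days`,
#'   `min_days`, `max_days`, `se_days`.
#' @export
summarize_durations <- function(durations, design) {
  stopifnot(length(durations) == length(design))
  groups <- split(durations, design)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(
      design = g, n = length(x), mean_days = mean(x),
      min_days = min(x), max_days = max(x),
      se_days = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    )
  }))
  rownames(out) <- NULL
  out
}

#' Argos error-class composition by tag design
#'
#' Per-design proportion of Argos fixes in each of the six location classes.
#' GPS fixes are excluded from the class table and summarized separately by
#' their horizontal error estimate.
#'
#' @param fixes Fix table with `source`, `loc_class`, `h_error_m`.
#' @param design Tag design per fix (character, same length as rows).
#' @return List with `classes` (data.frame: design, one proportion column
#'   per class in order 3,2,1,0,A,B, summing to 1 per row; designs with no
#'   Argos fixes omitted with a note in attribute `omitted`) and `gps`
#'   (data.frame of per-design mean/min/max h_error_m over GPS fixes).
#' @export
error_class_table <- function(fixes, design) {
  stopifnot(length(design) == nrow(fixes))
  cls <- argos_error_classes$classes
  is_argos <- fixes$source == "argos"
  omitted <- character(0)
  rows <- list()
  for (g in unique(design)) {
    sel <- is_argos & design == g
    if (!any(sel)) { omitted <- c(omitted, g); next }
    counts <- table(factor(fixes$loc_class[sel], levels = cls))
    prop <- as.numeric(counts) / sum(counts)
    row <- data.frame(design = g)
    for (k in seq_along(cls)) row[[paste0("class_", cls[k])]] <- prop[k]
    rows[[length(rows) + 1L]] <- row
  }
  classes <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(classes)) attr(classes, "omitted") <- omitted

  gps_rows <- list()
  for (g in unique(design)) {
    sel <- !is_argos & design == g
    if (!any(sel)) next
    he <- fixes$h_error_m[sel]
    gps_rows[[length(gps_rows) + 1L]] <- data.frame(
      design = g, n = sum(sel), mean_m = mean(he),
      min_m = min(he), max_m = max(he))
  }
  gps <- if (length(gps_rows)) do.call(rbind, gps_rows) else NULL
  list(classes = classes, gps = gps)
}
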