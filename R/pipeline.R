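#' Default pipeline configuration
#'
#' @param ... Overrides for any of the listed keys.
#' @return Named list: `truncate_days` (3), `vmax_kmh` (40),
#'   `speed_mode` ("rms"), `max_foray` (50), `gap_hours` (24),
#'   `min_segment_len` (100), `interval_hours` (4), `max_temp_gap_h` (6),
#'   `error_sd_by_class`, `gps_sd_km`, `ctcrw_max_iter` (500), `ctcrw_tol`
#'   (1e-10), `fallback_linear` (TRUE),
#'   `models` (the three transition models), `n_states` (2),
#'   `n_restarts` (50), `seed` (1), `landmask` (NULL: either a function
#'   `(lon, lat) -> logical` or a polygon accepted by
#'   [make_polygon_landmask()]).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    truncate_days = 3, vmax_kmh = 40, speed_mode = "rms",
    max_foray = 50, gap_hours = 24, min_segment_len = 100,
    interval_hours = 4, max_temp_gap_h = 6,
    error_sd_by_class = default_error_sd_km, gps_sd_km = default_gps_sd_km,
    ctcrw_max_iter = 500, ctcrw_tol = 1e-10,
    fallback_linear = TRUE,
    models = c("intercept_only", "temp", "temp2"),
    n_states = 2, n_restarts = 50, seed = 1, landmask = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  if (!is.null(cfg$landmask) && !is.function(cfg$landmask)) {
    cfg$landmask <- make_polygon_landmask(cfg$landmask)
  }
  cfg
}

#' Run the full telemetry analysis pipeline
#'
#' Executes, per deployment: post-capture truncation, RMS speed filtering
#' and terrestrial/foray selection; then gap-based segmentation, CTCRW
#' regularization onto the 4-h grid, temperature matching, step/turn
#' construction, HMM fitting of the configured transition models with AICc
#' selection, Viterbi decoding and time budgets; plus tag-performance
#' summaries on the unfiltered data. Stage counts are conserved: at every
#' stage, input = removed + retained.
#'
#' @param fixes Fix table ([read_fixes()]).
#' @param deployments Deployment table ([read_deployments()]).
#' @param temperature Temperature table ([read_temperature()]).
#' @param config [pipeline_config()] list.
#' @return Object of class `study_report`: stage `counts`, the tag
#'   `performance` summaries, `segments` kept, `regular_tracks`,
#'   `step_series`, `fits`, `selection` table, `best_fit`, `decoding`,
#'   `time_budget`, `stationary` curve, and `hmm_skipped` flag.
#' @export
run_study_pipeline <- function(fixes, deployments, temperature,
                               config = pipeline_config()) {
  validate_fixes(fixes)
  counts <- list(input = nrow(fixes))

  # tag performance on the full (pre-filter) data
  dur <- vapply(seq_len(nrow(deployments)), function(i) {
    functional_duration(deployments[i, ],
                        fixes[fixes$tag_id == deployments$tag_id[i], ,
                              drop = FALSE])
  }, numeric(1))
  perf <- list(
    durations = data.frame(tag_id = deployments$tag_id,
                           design = deployments$design, days = dur),
    duration_summary = summarize_durations(dur, deployments$design),
    error_classes = error_class_table(
      fixes, deployments$design[match(fixes$tag_id, deployments$tag_id)])
  )

  # per-deployment filtering
  kept <- list(); rem_trunc <- 0L; rem_speed <- 0L; rem_land <- 0L
  for (i in seq_len(nrow(deployments))) {
    f <- fixes[fixes$tag_id == deployments$tag_id[i], , drop = FALSE]
    n0 <- nrow(f)
    f <- truncate_post_capture(f, deployments[i, ], config$truncate_days)
    rem_trunc <- rem_trunc + (n0 - nrow(f))
    sf <- speed_filter(f, config$vmax_kmh, config$speed_mode)
    rem_speed <- rem_speed + nrow(sf$removed)
    f <- sf$retained
    n1 <- nrow(f)
    f <- terrestrial_filter(f, config$max_foray, config$landmask)
    rem_land <- rem_land + (n1 - nrow(f))
    kept[[i]] <- f
  }
  retained <- do.call(rbind, kept)
  counts$removed_truncation <- rem_trunc
  counts$removed_speed <- rem_speed
  counts$removed_terrestrial <- rem_land
  counts$after_filtering <- nrow(retained)

  seg <- segment_tracks(retained, config$gap_hours, config$min_segment_len)
  counts$removed_short_segments <- nrow(seg$discarded)
  counts$retained <- sum(vapply(seg$segments, nrow, integer(1)))

  report <- list(counts = counts, performance = perf,
                 segments = seg$segments, hmm_skipped = FALSE,
                 ctcrw_fallback = character(0), config = config)

  if (length(seg$segments) == 0) {
    report$hmm_skipped <- TRUE
    class(report) <- "study_report"
    return(report)
  }

  # regularize each segment and attach temperature from the nearest station
  tracks <- list()
  for (k in seq_along(seg$segments)) {
    s <- seg$segments[[k]]
    rt <- tryCatch({
      fit <- fit_ctcrw(s, config$error_sd_by_class, config$gps_sd_km,
                       max_iter = config$ctcrw_max_iter,
                       tol = config$ctcrw_tol)
      regularize_segment(s, fit, config$interval_hours)
    }, error = function(e) NULL)
    if (is.null(rt)) {
      if (!config$fallback_linear) {
        stop("CTCRW fit failed for segment ", k, " and fallback disabled",
             call. = FALSE)
      }
      report$ctcrw_fallback <- c(report$ctcrw_fallback,
                                 attr(s, "tag_id") %||% s$tag_id[1])
      rt <- regularize_linear(s, config$interval_hours)
    }
    rt <- attach_temperature(rt, nearest_station(s, temperature),
                             config$max_temp_gap_h)
    tracks[[k]] <- rt
  }
  report$regular_tracks <- tracks

  series <- bind_step_series(lapply(tracks, steps_and_turns),
                             drop_missing_temp = TRUE)
  report$step_series <- series

  if (nrow(series) < 10) {
    report$hmm_skipped <- TRUE
    class(report) <- "study_report"
    return(report)
  }

  fits <- list()
  for (m in config$models) {
    fits[[m]] <- fit_hmm(series, m, n_states = config$n_states,
                         n_restarts = config$n_restarts, seed = config$seed)
  }
  report$fits <- fits
  report$selection <- model_selection(fits)
  best_label <- report$selection$model[1]
  report$best_fit <- fits[[best_label]]
  report$decoding <- viterbi_decode(series, report$best_fit)
  report$time_budget <- time_budget(report$decoding, config$n_states)
  tr <- range(series$temp, na.rm = TRUE)
  report$stationary <- stationary_probs(report$best_fit,
                                        seq(tr[1], tr[2], length.out = 50))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Telemetry study report\n")
  cat("======================\n")
  c0 <- x$counts
  cat(sprintf("Fixes in: %d | removed: truncation %d, speed %d, terrestrial %d, short segments %d | retained: %d\n",
              c0$input, c0$removed_truncation, c0$removed_speed,
              c0$removed_terrestrial, c0$removed_short_segments, c0$retained))
  cat(sprintf("Track segments analysed: %d", length(x$segments)))
  if (length(x$ctcrw_fallback)) {
    cat(sprintf(" (linear fallback for: %s)",
                paste(x$ctcrw_fallback, collapse = ", ")))
  }
  cat("\n\nFunctional duration by design:\n")
  print(x$performance$duration_summary, row.names = FALSE)
  if (!is.null(x$performance$error_classes$classes)) {
    cat("\nArgos error-class proportions:\n")
    print(x$performance$error_classes$classes, row.names = FALSE, digits = 3)
  }
  if (x$hmm_skipped) {
    cat("\nHMM stage: skipped (no eligible segments)\n")
  } else {
    cat("\nModel selection (AICc):\n")
    print(x$selection, row.names = FALSE, digits = 6)
    cat("\nTime budget (decoded):",
        paste(sprintf("%s %.1f%%", names(x$time_budget),
                      100 * x$time_budget), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits a key/value `report.txt` with the stage counts plus delimited
#' result tables (duration summary, error-class proportions, model
#' selection, decoded states, stationary curve).
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kv <- c(
    sprintf("input=%d", report$counts$input),
    sprintf("removed_truncation=%d", report$counts$removed_truncation),
    sprintf("removed_speed=%d", report$counts$removed_speed),
    sprintf("removed_terrestrial=%d", report$counts$removed_terrestrial),
    sprintf("removed_short_segments=%d", report$counts$removed_short_segments),
    sprintf("retained=%d", report$counts$retained),
    sprintf("n_segments=%d", length(report$segments)),
    sprintf("hmm_skipped=%s", report$hmm_skipped),
    sprintf("ctcrw_fallback=%s", paste(report$ctcrw_fallback, collapse = ";"))
  )
  writeLines(kv, file.path(out_dir, "report.txt"))
  utils::write.csv(report$performance$duration_summary,
                   file.path(out_dir, "duration_summary.csv"), row.names = FALSE)
  if (!is.null(report$performance$error_classes$classes)) {
    utils::write.csv(report$performance$error_classes$classes,
                     file.path(out_dir, "error_classes.csv"), row.names = FALSE)
  }
  if (!report$hmm_skipped) {
    utils::write.csv(report$selection, file.path(out_dir, "model_selection.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report$decoding),
                     file.path(out_dir, "decoded_states.csv"), row.names = FALSE)
    utils::write.csv(report$stationary, file.path(out_dir, "stationary_curve.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
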