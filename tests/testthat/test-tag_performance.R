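inactive_fixes <- function(pattern, interval_h = 4) {
  f <- make_line_fixes(length(pattern), interval_h = interval_h)
  f$activity <- ifelse(pattern, "inactive", "active")
  f
}

test_that("a run of four or more inactive fixes means detachment at the run start", {
  f <- inactive_fixes(c(rep(FALSE, 6), rep(TRUE, 4)))
  det <- detect_detachment(f)
  expect_equal(det$status, "detached")
  expect_equal(det$event_time, f$time[7])

  # exactly three inactive fixes then active again: not a detachment
  g <- inactive_fixes(c(rep(FALSE, 4), rep(TRUE, 3), FALSE, FALSE))
  det2 <- detect_detachment(g)
  expect_equal(det2$status, "stopped")
  expect_equal(det2$event_time, g$time[nrow(g)])

  # no inactivity at all: stopped at last transmission
  h <- inactive_fixes(rep(FALSE, 5))
  expect_equal(detect_detachment(h)$status, "stopped")
  expect_equal(detect_detachment(h)$event_time, h$time[5])
})

test_that("functional duration runs from attachment to the failure event", {
  dep <- data.frame(tag_id = "T01", attach_time = t0_utc)
  # active transmissions ending 58 days after attachment
  f <- make_line_fixes(349, interval_h = 4)          # 0 .. 58 days
  expect_equal(functional_duration(dep, f), 58)
  # detachment run starting on day 10 caps the duration even if fixes continue
  g <- make_line_fixes(100, interval_h = 4)
  g$activity[g$time >= t0_utc + 10 * 86400] <- "inactive"
  expect_equal(functional_duration(dep, g), 10)
  # single fix at attachment; and the no-fix warning case
  expect_equal(functional_duration(dep, make_line_fixes(1)), 0)
  expect_warning(d0 <- functional_duration(dep, make_line_fixes(0)), "no fixes")
  expect_equal(d0, 0)
  # never longer than last fix - attach time
  expect_lte(functional_duration(dep, g),
             as.numeric(difftime(max(g$time), dep$attach_time, units = "days")))
})

test_that("duration summaries reproduce hand-computed group statistics", {
  # tribrush-like durations
  s <- summarize_durations(c(2, 3, 69, 114), rep("tribrush", 4))
  expect_equal(s$mean_days, 47)
  expect_equal(round(s$se_days, 1), 27.3)
  expect_equal(c(s$min_days, s$max_days), c(2, 114))
  # the two adhesive tribrush tags
  s2 <- summarize_durations(c(69, 114), rep("tribrush", 2))
  expect_equal(s2$mean_days, 91.5)
  expect_equal(round(s2$se_days, 1), 22.5)
  # singleton group has no SE
  s3 <- summarize_durations(58, "seatrkr")
  expect_true(is.na(s3$se_days))
  expect_equal(s3$mean_days, 58)
  # summaries invariant to input order
  perm <- sample(4)
  s4 <- summarize_durations(c(2, 3, 69, 114)[perm], rep("tribrush", 4))
  expect_equal(s4, s)
  # min <= mean <= max always
  expect_true(all(s$min_days <= s$mean_days & s$mean_days <= s$max_days))
})

test_that("error-class tables count Argos classes and summarize GPS separately", {
  f <- make_line_fixes(10)
  f$loc_class <- c(rep("B", 4), rep("A", 3), rep("0", 3))
  tab <- error_class_table(f, rep("ear", 10))
  row <- tab$classes[tab$classes$design == "ear", ]
  expect_equal(as.numeric(row[, -1]), c(0, 0, 0, 0.3, 0.3, 0.4))
  expect_equal(sum(as.numeric(row[, -1])), 1)

  # GPS fixes excluded from the class table, summarized by h_error_m
  g <- make_line_fixes(4, source = "gps")
  g$h_error_m <- c(4, 10, 12, 102)
  mixed <- rbind(f, g)
  tab2 <- error_class_table(mixed, c(rep("ear", 10), rep("seatrkr", 4)))
  expect_equal(tab2$classes$design, "ear")
  expect_equal(attr(tab2$classes, "omitted"), "seatrkr")
  expect_equal(tab2$gps$mean_m, 32)
  expect_equal(c(tab2$gps$min_m, tab2$gps$max_m), c(4, 102))
})

test_that("generated class mixes are recovered at large n", {
  cfg <- sim_config(seed = 8)
  set.seed(8)
  n <- 10000
  draws <- sample(names(cfg$class_mix), n, replace = TRUE, prob = cfg$class_mix)
  f <- make_line_fixes(1)[rep(1, n), ]
  f$loc_class <- draws
  tab <- error_class_table(f, rep("ear", n))
  got <- as.numeric(tab$classes[1, -1])
  expect_equal(got, unname(cfg$class_mix), tolerance = 0.05)
})
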