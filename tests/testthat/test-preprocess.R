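test_that("post-capture truncation removes exactly the first 3 days, boundary retained", {
  dep <- data.frame(tag_id = "T01", attach_time = t0_utc)
  f <- make_line_fixes(41, interval_h = 6)       # 0..240 h at 6-h spacing
  out <- truncate_post_capture(f, dep)
  expect_equal(nrow(f) - nrow(out), 12)          # fixes at 0..66 h removed
  expect_equal(min(out$time), t0_utc + 72 * 3600)  # 72-h fix retained

  # boundary fix exactly at attach + 72 h is retained
  one <- f[f$time == t0_utc + 72 * 3600, ]
  expect_equal(nrow(truncate_post_capture(one, dep)), 1)

  # everything within the window -> empty
  early <- make_line_fixes(10, interval_h = 4)
  expect_equal(nrow(truncate_post_capture(early, dep)), 0)
})

test_that("RMS speed filter removes a displaced spike and is idempotent", {
  # 5 fixes 4 h apart moving at 2 km/h along a meridian, middle fix displaced
  # far east so both adjacent legs imply ~100 km/h
  f <- make_line_fixes(5, speed_kmh = 2)
  f$lon[3] <- f$lon[3] + 400 / (111.1949 * cos(f$lat[3] * pi / 180))
  # hand check: with the displacement, legs 2-3 and 3-4 are ~400 km in 4 h
  v23 <- great_circle_km(f$lon[2], f$lat[2], f$lon[3], f$lat[3]) / 4
  expect_gt(v23, 90)
  out <- speed_filter(f)
  expect_equal(nrow(out$removed), 1)
  expect_equal(out$removed$time, f$time[3])
  expect_equal(out$retained$time, f$time[-3])
  # idempotent
  again <- speed_filter(out$retained)
  expect_equal(again$retained, out$retained)
  expect_equal(nrow(again$removed), 0)
})

test_that("slow tracks pass the speed filter untouched and endpoints survive", {
  f <- make_line_fixes(30, speed_kmh = 4)
  out <- speed_filter(f)
  expect_equal(out$retained, f)
  # stationary track: all fixes at one point
  s <- make_line_fixes(10, speed_kmh = 0)
  expect_equal(speed_filter(s)$retained, s)
  # a fast burst everywhere below threshold is kept (threshold is >= 40)
  f39 <- make_line_fixes(10, speed_kmh = 39.9)
  expect_equal(nrow(speed_filter(f39)$removed), 0)
  # re-scan invariant: no retained fix has RMS speed >= 40 among retained
  f$lat[c(8, 15, 21)] <- f$lat[c(8, 15, 21)] + c(2, 3, 2.5)
  ret <- speed_filter(f)$retained
  v <- polarmove:::.rms_speeds(ret$lon, ret$lat, as.numeric(ret$time))
  expect_true(all(v[-c(1, length(v))] < 40))
  # endpoints are never removed
  expect_true(f$time[1] %in% ret$time && f$time[nrow(f)] %in% ret$time)
})

test_that("terrestrial filter keeps bounded short forays and drops the rest", {
  runs <- function(land) {
    f <- make_line_fixes(length(land))
    f$on_land <- land
    f
  }
  # marine run of 49 bounded by land: all retained
  f49 <- runs(c(TRUE, rep(FALSE, 49), TRUE))
  expect_equal(nrow(terrestrial_filter(f49)), 51)
  # marine run of exactly 50 bounded by land: run removed
  f50 <- runs(c(TRUE, rep(FALSE, 50), TRUE))
  expect_equal(nrow(terrestrial_filter(f50)), 2)
  # trailing marine run (no return to land): removed
  ftrail <- runs(c(rep(TRUE, 5), rep(FALSE, 10)))
  expect_equal(nrow(terrestrial_filter(ftrail)), 5)
  # leading marine run removed too
  flead <- runs(c(rep(FALSE, 3), rep(TRUE, 4)))
  expect_equal(nrow(terrestrial_filter(flead)), 4)
  # idempotent and order-preserving
  mixed <- runs(c(TRUE, TRUE, FALSE, FALSE, TRUE, rep(FALSE, 60), TRUE, FALSE))
  once <- terrestrial_filter(mixed)
  expect_equal(terrestrial_filter(once), once)
  expect_true(!is.unsorted(once$time))
})

test_that("unresolved on_land needs a landmask; the mask resolves it", {
  f <- make_line_fixes(6)
  f$on_land <- NA
  expect_error(terrestrial_filter(f), "landmask")
  out <- terrestrial_filter(f, landmask = function(lon, lat) lat < 60)
  expect_equal(nrow(out), 6)
})

test_that("a polygon file yields a working point-in-polygon landmask", {
  sq <- data.frame(lon = c(-94, -93, -93, -94, -94),
                   lat = c(58, 58, 59, 59, 58))       # closed square ring
  mask <- make_polygon_landmask(sq)
  expect_equal(mask(c(-93.5, -92.5, -94.5, -93.0), c(58.5, 58.5, 58.5, 58.5)),
               c(TRUE, FALSE, FALSE, TRUE))           # inside/out/out/edge
  # same polygon via CSV path
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sq, path, row.names = FALSE)
  mask2 <- make_polygon_landmask(path)
  expect_equal(mask2(-93.5, 58.5), TRUE)
  expect_error(make_polygon_landmask(data.frame(lon = 1:2, lat = 1:2)),
               "3 distinct")
  # fixes resolved through the polygon: marine ones outside it
  f <- make_line_fixes(4)
  f$on_land <- NA
  f$lat <- c(58.5, 58.5, 59.5, 58.5)   # third point is outside (marine)
  out <- terrestrial_filter(f, landmask = mask)
  expect_equal(nrow(out), 4)           # bounded single-fix foray retained
})

test_that("segmentation splits strictly after gaps > 24 h and drops short segments", {
  f <- make_line_fixes(300)
  f$time[151:300] <- f$time[151:300] + 24.5 * 3600   # 4 + 24.5 h gap...
  # recompute: gap between fix 150 and 151 becomes 4 + 24.5 = 28.5 h
  seg <- segment_tracks(f, min_len = 100)
  expect_equal(length(seg$segments), 2)
  expect_equal(vapply(seg$segments, nrow, integer(1)), c(150L, 150L))
  expect_equal(attr(seg$segments[[1]], "segment_index"), 0L)

  # gap of exactly 24 h does not split (strict inequality)
  g <- make_line_fixes(300)
  g$time[151:300] <- g$time[151:300] + 20 * 3600     # gap becomes exactly 24 h
  seg2 <- segment_tracks(g, min_len = 100)
  expect_equal(length(seg2$segments), 1)

  # 99-fix segment is discarded and counted
  h <- make_line_fixes(99)
  seg3 <- segment_tracks(h, min_len = 100)
  expect_equal(length(seg3$segments), 0)
  expect_equal(nrow(seg3$discarded), 99)
})
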