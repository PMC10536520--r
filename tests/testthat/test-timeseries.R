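test_that("per-frame gaze labels follow the scleral position in all four directions", {
  for (g in c("up", "left", "right", "primary")) {
    sp <- clean_spec(gaze = g, seed = 3)
    fr <- render_frame(sp, 0)
    hx <- extract_eye_hexagons(landmark_set(fr$landmarks))
    expect_identical(classify_gaze(fr$image, hx$right), g)
    expect_identical(classify_gaze(fr$image, hx$left), g)
  }
})

test_that("exercise windows are detected from label schedules within a second", {
  fps <- 10
  ts <- (0:599) / fps  # 60 s
  g <- rep("primary", 600)
  g[31:570] <- "up"    # up-gaze from 3 s to 57 s
  w <- detect_exercise_window(g, g, ts, expected = "up")
  expect_true(w$available)
  expect_lt(abs(w$start - 3), 1)
  expect_lt(abs(w$end - 57), 1)
  expect_false(w$atypical)
  # constant primary gaze: unavailable for the up-gaze exercise
  expect_false(detect_exercise_window(rep("primary", 600), rep("primary", 600),
                                      ts, "up")$available)
  # eyes disagreeing throughout: unavailable
  expect_false(detect_exercise_window(rep("up", 600), rep("left", 600),
                                      ts, "up")$available)
  # a 20 s window inside a 60 s clip is atypical but available
  g2 <- rep("primary", 600); g2[201:400] <- "up"
  w2 <- detect_exercise_window(g2, g2, ts, "up")
  expect_true(w2$available)
  expect_true(w2$atypical)
})

test_that("frame rejection applies motion, instability and blink rules in priority order", {
  sp <- clean_spec(duration = 4, seed = 5)
  sq <- render_sequence(sp, keep_frames = FALSE)
  lms <- sq$landmarks
  el <- 36
  # clean static sequence: no rejections
  expect_true(all(reject_frames(lms, el) == "none"))
  # single-frame landmark jump of the eye points only -> landmark_instability
  lms2 <- lms
  lms2[[20]][37:48, 2] <- lms2[[20]][37:48, 2] + 0.3 * el
  r2 <- reject_frames(lms2, el)
  expect_identical(r2[20], "landmark_instability")
  expect_identical(r2[19], "none")
  # whole-head jump -> motion
  lms3 <- lms
  lms3[[30]] <- lms3[[30]] + 0.2 * el
  r3 <- reject_frames(lms3, el)
  expect_identical(r3[30], "motion")
  # blink frames are widened by one frame
  rb <- reject_frames(lms, el, blink_frames = 50:54)
  expect_true(all(rb[49:55] == "blink"))
  expect_identical(rb[48], "none")
  # lighting beats instability but not motion
  rl <- reject_frames(lms3, el, lighting_bad = seq_along(lms) == 30)
  expect_identical(rl[30], "motion")
  rl2 <- reject_frames(lms, el, lighting_bad = seq_along(lms) == 31)
  expect_identical(rl2[31], "lighting")
  # missing landmarks
  lms4 <- lms; lms4[12] <- list(NULL)
  expect_identical(reject_frames(lms4, el)[12], "no_landmarks")
})

test_that("series assembly interpolates sub-second holes and records longer gaps", {
  ts <- seq(0, 1, by = 0.25)
  v <- c(1, NA, NA, NA, 3)
  s <- assemble_series(ts, v)
  expect_equal(s$samples$value, c(1, 1.5, 2, 2.5, 3))
  expect_equal(nrow(s$gaps), 0)
  # interpolation is exact on linear ground truth
  ts2 <- seq(0, 10, by = 0.1)
  v2 <- 2 + 0.3 * ts2
  set.seed(7)
  v2[sample(seq_along(v2)[-c(1, length(v2))], 30)] <- NA
  s2 <- assemble_series(ts2, v2)
  expect_equal(s2$samples$value, 2 + 0.3 * s2$samples$timestamp, tolerance = 1e-12)
  # a hole longer than 1 s is a gap and never interpolated
  ts3 <- c(seq(0, 10, 0.5), seq(12, 20, 0.5))
  v3 <- rep(5, length(ts3))
  full_grid <- c(seq(0, 10, 0.5), 10.5, 11, 11.5, seq(12, 20, 0.5))
  v3g <- rep(5, length(full_grid)); v3g[full_grid > 10 & full_grid < 12] <- NA
  s3 <- assemble_series(full_grid, v3g)
  expect_equal(nrow(s3$gaps), 1)
  expect_equal(unname(unlist(s3$gaps)), c(10, 12))
  expect_true(all(is.na(s3$samples$value[s3$samples$in_gap])))
  # fewer than 2 valid samples -> empty series
  expect_equal(nrow(assemble_series(ts, c(1, NA, NA, NA, NA))$samples), 0)
})

test_that("the spectral filter preserves constants and ramps and removes fast oscillation", {
  ts <- seq(0, 60, by = 1 / 30)
  mk <- function(v) filter_series(assemble_series(ts, v))
  # constant: unchanged
  sc <- mk(rep(2.5, length(ts)))
  expect_equal(sc$samples$filtered, rep(2.5, length(ts)), tolerance = 1e-9)
  # pure linear ramp: within 1%
  ramp <- 1 - 0.15 * ts / 60
  sr <- mk(ramp)
  expect_lt(max(abs(sr$samples$filtered - ramp)) / diff(range(ramp)), 0.01)
  # ramp + 5 Hz sinusoid: sinusoid attenuated >= 20x, ramp preserved within 1%
  sig <- ramp + 0.2 * sin(2 * pi * 5 * ts)
  ss <- mk(sig)
  resid <- ss$samples$filtered - ramp
  expect_lt(max(abs(resid)), 0.2 / 20)
  # mean preserved within 0.1%
  expect_lt(abs(mean(ss$samples$filtered) - mean(sig)) / abs(mean(sig)), 0.001)
  # idempotent within 1%
  s2 <- ss
  s2$samples$value <- ss$samples$filtered
  s2 <- filter_series(s2)
  expect_lt(max(abs(s2$samples$filtered - ss$samples$filtered)) /
              diff(range(ss$samples$filtered)), 0.01)
})

test_that("gaps are conserved through filtering and short segments pass through flagged", {
  ts <- c(seq(0, 20, 0.1), seq(25, 45, 0.1))
  grid <- c(seq(0, 20, 0.1), seq(20.1, 24.9, 0.1), seq(25, 45, 0.1))
  v <- sin(grid / 3)
  v[grid > 20 & grid < 25] <- NA
  s <- filter_series(assemble_series(grid, v))
  expect_equal(nrow(s$gaps), 1)
  expect_true(all(is.na(s$samples$filtered[s$samples$in_gap])))
  expect_true(all(is.finite(s$samples$filtered[!s$samples$in_gap])))
  # a 2 s segment is returned unfiltered and counted
  ts_short <- c(seq(0, 2, 0.1), seq(10, 30, 0.1))
  grid_s <- c(seq(0, 2, 0.1), seq(2.1, 9.9, 0.1), seq(10, 30, 0.1))
  vs <- cos(grid_s)
  vs[grid_s > 2 & grid_s < 10] <- NA
  s2 <- filter_series(assemble_series(grid_s, vs))
  expect_equal(s2$short_segments, 1L)
  short_idx <- s2$samples$timestamp <= 2
  expect_equal(s2$samples$filtered[short_idx], s2$samples$value[short_idx])
})

test_that("trend fitting on normalized time recovers exact linear series", {
  ts <- seq(0, 60, 0.5)
  s <- assemble_series(ts, 1 - 0.15 * ts / 60)
  s <- fit_trend(s)
  expect_equal(unname(s$trend["slope"]), -0.15, tolerance = 1e-9)
  expect_equal(unname(s$trend["intercept"]), 1, tolerance = 1e-9)
  s0 <- fit_trend(assemble_series(ts, rep(3, length(ts))))
  expect_equal(unname(s0$trend["slope"]), 0, tolerance = 1e-12)
  # insufficient span -> unavailable
  few <- fit_trend(assemble_series(ts[1:6], rep(1:2, 3)), window = c(0, 60))
  expect_true(all(is.na(few$trend)))
})
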