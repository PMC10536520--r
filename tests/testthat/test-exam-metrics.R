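flat_curve <- function(y, xs = 270:298, accepted = TRUE) {
  cv <- interface_curve(xs, rep(y, length(xs)), "horizontal", "snake")
  cv$accepted <- accepted
  cv
}

test_that("per-frame ptosis metrics evaluate curves at the ROI center", {
  sp <- clean_spec()
  fr <- render_frame(sp, 0)
  hx <- extract_eye_hexagons(landmark_set(fr$landmarks))$right
  curves <- list(upper_lid = flat_curve(10), lower_lid = flat_curve(20),
                 iris_bottom = flat_curve(17))
  m <- ptosis_frame_metrics(curves, hx, timestamp = 1)
  expect_equal(m$lid_to_lid, 10)
  expect_equal(m$iris_to_lowerlid, 3)
  expect_equal(m$lid_to_lid_norm, 10 / 36)
  expect_true(m$valid)
  # iris bottom 1 px below the lower lid (sub-pixel error): still valid
  m2 <- ptosis_frame_metrics(list(upper_lid = flat_curve(10), lower_lid = flat_curve(20),
                                  iris_bottom = flat_curve(21)), hx)
  expect_equal(m2$iris_to_lowerlid, -1)
  expect_true(m2$valid)
  # missing required curve
  m3 <- ptosis_frame_metrics(list(upper_lid = flat_curve(10)), hx)
  expect_false(m3$valid)
  expect_identical(m3$rejection_reason, "segmentation_failed")
})

test_that("end-to-end frame metrics on a noiseless frame match ground truth within 0.5 px", {
  sp <- clean_spec(noise_sigma = 0.001, seed = 31)
  fr <- render_frame(sp, 0)
  hx <- extract_eye_hexagons(landmark_set(fr$landmarks))$right
  rects <- build_rectangles(hx, "ptosis", image_size = dim(fr$image))
  curves <- list()
  for (nm in names(rects)) {
    out <- segment_with_retry(fr$image, rects[[nm]], base_seed = 3)
    curves[[nm]] <- out$curve
  }
  m <- ptosis_frame_metrics(curves, hx)
  tr <- fr$truth[fr$truth$side == "right", ]
  expect_lt(abs(m$upper_lid_y - tr$upper_lid_y), 0.5)
  expect_lt(abs(m$lower_lid_y - tr$lower_lid_y), 0.5)
  expect_lt(abs(m$lid_to_lid - (tr$lower_lid_y - tr$upper_lid_y)), 0.5)
})

test_that("iris circle fit recovers diameter from arcs and rejects lines", {
  th <- seq(-60, 60, length.out = 25) * pi / 180
  x <- 100 + 12 * sin(th); y <- 50 + 12 * cos(th)
  fit <- iris_circle_fit(x, y)
  expect_true(fit$available)
  expect_equal(fit$diameter, 24, tolerance = 0.1 / 24)
  expect_true(fit$reliable)
  # collinear samples: unavailable
  expect_false(iris_circle_fit(1:10, 2 * (1:10) + 3)$available)
  # noisy semicircle: mean diameter error within 2% of 2r (seeded simulation)
  r <- 12
  rel_err <- vapply(1:10, function(s) {
    set.seed(s)
    th2 <- seq(0, pi, length.out = 60)
    x2 <- 60 + r * cos(th2) + rnorm(60, 0, 0.5)
    y2 <- 60 + r * sin(th2) + rnorm(60, 0, 0.5)
    abs(iris_circle_fit(x2, y2)$diameter - 2 * r) / (2 * r)
  }, numeric(1))
  expect_lt(mean(rel_err), 0.02)
  # a short arc is flagged unreliable
  th3 <- seq(-10, 10, length.out = 15) * pi / 180
  fit3 <- iris_circle_fit(100 + 12 * sin(th3), 50 + 12 * cos(th3))
  expect_false(fit3$reliable)
})

test_that("alpha is the anchored horizontal distance over EL and is translation invariant", {
  sp <- clean_spec(gaze = "left")
  fr <- render_frame(sp, 0)
  hx <- extract_eye_hexagons(landmark_set(fr$landmarks))$right
  corners_x <- hx$vertices[c(1, 4), 1]
  mk_lateral <- function(x_extreme, dx = 0, dy = 0) {
    ys <- (146:156) + dy
    xs <- x_extreme + dx - 0.02 * (ys - 151 - dy)^2
    cv <- interface_curve(ys, xs, "vertical", "snake")
    cv$accepted <- TRUE
    cv
  }
  hx_shift <- function(hex, dx, dy) {
    hex$vertices <- sweep(hex$vertices, 2, c(dx, dy), "+"); hex
  }
  # P at the anchor corner (gaze left -> anchor is the +x corner) -> alpha 0
  a0 <- alpha_coordinate(mk_lateral(max(corners_x)), hx, "left")
  expect_equal(a0$alpha, 0, tolerance = 1e-9)
  # P at the opposite corner -> alpha 1
  a1 <- alpha_coordinate(mk_lateral(min(corners_x)), hx, "left")
  expect_equal(a1$alpha, 1, tolerance = 1e-9)
  # whole-frame translation leaves alpha unchanged to 1e-9
  base <- alpha_coordinate(mk_lateral(280), hx, "left")
  for (d in list(c(5, 3), c(-5, -3), c(5, -3))) {
    tr <- alpha_coordinate(mk_lateral(280, d[1], d[2]), hx_shift(hx, d[1], d[2]), "left")
    expect_equal(tr$alpha, base$alpha, tolerance = 1e-9)
  }
})

test_that("alpha pair series measures drift from the baseline, not constant offsets", {
  ts <- seq(0, 60, by = 0.5)
  # identical alphas: zero deviation, no flag
  s0 <- alpha_pair_series(ts, rep(0.5, length(ts)), rep(0.5, length(ts)))
  expect_true(all(s0$deviation == 0))
  expect_false(any(s0$misalignment_flag))
  # constant offset 0.1 is not drift
  s1 <- alpha_pair_series(ts, rep(0.6, length(ts)), rep(0.5, length(ts)))
  expect_equal(unique(s1$baseline_delta), 0.1)
  expect_true(all(s1$deviation == 0))
  # linear drift 0 -> 0.12 over 60 s: flag raised once deviation crosses 0.05
  drift <- 0.12 * ts / 60
  s2 <- alpha_pair_series(ts, 0.5 + drift, rep(0.5, length(ts)))
  expect_false(s2$misalignment_flag[1])
  expect_true(any(s2$misalignment_flag))
  first_flag <- s2$timestamp[which(s2$misalignment_flag)[1]]
  # baseline is the median over the first 5 s (~0.005), flag near t = 27.5 s
  expect_gt(first_flag, 20); expect_lt(first_flag, 35)
  # no common valid frames -> empty
  expect_equal(nrow(alpha_pair_series(ts, rep(NA_real_, length(ts)),
                                      rep(0.5, length(ts)))), 0)
})

test_that("time-based ptosis grading follows the MG-CE scale", {
  expect_equal(grade_ptosis_time(30), 1L)
  expect_equal(grade_ptosis_time(NA, series_duration = 61), 0L)
  expect_equal(grade_ptosis_time(0.5), 3L)
  expect_equal(grade_ptosis_time(5), 2L)
  expect_equal(grade_ptosis_time(50), 0L)
  # a short series with no onset cannot certify grade 0
  expect_true(is.na(grade_ptosis_time(NA, series_duration = 30)))
  # monotone non-increasing in onset time
  onsets <- c(0.5, 1, 2, 9, 11, 30, 44, 46, 60)
  grades <- vapply(onsets, grade_ptosis_time, integer(1))
  expect_true(all(diff(grades) <= 0))
})

test_that("anatomic ptosis grading relates the lid margin to the fitted pupil", {
  fit <- list(available = TRUE, center = c(100, 50), radius = 12, diameter = 24)
  expect_equal(grade_ptosis_anatomic(50 - 12 - 10, fit), 0L)  # well above iris top
  expect_equal(grade_ptosis_anatomic(50 - 9, fit), 1L)        # above pupil band
  expect_equal(grade_ptosis_anatomic(50, fit), 2L)            # at the pupil center
  expect_equal(grade_ptosis_anatomic(50 + 12, fit), 3L)       # half-diameter below
  expect_true(is.na(grade_ptosis_anatomic(40, list(available = FALSE))))
})

test_that("droop onset is the first drop below the configured fraction", {
  ts <- seq(0, 60, 0.5)
  vals <- 1 - 0.2 * ts / 60      # falls below 0.9 at t = 30
  expect_equal(droop_onset_time(ts, vals), 30.5, tolerance = 0.5)
  expect_true(is.na(droop_onset_time(ts, rep(1, length(ts)))))
})
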