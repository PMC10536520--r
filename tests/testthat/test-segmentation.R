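test_that("contrast stretch maps the percentile range onto [0, 1]", {
  set.seed(2)
  p <- matrix(runif(400, 0.4, 0.6), 20, 20)
  e <- enhance_contrast(p)
  expect_gte(min(e), 0); expect_lte(max(e), 1)
  expect_lt(min(e), 0.02); expect_gt(max(e), 0.98)
  # constant patch: unchanged and flagged
  cst <- matrix(0.5, 8, 8)
  ec <- enhance_contrast(cst)
  expect_true(attr(ec, "zero_dynamic_range"))
  expect_equal(as.vector(ec), as.vector(cst))
  # two-tone order preserved
  tt <- two_tone_patch()
  et <- enhance_contrast(tt)
  expect_true(all(et[1, ] < et[12, ]))
  expect_equal(length(unique(round(as.vector(et), 6))), 2)
})

test_that("two-cluster partition matches the brute-force threshold oracle", {
  for (seed in 1:10) {
    p <- two_tone_patch(noise = 0.04, seed = seed)
    e <- enhance_contrast(p)
    seg <- segment_two_cluster(e, seed = seed)
    oracle <- oracle_threshold_labels(as.vector(e))
    expect_gte(mean(seg$labels == oracle), 0.99)
  }
  # clean two-tone: exactly the threshold partition, any seed
  p <- two_tone_patch()
  segs <- lapply(c(1, 77, 1234), function(s) segment_two_cluster(p, seed = s)$labels)
  expect_identical(segs[[1]], segs[[2]])
  expect_identical(segs[[1]], segs[[3]])
  expect_identical(as.vector(segs[[1]]), oracle_threshold_labels(as.vector(p)))
})

test_that("cluster separation is far lower on pure noise than on two-tone patches", {
  set.seed(5)
  p <- matrix(runif(400), 20, 20)
  seg <- segment_two_cluster(p, seed = 3)
  tt <- segment_two_cluster(two_tone_patch(noise = 0.04), seed = 3)
  expect_lt(seg$separation, tt$separation / 2)
  flat <- segment_two_cluster(matrix(0.5, 8, 8), seed = 1)
  expect_false(flat$ok)
  expect_identical(flat$reason, "contrast")
})

test_that("label fields convert to sub-pixel interfaces with cleanup", {
  rect <- search_rectangle(1, 13, 1, 13, "upper_lid")
  lab <- matrix(1L, 12, 12); lab[8:12, ] <- 2L  # step at the 7/8 boundary
  li <- labels_to_interface(lab, rect)
  expect_true(li$ok)
  expect_equal(li$curve$samples, rep(7.5, 12))
  expect_equal(li$curve$n_ambiguous, 0)
  # one salt-noise pixel is removed by the majority cleanup
  lab2 <- lab; lab2[3, 5] <- 2L
  li2 <- labels_to_interface(lab2, rect)
  expect_equal(li2$curve$samples, rep(7.5, 12))
  # checkerboard: no two-region structure
  cb <- matrix(rep(c(1L, 2L), 72)[1:144], 12, 12)
  cb <- outer(1:12, 1:12, function(i, j) ifelse((i + j) %% 2 == 0, 1L, 2L))
  expect_false(labels_to_interface(cb, rect)$ok)
})

test_that("the open snake converges to a noiseless step and fixes flat patches", {
  p <- two_tone_patch(16, 12, step_row = 8)
  rect <- search_rectangle(1, 13, 1, 17, "upper_lid")
  # init offset by 2 px from the true step at 8.5
  init <- interface_curve(1:12, rep(6.5, 12), "horizontal", "clustering")
  init$n_ambiguous <- 0L
  out <- segment_snake(p, init, rect)
  expect_lt(max(abs(out$samples - 8.5)), 0.5)
  # init already on the step: stays there
  init2 <- interface_curve(1:12, rep(8.5, 12), "horizontal", "clustering")
  init2$n_ambiguous <- 0L
  out2 <- segment_snake(p, init2, rect)
  expect_lt(max(abs(out2$samples - 8.5)), 0.1)
  # flat patch: returns the init, flagged
  flat <- matrix(0.5, 16, 12)
  out3 <- segment_snake(flat, init, rect)
  expect_equal(out3$samples, init$samples)
  expect_true("flat_gradient" %in% out3$flags)
})

test_that("hypothesis checks gate smoothness, crossing, convexity and connectedness", {
  rect <- search_rectangle(1, 13, 1, 13, "upper_lid")
  lab <- matrix(1L, 12, 12); lab[8:12, ] <- 2L
  straight <- interface_curve(1:12, rep(7.5, 12), "horizontal", "snake")
  h <- check_hypotheses(straight, lab, rect)
  expect_true(h$h1); expect_true(h$h2); expect_true(is.na(h$h3)); expect_true(h$h4)
  expect_true(h$passed)
  # zig-zag with 5 px jumps fails H1
  zig <- interface_curve(1:12, rep(c(4, 9), 6), "horizontal", "snake")
  expect_false(check_hypotheses(zig, lab, rect)$h1)
  # iris-bottom arcs must bulge downward (image-y grows down)
  rect_ib <- search_rectangle(1, 13, 1, 13, "iris_bottom")
  xs <- 1:12
  bulge_down <- 10 - 0.08 * (xs - 6.5)^2
  bulge_up <- 4 + 0.08 * (xs - 6.5)^2
  expect_true(check_hypotheses(interface_curve(xs, bulge_down, "horizontal", "snake"),
                               NULL, rect_ib)$h3)
  expect_false(check_hypotheses(interface_curve(xs, bulge_up, "horizontal", "snake"),
                                NULL, rect_ib)$h3)
  # split labels fail connectedness
  lab_split <- lab; lab_split[1:3, 1:6] <- 2L
  expect_false(check_hypotheses(straight, lab_split, rect)$h4)
})

test_that("retry segmentation recovers clean interfaces within 1 px of truth", {
  sp <- clean_spec(seed = 21)
  errs <- ptosis_frame_errors(sp, side = "right", base_seed = 4)
  expect_true(all(is.finite(errs)))
  expect_true(all(errs < 1))
})

test_that("a rectangle straddling two interfaces is resolved by shrinking", {
  # iris/sclera interface near the top, sclera/skin (lid) lower down
  img <- matrix(0.95, 60, 60)
  img[1:20, ] <- 0.2      # dark block: iris-like
  img[41:60, ] <- 0.55    # skin below the lid interface at 40.5
  set.seed(1); img <- pmin(pmax(img + rnorm(3600, 0, 0.01), 0), 1)
  rect <- search_rectangle(11, 41, 10, 55, "lower_lid", anchor = c(25, 41))
  out <- segment_with_retry(img, rect, base_seed = 2)
  expect_identical(out$failure_reason, "none")
  expect_gte(out$final_rectangle$shrink_level, 1)
  # final rectangle excludes the iris/sclera interface at 20.5
  expect_gt(out$final_rectangle$y0, 21)
  expect_lt(max(abs(out$curve$samples - 40.5)), 1)
})

test_that("pure-noise rectangles fail with an explanatory reason", {
  set.seed(9)
  img <- matrix(runif(3600), 60, 60)
  rect <- search_rectangle(11, 41, 11, 41, "lower_lid")
  out <- segment_with_retry(img, rect, base_seed = 1)
  expect_null(out$curve)
  expect_true(out$failure_reason %in% c("contrast", "hypothesis", "exhausted"))
})

test_that("retry outcomes are deterministic and shrinking is monotone", {
  sp <- clean_spec(seed = 13)
  fr <- render_frame(sp, 0)
  lm <- landmark_set(fr$landmarks, image_size = dim(fr$image))
  hx <- extract_eye_hexagons(lm)
  rects <- build_rectangles(hx$right, "ptosis", image_size = dim(fr$image))
  a <- segment_with_retry(fr$image, rects$lower_lid, base_seed = 5)
  b <- segment_with_retry(fr$image, rects$lower_lid, base_seed = 5)
  expect_identical(a, b)
  # shrink monotonicity: strictly decreasing area, anchor retained
  cfg <- mgceye_config()
  r <- rects$lower_lid
  for (i in 1:4) {
    r2 <- mgceye:::shrink_rect(r, cfg, dim(fr$image))
    if (is.null(r2)) break
    expect_lt((r2$x1 - r2$x0) * (r2$y1 - r2$y0), (r$x1 - r$x0) * (r$y1 - r$y0))
    expect_gte(r$anchor[1], r2$bx0); expect_lte(r$anchor[1], r2$bx1)
    expect_gte(r$anchor[2], r2$by0); expect_lte(r$anchor[2], r2$by1)
    r <- r2
  }
})

test_that("ptosis rectangles contain their ground-truth interfaces and respect image bounds", {
  sp <- clean_spec(seed = 2, noise_sigma = 0)
  fr <- render_frame(sp, 0)
  lm <- landmark_set(fr$landmarks, image_size = dim(fr$image))
  hx <- extract_eye_hexagons(lm)
  rects <- build_rectangles(hx$right, "ptosis", image_size = dim(fr$image))
  expect_setequal(names(rects), c("lower_lid", "upper_lid", "iris_bottom"))
  tr <- fr$truth[fr$truth$side == "right", ]
  expect_true(rects$upper_lid$y0 <= tr$upper_lid_y && tr$upper_lid_y < rects$upper_lid$y1)
  expect_true(rects$lower_lid$y0 <= tr$lower_lid_y && tr$lower_lid_y < rects$lower_lid$y1)
  expect_true(rects$iris_bottom$y0 <= tr$iris_bottom_y &&
                tr$iris_bottom_y < rects$iris_bottom$y1)
  # gaze left anchors the lateral box at the +x (right) corner of the eye
  rl <- build_rectangles(hx$right, "diplopia", gaze = "left",
                         image_size = dim(fr$image))
  corner_x <- unname(hx$right$vertices[4, 1])
  expect_equal(rl$iris_lateral$x1 - 1, round(corner_x))
  # hexagon near the image border yields clipped in-bounds rectangles
  sp2 <- clean_spec(seed = 2, eye_centers = list(right = c(12, 20), left = c(80, 20)))
  fr2 <- render_frame(sp2, 0)
  lm2 <- landmark_set(fr2$landmarks)
  hx2 <- extract_eye_hexagons(lm2)
  r2 <- build_rectangles(hx2$right, "ptosis", image_size = c(360, 640))
  for (r in r2) {
    expect_gte(r$x0, 1); expect_gte(r$y0, 1)
    expect_lte(r$x1, 641); expect_lte(r$y1, 361)
  }
})
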