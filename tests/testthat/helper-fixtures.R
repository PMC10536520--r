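# Shared fixture builders. All fixtures are generated in code at test time.

clean_spec <- function(seed = 1, ...) {
  args <- list(noise_sigma = 0.02, duration = 2, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_eye_spec, args)
}

# analytic truth curve over an x-range, rebuilt from the exported truth row
# and spec geometry (independent of the segmentation path under test)
truth_curve <- function(spec, truth_row, target, xs) {
  side <- truth_row$side
  ec <- spec$eye_centers[[side]]
  xc <- ec[1] + truth_row$jitter_x
  yc <- ec[2] + truth_row$jitter_y
  halfL <- spec$eye_length / 2
  u <- (xs - xc) / halfL
  switch(target,
    upper_lid = yc - (yc - truth_row$upper_lid_y) * (1 - u^2),
    lower_lid = yc + (truth_row$lower_lid_y - yc) * (1 - u^2),
    iris_bottom = truth_row$iris_y +
      sqrt(pmax(0, truth_row$iris_r^2 - (xs - truth_row$iris_x)^2))
  )
}

# segment all ptosis interfaces of one eye; returns per-target mean absolute
# error against the analytic truth curves (NA when not accepted)
ptosis_frame_errors <- function(spec, t = 0, side = "right", base_seed = 1) {
  fr <- render_frame(spec, t)
  lm <- landmark_set(fr$landmarks, image_size = dim(fr$image))
  hx <- extract_eye_hexagons(lm)
  rects <- build_rectangles(hx[[side]], "ptosis", image_size = dim(fr$image))
  tr <- fr$truth[fr$truth$side == side, ]
  vapply(c("upper_lid", "lower_lid", "iris_bottom"), function(nm) {
    if (is.null(rects[[nm]])) return(NA_real_)
    out <- segment_with_retry(fr$image, rects[[nm]], base_seed = base_seed)
    if (is.null(out$curve)) return(NA_real_)
    mean(abs(out$curve$samples -
               truth_curve(spec, tr, nm, out$curve$positions)))
  }, numeric(1))
}

# a hexagon built directly from vertices, in annotation order
make_hexagon <- function(vertices, side = "right") {
  pts <- matrix(200, 68, 2)
  idx <- if (side == "right") 37:42 else 43:48
  pts[idx, ] <- vertices
  lm <- landmark_set(pts)
  extract_eye_hexagons(lm)[[side]]
}

two_tone_patch <- function(nr = 12, nc = 12, step_row = 6, lo = 0.2, hi = 0.8,
                           noise = 0, seed = 1) {
  set.seed(seed)
  p <- matrix(lo, nr, nc)
  p[(step_row + 1):nr, ] <- hi
  if (noise > 0) p <- p + matrix(rnorm(nr * nc, 0, noise), nr, nc)
  p
}

# brute-force optimal single-threshold partition (between-class variance),
# the independent oracle for the two-cluster segmentation
oracle_threshold_labels <- function(v) {
  cand <- sort(unique(v))
  if (length(cand) < 2) return(rep(1L, length(v)))
  mids <- (cand[-1] + cand[-length(cand)]) / 2
  bcv <- vapply(mids, function(m) {
    a <- v[v <= m]; b <- v[v > m]
    length(a) * length(b) * (mean(a) - mean(b))^2
  }, numeric(1))
  thr <- mids[which.max(bcv)]
  ifelse(v > thr, 2L, 1L)
}
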