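# Per-frame exam metrics: lid and iris positions evaluated on the vertical
# line through the ROI center, the iris circle fit, the barycentric
# misalignment coordinate alpha, and the two 0-3 severity grading scales.

#' Per-frame ptosis measurement from accepted curves
#'
#' Evaluates the accepted upper-lid, lower-lid and (optionally) iris-bottom
#' curves at the x-coordinate of the eye-ROI center, and reports the lid
#' opening (`lid_to_lid`) and the iris-bottom-to-lower-lid distance
#' (`iris_to_lowerlid`), both raw and normalized by eye length. A small
#' negative `iris_to_lowerlid` (>= -2 px) from sub-pixel error keeps the
#' frame valid.
#'
#' @param curves named list of accepted [interface_curve()]s (needs
#'   `upper_lid`, `lower_lid`; `iris_bottom` optional).
#' @param hex the `eye_hexagon` the curves were searched from.
#' @param timestamp seconds.
#' @param config an [mgceye_config()].
#' @return A one-row data frame (`frame_measurement`): timestamp, side,
#'   upper_lid_y, lower_lid_y, iris_bottom_y, lid_to_lid, iris_to_lowerlid,
#'   lid_to_lid_norm, iris_to_lowerlid_norm, el, valid, rejection_reason.
#' @export
ptosis_frame_metrics <- function(curves, hex, timestamp = NA_real_,
                                 config = mgceye_config()) {
  cx <- hexagon_center(hex)[1]
  el <- eye_length(hex, config)$el
  has <- function(nm) !is.null(curves[[nm]]) && isTRUE(curves[[nm]]$accepted)
  if (!has("upper_lid") || !has("lower_lid"))
    return(frame_measurement_row(timestamp, hex$side, el = el, valid = FALSE,
                                 reason = "segmentation_failed"))
  uy <- curve_value_at(curves$upper_lid, cx)
  ly <- curve_value_at(curves$lower_lid, cx)
  iy <- if (has("iris_bottom")) curve_value_at(curves$iris_bottom, cx) else NA_real_
  lid_to_lid <- ly - uy
  iris_to_ll <- if (is.na(iy)) NA_real_ else ly - iy
  valid <- lid_to_lid >= 0 && (is.na(iris_to_ll) || iris_to_ll >= -2)
  frame_measurement_row(timestamp, hex$side, upper_lid_y = uy, lower_lid_y = ly,
                        iris_bottom_y = iy, lid_to_lid = lid_to_lid,
                        iris_to_lowerlid = iris_to_ll, el = el, valid = valid,
                        reason = if (valid) "none" else "segmentation_failed")
}

frame_measurement_row <- function(timestamp, side, upper_lid_y = NA_real_,
                                  lower_lid_y = NA_real_,
                                  iris_bottom_y = NA_real_,
                                  lid_to_lid = NA_real_,
                                  iris_to_lowerlid = NA_real_,
                                  alpha = NA_real_, el = NA_real_,
                                  valid = FALSE, reason = "none") {
  data.frame(timestamp = timestamp, side = side,
             upper_lid_y = upper_lid_y, lower_lid_y = lower_lid_y,
             iris_bottom_y = iris_bottom_y, lid_to_lid = lid_to_lid,
             iris_to_lowerlid = iris_to_lowerlid,
             lid_to_lid_norm = lid_to_lid / el,
             iris_to_lowerlid_norm = iris_to_lowerlid / el,
             alpha = alpha, el = el, valid = valid,
             rejection_reason = reason, stringsAsFactors = FALSE)
}

#' Iris diameter from boundary arc samples
#'
#' Circle fit to the samples of one or more accepted iris-boundary arcs: an
#' algebraic (Kasa) fit seeds a Gauss-Newton geometric refinement minimizing
#' the squared radial residuals (the algebraic fit alone is biased small on
#' noisy partial arcs); the diameter is twice the fitted radius. The
#' fit is flagged unreliable when the arc subtends less than
#' `iris_arc_min_deg` of the fitted circle, and unavailable for (near-)
#' collinear samples. The pupil center is approximated by the fitted circle
#' center (valid in primary gaze).
#'
#' @param x,y arc sample coordinates (absolute pixels).
#' @param config an [mgceye_config()].
#' @return List `diameter`, `center` (x, y), `radius`, `reliable`,
#'   `available`.
#' @export
iris_circle_fit <- function(x, y, config = mgceye_config()) {
  unavailable <- list(diameter = NA_real_, center = c(NA_real_, NA_real_),
                      radius = NA_real_, reliable = FALSE, available = FALSE)
  if (length(x) < 3) return(unavailable)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(stats::lm.fit(A, b), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(unavailable)
  cx <- unname(fit$coefficients[1]); cy <- unname(fit$coefficients[2])
  r2 <- unname(fit$coefficients[3]) + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(unavailable)
  r <- sqrt(r2)
  # geometric refinement: Gauss-Newton on the radial residuals
  for (it in 1:20) {
    d <- sqrt((x - cx)^2 + (y - cy)^2)
    if (any(d < 1e-9)) break
    J <- cbind(-(x - cx) / d, -(y - cy) / d, -1)
    step <- tryCatch(stats::lm.fit(J, r - d)$coefficients,
                     error = function(e) rep(NA_real_, 3))
    if (any(!is.finite(step))) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (r <= 0) return(unavailable)
    if (max(abs(step)) < 1e-8) break
  }
  cx <- unname(cx); cy <- unname(cy); r <- unname(r)
  # collinearity guard: residual spread of the radii must be a small
  # fraction of the radius, and the radius must not dwarf the arc chord
  radii <- sqrt((x - cx)^2 + (y - cy)^2)
  chord <- max(dist(cbind(x, y)))
  if (r > 50 * chord) return(unavailable)
  ang <- atan2(y - cy, x - cx)
  span <- diff(range(ang))
  if (span > pi) {  # handle wrap-around
    ang2 <- (ang + 2 * pi) %% (2 * pi)
    span <- min(span, diff(range(ang2)))
  }
  list(diameter = 2 * r, center = c(cx, cy), radius = r,
       reliable = span * 180 / pi >= config$iris_arc_min_deg,
       available = TRUE)
}

#' Barycentric misalignment coordinate alpha
#'
#' The horizontal distance from the visible lateral iris-boundary point `P`
#' (the extremal point of the accepted lateral-iris curve in the direction
#' opposite the gaze) to the anchoring eye corner (the corner the search box
#' was drawn from, i.e. the corner opposite the gaze direction), divided by
#' eye length. Being a ratio of coordinate differences within the frame, it
#' is quasi-invariant to small head translations.
#'
#' @param curve accepted `iris_lateral` [interface_curve()] (vertical
#'   crossing: x samples indexed by y).
#' @param hex the `eye_hexagon`.
#' @param gaze image-frame gaze direction, `"left"` or `"right"`.
#' @param config an [mgceye_config()].
#' @return List `alpha` (flagged > 1 as `overshoot`), `p` (the lateral point,
#'   x/y), `available`.
#' @export
alpha_coordinate <- function(curve, hex, gaze = c("left", "right"),
                             config = mgceye_config()) {
  gaze <- match.arg(gaze)
  el <- eye_length(hex, config)
  if (el$under_resolved || is.null(curve) || !isTRUE(curve$accepted))
    return(list(alpha = NA_real_, p = c(NA_real_, NA_real_), available = FALSE))
  corners <- if (hex$side == "right") c(37, 40) else c(43, 46)
  xs <- hex$vertices[hex_row(hex, corners), 1]
  # anchor corner = the corner opposite the gaze direction
  anchor_x <- if (gaze == "left") max(xs) else min(xs)
  k <- if (gaze == "left") which.max(curve$samples) else which.min(curve$samples)
  p <- c(curve$samples[k], curve$positions[k])
  alpha <- abs(p[1] - anchor_x) / el$el
  list(alpha = alpha, p = p, available = TRUE,
       overshoot = alpha > 1, out_of_range = alpha > 1.2)
}

#' Alpha pair series and misalignment deviation
#'
#' Per-frame difference `delta = alpha_left - alpha_right`; the baseline is
#' the median delta over the first `alpha_baseline_s` seconds of valid
#' frames; the deviation is `|delta - baseline|` (a constant inter-eye
#' offset is not drift). Frames whose deviation exceeds
#' `alpha_dev_threshold` carry the misalignment flag.
#'
#' @param timestamps seconds.
#' @param alpha_left,alpha_right per-frame alpha values (NA = invalid).
#' @param config an [mgceye_config()].
#' @return Data frame: timestamp, alpha_left, alpha_right, delta,
#'   baseline_delta, deviation, misalignment_flag. Empty when the eyes share
#'   no valid frame.
#' @export
alpha_pair_series <- function(timestamps, alpha_left, alpha_right,
                              config = mgceye_config()) {
  ok <- is.finite(alpha_left) & is.finite(alpha_right)
  if (!any(ok))
    return(data.frame(timestamp = numeric(0), alpha_left = numeric(0),
                      alpha_right = numeric(0), delta = numeric(0),
                      baseline_delta = numeric(0), deviation = numeric(0),
                      misalignment_flag = logical(0)))
  ts <- timestamps[ok]
  delta <- alpha_left[ok] - alpha_right[ok]
  early <- ts <= ts[1] + config$alpha_baseline_s
  baseline <- median(delta[early])
  deviation <- abs(delta - baseline)
  data.frame(timestamp = ts, alpha_left = alpha_left[ok],
             alpha_right = alpha_right[ok], delta = delta,
             baseline_delta = baseline, deviation = deviation,
             misalignment_flag = deviation > config$alpha_dev_threshold)
}

#' Time-based ptosis grade (0--3)
#'
#' Grade from the droop-onset time on the sustained up-gaze exercise:
#' no onset (or onset beyond 45 s) is 0, onset in (10, 45] s is 1, onset in
#' (1, 10] s is 2, onset within 1 s is 3. Onset is conventionally the first
#' time the filtered normalized lid opening falls below `onset_frac` of its
#' initial value (see [droop_onset_time()]).
#'
#' @param onset seconds, or `NA`/`NULL` when no onset was observed.
#' @param series_duration seconds of usable series; a series shorter than
#'   45 s with no onset cannot certify grade 0 and returns `NA`.
#' @return Integer grade 0--3, or `NA` when unavailable.
#' @export
grade_ptosis_time <- function(onset, series_duration = 61) {
  if (is.null(onset) || is.na(onset)) {
    if (series_duration < 45) return(NA_integer_)
    return(0L)
  }
  if (onset > 45) 0L
  else if (onset > 10) 1L
  else if (onset > 1) 2L
  else 3L
}

#' Droop onset time from a filtered lid-opening series
#'
#' First time the filtered normalized lid opening falls below `onset_frac`
#' of its initial (first-sample) value.
#'
#' @param timestamps,values filtered series.
#' @param config an [mgceye_config()].
#' @return Onset time in seconds, or `NA` if the series never drops below.
#' @export
droop_onset_time <- function(timestamps, values, config = mgceye_config()) {
  ok <- is.finite(values)
  timestamps <- timestamps[ok]; values <- values[ok]
  if (!length(values)) return(NA_real_)
  thr <- config$onset_frac * values[1]
  k <- which(values < thr)
  if (!length(k)) NA_real_ else timestamps[min(k)]
}

#' Anatomic ptosis grade (0--3)
#'
#' Grade from the upper-lid margin position relative to the fitted iris
#' circle on a primary-gaze frame, with the pupil center approximated by the
#' iris-circle center: lid above the iris top is 0 (no ptosis); between the
#' iris top and a quarter-diameter above the center is 1 (mild, lid above
#' pupil); within a quarter-diameter of the center is 2 (moderate, lid at
#' pupil); below that is 3 (severe, lid below pupil).
#'
#' @param upper_lid_y upper-lid margin y (pixels, image-down).
#' @param iris_fit an [iris_circle_fit()] result.
#' @return Integer grade 0--3, or `NA` when the iris fit is unavailable.
#' @export
grade_ptosis_anatomic <- function(upper_lid_y, iris_fit) {
  if (!isTRUE(iris_fit$available)) return(NA_integer_)
  cy <- iris_fit$center[2]; q <- iris_fit$diameter / 4
  iris_top <- cy - iris_fit$radius
  if (upper_lid_y < iris_top) 0L
  else if (upper_lid_y < cy - q) 1L
  else if (upper_lid_y <= cy + q) 2L
  else 3L
}
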