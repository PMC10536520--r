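#' Specification of a synthetic eye clip
#'
#' Parameterizes a ground-truthed synthetic face-scale gray image sequence
#' emulating telehealth acquisition of the two ocular MG-CE exercises:
#' two eye regions (palpebral apertures bounded by parabolic lid curves,
#' an iris disk clipped to the aperture) on a flat skin background, with
#' three intensity classes, additive Gaussian noise, a linear illumination
#' ramp, programmed lid droop, gaze direction, blinks, lateral iris drift and
#' small per-frame head translation. Every frame carries exact ground truth:
#' interface curves, the 68-point landmark layout (with the per-eye hexagons),
#' and the derived metrics (ED, EL, area, alpha).
#'
#' @param image_size integer (height, width) of the frame in pixels.
#' @param eye_length horizontal corner-to-corner eye length EL in pixels.
#' @param lid_upper,lid_lower apex heights of the upper/lower lid parabolas
#'   above/below the corner line, pixels; the open-eye lid distance at the
#'   hexagon mid-landmarks is `8/9 * (lid_upper + lid_lower)`.
#' @param iris_radius iris radius in pixels.
#' @param gaze one of `"up"`, `"left"`, `"right"`, `"primary"`. Lateral gaze
#'   directions are expressed in image coordinates (the direction the iris
#'   moves along +/- x).
#' @param gaze_shift_frac lateral iris displacement for left/right gaze as a
#'   fraction of EL.
#' @param intensities named numeric: mean gray levels in `[0, 1]` for
#'   `skin`, `sclera`, `iris`; must satisfy `iris < sclera` and
#'   `|skin - sclera| >= contrast_margin`.
#' @param contrast_margin minimum skin/sclera contrast, gray-level units.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param illum_gradient linear illumination ramp along x, gray level per pixel.
#' @param droop_rate upper-lid droop speed in normalized-ED units per second
#'   (the apex moves down by `droop_rate * eye_length * t` pixels at time t).
#' @param iris_drift named numeric (right, left): lateral iris drift in px/s,
#'   used to program ocular misalignment ramps for the diplopia exercise.
#' @param blink_times seconds at which symmetric blinks are centered.
#' @param blink_duration full closure/reopen duration of a blink, seconds;
#'   recycled over `blink_times` so longer voluntary closures can be mixed
#'   with ordinary blinks.
#' @param head_jitter_sigma per-frame random whole-head translation, pixels.
#' @param duration clip length in seconds.
#' @param fps frames per second.
#' @param seed integer seed; frames are bit-identical for identical spec+seed.
#' @param eye_centers optional list with elements `right` and `left`, each an
#'   (x, y) eye center in pixels; defaults to a centered layout with an
#'   inter-ocular distance of twice the eye length.
#' @return An object of class `synthetic_eye_spec`.
#' @seealso [render_frame()], [render_sequence()], [synthetic_clip()]
#' @export
synthetic_eye_spec <- function(image_size = c(360, 640),
                               eye_length = 36,
                               lid_upper = 7,
                               lid_lower = 5,
                               iris_radius = 7,
                               gaze = c("up", "left", "right", "primary"),
                               gaze_shift_frac = 0.25,
                               intensities = c(skin = 0.55, sclera = 0.95, iris = 0.20),
                               contrast_margin = 0.2,
                               noise_sigma = 0.02,
                               illum_gradient = 0,
                               droop_rate = 0,
                               iris_drift = c(right = 0, left = 0),
                               blink_times = numeric(0),
                               blink_duration = 0.2,
                               head_jitter_sigma = 0,
                               duration = 61,
                               fps = 30,
                               seed = 1L,
                               eye_centers = NULL) {
  gaze <- match.arg(gaze)
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            eye_length > 0, lid_upper >= 0, lid_lower >= 0,
            lid_upper + lid_lower > 0, iris_radius > 0,
            duration > 0, fps > 0, blink_duration > 0)
  ints <- intensities
  stopifnot(all(c("skin", "sclera", "iris") %in% names(ints)),
            all(ints >= 0 & ints <= 1))
  if (ints[["iris"]] >= ints[["sclera"]])
    stop("intensities must satisfy iris < sclera")
  if (abs(ints[["skin"]] - ints[["sclera"]]) < contrast_margin)
    stop("skin/sclera contrast below the configured margin")
  if (is.null(eye_centers)) {
    cx <- image_size[2] / 2; cy <- image_size[1] * 0.42
    iod <- 2 * eye_length
    eye_centers <- list(right = c(cx - iod / 2, cy), left = c(cx + iod / 2, cy))
  }
  drift <- iris_drift
  if (is.null(names(drift))) names(drift) <- c("right", "left")
  structure(list(
    image_size = as.integer(image_size), eye_length = eye_length,
    lid_upper = lid_upper, lid_lower = lid_lower, iris_radius = iris_radius,
    gaze = gaze, gaze_shift_frac = gaze_shift_frac,
    intensities = ints, contrast_margin = contrast_margin,
    noise_sigma = noise_sigma, illum_gradient = illum_gradient,
    droop_rate = droop_rate, iris_drift = drift,
    blink_times = blink_times, blink_duration = blink_duration,
    head_jitter_sigma = head_jitter_sigma,
    duration = duration, fps = fps, seed = as.integer(seed),
    eye_centers = eye_centers
  ), class = "synthetic_eye_spec")
}

#' @export
print.synthetic_eye_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic eye clip: %ds @ %g FPS, %dx%d px, gaze=%s, EL=%g px, droop=%g ED/s, %d blink(s)\n",
    round(x$duration), x$fps, x$image_size[1], x$image_size[2], x$gaze,
    x$eye_length, x$droop_rate, length(x$blink_times)))
  invisible(x)
}

# Blink closure factor in [0, 1]: 1 = fully closed, triangular profile.
# blink_duration recycles over blink_times, so a long voluntary closure can
# be programmed alongside ordinary 0.2 s blinks.
blink_closure <- function(spec, t) {
  if (!length(spec$blink_times)) return(0)
  half <- rep_len(spec$blink_duration, length(spec$blink_times)) / 2
  d <- abs(t - spec$blink_times)
  max(c(0, (1 - d / half)[d < half]))
}

in_blink_window <- function(spec, t) {
  length(spec$blink_times) &&
    any(abs(t - spec$blink_times) <
          rep_len(spec$blink_duration, length(spec$blink_times)) / 2)
}

# Per-eye geometric state at time t (before rendering). jitter = c(dx, dy).
eye_state <- function(spec, t, side, jitter = c(0, 0)) {
  ec <- spec$eye_centers[[side]]
  xc <- ec[1] + jitter[1]; yc <- ec[2] + jitter[2]
  L <- spec$eye_length; halfL <- L / 2
  hu0 <- spec$lid_upper; hl0 <- spec$lid_lower
  # droop consumes the upper apex height, then any remainder the lower one
  droop_px <- spec$droop_rate * L * t
  hu <- hu0 - droop_px
  hl <- hl0
  if (hu < 0) { hl <- max(0, hl + hu); hu <- 0 }
  scale <- 1 - blink_closure(spec, t)
  hu <- hu * scale; hl <- hl * scale
  r <- spec$iris_radius
  shift <- spec$gaze_shift_frac * L
  drift <- spec$iris_drift[[side]] * t
  ic <- switch(spec$gaze,
    up      = c(xc, yc - hu0 + 0.3 * r),
    primary = c(xc, yc),
    left    = c(xc - shift + drift, yc),
    right   = c(xc + shift + drift, yc))
  list(side = side, xc = xc, yc = yc, L = L, halfL = halfL,
       hu = hu, hl = hl, iris = ic, r = r,
       open = (hu + hl) > 0.5)
}

eye_lid_y <- function(st, x, which = c("upper", "lower")) {
  which <- match.arg(which)
  u <- (x - st$xc) / st$halfL
  h <- if (which == "upper") -st$hu else st$hl
  st$yc + h * (1 - u^2)
}

# Hexagon vertices in 68-point annotation order.
# Right eye rows map to indices 37..42, left to 43..48:
#   corner(temporal-in-image-left), upper x -L/6, upper x +L/6,
#   corner(+L/2), lower x +L/6, lower x -L/6.
eye_hexagon_truth <- function(st) {
  xs <- st$xc + c(-st$halfL, -st$L / 6, st$L / 6, st$halfL, st$L / 6, -st$L / 6)
  ys <- c(st$yc,
          eye_lid_y(st, xs[2], "upper"), eye_lid_y(st, xs[3], "upper"),
          st$yc,
          eye_lid_y(st, xs[5], "lower"), eye_lid_y(st, xs[6], "lower"))
  cbind(x = xs, y = ys)
}

# Full 68-point layout: jaw/brows/nose/mouth placed parametrically around the
# eye centers so landmark-provider plumbing (face box, nares-confusion checks)
# can be exercised; eye points are the true hexagons.
face_landmarks_truth <- function(spec, t, jitter = c(0, 0)) {
  str <- eye_state(spec, t, "right", jitter)
  stl <- eye_state(spec, t, "left", jitter)
  mid <- c((str$xc + stl$xc) / 2, (str$yc + stl$yc) / 2)
  iod <- stl$xc - str$xc
  rel <- function(x, y) cbind(mid[1] + x * iod, mid[2] + y * iod)
  pts <- matrix(NA_real_, 68, 2)
  th <- seq(0, pi, length.out = 17)
  pts[1:17, ] <- rel(-0.95 * cos(th), 0.10 + 1.35 * sin(th))          # jaw
  bx <- seq(-0.75, -0.25, length.out = 5)
  pts[18:22, ] <- rel(bx, -0.35 - 0.08 * (1 - (4 * (bx + 0.5))^2))     # right brow
  pts[23:27, ] <- rel(-rev(bx), -0.35 - 0.08 * (1 - (4 * (rev(bx) + 0.5))^2))
  pts[28:31, ] <- rel(rep(0, 4), seq(-0.05, 0.45, length.out = 4))     # nose bridge
  pts[32:36, ] <- rel(seq(-0.15, 0.15, length.out = 5), 0.60)          # nose base / nares
  pts[37:42, ] <- eye_hexagon_truth(str)
  pts[43:48, ] <- eye_hexagon_truth(stl)
  phi <- seq(0, 2 * pi, length.out = 13)[-13]
  pts[49:60, ] <- rel(0.28 * cos(phi + pi), 0.95 + 0.14 * sin(phi + pi))  # outer lips
  phi2 <- seq(0, 2 * pi, length.out = 9)[-9]
  pts[61:68, ] <- rel(0.16 * cos(phi2 + pi), 0.95 + 0.07 * sin(phi2 + pi))
  colnames(pts) <- c("x", "y")
  pts
}

# Visible lateral iris boundary point and barycentric coordinate alpha for a
# lateral-gaze state: the trailing iris edge, measured from the anchor corner
# (the eye corner opposite the gaze direction), relative to EL.
alpha_truth <- function(st, gaze) {
  if (!gaze %in% c("left", "right") || !st$open) return(NA_real_)
  if (gaze == "left") {
    p_x <- st$iris[1] + st$r
    anchor <- st$xc + st$halfL
  } else {
    p_x <- st$iris[1] - st$r
    anchor <- st$xc - st$halfL
  }
  abs(p_x - anchor) / st$L
}

# Ground truth rows (one per eye) for a frame.
frame_truth <- function(spec, t, frame_index, jitter = c(0, 0)) {
  rows <- lapply(c("right", "left"), function(side) {
    st <- eye_state(spec, t, side, jitter)
    hx <- eye_hexagon_truth(st)
    ed <- (abs(hx[5, "y"] - hx[2, "y"]) + abs(hx[6, "y"] - hx[3, "y"])) / 2
    el <- abs(hx[4, "x"] - hx[1, "x"])
    area <- polygon_area(hx)
    ib <- st$iris[2] + st$r
    iris_bottom_visible <- st$open &&
      ib < eye_lid_y(st, st$iris[1], "lower") && ib > eye_lid_y(st, st$iris[1], "upper")
    data.frame(
      frame = frame_index, t = t, side = side,
      upper_lid_y = st$yc - st$hu, lower_lid_y = st$yc + st$hl,
      iris_bottom_y = if (iris_bottom_visible) ib else NA_real_,
      iris_x = st$iris[1], iris_y = st$iris[2], iris_r = st$r,
      ed = ed, el = el, area = area,
      ed_norm = ed / el, area_norm = area / el^2,
      alpha = alpha_truth(st, spec$gaze),
      open = st$open, blink = in_blink_window(spec, t),
      degenerate = !st$open && !in_blink_window(spec, t),
      jitter_x = jitter[1], jitter_y = jitter[2],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

draw_eye <- function(img, st, ints) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(1L, floor(st$xc - st$halfL - 3)); x1 <- min(w, ceiling(st$xc + st$halfL + 3))
  y0 <- max(1L, floor(st$yc - st$hu - st$r - 3)); y1 <- min(h, ceiling(st$yc + st$hl + 3))
  if (x1 <= x0 || y1 <= y0 || !st$open) return(img)
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  u <- (X - st$xc) / st$halfL
  inx <- abs(u) <= 1
  yu <- st$yc - st$hu * (1 - u^2)
  yl <- st$yc + st$hl * (1 - u^2)
  # 1-px linear edge coverage gives sub-pixel interface localization
  A <- clamp(Y - yu + 0.5, 0, 1) * clamp(yl - Y + 0.5, 0, 1) * inx
  d <- st$r + 0.5 - sqrt((X - st$iris[1])^2 + (Y - st$iris[2])^2)
  Ic <- clamp(d, 0, 1)
  val <- ints[["skin"]] * (1 - A) +
    A * ((1 - Ic) * ints[["sclera"]] + Ic * ints[["iris"]])
  img[ys, xs] <- val
  img
}

#' Render one synthetic frame with its ground truth
#'
#' Draws the two eye regions at time `t` (skin background, scleral aperture
#' between the lid curves, iris disk clipped to the aperture), then applies
#' the linear illumination ramp and additive Gaussian noise. Deterministic:
#' the per-frame noise/jitter stream is derived from the spec seed and the
#' frame index `round(t * fps)`.
#'
#' @param spec a [synthetic_eye_spec()].
#' @param t time in seconds, within `[0, duration]`.
#' @return A list with `image` (numeric matrix in `[0, 1]`, rows = y),
#'   `truth` (two-row data frame, one per eye, with true lid/iris positions,
#'   ED, EL, area, alpha and degeneracy flags) and `landmarks` (68 x 2 matrix).
#' @examples
#' sp <- synthetic_eye_spec(noise_sigma = 0, duration = 2)
#' fr <- render_frame(sp, 0)
#' fr$truth[, c("side", "ed", "el", "alpha")]
#' @export
render_frame <- function(spec, t) {
  stopifnot(inherits(spec, "synthetic_eye_spec"), t >= 0, t <= spec$duration)
  i <- round(t * spec$fps)
  rs <- frame_seed(spec$seed, i)
  jitter <- c(0, 0)
  noise <- NULL
  h <- spec$image_size[1]; w <- spec$image_size[2]
  if (spec$head_jitter_sigma > 0 || spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(rs)
    if (spec$head_jitter_sigma > 0)
      jitter <- rnorm(2, 0, spec$head_jitter_sigma)
    if (spec$noise_sigma > 0)
      noise <- matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
  }
  img <- matrix(spec$intensities[["skin"]], h, w)
  for (side in c("right", "left"))
    img <- draw_eye(img, eye_state(spec, t, side, jitter), spec$intensities)
  if (spec$illum_gradient != 0)
    img <- img + spec$illum_gradient *
      matrix(seq_len(w) - (w + 1) / 2, h, w, byrow = TRUE)
  if (!is.null(noise)) img <- img + noise
  img <- clamp(img, 0, 1)
  list(image = img,
       truth = frame_truth(spec, t, i, jitter),
       landmarks = face_landmarks_truth(spec, t, jitter))
}

#' Render a synthetic sequence
#'
#' Renders `duration * fps` frames (optionally subsampled) with a per-frame
#' ground-truth table and landmark history. Head jitter is drawn per frame and
#' applied to the whole facial geometry.
#'
#' @param spec a [synthetic_eye_spec()].
#' @param every optional sampling interval in seconds (one frame kept per
#'   `every` seconds); `NULL` keeps every frame.
#' @param dir optional directory: frames are written as 8-bit gray PNGs with a
#'   `manifest.csv` (file, frame, timestamp, fps), the ground truth as
#'   `truth.csv`, landmarks as `landmarks.csv` and the spec as `spec.yaml`;
#'   images are then not kept in memory.
#' @param keep_frames logical; keep rendered images in the returned list
#'   (ignored when `dir` is given).
#' @return A list with `truth` (data frame), `landmarks` (list of 68 x 2
#'   matrices), `timestamps`, `frames` (list of images or `NULL`), `dir`.
#' @export
render_sequence <- function(spec, every = NULL, dir = NULL, keep_frames = is.null(dir)) {
  stopifnot(spec$duration * spec$fps >= 1)
  n <- floor(spec$duration * spec$fps)
  idx <- 0:(n - 1)
  if (!is.null(every)) {
    stopifnot(every >= 1 / spec$fps)
    step <- max(1L, round(every * spec$fps))
    idx <- idx[idx %% step == 0]
  }
  ts <- idx / spec$fps
  frames <- if (is.null(dir) && keep_frames) vector("list", length(idx)) else NULL
  lms <- vector("list", length(idx))
  truths <- vector("list", length(idx))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(idx))
  for (k in seq_along(idx)) {
    fr <- render_frame(spec, ts[k])
    truths[[k]] <- fr$truth
    lms[[k]] <- fr$landmarks
    if (!is.null(dir)) {
      files[k] <- sprintf("frame_%06d.png", idx[k])
      png::writePNG(fr$image, file.path(dir, files[k]))
    } else if (keep_frames) frames[[k]] <- fr$image
  }
  truth <- do.call(rbind, truths)
  if (!is.null(dir)) {
    utils::write.csv(data.frame(file = files, frame = idx, timestamp = ts,
                                fps = spec$fps),
                     file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    write_landmarks_csv(lms, idx, ts, file.path(dir, "landmarks.csv"))
    yaml::write_yaml(spec_to_list(spec), file.path(dir, "spec.yaml"))
  }
  list(truth = truth, landmarks = lms, timestamps = ts, frame_index = idx,
       frames = frames, dir = dir)
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$intensities <- as.list(out$intensities)
  out$iris_drift <- as.list(out$iris_drift)
  out
}

#' Rebuild a synthetic spec from its YAML export
#' @param path path to a `spec.yaml` written by [render_sequence()].
#' @return A `synthetic_eye_spec`.
#' @export
read_synthetic_spec <- function(path) {
  v <- yaml::read_yaml(path)
  synthetic_eye_spec(
    image_size = unlist(v$image_size), eye_length = v$eye_length,
    lid_upper = v$lid_upper, lid_lower = v$lid_lower,
    iris_radius = v$iris_radius, gaze = v$gaze,
    gaze_shift_frac = v$gaze_shift_frac,
    intensities = unlist(v$intensities), contrast_margin = v$contrast_margin,
    noise_sigma = v$noise_sigma, illum_gradient = v$illum_gradient,
    droop_rate = v$droop_rate, iris_drift = unlist(v$iris_drift),
    blink_times = if (length(v$blink_times)) unlist(v$blink_times) else numeric(0),
    blink_duration = v$blink_duration,
    head_jitter_sigma = v$head_jitter_sigma,
    duration = v$duration, fps = v$fps, seed = v$seed,
    eye_centers = lapply(v$eye_centers, unlist))
}

#' Droop rate that yields a target relative lid-opening decay
#'
#' Converts a programmed relative decay of the lid-to-lid opening over a clip
#' (e.g. 0.15 for a 15% decay) into the `droop_rate` parameter of
#' [synthetic_eye_spec()] (normalized-ED units per second).
#'
#' @param decay relative decay of the initial lid opening over `duration`.
#' @param spec_args named list of the other spec arguments (needs
#'   `lid_upper`, `lid_lower`, `eye_length`, `duration` or their defaults).
#' @return droop_rate value.
#' @export
droop_rate_for_decay <- function(decay, spec_args = list()) {
  get_arg <- function(nm) {
    if (!is.null(spec_args[[nm]])) spec_args[[nm]]
    else formals(synthetic_eye_spec)[[nm]]
  }
  # relative decay of the lid opening is droop_px / (lid_upper + lid_lower);
  # the hexagon's 8/9 sampling factor cancels in the ratio
  h0 <- get_arg("lid_upper") + get_arg("lid_lower")
  decay * h0 / (get_arg("eye_length") * get_arg("duration"))
}
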