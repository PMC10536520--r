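# Gap-aware time-series assembly for the one-minute exercises: exercise
# window detection from the scleral position, frame rejection, linear
# interpolation of sub-second holes, identification of > 1 s gaps, spectral
# low-pass filtering of each contiguous segment, and least-squares trends.

#' Classify per-frame gaze from the scleral position
#'
#' Two-cluster labeling of the eye-hexagon interior into iris-like (dark)
#' and sclera-like (bright) pixels; the gaze label is the position of the
#' sclera-majority region relative to the iris: sclera below the iris means
#' up-gaze, sclera on the right means the iris is displaced left (gaze
#' "left"), and vice versa; near-balanced offsets are "primary".
#'
#' @param img frame image.
#' @param hex an `eye_hexagon`.
#' @param seed RNG seed for the clustering.
#' @param config an [mgceye_config()].
#' @return One of `"up"`, `"left"`, `"right"`, `"primary"`, `"unknown"`.
#' @export
classify_gaze <- function(img, hex, seed = 0L, config = mgceye_config()) {
  if (hex$degenerate) return("unknown")
  el <- eye_length(hex, config)
  if (el$under_resolved) return("unknown")
  bb <- hexagon_bbox(hex)
  b <- clip_rect_bounds(bb["x0"], bb["x1"] + 1, bb["y0"], bb["y1"] + 1, dim(img))
  if (b[2] - b[1] < 4 || b[4] - b[3] < 4) return("unknown")
  xs <- b[1]:(b[2] - 1L); ys <- b[3]:(b[4] - 1L)
  patch <- img[ys, xs, drop = FALSE]
  # keep only pixels inside the hexagon (point-in-polygon on the 6 vertices)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  inside <- point_in_polygon(X, Y, hex$vertices)
  v <- patch[inside]
  if (length(v) < 16 || diff(range(v)) < 1e-6) return("unknown")
  thr <- mean(stats::quantile(v, c(0.1, 0.9), names = FALSE))
  dark <- v < thr
  if (!any(dark) || all(dark)) return("unknown")
  dx <- mean(X[inside][!dark]) - mean(X[inside][dark])
  dy <- mean(Y[inside][!dark]) - mean(Y[inside][dark])
  eps <- 0.05 * el$el
  if (abs(dy) >= abs(dx) && dy > eps) return("up")
  if (abs(dx) > eps) return(if (dx > 0) "left" else "right")
  "primary"
}

point_in_polygon <- function(X, Y, vert) {
  n <- nrow(vert)
  inside <- matrix(FALSE, nrow(X), ncol(X))
  j <- n
  for (i in 1:n) {
    xi <- vert[i, 1]; yi <- vert[i, 2]
    xj <- vert[j, 1]; yj <- vert[j, 2]
    cross <- ((yi > Y) != (yj > Y)) &
      (X < (xj - xi) * (Y - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Detect the exercise time window from per-frame gaze labels
#'
#' Per-eye gaze labels are smoothed by a majority vote over
#' `vote_window_s`; frames where the two eyes disagree are excluded; the
#' window is the longest run of the expected label. A window shorter than
#' `window_min_s` is unavailable; one outside 40--80 s is flagged atypical
#' (the exercises nominally last 61 s).
#'
#' @param gaze_right,gaze_left character vectors of per-frame labels.
#' @param timestamps seconds.
#' @param expected expected label: `"up"` for the ptosis exercise, `"left"`
#'   or `"right"` for diplopia.
#' @param config an [mgceye_config()].
#' @return List `available`, `start`, `end`, `atypical`.
#' @export
detect_exercise_window <- function(gaze_right, gaze_left, timestamps, expected,
                                   config = mgceye_config()) {
  n <- length(timestamps)
  stopifnot(length(gaze_right) == n, length(gaze_left) == n)
  dt <- if (n > 1) median(diff(timestamps)) else 1
  k <- max(1L, round(config$vote_window_s / dt))
  smooth_vote <- function(g) {
    vapply(seq_len(n), function(i) {
      w <- g[max(1, i - k %/% 2):min(n, i + k %/% 2)]
      tt <- table(w)
      names(tt)[which.max(tt)]
    }, character(1))
  }
  gr <- smooth_vote(gaze_right); gl <- smooth_vote(gaze_left)
  match_flag <- gr == expected & gl == expected
  runs <- true_runs(match_flag)
  if (!nrow(runs))
    return(list(available = FALSE, start = NA_real_, end = NA_real_,
                atypical = NA))
  dur <- timestamps[runs$end] - timestamps[runs$start]
  b <- which.max(dur)
  if (dur[b] < config$window_min_s)
    return(list(available = FALSE, start = NA_real_, end = NA_real_,
                atypical = NA))
  list(available = TRUE, start = timestamps[runs$start[b]],
       end = timestamps[runs$end[b]],
       atypical = dur[b] < 40 || dur[b] > 80)
}

#' Annotate frames with rejection reasons
#'
#' Applies the per-frame validity checks in exclusive priority order:
#' `motion` (median landmark displacement between consecutive frames above
#' `motion_frac * EL`), `lighting` (any search rectangle failed the
#' connectedness hypothesis H4), `landmark_instability` (eye-hexagon
#' centroid jump above `instab_frac * EL` while the median face landmark
#' moves less than `face_still_frac * EL`), `blink` (frame inside a detected
#' blink event, widened by one frame).
#'
#' @param landmarks list of 68 x 2 matrices (or `NULL` for frames without
#'   landmarks, rejected as `no_landmarks`).
#' @param el per-frame eye length (pixels; a scalar is recycled).
#' @param blink_frames integer frame indices (1-based into the list) inside
#'   blink events.
#' @param lighting_bad logical per frame.
#' @param config an [mgceye_config()].
#' @return Character vector of reasons (`"none"` for usable frames).
#' @export
reject_frames <- function(landmarks, el, blink_frames = integer(0),
                          lighting_bad = NULL,
                          config = mgceye_config()) {
  n <- length(landmarks)
  el <- rep_len(el, n)
  if (is.null(lighting_bad)) lighting_bad <- rep(FALSE, n)
  blink_set <- unique(clamp(c(blink_frames - 1L, blink_frames, blink_frames + 1L), 1L, n))
  reasons <- rep("none", n)
  eye_centroid <- function(p) colMeans(p[37:48, , drop = FALSE])
  for (i in seq_len(n)) {
    if (is.null(landmarks[[i]])) { reasons[i] <- "no_landmarks"; next }
    if (i > 1 && !is.null(landmarks[[i - 1]])) {
      d <- sqrt(rowSums((landmarks[[i]] - landmarks[[i - 1]])^2))
      face_idx <- setdiff(1:68, 37:48)
      med_face <- median(d[face_idx])
      if (median(d) > config$motion_frac * el[i]) {
        reasons[i] <- "motion"; next
      }
      ec_jump <- sqrt(sum((eye_centroid(landmarks[[i]]) -
                             eye_centroid(landmarks[[i - 1]]))^2))
      if (lighting_bad[i]) { reasons[i] <- "lighting"; next }
      if (ec_jump > config$instab_frac * el[i] &&
          med_face < config$face_still_frac * el[i]) {
        reasons[i] <- "landmark_instability"; next
      }
    } else if (lighting_bad[i]) { reasons[i] <- "lighting"; next }
    if (i %in% blink_set) reasons[i] <- "blink"
  }
  reasons
}

#' Assemble a gap-aware measurement series
#'
#' Sorted valid samples on the native acquisition grid; holes of at most
#' `gap_max_s` are filled by linear interpolation (never outside the convex
#' hull of the bracketing samples); longer intervals are recorded as gaps
#' and left empty.
#'
#' @param timestamps acquisition-grid timestamps (all frames, seconds).
#' @param values per-frame values (`NA` for invalid/rejected frames).
#' @param channel channel name.
#' @param config an [mgceye_config()].
#' @return Object of class `measurement_series`: `channel`, `samples` (data
#'   frame timestamp, raw, value, in_gap), `gaps` (start, end), `filtered`
#'   (`NULL` until [filter_series()]), `trend` (`NULL` until [fit_trend()]).
#'   Fewer than 2 valid samples yields an empty series.
#' @export
assemble_series <- function(timestamps, values, channel = "value",
                            config = mgceye_config()) {
  o <- order(timestamps)
  timestamps <- timestamps[o]; values <- values[o]
  ok <- is.finite(values)
  empty <- structure(list(channel = channel,
                          samples = data.frame(timestamp = numeric(0),
                                               raw = numeric(0), value = numeric(0),
                                               in_gap = logical(0)),
                          gaps = data.frame(start = numeric(0), end = numeric(0)),
                          filtered = NULL, trend = NULL),
                     class = "measurement_series")
  if (sum(ok) < 2) return(empty)
  tv <- timestamps[ok]; vv <- values[ok]
  grid <- timestamps[timestamps >= tv[1] & timestamps <= tv[length(tv)]]
  # gaps: intervals between consecutive valid samples longer than gap_max_s
  dg <- diff(tv)
  gi <- which(dg > config$gap_max_s)
  gaps <- data.frame(start = tv[gi], end = tv[gi + 1])
  interp <- stats::approx(tv, vv, xout = grid)$y
  in_gap <- rep(FALSE, length(grid))
  if (nrow(gaps)) for (g in seq_len(nrow(gaps)))
    in_gap <- in_gap | (grid > gaps$start[g] & grid < gaps$end[g])
  interp[in_gap] <- NA_real_
  raw <- values[timestamps >= tv[1] & timestamps <= tv[length(tv)]]
  structure(list(channel = channel,
                 samples = data.frame(timestamp = grid, raw = raw,
                                      value = interp, in_gap = in_gap),
                 gaps = gaps, filtered = NULL, trend = NULL),
            class = "measurement_series")
}

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("measurement series '%s': %d samples, %d gap(s) > 1 s%s\n",
              x$channel, nrow(x$samples), nrow(x$gaps),
              if (!is.null(x$trend))
                sprintf(", trend slope %.3f", x$trend["slope"]) else ""))
  invisible(x)
}

# Low-pass one uniformly-sampled segment: remove the line through the
# segment endpoints, extend the residual to twice the length by point
# reflection (odd symmetry; the residual vanishes at both ends, so the
# extension is periodic and C1-continuous, removing the periodicity mismatch
# without spectral leakage into the passband), apply a sharp cutoff at fc,
# invert, truncate and add the line back. Pure linear trends pass exactly.
lowpass_segment <- function(t, v, fc) {
  n <- length(v)
  if (n < 4) return(v)
  dt <- (t[n] - t[1]) / (n - 1)
  tg <- seq(t[1], t[n], length.out = n)
  vg <- stats::approx(t, v, xout = tg)$y
  slope <- (vg[n] - vg[1]) / (tg[n] - tg[1])
  line <- vg[1] + slope * (tg - tg[1])
  r <- vg - line
  z <- c(r, -r[(n - 1):2])
  N <- length(z)
  Z <- stats::fft(z)
  freq <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1)) / (N * dt)
  Z[abs(freq) > fc] <- 0
  sm <- Re(stats::fft(Z, inverse = TRUE)) / N
  out <- sm[1:n] + line
  stats::approx(tg, out, xout = t)$y
}

#' Low-pass filter a measurement series
#'
#' Each contiguous (non-gap) segment spanning at least `min_segment_s` is
#' resampled uniformly at its mean frame rate, linearly detrended (line
#' through its endpoints), mirror-extended to twice its length by point
#' reflection (making the extension periodic without a boundary mismatch),
#' transformed to the frequency domain, sharply low-passed at `fc_hz`,
#' inverted, truncated to its original support and re-trended. Linear
#' trends pass through unchanged; gaps are never bridged. Shorter segments
#' are passed through unfiltered and flagged.
#'
#' @param series a `measurement_series`.
#' @param config an [mgceye_config()].
#' @return The series with a `filtered` column added to `samples` and a
#'   `short_segments` count.
#' @export
filter_series <- function(series, config = mgceye_config()) {
  s <- series$samples
  filt <- rep(NA_real_, nrow(s))
  short <- 0L
  if (nrow(s)) {
    seg_flag <- !s$in_gap & is.finite(s$value)
    runs <- true_runs(seg_flag)
    for (k in seq_len(nrow(runs))) {
      i <- runs$start[k]:runs$end[k]
      span <- s$timestamp[runs$end[k]] - s$timestamp[runs$start[k]]
      if (span < config$min_segment_s) {
        filt[i] <- s$value[i]
        short <- short + 1L
      } else {
        filt[i] <- lowpass_segment(s$timestamp[i], s$value[i], config$fc_hz)
      }
    }
  }
  series$samples$filtered <- filt
  series$short_segments <- short
  series
}

#' Least-squares trend of a filtered series
#'
#' Ordinary least squares of the filtered values against time normalized to
#' `[0, 1]` over the exercise window, fitted on the non-gap support only, so
#' the slope equals the total change over the exercise in the channel's
#' units. Requires at least 10 samples spanning at least half the window.
#'
#' @param series a filtered `measurement_series`.
#' @param window optional `c(start, end)` seconds; defaults to the series
#'   extent.
#' @return The series with `trend = c(intercept, slope)` (NA when the
#'   support is insufficient).
#' @export
fit_trend <- function(series, window = NULL) {
  s <- series$samples
  y <- if (!is.null(s$filtered)) s$filtered else s$value
  ok <- is.finite(y) & !s$in_gap
  if (is.null(window))
    window <- range(s$timestamp[ok], na.rm = TRUE)
  span <- diff(window)
  tn <- (s$timestamp - window[1]) / span
  use <- ok & tn >= 0 & tn <= 1
  if (sum(use) < 10 ||
      diff(range(tn[use])) < 0.5) {
    series$trend <- c(intercept = NA_real_, slope = NA_real_)
    return(series)
  }
  cf <- stats::lm.fit(cbind(1, tn[use]), y[use])$coefficients
  series$trend <- c(intercept = unname(cf[1]), slope = unname(cf[2]))
  series
}
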