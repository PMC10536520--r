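# Landmark-only first-approximation ptosis metrics: eyelid distance (ED),
# eye area and eye length (EL), all computed from the 6-vertex eye hexagon,
# plus blink identification from the ED time series. ED and area are reported
# normalized by EL (resp. EL^2) so they are quasi-invariant to small head
# motion and to image resolution.

# vertex rows within a hexagon for the annotation indices
hex_row <- function(hex, index) match(index, hex$indices)

#' Eyelid distance from an eye hexagon
#'
#' Mean of the two vertical distances between the paired upper- and lower-lid
#' landmark points of the hexagon: indices 38/41 and 39/42 for the right eye,
#' 44/48 and 45/47 for the left eye.
#'
#' @param hex an `eye_hexagon`.
#' @return Distance in pixels, or `NA` for a degenerate hexagon.
#' @export
eyelid_distance <- function(hex) {
  if (hex$degenerate) return(NA_real_)
  y <- hex$vertices[, 2]
  if (hex$side == "right") {
    pairs <- rbind(c(hex_row(hex, 38), hex_row(hex, 41)),
                   c(hex_row(hex, 39), hex_row(hex, 42)))
  } else {
    pairs <- rbind(c(hex_row(hex, 44), hex_row(hex, 48)),
                   c(hex_row(hex, 45), hex_row(hex, 47)))
  }
  mean(abs(y[pairs[, 2]] - y[pairs[, 1]]))
}

#' Eye length from an eye hexagon
#'
#' Horizontal distance between the two corner landmarks (37/40 right,
#' 43/46 left).
#'
#' @param hex an `eye_hexagon`.
#' @param config an [mgceye_config()]; `el_min_px` flags under-resolved eyes.
#' @return List with `el` (pixels, `NA` if degenerate) and `under_resolved`.
#' @export
eye_length <- function(hex, config = mgceye_config()) {
  if (hex$degenerate) return(list(el = NA_real_, under_resolved = TRUE))
  x <- hex$vertices[, 1]
  corners <- if (hex$side == "right") c(37, 40) else c(43, 46)
  el <- abs(x[hex_row(hex, corners[2])] - x[hex_row(hex, corners[1])])
  list(el = el, under_resolved = el < config$el_min_px)
}

# TRUE when any two non-adjacent edges of the closed 6-vertex outline cross.
hexagon_self_intersects <- function(v) {
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  n <- nrow(v)
  for (i in 1:n) for (j in 1:n) {
    if (j <= i + 1 || (i == 1 && j == n)) next
    if (seg_int(v[i, ], v[i %% n + 1, ], v[j, ], v[j %% n + 1, ])) return(TRUE)
  }
  FALSE
}

#' Eye area from an eye hexagon
#'
#' Shoelace area of the ordered 6-vertex outline; orientation independent.
#'
#' @param hex an `eye_hexagon`.
#' @return Area in pixels squared; `NA` when the outline self-intersects or
#'   the hexagon is degenerate beyond a line (a zero-area outline returns 0).
#' @export
eye_area <- function(hex) {
  v <- hex$vertices
  if (hexagon_self_intersects(v)) return(NA_real_)
  polygon_area(v)
}

#' All coarse metrics for one eye
#'
#' @param hex an `eye_hexagon`.
#' @param config an [mgceye_config()].
#' @return List with `side`, `ed`, `el`, `area`, `ed_norm`, `area_norm`,
#'   `under_resolved`, `available`.
#' @export
coarse_eye_metrics <- function(hex, config = mgceye_config()) {
  ed <- eyelid_distance(hex)
  elr <- eye_length(hex, config)
  area <- if (hex$degenerate) NA_real_ else eye_area(hex)
  ok <- !is.na(ed) && !is.na(elr$el) && !elr$under_resolved
  list(side = hex$side, ed = ed, el = elr$el, area = area,
       ed_norm = if (ok) ed / elr$el else NA_real_,
       area_norm = if (ok && !is.na(area)) area / elr$el^2 else NA_real_,
       under_resolved = elr$under_resolved, available = ok)
}

#' Identify blinks in an eyelid-distance series
#'
#' A blink is a maximal run of frames where ED drops below a fraction
#' (default 0.5) of a rolling baseline (rolling median over 2 s), lasting at
#' most `blink_max_s`; single-frame dips count. Longer closures are voluntary
#' eye closure, not blinks, and are not returned as events.
#'
#' @param ed numeric ED per frame (NA allowed for invalid frames).
#' @param timestamps seconds, same length, increasing.
#' @param config an [mgceye_config()].
#' @return List with `events` (data frame `start`, `end`, `start_index`,
#'   `end_index` in seconds/frames) and `rate_per_min`.
#' @export
detect_blinks <- function(ed, timestamps, config = mgceye_config()) {
  n <- length(ed)
  stopifnot(length(timestamps) == n)
  if (n < 2 || all(is.na(ed)))
    return(list(events = data.frame(start = numeric(0), end = numeric(0),
                                    start_index = integer(0), end_index = integer(0)),
                rate_per_min = 0))
  dt <- median(diff(timestamps))
  if ((timestamps[n] - timestamps[1]) < 1) stop("need at least 1 s of frames")
  filled <- ed
  filled[is.na(filled)] <- median(ed, na.rm = TRUE)
  k <- max(3L, round(config$blink_baseline_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  k <- min(k, if (n %% 2 == 1) n else n - 1L)
  baseline <- stats::runmed(filled, k, endrule = "median")
  low <- !is.na(ed) & ed < config$blink_frac * baseline
  # frames with no ED (fully closed eye degenerates the hexagon) bridge a
  # dip when adjacent to low frames, so one blink is not split in two
  cand <- low | is.na(ed)
  runs <- true_runs(cand)
  if (nrow(runs))
    runs <- runs[vapply(seq_len(nrow(runs)),
                        function(i) any(low[runs$start[i]:runs$end[i]]),
                        logical(1)), , drop = FALSE]
  if (!nrow(runs))
    return(list(events = data.frame(start = numeric(0), end = numeric(0),
                                    start_index = integer(0), end_index = integer(0)),
                rate_per_min = 0))
  dur <- timestamps[runs$end] - timestamps[runs$start] + dt
  keep <- dur <= config$blink_max_s
  events <- data.frame(start = timestamps[runs$start[keep]],
                       end = timestamps[runs$end[keep]],
                       start_index = runs$start[keep],
                       end_index = runs$end[keep])
  total_s <- timestamps[n] - timestamps[1] + dt
  list(events = events, rate_per_min = nrow(events) / total_s * 60)
}
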