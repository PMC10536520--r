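#' Construct a 68-point landmark set
#'
#' Container for one frame's facial landmarks in the standard 68-point
#' annotation (1-based indices; the right-eye hexagon is points 37--42 and the
#' left-eye hexagon 43--48). Coordinates are continuous pixels, origin
#' top-left, x rightward, y downward.
#'
#' @param points 68 x 2 numeric matrix (x, y).
#' @param frame_index integer frame number.
#' @param timestamp seconds.
#' @param source `"external_model"` or `"fixture"`.
#' @param image_size optional (height, width); points outside the image mark
#'   the set invalid.
#' @return An object of class `landmark_set` with a `valid` flag.
#' @export
landmark_set <- function(points, frame_index = 0L, timestamp = 0,
                         source = c("fixture", "external_model"),
                         image_size = NULL) {
  source <- match.arg(source)
  points <- as.matrix(points)
  stopifnot(nrow(points) == 68, ncol(points) == 2)
  colnames(points) <- c("x", "y")
  valid <- all(is.finite(points))
  if (valid && !is.null(image_size))
    valid <- all(points[, 1] >= 1 & points[, 1] <= image_size[2] &
                 points[, 2] >= 1 & points[, 2] <= image_size[1])
  structure(list(points = points, frame_index = as.integer(frame_index),
                 timestamp = timestamp, source = source, valid = valid),
            class = "landmark_set")
}

#' Landmark providers
#'
#' A provider maps a frame to a [landmark_set()] or `NULL` (no face found).
#' `fixture_landmark_provider` replays precomputed (typically synthetic
#' ground-truth) landmarks by frame index, with an optional additive bias to
#' emulate systematic provider error (e.g. lower-lid points sitting below the
#' true contour). `external_landmark_provider` adapts a user function (e.g. a
#' wrapper around an external face-landmark model) returning a 68 x 2 matrix
#' or `NULL`.
#'
#' @param landmarks list of 68 x 2 matrices, one per frame.
#' @param frame_index integer vector matching `landmarks`.
#' @param timestamps numeric vector matching `landmarks`.
#' @param bias optional perturbation: a 68 x 2 matrix added to every frame's
#'   points, or a list `list(indices =, offset = c(dx, dy))` applied to the
#'   given 1-based indices only.
#' @param fn function(image) -> 68 x 2 matrix or `NULL`.
#' @return A provider object for [provide_landmarks()].
#' @export
fixture_landmark_provider <- function(landmarks, frame_index = seq_along(landmarks) - 1L,
                                      timestamps = NULL, bias = NULL) {
  stopifnot(length(landmarks) == length(frame_index))
  if (is.null(timestamps)) timestamps <- as.numeric(frame_index)
  structure(list(landmarks = landmarks, frame_index = as.integer(frame_index),
                 timestamps = timestamps, bias = bias),
            class = c("fixture_landmark_provider", "landmark_provider"))
}

#' @rdname fixture_landmark_provider
#' @export
external_landmark_provider <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn),
            class = c("external_landmark_provider", "landmark_provider"))
}

#' Acquire landmarks for a frame
#'
#' @param provider a landmark provider.
#' @param frame image matrix (may be ignored by fixture providers).
#' @param frame_index integer frame number used for fixture lookup.
#' @param timestamp seconds.
#' @param image_size optional (height, width) for the bounds validity check.
#' @return A [landmark_set()] or `NULL` when no face is found. A missing or
#'   non-functional provider is a configuration error (distinct from "no face
#'   found").
#' @export
provide_landmarks <- function(provider, frame = NULL, frame_index = 0L,
                              timestamp = NA_real_, image_size = NULL) {
  if (is.null(provider) || !inherits(provider, "landmark_provider"))
    stop("no landmark provider configured")
  UseMethod("provide_landmarks")
}

#' @export
provide_landmarks.fixture_landmark_provider <- function(provider, frame = NULL,
                                                        frame_index = 0L,
                                                        timestamp = NA_real_,
                                                        image_size = NULL) {
  k <- match(as.integer(frame_index), provider$frame_index)
  if (is.na(k)) return(NULL)
  pts <- provider$landmarks[[k]]
  if (!is.null(provider$bias)) {
    if (is.matrix(provider$bias)) {
      pts <- pts + provider$bias
    } else {
      idx <- provider$bias$indices
      pts[idx, ] <- sweep(pts[idx, , drop = FALSE], 2, provider$bias$offset, "+")
    }
  }
  ts <- if (is.na(timestamp)) provider$timestamps[k] else timestamp
  landmark_set(pts, frame_index, ts, source = "fixture", image_size = image_size)
}

#' @export
provide_landmarks.external_landmark_provider <- function(provider, frame = NULL,
                                                         frame_index = 0L,
                                                         timestamp = NA_real_,
                                                         image_size = NULL) {
  if (is.null(frame)) stop("external provider needs the frame image")
  pts <- provider$fn(frame)
  if (is.null(pts)) return(NULL)
  if (is.null(image_size)) image_size <- dim(frame)[1:2]
  landmark_set(pts, frame_index, timestamp, source = "external_model",
               image_size = image_size)
}

# 1-based annotation indices of the two eye hexagons.
eye_indices <- function(side) if (side == "right") 37:42 else 43:48

#' Extract the per-eye hexagon ROIs
#'
#' The right-eye hexagon is formed by annotation points 37--42, the left-eye
#' one by 43--48, kept in annotation order (corner, two upper-lid points,
#' corner, two lower-lid points). A hexagon is flagged degenerate when any two
#' of its vertices coincide within 1 px (the "pentagon" failure mode of
#' landmark models on narrow eyes).
#'
#' @param lm a valid [landmark_set()].
#' @return A list with elements `right` and `left`, each of class
#'   `eye_hexagon` with fields `side`, `vertices` (6 x 2), `indices`,
#'   `degenerate`.
#' @export
extract_eye_hexagons <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"), lm$valid)
  mk <- function(side) {
    idx <- eye_indices(side)
    v <- lm$points[idx, , drop = FALSE]
    d <- as.matrix(dist(v))
    degenerate <- any(d[upper.tri(d)] < 1)
    structure(list(side = side, vertices = v, indices = idx,
                   degenerate = degenerate),
              class = "eye_hexagon")
  }
  list(right = mk("right"), left = mk("left"))
}

hexagon_center <- function(hex) colMeans(hex$vertices)

hexagon_bbox <- function(hex, pad = 0) {
  v <- hex$vertices
  c(x0 = min(v[, 1]) - pad, x1 = max(v[, 1]) + pad,
    y0 = min(v[, 2]) - pad, y1 = max(v[, 2]) + pad)
}

#' Face box from a landmark set
#'
#' When the provider supplies landmarks without a detector face box, the face
#' box is taken as the landmark bounding box inflated by a fraction.
#'
#' @param lm a [landmark_set()].
#' @param inflate fractional inflation of each dimension.
#' @return Named vector `c(x0, y0, x1, y1)`.
#' @export
landmark_face_box <- function(lm, inflate = 0.2) {
  p <- lm$points
  w <- diff(range(p[, 1])); h <- diff(range(p[, 2]))
  c(x0 = min(p[, 1]) - inflate / 2 * w, y0 = min(p[, 2]) - inflate / 2 * h,
    x1 = max(p[, 1]) + inflate / 2 * w, y1 = max(p[, 2]) + inflate / 2 * h)
}

#' Sanity-check the located eyes against the face box
#'
#' Guards against gross mislocalization of the eye ROIs (e.g. a landmark
#' model latching onto the nares): the eyes must sit in the upper half of the
#' face box, the inter-ocular distance must be a plausible fraction of the
#' face-box width, and the inter-ocular line must be near horizontal.
#'
#' @param hexes list with `right` and `left` [extract_eye_hexagons()] output.
#' @param face_box `c(x0, y0, x1, y1)`.
#' @param config an [mgceye_config()] (thresholds `iod_min_frac`,
#'   `iod_max_frac`, `tilt_max_deg`).
#' @return List `valid` (logical) and `reason` (`"ok"`, `"below mid-face"`,
#'   `"implausible inter-ocular distance"`, `"tilted inter-ocular line"`).
#' @export
validate_eye_localization <- function(hexes, face_box, config = mgceye_config()) {
  cr <- hexagon_center(hexes$right); cl <- hexagon_center(hexes$left)
  mid_y <- (face_box["y0"] + face_box["y1"]) / 2
  if (cr[2] > mid_y && cl[2] > mid_y)
    return(list(valid = FALSE, reason = "below mid-face"))
  fw <- face_box["x1"] - face_box["x0"]
  iod <- sqrt(sum((cr - cl)^2))
  if (iod < config$iod_min_frac * fw || iod > config$iod_max_frac * fw)
    return(list(valid = FALSE, reason = "implausible inter-ocular distance"))
  ang <- abs(atan2(cl[2] - cr[2], cl[1] - cr[1])) * 180 / pi
  ang <- min(ang, 180 - ang)
  if (ang > config$tilt_max_deg)
    return(list(valid = FALSE, reason = "tilted inter-ocular line"))
  list(valid = TRUE, reason = "ok")
}

#' Landmark CSV I/O
#'
#' One row per frame: `frame_index`, `timestamp`, then `x1,y1,...,x68,y68`
#' (continuous pixel coordinates).
#'
#' @param landmarks list of 68 x 2 matrices.
#' @param frame_index,timestamps vectors matching `landmarks`.
#' @param path CSV file path.
#' @return `write_landmarks_csv`: the path, invisibly. `read_landmarks_csv`:
#'   a list with `landmarks`, `frame_index`, `timestamps`.
#' @export
write_landmarks_csv <- function(landmarks, frame_index, timestamps, path) {
  m <- t(vapply(landmarks, function(p) as.vector(t(p)), numeric(136)))
  colnames(m) <- as.vector(rbind(paste0("x", 1:68), paste0("y", 1:68)))
  df <- data.frame(frame_index = frame_index, timestamp = timestamps, m)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path)
  lms <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, -(1:2)])
    matrix(v, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  })
  list(landmarks = lms, frame_index = df$frame_index, timestamps = df$timestamp)
}
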