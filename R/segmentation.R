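# Local, hypothesis-validated interface segmentation. Each anatomic interface
# (upper lid, lower lid, iris bottom, lateral iris boundary) is recovered
# inside a small rectangle anchored at landmark positions: the patch is
# contrast-stretched, partitioned into two intensity clusters, the cluster
# boundary converted to a single-valued interface curve, refined by an open
# active contour maximizing the image gradient, and accepted only when the
# hypotheses hold: the curve is smooth (H1), crosses the rectangle fully
# (H2), iris arcs have the right convexity (H3), and both clusters are
# connected regions (H4). On failure the clustering is re-seeded, then the
# rectangle shrunk about its anchor, until acceptance or exhaustion.

#' Search rectangle for one interface
#'
#' Integer half-open pixel rectangle `[x0, x1) x [y0, y1)` with its target
#' interface, crossing axis (horizontal for lid/iris-bottom interfaces,
#' vertical for the lateral iris boundary), anchor point (the landmark
#' location shrinking contracts towards) and shrink level.
#'
#' @param x0,x1,y0,y1 integer bounds, half-open.
#' @param target one of `"lower_lid"`, `"upper_lid"`, `"iris_bottom"`,
#'   `"iris_lateral"`.
#' @param anchor numeric (x, y) anchor.
#' @param gaze for `iris_lateral`: `"left"` or `"right"` (image-frame gaze
#'   direction), used by the convexity hypothesis.
#' @param shrink_level integer >= 0.
#' @return Object of class `search_rectangle`.
#' @export
search_rectangle <- function(x0, x1, y0, y1,
                             target = c("lower_lid", "upper_lid",
                                        "iris_bottom", "iris_lateral"),
                             anchor = c((x0 + x1) / 2, (y0 + y1) / 2),
                             gaze = NULL, shrink_level = 0L) {
  target <- match.arg(target)
  stopifnot(x1 - x0 >= 4, y1 - y0 >= 4)
  axis <- if (target == "iris_lateral") "vertical" else "horizontal"
  structure(list(x0 = as.integer(x0), x1 = as.integer(x1),
                 y0 = as.integer(y0), y1 = as.integer(y1),
                 # continuous bounds carried so repeated shrinking is strictly
                 # monotone (integer bounds alone stall under rounding)
                 bx0 = as.numeric(x0), bx1 = as.numeric(x1),
                 by0 = as.numeric(y0), by1 = as.numeric(y1),
                 target = target, crossing_axis = axis, anchor = anchor,
                 gaze = gaze, shrink_level = as.integer(shrink_level)),
            class = "search_rectangle")
}

rect_width <- function(r) r$x1 - r$x0
rect_height <- function(r) r$y1 - r$y0

clip_rect_bounds <- function(x0, x1, y0, y1, image_size) {
  c(max(1L, floor(x0)), min(image_size[2] + 1L, ceiling(x1)),
    max(1L, floor(y0)), min(image_size[1] + 1L, ceiling(y1)))
}

#' Build the search rectangles for one eye
#'
#' For the ptosis exercise: a lower-lid rectangle around the two lower-lid
#' landmarks padded vertically by `pad_frac * EL`, an upper-lid rectangle
#' around the two upper-lid landmarks with the same padding, and an
#' iris-bottom rectangle spanning the x-range of the upper-lid landmarks and
#' the y-range from the upper-lid to the lower-lid landmarks. For the
#' diplopia exercise: the two lid rectangles plus a lateral-iris box drawn
#' from the corner landmark opposite the gaze direction to the upper/lower
#' lid landmarks on the gaze side. Rectangles are clipped to the image;
#' rectangles clipped below the minimum size are omitted (with a reason
#' attribute `omitted`).
#'
#' @param hex an `eye_hexagon` (non-degenerate).
#' @param exercise `"ptosis"` or `"diplopia"`.
#' @param gaze image-frame gaze direction for diplopia (`"left"`/`"right"`).
#' @param image_size (height, width) in pixels.
#' @param config an [mgceye_config()].
#' @return Named list of `search_rectangle`s (subset of `lower_lid`,
#'   `upper_lid`, `iris_bottom`, `iris_lateral`).
#' @export
build_rectangles <- function(hex, exercise = c("ptosis", "diplopia"),
                             gaze = NULL, image_size,
                             config = mgceye_config()) {
  exercise <- match.arg(exercise)
  stopifnot(!hex$degenerate)
  el <- eye_length(hex, config)
  stopifnot(!el$under_resolved)
  pad <- config$pad_frac * el$el
  v <- hex$vertices
  row_of <- function(i) v[hex_row(hex, i), ]
  if (hex$side == "right") {
    corners <- list(left = row_of(37), right = row_of(40))
    upper <- rbind(row_of(38), row_of(39))   # x order: -L/6, +L/6
    lower <- rbind(row_of(42), row_of(41))
  } else {
    corners <- list(left = row_of(43), right = row_of(46))
    upper <- rbind(row_of(44), row_of(45))
    lower <- rbind(row_of(48), row_of(47))
  }
  omitted <- character(0)
  rects <- list()
  add_rect <- function(name, x0, x1, y0, y1, target, anchor, gaze = NULL) {
    b <- clip_rect_bounds(x0, x1, y0, y1, image_size)
    if (b[2] - b[1] < config$min_rect_px || b[4] - b[3] < config$min_rect_px) {
      omitted <<- c(omitted, name)
      return(invisible())
    }
    rects[[name]] <<- search_rectangle(b[1], b[2], b[3], b[4], target,
                                       anchor = anchor, gaze = gaze)
  }
  xr_upper <- range(upper[, 1])
  add_rect("lower_lid",
           min(lower[, 1]), max(lower[, 1]) + 1,
           min(lower[, 2]) - pad, max(lower[, 2]) + pad + 1,
           "lower_lid", anchor = colMeans(lower))
  add_rect("upper_lid",
           xr_upper[1], xr_upper[2] + 1,
           min(upper[, 2]) - pad, max(upper[, 2]) + pad + 1,
           "upper_lid", anchor = colMeans(upper))
  if (exercise == "ptosis") {
    add_rect("iris_bottom",
             xr_upper[1], xr_upper[2] + 1,
             min(upper[, 2]), max(lower[, 2]) + 1,
             "iris_bottom",
             anchor = c(mean(xr_upper), (min(upper[, 2]) + max(lower[, 2])) / 2))
  } else {
    if (is.null(gaze)) stop("diplopia rectangles need a gaze direction")
    if (gaze == "left") {       # iris displaced towards -x; anchor = +x corner
      corner <- corners$right
      opp_upper <- upper[1, ]; opp_lower <- lower[1, ]
    } else {
      corner <- corners$left
      opp_upper <- upper[2, ]; opp_lower <- lower[2, ]
    }
    # the box runs from the anchor corner to the opposite-side lid landmarks;
    # the visible lateral iris boundary sits near the latter, inside the
    # aperture, so shrinking anchors there (at the eye-center row, where the
    # aperture is widest), not at the corner
    add_rect("iris_lateral",
             min(corner[1], opp_upper[1]), max(corner[1], opp_upper[1]) + 1,
             min(opp_upper[2], opp_lower[2]), max(opp_upper[2], opp_lower[2]) + 1,
             "iris_lateral",
             anchor = c((opp_upper[1] + opp_lower[1]) / 2, corner[2]),
             gaze = gaze)
  }
  attr(rects, "omitted") <- omitted
  rects
}

extract_patch <- function(img, rect) {
  img[rect$y0:(rect$y1 - 1L), rect$x0:(rect$x1 - 1L), drop = FALSE]
}

#' Percentile contrast stretch of a patch
#'
#' Rescales the 1st--99th intensity percentiles (configurable) to `[0, 1]`,
#' clamping the tails; a constant patch is returned unchanged with attribute
#' `zero_dynamic_range = TRUE`.
#'
#' @param patch numeric image matrix.
#' @param config an [mgceye_config()].
#' @return Stretched patch in `[0, 1]`.
#' @export
enhance_contrast <- function(patch, config = mgceye_config()) {
  stopifnot(nrow(patch) >= 4, ncol(patch) >= 4)
  q <- stats::quantile(patch, c(config$stretch_lo, config$stretch_hi),
                       names = FALSE)
  if (q[2] - q[1] < 1e-12) {
    attr(patch, "zero_dynamic_range") <- TRUE
    return(patch)
  }
  out <- clamp((patch - q[1]) / (q[2] - q[1]), 0, 1)
  attr(out, "zero_dynamic_range") <- FALSE
  out
}

#' Two-cluster intensity partition of a patch
#'
#' Lloyd k-means on the pixel intensities with two clusters, from a seeded
#' initialization (two intensity quantiles drawn from the seeded RNG), so the
#' partition is deterministic for a fixed seed. Label 1 is always the darker
#' cluster. The separation score is the centroid distance divided by the
#' pooled within-cluster standard deviation.
#'
#' @param patch enhanced image patch (>= 16 px).
#' @param seed integer RNG seed for the initialization.
#' @param config an [mgceye_config()].
#' @return List `labels` (integer matrix of 1/2), `centers` (sorted),
#'   `separation`, `ok` (FALSE with `reason = "contrast"` for a
#'   zero-dynamic-range patch).
#' @export
segment_two_cluster <- function(patch, seed = 0L, config = mgceye_config()) {
  stopifnot(length(patch) >= 16)
  v <- as.vector(patch)
  if (diff(range(v)) < 1e-12 || isTRUE(attr(patch, "zero_dynamic_range")))
    return(list(labels = NULL, centers = NULL, separation = 0,
                ok = FALSE, reason = "contrast"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% 2147483647L)
  qs <- sort(stats::runif(2))
  centers <- stats::quantile(v, qs, names = FALSE)
  if (diff(centers) < 1e-9) centers <- range(v)
  km <- stats::kmeans(v, centers = matrix(centers), iter.max = 100,
                      algorithm = "Lloyd")
  lab <- km$cluster
  if (km$centers[1] > km$centers[2]) lab <- 3L - lab
  centers <- sort(as.vector(km$centers))
  pooled <- sqrt(km$tot.withinss / length(v))
  separation <- if (pooled < 1e-12) Inf else diff(centers) / pooled
  list(labels = matrix(lab, nrow(patch), ncol(patch)),
       centers = centers, separation = separation, ok = TRUE, reason = "none")
}

# 3x3 majority filter on a 1/2 label field (border pixels use the available
# neighborhood). Suppresses salt noise without moving interfaces > 0.5 px.
majority_filter <- function(lab) {
  b <- (lab == 2L) + 0
  h <- nrow(b); w <- ncol(b)
  pad <- matrix(NA_real_, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- b
  s <- matrix(0, h, w); n <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2) {
    blk <- pad[dy + 1:h, dx + 1:w]
    ok <- !is.na(blk)
    s <- s + ifelse(ok, blk, 0)
    n <- n + ok
  }
  ifelse(s / n > 0.5, 2L, 1L)
}

#' Interface curve object
#'
#' A single-valued pixel polyline separating two regions inside a rectangle:
#' one sub-pixel interface coordinate per column (horizontal crossing) or per
#' row (vertical crossing), in absolute image coordinates.
#'
#' @param positions absolute coordinates along the crossing axis (column x or
#'   row y values).
#' @param samples interface coordinate at each position (y for horizontal
#'   crossings, x for vertical ones); `NA` marks an ambiguous sample.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param method `"clustering"` or `"snake"`.
#' @param flags character vector of quality flags.
#' @return Object of class `interface_curve` with `quality` (hypothesis
#'   record, filled by [check_hypotheses()]) and `accepted` fields.
#' @export
interface_curve <- function(positions, samples, axis, method,
                            flags = character(0)) {
  structure(list(positions = positions, samples = samples, axis = axis,
                 method = method, flags = flags,
                 quality = NULL, accepted = FALSE),
            class = "interface_curve")
}

#' Convert a two-label field to an interface curve
#'
#' After a 3x3 majority cleanup, each column (row for vertical crossings)
#' must consist of two opposing label runs; the interface sample is the
#' midpoint between the last pixel of one run and the first of the other.
#' Columns with more than two runs (or a single run) are ambiguous: more
#' than `ambiguous_max_frac` of them fails the conversion outright; a
#' smaller fraction is filled by linear interpolation from the neighbouring
#' columns, with the count carried on the curve (columns near a rectangle
#' corner can sit entirely outside the palpebral aperture, where no
#' interface crosses).
#'
#' @param labels integer 1/2 label matrix (patch coordinates).
#' @param rect the `search_rectangle` the labels came from.
#' @param config an [mgceye_config()].
#' @return List `ok`; on success `curve` (an [interface_curve()], absolute
#'   coordinates) and `labels_clean`; on failure `reason = "hypothesis"`.
#' @export
labels_to_interface <- function(labels, rect, config = mgceye_config()) {
  lab <- majority_filter(labels)
  m <- if (rect$crossing_axis == "horizontal") lab else t(lab)
  n_pos <- ncol(m)
  samples_rel <- rep(NA_real_, n_pos)
  for (j in seq_len(n_pos)) {
    r <- rle(m[, j])
    if (length(r$lengths) == 2L)
      samples_rel[j] <- r$lengths[1] + 0.5
  }
  ambiguous <- is.na(samples_rel)
  if (mean(ambiguous) > config$ambiguous_max_frac || all(ambiguous))
    return(list(ok = FALSE, reason = "hypothesis"))
  filled <- which(ambiguous)
  if (length(filled)) {
    good <- which(!ambiguous)
    samples_rel[filled] <- stats::approx(good, samples_rel[good], xout = filled,
                                         rule = 2)$y
  }
  if (rect$crossing_axis == "horizontal") {
    positions <- rect$x0:(rect$x1 - 1L)
    samples <- rect$y0 - 1 + samples_rel
  } else {
    positions <- rect$y0:(rect$y1 - 1L)
    samples <- rect$x0 - 1 + samples_rel
  }
  cv <- interface_curve(positions, samples, rect$crossing_axis, "clustering",
                        flags = if (length(filled)) "filled_ambiguous" else character(0))
  cv$n_ambiguous <- length(filled)
  list(ok = TRUE, curve = cv, labels_clean = lab)
}

# separable 3x3 Gaussian smoothing (sigma ~ 0.7 px) used by the snake's
# gradient field so single-pixel noise does not create spurious maxima
smooth3 <- function(img) {
  k <- c(0.25, 0.5, 0.25)
  h <- nrow(img); w <- ncol(img)
  px <- img[, c(1, 1:w, w)]
  img <- k[1] * px[, 1:w] + k[2] * px[, 1:w + 1] + k[3] * px[, 1:w + 2]
  py <- img[c(1, 1:h, h), ]
  k[1] * py[1:h, ] + k[2] * py[1:h + 1, ] + k[3] * py[1:h + 2, ]
}

#' Open-snake refinement of an interface curve
#'
#' Open active contour with free endpoints: each sample is displaced along
#' the crossing normal, within a band of `snake_band_px` around its initial
#' position, to maximize the smoothed image gradient magnitude along the
#' curve minus `snake_lambda` times a discrete curvature penalty. Iterates
#' until the largest displacement in a sweep falls below `snake_tol_px` or
#' `snake_max_iter` sweeps are reached (then the best iterate is returned,
#' flagged `not_converged`). A patch with no usable gradient returns the
#' initial curve flagged `flat_gradient`.
#'
#' @param patch image patch (original intensities, patch coordinates).
#' @param init an [interface_curve()] in absolute coordinates, single-valued
#'   over the patch extent.
#' @param rect the `search_rectangle` of the patch.
#' @param config an [mgceye_config()].
#' @return A refined [interface_curve()] with `method = "snake"`.
#' @export
segment_snake <- function(patch, init, rect, config = mgceye_config()) {
  stopifnot(inherits(init, "interface_curve"), all(is.finite(init$samples)))
  horiz <- rect$crossing_axis == "horizontal"
  g <- smooth3(patch)
  # patch-frame sample coordinates along the normal
  s0 <- if (horiz) init$samples - (rect$y0 - 1) else init$samples - (rect$x0 - 1)
  pos <- seq_along(s0)
  lim <- if (horiz) nrow(patch) else ncol(patch)
  gmag <- function(p, s) {
    if (horiz) gradient_magnitude_at(g, p, s) else gradient_magnitude_at(g, s, p)
  }
  if (max(gmag(pos, clamp(s0, 1, lim))) < 1e-6) {
    out <- init; out$method <- "snake"
    out$flags <- union(out$flags, "flat_gradient")
    out$n_ambiguous <- init$n_ambiguous
    return(out)
  }
  s <- s0
  band <- config$snake_band_px
  moves <- c(-1, -0.5, -0.2, 0, 0.2, 0.5, 1)
  n <- length(s)
  converged <- FALSE
  for (iter in seq_len(config$snake_max_iter)) {
    max_disp <- 0
    for (i in seq_len(n)) {
      cand <- clamp(clamp(s[i] + moves, s0[i] - band, s0[i] + band), 1, lim)
      nb <- c(if (i > 1) s[i - 1], if (i < n) s[i + 1])
      curv <- vapply(cand, function(y) mean((y - nb)^2), numeric(1))
      obj <- gmag(rep(pos[i], length(cand)), cand) - config$snake_lambda * curv
      best <- cand[which.max(obj)]
      max_disp <- max(max_disp, abs(best - s[i]))
      s[i] <- best
    }
    if (max_disp < config$snake_tol_px) { converged <- TRUE; break }
  }
  # sub-pixel refinement: parabolic interpolation of the gradient magnitude
  # at integer offsets recovers the continuous edge position exactly for a
  # one-pixel linear-coverage edge (the bilinear field is piecewise linear,
  # so the snake alone sticks to its nodes at ~0.5 px resolution)
  s_int <- clamp(round(s), 2, lim - 1)
  g0 <- gmag(pos, s_int)
  gm <- gmag(pos, s_int - 1)
  gp <- gmag(pos, s_int + 1)
  den <- gm - 2 * g0 + gp
  delta <- ifelse(abs(den) > 1e-12, (gm - gp) / (2 * den), 0)
  refined <- s_int + clamp(delta, -1, 1)
  use <- abs(refined - s) <= 1
  s[use] <- refined[use]
  s <- clamp(s, pmax(1, s0 - band), pmin(lim, s0 + band))
  samples_abs <- if (horiz) s + (rect$y0 - 1) else s + (rect$x0 - 1)
  out <- interface_curve(init$positions, samples_abs, rect$crossing_axis,
                         "snake",
                         flags = if (converged) character(0) else "not_converged")
  out$n_ambiguous <- init$n_ambiguous
  out
}

#' Check the acceptance hypotheses on a candidate interface
#'
#' H1 (smoothness): max absolute first difference of the samples at most
#' `h1_max_step_px` and total variation at most `h1_tv_frac` times the
#' rectangle extent. H2 (full crossing): exactly one finite sample per
#' column/row over the whole extent, with no ambiguous columns in the
#' underlying partition. H3 (iris arcs only): a least-squares
#' quadratic fit has residuals at most `h3_max_resid_px` and its curvature
#' sign matches an iris bulging into the sclera (arc extremal towards the
#' sclera side). H4 (connectedness): for each label, the largest 4-connected
#' component holds at least `h4_min_frac` of that label's pixels.
#'
#' When `patch` is supplied, an intensity-polarity prior is also checked for
#' the targets whose anatomy fixes the bright/dark ordering of the two
#' regions: the lower lid separates sclera (bright, above) from skin
#' (below); the iris bottom separates iris (dark, above) from sclera
#' (bright, below); the lateral iris boundary has the dark iris on the gaze
#' side. This disambiguates rectangles that still contain a second, equally
#' clean interface.
#'
#' @param curve an [interface_curve()].
#' @param labels cleaned 1/2 label matrix (patch coordinates) for H4, or
#'   `NULL` to skip H4.
#' @param rect the `search_rectangle`.
#' @param config an [mgceye_config()].
#' @param patch optional image patch (patch coordinates) for the polarity
#'   prior.
#' @return List `h1`, `h2`, `h3` (`NA` when not applicable), `h4`,
#'   `polarity` (`NA` when not applicable), `passed`.
#' @export
check_hypotheses <- function(curve, labels, rect, config = mgceye_config(),
                             patch = NULL) {
  s <- curve$samples
  extent <- length(s)
  h2 <- extent == (if (rect$crossing_axis == "horizontal") rect_width(rect)
                   else rect_height(rect)) && all(is.finite(s)) &&
    (is.null(curve$n_ambiguous) ||
       curve$n_ambiguous <= config$ambiguous_max_frac * extent)
  h1 <- FALSE
  if (all(is.finite(s)) && extent > 1) {
    d <- abs(diff(s))
    h1 <- max(d) <= config$h1_max_step_px && sum(d) <= config$h1_tv_frac * extent
  }
  h3 <- NA
  if (rect$target %in% c("iris_bottom", "iris_lateral") && all(is.finite(s))) {
    p <- curve$positions - mean(curve$positions)
    fit <- stats::lm.fit(cbind(1, p, p^2), s)
    a <- fit$coefficients[3]
    expected_sign <- if (rect$target == "iris_bottom") -1
      else if (identical(rect$gaze, "left")) -1 else 1
    h3 <- (sign(a) == expected_sign || abs(a) < 1e-9) &&
      max(abs(fit$residuals)) <= config$h3_max_resid_px
  }
  h4 <- NA
  if (!is.null(labels)) {
    h4 <- all(vapply(c(1L, 2L), function(l) {
      mask <- labels == l
      if (!any(mask)) return(TRUE)
      comp <- EBImage::bwlabel(mask)
      max(tabulate(comp[comp > 0])) >= config$h4_min_frac * sum(mask)
    }, logical(1)))
  }
  polarity <- NA
  if (!is.null(patch) && all(is.finite(s)) &&
      rect$target %in% c("lower_lid", "iris_bottom", "iris_lateral")) {
    horiz <- rect$crossing_axis == "horizontal"
    idx <- if (horiz) row(patch) else col(patch)
    srel <- if (horiz) s - (rect$y0 - 1) else s - (rect$x0 - 1)
    cut <- matrix(srel[if (horiz) col(patch) else row(patch)],
                  nrow(patch), ncol(patch))
    m_before <- mean(patch[idx < cut])   # above / left of the curve
    m_after <- mean(patch[idx > cut])
    polarity <- switch(rect$target,
      lower_lid   = m_before > m_after,            # sclera above skin
      iris_bottom = m_before < m_after,            # iris above sclera
      iris_lateral = if (identical(rect$gaze, "left"))
        m_before < m_after else m_before > m_after # iris on the gaze side
    )
    if (is.na(polarity)) polarity <- FALSE
  }
  passed <- h1 && h2 && (is.na(h3) || h3) && (is.na(h4) || h4) &&
    (is.na(polarity) || polarity)
  list(h1 = h1, h2 = h2, h3 = h3, h4 = h4, polarity = polarity,
       passed = passed)
}

shrink_rect <- function(rect, config, image_size) {
  f <- config$shrink_factor
  bw <- rect$bx1 - rect$bx0; bh <- rect$by1 - rect$by0
  w <- bw * f; h <- bh * f
  ax <- rect$anchor[1]; ay <- rect$anchor[2]
  # contract towards the anchor, keeping it inside the rectangle
  fx <- clamp((ax - rect$bx0) / bw, 0, 1)
  fy <- clamp((ay - rect$by0) / bh, 0, 1)
  x0 <- ax - fx * w; y0 <- ay - fy * h
  # integer bounds rounded inward so excluded structures stay excluded
  ix0 <- max(1, ceiling(x0)); ix1 <- min(image_size[2] + 1, floor(x0 + w) + 1)
  iy0 <- max(1, ceiling(y0)); iy1 <- min(image_size[1] + 1, floor(y0 + h) + 1)
  if (ix1 - ix0 < config$min_rect_px || iy1 - iy0 < config$min_rect_px)
    return(NULL)
  out <- search_rectangle(ix0, ix1, iy0, iy1, rect$target,
                          anchor = rect$anchor, gaze = rect$gaze,
                          shrink_level = rect$shrink_level + 1L)
  out$bx0 <- x0; out$bx1 <- x0 + w; out$by0 <- y0; out$by1 <- y0 + h
  out
}

#' Segment one interface with re-seeding and rectangle shrinking
#'
#' Runs the full local pipeline inside a search rectangle: contrast
#' enhancement, seeded two-cluster partition, interface extraction, snake
#' refinement, hypothesis checks, and a concurrence check requiring the
#' clustering-derived and snake-refined curves to agree within
#' `concurrence_tol_px` on average. On failure the clustering is re-run with
#' a new seed (up to `reseed_max` times), then the rectangle is shrunk by
#' `shrink_factor` about its anchor (up to `shrink_max` times, never below
#' `min_rect_px`). Deterministic for a fixed `base_seed`. The accepted curve
#' is the snake-refined one.
#'
#' @param img full frame image.
#' @param rect a `search_rectangle`.
#' @param base_seed integer; attempt k uses seed `base_seed + k`.
#' @param config an [mgceye_config()].
#' @return List (`segmentation_outcome`): `curve` (accepted
#'   [interface_curve()] or `NULL`), `attempts`, `final_rectangle`,
#'   `failure_reason` (`"none"`, `"contrast"`, `"hypothesis"`,
#'   `"exhausted"`), `separation`, `concurrence`, `cluster_curve`.
#' @export
segment_with_retry <- function(img, rect, base_seed = 0L,
                               config = mgceye_config()) {
  image_size <- dim(img)
  attempt <- 0L
  last_reason <- "exhausted"
  contrast_only <- TRUE
  h4_failed <- FALSE
  cur <- rect
  for (shrink in 0:config$shrink_max) {
    if (is.null(cur)) break
    patch <- extract_patch(img, cur)
    enhanced <- enhance_contrast(patch, config)
    if (isTRUE(attr(enhanced, "zero_dynamic_range")))
      return(list(curve = NULL, attempts = attempt, final_rectangle = cur,
                  failure_reason = "contrast", separation = 0,
                  concurrence = NA_real_, cluster_curve = NULL))
    for (reseed in 0:config$reseed_max) {
      attempt <- attempt + 1L
      seg <- segment_two_cluster(enhanced, seed = base_seed + attempt, config)
      if (!seg$ok || seg$separation < config$min_separation) {
        last_reason <- "contrast"
        next
      }
      li <- labels_to_interface(seg$labels, cur, config)
      if (!li$ok) { last_reason <- "hypothesis"; contrast_only <- FALSE; next }
      snake <- segment_snake(patch, li$curve, cur, config)
      hyp <- check_hypotheses(snake, li$labels_clean, cur, config,
                              patch = patch)
      if (isFALSE(hyp$h4)) h4_failed <- TRUE
      conc <- mean(abs(li$curve$samples - snake$samples))
      if (hyp$passed && conc <= config$concurrence_tol_px) {
        snake$quality <- hyp
        snake$accepted <- TRUE
        return(list(curve = snake, attempts = attempt, final_rectangle = cur,
                    failure_reason = "none", separation = seg$separation,
                    concurrence = conc, cluster_curve = li$curve,
                    h4_failed = FALSE))
      }
      last_reason <- "hypothesis"
      contrast_only <- FALSE
    }
    cur <- shrink_rect(cur, config, image_size)
  }
  reason <- if (contrast_only && last_reason == "contrast") "contrast"
    else if (is.null(cur)) "exhausted" else last_reason
  list(curve = NULL, attempts = attempt,
       final_rectangle = if (is.null(cur)) rect else cur,
       failure_reason = reason, separation = NA_real_,
       concurrence = NA_real_, cluster_curve = NULL, h4_failed = h4_failed)
}

#' Evaluate an interface curve at a coordinate along its crossing axis
#'
#' Linear interpolation of the curve samples at `at` (an x for horizontal
#' crossings, a y for vertical ones), clamped to the curve extent.
#'
#' @param curve an [interface_curve()].
#' @param at coordinate(s) along the crossing axis.
#' @return Interpolated interface coordinate(s).
#' @export
curve_value_at <- function(curve, at) {
  stats::approx(curve$positions, curve$samples, xout = at, rule = 2)$y
}
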