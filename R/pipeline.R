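# Clip ingestion and the end-to-end pipeline: frames -> landmarks -> coarse
# metrics and gaze labels -> local segmentation -> per-frame measurements ->
# rejection -> gap-aware series -> filtering, trends, grades, summary.

#' Describe a clip to process
#'
#' A clip is either a directory of gray PNG frames with a `manifest.csv`
#' (columns `file`, `frame`, `timestamp`, and optionally `fps`), or an
#' in-memory [synthetic_eye_spec()] rendered lazily frame by frame. Videos
#' must be exploded to frames upstream.
#'
#' @param source directory path or a `synthetic_eye_spec`.
#' @param fps frames per second (required for a frame directory whose
#'   manifest lacks an `fps` column).
#' @param sample_every optional sampling interval in seconds (at least one
#'   frame period); keeps one frame per interval.
#' @param exercise_hint optional `"ptosis"` or `"diplopia"`.
#' @return Object of class `clip_descriptor`.
#' @export
clip_descriptor <- function(source, fps = NULL, sample_every = NULL,
                            exercise_hint = NULL) {
  if (inherits(source, "synthetic_eye_spec")) {
    fps <- source$fps
  } else {
    stopifnot(is.character(source))
    if (!dir.exists(source)) stop("unreadable clip source: ", source)
  }
  if (!is.null(fps) && fps <= 0) stop("fps must be positive")
  if (!is.null(sample_every) && !is.null(fps) && sample_every < 1 / fps)
    stop("sampling interval below one frame period")
  structure(list(source = source, fps = fps, sample_every = sample_every,
                 exercise_hint = exercise_hint),
            class = "clip_descriptor")
}

#' Read the timestamped frame stream of a clip
#'
#' Resolves the clip to a lazy frame accessor: frames in temporal order with
#' timestamps `frame / fps`, sampling applied.
#'
#' @param clip a [clip_descriptor()] (a directory path or
#'   `synthetic_eye_spec` is promoted automatically).
#' @return List `n`, `timestamps`, `frame_index`, `fps`, `get(k)` (returns
#'   the k-th sampled frame as a matrix), `truth_landmarks(k)` (68 x 2 truth
#'   matrix for synthetic clips, else `NULL`), `landmarks_csv` (path if the
#'   directory ships one).
#' @export
read_frames <- function(clip) {
  if (!inherits(clip, "clip_descriptor")) clip <- clip_descriptor(clip)
  if (inherits(clip$source, "synthetic_eye_spec")) {
    spec <- clip$source
    n_total <- floor(spec$duration * spec$fps)
    idx <- 0:(n_total - 1)
    fps <- spec$fps
    landmarks_csv <- NULL
    get_frame <- function(frame) render_frame(spec, frame / fps)
    is_synth <- TRUE
  } else {
    man_path <- file.path(clip$source, "manifest.csv")
    if (file.exists(man_path)) {
      man <- utils::read.csv(man_path)
      fps <- if (!is.null(man$fps)) man$fps[1] else clip$fps
      files <- file.path(clip$source, man$file)
      idx <- man$frame
    } else {
      files <- sort(list.files(clip$source, pattern = "\\.(png|PNG)$",
                               full.names = TRUE))
      fps <- clip$fps
      idx <- seq_along(files) - 1L
    }
    if (!length(idx)) stop("no frames found in ", clip$source)
    if (is.null(fps)) stop("fps unknown: provide it in the manifest or descriptor")
    lm_path <- file.path(clip$source, "landmarks.csv")
    landmarks_csv <- if (file.exists(lm_path)) lm_path else NULL
    file_of <- stats::setNames(files, idx)
    get_frame <- function(frame) {
      img <- png::readPNG(file_of[[as.character(frame)]])
      if (length(dim(img)) == 3) img <- img[, , 1]
      list(image = img, truth = NULL, landmarks = NULL)
    }
    is_synth <- FALSE
  }
  if (!is.null(clip$sample_every)) {
    if (clip$sample_every < 1 / fps) stop("sampling interval below one frame period")
    step <- max(1L, round(clip$sample_every * fps))
    idx <- idx[(idx - idx[1]) %% step == 0]
  }
  cache <- new.env(parent = emptyenv())
  list(n = length(idx), frame_index = idx, timestamps = idx / fps, fps = fps,
       get = function(k) {
         key <- as.character(idx[k])
         if (!exists(key, cache)) assign(key, get_frame(idx[k]), cache)
         got <- get(key, cache); rm(list = key, envir = cache); got
       },
       synthetic = is_synth, landmarks_csv = landmarks_csv)
}

# expected gaze label of the exercise window
expected_gaze_label <- function(exercise, gaze) {
  if (exercise == "ptosis") "up" else gaze
}

#' Run the full pipeline on a clip
#'
#' For every sampled frame: landmark acquisition, eye-hexagon extraction and
#' localization sanity check, coarse metrics (ED/EL/area) and per-eye gaze
#' label, then local interface segmentation and per-frame exam metrics
#' (unless `coarse_only`). Afterwards: blink detection, frame rejection,
#' exercise-window detection, gap-aware series assembly, filtering, trends,
#' grades and a per-clip summary with full frame-disposition accounting.
#' Deterministic given clip, config and `base_seed`.
#'
#' @param clip a [clip_descriptor()] (or directory path /
#'   `synthetic_eye_spec`).
#' @param exercise `"ptosis"` or `"diplopia"`.
#' @param gaze image-frame gaze direction for diplopia.
#' @param config an [mgceye_config()].
#' @param base_seed integer seed for all stochastic stages.
#' @param provider optional landmark provider; defaults to the ground-truth
#'   fixture for synthetic clips, a landmarks CSV shipped with the frame
#'   directory, else an error (an external provider must be configured).
#' @param coarse_only skip local segmentation (landmark metrics and blinks
#'   only).
#' @param out_dir optional output directory for `frames.csv`, one
#'   `series_<channel>.csv` per channel, and `summary.json`.
#' @param overlay write per-frame debug overlays (synthetic/PNG frames only,
#'   needs `out_dir`).
#' @param window `"auto"` detects the exercise window from the scleral
#'   position, `"full"` uses the whole clip.
#' @return List with `frames` (per-frame data frame), `series` (named list
#'   of `measurement_series`), `alpha_pairs` (diplopia), `blinks` (per
#'   eye), `window`, `summary` (named list), `out_dir`.
#' @export
run_pipeline <- function(clip, exercise = c("ptosis", "diplopia"),
                         gaze = NULL, config = mgceye_config(),
                         base_seed = 0L, provider = NULL,
                         coarse_only = FALSE, out_dir = NULL,
                         overlay = FALSE, window = c("auto", "full")) {
  exercise <- match.arg(exercise)
  window <- match.arg(window)
  if (exercise == "diplopia" && is.null(gaze))
    stop("diplopia needs --gaze left|right")
  if (!inherits(clip, "clip_descriptor")) clip <- clip_descriptor(clip)
  fr <- read_frames(clip)
  if (is.null(provider) && !fr$synthetic && !is.null(fr$landmarks_csv)) {
    lmcsv <- read_landmarks_csv(fr$landmarks_csv)
    provider <- fixture_landmark_provider(lmcsv$landmarks, lmcsv$frame_index,
                                          lmcsv$timestamps)
  }
  if (is.null(provider) && !fr$synthetic)
    stop("no landmark provider configured and no landmarks.csv in the clip")

  n <- fr$n
  lm_list <- vector("list", n)
  gaze_r <- gaze_l <- rep("unknown", n)
  lighting_bad <- rep(FALSE, n)
  frame_rows <- vector("list", n)
  needed <- if (exercise == "ptosis") c("upper_lid", "lower_lid", "iris_bottom")
            else c("upper_lid", "lower_lid", "iris_lateral")
  do_overlay <- overlay && !is.null(out_dir)
  if (do_overlay)
    dir.create(file.path(out_dir, "overlays"), recursive = TRUE,
               showWarnings = FALSE)
  for (k in seq_len(n)) {
    ov <- list(rects = list(), curves = list())
    t_k <- fr$timestamps[k]
    got <- fr$get(k)
    img <- got$image
    lm <- if (!is.null(provider))
      provide_landmarks(provider, img, fr$frame_index[k], t_k, dim(img))
    else landmark_set(got$landmarks, fr$frame_index[k], t_k, "fixture",
                      image_size = dim(img))
    if (is.null(lm) || !lm$valid) {
      frame_rows[[k]] <- disposition_rows(t_k, "no_landmarks")
      next
    }
    lm_list[[k]] <- lm$points
    hexes <- extract_eye_hexagons(lm)
    loc <- validate_eye_localization(hexes, landmark_face_box(lm, config$face_box_inflate),
                                     config)
    if (!loc$valid) {
      frame_rows[[k]] <- disposition_rows(t_k, "bad_localization")
      next
    }
    rows <- lapply(c("right", "left"), function(side) {
      hex <- hexes[[side]]
      cm <- coarse_eye_metrics(hex, config)
      glab <- classify_gaze(img, hex, seed = frame_seed(base_seed, fr$frame_index[k]),
                            config = config)
      if (side == "right") gaze_r[k] <<- glab else gaze_l[k] <<- glab
      row <- frame_measurement_row(t_k, side, el = cm$el, valid = FALSE,
                                   reason = "none")
      row$ed <- cm$ed; row$ed_norm <- cm$ed_norm; row$area_norm <- cm$area_norm
      row$gaze_label <- glab
      if (!cm$available) {
        row$rejection_reason <- "segmentation_failed"
        return(row)
      }
      if (coarse_only) { row$valid <- TRUE; return(row) }
      rects <- build_rectangles(hex, exercise, gaze, dim(img), config)
      curves <- list(); reason <- "none"
      for (nm in intersect(needed, names(rects))) {
        out <- segment_with_retry(img, rects[[nm]],
                                  base_seed = frame_seed(base_seed, fr$frame_index[k]),
                                  config = config)
        if (isTRUE(out$h4_failed)) lighting_bad[k] <<- TRUE
        if (!is.null(out$curve)) curves[[nm]] <- out$curve
        else if (nm %in% c("upper_lid", "lower_lid")) reason <- "segmentation_failed"
      }
      if (do_overlay) {
        ov$rects <<- c(ov$rects, rects)
        ov$curves <<- c(ov$curves, curves)
      }
      if (exercise == "ptosis") {
        m <- ptosis_frame_metrics(curves, hex, t_k, config)
        m$ed <- cm$ed; m$ed_norm <- cm$ed_norm; m$area_norm <- cm$area_norm
        m$gaze_label <- glab
        m
      } else {
        ac <- alpha_coordinate(curves$iris_lateral, hex, gaze, config)
        row$alpha <- ac$alpha
        if (!is.null(curves$upper_lid) && !is.null(curves$lower_lid)) {
          cx <- hexagon_center(hex)[1]
          row$upper_lid_y <- curve_value_at(curves$upper_lid, cx)
          row$lower_lid_y <- curve_value_at(curves$lower_lid, cx)
          row$lid_to_lid <- row$lower_lid_y - row$upper_lid_y
          row$lid_to_lid_norm <- row$lid_to_lid / cm$el
        }
        row$valid <- ac$available
        row$rejection_reason <- if (ac$available) "none" else "segmentation_failed"
        row
      }
    })
    frame_rows[[k]] <- do.call(rbind, rows)
    if (do_overlay)
      write_debug_overlay(img,
                          file.path(out_dir, "overlays",
                                    sprintf("frame_%06d.png", fr$frame_index[k])),
                          rects = ov$rects, curves = ov$curves,
                          landmarks = lm$points)
  }
  frames <- do.call(rbind, frame_rows)
  frames <- frames[order(frames$timestamp, frames$side), ]

  # blink events per eye from the coarse ED series
  blinks <- lapply(c("right", "left"), function(side) {
    sel <- frames$side == side
    detect_blinks(frames$ed[sel][order(frames$timestamp[sel])],
                  sort(frames$timestamp[sel]), config)
  })
  names(blinks) <- c("right", "left")
  blink_frames <- unique(unlist(lapply(blinks, function(b) {
    if (!nrow(b$events)) return(integer(0))
    unlist(mapply(seq, b$events$start_index, b$events$end_index,
                  SIMPLIFY = FALSE))
  })))

  reasons <- reject_frames(lm_list, el = median(frames$el, na.rm = TRUE),
                           blink_frames = blink_frames,
                           lighting_bad = lighting_bad, config = config)
  # apply post-hoc rejections (motion/lighting/instability/blink) to frames
  # that got past landmarks/localization
  for (k in seq_len(n)) {
    if (reasons[k] %in% c("none", "no_landmarks")) next
    sel <- frames$timestamp == fr$timestamps[k] &
      !frames$rejection_reason %in% c("no_landmarks", "bad_localization")
    frames$valid[sel] <- FALSE
    frames$rejection_reason[sel] <- reasons[k]
  }

  win <- list(available = FALSE, start = min(fr$timestamps),
              end = max(fr$timestamps), atypical = NA)
  if (window == "auto") {
    w <- detect_exercise_window(gaze_r, gaze_l, fr$timestamps,
                                expected_gaze_label(exercise, gaze), config)
    if (w$available) win <- w
  } else win$available <- TRUE
  in_win <- frames$timestamp >= win$start & frames$timestamp <= win$end

  series <- list()
  mk_series <- function(channel, side = NULL) {
    sel <- in_win & frames$valid
    if (!is.null(side)) sel <- sel & frames$side == side
    ss <- frames[sel, ]
    ss <- ss[order(ss$timestamp), ]
    s <- assemble_series(ss$timestamp, ss[[channel]],
                         channel = if (is.null(side)) channel
                                   else paste(channel, side, sep = "_"),
                         config = config)
    fit_trend(filter_series(s, config))
  }
  alpha_pairs <- NULL
  if (!coarse_only) {
    if (exercise == "ptosis") {
      for (side in c("right", "left")) {
        series[[paste0("lid_to_lid_norm_", side)]] <- mk_series("lid_to_lid_norm", side)
        series[[paste0("iris_to_lowerlid_norm_", side)]] <-
          mk_series("iris_to_lowerlid_norm", side)
      }
    } else {
      for (side in c("right", "left"))
        series[[paste0("alpha_", side)]] <- mk_series("alpha", side)
      fa <- merge(frames[frames$side == "left" & frames$valid & in_win,
                         c("timestamp", "alpha")],
                  frames[frames$side == "right" & frames$valid & in_win,
                         c("timestamp", "alpha")],
                  by = "timestamp", suffixes = c("_left", "_right"))
      alpha_pairs <- alpha_pair_series(fa$timestamp, fa$alpha_left,
                                       fa$alpha_right, config)
    }
  }
  for (side in c("right", "left")) {
    series[[paste0("ed_norm_", side)]] <- mk_series("ed_norm", side)
    series[[paste0("area_norm_", side)]] <- mk_series("area_norm", side)
  }

  summary <- build_summary(frames, series, alpha_pairs, blinks, win,
                           exercise, config)
  res <- list(frames = frames, series = series, alpha_pairs = alpha_pairs,
              blinks = blinks, window = win, summary = summary,
              out_dir = out_dir)
  if (!is.null(out_dir)) write_outputs(res, out_dir)
  res
}

disposition_rows <- function(t, reason) {
  do.call(rbind, lapply(c("right", "left"), function(side) {
    r <- frame_measurement_row(t, side, valid = FALSE, reason = reason)
    r$ed <- NA_real_; r$ed_norm <- NA_real_; r$area_norm <- NA_real_
    r$gaze_label <- "unknown"
    r
  }))
}

build_summary <- function(frames, series, alpha_pairs, blinks, win,
                          exercise, config) {
  per_frame <- frames[frames$side == "right", ]  # one disposition per frame
  disp <- table(factor(ifelse(per_frame$valid, "used",
                              per_frame$rejection_reason),
                       levels = c("used", "no_landmarks", "bad_localization",
                                  "segmentation_failed", "blink", "motion",
                                  "lighting", "landmark_instability")))
  trends <- lapply(series, function(s) s$trend)
  decay <- lapply(series[grep("^lid_to_lid_norm", names(series))], function(s) {
    tr <- s$trend
    if (any(is.na(tr)) || abs(tr["intercept"]) < 1e-12) NA_real_
    else unname(-tr["slope"] / tr["intercept"])
  })
  onset <- grade_time <- NULL
  if (exercise == "ptosis" && length(series)) {
    ch <- series[["lid_to_lid_norm_right"]]
    if (!is.null(ch) && nrow(ch$samples)) {
      onset <- droop_onset_time(ch$samples$timestamp, ch$samples$filtered, config)
      grade_time <- grade_ptosis_time(onset, win$end - win$start)
    }
  }
  gaps <- unique(do.call(rbind, lapply(series, function(s) s$gaps)))
  list(
    exercise = exercise,
    n_frames = nrow(per_frame),
    disposition = as.list(disp),
    fraction_used = unname(disp["used"]) / max(1, nrow(per_frame)),
    window = win[c("available", "start", "end", "atypical")],
    trends = trends,
    lid_opening_relative_decay = decay,
    droop_onset_s = if (is.null(onset)) NA_real_ else onset,
    grade_ptosis_time = if (is.null(grade_time)) NA_integer_ else grade_time,
    alpha_deviation_max = if (!is.null(alpha_pairs) && nrow(alpha_pairs))
      max(alpha_pairs$deviation) else NA_real_,
    misalignment_flagged = if (!is.null(alpha_pairs) && nrow(alpha_pairs))
      any(alpha_pairs$misalignment_flag) else NA,
    blink_rate_per_min = lapply(blinks, function(b) b$rate_per_min),
    blink_count = lapply(blinks, function(b) nrow(b$events)),
    gaps = if (!is.null(gaps) && nrow(gaps)) gaps else NULL
  )
}

write_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$frames, file.path(out_dir, "frames.csv"),
                   row.names = FALSE)
  for (nm in names(res$series)) {
    s <- res$series[[nm]]
    utils::write.csv(s$samples, file.path(out_dir, paste0("series_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(res$alpha_pairs))
    utils::write.csv(res$alpha_pairs, file.path(out_dir, "alpha_pairs.csv"),
                     row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(out_dir)
}

#' Write a debug overlay image
#'
#' RGB PNG of a frame with search-rectangle outlines (blue), accepted
#' interface curves (green) and landmarks (red).
#'
#' @param img gray frame matrix.
#' @param path output PNG path.
#' @param rects list of `search_rectangle`s.
#' @param curves list of [interface_curve()]s.
#' @param landmarks 68 x 2 matrix (or any n x 2 points).
#' @return `path`, invisibly.
#' @export
write_debug_overlay <- function(img, path, rects = list(), curves = list(),
                                landmarks = NULL) {
  h <- nrow(img); w <- ncol(img)
  rgb <- array(rep(img, 3), dim = c(h, w, 3))
  put <- function(y, x, col) {
    y <- round(y); x <- round(x)
    ok <- y >= 1 & y <= h & x >= 1 & x <= w
    for (c in 1:3) rgb[cbind(y[ok], x[ok], c)] <<- col[c]
  }
  for (r in rects) {
    xs <- r$x0:(r$x1 - 1); ys <- r$y0:(r$y1 - 1)
    put(rep(r$y0, length(xs)), xs, c(0, 0, 1))
    put(rep(r$y1 - 1, length(xs)), xs, c(0, 0, 1))
    put(ys, rep(r$x0, length(ys)), c(0, 0, 1))
    put(ys, rep(r$x1 - 1, length(ys)), c(0, 0, 1))
  }
  for (cv in curves) {
    if (cv$axis == "horizontal") put(cv$samples, cv$positions, c(0, 1, 0))
    else put(cv$positions, cv$samples, c(0, 1, 0))
  }
  if (!is.null(landmarks)) put(landmarks[, 2], landmarks[, 1], c(1, 0, 0))
  png::writePNG(rgb, path)
  invisible(path)
}
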