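#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults. Every value can
#' be overridden by name, or loaded from a YAML file with [read_config()].
#'
#' @details The groups are:
#' \describe{
#'   \item{landmarks}{`face_box_inflate` (fraction the landmark bounding box is
#'     grown by when the provider gives no face box), `iod_min_frac` /
#'     `iod_max_frac` (admissible inter-ocular distance as a fraction of the
#'     face-box width), `tilt_max_deg` (maximum deviation of the inter-ocular
#'     line from horizontal).}
#'   \item{coarse}{`el_min_px` (eye length below which a frame is
#'     under-resolved), `blink_frac` (ED fraction of the rolling baseline below
#'     which a frame is inside a blink), `blink_baseline_s` (rolling-median
#'     window), `blink_max_s` (maximum blink duration).}
#'   \item{segmentation}{percentile-stretch bounds, minimum cluster separation
#'     score, re-seed and shrink budgets, shrink factor, minimum rectangle
#'     size, rectangle padding as a fraction of eye length, snake parameters
#'     (`snake_lambda` curvature weight, `snake_band_px` search band,
#'     `snake_max_iter`, `snake_tol_px`), clustering/snake concurrence
#'     tolerance, hypothesis thresholds (H1 step and total-variation bounds,
#'     H3 residual bound, H4 connected-component fraction), and the maximum
#'     fraction of ambiguous interface columns.}
#'   \item{exam}{`alpha_dev_threshold` (misalignment flag on the deviation of
#'     alpha_left - alpha_right from its baseline), `alpha_baseline_s`
#'     (baseline window), `onset_frac` (fraction of the initial filtered lid
#'     opening that defines droop onset), `iris_arc_min_deg` (arc subtended
#'     below which an iris-circle fit is unreliable).}
#'   \item{timeseries}{`gap_max_s` (largest hole bridged by linear
#'     interpolation), `fc_hz` (low-pass cutoff), `min_segment_s` (shortest
#'     segment the filter runs on), rejection thresholds (`motion_frac`,
#'     `instab_frac`, `face_still_frac`, all fractions of eye length),
#'     `vote_window_s` (gaze-label majority-vote window), `window_min_s`
#'     (shortest acceptable exercise window).}
#' }
#'
#' @param ... named overrides of any default listed above.
#' @return A named list of configuration values, class `mgceye_config`.
#' @examples
#' cfg <- mgceye_config(fc_hz = 1.0)
#' cfg$fc_hz
#' @export
mgceye_config <- function(...) {
  cfg <- list(
    # landmarks
    face_box_inflate = 0.2,
    iod_min_frac = 0.15,
    iod_max_frac = 0.8,
    tilt_max_deg = 25,
    # coarse metrics
    el_min_px = 4,
    blink_frac = 0.5,
    blink_baseline_s = 2,
    blink_max_s = 0.5,
    # local segmentation
    stretch_lo = 0.01,
    stretch_hi = 0.99,
    min_separation = 2.0,
    reseed_max = 2,
    shrink_factor = 0.8,
    shrink_max = 5,
    min_rect_px = 4,
    pad_frac = 0.15,
    snake_lambda = 0.3,
    snake_band_px = 3,
    snake_max_iter = 50,
    snake_tol_px = 0.1,
    concurrence_tol_px = 2,
    h1_max_step_px = 2,
    h1_tv_frac = 0.5,
    h3_max_resid_px = 2,
    h4_min_frac = 0.9,
    ambiguous_max_frac = 0.2,
    # exam metrics
    alpha_dev_threshold = 0.05,
    alpha_baseline_s = 5,
    onset_frac = 0.9,
    iris_arc_min_deg = 60,
    # timeseries
    gap_max_s = 1,
    fc_hz = 0.5,
    min_segment_s = 4,
    motion_frac = 0.1,
    instab_frac = 0.2,
    face_still_frac = 0.05,
    vote_window_s = 1,
    window_min_s = 10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "mgceye_config")
}

#' Read a configuration YAML file
#'
#' @param path YAML file with a flat mapping of configuration names to values.
#' @return An `mgceye_config` list (unknown names are an error).
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(mgceye_config, vals)
}

#' Write a configuration to YAML
#'
#' @param cfg an `mgceye_config` list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
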