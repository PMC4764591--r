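#' End-to-end analysis of a contraction movie
#'
#' Chains the full image-analysis pipeline on a fluorescence stack:
#' offset/flat-field correction, per-frame network segmentation, rotation
#' detection and correction, width measurement, the
#' exponential-relaxation fit of the fraction contracted, length-averaged
#' density profiles, and single-pass PIV between consecutive frames with
#' network masking.  Errors are re-raised with the failing stage named.
#'
#' @param stack a [frame_stack()] (raw; correction is applied here), or a
#'   TIFF path understood by [read_frame_stack()] (then `pixel_size` etc.
#'   must be supplied via `...`).
#' @param config list of options: `threshold_method` ("otsu" or
#'   "absolute"), `threshold`, `epsilon_threshold` (curve-fit cutoff,
#'   default 0.1), `profile_frames` (indices, default all),
#'   `piv_frames` (indices of the first frame of each PIV pair, default
#'   the middle pair), `piv_window`, `piv_step`, `piv_margin`.
#' @param ... passed to [read_frame_stack()] when `stack` is a path.
#' @return A list: the corrected `stack`, `masks`, `rotation` (radians),
#'   `widths` (um), `times` (min), `epsilon`, `fit`
#'   (a `contraction_fit`), `profiles`, and `piv` (list of masked
#'   `piv_field`s).
#' @export
analyze_movie <- function(stack, config = list(), ...) {
  cfg <- utils::modifyList(
    list(threshold_method = "otsu", threshold = NULL, epsilon_threshold = 0.1,
         profile_frames = NULL, piv_frames = NULL,
         piv_window = 16, piv_step = 8, piv_margin = 8),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_mtc("mtc_stage_error",
               sprintf("[%s] %s", name, conditionMessage(e)),
               stage = name, parent = e))
  }

  if (is.character(stack))
    stack <- stage("read", read_frame_stack(stack, ...))
  stopifnot(inherits(stack, "frame_stack"))

  corrected <- stage("flatfield", flatfield_correct(stack))
  masks <- stage("segmentation",
                 lapply(corrected$frames, segment_network,
                        method = cfg$threshold_method,
                        threshold = cfg$threshold))
  corrected <- stage("rotation", correct_rotation(corrected, masks))
  rotation <- attr(corrected, "rotation_applied")
  if (rotation != 0)
    masks <- stage("segmentation",
                   lapply(corrected$frames, segment_network,
                          method = cfg$threshold_method,
                          threshold = cfg$threshold))

  widths <- stage("width", measure_width(masks, corrected$pixel_size))
  times <- (seq_along(widths) - 1) * corrected$frame_interval / 60
  W0 <- max(widths)
  eps <- stage("epsilon", epsilon_curve(widths, W0))
  fit <- stage("curve-fit",
               tryCatch(fit_contraction_curve(times, eps,
                                              threshold = cfg$epsilon_threshold),
                        mtc_not_contracted_error = function(e) NULL))

  pf <- if (is.null(cfg$profile_frames)) seq_along(widths) else cfg$profile_frames
  profiles <- stage("profiles",
                    lapply(pf, function(t)
                      tryCatch(density_profile(corrected, masks, t),
                               mtc_profile_error = function(e) NULL)))
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]

  piv_first <- if (is.null(cfg$piv_frames)) {
    if (n_frames(corrected) >= 2) floor(n_frames(corrected) / 2) else integer(0)
  } else cfg$piv_frames
  piv_fields <- stage("piv", lapply(piv_first, function(t) {
    f <- piv(corrected$frames[[t]], corrected$frames[[t + 1]],
             window = cfg$piv_window, step = cfg$piv_step)
    mask_piv(f, masks[[t]], margin = cfg$piv_margin)
  }))

  list(stack = corrected, masks = masks, rotation = rotation,
       widths = widths, times = times, epsilon = eps, fit = fit,
       profiles = profiles, piv = piv_fields, config = cfg)
}

#' Run a width scan and write its report
#'
#' Convenience wrapper around [determine_alpha_beta()] that also writes
#' the per-width tau table (CSV) and the determined constants (JSON) when
#' an output directory is given.
#'
#' @param params a [model_params()].
#' @param out_dir optional output directory for `width_scan.csv` and
#'   `scaling_constants.json`.
#' @param ... passed to [determine_alpha_beta()].
#' @return The [determine_alpha_beta()] result.
#' @export
run_width_scan <- function(params, out_dir = NULL, ...) {
  constants <- determine_alpha_beta(params, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scaling_report(constants,
                         csv_path = file.path(out_dir, "width_scan.csv"),
                         json_path = file.path(out_dir, "scaling_constants.json"))
  }
  constants
}
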