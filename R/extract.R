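#' Extract the single-flash reflex parameters
#'
#' Measures the standard single-flash pupil-light-reflex parameter set
#' from a pupillogram: pre-flash (baseline) radius from the frame
#' preceding the flash; latency to the start of constriction as the
#' downward crossing of 90% of baseline; the frame-aligned post-flash
#' minimum and its latency; the plateau as the first upward crossing of
#' 75% of baseline after the minimum; the duration of constriction
#' (configurable, see \code{\link{extract_config}}); reflex amplitude =
#' baseline minus minimum; and constriction velocity = amplitude divided
#' by the configured interval. Radius parameters are reported both in
#' pixels and as pupil/iris ratios. Latencies are measured from the
#' flash; crossings are sub-frame (interpolated), minima frame-aligned.
#'
#' A recording whose blink report says excluded (more than three blinks)
#' is refused. Parameters whose defining crossing does not occur are
#' reported as \code{NA}, never fabricated.
#'
#' @param trace a \code{\link{build_trace}} pupillogram under a
#'   single-flash protocol.
#' @param config an \code{\link{extract_config}}.
#' @return a one-row data.frame of class \code{single_flash_params}.
#' @export
extract_single_flash <- function(trace, config = extract_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  protocol <- attr(trace, "protocol")
  if (protocol$type != "single")
    stop("trace was not recorded under the single-flash protocol")
  refuse_if_excluded(trace, config)
  iris <- attr(trace, "iris_radius_px")
  flash <- protocol$flash_times_s[1]
  t_end <- trace$time_s[nrow(trace)]

  B <- baseline_radius(trace, flash)
  onset_t <- crossing_time(trace, 0.9 * B,
                           c(flash, min(flash + config$post_flash_window_s, t_end)),
                           "down")
  mn <- window_minimum(trace, flash,
                       min(flash + config$post_flash_window_s, t_end))
  plateau_t <- if (!is.na(mn$time))
    crossing_time(trace, 0.75 * B, c(mn$time, t_end), "up") else NA_real_
  duration <- constriction_duration(trace, flash, onset_t, mn, B, config)
  amplitude <- B - mn$radius
  denom <- switch(config$velocity_denominator,
                  duration = duration,
                  onset_to_min = if (is.na(onset_t) || is.na(mn$time))
                    NA_real_ else mn$time - onset_t)
  velocity <- amplitude / denom

  out <- data.frame(
    baseline_radius_px = B,
    ratio_PI_darkness = B / iris,
    latency_to_constriction_s = if (is.na(onset_t)) NA_real_ else onset_t - flash,
    min_radius_px = mn$radius,
    ratio_PI_largest_constriction = mn$radius / iris,
    latency_to_largest_constriction_s = if (is.na(mn$time)) NA_real_ else mn$time - flash,
    plateau_radius_px = if (is.na(plateau_t)) NA_real_ else 0.75 * B,
    ratio_PI_plateau = if (is.na(plateau_t)) NA_real_ else 0.75 * B / iris,
    latency_to_plateau_s = if (is.na(plateau_t)) NA_real_ else plateau_t - flash,
    duration_of_constriction_s = duration,
    reflex_amplitude_px = amplitude,
    velocity_of_constriction_px_per_s = velocity)
  class(out) <- c("single_flash_params", "plr_params", "data.frame")
  out
}

#' Extract the 25-flash train parameters
#'
#' Measures the flash-train parameter set: pupil/iris ratios in the
#' frames preceding the 1st, 10th and 25th flashes and at the largest
#' constriction after each; per-flash latencies to the start of
#' constriction (90% of that flash's pre-flash radius) and to the
#' largest constriction, searched within each flash's own 1 s window;
#' and, after the 25th flash, the recovery plateau (first upward
#' crossing of 75% of the pre-25th-flash radius after the minimum), its
#' latency, and the duration of constriction of the 25th-flash
#' response.
#'
#' @param trace a pupillogram under the 25-flash, 1 Hz protocol.
#' @param config an \code{\link{extract_config}}.
#' @return a one-row data.frame of class \code{train_params}.
#' @export
extract_flash_train <- function(trace, config = extract_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  protocol <- attr(trace, "protocol")
  if (protocol$type != "train25")
    stop("trace was not recorded under the 25-flash protocol")
  refuse_if_excluded(trace, config)
  iris <- attr(trace, "iris_radius_px")
  ft <- protocol$flash_times_s
  t_end <- trace$time_s[nrow(trace)]

  per_flash <- function(k) {
    flash <- ft[k]
    w_end <- if (k < length(ft)) ft[k + 1] else t_end
    B <- baseline_radius(trace, flash)
    onset_t <- crossing_time(trace, 0.9 * B, c(flash, w_end), "down")
    mn <- window_minimum(trace, flash, w_end)
    list(flash = flash, pre = B, mn = mn,
         onset_latency = if (is.na(onset_t)) NA_real_ else onset_t - flash,
         min_latency = if (is.na(mn$time)) NA_real_ else mn$time - flash)
  }
  f1 <- per_flash(1); f10 <- per_flash(10); f25 <- per_flash(25)

  plateau_t <- if (!is.na(f25$mn$time))
    crossing_time(trace, 0.75 * f25$pre, c(f25$mn$time, t_end), "up")
  else NA_real_
  onset25_abs <- if (is.na(f25$onset_latency)) NA_real_ else
    ft[25] + f25$onset_latency
  duration <- constriction_duration(trace, ft[25], onset25_abs, f25$mn,
                                    f25$pre, config)

  out <- data.frame(
    pre_1st_radius_px = f1$pre,
    ratio_PI_pre_1st = f1$pre / iris,
    ratio_PI_min_after_1st = f1$mn$radius / iris,
    latency_to_constriction_1st_s = f1$onset_latency,
    latency_to_largest_constriction_1st_s = f1$min_latency,
    pre_10th_radius_px = f10$pre,
    ratio_PI_pre_10th = f10$pre / iris,
    ratio_PI_min_after_10th = f10$mn$radius / iris,
    latency_to_constriction_10th_s = f10$onset_latency,
    latency_to_largest_constriction_10th_s = f10$min_latency,
    pre_25th_radius_px = f25$pre,
    ratio_PI_pre_25th = f25$pre / iris,
    ratio_PI_min_after_25th = f25$mn$radius / iris,
    latency_to_constriction_25th_s = f25$onset_latency,
    latency_to_largest_constriction_25th_s = f25$min_latency,
    ratio_PI_plateau = if (is.na(plateau_t)) NA_real_ else
      0.75 * f25$pre / iris,
    latency_to_plateau_s = if (is.na(plateau_t)) NA_real_ else
      plateau_t - ft[25],
    duration_of_constriction_s = duration)
  class(out) <- c("train_params", "plr_params", "data.frame")
  out
}

refuse_if_excluded <- function(trace, config) {
  br <- detect_blinks(trace, config$jump_px_per_frame)
  if (br$excluded)
    stop(sprintf("recording excluded: blinked %d times (more than three)",
                 br$blink_count))
  invisible(br)
}

#' @export
print.plr_params <- function(x, ...) {
  cat(sprintf("%s parameters:\n",
              if (inherits(x, "single_flash_params")) "Single-flash"
              else "25-flash train"))
  df <- as.data.frame(x)
  for (nm in names(df))
    cat(sprintf("  %-40s %s\n", nm,
                ifelse(is.na(df[[nm]]), "missing", sprintf("%.4f", df[[nm]]))))
  invisible(x)
}
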