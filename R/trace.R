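#' Assemble a pupillogram from per-frame measurements
#'
#' Builds the radius-versus-time trace. Invalid frames are carried as
#' gaps (no interpolation): a blink can fake a minimum, so extraction
#' only ever interpolates crossings between adjacent valid frames.
#'
#' @param measurements a \code{\link{measure_sequence}} data.frame, or
#'   anything with columns \code{pupil_radius_px} and \code{valid} in
#'   frame order (a numeric vector of radii is accepted and treated as
#'   all-valid unless NA).
#' @param fps frames per second.
#' @param protocol the \code{\link{flash_protocol}} of the recording.
#' @param iris_radius_px per-recording iris radius; must exceed every
#'   valid pupil radius.
#' @return a data.frame of class \code{pupil_trace} with columns
#'   \code{frame}, \code{time_s}, \code{radius_px}, \code{valid}; fps,
#'   protocol and iris radius are attributes.
#' @export
build_trace <- function(measurements, fps, protocol, iris_radius_px) {
  if (is.numeric(measurements))
    measurements <- data.frame(pupil_radius_px = measurements,
                               valid = !is.na(measurements))
  if (nrow(measurements) == 0) stop("no measurements")
  stopifnot(inherits(protocol, "flash_protocol"), fps > 0)
  r <- measurements$pupil_radius_px
  valid <- measurements$valid & !is.na(r)
  if (!is.finite(iris_radius_px) || iris_radius_px <= 0 ||
      (any(valid) && iris_radius_px <= max(r[valid])))
    stop("iris_radius_px must be positive and exceed every pupil radius")
  n <- length(r)
  out <- data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / fps,
                    radius_px = ifelse(valid, r, NA_real_), valid = valid)
  attr(out, "fps") <- fps
  attr(out, "protocol") <- protocol
  attr(out, "iris_radius_px") <- iris_radius_px
  class(out) <- c("pupil_trace", "data.frame")
  out
}

#' @export
print.pupil_trace <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("Pupillogram: %d frames at %g fps (%s protocol), iris %.1f px, %d invalid frame(s)\n",
              nrow(x), attr(x, "fps"), p$type, attr(x, "iris_radius_px"),
              sum(!x$valid)))
  invisible(x)
}

#' Detect blinks and apply the exclusion rule
#'
#' Blink intervals are maximal runs of unusable frames: frames whose fit
#' is invalid, plus frames whose radius jumps by more than
#' \code{jump_px_per_frame} relative to the previous frame (eyelid
#' transit). A recording with more than three blinks is excluded from
#' parameter extraction.
#'
#' @param trace a \code{\link{build_trace}} pupillogram.
#' @param jump_px_per_frame frame-to-frame radius jump flagged as blink
#'   artifact.
#' @return a list of class \code{blink_report}: \code{blink_intervals}
#'   (data.frame of 0-based start/end frames), \code{blink_count},
#'   \code{excluded}.
#' @export
detect_blinks <- function(trace, jump_px_per_frame = 10) {
  stopifnot(inherits(trace, "pupil_trace"))
  bad <- !trace$valid
  r <- trace$radius_px
  jump <- c(FALSE, abs(diff(r)) > jump_px_per_frame)
  jump[is.na(jump)] <- FALSE
  bad <- bad | jump
  runs <- rle(bad)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  iv <- data.frame(start_frame = trace$frame[starts[runs$values]],
                   end_frame = trace$frame[ends[runs$values]])
  structure(list(blink_intervals = iv,
                 blink_count = nrow(iv),
                 excluded = nrow(iv) > 3),
            class = "blink_report")
}

#' @export
print.blink_report <- function(x, ...) {
  cat(sprintf("Blink report: %d blink(s)%s\n", x$blink_count,
              if (x$excluded) " -- recording EXCLUDED (more than three blinks)" else ""))
  invisible(x)
}

#' Pre-flash (baseline) pupil radius
#'
#' Radius of the last valid frame strictly before the flash — the
#' "frame preceding the flash" denominator of the pupil/iris ratios.
#'
#' @param trace a pupillogram.
#' @param flash_time flash time in seconds.
#' @return radius in pixels.
#' @export
baseline_radius <- function(trace, flash_time) {
  i <- which(trace$time_s < flash_time & trace$valid)
  if (length(i) == 0) stop("no valid frame before the flash")
  trace$radius_px[max(i)]
}

#' First level crossing of the pupillogram
#'
#' First time the radius crosses \code{level_px} in the stated direction
#' within the window, linearly interpolated between the two straddling
#' frames. Only pairs of adjacent valid frames are considered; a
#' crossing landing exactly on a frame returns that frame's time.
#'
#' @param trace a pupillogram.
#' @param level_px radius level to cross.
#' @param window \code{c(t0, t1)} search window in seconds.
#' @param direction \code{"down"} or \code{"up"}.
#' @return crossing time in seconds, or \code{NA_real_} when the trace
#'   does not cross the level within the window (the parameter is then
#'   reported missing, not fabricated).
#' @export
crossing_time <- function(trace, level_px, window, direction = c("down", "up")) {
  direction <- match.arg(direction)
  sel <- which(trace$time_s >= window[1] & trace$time_s <= window[2])
  if (length(sel) < 2) return(NA_real_)
  for (j in sel[-length(sel)]) {
    if (!trace$valid[j] || !trace$valid[j + 1]) next
    r0 <- trace$radius_px[j]; r1 <- trace$radius_px[j + 1]
    hit <- if (direction == "down") r0 >= level_px && r1 < level_px
           else r0 <= level_px && r1 > level_px
    if (hit) {
      f <- (r0 - level_px) / (r0 - r1)
      return(trace$time_s[j] + f * (trace$time_s[j + 1] - trace$time_s[j]))
    }
  }
  NA_real_
}

#' Extraction options
#'
#' The printed parameter list leaves two quantities open, surfaced here
#' as configuration instead of a guess. \emph{Duration of constriction}:
#' the default definition runs from the onset crossing (radius down to
#' 90% of baseline) to the first sustained redilation (radius rising for
#' \code{redilation_run} consecutive valid frames at or after the
#' minimum); alternatives are onset-to-minimum and onset-to-75%-recovery.
#' \emph{Velocity denominator}: the literal definition (amplitude
#' divided by the duration of constriction) is the default; the
#' onset-to-minimum interval is available as an alternative.
#'
#' @param duration_def endpoint rule for the duration of constriction.
#' @param velocity_denominator interval dividing the reflex amplitude.
#' @param post_flash_window_s search window after a single flash for the
#'   constriction minimum.
#' @param redilation_run consecutive rising valid frames declaring
#'   sustained redilation.
#' @param jump_px_per_frame blink jump threshold, passed to
#'   \code{\link{detect_blinks}}.
#' @return a list of class \code{extract_config}.
#' @export
extract_config <- function(duration_def = c("onset_to_redilation",
                                            "onset_to_min",
                                            "onset_to_recovery75"),
                           velocity_denominator = c("duration",
                                                    "onset_to_min"),
                           post_flash_window_s = 1.5,
                           redilation_run = 3,
                           jump_px_per_frame = 10) {
  duration_def <- match.arg(duration_def)
  velocity_denominator <- match.arg(velocity_denominator)
  stopifnot(post_flash_window_s > 0, redilation_run >= 1)
  structure(list(duration_def = duration_def,
                 velocity_denominator = velocity_denominator,
                 post_flash_window_s = post_flash_window_s,
                 redilation_run = redilation_run,
                 jump_px_per_frame = jump_px_per_frame),
            class = "extract_config")
}

## Frame-aligned minimum over valid frames in [t0, t1]; the printed
## minima are frame-based, so no interpolation here.
window_minimum <- function(trace, t0, t1) {
  sel <- which(trace$time_s >= t0 & trace$time_s <= t1 & trace$valid)
  if (length(sel) == 0) return(list(radius = NA_real_, time = NA_real_))
  i <- sel[which.min(trace$radius_px[sel])]
  list(radius = trace$radius_px[i], time = trace$time_s[i], index = i)
}

## First sustained redilation at/after frame index i0: earliest valid
## frame from which the radius strictly rises for `run` consecutive
## valid steps.
redilation_time <- function(trace, i0, run) {
  idx <- which(trace$valid & seq_len(nrow(trace)) >= i0)
  if (length(idx) < run + 1) return(NA_real_)
  r <- trace$radius_px[idx]
  for (k in seq_len(length(idx) - run)) {
    if (all(diff(r[k:(k + run)]) > 0)) return(trace$time_s[idx[k]])
  }
  NA_real_
}

## Duration of constriction under the configured definition.
constriction_duration <- function(trace, flash_t, onset_t, min_info,
                                  baseline, config) {
  if (is.na(onset_t)) return(NA_real_)
  end_t <- switch(config$duration_def,
    onset_to_min = min_info$time,
    onset_to_redilation = redilation_time(trace, min_info$index,
                                          config$redilation_run),
    onset_to_recovery75 = crossing_time(trace, 0.75 * baseline,
                                        c(min_info$time,
                                          trace$time_s[nrow(trace)]), "up"))
  if (is.na(end_t)) return(NA_real_)
  end_t - onset_t
}
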