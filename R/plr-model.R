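#' Generative pupil-light-reflex model
#'
#' Parameterizes an analytic pupil-radius response to a light flash: the
#' radius holds at \code{baseline_radius_px} until \code{latency_onset_s}
#' after the flash, decreases linearly to \code{min_radius_px} at
#' \code{time_to_min_s} after the flash, then recovers exponentially with
#' time constant \code{recovery_tau_s} toward a plateau at
#' \code{recovery_plateau_fraction * baseline_radius_px}. Under a 1 Hz
#' flash train the effective pre-flash baseline shrinks geometrically:
#' with adaptation factor \eqn{a}, the baseline before flash \eqn{k} is
#' \deqn{B_k = a B + (1 - a) B a^{k-1},}
#' i.e. it converges geometrically (rate \eqn{a}) to a steady state at
#' fraction \eqn{a} of the dark-adapted baseline. All measured reflex
#' parameters (onset-crossing latency, minimum, plateau crossing) are
#' analytically known, which is what makes the model useful as ground
#' truth for the detection and extraction stages.
#'
#' @param baseline_radius_px dark-adapted pupil radius (pixels, > 0).
#' @param min_radius_px radius at maximal constriction (pixels,
#'   < baseline). For the plateau crossing at 75% of baseline to exist
#'   the minimum must lie below 0.75 * baseline.
#' @param latency_onset_s delay between flash and the start of
#'   constriction (seconds, >= 0).
#' @param time_to_min_s time from flash to maximal constriction
#'   (seconds, > latency_onset_s). Must be < 1 s for the 25-flash train.
#' @param recovery_plateau_fraction fraction of the (per-flash) baseline
#'   the radius recovers toward, in (0, 1].
#' @param recovery_tau_s exponential recovery time constant (seconds).
#' @param train_adaptation_fraction per-flash baseline adaptation factor
#'   in (0, 1]; 1 disables adaptation.
#' @return an object of class \code{plr_model}.
#' @export
plr_model <- function(baseline_radius_px = 60,
                      min_radius_px = 42,
                      latency_onset_s = 0.2,
                      time_to_min_s = 0.9,
                      recovery_plateau_fraction = 0.85,
                      recovery_tau_s = 1.2,
                      train_adaptation_fraction = 0.6) {
  stopifnot(baseline_radius_px > 0,
            min_radius_px > 0,
            min_radius_px < baseline_radius_px,
            latency_onset_s >= 0,
            time_to_min_s > latency_onset_s,
            recovery_plateau_fraction > 0,
            recovery_plateau_fraction <= 1,
            recovery_tau_s > 0,
            train_adaptation_fraction > 0,
            train_adaptation_fraction <= 1)
  plateau <- recovery_plateau_fraction * baseline_radius_px
  if (plateau < min_radius_px)
    stop("plateau radius (recovery_plateau_fraction * baseline) must be >= min_radius_px")
  structure(list(baseline_radius_px = baseline_radius_px,
                 min_radius_px = min_radius_px,
                 latency_onset_s = latency_onset_s,
                 time_to_min_s = time_to_min_s,
                 recovery_plateau_fraction = recovery_plateau_fraction,
                 recovery_tau_s = recovery_tau_s,
                 train_adaptation_fraction = train_adaptation_fraction),
            class = "plr_model")
}

#' @export
print.plr_model <- function(x, ...) {
  cat("Pupil light reflex model\n")
  cat(sprintf("  baseline %.1f px, minimum %.1f px (%.0f%% constriction)\n",
              x$baseline_radius_px, x$min_radius_px,
              100 * (1 - x$min_radius_px / x$baseline_radius_px)))
  cat(sprintf("  onset latency %.3f s, time to minimum %.3f s\n",
              x$latency_onset_s, x$time_to_min_s))
  cat(sprintf("  recovery: tau %.2f s toward %.0f%% of baseline\n",
              x$recovery_tau_s, 100 * x$recovery_plateau_fraction))
  cat(sprintf("  train adaptation factor %.2f\n", x$train_adaptation_fraction))
  invisible(x)
}

#' Flash stimulation protocols
#'
#' A protocol records the flash times, the fixed flash characteristics
#' (10 ms duration, 250 cd intensity), the recording duration and the
#' frame rate. \code{single_flash_protocol} is the 3 s single-flash
#' recording; \code{train_protocol} is the 25-flash, 1 Hz, 30 s
#' recording. Flash times must be strictly increasing and covered by the
#' recording.
#'
#' @param flash_time_s time of the single flash (seconds into the recording).
#' @param recording_duration_s recording length in seconds.
#' @param fps frames per second (the recorder captures a frame every
#'   1/30 s by default).
#' @return an object of class \code{flash_protocol}.
#' @export
single_flash_protocol <- function(flash_time_s = 0.5,
                                  recording_duration_s = 3,
                                  fps = 30) {
  flash_protocol(flash_times_s = flash_time_s,
                 recording_duration_s = recording_duration_s,
                 fps = fps, type = "single")
}

#' @rdname single_flash_protocol
#' @param first_flash_s time of the first train flash; the remaining 24
#'   follow at 1 s spacing.
#' @export
train_protocol <- function(first_flash_s = 1,
                           recording_duration_s = 30,
                           fps = 30) {
  flash_protocol(flash_times_s = first_flash_s + 0:24,
                 recording_duration_s = recording_duration_s,
                 fps = fps, type = "train25")
}

#' @rdname single_flash_protocol
#' @param flash_times_s vector of flash times (seconds), strictly increasing.
#' @param type protocol tag, \code{"single"} or \code{"train25"}.
#' @export
flash_protocol <- function(flash_times_s, recording_duration_s, fps = 30,
                           type = c("single", "train25")) {
  type <- match.arg(type)
  stopifnot(length(flash_times_s) >= 1,
            all(diff(flash_times_s) > 0),
            all(flash_times_s >= 0),
            all(flash_times_s < recording_duration_s),
            fps > 0)
  if (type == "train25") {
    if (length(flash_times_s) != 25 || any(abs(diff(flash_times_s) - 1) > 1e-9))
      stop("train25 protocol requires 25 flashes at 1-s spacing")
  } else if (length(flash_times_s) != 1) {
    stop("single-flash protocol takes exactly one flash time")
  }
  structure(list(flash_times_s = as.numeric(flash_times_s),
                 flash_duration_ms = 10,
                 flash_intensity_cd = 250,
                 recording_duration_s = recording_duration_s,
                 fps = fps,
                 type = type),
            class = "flash_protocol")
}

#' @export
print.flash_protocol <- function(x, ...) {
  cat(sprintf("Flash protocol '%s': %d flash(es), %g s recording at %g fps\n",
              x$type, length(x$flash_times_s), x$recording_duration_s, x$fps))
  invisible(x)
}

## Effective pre-flash baselines B_k for the train protocol.
train_baselines <- function(model, n_flashes = 25) {
  a <- model$train_adaptation_fraction
  B <- model$baseline_radius_px
  Bss <- a * B
  Bss + (B - Bss) * a^(seq_len(n_flashes) - 1)
}

#' Evaluate the model pupil radius at time t
#'
#' Piecewise-analytic radius of the modeled reflex at arbitrary times
#' within the recording. For the single-flash protocol the response is
#' baseline / linear constriction / exponential recovery. For the
#' 25-flash train, the response within each 1 s inter-flash window runs
#' from the adapted baseline \eqn{B_k} down to \eqn{(m/B) B_k} and back
#' up linearly to \eqn{B_{k+1}} at the next flash, so the radius in the
#' frame preceding each flash tracks the geometric adaptation; the last
#' window uses the single-flash exponential recovery shape.
#'
#' @param model a \code{\link{plr_model}}.
#' @param protocol a \code{\link{flash_protocol}}.
#' @param t time(s) in seconds; must lie within
#'   \code{[0, recording_duration_s]}.
#' @return pupil radius (pixels), vectorized over \code{t}.
#' @export
plr_radius <- function(model, protocol, t) {
  stopifnot(inherits(model, "plr_model"), inherits(protocol, "flash_protocol"))
  if (any(t < 0 | t > protocol$recording_duration_s))
    stop("t outside the recording interval")
  if (protocol$type == "single") {
    single_flash_radius(model, protocol$flash_times_s[1],
                        model$baseline_radius_px, t)
  } else {
    train_radius(model, protocol, t)
  }
}

## Single-flash response with an arbitrary effective baseline B
## (minimum scales as (min/baseline) * B, plateau as plateau_fraction * B).
single_flash_radius <- function(model, flash_t, B, t) {
  f_min <- model$min_radius_px / model$baseline_radius_px
  m <- f_min * B
  P <- model$recovery_plateau_fraction * B
  L <- model$latency_onset_s
  Tm <- model$time_to_min_s
  u <- t - flash_t
  r <- rep(B, length(t))
  con <- u >= L & u < Tm
  r[con] <- B + (m - B) * (u[con] - L) / (Tm - L)
  rec <- u >= Tm
  r[rec] <- P - (P - m) * exp(-(u[rec] - Tm) / model$recovery_tau_s)
  r
}

## Under 1 Hz stimulation the constriction phase is faster than after an
## isolated flash (latency to largest constriction ~0.7 s), so the
## per-window constriction time is capped at TRAIN_TIME_TO_MIN; recovery
## then rises linearly to the next flash's adapted baseline, reached at
## TRAIN_HOLD so the frame preceding each flash sits exactly at B_k for
## any frame rate of 20 fps or more.
TRAIN_TIME_TO_MIN <- 0.68
TRAIN_HOLD <- 0.95

train_radius <- function(model, protocol, t) {
  ft <- protocol$flash_times_s
  n <- length(ft)
  Bk <- train_baselines(model, n)
  Tm <- min(model$time_to_min_s, TRAIN_TIME_TO_MIN)
  L <- model$latency_onset_s
  if (L >= Tm)
    stop("latency_onset_s must be below the train constriction time")
  f_min <- model$min_radius_px / model$baseline_radius_px
  r <- numeric(length(t))
  k <- findInterval(t, ft)           # 0 before first flash, n in last window
  pre <- k == 0
  r[pre] <- Bk[1]
  last <- k == n
  if (any(last)) {
    model25 <- model
    model25$time_to_min_s <- Tm
    r[last] <- single_flash_radius(model25, ft[n], Bk[n], t[last])
  }
  mid <- !pre & !last
  if (any(mid)) {
    ki <- k[mid]
    u <- t[mid] - ft[ki]
    B <- Bk[ki]
    m <- f_min * B
    Bnext <- Bk[ki + 1]
    ri <- B
    ri <- ifelse(u >= L & u < Tm, B + (m - B) * (u - L) / (Tm - L), ri)
    ri <- ifelse(u >= Tm & u < TRAIN_HOLD,
                 m + (Bnext - m) * (u - Tm) / (TRAIN_HOLD - Tm), ri)
    ri <- ifelse(u >= TRAIN_HOLD, Bnext, ri)
    r[mid] <- ri
  }
  r
}

#' Analytic values of the measured single-flash parameters
#'
#' Closed-form values, under the generative model, of the quantities the
#' extraction stage measures from a pupillogram: the 90%-of-baseline
#' downward-crossing latency (start of constriction), the latency to and
#' radius at maximal constriction, the 75%-of-baseline upward-crossing
#' latency (plateau), and the reflex amplitude. Latencies are measured
#' from the flash.
#'
#' @inheritParams plr_radius
#' @return a list with elements \code{baseline_px}, \code{min_px},
#'   \code{amplitude_px}, \code{onset_latency_s}, \code{min_latency_s},
#'   \code{plateau_latency_s} (NA when the model never falls below 75%
#'   of baseline).
#' @export
plr_truth <- function(model, protocol = single_flash_protocol()) {
  B <- model$baseline_radius_px
  m <- model$min_radius_px
  L <- model$latency_onset_s
  Tm <- model$time_to_min_s
  P <- model$recovery_plateau_fraction * B
  onset <- L + (Tm - L) * (0.1 * B) / (B - m)
  plateau <- NA_real_
  if (m < 0.75 * B && P > 0.75 * B)
    plateau <- Tm + model$recovery_tau_s * log((P - m) / (P - 0.75 * B))
  list(baseline_px = B, min_px = m, amplitude_px = B - m,
       onset_latency_s = onset, min_latency_s = Tm,
       plateau_latency_s = plateau)
}

#' Sample the model at the camera frame times
#'
#' Evaluates \code{\link{plr_radius}} at \code{frame / fps} for every
#' frame of the recording and optionally marks blink intervals (frames
#' rendered with the eye closed). The result is the ground-truth trace
#' against which detection and extraction are validated.
#'
#' @inheritParams plr_radius
#' @param fps frames per second; defaults to the protocol's.
#' @param blink_intervals optional list of integer vectors
#'   \code{c(start_frame, end_frame)} (0-based, inclusive) to render as
#'   closed-eye frames.
#' @return a data.frame of class \code{ground_truth} with columns
#'   \code{frame} (0-based), \code{time_s}, \code{radius_px},
#'   \code{blink}; the model and protocol are kept as attributes.
#' @export
generate_ground_truth <- function(model, protocol, fps = protocol$fps,
                                  blink_intervals = NULL) {
  n <- round(protocol$recording_duration_s * fps)
  frame <- 0:(n - 1)
  time_s <- frame / fps
  radius <- plr_radius(model, protocol, time_s)
  blink <- rep(FALSE, n)
  for (iv in blink_intervals) {
    stopifnot(length(iv) == 2, iv[1] <= iv[2], iv[1] >= 0, iv[2] < n)
    blink[(iv[1]:iv[2]) + 1] <- TRUE
  }
  out <- data.frame(frame = frame, time_s = time_s, radius_px = radius,
                    blink = blink)
  attr(out, "model") <- model
  attr(out, "protocol") <- protocol
  attr(out, "fps") <- fps
  class(out) <- c("ground_truth", "data.frame")
  out
}
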