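#' Measure pupil (and optionally iris) radius on one frame
#'
#' Runs the full offline measurement chain on a frame: ROI crop, glint
#' detection and fill, high-boost + gamma enhancement, Canny pupil-edge
#' detection, and circle-template correlation fitting. A frame whose
#' edge map is empty or whose fit score falls below the configured floor
#' (a blink, or occlusion beyond tolerance) yields a flagged invalid
#' measurement, not an error. Fit coordinates are reported in full-frame
#' pixels (ROI offset added back).
#'
#' @param frame grayscale matrix (8-bit levels).
#' @param roi optional \code{c(top, left, height, width)} (0-based);
#'   default is the full frame.
#' @param config a \code{\link{detect_config}}.
#' @param measure_iris also fit the iris on this frame (done on the
#'   glint-free image, before enhancement).
#' @return a list of class \code{frame_measurement}: \code{pupil}
#'   (\code{circle_fit} or NULL), \code{iris} (\code{circle_fit} or
#'   NULL), \code{valid}.
#' @export
measure_frame <- function(frame, roi = NULL, config = detect_config(),
                          measure_iris = FALSE) {
  stopifnot(is.matrix(frame))
  if (is.null(roi)) roi <- c(0, 0, nrow(frame), ncol(frame))
  sub <- crop_roi(frame, roi)
  off <- attr(sub, "roi_offset")
  glints <- detect_glints(sub, config)
  clean <- remove_glints(sub, glints, config$glint_fill_gray)
  iris <- NULL
  if (measure_iris) {
    iris <- tryCatch(fit_iris_circle(clean, config),
                     error = function(e) NULL)
    if (!is.null(iris)) iris$center_px <- iris$center_px + off
  }
  enh <- enhance(clean, config$boost_factor, config$gamma)
  edges <- pupil_edges(enh, config)
  pupil <- tryCatch(fit_pupil_circle(edges, config),
                    error = function(e) NULL)
  if (!is.null(pupil)) pupil$center_px <- pupil$center_px + off
  structure(list(pupil = pupil, iris = iris,
                 valid = !is.null(pupil) && pupil$converged),
            class = "frame_measurement")
}

#' Measure a frame sequence
#'
#' Applies \code{\link{measure_frame}} to every frame. The iris radius
#' is measured once, on the first frame whose pupil fit is valid, and
#' reused for the whole recording (the pupil/iris ratio denominator is
#' per-recording); set \code{iris_per_frame = TRUE} to re-measure per
#' frame.
#'
#' @param frames list of grayscale matrices in frame order.
#' @param roi optional ROI passed to \code{\link{measure_frame}}.
#' @param config a \code{\link{detect_config}}.
#' @param fps frames per second (for the time column).
#' @param iris_per_frame re-fit the iris on every frame.
#' @return a data.frame of class \code{frame_measurements} with columns
#'   \code{frame} (0-based), \code{time_s}, \code{pupil_radius_px},
#'   \code{pupil_row}, \code{pupil_col}, \code{score}, \code{valid},
#'   \code{iris_radius_px}.
#' @export
measure_sequence <- function(frames, roi = NULL, config = detect_config(),
                             fps = 30, iris_per_frame = FALSE) {
  stopifnot(is.list(frames), length(frames) > 0)
  n <- length(frames)
  out <- data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / fps,
                    pupil_radius_px = NA_real_, pupil_row = NA_real_,
                    pupil_col = NA_real_, score = NA_real_,
                    valid = FALSE, iris_radius_px = NA_real_)
  iris_r <- NA_real_
  for (i in seq_len(n)) {
    want_iris <- iris_per_frame || is.na(iris_r)
    m <- measure_frame(frames[[i]], roi, config, measure_iris = want_iris)
    if (!is.null(m$pupil)) {
      out$pupil_radius_px[i] <- m$pupil$radius_px
      out$pupil_row[i] <- m$pupil$center_px[1]
      out$pupil_col[i] <- m$pupil$center_px[2]
      out$score[i] <- m$pupil$score
    }
    out$valid[i] <- m$valid
    if (!is.null(m$iris) && m$valid) {
      out$iris_radius_px[i] <- m$iris$radius_px
      if (is.na(iris_r)) iris_r <- m$iris$radius_px
    }
  }
  if (!iris_per_frame) out$iris_radius_px <- iris_r
  class(out) <- c("frame_measurements", "data.frame")
  out
}
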