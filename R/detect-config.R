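#' Detection configuration
#'
#' Tunable constants of the per-frame measurement pipeline. The defaults
#' are the published operating point of the recorder's offline
#' algorithm: Canny threshold 0.8 for glint detection, glint fill gray
#' 35 (the pupil gray level under the fixed IR illumination), high-boost
#' edge enhancement followed by a 0.6-gamma intensity transformation,
#' Canny threshold 0.5 for the pupil-iris frontier, and a circle-radius
#' search from 20 to 90 px in 0.2 px steps. Quantities the published
#' description leaves open (hysteresis ratio, smoothing sigma, boost
#' factor, center search, score floor) are explicit here.
#'
#' @param glint_canny_threshold high Canny threshold for glint contours.
#' @param glint_fill_gray gray level written over glint regions.
#' @param glint_dilate_px dilation radius applied to the glint mask so
#'   the anti-aliased halo is covered.
#' @param glint_min_gray minimum peak gray level of a filled contour
#'   region for it to count as a specular reflection.
#' @param boost_factor high-boost amplification A in A*I - blur(I);
#'   must be > 1.
#' @param gamma exponent of the intensity transformation.
#' @param edge_canny_threshold high Canny threshold for pupil edges.
#' @param canny_low_ratio low/high hysteresis ratio for both detectors.
#' @param canny_sigma Gaussian pre-smoothing SD (pixels).
#' @param radius_min_px,radius_max_px,radius_step_px pupil radius search
#'   grid.
#' @param ring_thickness_px thickness of the annular correlation
#'   template.
#' @param center_window_px half-width of the integer-center search
#'   window around the edge centroid (\code{center_search = "window"});
#'   the window expands automatically if the best center lands on its
#'   hull.
#' @param center_window_coarse half-width of the coarse re-seeding sweep
#'   used when the windowed search ends below the score floor (heavy
#'   occlusion shifts the edge centroid).
#' @param center_coarse_step grid step of the coarse sweep.
#' @param center_search \code{"window"} (staged) or \code{"full"}
#'   (every integer center; exhaustive).
#' @param score_floor normalized correlation below which a fit is
#'   declared not converged (blink / occlusion beyond tolerance); about
#'   a quarter of the score of an ideal full ring.
#' @param iris_radius_range integer radius range of the circular Hough
#'   search for the iris.
#' @param iris_center_window_px half-width of the Hough center window.
#' @param iris_score_floor minimum normalized accumulator peak
#'   (votes / circumference) for an iris fit.
#' @param iris_edge_threshold high Canny threshold for the iris edge map.
#' @return an object of class \code{detect_config}.
#' @export
detect_config <- function(glint_canny_threshold = 0.8,
                          glint_fill_gray = 35,
                          glint_dilate_px = 2,
                          glint_min_gray = 200,
                          boost_factor = 2.0,
                          gamma = 0.6,
                          edge_canny_threshold = 0.5,
                          canny_low_ratio = 0.4,
                          canny_sigma = 1.0,
                          radius_min_px = 20,
                          radius_max_px = 90,
                          radius_step_px = 0.2,
                          ring_thickness_px = 1.0,
                          center_window_px = 5,
                          center_window_coarse = 40,
                          center_coarse_step = 4,
                          center_search = c("window", "full"),
                          score_floor = 0.2,
                          iris_radius_range = c(95, 140),
                          iris_center_window_px = 5,
                          iris_score_floor = 0.25,
                          iris_edge_threshold = 0.5) {
  center_search <- match.arg(center_search)
  stopifnot(glint_canny_threshold > 0, glint_canny_threshold < 1,
            edge_canny_threshold > 0, edge_canny_threshold < 1,
            iris_edge_threshold > 0, iris_edge_threshold < 1,
            canny_low_ratio > 0, canny_low_ratio <= 1,
            canny_sigma > 0,
            glint_fill_gray >= 0, glint_fill_gray <= 255,
            glint_dilate_px >= 0,
            gamma > 0,
            radius_min_px > 0, radius_min_px < radius_max_px,
            radius_step_px > 0,
            ring_thickness_px > 0,
            center_window_px >= 1,
            score_floor >= 0,
            length(iris_radius_range) == 2,
            iris_radius_range[1] < iris_radius_range[2])
  if (boost_factor <= 1)
    stop("boost_factor must be > 1")
  structure(as.list(environment()), class = "detect_config")
}

#' Crop a region of interest
#'
#' Extracts the half-open ROI \code{[top, top+height) x [left,
#' left+width)} (0-based offsets) from a frame. Downstream fits on the
#' cropped image report full-frame coordinates by adding the ROI offset
#' back.
#'
#' @param frame grayscale matrix.
#' @param roi c(top, left, height, width), 0-based.
#' @return the sub-matrix, with the offset kept as attribute
#'   \code{roi_offset}.
#' @export
crop_roi <- function(frame, roi) {
  stopifnot(is.matrix(frame), length(roi) == 4)
  top <- roi[1]; left <- roi[2]; h <- roi[3]; w <- roi[4]
  if (top < 0 || left < 0 || h < 1 || w < 1 ||
      top + h > nrow(frame) || left + w > ncol(frame))
    stop("ROI extends outside the frame")
  sub <- frame[(top + 1):(top + h), (left + 1):(left + w), drop = FALSE]
  attr(sub, "roi_offset") <- c(top, left)
  sub
}
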