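#' Synthetic eye scene description
#'
#' Geometry and gray levels of the rendered infrared eye image: a dark
#' pupil disk (gray ~35) on a brighter iris annulus over a dark
#' background (the blackened cone interior), with four bright IR-LED
#' glints near the pupil center, an optional eyelid occluder over the
#' top of the pupil, and optional additive Gaussian gray-level noise.
#'
#' @param image_size_px c(height, width) of the frame.
#' @param pupil_center_px c(row, col) of the pupil/iris center
#'   (1-based pixel coordinates; integer centers are used by default,
#'   radius being the measurand).
#' @param iris_radius_px iris radius in pixels; the iris annulus must
#'   lie fully inside the image.
#' @param pupil_gray,iris_gray,background_gray 8-bit gray levels; the
#'   pupil must be darker than the iris.
#' @param glint_offsets 4 x 2 matrix of (row, col) offsets of the glint
#'   centers relative to the pupil center.
#' @param glint_radius_px,glint_gray glint disk radius and gray level
#'   (brighter than the iris).
#' @param eyelid_coverage_fraction fraction of the pupil circumference
#'   occluded from the top by the eyelid, in [0, 0.5) so at least half
#'   the circumference stays visible.
#' @param noise_sigma_gray SD of additive Gaussian noise (gray levels).
#' @param seed RNG seed used by \code{\link{render_sequence}}.
#' @return an object of class \code{eye_scene}.
#' @export
eye_scene <- function(image_size_px = c(240, 320),
                      pupil_center_px = c(120, 160),
                      iris_radius_px = 110,
                      pupil_gray = 35,
                      iris_gray = 160,
                      background_gray = 10,
                      glint_offsets = rbind(c(-8, -8), c(-8, 8),
                                            c(8, -8), c(8, 8)),
                      glint_radius_px = 3,
                      glint_gray = 250,
                      eyelid_coverage_fraction = 0,
                      noise_sigma_gray = 0,
                      seed = 1L) {
  stopifnot(length(image_size_px) == 2, all(image_size_px >= 16),
            length(pupil_center_px) == 2,
            iris_radius_px > 0,
            pupil_gray >= 0, pupil_gray <= 255,
            iris_gray > pupil_gray, iris_gray <= 255,
            background_gray >= 0, background_gray <= 255,
            is.matrix(glint_offsets), ncol(glint_offsets) == 2,
            glint_radius_px > 0,
            glint_gray > iris_gray, glint_gray <= 255,
            eyelid_coverage_fraction >= 0, eyelid_coverage_fraction < 0.5,
            noise_sigma_gray >= 0)
  if (pupil_center_px[1] - iris_radius_px < 1 ||
      pupil_center_px[1] + iris_radius_px > image_size_px[1] ||
      pupil_center_px[2] - iris_radius_px < 1 ||
      pupil_center_px[2] + iris_radius_px > image_size_px[2])
    stop("iris annulus extends outside the image")
  structure(list(image_size_px = as.integer(image_size_px),
                 pupil_center_px = pupil_center_px,
                 iris_radius_px = iris_radius_px,
                 pupil_gray = pupil_gray,
                 iris_gray = iris_gray,
                 background_gray = background_gray,
                 glint_offsets = glint_offsets,
                 glint_radius_px = glint_radius_px,
                 glint_gray = glint_gray,
                 eyelid_coverage_fraction = eyelid_coverage_fraction,
                 noise_sigma_gray = noise_sigma_gray,
                 seed = seed),
            class = "eye_scene")
}

## Anti-aliased disk coverage: fraction of each pixel inside the circle,
## linearized over a 1 px band at the boundary.
disk_coverage <- function(d, radius) pmin(pmax(radius - d + 0.5, 0), 1)

#' Render one synthetic eye frame
#'
#' Anti-aliased rendering of the scene at a given pupil radius. Glint
#' disks overwrite the pupil, the eyelid (at iris gray level) occludes
#' the stated fraction of the pupil circumference from the top, and
#' \code{blink = TRUE} renders a fully occluded (closed) eye. Additive
#' Gaussian noise uses the current RNG state; seed externally (or via
#' \code{\link{render_sequence}}) for reproducibility.
#'
#' @param scene an \code{\link{eye_scene}}.
#' @param pupil_radius_px pupil radius for this frame; must be smaller
#'   than the iris radius.
#' @param blink render a closed eye.
#' @return an integer-valued matrix (height x width) of 8-bit gray levels.
#' @export
render_eye_frame <- function(scene, pupil_radius_px, blink = FALSE) {
  stopifnot(inherits(scene, "eye_scene"))
  nr <- scene$image_size_px[1]; nc <- scene$image_size_px[2]
  if (!blink && pupil_radius_px >= scene$iris_radius_px)
    stop("pupil radius must be smaller than the iris radius")
  if (blink) {
    img <- matrix(scene$iris_gray, nr, nc)
  } else {
    cr <- scene$pupil_center_px[1]; cc <- scene$pupil_center_px[2]
    dr2 <- (seq_len(nr) - cr)^2
    dc2 <- (seq_len(nc) - cc)^2
    d <- sqrt(outer(dr2, dc2, `+`))
    img <- matrix(scene$background_gray, nr, nc)
    ci <- disk_coverage(d, scene$iris_radius_px)
    img <- img * (1 - ci) + scene$iris_gray * ci
    cp <- disk_coverage(d, pupil_radius_px)
    img <- img * (1 - cp) + scene$pupil_gray * cp
    for (g in seq_len(nrow(scene$glint_offsets))) {
      gr <- cr + scene$glint_offsets[g, 1]
      gc <- cc + scene$glint_offsets[g, 2]
      dg <- sqrt(outer((seq_len(nr) - gr)^2, (seq_len(nc) - gc)^2, `+`))
      cg <- disk_coverage(dg, scene$glint_radius_px)
      img <- img * (1 - cg) + scene$glint_gray * cg
    }
    if (scene$eyelid_coverage_fraction > 0) {
      # lid edge row such that the occluded top arc is the stated
      # fraction of the pupil circumference
      lid_row <- cr - pupil_radius_px *
        cos(pi * scene$eyelid_coverage_fraction)
      cl <- pmin(pmax(lid_row - (seq_len(nr) - 0.5), 0), 1)
      cl <- matrix(cl, nr, nc)
      img <- img * (1 - cl) + scene$iris_gray * cl
    }
  }
  if (scene$noise_sigma_gray > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, scene$noise_sigma_gray), nr, nc)
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

#' Render a full frame sequence from a ground-truth trace
#'
#' One frame per ground-truth sample; blink samples are rendered as a
#' closed eye. The scene seed is applied once at the start so the stack
#' is bit-identical across runs with the same scene and truth.
#'
#' @param scene an \code{\link{eye_scene}}.
#' @param truth a \code{\link{generate_ground_truth}} trace.
#' @return a list of frame matrices.
#' @export
render_sequence <- function(scene, truth) {
  stopifnot(inherits(truth, "ground_truth"), nrow(truth) > 0)
  set.seed(scene$seed)
  lapply(seq_len(nrow(truth)), function(i)
    render_eye_frame(scene, truth$radius_px[i], blink = truth$blink[i]))
}
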