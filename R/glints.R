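#' Detect IR-LED glints
#'
#' The specular reflections of the four IR illumination LEDs are the
#' highest-contrast structures in the image, so a Canny detector with a
#' high threshold (default 0.8 on the max-normalized gradient) returns
#' one-pixel contour lines around the glints only. The closed contours
#' are then filled to form the glint mask: the contour map is dilated to
#' seal one-pixel diagonal gaps, contours running off the image are
#' closed against the border, and everything not reachable from the
#' border background is taken as glint. The mask is finally dilated by
#' \code{glint_dilate_px} so the anti-aliased halo around each glint is
#' covered.
#'
#' @param sub grayscale matrix (ROI).
#' @param config a \code{\link{detect_config}}.
#' @return a logical matrix, \code{TRUE} on glint pixels (empty when the
#'   image has no high-contrast reflections).
#' @export
detect_glints <- function(sub, config = detect_config()) {
  stopifnot(is.matrix(sub))
  e <- canny_edges(sub, high = config$glint_canny_threshold,
                   low_ratio = config$canny_low_ratio,
                   sigma = config$canny_sigma)
  if (!any(e)) return(matrix(FALSE, nrow(sub), ncol(sub)))
  barrier <- close_against_border(e)
  # 4-connected background flood from the border; glint = not background.
  # (A 4-connected flood cannot leak through an 8-connected one-pixel
  # contour, so the raw Canny line is a sufficient barrier.)
  bg <- EBImage::bwlabel(!barrier)
  nr <- nrow(sub); nc <- ncol(sub)
  border_labels <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  border_labels <- border_labels[border_labels > 0]
  mask <- matrix(!(bg %in% border_labels), nr, nc)
  # Glints are near-saturated specular reflections; on a glint-free
  # frame the highest-contrast contour is the iris rim, whose filled
  # interior is nowhere near white. Screen every filled component by
  # its peak gray level so only true reflections are replaced.
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    peak <- tapply(sub[lab > 0], lab[lab > 0], max)
    keep <- as.integer(names(peak))[peak >= config$glint_min_gray]
    mask <- matrix(lab %in% keep, nr, nc)
  }
  if (config$glint_dilate_px > 0) {
    b <- EBImage::makeBrush(2 * ceiling(config$glint_dilate_px) + 1, "box")
    mask <- EBImage::dilate(mask * 1, b) > 0
  }
  matrix(as.logical(mask), nr, nc)
}

## Close contour components that touch the image border: on each border
## line, bridge gaps between nearby contour endpoints so that regions
## cut by the ROI edge can still be filled.
close_against_border <- function(barrier, max_gap = 25) {
  nr <- nrow(barrier); nc <- ncol(barrier)
  bridge <- function(v) {
    pos <- which(v)
    if (length(pos) >= 2) {
      gaps <- diff(pos)
      for (i in which(gaps > 1 & gaps <= max_gap))
        v[pos[i]:pos[i + 1]] <- TRUE
    }
    v
  }
  barrier[1, ] <- bridge(barrier[1, ])
  barrier[nr, ] <- bridge(barrier[nr, ])
  barrier[, 1] <- bridge(barrier[, 1])
  barrier[, nc] <- bridge(barrier[, nc])
  barrier
}

#' Replace glint pixels by the pupil gray level
#'
#' Writes \code{fill_gray} (default 35, the pupil gray level under the
#' recorder's fixed IR illumination) over every masked pixel; all other
#' pixels are untouched.
#'
#' @param sub grayscale matrix.
#' @param mask logical matrix from \code{\link{detect_glints}}.
#' @param fill_gray replacement gray level.
#' @return the filled matrix.
#' @export
remove_glints <- function(sub, mask, fill_gray = 35) {
  stopifnot(is.matrix(sub), is.logical(mask))
  if (!all(dim(mask) == dim(sub)))
    stop("glint mask shape does not match the image")
  if (is.integer(sub)) fill_gray <- as.integer(round(fill_gray))
  sub[mask] <- fill_gray
  sub
}

#' High-boost edge enhancement with gamma correction
#'
#' Sharpens the glint-free image with an unsharp-mask-family high-boost
#' filter, \code{A * I - blur3x3(I)} on intensities normalized to
#' [0, 1] and clipped, then applies the pointwise gamma transformation
#' \code{s = r^gamma} (default 0.6), which expands contrast at the dark
#' end where the pupil-iris frontier lives. The result is rescaled to
#' 8 bits.
#'
#' @param sub grayscale matrix (glint-free).
#' @param boost_factor amplification A > 1.
#' @param gamma exponent of the intensity transformation.
#' @return enhanced matrix on the 0-255 scale.
#' @export
enhance <- function(sub, boost_factor = 2.0, gamma = 0.6) {
  stopifnot(is.matrix(sub))
  if (boost_factor <= 1)
    stop("boost_factor must be > 1")
  r <- sub / 255
  hb <- boost_factor * r - box_blur3(r)
  hb <- pmin(pmax(hb, 0), 1)
  hb^gamma * 255
}

#' Pupil-iris frontier edge map
#'
#' Canny edge detection (default high threshold 0.5) on the enhanced
#' image. On a clean frame the edge pixels form a ring at the pupil-iris
#' frontier (plus the iris outer rim, which lies beyond the pupil radius
#' search range); under eyelid/eyelash occlusion the ring is broken but
#' the visible arc remains.
#'
#' @param enhanced matrix from \code{\link{enhance}}.
#' @param config a \code{\link{detect_config}}.
#' @return logical edge map.
#' @export
pupil_edges <- function(enhanced, config = detect_config()) {
  canny_edges(enhanced, high = config$edge_canny_threshold,
              low_ratio = config$canny_low_ratio,
              sigma = config$canny_sigma)
}
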