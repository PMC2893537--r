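#' Locate the iris by circular Hough transform
#'
#' Canny edge detection on the glint-free image followed by circular
#' Hough accumulation restricted to radii beyond the pupil search range
#' (default 95-140 px). For each candidate integer center in a window
#' around the edge centroid, edge pixels vote into 1 px radius bins by
#' their rounded distance; votes are normalized by the circle
#' circumference so radii compete fairly. The peak accumulator cell
#' gives (center, radius) and the radius is refined below the bin width
#' by quadratic interpolation of the accumulator around the peak.
#'
#' @param sub glint-free grayscale matrix containing the full iris.
#' @param config a \code{\link{detect_config}}.
#' @return a \code{circle_fit}. A missing or too-weak accumulator peak
#'   (normalized votes below \code{iris_score_floor}) raises a no-fit
#'   error.
#' @export
fit_iris_circle <- function(sub, config = detect_config()) {
  stopifnot(is.matrix(sub))
  e <- canny_edges(sub, high = config$iris_edge_threshold,
                   low_ratio = config$canny_low_ratio,
                   sigma = config$canny_sigma)
  ep <- which(e, arr.ind = TRUE)
  if (nrow(ep) == 0)
    stop("no edges: cannot locate the iris")
  rr <- as.integer(round(config$iris_radius_range))
  r_ints <- rr[1]:rr[2]
  nbin <- length(r_ints)
  er <- as.numeric(ep[, 1]); ec <- as.numeric(ep[, 2])
  cr0 <- round(mean(er)); cc0 <- round(mean(ec))
  w <- config$iris_center_window_px
  best <- list(score = -Inf, votes = NULL, ir = NA, cr = NA, cc = NA)
  for (cr in max(1, cr0 - w):min(nrow(sub), cr0 + w)) {
    for (cc in max(1, cc0 - w):min(ncol(sub), cc0 + w)) {
      d <- round(sqrt((er - cr)^2 + (ec - cc)^2)) - rr[1] + 1
      votes <- tabulate(d[d >= 1 & d <= nbin], nbins = nbin)
      nv <- votes / (2 * pi * r_ints)
      i <- which.max(nv)
      if (nv[i] > best$score)
        best <- list(score = nv[i], votes = nv, ir = i, cr = cr, cc = cc)
    }
  }
  if (!is.finite(best$score) || best$score < config$iris_score_floor)
    stop("no iris-scale circle found (accumulator peak below floor)")
  radius <- r_ints[best$ir]
  i <- best$ir
  if (i > 1 && i < nbin) {
    v <- best$votes[(i - 1):(i + 1)]
    denom <- v[1] - 2 * v[2] + v[3]
    if (denom < 0)
      radius <- radius + 0.5 * (v[1] - v[3]) / denom
  }
  circle_fit(center_px = c(best$cr, best$cc), radius_px = radius,
             score = best$score, converged = TRUE)
}
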