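## Sub-pixel circle fitting by annular-template correlation.
##
## For every candidate radius r on the configured grid (default 20-90 px
## in 0.2 px steps) an annular contour template of thickness
## ring_thickness_px is formed, anti-aliased by fractional-coverage
## weighting: a pixel at distance d from the center gets weight
##   w(u) = clamp((t+1)/2 - u, 0, min(1, t)),   u = |d - r|,
## the overlap length of the unit pixel interval with the ring band.
## The template is normalized to zero mean over the full image domain
## and correlated with the binary edge map; the reported fit maximizes
## the normalized correlation over (integer center) x (radius grid),
## ties broken toward the smaller radius, then smaller center.
##
## The score of a candidate (c, r) only needs three radial sums --
## sum(w) over edge pixels, and sum(w), sum(w^2) over all pixels --
## which are computed exactly from sorted pixel-center distances and
## prefix sums. For centers far enough from the image border the
## all-pixel sums are translation invariant and cached per radius grid.

circle_fit <- function(center_px, radius_px, score, converged) {
  structure(list(center_px = center_px, radius_px = radius_px,
                 score = score, converged = converged),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.2f, %.2f), radius %.2f px, score %.4f%s\n",
              x$center_px[1], x$center_px[2], x$radius_px, x$score,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

## Exact radial sums. ds: sorted distances; p1, p2: prefix sums of ds
## and ds^2 (leading 0); r: vector of radii; t: ring thickness.
## Returns S = sum(w) and (optionally) Q = sum(w^2) per radius.
ring_sums <- function(ds, p1, p2, r, t, squares = TRUE) {
  b2 <- (t + 1) / 2
  m <- min(1, t)
  b1 <- b2 - m
  iL0 <- findInterval(r - b2, ds)
  iL1 <- findInterval(r - b1, ds)
  iR0 <- findInterval(r + b1, ds)
  iR1 <- findInterval(r + b2, ds)
  nL <- iL1 - iL0
  sL <- p1[iL1 + 1] - p1[iL0 + 1]
  cL <- r - b2
  nF <- iR0 - iL1
  nR <- iR1 - iR0
  sR <- p1[iR1 + 1] - p1[iR0 + 1]
  cR <- r + b2
  S <- (sL - nL * cL) + m * nF + (nR * cR - sR)
  if (!squares) return(list(S = S))
  s2L <- p2[iL1 + 1] - p2[iL0 + 1]
  s2R <- p2[iR1 + 1] - p2[iR0 + 1]
  Q <- (s2L - 2 * cL * sL + nL * cL^2) + m^2 * nF +
    (nR * cR^2 - 2 * cR * sR + s2R)
  list(S = S, Q = Q)
}

.fit_cache <- new.env(parent = emptyenv())

## Translation-invariant all-pixel sums S(r), Q(r) for centers whose
## full ring support lies inside the image; cached per radius grid.
ring_norm_profile <- function(rmin, rmax, step, t) {
  key <- paste(rmin, rmax, step, t, sep = "|")
  hit <- .fit_cache[[key]]
  if (!is.null(hit)) return(hit)
  b2 <- (t + 1) / 2
  Rc <- as.integer(ceiling(rmax + b2))
  off2 <- (-Rc:Rc)^2
  d <- sqrt(outer(off2, off2, `+`))
  d <- d[d < rmax + b2 & d > rmin - b2]
  ds <- sort(d)
  p1 <- c(0, cumsum(ds))
  p2 <- c(0, cumsum(ds^2))
  r_grid <- seq(rmin, rmax, by = step)
  sq <- ring_sums(ds, p1, p2, r_grid, t, squares = TRUE)
  out <- list(Rc = Rc, r_grid = r_grid, S = sq$S, Q = sq$Q)
  .fit_cache[[key]] <- out
  out
}

## All-pixel sums for a center too close to the border (ring support
## clipped by the image): exact sums over the clipped support.
ring_norm_clipped <- function(cr, cc, nr, nc, rmin, rmax, t, r_grid, Rc) {
  b2 <- (t + 1) / 2
  rows <- max(1L, cr - Rc):min(nr, cr + Rc)
  cols <- max(1L, cc - Rc):min(nc, cc + Rc)
  d <- sqrt(outer((rows - cr)^2, (cols - cc)^2, `+`))
  d <- d[d < rmax + b2 & d > rmin - b2]
  ds <- sort(d)
  p1 <- c(0, cumsum(ds))
  p2 <- c(0, cumsum(ds^2))
  ring_sums(ds, p1, p2, r_grid, t, squares = TRUE)
}

#' Fit the pupil circle to an edge map
#'
#' Maximizes the normalized correlation between the binary edge map and
#' zero-mean annular contour templates over all radii on the configured
#' grid (default 20-90 px, 0.2 px resolution) and integer circle
#' centers. The center search is staged: a window of
#' \code{center_window_px} around the edge-pixel centroid is scanned
#' exhaustively and expanded whenever the best center lies on the window
#' hull, so the staged search agrees with brute force over every integer
#' center; \code{center_search = "full"} forces the exhaustive scan.
#' Score ties break toward the smaller radius, then the smaller center
#' (row, then column). A fit whose score falls below
#' \code{score_floor} (about a quarter of an ideal full-ring score) is
#' flagged \code{converged = FALSE}, the blink/occlusion signal.
#'
#' @param edges logical edge map (e.g. from \code{\link{pupil_edges}}).
#' @param config a \code{\link{detect_config}}.
#' @return a \code{circle_fit}: center (row, col), radius (px),
#'   normalized correlation score, convergence flag.
#' @export
fit_pupil_circle <- function(edges, config = detect_config()) {
  stopifnot(is.matrix(edges))
  ep <- which(edges != 0, arr.ind = TRUE)
  if (nrow(ep) == 0)
    stop("empty edge map: no circle to fit")
  nr <- nrow(edges); nc <- ncol(edges)
  N <- as.numeric(nr) * nc
  nE <- nrow(ep)
  t <- config$ring_thickness_px
  prof <- ring_norm_profile(config$radius_min_px, config$radius_max_px,
                            config$radius_step_px, t)
  r_grid <- prof$r_grid
  Rc <- prof$Rc
  eden <- nE - nE^2 / N
  er <- as.numeric(ep[, 1]); ec <- as.numeric(ep[, 2])

  score_center <- function(cr, cc) {
    de <- sort(sqrt((er - cr)^2 + (ec - cc)^2))
    pe <- c(0, cumsum(de))
    A <- ring_sums(de, pe, NULL, r_grid, t, squares = FALSE)$S
    if (cr - Rc >= 1 && cr + Rc <= nr && cc - Rc >= 1 && cc + Rc <= nc) {
      S <- prof$S; Q <- prof$Q
    } else {
      sq <- ring_norm_clipped(cr, cc, nr, nc, config$radius_min_px,
                              config$radius_max_px, t, r_grid, Rc)
      S <- sq$S; Q <- sq$Q
    }
    num <- A - S * (nE / N)
    den2 <- pmax(Q - S^2 / N, 0) * eden
    sc <- ifelse(den2 > 0, num / sqrt(den2), -Inf)
    i <- which.max(sc)                 # first max: smallest radius wins ties
    c(sc[i], r_grid[i])
  }

  best <- c(-Inf, NA_real_, NA_real_, NA_real_)  # score, r, cr, cc
  seen <- matrix(FALSE, nr, nc)
  consider <- function(cr, cc) {
    s <- score_center(cr, cc)
    b <- best
    if (s[1] > b[1] ||
        (s[1] == b[1] && (s[2] < b[2] ||
                          (s[2] == b[2] && (cr < b[3] ||
                                            (cr == b[3] && cc < b[4]))))))
      best <<- c(s[1], s[2], cr, cc)
  }

  scan_window <- function(cr0, cc0, w) {
    repeat {
      rows <- max(1L, cr0 - w):min(nr, cr0 + w)
      cols <- max(1L, cc0 - w):min(nc, cc0 + w)
      for (cc in cols) for (cr in rows) {
        if (!seen[cr, cc]) {
          seen[cr, cc] <<- TRUE
          consider(cr, cc)
        }
      }
      on_hull <- (best[3] == rows[1] && rows[1] > 1) ||
        (best[3] == rows[length(rows)] && rows[length(rows)] < nr) ||
        (best[4] == cols[1] && cols[1] > 1) ||
        (best[4] == cols[length(cols)] && cols[length(cols)] < nc)
      if (!on_hull) break
      cr0 <- best[3]; cc0 <- best[4]
      w <- w + config$center_window_px
      if (w > max(nr, nc)) break
    }
  }

  if (config$center_search == "full") {
    for (cc in seq_len(nc)) for (cr in seq_len(nr)) consider(cr, cc)
  } else {
    cr0 <- round(mean(er)); cc0 <- round(mean(ec))
    scan_window(cr0, cc0, config$center_window_px)
    if (best[1] < config$score_floor) {
      # Heavy occlusion biases the edge centroid and can trap the local
      # window on a sidelobe: re-seed from a coarse sweep of candidate
      # centers, then refine locally.
      W2 <- config$center_window_coarse
      st <- config$center_coarse_step
      for (cc in seq(max(1L, cc0 - W2), min(nc, cc0 + W2), by = st))
        for (cr in seq(max(1L, cr0 - W2), min(nr, cr0 + W2), by = st)) {
          if (!seen[cr, cc]) {
            seen[cr, cc] <- TRUE
            consider(cr, cc)
          }
        }
      scan_window(best[3], best[4], config$center_window_px)
    }
  }
  circle_fit(center_px = c(best[3], best[4]),
             radius_px = best[2],
             score = best[1],
             converged = is.finite(best[1]) && best[1] >= config$score_floor)
}
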