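## Low-level image operations (matrices, replicate border padding) and a
## Canny edge detector. No installed R package in this stack provides an
## edge detector, so it is implemented here: Gaussian smoothing, Sobel
## gradients, quantized non-maximum suppression, and hysteresis
## thresholding on the max-normalized gradient magnitude. The threshold
## arguments follow the single-threshold convention used throughout the
## pipeline: the given value is the HIGH hysteresis threshold and the
## low threshold is low_ratio * high.

pad_replicate <- function(m, k) {
  if (k == 0) return(m)
  m <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), , drop = FALSE]
  m[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
}

## Separable convolution: kr along rows (vertical), kc along columns
## (horizontal), both odd-length, replicate padding.
conv_sep <- function(m, kr, kc) {
  hr <- (length(kr) - 1L) / 2L
  hc <- (length(kc) - 1L) / 2L
  p <- pad_replicate(m, max(hr, hc))
  off <- max(hr, hc)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, ncol(p))
  for (i in seq_along(kr))
    tmp <- tmp + kr[i] * p[(off - hr + i - 1L) + seq_len(nr), ]
  out <- matrix(0, nr, nc)
  for (j in seq_along(kc))
    out <- out + kc[j] * tmp[, (off - hc + j - 1L) + seq_len(nc)]
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  conv_sep(m, k, k)
}

## 3x3 box blur (the high-boost smoother).
box_blur3 <- function(m) conv_sep(m, rep(1 / 3, 3), rep(1 / 3, 3))

sobel_gradients <- function(m) {
  # gx: horizontal derivative (along columns), gy: vertical (along rows)
  gx <- conv_sep(m, c(1, 2, 1), c(-1, 0, 1))
  gy <- conv_sep(m, c(-1, 0, 1), c(1, 2, 1))
  list(gx = gx, gy = gy)
}

## Shift matrix by (dr, dc) with zero fill.
mat_shift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## 8-connected labeling built on EBImage's 4-connected bwlabel: label a
## 3x3-dilated mask and project the labels back onto the original pixels.
## Components closer than 2 px may merge, which is harmless for
## hysteresis linking and region screening.
label8 <- function(mask) {
  dil <- EBImage::dilate(mask * 1, EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(dil)
  lab[!mask] <- 0
  lab
}

#' Canny edge detection
#'
#' Classical Canny detector on an 8-bit grayscale matrix: Gaussian
#' pre-smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then hysteresis thresholding. The
#' gradient magnitude is normalized by its maximum so thresholds live on
#' [0, 1]; \code{high} is the high hysteresis threshold and the low
#' threshold is \code{low_ratio * high}. Weak edge pixels are kept only
#' when 8-connected to a strong pixel.
#'
#' @param img numeric matrix of gray levels (any range; only gradients
#'   relative to the image maximum matter).
#' @param high high hysteresis threshold in (0, 1).
#' @param low_ratio low/high threshold ratio.
#' @param sigma Gaussian pre-smoothing SD in pixels.
#' @return a logical matrix marking edge pixels.
#' @export
canny_edges <- function(img, high = 0.5, low_ratio = 0.4, sigma = 1.0) {
  stopifnot(is.matrix(img), high > 0, high < 1, low_ratio > 0, low_ratio <= 1)
  nr <- nrow(img); nc <- ncol(img)
  g <- gaussian_blur(img, sigma)
  gr <- sobel_gradients(g)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  mag[1, ] <- 0; mag[nr, ] <- 0; mag[, 1] <- 0; mag[, nc] <- 0
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nr, nc))
  mag <- mag / mx
  # non-maximum suppression only at above-low-threshold candidates
  low <- low_ratio * high
  cand <- which(mag >= low)
  if (length(cand) == 0) return(matrix(FALSE, nr, nc))
  gx <- gr$gx[cand]; gy <- gr$gy[cand]
  ax <- abs(gx); ay <- abs(gy)
  tt <- tan(pi / 8)
  # quantized gradient direction -> neighbor offset in column-major index
  off <- ifelse(ay <= tt * ax, nr,                    # ~ horizontal gradient
         ifelse(ax <= tt * ay, 1L,                    # ~ vertical
         ifelse(gx * gy > 0, nr + 1L, nr - 1L)))      # diagonals
  mc <- mag[cand]
  keep <- mc >= mag[cand + off] & mc > mag[cand - off]
  cand <- cand[keep]
  if (length(cand) == 0) return(matrix(FALSE, nr, nc))
  weak <- matrix(FALSE, nr, nc)
  weak[cand] <- TRUE
  strong_idx <- cand[mag[cand] >= high]
  if (length(strong_idx) == 0) return(matrix(FALSE, nr, nc))
  lab <- label8(weak)
  keep_lab <- unique(lab[strong_idx])
  keep_lab <- keep_lab[keep_lab > 0]
  out <- matrix(FALSE, nr, nc)
  out[cand[lab[cand] %in% keep_lab]] <- TRUE
  out
}
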