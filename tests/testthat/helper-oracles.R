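# Independent oracles used to validate the implementation paths.

# Brute-force circle fit: for every integer center and grid radius,
# build the anti-aliased annular template explicitly as a full image,
# normalize to zero mean, and compute the normalized correlation with
# the edge map directly. Ties: smaller radius, then smaller center.
oracle_circle_fit <- function(edges, rmin, rmax, step, t = 1) {
  nr <- nrow(edges); nc <- ncol(edges); N <- nr * nc
  E <- which(edges); nE <- length(E)
  r_grid <- seq(rmin, rmax, by = step)
  b2 <- (t + 1) / 2; mcap <- min(1, t)
  best <- c(-Inf, NA_real_, NA_real_, NA_real_)
  for (cc in 1:nc) for (cr in 1:nr) {
    d <- sqrt(outer((1:nr - cr)^2, (1:nc - cc)^2, `+`))
    for (r in r_grid) {
      w <- pmin(pmax(b2 - abs(d - r), 0), mcap)
      S <- sum(w); Q <- sum(w * w)
      num <- sum(w[E]) - S * nE / N
      den2 <- (Q - S^2 / N) * (nE - nE^2 / N)
      sc <- if (den2 > 0) num / sqrt(den2) else -Inf
      if (sc > best[1] ||
          (sc == best[1] && (r < best[2] ||
            (r == best[2] && (cr < best[3] ||
              (cr == best[3] && cc < best[4]))))))
        best <- c(sc, r, cr, cc)
    }
  }
  list(score = best[1], radius = best[2], center = best[3:4])
}

# Rasterize a circle (or partial arc) into a binary edge map.
mk_circle_edges <- function(nr, nc, cr, cc, r, arc_frac = 1, arc_start = 0) {
  th <- arc_start + seq(0, 2 * pi * arc_frac,
                        length.out = max(32, round(4 * pi * r)))
  rows <- round(cr + r * sin(th))
  cols <- round(cc + r * cos(th))
  ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  e <- matrix(FALSE, nr, nc)
  e[cbind(rows[ok], cols[ok])] <- TRUE
  e
}

# Explicit sum-of-squares one-way ANOVA.
anova_oracle <- function(groups) {
  x <- unlist(groups)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(x) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Explicit rank-sum Kruskal-Wallis with tie correction.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  rk <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rs <- tapply(rk, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(statistic = h,
       p_value = stats::pchisq(h, length(groups) - 1, lower.tail = FALSE))
}

# Connected components by explicit flood fill (8-connectivity).
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in 1:nc) for (i in 1:nr) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# Default test scene/model shared by several files.
test_scene <- function(...) eye_scene(...)
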