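test_that("an exact circle is recovered to the 0.2 px search resolution", {
  e <- mk_circle_edges(120, 120, 60, 60, 43.0)
  fit <- fit_pupil_circle(e, detect_config(radius_min_px = 20,
                                           radius_max_px = 60))
  expect_lte(abs(fit$radius_px - 43.0), 0.2)
  expect_equal(fit$center_px, c(60, 60))
  expect_true(fit$converged)
})

test_that("a quarter-erased circle still fits within 1 px", {
  e <- mk_circle_edges(140, 140, 70, 70, 50, arc_frac = 0.75,
                       arc_start = pi / 4)
  fit <- fit_pupil_circle(e, detect_config(radius_min_px = 20,
                                           radius_max_px = 70))
  expect_lte(abs(fit$radius_px - 50), 1.0)
})

test_that("the staged search equals the brute-force oracle on small instances", {
  cfg <- detect_config(radius_min_px = 10, radius_max_px = 26,
                       radius_step_px = 1, center_window_px = 10)
  set.seed(101)
  for (i in 1:3) {
    cr <- sample(26:38, 1); cc <- sample(26:38, 1)
    r <- runif(1, 12, 22)
    e <- mk_circle_edges(64, 64, cr, cc, r,
                         arc_frac = sample(c(1, 0.8), 1))
    ora <- oracle_circle_fit(e, 10, 26, 1)
    fit <- fit_pupil_circle(e, cfg)
    expect_equal(fit$radius_px, ora$radius)
    expect_equal(fit$center_px, ora$center)
    expect_equal(fit$score, ora$score, tolerance = 1e-10)
  }
})

test_that("the score at the true circle dominates displaced candidates", {
  e <- mk_circle_edges(120, 120, 60, 60, 40)
  cfg <- detect_config(radius_min_px = 20, radius_max_px = 60)
  fit <- fit_pupil_circle(e, cfg)
  score_at <- function(cr, cc, r) {
    # direct template score at one candidate (same definition as oracle)
    N <- 120 * 120; E <- which(e); nE <- length(E)
    d <- sqrt(outer((1:120 - cr)^2, (1:120 - cc)^2, `+`))
    w <- pmin(pmax(1 - abs(d - r), 0), 1)
    S <- sum(w); Q <- sum(w * w)
    (sum(w[E]) - S * nE / N) /
      sqrt((Q - S^2 / N) * (nE - nE^2 / N))
  }
  for (dd in list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(0, 0, -2),
                  c(-2, 2, 2))) {
    expect_gt(fit$score, score_at(60 + dd[1], 60 + dd[2], 40 + dd[3]))
  }
})

test_that("an empty edge map is a no-fit error and weak scores flag non-convergence", {
  expect_error(fit_pupil_circle(matrix(FALSE, 50, 50), detect_config()),
               "empty edge map")
  # a scatter of unstructured pixels must not converge
  set.seed(5)
  e <- matrix(FALSE, 120, 120)
  e[cbind(sample(120, 25), sample(120, 25))] <- TRUE
  fit <- fit_pupil_circle(e, detect_config(radius_min_px = 20,
                                           radius_max_px = 60))
  expect_false(fit$converged)
})

test_that("iris localization by Hough transform is accurate to ~1 px", {
  sc <- test_scene()
  cfg <- detect_config()
  f <- render_eye_frame(sc, 50)
  clean <- remove_glints(f, detect_glints(f, cfg), 35)
  fit <- fit_iris_circle(clean, cfg)
  expect_lte(abs(fit$radius_px - 110), 1)
  # no iris-scale circle -> no-fit error
  expect_error(fit_iris_circle(matrix(35, 100, 100), cfg), "no")
  # randomized scenes: max error within 2 px
  errs <- vapply(1:6, function(s) {
    set.seed(s)
    ir <- runif(1, 100, 120)
    sci <- eye_scene(iris_radius_px = ir, seed = s)
    fi <- render_eye_frame(sci, runif(1, 30, 60))
    ci <- remove_glints(fi, detect_glints(fi, cfg), 35)
    abs(fit_iris_circle(ci, cfg)$radius_px - ir)
  }, 0)
  expect_lte(max(errs), 2)
})

test_that("measure_frame composes the chain and flags blinks invalid", {
  sc <- test_scene()
  m <- measure_frame(render_eye_frame(sc, 60), measure_iris = TRUE)
  expect_true(m$valid)
  expect_lte(abs(m$pupil$radius_px - 60), 0.2)
  expect_lte(abs(m$iris$radius_px - 110), 1)
  mb <- measure_frame(render_eye_frame(sc, 60, blink = TRUE))
  expect_false(mb$valid)
})

test_that("a short sequence yields ordered measurements with a shared iris", {
  sc <- test_scene()
  radii <- c(55, 54, 53)
  frames <- lapply(radii, function(r) render_eye_frame(sc, r))
  ms <- measure_sequence(frames, fps = 30)
  expect_equal(nrow(ms), 3)
  expect_equal(ms$frame, 0:2)
  expect_equal(ms$pupil_radius_px, radii, tolerance = 0.01)
  expect_equal(length(unique(ms$iris_radius_px)), 1)
})

test_that("noise at sigma 5 keeps the radius error within 0.5 px", {
  sc <- eye_scene(noise_sigma_gray = 5)
  set.seed(11)
  errs <- vapply(c(25, 50, 80), function(r)
    abs(measure_frame(render_eye_frame(sc, r))$pupil$radius_px - r), 0)
  expect_lte(max(errs), 0.5)
})
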