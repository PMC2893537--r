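test_that("model radius is baseline before onset, minimum at time-to-min, plateau in the limit", {
  m <- plr_model(baseline_radius_px = 60, min_radius_px = 48,
                 latency_onset_s = 0.2, time_to_min_s = 0.9,
                 recovery_plateau_fraction = 0.83, recovery_tau_s = 0.5)
  p <- single_flash_protocol(flash_time_s = 0, recording_duration_s = 60)
  expect_equal(plr_radius(m, p, 0), 60)
  expect_equal(plr_radius(m, p, 0.9), 48)
  # closed-form limit of the exponential recovery: 0.83 * 60 = 49.8,
  # checked against numerical evaluation at large t
  expect_equal(plr_radius(m, p, 59), 49.8, tolerance = 1e-6)
  expect_error(plr_radius(m, p, 61), "outside")
  expect_error(plr_radius(m, p, -0.1), "outside")
})

test_that("model construction enforces the parameter invariants", {
  expect_error(plr_model(min_radius_px = 70), "min_radius")
  expect_error(plr_model(time_to_min_s = 0.1, latency_onset_s = 0.2))
  expect_error(plr_model(recovery_tau_s = 0))
  expect_error(plr_model(recovery_plateau_fraction = 0.5, min_radius_px = 42),
               "plateau")
})

test_that("protocols validate flash timing", {
  expect_error(flash_protocol(c(1, 1), 30, type = "train25"))
  expect_error(flash_protocol(c(1, 2), 30, type = "train25"), "25 flashes")
  expect_error(flash_protocol(c(0.5, 0.4), 3))
  p <- train_protocol()
  expect_length(p$flash_times_s, 25)
  expect_equal(unique(diff(p$flash_times_s)), 1)
})

test_that("ground truth samples at frame times and injects blinks", {
  m <- plr_model()
  g1 <- generate_ground_truth(m, single_flash_protocol())
  expect_equal(nrow(g1), 90)
  expect_equal(g1$time_s, (0:89) / 30)
  g2 <- generate_ground_truth(m, train_protocol())
  expect_equal(nrow(g2), 900)
  gb <- generate_ground_truth(m, single_flash_protocol(),
                              blink_intervals = list(c(10, 13)))
  expect_equal(which(gb$blink), 11:14)
  # flat model: no reflex
  mf <- plr_model(baseline_radius_px = 60, min_radius_px = 59.9999,
                  recovery_plateau_fraction = 1)
  gf <- generate_ground_truth(mf, single_flash_protocol())
  expect_lt(diff(range(gf$radius_px)), 1e-3)
  # radii bounded by the dark baseline above and the fully adapted
  # minimum (constriction fraction times the steady-state baseline) below
  f_min <- m$min_radius_px / m$baseline_radius_px
  floor_px <- f_min * m$train_adaptation_fraction * m$baseline_radius_px
  expect_true(all(g2$radius_px >= floor_px - 1e-9))
  expect_true(all(g2$radius_px <= m$baseline_radius_px + 1e-9))
})

test_that("analytic truth matches a numeric root-finder on the model curve", {
  m <- plr_model()
  p <- single_flash_protocol()
  tru <- plr_truth(m, p)
  f <- function(t) plr_radius(m, p, t)
  on <- uniroot(function(t) f(t) - 0.9 * m$baseline_radius_px,
                c(p$flash_times_s + m$latency_onset_s,
                  p$flash_times_s + m$time_to_min_s), tol = 1e-10)$root
  expect_equal(tru$onset_latency_s, on - p$flash_times_s, tolerance = 1e-6)
  pl <- uniroot(function(t) f(t) - 0.75 * m$baseline_radius_px,
                c(p$flash_times_s + m$time_to_min_s, 3), tol = 1e-10)$root
  expect_equal(tru$plateau_latency_s, pl - p$flash_times_s, tolerance = 1e-6)
})

test_that("train baseline adapts geometrically toward the steady state", {
  m <- plr_model(train_adaptation_fraction = 0.6)
  p <- train_protocol()
  g <- generate_ground_truth(m, p)
  pres <- vapply(seq_len(25), function(k)
    g$radius_px[max(which(g$time_s < p$flash_times_s[k]))], 0)
  expect_true(all(diff(pres) <= 1e-9))
  dec <- -diff(pres)
  ratios <- dec[-1] / dec[-length(dec)]
  expect_equal(ratios[1:8], rep(0.6, 8), tolerance = 1e-6)
  expect_equal(pres[25], 0.6 * 60 + 0.4 * 60 * 0.6^24, tolerance = 1e-6)
  # non-adapting train: all pre-flash radii equal the dark baseline
  g0 <- generate_ground_truth(plr_model(train_adaptation_fraction = 1), p)
  pres0 <- vapply(c(1, 10, 25), function(k)
    g0$radius_px[max(which(g0$time_s < p$flash_times_s[k]))], 0)
  expect_equal(pres0, rep(60, 3))
})
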