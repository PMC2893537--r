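single_trace <- function(model = plr_model(), protocol = single_flash_protocol(),
                         iris = 110, blink_intervals = NULL) {
  truth <- generate_ground_truth(model, protocol,
                                 blink_intervals = blink_intervals)
  r <- ifelse(truth$blink, NA_real_, truth$radius_px)
  build_trace(r, protocol$fps, protocol, iris)
}

test_that("trace assembly spans the recording and carries gaps", {
  tr <- single_trace()
  expect_equal(nrow(tr), 90)
  expect_equal(range(tr$time_s), c(0, 89 / 30))
  m <- data.frame(pupil_radius_px = c(50, 50, NA, 50), valid = c(TRUE, TRUE, FALSE, TRUE))
  tr2 <- build_trace(m, 30, single_flash_protocol(), 110)
  expect_equal(tr2$valid, c(TRUE, TRUE, FALSE, TRUE))
  expect_true(is.na(tr2$radius_px[3]))
  expect_error(build_trace(m, 30, single_flash_protocol(), 0), "iris")
  expect_error(build_trace(m[0, ], 30, single_flash_protocol(), 110), "no measurements")
})

test_that("blink intervals are maximal runs and the more-than-three rule excludes", {
  mk <- function(bad_runs) {
    v <- rep(TRUE, 90)
    for (iv in bad_runs) v[iv] <- FALSE
    build_trace(data.frame(pupil_radius_px = ifelse(v, 50, NA), valid = v),
                30, single_flash_protocol(), 110)
  }
  b4 <- detect_blinks(mk(list(3:5, 20:22, 50:53, 80:81)))
  expect_equal(b4$blink_count, 4)
  expect_true(b4$excluded)
  b1 <- detect_blinks(mk(list(40:44)))
  expect_equal(b1$blink_count, 1)
  expect_equal(b1$blink_intervals$start_frame, 39)
  expect_equal(b1$blink_intervals$end_frame, 43)
  expect_false(b1$excluded)
  b0 <- detect_blinks(single_trace())
  expect_equal(b0$blink_count, 0)
  # a >10 px/frame jump counts as blink artifact even if fits "succeeded"
  r <- rep(50, 90); r[30] <- 70
  bj <- detect_blinks(build_trace(r, 30, single_flash_protocol(), 110))
  expect_gte(bj$blink_count, 1)
})

test_that("baseline is the last valid frame strictly before the flash", {
  tr <- single_trace()
  expect_equal(baseline_radius(tr, 0.5), 60)
  tr$valid[15] <- FALSE; tr$radius_px[15] <- NA   # frame at t=0.4667
  tr$radius_px[14] <- 59.8
  expect_equal(baseline_radius(tr, 0.5), 59.8)
  expect_error(baseline_radius(tr, 0), "no valid frame")
})

test_that("crossing times interpolate linearly between valid frames", {
  r <- seq(100, 80, length.out = 31)                 # linear over [0, 1] s
  tr <- build_trace(r, 30, single_flash_protocol(flash_time_s = 0.1,
                                                 recording_duration_s = 31 / 30), 150)
  expect_equal(crossing_time(tr, 90, c(0, 31 / 30), "down"), 0.5)
  # constant trace never crosses a level below it
  trc <- build_trace(rep(70, 31), 30, single_flash_protocol(flash_time_s = 0.1,
                                                            recording_duration_s = 31 / 30), 150)
  expect_true(is.na(crossing_time(trc, 60, c(0, 1), "down")))
  # crossing exactly at a frame time returns that frame's time
  expect_equal(crossing_time(tr, r[16], c(0, 31 / 30), "down"), 15 / 30)
})

test_that("single-flash parameters recover the generator truth on analytic traces", {
  model <- plr_model()
  prot <- single_flash_protocol()
  tr <- single_trace(model, prot)
  p <- extract_single_flash(tr)
  tru <- plr_truth(model, prot)
  expect_equal(p$baseline_radius_px, 60)
  expect_lte(abs(p$latency_to_constriction_s - tru$onset_latency_s), 1 / 30)
  expect_lte(abs(p$latency_to_largest_constriction_s - tru$min_latency_s), 1 / 30)
  expect_lte(abs(p$latency_to_plateau_s - tru$plateau_latency_s), 1 / 30)
  expect_equal(p$reflex_amplitude_px, 18)
  expect_equal(p$ratio_PI_darkness, 60 / 110)
  # velocity identity holds to machine precision
  expect_equal(p$velocity_of_constriction_px_per_s * p$duration_of_constriction_s,
               p$reflex_amplitude_px, tolerance = 1e-12)
})

test_that("a flat trace yields zero amplitude and missing crossings", {
  mf <- plr_model(baseline_radius_px = 60, min_radius_px = 59.9999,
                  recovery_plateau_fraction = 1)
  p <- extract_single_flash(single_trace(mf))
  expect_lt(p$reflex_amplitude_px, 1e-3)
  expect_true(is.na(p$latency_to_constriction_s))
  expect_true(is.na(p$latency_to_plateau_s))
})

test_that("parameter ordering and ratio invariants hold over sampled models", {
  set.seed(42)
  for (i in 1:8) {
    iris <- 110
    B <- runif(1, 35, 75)
    model <- plr_model(baseline_radius_px = B,
                       min_radius_px = runif(1, 0.55, 0.72) * B,
                       latency_onset_s = runif(1, 0.1, 0.35),
                       time_to_min_s = runif(1, 0.6, 0.95),
                       recovery_plateau_fraction = runif(1, 0.8, 0.92),
                       recovery_tau_s = runif(1, 0.6, 1.5))
    p <- extract_single_flash(single_trace(model))
    lats <- c(p$latency_to_constriction_s, p$latency_to_largest_constriction_s,
              p$latency_to_plateau_s)
    lats <- lats[!is.na(lats)]
    expect_true(all(diff(lats) >= 0))
    ratios <- c(p$ratio_PI_largest_constriction, p$ratio_PI_plateau,
                p$ratio_PI_darkness)
    ratios <- ratios[!is.na(ratios)]
    expect_true(all(ratios > 0 & ratios < 1))
    expect_true(all(diff(ratios) >= 0))
    expect_equal(p$velocity_of_constriction_px_per_s * p$duration_of_constriction_s,
                 p$reflex_amplitude_px, tolerance = 1e-12)
  }
})

test_that("train extraction tracks the adapting baseline and keeps latencies under 1 s", {
  model <- plr_model()
  prot <- train_protocol()
  truth <- generate_ground_truth(model, prot)
  tr <- build_trace(truth$radius_px, prot$fps, prot, 110)
  p <- extract_flash_train(tr)
  pre_truth <- vapply(c(1, 10, 25), function(k)
    truth$radius_px[max(which(truth$time_s < prot$flash_times_s[k]))], 0)
  expect_equal(c(p$pre_1st_radius_px, p$pre_10th_radius_px, p$pre_25th_radius_px),
               pre_truth, tolerance = 1e-9)
  expect_true(all(c(p$latency_to_constriction_10th_s,
                    p$latency_to_largest_constriction_10th_s,
                    p$latency_to_constriction_25th_s,
                    p$latency_to_largest_constriction_25th_s) < 1))
  expect_true(p$ratio_PI_plateau > 0 && p$ratio_PI_plateau < 1)
})

test_that("excluded recordings are refused by extraction", {
  tr <- single_trace(blink_intervals = list(c(5, 7), c(20, 22), c(70, 72),
                                            c(80, 82)))
  expect_error(extract_single_flash(tr), "excluded")
  tr3 <- single_trace(blink_intervals = list(c(5, 7), c(20, 22), c(80, 82)))
  expect_s3_class(extract_single_flash(tr3), "single_flash_params")
})

test_that("extraction refuses a protocol mismatch", {
  tr <- single_trace()
  expect_error(extract_flash_train(tr), "protocol")
})
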