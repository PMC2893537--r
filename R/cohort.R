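#' Default per-group reflex-parameter distributions
#'
#' Group-level distributions (means and SDs) for sampling per-subject
#' generative reflex models, shaped after the published three-group
#' comparison: the dark-adapted pupil/iris ratio and onset latency are
#' taken from the study's group statistics (healthy 0.55 +/- 0.056,
#' diabetic without CAN 0.42 +/- 0.045, diabetic with CAN
#' 0.35 +/- 0.077; onset latencies 0.20/0.26/0.29 s), while the
#' constriction fraction (minimum / baseline, from the ratio of the
#' printed constriction and darkness ratios) gets a small SD so the
#' plateau at 75% of baseline exists for nearly every sampled subject.
#'
#' @param iris_radius_px fixed iris radius used to map ratios to pixels.
#' @return a named list of group specifications, each a list of
#'   \code{c(mean, sd)} entries.
#' @export
default_group_specs <- function(iris_radius_px = 110) {
  mk <- function(ratio_dark, ratio_dark_sd, constrict_frac, latency, latency_sd)
    list(ratio_dark = c(ratio_dark, ratio_dark_sd),
         constrict_frac = c(constrict_frac, 0.02),
         latency_onset_s = c(latency, latency_sd),
         time_to_min_s = c(0.9, 0.08),
         recovery_plateau_fraction = c(0.85, 0.02),
         recovery_tau_s = c(1.2, 0.15),
         train_adaptation_fraction = c(0.6, 0.03),
         iris_radius_px = iris_radius_px)
  list(healthy = mk(0.55, 0.056, 0.70, 0.20, 0.078),
       diabetic_no_CAN = mk(0.42, 0.045, 0.71, 0.26, 0.070),
       diabetic_CAN = mk(0.35, 0.077, 0.72, 0.29, 0.100))
}

#' Sample a synthetic subject cohort
#'
#' Draws per-subject generative reflex models from the per-group
#' parameter distributions, truncating each draw to its valid range
#' (positive radii, minimum below 74% of baseline so the plateau
#' exists, time-to-minimum inside the 1 s train window). The cohort
#' carries known group effect sizes and is the input for end-to-end
#' exercise of the statistics stage.
#'
#' @param group_specs named list as from \code{\link{default_group_specs}}.
#' @param n_per_group subjects per group (scalar or one per group).
#' @param seed RNG seed.
#' @return data.frame of class \code{plr_cohort_models}: subject_id,
#'   group, iris_radius_px and one column per model parameter.
#' @export
generate_synthetic_cohort <- function(group_specs = default_group_specs(),
                                      n_per_group = c(16, 16, 8),
                                      seed = 1L) {
  stopifnot(is.list(group_specs), length(group_specs) >= 1)
  if (length(n_per_group) == 1)
    n_per_group <- rep(n_per_group, length(group_specs))
  if (length(n_per_group) != length(group_specs))
    stop("n_per_group must be scalar or one per group")
  if (any(n_per_group <= 0)) stop("n_per_group must be positive")
  set.seed(seed)
  rows <- list()
  sid <- 0
  rtrunc <- function(spec, lo, hi) {
    min(max(stats::rnorm(1, spec[1], spec[2]), lo), hi)
  }
  for (gi in seq_along(group_specs)) {
    gname <- names(group_specs)[gi]
    sp <- group_specs[[gi]]
    for (i in seq_len(n_per_group[gi])) {
      sid <- sid + 1
      iris <- sp$iris_radius_px
      ratio <- rtrunc(sp$ratio_dark, 0.2, 0.8)
      frac <- rtrunc(sp$constrict_frac, 0.5, 0.74)
      lat <- rtrunc(sp$latency_onset_s, 0.05, 0.6)
      tmin <- rtrunc(sp$time_to_min_s, lat + 0.1, 0.95)
      rows[[sid]] <- data.frame(
        subject_id = sprintf("S%03d", sid),
        group = gname,
        iris_radius_px = iris,
        baseline_radius_px = ratio * iris,
        min_radius_px = frac * ratio * iris,
        latency_onset_s = lat,
        time_to_min_s = tmin,
        recovery_plateau_fraction = rtrunc(sp$recovery_plateau_fraction,
                                           0.78, 0.95),
        recovery_tau_s = rtrunc(sp$recovery_tau_s, 0.5, 2.5),
        train_adaptation_fraction = rtrunc(sp$train_adaptation_fraction,
                                           0.4, 0.9),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("plr_cohort_models", "data.frame")
  out
}

#' Subject row to generative model
#'
#' @param row one row of a \code{\link{generate_synthetic_cohort}} table.
#' @return a \code{\link{plr_model}}.
#' @export
cohort_model <- function(row) {
  plr_model(baseline_radius_px = row$baseline_radius_px,
            min_radius_px = row$min_radius_px,
            latency_onset_s = row$latency_onset_s,
            time_to_min_s = row$time_to_min_s,
            recovery_plateau_fraction = row$recovery_plateau_fraction,
            recovery_tau_s = row$recovery_tau_s,
            train_adaptation_fraction = row$train_adaptation_fraction)
}

#' Extracted parameter table for a synthetic cohort
#'
#' For every subject, generates the analytic ground-truth pupillogram
#' under the given protocol, builds the trace and runs the parameter
#' extraction, yielding the per-subject parameter table the statistics
#' stage consumes. No image rendering is involved: this path exercises
#' trace extraction and statistics end-to-end at cohort scale.
#'
#' @param cohort a \code{\link{generate_synthetic_cohort}} table.
#' @param protocol a \code{\link{flash_protocol}} (single-flash default).
#' @param config an \code{\link{extract_config}}.
#' @return data.frame: subject_id, group, and the extracted parameters.
#' @export
cohort_parameters <- function(cohort, protocol = single_flash_protocol(),
                              config = extract_config()) {
  stopifnot(inherits(cohort, "plr_cohort_models"))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    model <- cohort_model(row)
    truth <- generate_ground_truth(model, protocol)
    trace <- build_trace(truth$radius_px, fps = protocol$fps,
                         protocol = protocol,
                         iris_radius_px = row$iris_radius_px)
    params <- if (protocol$type == "single")
      extract_single_flash(trace, config)
    else extract_flash_train(trace, config)
    cbind(data.frame(subject_id = row$subject_id, group = row$group,
                     stringsAsFactors = FALSE),
          as.data.frame(params))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
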