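#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way analysis of variance: the ratio of
#' between-group to within-group mean squares, referred to the F
#' distribution on (k - 1, N - k) degrees of freedom (via
#' \code{stats::oneway.test} with equal variances). A fully degenerate
#' input (zero between- and within-group variance) returns F = 0,
#' p = 1 by convention.
#'
#' @param groups list of numeric vectors, one per group; at least two
#'   groups of at least two finite values each.
#' @return list with \code{statistic} (F), \code{p_value}, \code{df}
#'   (numerator, denominator).
#' @export
one_way_anova <- function(groups) {
  check_groups(groups, min_groups = 2)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(x) == 0)
    return(list(statistic = 0, p_value = 1,
                df = c(length(groups) - 1, length(x) - length(groups))))
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       df = unname(ft$parameter))
}

#' Bonferroni post-hoc pairwise comparisons
#'
#' Two-sample t-tests per group pair using the pooled within-group
#' standard deviation (the classical post-hoc companion to one-way
#' ANOVA, via \code{stats::pairwise.t.test} with \code{pool.sd}), with
#' raw p-values multiplied by the number of pairs and capped at 1.
#'
#' @param groups list of numeric vectors (named names are carried
#'   through).
#' @return data.frame with one row per pair: \code{group_a},
#'   \code{group_b}, \code{p_raw}, \code{p_adjusted}.
#' @export
bonferroni_pairwise <- function(groups) {
  check_groups(groups, min_groups = 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  pt <- stats::pairwise.t.test(x, g, p.adjust.method = "none",
                               pool.sd = TRUE)
  pm <- pt$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  npair <- nrow(pairs)
  data.frame(group_a = colnames(pm)[pairs[, 2]],
             group_b = rownames(pm)[pairs[, 1]],
             p_raw = pm[pairs],
             p_adjusted = pmin(1, pm[pairs] * npair))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction, referred to the
#' chi-square approximation (k - 1 df); implemented in its general
#' k-group form via \code{stats::kruskal.test} and used here, as in the
#' source study, mostly with two groups. All-identical samples return
#' H = 0, p = 1.
#'
#' @param ... numeric vectors (two or more groups), or a single list of
#'   them.
#' @return list with \code{statistic} (H), \code{p_value}, \code{df}.
#' @export
kruskal_wallis <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  check_groups(groups, min_groups = 2)
  x <- unlist(groups)
  if (stats::var(x) == 0)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

check_groups <- function(groups, min_groups = 2) {
  if (!is.list(groups) || length(groups) < min_groups)
    stop(sprintf("need at least %d groups", min_groups))
  for (gr in groups) {
    if (length(gr) < 2 || !all(is.finite(gr)))
      stop("each group needs at least two finite values")
  }
  invisible(TRUE)
}

#' Group-comparison table over a cohort of pupillometry parameters
#'
#' Mirrors the study's reporting: per parameter, mean and sample SD
#' (n - 1) per group; one-way ANOVA with Bonferroni post-hoc for the
#' healthy-vs-diabetic contrasts (p1 = healthy vs diabetic without CAN,
#' p2 = healthy vs diabetic with CAN); Kruskal-Wallis for the
#' diabetic-vs-diabetic contrast (p3). Significance markers follow the
#' study's notation: * p < 0.05, # p < 0.01, $ p < 0.001, ns otherwise.
#' No multiplicity correction is applied across parameters.
#'
#' @param cohort data.frame with a \code{group} column (levels
#'   \code{healthy}, \code{diabetic_no_CAN}, \code{diabetic_CAN}) and
#'   one numeric column per parameter.
#' @param parameters parameter columns to test; default, every numeric
#'   column except identifiers.
#' @param alpha significance level for the \code{significant} flags.
#' @return data.frame of class \code{plr_stats_table}, one row per
#'   parameter.
#' @export
build_results_table <- function(cohort, parameters = NULL, alpha = 0.05) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("empty cohort")
  if (!"group" %in% names(cohort)) stop("cohort needs a 'group' column")
  lev <- c("healthy", "diabetic_no_CAN", "diabetic_CAN")
  g <- factor(as.character(cohort$group), levels = lev)
  if (any(is.na(g))) stop("group labels must be one of: ",
                          paste(lev, collapse = ", "))
  if (is.null(parameters)) {
    parameters <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    parameters <- setdiff(parameters, c("subject_id"))
  }
  rows <- list()
  for (p in parameters) {
    if (!p %in% names(cohort)) {
      warning(sprintf("parameter column '%s' missing: skipped", p))
      next
    }
    x <- cohort[[p]]
    ok <- is.finite(x)
    gl <- split(x[ok], g[ok])
    if (any(lengths(gl) < 2)) {
      warning(sprintf("parameter '%s': fewer than 2 values in some group: skipped", p))
      next
    }
    an <- one_way_anova(gl)
    bf <- bonferroni_pairwise(gl)
    key <- paste(bf$group_a, bf$group_b)
    p1 <- bf$p_adjusted[match("healthy diabetic_no_CAN", key)]
    p2 <- bf$p_adjusted[match("healthy diabetic_CAN", key)]
    p3 <- kruskal_wallis(gl$diabetic_no_CAN, gl$diabetic_CAN)$p_value
    rows[[p]] <- data.frame(
      parameter = p,
      mean_healthy = mean(gl$healthy), sd_healthy = stats::sd(gl$healthy),
      mean_no_CAN = mean(gl$diabetic_no_CAN),
      sd_no_CAN = stats::sd(gl$diabetic_no_CAN),
      mean_CAN = mean(gl$diabetic_CAN), sd_CAN = stats::sd(gl$diabetic_CAN),
      anova_F = an$statistic, anova_p = an$p_value,
      p1 = p1, p2 = p2, p3 = p3,
      sig1 = sig_mark(p1), sig2 = sig_mark(p2), sig3 = sig_mark(p3),
      significant = an$p_value < alpha,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no testable parameter columns in the cohort")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("plr_stats_table", "data.frame")
  out
}

sig_mark <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "$" else if (p < 0.01) "#" else if (p < 0.05) "*" else "ns"
}
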