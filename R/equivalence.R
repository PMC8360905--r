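#' Nonparametric bootstrap confidence intervals for a mean
#'
#' Percentile bootstrap of the sample mean: `n_boot` resamples with
#' replacement, with the 90% and 95% intervals taken as quantiles of the same
#' set of resampled means (which guarantees the 90% interval nests inside the
#' 95% one).
#'
#' @param values Numeric vector (length >= 2, finite).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional seed for the resampling.
#' @return An object of class `boot_ci`: `estimate` (the sample mean),
#'   `ci90`, `ci95` (length-2 vectors), `n`, `n_boot`.
#' @examples
#' bootstrap_mean_ci(rnorm(24, 0.3, 0.05), seed = 1)
#' @export
bootstrap_mean_ci <- function(values, n_boot = 1000, seed = NULL) {
  if (!is.numeric(values) || length(values) < 2 || !all(is.finite(values))) {
    stop("`values` must be at least two finite numbers", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  means <- colMeans(matrix(values[idx], nrow = n))
  structure(list(
    estimate = mean(values),
    ci90 = unname(stats::quantile(means, c(0.05, 0.95))),
    ci95 = unname(stats::quantile(means, c(0.025, 0.975))),
    n = n, n_boot = n_boot
  ), class = "boot_ci")
}

#' @export
print.boot_ci <- function(x, ...) {
  cat(sprintf("<boot_ci> mean %.4f, 90%% CI [%.4f, %.4f], 95%% CI [%.4f, %.4f] (%d resamples of n = %d)\n",
              x$estimate, x$ci90[1], x$ci90[2], x$ci95[1], x$ci95[2],
              x$n_boot, x$n))
  invisible(x)
}

#' TOST equivalence classification of paired differences
#'
#' Two one-sided tests (TOST) operationalized through bootstrap confidence
#' intervals: the 90% CI of the mean difference is compared against the
#' smallest-effect-size-of-interest (sesoi) interval `[-sesoi, sesoi]` and
#' the 95% CI against zero, giving one of four outcomes:
#' \describe{
#'   \item{equivalent}{90% CI within the sesoi and 0 inside the 95% CI.}
#'   \item{trivial_difference}{90% CI within the sesoi but 0 outside the 95%
#'     CI (a statistically detectable yet practically trivial effect).}
#'   \item{inconclusive}{90% CI not within the sesoi and 0 inside the 95%
#'     CI.}
#'   \item{different}{90% CI not within the sesoi and 0 outside the 95% CI.}
#' }
#'
#' @param differences Per-subject paired differences in discrimination
#'   performance.
#' @param sesoi Smallest effect size of interest (default 0.1 performance
#'   units).
#' @param n_boot,seed Passed to [bootstrap_mean_ci()].
#' @return An object of class `tost_result`: `outcome`, `ci` (a `boot_ci`),
#'   `sesoi`.
#' @examples
#' tost_classify(rep(0.05, 10))$outcome # "trivial_difference"
#' @export
tost_classify <- function(differences, sesoi = 0.1, n_boot = 1000,
                          seed = NULL) {
  .check_scalar(sesoi, "sesoi", lower = 0, strict_lower = TRUE)
  ci <- bootstrap_mean_ci(differences, n_boot = n_boot, seed = seed)
  within_sesoi <- ci$ci90[1] >= -sesoi && ci$ci90[2] <= sesoi
  includes_null <- ci$ci95[1] <= 0 && ci$ci95[2] >= 0
  outcome <- if (within_sesoi) {
    if (includes_null) "equivalent" else "trivial_difference"
  } else {
    if (includes_null) "inconclusive" else "different"
  }
  structure(list(outcome = outcome, ci = ci, sesoi = sesoi),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("<tost_result> %s (sesoi %g)\n", x$outcome, x$sesoi))
  print(x$ci)
  invisible(x)
}

#' Familywise alpha correction for equivalence-test families
#'
#' Within a family of equivalence tests, only the "problematic" cases (where
#' equivalence is supported but the mean difference is close to a sesoi
#' bound) inflate the type I error, so alpha is divided by `k^2 / 4`, where
#' `k` counts those cases. The correction never inflates alpha (k of 0, 1 or
#' 2 leaves it unchanged).
#'
#' @param alpha Uncorrected significance level, in (0, 1).
#' @param k Number of problematic cases (non-negative integer).
#' @return The corrected alpha.
#' @examples
#' familywise_alpha(0.05, 2) # 0.05
#' familywise_alpha(0.05, 8) # 0.003125
#' @export
familywise_alpha <- function(alpha, k) {
  .check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  .check_scalar(k, "k", lower = 0)
  stopifnot(k == round(k))
  alpha / max(k^2 / 4, 1)
}

#' Count problematic cases in a family of TOST results
#'
#' A case is counted as problematic when equivalence is supported (outcome
#' "equivalent" or "trivial_difference") and at least one endpoint of the 90%
#' CI lies within `margin` of a sesoi bound. The margin is a documented
#' heuristic (default 0.02) and `k` can always be set directly in
#' [familywise_alpha()].
#'
#' @param results List of `tost_result` objects.
#' @param margin Closeness margin on the 90% CI endpoints.
#' @return Integer count `k`.
#' @export
count_problematic_cases <- function(results, margin = 0.02) {
  sum(vapply(results, function(r) {
    supported <- r$outcome %in% c("equivalent", "trivial_difference")
    close <- any(abs(abs(r$ci$ci90) - r$sesoi) <= margin)
    supported && close
  }, logical(1)))
}

# per-mouse paired differences between two conditions of a performance table
.paired_differences <- function(perf, experiment_x, condition_x,
                                experiment_y, condition_y,
                                flip_x = FALSE) {
  pick <- function(e, cond) {
    rows <- perf[perf$experiment == e & perf$condition == cond &
                   !perf$flagged, c("mouse_id", "performance")]
    if (nrow(rows) == 0) {
      stop(sprintf("no usable records for condition %s in experiment %s",
                   cond, e), call. = FALSE)
    }
    rows
  }
  x <- pick(experiment_x, condition_x)
  y <- pick(experiment_y, condition_y)
  merged <- merge(x, y, by = "mouse_id", suffixes = c("_x", "_y"))
  px <- merged$performance_x
  if (flip_x) px <- 1 - px
  data.frame(mouse_id = merged$mouse_id, difference = px - merged$performance_y)
}

#' Baseline-vs-congruent/incongruent contrast table
#'
#' Builds the eight contrasts of an experiment: the congruent ("C") and
#' incongruent ("I") conditions each contrasted against the four baselines
#' (BPLV, BPHV, BVLP, BVHP), as per-mouse paired differences (condition minus
#' baseline) classified by [tost_classify()]. The incongruent performance is
#' re-scored per contrast: toward the higher-probability option (`1 - p`)
#' against the probability baselines, toward the higher-volume option (`p`,
#' the stored scoring) against the volume baselines. In experiment 2 the BVLP
#' baseline was not re-run, so its experiment-1 records are reused and must
#' be present in the table.
#'
#' @param perf A [performance_table()] (flagged records are dropped).
#' @param experiment 1, 2 or 4.
#' @param sesoi Equivalence bound on performance differences (default 0.1).
#' @param n_boot Bootstrap resamples per contrast.
#' @param seed Seed; each contrast uses a derived sub-stream.
#' @return A data.frame with one row per contrast: `contrast`, `n` (mice),
#'   `mean_difference`, `ci90_lower`, `ci90_upper`, `ci95_lower`,
#'   `ci95_upper`, `outcome`.
#' @export
contrast_table <- function(perf, experiment, sesoi = 0.1, n_boot = 1000,
                           seed = 1) {
  if (!experiment %in% c(1, 2, 4)) {
    stop("contrasts are defined for experiments 1, 2 and 4", call. = FALSE)
  }
  baselines <- c("BPLV", "BPHV", "BVLP", "BVHP")
  specs <- expand.grid(condition = c("C", "I"), baseline = baselines,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    cond <- specs$condition[i]
    base <- specs$baseline[i]
    # experiment 2 reuses the experiment-1 BVLP baseline
    base_exp <- if (experiment == 2 && base == "BVLP") 1 else experiment
    flip <- cond == "I" && base %in% c("BPLV", "BPHV")
    diffs <- .paired_differences(perf, experiment, cond, base_exp, base,
                                 flip_x = flip)
    res <- tost_classify(diffs$difference, sesoi = sesoi, n_boot = n_boot,
                         seed = substream_seed(seed, i))
    data.frame(
      contrast = sprintf("%s-%s", cond, base), n = nrow(diffs),
      mean_difference = res$ci$estimate,
      ci90_lower = res$ci$ci90[1], ci90_upper = res$ci$ci90[2],
      ci95_lower = res$ci$ci95[1], ci95_upper = res$ci$ci95[2],
      outcome = res$outcome, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-mouse background-dimension regressions (experiment 3)
#'
#' For each mouse and each relevant dimension, fits an ordinary
#' least-squares regression of discrimination performance on background level
#' across the four background levels, then classifies the group of per-mouse
#' slopes with a TOST against the slope sesoi (default 0.125, the slope that
#' would produce a 0.1 performance difference between the lowest and highest
#' background levels, 0.2 and 1).
#'
#' @param perf A [performance_table()] containing experiment-3 records.
#' @param cohort_variant Catalogue variant used to map conditions to
#'   background levels.
#' @param sesoi Slope equivalence bound (default 0.125).
#' @param n_boot,seed Bootstrap controls.
#' @return A list with `slopes` (data.frame: `mouse_id`,
#'   `relevant_dimension`, `slope`, `intercept`) and `tost` (named list of
#'   `tost_result`, one per relevant dimension).
#' @export
background_slopes <- function(perf, cohort_variant = "standard",
                              sesoi = 0.125, n_boot = 1000, seed = 1) {
  cat3 <- condition_catalogue(3, cohort_variant)
  p3 <- perf[perf$experiment == 3 & !perf$flagged, ]
  if (nrow(p3) == 0) stop("no experiment-3 records in `perf`", call. = FALSE)
  p3 <- merge(p3, cat3[, c("label", "relevant_dimension",
                           "background_level")],
              by.x = "condition", by.y = "label")
  rows <- list()
  for (m in unique(p3$mouse_id)) {
    for (dim in unique(p3$relevant_dimension)) {
      sub <- p3[p3$mouse_id == m & p3$relevant_dimension == dim, ]
      if (nrow(sub) != 4) {
        stop(sprintf(
          "mouse %s, relevant dimension %s: expected 4 background levels, found %d",
          m, dim, nrow(sub)), call. = FALSE)
      }
      fit <- stats::lm(performance ~ background_level, data = sub)
      rows[[length(rows) + 1]] <- data.frame(
        mouse_id = m, relevant_dimension = dim,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        stringsAsFactors = FALSE
      )
    }
  }
  slopes <- do.call(rbind, rows)
  dims <- sort(unique(slopes$relevant_dimension))
  tost <- lapply(seq_along(dims), function(i) {
    tost_classify(slopes$slope[slopes$relevant_dimension == dims[i]],
                  sesoi = sesoi, n_boot = n_boot,
                  seed = substream_seed(seed, i))
  })
  names(tost) <- dims
  list(slopes = slopes, tost = tost)
}
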