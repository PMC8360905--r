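#' Coefficient-of-variation search grid
#'
#' The default calibration grid for gamma: 0.05 to 2.00 inclusive in steps of
#' 0.05 (40 points).
#'
#' @param from,to,by Grid range and step.
#' @return Numeric vector of grid values.
#' @export
gamma_grid <- function(from = 0.05, to = 2, by = 0.05) {
  seq(from, to, by = by)
}

#' Calibration conditions
#'
#' The probability baselines used to calibrate gamma: BPLV and BPHV in
#' experiments 1 and 4. These conditions are excluded from the out-of-sample
#' RMSE in [rank_models()].
#'
#' @return A data.frame with columns `experiment` and `condition`.
#' @export
calibration_conditions <- function() {
  expand.grid(experiment = c(1, 4), condition = c("BPLV", "BPHV"),
              stringsAsFactors = FALSE)
}

# predicted-performance curve over the gamma grid for one condition pair
.gamma_curve <- function(kind, cond, grid, n_mice, n_choices, seed,
                         spec_args) {
  vapply(seq_along(grid), function(i) {
    spec <- do.call(sut_model, c(list(kind = kind, gamma = grid[i]),
                                 spec_args))
    predict_performance(spec, cond, n_mice, n_choices,
                        seed = substream_seed(seed, i))$prediction
  }, numeric(1))
}

#' Calibrate gamma for one model by grid search
#'
#' Simulates the model's predicted discrimination performance for each
#' observed calibration condition at every grid value of gamma, smooths each
#' predicted curve over the grid with local regression (loess, locally linear
#' with tricube weights, span 0.75), and returns the grid value minimizing
#' the root-mean-square error between the smoothed predictions and the
#' observations.
#'
#' @param kind Model kind ([model_kinds()]).
#' @param observations A data.frame with columns `experiment`, `condition`
#'   and `performance` (typically per-condition means across mice for the
#'   probability baselines of experiments 1 and 4).
#' @param grid Gamma grid ([gamma_grid()]).
#' @param n_mice,n_choices Simulation size per grid cell (defaults 100 x
#'   100).
#' @param seed Master seed; every grid cell uses a derived sub-stream.
#' @param span Loess span (default 0.75).
#' @param spec_args Extra arguments passed to [sut_model()] (e.g. `theta_v`).
#' @param cohort_variant Catalogue variant for resolving conditions.
#' @return An object of class `gamma_fit`: `kind`, `gamma` (the fitted
#'   value), `rmse` (at the optimum), `rmse_curve`, and `curves` (long
#'   data.frame of raw and smoothed predictions per condition and grid
#'   value).
#' @export
fit_gamma <- function(kind, observations, grid = gamma_grid(),
                      n_mice = 100, n_choices = 100, seed = 1,
                      span = 0.75, spec_args = list(),
                      cohort_variant = "standard") {
  kind <- match.arg(kind, model_kinds())
  needed <- c("experiment", "condition", "performance")
  if (!is.data.frame(observations) ||
      !all(needed %in% names(observations)) || nrow(observations) == 0) {
    stop("`observations` must be a non-empty data.frame with columns experiment, condition, performance",
         call. = FALSE)
  }
  stopifnot(length(grid) >= 1, all(grid > 0))
  keys <- unique(observations[, c("experiment", "condition")])
  curves <- lapply(seq_len(nrow(keys)), function(i) {
    cond <- condition_row(keys$experiment[i], keys$condition[i],
                          cohort_variant = cohort_variant)
    raw <- .gamma_curve(kind, cond, grid, n_mice, n_choices,
                        seed = substream_seed(seed, 1000 + i),
                        spec_args = spec_args)
    smooth <- if (length(grid) >= 4) {
      fit <- stats::loess(raw ~ grid, span = span, degree = 1)
      stats::predict(fit, newdata = data.frame(grid = grid))
    } else {
      raw
    }
    data.frame(experiment = keys$experiment[i],
               condition = keys$condition[i],
               gamma = grid, raw = raw, smoothed = smooth,
               stringsAsFactors = FALSE)
  })
  curves <- do.call(rbind, curves)
  # RMSE over observation rows at each grid value
  rmse_curve <- vapply(seq_along(grid), function(i) {
    pred <- vapply(seq_len(nrow(observations)), function(j) {
      curves$smoothed[curves$experiment == observations$experiment[j] &
                        curves$condition == observations$condition[j]][i]
    }, numeric(1))
    sqrt(mean((pred - observations$performance)^2))
  }, numeric(1))
  best <- which.min(rmse_curve)
  structure(list(kind = kind, gamma = grid[best], rmse = rmse_curve[best],
                 grid = grid, rmse_curve = rmse_curve, curves = curves,
                 spec_args = spec_args),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma_fit> %s: gamma = %.2f (RMSE %.4f over %d grid points)\n",
              x$kind, x$gamma, x$rmse, length(x$grid)))
  invisible(x)
}

#' Rank decision models by out-of-sample RMSE
#'
#' For every observed condition, each calibrated model's prediction is the
#' median discrimination performance of simulated mice
#' ([predict_performance()]). Models are ranked by the root-mean-square error
#' between predictions and observations over all conditions except the
#' calibration conditions ([calibration_conditions()] by default). Exact RMSE
#' ties are broken by canonical model order ([model_kinds()]) and flagged.
#'
#' @param models Named list of calibrated [sut_model()] objects.
#' @param observations Data.frame with columns `experiment`, `condition`,
#'   `performance` (one row per condition; typically means across mice).
#' @param exclude Data.frame of (experiment, condition) rows to exclude from
#'   the RMSE; `NULL` to include everything.
#' @param n_mice,n_choices Simulation size per prediction.
#' @param seed Master seed; each (model, condition) cell uses a derived
#'   sub-stream.
#' @param cohort_variant Catalogue variant for resolving conditions.
#' @return A data.frame with one row per model: `model`, `rmse`, `rank`,
#'   `tie`, plus attribute `"predictions"` (long data.frame of per-condition
#'   predictions).
#' @export
rank_models <- function(models, observations,
                        exclude = calibration_conditions(),
                        n_mice = 100, n_choices = 100, seed = 1,
                        cohort_variant = "standard") {
  stopifnot(is.list(models), length(models) >= 1,
            all(vapply(models, inherits, logical(1), "sut_model")))
  needed <- c("experiment", "condition", "performance")
  if (!all(needed %in% names(observations))) {
    stop("`observations` must have columns experiment, condition, performance",
         call. = FALSE)
  }
  obs <- observations
  if (!is.null(exclude)) {
    drop <- interaction(obs$experiment, obs$condition) %in%
      interaction(exclude$experiment, exclude$condition)
    obs <- obs[!drop, ]
  }
  if (nrow(obs) == 0) {
    stop("no observation rows remain after exclusion", call. = FALSE)
  }
  kinds <- unname(vapply(models, `[[`, character(1), "kind"))
  cats <- lapply(unique(obs$experiment), condition_catalogue,
                 cohort_variant = cohort_variant)
  names(cats) <- as.character(unique(obs$experiment))
  conds <- lapply(seq_len(nrow(obs)), function(j) {
    cat_e <- cats[[as.character(obs$experiment[j])]]
    hit <- cat_e[cat_e$label == obs$condition[j], ]
    if (nrow(hit) != 1) {
      stop(sprintf("unknown condition '%s' in experiment %s",
                   obs$condition[j], obs$experiment[j]), call. = FALSE)
    }
    hit
  })
  preds <- list()
  rmse <- numeric(length(models))
  for (mi in seq_along(models)) {
    pred <- vapply(seq_len(nrow(obs)), function(j) {
      predict_performance(models[[mi]], conds[[j]], n_mice, n_choices,
                          seed = substream_seed(seed, mi * 1000 + j)
                          )$prediction
    }, numeric(1))
    preds[[mi]] <- data.frame(model = kinds[mi],
                              experiment = obs$experiment,
                              condition = obs$condition,
                              observed = obs$performance,
                              predicted = pred,
                              stringsAsFactors = FALSE)
    rmse[mi] <- sqrt(mean((pred - obs$performance)^2))
  }
  canon <- match(kinds, model_kinds())
  ord <- order(rmse, canon)
  out <- data.frame(model = kinds[ord], rmse = rmse[ord],
                    rank = seq_along(ord),
                    tie = duplicated(rmse[ord]) |
                      duplicated(rmse[ord], fromLast = TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "predictions") <- do.call(rbind, preds)
  out
}

#' Sensitivity scan over a criterion parameter
#'
#' Varies one criterion parameter of a non-compensatory rule — `theta_v`
#' (randomly non-compensatory) or a salience threshold (`threshold_v`,
#' `threshold_p`; lexicographic rules) — over a grid at fixed gamma, and
#' reports the median predicted discrimination performance per condition.
#'
#' @param kind Model kind the parameter belongs to ("rnonc" for `theta_v`;
#'   "pfirst"/"vfirst" for thresholds).
#' @param parameter One of "theta_v", "threshold_v", "threshold_p".
#' @param values Parameter grid (default 0.05 to 0.95 by 0.05).
#' @param gamma Fixed coefficient of variation.
#' @param conditions Data.frame with columns `experiment` and `condition`.
#' @param n_mice,n_choices,seed Simulation controls.
#' @param cohort_variant Catalogue variant.
#' @return Long data.frame: `parameter`, `value`, `experiment`, `condition`,
#'   `prediction`.
#' @export
sensitivity_scan <- function(kind,
                             parameter = c("theta_v", "threshold_v",
                                           "threshold_p"),
                             values = seq(0.05, 0.95, by = 0.05),
                             gamma, conditions, n_mice = 100,
                             n_choices = 100, seed = 1,
                             cohort_variant = "standard") {
  kind <- match.arg(kind, model_kinds())
  parameter <- match.arg(parameter)
  ok <- (parameter == "theta_v" && kind == "rnonc") ||
    (parameter %in% c("threshold_v", "threshold_p") &&
       kind %in% c("pfirst", "vfirst"))
  if (!ok) {
    stop(sprintf("parameter '%s' does not apply to model kind '%s'",
                 parameter, kind), call. = FALSE)
  }
  rows <- list()
  for (vi in seq_along(values)) {
    args <- list(kind = kind, gamma = gamma)
    args[[parameter]] <- values[vi]
    spec <- do.call(sut_model, args)
    for (j in seq_len(nrow(conditions))) {
      cond <- condition_row(conditions$experiment[j],
                            conditions$condition[j],
                            cohort_variant = cohort_variant)
      pred <- predict_performance(spec, cond, n_mice, n_choices,
                                  seed = substream_seed(seed,
                                                        vi * 1000 + j))
      rows[[length(rows) + 1]] <- data.frame(
        parameter = parameter, value = values[vi],
        experiment = conditions$experiment[j],
        condition = conditions$condition[j],
        prediction = pred$prediction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
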