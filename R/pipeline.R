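#' Configure the end-to-end analysis pipeline
#'
#' Bundles every stage's settings under one master seed: cohort generation,
#' cut-off policy, equivalence testing, gamma calibration and model ranking.
#' All stage seeds are derived deterministically from `seed`, so identical
#' configs produce byte-identical outputs.
#'
#' @param seed Master seed.
#' @param generator A [generator_config()].
#' @param policy Cut-off policy ([cutoff_policies()]).
#' @param sesoi Equivalence bound on performance differences.
#' @param slope_sesoi Equivalence bound on experiment-3 slopes.
#' @param n_boot Bootstrap resamples per contrast.
#' @param grid Gamma calibration grid.
#' @param models Model kinds to calibrate and rank (default all six).
#' @param fit_n_mice,fit_n_choices Simulation size per grid cell and per
#'   ranking prediction.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            generator = generator_config(),
                            policy = "drop_first_150",
                            sesoi = 0.1, slope_sesoi = 0.125,
                            n_boot = 1000,
                            grid = gamma_grid(),
                            models = model_kinds(),
                            fit_n_mice = 100, fit_n_choices = 100) {
  stopifnot(inherits(generator, "generator_config"),
            all(models %in% model_kinds()))
  structure(list(seed = seed, generator = generator, policy = policy,
                 sesoi = sesoi, slope_sesoi = slope_sesoi, n_boot = n_boot,
                 grid = grid, models = models, fit_n_mice = fit_n_mice,
                 fit_n_choices = fit_n_choices),
            class = "pipeline_config")
}

# per-condition mean performance across mice (unflagged records)
.condition_means <- function(perf) {
  ok <- perf[!perf$flagged, ]
  agg <- stats::aggregate(performance ~ experiment + condition, data = ok,
                          FUN = mean)
  agg[order(agg$experiment, agg$condition), ]
}

#' Run the full analysis pipeline
#'
#' Executes generate -> analyze -> equivalence -> slopes -> fit -> rank and
#' writes every artifact as a tab-separated table plus a JSON manifest:
#' `event_log.tsv`, `performance.tsv`, `contrasts_exp<k>.tsv` (experiments
#' 1, 2, 4 when present), `slopes.tsv` (when experiment 3 is present),
#' `gamma_fits.tsv`, `ranking.tsv` and `manifest.json`. Identical configs
#' yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory artifacts (`log`, `perf`,
#'   `contrasts`, `slopes`, `fits`, `ranking`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exps <- config$generator$experiments
  variant <- config$generator$cohort_variant

  log <- generate_cohort(config$generator,
                         seed = substream_seed(config$seed, 1))
  write_event_log(log, file.path(out_dir, "event_log.tsv"))

  perf <- performance_table(log, policy = config$policy)
  utils::write.table(perf, file.path(out_dir, "performance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  contrasts <- list()
  for (e in intersect(c(1, 2, 4), exps)) {
    if (e == 2 && !1 %in% exps) next # BVLP baseline unavailable
    ct <- contrast_table(perf, e, sesoi = config$sesoi,
                         n_boot = config$n_boot,
                         seed = substream_seed(config$seed, 100 + e))
    contrasts[[as.character(e)]] <- ct
    utils::write.table(ct,
                       file.path(out_dir, sprintf("contrasts_exp%d.tsv", e)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  slopes <- NULL
  if (3 %in% exps) {
    slopes <- background_slopes(perf, cohort_variant = variant,
                                sesoi = config$slope_sesoi,
                                n_boot = config$n_boot,
                                seed = substream_seed(config$seed, 200))
    slope_tab <- slopes$slopes
    slope_tab$group_outcome <- vapply(
      slope_tab$relevant_dimension,
      function(d) slopes$tost[[d]]$outcome, character(1))
    utils::write.table(slope_tab, file.path(out_dir, "slopes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  means <- .condition_means(perf)
  calib <- calibration_conditions()
  calib <- calib[calib$experiment %in% exps, ]
  calib_obs <- merge(means, calib)
  fits <- NULL
  ranking <- NULL
  if (nrow(calib_obs) > 0) {
    fits <- lapply(config$models, function(kind) {
      fit_gamma(kind, calib_obs, grid = config$grid,
                n_mice = config$fit_n_mice,
                n_choices = config$fit_n_choices,
                seed = substream_seed(config$seed, 300),
                cohort_variant = variant)
    })
    names(fits) <- config$models
    fit_tab <- data.frame(
      model = config$models,
      gamma = vapply(fits, `[[`, numeric(1), "gamma"),
      calibration_rmse = vapply(fits, `[[`, numeric(1), "rmse"),
      stringsAsFactors = FALSE)
    utils::write.table(fit_tab, file.path(out_dir, "gamma_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    specs <- lapply(fits, function(f) {
      do.call(sut_model, c(list(kind = f$kind, gamma = f$gamma),
                           f$spec_args))
    })
    ranking <- rank_models(specs, means, exclude = calib,
                           n_mice = config$fit_n_mice,
                           n_choices = config$fit_n_choices,
                           seed = substream_seed(config$seed, 400),
                           cohort_variant = variant)
    utils::write.table(ranking, file.path(out_dir, "ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "sutility",
    version = as.character(utils::packageVersion("sutility")),
    seed = config$seed,
    experiments = exps,
    cohort_variant = variant,
    n_mice = config$generator$n_mice,
    ground_truth_model = config$generator$model$kind,
    ground_truth_gamma = config$generator$model$gamma,
    policy = config$policy,
    sesoi = config$sesoi,
    slope_sesoi = config$slope_sesoi,
    n_boot = config$n_boot,
    grid = range(config$grid),
    models = config$models
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(log = log, perf = perf, contrasts = contrasts,
                 slopes = slopes, fits = fits, ranking = ranking,
                 manifest = manifest))
}
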