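.condition_options <- function(condition) {
  # accepts a one-row catalogue data.frame or a list with the same fields
  cond <- as.list(condition)
  list(a = reward_option(cond$volume_a[[1]], cond$prob_a[[1]]),
       b = reward_option(cond$volume_b[[1]], cond$prob_b[[1]]),
       label = if (!is.null(cond$label)) cond$label[[1]] else NA_character_)
}

#' Simulate a cohort of virtual mice in one condition
#'
#' Recreates an experimental condition as a binary choice between its two
#' rewarding options. Virtual mice start in a learned state (remembered
#' values equal to the true reward dimensions; learning is not simulated) and
#' each makes `n_choices` independent choices. The environment is not
#' spatially or temporally explicit: no reversals, travel or sessions, and
#' reward outcomes need not be drawn because post-acquisition choice depends
#' only on the remembered values.
#'
#' Each mouse draws from its own random sub-stream derived from `seed` and
#' the mouse index ([substream_seed()]), so increasing `n_mice` extends the
#' cohort without reshuffling existing mice.
#'
#' @param spec A [sut_model()].
#' @param condition A one-row data.frame from [condition_catalogue()] (or any
#'   list with `volume_a`, `prob_a`, `volume_b`, `prob_b`).
#' @param n_mice Number of virtual mice (default 100).
#' @param n_choices Choices per mouse (default 100).
#' @param seed Master seed.
#' @return An object of class `sut_sim`: the spec, condition label, sizes,
#'   seed, and `counts_a`, the per-mouse counts of choices of option A.
#' @examples
#' simulate_condition(sut_model("sev", 1.05), condition_row(1, "BPLV"),
#'                    n_mice = 5, n_choices = 20, seed = 1)
#' @export
simulate_condition <- function(spec, condition, n_mice = 100,
                               n_choices = 100, seed = 1) {
  stopifnot(inherits(spec, "sut_model"), n_mice >= 1, n_choices >= 1)
  opts <- .condition_options(condition)
  if (opts$a$probability == 0 || opts$b$probability == 0) {
    stop("cannot simulate a condition whose rewarding pair includes a zero-probability option",
         call. = FALSE)
  }
  counts <- integer(n_mice)
  for (m in seq_len(n_mice)) {
    set.seed(substream_seed(seed, m))
    counts[m] <- sum(.sample_choices(
      spec, opts$a$volume, opts$a$probability,
      opts$b$volume, opts$b$probability, n_choices))
  }
  structure(list(spec = spec, condition = opts$label, n_mice = n_mice,
                 n_choices = n_choices, seed = seed, counts_a = counts),
            class = "sut_sim")
}

#' @export
print.sut_sim <- function(x, ...) {
  cat(sprintf("<sut_sim> %s on %s: %d mice x %d choices, median performance %.3f\n",
              x$spec$kind, x$condition, x$n_mice, x$n_choices,
              stats::median(x$counts_a / x$n_choices)))
  invisible(x)
}

#' Model-predicted discrimination performance for a condition
#'
#' Runs [simulate_condition()], scores each virtual mouse's discrimination
#' performance as the fraction of choices of option A (the more profitable
#' option; in equal-expected-value incongruent conditions, the higher-volume
#' option, matching the empirical scoring convention), and returns the median
#' across mice as the model prediction.
#'
#' @inheritParams simulate_condition
#' @return An object of class `sut_prediction`: `condition`, `prediction`
#'   (the median), and `performances` (per-mouse values).
#' @examples
#' predict_performance(sut_model("sev", 1.05), condition_row(1, "BPLV"),
#'                     n_mice = 20, n_choices = 50, seed = 1)
#' @export
predict_performance <- function(spec, condition, n_mice = 100,
                                n_choices = 100, seed = 1) {
  run <- simulate_condition(spec, condition, n_mice, n_choices, seed)
  perf <- run$counts_a / run$n_choices
  structure(list(condition = run$condition,
                 prediction = stats::median(perf),
                 performances = perf,
                 n_mice = n_mice, n_choices = n_choices, seed = seed),
            class = "sut_prediction")
}

#' @export
print.sut_prediction <- function(x, ...) {
  cat(sprintf("<sut_prediction> %s: median performance %.3f (%d mice x %d choices)\n",
              x$condition, x$prediction, x$n_mice, x$n_choices))
  invisible(x)
}
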