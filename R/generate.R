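#' Configure the synthetic event-log generator
#'
#' The generator emulates the automated home-cage study design: cohorts of
#' mice poke four water dispensers (two rewarding, two not) during daily
#' drinking sessions; each condition is presented on an acquisition day and a
#' spatially reversed day; rewards follow the fixed pseudo-random sequences.
#' Session-level descriptive statistics default to the empirical ones:
#' 477 +/- 163 pokes per session, of which a proportion of 0.79 +/- 0.10 are
#' at the rewarding dispensers (the proportion is drawn once per session,
#' emulating between-session variability).
#'
#' @param n_mice Mice per cohort (default 8).
#' @param experiments Experiments to include (subset of 1:4; default all).
#' @param cohort_variant "standard" or "cohort2" (see
#'   [condition_catalogue()]).
#' @param model Ground-truth decision model generating the choices (a
#'   [sut_model()]; default sev with gamma 1.05).
#' @param pokes_mean,pokes_sd Mean and sd of total pokes per session; the
#'   per-session draw is clipped to at least 1.
#' @param rewarding_prop_mean,rewarding_prop_sd Mean and sd of the
#'   per-session proportion of pokes at rewarding dispensers; clipped to
#'   \[0, 1\].
#' @param volume_jitter_sd Standard deviation (uL) of optional delivery
#'   jitter added to rewarded volumes; 0 (default) delivers exact volumes.
#' @param session_hours Session length used to scale synthetic timestamps
#'   (default 18 h); analyses use poke order only.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_mice = 8, experiments = 1:4,
                             cohort_variant = "standard",
                             model = sut_model("sev", gamma = 1.05),
                             pokes_mean = 477, pokes_sd = 163,
                             rewarding_prop_mean = 0.79,
                             rewarding_prop_sd = 0.10,
                             volume_jitter_sd = 0,
                             session_hours = 18) {
  stopifnot(n_mice >= 1, all(experiments %in% 1:4),
            inherits(model, "sut_model"),
            pokes_mean > 0, pokes_sd >= 0,
            rewarding_prop_mean > 0, rewarding_prop_sd >= 0,
            volume_jitter_sd >= 0, session_hours > 0)
  structure(list(
    n_mice = n_mice, experiments = experiments,
    cohort_variant = cohort_variant, model = model,
    pokes_mean = pokes_mean, pokes_sd = pokes_sd,
    rewarding_prop_mean = rewarding_prop_mean,
    rewarding_prop_sd = rewarding_prop_sd,
    volume_jitter_sd = volume_jitter_sd,
    session_hours = session_hours
  ), class = "generator_config")
}

.event_log_columns <- c("timestamp_s", "mouse_id", "dispenser", "day",
                        "experiment", "condition_label", "reversal",
                        "rewarded", "volume_ul", "option")

# reward outcomes for k consecutive pokes at a dispenser with probability p,
# using the fixed sequences (cursor starts at 0 each session)
.reward_outcomes <- function(p, k) {
  if (k == 0) return(integer(0))
  if (p == 1) return(rep(1L, k))
  if (p == 0) return(rep(0L, k))
  lab <- format(p)
  if (lab %in% names(reward_sequences())) {
    sequence_outcome(p, seq_len(k) - 1L)
  } else {
    warning(sprintf(
      "no stored reward sequence for probability %g; falling back to Bernoulli draws", p),
      call. = FALSE)
    stats::rbinom(k, 1L, p)
  }
}

# one session (one plan row) -> event data.frame
.generate_session <- function(config, plan_row, cond, seed) {
  set.seed(seed)
  n <- max(1L, as.integer(round(stats::rnorm(1, config$pokes_mean,
                                             config$pokes_sd))))
  prop <- min(1, max(0, stats::rnorm(1, config$rewarding_prop_mean,
                                     config$rewarding_prop_sd)))
  at_rewarding <- stats::runif(n) < prop
  k <- sum(at_rewarding)

  disp_a <- plan_row$dispenser_a
  disp_b <- plan_row$dispenser_b
  nonrew <- setdiff(1:4, c(disp_a, disp_b))

  dispenser <- integer(n)
  option <- rep("none", n)
  rewarded <- integer(n)
  volume <- numeric(n)

  if (k > 0) {
    chose_a <- .sample_choices(config$model,
                               cond$volume_a, cond$prob_a,
                               cond$volume_b, cond$prob_b, k)
    disp <- ifelse(chose_a, disp_a, disp_b)
    dispenser[at_rewarding] <- disp
    option[at_rewarding] <- ifelse(chose_a, "A", "B")
    # per-(mouse, dispenser) sequence cursors, reset at session start
    rew <- integer(k)
    ia <- which(chose_a)
    ib <- which(!chose_a)
    rew[ia] <- .reward_outcomes(cond$prob_a, length(ia))
    rew[ib] <- .reward_outcomes(cond$prob_b, length(ib))
    rewarded[at_rewarding] <- rew
    vol <- ifelse(chose_a, cond$volume_a, cond$volume_b)
    if (config$volume_jitter_sd > 0) {
      vol <- pmax(0, vol + stats::rnorm(k, 0, config$volume_jitter_sd))
    }
    volume[at_rewarding] <- rew * vol
  }
  if (k < n) {
    dispenser[!at_rewarding] <- sample(nonrew, n - k, replace = TRUE)
  }
  timestamp <- cumsum(stats::rexp(n, rate = n / (config$session_hours * 3600)))

  data.frame(
    timestamp_s = round(timestamp, 3),
    mouse_id = plan_row$mouse_id,
    dispenser = dispenser,
    day = plan_row$day,
    experiment = plan_row$experiment,
    condition_label = plan_row$condition_label,
    reversal = plan_row$reversal,
    rewarded = rewarded,
    volume_ul = volume,
    option = option,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort event log
#'
#' Simulates the full session schedule for a cohort under a known
#' ground-truth decision model and returns a nose-poke event log in the
#' package's interchange schema. Deterministic given `seed`: every session
#' draws from a sub-stream derived from (seed, mouse, day).
#'
#' Per session: the total poke count and the proportion of pokes at the
#' rewarding dispensers are drawn from the configured (clipped) normals;
#' choices among the two rewarding dispensers follow the ground-truth model;
#' reward outcomes follow the fixed sequences via per-(mouse, dispenser)
#' cyclic cursors that reset each session (probability 1 is always rewarded;
#' probabilities without a stored sequence fall back to Bernoulli draws with
#' a warning); reversal days swap the two rewarding dispensers' options.
#'
#' @param config A [generator_config()].
#' @param seed Master seed.
#' @return An `event_log`: a data.frame of poke events (columns
#'   `timestamp_s`, `mouse_id`, `dispenser`, `day`, `experiment`,
#'   `condition_label`, `reversal`, `rewarded`, `volume_ul`, `option`) with
#'   the generating [session_plan()] attached as attribute `"plan"`.
#' @examples
#' cfg <- generator_config(n_mice = 2, experiments = 1, pokes_mean = 60,
#'                         pokes_sd = 5)
#' log <- generate_cohort(cfg, seed = 1)
#' head(log)
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  plan <- session_plan(config$n_mice, config$experiments,
                       config$cohort_variant, seed = seed)
  cats <- lapply(config$experiments, condition_catalogue,
                 cohort_variant = config$cohort_variant)
  names(cats) <- as.character(config$experiments)
  n_days <- max(plan$day)
  sessions <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pr <- plan[i, ]
    cat_e <- cats[[as.character(pr$experiment)]]
    cond <- cat_e[cat_e$label == pr$condition_label, ]
    if (cond$prob_a == 0 || cond$prob_b == 0) {
      stop("rewarding option pair contains a zero-probability option",
           call. = FALSE)
    }
    sessions[[i]] <- .generate_session(
      config, pr, cond,
      seed = substream_seed(seed, pr$mouse_id * (n_days + 1L) + pr$day))
  }
  events <- do.call(rbind, sessions)
  rownames(events) <- NULL
  structure(events, plan = plan, class = c("event_log", "data.frame"))
}

#' Validate an event log
#'
#' Checks the interchange-schema invariants: required columns present,
#' timestamps non-decreasing within each (mouse, day), rewards only at
#' rewarding-dispenser pokes, and every (mouse, experiment, condition)
#' present on exactly two days (acquisition + reversal).
#'
#' @param events An event-log data.frame.
#' @return The validated log, invisibly. Errors name the offending
#'   mouse/session.
#' @export
validate_event_log <- function(events) {
  missing <- setdiff(.event_log_columns, names(events))
  if (length(missing) > 0) {
    stop("event log is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(events), .event_log_columns)
  if (length(extra) > 0) {
    warning("ignoring unknown event-log columns: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) == 0) return(invisible(events))
  key <- interaction(events$mouse_id, events$day, drop = TRUE)
  for (k in levels(key)) {
    ts <- events$timestamp_s[key == k]
    if (is.unsorted(ts)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      stop(sprintf(
        "timestamps out of order for mouse %s, day %s", parts[1], parts[2]),
        call. = FALSE)
    }
  }
  if (any(events$rewarded == 1 & events$option == "none")) {
    stop("rewarded pokes found at non-rewarding dispensers", call. = FALSE)
  }
  days_per_cond <- tapply(events$day,
    interaction(events$mouse_id, events$experiment,
                events$condition_label, drop = TRUE),
    function(d) length(unique(d)))
  if (any(days_per_cond != 2)) {
    bad <- names(days_per_cond)[days_per_cond != 2][1]
    stop(sprintf(
      "condition does not appear on exactly two days (mouse.experiment.condition %s)",
      bad), call. = FALSE)
  }
  invisible(events)
}

#' Write / read an event log
#'
#' The interchange format is plain tab-separated text with one header line
#' and columns `timestamp_s`, `mouse_id`, `dispenser`, `day`, `experiment`,
#' `condition_label`, `reversal`, `rewarded`, `volume_ul`, `option`. A write
#' followed by a read reproduces the log exactly; reading validates the
#' schema ([validate_event_log()]).
#'
#' @param log An event log (from [generate_cohort()] or [read_event_log()]).
#' @param path File path.
#' @return `read_event_log()` returns an `event_log` data.frame.
#' @export
write_event_log <- function(log, path) {
  utils::write.table(as.data.frame(log), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  events <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = c(
                                timestamp_s = "numeric",
                                mouse_id = "integer",
                                dispenser = "integer",
                                day = "integer",
                                experiment = "integer",
                                condition_label = "character",
                                reversal = "integer",
                                rewarded = "integer",
                                volume_ul = "numeric",
                                option = "character"))
  validate_event_log(events)
  structure(events, class = c("event_log", "data.frame"))
}
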