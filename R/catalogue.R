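#' Condition catalogue for the four discrimination experiments
#'
#' Builds the table of binary-choice conditions. Each condition pairs two
#' reward options that differ on one reward dimension (baselines and the
#' experiment-3 background series), or on both, either congruently (one option
#' superior on both dimensions, label "C") or incongruently (each option
#' superior on one dimension, label "I").
#'
#' Option A is always the option toward which discrimination performance is
#' scored: the more profitable option or, when both options have the same
#' expected value (the experiment-2 incongruent condition), the option with
#' the higher volume.
#'
#' Experiments:
#' \describe{
#'   \item{1}{Six conditions from volumes \{4, 20\} uL and probabilities
#'     \{0.2, 0.5\}: BPLV, BPHV, BVLP, BVHP, C, I.}
#'   \item{2}{Probability 0.5 replaced by 1.0 and the BVLP condition omitted
#'     (five conditions; experiment-1 BVLP results are reused downstream).}
#'   \item{3}{Eight single-relevant-dimension conditions: probability 0.2 vs
#'     0.5 at volume backgrounds \{4, 10, 15, 20\} uL (labels "PV1-volume" ..
#'     "PV4-volume"), and volume 4 vs 10 uL at probability backgrounds
#'     \{0.2, 0.5, 0.8, 1.0\} (labels "PV1-probability" ..
#'     "PV4-probability").}
#'   \item{4}{Identical to experiment 1.}
#' }
#'
#' The cohort-2 apparatus delivered slightly different volumes: 4.7 for 4,
#' 9.4 for 10, 14.0 for 15 and 20.3 for 20 uL. For the experiment-3 relevant
#' volume pair two published variants exist (4.7/9.4 and 4.8/9.6);
#' `cohort2_exp3_source` selects between them.
#'
#' @param experiment Experiment number, 1-4.
#' @param cohort_variant "standard" (cohorts 1 and 3) or "cohort2".
#' @param cohort2_exp3_source For `cohort_variant = "cohort2"` in experiment
#'   3, which published volume pair to use for the relevant dimension:
#'   "figure" (4.7 and 9.4 uL, the default) or "text" (4.8 and 9.6 uL).
#' @return A data.frame with one row per condition: `experiment`, `label`,
#'   `volume_a`, `prob_a`, `volume_b`, `prob_b`, `ev_a`, `ev_b`,
#'   `relative_value`, `relevant_dimension` ("volume", "probability" or
#'   "both"), `background_dimension`, `background_value`, `background_level`,
#'   `cohort_variant`.
#' @examples
#' condition_catalogue(1)
#' nrow(condition_catalogue(3)) # 8
#' @export
condition_catalogue <- function(experiment,
                                cohort_variant = c("standard", "cohort2"),
                                cohort2_exp3_source = c("figure", "text")) {
  if (!is.numeric(experiment) || length(experiment) != 1 ||
      !experiment %in% 1:4) {
    stop("`experiment` must be one of 1, 2, 3, 4", call. = FALSE)
  }
  cohort_variant <- match.arg(cohort_variant)
  cohort2_exp3_source <- match.arg(cohort2_exp3_source)

  # cohort-2 pump calibration: programmed -> delivered volume
  vmap <- function(v) {
    if (cohort_variant == "standard") return(v)
    map <- c("4" = 4.7, "10" = 9.4, "15" = 14.0, "20" = 20.3)
    unname(map[as.character(v)])
  }

  row <- function(label, va, pa, vb, pb, relevant,
                  bg_dim = NA_character_, bg_value = NA_real_,
                  bg_level = NA_real_) {
    data.frame(
      experiment = as.integer(experiment), label = label,
      volume_a = va, prob_a = pa, volume_b = vb, prob_b = pb,
      ev_a = va * pa, ev_b = vb * pb,
      relative_value = (va * pa) / (vb * pb),
      relevant_dimension = relevant,
      background_dimension = bg_dim,
      background_value = bg_value,
      background_level = bg_level,
      cohort_variant = cohort_variant,
      stringsAsFactors = FALSE
    )
  }

  if (experiment %in% c(1, 2, 4)) {
    v_lo <- vmap(4); v_hi <- vmap(20)
    p_lo <- 0.2
    p_hi <- if (experiment == 2) 1.0 else 0.5
    rows <- list(
      row("BPLV", v_lo, p_hi, v_lo, p_lo, "probability", "volume", v_lo),
      row("BPHV", v_hi, p_hi, v_hi, p_lo, "probability", "volume", v_hi),
      row("BVLP", v_hi, p_lo, v_lo, p_lo, "volume", "probability", p_lo),
      row("BVHP", v_hi, p_hi, v_lo, p_hi, "volume", "probability", p_hi),
      row("C", v_hi, p_hi, v_lo, p_lo, "both"),
      # incongruent: higher volume carries the lower probability; option A is
      # the higher-volume option (also the more profitable one in
      # experiments 1 and 4; equally profitable in experiment 2)
      row("I", v_hi, p_lo, v_lo, p_hi, "both")
    )
    if (experiment == 2) rows <- rows[-3] # BVLP not repeated
  } else {
    # experiment 3: one relevant, one background dimension, four background
    # levels each (full factorial of background level x relevant dimension)
    vol_bg <- vmap(c(4, 10, 15, 20))
    prob_bg <- c(0.2, 0.5, 0.8, 1.0)
    if (cohort_variant == "cohort2") {
      rel_vol <- if (cohort2_exp3_source == "figure") c(4.7, 9.4)
                 else c(4.8, 9.6)
    } else {
      rel_vol <- c(4, 10)
    }
    rows <- c(
      lapply(seq_along(vol_bg), function(i) {
        row(sprintf("PV%d-volume", i), vol_bg[i], 0.5, vol_bg[i], 0.2,
            "probability", "volume", vol_bg[i], vol_bg[i] / max(vol_bg))
      }),
      lapply(seq_along(prob_bg), function(i) {
        row(sprintf("PV%d-probability", i), rel_vol[2], prob_bg[i],
            rel_vol[1], prob_bg[i],
            "volume", "probability", prob_bg[i], prob_bg[i] / max(prob_bg))
      })
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Look up one condition row
#'
#' @param experiment Experiment number 1-4.
#' @param label Condition label (e.g. "BPLV", "C", "PV2-volume").
#' @param ... Passed to [condition_catalogue()].
#' @return A one-row data.frame.
#' @export
condition_row <- function(experiment, label, ...) {
  cat_ <- condition_catalogue(experiment, ...)
  hit <- cat_[cat_$label == label, , drop = FALSE]
  if (nrow(hit) != 1) {
    stop(sprintf("no condition '%s' in experiment %d; available: %s",
                 label, experiment, paste(cat_$label, collapse = ", ")),
         call. = FALSE)
  }
  hit
}

#' Number of scheduled days
#'
#' Every condition is presented on an acquisition day followed by one spatial
#' reversal day, so the schedule length is twice the number of conditions.
#'
#' @param experiments Experiments to include (subset of 1:4).
#' @return Total number of days.
#' @examples
#' schedule_days(1:4) # 50
#' @export
schedule_days <- function(experiments = 1:4) {
  stopifnot(all(experiments %in% 1:4))
  sum(vapply(experiments,
             function(e) 2L * nrow(condition_catalogue(e)), integer(1)))
}

#' Build a session plan for a cohort
#'
#' Assigns each mouse a randomized condition order per experiment, with each
#' condition presented on an acquisition day followed by a reversal day on
#' which the two rewarding dispensers swap options while the non-rewarding
#' dispensers are unchanged. Half the mice use dispensers 1-2 as the rewarding
#' pair, the other half dispensers 3-4.
#'
#' @param n_mice Number of mice in the cohort.
#' @param experiments Experiments to schedule (subset of 1:4).
#' @param cohort_variant Passed to [condition_catalogue()].
#' @param seed Seed for the per-mouse condition-order randomization.
#' @return A data.frame with one row per (mouse, day): `mouse_id`, `day`,
#'   `experiment`, `condition_label`, `reversal` (0/1), `dispenser_a`,
#'   `dispenser_b` (which dispenser holds option A / B that day).
#' @export
session_plan <- function(n_mice = 8, experiments = 1:4,
                         cohort_variant = "standard", seed = 1) {
  stopifnot(n_mice >= 1, all(experiments %in% 1:4))
  plans <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    set.seed(substream_seed(seed, m))
    rewarding <- if (m %% 2 == 1) c(1L, 2L) else c(3L, 4L)
    day <- 0L
    rows <- list()
    for (e in experiments) {
      labels <- condition_catalogue(e, cohort_variant)$label
      labels <- sample(labels)
      for (lab in labels) {
        rows[[length(rows) + 1]] <- data.frame(
          mouse_id = as.integer(m), day = day + 1:2,
          experiment = as.integer(e),
          condition_label = lab, reversal = 0:1,
          dispenser_a = c(rewarding[1], rewarding[2]),
          dispenser_b = c(rewarding[2], rewarding[1]),
          stringsAsFactors = FALSE
        )
        day <- day + 2L
      }
    }
    plans[[m]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, plans)
  rownames(out) <- NULL
  out
}

#' Write / read a condition catalogue as a flat tab-separated file
#'
#' @param catalogue A catalogue data.frame from [condition_catalogue()].
#' @param path File path.
#' @return `read_catalogue()` returns the catalogue data.frame.
#' @export
write_catalogue <- function(catalogue, path) {
  utils::write.table(catalogue, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    experiment = "integer", label = "character",
    volume_a = "numeric", prob_a = "numeric",
    volume_b = "numeric", prob_b = "numeric",
    ev_a = "numeric", ev_b = "numeric", relative_value = "numeric",
    relevant_dimension = "character", background_dimension = "character",
    background_value = "numeric", background_level = "numeric",
    cohort_variant = "character"))
}
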