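#' Cutoff policies
#'
#' Names of the supported acquisition cut-off policies, applied per mouse and
#' per drinking session to the pokes at the rewarding dispensers only:
#' \describe{
#'   \item{drop_first_150}{Exclude the first 150 rewarding pokes (default).}
#'   \item{window_151_to_251}{Keep the 100 pokes from the 151st to the
#'     250th.}
#'   \item{last_100}{Keep the final 100 pokes.}
#'   \item{last_20}{Keep the final 20 pokes.}
#'   \item{criterion_blocks}{Keep the pokes after the first pair of
#'     consecutive non-overlapping 20-poke blocks whose block performances
#'     both strictly exceed the session's overall performance.}
#' }
#'
#' @return Character vector of policy names.
#' @export
cutoff_policies <- function() {
  c("drop_first_150", "window_151_to_251", "last_100", "last_20",
    "criterion_blocks")
}

#' Apply an acquisition cut-off to one session
#'
#' @param high Logical vector, in poke order, over one session's pokes at the
#'   rewarding dispensers: `TRUE` where the poke was at the
#'   high-profitability dispenser. Only `criterion_blocks` uses the values;
#'   the other policies use only the length.
#' @param policy One of [cutoff_policies()].
#' @return Integer indices of the retained pokes (possibly empty; a session
#'   with 150 or fewer rewarding pokes retains nothing under the default
#'   policy).
#' @examples
#' length(apply_cutoff(rep(TRUE, 200), "drop_first_150")) # 50
#' @export
apply_cutoff <- function(high, policy = cutoff_policies()) {
  stopifnot(is.logical(high))
  policy <- match.arg(policy)
  n <- length(high)
  switch(policy,
    drop_first_150 = if (n > 150) 151:n else integer(0),
    window_151_to_251 = if (n > 150) 151:min(250L, n) else integer(0),
    last_100 = if (n == 0) integer(0) else max(1L, n - 99L):n,
    last_20 = if (n == 0) integer(0) else max(1L, n - 19L):n,
    criterion_blocks = {
      nb <- n %/% 20L
      if (nb < 2) return(integer(0))
      overall <- mean(high)
      block_perf <- vapply(seq_len(nb), function(j) {
        mean(high[(20L * (j - 1L) + 1L):(20L * j)])
      }, numeric(1))
      qual <- block_perf > overall
      pair <- which(qual[-nb] & qual[-1])
      if (length(pair) == 0) return(integer(0))
      start <- 20L * (pair[1] + 1L) + 1L
      if (start > n) integer(0) else start:n
    }
  )
}

# retained (n_high, n_low) for one session's rewarding pokes
.session_counts <- function(high, policy) {
  keep <- apply_cutoff(high, policy)
  c(n_high = sum(high[keep]), n_low = sum(!high[keep]))
}

#' Discrimination performance of one mouse in one condition
#'
#' Pools the two presentations of a condition (acquisition and reversal):
#' after applying the cut-off per drinking session, performance is the total
#' number of retained pokes at the high-profitability dispenser divided by
#' the total retained pokes at the high- and low-profitability dispensers.
#' Pokes at non-rewarding dispensers are ignored. In equal-expected-value
#' incongruent conditions, the higher-volume option counts as
#' high-profitability (option "A" in the catalogue and event log).
#'
#' @param log An event log.
#' @param mouse Mouse id.
#' @param experiment Experiment number.
#' @param condition Condition label.
#' @param policy A cut-off policy ([cutoff_policies()]).
#' @return A one-row data.frame: `mouse_id`, `experiment`, `condition`,
#'   `n_high`, `n_low`, `performance` (`NA` and `flagged = TRUE` when no
#'   pokes survive the cut-off).
#' @export
discrimination_performance <- function(log, mouse, experiment, condition,
                                       policy = "drop_first_150") {
  ev <- log[log$mouse_id == mouse & log$experiment == experiment &
              log$condition_label == condition &
              log$option %in% c("A", "B"), ]
  days <- sort(unique(log$day[log$mouse_id == mouse &
                                log$experiment == experiment &
                                log$condition_label == condition]))
  if (length(days) != 2) {
    stop(sprintf(
      "mouse %s, experiment %s, condition %s: expected two session days, found %d",
      mouse, experiment, condition, length(days)), call. = FALSE)
  }
  totals <- c(n_high = 0L, n_low = 0L)
  for (d in days) {
    sess <- ev[ev$day == d, ]
    sess <- sess[order(sess$timestamp_s), ]
    totals <- totals + .session_counts(sess$option == "A", policy)
  }
  n <- sum(totals)
  data.frame(
    mouse_id = mouse, experiment = experiment, condition = condition,
    n_high = unname(totals["n_high"]), n_low = unname(totals["n_low"]),
    performance = if (n > 0) unname(totals["n_high"]) / n else NA_real_,
    flagged = n == 0,
    stringsAsFactors = FALSE
  )
}

#' Discrimination performances for every (mouse, condition)
#'
#' Applies [discrimination_performance()] over all (mouse, experiment,
#' condition) combinations present in the log.
#'
#' @inheritParams discrimination_performance
#' @return A data.frame with one row per (mouse, experiment, condition):
#'   columns `mouse_id`, `experiment`, `condition`, `n_high`, `n_low`,
#'   `performance`, `flagged`.
#' @export
performance_table <- function(log, policy = "drop_first_150") {
  if (nrow(log) == 0) {
    return(data.frame(mouse_id = integer(0), experiment = integer(0),
                      condition = character(0), n_high = integer(0),
                      n_low = integer(0), performance = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  combos <- unique(as.data.frame(log)[, c("mouse_id", "experiment",
                                          "condition_label")])
  combos <- combos[order(combos$mouse_id, combos$experiment,
                         combos$condition_label), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    discrimination_performance(log, combos$mouse_id[i],
                               combos$experiment[i],
                               combos$condition_label[i], policy)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_flag <- sum(out$flagged)
  if (n_flag > 0) {
    message(sprintf(
      "%d record(s) had no pokes surviving the cut-off and are flagged", n_flag))
  }
  out
}
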