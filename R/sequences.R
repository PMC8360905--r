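#' Fixed pseudo-random reward sequences
#'
#' The five fixed repeating 20-poke reward sequences used to schedule
#' probabilistic rewards. Each sequence is a binary vector (1 = rewarded poke,
#' 0 = unrewarded poke) whose proportion of ones equals its nominal
#' probability exactly, so that over whole cycles the delivered reward rate
#' matches the programmed probability with no sampling error.
#'
#' @return A named list of integer vectors of length 20; names are the
#'   nominal probabilities ("0.2", "0.3", "0.5", "0.7", "0.8").
#' @examples
#' lengths(reward_sequences())
#' @export
reward_sequences <- function() {
  strings <- c(
    "0.8" = "11101111101101111110",
    "0.7" = "11011101110101101110",
    "0.5" = "10110101101001001010",
    "0.3" = "10010100100001001000",
    "0.2" = "10001000010001000000"
  )
  out <- lapply(strings, function(s) {
    as.integer(strsplit(s, "")[[1]])
  })
  out[order(as.numeric(names(out)))]
}

.sequence_label <- function(label) {
  lab <- format(as.numeric(label))
  seqs <- reward_sequences()
  if (!lab %in% names(seqs)) {
    stop(sprintf(
      "no stored reward sequence for probability '%s'; valid labels: %s",
      as.character(label), paste(names(seqs), collapse = ", ")
    ), call. = FALSE)
  }
  seqs[[lab]]
}

#' Outcome of a reward sequence at a given poke index
#'
#' Reward sequences repeat cyclically: the outcome of poke `i` (0-based cursor
#' position, as advanced by one per eligible poke at the dispenser) is element
#' `i mod 20` of the 20-element pattern.
#'
#' @param label Nominal sequence probability (0.2, 0.3, 0.5, 0.7 or 0.8; a
#'   number or its character form).
#' @param poke_index Non-negative 0-based poke index (vectorized).
#' @return Integer outcome(s), 1 = rewarded, 0 = unrewarded.
#' @examples
#' sequence_outcome(0.8, 0:19)
#' sequence_outcome(0.5, 20) == sequence_outcome(0.5, 0)
#' @export
sequence_outcome <- function(label, poke_index) {
  stopifnot(is.numeric(poke_index), all(poke_index >= 0))
  pattern <- .sequence_label(label)
  pattern[(poke_index %% 20L) + 1L]
}
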