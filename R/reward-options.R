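#' Define a reward option
#'
#' A reward option is one dispenser's payoff schedule: a water volume (in
#' microlitres) delivered with some probability on each nose poke.
#'
#' @param volume Reward volume in microlitres; must be positive.
#' @param probability Reward probability in \[0, 1\]. Non-rewarding dispensers
#'   are represented with probability 0.
#' @return An object of class `reward_option` (a named list).
#' @examples
#' reward_option(20, 0.2)
#' @export
reward_option <- function(volume, probability) {
  .check_scalar(volume, "volume", lower = 0, strict_lower = TRUE)
  .check_scalar(probability, "probability", lower = 0, upper = 1)
  structure(list(volume = volume, probability = probability),
            class = "reward_option")
}

#' @export
print.reward_option <- function(x, ...) {
  cat(sprintf("<reward_option> %g uL @ p = %g (EV = %g uL/visit)\n",
              x$volume, x$probability, x$volume * x$probability))
  invisible(x)
}

#' Expected value of a reward option
#'
#' The long-run payoff per visit, volume times probability (microlitres per
#' visit).
#'
#' @param option A [reward_option()], or a volume when `probability` is given.
#' @param probability Optional probability when `option` is a bare volume.
#' @return Expected value in microlitres per visit.
#' @examples
#' expected_value(reward_option(20, 0.2)) # 4
#' expected_value(4, 1.0)                 # 4
#' @export
expected_value <- function(option, probability = NULL) {
  if (inherits(option, "reward_option")) {
    return(option$volume * option$probability)
  }
  stopifnot(is.numeric(option), is.numeric(probability))
  option * probability
}

#' Relative intensity of two stimulus values
#'
#' The absolute difference between two values divided by their mean
#' (difference/mean ratio). For two options this equals the salience of the
#' dimension (see [salience()]). Lies in \[0, 2).
#'
#' @param a,b Positive stimulus values (volumes or probabilities).
#' @return Dimensionless relative intensity.
#' @examples
#' relative_intensity(4, 20)    # 1.33
#' relative_intensity(0.2, 0.5) # 0.857
#' @export
relative_intensity <- function(a, b) {
  .check_scalar(a, "a", lower = 0, strict_lower = TRUE)
  .check_scalar(b, "b", lower = 0, strict_lower = TRUE)
  abs(a - b) / ((a + b) / 2)
}

#' Background level of a tested value
#'
#' Normalizes a background-dimension value to the proportion of the maximum of
#' the values tested, e.g. volumes 4, 10, 15, 20 map to levels 0.2, 0.5, 0.75
#' and 1.
#'
#' @param value The value whose level is sought; must be one of
#'   `tested_values`.
#' @param tested_values Positive vector of all levels tested for that
#'   dimension.
#' @return The level, in (0, 1\].
#' @examples
#' background_level(15, c(4, 10, 15, 20)) # 0.75
#' @export
background_level <- function(value, tested_values) {
  stopifnot(is.numeric(tested_values), all(tested_values > 0))
  .check_scalar(value, "value", lower = 0, strict_lower = TRUE)
  if (!any(abs(tested_values - value) < 1e-9)) {
    stop(sprintf("value %g is not among the tested values (%s)",
                 value, paste(tested_values, collapse = ", ")), call. = FALSE)
  }
  value / max(tested_values)
}
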