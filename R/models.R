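#' Canonical model kinds
#'
#' The six scalar-utility-theory decision rules, in canonical order: scalar
#' expected value ("sev"), two-scalar ("2scal"), randomly non-compensatory
#' ("rnonc"), winner-takes-all ("wta"), probability first ("pfirst") and
#' volume first ("vfirst"). This order also breaks RMSE ties in
#' [rank_models()].
#'
#' @return Character vector of the six kinds.
#' @export
model_kinds <- function() c("sev", "2scal", "rnonc", "wta", "pfirst", "vfirst")

#' Specify a scalar-utility-theory decision model
#'
#' All six rules share the scalar property: a remembered value is a normal
#' distribution whose standard deviation is `gamma` times its mean (the
#' coefficient of variation). The rules differ in how the two reward
#' dimensions (volume `v`, probability `p`) are combined:
#' \describe{
#'   \item{sev}{Scalar expected value: one trace per option,
#'     `p * Normal(v, gamma * v)` (an integrative rule).}
#'   \item{2scal}{Two-scalar: independent traces per dimension, multiplied:
#'     `Normal(p, gamma_p * p) * Normal(v, gamma_v * v)` (integrative).}
#'   \item{rnonc}{Randomly non-compensatory: each decision uses the volume
#'     dimension with probability `theta_v`, otherwise the probability
#'     dimension.}
#'   \item{wta}{Winner-takes-all: uses the dimension with the higher salience
#'     with probability `theta` (the other with `1 - theta`); reverts to
#'     random choice when the saliences are equal.}
#'   \item{pfirst}{Lexicographic, probability first: uses probability if its
#'     salience exceeds `threshold_p`, else volume if its salience exceeds
#'     `threshold_v`, else random choice.}
#'   \item{vfirst}{Lexicographic, volume first: mirror image of pfirst.}
#' }
#' On the selected single dimension the trace is `Normal(r, gamma * r)`.
#' Choice takes a single sample per option and picks the larger.
#'
#' @param kind One of [model_kinds()].
#' @param gamma Coefficient of variation (> 0).
#' @param theta_v Probability of selecting the volume dimension (rnonc only).
#' @param theta Probability of selecting the higher-salience dimension (wta
#'   only).
#' @param salience_threshold Default salience threshold for the lexicographic
#'   rules (0.8, the psychometric threshold for probability discrimination).
#' @param threshold_v,threshold_p Per-dimension threshold overrides for the
#'   lexicographic rules; default to `salience_threshold`.
#' @param gamma_v,gamma_p Optional per-dimension coefficients of variation
#'   (default: both equal `gamma`).
#' @param truncate_at_zero If `TRUE`, remembered-value samples are redrawn
#'   until non-negative (sensitivity option; the closed-form choice
#'   probability then no longer applies and [choice_probability()] returns
#'   `NA`).
#' @return An object of class `sut_model`.
#' @examples
#' sut_model("sev", gamma = 1.05)
#' sut_model("rnonc", gamma = 0.05, theta_v = 0.5)
#' @export
sut_model <- function(kind, gamma, theta_v = 0.5, theta = 1,
                      salience_threshold = 0.8,
                      threshold_v = salience_threshold,
                      threshold_p = salience_threshold,
                      gamma_v = NULL, gamma_p = NULL,
                      truncate_at_zero = FALSE) {
  kind <- match.arg(kind, model_kinds())
  .check_scalar(gamma, "gamma", lower = 0, strict_lower = TRUE)
  .check_scalar(theta_v, "theta_v", lower = 0, upper = 1)
  .check_scalar(theta, "theta", lower = 0, upper = 1)
  .check_scalar(threshold_v, "threshold_v")
  .check_scalar(threshold_p, "threshold_p")
  if (!is.null(gamma_v)) .check_scalar(gamma_v, "gamma_v", 0, strict_lower = TRUE)
  if (!is.null(gamma_p)) .check_scalar(gamma_p, "gamma_p", 0, strict_lower = TRUE)
  structure(list(
    kind = kind, gamma = gamma, theta_v = theta_v, theta = theta,
    salience_threshold = salience_threshold,
    threshold_v = threshold_v, threshold_p = threshold_p,
    gamma_v = gamma_v %||% gamma, gamma_p = gamma_p %||% gamma,
    truncate_at_zero = isTRUE(truncate_at_zero)
  ), class = "sut_model")
}

#' @export
print.sut_model <- function(x, ...) {
  extra <- switch(x$kind,
    rnonc = sprintf(", theta_v = %g", x$theta_v),
    wta = sprintf(", theta = %g", x$theta),
    pfirst = ,
    vfirst = sprintf(", thresholds (v, p) = (%g, %g)",
                     x$threshold_v, x$threshold_p),
    "")
  cat(sprintf("<sut_model> %s, gamma = %g%s\n", x$kind, x$gamma, extra))
  invisible(x)
}

#' Reference model set
#'
#' The six decision models at their published coefficient-of-variation
#' calibrations (sev 1.05, 2scal 0.65, rnonc 0.05, wta 0.7, pfirst 0.95,
#' vfirst 0.5), with default criterion parameters (theta_v = 0.5, theta = 1,
#' salience thresholds 0.8).
#'
#' @return Named list of `sut_model` objects in canonical order.
#' @export
reference_models <- function() {
  gammas <- c(sev = 1.05, "2scal" = 0.65, rnonc = 0.05, wta = 0.7,
              pfirst = 0.95, vfirst = 0.5)
  out <- lapply(names(gammas), function(k) sut_model(k, gamma = gammas[[k]]))
  names(out) <- names(gammas)
  out
}

#' Salience of a reward dimension
#'
#' For a vector of option values along one dimension, salience is
#' `(max - min) / mean`. With two options this equals the relative intensity
#' of the pair ([relative_intensity()]).
#'
#' @param values Positive option values along one dimension (length >= 2).
#' @return Dimensionless salience.
#' @examples
#' salience(c(4, 20))    # 1.33
#' salience(c(0.2, 0.5)) # 0.857
#' @export
salience <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    stop("salience needs at least two option values", call. = FALSE)
  }
  stopifnot(all(values > 0))
  (max(values) - min(values)) / mean(values)
}

# Vectorized dimension selection for the non-compensatory rules.
# Returns a character vector of length n: "volume", "probability", "random".
.draw_dimensions <- function(spec, va, pa, vb, pb, n) {
  switch(spec$kind,
    rnonc = ifelse(stats::runif(n) < spec$theta_v, "volume", "probability"),
    wta = {
      sv <- salience(c(va, vb)); sp <- salience(c(pa, pb))
      if (isTRUE(all.equal(sv, sp))) { # equal saliences: random choice
        rep("random", n)
      } else {
        hi <- if (sv > sp) "volume" else "probability"
        lo <- if (sv > sp) "probability" else "volume"
        ifelse(stats::runif(n) < spec$theta, hi, lo)
      }
    },
    pfirst = {
      sv <- salience(c(va, vb)); sp <- salience(c(pa, pb))
      dim <- if (sp > spec$threshold_p) "probability"
             else if (sv > spec$threshold_v) "volume" else "random"
      rep(dim, n)
    },
    vfirst = {
      sv <- salience(c(va, vb)); sp <- salience(c(pa, pb))
      dim <- if (sv > spec$threshold_v) "volume"
             else if (sp > spec$threshold_p) "probability" else "random"
      rep(dim, n)
    },
    stop(sprintf(
      "decision dimensions are only drawn for non-compensatory rules, not '%s'",
      spec$kind), call. = FALSE)
  )
}

#' Select the decision dimension for a non-compensatory rule
#'
#' Applies the model's criterion (Table of rules in [sut_model()]) to one
#' binary choice: which single reward dimension the decision will be based
#' on, or whether the rule reverts to random choice.
#'
#' @param spec A `sut_model` of kind rnonc, wta, pfirst or vfirst.
#' @param volumes,probabilities Numeric length-2 vectors: the two options'
#'   remembered volume and probability estimates.
#' @return One of "volume", "probability", "random".
#' @examples
#' m <- sut_model("vfirst", gamma = 0.5)
#' decision_dimension(m, volumes = c(4, 4), probabilities = c(0.2, 0.5))
#' @export
decision_dimension <- function(spec, volumes, probabilities) {
  stopifnot(inherits(spec, "sut_model"),
            length(volumes) == 2, length(probabilities) == 2)
  .draw_dimensions(spec, volumes[1], probabilities[1],
                   volumes[2], probabilities[2], 1L)
}

# normal draws, optionally redrawn until non-negative (truncation)
.rnorm_trace <- function(n, mean, sd, truncate) {
  x <- stats::rnorm(n, mean, sd)
  if (truncate) {
    bad <- which(x < 0)
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] < 0]
    }
  }
  x
}

#' Sample remembered values for one option
#'
#' Draws from the option's remembered-value (utility) distribution under the
#' given rule: `p * Normal(v, gamma v)` for sev, the product
#' `Normal(p, gamma p) * Normal(v, gamma v)` for 2scal, and
#' `Normal(r, gamma r)` on the selected dimension `r` for the
#' non-compensatory rules. Draws are not truncated at zero unless the spec
#' sets `truncate_at_zero`.
#'
#' @param spec A `sut_model`.
#' @param volume,probability The option's (remembered) volume and probability.
#' @param dimension For non-compensatory kinds, the selected dimension
#'   ("volume" or "probability") as returned by [decision_dimension()].
#' @param n Number of samples.
#' @return Numeric vector of `n` samples in utility units.
#' @export
sample_remembered_value <- function(spec, volume, probability,
                                    dimension = NULL, n = 1) {
  stopifnot(inherits(spec, "sut_model"))
  tr <- spec$truncate_at_zero
  switch(spec$kind,
    sev = {
      mu <- probability * volume
      .rnorm_trace(n, mu, spec$gamma * mu, tr)
    },
    "2scal" = {
      .rnorm_trace(n, probability, spec$gamma_p * probability, tr) *
        .rnorm_trace(n, volume, spec$gamma_v * volume, tr)
    },
    {
      if (is.null(dimension) ||
          !dimension %in% c("volume", "probability")) {
        stop("non-compensatory rules need `dimension` = \"volume\" or \"probability\"",
             call. = FALSE)
      }
      if (dimension == "volume") {
        .rnorm_trace(n, volume, spec$gamma_v * volume, tr)
      } else {
        .rnorm_trace(n, probability, spec$gamma_p * probability, tr)
      }
    }
  )
}

# Vectorized single-sample action selection between two options.
# Returns a logical vector: TRUE where option A was chosen.
.sample_choices <- function(spec, va, pa, vb, pb, n) {
  tr <- spec$truncate_at_zero
  kind <- spec$kind
  if (kind == "sev") {
    ma <- pa * va; mb <- pb * vb
    sa <- .rnorm_trace(n, ma, spec$gamma * ma, tr)
    sb <- .rnorm_trace(n, mb, spec$gamma * mb, tr)
  } else if (kind == "2scal") {
    sa <- .rnorm_trace(n, pa, spec$gamma_p * pa, tr) *
          .rnorm_trace(n, va, spec$gamma_v * va, tr)
    sb <- .rnorm_trace(n, pb, spec$gamma_p * pb, tr) *
          .rnorm_trace(n, vb, spec$gamma_v * vb, tr)
  } else {
    dims <- .draw_dimensions(spec, va, pa, vb, pb, n)
    sa <- sb <- numeric(n)
    iv <- dims == "volume"
    ip <- dims == "probability"
    if (any(iv)) {
      sa[iv] <- .rnorm_trace(sum(iv), va, spec$gamma_v * va, tr)
      sb[iv] <- .rnorm_trace(sum(iv), vb, spec$gamma_v * vb, tr)
    }
    if (any(ip)) {
      sa[ip] <- .rnorm_trace(sum(ip), pa, spec$gamma_p * pa, tr)
      sb[ip] <- .rnorm_trace(sum(ip), pb, spec$gamma_p * pb, tr)
    }
    # "random" rows keep sa == sb == 0 and fall through to the coin flip
  }
  chose_a <- sa > sb
  tie <- sa == sb
  if (any(tie)) chose_a[tie] <- stats::runif(sum(tie)) < 0.5
  chose_a
}

#' Simulate choices between two options
#'
#' Action selection: one sample from each option's remembered-value
#' distribution; the option with the larger sample is chosen. Exact sample
#' ties (and the random-choice branches of the non-compensatory rules) are
#' resolved by a fair coin.
#'
#' @param spec A `sut_model`.
#' @param option_a,option_b [reward_option()] objects (or lists with
#'   `volume` and `probability`).
#' @param n Number of independent choices.
#' @return Logical vector of length `n`; `TRUE` where option A was chosen.
#' @examples
#' set.seed(1)
#' mean(choose_option(sut_model("sev", 1.05),
#'                    reward_option(4, 0.5), reward_option(4, 0.2), 1e4))
#' @export
choose_option <- function(spec, option_a, option_b, n = 1) {
  stopifnot(inherits(spec, "sut_model"))
  .sample_choices(spec, option_a$volume, option_a$probability,
                  option_b$volume, option_b$probability, n)
}

# P(N(ma, g*ma) > N(mb, g*mb)) for independent scalar traces
.phi_pair <- function(ma, mb, g) {
  if (g == 0 || (ma == 0 && mb == 0)) {
    return(if (ma > mb) 1 else if (ma < mb) 0 else 0.5)
  }
  stats::pnorm((ma - mb) / (g * sqrt(ma^2 + mb^2)))
}

#' Closed-form choice probability
#'
#' Analytic probability of choosing option A over option B. For two
#' independent scalar traces `A ~ Normal(mu_A, gamma mu_A)` and
#' `B ~ Normal(mu_B, gamma mu_B)`,
#' `P(A > B) = pnorm((mu_A - mu_B) / (gamma * sqrt(mu_A^2 + mu_B^2)))`.
#' The sev rule uses `mu = p * v`; the non-compensatory rules mix the
#' dimension-wise probabilities by their dimension-selection weights, with
#' random-choice branches contributing 0.5. The product of two normals
#' (2scal) has no elementary closed form, so `NA` is returned; use a
#' Monte-Carlo estimate via [choose_option()] instead. Also `NA` when the
#' spec requests truncated sampling, which invalidates the normal algebra.
#'
#' @param spec A `sut_model`.
#' @param option_a,option_b [reward_option()] objects.
#' @return Probability of choosing A, or `NA` where no closed form exists.
#' @examples
#' choice_probability(sut_model("sev", 1.05),
#'                    reward_option(4, 0.5), reward_option(4, 0.2)) # 0.702
#' @export
choice_probability <- function(spec, option_a, option_b) {
  stopifnot(inherits(spec, "sut_model"))
  if (spec$truncate_at_zero) return(NA_real_)
  va <- option_a$volume; pa <- option_a$probability
  vb <- option_b$volume; pb <- option_b$probability
  g <- spec$gamma
  phi_v <- function() .phi_pair(va, vb, spec$gamma_v)
  phi_p <- function() .phi_pair(pa, pb, spec$gamma_p)
  switch(spec$kind,
    sev = .phi_pair(pa * va, pb * vb, g),
    "2scal" = NA_real_,
    rnonc = spec$theta_v * phi_v() + (1 - spec$theta_v) * phi_p(),
    wta = {
      sv <- salience(c(va, vb)); sp <- salience(c(pa, pb))
      if (isTRUE(all.equal(sv, sp))) 0.5
      else if (sv > sp) spec$theta * phi_v() + (1 - spec$theta) * phi_p()
      else spec$theta * phi_p() + (1 - spec$theta) * phi_v()
    },
    pfirst = {
      sv <- salience(c(va, vb)); sp <- salience(c(pa, pb))
      if (sp > spec$threshold_p) phi_p()
      else if (sv > spec$threshold_v) phi_v()
      else 0.5
    },
    vfirst = {
      sv <- salience(c(va, vb)); sp <- salience(c(pa, pb))
      if (sv > spec$threshold_v) phi_v()
      else if (sp > spec$threshold_p) phi_p()
      else 0.5
    }
  )
}
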