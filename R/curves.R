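#' Effort-by-outcome discount curve parameters
#'
#' Constructs and validates the parameter set of one discount-curve family.
#' Curves map normalized outcome magnitude x (0, 1] to the effort y (button
#' presses) a subject is willing to exert:
#'
#' * linear: `y = m * x + c` (m gradient in presses per unit outcome,
#'   c intercept in presses);
#' * sigmoid: `y = c / (1 + exp(-(x - bias) / sigma))` — `bias` is the
#'   left-right shift (the outcome threshold for effort initiation; higher
#'   bias = lower motivation), `sigma` the slope width (outcome sensitivity;
#'   higher sigma = flatter curve), `c` the effort asymptote;
#' * weibull: `y = A * (1 - 2^(-(x * L)^S))` — `L` the latency (minimum
#'   outcome needed to initiate effort; half-height at x = 1/L), `S` the
#'   abruptness, `A` the asymptote.
#'
#' @param family `"linear"`, `"sigmoid"` or `"weibull"`.
#' @param ... named family parameters (see Details above).
#' @param effort_cap press cap used to bound asymptotes.
#' @return A list of class `"curve_params"`.
#' @examples
#' p <- curve_params("sigmoid", c = 70, bias = 0.5, sigma = 0.1)
#' eval_curve(p, 0.5)  # half-height: 35
#' @export
curve_params <- function(family = c("linear", "sigmoid", "weibull"), ...,
                         effort_cap = 70) {
  family <- match.arg(family)
  p <- list(...)
  need <- switch(family,
                 linear = c("m", "c"),
                 sigmoid = c("c", "bias", "sigma"),
                 weibull = c("A", "L", "S"))
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop(family, " curve requires parameters: ", paste(miss, collapse = ", "))
  p <- p[need]
  if (family == "sigmoid") {
    if (p$sigma <= 0) stop("sigmoid sigma must be > 0")
    if (p$c <= 0 || p$c > effort_cap)
      stop("sigmoid asymptote c must lie in (0, effort_cap]")
  }
  if (family == "weibull") {
    if (p$A <= 0 || p$A > effort_cap)
      stop("weibull asymptote A must lie in (0, effort_cap]")
    if (p$L <= 0) stop("weibull latency L must be > 0")
    if (p$S <= 0) stop("weibull abruptness S must be > 0")
  }
  structure(c(list(family = family), p), class = "curve_params")
}

#' Observation (response-noise) parameters
#'
#' The curve value at x is the subject's indifference effort. Extrinsic
#' accept/reject choices follow a logistic rule on the gap between the curve
#' and the offer, with temperature `choice_temperature` (presses); intrinsic
#' self-set effort is the curve value plus Gaussian noise with sd
#' `intrinsic_sd` (presses).
#'
#' @param choice_temperature logistic temperature, presses, > 0.
#' @param intrinsic_sd Gaussian report sd, presses, > 0.
#' @return A list of class `"observation_params"`.
#' @export
observation_params <- function(choice_temperature = 5, intrinsic_sd = 5) {
  if (choice_temperature <= 0) stop("choice_temperature must be > 0")
  if (intrinsic_sd <= 0) stop("intrinsic_sd must be > 0")
  structure(list(choice_temperature = choice_temperature,
                 intrinsic_sd = intrinsic_sd),
            class = "observation_params")
}

#' Evaluate a discount curve
#'
#' Raw curve evaluation: no clamping to the press cap is applied here —
#' clamping belongs to the observation stage ([loglik_extrinsic()],
#' [loglik_intrinsic()], [simulate_responses()]).
#'
#' @param params a [curve_params()] object.
#' @param x normalized outcome magnitude(s), >= 0.
#' @return Predicted effort (presses), same length as `x`.
#' @export
eval_curve <- function(params, x) {
  stopifnot(inherits(params, "curve_params"), all(x >= 0))
  switch(params$family,
         linear = params$m * x + params$c,
         sigmoid = params$c / (1 + exp(-(x - params$bias) / params$sigma)),
         weibull = params$A * (1 - 2^(-(x * params$L)^params$S)))
}

#' Order two sigmoid curves by flatness
#'
#' A larger sigma yields a flatter effort-by-outcome curve: the effort range
#' spanned between two outcome levels shrinks as sigma grows. Both inputs
#' must be sigmoid curves sharing asymptote and bias, so the comparison
#' isolates sigma.
#'
#' @param params_a,params_b sigmoid [curve_params()] with identical `c` and
#'   `bias`.
#' @param x_lo,x_hi outcome interval endpoints, `x_lo < x_hi`.
#' @return List with `range_a`, `range_b` (effort spans in presses) and
#'   `flatter` (`"a"`, `"b"` or `"equal"`).
#' @export
flatness_order <- function(params_a, params_b, x_lo, x_hi) {
  if (params_a$family != "sigmoid" || params_b$family != "sigmoid")
    stop("flatness_order is defined for sigmoid curves only")
  if (params_a$c != params_b$c || params_a$bias != params_b$bias)
    stop("curves must share asymptote c and bias")
  stopifnot(x_lo < x_hi)
  ra <- abs(eval_curve(params_a, x_hi) - eval_curve(params_a, x_lo))
  rb <- abs(eval_curve(params_b, x_hi) - eval_curve(params_b, x_lo))
  flat <- if (isTRUE(all.equal(ra, rb))) "equal" else if (ra < rb) "a" else "b"
  list(range_a = ra, range_b = rb, flatter = flat)
}

# Clamp predicted effort to the feasible press range (observation stage).
.clamp_effort <- function(y, effort_cap) pmin(pmax(y, 0), effort_cap)

#' Log-likelihood of extrinsic accept/reject responses
#'
#' The subject accepts an offered effort e for outcome x with probability
#' `P(accept) = 1 / (1 + exp(-(y(x) - e) / tau))`: offers below the
#' indifference curve are accepted, with logistic noise of temperature tau.
#' Vectorized over trials; returns the sum of per-trial log terms.
#'
#' @param params a [curve_params()].
#' @param obs an [observation_params()].
#' @param trial data.frame with columns `control`, `outcome_norm`,
#'   `offered_effort` (one or more extrinsic trials).
#' @param accepted logical vector, one per trial row.
#' @param effort_cap press cap used to clamp the curve at the observation
#'   stage.
#' @return Total log-likelihood (finite for all valid inputs).
#' @export
loglik_extrinsic <- function(params, obs, trial, accepted, effort_cap = 70) {
  if (any(trial$control != "extrinsic"))
    stop("loglik_extrinsic applies to extrinsic trials only")
  y <- .clamp_effort(eval_curve(params, trial$outcome_norm), effort_cap)
  z <- (y - trial$offered_effort) / obs$choice_temperature
  sum(plogis(ifelse(accepted, z, -z), log.p = TRUE))
}

#' Log-likelihood of intrinsic self-set effort reports
#'
#' Reported effort is modelled as Gaussian around the (clamped) curve value
#' with sd `intrinsic_sd`. Vectorized over trials; returns the summed log
#' density.
#'
#' @inheritParams loglik_extrinsic
#' @param reported_effort numeric vector of self-set efforts in
#'   `[0, effort_cap]`.
#' @export
loglik_intrinsic <- function(params, obs, trial, reported_effort,
                             effort_cap = 70) {
  if (any(trial$control != "intrinsic"))
    stop("loglik_intrinsic applies to intrinsic trials only")
  if (any(reported_effort < 0 | reported_effort > effort_cap))
    stop("reported_effort outside [0, effort_cap]")
  y <- .clamp_effort(eval_curve(params, trial$outcome_norm), effort_cap)
  sum(dnorm(reported_effort, mean = y, sd = obs$intrinsic_sd, log = TRUE))
}

#' @export
print.curve_params <- function(x, ...) {
  p <- unlist(x[setdiff(names(x), "family")])
  cat(x$family, "curve:",
      paste(names(p), signif(p, 4), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
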