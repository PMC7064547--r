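#' Learning-curve parameters for one patient-stage
#'
#' Container for the two parameters of the Bernoulli learning-curve model
#' that describes trial-level success in one stage of the Goalkeeper Game:
#' `beta`, the per-trial learning rate, and `gamma`, the asymptotic success
#' probability ("total learning"). With three response options the model
#' pins the success probability of the first trial at chance (1/3) for every
#' parameter value, which requires `gamma > 1/3`.
#'
#' @param beta Learning rate per trial; finite, nonnegative by default.
#' @param gamma Asymptotic success probability, in (1/3, 1].
#' @param allow_negative_beta Permit `beta < 0` (forgetting curves) for
#'   sensitivity analyses. Default `FALSE`.
#'
#' @return An object of class `lc_params` (a named list with `beta`,
#'   `gamma`).
#' @export
#'
#' @examples
#' p <- lc_params(beta = 1, gamma = 0.8)
#' success_probability(p, t = 1:10)
lc_params <- function(beta, gamma, allow_negative_beta = FALSE) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (gamma <= 1 / 3)
    stop("gamma must exceed 1/3 (chance level with three options); got ",
         format(gamma), call. = FALSE)
  if (gamma > 1)
    stop("gamma is a probability and cannot exceed 1; got ", format(gamma),
         call. = FALSE)
  if (beta < 0 && !allow_negative_beta)
    stop("beta must be nonnegative (set allow_negative_beta = TRUE for ",
         "sensitivity analyses)", call. = FALSE)
  structure(list(beta = beta, gamma = gamma), class = "lc_params")
}

#' @export
print.lc_params <- function(x, ...) {
  cat(sprintf("learning-curve parameters: beta = %.4g, gamma = %.4g\n",
              x$beta, x$gamma))
  invisible(x)
}

as_lc_params <- function(params) {
  if (inherits(params, "lc_params")) return(params)
  if (is.numeric(params) && length(params) == 2L && !is.null(names(params)))
    return(lc_params(params[["beta"]], params[["gamma"]]))
  stop("expected an lc_params object", call. = FALSE)
}

#' Per-trial success probability of the learning-curve model
#'
#' The model sets `lambda_t = (t - 1) * beta - log(3 * gamma - 1)` and
#' `P(X_t = 1) = gamma * plogis(lambda_t)`. At `t = 1` this equals 1/3
#' exactly for every valid parameter pair (the player has no information and
#' three options); for `beta > 0` the probability increases strictly in `t`
#' towards the asymptote `gamma`; for `beta = 0` it stays flat at 1/3.
#'
#' @param params An [lc_params()] object.
#' @param t Integer trial index (vectorized), `t >= 1`.
#'
#' @return Numeric vector of success probabilities in (0, 1).
#' @export
success_probability <- function(params, t) {
  params <- as_lc_params(params)
  if (any(t < 1) || any(t != floor(t)))
    stop("trial index t must be an integer >= 1", call. = FALSE)
  lambda <- (t - 1) * params$beta - log(3 * params$gamma - 1)
  params$gamma * stats::plogis(lambda)
}

# Vectorized over a parameter grid: beta, gamma vectors of equal length,
# t a vector of trial indices; returns length(beta) x length(t) matrix of
# success probabilities. Used by the quadrature fitter.
success_probability_grid <- function(beta, gamma, t) {
  lambda <- outer(beta, t - 1) - log(3 * gamma - 1)  # recycles gamma by row
  gamma * stats::plogis(lambda)
}

#' Log-likelihood of a trial-outcome sequence
#'
#' Trials within a stage are conditionally independent Bernoulli draws given
#' the parameters, with per-trial success probabilities from
#' [success_probability()]. The empty sequence has log-likelihood 0.
#'
#' @param params An [lc_params()] object.
#' @param outcomes Integer vector of 0/1 success indicators, trial `t`
#'   running from 1 in order.
#'
#' @return The log-likelihood (a real number `<= 0`).
#' @export
sequence_log_likelihood <- function(params, outcomes) {
  if (length(outcomes) == 0L) return(0)
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  p <- success_probability(params, seq_along(outcomes))
  sum(ifelse(outcomes == 1, log(p), log1p(-p)))
}

#' Simulate one stage of trial outcomes
#'
#' Forward-samples the learning-curve model: independent Bernoulli draws
#' with the per-trial probabilities of [success_probability()].
#'
#' @param params An [lc_params()] object.
#' @param n_trials Number of trials (`>= 0`).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is left untouched.
#'
#' @return Integer vector of 0/1 outcomes of length `n_trials`.
#' @export
simulate_stage <- function(params, n_trials, seed = NULL) {
  params <- as_lc_params(params)
  stopifnot(n_trials >= 0)
  if (n_trials == 0L) return(integer(0))
  draw <- function() {
    p <- success_probability(params, seq_len(n_trials))
    as.integer(stats::runif(n_trials) < p)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Run code under a local RNG seed, restoring the global state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of a global seed into per-module streams, so partial
# reruns of the pipeline stay mutually consistent.
derive_seed <- function(seed, stream) {
  offsets <- c(simulate = 11L, fit = 23L, association = 37L,
               prediction = 53L, calibration = 71L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(seed) * 97L + offsets[[stream]]) %% 2147483629L
}
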