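#' Prior configuration for learning-curve fits
#'
#' The asymptote `gamma` gets a uniform prior on its support (1/3, 1]; the
#' learning rate `beta` a half-normal prior with scale `beta_scale`,
#' truncated at `beta_max` for quadrature (the mass beyond six prior scales
#' is negligible). Both choices are weakly informative on the constrained
#' domain.
#'
#' @param beta_scale Half-normal scale of the `beta` prior (default 2).
#' @param beta_max Upper quadrature bound for `beta` (default
#'   `6 * beta_scale`).
#'
#' @return A `prior_config` list.
#' @export
prior_config <- function(beta_scale = 2, beta_max = 6 * beta_scale) {
  stopifnot(beta_scale > 0, beta_max > 0)
  structure(list(beta_scale = beta_scale, beta_max = beta_max),
            class = "prior_config")
}

#' Quadrature configuration for learning-curve fits
#'
#' The posterior over (beta, gamma) is integrated deterministically in two
#' passes: a coarse midpoint grid over the whole prior domain locates the
#' posterior bulk, then a tensor Gauss-Legendre rule is laid over the
#' bounding box of nodes within `loglik_drop` log-units of the posterior
#' mode (expanded by one coarse cell). Deterministic quadrature makes fits
#' exactly reproducible with no sampler tuning.
#'
#' @param coarse_n Nodes per dimension in the locating pass (default 61).
#' @param fine_n Gauss-Legendre nodes per dimension in the refined pass
#'   (default 64).
#' @param loglik_drop Log-posterior drop defining the refinement box
#'   (default 25, i.e. mass down to `exp(-25)` of the mode is covered).
#' @param level Central credible-interval level (default 0.90).
#'
#' @return A `quad_config` list.
#' @export
quad_config <- function(coarse_n = 61, fine_n = 64, loglik_drop = 25,
                        level = 0.90) {
  stopifnot(coarse_n >= 11, fine_n >= 8, loglik_drop > 0,
            level > 0, level < 1)
  structure(list(coarse_n = coarse_n, fine_n = fine_n,
                 loglik_drop = loglik_drop, level = level),
            class = "quad_config")
}

# Gauss-Legendre nodes/weights on [a, b] by Golub-Welsch.
gauss_legendre <- function(n, a = -1, b = 1) {
  if (n == 1L) return(list(nodes = (a + b) / 2, weights = b - a))
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  weights <- 2 * e$vectors[1, ord]^2
  list(nodes = (nodes + 1) / 2 * (b - a) + a, weights = weights * (b - a) / 2)
}

# Log-likelihood of `outcomes` on every (beta, gamma) combination.
# Returns length(beta)-by-length(gamma) matrix.
loglik_surface <- function(outcomes, beta, gamma) {
  t_idx <- seq_along(outcomes)
  out <- matrix(0, length(beta), length(gamma))
  for (j in seq_along(gamma)) {
    lambda <- outer(beta, t_idx - 1) - log(3 * gamma[j] - 1)
    p <- gamma[j] * stats::plogis(lambda)
    out[, j] <- log(p) %*% outcomes + log1p(-p) %*% (1 - outcomes)
  }
  out
}

log_prior_beta <- function(beta, prior) {
  # half-normal, truncated to [0, beta_max]; normalizing constant constant
  # across the domain so it cancels in posterior means
  stats::dnorm(beta, 0, prior$beta_scale, log = TRUE)
}

#' Fit the learning-curve model to one stage by Bayesian quadrature
#'
#' Computes the joint posterior of (beta, gamma) under the priors of
#' [prior_config()] by two-pass deterministic quadrature and returns
#' posterior means, central credible intervals, and identification
#' diagnostics. Degenerate sequences (all failures, very short stages) give
#' wide, flagged posteriors rather than failures.
#'
#' @param outcomes Integer 0/1 vector of within-stage trial outcomes.
#' @param prior A [prior_config()].
#' @param quad A [quad_config()].
#'
#' @return A `posterior_summary` list: `beta_hat`, `gamma_hat` (posterior
#'   means), `beta_sd`, `gamma_sd`, `beta_interval`, `gamma_interval`
#'   (central credible intervals at `quad$level`), and `diagnostics`
#'   (`log_evidence`, `weak_beta`, `weak_gamma`, `n_trials`, `n_success`,
#'   refinement `box`).
#' @export
#'
#' @examples
#' y <- simulate_stage(lc_params(1.76, 0.64), 50, seed = 1)
#' fit_stage(y)
fit_stage <- function(outcomes, prior = prior_config(), quad = quad_config()) {
  if (length(outcomes) == 0L)
    stop("cannot fit an empty outcome sequence", call. = FALSE)
  if (!all(outcomes %in% c(0, 1)))
    stop("outcomes must be binary 0/1", call. = FALSE)
  outcomes <- as.numeric(outcomes)

  g_lo <- 1 / 3
  # pass 1: midpoint grid over the full domain
  nb <- quad$coarse_n
  cb <- (seq_len(nb) - 0.5) / nb * prior$beta_max
  cg <- g_lo + (seq_len(nb) - 0.5) / nb * (1 - g_lo)
  ll <- loglik_surface(outcomes, cb, cg)
  lp <- ll + log_prior_beta(cb, prior)  # gamma prior flat
  keep <- which(lp >= max(lp) - quad$loglik_drop, arr.ind = TRUE)
  db <- prior$beta_max / nb
  dg <- (1 - g_lo) / nb
  b_box <- c(max(0, min(cb[keep[, 1]]) - db), min(prior$beta_max,
                                                 max(cb[keep[, 1]]) + db))
  g_box <- c(max(g_lo + 1e-9, min(cg[keep[, 2]]) - dg),
             min(1, max(cg[keep[, 2]]) + dg))

  # pass 2: tensor Gauss-Legendre on the box
  glb <- gauss_legendre(quad$fine_n, b_box[1], b_box[2])
  glg <- gauss_legendre(quad$fine_n, g_box[1], g_box[2])
  ll2 <- loglik_surface(outcomes, glb$nodes, glg$nodes)
  lp2 <- ll2 + log_prior_beta(glb$nodes, prior)
  m <- max(lp2)
  w <- exp(lp2 - m) * outer(glb$weights, glg$weights)
  Z <- sum(w)
  w <- w / Z

  wb <- rowSums(w)
  wg <- colSums(w)
  beta_hat <- sum(wb * glb$nodes)
  gamma_hat <- sum(wg * glg$nodes)
  beta_sd <- sqrt(max(0, sum(wb * glb$nodes^2) - beta_hat^2))
  gamma_sd <- sqrt(max(0, sum(wg * glg$nodes^2) - gamma_hat^2))

  alpha <- (1 - quad$level) / 2
  beta_int <- weighted_quantile(glb$nodes, wb, c(alpha, 1 - alpha))
  gamma_int <- weighted_quantile(glg$nodes, wg, c(alpha, 1 - alpha))
  # intervals must bracket their point estimates even in near-degenerate fits
  beta_int <- c(min(beta_int[1], beta_hat), max(beta_int[2], beta_hat))
  gamma_int <- c(min(gamma_int[1], gamma_hat), max(gamma_int[2], gamma_hat))

  # weak identification: credible width above half the matching central
  # prior interval width; |N(0, s)| has quantile q(p) = s * qnorm((1 + p) / 2)
  prior_beta_w <- prior$beta_scale *
    (stats::qnorm(1 - alpha / 2) - stats::qnorm(0.5 + alpha / 2))
  prior_gamma_w <- quad$level * (1 - g_lo)

  structure(list(
    beta_hat = beta_hat, gamma_hat = gamma_hat,
    beta_sd = beta_sd, gamma_sd = gamma_sd,
    beta_interval = beta_int, gamma_interval = gamma_int,
    level = quad$level,
    diagnostics = list(
      log_evidence = m + log(Z),
      weak_beta = diff(beta_int) > prior_beta_w / 2,
      weak_gamma = diff(gamma_int) > prior_gamma_w / 2,
      n_trials = length(outcomes), n_success = sum(outcomes),
      box = list(beta = b_box, gamma = g_box))),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "posterior: beta = %.3f [%.3f, %.3f], gamma = %.3f [%.3f, %.3f] (%d%% CI)\n",
    x$beta_hat, x$beta_interval[1], x$beta_interval[2],
    x$gamma_hat, x$gamma_interval[1], x$gamma_interval[2],
    round(100 * x$level)))
  if (isTRUE(x$diagnostics$weak_gamma) || isTRUE(x$diagnostics$weak_beta))
    cat("note: weakly identified (credible width > half the prior width)\n")
  invisible(x)
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  sapply(probs, function(p) x[ord][which(cw >= p)[1]])
}

#' Extract the nine-variable Goalkeeper Game feature vector for one patient
#'
#' Fits the learning curve separately to each of the three stages (motor
#' baseline, learning, memory) and appends the arithmetic mean response
#' time per stage: `(beta1..beta3, gamma1..gamma3, tbar1..tbar3)`.
#'
#' @param patient_trials Data frame with columns `stage` (1, 2, 3),
#'   `trial_index`, `outcome` (0/1) and `response_time_s` for a single
#'   patient.
#' @param prior,quad Passed to [fit_stage()].
#'
#' @return Named numeric vector of length 9.
#' @export
extract_features <- function(patient_trials, prior = prior_config(),
                             quad = quad_config()) {
  stages <- sort(unique(patient_trials$stage))
  if (!identical(as.integer(stages), 1:3)) {
    miss <- setdiff(1:3, stages)
    id <- if ("patient_id" %in% names(patient_trials))
      patient_trials$patient_id[1] else "<unknown>"
    stop(sprintf("patient %s: missing stage(s) %s", id,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- numeric(9)
  names(out) <- c(paste0("beta", 1:3), paste0("gamma", 1:3),
                  paste0("tbar", 1:3))
  for (s in 1:3) {
    rows <- patient_trials[patient_trials$stage == s, ]
    rows <- rows[order(rows$trial_index), ]
    fit <- fit_stage(rows$outcome, prior, quad)
    out[paste0("beta", s)] <- fit$beta_hat
    out[paste0("gamma", s)] <- fit$gamma_hat
    out[paste0("tbar", s)] <- mean(rows$response_time_s)
  }
  out
}

#' Fit the learning-curve model to a whole cohort
#'
#' Runs [extract_features()] for every patient in a trials table. Failures
#' for individual patients are reported as warnings and yield `NA` rows
#' rather than aborting the batch.
#'
#' @param trials Data frame with columns `patient_id`, `stage`,
#'   `trial_index`, `outcome`, `response_time_s`.
#' @param prior,quad Passed to [fit_stage()].
#'
#' @return Data frame: `patient_id` plus the nine feature columns, one row
#'   per patient in first-appearance order.
#' @export
fit_cohort <- function(trials, prior = prior_config(), quad = quad_config()) {
  validate_trials(trials)
  feat_names <- c(paste0("beta", 1:3), paste0("gamma", 1:3),
                  paste0("tbar", 1:3))
  if (nrow(trials) == 0L) {
    warning("empty trials table; returning empty feature table")
    out <- as.data.frame(c(list(patient_id = character(0)),
                           stats::setNames(rep(list(numeric(0)), 9),
                                           feat_names)))
    return(out)
  }
  ids <- unique(trials$patient_id)
  mat <- matrix(NA_real_, length(ids), 9, dimnames = list(NULL, feat_names))
  for (i in seq_along(ids)) {
    res <- tryCatch(
      extract_features(trials[trials$patient_id == ids[i], ], prior, quad),
      error = function(e) {
        warning(sprintf("patient %s skipped: %s", ids[i], conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (!is.null(res)) mat[i, ] <- res
  }
  cbind(data.frame(patient_id = ids, stringsAsFactors = FALSE),
        as.data.frame(mat))
}

validate_trials <- function(trials) {
  needed <- c("patient_id", "stage", "trial_index", "outcome",
              "response_time_s")
  miss <- setdiff(needed, names(trials))
  if (length(miss))
    stop("trials table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0L) return(invisible(trials))
  bad <- which(!(trials$stage %in% 1:3))
  if (length(bad))
    stop("invalid stage value(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (stages must be 1, 2 or 3)", call. = FALSE)
  if (!all(trials$outcome %in% c(0, 1)))
    stop("outcome column must be binary 0/1", call. = FALSE)
  if (any(trials$response_time_s < 0, na.rm = TRUE))
    stop("response times must be nonnegative", call. = FALSE)
  key <- paste(trials$patient_id, trials$stage, trials$trial_index)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, stage, trial_index) key(s), e.g. ",
         key[anyDuplicated(key)], call. = FALSE)
  invisible(trials)
}
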