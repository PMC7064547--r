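# Latent-normal association measures (polyserial, polychoric) and a
# cumulative-logit proportional-odds fitter. Both correlation estimators
# use the classical two-step scheme: thresholds from the ordinal marginal
# cumulative proportions, then one-dimensional maximum likelihood over the
# latent correlation.

# Vectorized bivariate standard-normal CDF P(Z1 <= h, Z2 <= k; rho).
# Gauss-Legendre integration of the tetrachoric series representation
# d Phi2 / d rho = phi2(h, k; r); accurate to ~1e-12 for |rho| <= 0.95 and
# adequate near the boundary for likelihood maximization.
bvn_cdf <- function(h, k, rho, n_nodes = 48) {
  h <- pmax(pmin(h, 8.2), -8.2)
  k <- pmax(pmin(k, 8.2), -8.2)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  gl <- gauss_legendre(n_nodes, 0, rho)
  acc <- 0
  for (i in seq_along(gl$nodes)) {
    r <- gl$nodes[i]
    acc <- acc + gl$weights[i] *
      exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) / sqrt(1 - r^2)
  }
  pmin(pmax(base + acc / (2 * pi), 0), 1)
}

ordinal_thresholds <- function(y) {
  tab <- table(y)
  if (length(tab) < 2)
    stop("ordinal variable has fewer than 2 observed categories",
         call. = FALSE)
  cum <- cumsum(as.numeric(tab)) / length(y)
  stats::qnorm(pmin(pmax(cum[-length(cum)], 1e-12), 1 - 1e-12))
}

association_result <- function(estimate, p_value, method, n,
                               boundary = FALSE, variable = NA_character_) {
  structure(list(variable = variable, estimate = unname(estimate),
                 p_value = unname(p_value), method = method, n = n,
                 boundary = boundary),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s correlation: %.3f (p = %.3g, n = %d)%s\n", x$method,
              x$estimate, x$p_value, x$n,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Polyserial correlation between a continuous and an ordinal variable
#'
#' Assumes the ordinal variable discretizes a normal latent that is
#' bivariate normal with the (standardized) continuous variable. Two-step
#' maximum likelihood: thresholds from the ordinal marginal, then 1-D ML
#' over the latent correlation. The p-value is a likelihood-ratio test of
#' zero correlation.
#'
#' @param x Continuous numeric vector.
#' @param y Ordinal vector (numeric scores or ordered factor), paired with
#'   `x`.
#'
#' @return An `association_result`: `estimate`, `p_value`, `method`, `n`,
#'   `boundary` flag.
#' @export
polyserial_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 10)
    stop("need at least 10 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("x is constant; polyserial correlation undefined", call. = FALSE)
  z <- (x - mean(x)) / stats::sd(x)
  tau <- c(-Inf, ordinal_thresholds(y), Inf)
  cat_idx <- as.integer(factor(y, levels = sort(unique(y))))
  lo <- tau[cat_idx]; hi <- tau[cat_idx + 1L]

  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    pr <- stats::pnorm((hi - rho * z) / s) - stats::pnorm((lo - rho * z) / s)
    -sum(log(pmax(pr, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.995, 0.995), tol = 1e-8)
  lrt <- 2 * (nll(0) - opt$objective)
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  association_result(opt$minimum, p, "polyserial", length(x),
                     boundary = abs(opt$minimum) > 0.99)
}

#' Polychoric correlation between two ordinal variables
#'
#' Both variables are assumed to discretize a latent bivariate normal.
#' Two-step maximum likelihood with marginal thresholds, a 1-D search over
#' the latent correlation, and a likelihood-ratio p-value for zero
#' correlation. Empty cells are handled naturally by the likelihood.
#'
#' @param y1,y2 Ordinal vectors (numeric scores or ordered factors) of
#'   equal length.
#'
#' @return An `association_result`.
#' @export
polychoric_correlation <- function(y1, y2) {
  if (length(y1) != length(y2)) stop("lengths differ", call. = FALSE)
  keep <- stats::complete.cases(y1, y2)
  y1 <- y1[keep]; y2 <- y2[keep]
  if (length(y1) < 10)
    stop("need at least 10 complete pairs", call. = FALSE)
  t1 <- c(-Inf, ordinal_thresholds(y1), Inf)
  t2 <- c(-Inf, ordinal_thresholds(y2), Inf)
  counts <- table(factor(y1, levels = sort(unique(y1))),
                  factor(y2, levels = sort(unique(y2))))
  nz <- which(counts > 0, arr.ind = TRUE)
  n_ij <- counts[nz]
  h_hi <- t1[nz[, 1] + 1L]; h_lo <- t1[nz[, 1]]
  k_hi <- t2[nz[, 2] + 1L]; k_lo <- t2[nz[, 2]]

  nll <- function(rho) {
    pr <- bvn_cdf(h_hi, k_hi, rho) - bvn_cdf(h_lo, k_hi, rho) -
      bvn_cdf(h_hi, k_lo, rho) + bvn_cdf(h_lo, k_lo, rho)
    -sum(n_ij * log(pmax(pr, 1e-300)))
  }
  opt <- stats::optimize(nll, c(-0.995, 0.995), tol = 1e-8)
  lrt <- 2 * (nll(0) - opt$objective)
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  association_result(opt$minimum, p, "polychoric", length(y1),
                     boundary = abs(opt$minimum) > 0.99)
}

#' Proportional-odds (cumulative logit) regression
#'
#' Maximum-likelihood fit of `logit P(Y <= j | x) = zeta_j - x %*% beta`
#' with parallel slopes, the standard cumulative-logit model for ordinal
#' responses. Thresholds are kept ordered through a log-difference
#' parameterization during optimization; standard errors come from the
#' observed information at the optimum. With a two-category response the
#' model is ordinary logistic regression.
#'
#' @param X Numeric predictor matrix (or vector), one row per observation.
#' @param y Ordinal response (numeric scores or ordered factor).
#' @param standardize Standardize columns of `X` before fitting (default
#'   `FALSE`: per-unit coefficients).
#'
#' @return An `ordinal_fit` list: `coefficients`, `se`, `p_values` (Wald),
#'   `zeta` (thresholds), `logLik`, `converged`, `n`.
#' @export
proportional_odds_fit <- function(X, y, standardize = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  lev <- sort(unique(as.numeric(y)))
  K <- length(lev)
  if (K < 2) stop("response has a single category", call. = FALSE)
  p <- ncol(X)
  n <- nrow(X)
  if (n <= p + K - 1)
    stop("too few observations for ", p, " predictors and ", K - 1,
         " thresholds", call. = FALSE)
  if (standardize) X <- scale(X)
  j <- match(as.numeric(y), lev)

  # theta = (zeta_1, log(zeta_2 - zeta_1), ..., beta)
  unpack <- function(theta) {
    zr <- theta[seq_len(K - 1)]
    zeta <- cumsum(c(zr[1], exp(zr[-1])))
    list(zeta = zeta, beta = theta[K:(K - 1 + p)])
  }
  nll_direct <- function(zeta, beta) {
    eta <- drop(X %*% beta)
    up <- c(zeta, Inf)[j] - eta
    lo <- c(-Inf, zeta)[j] - eta
    -sum(log(pmax(stats::plogis(up) - stats::plogis(lo), 1e-300)))
  }
  nll <- function(theta) {
    u <- unpack(theta)
    nll_direct(u$zeta, u$beta)
  }
  # starts: thresholds from marginal logits, slopes at 0
  cum <- cumsum(tabulate(j, K))[-K] / n
  z0 <- stats::qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6))
  z0 <- cummax(z0 + seq_len(K - 1) * 1e-9)  # guard exact ties
  theta0 <- c(z0[1], log(pmax(diff(z0), 1e-6)), rep(0, p))
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  # Newton polish in the direct parameterization for high-precision MLE
  u <- unpack(opt$par)
  par_d <- c(u$zeta, u$beta)
  nld <- function(v) nll_direct(v[seq_len(K - 1)], v[K:(K - 1 + p)])
  H <- NULL
  converged <- opt$convergence == 0
  for (it in 1:25) {
    g <- numDeriv_grad(nld, par_d)
    H <- stats::optimHess(par_d, nld)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par_d - step
    if (any(diff(cand[seq_len(K - 1)]) <= 0) || nld(cand) > nld(par_d) + 1e-9)
      break
    par_d <- cand
    if (max(abs(step)) < 1e-10) break
  }
  zeta <- par_d[seq_len(K - 1)]
  beta <- par_d[K:(K - 1 + p)]
  names(beta) <- colnames(X)
  vcov <- tryCatch(solve(stats::optimHess(par_d, nld)),
                   error = function(e) matrix(NA, K - 1 + p, K - 1 + p))
  se <- sqrt(pmax(diag(vcov)[K:(K - 1 + p)], 0))
  if (any(!is.finite(se))) converged <- FALSE
  zval <- beta / se
  structure(list(
    coefficients = beta, se = stats::setNames(se, colnames(X)),
    p_values = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(X)),
    zeta = stats::setNames(zeta, paste(lev[-K], lev[-1], sep = "|")),
    logLik = -nld(par_d), converged = converged, n = n,
    levels = lev),
    class = "ordinal_fit")
}

# central-difference gradient; adequate for smooth log-likelihoods
numDeriv_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("proportional-odds fit (%d obs, %d categories)%s\n", x$n,
              length(x$levels),
              if (!x$converged) " [did not converge]" else ""))
  print(data.frame(coef = x$coefficients, se = x$se, p = x$p_values))
  invisible(x)
}

#' Pairwise associations between DGI and the explanatory variables
#'
#' Builds the ten-row association table: polychoric correlation for the
#' MoCA-DGI pair (both discrete scores) and polyserial correlations for
#' the nine continuous Goalkeeper Game variables against DGI, in the order
#' MoCA, then (beta, gamma, tbar) for stages 1-3.
#'
#' @param features Feature table from [fit_cohort()] (`patient_id` + nine
#'   feature columns).
#' @param clinical Clinical table with `patient_id`, `dgi_total`,
#'   `moca_total`.
#' @param max_missing Warn when more than this fraction of patients is
#'   dropped as incomplete (default 0.1).
#'
#' @return Data frame with columns `variable`, `estimate`, `p_value`,
#'   `method`; one row per explanatory variable.
#' @export
association_table <- function(features, clinical, max_missing = 0.1) {
  dat <- merge(features, clinical, by = "patient_id")
  vars <- c("moca_total", "beta1", "gamma1", "tbar1", "beta2", "gamma2",
            "tbar2", "beta3", "gamma3", "tbar3")
  cc <- stats::complete.cases(dat[, c(vars, "dgi_total")])
  if (mean(!cc) > max_missing)
    warning(sprintf("%d of %d patients dropped as incomplete", sum(!cc),
                    nrow(dat)))
  dat <- dat[cc, ]
  rows <- lapply(vars, function(v) {
    res <- if (v == "moca_total")
      polychoric_correlation(dat[[v]], dat$dgi_total)
    else polyserial_correlation(dat[[v]], dat$dgi_total)
    data.frame(variable = sub("_total", "", v), estimate = res$estimate,
               p_value = res$p_value, method = res$method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
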