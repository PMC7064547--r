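# Independent oracles used by the tests. Everything here is written
# directly from first principles (plain loops, explicit enumeration) and
# must stay independent of the package's own implementation paths.

# Dense-grid posterior oracle: 200x200 midpoint rule over the full
# constrained domain, uniform prior on gamma, half-normal(scale) on beta.
grid_posterior_oracle <- function(outcomes, beta_scale = 2, beta_max = 12,
                                  nb = 200) {
  b <- (seq_len(nb) - 0.5) / nb * beta_max
  g <- 1 / 3 + (seq_len(nb) - 0.5) / nb * (2 / 3)
  ll <- matrix(0, nb, nb)
  t_idx <- seq_along(outcomes)
  for (j in seq_len(nb)) {
    lam <- outer(b, t_idx - 1) - log(3 * g[j] - 1)
    p <- g[j] * plogis(lam)
    ll[, j] <- log(p) %*% outcomes + log1p(-p) %*% (1 - outcomes)
  }
  lp <- ll + dnorm(b, 0, beta_scale, log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(beta = sum(rowSums(w) * b), gamma = sum(colSums(w) * g))
}

# Draw an ordinal variable by cutting a normal latent at thresholds that
# reproduce a discretized-normal marginal over integer scores lo..hi.
cut_latent_ordinal <- function(z, lo, hi, mean, sd) {
  k <- lo:hi
  p <- pnorm(k + 0.5, mean, sd) - pnorm(k - 0.5, mean, sd)
  p <- p / sum(p)
  cuts <- qnorm(cumsum(p)[-length(p)])
  k[findInterval(z, cuts) + 1L]
}

# Brute-force DeLong machinery: placement values by explicit double
# loops and the paired-difference variance from the textbook formula.
delong_brute <- function(scores_a, scores_b, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  place <- function(s) {
    v10 <- numeric(length(pos))
    for (i in seq_along(pos)) {
      acc <- 0
      for (j in seq_along(neg)) {
        d <- s[pos[i]] - s[neg[j]]
        acc <- acc + (d > 0) + 0.5 * (d == 0)
      }
      v10[i] <- acc / length(neg)
    }
    v01 <- numeric(length(neg))
    for (j in seq_along(neg)) {
      acc <- 0
      for (i in seq_along(pos)) {
        d <- s[pos[i]] - s[neg[j]]
        acc <- acc + (d > 0) + 0.5 * (d == 0)
      }
      v01[j] <- acc / length(pos)
    }
    list(v10 = v10, v01 = v01)
  }
  pa <- place(scores_a)
  pb <- place(scores_b)
  v <- (var(pa$v10) + var(pb$v10) - 2 * cov(pa$v10, pb$v10)) / length(pos) +
    (var(pa$v01) + var(pb$v01) - 2 * cov(pa$v01, pb$v01)) / length(neg)
  list(auc_a = mean(pa$v10), auc_b = mean(pb$v10), variance = v)
}

# AUC by explicit enumeration of all positive-negative pairs.
auc_pair_count <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  acc <- 0
  for (xi in x) for (yj in y) acc <- acc + (xi > yj) + 0.5 * (xi == yj)
  acc / (length(x) * length(y))
}

random_valid_params <- function(n) {
  data.frame(beta = runif(n, 0, 5), gamma = runif(n, 1 / 3 + 1e-6, 1))
}

# coarser quadrature used inside large replicate loops, where per-fit
# precision far exceeds what the downstream classification can resolve
fast_quad <- function() quad_config(coarse_n = 31, fine_n = 32)
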