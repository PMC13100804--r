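# Independent oracles, coded from the published definitions by a route
# separate from the package implementation. They stay deliberately naive
# (explicit loops, solve(), uniroot) so equality against the package is a
# genuine dual-route check.

# --- empirical-Bayes moderated t, direct-formula route ---------------------
# Per-feature OLS via explicit normal equations; prior (d0, s0^2) by moment
# matching of log s^2, with the trigamma inversion done by uniroot.
oracle_ebayes <- function(Y, X, contrast) {
  nf <- ncol(Y)
  beta <- u <- s2 <- df <- numeric(nf)
  for (g in seq_len(nf)) {
    y <- Y[, g]
    XtX <- t(X) %*% X
    b <- solve(XtX, t(X) %*% y)
    r <- y - X %*% b
    df[g] <- nrow(X) - ncol(X)
    s2[g] <- sum(r^2) / df[g]
    beta[g] <- sum(contrast * b)
    u[g] <- drop(t(contrast) %*% solve(XtX) %*% contrast)
  }
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * stats::uniroot(function(x) trigamma(x) - evar,
                             c(1e-6, 1e6), tol = 1e-14)$root
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, nf) else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  t_mod <- beta / sqrt(u * s2_post)
  p <- 2 * stats::pt(-abs(t_mod), pmin(d0 + df, sum(df)))
  list(d0 = d0, s0_sq = s0_sq, t = t_mod, p = p, beta = beta)
}

# --- Benjamini-Hochberg, O(m^2) definitional route -------------------------
# q_i = min over thresholds t in {p_j : p_j >= p_i} of min(1, m t / #{p <= t})
oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[p >= p[i]]
    q[i] <- min(1, min(sapply(cand, function(t) m * t / sum(p <= t))))
  }
  q
}

# --- chi-square(4) upper tail by numerical integration ---------------------
oracle_chisq4_tail <- function(x) {
  dens <- function(t) t * exp(-t / 2) / 4
  stats::integrate(dens, x, Inf, rel.tol = 1e-12)$value
}

# --- Spearman rho: rank then base-R Pearson --------------------------------
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# --- balanced one-way random-intercept model, ML closed form ---------------
# a subjects, n observations each, intercept-only fixed part:
#   mu^ = grand mean, sigma_e^2 = SSW / (a(n-1)), tau^2 = SSB / a,
#   sigma_b^2 = max(0, (tau^2 - sigma_e^2) / n)
oracle_balanced_lmm <- function(y, subject) {
  groups <- split(y, subject)
  a <- length(groups)
  n <- length(groups[[1]])
  stopifnot(all(lengths(groups) == n))
  gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ssb <- n * sum((means - gm)^2)
  sigma_e2 <- ssw / (a * (n - 1))
  tau2 <- ssb / a
  sigma_b2 <- max(0, (tau2 - sigma_e2) / n)
  tau2 <- sigma_e2 + n * sigma_b2  # truncated at the boundary
  N <- a * n
  ll <- -0.5 * (N * log(2 * pi) + a * (n - 1) * log(sigma_e2) +
                  a * log(tau2) + ssw / sigma_e2 + ssb / tau2)
  list(mu = gm, sigma_e2 = sigma_e2, sigma_b2 = sigma_b2, loglik = ll)
}

# --- shared fixture builders ----------------------------------------------
toy_log2_matrix <- function(values, samples, features) {
  m <- matrix(values, nrow = length(samples),
              dimnames = list(samples, features))
  feature_matrix(m, scale = "log2")
}
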