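two_group_meta <- function(n1 = 3, n2 = 3) {
  data.frame(sample_id = sprintf("s%d", seq_len(n1 + n2)),
             grp = rep(c("a", "b"), c(n1, n2)),
             stringsAsFactors = FALSE)
}

test_that("group-means design with (-1, +1) contrast estimates the mean difference", {
  meta <- two_group_meta()
  X <- build_design(meta, "grp")
  expect_equal(ncol(X), 2L)
  m <- toy_log2_matrix(c(1, 2, 3, 3, 4, 5), meta$sample_id, "f1")
  m$values <- cbind(m$values, f2 = c(0, 1, 2, 10, 11, 12))
  fits <- fit_feature_models(feature_matrix(m$values, "log2"), X)
  f1 <- fits$fits$f1
  ct <- group_contrast(X, "b", "a")
  expect_equal(sum(ct * f1$coefficients), 2)
  expect_equal(f1$s2, 1)
  expect_equal(f1$df, 4)
})

test_that("a covariate orthogonal to the contrast leaves the estimate unchanged", {
  meta <- two_group_meta(4, 4)
  ## mean-zero within each group => orthogonal to both group indicators
  meta$cov <- rep(c(-1, 1, -0.5, 0.5), 2)
  set.seed(1)
  y <- rnorm(8) + rep(c(0, 1), each = 4)
  m <- toy_log2_matrix(y, meta$sample_id, "f1")
  X0 <- build_design(meta, "grp")
  X1 <- build_design(meta, "grp", covariates = "cov")
  b0 <- fit_feature_models(m, X0)$fits$f1$coefficients
  b1 <- fit_feature_models(m, X1)$fits$f1$coefficients
  expect_equal(unname(b1["b"] - b1["a"]), unname(b0["b"] - b0["a"]),
               tolerance = 1e-12)
})

test_that("rank-deficient designs error naming the collinear columns", {
  meta <- two_group_meta()
  meta$c1 <- 1
  expect_error(build_design(meta, "grp", covariates = "c1"), "c1")
  meta$c2 <- meta$c1
  expect_error(build_design(meta, "grp", covariates = c("c1", "c2")),
               "collinear")
})

test_that("per-feature fitting handles noiseless data and skips short features", {
  meta <- two_group_meta(4, 4)
  X <- build_design(meta, "grp")
  beta <- c(a = 2, b = 5)
  y <- drop(X %*% beta)
  v <- cbind(clean = y, short = c(y[1], y[2], rep(NA, 6)))
  rownames(v) <- meta$sample_id
  fits <- fit_feature_models(feature_matrix(v, "log2"), X)
  expect_equal(unname(fits$fits$clean$coefficients), unname(beta))
  expect_equal(fits$fits$clean$s2, 0, tolerance = 1e-20)
  expect_identical(fits$skipped, "short")
  expect_error(fit_feature_models(
    feature_matrix(v[, "short", drop = FALSE], "log2"), X), "all features")
})

test_that("moderated statistics match limma on complete data", {
  skip_if_not_installed("limma")
  set.seed(10)
  n <- 12; nf <- 80
  meta <- two_group_meta(6, 6)
  meta$bw <- rnorm(n, 30, 3)
  Y <- matrix(rnorm(n * nf), n, nf,
              dimnames = list(meta$sample_id, sprintf("f%03d", 1:nf)))
  Y[, 1:10] <- Y[, 1:10] + outer(meta$grp == "b", rep(1, 10))
  X <- build_design(meta, "grp", covariates = "bw")
  fits <- fit_feature_models(feature_matrix(Y, "log2"), X)
  ev <- ebayes_moderate(fits, group_contrast(X, "b", "a"))

  lfit <- limma::lmFit(t(Y), X)
  lfit <- limma::contrasts.fit(lfit, c(-1, 1, 0))
  lfit <- limma::eBayes(lfit)
  expect_equal(attr(ev, "moderation")$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(attr(ev, "moderation")$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(ev$t, unname(lfit$t[, 1]), tolerance = 1e-8)
  expect_equal(ev$p, unname(lfit$p.value[, 1]), tolerance = 1e-8)
  expect_equal(ev$estimate, unname(lfit$coefficients[, 1]), tolerance = 1e-10)
})

test_that("zero variance spread collapses to the infinite-prior limit", {
  meta <- two_group_meta()
  X <- build_design(meta, "grp")
  ## identical residual pattern for every feature -> identical s2
  base <- c(-1, 0, 1, -1, 0, 1)
  Y <- sapply(1:6, function(k) base + k)
  dimnames(Y) <- list(meta$sample_id, sprintf("f%d", 1:6))
  fits <- fit_feature_models(feature_matrix(Y, "log2"), X)
  ev <- ebayes_moderate(fits, group_contrast(X, "b", "a"))
  mod <- attr(ev, "moderation")
  expect_identical(mod$d0, Inf)
  ## every moderated variance collapses onto the prior variance
  expect_equal(unname(ev$se^2 / sapply(fits$fits, function(f) {
    drop(group_contrast(X, "b", "a") %*% f$cov_unscaled %*%
           group_contrast(X, "b", "a"))
  })), rep(mod$s0_sq, 6), tolerance = 1e-10)
})

test_that("moderated p-values hold their nominal type-I rate under the null", {
  set.seed(123)
  n <- 12; nf <- 10000
  meta <- two_group_meta(6, 6)
  Y <- matrix(rnorm(n * nf), n, nf,
              dimnames = list(meta$sample_id, sprintf("f%05d", 1:nf)))
  X <- build_design(meta, "grp")
  ev <- ebayes_moderate(fit_feature_models(feature_matrix(Y, "log2"), X),
                        group_contrast(X, "b", "a"))
  rate <- mean(ev$p < 0.05)
  bound <- 2.576 * sqrt(0.05 * 0.95 / nf)
  expect_lt(abs(rate - 0.05), bound)
})

test_that("BH adjustment follows the definitional oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(99)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    p <- signif(runif(m), sample(1:3, 1))  # encourage ties
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  ## agreement with the reference implementation
  set.seed(100)
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
})

test_that("shrinking a p-value never loses discoveries (BH monotonicity)", {
  set.seed(5)
  for (i in 1:30) {
    p <- runif(25)
    q1 <- sum(bh_adjust(p) < 0.1)
    j <- sample(25, 1)
    p[j] <- p[j] * runif(1)
    expect_gte(sum(bh_adjust(p) < 0.1), q1)
  }
})

test_that("Fisher combination matches the chi-square(4) tail", {
  expect_equal(fisher_combine(1, 1), 1)
  expect_equal(fisher_combine(0.2, 0.7), fisher_combine(0.7, 0.2))
  expect_error(fisher_combine(0, 0.5), "0, 1")
  x2 <- -2 * (log(0.1) + log(0.1))
  expect_equal(x2, 9.21034, tolerance = 1e-6)
  expect_equal(fisher_combine(0.1, 0.1), oracle_chisq4_tail(x2),
               tolerance = 1e-8)
  set.seed(2)
  p1 <- runif(20); p2 <- runif(20)
  comb <- fisher_combine(p1, p2)
  for (k in 1:20) {
    expect_equal(comb[k], oracle_chisq4_tail(-2 * (log(p1[k]) + log(p2[k]))),
                 tolerance = 1e-8)
  }
  ## (p, 1) keeps the p (1 - ln p) closed form
  p <- c(0.01, 0.2, 0.9)
  expect_equal(fisher_combine(p, rep(1, 3)), p * (1 - log(p)),
               tolerance = 1e-10)
})
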