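simulate_lmm <- function(n_subj, n_per, beta, sd_subj, sd_e, seed,
                         doses = c(0, 25, 50, 100)) {
  set.seed(seed)
  subject <- rep(sprintf("s%03d", 1:n_subj), each = n_per)
  dose <- rep(sample(doses, n_per, replace = n_per > length(doses)),
              times = n_subj)
  X <- cbind(1, dose, dose^2)[, seq_along(beta), drop = FALSE]
  y <- drop(X %*% beta) + rep(rnorm(n_subj, 0, sd_subj), each = n_per) +
    rnorm(n_subj * n_per, 0, sd_e)
  list(y = y, dose = dose, subject = subject)
}

test_that("one observation per subject reduces exactly to OLS", {
  set.seed(1)
  n <- 40
  dose <- sample(c(0, 25, 50, 100), n, replace = TRUE)
  y <- 2 + 0.01 * dose + rnorm(n)
  fit <- fit_dose_model(y, dose, sprintf("s%02d", 1:n), order = 1)
  expect_equal(fit$sigma2_subject, 0)
  ols <- lm(y ~ dose)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
})

test_that("balanced two-observation fits match the closed-form ML solution", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- 30
    subject <- rep(sprintf("s%02d", 1:a), each = 2)
    y <- rep(rnorm(a, 0, 1.5), each = 2) + rnorm(2 * a, 5, 1)
    fit <- fit_random_intercept_lmm(y, matrix(1, 2 * a, 1,
                                              dimnames = list(NULL, "mu")),
                                    subject)
    oracle <- oracle_balanced_lmm(y, subject)
    expect_equal(unname(coef(fit)), oracle$mu, tolerance = 1e-6)
    expect_equal(fit$sigma2_resid, oracle$sigma_e2, tolerance = 1e-6)
    expect_equal(fit$sigma2_subject, oracle$sigma_b2, tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  }
})

test_that("ML estimates agree with lme4 on an unbalanced dose design", {
  skip_if_not_installed("lme4")
  d <- simulate_lmm(25, 4, c(1, 0.02, -2e-4), sd_subj = 0.5, sd_e = 0.3,
                    seed = 9)
  fit <- fit_dose_model(d$y, d$dose, d$subject, order = 2)
  df <- data.frame(y = d$y, dose = d$dose, subject = d$subject)
  lfit <- suppressWarnings(
    lme4::lmer(y ~ dose + I(dose^2) + (1 | subject), data = df,
               REML = FALSE))
  expect_equal(unname(coef(fit)), unname(lme4::fixef(lfit)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma2_subject, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(lfit)), tolerance = 1e-6)
})

test_that("parameters are recovered within 3 SE at n = 200 subjects", {
  beta <- c(1, 0.02, -2e-4)
  d <- simulate_lmm(200, 4, beta, sd_subj = 0.4, sd_e = 0.25, seed = 31)
  fit <- fit_dose_model(d$y, d$dose, d$subject, order = 2)
  fe <- fit$fixed_effects
  expect_true(all(abs(fe$estimate - beta) < 3 * fe$se))
  ## variance components in the right neighbourhood
  expect_lt(abs(fit$sigma2_subject - 0.16), 0.08)
  expect_lt(abs(fit$sigma2_resid - 0.0625), 0.02)
})

test_that("optimum likelihood dominates the OLS boundary and deviance is monotone in order", {
  d <- simulate_lmm(20, 3, c(1, 0.01, -1e-4), sd_subj = 0.6, sd_e = 0.3,
                    seed = 12)
  fit <- fit_dose_model(d$y, d$dose, d$subject, order = 2)
  X <- rejuvmet:::dose_design_matrix(d$dose, 2)
  idx <- split(seq_along(d$y), factor(d$subject))
  ll0 <- rejuvmet:::profile_fit(0, d$y, X, idx, lengths(idx))$loglik
  expect_gte(fit$loglik, ll0)
  sel <- suppressWarnings(select_polynomial_order(d$y, d$dose, d$subject))
  devs <- sel$table$deviance
  expect_true(all(diff(devs) <= 1e-6))
})

test_that("unfittable polynomial orders are excluded with a warning", {
  d <- simulate_lmm(15, 3, c(1, 0.01), sd_subj = 0.3, sd_e = 0.3, seed = 4,
                    doses = c(0, 50))
  expect_warning(sel <- select_polynomial_order(d$y, d$dose, d$subject),
                 "exceed distinct doses")
  expect_identical(sel$table$order, 1L)
  expect_error(fit_dose_model(d$y, d$dose, d$subject, order = 3),
               "distinct doses")
})

test_that("class dose models recover an injected quadratic effect", {
  set.seed(21)
  n_subj <- 40
  meta <- data.frame(
    sample_id = sprintf("h%03d_v%d", rep(1:n_subj, each = 4), rep(0:3, n_subj)),
    subject_id = sprintf("h%03d", rep(1:n_subj, each = 4)),
    dose_mg = rep(c(0, 25, 50, 100), n_subj),
    bmi = rep(round(rnorm(n_subj, 27, 3), 1), each = 4),
    stringsAsFactors = FALSE)
  ## PC total dips at 50 mg (positive curvature on log2 concentration),
  ## AA flat
  mag <- 0.012 * meta$dose_mg - 1.2e-4 * meta$dose_mg^2
  pc <- 2^(log2(100) - mag + rnorm(nrow(meta), 0, 0.1) +
             rep(rnorm(n_subj, 0, 0.2), each = 4))
  aa <- 2^(log2(50) + rnorm(nrow(meta), 0, 0.1) +
             rep(rnorm(n_subj, 0, 0.2), each = 4))
  cs <- structure(list(values = cbind(PC = pc, AA = aa), scale = "natural"),
                  class = c("class_matrix", "feature_matrix"))
  rownames(cs$values) <- meta$sample_id
  res <- fit_class_dose_models(cs, meta)
  tab <- res$table
  pc_quad <- tab[tab$class == "PC" & tab$term == "dose2", ]
  expect_gt(pc_quad$estimate, 0)      # U-shape opening upward
  expect_lt(pc_quad$q, 0.05)
  pc_lin <- tab[tab$class == "PC" & tab$term == "dose", ]
  expect_lt(pc_lin$estimate, 0)
  aa_quad <- tab[tab$class == "AA" & tab$term == "dose2", ]
  expect_gt(aa_quad$p, 0.05)
  ## permuted dose kills the signal
  meta_perm <- meta
  set.seed(22)
  meta_perm$dose_mg <- sample(meta$dose_mg)
  res_perm <- fit_class_dose_models(cs, meta_perm)
  expect_gt(min(res_perm$table$q, na.rm = TRUE), 0.01)
})

test_that("constant class outcome is handled without a crash", {
  set.seed(11)
  meta <- data.frame(sample_id = sprintf("s%d", 1:12),
                     subject_id = rep(sprintf("p%d", 1:6), each = 2),
                     dose_mg = rep(c(0, 50), 6),
                     bmi = rep(round(rnorm(6, 26, 3), 1), each = 2))
  cs <- structure(list(values = matrix(8, 12, 1,
                                       dimnames = list(meta$sample_id, "AA")),
                       scale = "natural"),
                  class = c("class_matrix", "feature_matrix"))
  res <- fit_class_dose_models(cs, meta, order = 1)
  fe <- res$fits$AA$fixed_effects
  expect_equal(fe$estimate[fe$term == "dose"], 0, tolerance = 1e-8)
})

test_that("mouse class model attributes the aging effect to the right class", {
  ## AC carries a -0.3 age effect, PC none; one sample per mouse
  set.seed(33)
  n <- 60
  meta <- data.frame(
    sample_id = sprintf("m%03d", 1:n),
    subject_id = sprintf("m%03d", 1:n),
    age_group = rep(c("young", "old"), each = n / 2),
    genotype = "WT",
    treatment = rep(c("control", "control", "control", "losartan"),
                    length.out = n),
    body_weight_g = rnorm(n, 30, 2),
    stringsAsFactors = FALSE)
  old <- meta$age_group == "old"
  ac <- 2^(log2(20) - 0.3 * old + rnorm(n, 0, 0.15))
  pc <- 2^(log2(100) + rnorm(n, 0, 0.15))
  cs <- structure(list(values = cbind(AC = ac, PC = pc), scale = "natural"),
                  class = c("class_matrix", "feature_matrix"))
  rownames(cs$values) <- meta$sample_id
  expect_warning(fit_mouse_class_model(cs, meta), "single genotype")
  res <- suppressWarnings(fit_mouse_class_model(cs, meta))
  tab <- res$table
  ac_age <- tab[tab$class == "AC" & tab$term == "age", ]
  expect_lt(ac_age$estimate, -0.15)
  expect_lt(ac_age$p, 0.01)
  pc_age <- tab[tab$class == "PC" & tab$term == "age", ]
  expect_lt(abs(pc_age$estimate), 0.15)

  ## no treatment arm -> treatment columns absent
  meta_ctl <- meta
  meta_ctl$treatment <- "control"
  expect_warning(fit_mouse_class_model(cs, meta_ctl))
  res2 <- suppressWarnings(fit_mouse_class_model(cs, meta_ctl))
  expect_false(any(grepl("treatment", res2$table$term)))
})

test_that("duplicating every mouse as two visits leaves fixed effects unchanged", {
  set.seed(44)
  n <- 30
  meta <- data.frame(
    sample_id = sprintf("m%03d", 1:n),
    subject_id = sprintf("m%03d", 1:n),
    age_group = rep(c("young", "old"), each = n / 2),
    genotype = "WT", treatment = "control",
    body_weight_g = rnorm(n, 30, 2),
    stringsAsFactors = FALSE)
  vals <- matrix(2^(5 + 0.4 * (meta$age_group == "old") + rnorm(n, 0, 0.2)),
                 ncol = 1, dimnames = list(meta$sample_id, "AA"))
  cs <- structure(list(values = vals, scale = "natural"),
                  class = c("class_matrix", "feature_matrix"))
  fit1 <- suppressWarnings(fit_mouse_class_model(cs, meta))
  meta2 <- rbind(meta, transform(meta, sample_id = paste0(sample_id, "_b")))
  vals2 <- rbind(vals, vals)
  rownames(vals2) <- meta2$sample_id
  cs2 <- structure(list(values = vals2, scale = "natural"),
                   class = c("class_matrix", "feature_matrix"))
  fit2 <- suppressWarnings(fit_mouse_class_model(cs2, meta2))
  expect_equal(fit2$table$estimate, fit1$table$estimate, tolerance = 1e-6)
})
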