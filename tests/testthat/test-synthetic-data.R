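test_that("degenerate mouse config (no effects, no noise) reproduces the class baseline", {
  cfg <- mouse_design(frac_age_affected = 0, noise_sd_log2 = 0,
                      lod_censor_rate = 0, seed = 7)
  st <- generate_mouse_study(cfg)
  v <- st$matrix$values
  expect_true(all(apply(v, 2, function(col) max(abs(col - col[1]))) < 1e-12))
  expect_true(all(st$ground_truth$aging_effect_per_feature == 0))
})

test_that("generators are pure functions of their seed", {
  a <- generate_mouse_study(mouse_design(seed = 11))
  b <- generate_mouse_study(mouse_design(seed = 11))
  c <- generate_mouse_study(mouse_design(seed = 12))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_false(identical(a$matrix$values, c$matrix$values))

  h1 <- generate_human_study(human_design(seed = 3))
  h2 <- generate_human_study(human_design(seed = 3))
  expect_identical(h1$matrix$values, h2$matrix$values)
})

test_that("affected-feature count follows the configured fraction exactly", {
  cfg <- mouse_design(n_features = 100, frac_age_affected = 0.5, seed = 5)
  st <- generate_mouse_study(cfg)
  expect_identical(sum(st$ground_truth$aging_effect_per_feature != 0), 50L)
  ## reversed features satisfy sign(treatment) = -sign(aging)
  gt <- st$ground_truth
  rev <- gt$reversed_feature_flags
  expect_true(all(sign(gt$treatment_effect_per_feature[rev]) ==
                    -sign(gt$aging_effect_per_feature[rev])))
})

test_that("per-class feature counts follow largest-remainder apportionment", {
  for (n in c(50, 118, 122, 160, 186)) {
    ann <- rejuvmet:::build_panel(n)
    counts <- table(factor(ann$class_label,
                           levels = names(rejuvmet::p180_class_proportions())))
    expected <- rejuvmet:::largest_remainder(n, p180_class_proportions())
    expect_equal(as.integer(counts), expected)
    expect_equal(sum(counts), n)
  }
})

test_that("empty or invalid designs are rejected", {
  expect_error(generate_mouse_study(
    mouse_design(n_young_wt = 0, n_old_wt_ctrl = 0, n_old_wt_los = 0,
                 n_old_at1ko_ctrl = 0, n_old_at1ko_los = 0,
                 n_old_at2ko_ctrl = 0, n_old_at2ko_los = 0)), "empty design")
  expect_error(mouse_design(class_proportions = c(AA = 0.5, PC = 0.4)),
               "sum to 1")
  expect_error(mouse_design(frac_age_affected = 1.5), "0,1")
  expect_error(human_design(dose_schedule = data.frame(visit = c(0, 0),
                                                       dose = c(0, 25))),
               "strictly increasing")
  expect_error(human_design(dose_schedule = data.frame(visit = 0:1,
                                                       dose = c(0, 30))),
               "25, 50, 100")
  expect_error(human_design(dose_schedule = data.frame(visit = 0:1,
                                                       dose = c(25, 50))),
               "baseline")
})

test_that("human study follows the dose schedule", {
  st <- generate_human_study(human_design(n_placebo = 0, n_treated = 1,
                                          seed = 2))
  expect_equal(nrow(st$metadata), 4L)
  expect_equal(st$metadata$dose_mg, c(0, 25, 50, 100))
  ## placebo stays at dose 0
  st2 <- generate_human_study(human_design(n_placebo = 2, n_treated = 1,
                                           seed = 2))
  plc <- st2$metadata[st2$metadata$treatment == "placebo", ]
  expect_true(all(plc$dose_mg == 0))
})

test_that("null dose-response shape removes treatment-placebo differences", {
  cfg <- human_design(n_placebo = 1, n_treated = 1,
                      dose_response_shape = c(0, 0),
                      subject_sd = 0, noise_sd_log2 = 0, seed = 4)
  st <- generate_human_study(cfg)
  v <- st$matrix$values
  expect_lt(max(abs(sweep(v, 2, v[1, ]))), 1e-12)
})

test_that("injected reversal magnitude peaks at 50 mg under the default quadratic shape", {
  cfg <- human_design(n_placebo = 0, n_treated = 5, subject_sd = 0,
                      noise_sd_log2 = 0, seed = 9)
  st <- generate_human_study(cfg)
  lm2 <- log2(st$matrix$values)
  meta <- st$metadata
  mag <- sapply(c(25, 50, 100), function(d) {
    rows <- meta$sample_id[meta$dose_mg == d]
    base <- meta$sample_id[meta$visit_index == 0]
    base <- base[match(meta$subject_id[match(rows, meta$sample_id)],
                       meta$subject_id[match(base, meta$sample_id)])]
    mean(abs(lm2[rows, , drop = FALSE] - lm2[base, , drop = FALSE]))
  })
  expect_gt(mag[2], mag[1])
  expect_gt(mag[2], mag[3])
})

test_that("realized group differences converge to the configured effects", {
  cfg <- mouse_design(n_young_wt = 500, n_old_wt_ctrl = 500, n_old_wt_los = 0,
                      n_old_at1ko_ctrl = 0, n_old_at1ko_los = 0,
                      n_old_at2ko_ctrl = 0, n_old_at2ko_los = 0,
                      lod_censor_rate = 0, seed = 21)
  st <- generate_mouse_study(cfg)
  lm2 <- log2(st$matrix$values)
  old <- st$metadata$age_group == "old"
  diff <- colMeans(lm2[old, ]) - colMeans(lm2[!old, ])
  truth <- st$ground_truth$aging_effect_per_feature
  ## per-observation SD includes the shared class latent (0.5 * noise)
  se <- cfg$noise_sd_log2 * sqrt(1 + cfg$class_cov_frac^2) * sqrt(2 / 500)
  expect_gte(mean(abs(diff - truth) < 3 * se), 0.95)
})

test_that("external age coefficients track the ground truth", {
  st <- generate_human_study(human_design(seed = 6))
  gt <- st$ground_truth
  exact <- generate_external_age_coefficients(gt, error_sd = 0, seed = 1)
  expect_equal(exact$estimate, unname(gt$aging_effect_per_feature))
  a <- generate_external_age_coefficients(gt, error_sd = 0.05, seed = 1)
  b <- generate_external_age_coefficients(gt, error_sd = 0.05, seed = 2)
  expect_false(identical(a$estimate, b$estimate))
  expect_identical(a$feature_id, b$feature_id)
  ## correlation with truth decreases with the error level
  mean_cor <- sapply(c(0.005, 0.05, 0.5), function(sd) {
    mean(sapply(1:20, function(s) {
      cor(generate_external_age_coefficients(gt, sd, seed = s)$estimate,
          gt$aging_effect_per_feature)
    }))
  })
  expect_true(all(diff(mean_cor) < 0))
  expect_gt(mean_cor[1], 0.9)
  expect_error(generate_external_age_coefficients(gt, error_sd = -1), ">= 0")
})

test_that("survival cohort generator censors at follow-up and echoes counts", {
  coh <- generate_survival_cohort(n_treated = 19, n_control = 14, seed = 1)
  expect_equal(nrow(coh), 33L)
  zero <- generate_survival_cohort(followup_days = 0, seed = 1)
  expect_true(all(zero$time_days == 0))
  expect_true(all(zero$event == 0))
  expect_error(generate_survival_cohort(hazard_treated = 0), "> 0")
})

test_that("clinical panel sodium responds to dose only through the configured effect", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     dose_mg = rep(c(0, 25, 50, 100), 10))
  flat <- generate_clinical_panel(meta, dose_effect_na = 0, seed = 8)
  meta_shuf <- meta
  meta_shuf$dose_mg <- rev(meta$dose_mg)
  flat2 <- generate_clinical_panel(meta_shuf, dose_effect_na = 0, seed = 8)
  expect_identical(flat$sodium_mmol_l, flat2$sodium_mmol_l)
  expect_identical(flat, generate_clinical_panel(meta, dose_effect_na = 0,
                                                 seed = 8))
  ## quadratic-peak dose effect: mean osmolality highest at 50 mg (large n)
  big <- data.frame(sample_id = sprintf("s%04d", 1:4000),
                    dose_mg = rep(c(0, 25, 50, 100), 1000))
  pan <- generate_clinical_panel(big, dose_effect_na = 5, seed = 8)
  osmo <- calculated_osmolality(pan$sodium_mmol_l, pan$glucose_mg_dl,
                                pan$bun_mg_dl)
  means <- tapply(osmo, big$dose_mg, mean)
  expect_identical(names(which.max(means)), "50")
})
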