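## End-to-end demo pipeline: generates both species' studies at the default
## ("stated world") configurations, runs every analysis stage, and writes
## all outputs as CSV/JSON. Deterministic given the seed — two runs with
## the same seed produce byte-identical files.

write_effect_csv <- function(ev, path) {
  df <- as.data.frame(ev)
  df$label <- attr(ev, "label")
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Run the full cross-species rejuvenation analysis on synthetic data
#'
#' Generation -> QC -> differential abundance -> signature reversal scoring
#' -> class-level and dose-response mixed models -> survival -> osmolality
#' -> network/PCA integration -> marker-set enrichment, with every result
#' written under `out_dir`.
#'
#' @param out_dir output directory (created).
#' @param seed master seed; stage seeds are fixed offsets of it.
#' @param mouse_config,human_config design objects; defaults are the
#'   package's stated-world configurations (the seed argument overrides
#'   their seeds).
#' @return invisibly, a list with all in-memory results.
#' @export
run_rejuvenation_pipeline <- function(out_dir, seed = 1L,
                                      mouse_config = NULL,
                                      human_config = NULL) {
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, paste0(...))

  ## ---- mouse arm -------------------------------------------------------
  if (is.null(mouse_config)) mouse_config <- mouse_design(seed = seed)
  mouse_config$seed <- seed
  mouse <- generate_mouse_study(mouse_config)
  write_study(mouse, out_dir, "mouse", config = mouse_config)

  m_log2 <- log2_transform(mouse$matrix)
  qc <- flag_outlier_samples(m_log2)
  utils::write.csv(qc, fp("mouse_qc.csv"), row.names = FALSE)
  keep <- qc$sample_id[!qc$flagged]
  meta_m <- mouse$metadata[mouse$metadata$sample_id %in% keep, ]
  m_log2 <- feature_matrix(m_log2$values[meta_m$sample_id, , drop = FALSE],
                           scale = "log2")

  aging <- differential_effects(m_log2, meta_m, "arm",
                                "old_wt_ctrl", "young_wt",
                                covariates = "body_weight_g",
                                label = "mouse aging")
  treat_arms <- c("old_wt_los", "old_at1ko_ctrl", "old_at1ko_los",
                  "old_at2ko_ctrl", "old_at2ko_los")
  treat_labels <- c("Los WT", "AT1KO", "Los AT1KO", "AT2KO", "Los AT2KO")
  treat_effects <- Map(function(arm, lab) {
    differential_effects(m_log2, meta_m, "arm", arm, "old_wt_ctrl",
                         covariates = "body_weight_g", label = lab)
  }, treat_arms, treat_labels)
  write_effect_csv(aging, fp("mouse_aging_effect.csv"))
  for (i in seq_along(treat_effects)) {
    write_effect_csv(treat_effects[[i]],
                     fp("mouse_effect_", gsub(" ", "_", treat_labels[i]),
                        ".csv"))
  }

  ## bubble-plot support: Fisher-combined significance across the aging and
  ## primary-treatment comparisons, BH across features
  shared <- intersect(aging$feature_id, treat_effects[[1]]$feature_id)
  fish_p <- fisher_combine(aging$p[match(shared, aging$feature_id)],
                           treat_effects[[1]]$p[match(shared,
                             treat_effects[[1]]$feature_id)])
  utils::write.csv(data.frame(feature_id = shared, fisher_p = fish_p,
                              fisher_q = bh_adjust(fish_p)),
                   fp("mouse_fisher_combined.csv"), row.names = FALSE)

  scores_m <- score_family(aging, treat_effects)
  utils::write.csv(scores_m, fp("mouse_signature_scores.csv"),
                   row.names = FALSE)

  cls_m <- class_sums(mouse$matrix, mouse$annotation)
  mouse_class <- fit_mouse_class_model(cls_m, meta_m)
  utils::write.csv(mouse_class$table, fp("mouse_class_model.csv"),
                   row.names = FALSE)

  ## ---- human arm -------------------------------------------------------
  if (is.null(human_config)) human_config <- human_design(seed = seed + 1L)
  human_config$seed <- seed + 1L
  human <- generate_human_study(human_config)
  write_study(human, out_dir, "human", config = human_config)
  beta_age <- generate_external_age_coefficients(human$ground_truth,
                                                 error_sd = 0.01,
                                                 seed = seed + 2L)
  write_effect_csv(beta_age, fp("human_beta_age.csv"))

  h_log2 <- log2_transform(human$matrix)
  qc_h <- flag_outlier_samples(h_log2)
  utils::write.csv(qc_h, fp("human_qc.csv"), row.names = FALSE)

  subj_scores <- subject_signature_scores(h_log2, human$metadata, beta_age)
  utils::write.csv(subj_scores, fp("human_subject_scores.csv"),
                   row.names = FALSE)

  ok <- !is.na(subj_scores$rho)
  sel <- select_polynomial_order(subj_scores$rho[ok],
                                 subj_scores$dose_mg[ok],
                                 subj_scores$subject_id[ok])
  best <- sel$fits[[as.character(sel$selected)]]
  jsonlite::write_json(list(selected_order = sel$selected,
                            candidates = sel$table,
                            fixed_effects = best$fixed_effects,
                            sigma2_subject = best$sigma2_subject,
                            sigma2_resid = best$sigma2_resid,
                            deviance = best$deviance),
                       fp("human_dose_model.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")

  cls_h <- class_sums(human$matrix, human$annotation)
  class_dose <- fit_class_dose_models(cls_h, human$metadata,
                                      covariate = "bmi")
  utils::write.csv(class_dose$table, fp("human_class_dose_models.csv"),
                   row.names = FALSE)

  ## ---- survival and clinical osmolality --------------------------------
  cohort <- generate_survival_cohort(seed = seed + 3L)
  utils::write.csv(as.data.frame(cohort), fp("survival_cohort.csv"),
                   row.names = FALSE)
  km <- kaplan_meier(cohort)
  km_tab <- do.call(rbind, Map(function(g, cv) cbind(group = g, cv),
                               km$groups, km$curves))
  utils::write.csv(km_tab, fp("km_curves.csv"), row.names = FALSE)
  lr <- logrank_test(cohort)
  jsonlite::write_json(lr, fp("logrank.json"), digits = NA,
                       auto_unbox = TRUE)

  panel <- generate_clinical_panel(human$metadata, seed = seed + 4L)
  panel$osmolality <- calculated_osmolality(panel$sodium_mmol_l,
                                            panel$glucose_mg_dl,
                                            panel$bun_mg_dl)
  utils::write.csv(panel, fp("clinical_panel.csv"), row.names = FALSE)
  osmo_fit <- fit_dose_model(panel$osmolality, human$metadata$dose_mg,
                             human$metadata$subject_id, order = 2,
                             covariates = data.frame(
                               bmi = human$metadata$bmi))
  jsonlite::write_json(list(fixed_effects = osmo_fit$fixed_effects,
                            sigma2_subject = osmo_fit$sigma2_subject,
                            sigma2_resid = osmo_fit$sigma2_resid,
                            deviance = osmo_fit$deviance),
                       fp("osmolality_model.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")

  ## ---- cross-species integration ---------------------------------------
  ## human losartan effect: pooled 50 mg-vs-baseline contrast with subject
  ## fixed blocks
  meta_h <- human$metadata
  meta_h$dose_level <- paste0("d", meta_h$dose_mg)
  treated <- meta_h[meta_h$treatment == "losartan", ]
  h_treated <- feature_matrix(h_log2$values[treated$sample_id, , drop = FALSE],
                              scale = "log2")
  human_los <- differential_effects(h_treated, treated, "dose_level",
                                    "d50", "d0", block = "subject_id",
                                    label = "human losartan")
  conditions <- c(list(aging), treat_effects,
                  list(beta_age, human_los))
  net <- build_effect_network(conditions)
  utils::write.csv(net$edges, fp("network_edges.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node = rownames(net$layout), net$layout),
                   fp("network_layout.csv"), row.names = FALSE)
  pca <- effect_pca(conditions)
  utils::write.csv(data.frame(condition = rownames(pca$scores), pca$scores),
                   fp("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature_id = rownames(pca$loadings),
                              pca$loadings),
                   fp("pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(pca$variance_fraction),
                              variance_fraction = pca$variance_fraction),
                   fp("pca_variance.csv"), row.names = FALSE)

  ## ---- marker-set enrichment (proteome stand-in) -----------------------
  ## ranked by the moderated t of the treatment effect; metabolite classes
  ## stand in for cell-type marker sets
  stats <- stats::setNames(treat_effects[[1]]$t, treat_effects[[1]]$feature_id)
  sets <- split(mouse$annotation$feature_id, mouse$annotation$class_label)
  enr <- permutation_pvalues(stats, sets, n_perm = 500, seed = seed + 5L)
  utils::write.csv(enr, fp("enrichment.csv"), row.names = FALSE)

  invisible(list(mouse = mouse, mouse_aging = aging,
                 mouse_treatment_effects = treat_effects,
                 mouse_scores = scores_m, mouse_class = mouse_class,
                 human = human, beta_age = beta_age,
                 subject_scores = subj_scores, dose_selection = sel,
                 class_dose = class_dose, km = km, logrank = lr,
                 panel = panel, osmolality_fit = osmo_fit,
                 network = net, pca = pca, enrichment = enr))
}
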