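## Synthetic-study generators. They emulate the two designs the pipeline is
## built for: a cross-sectional mouse study (young/old wild-type plus aged
## angiotensin-receptor knockouts, with and without losartan) in which aging
## broadly DECREASES serum metabolite levels, and a longitudinal human
## dose-escalation trial (0/25/50/100 mg across 8-week visits) in which
## aging broadly INCREASES metabolite levels. Treatment partially reverses
## the aging effect; the per-dose reversal magnitude follows a configurable
## polynomial supporting the U-shape peaking at 50 mg.
##
## Concentrations are generated on the log2 scale and exponentiated, so the
## log2 fold change is the natural effect unit throughout.

#' Default class proportions of the targeted panel
#'
#' Approximate composition of a 188-analyte targeted metabolomics kit:
#' amino acids, acylcarnitines, biogenic amines, lysophosphatidylcholines,
#' phosphatidylcholines, sphingomyelins and hexoses.
#'
#' @return named fractions summing to 1.
#' @export
p180_class_proportions <- function() {
  p <- c(AA = 21, AC = 40, BA = 21, LysoPC = 14, PC = 76, SM = 15, H = 1)
  p / sum(p)
}

## Deterministic panel: per-class feature counts by largest-remainder
## apportionment, names <class>_<index>. Two panels of different sizes but
## identical proportions overlap in their common per-class prefix, mimicking
## partially-overlapping quantifiable subsets of one kit.
build_panel <- function(n_features, class_proportions = p180_class_proportions()) {
  counts <- largest_remainder(n_features, class_proportions)
  cls <- rep(names(class_proportions), counts)
  id <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) return(character(0))
    sprintf("%s_%03d", names(class_proportions)[i], seq_len(counts[i]))
  }))
  feature_annotation(id, cls)
}

## Class-level baseline log2 concentrations (micromolar scale): lipid classes
## high (PC ~ 100 uM), amines low, hexoses (glucose) ~ 5 mM.
class_baseline_log2 <- c(AA = log2(100), AC = log2(2), BA = log2(5),
                         LysoPC = log2(30), PC = log2(100), SM = log2(80),
                         H = log2(5000), other = log2(10))

#' Mouse study design configuration
#'
#' Arm sizes default to the emulated study: young wild-type 7, old wild-type
#' control 10 and losartan 14, old AT1-knockout control 8 / losartan 5, old
#' AT2-knockout control 7 / losartan 6. Aging decreases metabolite levels on
#' average (`mean_aging_log2fc` negative); losartan reverses a fraction of
#' the affected features, with the treatment effect attenuated by genotype
#' (wild-type x1, AT1KO x0.5, AT2KO x0) to encode receptor dependence.
#'
#' @param n_young_wt,n_old_wt_ctrl,n_old_wt_los,n_old_at1ko_ctrl,n_old_at1ko_los,n_old_at2ko_ctrl,n_old_at2ko_los arm sizes.
#' @param n_features panel size (122 metabolites quantifiable by default).
#' @param class_proportions named fractions over the panel classes, sum 1.
#' @param frac_age_affected fraction of features carrying an aging effect.
#' @param mean_aging_log2fc mean log2 fold change old vs young on affected
#'   features (negative: aged mouse serum is broadly depleted).
#' @param reversal_fraction fraction of affected features whose aging effect
#'   the treatment reverses.
#' @param reversal_strength multiplier in (0, 1]: treatment effect =
#'   `-reversal_strength * aging_effect` on reversed features.
#' @param genotype_attenuation treatment-effect multipliers by genotype.
#' @param independent_treatment_sd if > 0, treatment effects are instead
#'   drawn independently of the aging effects (null-calibration mode).
#' @param noise_sd_log2 residual log2 SD per measurement.
#' @param class_cov_frac fraction of `noise_sd_log2` used as the SD of a
#'   shared per-sample, per-class latent shift (class-structured covariance).
#' @param lod_censor_rate fraction of each feature's lowest values recorded
#'   as missing (below limit of detection).
#' @param bodyweight_mean_sd mean and SD of body weight in grams; aged mice
#'   are shifted +3 g.
#' @param seed integer seed; identical seeds give identical studies.
#' @return a named list of class `mouse_design`.
#' @export
mouse_design <- function(n_young_wt = 7, n_old_wt_ctrl = 10, n_old_wt_los = 14,
                         n_old_at1ko_ctrl = 8, n_old_at1ko_los = 5,
                         n_old_at2ko_ctrl = 7, n_old_at2ko_los = 6,
                         n_features = 122,
                         class_proportions = p180_class_proportions(),
                         frac_age_affected = 0.5,
                         mean_aging_log2fc = -0.3,
                         reversal_fraction = 0.5,
                         reversal_strength = 0.5,
                         genotype_attenuation = c(WT = 1, AT1KO = 0.5, AT2KO = 0),
                         independent_treatment_sd = 0,
                         noise_sd_log2 = 0.5,
                         class_cov_frac = 0.5,
                         lod_censor_rate = 0.02,
                         bodyweight_mean_sd = c(30, 3),
                         seed = 1L) {
  cfg <- as.list(environment())
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  for (f in c("frac_age_affected", "reversal_fraction", "reversal_strength",
              "lod_censor_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0,1]", call. = FALSE)
  }
  if (noise_sd_log2 < 0) stop("noise_sd_log2 must be >= 0", call. = FALSE)
  structure(cfg, class = "mouse_design")
}

mouse_arms <- function(config) {
  a <- data.frame(
    arm = c("young_wt", "old_wt_ctrl", "old_wt_los", "old_at1ko_ctrl",
            "old_at1ko_los", "old_at2ko_ctrl", "old_at2ko_los"),
    n = c(config$n_young_wt, config$n_old_wt_ctrl, config$n_old_wt_los,
          config$n_old_at1ko_ctrl, config$n_old_at1ko_los,
          config$n_old_at2ko_ctrl, config$n_old_at2ko_los),
    age_group = c("young", rep("old", 6)),
    genotype = c("WT", "WT", "WT", "AT1KO", "AT1KO", "AT2KO", "AT2KO"),
    treatment = c("control", "control", "losartan", "control", "losartan",
                  "control", "losartan"),
    stringsAsFactors = FALSE)
  a[a$n > 0, , drop = FALSE]
}

#' Generate a synthetic mouse metabolomics study
#'
#' @param config a [mouse_design()].
#' @return list with elements `matrix` (natural-scale [feature_matrix()]),
#'   `annotation`, `metadata` (one row per mouse) and `ground_truth`
#'   (per-feature aging and treatment effects, reversed-feature flags).
#' @export
generate_mouse_study <- function(config = mouse_design()) {
  stopifnot(inherits(config, "mouse_design"))
  arms <- mouse_arms(config)
  n_samples <- sum(arms$n)
  if (n_samples == 0L) stop("empty design", call. = FALSE)
  ann <- build_panel(config$n_features, config$class_proportions)
  nf <- nrow(ann)

  with_seed(config$seed, {
    baseline <- class_baseline_log2[ann$class_label] + stats::rnorm(nf, 0, 1)
    names(baseline) <- ann$feature_id

    aging <- numeric(nf)
    n_aff <- round(config$frac_age_affected * nf)
    aff <- sample.int(nf, n_aff)
    aging[aff] <- config$mean_aging_log2fc * stats::runif(n_aff, 0.5, 1.5)

    reversed <- logical(nf)
    treat <- numeric(nf)
    if (config$independent_treatment_sd > 0) {
      treat <- stats::rnorm(nf, 0, config$independent_treatment_sd)
    } else if (n_aff > 0 && config$reversal_fraction > 0) {
      n_rev <- round(config$reversal_fraction * n_aff)
      rev_idx <- aff[sample.int(n_aff, n_rev)]
      reversed[rev_idx] <- TRUE
      treat[rev_idx] <- -config$reversal_strength * aging[rev_idx]
    }

    meta <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
      data.frame(arm = arms$arm[i], age_group = arms$age_group[i],
                 genotype = arms$genotype[i], treatment = arms$treatment[i],
                 stringsAsFactors = FALSE)[rep(1, arms$n[i]), , drop = FALSE]
    }))
    meta$sample_id <- sprintf("M%03d", seq_len(n_samples))
    meta$subject_id <- meta$sample_id
    meta$species <- "mouse"
    bw <- stats::rnorm(n_samples, config$bodyweight_mean_sd[1],
                       config$bodyweight_mean_sd[2])
    meta$body_weight_g <- round(bw + 3 * (meta$age_group == "old"), 2)
    meta <- meta[c("sample_id", "subject_id", "species", "arm", "age_group",
                   "genotype", "treatment", "body_weight_g")]

    is_old <- meta$age_group == "old"
    is_los <- meta$treatment == "losartan"
    atten <- config$genotype_attenuation[meta$genotype]

    log2val <- matrix(rep(baseline, each = n_samples), nrow = n_samples,
                      dimnames = list(meta$sample_id, ann$feature_id))
    log2val <- log2val + outer(as.numeric(is_old), aging) +
      outer(as.numeric(is_los) * atten, treat)
    if (config$noise_sd_log2 > 0) {
      classes <- unique(ann$class_label)
      latent <- matrix(stats::rnorm(n_samples * length(classes), 0,
                                    config$class_cov_frac * config$noise_sd_log2),
                       n_samples, length(classes),
                       dimnames = list(NULL, classes))
      log2val <- log2val + latent[, ann$class_label, drop = FALSE]
      log2val <- log2val + stats::rnorm(n_samples * nf, 0, config$noise_sd_log2)
    }
    vals <- 2^log2val
    vals <- censor_below_lod(vals, config$lod_censor_rate)

    list(matrix = feature_matrix(vals, scale = "natural"),
         annotation = ann,
         metadata = meta,
         ground_truth = list(
           aging_effect_per_feature = stats::setNames(aging, ann$feature_id),
           treatment_effect_per_feature = stats::setNames(treat, ann$feature_id),
           reversed_feature_flags = stats::setNames(reversed, ann$feature_id),
           subject_random_intercepts = stats::setNames(
             numeric(n_samples), meta$subject_id)))
  })
}

## Below-LOD censoring: the lowest floor(rate * n) values of each feature
## become missing — deterministic in the configured rate.
censor_below_lod <- function(vals, rate) {
  if (rate <= 0) return(vals)
  k <- floor(rate * nrow(vals))
  if (k == 0L) return(vals)
  for (j in seq_len(ncol(vals))) {
    ord <- order(vals[, j])[seq_len(k)]
    vals[ord, j] <- NA
  }
  vals
}

#' Human dose-escalation design configuration
#'
#' Defaults emulate the trial arm of the analysis: 9 placebo and 7 treated
#' pre-frail men aged 70+, visits every 8 weeks with doses escalating
#' 0 -> 25 -> 50 -> 100 mg. The per-dose reversal magnitude is the polynomial
#' `shape[1]*dose + shape[2]*dose^2`, interpreted as "years of aging
#' reversed"; the default `c(0.4, -0.004)` peaks at 50 mg (10 years) and
#' returns to zero at 100 mg, the U-shape the dose-response module must
#' recover.
#'
#' @param n_placebo,n_treated subject counts.
#' @param dose_schedule data.frame with columns `visit` (strictly increasing
#'   integers starting at the baseline visit) and `dose` (mg, from
#'   {0,25,50,100}); applies to treated subjects, placebo stays at 0.
#' @param n_features panel size (160 quantifiable by default).
#' @param class_proportions as in [mouse_design()].
#' @param frac_age_affected,reversal_fraction fractions of features with an
#'   aging effect / whose aging effect treatment reverses.
#' @param mean_aging_beta mean per-year log2 change on affected features
#'   (positive: human serum metabolites broadly increase with age).
#' @param dose_response_shape coefficients (linear, quadratic) of the
#'   years-of-aging-reversed polynomial in dose (mg).
#' @param subject_sd SD of the per-subject random intercept (log2 units,
#'   a global concentration shift inducing within-subject correlation).
#' @param noise_sd_log2 residual per-measurement log2 SD.
#' @param class_cov_frac as in [mouse_design()].
#' @param bmi_mean_sd mean and SD of body-mass index.
#' @param seed integer seed.
#' @return a named list of class `human_design`.
#' @export
human_design <- function(n_placebo = 9, n_treated = 7,
                         dose_schedule = data.frame(visit = 0:3,
                                                    dose = c(0, 25, 50, 100)),
                         n_features = 160,
                         class_proportions = p180_class_proportions(),
                         frac_age_affected = 0.5,
                         reversal_fraction = 0.5,
                         mean_aging_beta = 0.03,
                         dose_response_shape = c(0.4, -0.004),
                         subject_sd = 0.3,
                         noise_sd_log2 = 0.3,
                         class_cov_frac = 0.5,
                         bmi_mean_sd = c(27, 4),
                         seed = 1L) {
  cfg <- as.list(environment())
  if (n_placebo < 0 || n_treated < 0) stop("counts must be >= 0", call. = FALSE)
  ds <- dose_schedule
  if (!all(c("visit", "dose") %in% names(ds))) {
    stop("dose_schedule needs columns visit and dose", call. = FALSE)
  }
  if (any(diff(ds$visit) <= 0)) {
    stop("dose_schedule must be strictly increasing in visit", call. = FALSE)
  }
  if (!all(ds$dose %in% c(0, 25, 50, 100))) {
    stop("doses must come from {0, 25, 50, 100}", call. = FALSE)
  }
  if (n_treated > 0 && ds$dose[1] != 0) {
    stop("treated subjects have no baseline (dose-0 first) visit", call. = FALSE)
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  structure(cfg, class = "human_design")
}

## Years-of-aging reversed at a given dose.
dose_reversal_years <- function(dose, shape) shape[1] * dose + shape[2] * dose^2

#' Generate a synthetic human dose-escalation study
#'
#' @param config a [human_design()].
#' @return list with `matrix` (one row per subject-visit, natural scale),
#'   `annotation`, `metadata` and `ground_truth` (including the per-subject
#'   random intercepts).
#' @export
generate_human_study <- function(config = human_design()) {
  stopifnot(inherits(config, "human_design"))
  n_sub <- config$n_placebo + config$n_treated
  if (n_sub == 0L) stop("empty design", call. = FALSE)
  ann <- build_panel(config$n_features, config$class_proportions)
  nf <- nrow(ann)
  sched <- config$dose_schedule

  with_seed(config$seed, {
    baseline <- class_baseline_log2[ann$class_label] + stats::rnorm(nf, 0, 1)

    aging <- numeric(nf)
    n_aff <- round(config$frac_age_affected * nf)
    aff <- sample.int(nf, n_aff)
    aging[aff] <- config$mean_aging_beta * stats::runif(n_aff, 0.5, 1.5)

    reversed <- logical(nf)
    n_rev <- if (n_aff > 0) round(config$reversal_fraction * n_aff) else 0L
    if (n_rev > 0) reversed[aff[sample.int(n_aff, n_rev)]] <- TRUE

    subj <- data.frame(
      subject_id = sprintf("H%03d", seq_len(n_sub)),
      treatment = rep(c("placebo", "losartan"),
                      c(config$n_placebo, config$n_treated)),
      age_years = round(stats::runif(n_sub, 70, 85), 1),
      bmi = round(stats::rnorm(n_sub, config$bmi_mean_sd[1],
                               config$bmi_mean_sd[2]), 1),
      intercept = stats::rnorm(n_sub, 0, config$subject_sd),
      stringsAsFactors = FALSE)

    meta <- merge(subj, sched, by = NULL)
    meta$dose_mg <- ifelse(meta$treatment == "placebo", 0, meta$dose)
    meta$visit_index <- meta$visit
    meta <- meta[order(meta$subject_id, meta$visit_index), ]
    meta$sample_id <- sprintf("%s_v%d", meta$subject_id, meta$visit_index)
    meta$species <- "human"
    rownames(meta) <- NULL

    years_rev <- dose_reversal_years(meta$dose_mg, config$dose_response_shape)
    shift <- outer(years_rev, -aging * reversed)

    n_rows <- nrow(meta)
    log2val <- matrix(rep(baseline, each = n_rows), nrow = n_rows,
                      dimnames = list(meta$sample_id, ann$feature_id))
    log2val <- log2val + shift + meta$intercept
    if (config$noise_sd_log2 > 0) {
      classes <- unique(ann$class_label)
      latent <- matrix(stats::rnorm(n_rows * length(classes), 0,
                                    config$class_cov_frac * config$noise_sd_log2),
                       n_rows, length(classes), dimnames = list(NULL, classes))
      log2val <- log2val + latent[, ann$class_label, drop = FALSE]
      log2val <- log2val + stats::rnorm(n_rows * nf, 0, config$noise_sd_log2)
    }

    meta_out <- meta[c("sample_id", "subject_id", "species", "treatment",
                       "dose_mg", "visit_index", "age_years", "bmi")]
    list(matrix = feature_matrix(2^log2val, scale = "natural"),
         annotation = ann,
         metadata = meta_out,
         ground_truth = list(
           aging_effect_per_feature = stats::setNames(aging, ann$feature_id),
           treatment_effect_per_feature = stats::setNames(
             -aging * reversed, ann$feature_id),
           reversed_feature_flags = stats::setNames(reversed, ann$feature_id),
           subject_random_intercepts = stats::setNames(subj$intercept,
                                                       subj$subject_id)))
  })
}

#' Generate noisy external per-feature age coefficients
#'
#' Emulates importing an aging signature estimated in an independent cohort
#' on the same platform: the true per-feature aging effect plus estimation
#' noise, with nominal standard errors and p-values.
#'
#' @param ground_truth the `ground_truth` element of a generated study.
#' @param error_sd SD of the estimation noise (log2-per-year units).
#' @param seed integer seed.
#' @return an [effect_vector()] labelled `"beta_age"`.
#' @export
generate_external_age_coefficients <- function(ground_truth, error_sd = 0.01,
                                               seed = 1L) {
  if (error_sd < 0) stop("error_sd must be >= 0", call. = FALSE)
  truth <- ground_truth$aging_effect_per_feature
  with_seed(seed, {
    beta <- truth + stats::rnorm(length(truth), 0, error_sd)
    se <- rep(max(error_sd, 1e-8), length(truth))
    p <- 2 * stats::pnorm(-abs(beta) / se)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    effect_vector(names(truth), estimate = beta, se = se, p = p,
                  label = "beta_age")
  })
}

#' Generate a synthetic survival cohort
#'
#' Exponential event times per group, administratively censored at the end
#' of follow-up. Defaults echo the emulated geriatric-mouse experiment: 19
#' treated vs 14 control animals observed for two months.
#'
#' @param n_treated,n_control group sizes.
#' @param hazard_treated,hazard_control event rates per day (> 0).
#' @param followup_days administrative censoring time.
#' @param seed integer seed.
#' @return a [survival_cohort()].
#' @export
generate_survival_cohort <- function(n_treated = 19, n_control = 14,
                                     hazard_treated = 0.004,
                                     hazard_control = 0.012,
                                     followup_days = 60, seed = 1L) {
  if (hazard_treated <= 0 || hazard_control <= 0) {
    stop("hazard rates must be > 0", call. = FALSE)
  }
  if (n_treated < 0 || n_control < 0) stop("counts must be >= 0", call. = FALSE)
  with_seed(seed, {
    t_trt <- stats::rexp(n_treated, hazard_treated)
    t_ctl <- stats::rexp(n_control, hazard_control)
    times <- c(t_trt, t_ctl)
    event <- as.integer(times <= followup_days)
    times <- pmin(times, followup_days)
    survival_cohort(
      subject_id = sprintf("S%03d", seq_along(times)),
      group = rep(c("losartan", "control"), c(n_treated, n_control)),
      time_days = times, event = event)
  })
}

#' Generate a synthetic clinical metabolic panel
#'
#' Sodium, glucose and blood urea nitrogen per sample, drawn from standard
#' physiologic ranges (Na ~ N(140, 2) mmol/L, glucose ~ N(95, 10) mg/dL,
#' BUN ~ N(16, 4) mg/dL), with sodium shifted by
#' `dose_effect_na * (dose_shape[1]*dose + dose_shape[2]*dose^2)` — the
#' default shape is normalized to 1 at its 50 mg peak, so `dose_effect_na`
#' is the sodium shift (mmol/L) at the peak dose.
#'
#' @param metadata sample metadata with `sample_id` and `dose_mg`.
#' @param dose_effect_na peak sodium shift in mmol/L (0 = no dose effect).
#' @param dose_shape polynomial coefficients of the dose shape.
#' @param seed integer seed.
#' @return data.frame (sample_id, sodium_mmol_l, glucose_mg_dl, bun_mg_dl).
#' @export
generate_clinical_panel <- function(metadata, dose_effect_na = 2,
                                    dose_shape = c(0.04, -4e-4), seed = 1L) {
  if (!"dose_mg" %in% names(metadata)) {
    stop("metadata must carry dose_mg", call. = FALSE)
  }
  n <- nrow(metadata)
  with_seed(seed, {
    shape <- dose_shape[1] * metadata$dose_mg + dose_shape[2] * metadata$dose_mg^2
    data.frame(
      sample_id = metadata$sample_id,
      sodium_mmol_l = stats::rnorm(n, 140, 2) + dose_effect_na * shape,
      glucose_mg_dl = stats::rnorm(n, 95, 10),
      bun_mg_dl = stats::rnorm(n, 16, 4),
      stringsAsFactors = FALSE)
  })
}

#' Write a generated study to disk
#'
#' Feature matrix, annotation and metadata as CSV; ground truth as JSON;
#' the generating configuration as YAML.
#'
#' @param study result of [generate_mouse_study()] / [generate_human_study()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param config optional design object to record alongside.
#' @return invisibly, the output directory.
#' @export
write_study <- function(study, dir, prefix, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, paste0(prefix, "_", x))
  write_feature_matrix(study$matrix, fp("matrix.csv"),
                       annotation = study$annotation,
                       annotation_path = fp("annotation.csv"))
  write_sample_metadata(study$metadata, fp("metadata.csv"))
  gt <- study$ground_truth
  gt$reversed_feature_flags <- as.logical(gt$reversed_feature_flags)
  jsonlite::write_json(gt, fp("ground_truth.json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(config)) write_config(config, fp("config.yaml"))
  invisible(dir)
}
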