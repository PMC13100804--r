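## Per-feature linear models with covariates, empirical-Bayes variance
## moderation, BH FDR and Fisher-combined p-values.
##
## The moderated t-statistic borrows strength across features: per-feature
## residual variances s2_g on d_g df are shrunk toward a prior (d0, s0^2)
## estimated from the ensemble by moment-matching of log s2 to a scaled-F
## distribution, giving
##   s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g),
##   t_g = beta_g / (sqrt(u_g) * sqrt(s2_post)),  df = d0 + d_g.

#' Build a design matrix from sample metadata
#'
#' Group means coding (one indicator column per group level, no intercept)
#' plus numeric covariate columns, optionally plus subject-block indicator
#' columns (first subject as reference) implementing fixed-effect blocking
#' for longitudinal designs.
#'
#' @param meta data.frame of sample metadata (rownames or `sample_id` column
#'   give sample ids).
#' @param group name of the group factor column.
#' @param covariates character vector of numeric covariate columns.
#' @param block optional name of a subject-id column to block on.
#' @return a `design_matrix`: numeric matrix with a `groups` attribute.
#' @export
build_design <- function(meta, group, covariates = character(), block = NULL) {
  for (f in c(group, covariates, block)) {
    if (!f %in% names(meta)) stop("metadata lacks field '", f, "'", call. = FALSE)
    if (anyNA(meta[[f]])) stop("field '", f, "' has missing values", call. = FALSE)
  }
  g <- factor(meta[[group]])
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  for (cv in covariates) {
    X <- cbind(X, as.numeric(meta[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  if (!is.null(block)) {
    b <- factor(meta[[block]])
    if (nlevels(b) > 1) {
      B <- stats::model.matrix(~ b)[, -1, drop = FALSE]
      colnames(B) <- paste0("block_", levels(b)[-1])
      X <- cbind(X, B)
    }
  }
  rownames(X) <- if ("sample_id" %in% names(meta)) meta$sample_id else rownames(meta)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  structure(X, groups = levels(g), class = c("design_matrix", "matrix", "array"))
}

#' Contrast vector comparing two groups
#'
#' @param design a [build_design()] matrix.
#' @param test,reference group level names; the contrast estimates
#'   mean(test) - mean(reference).
#' @return named numeric vector over design columns.
#' @export
group_contrast <- function(design, test, reference) {
  cn <- colnames(design)
  if (!test %in% cn || !reference %in% cn) {
    stop("groups not present in design: ",
         paste(setdiff(c(test, reference), cn), collapse = ", "), call. = FALSE)
  }
  ct <- stats::setNames(numeric(length(cn)), cn)
  ct[test] <- 1
  ct[reference] <- -1
  ct
}

#' Fit per-feature ordinary least squares models
#'
#' Each feature is fitted on its own non-missing samples (row deletion, no
#' imputation). Features with fewer usable samples than design columns plus
#' one residual df, or whose reduced design loses rank, are skipped.
#'
#' @param m a log2-scale [feature_matrix()].
#' @param design a [build_design()] matrix aligned to the samples of `m`.
#' @return a `feature_fits` list: per-feature coefficients, residual
#'   variance `s2`, residual df, unscaled covariance; plus skipped features.
#' @export
fit_feature_models <- function(m, design) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$scale != "log2") stop("fit expects log2-scale data", call. = FALSE)
  if (!identical(rownames(design), sample_ids(m))) {
    design <- design[sample_ids(m), , drop = FALSE]
  }
  p <- ncol(design)
  fits <- vector("list", ncol(m$values))
  names(fits) <- feature_ids(m)
  skipped <- character(0)
  for (j in seq_along(fits)) {
    y <- m$values[, j]
    ok <- !is.na(y)
    if (sum(ok) <= p) { skipped <- c(skipped, names(fits)[j]); next }
    X <- design[ok, , drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < p) { skipped <- c(skipped, names(fits)[j]); next }
    fit <- stats::lm.fit(X, y[ok])
    rss <- sum(fit$residuals^2)
    df <- fit$df.residual
    R <- qr.R(qrX)
    cov_unscaled <- chol2inv(R)[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
    dimnames(cov_unscaled) <- list(colnames(design), colnames(design))
    fits[[j]] <- list(coefficients = fit$coefficients,
                      s2 = rss / df, df = df,
                      n_used = sum(ok),
                      cov_unscaled = cov_unscaled)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) stop("all features skipped", call. = FALSE)
  if (length(skipped)) {
    vlog(length(skipped), " features skipped for insufficient data")
  }
  structure(list(fits = fits, skipped = skipped, design = design),
            class = "feature_fits")
}

## Newton inversion of the trigamma function (y > 0 -> x with
## trigamma(x) = y), as used in moment estimation of the prior df.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:80) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-13) break
  }
  x
}

## Moment estimation of (d0, s0^2) from residual variances s2 on df d:
## e_g = log s2_g - digamma(d_g/2) + log(d_g/2) has mean log s0^2 +
## digamma(d0/2) - log(d0/2) and variance trigamma(d_g/2) + trigamma(d0/2).
estimate_variance_prior <- function(s2, df) {
  ok <- df > 0 & is.finite(s2)
  s2 <- s2[ok]; df <- df[ok]
  if (length(s2) < 2) stop("need >= 2 features with positive residual df",
                           call. = FALSE)
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated contrast statistics
#'
#' Estimates the variance prior across features, shrinks each feature's
#' residual variance toward it, and returns moderated t-statistics and
#' two-sided p-values for the requested contrast, BH-adjusted across
#' features.
#'
#' @param fits a [fit_feature_models()] result.
#' @param contrast named numeric vector over design columns (see
#'   [group_contrast()]).
#' @param label condition label for the returned [effect_vector()].
#' @return an [effect_vector()] with attribute `moderation` carrying
#'   `d0` and `s0_sq`.
#' @export
ebayes_moderate <- function(fits, contrast, label = "") {
  stopifnot(inherits(fits, "feature_fits"))
  cols <- colnames(fits$design)
  ct <- stats::setNames(numeric(length(cols)), cols)
  ct[names(contrast)] <- contrast
  fl <- fits$fits
  s2 <- vapply(fl, `[[`, numeric(1), "s2")
  df <- vapply(fl, `[[`, numeric(1), "df")
  beta <- vapply(fl, function(f) sum(ct * f$coefficients), numeric(1))
  u <- vapply(fl, function(f) drop(ct %*% f$cov_unscaled %*% ct), numeric(1))

  prior <- estimate_variance_prior(s2, df)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  se <- sqrt(u * s2_post)
  t_mod <- beta / se
  ## total df capped at the pooled residual df, the standard convention of
  ## the moderated-t framework (binds only when the prior df is very large)
  df_total <- pmin(d0 + df, sum(df))
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  ev <- effect_vector(names(fl), estimate = beta, se = se, t = t_mod,
                      p = p, q = bh_adjust(p),
                      n_used = max(vapply(fl, `[[`, numeric(1), "n_used")),
                      label = label)
  attr(ev, "moderation") <- prior
  ev
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure with monotonicity enforcement, returned in the input
#' order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Fisher's combined probability across two comparisons
#'
#' Combines per-feature p-values from two independent comparisons via
#' X2 = -2 (ln p1 + ln p2), referred to a chi-square with 4 df.
#'
#' @param p1,p2 vectors of p-values in (0, 1].
#' @return vector of combined p-values (BH across features is the caller's
#'   responsibility).
#' @export
fisher_combine <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  for (p in list(p1, p2)) {
    if (any(is.na(p)) || any(p <= 0 | p > 1)) {
      stop("p-values must lie in (0, 1] (p = 0 has undefined log)",
           call. = FALSE)
    }
  }
  x2 <- -2 * (log(p1) + log(p2))
  stats::pchisq(x2, df = 4, lower.tail = FALSE)
}

#' Covariate-adjusted differential abundance between two groups
#'
#' Convenience wrapper: builds the design, fits per-feature models, and
#' returns moderated statistics for the test-vs-reference contrast.
#'
#' @param m log2-scale [feature_matrix()].
#' @param meta sample metadata aligned to `m`.
#' @param group,test,reference group column and the two levels to compare.
#' @param covariates numeric covariate columns.
#' @param block optional subject-block column.
#' @param label label for the result (defaults to "test vs reference").
#' @return an [effect_vector()] of log2 fold changes with moderated
#'   statistics.
#' @export
differential_effects <- function(m, meta, group, test, reference,
                                 covariates = character(), block = NULL,
                                 label = paste(test, "vs", reference)) {
  keep <- meta[[group]] %in% c(test, reference)
  meta_sub <- meta[keep, , drop = FALSE]
  m_sub <- feature_matrix(m$values[meta$sample_id[keep], , drop = FALSE],
                          scale = m$scale)
  design <- build_design(meta_sub, group, covariates, block)
  fits <- fit_feature_models(m_sub, design)
  ebayes_moderate(fits, group_contrast(design, test, reference), label = label)
}
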