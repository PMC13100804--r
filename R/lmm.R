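## Random-intercept linear mixed models, fitted by maximum likelihood via
## the profiled likelihood: with variance ratio lambda = s2_subject/s2_resid
## the marginal covariance is s2_resid * Sigma(lambda), Sigma block-diagonal
## per subject with Sigma_j = I + lambda J. For fixed lambda the GLS fixed
## effects and the residual variance have closed forms, so the fit is a
## bounded one-dimensional search over lambda. ML (not REML) throughout so
## that deviances are comparable across fixed-effect structures.

## Sigma^{-1} w blockwise: Sigma_j^{-1} = I - (lambda/(1+n_j lambda)) J.
solve_sigma <- function(w, subject_idx, n_per, lambda) {
  if (lambda == 0) return(w)
  w <- as.matrix(w)
  for (j in seq_along(subject_idx)) {
    idx <- subject_idx[[j]]
    shrink <- lambda / (1 + n_per[j] * lambda)
    w[idx, ] <- w[idx, , drop = FALSE] -
      shrink * matrix(colSums(w[idx, , drop = FALSE]),
                      nrow = length(idx), ncol = ncol(w), byrow = TRUE)
  }
  w
}

profile_fit <- function(lambda, y, X, subject_idx, n_per) {
  n <- length(y)
  SiX <- solve_sigma(X, subject_idx, n_per, lambda)
  Siy <- solve_sigma(matrix(y), subject_idx, n_per, lambda)
  XtSiX <- crossprod(X, SiX)
  beta <- solve(XtSiX, crossprod(X, Siy))
  r <- y - X %*% beta
  Sir <- solve_sigma(r, subject_idx, n_per, lambda)
  ## floor keeps a degenerate (constant-outcome) fit finite
  s2 <- max(drop(crossprod(r, Sir)) / n, .Machine$double.eps)
  logdet <- sum(log1p(n_per * lambda))
  ll <- -0.5 * (n * log(2 * pi * s2) + n + logdet)
  list(loglik = ll, beta = drop(beta), s2_resid = s2,
       cov_beta = s2 * solve(XtSiX))
}

#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' @param y numeric outcome vector.
#' @param X fixed-effects design matrix (including the intercept column),
#'   full rank.
#' @param subject subject identifier per observation; each subject gets a
#'   random intercept.
#' @return a `lmm_fit`: `fixed_effects` table (estimate, se, Wald z, p),
#'   `sigma2_subject`, `sigma2_resid`, `loglik`, `deviance` (-2 loglik),
#'   `aic`, `bic`, `n_obs`, `n_subjects`, `converged`. A boundary fit at
#'   zero subject variance reduces exactly to OLS.
#' @export
fit_random_intercept_lmm <- function(y, X, subject) {
  X <- as.matrix(X)
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  y <- y[ok]; X <- X[ok, , drop = FALSE]; subject <- as.character(subject)[ok]
  n <- length(y)
  if (n < ncol(X) + 1) stop("too few observations", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design is rank deficient",
                                 call. = FALSE)
  subj <- factor(subject)
  if (nlevels(subj) < 2) stop("need >= 2 subjects", call. = FALSE)
  subject_idx <- split(seq_len(n), subj)
  n_per <- lengths(subject_idx)

  obj <- function(u) -profile_fit(exp(u), y, X, subject_idx, n_per)$loglik
  opt <- stats::optimize(obj, interval = c(-20, 15), tol = 1e-10)
  ll0 <- profile_fit(0, y, X, subject_idx, n_per)$loglik
  converged <- TRUE
  ## strict improvement over the lambda = 0 boundary required: with one
  ## observation per subject the profile likelihood is flat in lambda and
  ## the fit must reduce to OLS
  if (-opt$objective > ll0 + 1e-8 && exp(opt$minimum) > 1e-8) {
    lambda <- exp(opt$minimum)
    if (opt$minimum > 14.9) converged <- FALSE  # ran into the search bound
  } else {
    lambda <- 0
  }
  fit <- profile_fit(lambda, y, X, subject_idx, n_per)
  se <- sqrt(diag(fit$cov_beta))
  z <- fit$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  fe <- data.frame(term = colnames(X), estimate = fit$beta, se = se,
                   z = z, p = p, stringsAsFactors = FALSE, row.names = NULL)
  k <- ncol(X) + 2  # fixed effects + two variance components
  structure(list(fixed_effects = fe,
                 sigma2_subject = lambda * fit$s2_resid,
                 sigma2_resid = fit$s2_resid,
                 lambda = lambda,
                 loglik = fit$loglik,
                 deviance = -2 * fit$loglik,
                 aic = -2 * fit$loglik + 2 * k,
                 bic = -2 * fit$loglik + log(length(y)) * k,
                 n_obs = length(y),
                 n_subjects = nlevels(subj),
                 converged = converged),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("random-intercept LMM (ML): %d obs, %d subjects\n",
              x$n_obs, x$n_subjects))
  cat(sprintf("  sigma2_subject = %.4g, sigma2_resid = %.4g, deviance = %.2f\n",
              x$sigma2_subject, x$sigma2_resid, x$deviance))
  print(x$fixed_effects, digits = 4)
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' @export
logLik.lmm_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$fixed_effects) + 2,
            nobs = object$n_obs, class = "logLik")
}

## Polynomial dose design: intercept, dose, dose^2, ... in raw mg, plus
## optional covariate columns; orthogonal recoding available for
## conditioning.
dose_design_matrix <- function(dose, order, covariates = NULL,
                               orthogonal = FALSE) {
  if (order < 1) stop("polynomial order must be >= 1", call. = FALSE)
  if (orthogonal) {
    P <- stats::poly(dose, degree = order)
    colnames(P) <- paste0("dose_o", seq_len(order))
  } else {
    P <- sapply(seq_len(order), function(k) dose^k)
    colnames(P) <- c("dose", paste0("dose", seq_len(order))[-1])[seq_len(order)]
  }
  X <- cbind(intercept = 1, P)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    X <- cbind(X, cv)
  }
  X
}

#' Polynomial dose-response mixed model
#'
#' Fits `outcome ~ 1 + dose + dose^2 + ... (+ covariates) + (1 | subject)`
#' by ML with raw dose in mg.
#'
#' @param y outcome per observation.
#' @param dose dose in mg per observation.
#' @param subject subject id per observation.
#' @param order polynomial order (1-3).
#' @param covariates optional data.frame/matrix of extra fixed effects.
#' @param orthogonal use orthogonal polynomial coding instead of raw powers.
#' @return a `lmm_fit`.
#' @export
fit_dose_model <- function(y, dose, subject, order = 2, covariates = NULL,
                           orthogonal = FALSE) {
  if (order > length(unique(dose)) - 1) {
    stop("polynomial order exceeds distinct doses - 1", call. = FALSE)
  }
  X <- dose_design_matrix(dose, order, covariates, orthogonal)
  fit_random_intercept_lmm(y, X, subject)
}

#' Select the polynomial dose order by ML deviance
#'
#' Fits all candidate orders on identical observations and returns the
#' order with the lowest deviance (AIC and BIC reported alongside). Orders
#' exceeding the number of distinct doses minus one are excluded with a
#' warning.
#'
#' @inheritParams fit_dose_model
#' @param orders candidate polynomial orders.
#' @return list with `selected` (order), `fits` (named list of `lmm_fit`),
#'   and `table` (order, deviance, aic, bic).
#' @export
select_polynomial_order <- function(y, dose, subject, orders = 1:3,
                                    covariates = NULL) {
  max_order <- length(unique(dose)) - 1
  drop <- orders > max_order
  if (any(drop)) {
    warning("orders ", paste(orders[drop], collapse = ", "),
            " exceed distinct doses - 1; excluded", call. = FALSE)
    orders <- orders[!drop]
  }
  if (length(orders) == 0) stop("no fittable polynomial order", call. = FALSE)
  fits <- list()
  for (o in orders) {
    f <- tryCatch(fit_dose_model(y, dose, subject, order = o,
                                 covariates = covariates),
                  error = function(e) {
                    warning("order ", o, " unfittable: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(f)) fits[[as.character(o)]] <- f
  }
  if (length(fits) == 0) stop("no candidate order could be fitted", call. = FALSE)
  tab <- data.frame(order = as.integer(names(fits)),
                    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    row.names = NULL)
  list(selected = tab$order[which.min(tab$deviance)], fits = fits, table = tab)
}

#' Dose-response mixed models for each metabolite class
#'
#' One `log2(class total) ~ 1 + dose + dose^2 + BMI + (1 | subject)` fit per
#' class, with BH adjustment of each dose term's p-values across classes.
#'
#' @param classes a `class_matrix` from [class_sums()] (natural scale).
#' @param meta sample metadata with `sample_id`, `subject_id`, `dose_mg`
#'   and the covariate column.
#' @param covariate name of the covariate column (default `"bmi"`).
#' @param order polynomial order.
#' @return list with `fits` (per class) and `table` (class, term, estimate,
#'   se, p, q) where q is BH within each dose term across classes.
#' @export
fit_class_dose_models <- function(classes, meta, covariate = "bmi",
                                  order = 2) {
  vals <- classes$values[meta$sample_id, , drop = FALSE]
  fits <- list()
  for (cl in colnames(vals)) {
    y <- log2(vals[, cl])
    if (sum(is.finite(y)) < 3) {
      warning("class ", cl, " skipped: all-missing sums", call. = FALSE)
      next
    }
    cv <- stats::setNames(data.frame(as.numeric(meta[[covariate]])), covariate)
    fits[[cl]] <- fit_dose_model(y, meta$dose_mg, meta$subject_id,
                                 order = order, covariates = cv)
  }
  if (length(fits) == 0) stop("no class could be fitted", call. = FALSE)
  tab <- do.call(rbind, lapply(names(fits), function(cl) {
    fe <- fits[[cl]]$fixed_effects
    cbind(class = cl, fe)
  }))
  tab$q <- NA_real_
  for (term in unique(tab$term)) {
    if (!grepl("^dose", term)) next
    i <- tab$term == term
    tab$q[i] <- bh_adjust(tab$p[i])
  }
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Mouse class-level mixed model of age, body weight, genotype and treatment
#'
#' Fits `log2(class total) ~ 1 + age + body weight + genotype * treatment +
#' (1 | mouse)` per class. With one serum sample per mouse the random
#' intercept is unidentifiable and the fit lands on the zero-variance
#' boundary, reducing to OLS — the formula is honoured, the boundary
#' handled. Genotype or treatment columns that do not vary in the data are
#' dropped with a warning.
#'
#' @param classes a `class_matrix` from [class_sums()].
#' @param meta mouse metadata with `sample_id`, `subject_id`, `age_group`,
#'   `body_weight_g`, `genotype`, `treatment`.
#' @return list with `fits` per class and `table` (class, term, estimate,
#'   se, p) — the heatmap data of per-class fixed effects.
#' @export
fit_mouse_class_model <- function(classes, meta) {
  vals <- classes$values[meta$sample_id, , drop = FALSE]
  mf <- data.frame(
    age = as.integer(meta$age_group == "old"),
    bw = as.numeric(meta$body_weight_g),
    genotype = factor(meta$genotype,
                      levels = intersect(c("WT", "AT1KO", "AT2KO"),
                                         unique(meta$genotype))),
    treatment = factor(meta$treatment,
                       levels = intersect(c("control", "losartan"),
                                          unique(meta$treatment))))
  form <- ~ age + bw
  if (nlevels(mf$genotype) > 1 && nlevels(mf$treatment) > 1) {
    form <- ~ age + bw + genotype * treatment
  } else if (nlevels(mf$genotype) > 1) {
    warning("single treatment level: treatment columns absent", call. = FALSE)
    form <- ~ age + bw + genotype
  } else if (nlevels(mf$treatment) > 1) {
    warning("single genotype: interaction columns dropped", call. = FALSE)
    form <- ~ age + bw + treatment
  } else {
    warning("single genotype and treatment: only age and body weight fitted",
            call. = FALSE)
  }
  X <- stats::model.matrix(form, mf)
  keep <- colnames(X) == "(Intercept)" | apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  fits <- list()
  for (cl in colnames(vals)) {
    y <- log2(vals[, cl])
    fits[[cl]] <- fit_random_intercept_lmm(y, X, meta$subject_id)
  }
  tab <- do.call(rbind, lapply(names(fits), function(cl) {
    cbind(class = cl, fits[[cl]]$fixed_effects)
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
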