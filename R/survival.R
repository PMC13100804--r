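## Kaplan-Meier product-limit estimation, the k-group log-rank test, and
## calculated serum osmolality. The estimators are authored here;
## survival::survfit / survdiff serve only as independent oracles in tests.

#' Kaplan-Meier product-limit estimate per group
#'
#' Events tied at the same time are processed simultaneously; observations
#' censored at an event time remain at risk for that event (the standard
#' convention: censoring is processed after events).
#'
#' @param cohort a [survival_cohort()].
#' @return a `km_estimate`: per-group data.frame of (time, n_risk, n_event,
#'   n_censor, survival), starting from survival 1 at time 0.
#' @export
kaplan_meier <- function(cohort) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (any(cohort$time_days < 0)) stop("negative time", call. = FALSE)
  groups <- split(cohort, cohort$group)
  curves <- lapply(groups, function(g) {
    times <- sort(unique(g$time_days))
    n_risk <- vapply(times, function(t) sum(g$time_days >= t), numeric(1))
    n_event <- vapply(times, function(t) {
      sum(g$time_days == t & g$event == 1)
    }, numeric(1))
    n_censor <- vapply(times, function(t) {
      sum(g$time_days == t & g$event == 0)
    }, numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = times, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = surv)
  })
  structure(list(curves = curves, groups = names(curves)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  for (g in x$groups) {
    cv <- x$curves[[g]]
    cat(sprintf("%s: %d subjects, %d events, final survival %.3f\n",
                g, cv$n_risk[1], sum(cv$n_event),
                cv$survival[nrow(cv)]))
  }
  invisible(x)
}

#' Log-rank test across groups
#'
#' At each event time the observed events per group are compared with their
#' hypergeometric expectation given the risk sets; the chi-square statistic
#' uses the full hypergeometric covariance over k - 1 groups, k - 1 df.
#'
#' @param cohort a [survival_cohort()] with >= 2 groups and >= 1 event.
#' @return list (chi_square, df, p, observed, expected) with per-group
#'   observed and expected event counts.
#' @export
logrank_test <- function(cohort) {
  stopifnot(inherits(cohort, "survival_cohort"))
  groups <- sort(unique(cohort$group))
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(cohort$event) == 0) stop("no events", call. = FALSE)
  gidx <- match(cohort$group, groups)
  event_times <- sort(unique(cohort$time_days[cohort$event == 1]))
  O <- stats::setNames(numeric(k), groups)
  E <- stats::setNames(numeric(k), groups)
  V <- matrix(0, k - 1, k - 1)
  for (t in event_times) {
    at_risk <- cohort$time_days >= t
    n <- sum(at_risk)
    n_g <- vapply(seq_len(k), function(g) sum(at_risk & gidx == g), numeric(1))
    d <- sum(cohort$time_days == t & cohort$event == 1)
    d_g <- vapply(seq_len(k), function(g) {
      sum(cohort$time_days == t & cohort$event == 1 & gidx == g)
    }, numeric(1))
    O <- O + d_g
    E <- E + d * n_g / n
    if (n > 1) {
      frac <- n_g / n
      vmat <- (diag(frac[-k], k - 1) - tcrossprod(frac[-k])) *
        d * (n - d) / (n - 1)
      V <- V + vmat
    }
  }
  u <- (O - E)[-k]
  chi <- tryCatch(drop(t(u) %*% solve(V, u)), error = function(e) 0)
  if (!is.finite(chi) || chi < 0) chi <- 0
  p <- stats::pchisq(chi, df = k - 1, lower.tail = FALSE)
  list(chi_square = chi, df = k - 1, p = p, observed = O, expected = E)
}

#' Calculated serum osmolality
#'
#' The standard clinical estimate `2 Na + glucose/18 + BUN/2.8` with sodium
#' in mmol/L and glucose / blood urea nitrogen in mg/dL, returning mOsm/kg.
#'
#' @param sodium_mmol_l,glucose_mg_dl,bun_mg_dl positive clinical panel
#'   values (vectors recycle elementwise).
#' @return calculated osmolality in mOsm/kg.
#' @export
calculated_osmolality <- function(sodium_mmol_l, glucose_mg_dl, bun_mg_dl) {
  if (any(sodium_mmol_l <= 0) || any(glucose_mg_dl <= 0) ||
      any(bun_mg_dl <= 0)) {
    stop("clinical panel values must be > 0", call. = FALSE)
  }
  2 * sodium_mmol_l + glucose_mg_dl / 18 + bun_mg_dl / 2.8
}
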