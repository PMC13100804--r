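## Aging-signature reversal scoring: Spearman correlation between a
## per-feature aging signature (old-vs-young log2FC, or external per-year
## age coefficients) and a treatment's per-feature effects. Negative rho
## means the treatment shifts the profile against aging ("rejuvenation").

## Spearman rho via average ranks then the Pearson product-moment formula —
## authored here; stats::cor.test serves only as a test oracle.
spearman_rho <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  sx <- rx - mean(rx)
  sy <- ry - mean(ry)
  denom <- sqrt(sum(sx^2) * sum(sy^2))
  if (denom == 0) stop("zero rank variance", call. = FALSE)
  sum(sx * sy) / denom
}

spearman_p <- function(rho, n, method = c("t", "permutation"),
                       n_perm = 9999, x = NULL, y = NULL) {
  method <- match.arg(method)
  if (method == "t") {
    if (abs(rho) >= 1) return(.Machine$double.xmin)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    return(min(max(p, .Machine$double.xmin), 1))
  }
  ## permutation null for tiny panels
  hits <- 0L
  for (i in seq_len(n_perm)) {
    hits <- hits + (abs(spearman_rho(x, sample(y))) >= abs(rho) - 1e-12)
  }
  (1 + hits) / (1 + n_perm)
}

#' Signature reversal score
#'
#' Spearman correlation between two per-feature effect vectors over their
#' shared features (exact name intersection), with a two-sided p-value from
#' the t-approximation on n - 2 df (an exact permutation option is
#' available for tiny panels).
#'
#' @param signature an [effect_vector()] — the aging signature.
#' @param effect an [effect_vector()] — the treatment (or comparison)
#'   effects.
#' @param method p-value method: `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return a `signature_score` list: rho, p, q (NA until adjusted within a
#'   family), n_features, label_x, label_y.
#' @export
reversal_score <- function(signature, effect, method = "t", n_perm = 9999) {
  shared <- intersect(trimws(signature$feature_id), trimws(effect$feature_id))
  x <- signature$estimate[match(shared, trimws(signature$feature_id))]
  y <- effect$estimate[match(shared, trimws(effect$feature_id))]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 shared finite features", call. = FALSE)
  rho <- spearman_rho(x, y)
  p <- spearman_p(rho, length(x), method = method, n_perm = n_perm,
                  x = x, y = y)
  structure(list(rho = rho, p = p, q = NA_real_, n_features = length(x),
                 label_x = attr(signature, "label"),
                 label_y = attr(effect, "label")),
            class = "signature_score")
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("signature score [%s ~ %s]: rho = %.3f, p = %.3g%s (n = %d)\n",
              x$label_x, x$label_y, x$rho, x$p,
              if (!is.na(x$q)) sprintf(", q = %.3g", x$q) else "",
              x$n_features))
  invisible(x)
}

#' Score a family of effects against one signature
#'
#' One reversal score per effect, with BH adjustment across the family —
#' the data behind a forest plot of condition-vs-signature correlations.
#'
#' @param signature an [effect_vector()].
#' @param effects a list of [effect_vector()]s.
#' @param ... passed to [reversal_score()].
#' @return data.frame (label_x, label_y, rho, p, q, n_features), one row
#'   per effect, in input order.
#' @export
score_family <- function(signature, effects, ...) {
  scores <- lapply(seq_along(effects), function(i) {
    tryCatch(reversal_score(signature, effects[[i]], ...),
             error = function(e) {
               stop("scoring effect ", i, " ('",
                    attr(effects[[i]], "label"), "') failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  out <- data.frame(
    label_x = vapply(scores, `[[`, character(1), "label_x"),
    label_y = vapply(scores, `[[`, character(1), "label_y"),
    rho = vapply(scores, `[[`, numeric(1), "rho"),
    p = vapply(scores, `[[`, numeric(1), "p"),
    n_features = vapply(scores, `[[`, integer(1), "n_features"),
    stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  out[c("label_x", "label_y", "rho", "p", "q", "n_features")]
}

#' Per-subject aging-signature scores across visits
#'
#' For each subject and each post-baseline visit, the change from that
#' subject's own baseline (per-feature log2FC, computed as visit minus
#' baseline on the log2 scale) is correlated against the external age
#' coefficients. A subject-visit whose change vector is all zero (no
#' observable change) is recorded with a missing score and a reason.
#'
#' @param m a log2-scale [feature_matrix()] of subject-visit samples.
#' @param meta sample metadata with `sample_id`, `subject_id`,
#'   `visit_index`, `dose_mg`.
#' @param beta_age an [effect_vector()] of per-feature age coefficients.
#' @return data.frame (subject_id, visit_index, dose_mg, rho, p,
#'   n_features, reason), one row per subject x post-baseline visit.
#' @export
subject_signature_scores <- function(m, meta, beta_age) {
  stopifnot(m$scale == "log2")
  subjects <- unique(meta$subject_id)
  rows <- list()
  for (s in subjects) {
    ms <- meta[meta$subject_id == s, , drop = FALSE]
    ms <- ms[order(ms$visit_index), , drop = FALSE]
    base <- ms[ms$visit_index == min(ms$visit_index) & ms$dose_mg == 0, , drop = FALSE]
    if (nrow(base) == 0) {
      stop("subject '", s, "' has no baseline (dose-0 first) visit",
           call. = FALSE)
    }
    y0 <- m$values[base$sample_id[1], ]
    for (k in which(ms$visit_index > base$visit_index[1])) {
      change <- m$values[ms$sample_id[k], ] - y0
      ev <- effect_vector(feature_ids(m), estimate = change,
                          label = sprintf("%s_v%d", s, ms$visit_index[k]))
      row <- data.frame(subject_id = s, visit_index = ms$visit_index[k],
                        dose_mg = ms$dose_mg[k], rho = NA_real_,
                        p = NA_real_, n_features = NA_integer_,
                        reason = "", stringsAsFactors = FALSE)
      ch <- change[is.finite(change)]
      if (length(ch) >= 3 && stats::sd(ch) > 0) {
        sc <- reversal_score(beta_age, ev)
        row$rho <- sc$rho; row$p <- sc$p; row$n_features <- sc$n_features
      } else {
        row$reason <- "all-zero or degenerate change vector"
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
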