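## Cross-condition integration: a correlation network over effect vectors
## (all pairwise Spearman correlations with BH significance, laid out by
## classical multidimensional scaling of 1 - rho) and a PCA of the
## condition effects, z-scaled without centering so that per-year age
## coefficients and log2 fold changes are comparable.

## Intersect a list of effect vectors into a complete features x conditions
## matrix (shared features only).
effect_matrix <- function(effects) {
  labels <- vapply(effects, function(e) attr(e, "label"), character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels", call. = FALSE)
  shared <- Reduce(intersect, lapply(effects, function(e) trimws(e$feature_id)))
  if (length(shared) < 3) stop("fewer than 3 shared features", call. = FALSE)
  mat <- sapply(effects, function(e) {
    e$estimate[match(shared, trimws(e$feature_id))]
  })
  dimnames(mat) <- list(shared, labels)
  mat
}

#' Cross-condition correlation network of effect vectors
#'
#' All pairwise Spearman correlations between condition effect vectors over
#' their shared features, with two-sided p-values (t-approximation), BH
#' adjustment across all pairs, and a 2-D layout from classical
#' multidimensional scaling of the distance 1 - rho (anticorrelated
#' conditions sit far apart).
#'
#' @param effects list of [effect_vector()]s with distinct labels.
#' @param alpha significance threshold on q for the `significant` flag.
#' @return an `effect_network`: `nodes` (labels), `edges` data.frame
#'   (node_a, node_b, rho, p, q, significant, n_features), `layout`
#'   (nodes x 2 coordinates).
#' @export
build_effect_network <- function(effects, alpha = 0.05) {
  if (length(effects) < 2) stop("need >= 2 effect vectors", call. = FALSE)
  mat <- effect_matrix(effects)
  labels <- colnames(mat)
  pairs <- utils::combn(length(labels), 2)
  edges <- data.frame(node_a = labels[pairs[1, ]],
                      node_b = labels[pairs[2, ]],
                      rho = NA_real_, p = NA_real_,
                      n_features = nrow(mat),
                      stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- mat[, pairs[1, k]]; y <- mat[, pairs[2, k]]
    edges$rho[k] <- tryCatch(spearman_rho(x, y), error = function(e) NA_real_)
    if (!is.na(edges$rho[k])) {
      edges$p[k] <- spearman_p(edges$rho[k], nrow(mat))
    }
  }
  defined <- !is.na(edges$p)
  edges$q <- NA_real_
  if (any(defined)) edges$q[defined] <- bh_adjust(edges$p[defined])
  edges$significant <- !is.na(edges$q) & edges$q < alpha

  ## MDS layout on signed distance 1 - rho; undefined edges get distance 1
  d <- matrix(1, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(d) <- 0
  for (k in seq_len(ncol(pairs))) {
    if (is.na(edges$rho[k])) next
    d[pairs[1, k], pairs[2, k]] <- d[pairs[2, k], pairs[1, k]] <-
      1 - edges$rho[k]
  }
  layout <- stats::cmdscale(stats::as.dist(d), k = min(2, length(labels) - 1))
  if (ncol(layout) < 2) layout <- cbind(layout, 0)
  colnames(layout) <- c("x", "y")
  structure(list(nodes = labels, edges = edges, layout = layout),
            class = "effect_network")
}

#' @export
print.effect_network <- function(x, ...) {
  cat(sprintf("effect network: %d conditions, %d edges (%d significant)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$significant)))
  invisible(x)
}

#' PCA of condition effect vectors, z-scaled without centering
#'
#' Each condition's effect vector is divided by its own standard deviation
#' (computed about its mean) with no mean subtraction, equalizing the
#' scales of per-year age coefficients and log2 fold changes; the scaled
#' conditions x features matrix is then decomposed by SVD. Because the data
#' are not centered, the first component typically captures the global
#' (all-features-shift) axis.
#'
#' @param effects list of [effect_vector()]s with distinct labels.
#' @return an `effect_pca`: `scores` (conditions x components), `loadings`
#'   (features x components, orthonormal), `variance_fraction`, `sdev`.
#' @export
effect_pca <- function(effects) {
  if (length(effects) < 2) stop("need >= 2 effect vectors", call. = FALSE)
  mat <- effect_matrix(effects)           # features x conditions
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance condition: ",
         paste(colnames(mat)[sds == 0], collapse = ", "), call. = FALSE)
  }
  X <- t(sweep(mat, 2, sds, "/"))         # conditions x features, uncentered
  sv <- svd(X)
  ncomp <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, ncomp)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncomp)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = loadings,
                 sdev = sv$d,
                 variance_fraction = sv$d^2 / sum(sv$d^2)),
            class = "effect_pca")
}

#' @export
print.effect_pca <- function(x, ...) {
  cat("uncentered PCA of condition effects\n")
  vf <- round(100 * x$variance_fraction, 2)
  cat("  variance explained (%): ", paste(vf, collapse = ", "), "\n")
  invisible(x)
}
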