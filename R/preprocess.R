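## Preprocessing: log2 transformation, outlier-sample QC by mean z-score,
## and metabolite-class summation.

#' Log2-transform a natural-scale feature matrix
#'
#' @param m a natural-scale [feature_matrix()].
#' @return the matrix on the log2 scale; missing values preserved.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$scale != "natural") stop("matrix is already log2 scale", call. = FALSE)
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad[seq_len(min(5, nrow(bad))), , drop = FALSE], 1,
                   function(i) sprintf("(%s, %s)", rownames(m$values)[i[1]],
                                       colnames(m$values)[i[2]]))
    stop("non-positive values cannot be log2 transformed: ",
         paste(cells, collapse = ", "),
         if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5),
         call. = FALSE)
  }
  feature_matrix(log2(m$values), scale = "log2")
}

#' Flag outlier samples by mean metabolite z-score
#'
#' Each feature is z-scored across samples (mean 0, SD 1 with the n-1
#' denominator, missing values skipped); a sample's `mean_z` is the mean of
#' its z-scores over its non-missing features, and samples with
#' `|mean_z| > threshold` are flagged. Zero-variance features contribute
#' z = 0 for all samples.
#'
#' @param m a log2-scale [feature_matrix()] with at least 3 samples.
#' @param threshold flagging threshold on |mean z| (default 3).
#' @return a `qc_report` data.frame: sample_id, mean_z, flagged, threshold.
#' @export
flag_outlier_samples <- function(m, threshold = 3) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$scale != "log2") stop("QC expects log2-scale data", call. = FALSE)
  if (nrow(m$values) < 3) stop("need at least 3 samples", call. = FALSE)
  v <- m$values
  mu <- colMeans(v, na.rm = TRUE)
  sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
  zerovar <- !is.na(sdv) & sdv == 0
  if (any(zerovar)) {
    vlog("zero-variance features contribute z = 0: ",
         paste(colnames(v)[zerovar], collapse = ", "))
    sdv[zerovar] <- Inf  # z = 0 for every sample
  }
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  rep <- data.frame(sample_id = rownames(v),
                    mean_z = rowMeans(z, na.rm = TRUE),
                    stringsAsFactors = FALSE)
  rep$flagged <- abs(rep$mean_z) > threshold
  rep$threshold <- threshold
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Sum natural-scale concentrations by metabolite class
#'
#' Class totals are computed on the natural (concentration) scale; summing
#' log values would be dimensionally meaningless. Missing member features
#' are absent from the sum; a sample-class cell with no observed members is
#' missing. Classes with zero member features are absent from the output.
#'
#' @param m a natural-scale [feature_matrix()].
#' @param ann a [feature_annotation()] covering the matrix features.
#' @return a `class_matrix`: samples x classes matrix with scale tag.
#' @export
class_sums <- function(m, ann) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$scale != "natural") {
    stop("class sums are defined on the natural scale", call. = FALSE)
  }
  cls <- ann$class_label[match(feature_ids(m), ann$feature_id)]
  if (anyNA(cls)) {
    stop("features missing from annotation: ",
         paste(utils::head(feature_ids(m)[is.na(cls)], 5), collapse = ", "),
         call. = FALSE)
  }
  classes <- intersect(c(P180_CLASSES, "other"), unique(cls))
  out <- sapply(classes, function(cl) {
    sub <- m$values[, cls == cl, drop = FALSE]
    s <- rowSums(sub, na.rm = TRUE)
    s[rowSums(!is.na(sub)) == 0] <- NA  # no observed members
    s
  })
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(sample_ids(m), classes))
  structure(list(values = out, scale = "natural"),
            class = c("class_matrix", "feature_matrix"))
}
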