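## Shared data containers: FeatureMatrix, FeatureAnnotation, SampleMetadata,
## EffectVector, SurvivalCohort. Plain-matrix / data.frame backed S3 so that
## downstream numerical code stays transparent.

P180_CLASSES <- c("AA", "AC", "BA", "LysoPC", "PC", "SM", "H")

#' Construct a feature matrix
#'
#' A feature matrix holds one sample per row and one metabolite (or protein)
#' per column, with a scale tag distinguishing natural-scale concentrations
#' (micromolar, strictly positive) from log2-transformed values. Missing
#' values (below limit of detection, or analytes not quantifiable on a
#' panel) are `NA`.
#'
#' @param values numeric matrix, samples x features, with row and column
#'   names giving sample and feature ids.
#' @param scale one of `"natural"` or `"log2"`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, scale = c("natural", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample ids (rownames) and feature ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (scale == "natural" && any(values <= 0, na.rm = TRUE)) {
    stop("natural-scale values must be > 0 where present", call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s scale), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

sample_ids <- function(m) rownames(m$values)
feature_ids <- function(m) colnames(m$values)

#' Construct a feature annotation table
#'
#' Maps each feature to one of the targeted-panel classes: AA (amino acids),
#' AC (acylcarnitines), BA (biogenic amines), LysoPC
#' (lysophosphatidylcholines), PC (phosphatidylcholines), SM
#' (sphingomyelins), H (hexoses), or "other". Unknown labels are mapped to
#' "other" with a warning.
#'
#' @param feature_id character vector of feature ids.
#' @param class_label character vector of class labels, same length.
#' @return a data.frame of class `feature_annotation`.
#' @export
feature_annotation <- function(feature_id, class_label) {
  stopifnot(length(feature_id) == length(class_label))
  if (anyDuplicated(feature_id)) {
    stop("duplicate feature ids in annotation", call. = FALSE)
  }
  class_label <- as.character(class_label)
  unknown <- !(class_label %in% c(P180_CLASSES, "other"))
  if (any(unknown)) {
    warning("unknown class labels mapped to 'other': ",
            paste(unique(class_label[unknown]), collapse = ", "),
            call. = FALSE)
    class_label[unknown] <- "other"
  }
  ann <- data.frame(feature_id = as.character(feature_id),
                    class_label = class_label,
                    stringsAsFactors = FALSE)
  class(ann) <- c("feature_annotation", "data.frame")
  ann
}

#' Construct an effect vector
#'
#' The common currency of the pipeline: a per-feature vector of signed effect
#' estimates (a log2 fold change, or a per-year age coefficient) with
#' standard errors and (adjusted) p-values.
#'
#' @param feature_ids character vector.
#' @param estimate,se,p,q numeric vectors aligned to `feature_ids`; `se`
#'   positive, `p` and `q` in (0, 1].
#' @param t optional per-feature statistic.
#' @param n_used number of samples behind the estimates.
#' @param label free-text condition label (e.g. "mouse aging", "Los WT").
#' @return a data.frame of class `effect_vector` with attributes `label` and
#'   `n_used`.
#' @export
effect_vector <- function(feature_ids, estimate, se = NA_real_, p = NA_real_,
                          q = NA_real_, t = NA_real_, n_used = NA_integer_,
                          label = "") {
  n <- length(feature_ids)
  stopifnot(length(estimate) == n)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids", call. = FALSE)
  chk <- function(v) if (length(v) == 1L) rep(v, n) else v
  ev <- data.frame(feature_id = as.character(feature_ids),
                   estimate = as.numeric(estimate),
                   se = as.numeric(chk(se)),
                   t = as.numeric(chk(t)),
                   p = as.numeric(chk(p)),
                   q = as.numeric(chk(q)),
                   stringsAsFactors = FALSE)
  bad_p <- !is.na(ev$p) & (ev$p <= 0 | ev$p > 1)
  if (any(bad_p)) stop("p-values must lie in (0, 1]", call. = FALSE)
  attr(ev, "label") <- label
  attr(ev, "n_used") <- n_used
  class(ev) <- c("effect_vector", "data.frame")
  ev
}

#' @export
print.effect_vector <- function(x, ...) {
  cat(sprintf("effect_vector '%s': %d features", attr(x, "label"), nrow(x)))
  if (!all(is.na(x$q))) {
    cat(sprintf(", %d at q < 0.05", sum(x$q < 0.05, na.rm = TRUE)))
  }
  cat("\n")
  NextMethod()
}

#' Construct a survival cohort
#'
#' @param subject_id,group character vectors.
#' @param time_days non-negative finite times.
#' @param event 1 = event observed, 0 = censored.
#' @return a data.frame of class `survival_cohort`.
#' @export
survival_cohort <- function(subject_id, group, time_days, event) {
  n <- length(subject_id)
  if (length(group) == 1L) group <- rep(group, n)
  stopifnot(length(group) == n, length(time_days) == n, length(event) == n)
  if (any(!is.finite(time_days)) || any(time_days < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event flags must be 0 or 1", call. = FALSE)
  d <- data.frame(subject_id = as.character(subject_id),
                  group = as.character(group),
                  time_days = as.numeric(time_days),
                  event = as.integer(event),
                  stringsAsFactors = FALSE)
  class(d) <- c("survival_cohort", "data.frame")
  d
}

# ---------------------------------------------------------------------------
# File I/O. CSV throughout (empty cell = missing); YAML for configs, JSON
# for ground truth / scores / fits.

#' Write a feature matrix (and optional annotation) to CSV
#'
#' First column is `sample_id`, remaining columns are features; missing
#' values are written as empty cells. Round-trips losslessly at 15
#' significant digits.
#'
#' @param m a [feature_matrix()].
#' @param path output CSV path.
#' @param annotation optional [feature_annotation()].
#' @param annotation_path where to write the annotation CSV.
#' @export
write_feature_matrix <- function(m, path, annotation = NULL,
                                 annotation_path = NULL) {
  df <- data.frame(sample_id = sample_ids(m),
                   format(m$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(m$values)] <- ""
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(annotation)) {
    if (is.null(annotation_path)) {
      stop("annotation_path required when annotation given", call. = FALSE)
    }
    utils::write.csv(as.data.frame(annotation), annotation_path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV with a `sample_id` first column and one column per
#'   feature; empty cells are missing.
#' @param annotation_path optional annotation CSV with columns `feature_id`,
#'   `class_label`.
#' @param scale scale tag of the stored values.
#' @return the [feature_matrix()], or a list `(matrix, annotation)` when an
#'   annotation path is given.
#' @export
read_feature_matrix <- function(path, annotation_path = NULL,
                                scale = "natural") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "sample_id") {
    stop("first column must be sample_id", call. = FALSE)
  }
  feats <- names(df)[-1]
  if (anyDuplicated(feats)) {
    stop("duplicated feature column: ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(df[-1])
  vals[vals == ""] <- NA
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- is.na(num) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at sample '%s', feature '%s'",
                 df$sample_id[idx[1]], feats[idx[2]]), call. = FALSE)
  }
  dimnames(num) <- list(df$sample_id, feats)
  m <- feature_matrix(num, scale = scale)
  if (is.null(annotation_path)) return(m)
  ad <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  list(matrix = m,
       annotation = feature_annotation(ad$feature_id, ad$class_label))
}

#' Restrict two feature matrices to their shared features
#'
#' Harmonizes panels from different species or fractions by exact feature
#' name (whitespace-trimmed), returning both matrices restricted to the
#' intersection in a common feature order.
#'
#' @param a,b [feature_matrix()] objects.
#' @return list of the two restricted matrices.
#' @export
harmonize_features <- function(a, b) {
  fa <- trimws(feature_ids(a))
  fb <- trimws(feature_ids(b))
  shared <- intersect(fa, fb)
  if (length(shared) == 0L) {
    stop("no shared features between the two panels", call. = FALSE)
  }
  va <- a$values; colnames(va) <- fa
  vb <- b$values; colnames(vb) <- fb
  list(a = feature_matrix(va[, shared, drop = FALSE], scale = a$scale),
       b = feature_matrix(vb[, shared, drop = FALSE], scale = b$scale))
}

#' @rdname write_feature_matrix
#' @param metadata a sample-metadata data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_feature_matrix
#' @export
read_sample_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write generator configurations as YAML
#' @param config a named list (e.g. from [mouse_design()]).
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
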