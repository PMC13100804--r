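## Preranked set enrichment: weighted Kolmogorov-Smirnov running-sum
## enrichment scores with gene-label permutation p-values, used to test
## cell-type marker sets against a preranked proteome effect vector.

## Order feature ids by a signed statistic, descending, ties broken by id
## (lexicographic, C locale) for determinism.
rank_features <- function(stats) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be uniquely named by feature id", call. = FALSE)
  }
  ord <- order(-stats, names(stats), method = "radix")
  stats[ord]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranking from top to bottom, incrementing by
#' `|stat|^weight / sum(|stat in set|^weight)` at set members and
#' decrementing by `1/(N - m)` elsewhere; the enrichment score is the
#' extremum of the running sum (signed). A set spanning every feature has
#' no decrement steps and scores 1.
#'
#' @param stats named vector of ranking statistics (any order; ranked
#'   internally, ties broken by feature id).
#' @param gene_set character vector of member feature ids.
#' @param weight_exponent weight on the statistic (0 = classic KS, 1 =
#'   default weighted form).
#' @return the enrichment score in [-1, 1].
#' @export
enrichment_score <- function(stats, gene_set, weight_exponent = 1) {
  ranked <- rank_features(stats)
  inset <- names(ranked) %in% gene_set
  m <- sum(inset)
  if (m == 0) stop("no overlap between gene set and ranking", call. = FALSE)
  N <- length(ranked)
  w <- abs(ranked)^weight_exponent
  inc <- ifelse(inset, w / sum(w[inset]), 0)
  dec <- if (N > m) 1 / (N - m) else 0
  running <- cumsum(inc - ifelse(inset, 0, dec))
  running[which.max(abs(running))]
}

#' Permutation p-values for a collection of gene sets
#'
#' Gene-label permutation: for each set, the null distribution of the
#' enrichment score is obtained by drawing random member sets of the same
#' size from the ranked features. Two-sided p = (1 + #{|ES_perm| >=
#' |ES_obs|}) / (1 + n_perm); normalized ES divides by the mean |ES_perm|;
#' BH across sets.
#'
#' @param stats named vector of ranking statistics.
#' @param sets named list of character vectors (the gene sets).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param min_size sets with fewer overlapping members are dropped.
#' @param weight_exponent passed to [enrichment_score()].
#' @return data.frame (set, size, es, nes, p, q), one row per retained set.
#' @export
permutation_pvalues <- function(stats, sets, n_perm = 1000, seed = 1L,
                                min_size = 3, weight_exponent = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  ids <- names(stats)
  sizes <- vapply(sets, function(s) sum(ids %in% s), integer(1))
  keep <- sizes >= min_size
  if (!any(keep)) stop("no gene set meets min_size", call. = FALSE)
  sets <- sets[keep]; sizes <- sizes[keep]
  es_obs <- vapply(names(sets), function(nm) {
    enrichment_score(stats, sets[[nm]], weight_exponent)
  }, numeric(1))

  with_seed(seed, {
    ## one null ES matrix per distinct set size
    null_by_size <- lapply(unique(sizes), function(m) {
      vapply(seq_len(n_perm), function(i) {
        enrichment_score(stats, sample(ids, m), weight_exponent)
      }, numeric(1))
    })
    names(null_by_size) <- as.character(unique(sizes))
  })

  p <- nes <- numeric(length(sets))
  for (i in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    p[i] <- (1 + sum(abs(null_es) >= abs(es_obs[i]))) / (1 + n_perm)
    nes[i] <- es_obs[i] / mean(abs(null_es))
  }
  data.frame(set = names(sets), size = sizes, es = es_obs, nes = nes,
             p = p, q = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) strsplit(l, "\t")[[1]][-(1:2)])
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}
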