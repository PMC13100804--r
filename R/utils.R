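#' @keywords internal
"_PACKAGE"

## Seed handling: every generator is a pure function of (config, seed).
## The caller's RNG state is saved and restored so simulation loops in user
## code are not perturbed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Largest-remainder apportionment of n items to proportions that sum to 1.
## Ties in the remainder broken by position for determinism.
largest_remainder <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0))
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  quota <- n * proportions
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

vlog <- function(..., verbose = getOption("rejuvmet.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[rejuvmet] ", ...)
  invisible(NULL)
}
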