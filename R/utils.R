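#' Summarise an uncertainty vector
#'
#' Collapses a vector carried over uncertainty iterations into its mean and
#' equal-tailed 95% interval, the summary used throughout the package for
#' reporting second-order Monte Carlo results.
#'
#' @param x Numeric vector, one value per uncertainty iteration.
#' @return A tibble with columns `mean`, `lo` (2.5th percentile) and `hi`
#'   (97.5th percentile).
#' @export
#' @examples
#' summarise_uncertain(rnorm(1000))
summarise_uncertain <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  tibble::tibble(mean = mean(x), lo = q[1], hi = q[2])
}

# Deterministic child seeds below 2^31, one per labelled stream, so strata
# (and the shared weight stream) are reproducible independently of each other.
child_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Stratified (Latin-hypercube) draws from a normal truncated below at 0,
# via the inverse CDF on jittered, permuted strata of (P(X<0), 1). The
# stratification pins the sample mean of the stream close to its expectation,
# which keeps seed-to-seed drift of mean DALY well under the 1% stability
# margin at the default 1000 uncertainty iterations.
rnorm_trunc0_lhs <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  u <- (sample.int(n) - stats::runif(n)) / n
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + u * (1 - p0), mean, sd)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
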