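#' Uncertainty samplers for intake distribution parameters
#'
#' The outer (uncertainty) dimension of the second-order Monte Carlo draws
#' one `(meanlog, sdlog)` pair per iteration. Three interchangeable sources
#' are provided:
#' \describe{
#'   \item{`sampler_ci()`}{independent normals centred on the published
#'     point estimates with sd = (CI_hi - CI_lo) / (2 x 1.96), the minimal
#'     assumption when only a point and a 95% CI are published. Draws are
#'     stratified (Latin hypercube, independently permuted per parameter):
#'     the marginals are exact and the stream mean is pinned to its
#'     expectation, which stabilises run-to-run output means. Non-positive
#'     `sdlog` mass is handled by truncation (distributionally identical to
#'     redrawing); the expected number of rejected draws is attached as
#'     attribute `n_redraws`, with a warning when it exceeds 1% of draws.}
#'   \item{`sampler_bootstrap()`}{resamples the replicate pairs of a
#'     [bootstrap_fit()], preserving the correlation between the two
#'     parameters.}
#'   \item{`sampler_point()`}{degenerate sampler returning the point
#'     estimate, used to switch uncertainty off.}
#' }
#' Each returns a function of `n` yielding a tibble with columns `meanlog`
#' and `sdlog`; draws consume the caller's RNG stream.
#'
#' @param meanlog,sdlog Point estimates of the lognormal parameters.
#' @param meanlog_lo,meanlog_hi,sdlog_lo,sdlog_hi 95% CI bounds.
#' @return A function `n -> tibble(meanlog, sdlog)`.
#' @export
#' @examples
#' set.seed(1)
#' s <- sampler_ci(0.52, 0.46, 0.58, 0.37, 0.33, 0.42)
#' s(3)
sampler_ci <- function(meanlog, meanlog_lo, meanlog_hi,
                       sdlog, sdlog_lo, sdlog_hi) {
  z <- 2 * stats::qnorm(0.975)
  ml_sd <- (meanlog_hi - meanlog_lo) / z
  sl_sd <- (sdlog_hi - sdlog_lo) / z
  lhs_u <- function(n) (sample.int(n) - stats::runif(n)) / n
  function(n) {
    ml <- if (ml_sd == 0) rep(meanlog, n) else {
      stats::qnorm(lhs_u(n), meanlog, ml_sd)
    }
    if (sl_sd == 0) {
      sl <- rep(sdlog, n)
      redraws <- 0
    } else {
      p0 <- stats::pnorm(0, sdlog, sl_sd)
      sl <- stats::qnorm(p0 + lhs_u(n) * (1 - p0), sdlog, sl_sd)
      redraws <- round(n * p0 / (1 - p0))
      if (redraws > 0.01 * n) {
        warning("more than 1% of sdlog draws are non-positive ",
          "(truncated at zero)")
      }
    }
    out <- tibble::tibble(meanlog = ml, sdlog = sl)
    attr(out, "n_redraws") <- redraws
    out
  }
}

#' @rdname sampler_ci
#' @param fit A `fitted_intake` object from [bootstrap_fit()].
#' @export
sampler_bootstrap <- function(fit) {
  stopifnot(inherits(fit, "fitted_intake"))
  reps <- fit$replicates
  function(n) {
    out <- reps[sample.int(nrow(reps), n, replace = TRUE), ]
    attr(out, "n_redraws") <- 0L
    out
  }
}

#' @rdname sampler_ci
#' @export
sampler_point <- function(meanlog, sdlog) {
  function(n) {
    out <- tibble::tibble(
      meanlog = rep(meanlog, n),
      sdlog = rep(sdlog, n)
    )
    attr(out, "n_redraws") <- 0L
    out
  }
}
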