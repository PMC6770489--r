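#' Iron-deficiency-anaemia prevalence from ID prevalence
#'
#' Multiplies the ID prevalence uncertainty vector by the per-stratum
#' proportion of iron deficiencies that present as anaemia. The proportion
#' is a deterministic input; strata with `prop_ida = 0` carry no anaemia
#' burden at all.
#'
#' @param prev_id Numeric vector of ID prevalences (one per uncertainty
#'   iteration).
#' @param prop_ida Proportion in \[0, 1\].
#' @return Numeric vector of IDA prevalences.
#' @export
#' @examples
#' ida_prevalence(c(0.437, 0.42), 0.5)
ida_prevalence <- function(prev_id, prop_ida) {
  stopifnot(prop_ida >= 0, prop_ida <= 1)
  prev_id * prop_ida
}

#' Allocate anaemia to severity bands from the haemoglobin distribution
#'
#' With haemoglobin N(`hb_mean`, `hb_sd`) g/dL and WHO thresholds, anaemia
#' is Hb below the mild threshold; the anaemic fraction is partitioned into
#' severe `[0, severe)`, moderate `[severe, moderate)` and mild
#' `[moderate, mild)` bands by the normal CDF, in closed form. The same
#' allocation is applied to iron-deficiency anaemia as to all-cause anaemia.
#'
#' Vectorised over strata. If a stratum has (numerically) zero anaemia
#' probability the allocation is undefined and returned as all zeros with a
#' warning.
#'
#' @param hb_mean,hb_sd Haemoglobin normal parameters (g/dL).
#' @param thr_mild,thr_moderate,thr_severe Ordered thresholds (g/dL),
#'   severe < moderate < mild.
#' @return Tibble with columns `anaemia` (total probability of Hb below the
#'   mild threshold) and fractions `mild`, `moderate`, `severe` summing to 1.
#' @export
#' @examples
#' severity_allocation(13.5, 1.5, 11.9, 10.9, 8.0)
severity_allocation <- function(hb_mean, hb_sd, thr_mild, thr_moderate,
                                thr_severe) {
  stopifnot(all(thr_severe < thr_moderate), all(thr_moderate < thr_mild))
  a <- stats::pnorm(thr_mild, hb_mean, hb_sd)
  p_sev <- stats::pnorm(thr_severe, hb_mean, hb_sd)
  p_mod <- stats::pnorm(thr_moderate, hb_mean, hb_sd)
  zero <- a <= 0
  if (any(zero)) {
    warning("degenerate haemoglobin distribution: zero anaemia probability; ",
      "allocation undefined, returning zeros")
    a[zero] <- NA_real_
  }
  out <- tibble::tibble(
    anaemia = ifelse(zero, 0, a),
    mild = (a - p_mod) / a,
    moderate = (p_mod - p_sev) / a,
    severe = p_sev / a
  )
  out[zero, c("mild", "moderate", "severe")] <- 0
  out
}

#' Case counts by severity
#'
#' Number of IDA cases per severity band: population times IDA prevalence
#' times the severity allocation fraction, carried over the uncertainty
#' vector. The severity totals sum to population x prevalence.
#'
#' @param population Stratum population (persons).
#' @param prev_ida IDA prevalence uncertainty vector.
#' @param alloc One-row allocation as returned by [severity_allocation()].
#' @return Tibble with columns `mild`, `moderate`, `severe` (absolute case
#'   vectors over uncertainty iterations).
#' @export
severity_cases <- function(population, prev_ida, alloc) {
  stopifnot(population >= 0)
  total <- population * prev_ida
  tibble::tibble(
    mild = total * alloc$mild,
    moderate = total * alloc$moderate,
    severe = total * alloc$severe
  )
}

#' Draw the shared disability-weight uncertainty stream
#'
#' Disability weights are epistemic: one triplet (mild, moderate, severe) is
#' drawn per outer iteration and shared across all strata, since a weight is
#' a property of the health state, not of the stratum. Draws are normal,
#' truncated below at zero (the mild weight N(0.005, 0.002) has small
#' negative mass), and stratified (Latin hypercube) so the stream's mean is
#' tightly pinned to its expectation.
#'
#' @param weights 3-row tibble with columns `severity`, `mean`, `sd`
#'   (ordered mild, moderate, severe).
#' @param n_unc Number of uncertainty iterations.
#' @return `n_unc` x 3 matrix with columns mild, moderate, severe. Uses the
#'   current RNG stream.
#' @export
draw_disability_weights <- function(weights, n_unc) {
  stopifnot(identical(weights$severity, c("mild", "moderate", "severe")))
  m <- vapply(
    seq_len(3),
    function(i) rnorm_trunc0_lhs(n_unc, weights$mean[i], weights$sd[i]),
    numeric(n_unc)
  )
  colnames(m) <- weights$severity
  m
}

#' DALY uncertainty vector from severity cases and weight draws
#'
#' Annual burden in disability-adjusted life years: per uncertainty
#' iteration, the sum over severities of case counts times the disability
#' weight. No mortality term is modelled (no IDA fatality data), and the
#' disability duration is one year, so DALY equals annual YLD.
#'
#' @param cases Tibble from [severity_cases()].
#' @param weight_draws Matrix from [draw_disability_weights()] with the same
#'   number of rows.
#' @return Numeric DALY vector over uncertainty iterations.
#' @export
daly_burden <- function(cases, weight_draws) {
  stopifnot(nrow(cases) == nrow(weight_draws))
  cases$mild * weight_draws[, "mild"] +
    cases$moderate * weight_draws[, "moderate"] +
    cases$severe * weight_draws[, "severe"]
}

#' Convert ID prevalence into anaemia cases and DALY
#'
#' Applies the burden chain to a [run_mc2d()] result: IDA prevalence
#' (ID prevalence x per-stratum proportion), severity allocation from the
#' haemoglobin distribution, absolute and per-100,000 case counts, and DALY
#' with disability weights drawn once per uncertainty iteration and shared
#' across strata. National totals are accumulated per iteration and then
#' summarised, so the total's interval reflects the correlation induced by
#' the shared weights.
#'
#' @param prev An `iron_prevalence` tibble from [run_mc2d()].
#' @param params The `iron_parameters` the prevalences were computed from.
#' @param seed Seed for the disability-weight stream; defaults to the seed
#'   recorded on `prev`.
#' @return An object of class `iron_burden`; use [tidy()] for the
#'   per-stratum table, [glance()] for national totals, and
#'   [ggplot2::autoplot()] for a summary figure.
#' @export
compute_burden <- function(prev, params, seed = NULL) {
  stopifnot(inherits(prev, "iron_prevalence"), inherits(params, "iron_parameters"))
  seed <- seed %||% attr(prev, "seed") %||% 1L
  n_unc <- attr(prev, "n_unc") %||% length(prev$prev_id[[1]])
  denom <- params$total_population
  per100k <- 1e5 / denom

  s <- dplyr::left_join(
    prev, params$strata,
    by = c("gender", "age_class", "menstrual_status")
  )
  if (anyNA(s$population)) {
    stop("prevalence table contains strata absent from the parameter set",
      call. = FALSE)
  }

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(child_seeds(seed, 20)[20])
  w <- draw_disability_weights(params$weights, n_unc)

  alloc <- severity_allocation(
    s$hb_mean, s$hb_sd, s$thr_mild, s$thr_moderate, s$thr_severe
  )

  rows <- purrr::map(seq_len(nrow(s)), function(i) {
    v_id <- s$prev_id[[i]]
    if (length(v_id) != n_unc) {
      stop("uncertainty vectors have mismatched lengths", call. = FALSE)
    }
    v_ida <- ida_prevalence(v_id, s$prop_ida[i])
    cs <- severity_cases(s$population[i], v_ida, alloc[i, ])
    v_daly <- daly_burden(cs, w)
    cases_total <- cs$mild + cs$moderate + cs$severe
    sm <- function(x) summarise_uncertain(x)
    p_id <- sm(v_id); p_ida <- sm(v_ida)
    ck <- sm(cases_total * per100k); dk <- sm(v_daly * per100k)
    tibble::tibble(
      gender = s$gender[i], age_class = s$age_class[i],
      menstrual_status = s$menstrual_status[i],
      population = s$population[i], prop_ida = s$prop_ida[i],
      alloc_mild = alloc$mild[i], alloc_moderate = alloc$moderate[i],
      alloc_severe = alloc$severe[i],
      prev_id = list(v_id), prev_ida = list(v_ida),
      cases = list(cases_total), daly = list(v_daly),
      prev_id_mean = p_id$mean, prev_id_lo = p_id$lo, prev_id_hi = p_id$hi,
      prev_ida_mean = p_ida$mean, prev_ida_lo = p_ida$lo, prev_ida_hi = p_ida$hi,
      cases_mean = mean(cases_total),
      cases_per_100k_mean = ck$mean, cases_per_100k_lo = ck$lo,
      cases_per_100k_hi = ck$hi,
      cases_mild_per_100k_mean = mean(cs$mild) * per100k,
      cases_moderate_per_100k_mean = mean(cs$moderate) * per100k,
      cases_severe_per_100k_mean = mean(cs$severe) * per100k,
      daly_mean = mean(v_daly),
      daly_per_100k_mean = dk$mean, daly_per_100k_lo = dk$lo,
      daly_per_100k_hi = dk$hi,
      id_cases_per_100k_mean = mean(v_id) * s$population[i] * per100k
    )
  })
  strata <- dplyr::bind_rows(rows)

  sum_iter <- function(col) {
    Reduce(`+`, strata[[col]]) * per100k
  }
  totals <- list(
    id_cases_per_100k = Reduce(`+`, purrr::map2(
      strata$prev_id, strata$population, ~ .x * .y
    )) * per100k,
    ida_cases_per_100k = sum_iter("cases"),
    daly_per_100k = sum_iter("daly")
  )

  structure(
    list(
      strata = strata, totals = totals, weights = w,
      n_unc = n_unc, n_var = attr(prev, "n_var"),
      seed = seed, total_population = denom
    ),
    class = "iron_burden"
  )
}

#' National totals of a burden run
#'
#' Sums absolute ID cases, IDA cases and DALY across strata within each
#' uncertainty iteration, scales to the shared per-100,000 denominator, and
#' summarises (so the sum of stratum means equals the mean of the summed
#' vector exactly).
#'
#' @param burden An `iron_burden` object.
#' @return One-row tibble with mean/lo/hi for `id_cases_per_100k`,
#'   `ida_cases_per_100k` and `daly_per_100k`.
#' @export
aggregate_burden <- function(burden) {
  stopifnot(inherits(burden, "iron_burden"))
  out <- purrr::imap(burden$totals, function(v, nm) {
    sm <- summarise_uncertain(v)
    names(sm) <- paste0(nm, "_", names(sm))
    sm
  })
  dplyr::bind_cols(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname compute_burden
#' @method tidy iron_burden
#' @param x An `iron_burden` object.
#' @param ... Unused.
tidy.iron_burden <- function(x, ...) {
  dplyr::select(
    x$strata,
    -dplyr::all_of(c("prev_id", "prev_ida", "cases", "daly"))
  )
}

#' @export
#' @rdname compute_burden
#' @method glance iron_burden
glance.iron_burden <- function(x, ...) {
  dplyr::bind_cols(
    aggregate_burden(x),
    tibble::tibble(n_unc = x$n_unc, n_var = x$n_var %||% NA_integer_,
      seed = x$seed)
  )
}

#' @export
print.iron_burden <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0(
      "<iron_burden> %d strata, n_unc = %d, n_var = %s, seed = %s\n",
      "  ID cases  per 100,000: %8.0f (%0.0f-%0.0f)\n",
      "  IDA cases per 100,000: %8.0f (%0.0f-%0.0f)\n",
      "  DALY      per 100,000: %8.1f (%0.1f-%0.1f)\n"
    ),
    nrow(x$strata), x$n_unc, format(x$n_var), format(x$seed),
    g$id_cases_per_100k_mean, g$id_cases_per_100k_lo, g$id_cases_per_100k_hi,
    g$ida_cases_per_100k_mean, g$ida_cases_per_100k_lo, g$ida_cases_per_100k_hi,
    g$daly_per_100k_mean, g$daly_per_100k_lo, g$daly_per_100k_hi
  ))
  invisible(x)
}

#' Run the full baseline pipeline
#'
#' Convenience composition of [run_mc2d()] and [compute_burden()].
#'
#' @inheritParams run_mc2d
#' @return An `iron_burden` object.
#' @export
#' @examples
#' \donttest{
#' b <- run_pipeline(load_parameters(), n_unc = 100, n_var = 1000, seed = 1)
#' glance(b)
#' }
run_pipeline <- function(params, n_unc = 1000, n_var = 10000, seed = 1L,
                         samplers = NULL) {
  prev <- run_mc2d(params, n_unc = n_unc, n_var = n_var, seed = seed,
    samplers = samplers)
  compute_burden(prev, params, seed = seed)
}
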