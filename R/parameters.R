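#' Path to the packaged France parameter configuration
#'
#' The package ships the full model parameterisation for metropolitan France
#' (population counts, absorbed-intake lognormal parameters with 95% CIs,
#' normal requirement and haemoglobin distributions, iron-deficiency-to-IDA
#' proportions, anaemia severity thresholds, disability weights) as a JSON
#' document, with a flat CSV mirror alongside for human inspection.
#'
#' @return File path of the packaged JSON config.
#' @export
default_config <- function() {
  system.file("extdata", "france_iron_parameters.json",
    package = "irondaly", mustWork = TRUE
  )
}

#' Load and validate a model parameter set
#'
#' Reads a JSON parameter configuration and validates it: all 17 strata of
#' [stratum_grid()] present exactly once, positive standard deviations,
#' CI bounds bracketing point estimates, ordered severity thresholds,
#' proportions in \[0, 1\], haemoglobin means in a physiological range.
#' Any violation is a hard error naming the offending stratum and field.
#'
#' @param path Path to a JSON config; defaults to the packaged France set.
#' @return An object of class `iron_parameters`: a list with
#'   \describe{
#'     \item{strata}{17-row tibble of per-stratum inputs (population, intake
#'       `meanlog`/`sdlog` with `_lo`/`_hi` CI bounds, `req_mean`/`req_sd`,
#'       `prop_ida`, `hb_mean`/`hb_sd`, `thr_mild`/`thr_moderate`/`thr_severe}
#'     \item{weights}{3-row tibble of disability weights (severity, mean, sd)}
#'     \item{absorption}{named list of absorption coefficients}
#'     \item{total_population}{reference denominator for per-100,000 rates}
#'   }
#' @export
#' @examples
#' params <- load_parameters()
#' params$strata
load_parameters <- function(path = default_config()) {
  if (!file.exists(path)) {
    stop("parameter config not found: ", path, call. = FALSE)
  }
  cfg <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse parameter config '", path, "': ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  for (field in c(
    "total_reference_population", "absorption_coefficients",
    "disability_weights", "strata"
  )) {
    if (is.null(cfg[[field]])) {
      stop("parameter config is missing field '", field, "'", call. = FALSE)
    }
  }
  strata <- purrr::map_dfr(cfg$strata, function(s) {
    tibble::tibble(
      gender = s$gender,
      age_class = s$age_class,
      menstrual_status = s$menstrual_status,
      population = as.numeric(s$population),
      meanlog = s$intake$meanlog,
      meanlog_lo = s$intake$meanlog_ci[[1]],
      meanlog_hi = s$intake$meanlog_ci[[2]],
      sdlog = s$intake$sdlog,
      sdlog_lo = s$intake$sdlog_ci[[1]],
      sdlog_hi = s$intake$sdlog_ci[[2]],
      req_mean = s$requirement$mean,
      req_sd = s$requirement$sd,
      prop_ida = s$prop_ida,
      hb_mean = s$hemoglobin$mean,
      hb_sd = s$hemoglobin$sd,
      thr_mild = s$thresholds$mild,
      thr_moderate = s$thresholds$moderate,
      thr_severe = s$thresholds$severe
    )
  })
  weights <- purrr::map_dfr(cfg$disability_weights, tibble::as_tibble)
  params <- structure(
    list(
      strata = strata,
      weights = weights,
      absorption = cfg$absorption_coefficients,
      total_population = as.numeric(cfg$total_reference_population)
    ),
    class = "iron_parameters"
  )
  validate_parameters(params)
  params
}

#' @rdname load_parameters
#' @param params An `iron_parameters` object.
#' @export
validate_parameters <- function(params) {
  s <- params$strata
  fail <- function(...) stop(..., call. = FALSE)
  grid <- stratum_grid()
  key <- function(d) paste(d$gender, d$age_class, d$menstrual_status)
  missing <- setdiff(key(grid), key(s))
  if (length(missing) > 0) {
    fail("parameter set incomplete; missing strata: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(key(s), key(grid))
  if (length(extra) > 0 || nrow(s) != 17) {
    fail("parameter set has unknown or duplicated strata: ",
         paste(c(extra, if (nrow(s) != 17) "(17 strata required)"),
               collapse = ", "))
  }
  lab <- key(s)
  chk <- function(ok, what) {
    if (any(!ok)) fail(what, " for stratum ", lab[which(!ok)[1]])
  }
  chk(s$population > 0, "population must be positive")
  chk(s$sdlog > 0, "sdlog must be positive")
  chk(s$meanlog_lo <= s$meanlog & s$meanlog <= s$meanlog_hi,
      "meanlog CI must bracket the point estimate")
  chk(s$sdlog_lo <= s$sdlog & s$sdlog <= s$sdlog_hi,
      "sdlog CI must bracket the point estimate")
  chk(s$req_mean > 0 & s$req_sd > 0, "requirement mean and sd must be positive")
  chk(s$prop_ida >= 0 & s$prop_ida <= 1, "prop_ida must be in [0, 1]")
  chk(s$hb_mean >= 10 & s$hb_mean <= 20, "hb_mean must lie in [10, 20] g/dL")
  chk(s$hb_sd > 0, "hb_sd must be positive")
  chk(s$thr_severe < s$thr_moderate & s$thr_moderate < s$thr_mild,
      "severity thresholds must be ordered severe < moderate < mild")
  w <- params$weights
  if (!identical(w$severity, c("mild", "moderate", "severe"))) {
    fail("disability weights must list severities mild, moderate, severe in order")
  }
  if (any(w$sd <= 0) || any(w$mean < 0 | w$mean > 1)) {
    fail("disability weight means must be in [0, 1] with positive sd")
  }
  if (is.unsorted(w$mean, strictly = TRUE)) {
    fail("disability weight means must increase with severity")
  }
  if (!is.numeric(params$total_population) || params$total_population <= 0) {
    fail("total_reference_population must be a positive number")
  }
  invisible(params)
}

#' Reference population denominator
#'
#' The denominator used for all per-100,000 rates. The model covers ages
#' 3-74 and excludes pregnant women, so the stratum populations sum to less
#' than this national reference count (default 61.8 million, metropolitan
#' France 2007); rates are nevertheless expressed per 100,000 of the whole
#' population, matching how the national estimates are reported.
#'
#' @param params An `iron_parameters` object.
#' @return Number of persons.
#' @export
#' @examples
#' total_population(load_parameters())
total_population <- function(params) {
  stopifnot(inherits(params, "iron_parameters"))
  params$total_population
}

#' Write a parameter set back to JSON (round-trip safe)
#'
#' @param params An `iron_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "iron_parameters"))
  s <- params$strata
  strata <- purrr::map(seq_len(nrow(s)), function(i) {
    r <- s[i, ]
    list(
      gender = r$gender, age_class = r$age_class,
      menstrual_status = r$menstrual_status,
      population = r$population,
      intake = list(
        meanlog = r$meanlog, meanlog_ci = c(r$meanlog_lo, r$meanlog_hi),
        sdlog = r$sdlog, sdlog_ci = c(r$sdlog_lo, r$sdlog_hi)
      ),
      requirement = list(mean = r$req_mean, sd = r$req_sd),
      prop_ida = r$prop_ida,
      hemoglobin = list(mean = r$hb_mean, sd = r$hb_sd),
      thresholds = list(
        mild = r$thr_mild, moderate = r$thr_moderate,
        severe = r$thr_severe
      )
    )
  })
  cfg <- list(
    total_reference_population = params$total_population,
    absorption_coefficients = params$absorption,
    disability_weights = purrr::map(
      seq_len(nrow(params$weights)),
      function(i) as.list(params$weights[i, ])
    ),
    strata = strata
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Flat CSV export of a parameter set
#'
#' @inheritParams write_parameters
#' @export
write_parameters_csv <- function(params, path) {
  stopifnot(inherits(params, "iron_parameters"))
  out <- params$strata |>
    dplyr::rename(status = "menstrual_status", pop = "population")
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
#' @method as_tibble iron_parameters
as_tibble.iron_parameters <- function(x, ...) x$strata

#' @export
print.iron_parameters <- function(x, ...) {
  cat("<iron_parameters> ", nrow(x$strata), " strata, reference population ",
    format(x$total_population, big.mark = ","), "\n",
    sep = ""
  )
  print(x$strata, n = 5)
  invisible(x)
}
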