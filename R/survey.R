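#' Read or write individual dietary-survey records
#'
#' The survey CSV dialect has one row per person with columns `person_id`,
#' `age`, `sex` (`male`/`female`), `pregnant` and `menopausal`
#' (`yes`/`no`/`unknown`/`not_applicable`), `iron_mg_day` (total dietary
#' iron), `red_meat_g_day` (cooked-equivalent unprocessed red meat) and
#' `red_meat_iron_mg_day` (iron contributed by red meat).
#'
#' @param path CSV file path.
#' @return A tibble of survey records.
#' @export
read_survey <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      pregnant = readr::col_character(),
      menopausal = readr::col_character(),
      iron_mg_day = readr::col_double(),
      red_meat_g_day = readr::col_double(),
      red_meat_iron_mg_day = readr::col_double()
    )
  )
}

#' @rdname read_survey
#' @param records Tibble of survey records.
#' @export
write_survey <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Resolve missing pregnancy/menopause answers
#'
#' Applies the status decision table to female records, in order:
#' \enumerate{
#'   \item under 18, women are considered not pregnant;
#'   \item menopausal unknown with pregnancy negative: menopausal if aged
#'     over 50 (average menopause age), premenopausal otherwise;
#'   \item pregnancy unknown with menopausal negative (or unresolved at 50
#'     or under): considered pregnant;
#'   \item pregnancy unknown with menopausal positive: not pregnant;
#'   \item pregnant women are excluded from the analysis.
#' }
#' Male records pass through untouched. A contradictory record (pregnant and
#' menopausal both "yes") raises a warning and is excluded. The operation is
#' idempotent.
#'
#' @param records Tibble of survey records (see [read_survey()]).
#' @return `records` with resolved `pregnant`/`menopausal` columns plus
#'   logical `excluded` and character `exclusion_reason`.
#' @export
impute_status <- function(records) {
  r <- records
  if (!"excluded" %in% names(r)) r$excluded <- FALSE
  if (!"exclusion_reason" %in% names(r)) r$exclusion_reason <- NA_character_
  f <- r$sex == "female"

  # minors: not pregnant; menstrual status is decided by age alone
  minor <- f & r$age < 18
  r$pregnant[minor & r$pregnant == "unknown"] <- "no"

  adult <- f & r$age >= 18
  contradiction <- adult & r$pregnant == "yes" & r$menopausal == "yes"
  if (any(contradiction)) {
    warning(sum(contradiction), " record(s) both pregnant and menopausal; excluded")
    r$excluded[contradiction] <- TRUE
    r$exclusion_reason[contradiction] <- "contradictory_status"
  }
  ok <- adult & !contradiction

  # menopausal unknown, pregnancy negative: decide from age (menopause at ~50)
  i <- ok & r$menopausal == "unknown" & r$pregnant == "no"
  r$menopausal[i] <- ifelse(r$age[i] > 50, "yes", "no")

  # pregnancy unknown, menopausal negative: considered pregnant
  i <- ok & r$pregnant == "unknown" & r$menopausal == "no"
  r$pregnant[i] <- "yes"
  # pregnancy unknown, menopausal positive: menopausal women are not pregnant
  i <- ok & r$pregnant == "unknown" & r$menopausal == "yes"
  r$pregnant[i] <- "no"

  # both unresolved: over 50 assumed menopausal (hence not pregnant);
  # 50 or under assumed premenopausal with pregnancy still open, which the
  # pregnancy rule then resolves to pregnant
  i <- ok & r$pregnant == "unknown" & r$menopausal == "unknown"
  over50 <- i & r$age > 50
  r$menopausal[over50] <- "yes"
  r$pregnant[over50] <- "no"
  under <- i & r$age <= 50
  r$menopausal[under] <- "no"
  r$pregnant[under] <- "yes"

  preg <- f & r$pregnant == "yes" & !r$excluded
  r$excluded[preg] <- TRUE
  r$exclusion_reason[preg] <- "pregnant"
  r
}

#' Mean dietary iron absorption coefficient
#'
#' Fraction of ingested iron absorbed, as used to put survey intakes on the
#' absorbed scale: 10% for children under 11, 16% for adolescents (both
#' sexes, 12-17) and adult males, 18% for adult females.
#'
#' @param age Ages in years (minimum 3).
#' @param sex `"male"` or `"female"`, recycled.
#' @return Numeric vector of fractions.
#' @export
#' @examples
#' absorption_coefficient(c(8, 15, 35), c("male", "female", "female"))
absorption_coefficient <- function(age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  if (any(age < 3)) {
    stop("absorption coefficients are defined for ages 3 and over", call. = FALSE)
  }
  dplyr::case_when(
    age <= 11 ~ 0.10,
    age <= 17 ~ 0.16,
    sex == "male" ~ 0.16,
    TRUE ~ 0.18
  )
}

#' Absorbed daily iron per record
#'
#' Adds an `absorbed_mg_day` column: total dietary iron times the age/sex
#' absorption coefficient.
#'
#' @param records Tibble of survey records.
#' @return `records` with `absorbed_mg_day` added.
#' @export
absorbed_intake <- function(records) {
  records |>
    dplyr::mutate(
      absorbed_mg_day = .data$iron_mg_day *
        absorption_coefficient(.data$age, .data$sex)
    )
}

#' Maximum-likelihood lognormal fit
#'
#' Closed-form MLE for a lognormal sample: `meanlog` is the mean of the log
#' values and `sdlog` their population (divisor n) standard deviation.
#'
#' @param x Positive intake values (mg/day).
#' @param floor Minimum sample size accepted for fitting.
#' @param label Optional stratum label used in error messages.
#' @return A list with `meanlog`, `sdlog` and `n`.
#' @export
#' @examples
#' fit_lognormal(c(1, exp(2))) # meanlog 1, sdlog 1
fit_lognormal <- function(x, floor = 2, label = NULL) {
  tag <- if (is.null(label)) "" else paste0(" [", label, "]")
  if (length(x) < floor) {
    stop("need at least ", floor, " observations to fit", tag, call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all intake values must be positive and finite", tag, call. = FALSE)
  }
  lx <- log(x)
  sdlog <- sqrt(mean((lx - mean(lx))^2))
  if (sdlog == 0) {
    stop("degenerate sample: zero variance on the log scale", tag, call. = FALSE)
  }
  list(meanlog = mean(lx), sdlog = sdlog, n = length(x))
}

#' Lognormal fit with nonparametric bootstrap uncertainty
#'
#' Resamples the data with replacement `B` times, refits the lognormal MLE
#' on each resample, and reports percentile 95% intervals for both
#' parameters. The replicate pairs are kept so they can feed the outer
#' (uncertainty) dimension of the second-order Monte Carlo via
#' [sampler_bootstrap()].
#'
#' @inheritParams fit_lognormal
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed; the same seed reproduces identical replicates.
#' @param min_n Minimum sample size accepted for fitting (default 30).
#' @return An object of class `fitted_intake`: list with the point fit
#'   (`meanlog`, `sdlog`, `n`), `replicates` (a `B`-row tibble) and `ci`
#'   (percentile bounds per parameter).
#' @export
bootstrap_fit <- function(x, B = 1000, seed = 1L, min_n = 30, label = NULL) {
  stopifnot(B >= 1)
  point <- fit_lognormal(x, floor = min_n, label = label)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(x)
  lx <- log(x)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  failed <- 0L
  reps <- purrr::map_dfr(seq_len(B), function(b) {
    lb <- lx[idx[, b]]
    s <- sqrt(mean((lb - mean(lb))^2))
    if (s == 0) {
      failed <<- failed + 1L
      return(tibble::tibble(meanlog = NA_real_, sdlog = NA_real_))
    }
    tibble::tibble(meanlog = mean(lb), sdlog = s)
  })
  if (failed > 0.05 * B) {
    stop("more than 5% of bootstrap replicates failed to fit", call. = FALSE)
  }
  reps <- tidyr::drop_na(reps)
  ci <- tibble::tibble(
    parameter = c("meanlog", "sdlog"),
    lo = c(
      stats::quantile(reps$meanlog, 0.025, names = FALSE),
      stats::quantile(reps$sdlog, 0.025, names = FALSE)
    ),
    hi = c(
      stats::quantile(reps$meanlog, 0.975, names = FALSE),
      stats::quantile(reps$sdlog, 0.975, names = FALSE)
    )
  )
  structure(
    list(
      meanlog = point$meanlog, sdlog = point$sdlog, n = point$n,
      replicates = reps, ci = ci, B = B, seed = seed
    ),
    class = "fitted_intake"
  )
}

#' @export
print.fitted_intake <- function(x, ...) {
  cat(sprintf(
    "<fitted_intake> LogN(%.3f, %.3f), n = %d, %d bootstrap replicates\n",
    x$meanlog, x$sdlog, x$n, nrow(x$replicates)
  ))
  invisible(x)
}

#' Fit per-stratum absorbed-intake distributions from survey records
#'
#' Full survey ingestion: impute statuses, drop excluded (pregnant or
#' contradictory) records, map to strata, convert to absorbed intake, and
#' fit a bootstrap lognormal per stratum.
#'
#' @param records Tibble of survey records.
#' @param B Bootstrap replicates per stratum.
#' @param seed Root seed; each stratum gets a deterministic child stream.
#' @param min_n Minimum records per stratum for fitting.
#' @return Tibble with stratum fields, `n_records`, `meanlog`, `sdlog` and a
#'   `fit` list-column of `fitted_intake` objects.
#' @export
fit_survey <- function(records, B = 1000, seed = 1L, min_n = 30) {
  prepared <- records |>
    impute_status() |>
    dplyr::filter(!.data$excluded) |>
    assign_stratum() |>
    dplyr::filter(!is.na(.data$age_class)) |>
    absorbed_intake()
  grp <- prepared |>
    dplyr::group_by(.data$gender, .data$age_class, .data$menstrual_status) |>
    dplyr::summarise(values = list(.data$absorbed_mg_day), .groups = "drop")
  seeds <- child_seeds(seed, nrow(grp))
  labels <- paste(grp$gender, grp$age_class, grp$menstrual_status)
  grp |>
    dplyr::mutate(
      fit = purrr::pmap(
        list(.data$values, seeds, labels),
        function(v, s, lab) bootstrap_fit(v, B = B, seed = s, min_n = min_n, label = lab)
      ),
      n_records = purrr::map_int(.data$values, length),
      meanlog = purrr::map_dbl(.data$fit, "meanlog"),
      sdlog = purrr::map_dbl(.data$fit, "sdlog")
    ) |>
    dplyr::select(-"values")
}
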