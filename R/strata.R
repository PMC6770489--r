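#' The stratum grid of the model
#'
#' The model's unit of analysis is the stratum: gender x age class x
#' menstrual/menopausal status. Males carry a merged 12-17 adolescent class;
#' females split adolescence into 12-14 (assumed non-menstruating, mean
#' menarcheal age 13 in France) and 15-17 (assumed menstruating, adult-female
#' iron needs). Menstruating and menopausal women coexist in the 25-44 and
#' 45-64 classes; from 65 onwards all women are considered menopausal.
#' Exactly 17 strata result: 7 male, 7 premenopausal female, 3 postmenopausal
#' female.
#'
#' @return A 17-row tibble with columns `gender`, `age_class` and
#'   `menstrual_status`.
#' @export
#' @examples
#' stratum_grid()
stratum_grid <- function() {
  tibble::tibble(
    gender = c(rep("male", 7), rep("female", 10)),
    age_class = c(
      "3-6", "7-11", "12-17", "18-24", "25-44", "45-64", "65-74",
      "3-6", "7-11", "12-14", "15-17", "18-24", "25-44", "45-64",
      "25-44", "45-64", "65-74"
    ),
    menstrual_status = c(
      rep("not_applicable", 7),
      rep("premenopausal", 7),
      rep("postmenopausal", 3)
    )
  )
}

male_age_classes <- c("3-6", "7-11", "12-17", "18-24", "25-44", "45-64", "65-74")
female_age_classes <- c("3-6", "7-11", "12-14", "15-17", "18-24", "25-44", "45-64", "65-74")

age_class_bounds <- function(age_class) {
  parts <- strsplit(age_class, "-", fixed = TRUE)
  lo <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  hi <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  cbind(lo = lo, hi = hi)
}

#' Map an age to its model age class
#'
#' Vectorised over `age` and `sex`. Males use the merged 12-17 class;
#' females use 12-14 and 15-17. Ages outside 3-74 fall outside the model and
#' return `NA`.
#'
#' @param age Integer ages in years.
#' @param sex `"male"` or `"female"`, recycled against `age`.
#' @return Character vector of age-class labels (or `NA`).
#' @export
#' @examples
#' age_to_class(c(5, 13, 13), c("male", "male", "female"))
age_to_class <- function(age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  out <- rep(NA_character_, n)
  cuts <- function(a, classes) {
    b <- age_class_bounds(classes)
    idx <- vapply(a, function(x) {
      w <- which(x >= b[, "lo"] & x <= b[, "hi"])
      if (length(w) == 1) w else NA_integer_
    }, integer(1))
    classes[idx]
  }
  out[sex == "male"] <- cuts(age[sex == "male"], male_age_classes)
  out[sex == "female"] <- cuts(age[sex == "female"], female_age_classes)
  out
}

#' Assign survey records to model strata
#'
#' Maps imputed records onto the stratum grid: age class via
#' [age_to_class()]; menstrual status from the (resolved) menopausal answer
#' for women aged 25-64, forced premenopausal below 25 and postmenopausal at
#' 65-74. Records outside the 3-74 age range, or flagged excluded, get `NA`
#' stratum fields.
#'
#' @param records Tibble of survey records (see [read_survey()] for the
#'   column dialect), normally after [impute_status()].
#' @return `records` with `age_class` and `menstrual_status` columns added.
#' @export
assign_stratum <- function(records) {
  records |>
    dplyr::mutate(
      gender = .data$sex,
      age_class = age_to_class(.data$age, .data$sex),
      menstrual_status = dplyr::case_when(
        is.na(.data$age_class) ~ NA_character_,
        .data$sex == "male" ~ "not_applicable",
        .data$age < 25 ~ "premenopausal",
        .data$age_class == "65-74" ~ "postmenopausal",
        .data$menopausal == "yes" ~ "postmenopausal",
        TRUE ~ "premenopausal"
      )
    )
}
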