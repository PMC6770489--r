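test_that("status imputation reproduces the hand-worked decision table", {
  worked <- readr::read_csv(
    system.file("extdata", "imputation_worked_examples.csv",
      package = "irondaly", mustWork = TRUE
    ),
    show_col_types = FALSE
  )
  input <- dplyr::select(worked, -dplyr::starts_with("expected_"))
  expect_warning(out <- impute_status(input), "pregnant and menopausal")
  expect_equal(out$pregnant, worked$expected_pregnant)
  expect_equal(out$menopausal, worked$expected_menopausal)
  expect_equal(out$excluded, worked$expected_excluded)
  # pregnant exclusions are labelled as such
  expect_true(all(
    out$exclusion_reason[out$excluded & out$pregnant == "yes" &
      out$menopausal != "yes"] == "pregnant"
  ))
})

test_that("status imputation is idempotent and leaves males untouched", {
  spec <- generator_spec(params_france, n_per_stratum = 150)
  rec <- generate_survey(spec, seed = 7)
  once <- impute_status(rec)
  twice <- impute_status(once)
  expect_equal(twice, once)
  males <- dplyr::filter(rec, sex == "male")
  out <- impute_status(males)
  expect_equal(out$pregnant, males$pregnant)
  expect_equal(out$menopausal, males$menopausal)
  expect_false(any(out$excluded))
})

test_that("absorption coefficients follow the age/sex schedule", {
  expect_equal(absorption_coefficient(8, "male"), 0.10)
  expect_equal(absorption_coefficient(8, "female"), 0.10)
  expect_equal(absorption_coefficient(15, "female"), 0.16)
  expect_equal(absorption_coefficient(15, "male"), 0.16)
  expect_equal(absorption_coefficient(35, "male"), 0.16)
  expect_equal(absorption_coefficient(35, "female"), 0.18)
  expect_equal(absorption_coefficient(70, "female"), 0.18)
  expect_error(absorption_coefficient(2, "male"), "ages 3 and over")
  # absorbed intake is monotone in total intake
  r <- make_record(35, "female", iron = c(5, 10, 20))
  r$person_id <- paste0("p", 1:3)
  expect_true(!is.unsorted(absorbed_intake(r)$absorbed_mg_day))
})

test_that("lognormal MLE has the closed form and recovers parameters", {
  fit <- fit_lognormal(c(1, exp(2)))
  expect_equal(fit$meanlog, 1)
  expect_equal(fit$sdlog, 1)

  expect_error(fit_lognormal(rep(exp(1), 4)), "degenerate")
  expect_error(fit_lognormal(c(1, 2, -1)), "positive")
  expect_error(fit_lognormal(c(1, 2), floor = 30), "at least 30")

  set.seed(42)
  x <- rlnorm(10000, 0.52, 0.37)
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$meanlog - 0.52), 0.02)
  expect_lt(abs(fit$sdlog - 0.37), 0.02)
})

test_that("MLE agrees with an independent fitting routine", {
  skip_if_not_installed("fitdistrplus")
  set.seed(9)
  x <- rlnorm(500, -0.21, 0.31)
  ours <- fit_lognormal(x)
  ref <- fitdistrplus::fitdist(x, "lnorm", method = "mle")
  expect_equal(ours$meanlog, unname(ref$estimate["meanlog"]), tolerance = 1e-5)
  expect_equal(ours$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-4)
})

test_that("bootstrap fitting is deterministic and covers the truth", {
  set.seed(3)
  x <- rlnorm(5000, -0.21, 0.31)
  f1 <- bootstrap_fit(x, B = 300, seed = 11)
  f2 <- bootstrap_fit(x, B = 300, seed = 11)
  expect_equal(f1$replicates, f2$replicates)

  ci <- f1$ci
  expect_true(ci$lo[1] <= -0.21 && -0.21 <= ci$hi[1])
  expect_true(ci$lo[2] <= 0.31 && 0.31 <= ci$hi[2])

  # B = 1: degenerate interval equal to the single replicate
  f3 <- bootstrap_fit(x, B = 1, seed = 5)
  expect_equal(f3$ci$lo, f3$ci$hi)
  expect_equal(f3$ci$lo[1], f3$replicates$meanlog[1])
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(8)
  x_big <- rlnorm(2000, 0.4, 0.36)
  width <- function(x) {
    f <- bootstrap_fit(x, B = 400, seed = 21)
    f$ci$hi[1] - f$ci$lo[1]
  }
  w_small <- width(x_big[1:500])
  w_big <- width(x_big)
  # n grows 4x, width should drop ~2x; allow generous slack
  expect_gt(w_small / w_big, 1.4)
  expect_lt(w_small / w_big, 2.9)
})

test_that("survey fitting maps records to strata and fits each one", {
  spec <- generator_spec(params_france, n_per_stratum = 400)
  rec <- generate_survey(spec, seed = 2)
  fits <- fit_survey(rec, B = 50, seed = 4)
  expect_equal(nrow(fits), 17)
  expect_setequal(stratum_key(fits), stratum_key(params_france$strata))
  expect_true(all(fits$n_records > 300))
  expect_s3_class(fits$fit[[1]], "fitted_intake")
})
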