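test_that("generated surveys are reproducible byte-for-byte", {
  spec <- generator_spec(params_france, n_per_stratum = 120)
  r1 <- generate_survey(spec, seed = 5)
  r2 <- generate_survey(spec, seed = 5)
  expect_equal(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survey(r1, f1)
  write_survey(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  r3 <- generate_survey(spec, seed = 6)
  expect_false(identical(r1$iron_mg_day, r3$iron_mg_day))
})

test_that("generated records satisfy the record invariants", {
  rec <- generate_survey(generator_spec(params_france, n_per_stratum = 300),
    seed = 9
  )
  expect_equal(nrow(rec), 17 * 300)
  expect_true(all(rec$iron_mg_day > 0))
  expect_true(all(rec$red_meat_iron_mg_day >= 0))
  expect_true(all(rec$red_meat_iron_mg_day <= rec$iron_mg_day))
  expect_true(all(rec$age >= 3 & rec$age <= 74))
  males <- dplyr::filter(rec, sex == "male")
  expect_true(all(males$pregnant == "no"))
  expect_true(all(males$menopausal == "not_applicable"))
  # stratum coverage after imputation and assignment is the full grid
  strata <- rec |>
    impute_status() |>
    dplyr::filter(!excluded) |>
    assign_stratum()
  expect_setequal(
    unique(stratum_key(strata)),
    stratum_key(stratum_grid())
  )
})

test_that("with no injected unknowns the imputation is a no-op", {
  spec <- generator_spec(params_france,
    n_per_stratum = 200,
    unknown_menopausal_rate = 0, unknown_pregnant_rate = 0,
    pregnancy_rate = 0
  )
  rec <- generate_survey(spec, seed = 14)
  out <- impute_status(rec)
  expect_equal(out$pregnant, rec$pregnant)
  expect_equal(out$menopausal, rec$menopausal)
  expect_false(any(out$excluded))
})

test_that("injected unknowns are resolved back to the true stratum", {
  spec <- generator_spec(params_france,
    n_per_stratum = 400,
    unknown_menopausal_rate = 0.3, unknown_pregnant_rate = 0.3,
    pregnancy_rate = 0
  )
  rec <- generate_survey(spec, seed = 15)
  expect_gt(sum(rec$menopausal == "unknown"), 0)
  resolved <- rec |>
    impute_status() |>
    dplyr::filter(!excluded) |>
    assign_stratum()
  # the generator encodes the intended stratum in the person id
  intended <- sub("_[0-9]+$", "", resolved$person_id)
  observed <- paste0(
    substr(resolved$gender, 1, 1), "_", resolved$age_class, "_",
    substr(resolved$menstrual_status, 1, 4)
  )
  expect_equal(observed, intended)
})

test_that("absorbed-scale fits recover the published parameters", {
  spec <- generator_spec(params_france, n_per_stratum = 10000)
  rec <- generate_survey(spec, seed = 20)
  absorbed <- rec |>
    impute_status() |>
    dplyr::filter(!excluded) |>
    assign_stratum() |>
    absorbed_intake()
  target <- params_france$strata
  for (k in c(
    "male 3-6 not_applicable", "female 15-17 premenopausal",
    "female 45-64 postmenopausal"
  )) {
    sub <- absorbed[stratum_key(absorbed) == k, ]
    fit <- fit_lognormal(sub$absorbed_mg_day)
    t <- target[stratum_key(target) == k, ]
    expect_lt(abs(fit$meanlog - t$meanlog), 0.03)
    expect_lt(abs(fit$sdlog - t$sdlog), 0.03)
    # goodness of fit: KS distance against the target lognormal
    ks <- suppressWarnings(stats::ks.test(
      sub$absorbed_mg_day, "plnorm", t$meanlog, t$sdlog
    ))
    expect_lt(unname(ks$statistic), 0.025)
  }
})

test_that("infeasible red-meat settings are rejected with advice", {
  spec <- generator_spec(params_france,
    n_per_stratum = 200,
    red_meat_mean_g_day = c(children = 1e5, adolescents = 1e5, adults = 1e5)
  )
  expect_error(generate_survey(spec, seed = 1), "red-meat iron exceeds")
})

test_that("the end-to-end fixture pairs records with the packaged set", {
  fx <- end_to_end_fixture(seed = 3, n_per_stratum = 60)
  expect_s3_class(fx$params, "iron_parameters")
  expect_equal(nrow(fx$records), 17 * 60)
  fx2 <- end_to_end_fixture(seed = 3, n_per_stratum = 60)
  expect_equal(fx$records, fx2$records)
})
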