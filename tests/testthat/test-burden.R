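test_that("severity allocation matches hand-computed normal-CDF bands", {
  # adult premenopausal women 18-24: Hb N(13.5, 1.5), thresholds 11.9/10.9/8
  a <- severity_allocation(13.5, 1.5, 11.9, 10.9, 8.0)
  expect_equal(a$mild, 0.709787, tolerance = 1e-3)
  expect_equal(a$moderate, 0.289354, tolerance = 1e-3)
  expect_equal(a$severe, 0.000859, tolerance = 1e-3)

  # young boys: Hb N(12.8, 1.0), thresholds 10.9/9.9/7
  b <- severity_allocation(12.8, 1.0, 10.9, 9.9, 7.0)
  expect_equal(b$mild, 0.935027, tolerance = 1e-3)
  expect_equal(b$moderate, 0.064973, tolerance = 1e-3)
  expect_lt(b$severe, 1e-6)

  # fractions sum to one in every stratum of the packaged set
  s <- params_france$strata
  al <- severity_allocation(
    s$hb_mean, s$hb_sd, s$thr_mild, s$thr_moderate, s$thr_severe
  )
  expect_equal(al$mild + al$moderate + al$severe, rep(1, 17),
    tolerance = 1e-12
  )
  expect_true(all(al$anaemia > 0 & al$anaemia < 1))
})

test_that("a degenerate healthy population triggers the zero-anaemia path", {
  expect_warning(
    a <- severity_allocation(15, 1e-9, 11.9, 10.9, 8.0),
    "zero anaemia"
  )
  expect_equal(unlist(a[, c("mild", "moderate", "severe")]),
    c(mild = 0, moderate = 0, severe = 0)
  )
})

test_that("the prevalence-to-cases-to-DALY arithmetic is exact", {
  expect_equal(ida_prevalence(0.437, 0.5), 0.2185)
  v <- c(0.3, 0.4)
  expect_equal(ida_prevalence(v, 0), c(0, 0))
  expect_equal(ida_prevalence(v, 1), v)

  alloc <- tibble::tibble(mild = 1, moderate = 0, severe = 0)
  cs <- severity_cases(1000, c(0.1, 0.2), alloc)
  expect_equal(cs$mild, c(100, 200))
  expect_equal(cs$moderate + cs$severe, c(0, 0))

  # severity totals always recompose to population x prevalence
  alloc2 <- severity_allocation(13.4, 1.0, 11.9, 10.9, 8.0)
  cs2 <- severity_cases(1159862, c(0.2185, 0.25), alloc2)
  expect_equal(cs2$mild + cs2$moderate + cs2$severe, 1159862 * c(0.2185, 0.25))

  # degenerate weights: 1000 mild cases at weight 0.005 is exactly 5 DALY
  w <- matrix(rep(c(0.005, 0.058, 0.164), each = 2), ncol = 3)
  colnames(w) <- c("mild", "moderate", "severe")
  cs3 <- tibble::tibble(mild = c(1000, 1000), moderate = 0, severe = 0)
  expect_equal(daly_burden(cs3, w), c(5, 5))
})

test_that("weight draws are truncated, stratified and mean-accurate", {
  set.seed(10)
  w <- draw_disability_weights(params_france$weights, 1000)
  expect_true(all(w >= 0))
  expect_equal(colnames(w), c("mild", "moderate", "severe"))
  # stratified draws pin the stream means very close to the truncated-normal
  # expectations; for these parameters truncation shifts means by < 1e-4
  expect_equal(unname(colMeans(w)), c(0.005, 0.058, 0.164), tolerance = 0.01)
  expect_lt(abs(mean(w[, "moderate"]) - 0.058), 1e-3)
})

test_that("with all randomness degenerate the pipeline equals the closed form", {
  p0 <- degenerate_params(params_france)
  burden <- run_pipeline(p0,
    n_unc = 5, n_var = 10, seed = 99,
    samplers = point_samplers(p0)
  )
  oracle <- oracle_burden_closed_form(params_france)
  td <- tidy(burden)
  expect_equal(td$prev_id_mean, unname(oracle$per_stratum[, "prev_id"]),
    tolerance = 1e-12
  )
  expect_equal(td$cases_mean, unname(oracle$per_stratum[, "cases"]),
    tolerance = 1e-12
  )
  expect_equal(td$daly_mean, unname(oracle$per_stratum[, "daly"]),
    tolerance = 1e-12
  )
  g <- glance(burden)
  expect_equal(g$ida_cases_per_100k_mean, oracle$total_ida_per_100k,
    tolerance = 1e-12
  )
  expect_equal(g$daly_per_100k_mean, oracle$total_daly_per_100k,
    tolerance = 1e-12
  )
  # no spread anywhere
  expect_equal(g$daly_per_100k_lo, g$daly_per_100k_hi)

  # equation-chain consistency: cases x allocated mean weight = DALY
  w <- params_france$weights$mean
  mean_w <- td$alloc_mild * w[1] + td$alloc_moderate * w[2] +
    td$alloc_severe * w[3]
  expect_equal(td$cases_per_100k_mean * mean_w, td$daly_per_100k_mean,
    tolerance = 1e-12
  )
})

test_that("totals aggregate per iteration and match stratum sums", {
  b <- run_pipeline(params_france, n_unc = 40, n_var = 300, seed = 6)
  # mean of the summed vector equals the sum of stratum means
  expect_equal(
    mean(b$totals$ida_cases_per_100k),
    sum(tidy(b)$cases_per_100k_mean)
  )
  expect_equal(
    mean(b$totals$daly_per_100k),
    sum(tidy(b)$daly_per_100k_mean)
  )
  # per-100k of aggregated absolute cases equals aggregate of per-100k
  abs_total <- Reduce(`+`, b$strata$cases)
  expect_equal(
    summarise_uncertain(abs_total * 1e5 / total_population(params_france))$mean,
    glance(b)$ida_cases_per_100k_mean
  )
  # strata with no anaemia proportion contribute exactly zero
  zero_rows <- tidy(b) |> dplyr::filter(prop_ida == 0)
  expect_true(all(zero_rows$cases_per_100k_mean == 0))
  expect_true(all(zero_rows$daly_per_100k_mean == 0))
})
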