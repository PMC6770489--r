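# Shared fixtures: the packaged parameter set, loaded once per test run.
params_france <- load_parameters()

stratum_key <- function(d) paste(d$gender, d$age_class, d$menstrual_status)

# A minimal records tibble builder for targeted survey tests.
make_record <- function(age, sex, pregnant = "no",
                        menopausal = if (sex == "male") "not_applicable" else "no",
                        iron = 10, red_meat_g = 20, red_meat_iron = 0.4) {
  tibble::tibble(
    person_id = "p1", age = as.integer(age), sex = sex,
    pregnant = pregnant, menopausal = menopausal,
    iron_mg_day = iron, red_meat_g_day = red_meat_g,
    red_meat_iron_mg_day = red_meat_iron
  )
}

# Independent closed-form burden chain used as oracle when all randomness is
# degenerate: coded from the model definition (normal/lognormal CDFs and
# products only), deliberately without calling the package's burden
# functions.
oracle_burden_closed_form <- function(params) {
  s <- params$strata
  w <- params$weights$mean
  denom <- params$total_population
  per_stratum <- lapply(seq_len(nrow(s)), function(i) {
    r <- s[i, ]
    prev_id <- stats::pnorm((log(r$req_mean) - r$meanlog) / r$sdlog)
    prev_ida <- prev_id * r$prop_ida
    anaemia <- stats::pnorm((r$thr_mild - r$hb_mean) / r$hb_sd)
    f_sev <- stats::pnorm((r$thr_severe - r$hb_mean) / r$hb_sd) / anaemia
    f_mod <- (stats::pnorm((r$thr_moderate - r$hb_mean) / r$hb_sd) -
      stats::pnorm((r$thr_severe - r$hb_mean) / r$hb_sd)) / anaemia
    f_mil <- 1 - f_sev - f_mod
    cases <- r$population * prev_ida
    daly <- cases * (f_mil * w[1] + f_mod * w[2] + f_sev * w[3])
    c(prev_id = prev_id, cases = cases, daly = daly)
  })
  m <- do.call(rbind, per_stratum)
  list(
    per_stratum = m,
    total_ida_per_100k = sum(m[, "cases"]) * 1e5 / denom,
    total_daly_per_100k = sum(m[, "daly"]) * 1e5 / denom
  )
}

# Degenerate inputs: point intake samplers, zero requirement/weight spread.
degenerate_params <- function(params) {
  params$strata$req_sd <- 0
  params$weights$sd <- c(0, 0, 0)
  params
}

point_samplers <- function(params) {
  s <- params$strata
  out <- lapply(seq_len(nrow(s)), function(i) {
    sampler_point(s$meanlog[i], s$sdlog[i])
  })
  names(out) <- stratum_key(s)
  out
}
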