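test_that("organ-dose sampler matches configured moments and degenerates cleanly", {
  d <- sample_organ_doses(1e5, mean = 48.0, sd = 27.3, seed = 11)
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - 48.0) / 48.0, 0.01)
  d2 <- sample_organ_doses(1e5, mean = 21.5, sd = 13.5, seed = 12)
  expect_lt(abs(sd(d2) - 13.5) / 13.5, 0.02)
  expect_equal(sample_organ_doses(5, mean = 7, sd = 0), rep(7, 5))
  expect_error(sample_organ_doses(1, mean = 0, sd = 1), "mean")
  expect_error(sample_organ_doses(1, mean = 1, sd = -1), "sd")
})

test_that("registry generation is bit-reproducible and respects zero-probability flags", {
  cfg <- registry_config(n_patients = 400, seed = 42)
  expect_identical(generate_registry(cfg), generate_registry(cfg))

  cfg0 <- cfg
  cfg0$eol_prob$eol_prob <- 0
  cfg0$excluded_probs[] <- 0
  reg <- generate_registry(cfg0)
  expect_false(any(reg$last_year_of_life))
  expect_true(all(reg$excluded_reason == "none"))
  expect_true(all(reg$age_years >= 0 & reg$age_years <= 99))
  # categories consistent with life stage
  keys <- strata_keys()
  expect_true(all(paste(reg$sex, reg$age_group, reg$category) %in%
    paste(keys$sex, keys$age_group, keys$category)))
})

test_that("exams per patient match the configured mean within sampling error", {
  cfg <- registry_config(n_patients = 20000, seed = 5)
  cfg$exams_per_patient$mean_exams <- 1.5
  reg <- generate_registry(cfg)
  obs <- nrow(reg) / cfg$n_patients
  se <- sqrt(0.5 / cfg$n_patients) # var of 1 + Poisson(0.5)
  expect_lt(abs(obs - 1.5), 3 * se)
})

test_that("default national-mimic config yields ~3.3% pediatric exam share", {
  cfg <- registry_config(n_patients = 30000, seed = 9)
  reg <- generate_registry(cfg)
  share <- mean(reg$age_years < 18)
  se <- sqrt(0.033 * 0.967 / nrow(reg))
  expect_lt(abs(share - 0.033), 4 * se)
})

test_that("overall last-year-of-life fraction equals the exam-weighted average of the map", {
  cfg <- registry_config(n_patients = 20000, seed = 13)
  reg <- generate_registry(cfg)
  expected <- reg |>
    dplyr::left_join(cfg$eol_prob, by = c("sex", "age_group")) |>
    dplyr::pull(eol_prob) |>
    mean()
  obs <- mean(reg$last_year_of_life)
  # patient-level flag clusters within patients; bound SE by patient count
  se <- sqrt(expected * (1 - expected) / cfg$n_patients)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("a missing dose parameter names the offending stratum", {
  cfg <- registry_config(n_patients = 300, seed = 2)
  cfg$dose_params <- cfg$dose_params[cfg$dose_params$organ != "lung" |
    cfg$dose_params$category != "head_routine", ]
  expect_error(generate_registry(cfg), "head_routine.*lung")
})

test_that("registry round-trips through CSV", {
  cfg <- registry_config(n_patients = 100, seed = 3)
  reg <- generate_registry(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(reg, path)
  back <- read_registry_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(reg))
})

test_that("life tables satisfy survival-curve invariants and closed forms", {
  expect_equal(const_hazard_life_table(0)$survival, rep(1, 202))
  h <- 0.023
  lt <- generate_life_table("male", gompertz_scale = 0, gompertz_rate = 0, makeham = h)
  expect_equal(lt$survival, exp(-h * (0:100)), tolerance = 1e-12)
  for (s in sexes()) {
    lt <- generate_life_table(s)
    expect_equal(lt$survival[1], 1)
    expect_true(all(diff(lt$survival) < 0))
    expect_gt(lt$survival[101], 0)
    expect_true(lt$survival[101] < lt$survival[61] && lt$survival[61] < lt$survival[1])
  }
})

test_that("baseline incidence templates behave per site and sex", {
  expect_equal(generate_baseline_incidence("prostate", "female")$rate, rep(0, 101))
  expect_equal(generate_baseline_incidence("ovary", "male")$rate, rep(0, 101))
  flat <- generate_baseline_incidence("colon", "male", rate60 = 2e-3, exponent = 0)
  expect_equal(flat$rate, rep(2e-3, 101))
  lung <- generate_baseline_incidence("lung", "female")
  expect_gt(lung$rate[lung$age == 70], lung$rate[lung$age == 40])
  leuk <- default_baseline_incidence() |> dplyr::filter(site == "leukemia", sex == "male")
  expect_gt(leuk$rate[leuk$age == 0], leuk$rate[leuk$age == 20]) # childhood peak
  expect_error(generate_baseline_incidence("spleen", "male"), "valid sites")
})
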