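test_that("a single homogeneous stratum summarizes to proportion 1 with exact moments", {
  rec <- toy_records(24, dose = 10)
  s <- summarize_strata(rec)
  expect_equal(nrow(s), 1)
  expect_equal(s$proportion, 1)
  expect_equal(s$n_exams, 24)
  expect_equal(s$dose_mean_colon, 10)
  expect_equal(s$dose_sd_colon, 0)
})

test_that("strata under 12 exams are dropped and proportions renormalized", {
  rec <- dplyr::bind_rows(
    toy_records(11, category = "head_routine"),
    toy_records(100, category = "abdomen_pelvis_routine")
  )
  s <- summarize_strata(rec)
  expect_equal(s$category, "abdomen_pelvis_routine")
  expect_equal(s$proportion, 1)
  # at exactly 12 the stratum is retained
  rec2 <- dplyr::bind_rows(
    toy_records(12, category = "head_routine"),
    toy_records(100, category = "abdomen_pelvis_routine")
  )
  expect_equal(nrow(summarize_strata(rec2)), 2)
})

test_that("flagged records are excluded before summarization", {
  rec <- dplyr::bind_rows(
    toy_records(50, excluded_reason = "none"),
    toy_records(30, excluded_reason = "pet"),
    toy_records(30, excluded_reason = "biopsy_procedure")
  )
  expect_equal(summarize_strata(rec)$n_exams, 50)
  all_excl <- toy_records(20, excluded_reason = "research")
  expect_error(summarize_strata(all_excl), "exclusion")
})

test_that("per-stratum dose moments equal a brute-force group-by oracle", {
  cfg <- registry_config(n_patients = 2000, seed = 21)
  reg <- generate_registry(cfg)
  s <- summarize_strata(reg)
  expect_equal(sum(s$proportion), 1, tolerance = 1e-12)
  kept <- reg[reg$excluded_reason == "none", ]
  key <- paste(kept$sex, kept$age_group, kept$category)
  means <- tapply(kept$dose_colon_mGy, key, mean)
  sds <- tapply(kept$dose_colon_mGy, key, sd)
  skey <- paste(s$sex, s$age_group, s$category)
  expect_equal(as.numeric(means[skey]), s$dose_mean_colon)
  expect_equal(as.numeric(sds[skey]), s$dose_sd_colon)
})

test_that("retained proportions are invariant to duplicating every record", {
  cfg <- registry_config(n_patients = 1500, seed = 8)
  reg <- generate_registry(cfg)
  s1 <- summarize_strata(reg)
  s2 <- summarize_strata(dplyr::bind_rows(reg, reg))
  j <- dplyr::inner_join(s1, s2,
    by = c("sex", "age_group", "category"), suffix = c("_1", "_2")
  )
  # doubling can only add strata (11 -> 22 crosses the cutoff), never drop
  expect_equal(nrow(j), nrow(s1))
  expect_equal(
    j$proportion_1 / sum(j$proportion_1),
    j$proportion_2 / sum(j$proportion_2),
    tolerance = 1e-12
  )
})

test_that("exams per patient are exams over distinct patients", {
  one_each <- toy_records(10)
  expect_equal(estimate_exams_per_patient(one_each)$overall, 1)
  two <- toy_records(3, patient_id = c("A", "B", "B"))
  est <- estimate_exams_per_patient(two)
  expect_equal(est$overall, 1.5)
  expect_equal(est$by_group$mean_exams, 1.5)
})

test_that("largest-remainder apportionment conserves totals exactly", {
  w <- c(0.3331, 0.3331, 0.3338)
  x <- ctlar:::largest_remainder(w, 100)
  expect_equal(sum(x), 100)
  expect_true(all(abs(x - w / sum(w) * 100) < 1))
  set.seed(4)
  for (i in 1:20) {
    w <- runif(sample(2:50, 1))
    tot <- sample(1e6, 1)
    x <- ctlar:::largest_remainder(w, tot)
    expect_equal(sum(x), tot)
  }
})

test_that("national scaling allocates the pediatric share first, then proportions", {
  s <- toy_summary(
    sex = c("female", "female", "male"),
    age_group = c("5-9", "50-59", "50-59"),
    category = c("head_routine", "abdomen_pelvis_routine", "abdomen_pelvis_routine"),
    n_exams = c(50, 100, 100)
  )
  counts <- scale_to_national(s, 93e6, pediatric_share = 0.033)
  expect_equal(sum(counts$scaled_exams), 93e6)
  child <- counts$scaled_exams[counts$age_group == "5-9"]
  expect_equal(child, 3069000)
  # equal adult proportions split the remainder evenly
  adult <- counts$scaled_exams[counts$age_group == "50-59"]
  expect_equal(adult[1], adult[2])

  two <- toy_summary(
    sex = c("female", "male"), age_group = "50-59",
    category = "abdomen_pelvis_routine", n_exams = c(50, 50)
  )
  c2 <- scale_to_national(two, 100, pediatric_share = 0)
  expect_equal(c2$scaled_exams, c(50, 50))
  expect_error(
    scale_to_national(two, 100, pediatric_share = 0.1),
    "no pediatric strata"
  )
})

test_that("scaled stratum counts conserve total volume for arbitrary mixes", {
  cfg <- registry_config(n_patients = 20000, seed = 31)
  s <- summarize_strata(generate_registry(cfg))
  counts <- scale_to_national(s, 93e6, 0.033)
  expect_equal(sum(counts$scaled_exams), 93e6)
  expect_equal(attr(counts, "total_exams"), 93e6)
})

test_that("end-of-life exclusion reduces counts by the configured fractions", {
  s <- toy_summary(
    sex = c("female", "male"), age_group = "50-59",
    category = "abdomen_pelvis_routine", n_exams = c(60, 40)
  )
  counts <- scale_to_national(s, 93e6, pediatric_share = 0)

  zero <- default_eol_prob()
  zero$eol_prob <- 0
  c0 <- apply_eol_exclusion(counts, zero)
  expect_equal(c0$included_exams, as.numeric(c0$scaled_exams))

  flat <- default_eol_prob()
  flat$eol_prob <- 0.106
  c1 <- apply_eol_exclusion(counts, flat)
  expect_equal(attr(c1, "total_included"), 83142000)

  # cell-specific map equals the brute-force weighted average
  eol <- default_eol_prob()
  c2 <- apply_eol_exclusion(counts, eol)
  j <- dplyr::left_join(counts, eol, by = c("sex", "age_group"))
  expect_equal(
    attr(c2, "total_eol_excluded"),
    sum(j$scaled_exams * j$eol_prob)
  )

  expect_error(
    apply_eol_exclusion(counts, eol[eol$sex == "female", ]),
    "male.*50-59"
  )
})
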