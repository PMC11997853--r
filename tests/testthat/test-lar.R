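test_that("zero dose gives zero LAR for every site, sex and draw", {
  draws <- sample_uncertainty(n_draws = 25, seed = 2)
  for (site in c("lung", "thyroid", "leukemia", "breast")) {
    for (s in sexes()) {
      expect_equal(lar_site(0, 10, s, site, draws = draws), rep(0, 25))
    }
  }
})

test_that("toy configuration reduces to the closed form lambda * D * (100 - e)", {
  lt <- const_hazard_life_table(0)
  lam <- 2e-3
  bl <- const_baseline(lam)
  rc <- zeroed_risk_config(list(stomach = list(
    beta_err = 1, gamma_err = 0, eta_err = 0, transfer_weight = 1
  )))
  d <- fixed_draw(rc, ddref = 1, mu = -1000) # weight == 1, DDREF 1
  for (e in c(0, 20, 55, 99)) {
    lar <- lar_site(0.5, e, "male", "stomach",
      life_table = lt, baseline = bl,
      risk_config = rc, draws = d
    )
    expect_equal(lar, lam * 0.5 * (100 - e), tolerance = 1e-12)
  }
  # LAR at the end of the horizon is zero
  expect_equal(
    lar_site(0.5, 100, "male", "stomach",
      life_table = lt, baseline = bl, risk_config = rc, draws = d
    ), 0
  )
})

test_that("lar_site agrees with the independent summation oracle on random configurations", {
  set.seed(17)
  lt <- default_life_tables()
  bl <- default_baseline_incidence()
  lc <- default_latency_config()
  for (i in 1:10) {
    site <- sample(cancer_sites(), 1)
    sex <- sample(sexes(), 1)
    rc <- default_risk_config()
    j <- rc$site == site
    rc$beta_err[j] <- runif(1, 0, 2)
    rc$beta_ear[j] <- runif(1, 0, 5)
    e <- runif(1, 0, 95)
    dgy <- runif(1, 0, 0.2)
    got <- lar_site(dgy, e, sex, site,
      life_table = lt, baseline = bl,
      risk_config = rc, latency_config = lc
    )
    want <- lar_oracle(dgy, e, sex, site, lt, bl, rc, lc, ddref = 1.5)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("solid LAR is exactly proportional to dose; leukemia is super-linear", {
  lar1 <- lar_site(0.05, 30, "female", "colon")
  lar2 <- lar_site(0.10, 30, "female", "colon")
  expect_equal(lar2, 2 * lar1, tolerance = 1e-12)
  l1 <- lar_site(0.5, 30, "female", "leukemia")
  l2 <- lar_site(1.0, 30, "female", "leukemia")
  expect_gt(l2, 2 * l1)
})

test_that("sites not applicable to a sex return zero, not an error", {
  expect_equal(lar_site(0.1, 40, "female", "prostate"), 0)
  expect_equal(lar_site(0.1, 40, "male", "ovary"), 0)
  expect_equal(lar_site(0.1, 40, "male", "breast"), 0)
})

test_that("increasing DDREF decreases solid LAR and leaves leukemia unchanged", {
  rc <- default_risk_config()
  d1 <- fixed_draw(rc, ddref = 1, mu = 7.5)
  d2 <- fixed_draw(rc, ddref = 2, mu = 7.5)
  s1 <- lar_site(0.1, 30, "male", "colon", risk_config = rc, draws = d1)
  s2 <- lar_site(0.1, 30, "male", "colon", risk_config = rc, draws = d2)
  expect_equal(s2, s1 / 2, tolerance = 1e-12)
  d1$mu_leukemia <- 2.25
  d2$mu_leukemia <- 2.25
  l1 <- lar_site(0.1, 30, "male", "leukemia", risk_config = rc, draws = d1)
  l2 <- lar_site(0.1, 30, "male", "leukemia", risk_config = rc, draws = d2)
  expect_equal(l1, l2)
})

test_that("LAR is continuous in dose and exposure age", {
  eps <- 1e-6
  base <- lar_site(0.1, 40.25, "female", "lung")
  expect_lt(abs(lar_site(0.1 + eps, 40.25, "female", "lung") - base), 1e-4)
  expect_lt(abs(lar_site(0.1, 40.25 + eps, "female", "lung") - base), 1e-4)
})

test_that("per-exam risk table is consistent with direct lar_site calls", {
  s <- toy_summary(dose_mgy = 25)
  draws <- sample_uncertainty(n_draws = 30, seed = 5)
  risks <- lar_per_exam(s, draws)
  expect_equal(nrow(risks$table), 18)
  expect_equal(risks$n_draws, 30)
  expect_true(all(risks$table$central >= 0))
  # every site row equals the direct evaluation at the stratum midpoint
  e_mid <- age_groups()$age_mid[age_groups()$age_group == "50-59"]
  for (site in c("colon", "thyroid", "leukemia")) {
    direct <- lar_site(25 / 1000, e_mid, "female", site)
    expect_equal(risks$table$central[risks$table$site == site], direct,
      tolerance = 1e-12
    )
    direct_draws <- lar_site(25 / 1000, e_mid, "female", site, draws = draws)
    expect_equal(unname(risks$draws[which(risks$table$site == site), ]),
      direct_draws,
      tolerance = 1e-12
    )
  }
})

test_that("per-exam risk scales with dose for solid-only configurations", {
  s <- toy_summary(dose_mgy = 10)
  draws <- sample_uncertainty(n_draws = 20, seed = 6)
  rc <- solid_only_config()
  r1 <- lar_per_exam(s, draws, risk_config = rc)
  r2 <- lar_per_exam(s, draws, risk_config = rc, dose_scale = 2)
  expect_equal(r2$table$central, 2 * r1$table$central, tolerance = 1e-12)
  expect_equal(r2$draws, 2 * r1$draws, tolerance = 1e-12)
})

test_that("zero stratum doses give zero total risk and missing organs error", {
  s <- toy_summary(dose_mgy = 0)
  draws <- sample_uncertainty(n_draws = 20, seed = 2)
  risks <- lar_per_exam(s, draws)
  expect_equal(sum(risks$table$central), 0)
  s2 <- toy_summary()
  s2$dose_mean_lung <- NULL
  expect_error(lar_per_exam(s2, draws), "dose_mean_lung")
})
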