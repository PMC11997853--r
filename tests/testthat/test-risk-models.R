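test_that("solid ERR/EAR models are linear in dose with the exposure-age cap at 30", {
  expect_equal(err_solid(0, 10, 60, beta = 1), 0)
  expect_equal(ear_solid(0, 10, 60, beta = 1), 0)
  expect_equal(err_solid(0.1, 40, 60, beta = 1, gamma = 0, eta = 0), 0.1)
  expect_equal(
    err_solid(0.2, 15, 70, beta = 0.5),
    2 * err_solid(0.1, 15, 70, beta = 0.5)
  )
  # e* is capped: exposures at 30 and 40 give identical risk
  expect_equal(
    err_solid(0.1, 30, 60, beta = 1, gamma = -0.3),
    err_solid(0.1, 40, 60, beta = 1, gamma = -0.3)
  )
  expect_equal(
    ear_solid(0.1, 30, 60, beta = 1, gamma = -0.41),
    ear_solid(0.1, 40, 60, beta = 1, gamma = -0.41)
  )
  # risk declines with younger exposure reversed: gamma < 0 raises child risk
  expect_gt(
    err_solid(0.1, 5, 60, beta = 1),
    err_solid(0.1, 30, 60, beta = 1)
  )
  expect_error(err_solid(0.1, 50, 40, beta = 1), "attained age")
  expect_error(ear_solid(0.1, 30, 120, beta = 1), "\\[0, 100\\]")
  expect_error(err_solid(-0.1, 10, 60, beta = 1), "dose")
})

test_that("leukemia model is linear-quadratic with convex dose response", {
  expect_equal(excess_leukemia(0, 10, 5, beta = 1), 0)
  d <- 0.5
  expect_gt(
    excess_leukemia(2 * d, 10, 5, beta = 1, theta = 0.87),
    2 * excess_leukemia(d, 10, 5, beta = 1, theta = 0.87)
  )
  expect_equal(
    excess_leukemia(2 * d, 10, 5, beta = 1, theta = 0),
    2 * excess_leukemia(d, 10, 5, beta = 1, theta = 0)
  )
  expect_error(excess_leukemia(0.1, 10, 0, beta = 1), "time since exposure")
})

test_that("latency ramp hits 0.5 at its midpoint and spans 5-95% over the window", {
  expect_equal(latency_weight(7.5, mu = 7.5, window = c(4, 11)), 0.5)
  expect_equal(latency_weight(4, mu = 7.5, window = c(4, 11)), 0.05, tolerance = 1e-10)
  expect_equal(latency_weight(11, mu = 7.5, window = c(4, 11)), 0.95, tolerance = 1e-10)
  # thyroid and leukemia windows at their modal midpoints; the thyroid
  # window is slightly asymmetric around the mode, so near-5% there
  expect_lt(abs(latency_weight(2.5, mu = 5, window = c(2.5, 7.6)) - 0.05), 0.01)
  expect_equal(latency_weight(4.1, mu = 2.25, window = c(0.4, 4.1)), 0.95, tolerance = 1e-10)
  # weight at exposure is small for solid cancers, saturates far out
  expect_lte(latency_weight(0, mu = 7.5, window = c(4, 11)), 0.05)
  expect_equal(latency_weight(7.5 + 70, mu = 7.5, window = c(4, 11)), 1, tolerance = 1e-06)
  t <- seq(0, 40, by = 0.5)
  expect_true(all(diff(latency_weight(t, mu = 7.5, window = c(4, 11))) > 0))
})

test_that("default latency groups match the stated triangular midpoints and windows", {
  lc <- default_latency_config()
  expect_setequal(lc$group, c("solid", "thyroid", "leukemia"))
  expect_true(all(lc$tri_min <= lc$tri_mode & lc$tri_mode <= lc$tri_max))
  expect_true(all(lc$window_start < lc$window_end))
})

test_that("DDREF lognormal reproduces the median and approximates the 90% interval", {
  cfg <- default_ddref_config()
  expect_equal(qlnorm(0.5, log(cfg$median), cfg$sigma), 1.5)
  # interval (1.1, 2.3) is not log-symmetric; the LS fit lands between the
  # two one-sided solutions and beats both on total squared endpoint error
  s_lo <- log(1.5 / 1.1) / qnorm(0.95)
  s_hi <- log(2.3 / 1.5) / qnorm(0.95)
  expect_gt(cfg$sigma, s_lo)
  expect_lt(cfg$sigma, s_hi)
  sq_err <- function(s) {
    (qlnorm(0.05, log(1.5), s) - 1.1)^2 + (qlnorm(0.95, log(1.5), s) - 2.3)^2
  }
  expect_lte(sq_err(cfg$sigma), sq_err(s_lo))
  expect_lte(sq_err(cfg$sigma), sq_err(s_hi))
  # both endpoints land within ~0.15 of the printed interval
  expect_lt(abs(qlnorm(0.05, log(1.5), cfg$sigma) - 1.1), 0.15)
  expect_lt(abs(qlnorm(0.95, log(1.5), cfg$sigma) - 2.3), 0.15)
})

test_that("default coefficient table covers 18 sites x 2 sexes with valid fields", {
  rc <- default_risk_config()
  expect_equal(nrow(rc), 36)
  expect_setequal(unique(rc$site), cancer_sites())
  expect_true(all(rc$beta_err >= 0 & rc$beta_ear >= 0))
  expect_true(all(rc$transfer_weight >= 0 & rc$transfer_weight <= 1))
  expect_true(all(rc$theta[rc$model_class == "solid"] == 0))
  expect_true(all(rc$theta[rc$model_class == "leukemia"] > 0))
  # sex-restricted sites are zeroed in the other sex
  expect_equal(rc$beta_err[rc$site == "prostate" & rc$sex == "female"], 0)
  expect_equal(rc$beta_ear[rc$site == "uterus" & rc$sex == "male"], 0)
  # transfer exceptions: breast EAR-only, thyroid ERR-only
  expect_equal(unique(rc$transfer_weight[rc$site == "breast"]), 0)
  expect_equal(unique(rc$transfer_weight[rc$site == "thyroid"]), 1)
})
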