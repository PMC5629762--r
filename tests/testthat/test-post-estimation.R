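test_that("the smearing factor matches hand and closed-form values", {
  expect_equal(smearing_factor(c(0, 0, 0)), 1)
  expect_equal(smearing_factor(c(-0.1, 0, 0.1)),
               (exp(-0.1) + 1 + exp(0.1)) / 3, tolerance = 1e-12)
  expect_equal(smearing_factor(c(-0.1, 0, 0.1)), 1.003336,
               tolerance = 1e-6)
  expect_error(smearing_factor(numeric(0)), "empty")
  # per-draw computation on a matrix
  m <- rbind(c(0, 0), c(log(2), log(2)))
  expect_equal(smearing_factor(m), c(1, 2))
})

# a point-mass fit shared by the closed-form checks below
pm_fit <- function(slope = 0.77, extra = c(hospital = log(1.5))) {
  point_mass_fit(c(intercept = 2, log_doses = slope, extra))
}

test_that("first differences hit their closed forms under a point-mass
          posterior", {
  base <- tiny_table(cost = exp(rnorm(8, 7, 0.5)) ,
                     doses = round(exp(rnorm(8, 6, 0.8))))
  fit <- pm_fit()
  fit$data <- base
  # null contrast
  fd0 <- first_difference(fit, "hospital", from = 1, to = 1)
  expect_equal(fd0$percent_change, 0, tolerance = 1e-12)
  # binary contrast: exp(beta) - 1
  fd1 <- first_difference(fit, "hospital", from = 0, to = 1)
  expect_equal(fd1$percent_change, 100 * (exp(log(1.5)) - 1),
               tolerance = 1e-10)
  expect_equal(fd1$percent_change, 50, tolerance = 1e-10)
  # volume doubling: 2^(b-1) - 1 at constant slope b
  vd <- volume_doubling_difference(fit, base)
  expect_equal(vd$percent_change[vd$scope == "overall (site mean)"],
               100 * (2^(0.77 - 1) - 1), tolerance = 1e-10)
  expect_equal(vd$percent_change[vd$scope == "A"],
               100 * (2^(0.77 - 1) - 1), tolerance = 1e-10)
  expect_equal(100 * (2^(0.77 - 1) - 1), -14.74, tolerance = 1e-3)
})

test_that("first differences are invariant to the smearing factor", {
  base <- tiny_table(cost = exp(rnorm(6, 7, 0.3)),
                     doses = round(exp(rnorm(6, 6, 0.5))))
  fit <- point_mass_fit(c(intercept = 2, log_doses = 0.8,
                          hospital = 0.3), sigma = 0, table = base)
  fd1 <- first_difference(fit, "hospital", 0, 1)
  # perturb the residual scale (hence any smearing factor): no effect
  fit2 <- point_mass_fit(c(intercept = 2, log_doses = 0.8,
                           hospital = 0.3), sigma = 0.9, table = base)
  fit2$mu <- matrix(0, 1, 6); fit2$y <- rnorm(6, 2, 1)
  fd2 <- first_difference(fit2, "hospital", 0, 1)
  expect_equal(fd1$percent_change, fd2$percent_change, tolerance = 1e-12)
})

test_that("output elasticity is the reciprocal of the volume derivative", {
  tab <- tiny_table(cost = rep(1000, 6), doses = c(50, 100, 200, 400,
                                                   800, 1600))
  # constant slope 0.8: elasticity 1.25 everywhere
  fit <- point_mass_fit(c(intercept = 1, log_doses = 0.8), table = tab)
  el <- output_elasticity(fit, tab)
  expect_equal(el$elasticity, rep(1.25, nrow(el)), tolerance = 1e-10)
  # quadratic: log C = a + 0.5 log V + 0.05 (log V)^2, at log V = 2
  tab1 <- tiny_table(cost = 1000, doses = exp(2))
  fit2 <- point_mass_fit(c(intercept = 1, log_doses = 0.5,
                           log_doses_sq = 0.05), table = tab1)
  el2 <- output_elasticity(fit2, tab1)
  expect_equal(el2$elasticity[el2$country == "pooled"], 1 / 0.7,
               tolerance = 1e-10)
  expect_equal(1 / 0.7, 1.42857, tolerance = 1e-5)
})

test_that("pooled elasticity is the site-weighted mean of country values", {
  tab <- tiny_table(cost = rep(1000, 9),
                    doses = c(50, 100, 200, 400, 800, 1600, 90, 70, 60),
                    country = rep(c("A", "B", "C"), times = c(4, 3, 2)))
  fit <- point_mass_fit(c(intercept = 1, log_doses = 0.6,
                          log_doses_sq = 0.02), table = tab)
  el <- output_elasticity(fit, tab)
  cn <- table(tab$country)
  pooled <- el$elasticity[el$country == "pooled"]
  country_mean <- sum(el$elasticity[match(names(cn), el$country)] * cn) /
    sum(cn)
  expect_equal(pooled, country_mean, tolerance = 1e-10)
})

test_that("cost curves obey the noiseless limit and the total/average
          identity", {
  prof <- data.frame(country = "A", hospital = 1, gdp_pc = 1000)
  fit <- point_mass_fit(c(intercept = 2, log_doses = 0.7,
                          hospital = 0.2))
  grid <- c(100, 400, 1600, 6400)
  cc <- predict_cost_curve(fit, prof, grid)
  eta <- 2 + 0.7 * log(grid) + 0.2
  expect_equal(cc$total_mean, exp(eta), tolerance = 1e-12)
  expect_equal(cc$avg_mean * cc$volume, cc$total_mean, tolerance = 1e-12)
  expect_equal(cc$avg_lo * cc$volume, cc$total_lo, tolerance = 1e-12)
  # slope < 1 everywhere: average cost declines monotonically
  expect_true(all(diff(cc$avg_mean) < 0))
  expect_error(predict_cost_curve(fit, prof, c(-5, 10)), "positive")
})

test_that("volume-quintile contrasts match brute force and flip sign with
          diseconomies", {
  doses <- c(20, 40, 80, 160, 320, 640, 1280, 2560, 5120, 10240)
  tab <- tiny_table(cost = rep(1000, 10), doses = doses)
  fit <- point_mass_fit(c(intercept = 3, log_doses = 0.5), table = tab)
  qc <- volume_quintile_contrast(fit, tab)
  # brute force: predicted unit cost exp(3 + 0.5 log V)/V at each site
  u <- exp(3 + 0.5 * log(doses)) / doses
  expected <- 100 * (1 - mean(u[9:10]) / mean(u[1:2]))
  expect_equal(qc$percent_lower, expected, tolerance = 1e-10)
  # derivative 1: no difference
  fit1 <- point_mass_fit(c(intercept = 3, log_doses = 1), table = tab)
  expect_equal(volume_quintile_contrast(fit1, tab)$percent_lower, 0,
               tolerance = 1e-10)
  # slope above 1: large sites predicted more expensive per dose
  fit2 <- point_mass_fit(c(intercept = 3, log_doses = 1.3), table = tab)
  expect_lt(volume_quintile_contrast(fit2, tab)$percent_lower, 0)
})

test_that("posterior cost curves from a fitted model stay internally
          consistent", {
  d <- generate_dataset(small_config(seed = 13))
  fit <- quiet_fit(d$table, model_spec(
    predictors = c("log_doses", "log_gdp"),
    random_effects = c("country_intercept", "province_intercept")),
    fast_mcmc(seed = 6))
  prof <- site_profile(d$table, "B")
  grid <- exp(seq(log(200), log(5000), length.out = 11))
  cc <- predict_cost_curve(fit, prof, grid)
  expect_equal(cc$avg_mean * cc$volume, cc$total_mean, tolerance = 1e-10)
  expect_true(all(cc$total_lo <= cc$total_mean &
                    cc$total_mean <= cc$total_hi))
  expect_gt(attr(cc, "smearing_factor"), 1)
  # average cost declines over the grid (estimated slope well below 1)
  expect_true(all(diff(cc$avg_mean) < 0))
})
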