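test_that("generation is deterministic for a fixed config and seed", {
  d1 <- generate_dataset(small_config(seed = 42))
  d2 <- generate_dataset(small_config(seed = 42))
  expect_identical(d1$table, d2$table)
  expect_identical(d1$truth$coefficients, d2$truth$coefficients)
  d3 <- generate_dataset(small_config(seed = 43))
  expect_false(identical(d1$table$total_cost_usd, d3$table$total_cost_usd))
})

test_that("noiseless limit: log cost equals the linear predictor exactly", {
  cfg <- small_config(seed = 5, residual_sd = 0, re_sd_country = 0,
                      re_sd_province = 0)
  d <- generate_dataset(cfg)
  expect_equal(log(d$table$total_cost_usd), d$truth$linear_predictor,
               tolerance = 1e-12)
  # and the predictor is rebuildable from the stored truth
  b <- d$truth$coefficients
  eta <- b[["intercept"]] + b[["log_doses"]] * log(d$table$doses) +
    b[["log_gdp"]] * log(d$table$gdp_pc)
  expect_equal(unname(eta), d$truth$linear_predictor, tolerance = 1e-12)
})

test_that("the six-country preset reproduces the published sample sizes", {
  d <- generate_dataset(epic_like_config(seed = 1))
  counts <- table(d$table$country)
  expect_setequal(names(counts),
                  c("Benin", "Ghana", "Honduras", "Moldova", "Uganda",
                    "Zambia"))
  expect_identical(as.integer(counts[c("Benin", "Ghana", "Honduras",
                                       "Moldova", "Uganda", "Zambia")]),
                   c(45L, 50L, 71L, 50L, 49L, 51L))
  expect_equal(nrow(d$table), 316L)
})

test_that("realized province intercepts match their nominal SD", {
  # one country, many provinces: sample-moment oracle for the RE stream
  cfg <- small_config(seed = 9, n_sites = c(3, 3, 3), n_provinces = 3500)
  d <- generate_dataset(cfg)
  sds <- vapply(d$truth$province_intercepts, stats::sd, 0)
  expect_true(all(abs(sds - 0.1) / 0.1 < 0.05))
})

test_that("generated costs are right-skewed and coverage exceeds 100% at a
          positive rate", {
  for (s in c(1, 2)) {
    tab <- generate_dataset(epic_like_config(seed = s))$table
    by_c <- split(tab$total_cost_usd, tab$country)
    expect_true(all(vapply(by_c, mean, 0) > vapply(by_c, median, 0)))
    expect_gt(mean(tab$dtp3_coverage > 1), 0)
  }
})

test_that("invalid configs fail naming the offending field", {
  expect_error(small_config(residual_sd = -1), "residual_sd")
  expect_error(small_config(sampling_fraction = c(0, 1)),
               "sampling_fraction")
  cfg <- small_config()
  cfg$countries[[1]]$n_sites <- 0L
  expect_error(country_profile("X", 0, 1, 100, 5, 1, list()), "zero sites")
  expect_error(country_profile("X", 5, 1, -2, 5, 1, list()),
               "gdp_per_capita")
})

test_that("census sampling keeps all sites with unit weights", {
  cfg <- small_config(seed = 3)
  d <- generate_dataset(cfg)
  expect_true(all(d$table$weight == 1))
  expect_equal(sum(d$table$doses),
               sum(tapply(d$table$doses, d$table$country, sum)))
})

test_that("two-stage sampling yields inverse-probability weights", {
  frame <- tiny_table(cost = rep(100, 8), doses = rep(50, 8),
                      province = rep(c("P1", "P2", "P3", "P4"), each = 2))
  out <- sample_survey_design(frame, c(0.5, 0.5), seed = 1)
  # 2 of 4 provinces, 1 of 2 sites each: inclusion prob 1/4, weight 4
  expect_equal(nrow(out), 2L)
  expect_true(all(out$weight == 4))
  expect_error(sample_survey_design(frame, c(0.05, 1), seed = 1),
               "minimum fraction")
  expect_true(all(sample_survey_design(frame, c(1, 1))$weight == 1))
})

test_that("the weighted total is unbiased under the two-stage design", {
  # Horvitz-Thompson simulation oracle
  set.seed(7)
  frame <- tiny_table(cost = exp(rnorm(40, 5, 1)), doses = rep(50, 40),
                      province = rep(paste0("P", 1:8), each = 5))
  truth <- sum(frame$total_cost_usd)
  est <- vapply(1:1000, function(r) {
    s <- sample_survey_design(frame, c(0.5, 0.6), seed = r)
    sum(s$weight * s$total_cost_usd)
  }, 0)
  mc_se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * mc_se)
})
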