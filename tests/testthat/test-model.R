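test_that("standardization centers, scales and inverts exactly", {
  tab <- generate_dataset(small_config(seed = 1))$table
  spec <- model_spec(predictors = c("log_doses", "log_doses_sq", "log_gdp",
                                    "govt_owned", "anc4"),
                     random_effects = "country_intercept")
  des <- standardize_predictors(tab, spec)
  X <- des$X
  expect_equal(colnames(X), spec$predictors)
  for (nm in c("log_doses", "log_gdp", "anc4")) {
    expect_equal(mean(X[, nm]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(X[, nm]), 1, tolerance = 1e-12)
  }
  expect_true(all(X[, "govt_owned"] %in% c(0, 1)))
  # the quadratic is the z-score of the squared z-score
  expect_equal(stats::sd(X[, "log_doses_sq"]), 1, tolerance = 1e-12)
  # round trip
  expect_equal(destandardize(X[, "anc4"], des$info, "anc4"), tab$anc4,
               tolerance = 1e-12)
  expect_equal(destandardize(X[, "log_doses"], des$info, "log_doses"),
               log(tab$doses), tolerance = 1e-12)
  # a value at the column mean standardizes to zero
  nd <- tab[1, ]; nd$anc4 <- mean(tab$anc4)
  expect_equal(standardize_predictors(nd, spec, des$info)$X[, "anc4"],
               c(anc4 = 0), tolerance = 1e-12)
})

test_that("standardization errors name the offending column", {
  tab <- generate_dataset(small_config(seed = 1))$table
  tab$anc4 <- 0.5
  spec <- model_spec(predictors = c("log_doses", "anc4"))
  expect_error(standardize_predictors(tab, spec), "anc4")
  tab$distance_km <- NULL
  spec2 <- model_spec(predictors = "log_distance")
  expect_error(standardize_predictors(tab, spec2), "distance_km")
  expect_error(model_spec(predictors = "log_doses_sq"), "requires")
  expect_error(model_spec(predictors = "nonsense"), "unknown predictor")
})

test_that("standardized coefficients back-transform to the raw scale", {
  # refit oracle: OLS on the standardized design vs OLS on raw columns
  tab <- generate_dataset(small_config(seed = 2))$table
  spec <- model_spec(predictors = c("log_doses", "log_gdp", "anc4"))
  des <- standardize_predictors(tab, spec)
  y <- log(tab$total_cost_usd)
  b_std <- stats::coef(stats::lm(y ~ des$X))[-1]
  b_raw <- stats::coef(stats::lm(y ~ log(tab$doses) + log(tab$gdp_pc) +
                                   tab$anc4))[-1]
  expect_equal(unname(b_std[1] / des$info$volume[["sd"]]),
               unname(b_raw[1]), tolerance = 1e-10)
  expect_equal(unname(b_std[3] / des$info$predictors$anc4[["sd"]]),
               unname(b_raw[3]), tolerance = 1e-10)
})

test_that("top-coding caps coverage at exactly one", {
  x <- c(0.2, 1, 1.4, 0.99)
  expect_identical(top_code(x), c(0.2, 1, 1, 0.99))
})

test_that("WAIC matches the defining formulas", {
  # hand-computed two-draw example
  ll <- log(matrix(c(0.2, 0.4), 2, 1))
  w <- compute_waic(ll)
  expect_equal(w$lppd, log(0.3), tolerance = 1e-10)
  expect_equal(w$p_waic, stats::var(log(c(0.2, 0.4))), tolerance = 1e-10)
  expect_equal(w$p_waic, 0.24023, tolerance = 1e-4)
  expect_equal(w$waic, 2.88840, tolerance = 1e-4)
  # identical draws: zero penalty
  ll2 <- matrix(rep(c(-1.3, -0.4, -2.2), each = 10), 10, 3)
  w2 <- compute_waic(ll2)
  expect_equal(w2$p_waic, 0)
  expect_equal(w2$waic, -2 * sum(c(-1.3, -0.4, -2.2)))
  expect_error(compute_waic(matrix(-Inf, 3, 2)), "finite")
})

test_that("model comparison ranks by WAIC and guards observation counts", {
  d1 <- list(waic = 10, n_obs = 50, lppd = -4, p_waic = 1, label = "a")
  d2 <- list(waic = 4, n_obs = 50, lppd = -1, p_waic = 1, label = "b")
  r <- compare_models(list(a = d1, b = d2, a2 = d1))
  expect_equal(r$model, c("b", "a", "a2"))
  expect_equal(r$delta_waic, c(0, 6, 6))
  d3 <- list(waic = 4, n_obs = 49, lppd = -1, p_waic = 1)
  expect_error(compare_models(list(d1, d3)), "observation counts")
})

test_that("an intercept-only hierarchical fit recovers the grand mean", {
  tab <- generate_dataset(small_config(seed = 3))$table
  fit <- quiet_fit(tab, model_preset(1), fast_mcmc(seed = 1, thin = 3))
  b0 <- fit$draws[, "(Intercept)"]
  gm <- mean(log(tab$total_cost_usd))
  expect_lt(abs(mean(b0) - gm), 3 * stats::sd(b0))
})

test_that("with no random effects the posterior matches least squares", {
  cfg <- small_config(seed = 11, n_sites = c(300, 300, 300),
                      re_sd_country = 0, re_sd_province = 0,
                      residual_sd = 0.3)
  tab <- generate_dataset(cfg)$table
  spec <- model_spec(predictors = c("log_doses", "log_gdp", "anc4",
                                    "govt_owned"),
                     random_effects = character(0))
  fit <- quiet_fit(tab, spec, fast_mcmc(seed = 2))
  des <- standardize_predictors(tab, spec)
  ols <- stats::lm(log(tab$total_cost_usd) ~ des$X)
  b_ols <- stats::coef(ols)
  for (j in seq_along(spec$predictors)) {
    b_post <- mean(fit$draws[, spec$predictors[j]])
    ref <- unname(b_ols[j + 1])
    expect_lt(abs(b_post - ref), max(0.02 * abs(ref), 0.01))
  }
  ref0 <- unname(b_ols[1])
  expect_lt(abs(mean(fit$draws[, "(Intercept)"]) - ref0),
            max(0.02 * abs(ref0), 0.01))
})

test_that("robust and fixed-effect variants agree with the main model on
          clean data", {
  tab <- generate_dataset(epic_like_config(seed = 12))$table
  f_norm <- quiet_fit(tab, model_preset(4), fast_mcmc(seed = 3))
  f_t <- quiet_fit(tab, model_preset(4, residual_family = "student_t"),
                   fast_mcmc(seed = 3))
  f_fix <- quiet_fit(tab, model_preset(
    4, country_effect_style = "fixed",
    random_effects = "province_intercept"), fast_mcmc(seed = 3))
  for (nm in f_norm$spec$predictors) {
    m <- mean(f_norm$draws[, nm]); s <- stats::sd(f_norm$draws[, nm])
    expect_lt(abs(mean(f_t$draws[, nm]) - m), 1 * s + 0.02)
    expect_lt(abs(mean(f_fix$draws[, nm]) - m), 1 * s + 0.02)
  }
  # Student-t degrees of freedom drift large on Gaussian data
  expect_gt(mean(f_t$draws[, "nu"]), 10)
})

test_that("the latent-coverage model tracks true coverage better than the
          observed measure", {
  cfg <- small_config(seed = 21, n_sites = c(40, 40, 40),
                      coefficients = c(intercept = 2, log_doses = 0.6,
                                       log_gdp = 0.3))
  cfg$coverage_error_sd <- 0.5
  d <- generate_dataset(cfg)
  spec <- model_spec(predictors = c("log_doses", "log_gdp"),
                     random_effects = c("country_intercept",
                                        "province_intercept"),
                     eiv_coverage = TRUE)
  fit <- quiet_fit(d$table, spec, fast_mcmc(seed = 4))
  kappa_hat <- colMeans(fit$kappa)
  r_latent <- stats::cor(kappa_hat, d$truth$true_coverage)
  r_obs <- stats::cor(d$table$dtp3_coverage, d$truth$true_coverage)
  expect_gt(r_latent, r_obs)
})

test_that("irrelevant predictors perturb WAIC less than removing volume", {
  tab <- generate_dataset(small_config(seed = 31))$table
  base <- c("log_doses", "log_gdp")
  res <- c("country_intercept", "province_intercept")
  f_base <- quiet_fit(tab, model_spec(base, random_effects = res),
                      fast_mcmc(seed = 5))
  f_noise <- quiet_fit(tab, model_spec(c(base, "staffing_index"),
                                       random_effects = res),
                       fast_mcmc(seed = 5))
  f_novol <- quiet_fit(tab, model_spec("log_gdp", random_effects = res),
                       fast_mcmc(seed = 5))
  d_noise <- abs(f_noise$diagnostics$waic - f_base$diagnostics$waic)
  d_novol <- f_novol$diagnostics$waic - f_base$diagnostics$waic
  expect_lt(d_noise, d_novol)
})
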