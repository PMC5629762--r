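test_that("weighted average cost is total cost over total output", {
  tab <- tiny_table(cost = c(1000, 2000), doses = c(100, 100))
  expect_equal(weighted_average_cost(tab, "dose", by = "pooled")$point, 15)
  tab2 <- tiny_table(cost = c(100, 300), doses = c(100, 50))
  expect_equal(weighted_average_cost(tab2, "dose", by = "pooled")$point,
               400 / 150)
  expect_equal(weighted_average_cost(tab2, "site", by = "pooled")$point, 200)
  # weights matter: upweighting the cheap site lowers the estimate
  tab3 <- tiny_table(cost = c(100, 300), doses = c(100, 50),
                     weight = c(3, 1))
  expect_equal(weighted_average_cost(tab3, "dose", by = "pooled")$point,
               (3 * 100 + 300) / (3 * 100 + 50))
})

test_that("simple average cost is the weighted mean of site unit costs", {
  tab <- tiny_table(cost = c(100, 300), doses = c(100, 50))
  expect_equal(simple_average_cost(tab, "dose", by = "pooled")$point, 3.5)
  # equal volumes: simple equals weighted
  tab_eq <- tiny_table(cost = c(120, 260, 80), doses = c(70, 70, 70))
  expect_equal(simple_average_cost(tab_eq, "dose", by = "pooled")$point,
               weighted_average_cost(tab_eq, "dose", by = "pooled")$point)
  # equal unit costs: also equal
  tab_u <- tiny_table(cost = c(100, 500), doses = c(50, 250))
  expect_equal(simple_average_cost(tab_u, "dose", by = "pooled")$point,
               weighted_average_cost(tab_u, "dose", by = "pooled")$point)
  tab_bad <- tiny_table(cost = c(100, 300), doses = c(100, 50))
  tab_bad$dtp3 <- c(10, 0)
  expect_error(simple_average_cost(tab_bad, "dtp3"), "zero")
})

test_that("simple averages exceed weighted ones when unit costs fall with
          volume", {
  # economies of scale in the generator: log C = a + 0.6 log V
  for (s in 1:2) {
    tab <- generate_dataset(small_config(seed = s))$table
    w <- weighted_average_cost(tab, "dose", by = "country")
    si <- simple_average_cost(tab, "dose", by = "country")
    expect_true(all(si$point > w$point))
  }
})

rbind2_summary <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out$scope <- c("A", "A")
  class(out) <- c("cost_summary", "data.frame")
  out
}

test_that("above-site markups scale summaries multiplicatively", {
  tab <- tiny_table(cost = c(100, 300), doses = c(100, 50))
  summ <- weighted_average_cost(tab, "dose", by = "country")
  m0 <- markup_schedule("A", 0, 0)
  expect_equal(apply_above_site_markup(summ, m0)$point, summ$point)
  m1 <- markup_schedule("A", 0.6, 0.4)
  expect_equal(apply_above_site_markup(summ, m1)$point, 2 * summ$point)
  marked <- apply_above_site_markup(summ, m1)
  expect_error(apply_above_site_markup(marked, m1), "already includes")
  # published example: $2.75/dose with 4.5% + 1.5% markup prints as $2.91
  expect_equal(round(2.75 * (1 + 0.045 + 0.015), 2), 2.91)
  # linearity: markup of a sum equals the sum of markups
  s2 <- summ; s2$point <- 7
  expect_equal(apply_above_site_markup(rbind2_summary(summ, s2), m1)$point,
               c(apply_above_site_markup(summ, m1)$point,
                 apply_above_site_markup(s2, m1)$point))
})

test_that("multi-stage bootstrap intervals behave as percentile intervals", {
  tab <- generate_dataset(small_config(seed = 4))$table
  const <- function(t) 5
  ci <- multistage_bootstrap_ci(tab, const, replicates = 50, seed = 1)
  expect_equal(unname(ci$interval), c(5, 5))
  ci1 <- multistage_bootstrap_ci(tab, "weighted_cost_per_dose",
                                 replicates = 200, seed = 9)
  ci2 <- multistage_bootstrap_ci(tab, "weighted_cost_per_dose",
                                 replicates = 200, seed = 9)
  expect_identical(ci1$interval, ci2$interval)
  expect_lte(ci1$interval[["low"]], ci1$interval[["high"]])
  # the fast built-in path agrees with the equivalent function statistic
  fn <- function(t) sum(t$weight * t$total_cost_usd) /
    sum(t$weight * t$doses)
  ci3 <- multistage_bootstrap_ci(tab, fn, replicates = 200, seed = 9)
  expect_equal(ci1$interval, ci3$interval, tolerance = 1e-12)
  expect_equal(ci1$point, fn(tab))
})

test_that("single-province countries fall back to site-only resampling", {
  tab <- tiny_table(cost = rexp(10, 0.01) + 50, doses = rep(100, 10))
  expect_warning(
    ci <- multistage_bootstrap_ci(tab, "weighted_cost_per_dose",
                                  replicates = 100, seed = 2),
    "single province")
  expect_true(is.finite(ci$interval[["low"]]))
})

test_that("bootstrap interval width shrinks with sample size", {
  widths <- vapply(c(1, 3, 9), function(mult) {
    cfg <- small_config(seed = 8, n_sites = rep(8L * mult, 3),
                        n_provinces = 2L * mult)
    tab <- generate_dataset(cfg)$table
    ci <- multistage_bootstrap_ci(tab, "weighted_cost_per_dose",
                                  replicates = 200, seed = 3)
    diff(ci$interval)
  }, 0)
  expect_true(widths[1] > widths[2] && widths[2] > widths[3])
})

test_that("dispersion statistics match hand-computed values", {
  tab <- tiny_table(cost = (1:10) * 100, doses = rep(100, 10))
  d <- dispersion_stats(tab)
  expect_equal(d$quintile_ratio, 9.5 / 1.5 - 1, tolerance = 1e-12)
  expect_equal(d$cv, stats::sd(1:10) / 5.5, tolerance = 1e-12)
  tab_c <- tiny_table(cost = rep(500, 6), doses = rep(100, 6))
  d_c <- dispersion_stats(tab_c)
  expect_equal(d_c$cv, 0)
  expect_equal(d_c$quintile_ratio, 0)
  expect_warning(d_s <- dispersion_stats(
    tiny_table(cost = c(100, 200, 300), doses = rep(10, 3))), "< 5 sites")
  expect_true(is.na(d_s$quintile_ratio))
})

test_that("the full summary table carries intervals and markups", {
  tab <- generate_dataset(small_config(seed = 6))$table
  mk <- markup_schedule(c("A", "B", "C"), c(0.1, 0.2, 0), c(0.02, 0, 0.05))
  out <- cost_summary_table(tab, markups = mk, replicates = 100, seed = 1)
  expect_true(all(out$interval_low <= out$interval_high))
  base <- out[!out$includes_above_site, ]
  up <- out[out$includes_above_site, ]
  expect_equal(nrow(base), nrow(up))
  f <- 1 + mk$total[match(up$scope, mk$country)]
  expect_equal(up$point, base$point * f, tolerance = 1e-12)
})
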