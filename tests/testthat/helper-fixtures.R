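# Shared fixtures, built in code.

# A minimal valid site table with chosen costs/doses/weights.
tiny_table <- function(cost, doses, weight = rep(1, length(cost)),
                       country = rep("A", length(cost)),
                       province = rep("P1", length(cost)),
                       dtp3 = pmax(round(doses / 10), 0)) {
  n <- length(cost)
  data.frame(
    site_id = sprintf("S%02d", seq_len(n)),
    country = country, province = province,
    weight = weight, total_cost_usd = cost, doses = doses, dtp3 = dtp3,
    govt_owned = rep_len(c(1, 0), n), hospital = 0, rural = rep_len(c(0, 1), n),
    fraction_outreach = 0.2, fraction_mgmt = 0.1,
    dtp3_per_dose = dtp3 / doses, anc4 = 0.8, wealth_ratio = 1.0,
    gdp_pc = 1000, stringsAsFactors = FALSE)
}

# A small 3-country generator config for fast simulation tests.
small_config <- function(seed = 1L, n_sites = c(24, 24, 24),
                         n_provinces = 6, residual_sd = 0.4,
                         coefficients = c(intercept = 2, log_doses = 0.6,
                                          log_gdp = 0.3),
                         re_sd_country = 0.2, re_sd_province = 0.1,
                         re_sd_slope = 0, sampling_fraction = c(1, 1)) {
  mk <- function(nm, n, gdp, mu)
    country_profile(nm, n, n_provinces, gdp, mu, 0.8,
                    covariates = list(
                      rural = 0.5, govt_owned = 0.8, hospital = 0.1,
                      anc4 = c(0.8, 0.1), wealth_ratio = c(1.1, 0.3),
                      fraction_outreach = c(0.3, 0.15),
                      fraction_mgmt = c(0.1, 0.05),
                      dtp3_per_dose = c(0.1, 0.02),
                      staffing_index = c(1, 0.3),
                      dedication_index = c(0.4, 0.2),
                      days_per_week = c(4, 1.5), distance_km = c(15, 10),
                      dtp3_coverage = c(0.8, 0.15)),
                    markup_subnational = 0.1, markup_national = 0.02)
  generator_config(
    countries = list(mk("A", n_sites[1], 800, 8),
                     mk("B", n_sites[2], 1500, 7),
                     mk("C", n_sites[3], 2200, 7.5)),
    true_coefficients = coefficients,
    re_sd_country_intercept = re_sd_country,
    re_sd_province_intercept = re_sd_province,
    re_sd_country_slope = re_sd_slope,
    residual_sd = residual_sd,
    sampling_fraction = sampling_fraction,
    seed = seed)
}

fast_mcmc <- function(seed = 1L, ...)
  mcmc_control(chains = 2, adapt = 300, warmup = 300, samples = 500,
               seed = seed, rhat_action = "warn", ...)

quiet_fit <- function(...) suppressWarnings(suppressMessages(fit_model(...)))
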