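#' Country profile for the synthetic-data generator
#'
#' Describes one country in a multi-country facility costing survey: its
#' price level (per-capita GDP), the lognormal distribution of annual doses
#' delivered across its sites, marginal distributions of site covariates,
#' and the above-site (subnational/national) cost markups.
#'
#' @param name Country label.
#' @param n_sites Number of facilities to generate.
#' @param n_provinces Number of provinces the sites are nested in.
#' @param gdp_per_capita Per-capita GDP, USD/person/year (2011 USD).
#' @param doses_meanlog,doses_sdlog Lognormal parameters for annual doses.
#' @param covariates Named list. Bernoulli covariates (`rural`, `govt_owned`,
#'   `hospital`) give a probability; continuous covariates give `c(mean, sd)`:
#'   `anc4`, `wealth_ratio`, `fraction_outreach`, `fraction_mgmt`,
#'   `dtp3_per_dose`, plus optional `staffing_index`, `dedication_index`,
#'   `days_per_week`, `distance_km`, `dtp3_coverage`.
#' @param markup_subnational,markup_national Above-site cost markups as
#'   fractions of site-level costs (>= 0).
#' @param schedule_doses_per_child Average doses in the infant schedule;
#'   the reciprocal is the expected DTP3-per-dose ratio.
#' @return An object of class `country_profile`.
#' @export
country_profile <- function(name, n_sites, n_provinces, gdp_per_capita,
                            doses_meanlog, doses_sdlog,
                            covariates,
                            markup_subnational = 0, markup_national = 0,
                            schedule_doses_per_child = 10) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(gdp_per_capita) || gdp_per_capita <= 0)
    stop("country_profile: 'gdp_per_capita' must be > 0 for ", name)
  if (n_sites < 1) stop("country_profile: zero sites in country ", name)
  if (n_provinces < 1) stop("country_profile: need >= 1 province in ", name)
  if (markup_subnational < 0 || markup_national < 0)
    stop("country_profile: markups must be >= 0 for ", name)
  for (nm in c("rural", "govt_owned", "hospital")) {
    p <- covariates[[nm]]
    if (!is.null(p) && (p < 0 || p > 1))
      stop("country_profile: Bernoulli probability '", nm,
           "' outside [0,1] for ", name)
  }
  structure(list(
    name = name, n_sites = as.integer(n_sites),
    n_provinces = as.integer(n_provinces),
    gdp_per_capita = gdp_per_capita,
    doses_meanlog = doses_meanlog, doses_sdlog = doses_sdlog,
    covariates = covariates,
    markup_subnational = markup_subnational,
    markup_national = markup_national,
    schedule_doses_per_child = schedule_doses_per_child
  ), class = "country_profile")
}

#' Generator configuration
#'
#' Fully specifies the ground-truth data-generating process for a synthetic
#' multi-country site table: country profiles, the raw-scale (unstandardized)
#' coefficients of the log-linear cost model, random-effect standard
#' deviations, the residual family, the two-stage sampling fractions used to
#' attach survey weights, and the seed.
#'
#' The cost model generating log total site cost is
#' \deqn{\log C_i = \beta_0 + \beta_1 \log V_i + \beta_2 (\log V_i)^2 +
#'   \beta' x_i + \alpha_{c(i)} + \alpha_{p(i)} +
#'   \gamma_{c(i)} (\log V_i - \bar{\ell}) + \epsilon_i}
#' with \eqn{V_i} doses, \eqn{x_i} the other covariates,
#' \eqn{\alpha_c \sim N(0, \sigma_c^2)}, \eqn{\alpha_p \sim N(0, \sigma_p^2)},
#' \eqn{\gamma_c \sim N(0, \sigma_\gamma^2)} centred at the realized pooled
#' mean log volume \eqn{\bar{\ell}}, and \eqn{\epsilon_i} normal or Student-t
#' with scale `residual_sd`.
#'
#' @param countries List of [country_profile()] objects.
#' @param true_coefficients Named numeric vector of raw-scale coefficients.
#'   Recognised names: `intercept`, `log_doses`, `log_doses_sq`, `log_gdp`,
#'   `govt_owned`, `hospital`, `fraction_outreach`, `fraction_mgmt`,
#'   `dtp3_per_dose`, `rural`, `anc4`, `wealth_ratio` (others are generated
#'   as columns but may carry zero weight by omission).
#' @param re_sd_country_intercept,re_sd_province_intercept,re_sd_country_slope
#'   Random-effect SDs (>= 0).
#' @param residual_sd Residual scale on the log-cost scale (>= 0).
#' @param residual_family `"normal"` or `"student_t"`.
#' @param residual_t_df Degrees of freedom when `residual_family =
#'   "student_t"`.
#' @param sampling_fraction Length-2 vector `(province, site)` in (0, 1]:
#'   fractions retained at each stage of the two-stage cluster sample that
#'   attaches survey weights.
#' @param coverage_error_sd SD of the multiplicative lognormal error on the
#'   reported catchment denominator (log scale, >= 0). Reported DTP3
#'   coverage = DTP3 / reported catchment infants, so large values produce
#'   observed coverage above 100%.
#' @param seed Integer master seed; per-country sub-streams are derived
#'   from it deterministically.
#' @return An object of class `generator_config`.
#' @seealso [epic_like_config()] for the bundled six-country preset,
#'   [generate_dataset()].
#' @export
generator_config <- function(countries,
                             true_coefficients,
                             re_sd_country_intercept = 0.25,
                             re_sd_province_intercept = 0.15,
                             re_sd_country_slope = 0.10,
                             residual_sd = 0.35,
                             residual_family = c("normal", "student_t"),
                             residual_t_df = 4,
                             sampling_fraction = c(1, 1),
                             coverage_error_sd = 0.30,
                             seed = 1L) {
  residual_family <- match.arg(residual_family)
  if (!length(countries) || !all(vapply(countries, inherits, TRUE,
                                        "country_profile")))
    stop("generator_config: 'countries' must be a list of country_profile")
  sds <- c(re_sd_country_intercept = re_sd_country_intercept,
           re_sd_province_intercept = re_sd_province_intercept,
           re_sd_country_slope = re_sd_country_slope,
           residual_sd = residual_sd,
           coverage_error_sd = coverage_error_sd)
  bad <- names(sds)[!is.finite(sds) | sds < 0]
  if (length(bad))
    stop("generator_config: field '", bad[[1]], "' must be >= 0")
  if (length(sampling_fraction) != 2 ||
      any(sampling_fraction <= 0 | sampling_fraction > 1))
    stop("generator_config: field 'sampling_fraction' must lie in (0,1]")
  if (is.null(names(true_coefficients)) ||
      !"intercept" %in% names(true_coefficients))
    stop("generator_config: field 'true_coefficients' needs named entries ",
         "including 'intercept'")
  if (residual_family == "student_t" && residual_t_df <= 2)
    stop("generator_config: field 'residual_t_df' must exceed 2")
  structure(list(
    countries = countries,
    true_coefficients = true_coefficients,
    re_sd_country_intercept = re_sd_country_intercept,
    re_sd_province_intercept = re_sd_province_intercept,
    re_sd_country_slope = re_sd_country_slope,
    residual_sd = residual_sd,
    residual_family = residual_family,
    residual_t_df = residual_t_df,
    sampling_fraction = sampling_fraction,
    coverage_error_sd = coverage_error_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Lognormal meanlog/sdlog from an arithmetic mean and SD (method of moments).
lnorm_from_moments <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Six-country survey preset
#'
#' A [generator_config()] emulating the pooled six-country immunization
#' costing sample: 316 sites (45, 50, 71, 50, 49, 51 per country) nested in
#' provinces, per-capita GDP from US$531 to US$2277, strongly right-skewed
#' dose volumes, and country-specific above-site markups. Covariate
#' marginals (rural/government/hospital frequencies, ANC4, wealth ratio,
#' outreach and management fractions, DTP3-per-dose) follow the published
#' sample characteristics; dose volumes are lognormal with moments matched
#' to the per-country mean and SD of total doses.
#'
#' The true raw-scale coefficients give a volume derivative
#' \eqn{d\log C / d\log V \approx 0.7} at typical volumes (output
#' elasticity near 1.4) and a residual SD of 0.35 on the log scale.
#'
#' @param seed Master seed stored in the config.
#' @param sampling_fraction Two-stage sampling fractions; the default
#'   `c(1, 1)` is a census of the frame so site counts are exact and all
#'   survey weights equal 1.
#' @return A `generator_config`.
#' @export
epic_like_config <- function(seed = 1L, sampling_fraction = c(1, 1)) {
  row <- function(name, n, prov, gdp, dm, dsd, rural, govt, hosp,
                  anc4, wealth, outr, mgmt, dpd, sub, nat,
                  days, dist, cov) {
    ln <- lnorm_from_moments(dm, dsd)
    country_profile(
      name = name, n_sites = n, n_provinces = prov, gdp_per_capita = gdp,
      doses_meanlog = ln[["meanlog"]], doses_sdlog = ln[["sdlog"]],
      covariates = list(
        rural = rural, govt_owned = govt, hospital = hosp,
        anc4 = anc4, wealth_ratio = wealth,
        fraction_outreach = outr, fraction_mgmt = mgmt,
        dtp3_per_dose = dpd,
        staffing_index = c(1.00, 0.30),
        dedication_index = c(0.40, 0.20),
        days_per_week = days, distance_km = dist,
        dtp3_coverage = cov
      ),
      markup_subnational = sub, markup_national = nat,
      schedule_doses_per_child = 1 / dpd[[1]]
    )
  }
  countries <- list(
    row("Benin",    45, 7,  745, 7014,  4684, 25/45, 41/45,  0/45,
        c(0.69, 0.13), c(1.17, 0.31), c(0.20, 0.21), c(0.02, 0.03),
        c(0.10, 0.03), 0.045, 0.015, c(3.8, 1.5), c(15.5, 18.5),
        c(0.80, 0.18)),
    row("Ghana",    50, 8, 1594, 3512,  3775, 31/50, 47/50,  6/50,
        c(0.83, 0.04), c(1.03, 0.26), c(0.63, 0.32), c(0.07, 0.06),
        c(0.12, 0.06), 0.122, 0.015, c(4.3, 1.9), c(8.0, 11.5),
        c(0.72, 0.20)),
    row("Honduras", 71, 9, 2277, 4244,  7175, 53/71, 71/71,  3/71,
        c(0.90, 0.03), c(1.09, 0.36), c(0.14, 0.07), c(0.05, 0.05),
        c(0.08, 0.01), 0.088, 0.099, c(4.0, 1.5), c(15.0, 13.0),
        c(0.83, 0.15)),
    row("Moldova",  50, 8, 1971,  557,  1172, 42/50, 50/50,  0/50,
        c(0.93, 0.01), c(0.92, 0.30), c(0.00, 0.00), c(0.19, 0.06),
        c(0.10, 0.02), 0.203, 0.022, c(3.9, 1.6), c(19.6, 13.1),
        c(0.85, 0.13)),
    row("Uganda",   49, 8,  531, 6561, 12144, 29/49, 37/49, 13/49,
        c(0.52, 0.06), c(1.10, 0.47), c(0.38, 0.08), c(0.13, 0.06),
        c(0.11, 0.02), 0.123, 0.077, c(2.7, 2.2), c(12.9, 12.6),
        c(0.60, 0.25)),
    row("Zambia",   51, 8, 1741, 7069, 11343, 36/51, 49/51,  4/51,
        c(0.62, 0.02), c(1.42, 0.45), c(0.46, 0.20), c(0.12, 0.07),
        c(0.11, 0.02), 0.058, 0.015, c(1.9, 1.5), c(50.2, 44.8),
        c(0.75, 0.19))
  )
  generator_config(
    countries = countries,
    true_coefficients = c(
      intercept = 1.10,
      log_doses = 0.55, log_doses_sq = 0.01,
      log_gdp = 0.35,
      govt_owned = -0.13, hospital = 0.30,
      fraction_outreach = 0.30, fraction_mgmt = 1.80,
      dtp3_per_dose = 5.0,
      rural = -0.04, anc4 = 0.70, wealth_ratio = -0.20
    ),
    re_sd_country_intercept = 0.25,
    re_sd_province_intercept = 0.15,
    re_sd_country_slope = 0.10,
    residual_sd = 0.35,
    sampling_fraction = sampling_fraction,
    coverage_error_sd = 0.30,
    seed = seed
  )
}

# Deterministic per-country sub-seed (kept < 2^31).
country_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131L + i * 7919) %% 2147483629)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Beta draw with given mean/sd (method of moments); degenerate sd -> constant
rbeta_ms <- function(n, m, s) {
  if (s <= 0 || m <= 0 || m >= 1) return(rep(m, n))
  v <- min(s^2, m * (1 - m) * 0.95)
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, m * k, (1 - m) * k)
}

#' Generate a synthetic multi-country site table
#'
#' Draws facilities country by country from the ground-truth model in
#' `config`: doses are lognormal, DTP3 is a beta-distributed fraction of
#' doses, covariates follow the per-country marginals, and log total cost
#' equals the raw-scale linear predictor plus realized country/province
#' intercepts, a country-specific volume slope, and residual noise.
#' Observed DTP3 coverage is DTP3 divided by a noisily reported catchment
#' denominator, so values above 100% arise by construction. Survey weights
#' are attached by passing the full frame through [sample_survey_design()]
#' with the config's sampling fractions.
#'
#' @param config A [generator_config()].
#' @return A list with class `synthetic_dataset`:
#'   \describe{
#'     \item{table}{the site table (`data.frame`), validated;}
#'     \item{truth}{a `true_params` list holding the realized ground truth:
#'       raw-scale coefficients, country/province intercepts, country
#'       slopes and their centring constant, residual scale, per-site
#'       noiseless linear predictor, true coverage and true catchment.}
#'   }
#' @examples
#' d <- generate_dataset(epic_like_config(seed = 7))
#' table(d$table$country)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("generate_dataset: 'config' must be a generator_config")
  beta <- config$true_coefficients
  frames <- vector("list", length(config$countries))
  re <- list(country = numeric(0), province = list(), slope = numeric(0))

  for (i in seq_along(config$countries)) {
    cp <- config$countries[[i]]
    set.seed(country_seed(config$seed, i))
    n <- cp$n_sites
    doses <- pmax(round(stats::rlnorm(n, cp$doses_meanlog, cp$doses_sdlog)),
                  20)
    cv <- cp$covariates
    dpd <- rbeta_ms(n, cv$dtp3_per_dose[[1]], cv$dtp3_per_dose[[2]])
    dtp3 <- pmax(pmin(round(doses * dpd), doses), 1)
    dat <- data.frame(
      site_id = sprintf("%s_%03d", toupper(substr(cp$name, 1, 3)), seq_len(n)),
      country = cp$name,
      province = sprintf("%s_P%02d", toupper(substr(cp$name, 1, 3)),
                         1L + (seq_len(n) - 1L) %% cp$n_provinces),
      doses = doses,
      dtp3 = dtp3,
      govt_owned = stats::rbinom(n, 1, cv$govt_owned),
      hospital = stats::rbinom(n, 1, cv$hospital),
      rural = stats::rbinom(n, 1, cv$rural),
      fraction_outreach = rtruncnorm1(n, cv$fraction_outreach[[1]],
                                      cv$fraction_outreach[[2]], 0, 1),
      fraction_mgmt = rtruncnorm1(n, cv$fraction_mgmt[[1]],
                                  cv$fraction_mgmt[[2]], 0, 1),
      dtp3_per_dose = dtp3 / doses,
      anc4 = rtruncnorm1(n, cv$anc4[[1]], cv$anc4[[2]], 0.05, 1),
      wealth_ratio = rtruncnorm1(n, cv$wealth_ratio[[1]],
                                 cv$wealth_ratio[[2]], 0.1, 3.5),
      gdp_pc = cp$gdp_per_capita,
      staffing_index = rtruncnorm1(n, cv$staffing_index[[1]],
                                   cv$staffing_index[[2]], 0.2, 3),
      dedication_index = rtruncnorm1(n, cv$dedication_index[[1]],
                                     cv$dedication_index[[2]], 0.02, 1),
      days_per_week = pmin(pmax(round(stats::rnorm(
        n, cv$days_per_week[[1]], cv$days_per_week[[2]])), 1), 7),
      distance_km = pmax(stats::rnorm(n, cv$distance_km[[1]],
                                      cv$distance_km[[2]]), 0.5),
      stringsAsFactors = FALSE
    )
    # latent true coverage and the mismeasured reported denominator
    kappa <- rbeta_ms(n, cv$dtp3_coverage[[1]], cv$dtp3_coverage[[2]])
    true_catch <- pmax(dtp3, 1) / kappa
    rep_catch <- true_catch *
      exp(stats::rnorm(n, 0, config$coverage_error_sd))
    dat$catchment_pop <- round(rep_catch / 0.035)  # infants ~3.5% of pop
    dat$dtp3_coverage <- dtp3 / rep_catch
    dat$.kappa <- kappa
    dat$.true_catch <- true_catch

    re$country[i] <- stats::rnorm(1, 0, config$re_sd_country_intercept)
    re$slope[i] <- stats::rnorm(1, 0, config$re_sd_country_slope)
    re$province[[i]] <- stats::rnorm(cp$n_provinces, 0,
                                     config$re_sd_province_intercept)
    frames[[i]] <- dat
  }

  tab <- do.call(rbind, frames)
  rownames(tab) <- NULL
  log_v <- log(tab$doses)
  center <- mean(log_v)

  eta <- rep(beta[["intercept"]], nrow(tab))
  covs <- setdiff(names(beta), "intercept")
  for (nm in covs) {
    x <- switch(nm,
      log_doses = log_v,
      log_doses_sq = log_v^2,
      log_gdp = log(tab$gdp_pc),
      log_distance = log(tab$distance_km),
      log_population = log(tab$catchment_pop),
      tab[[nm]])
    if (is.null(x)) stop("generate_dataset: no generated column for true ",
                         "coefficient '", nm, "'")
    eta <- eta + beta[[nm]] * x
  }
  ci <- match(tab$country, vapply(config$countries, `[[`, "", "name"))
  pidx <- as.integer(sub(".*_P", "", tab$province))
  alpha_p <- mapply(function(c, p) re$province[[c]][p], ci, pidx)
  eta <- eta + re$country[ci] + alpha_p + re$slope[ci] * (log_v - center)

  set.seed(country_seed(config$seed, 0L))
  eps <- if (config$residual_family == "normal") {
    stats::rnorm(nrow(tab), 0, config$residual_sd)
  } else {
    config$residual_sd * stats::rt(nrow(tab), config$residual_t_df)
  }
  tab$total_cost_usd <- exp(eta + eps)

  truth <- structure(list(
    coefficients = beta,
    country_intercepts = stats::setNames(
      re$country, vapply(config$countries, `[[`, "", "name")),
    province_intercepts = stats::setNames(
      re$province, vapply(config$countries, `[[`, "", "name")),
    country_slopes = stats::setNames(
      re$slope, vapply(config$countries, `[[`, "", "name")),
    slope_center = center,
    residual_sd = config$residual_sd,
    residual_family = config$residual_family,
    linear_predictor = as.numeric(eta),
    true_coverage = tab$.kappa,
    true_catchment = tab$.true_catch,
    seed = config$seed
  ), class = "true_params")

  frame_ids <- tab$site_id
  tab$.kappa <- NULL
  tab$.true_catch <- NULL
  tab <- sample_survey_design(tab, config$sampling_fraction,
                              seed = country_seed(config$seed, 999L))
  # subset per-site truth to retained sites
  sel <- match(tab$site_id, frame_ids)
  truth$linear_predictor <- truth$linear_predictor[sel]
  truth$true_coverage <- truth$true_coverage[sel]
  truth$true_catchment <- truth$true_catchment[sel]

  tab <- validate_site_table(tab)
  structure(list(table = tab, truth = truth), class = "synthetic_dataset")
}

#' Two-stage cluster sample with inverse-probability weights
#'
#' Samples provinces within each country (simple random sample of
#' `max(1, round(fraction * P))` provinces without replacement), then sites
#' within each sampled province (likewise), and sets each retained site's
#' survey weight to the inverse of its overall inclusion probability, the
#' product of the province- and site-stage probabilities. With fractions
#' `(1, 1)` the frame is returned intact with all weights equal to 1.
#'
#' @param frame Site table carrying `country` and `province` columns.
#' @param fractions Length-2 numeric `(province_fraction, site_fraction)`
#'   in (0, 1].
#' @param seed Integer seed.
#' @return The sampled site table with a `weight` column.
#' @export
sample_survey_design <- function(frame, fractions, seed = 1L) {
  if (length(fractions) != 2 || any(fractions <= 0 | fractions > 1))
    stop("sample_survey_design: fractions must lie in (0,1]")
  if (!all(c("country", "province") %in% names(frame)))
    stop("sample_survey_design: frame must carry country and province")
  fp <- fractions[[1]]; fs <- fractions[[2]]
  set.seed(seed)
  out <- lapply(split(frame, frame$country), function(cdat) {
    provs <- unique(cdat$province)
    P <- length(provs)
    m <- round(fp * P)
    if (m < 1)
      stop("sample_survey_design: province fraction ", fp, " selects no ",
           "province in ", cdat$country[[1]], "; minimum fraction is ",
           signif(0.5 / P, 3))
    sel_p <- sample(provs, m)
    pieces <- lapply(sel_p, function(pv) {
      sdat <- cdat[cdat$province == pv, , drop = FALSE]
      Nj <- nrow(sdat)
      nj <- max(1L, as.integer(round(fs * Nj)))
      sdat <- sdat[sample.int(Nj, nj), , drop = FALSE]
      sdat$weight <- (P / m) * (Nj / nj)
      sdat
    })
    do.call(rbind, pieces)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$country, unique(frame$country)), out$site_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to disk
#'
#' Writes the site table as CSV and the realized ground truth as a JSON
#' side-car file next to it (`<stem>_true_params.json`).
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param path CSV path for the site table.
#' @return Invisibly, the two paths written.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  write_site_table(dataset$table, path)
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, "_true_params.json")
  tr <- unclass(dataset$truth)
  # listify named vectors so names survive the JSON round trip
  for (nm in c("coefficients", "country_intercepts", "country_slopes"))
    tr[[nm]] <- as.list(tr[[nm]])
  jsonlite::write_json(tr, side, digits = NA, auto_unbox = TRUE)
  invisible(c(path, side))
}

#' Read a ground-truth side-car file
#' @param path JSON path written by [write_dataset()].
#' @return A `true_params` object.
#' @export
read_true_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("coefficients", "country_intercepts", "country_slopes"))
    x[[nm]] <- unlist(x[[nm]])
  structure(x, class = "true_params")
}
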