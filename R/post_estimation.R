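# Post-estimation economics: smearing retransformation, cost curves,
# first differences, output elasticity, volume-quintile contrasts.

#' Duan smearing factor
#'
#' The nonparametric retransformation factor for log-linear models:
#' \eqn{\phi = \frac{1}{n}\sum_i e^{r_i}} over log-scale residuals
#' \eqn{r_i}. Multiplying \eqn{e^{\hat\eta}} by \eqn{\phi} corrects the
#' downward bias of naive exponentiation of log-scale predictions. Given a
#' matrix (draws x observations) the factor is computed per posterior draw
#' from that draw's residuals.
#'
#' @param residuals Numeric vector, or draws-by-observations matrix.
#' @return A scalar, or one factor per draw.
#' @examples
#' smearing_factor(c(-0.1, 0, 0.1))
#' @export
smearing_factor <- function(residuals) {
  if (length(residuals) == 0) stop("smearing_factor: empty residuals")
  if (any(!is.finite(residuals)))
    stop("smearing_factor: non-finite residuals")
  if (is.matrix(residuals)) rowMeans(exp(residuals)) else
    mean(exp(residuals))
}

#' Per-draw residuals of a fitted cost model
#' @param object A `cost_fit`.
#' @param ... Unused.
#' @return Draws-by-observations matrix of log-scale residuals.
#' @export
residuals.cost_fit <- function(object, ...) {
  fit_residuals(object)
}

fit_residuals <- function(fit) {
  if (is.null(fit$mu)) return(matrix(0, nrow(fit$draws), 1L))
  t(fit$y - t(fit$mu))
}

#' Posterior linear predictor for new data
#'
#' Evaluates \eqn{\eta} for each posterior draw and each row of `newdata`,
#' standardizing the new data with the fit's frozen standardization info.
#' Country intercepts and country volume slopes are included for rows whose
#' country was in the estimation sample; province intercepts are included
#' when `newdata` carries a `province` seen in estimation and
#' `include_province` is `TRUE`. Unknown countries contribute the average
#' (zero) random effect.
#'
#' @param fit A `cost_fit`.
#' @param newdata Data frame with the predictor source columns and
#'   `country` (and optionally `province`).
#' @param include_province Include province intercepts when available.
#' @return Draws-by-rows matrix of linear predictors.
#' @export
linpred <- function(fit, newdata, include_province = FALSE) {
  des <- standardize_predictors(newdata, fit$spec, info = fit$std_info)
  d <- fit$draws
  S <- nrow(d); m <- nrow(newdata)
  eta <- matrix(d[, "(Intercept)"], S, m)
  if (ncol(des$X) > 0)
    eta <- eta + d[, colnames(des$X), drop = FALSE] %*% t(des$X)
  add_group <- function(eta, prefix, keys, scale = NULL) {
    for (j in seq_len(m)) {
      col <- paste0(prefix, "[", keys[[j]], "]")
      if (col %in% colnames(d)) {
        contrib <- d[, col]
        if (!is.null(scale)) contrib <- contrib * scale[[j]]
        eta[, j] <- eta[, j] + contrib
      }
    }
    eta
  }
  if (!is.null(newdata$country)) {
    eta <- add_group(eta, "alpha_country", newdata$country)
    if (!is.null(des$z_log_volume))
      eta <- add_group(eta, "gamma_country", newdata$country,
                       scale = des$z_log_volume)
    if (include_province && !is.null(newdata$province))
      eta <- add_group(eta, "alpha_province",
                       paste(newdata$country, newdata$province, sep = ":"))
  }
  eta
}

#' Typical-site covariate profile
#'
#' Builds a one-row profile for a country: medians of continuous
#' covariates and modal values of binary covariates over that country's
#' sites, with the country's GDP, for use in [predict_cost_curve()].
#'
#' @param table A site table.
#' @param country Country name.
#' @return One-row data frame.
#' @export
site_profile <- function(table, country) {
  cdat <- table[table$country == country, , drop = FALSE]
  if (!nrow(cdat)) stop("site_profile: no sites for country ", country)
  prof <- data.frame(country = country, stringsAsFactors = FALSE)
  for (nm in setdiff(names(cdat), c("site_id", "country", "province",
                                    "district"))) {
    x <- cdat[[nm]]
    prof[[nm]] <- if (all(x %in% c(0, 1))) as.numeric(names(which.max(
      table(x)))) else stats::median(x)
  }
  prof
}

#' Smearing-retransformed cost curves over a volume grid
#'
#' For each posterior draw and each grid volume, predicted total cost is
#' \eqn{\phi_s \exp(\eta_s(v))} with \eqn{\phi_s} that draw's Duan smearing
#' factor (pooled over the estimation sample); the average cost is the
#' total divided by the volume, pointwise. Draws are summarized by the
#' posterior mean and the equal-tailed 95% band.
#'
#' @param fit A `cost_fit`.
#' @param profile One-row covariate profile (see [site_profile()]); its
#'   `country` selects the random effects.
#' @param volume_grid Strictly positive, increasing volumes (doses/year).
#' @param smearing `"pooled"` (default) computes \eqn{\phi_s} from all
#'   residuals of the draw; `"country"` restricts to the profile's country.
#' @return A `cost_curve` data frame: `country`, `volume`, total-cost mean
#'   and 95% band, average-cost mean and band, with the mean smearing
#'   factor as attribute `smearing_factor` and a flag for grid points
#'   outside the observed country volume range.
#' @export
predict_cost_curve <- function(fit, profile, volume_grid,
                               smearing = c("pooled", "country")) {
  smearing <- match.arg(smearing)
  if (any(volume_grid <= 0))
    stop("predict_cost_curve: volume grid must be positive")
  volume_grid <- sort(volume_grid)
  newdata <- profile[rep(1L, length(volume_grid)), , drop = FALSE]
  newdata[[fit$spec$volume_measure]] <- volume_grid
  eta <- linpred(fit, newdata)
  res <- fit_residuals(fit)
  if (smearing == "country" && !is.null(fit$data))
    res <- res[, fit$data$country == profile$country[[1]], drop = FALSE]
  phi <- smearing_factor(res)
  total <- phi * exp(eta)                      # draws x grid
  qs <- function(mat, p) apply(mat, 2, stats::quantile, p)
  observed <- if (!is.null(fit$data)) {
    rng <- range(fit$data[[fit$spec$volume_measure]][
      fit$data$country == profile$country[[1]]])
    volume_grid >= rng[1] & volume_grid <= rng[2]
  } else rep(NA, length(volume_grid))
  out <- data.frame(
    country = profile$country[[1]], volume = volume_grid,
    total_mean = colMeans(total),
    total_lo = qs(total, 0.025), total_hi = qs(total, 0.975),
    avg_mean = colMeans(total) / volume_grid,
    avg_lo = qs(total, 0.025) / volume_grid,
    avg_hi = qs(total, 0.975) / volume_grid,
    within_observed_range = observed,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "smearing_factor") <- mean(phi)
  class(out) <- c("cost_curve", "data.frame")
  out
}

new_first_difference <- function(contrast, scope, vals) {
  data.frame(contrast = contrast, scope = scope,
             percent_change = 100 * (mean(vals) - 1),
             ci_low = 100 * (stats::quantile(vals, 0.025) - 1),
             ci_high = 100 * (stats::quantile(vals, 0.975) - 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' First difference for a predictor contrast
#'
#' The posterior percent change in cost per dose when one predictor moves
#' `from` one value `to` another, all else fixed. Because volume is held
#' fixed, the cost-per-dose ratio equals the total-cost ratio
#' \eqn{\exp(\Delta\eta)} and the smearing factor cancels. When `from`/`to`
#' are omitted for a continuous predictor, the default contrast is the
#' 25th to the 75th percentile of the sample distribution; binary
#' predictors default to 0 to 1. The ratio is computed per site of the
#' base sample and averaged within each draw (for scalar contrasts all
#' sites share the ratio), then summarized by the posterior mean and
#' equal-tailed 95% interval.
#'
#' @param fit A `cost_fit`.
#' @param predictor A predictor of the fitted spec.
#' @param from,to Raw-scale values of the contrast.
#' @param base Base sample (defaults to the estimation data).
#' @return A `first_difference` row: `contrast`, `scope`,
#'   `percent_change`, `ci_low`, `ci_high`.
#' @export
first_difference <- function(fit, predictor, from = NULL, to = NULL,
                             base = fit$data) {
  if (!predictor %in% fit$spec$predictors)
    stop("first_difference: predictor '", predictor,
         "' is not in the fitted specification")
  if (is.null(from) || is.null(to)) {
    if (predictor %in% .binary_predictors) {
      from <- from %||% 0; to <- to %||% 1
    } else {
      if (is.null(base))
        stop("first_difference: need a base sample for default quartile ",
             "contrast")
      x <- raw_predictor_column(base, predictor, fit$spec$volume_measure)
      q <- stats::quantile(x, c(0.25, 0.75))
      from <- from %||% q[[1]]; to <- to %||% q[[2]]
    }
  }
  # standardized shift is the same for every site
  st <- if (predictor == "log_doses") fit$std_info$volume else
    if (predictor == "log_doses_sq") fit$std_info$quad else
      fit$std_info$predictors[[predictor]]
  dz <- (to - from) / st[["sd"]]
  b <- fit$draws[, predictor]
  ratio <- exp(b * dz)
  new_first_difference(
    sprintf("%s: %.4g -> %.4g", predictor, from, to), "overall", ratio)
}

#' First difference for doubled service volume
#'
#' The posterior percent change in cost per dose when a site's annual dose
#' volume doubles: per draw, \eqn{\exp(\eta(2V) - \eta(V)) / 2}, which is
#' below 1 whenever the local volume derivative of log cost is below 1.
#' Per country, the base is a typical site ([site_profile()]) at the
#' country's median observed volume; the overall row is reported both as
#' the average over countries and as the per-site average over the whole
#' sample (each site's own volume doubled).
#'
#' @param fit A `cost_fit` with volume among its predictors.
#' @param table Base sample (defaults to the estimation data).
#' @return A `first_difference` data frame, one row per country plus
#'   `overall (country mean)` and `overall (site mean)` rows.
#' @export
volume_doubling_difference <- function(fit, table = fit$data) {
  if (!"log_doses" %in% fit$spec$predictors)
    stop("volume_doubling_difference: fitted spec lacks log_doses")
  vm <- fit$spec$volume_measure
  rows <- list()
  country_ratio <- list()
  for (cc in unique(table$country)) {
    prof <- site_profile(table, cc)
    v0 <- stats::median(table[[vm]][table$country == cc])
    nd <- prof[c(1L, 1L), , drop = FALSE]
    nd[[vm]] <- c(v0, 2 * v0)
    eta <- linpred(fit, nd)
    ratio <- exp(eta[, 2] - eta[, 1]) / 2
    country_ratio[[cc]] <- ratio
    rows[[cc]] <- new_first_difference("volume doubled from median", cc,
                                       ratio)
  }
  rows[["overall_country"]] <- new_first_difference(
    "volume doubled from median", "overall (country mean)",
    Reduce(`+`, country_ratio) / length(country_ratio))
  nd0 <- table; nd1 <- table
  nd1[[vm]] <- 2 * nd1[[vm]]
  ratio_site <- exp(linpred(fit, nd1, include_province = TRUE) -
                      linpred(fit, nd0, include_province = TRUE)) / 2
  rows[["overall_site"]] <- new_first_difference(
    "volume doubled (each site)", "overall (site mean)",
    rowMeans(ratio_site))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Country contrasts against the all-country mean
#'
#' For each country, the posterior percent difference in cost per dose
#' relative to the cross-country average, combining the country random
#' intercept, the country volume-slope contribution at the country's
#' median volume, and the GDP term at the country's per-capita GDP. The
#' comparator is the unweighted mean of the same quantity over countries,
#' so contrasts include cross-country differences in GDP while controlling
#' for the other predictors.
#'
#' @param fit A `cost_fit` including `log_gdp`.
#' @param table Base sample (defaults to the estimation data).
#' @return A `first_difference` data frame, one row per country.
#' @export
country_first_differences <- function(fit, table = fit$data) {
  vm <- fit$spec$volume_measure
  countries <- unique(table$country)
  d <- fit$draws
  S <- nrow(d)
  terms <- matrix(0, S, length(countries),
                  dimnames = list(NULL, countries))
  for (j in seq_along(countries)) {
    cc <- countries[[j]]
    t_c <- rep(0, S)
    col <- paste0("alpha_country[", cc, "]")
    if (col %in% colnames(d)) t_c <- t_c + d[, col]
    gcol <- paste0("gamma_country[", cc, "]")
    if (gcol %in% colnames(d)) {
      v0 <- stats::median(table[[vm]][table$country == cc])
      z <- (log(v0) - fit$std_info$volume[["mean"]]) /
        fit$std_info$volume[["sd"]]
      t_c <- t_c + d[, gcol] * z
    }
    if ("log_gdp" %in% colnames(d)) {
      gdp <- table$gdp_pc[table$country == cc][[1]]
      st <- fit$std_info$predictors[["log_gdp"]]
      t_c <- t_c + d[, "log_gdp"] * (log(gdp) - st[["mean"]]) / st[["sd"]]
    }
    terms[, j] <- t_c
  }
  rows <- lapply(countries, function(cc) {
    ratio <- exp(terms[, cc] - rowMeans(terms))
    new_first_difference("country vs overall mean", cc, ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-draw, per-site derivative d log C / d log V on the raw scale.
volume_derivative <- function(fit, table) {
  info <- fit$std_info
  s1 <- info$volume[["sd"]]; m1 <- info$volume[["mean"]]
  lv <- raw_predictor_column(table, "log_doses", fit$spec$volume_measure)
  z1 <- (lv - m1) / s1
  d <- fit$draws
  S <- nrow(d); n <- nrow(table)
  b1 <- if ("log_doses" %in% colnames(d)) d[, "log_doses"] else rep(0, S)
  D <- matrix(b1 / s1, S, n)
  if ("log_doses_sq" %in% colnames(d)) {
    b2 <- d[, "log_doses_sq"]
    if (fit$spec$quad_style == "z_of_zsq") {
      sq <- info$quad[["sd"]]
      D <- D + (b2 / (s1 * sq)) %o% (2 * z1)
    } else {
      sq <- info$quad[["sd"]]
      D <- D + (b2 / sq) %o% (2 * lv)
    }
  }
  for (cc in unique(table$country)) {
    gcol <- paste0("gamma_country[", cc, "]")
    if (gcol %in% colnames(d)) {
      idx <- which(table$country == cc)
      D[, idx] <- D[, idx] + d[, gcol] / s1
    }
  }
  D
}

#' Output elasticity by country
#'
#' The output elasticity is the percent increase in service volume
#' associated with a 1% increase in total costs; values above 1 indicate
#' economies of scale. At each site it is the reciprocal of the local
#' volume derivative of log cost, \eqn{1 / (d\log C / d\log V)}, with the
#' derivative evaluated analytically on the raw scale from the linear,
#' quadratic and country-slope terms. Per draw, site elasticities are
#' averaged within country (and over the pooled sample); draws are
#' summarized by the posterior mean and equal-tailed 95% interval.
#'
#' @param fit A `cost_fit` whose spec includes `log_doses`.
#' @param table Site sample (defaults to the estimation data).
#' @param average `"site_reciprocal"` (default) averages per-site
#'   reciprocals; `"reciprocal_of_mean"` inverts the average derivative.
#' @return Data frame: `country` (including `"pooled"`), `elasticity`,
#'   `ci_low`, `ci_high`.
#' @export
output_elasticity <- function(fit, table = fit$data,
                              average = c("site_reciprocal",
                                          "reciprocal_of_mean")) {
  average <- match.arg(average)
  if (!"log_doses" %in% fit$spec$predictors)
    stop("output_elasticity: fitted spec lacks log_doses")
  D <- volume_derivative(fit, table)
  frac_nonpos <- mean(colMeans(D) <= 0)
  if (frac_nonpos > 0.05)
    warning("output_elasticity: derivative of log cost non-positive at ",
            round(100 * frac_nonpos, 1), "% of sites; the elasticity ",
            "interpretation breaks down there", call. = FALSE)
  agg <- function(idx) {
    if (average == "site_reciprocal") rowMeans(1 / D[, idx, drop = FALSE])
    else 1 / rowMeans(D[, idx, drop = FALSE])
  }
  scopes <- c(as.list(unique(table$country)), list("pooled"))
  rows <- lapply(scopes, function(cc) {
    idx <- if (identical(cc, "pooled")) seq_len(nrow(table)) else
      which(table$country == cc)
    e <- agg(idx)
    data.frame(country = cc, elasticity = mean(e),
               ci_low = stats::quantile(e, 0.025),
               ci_high = stats::quantile(e, 0.975),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Volume-quintile contrast in predicted unit costs
#'
#' For each draw, the model-predicted cost per dose at each site's
#' observed volume and covariates (smearing factors cancel in the ratio);
#' sites are grouped into within-country quintiles by observed dose
#' volume, and the reported value is the percent by which the mean
#' predicted unit cost of the largest-volume quintile lies below that of
#' the smallest-volume quintile, \eqn{100 (1 - \bar u_{top} / \bar
#' u_{bottom})}.
#'
#' @param fit A `cost_fit`.
#' @param table Site sample (defaults to the estimation data).
#' @return Data frame: `country`, `percent_lower`, `ci_low`, `ci_high`.
#' @export
volume_quintile_contrast <- function(fit, table = fit$data) {
  vm <- fit$spec$volume_measure
  eta <- if (!is.null(fit$mu) && identical(table, fit$data)) fit$mu else
    linpred(fit, table, include_province = TRUE)
  u <- exp(eta) / matrix(table[[vm]], nrow(eta), nrow(table), byrow = TRUE)
  rows <- lapply(unique(table$country), function(cc) {
    idx <- which(table$country == cc)
    if (length(idx) < 5) {
      warning("country ", cc, " has < 5 sites; quintile contrast omitted",
              call. = FALSE)
      return(data.frame(country = cc, percent_lower = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        stringsAsFactors = FALSE))
    }
    g <- ceiling(5 * rank(table[[vm]][idx], ties.method = "first") /
                   length(idx))
    top <- idx[g == 5]; bot <- idx[g == 1]
    val <- 1 - rowMeans(u[, top, drop = FALSE]) /
      rowMeans(u[, bot, drop = FALSE])
    data.frame(country = cc, percent_lower = 100 * mean(val),
               ci_low = 100 * stats::quantile(val, 0.025),
               ci_high = 100 * stats::quantile(val, 0.975),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
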