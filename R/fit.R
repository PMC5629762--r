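# Bayesian hierarchical regression of log site costs, fitted with JAGS.

#' MCMC settings
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param adapt Adaptation iterations.
#' @param warmup Burn-in iterations after adaptation.
#' @param samples Posterior draws kept per chain.
#' @param seed Integer seed; per-chain RNG streams are derived from it.
#' @param rhat_threshold Hard convergence threshold on split-free Gelman
#'   R-hat of reported (recentred) parameters; 1.01 is flagged as advisory.
#' @param rhat_action `"error"` (default) or `"warn"` when the threshold is
#'   exceeded.
#' @return A list of settings.
#' @export
mcmc_control <- function(chains = 4, adapt = 500, warmup = 500,
                         samples = 1000, thin = 1, seed = 1L,
                         rhat_threshold = 1.05,
                         rhat_action = c("error", "warn")) {
  stopifnot(chains >= 2, samples >= 2, thin >= 1)
  list(chains = as.integer(chains), adapt = as.integer(adapt),
       warmup = as.integer(warmup), samples = as.integer(samples),
       thin = as.integer(thin), seed = as.integer(seed),
       rhat_threshold = rhat_threshold,
       rhat_action = match.arg(rhat_action))
}

# Assemble the JAGS model string for a given spec. Country-constant
# predictors (p_c of them) are hierarchically centred: they enter the
# country-level mean of the country intercepts rather than the site-level
# predictor, which leaves the marginal model unchanged but lets the Gibbs
# sampler mix over the country-effect/GDP trade-off.
build_jags_model <- function(spec, p, p_c = 0) {
  wk <- spec$prior_style == "weakly_informative"
  coef_prior <- if (wk) "dnorm(0, 0.16)" else "dnorm(0, 1.0E-6)"
  sd_prior <- if (wk) "dnorm(0, 1) T(0,)" else "dunif(0, 100)"
  terms <- "b0"
  if (p > 0) terms <- c(terms, "inprod(X[i,], beta)")
  lines <- character(0)
  re <- spec$random_effects
  cmean <- if (p_c > 0) "inprod(Xc[c,], beta_c)" else "0"
  beta_c_prior <- if (p_c > 0)
    paste0("for (j in 1:p_c) { beta_c[j] ~ ", coef_prior, " }")
  if (spec$country_effect_style == "fixed") {
    # unpooled country effects under the coefficient prior (no learned SD)
    terms <- c(terms, "a_c[country[i]]")
    lines <- c(lines,
      paste0("for (c in 1:n_country) { a_c[c] ~ dnorm(", cmean, ", ",
             if (wk) "0.16" else "1.0E-6", ") }"),
      beta_c_prior)
  } else if ("country_intercept" %in% re) {
    terms <- c(terms, "a_c[country[i]]")
    lines <- c(lines,
      paste0("for (c in 1:n_country) { a_c[c] ~ dnorm(", cmean,
             ", 1/pow(sig_c, 2)) }"),
      beta_c_prior,
      paste("sig_c ~", sd_prior))
  }
  if ("province_intercept" %in% re) {
    terms <- c(terms, "a_p[province[i]]")
    lines <- c(lines,
      "for (k in 1:n_province) { a_p[k] ~ dnorm(0, 1/pow(sig_p, 2)) }",
      paste("sig_p ~", sd_prior))
  }
  if ("district_intercept" %in% re) {
    terms <- c(terms, "a_d[district[i]]")
    lines <- c(lines,
      "for (d in 1:n_district) { a_d[d] ~ dnorm(0, 1/pow(sig_d, 2)) }",
      paste("sig_d ~", sd_prior))
  }
  if ("country_slope_log_volume" %in% re) {
    terms <- c(terms, "g_c[country[i]] * zv[i]")
    lines <- c(lines,
      "for (c in 1:n_country) { g_c[c] ~ dnorm(0, 1/pow(sig_g, 2)) }",
      paste("sig_g ~", sd_prior))
  }
  if (spec$eiv_coverage) {
    terms <- c(terms, "b_cov * ((kappa[i] - cov_m) / cov_s)")
    lines <- c(lines,
      paste("b_cov ~", coef_prior),
      "sd_e ~ dnorm(0, 4) T(0,)")
  }
  # Student-t written as a normal scale mixture so the glm module can
  # still block-sample the linear coefficients; marginally y is t(nu).
  lik <- if (spec$residual_family == "normal")
    "y[i] ~ dnorm(mu[i], tau)" else
      paste0("y[i] ~ dnorm(mu[i], tau * lam[i])\n",
             "    lam[i] ~ dgamma(0.5 * nu, 0.5 * nu)")
  eiv_obs <- if (spec$eiv_coverage) paste0(
    "    kappa[i] ~ dbeta(2, 2)\n",
    "    obs_cov[i] ~ dlnorm(log(kappa[i]), 1/pow(sd_e, 2))\n") else ""
  paste0(
    "model {\n",
    "  for (i in 1:n) {\n",
    "    mu[i] <- ", paste(terms, collapse = " + "), "\n",
    "    ", lik, "\n", eiv_obs,
    "  }\n",
    "  b0 ~ ", coef_prior, "\n",
    if (p > 0) paste0("  for (j in 1:p) { beta[j] ~ ", coef_prior, " }\n")
    else "",
    if (spec$residual_family == "student_t") "  nu ~ dunif(2, 100)\n"
    else "",
    "  sig ~ ", sd_prior, "\n",
    "  tau <- 1/pow(sig, 2)\n",
    paste0("  ", lines, "\n", collapse = ""),
    "}\n")
}

#' Fit a Bayesian hierarchical cost regression
#'
#' Regresses the natural log of total site-level cost (excluding above-site
#' costs) on standardized predictors with the random-effect structure,
#' residual family and priors given by `spec`, using JAGS. The linear
#' predictor is
#' \deqn{\eta_i = \beta_0 + x_i'\beta + \alpha_{c(i)} + \alpha_{p(i)}
#'   [+ \alpha_{d(i)}] [+ \gamma_{c(i)} z(\log V_i)]}
#' with half-Normal(0,1) hierarchical SDs and Normal(0, 2.5) coefficient
#' priors by default. With `eiv_coverage`, observed DTP3 coverage is
#' treated as a latent true coverage times multiplicative lognormal error,
#' and the (standardized) latent coverage enters the linear predictor.
#'
#' Random-effect draws are recentred for reporting (group means swept into
#' the intercept, and the mean country slope into the `log_doses`
#' coefficient) because the raw split is only weakly identified with few
#' groups; convergence diagnostics are computed on the recentred
#' parameters and the fit fails (or warns, per `mcmc$rhat_action`) if any
#' R-hat exceeds the threshold.
#'
#' @param table A validated site table with positive costs.
#' @param spec A [model_spec()].
#' @param mcmc Settings from [mcmc_control()].
#' @return An object of class `cost_fit`: posterior draw matrix
#'   (`$draws`, chains stacked, with `$chain` indices), per-draw linear
#'   predictors `$mu`, pointwise log-likelihood `$loglik`, the outcome
#'   `$y`, `$spec`, `$std_info`, group levels, and `$diagnostics` (R-hat,
#'   effective sample sizes, WAIC).
#' @export
fit_model <- function(table, spec, mcmc = mcmc_control()) {
  if (any(table$total_cost_usd <= 0))
    stop("fit_model: non-positive costs; log outcome undefined")
  y <- log(table$total_cost_usd)
  n <- length(y)
  des <- standardize_predictors(table, spec)
  X <- des$X
  country_lv <- unique(table$country)
  ci_map <- match(table$country, country_lv)
  prov_key <- paste(table$country, table$province, sep = ":")
  prov_lv <- unique(prov_key)
  need_country <- spec$country_effect_style == "fixed" ||
    any(c("country_intercept", "country_slope_log_volume") %in%
          spec$random_effects)
  has_cre <- spec$country_effect_style == "fixed" ||
    "country_intercept" %in% spec$random_effects
  # country-constant predictors move to the country level (hierarchical
  # centring); the marginal model is unchanged
  hc_cols <- character(0)
  if (has_cre && ncol(X) > 0) {
    rng <- vapply(seq_len(ncol(X)), function(j)
      max(tapply(X[, j], ci_map, function(v) diff(range(v)))),
      numeric(1))
    hc_cols <- colnames(X)[rng < 1e-12]
  }
  Xc <- NULL
  if (length(hc_cols)) {
    Xc <- as.matrix(X[match(country_lv, table$country), hc_cols,
                      drop = FALSE])
    X <- X[, setdiff(colnames(X), hc_cols), drop = FALSE]
  }
  p <- ncol(X)
  p_c <- length(hc_cols)
  data <- list(n = n, y = y)
  if (p > 0) { data$X <- X; data$p <- p }
  if (p_c > 0) { data$Xc <- Xc; data$p_c <- p_c }
  if (need_country) {
    data$country <- ci_map
    data$n_country <- length(country_lv)
  }
  if ("province_intercept" %in% spec$random_effects) {
    data$province <- match(prov_key, prov_lv)
    data$n_province <- length(prov_lv)
  }
  dist_lv <- NULL
  if ("district_intercept" %in% spec$random_effects) {
    if (is.null(table$district))
      stop("fit_model: district random effects need a 'district' column")
    dist_key <- paste(table$country, table$district, sep = ":")
    dist_lv <- unique(dist_key)
    data$district <- match(dist_key, dist_lv)
    data$n_district <- length(dist_lv)
  }
  if ("country_slope_log_volume" %in% spec$random_effects)
    data$zv <- des$z_log_volume
  if (spec$eiv_coverage) {
    if (is.null(table$dtp3_coverage))
      stop("fit_model: eiv_coverage needs a 'dtp3_coverage' column")
    data$obs_cov <- table$dtp3_coverage
    tc <- top_code(table$dtp3_coverage)
    data$cov_m <- mean(tc); data$cov_s <- stats::sd(tc)
  }

  monitors <- c("b0", "sig", "mu")
  if (p > 0) monitors <- c(monitors, "beta")
  if (p_c > 0) monitors <- c(monitors, "beta_c")
  if (spec$country_effect_style != "fixed" &&
      "country_intercept" %in% spec$random_effects)
    monitors <- c(monitors, "a_c", "sig_c")
  if (spec$country_effect_style == "fixed") monitors <- c(monitors, "a_c")
  if ("province_intercept" %in% spec$random_effects)
    monitors <- c(monitors, "a_p", "sig_p")
  if ("district_intercept" %in% spec$random_effects)
    monitors <- c(monitors, "a_d", "sig_d")
  if ("country_slope_log_volume" %in% spec$random_effects)
    monitors <- c(monitors, "g_c", "sig_g")
  if (spec$residual_family == "student_t") monitors <- c(monitors, "nu")
  if (spec$eiv_coverage) monitors <- c(monitors, "b_cov", "sd_e", "kappa")

  # block-samples the linear-model coefficients; essential for mixing over
  # the country-effect / country-covariate trade-off
  suppressMessages(try(rjags::load.module("glm", quiet = TRUE),
                       silent = TRUE))
  model_txt <- build_jags_model(spec, p, p_c)
  inits <- lapply(seq_len(mcmc$chains), function(ch) list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = (mcmc$seed * 101 + ch * 977) %% 2147483629))
  jm <- rjags::jags.model(textConnection(model_txt), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$adapt, quiet = TRUE)
  if (mcmc$warmup > 0)
    update(jm, n.iter = mcmc$warmup, progress.bar = "none")
  thin <- mcmc$thin %||% 1L
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = mcmc$samples * thin, thin = thin,
                              progress.bar = "none")

  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain <- rep(seq_len(mcmc$chains), each = mcmc$samples)

  # readable parameter names
  cn <- colnames(draws)
  rename <- function(prefix, levels, new) {
    idx <- grep(paste0("^", prefix, "\\["), cn)
    if (length(idx))
      cn[idx] <<- paste0(new, "[", levels[as.integer(
        sub(paste0(prefix, "\\[(\\d+)\\]"), "\\1", cn[idx]))], "]")
  }
  rename_vec <- function(var, new_names) {
    idx <- grep(paste0("^", var, "(\\[|$)"), cn)
    if (!length(idx)) return(invisible())
    num <- sub(paste0(var, "\\[(\\d+)\\]"), "\\1", cn[idx])
    num[cn[idx] == var] <- "1"   # coda drops brackets for length-1 vectors
    cn[idx] <<- new_names[as.integer(num)]
  }
  if (p > 0) rename_vec("beta", colnames(X))
  if (p_c > 0) rename_vec("beta_c", hc_cols)
  rename("a_c", country_lv, "alpha_country")
  rename("a_p", prov_lv, "alpha_province")
  if (!is.null(dist_lv)) rename("a_d", dist_lv, "alpha_district")
  rename("g_c", country_lv, "gamma_country")
  cn[cn == "b0"] <- "(Intercept)"
  colnames(draws) <- cn

  # express country effects as deviations from their country-level mean
  ac_idx <- grep("^alpha_country\\[", colnames(draws))
  if (length(ac_idx) && p_c > 0) {
    pred_c <- draws[, hc_cols, drop = FALSE] %*% t(Xc)
    draws[, ac_idx] <- draws[, ac_idx, drop = FALSE] - pred_c
  }
  # recentre random effects into the intercept / slope coefficient
  sweep_mean <- function(group_prefix, into) {
    idx <- grep(paste0("^", group_prefix, "\\["), colnames(draws))
    if (length(idx) < 2) return(invisible())
    m <- rowMeans(draws[, idx, drop = FALSE])
    draws[, idx] <<- draws[, idx, drop = FALSE] - m
    draws[, into] <<- draws[, into] + m
  }
  sweep_mean("alpha_country", "(Intercept)")
  sweep_mean("alpha_province", "(Intercept)")
  sweep_mean("alpha_district", "(Intercept)")
  if ("country_slope_log_volume" %in% spec$random_effects &&
      "log_doses" %in% colnames(draws))
    sweep_mean("gamma_country", "log_doses")

  mu_idx <- grep("^mu\\[", colnames(draws))
  mu <- draws[, mu_idx[order(as.integer(sub("mu\\[(\\d+)\\]", "\\1",
                                            colnames(draws)[mu_idx])))],
              drop = FALSE]
  kappa <- NULL
  ki <- grep("^kappa\\[", colnames(draws))
  if (length(ki)) {
    kappa <- draws[, ki[order(as.integer(sub("kappa\\[(\\d+)\\]", "\\1",
                                             colnames(draws)[ki])))],
                   drop = FALSE]
  }
  draws <- draws[, -c(mu_idx, ki), drop = FALSE]

  sig <- draws[, "sig"]
  loglik <- if (spec$residual_family == "normal") {
    matrix(stats::dnorm(rep(y, each = nrow(mu)), mu, sig, log = TRUE),
           nrow(mu), n)
  } else {
    nu <- draws[, "nu"]
    t(vapply(seq_len(nrow(mu)), function(s)
      stats::dt((y - mu[s, ]) / sig[s], nu[s], log = TRUE) - log(sig[s]),
      numeric(n)))
  }

  waic <- compute_waic(loglik)
  structural <- setdiff(colnames(draws), character(0))
  mcl <- coda::as.mcmc.list(lapply(split.data.frame(draws, chain),
                                   coda::mcmc))
  keep <- structural[apply(draws, 2, stats::sd) > 1e-12]
  gd <- try(coda::gelman.diag(mcl[, keep, drop = FALSE],
                              multivariate = FALSE,
                              autoburnin = FALSE)$psrf[, 1], silent = TRUE)
  rhat <- if (inherits(gd, "try-error"))
    stats::setNames(rep(NA_real_, length(keep)), keep) else gd
  ess <- coda::effectiveSize(mcl[, keep, drop = FALSE])

  diagnostics <- list(rhat = rhat, ess = ess, waic = waic$waic,
                      waic_se = waic$waic_se, lppd = waic$lppd,
                      p_waic = waic$p_waic, n_obs = n,
                      pointwise = waic$pointwise, label = spec$label)
  fit <- structure(list(
    draws = draws, chain = chain, mu = mu, loglik = loglik, y = y,
    kappa = kappa, spec = spec, std_info = des$info,
    z_log_volume = des$z_log_volume,
    countries = country_lv, provinces = prov_lv, districts = dist_lv,
    data = table, mcmc = mcmc, diagnostics = diagnostics
  ), class = "cost_fit")

  bad <- rhat[is.finite(rhat) & rhat > mcmc$rhat_threshold]
  if (length(bad)) {
    msg <- paste0("fit_model: R-hat exceeds ", mcmc$rhat_threshold,
                  " for ", paste0(names(bad), " (", round(bad, 3), ")",
                                  collapse = ", "))
    if (mcmc$rhat_action == "error")
      stop(errorCondition(msg, class = c("imcost_convergence_error",
                                         "error", "condition")))
    warning(msg, call. = FALSE)
  } else if (any(is.finite(rhat) & rhat > 1.01)) {
    message("fit_model: advisory: some R-hat values exceed 1.01")
  }
  fit
}

#' @export
print.cost_fit <- function(x, ...) {
  cat("Hierarchical cost regression (", x$spec$label, ")\n", sep = "")
  cat("  n =", x$diagnostics$n_obs, "sites;",
      length(x$countries), "countries\n")
  cat("  WAIC =", round(x$diagnostics$waic, 1),
      " (lppd", round(x$diagnostics$lppd, 1),
      ", p_waic", round(x$diagnostics$p_waic, 1), ")\n")
  cat("  max R-hat =", round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Posterior summary of fitted parameters
#' @param object A `cost_fit`.
#' @param ... Unused.
#' @return Data frame with posterior mean, SD and 95% equal-tailed
#'   interval per parameter.
#' @export
summary.cost_fit <- function(object, ...) {
  d <- object$draws
  data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2, stats::sd),
    q2.5 = apply(d, 2, stats::quantile, 0.025),
    q97.5 = apply(d, 2, stats::quantile, 0.975),
    rhat = object$diagnostics$rhat[colnames(d)],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Watanabe-Akaike information criterion
#'
#' From a draws-by-observations matrix of pointwise log-likelihoods:
#' the log pointwise predictive density is
#' \eqn{\mathrm{lppd} = \sum_j \log\left(\frac{1}{S}\sum_s
#' \exp \ell_{sj}\right)} (computed in log space), the effective number of
#' parameters is \eqn{p_{\mathrm{WAIC}} = \sum_j \mathrm{Var}_s(\ell_{sj})}
#' (sample variance, n-1 denominator), and
#' \eqn{\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})}. Lower
#' values indicate better estimated out-of-sample fit.
#'
#' @param loglik Numeric matrix, draws in rows, observations in columns.
#' @return List with `lppd`, `p_waic`, `waic`, `waic_se`, and the
#'   `pointwise` WAIC contributions.
#' @examples
#' compute_waic(log(matrix(c(0.2, 0.4), 2, 1)))
#' @export
compute_waic <- function(loglik) {
  if (!is.matrix(loglik) || nrow(loglik) < 2)
    stop("compute_waic: need a matrix with >= 2 draws")
  if (any(!is.finite(loglik)))
    stop("compute_waic: non-finite log-likelihood entries (zero or ",
         "underflowed likelihoods must be handled upstream in log space)")
  S <- nrow(loglik)
  m <- apply(loglik, 2, max)
  lppd_i <- m + log(colMeans(exp(sweep(loglik, 2, m, "-"))))
  p_i <- apply(loglik, 2, stats::var)
  pointwise <- -2 * (lppd_i - p_i)
  list(lppd = sum(lppd_i), p_waic = sum(p_i),
       waic = sum(pointwise),
       waic_se = sqrt(ncol(loglik) * stats::var(pointwise)),
       pointwise = pointwise)
}

#' Rank fitted models by WAIC
#'
#' @param fits A named list of `cost_fit` objects (or of diagnostics lists
#'   carrying `waic` and `n_obs`), all fitted to the identical observation
#'   set.
#' @return Data frame sorted ascending by WAIC with the difference to the
#'   best model (`delta_waic`).
#' @export
compare_models <- function(fits) {
  diag1 <- lapply(fits, function(f)
    if (inherits(f, "cost_fit")) f$diagnostics else f)
  n_obs <- vapply(diag1, `[[`, 0, "n_obs")
  if (length(unique(n_obs)) != 1)
    stop("compare_models: fits cover differing observation counts")
  waic <- vapply(diag1, `[[`, 0, "waic")
  lab <- names(fits) %||% vapply(diag1, function(d)
    d$label %||% "model", "")
  ord <- order(waic)
  data.frame(model = lab[ord], waic = waic[ord],
             delta_waic = waic[ord] - min(waic),
             lppd = vapply(diag1, `[[`, 0, "lppd")[ord],
             p_waic = vapply(diag1, `[[`, 0, "p_waic")[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Degenerate (point-mass) posterior at known raw-scale parameters
#'
#' Builds a `cost_fit`-shaped object whose single posterior draw places all
#' mass at given raw-scale coefficients, for closed-form checks of
#' post-estimation quantities. The standardization info is the identity
#' (mean 0, SD 1), so standardized and raw scales coincide; country
#' intercepts and volume slopes can be supplied directly, and the residual
#' scale defaults to 0 (smearing factor exactly 1).
#'
#' @param coefficients Named numeric vector including `intercept`; other
#'   names must be valid predictors.
#' @param country_effects,country_slopes Optional named numeric vectors of
#'   per-country intercepts / log-volume slopes.
#' @param sigma Residual scale (default 0).
#' @param table Optional site table attached as `$data` for sample-based
#'   contrasts.
#' @param n_draws Number of identical draws (default 1).
#' @return A `cost_fit` object.
#' @export
point_mass_fit <- function(coefficients, country_effects = NULL,
                           country_slopes = NULL, sigma = 0,
                           table = NULL, n_draws = 1L) {
  stopifnot("intercept" %in% names(coefficients))
  preds <- setdiff(names(coefficients), "intercept")
  res <- c(if (!is.null(country_effects)) "country_intercept",
           if (!is.null(country_slopes)) "country_slope_log_volume")
  spec <- model_spec(predictors = preds,
                     random_effects = res %||% character(0),
                     quad_style = "z_of_zsq",
                     label = "point mass")
  info <- list(predictors = stats::setNames(
    lapply(preds, function(x) c(mean = 0, sd = 1)), preds),
    volume = c(mean = 0, sd = 1), quad = c(mean = 0, sd = 1),
    quad_style = "z_of_zsq", volume_measure = "doses")
  class(info) <- "standardization_info"
  cols <- c("(Intercept)", preds,
            if (!is.null(country_effects))
              paste0("alpha_country[", names(country_effects), "]"),
            if (!is.null(country_slopes))
              paste0("gamma_country[", names(country_slopes), "]"),
            "sig")
  vals <- c(coefficients[["intercept"]],
            unname(coefficients[preds]),
            unname(country_effects), unname(country_slopes), sigma)
  draws <- matrix(rep(vals, each = n_draws), n_draws, length(vals),
                  dimnames = list(NULL, cols))
  countries <- union(names(country_effects), names(country_slopes))
  structure(list(
    draws = draws, chain = rep(1L, n_draws), mu = NULL,
    loglik = NULL, y = NULL, kappa = NULL, spec = spec, std_info = info,
    countries = countries %||% character(0), provinces = character(0),
    districts = NULL, data = table, mcmc = NULL,
    diagnostics = list(rhat = NA, waic = NA, n_obs = NA)
  ), class = "cost_fit")
}
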