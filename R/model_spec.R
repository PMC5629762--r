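# Declarative regression specifications and predictor standardization.

.all_predictors <- c("log_doses", "log_doses_sq", "log_gdp", "govt_owned",
                     "hospital", "fraction_outreach", "fraction_mgmt",
                     "dtp3_per_dose", "rural", "anc4", "wealth_ratio",
                     "staffing_index", "dedication_index", "days_per_week",
                     "log_distance", "inpatient_beds_cat",
                     "dtp3_coverage_topcoded", "log_population")
.binary_predictors <- c("govt_owned", "hospital", "rural")
.all_res <- c("country_intercept", "province_intercept", "district_intercept",
              "country_slope_log_volume")

#' Specify one regression variant
#'
#' A declarative description of one Bayesian hierarchical regression of log
#' total site cost: which predictors enter, which volume measure is used,
#' the random-effect structure, the residual family, the prior style, and
#' whether reported DTP3 coverage is modelled with measurement error
#' (error-in-variables).
#'
#' @param predictors Character vector of predictor names (see Details).
#' @param volume_measure `"doses"` (default) or `"dtp3"`: the count whose
#'   log enters as `log_doses` and drives the country volume slopes.
#' @param random_effects Subset of `"country_intercept"`,
#'   `"province_intercept"`, `"district_intercept"`,
#'   `"country_slope_log_volume"`.
#' @param country_effect_style `"random"` or `"fixed"`; fixed country
#'   effects are reference-coded dummies and exclude the country random
#'   intercept.
#' @param residual_family `"normal"` or `"student_t"` (robust variant).
#' @param prior_style `"weakly_informative"` (Normal(0, 2.5) coefficients,
#'   half-Normal(0, 1) scales) or `"non_informative"` (essentially flat).
#' @param eiv_coverage Model observed DTP3 coverage as a latent true
#'   coverage times multiplicative lognormal error; the latent value enters
#'   the linear predictor.
#' @param standardize_binary Z-score binary predictors too (default FALSE:
#'   binary predictors stay on the 0/1 scale).
#' @param quad_style How the squared-volume term is built:
#'   `"z_of_zsq"` (default) z-scores the square of the z-scored log volume,
#'   preserving the per-SD reading of coefficients; `"raw_sq"` z-scores the
#'   square of raw log volume.
#' @param label Optional display label.
#' @return An object of class `model_spec`.
#' @seealso [model_preset()] for the nested Model 1-5 series.
#' @export
model_spec <- function(predictors = character(0),
                       volume_measure = c("doses", "dtp3"),
                       random_effects = c("country_intercept",
                                          "province_intercept"),
                       country_effect_style = c("random", "fixed"),
                       residual_family = c("normal", "student_t"),
                       prior_style = c("weakly_informative",
                                       "non_informative"),
                       eiv_coverage = FALSE,
                       standardize_binary = FALSE,
                       quad_style = c("z_of_zsq", "raw_sq"),
                       label = NULL) {
  volume_measure <- match.arg(volume_measure)
  country_effect_style <- match.arg(country_effect_style)
  residual_family <- match.arg(residual_family)
  prior_style <- match.arg(prior_style)
  quad_style <- match.arg(quad_style)
  bad <- setdiff(predictors, .all_predictors)
  if (length(bad))
    stop("model_spec: unknown predictor(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(random_effects, .all_res)
  if (length(bad))
    stop("model_spec: unknown random effect(s): ", paste(bad, collapse = ", "))
  if ("log_doses_sq" %in% predictors && !"log_doses" %in% predictors)
    stop("model_spec: log_doses_sq requires log_doses")
  if (country_effect_style == "fixed" &&
      "country_intercept" %in% random_effects)
    stop("model_spec: fixed country effects exclude the country random ",
         "intercept")
  if (eiv_coverage && "dtp3_coverage_topcoded" %in% predictors)
    stop("model_spec: eiv_coverage replaces dtp3_coverage_topcoded; do not ",
         "include both")
  structure(list(
    predictors = predictors, volume_measure = volume_measure,
    random_effects = random_effects,
    country_effect_style = country_effect_style,
    residual_family = residual_family, prior_style = prior_style,
    eiv_coverage = eiv_coverage, standardize_binary = standardize_binary,
    quad_style = quad_style,
    label = label %||% paste0(length(predictors), "-predictor model")
  ), class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The nested Model 1-5 presets
#'
#' Model 1 is intercept plus country- and province-level random intercepts;
#' Model 2 adds log volume and its square; Model 3 adds log per-capita GDP
#' and site characteristics (government ownership, hospital status,
#' outreach and management fractions, DTP3 per dose); Model 4 adds
#' operating-environment variables (rural, ANC4, wealth ratio); Model 5
#' adds country-level random slopes for log volume.
#'
#' @param k Integer 1-5.
#' @param ... Overrides passed on to [model_spec()] (e.g.
#'   `residual_family`, `prior_style`, `volume_measure`).
#' @return A `model_spec`.
#' @export
model_preset <- function(k, ...) {
  stopifnot(k %in% 1:5)
  p2 <- c("log_doses", "log_doses_sq")
  p3 <- c(p2, "log_gdp", "govt_owned", "hospital", "fraction_outreach",
          "fraction_mgmt", "dtp3_per_dose")
  p4 <- c(p3, "rural", "anc4", "wealth_ratio")
  preds <- list(character(0), p2, p3, p4, p4)[[k]]
  res <- c("country_intercept", "province_intercept")
  if (k == 5) res <- c(res, "country_slope_log_volume")
  args <- utils::modifyList(
    list(predictors = preds, random_effects = res,
         label = paste("Model", k)),
    list(...))
  do.call(model_spec, args)
}

continuous_stats <- function(x, name) {
  if (any(!is.finite(x)))
    stop("standardize_predictors: non-finite values in column '", name, "'")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("standardize_predictors: continuous column '", name,
         "' is constant")
  c(mean = mean(x), sd = s)
}

# Raw column for a predictor name, deriving logs and top-coding as needed.
raw_predictor_column <- function(table, name, volume_measure = "doses") {
  need <- function(col) {
    if (is.null(table[[col]]))
      stop("standardize_predictors: missing column '", col, "'")
    table[[col]]
  }
  switch(name,
    log_doses = log(need(volume_measure)),
    log_gdp = log(need("gdp_pc")),
    log_distance = log(need("distance_km")),
    log_population = log(need("catchment_pop")),
    dtp3_coverage_topcoded = top_code(need("dtp3_coverage")),
    need(name))
}

#' Standardize predictors into a design matrix
#'
#' Continuous predictors are z-scored on the pooled estimation sample;
#' binary predictors pass through on the 0/1 scale (unless
#' `standardize_binary`); the squared-volume term is the z-score of the
#' square of the z-scored log volume (default `quad_style`). Fitted
#' coefficients on this scale read as the change in log total cost per
#' 1 SD change in the predictor. The returned standardization info is
#' sufficient to rebuild the design for new data and to invert the
#' transform exactly.
#'
#' @param table A site table.
#' @param spec A [model_spec()].
#' @param info A `standardization_info` from a previous call; when given,
#'   its means/SDs are reused (for predictions on new data) instead of
#'   being recomputed.
#' @return A list with `X` (design matrix, no intercept column),
#'   `z_log_volume` (the z-scored log volume, used by country slopes), and
#'   `info` (class `standardization_info`).
#' @export
standardize_predictors <- function(table, spec, info = NULL) {
  vm <- spec$volume_measure
  build <- is.null(info)
  if (build) {
    info <- list(predictors = list(), volume = NULL, quad = NULL,
                 quad_style = spec$quad_style, volume_measure = vm)
  }
  # volume z-score (needed for country slopes even without the predictor)
  need_vol <- "log_doses" %in% spec$predictors ||
    "country_slope_log_volume" %in% spec$random_effects
  z1 <- NULL
  if (need_vol) {
    lv <- raw_predictor_column(table, "log_doses", vm)
    if (build) info$volume <- continuous_stats(lv, "log_doses")
    z1 <- (lv - info$volume[["mean"]]) / info$volume[["sd"]]
  }
  cols <- list()
  for (nm in spec$predictors) {
    if (nm == "log_doses") {
      cols[[nm]] <- z1
    } else if (nm == "log_doses_sq") {
      q <- if (spec$quad_style == "z_of_zsq") z1^2 else
        raw_predictor_column(table, "log_doses", vm)^2
      if (build) info$quad <- continuous_stats(q, "log_doses_sq")
      cols[[nm]] <- (q - info$quad[["mean"]]) / info$quad[["sd"]]
    } else {
      x <- raw_predictor_column(table, nm, vm)
      is_bin <- nm %in% .binary_predictors && !spec$standardize_binary
      if (is_bin) {
        cols[[nm]] <- x
        if (build) info$predictors[[nm]] <- c(mean = 0, sd = 1)
      } else {
        if (build) info$predictors[[nm]] <- continuous_stats(x, nm)
        st <- info$predictors[[nm]]
        cols[[nm]] <- (x - st[["mean"]]) / st[["sd"]]
      }
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(table), 0)
  colnames(X) <- names(cols)
  class(info) <- "standardization_info"
  list(X = X, z_log_volume = z1, info = info)
}

#' De-standardize a column (round-trip inverse)
#' @param z Standardized values.
#' @param info A `standardization_info`.
#' @param name Predictor name.
#' @return The raw-scale values.
#' @export
destandardize <- function(z, info, name) {
  st <- if (name == "log_doses") info$volume else
    if (name == "log_doses_sq") info$quad else info$predictors[[name]]
  if (is.null(st)) stop("destandardize: no standardization info for ", name)
  z * st[["sd"]] + st[["mean"]]
}

#' Expected standardized-scale coefficients from generator ground truth
#'
#' Maps the generator's raw-scale coefficients onto the scale of a fitted
#' standardized design, for parameter-recovery checks. For volume the
#' quadratic raw model \eqn{b_1 x + b_2 x^2} plus the mean realized country
#' slope re-expressed in the z-basis gives a `log_doses` coefficient
#' \eqn{(b_1 + 2 m b_2 + \bar\gamma)\,s} and a `log_doses_sq` coefficient
#' \eqn{b_2 s^2 s_q}, with \eqn{m, s} the mean/SD of log volume and
#' \eqn{s_q} the SD of the squared z-score. Other continuous predictors
#' scale by their SD; binary predictors are unchanged.
#'
#' @param truth A `true_params` object from [generate_dataset()].
#' @param info The `standardization_info` of the fit.
#' @param spec The fitted [model_spec()].
#' @return Named numeric vector of expected standardized coefficients.
#' @export
true_standardized_coefficients <- function(truth, info, spec) {
  b <- truth$coefficients
  out <- numeric(0)
  for (nm in spec$predictors) {
    val <- if (nm == "log_doses") {
      m1 <- info$volume[["mean"]]; s1 <- info$volume[["sd"]]
      (b[["log_doses"]] + 2 * m1 * (b["log_doses_sq"] %|NA|% 0) +
         mean(truth$country_slopes)) * s1
    } else if (nm == "log_doses_sq") {
      (b["log_doses_sq"] %|NA|% 0) * info$volume[["sd"]]^2 *
        info$quad[["sd"]]
    } else if (nm %in% .binary_predictors && !spec$standardize_binary) {
      b[nm] %|NA|% 0
    } else {
      (b[nm] %|NA|% 0) * info$predictors[[nm]][["sd"]]
    }
    out[nm] <- unname(val)
  }
  out
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
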