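# Survey-weighted average-cost estimation and multi-stage bootstrap.

.estimands <- c(dose = "cost_per_dose", dtp3 = "cost_per_dtp3",
                site = "cost_per_site")

outcome_vector <- function(table, outcome) {
  switch(outcome,
         dose = table$doses,
         dtp3 = table$dtp3,
         site = rep(1, nrow(table)),
         stop("unknown outcome '", outcome, "'"))
}

new_cost_summary <- function(scope, estimand, estimator, point,
                             low = NA_real_, high = NA_real_,
                             interval_method = NA_character_,
                             includes_above_site = FALSE) {
  structure(data.frame(
    scope = scope, estimand = estimand, estimator = estimator,
    point = point, interval_low = low, interval_high = high,
    interval_method = interval_method,
    includes_above_site = includes_above_site,
    stringsAsFactors = FALSE
  ), class = c("cost_summary", "data.frame"))
}

#' Program-level (volume-weighted) average cost
#'
#' The weighted average cost per outcome is the survey-weighted sum of site
#' costs divided by the survey-weighted sum of outputs,
#' \eqn{\sum_i w_i C_i / \sum_i w_i O_i}, equivalent to a weighted average
#' of site-level unit costs with weights proportional to service volume:
#' the cost per outcome assessed at the program level. For
#' `outcome = "site"` the denominator is \eqn{\sum_i w_i}.
#'
#' @param table A validated site table.
#' @param outcome One of `"dose"`, `"dtp3"`, `"site"`.
#' @param by `"country"`, `"pooled"`, or `"both"`.
#' @return A `cost_summary` data frame (one row per scope) with the point
#'   estimate; intervals are attached by [multistage_bootstrap_ci()] or
#'   [cost_summary_table()].
#' @examples
#' tab <- generate_dataset(epic_like_config(seed = 1))$table
#' weighted_average_cost(tab, "dose")
#' @export
weighted_average_cost <- function(table, outcome = c("dose", "dtp3", "site"),
                                  by = c("both", "country", "pooled")) {
  outcome <- match.arg(outcome); by <- match.arg(by)
  o <- outcome_vector(table, outcome)
  est <- function(rows, scope) {
    den <- sum(table$weight[rows] * o[rows])
    if (den <= 0)
      stop("weighted_average_cost: zero aggregate outcome for estimand ",
           .estimands[[outcome]], " in scope ", scope)
    new_cost_summary(scope, .estimands[[outcome]], "weighted",
                     sum(table$weight[rows] * table$total_cost_usd[rows]) /
                       den)
  }
  rows_by_scope(table, by, est)
}

#' Simple (per-site) average cost
#'
#' The survey-weighted mean of per-site unit costs,
#' \eqn{\sum_i w_i (C_i/O_i) / \sum_i w_i}. Unlike the program-level
#' estimator this gives every site equal (design-weighted) influence, so
#' it exceeds the volume-weighted average whenever small sites have higher
#' unit costs.
#'
#' @inheritParams weighted_average_cost
#' @export
simple_average_cost <- function(table, outcome = c("dose", "dtp3", "site"),
                                by = c("both", "country", "pooled")) {
  outcome <- match.arg(outcome); by <- match.arg(by)
  o <- outcome_vector(table, outcome)
  if (any(o == 0))
    stop("simple_average_cost: site with zero ", outcome,
         " makes cost per ", outcome, " undefined")
  ratio <- table$total_cost_usd / o
  est <- function(rows, scope) {
    new_cost_summary(scope, .estimands[[outcome]], "simple",
                     stats::weighted.mean(ratio[rows], table$weight[rows]))
  }
  rows_by_scope(table, by, est)
}

rows_by_scope <- function(table, by, est) {
  out <- list()
  if (by %in% c("both", "country")) {
    for (cc in unique(table$country))
      out[[cc]] <- est(which(table$country == cc), cc)
  }
  if (by %in% c("both", "pooled"))
    out[["pooled"]] <- est(seq_len(nrow(table)), "pooled")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cost_summary", "data.frame")
  res
}

#' Above-site markup schedule
#'
#' Above-site program-support costs (subnational and national
#' administration) are applied as a fixed percentage markup on site-level
#' costs; the total markup is the sum of the two components, i.e. a
#' multiplicative factor \eqn{1 + m_{sub} + m_{nat}}.
#'
#' @param country Character vector of country names.
#' @param subnational,national Markup fractions (>= 0).
#' @return A `markup_schedule` data frame with a `total` column.
#' @export
markup_schedule <- function(country, subnational, national) {
  if (any(subnational < 0) || any(national < 0))
    stop("markup_schedule: markups must be >= 0")
  structure(data.frame(country = country, subnational = subnational,
                       national = national,
                       total = subnational + national,
                       stringsAsFactors = FALSE),
            class = c("markup_schedule", "data.frame"))
}

#' Markup schedule from a generator configuration
#' @param config A [generator_config()].
#' @return A [markup_schedule()] with one row per country.
#' @export
config_markups <- function(config) {
  markup_schedule(
    vapply(config$countries, `[[`, "", "name"),
    vapply(config$countries, `[[`, 0, "markup_subnational"),
    vapply(config$countries, `[[`, 0, "markup_national"))
}

#' Apply above-site markups to a cost summary
#'
#' Multiplies point estimates and interval endpoints by the country's
#' markup factor \eqn{1 + m_{sub} + m_{nat}} and flags the summary as
#' including above-site costs. Applying a markup twice is an error, as is
#' applying per-country markups to a pooled-scope row.
#'
#' @param summary A `cost_summary` excluding above-site costs.
#' @param markups A [markup_schedule()].
#' @return The marked-up `cost_summary`.
#' @export
apply_above_site_markup <- function(summary, markups) {
  if (any(summary$includes_above_site))
    stop("apply_above_site_markup: summary already includes above-site costs")
  if (any(summary$scope == "pooled"))
    stop("apply_above_site_markup: per-country markups cannot be applied to ",
         "a pooled row; apply per country and re-pool")
  idx <- match(summary$scope, markups$country)
  if (anyNA(idx))
    stop("apply_above_site_markup: no markup for country ",
         summary$scope[which(is.na(idx))[1]])
  f <- 1 + markups$total[idx]
  for (col in c("point", "interval_low", "interval_high"))
    summary[[col]] <- summary[[col]] * f
  summary$includes_above_site <- TRUE
  summary
}

# Built-in fast statistics for the bootstrap, computed from index vectors.
.builtin_stats <- c("weighted_cost_per_dose", "weighted_cost_per_dtp3",
                    "weighted_cost_per_site", "simple_cost_per_dose",
                    "simple_cost_per_dtp3", "simple_cost_per_site")

builtin_stat_fun <- function(name, table) {
  parts <- strsplit(name, "_per_")[[1]]
  outcome <- parts[[2]]
  o <- outcome_vector(table, outcome)
  w <- table$weight; cst <- table$total_cost_usd
  if (startsWith(name, "weighted")) {
    wc <- w * cst; wo <- w * o
    function(idx) sum(wc[idx]) / sum(wo[idx])
  } else {
    r <- cst / o
    function(idx) stats::weighted.mean(r[idx], w[idx])
  }
}

#' Multi-stage bootstrap percentile interval
#'
#' For each replicate, provinces are resampled with replacement within
#' each country, then sites are resampled with replacement within each
#' selected province (survey weights travel with their sites), and the
#' statistic is recomputed; the interval is the percentile interval of the
#' replicate distribution. A country with a single province degenerates to
#' site-level resampling only (with a warning).
#'
#' @param table A site table.
#' @param statistic Either a function mapping a site table to a single
#'   number, or one of the built-in names
#'   `"weighted_cost_per_dose"`, `"weighted_cost_per_dtp3"`,
#'   `"weighted_cost_per_site"`, `"simple_cost_per_dose"`,
#'   `"simple_cost_per_dtp3"`, `"simple_cost_per_site"` (these avoid
#'   per-replicate data-frame construction and are much faster).
#' @param replicates Number of bootstrap replicates (default 50000, as
#'   used for the published interval estimates; tests and exploratory runs
#'   use fewer).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return A list with `interval` (named `c(low, high)`), `point` (the
#'   statistic on the original table), `replicates`, `level`, `seed`, and
#'   the replicate values `stats`.
#' @export
multistage_bootstrap_ci <- function(table, statistic, replicates = 50000,
                                    level = 0.95, seed = 1L) {
  stopifnot(replicates >= 1)
  countries <- unique(table$country)
  prov_sites <- lapply(countries, function(cc) {
    rows <- which(table$country == cc)
    sp <- split(rows, table$province[rows])
    if (length(sp) == 1L)
      warning("country ", cc, " has a single province; falling back to ",
              "site-only resampling", call. = FALSE)
    sp
  })
  if (is.character(statistic)) {
    statistic <- match.arg(statistic, .builtin_stats)
    stat_idx <- builtin_stat_fun(statistic, table)
    point <- stat_idx(seq_len(nrow(table)))
  } else {
    stat_fun <- statistic
    stat_idx <- function(idx) stat_fun(table[idx, , drop = FALSE])
    point <- stat_fun(table)
  }
  set.seed(seed)
  vals <- vapply(seq_len(replicates), function(r) {
    idx <- unlist(lapply(prov_sites, function(sp) {
      P <- length(sp)
      ps <- if (P == 1L) 1L else sample.int(P, P, replace = TRUE)
      unlist(lapply(sp[ps], function(si) {
        si[sample.int(length(si), length(si), replace = TRUE)]
      }), use.names = FALSE)
    }), use.names = FALSE)
    stat_idx(idx)
  }, numeric(1))
  a <- (1 - level) / 2
  iv <- unname(stats::quantile(vals, c(a, 1 - a), type = 7, na.rm = TRUE))
  list(interval = c(low = iv[[1]], high = iv[[2]]), point = point,
       replicates = replicates, level = level, seed = seed, stats = vals)
}

#' Within-country dispersion of unit costs
#'
#' Per country: the coefficient of variation of the site-level cost per
#' dose (unweighted sample SD over mean, n-1 denominator) and the quintile
#' ratio, the mean cost per dose in the most expensive quintile of sites
#' over the mean in the least expensive quintile, minus one. Quintiles are
#' defined by within-country rank of cost per dose. Countries with fewer
#' than 5 sites get `NA` for the quintile ratio, with a warning.
#'
#' @param table A site table.
#' @return A data frame with columns `country`, `n`, `cv`, `quintile_ratio`.
#' @export
dispersion_stats <- function(table) {
  res <- lapply(split(table, table$country), function(cdat) {
    u <- cdat$total_cost_usd / cdat$doses
    n <- length(u)
    cv <- stats::sd(u) / mean(u)
    if (n < 5) {
      warning("country ", cdat$country[[1]], " has < 5 sites; quintile ",
              "ratio omitted", call. = FALSE)
      qr <- NA_real_
    } else {
      g <- ceiling(5 * rank(u, ties.method = "first") / n)
      qr <- mean(u[g == 5]) / mean(u[g == 1]) - 1
    }
    data.frame(country = cdat$country[[1]], n = n, cv = cv,
               quintile_ratio = qr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full average-cost summary table with bootstrap intervals
#'
#' Builds the per-country summary of average costs per site, per dose and
#' per DTP3 (weighted and simple estimators), with multi-stage bootstrap
#' percentile intervals, excluding and (when a markup schedule is given)
#' including above-site costs.
#'
#' @param table A site table.
#' @param markups Optional [markup_schedule()].
#' @param replicates,level,seed Passed to [multistage_bootstrap_ci()].
#' @return A `cost_summary` data frame.
#' @export
cost_summary_table <- function(table, markups = NULL, replicates = 2000,
                               level = 0.95, seed = 1L) {
  combos <- expand.grid(outcome = c("site", "dose", "dtp3"),
                        estimator = c("weighted", "simple"),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    oc <- combos$outcome[[k]]; es <- combos$estimator[[k]]
    fn <- if (es == "weighted") weighted_average_cost else simple_average_cost
    summ <- fn(table, oc, by = "country")
    stat <- paste0(es, "_cost_per_", oc)
    for (j in seq_len(nrow(summ))) {
      cc <- summ$scope[[j]]
      ci <- multistage_bootstrap_ci(table[table$country == cc, , drop = FALSE],
                                    stat, replicates = replicates,
                                    level = level,
                                    seed = seed + 13L * (k - 1L) + j)
      summ$interval_low[[j]] <- ci$interval[["low"]]
      summ$interval_high[[j]] <- ci$interval[["high"]]
      summ$interval_method[[j]] <- "multistage_bootstrap"
    }
    summ$replicates <- replicates
    summ$seed <- seed
    rows[[stat]] <- summ
  }
  out <- do.call(rbind, rows)
  if (!is.null(markups)) {
    marked <- apply_above_site_markup(out, markups)
    out <- rbind(out, marked)
  }
  rownames(out) <- NULL
  class(out) <- c("cost_summary", "data.frame")
  out
}
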