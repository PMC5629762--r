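# Orchestration: generate -> summarize -> fit -> post-estimate, with a
# reproducible run manifest.

#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' before any computation.
#'
#' @param out_dir Output directory (created if needed).
#' @param input Optional CSV path of an existing site table; when `NULL`
#'   the site table is generated from `preset`.
#' @param preset Generator preset; currently `"epic_like"`.
#' @param models Integer subset of 1:5, the regression presets to fit.
#' @param mcmc [mcmc_control()] settings.
#' @param bootstrap List with `replicates` and `level`.
#' @param seed Master seed for generation, bootstrap and MCMC.
#' @param export_draws Write long-format posterior draws for the best
#'   model.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input = NULL, preset = "epic_like",
                            models = 1:5, mcmc = mcmc_control(thin = 5),
                            bootstrap = list(replicates = 2000,
                                             level = 0.95),
                            seed = 1L, export_draws = FALSE) {
  cfg <- as.list(environment())
  known <- c("out_dir", "input", "preset", "models", "mcmc", "bootstrap",
             "seed", "export_draws")
  validate_pipeline_config(cfg, known)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg, known) {
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    validation_error("pipeline config has unknown key(s): ",
                     paste(extra, collapse = ", "))
  if (!all(cfg$models %in% 1:5))
    validation_error("pipeline config: 'models' must be a subset of 1:5")
  if (!identical(cfg$preset, "epic_like"))
    validation_error("pipeline config: unknown preset '", cfg$preset, "'")
  if (!is.numeric(cfg$bootstrap$replicates) ||
      cfg$bootstrap$replicates < 1)
    validation_error("pipeline config: bootstrap replicates must be >= 1")
  invisible(cfg)
}

#' Coerce a plain list into a pipeline configuration
#'
#' Useful for configs read from JSON; unknown keys are rejected.
#' @param x A named list.
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  stopifnot(is.list(x), !is.null(x$out_dir))
  extra <- setdiff(names(x), names(formals(pipeline_config)))
  if (length(extra))
    validation_error("pipeline config has unknown key(s): ",
                     paste(extra, collapse = ", "))
  do.call(pipeline_config, x)
}

stage_log <- function(stage, t0, seed) {
  message(sprintf("[%s] done elapsed=%.2fs seed=%s", stage,
                  as.numeric(Sys.time() - t0, units = "secs"), seed))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: obtain a site table (generate from the
#' preset, or read `input`), compute the average-cost summary table with
#' multi-stage bootstrap intervals and dispersion statistics, fit the
#' requested regression presets and rank them by WAIC, and run
#' post-estimation (country and predictor first differences, volume
#' doubling, output elasticities, cost curves) on the best-fitting model.
#' All tabular outputs are written as CSV under `config$out_dir`; a run
#' manifest with per-file MD5 checksums, per-stage runtimes and seeds is
#' written as `manifest.json`. An identical config and seed reproduces
#' identical checksums.
#'
#' Failures raise classed conditions: `imcost_validation_error` (bad
#' input), `imcost_convergence_error` (R-hat above threshold),
#' `imcost_io_error` (unreadable input).
#'
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("imcost")), seed = config$seed,
    stages = list(), files = list())
  files <- character(0)
  t_all <- Sys.time()

  # --- stage: data
  t0 <- Sys.time()
  markups <- NULL; truth <- NULL
  if (!is.null(config$input)) {
    tab <- read_site_table(config$input)
  } else {
    gen_cfg <- epic_like_config(seed = config$seed)
    ds <- generate_dataset(gen_cfg)
    tab <- ds$table; truth <- ds$truth
    markups <- config_markups(gen_cfg)
    files <- c(files, write_dataset(ds, file.path(config$out_dir,
                                                  "site_table.csv")))
  }
  manifest$stages$data <- as.numeric(Sys.time() - t0, units = "secs")
  stage_log("data", t0, config$seed)

  # --- stage: summarize
  t0 <- Sys.time()
  summ <- cost_summary_table(tab, markups = markups,
                             replicates = config$bootstrap$replicates,
                             level = config$bootstrap$level,
                             seed = config$seed)
  f <- file.path(config$out_dir, "table2_analogue.csv")
  utils::write.csv(summ, f, row.names = FALSE); files <- c(files, f)
  disp <- dispersion_stats(tab)
  f <- file.path(config$out_dir, "dispersion.csv")
  utils::write.csv(disp, f, row.names = FALSE); files <- c(files, f)
  manifest$stages$summarize <- as.numeric(Sys.time() - t0, units = "secs")
  stage_log("summarize", t0, config$seed)

  # --- stage: fit
  t0 <- Sys.time()
  fits <- list()
  for (k in config$models) {
    mc <- config$mcmc
    mc$seed <- config$seed + k
    fits[[paste0("Model ", k)]] <- fit_model(tab, model_preset(k), mc)
  }
  ranking <- compare_models(fits)
  f <- file.path(config$out_dir, "waic.csv")
  utils::write.csv(ranking, f, row.names = FALSE); files <- c(files, f)
  f <- file.path(config$out_dir, "table3_analogue.csv")
  utils::write.csv(coefficient_table(fits), f, row.names = FALSE)
  files <- c(files, f)
  best <- fits[[ranking$model[[1]]]]
  if (isTRUE(config$export_draws)) {
    f <- file.path(config$out_dir, "posterior_draws.csv")
    export_draws(best, f); files <- c(files, f)
  }
  if (!is.null(truth) && length(best$spec$predictors)) {
    tru <- true_standardized_coefficients(truth, best$std_info, best$spec)
    ss <- summary(best)
    ss <- ss[match(names(tru), ss$parameter), ]
    rec <- data.frame(parameter = names(tru), truth = unname(tru),
                      posterior_mean = ss$mean, posterior_sd = ss$sd,
                      q2.5 = ss$q2.5, q97.5 = ss$q97.5,
                      covered = tru >= ss$q2.5 & tru <= ss$q97.5)
    f <- file.path(config$out_dir, "recovery.csv")
    utils::write.csv(rec, f, row.names = FALSE); files <- c(files, f)
  }
  manifest$stages$fit <- as.numeric(Sys.time() - t0, units = "secs")
  stage_log("fit", t0, config$seed)

  # --- stage: postest
  t0 <- Sys.time()
  if (length(best$spec$predictors)) {
    fd <- rbind(
      country_first_differences(best, tab),
      do.call(rbind, lapply(
        intersect(best$spec$predictors,
                  c("govt_owned", "hospital", "rural", "fraction_outreach",
                    "fraction_mgmt", "dtp3_per_dose", "anc4",
                    "wealth_ratio")),
        function(p) first_difference(best, p))),
      volume_doubling_difference(best, tab))
    f <- file.path(config$out_dir, "table4_analogue.csv")
    utils::write.csv(fd, f, row.names = FALSE); files <- c(files, f)
    el <- output_elasticity(best, tab)
    f <- file.path(config$out_dir, "elasticity.csv")
    utils::write.csv(el, f, row.names = FALSE); files <- c(files, f)
    qc <- volume_quintile_contrast(best, tab)
    f <- file.path(config$out_dir, "quintile_contrast.csv")
    utils::write.csv(qc, f, row.names = FALSE); files <- c(files, f)
    curves <- do.call(rbind, lapply(unique(tab$country), function(cc) {
      v <- tab[[best$spec$volume_measure]][tab$country == cc]
      grid <- exp(seq(log(min(v)), log(max(v)), length.out = 40))
      predict_cost_curve(best, site_profile(tab, cc), grid)
    }))
    f <- file.path(config$out_dir, "fig1_data.csv")
    utils::write.csv(curves, f, row.names = FALSE); files <- c(files, f)
  }
  manifest$stages$postest <- as.numeric(Sys.time() - t0, units = "secs")
  stage_log("postest", t0, config$seed)

  manifest$total_runtime <- as.numeric(Sys.time() - t_all, units = "secs")
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Table 3-style coefficient summary across fitted models
#' @param fits Named list of `cost_fit` objects.
#' @return Data frame: one row per parameter, posterior mean and SD per
#'   model, plus WAIC and sample-size rows.
#' @export
coefficient_table <- function(fits) {
  summaries <- lapply(fits, summary)
  pars <- unique(unlist(lapply(summaries, `[[`, "parameter")))
  pars <- pars[!grepl("^(alpha_|gamma_|mu\\[)", pars)]
  out <- data.frame(parameter = pars, stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    s <- summaries[[nm]]
    i <- match(pars, s$parameter)
    out[[paste0(nm, "_mean")]] <- round(s$mean[i], 3)
    out[[paste0(nm, "_sd")]] <- round(s$sd[i], 3)
  }
  extra <- data.frame(parameter = c("WAIC", "n"),
                      stringsAsFactors = FALSE)
  for (nm in names(fits)) {
    extra[[paste0(nm, "_mean")]] <- c(
      round(fits[[nm]]$diagnostics$waic, 1), fits[[nm]]$diagnostics$n_obs)
    extra[[paste0(nm, "_sd")]] <- NA
  }
  rbind(out, extra)
}

#' Export posterior draws in long format
#' @param fit A `cost_fit`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
export_draws <- function(fit, path) {
  d <- fit$draws
  long <- data.frame(
    chain = rep(fit$chain, ncol(d)),
    draw = rep(ave(fit$chain, fit$chain, FUN = seq_along), ncol(d)),
    parameter = rep(colnames(d), each = nrow(d)),
    value = as.vector(d), stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / read a model specification as JSON
#' @param spec A [model_spec()].
#' @param path JSON path.
#' @return `write_model_spec`: invisibly `path`; `read_model_spec`: a
#'   `model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$predictors <- as.character(x$predictors %||% character(0))
  x$random_effects <- as.character(x$random_effects %||% character(0))
  do.call(model_spec, x)
}
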