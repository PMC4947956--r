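input_schemas <- list(
  dose = c("dose_Gy", "n_cells", "n_dead"),
  growth = c("time_h", "biomass_gL"),
  screening = "strain_id",   # plus >= 2 numeric rating columns
  ph = c("time_h", "pH"),
  fermentation = c("time_h", "butyrate_gL", "acetate_gL", "glucose_gL",
                   "od600", "gas")
)

#' Read and validate a pipeline input table
#'
#' Reads a headered CSV of one of the five pipeline input kinds,
#' validates its columns against the expected schema with per-column
#' error messages, warns about (and drops) unknown columns, and returns
#' the corresponding validated container.
#'
#' @param path CSV file path.
#' @param kind one of `"dose"`, `"growth"`, `"screening"`, `"ph"`,
#'   `"fermentation"`.
#' @return A [dose_table()], [growth_series()], [screening_matrix()],
#'   [ph_series()] or [fermentation_series()].
#' @export
read_input_table <- function(path, kind = c("dose", "growth", "screening",
                                            "ph", "fermentation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort_validation(sprintf("file '%s' not found", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   abort_validation(sprintf("cannot parse '%s' as CSV: %s",
                                            path, conditionMessage(e))))
  if (nrow(df) == 0L) abort_validation(sprintf("'%s' contains no data rows", path))
  required <- input_schemas[[kind]]
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort_validation(sprintf("'%s' is missing required column(s): %s",
                             path, paste(missing, collapse = ", ")))
  if (kind != "screening") {
    extra <- setdiff(names(df), c(required, "log_dose", "latent_pH"))
    if (length(extra)) {
      warning(sprintf("ignoring unknown column(s) in '%s': %s", path,
                      paste(extra, collapse = ", ")))
      df <- df[setdiff(names(df), extra)]
    }
    numeric_cols <- setdiff(names(df), "strain_id")
    for (cl in numeric_cols)
      if (!is.numeric(df[[cl]]))
        abort_validation(sprintf("column '%s' in '%s' has non-numeric cells",
                                 cl, path))
  }
  switch(kind,
    dose = {
      bad <- which(df$n_dead > df$n_cells)
      if (length(bad))
        abort_validation(sprintf("row %d of '%s' has deaths > cells at risk",
                                 bad[1], path))
      dose_table(df$dose_Gy, df$n_cells, df$n_dead)
    },
    growth = growth_series(df$time_h, df$biomass_gL),
    screening = {
      ratings <- df[setdiff(names(df), "strain_id")]
      for (cl in names(ratings))
        if (!is.numeric(ratings[[cl]]))
          abort_validation(sprintf("rating column '%s' in '%s' is non-numeric",
                                   cl, path))
      screening_matrix(as.matrix(ratings), strain_id = df$strain_id)
    },
    ph = ph_series(df$time_h, df$pH, latent_pH = df$latent_pH),
    fermentation = fermentation_series(df$time_h, df$butyrate_gL,
                                       df$acetate_gL, df$glucose_gL,
                                       df$od600, df$gas))
}

#' Write a pipeline input table as CSV
#'
#' Inverse of [read_input_table()]: writes any of the five validated
#' containers in the CSV dialect the readers accept (comma separator,
#' dot decimal, one header row). Round-trips are value-identical.
#'
#' @param x a validated input container.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_input_table <- function(x, path) {
  df <- if (inherits(x, "dose_table"))
    data.frame(dose_Gy = x$dose, n_cells = x$n, n_dead = x$deaths)
  else if (inherits(x, "growth_series"))
    data.frame(time_h = x$time_h, biomass_gL = x$biomass_gL)
  else if (inherits(x, "screening_matrix"))
    data.frame(strain_id = x$strain_id, x$ratings, check.names = FALSE)
  else if (inherits(x, "ph_series") || inherits(x, "fermentation_series"))
    as.data.frame(x)
  else abort_validation("unsupported object type for write_input_table")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Stage selection and per-stage parameter blocks for [run_pipeline()].
#' Unknown stage names or parameter-block names are rejected.
#'
#' @param stages character subset of
#'   `c("fixtures", "doseresponse", "growth", "screen", "ph", "ferment")`,
#'   executed in that order.
#' @param seed global integer seed; stage seeds are derived from it.
#' @param doseresponse,growth,screen,ph,ferment named lists of stage
#'   overrides (e.g. `doseresponse = list(n_steps = 1000)`).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(stages = c("fixtures", "doseresponse", "growth",
                                       "screen", "ph", "ferment"),
                            seed = 1,
                            doseresponse = list(), growth = list(),
                            screen = list(), ph = list(), ferment = list()) {
  all_stages <- c("fixtures", "doseresponse", "growth", "screen", "ph",
                  "ferment")
  unknown <- setdiff(stages, all_stages)
  if (length(unknown))
    abort_validation(sprintf("unknown stage(s): %s",
                             paste(unknown, collapse = ", ")))
  check_number(seed, "seed", lower = 0)
  blocks <- list(doseresponse = doseresponse, growth = growth,
                 screen = screen, ph = ph, ferment = ferment)
  known_keys <- list(
    doseresponse = c("n_steps", "link"),
    growth = c("method", "n_steps", "scenarios", "noise_sd"),
    screen = c("n_strains", "components"),
    ph = c("scenarios"),
    ferment = c("scenarios"))
  for (b in names(blocks)) {
    bad <- setdiff(names(blocks[[b]]), known_keys[[b]])
    if (length(bad))
      abort_validation(sprintf("unknown key(s) in '%s' block: %s", b,
                               paste(bad, collapse = ", ")))
  }
  structure(c(list(stages = stages, seed = seed), blocks),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in order on packaged/synthetic inputs --
#' fixture materialization, dose-response MLE + DRAM posterior, growth
#' fits, PCA screening, Kalman filtering and fermentation summaries --
#' writing every artifact under `outdir` together with a resolved-config
#' copy and a manifest listing each output file with its stage. Fully
#' deterministic under the config's seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory, created if needed.
#' @return Invisibly, the manifest `data.frame` (columns `stage`, `file`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  seed <- config$seed
  manifest <- list()
  add <- function(stage, file) manifest[[length(manifest) + 1]] <<-
    data.frame(stage = stage, file = file)
  emit_json <- function(x, file) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
    file
  }

  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  for (stage in config$stages) switch(stage,
    fixtures = run_stage("fixtures", {
      fdir <- file.path(outdir, "fixtures")
      files <- write_fixtures(fdir, seed = seed)
      for (f in files) add("fixtures", f)
    }),
    doseresponse = run_stage("doseresponse", {
      opts <- utils::modifyList(list(n_steps = 5000, link = "logit"),
                                config$doseresponse)
      tab <- table1_dose_response()
      fit <- fit_dose_response(tab, link = opts$link)
      f1 <- emit_json(list(beta0 = coef(fit)[["beta0"]],
                           beta1 = coef(fit)[["beta1"]],
                           link = opts$link, loglik = fit$loglik,
                           deviance = fit$deviance,
                           vcov = fit$vcov),
                      file.path(outdir, "dose_response_fit.json"))
      chain <- dose_posterior_chain(tab, fit, n_steps = opts$n_steps,
                                    seed = seed + 10)
      f2 <- write_chain_csv(chain, file.path(outdir, "dose_response_chain.csv"))
      env <- predictive_envelope(chain,
        function(th, g) inv_link(th[1] + th[2] * log10(g), opts$link),
        grid = tab$dose, seed = seed + 11)
      f3 <- write_envelope_csv(env, file.path(outdir, "dose_response_envelope.csv"))
      ppp <- posterior_predictive_p(chain, tab, seed = seed + 12)
      f4 <- emit_json(list(posterior_predictive_p = ppp),
                      file.path(outdir, "dose_response_ppp.json"))
      for (f in c(f1, f2, f3, f4)) add("doseresponse", f)
    }),
    growth = run_stage("growth", {
      opts <- utils::modifyList(list(method = "linear", n_steps = 5000,
                                     scenarios = c("butyrate10", "butyrate12"),
                                     noise_sd = 0), config$growth)
      for (sc in opts$scenarios) {
        p <- growth_scenario(sc)
        s <- gen_growth_curve(sc, noise_sd = opts$noise_sd, seed = seed + 20)
        fit <- fit_growth_linear(s, x_m = p$x_m)
        f <- emit_json(list(scenario = sc, mu_m = fit$mu_m,
                            intercept = fit$intercept,
                            x0_implied = fit$x0_implied, rss = fit$rss),
                       file.path(outdir, paste0("growth_fit_", sc, ".json")))
        add("growth", f)
        if (opts$method == "bayes") {
          bf <- fit_growth_bayes(s, x_m = p$x_m, n_steps = opts$n_steps,
                                 seed = seed + 21)
          fc <- write_chain_csv(bf$chain,
                                file.path(outdir, paste0("growth_chain_", sc, ".csv")))
          fe <- write_envelope_csv(bf$envelope_obs,
                                   file.path(outdir, paste0("growth_envelope_", sc, ".csv")))
          add("growth", fc); add("growth", fe)
        }
      }
    }),
    screen = run_stage("screen", {
      opts <- utils::modifyList(list(n_strains = 329, components = 3),
                                config$screen)
      m <- gen_screening_matrix(n_strains = opts$n_strains, seed = seed + 30)
      pc <- weighted_pca(m)
      t2 <- hotelling_t2(pc, k = opts$components)
      f1 <- file.path(outdir, "screen_scores.csv")
      utils::write.csv(data.frame(strain_id = pc$strain_id, pc$scores),
                       f1, row.names = FALSE)
      f2 <- file.path(outdir, "screen_t2.csv")
      utils::write.csv(data.frame(strain_id = pc$strain_id, t2 = t2,
                                  rank = match(pc$strain_id,
                                               rank_outliers(t2, pc$strain_id))),
                       f2, row.names = FALSE)
      add("screen", f1); add("screen", f2)
    }),
    ph = run_stage("ph", {
      opts <- utils::modifyList(list(scenarios = c("pH5.0", "pH4.5")),
                                config$ph)
      for (sc in opts$scenarios) {
        s <- gen_ph_trajectory(sc, seed = seed + 40)
        kf <- kalman_filter(s)
        f <- file.path(outdir, paste0("ph_filtered_", sc, ".csv"))
        utils::write.csv(kf$states, f, row.names = FALSE)
        add("ph", f)
      }
    }),
    ferment = run_stage("ferment", {
      opts <- utils::modifyList(list(scenarios = c("pH5.0", "pH4.5")),
                                config$ferment)
      for (sc in opts$scenarios) {
        s <- gen_fermentation(sc, seed = seed + 50)
        sm <- summarize_fermentation(s)
        f <- emit_json(unclass(sm),
                       file.path(outdir, paste0("ferment_summary_", sc, ".json")))
        add("ferment", f)
      }
    }))

  emit_json(list(stages = config$stages, seed = seed,
                 doseresponse = config$doseresponse, growth = config$growth,
                 screen = config$screen, ph = config$ph,
                 ferment = config$ferment),
            file.path(outdir, "config.json"))
  man <- do.call(rbind, manifest)
  if (is.null(man)) man <- data.frame(stage = character(), file = character())
  utils::write.csv(man, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' DRAM chain for the binomial dose-response posterior
#'
#' Convenience wrapper: samples the flat-prior posterior of
#' `(beta0, beta1)` for a dose-response table with the DRAM sampler,
#' initialized at (and proposal-scaled by) the maximum-likelihood fit.
#'
#' @param table a [dose_table()].
#' @param fit optional pre-computed [fit_dose_response()] result.
#' @param n_steps chain length (default 5000).
#' @param seed optional integer seed.
#' @param link link function.
#' @return A `"dram_chain"` with columns `beta0`, `beta1`.
#' @export
dose_posterior_chain <- function(table, fit = NULL, n_steps = 5000,
                                 seed = NULL, link = "logit") {
  if (is.null(fit)) fit <- fit_dose_response(table, link = link)
  lp <- function(th)
    dose_log_likelihood(link_params(th[1], th[2], link), table)
  run_dram(lp, init = coef(fit), n_steps = n_steps,
           options = dram_options(init_cov = fit$vcov), seed = seed,
           param_names = c("beta0", "beta1"))
}
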