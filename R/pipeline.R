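#' Build and validate a pipeline configuration
#'
#' The whole analysis — load or simulate a design, fit the polynomial,
#' run the ANOVA/adequacy report, residual and Box-Cox diagnostics,
#' desirability optimisation, network training and model comparison —
#' is driven by one configuration object. Exactly one input source must
#' be given: `input = list(bundled = TRUE)` for the packaged 30-run
#' dataset, `input = list(csv = "path")` for a design CSV (read with
#' the bundled factor specs unless `factors` is supplied), or
#' `input = list(simulate = list(noise_sd = ..., seed = ...))` to draw
#' synthetic responses from the bundled ground-truth surface.
#'
#' All stochastic stages (simulation, network training, optimiser
#' starts) derive their seeds from the single global `seed`.
#'
#' @param input Input-source list (see above).
#' @param model Model order for the surface fit.
#' @param ann Named list of overrides for [ann_config()] (e.g.
#'   `list(restarts = 200)`).
#' @param desirability Named list: `direction`, `n_starts`, optional
#'   `bounds` (k x 2 matrix).
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @param factors Optional list of [factor_spec()] for CSV input.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(bundled = TRUE),
                            model = "quadratic",
                            ann = list(),
                            desirability = list(),
                            out_dir = tempfile("rsmnet-run-"),
                            seed = 1L,
                            log_level = "info",
                            factors = NULL) {
  cfg <- list(input = input, model = model, ann = ann,
              desirability = desirability, out_dir = out_dir,
              seed = as.integer(seed), log_level = log_level,
              factors = factors)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("input", "model", "ann", "desirability", "out_dir", "seed",
             "log_level", "factors")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (nm in setdiff(known, names(cfg))) cfg[[nm]] <- formals(pipeline_config)[[nm]]
  src <- intersect(names(cfg$input), c("bundled", "csv", "simulate"))
  if (length(src) != 1L)
    stop("`input` must name exactly one source: bundled, csv or simulate",
         call. = FALSE)
  bad_in <- setdiff(names(cfg$input), c("bundled", "csv", "simulate"))
  if (length(bad_in))
    stop("unknown input key(s): ", paste(bad_in, collapse = ", "),
         call. = FALSE)
  if (!cfg$model %in% c("linear", "2fi", "quadratic"))
    stop("`model` must be linear, 2fi or quadratic", call. = FALSE)
  if (!cfg$log_level %in% c("info", "quiet"))
    stop("`log_level` must be info or quiet", call. = FALSE)
  bad_ann <- setdiff(names(cfg$ann), names(formals(ann_config)))
  if (length(bad_ann))
    stop("unknown ann key(s): ", paste(bad_ann, collapse = ", "),
         call. = FALSE)
  bad_des <- setdiff(names(cfg$desirability),
                     c("direction", "n_starts", "bounds", "weight"))
  if (length(bad_des))
    stop("unknown desirability key(s): ", paste(bad_des, collapse = ", "),
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full optimisation analysis
#'
#' Executes every stage on the configured input and writes the report
#' bundle to `out_dir`: the design with per-model predictions
#' (`design.csv`), the ANOVA (`anova.csv`/`anova.json`), the three-model
#' fit summary (`fit_summary.csv`), per-run diagnostics
#' (`diagnostics.csv`), the Box-Cox profile summary (`boxcox.json`),
#' the desirability optimum (`optimization.json`), the network weights
#' (`ann_weights.json`), the model comparison (`comparison.csv` /
#' `comparison.json`) and a text log (`run.log`). Identical
#' configurations and seeds give byte-identical JSON/CSV reports.
#'
#' @param config A [pipeline_config()], a plain list of its fields, or
#'   the path of a YAML file holding them.
#' @return Invisibly, a list with the fitted objects and the vector of
#'   files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg, "\n",
        file = logf, append = TRUE, sep = "")
    if (identical(config$log_level, "info")) message(msg)
  }
  seed <- config$seed

  data <- if (!is.null(config$input$bundled)) {
    say("loading bundled 30-run dataset")
    load_aunps_ccd()
  } else if (!is.null(config$input$csv)) {
    path <- config$input$csv
    if (!file.exists(path))
      stop("input file not found: ", path, call. = FALSE)
    say("reading design from %s", path)
    read_design_csv(path, config$factors %||% aunps_factors())
  } else {
    sim <- config$input$simulate
    say("simulating responses from the bundled ground-truth surface")
    truth <- aunps_true_model(
      noise_sd = sim$noise_sd %||% 26.47,
      seed = sim$seed %||% (seed + 101L))
    simulate_response(make_ccd(aunps_factors(), n_center = 6), truth)
  }

  fit <- fit_model(data, config$model)
  av <- anova(fit)
  ad <- adequacy(fit)
  say("fitted %s model: R2 %.4f, PRESS %.2f", config$model, ad$r2, ad$press)
  fs <- fit_summary(data)
  diag <- residual_diagnostics(fit)
  bc <- box_cox(data, order = config$model)
  say("Box-Cox lambda_hat %.2f, CI (%.2f, %.2f)", bc$lambda_hat,
      bc$ci[1], bc$ci[2])

  des <- config$desirability
  opt <- optimize_desirability(
    fit,
    g = goal(des$direction %||% "maximize", weight = des$weight %||% 1),
    bounds = des$bounds,
    n_starts = des$n_starts %||% 32L,
    seed = seed + 211L)
  say("desirability optimum: predicted %.2f at coded (%s)",
      opt$predicted, paste(sprintf("%.2f", opt$coded), collapse = ", "))

  acfg <- do.call(ann_config, modifyList(list(seed = seed + 307L),
                                         config$ann))
  ann <- train_ann(data, acfg)
  cmp <- build_comparison(data, fit, ann)
  say("network: overall R2 %.4f vs surface %.4f",
      cmp$metrics$ann_overall$r2, cmp$metrics$rsm_overall$r2)

  out <- config$out_dir
  files <- c(
    design = file.path(out, "design.csv"),
    anova_csv = file.path(out, "anova.csv"),
    anova_json = file.path(out, "anova.json"),
    fit_summary = file.path(out, "fit_summary.csv"),
    diagnostics = file.path(out, "diagnostics.csv"),
    boxcox = file.path(out, "boxcox.json"),
    optimization = file.path(out, "optimization.json"),
    ann_weights = file.path(out, "ann_weights.json"),
    comparison_csv = file.path(out, "comparison.csv"),
    comparison_json = file.path(out, "comparison.json")
  )
  write_design_csv(data, files["design"])
  write.csv(as.data.frame(av), files["anova_csv"], row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(
    list(anova = as.data.frame(av), adequacy = unclass(ad)),
    files["anova_json"], digits = 10, auto_unbox = TRUE)
  write.csv(as.data.frame(fs), files["fit_summary"], row.names = FALSE,
            quote = FALSE)
  write.csv(diag$table, files["diagnostics"], row.names = FALSE,
            quote = FALSE)
  jsonlite::write_json(
    list(lambda_hat = bc$lambda_hat, ci = bc$ci,
         conf_level = bc$conf_level),
    files["boxcox"], digits = 10, auto_unbox = TRUE)
  jsonlite::write_json(
    list(coded = as.list(opt$coded), actual = as.list(opt$actual),
         predicted = opt$predicted, desirability = opt$desirability),
    files["optimization"], digits = 10, auto_unbox = TRUE)
  write_ann_json(ann, files["ann_weights"])
  write_comparison(cmp, files["comparison_csv"], files["comparison_json"])
  say("report bundle written to %s", out)

  invisible(list(data = data, fit = fit, anova = av, adequacy = ad,
                 fit_summary = fs, diagnostics = diag, boxcox = bc,
                 optimum = opt, ann = ann, comparison = cmp,
                 files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
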