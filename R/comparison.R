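#' Goodness-of-fit metrics for a set of predictions
#'
#' The four statistics used to compare regression models run for run:
#' `SSE = sum(e^2)`, `RASE = sqrt(SSE / n)` (root average squared
#' error), `AAE = mean(|e|)` (average absolute error; the same statistic
#' is called MAD, mean absolute deviation, when quoted per data subset)
#' and `R2 = 1 - SSE / sum((y - mean(y))^2)`.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return A list of class `model_metrics` with `n`, `r2`, `rase`,
#'   `aae`, `sse`.
#' @export
model_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  if (length(actual) < 1L) stop("need at least one observation", call. = FALSE)
  e <- actual - predicted
  sse <- sum(e^2)
  structure(
    list(n = length(e),
         r2 = 1 - sse / sum((actual - mean(actual))^2),
         rase = sqrt(sse / length(e)),
         aae = mean(abs(e)),
         sse = sse),
    class = "model_metrics"
  )
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("<model_metrics> n %d  R2 %.4f  RASE %.4f  AAE %.4f  SSE %.4f\n",
              x$n, x$r2, x$rase, x$aae, x$sse))
  invisible(x)
}

#' Side-by-side comparison of the polynomial and network models
#'
#' Assembles the per-run prediction table (actual, prediction and
#' residual under each model, residuals as actual minus predicted), the
#' metric block (overall metrics for both models, plus training- and
#' validation-subset metrics for the network) and a verification block:
#' both models' predictions at a chosen coded point next to the
#' experimental response measured there, if that point is in the data.
#'
#' @param data The `experiment_table` both models were fitted to.
#' @param fit An `rsm_fit` on `data`.
#' @param ann An `ann_fit` on `data`.
#' @param validation_point Coded point for the verification block
#'   (default `c(0, 0, 2, 0)` for four factors: the axial run at the
#'   high level of the third factor).
#' @return A list of class `comparison_report` with elements `runs`
#'   (data frame), `metrics` (named list of [model_metrics()]) and
#'   `validation` (list: `coded`, `actual_settings`, `predicted_rsm`,
#'   `predicted_ann`, `experimental`).
#' @export
build_comparison <- function(data, fit, ann,
                             validation_point = NULL) {
  stopifnot(inherits(data, "experiment_table"), inherits(fit, "rsm_fit"),
            inherits(ann, "ann_fit"))
  k <- length(attr(data, "factors"))
  if (is.null(validation_point))
    validation_point <- c(rep(0, min(2L, k)), 2, rep(0, k - min(2L, k) - 1L))
  cm <- coded_matrix(data)
  pr <- predict(fit, cm)
  pa <- ann_predict(ann, cm)
  y <- data$response
  runs <- data.frame(
    std = data$std, run = data$run, type = data$type,
    actual = y,
    predicted_rsm = pr, residual_rsm = y - pr,
    predicted_ann = pa, residual_ann = y - pa
  )
  metrics <- list(
    rsm_overall = model_metrics(y, pr),
    ann_overall = model_metrics(y, pa),
    ann_training = model_metrics(y[ann$train_idx], pa[ann$train_idx]),
    ann_validation = model_metrics(y[ann$val_idx], pa[ann$val_idx])
  )
  match_row <- which(apply(cm, 1L, function(r)
    all(abs(r - validation_point) < 1e-9)))
  factors <- attr(data, "factors")
  settings <- setNames(
    mapply(function(x, f) suppressMessages(decode_value(x, f)),
           validation_point, factors),
    vapply(factors, `[[`, "", "name"))
  validation <- list(
    coded = validation_point,
    actual_settings = settings,
    predicted_rsm = unname(predict(fit, validation_point)),
    predicted_ann = unname(ann_predict(ann, validation_point)),
    experimental = if (length(match_row)) y[match_row[1]] else NA_real_
  )
  structure(list(runs = runs, metrics = metrics, validation = validation),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n  overall metrics:\n")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("    %-15s n %2d  R2 %.4f  RASE %7.3f  AAE %7.3f\n",
                nm, m$n, m$r2, m$rase, m$aae))
  }
  v <- x$validation
  cat(sprintf(
    "  verification at coded (%s): surface %.2f, network %.2f, experimental %s\n",
    paste(v$coded, collapse = ","), v$predicted_rsm, v$predicted_ann,
    ifelse(is.na(v$experimental), "-", sprintf("%.2f", v$experimental))))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' `runs` goes to CSV (one row per run, mirroring the design table
#' layout); the metric and verification blocks go to JSON.
#'
#' @param report A `comparison_report`.
#' @param csv_path,json_path Output files (either may be `NULL`).
#' @return The report, invisibly.
#' @export
write_comparison <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  if (!is.null(csv_path))
    write.csv(report$runs, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(metrics = lapply(report$metrics, unclass),
           validation = report$validation),
      json_path, digits = 10, auto_unbox = TRUE)
  invisible(report)
}
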