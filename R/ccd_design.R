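#' Describe a process factor and its coding
#'
#' A factor specification ties a named process variable (with its physical
#' unit) to the linear coding used throughout response-surface work:
#' `coded = (actual - center) / step`. Coded level 0 is the centre of the
#' experimental region and one coded unit corresponds to `step` actual
#' units.
#'
#' @param name Factor name, e.g. `"temperature"`.
#' @param center Actual value at coded level 0.
#' @param step Actual units per coded unit; must be positive.
#' @param unit Physical unit label, used only for display and file output.
#' @param code_range Numeric pair giving the coded extent of the
#'   experimental region (default `c(-2, 2)`, the axial levels of a
#'   rotatable four-factor design).
#'
#' @return An object of class `factor_spec`.
#' @examples
#' temp <- factor_spec("temperature", center = 35, step = 5, unit = "degC")
#' code_value(45, temp)    # +2
#' decode_value(-1, temp)  # 30
#' @export
factor_spec <- function(name, center, step, unit = "", code_range = c(-2, 2)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a single positive number", call. = FALSE)
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("`center` must be a single finite number", call. = FALSE)
  if (length(code_range) != 2L || code_range[1] >= code_range[2])
    stop("`code_range` must be an increasing pair of numbers", call. = FALSE)
  structure(
    list(name = name, unit = unit, center = center, step = step,
         code_range = as.numeric(code_range)),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s%s: center %g, step %g, coded range [%g, %g]\n",
              x$name, if (nzchar(x$unit)) paste0(" (", x$unit, ")") else "",
              x$center, x$step, x$code_range[1], x$code_range[2]))
  invisible(x)
}

#' Convert between actual and coded factor levels
#'
#' `code_value()` maps actual units onto the coded scale,
#' `decode_value()` is its exact inverse. Values outside the declared
#' `code_range` are legal (they are extrapolation, not errors) but are
#' reported with a message.
#'
#' @param actual,coded Numeric vectors.
#' @param spec A [factor_spec()].
#' @return Numeric vector of the same length.
#' @export
code_value <- function(actual, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  out <- (actual - spec$center) / spec$step
  flag_out_of_range(out, spec)
  out
}

#' @rdname code_value
#' @export
decode_value <- function(coded, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  flag_out_of_range(coded, spec)
  coded * spec$step + spec$center
}

flag_out_of_range <- function(coded, spec) {
  bad <- sum(coded < spec$code_range[1] | coded > spec$code_range[2],
             na.rm = TRUE)
  if (bad > 0L)
    message(sprintf("%d value(s) of '%s' lie outside the coded range [%g, %g]",
                    bad, spec$name, spec$code_range[1], spec$code_range[2]))
  invisible(NULL)
}

new_experiment_table <- function(df, factors) {
  rownames(df) <- NULL
  structure(df, factors = factors, class = c("experiment_table", "data.frame"))
}

#' @export
print.experiment_table <- function(x, ...) {
  f <- attr(x, "factors")
  cat(sprintf("<experiment_table> %d runs, %d factors (%s)\n",
              nrow(x), length(f),
              paste(vapply(f, `[[`, "", "name"), collapse = ", ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

coded_names <- function(k) paste0("X", seq_len(k))

#' Extract the coded design matrix of an experiment table
#'
#' @param tab An `experiment_table`.
#' @return Numeric matrix of coded levels, one column per factor.
#' @export
coded_matrix <- function(tab) {
  k <- length(attr(tab, "factors"))
  as.matrix(as.data.frame(tab)[, coded_names(k), drop = FALSE])
}

#' Construct a central composite design
#'
#' Builds the classical CCD in standard order: the full 2^k factorial at
#' coded levels +/-1, then the 2k axial (star) points at +/-`alpha` on one
#' axis at a time, then `n_center` replicated centre runs. Responses are
#' left missing; run order equals standard order (randomise at the bench,
#' not here).
#'
#' @param factors List of [factor_spec()] objects (k >= 2).
#' @param n_center Number of replicated centre points (>= 1); the centre
#'   replicates are what provide the pure-error estimate downstream.
#' @param alpha Axial distance in coded units. Defaults to the rotatable
#'   value `(2^k)^(1/4)`, which is 2 for four factors.
#' @return An `experiment_table` with `2^k + 2k + n_center` rows and
#'   columns `std`, `run`, `type`, `X1..Xk`, `response` (all `NA`).
#' @examples
#' fs <- list(
#'   factor_spec("temperature", 35, 5, "degC"),
#'   factor_spec("time",         4, 1, "days"),
#'   factor_spec("haucl4",     600, 200, "ug/mL"),
#'   factor_spec("ph",           6, 1)
#' )
#' des <- make_ccd(fs, n_center = 6)
#' table(des$type)  # 16 factorial, 8 axial, 6 center
#' @export
make_ccd <- function(factors, n_center, alpha = NULL) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("`factors` must be a list of factor_spec objects", call. = FALSE)
  k <- length(factors)
  if (k < 2L) stop("a central composite design needs at least 2 factors",
                   call. = FALSE)
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 1)
    stop("`n_center` must be at least 1", call. = FALSE)
  n_center <- as.integer(n_center)
  if (is.null(alpha)) alpha <- (2^k)^(1 / 4)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a single positive number", call. = FALSE)

  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2L * k, ncol = k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -alpha
    axial[2L * i, i] <- alpha
  }
  ctr <- matrix(0, nrow = n_center, ncol = k)
  coded <- rbind(fact, axial, ctr)
  colnames(coded) <- coded_names(k)
  n <- nrow(coded)
  df <- data.frame(
    std = seq_len(n),
    run = seq_len(n),
    type = rep(c("factorial", "axial", "center"),
               c(2^k, 2L * k, n_center)),
    coded,
    response = NA_real_,
    check.names = FALSE
  )
  out <- new_experiment_table(df, factors)
  validate_experiment_table(out)
  out
}

#' Validate the structural invariants of an experiment table
#'
#' Checks that factorial rows sit at coded +/-1 on every axis, axial rows
#' have exactly one nonzero coded entry (equal on both sides of 0 within a
#' row set), centre rows are all-zero, and `std` identifiers are unique.
#'
#' @param tab An `experiment_table`.
#' @return `tab`, invisibly; errors on violation.
#' @export
validate_experiment_table <- function(tab) {
  stopifnot(inherits(tab, "experiment_table"))
  k <- length(attr(tab, "factors"))
  need <- c("std", "run", "type", coded_names(k), "response")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("experiment table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$std))
    stop("`std` identifiers must be unique", call. = FALSE)
  if (!all(tab$type %in% c("factorial", "axial", "center")))
    stop("`type` must be one of factorial/axial/center", call. = FALSE)
  cm <- coded_matrix(tab)
  fc <- cm[tab$type == "factorial", , drop = FALSE]
  if (nrow(fc) && !all(abs(abs(fc) - 1) < 1e-9))
    stop("factorial rows must have every coded level at +/-1", call. = FALSE)
  ax <- cm[tab$type == "axial", , drop = FALSE]
  if (nrow(ax)) {
    nz <- rowSums(abs(ax) > 1e-9)
    if (!all(nz == 1L))
      stop("axial rows must have exactly one nonzero coded level",
           call. = FALSE)
  }
  cc <- cm[tab$type == "center", , drop = FALSE]
  if (nrow(cc) && !all(abs(cc) < 1e-9))
    stop("center rows must be all-zero in coded units", call. = FALSE)
  invisible(tab)
}

#' Read and write experiment tables as CSV
#'
#' The on-disk layout mirrors the usual design-of-experiments worksheet:
#' `std`, `run`, `type`, one coded column per factor (`X1..Xk`), one
#' actual-units column per factor (named after the factor), and
#' `response`. Extra columns present on the table are preserved.
#'
#' @param tab An `experiment_table`.
#' @param path File path.
#' @param factors For `read_design_csv()`, the list of [factor_spec()]
#'   objects describing the coded columns.
#' @return `write_design_csv()` returns `path` invisibly;
#'   `read_design_csv()` returns an `experiment_table`.
#' @export
write_design_csv <- function(tab, path) {
  stopifnot(inherits(tab, "experiment_table"))
  factors <- attr(tab, "factors")
  k <- length(factors)
  df <- as.data.frame(tab)
  cm <- coded_matrix(tab)
  for (i in seq_len(k)) {
    nm <- factors[[i]]$name
    if (!nm %in% names(df))
      df[[nm]] <- suppressMessages(decode_value(cm[, i], factors[[i]]))
  }
  front <- c("std", "run", "type", coded_names(k),
             vapply(factors, `[[`, "", "name"), "response")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, factors) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  k <- length(factors)
  need <- c("std", "run", "type", coded_names(k), "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- new_experiment_table(df, factors)
  validate_experiment_table(out)
  out
}
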