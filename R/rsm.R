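#' Term set of a response-surface model
#'
#' The three nested model orders used in response-surface work: `linear`
#' (main effects only), `2fi` (plus all two-factor interactions) and
#' `quadratic` (plus pure quadratic terms). Term labels are `X1`,
#' `X1:X2`, `X1^2`, etc., always on the coded scale.
#'
#' @param order One of `"quadratic"`, `"2fi"`, `"linear"`.
#' @param k Number of factors.
#' @return An object of class `model_spec` with elements `order`, `k`
#'   and `terms` (character vector, intercept excluded).
#' @export
model_spec <- function(order = c("quadratic", "2fi", "linear"), k) {
  order <- match.arg(tolower(order), c("quadratic", "2fi", "linear"))
  k <- as.integer(k)
  stopifnot(k >= 1L)
  lin <- coded_names(k)
  terms <- lin
  if (order %in% c("2fi", "quadratic")) {
    for (i in seq_len(k - 1L))
      for (j in seq((i + 1L), k))
        terms <- c(terms, paste0("X", i, ":X", j))
  }
  if (order == "quadratic")
    terms <- c(terms, paste0(lin, "^2"))
  structure(list(order = order, k = k, terms = terms), class = "model_spec")
}

# Model matrix (with intercept) for a coded-level matrix under a spec.
build_term_matrix <- function(coded, spec) {
  coded <- as.matrix(coded)
  if (ncol(coded) != spec$k)
    stop("coded points have ", ncol(coded), " columns but the model expects ",
         spec$k, call. = FALSE)
  colnames(coded) <- coded_names(spec$k)
  cols <- lapply(spec$terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      ij <- strsplit(tm, ":", fixed = TRUE)[[1]]
      coded[, ij[1]] * coded[, ij[2]]
    } else if (grepl("^", tm, fixed = TRUE)) {
      v <- sub("\\^2$", "", tm)
      coded[, v]^2
    } else coded[, tm]
  })
  X <- cbind(1, do.call(cbind, cols))
  dimnames(X) <- list(NULL, c("(Intercept)", spec$terms))
  X
}

#' Fit a response-surface model by ordinary least squares
#'
#' Fits the chosen polynomial (see [model_spec()]) to the coded factor
#' levels of an experiment table. Coefficients are reported in coded
#' units, the convention of every response-surface ANOVA table; the
#' actual-units equation is recoverable through the factor specs but is
#' never used for fitting.
#'
#' @param data An `experiment_table` with no missing responses.
#' @param order Model order, `"quadratic"` (default), `"2fi"` or
#'   `"linear"`.
#' @return An object of class `rsm_fit`: coefficients, fitted values,
#'   residuals (actual minus predicted), leverages (hat diagonal),
#'   residual degrees of freedom and mean square, plus the underlying
#'   `lm` fit and the data.
#' @examples
#' fit <- fit_model(load_aunps_ccd())
#' coef(fit)[c("(Intercept)", "X3", "X4^2")]
#' predict(fit, c(0, 0, 2, 0))  # verification point
#' @export
fit_model <- function(data, order = "quadratic") {
  stopifnot(inherits(data, "experiment_table"))
  validate_experiment_table(data)
  y <- data$response
  if (anyNA(y)) stop("`data` has missing responses; fit needs all of them",
                     call. = FALSE)
  k <- length(attr(data, "factors"))
  spec <- if (inherits(order, "model_spec")) order else model_spec(order, k)
  X <- build_term_matrix(coded_matrix(data), spec)
  p <- ncol(X)
  if (nrow(X) <= p)
    stop("need more runs (", nrow(X), ") than model terms (", p, ")",
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    aliased <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p)]]
    stop("design is rank-deficient; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  # lm on the prebuilt columns gives us the standard hat/studentization
  # machinery; backticked names keep ^ and : literal.
  dat <- as.data.frame(X[, -1, drop = FALSE], check.names = FALSE)
  dat$.y <- y
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", spec$terms), collapse = " + ")))
  lmfit <- lm(fml, data = dat)
  beta <- coef(lmfit)
  names(beta) <- c("(Intercept)", spec$terms)
  res <- unname(resid(lmfit))
  structure(
    list(
      spec = spec,
      coefficients = beta,
      fitted = unname(fitted(lmfit)),
      residuals = res,
      leverages = unname(hatvalues(lmfit)),
      df_residual = lmfit$df.residual,
      mse = sum(res^2) / lmfit$df.residual,
      lm = lmfit,
      data = data
    ),
    class = "rsm_fit"
  )
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<rsm_fit> %s model, %d terms, %d runs; residual SD %.4g\n",
              x$spec$order, length(x$coefficients), nrow(x$data),
              sqrt(x$mse)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a fitted response-surface model
#'
#' @param object An `rsm_fit`.
#' @param newdata Coded point(s): a numeric vector of length k, a matrix
#'   with k columns, or a data frame with columns `X1..Xk`. Omitted:
#'   the design points.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  k <- object$spec$k
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != k)
      stop("coded point must have length ", k, call. = FALSE)
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, coded_names(k), drop = FALSE])
  if (ncol(newdata) != k)
    stop("coded points must have ", k, " columns", call. = FALSE)
  X <- build_term_matrix(newdata, object$spec)
  drop(X %*% object$coefficients)
}

# Pure-error decomposition: replicate groups are rows with exactly equal
# coded settings (the centre points in a plain CCD).
pure_error <- function(data) {
  cm <- coded_matrix(data)
  key <- apply(cm, 1L, paste, collapse = "\r")
  groups <- split(data$response, key)
  reps <- groups[lengths(groups) > 1L]
  if (!length(reps)) return(NULL)
  ss <- sum(vapply(reps, function(y) sum((y - mean(y))^2), 0))
  df <- sum(vapply(reps, length, 0L) - 1L)
  list(ss = ss, df = df)
}

#' Analysis of variance for a response-surface fit
#'
#' Builds the full ANOVA report: the model row, a Type-III (partial)
#' sum-of-squares row per term (full-model residual SS minus that of the
#' model without the term), the residual row, and — when the design
#' contains exact replicate runs — the lack-of-fit / pure-error split.
#' Term and model F statistics are tested against the residual mean
#' square; lack of fit against the pure-error mean square.
#'
#' @param object An `rsm_fit`.
#' @param ... Unused.
#' @return A data frame of class `rsm_anova` with columns `source`,
#'   `estimate` (coded-unit coefficient; the intercept is shown on the
#'   model row), `ss`, `df`, `ms`, `f_value`, `p_value`.
#' @examples
#' a <- anova(fit_model(load_aunps_ccd()))
#' a[a$source %in% c("Model", "X3", "Lack of fit"), ]
#' @export
anova.rsm_fit <- function(object, ...) {
  data <- object$data
  y <- data$response
  n <- length(y)
  X <- build_term_matrix(coded_matrix(data), object$spec)
  rss <- sum(object$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssm <- sst - rss
  dfm <- length(object$spec$terms)
  mse <- object$mse

  term_ss <- vapply(object$spec$terms, function(tm) {
    Xr <- X[, colnames(X) != tm, drop = FALSE]
    sum(lm.fit(Xr, y)$residuals^2) - rss
  }, 0)

  rows <- data.frame(
    source = c("Model", object$spec$terms, "Residual"),
    estimate = c(object$coefficients, NA_real_),
    ss = c(ssm, term_ss, rss),
    df = c(dfm, rep(1L, length(term_ss)), object$df_residual),
    stringsAsFactors = FALSE
  )
  rows$ms <- rows$ss / rows$df
  rows$f_value <- rows$ms / mse
  rows$f_value[rows$source == "Residual"] <- NA_real_
  rows$p_value <- pf(rows$f_value, rows$df, object$df_residual,
                     lower.tail = FALSE)

  pe <- pure_error(data)
  if (is.null(pe)) {
    warning("no replicated runs: lack-of-fit and pure-error rows omitted")
  } else {
    lof_ss <- rss - pe$ss
    lof_df <- object$df_residual - pe$df
    lof_ms <- lof_ss / lof_df
    pe_ms <- pe$ss / pe$df
    lof_f <- lof_ms / pe_ms
    rows <- rbind(rows, data.frame(
      source = c("Lack of fit", "Pure error"),
      estimate = NA_real_,
      ss = c(lof_ss, pe$ss), df = c(lof_df, pe$df),
      ms = c(lof_ms, pe_ms),
      f_value = c(lof_f, NA_real_),
      p_value = c(pf(lof_f, lof_df, pe$df, lower.tail = FALSE), NA_real_)
    ))
  }
  rows <- rbind(rows, data.frame(
    source = "Corrected total", estimate = NA_real_, ss = sst,
    df = n - 1L, ms = NA_real_, f_value = NA_real_, p_value = NA_real_))
  rownames(rows) <- NULL
  class(rows) <- c("rsm_anova", "data.frame")
  rows
}

#' @export
print.rsm_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_value <- ifelse(is.na(df$p_value), NA,
                       ifelse(df$p_value < 1e-4, "< 0.0001",
                              sprintf("%.4f", df$p_value)))
  print(df, digits = 6, ...)
  invisible(x)
}

#' Adequacy metrics of a response-surface fit
#'
#' The standard response-surface report: the R-squared family, the
#' leave-one-out PRESS statistic computed through the hat-matrix
#' shortcut `PRESS = sum((e_i / (1 - h_ii))^2)`, the predicted R-squared
#' `1 - PRESS / SS_total`, the adequate-precision signal-to-noise ratio
#' `(max(yhat) - min(yhat)) / sqrt(p * MSE / n)`, and the residual
#' standard deviation.
#'
#' @param fit An `rsm_fit`.
#' @return An object of class `adequacy_metrics` (a named list with
#'   `r2`, `adj_r2`, `pred_r2`, `press`, `adeq_precision`, `std_dev`).
#' @export
adequacy <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  if (fit$df_residual < 1L) stop("fit has no residual degrees of freedom",
                                 call. = FALSE)
  y <- fit$data$response
  n <- length(y)
  p <- length(fit$coefficients)
  h <- fit$leverages
  if (any(h > 1 - 1e-10)) {
    bad <- fit$data$run[h > 1 - 1e-10]
    stop("PRESS is undefined: leverage is 1 for run(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sst <- sum((y - mean(y))^2)
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / sst
  press <- sum((fit$residuals / (1 - h))^2)
  structure(
    list(
      r2 = r2,
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p),
      pred_r2 = 1 - press / sst,
      press = press,
      adeq_precision = (max(fit$fitted) - min(fit$fitted)) /
        sqrt(p * fit$mse / n),
      std_dev = sqrt(fit$mse)
    ),
    class = "adequacy_metrics"
  )
}

#' @export
print.adequacy_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("R2 %.4f  adj R2 %.4f  pred R2 %.4f\n",
           "PRESS %.2f  std dev %.2f  adeq precision %.4f\n"),
    x$r2, x$adj_r2, x$pred_r2, x$press, x$std_dev, x$adeq_precision))
  invisible(x)
}

#' Fit-summary comparison of the linear, 2FI and quadratic models
#'
#' Fits all three nested model orders to the same data and tabulates the
#' lack-of-fit test of each (against the common pure-error estimate from
#' replicate runs) next to its summary statistics, the table used to
#' choose the model order.
#'
#' @param data An `experiment_table` with replicated runs.
#' @return A data frame of class `fit_summary`, one row per model order,
#'   with columns `order`, `lof_ss`, `lof_df`, `lof_ms`, `lof_f`,
#'   `lof_p`, `std_dev`, `r2`, `adj_r2`, `pred_r2`, `press`.
#' @export
fit_summary <- function(data) {
  orders <- c("linear", "2fi", "quadratic")
  pe <- pure_error(data)
  rows <- lapply(orders, function(ord) {
    fit <- fit_model(data, ord)
    ad <- adequacy(fit)
    rss <- sum(fit$residuals^2)
    lof <- if (is.null(pe)) list(ss = NA_real_, df = NA_real_) else
      list(ss = rss - pe$ss, df = fit$df_residual - pe$df)
    lof_ms <- lof$ss / lof$df
    lof_f <- if (is.null(pe)) NA_real_ else lof_ms / (pe$ss / pe$df)
    data.frame(
      order = ord, lof_ss = lof$ss, lof_df = lof$df, lof_ms = lof_ms,
      lof_f = lof_f,
      lof_p = if (is.null(pe)) NA_real_ else
        pf(lof_f, lof$df, pe$df, lower.tail = FALSE),
      std_dev = ad$std_dev, r2 = ad$r2, adj_r2 = ad$adj_r2,
      pred_r2 = ad$pred_r2, press = ad$press,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fit_summary", "data.frame")
  out
}
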