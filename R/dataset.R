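AUNPS_CSV_MD5 <- "0370e4b47a2c310030977b1dfb0c7573"

#' Factor specifications of the bundled AuNPs optimisation study
#'
#' The four bioprocess factors of the gold-nanoparticle biosynthesis
#' experiment, coded so that one step is 5 degC (temperature), 1 day
#' (incubation time), 200 ug/mL (chloroauric acid concentration) and
#' 1 pH unit, with centres 35 degC, 4 days, 600 ug/mL and pH 6.
#'
#' @return A list of four [factor_spec()] objects.
#' @export
aunps_factors <- function() {
  list(
    factor_spec("temperature", center = 35, step = 5, unit = "degC"),
    factor_spec("time", center = 4, step = 1, unit = "days"),
    factor_spec("haucl4", center = 600, step = 200, unit = "ug/mL"),
    factor_spec("ph", center = 6, step = 1, unit = "pH")
  )
}

#' Load the bundled 30-run AuNPs biosynthesis dataset
#'
#' A four-factor central composite design (16 factorial, 8 axial and 6
#' centre runs) measuring gold-nanoparticle yield (ug AuNPs/mL) from a
#' cell-free *Streptomyces* supernatant. Rows appear in the original
#' randomised run order; `std` holds the standard-order identifier.
#'
#' Columns prefixed `ref_` carry the originally reported per-run
#' predictions and residuals of the quadratic response-surface model and
#' of the neural network, exactly as published. They are reference values
#' for regression tests, not inputs: in the `ref_resid_ccd` column the
#' sign convention is actual minus predicted, while `ref_resid_ann` is
#' predicted minus actual (as printed).
#'
#' @param path Optional path to an alternative copy of the CSV (used in
#'   tests); defaults to the file installed with the package.
#' @param checksum Verify the bundled file's MD5 before parsing.
#' @return An `experiment_table` with 30 rows and the factors of
#'   [aunps_factors()].
#' @examples
#' tab <- load_aunps_ccd()
#' subset(as.data.frame(tab), std == 22)$response  # 866.29
#' @export
load_aunps_ccd <- function(path = NULL, checksum = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "aunps_ccd30.csv", package = "rsmnet",
                        mustWork = TRUE)
  if (isTRUE(checksum)) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, AUNPS_CSV_MD5))
      stop("bundled dataset failed its checksum (expected ", AUNPS_CSV_MD5,
           ", got ", md5, "); the file is corrupted", call. = FALSE)
  }
  read_design_csv(path, aunps_factors())
}

#' Ground-truth quadratic surface for simulation
#'
#' Bundles the 15 coefficients of a full second-order model in k = 4
#' coded factors (intercept, 4 linear, 6 pairwise-interaction and 4 pure
#' quadratic terms) together with a homoscedastic Gaussian noise level,
#' for use with [simulate_response()].
#'
#' @param coefficients Named numeric vector; names must be exactly the
#'   quadratic term set returned by `model_spec("quadratic", k)` plus
#'   `"(Intercept)"`.
#' @param noise_sd Standard deviation of the additive response noise
#'   (response units, >= 0).
#' @param seed Optional integer seed making [simulate_response()]
#'   reproducible.
#' @param k Number of factors (default 4).
#' @return An object of class `true_model`.
#' @export
true_model <- function(coefficients, noise_sd = 0, seed = NULL, k = 4L) {
  spec <- model_spec("quadratic", k)
  want <- c("(Intercept)", spec$terms)
  if (is.null(names(coefficients)) || !setequal(names(coefficients), want))
    stop("`coefficients` must be named with exactly the ", length(want),
         " quadratic-model terms: ", paste(want, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single number >= 0", call. = FALSE)
  structure(
    list(coefficients = coefficients[want], noise_sd = noise_sd,
         seed = seed, k = as.integer(k)),
    class = "true_model"
  )
}

#' Ground-truth surface matching the bundled study's reported fit
#'
#' Convenience constructor: a [true_model()] whose coefficients are the
#' reported coded-unit estimates of the bundled AuNPs quadratic fit and
#' whose default noise level is the fit's residual standard deviation
#' (26.47 ug/mL). Useful as a realistic simulation truth.
#'
#' @inheritParams true_model
#' @return A `true_model` for k = 4.
#' @export
aunps_true_model <- function(noise_sd = 26.47, seed = NULL) {
  beta <- c(
    "(Intercept)" = 575.71,
    "X1" = 20, "X2" = -39.19, "X3" = 152.55, "X4" = 47.37,
    "X1:X2" = 17.98, "X1:X3" = 43.36, "X1:X4" = -19.82,
    "X2:X3" = -32.95, "X2:X4" = 37.35, "X3:X4" = 25.46,
    "X1^2" = -1.88, "X2^2" = -10.37, "X3^2" = -8.85, "X4^2" = -74.24
  )
  true_model(beta, noise_sd = noise_sd, seed = seed, k = 4L)
}

#' Simulate CCD responses from a known quadratic surface
#'
#' Evaluates the ground-truth polynomial at every coded design point and
#' adds independent Gaussian noise, emulating a response-surface
#' experiment whose generating surface is known. With `noise_sd = 0` the
#' responses are the exact polynomial values, so a subsequent quadratic
#' fit recovers the truth to machine precision.
#'
#' @param design An `experiment_table` whose factor count matches the
#'   truth (responses, if any, are overwritten).
#' @param truth A [true_model()].
#' @return The design with simulated `response` values.
#' @export
simulate_response <- function(design, truth) {
  stopifnot(inherits(design, "experiment_table"), inherits(truth, "true_model"))
  k <- length(attr(design, "factors"))
  if (k != truth$k)
    stop("design has ", k, " factors but the true model expects ", truth$k,
         call. = FALSE)
  spec <- model_spec("quadratic", k)
  X <- build_term_matrix(coded_matrix(design), spec)
  mu <- drop(X %*% truth$coefficients[colnames(X)])
  eps <- with_seed(truth$seed, rnorm(nrow(X), 0, truth$noise_sd))
  design$response <- mu + eps
  design
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
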