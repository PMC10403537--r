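#' Ellipsoid tumour volume from caliper diameters
#'
#' `volume = A * B^2 * 0.5`, with `A` the largest diameter and `B` its
#' perpendicular (both mm). Vectorized.
#'
#' @param a Largest tumour diameter (mm), `a >= b`.
#' @param b Perpendicular diameter (mm), `>= 0`.
#' @return Tumour volume in mm^3.
#' @examples
#' tumor_volume(10, 4)  # 80
#' @export
tumor_volume <- function(a, b) {
  if (any(a < 0 | b < 0)) stop("diameters must be non-negative", call. = FALSE)
  if (any(b > a))
    stop("`a` must be the largest diameter (a >= b)", call. = FALSE)
  a * b^2 * 0.5
}

#' Tumour growth inhibition from mean tumour weights
#'
#' `TGI% = 100 * (control - treated) / control` using the mean tumour
#' weight of the untreated control group and of a treated group.
#'
#' @param mean_control_weight Mean tumour weight of the control group
#'   (g, > 0).
#' @param mean_treated_weight Mean tumour weight of the treated group
#'   (g, >= 0).
#' @return Percent growth inhibition.
#' @examples
#' growth_inhibition(2, 0.4)  # 80
#' @export
growth_inhibition <- function(mean_control_weight, mean_treated_weight) {
  if (any(mean_control_weight <= 0))
    stop("control weight must be positive", call. = FALSE)
  if (any(mean_treated_weight < 0))
    stop("treated weight must be non-negative", call. = FALSE)
  100 * (mean_control_weight - mean_treated_weight) / mean_control_weight
}

#' Default concentration series of the cytotoxicity assay
#'
#' The five-point, four-fold dilution series (ug/mL) used in the MTT
#' viability experiments.
#' @return Numeric vector `c(100, 25, 6.25, 1.56, 0.39)`.
#' @export
default_concentrations <- function() c(100, 25, 6.25, 1.56, 0.39)

#' Simulate a sigmoidal viability assay
#'
#' Generates percent-viability readings from a four-parameter logistic
#' curve on log10 concentration plus Gaussian noise — the synthetic
#' counterpart of an MTT dose-response experiment.
#'
#' @param ic50 True half-maximal concentration (same units as
#'   `concentrations`).
#' @param hill Hill slope (> 0 for viability falling with dose).
#' @param bottom,top Lower/upper viability asymptotes (percent).
#' @param concentrations Dose series; defaults to
#'   [default_concentrations()].
#' @param replicates Readings per concentration.
#' @param noise_sd SD of the additive noise (percent viability,
#'   default 2).
#' @param seed Optional seed.
#' @return Data frame with columns `concentration`, `response`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, bottom = 0, top = 100,
                                   concentrations = default_concentrations(),
                                   replicates = 3L, noise_sd = 2,
                                   seed = NULL) {
  stopifnot(ic50 > 0, all(concentrations > 0), noise_sd >= 0)
  conc <- rep(concentrations, each = replicates)
  mu <- bottom + (top - bottom) /
    (1 + 10^(hill * (log10(conc) - log10(ic50))))
  resp <- mu + with_seed(seed, rnorm(length(conc), 0, noise_sd))
  data.frame(concentration = conc, response = resp)
}

#' Fit a sigmoidal concentration-response curve and estimate IC50
#'
#' Least-squares fit of the four-parameter logistic (Boltzmann-type
#' sigmoid) on log10 concentration,
#' `response = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) - log10(IC50))))`,
#' by Levenberg-Marquardt. The IC50 is the concentration at the curve's
#' midpoint between its fitted asymptotes (half-maximal inhibition).
#'
#' @param concentration Doses (> 0), at least 4 distinct values
#'   spanning the transition.
#' @param response Percent viability, same length.
#' @return A list of class `dose_response_fit`: `bottom`, `top`,
#'   `ic50`, `hill`, `fitted`, `residuals`, plus the input data.
#'   A flat response (no transition) raises a non-identifiability
#'   error.
#' @examples
#' dr <- simulate_dose_response(ic50 = 10, noise_sd = 1, seed = 42)
#' fit <- fit_ic50(dr$concentration, dr$response)
#' fit$ic50
#' @export
fit_ic50 <- function(concentration, response) {
  if (length(concentration) != length(response))
    stop("`concentration` and `response` must have equal length",
         call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  if (length(unique(concentration)) < 4L)
    stop("need at least 4 distinct concentrations", call. = FALSE)
  if (diff(range(response)) < 1e-8)
    stop("response is flat across doses: IC50 is non-identifiable",
         call. = FALSE)
  lx <- log10(concentration)
  top0 <- max(response); bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  # start log-IC50 at the dose whose mean response is nearest midway
  mt <- tapply(response, lx, mean)
  l50_0 <- as.numeric(names(mt))[which.min(abs(mt - mid))]
  dat <- data.frame(lx = lx, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - l50))),
      data = dat,
      start = list(bottom = bot0, top = top0, hill = 1, l50 = l50_0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("sigmoid fit failed (", conditionMessage(e),
           "): IC50 is non-identifiable", call. = FALSE))
  p <- coef(fit)
  if (abs(p["top"] - p["bottom"]) < 1e-6 * max(1, abs(p["top"])))
    stop("fitted curve is flat: IC50 is non-identifiable", call. = FALSE)
  structure(
    list(concentration = concentration, response = response,
         bottom = unname(p["bottom"]), top = unname(p["top"]),
         ic50 = unname(10^p["l50"]), hill = unname(p["hill"]),
         fitted = unname(fitted(fit)), residuals = unname(resid(fit))),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> IC50 %.4g, hill %.3f, asymptotes [%.2f, %.2f]\n",
    x$ic50, x$hill, x$bottom, x$top))
  invisible(x)
}
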