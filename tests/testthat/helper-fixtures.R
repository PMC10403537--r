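# Shared fixtures: everything is built in code at test time.

toy_factors <- function(k) {
  lapply(seq_len(k), function(i)
    factor_spec(paste0("f", i), center = 10 * i, step = i))
}

# The reported coded-unit coefficients of the bundled study's quadratic
# fit (used as a simulation ground truth).
reported_beta <- function() {
  c("(Intercept)" = 575.71,
    "X1" = 20, "X2" = -39.19, "X3" = 152.55, "X4" = 47.37,
    "X1:X2" = 17.98, "X1:X3" = 43.36, "X1:X4" = -19.82,
    "X2:X3" = -32.95, "X2:X4" = 37.35, "X3:X4" = 25.46,
    "X1^2" = -1.88, "X2^2" = -10.37, "X3^2" = -8.85, "X4^2" = -74.24)
}

# Quadratic polynomial evaluated directly from a named coefficient
# vector at a single coded point (independent of build_term_matrix).
eval_quadratic <- function(beta, x) {
  k <- length(x)
  val <- beta[["(Intercept)"]]
  for (i in seq_len(k)) val <- val + beta[[paste0("X", i)]] * x[i]
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    val <- val + beta[[paste0("X", i, ":X", j)]] * x[i] * x[j]
  for (i in seq_len(k)) val <- val + beta[[paste0("X", i, "^2")]] * x[i]^2
  val
}

study_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_aunps_ccd()
    cache
  }
})

study_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_model(study_data(), "quadratic")
    cache
  }
})
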