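#' Configuration of the single-hidden-layer tanh network
#'
#' Hyperparameters of the neural-network regression used to benchmark
#' the polynomial response surface: 20 tanh hidden nodes, a random
#' holdback fraction of 0.2 of the runs kept aside as a validation set,
#' and repeated random restarts ("tours") of which the best fit by
#' validation error is retained. The network is trained by penalized
#' least squares (BFGS on the squared-error objective with a small L2
#' weight penalty); restarts, not a learning-rate schedule, supply the
#' stochastic search.
#'
#' @param hidden_nodes Hidden-layer width (>= 1, default 20).
#' @param holdback Fraction of rows held out for validation, in (0, 1)
#'   (default 0.2).
#' @param restarts Number of random initialisations (default 2000).
#' @param max_iterations BFGS iteration cap per restart (default 300).
#' @param l2 L2 penalty on the weights (not the biases), default 1e-4.
#' @param seed Integer seed governing the holdback split and all
#'   initialisations.
#' @param standardize Standardize inputs to mean 0 / SD 1 over all rows
#'   (default `TRUE`); the response is left on its own scale.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden_nodes = 20L, holdback = 0.2, restarts = 2000L,
                       max_iterations = 300L, l2 = 1e-4, seed = 1L,
                       standardize = TRUE) {
  if (hidden_nodes < 1L) stop("`hidden_nodes` must be >= 1", call. = FALSE)
  if (!is.numeric(holdback) || holdback <= 0 || holdback >= 1)
    stop("`holdback` must be in (0, 1)", call. = FALSE)
  if (l2 < 0) stop("`l2` must be >= 0", call. = FALSE)
  structure(
    list(hidden_nodes = as.integer(hidden_nodes), holdback = holdback,
         restarts = as.integer(restarts),
         max_iterations = as.integer(max_iterations), l2 = l2,
         seed = as.integer(seed), standardize = isTRUE(standardize)),
    class = "ann_config"
  )
}

ann_forward <- function(X, W1, b1, w2, b2) {
  A <- tanh(sweep(X %*% t(W1), 2L, b1, "+"))
  drop(A %*% w2) + b2
}

# Pack/unpack the parameter vector: W1 (H x k), b1, w2, b2.
ann_unpack <- function(par, H, k) {
  i <- H * k
  list(W1 = matrix(par[seq_len(i)], H, k),
       b1 = par[i + seq_len(H)],
       w2 = par[i + H + seq_len(H)],
       b2 = par[i + 2L * H + 1L])
}

ann_objective <- function(par, X, y, H, k, l2) {
  w <- ann_unpack(par, H, k)
  r <- ann_forward(X, w$W1, w$b1, w$w2, w$b2) - y
  sum(r^2) + l2 * (sum(w$W1^2) + sum(w$w2^2))
}

ann_gradient <- function(par, X, y, H, k, l2) {
  w <- ann_unpack(par, H, k)
  Z <- sweep(X %*% t(w$W1), 2L, w$b1, "+")
  A <- tanh(Z)
  r <- drop(A %*% w$w2) + w$b2 - y
  delta <- (r %o% w$w2) * (1 - A^2)       # n x H
  c(as.vector(2 * (t(delta) %*% X) + 2 * l2 * w$W1),
    2 * colSums(delta),
    2 * drop(t(A) %*% r) + 2 * l2 * w$w2,
    2 * sum(r))
}

#' Train the tanh network on an experiment table
#'
#' Fits `y ~ net(X)` on the coded factor levels. The holdback split is
#' drawn once from the seed; each restart then draws a fresh random
#' initialisation (hidden weights uniform, output layer solved by ridge
#' regression on the initial hidden activations) and is polished by
#' BFGS on the penalized squared-error objective over the training
#' rows. The restart with the lowest validation error wins, ties going
#' to the lower training error. Identical seeds give identical fits.
#'
#' @param data An `experiment_table` with responses.
#' @param config An [ann_config()].
#' @return A list of class `ann_fit`: input scaling (`center`,
#'   `scale`), weights (`W1`, `b1`, `w2`, `b2`), `train_idx`,
#'   `val_idx`, `objective` (final penalized training objective),
#'   `train_sse`, `val_sse`, per-row `predictions`, and the `config`.
#' @export
train_ann <- function(data, config = ann_config()) {
  stopifnot(inherits(data, "experiment_table"), inherits(config, "ann_config"))
  y <- data$response
  if (anyNA(y)) stop("`data` has missing responses", call. = FALSE)
  X <- coded_matrix(data)
  n <- nrow(X); k <- ncol(X); H <- config$hidden_nodes
  if (n < H)
    message("fewer runs (", n, ") than hidden nodes (", H,
            "): the network can interpolate the training data")
  ctr <- if (config$standardize) colMeans(X) else rep(0, k)
  scl <- if (config$standardize) apply(X, 2L, sd) else rep(1, k)
  if (any(scl == 0)) stop("constant input column cannot be standardized",
                          call. = FALSE)
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")

  with_seed(config$seed, {
    n_val <- round(config$holdback * n)
    if (n_val < 2L) stop("holdback split leaves fewer than 2 validation rows",
                         call. = FALSE)
    if (n - n_val < 2L)
      stop("holdback split leaves insufficient training rows", call. = FALSE)
    val_idx <- sort(sample.int(n, n_val))
    train_idx <- setdiff(seq_len(n), val_idx)
    Xt <- Xs[train_idx, , drop = FALSE]; yt <- y[train_idx]
    Xv <- Xs[val_idx, , drop = FALSE]; yv <- y[val_idx]

    best <- NULL
    for (r in seq_len(config$restarts)) {
      W1 <- matrix(runif(H * k, -1, 1), H, k)
      b1 <- runif(H, -0.5, 0.5)
      A <- tanh(sweep(Xt %*% t(W1), 2L, b1, "+"))
      # ridge-initialised output layer: cheap, well-conditioned start
      Ai <- cbind(A, 1)
      co <- tryCatch(
        solve(crossprod(Ai) + diag(1e-6, H + 1L), crossprod(Ai, yt)),
        error = function(e) rbind(matrix(0, H, 1L), mean(yt)))
      par <- c(as.vector(W1), b1, co[seq_len(H)], co[H + 1L])
      opt <- optim(par, ann_objective, ann_gradient, method = "BFGS",
                   X = Xt, y = yt, H = H, k = k, l2 = config$l2,
                   control = list(maxit = config$max_iterations,
                                  reltol = 1e-12))
      w <- ann_unpack(opt$par, H, k)
      tr_sse <- sum((ann_forward(Xt, w$W1, w$b1, w$w2, w$b2) - yt)^2)
      va_sse <- sum((ann_forward(Xv, w$W1, w$b1, w$w2, w$b2) - yv)^2)
      if (is.null(best) || va_sse < best$val_sse - 1e-12 ||
          (abs(va_sse - best$val_sse) <= 1e-12 && tr_sse < best$train_sse)) {
        best <- list(w = w, objective = opt$value,
                     train_sse = tr_sse, val_sse = va_sse)
      }
    }

    fit <- structure(
      list(center = ctr, scale = scl,
           W1 = best$w$W1, b1 = best$w$b1, w2 = best$w$w2, b2 = best$w$b2,
           train_idx = train_idx, val_idx = val_idx,
           objective = best$objective,
           train_sse = best$train_sse, val_sse = best$val_sse,
           predictions = NULL, config = config),
      class = "ann_fit")
    fit$predictions <- ann_predict(fit, X)
    fit
  })
}

#' Predict from a trained network
#'
#' Applies the stored input standardization and the forward pass
#' `yhat = b2 + sum(w2 * tanh(W1 %*% x + b1))`.
#'
#' @param fit An `ann_fit`.
#' @param coded_points Coded point(s): vector of length k or matrix
#'   with k columns.
#' @return Numeric vector of predictions.
#' @export
ann_predict <- function(fit, coded_points) {
  stopifnot(inherits(fit, "ann_fit"))
  k <- ncol(fit$W1)
  if (is.numeric(coded_points) && is.null(dim(coded_points))) {
    if (length(coded_points) != k)
      stop("coded point must have length ", k, call. = FALSE)
    coded_points <- matrix(coded_points, nrow = 1L)
  }
  coded_points <- as.matrix(coded_points)
  if (ncol(coded_points) != k)
    stop("coded points must have ", k, " columns", call. = FALSE)
  Xs <- sweep(sweep(coded_points, 2L, fit$center), 2L, fit$scale, "/")
  ann_forward(Xs, fit$W1, fit$b1, fit$w2, fit$b2)
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf(
    "<ann_fit> %d tanh nodes; %d train / %d validation rows; val SSE %.4g\n",
    nrow(x$W1), length(x$train_idx), length(x$val_idx), x$val_sse))
  invisible(x)
}

#' Serialize network weights to JSON
#'
#' Writes everything needed to reproduce predictions — scaling, weights
#' and the holdback split — as a JSON document.
#'
#' @param fit An `ann_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ann_json <- function(fit, path) {
  stopifnot(inherits(fit, "ann_fit"))
  obj <- list(
    hidden_nodes = nrow(fit$W1),
    center = fit$center, scale = fit$scale,
    W1 = fit$W1, b1 = fit$b1, w2 = fit$w2, b2 = fit$b2,
    train_idx = fit$train_idx, val_idx = fit$val_idx,
    train_sse = fit$train_sse, val_sse = fit$val_sse,
    config = unclass(fit$config)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
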