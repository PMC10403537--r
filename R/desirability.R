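#' Define an optimisation goal for one response
#'
#' Derringer-Suich desirability maps a predicted response onto a score
#' in \[0, 1\]. For `maximize`, `d = ((y - low) / (target - low))^weight`
#' clamped to \[0, 1\]; for `minimize` the mirror image; for `target` a
#' two-sided ramp peaking at `target`; `in_range` scores 1 inside
#' \[low, high\] and 0 outside. Unset anchors default, at optimisation
#' time, to the observed response range of the fitted data.
#'
#' @param direction One of `"maximize"`, `"minimize"`, `"target"`,
#'   `"in_range"`.
#' @param low,target,high Response-unit anchors (`low <= target <= high`
#'   where applicable).
#' @param weight Exponent of the ramp (> 0, default 1).
#' @return An object of class `goal`.
#' @export
goal <- function(direction = c("maximize", "minimize", "target", "in_range"),
                 low = NULL, target = NULL, high = NULL, weight = 1) {
  direction <- match.arg(direction)
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0)
    stop("`weight` must be a single positive number", call. = FALSE)
  anchors <- c(low = low, target = target, high = high)
  if (length(anchors) > 1L && is.unsorted(anchors))
    stop("goal anchors must satisfy low <= target <= high", call. = FALSE)
  structure(list(direction = direction, low = low, target = target,
                 high = high, weight = weight),
            class = "goal")
}

# Fill unset goal anchors from the observed response range.
resolve_goal <- function(g, observed) {
  rng <- range(observed)
  switch(g$direction,
    maximize = {
      if (is.null(g$low)) g$low <- rng[1]
      if (is.null(g$target)) g$target <- rng[2]
    },
    minimize = {
      if (is.null(g$target)) g$target <- rng[1]
      if (is.null(g$high)) g$high <- rng[2]
    },
    target = {
      if (is.null(g$low)) g$low <- rng[1]
      if (is.null(g$high)) g$high <- rng[2]
      if (is.null(g$target)) g$target <- mean(rng)
    },
    in_range = {
      if (is.null(g$low)) g$low <- rng[1]
      if (is.null(g$high)) g$high <- rng[2]
    })
  g
}

#' Desirability score of response values under a goal
#'
#' @param y Numeric vector of response values.
#' @param g A [goal()] whose anchors are all set (see [resolve_goal]
#'   behaviour in [optimize_desirability()] for defaults).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
desirability_value <- function(y, g) {
  stopifnot(inherits(g, "goal"))
  clamp <- function(x) pmin(1, pmax(0, x))
  w <- g$weight
  switch(g$direction,
    maximize = clamp((y - g$low) / (g$target - g$low))^w,
    minimize = clamp((g$high - y) / (g$high - g$target))^w,
    target = {
      d <- ifelse(y <= g$target,
                  (y - g$low) / (g$target - g$low),
                  (g$high - y) / (g$high - g$target))
      clamp(d)^w
    },
    in_range = as.numeric(y >= g$low & y <= g$high)
  )
}

#' Desirability optimisation of a fitted response surface
#'
#' Searches the coded design region for the settings that maximise the
#' desirability of the model's prediction, by multi-start bounded
#' quasi-Newton (L-BFGS-B) search. Ties in desirability (in particular
#' the plateau at d = 1) are broken by higher predicted response, then
#' by lexicographically smallest coded point; for the monotone
#' `maximize`/`minimize` goals the search therefore works directly on
#' the predicted response, which is equivalent and avoids the flat
#' clamped regions.
#'
#' @param fit An `rsm_fit`.
#' @param g A [goal()] (default: maximize, anchored at the observed
#'   response range).
#' @param bounds Matrix with k rows and columns `lower`, `upper` in
#'   coded units; defaults to each factor's `code_range` (the
#'   experimental region — beyond it the model extrapolates).
#' @param n_starts Number of random starting points (default 32); the
#'   centre of the region is always included as an extra start.
#' @param seed Integer seed for the start points.
#' @return A list of class `desirability_optimum`: `coded` (named
#'   vector), `actual` (named vector in factor units), `predicted`,
#'   `desirability`, `goal` (anchors as used) and `trace` (start
#'   count, convergence codes, best objective per start).
#' @examples
#' fit <- fit_model(load_aunps_ccd())
#' opt <- optimize_desirability(fit, seed = 1)
#' opt$predicted  # best predicted yield in the design region
#' @export
optimize_desirability <- function(fit, g = goal("maximize"), bounds = NULL,
                                  n_starts = 32L, seed = 1L) {
  stopifnot(inherits(fit, "rsm_fit"), inherits(g, "goal"))
  factors <- attr(fit$data, "factors")
  k <- fit$spec$k
  if (is.null(bounds)) {
    bounds <- t(vapply(factors, `[[`, numeric(2), "code_range"))
    colnames(bounds) <- c("lower", "upper")
  }
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != k || ncol(bounds) != 2L)
    stop("`bounds` must be a k x 2 matrix of coded intervals", call. = FALSE)
  if (any(bounds[, 1] > bounds[, 2]))
    stop("degenerate bounds: lower exceeds upper", call. = FALSE)
  g <- resolve_goal(g, fit$data$response)

  # Monotone goals: optimise the prediction itself (sign chosen by
  # direction); otherwise optimise desirability directly.
  obj <- switch(g$direction,
    maximize = function(x) -predict(fit, x),
    minimize = function(x) predict(fit, x),
    function(x) -desirability_value(predict(fit, x), g))

  starts <- with_seed(seed, {
    s <- matrix(runif(n_starts * k, bounds[, 1], bounds[, 2]),
                ncol = k, byrow = TRUE)
    rbind(pmin(pmax((bounds[, 1] + bounds[, 2]) / 2, bounds[, 1]),
               bounds[, 2]), s)
  })
  # dimensions pinned by equal bounds are excluded from the search:
  # numerical gradients are undefined on a zero-width interval
  fixed <- bounds[, 1] == bounds[, 2]
  free <- which(!fixed)
  expand <- function(xf) {
    x <- bounds[, 1]
    x[free] <- xf
    x
  }
  runs <- apply(starts, 1L, function(x0) {
    if (!length(free))
      return(list(par = expand(numeric(0)), value = obj(expand(numeric(0))),
                  convergence = 0L))
    r <- optim(x0[free], function(xf) obj(expand(xf)), method = "L-BFGS-B",
               lower = bounds[free, 1], upper = bounds[free, 2],
               control = list(maxit = 200))
    r$par <- expand(r$par)
    r
  })
  cand <- t(vapply(runs, function(r)
    c(r$par, unname(r$value), r$convergence), numeric(k + 2)))
  yhat <- predict(fit, cand[, seq_len(k), drop = FALSE])
  d <- desirability_value(yhat, g)
  # tie-breaks: max d, then max predicted, then lexicographic coded point
  keep <- which(d >= max(d) - 1e-9)
  keep <- keep[order(-yhat[keep])]
  keep <- keep[yhat[keep] >= max(yhat[keep]) - 1e-9]
  lex <- do.call(order, as.data.frame(cand[keep, seq_len(k), drop = FALSE]))
  best <- keep[lex[1]]

  coded <- setNames(cand[best, seq_len(k)], coded_names(k))
  actual <- setNames(
    mapply(function(x, f) suppressMessages(decode_value(x, f)),
           coded, factors),
    vapply(factors, `[[`, "", "name"))
  structure(
    list(coded = coded, actual = actual,
         predicted = yhat[best], desirability = d[best], goal = g,
         trace = list(n_starts = nrow(starts),
                      convergence = cand[, k + 2],
                      objective = cand[, k + 1])),
    class = "desirability_optimum"
  )
}

#' @export
print.desirability_optimum <- function(x, ...) {
  cat(sprintf("<desirability_optimum> predicted %.4g (desirability %.4f)\n",
              x$predicted, x$desirability))
  cat("coded:  ", paste(sprintf("%s=%.3f", names(x$coded), x$coded),
                        collapse = ", "), "\n")
  cat("actual: ", paste(sprintf("%s=%.4g", names(x$actual), x$actual),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Response-surface grid over a factor pair
#'
#' Evaluates the fitted model on a regular grid over the coded ranges of
#' two factors, holding the remaining factors at fixed coded levels
#' (their centre, 0, by default) — the data behind the familiar 3D
#' surface plots.
#'
#' @param fit An `rsm_fit`.
#' @param i,j Indices of the two varying factors (`i != j`).
#' @param fixed Named or positional numeric vector of coded levels for
#'   the remaining factors; default all 0.
#' @param resolution Grid points per axis (default 21).
#' @return A list of class `surface_grid`: `factor_i`, `factor_j`
#'   (names), `x`, `y` (coded grid axes), `z` (resolution x resolution
#'   prediction matrix, rows indexed by `x`), `fixed`.
#' @export
surface_grid <- function(fit, i, j, fixed = NULL, resolution = 21L) {
  stopifnot(inherits(fit, "rsm_fit"))
  k <- fit$spec$k
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("`i` and `j` must be different factors", call. = FALSE)
  if (any(c(i, j) < 1L) || any(c(i, j) > k))
    stop("factor index out of range", call. = FALSE)
  factors <- attr(fit$data, "factors")
  others <- setdiff(seq_len(k), c(i, j))
  lev <- setNames(rep(0, length(others)), coded_names(k)[others])
  if (!is.null(fixed)) {
    if (is.null(names(fixed))) {
      if (length(fixed) != length(others))
        stop("`fixed` must cover the ", length(others), " remaining factors",
             call. = FALSE)
      lev[] <- fixed
    } else {
      unknown <- setdiff(names(fixed), names(lev))
      if (length(unknown))
        stop("`fixed` names not among held factors: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      lev[names(fixed)] <- fixed
    }
  }
  xr <- factors[[i]]$code_range
  yr <- factors[[j]]$code_range
  x <- seq(xr[1], xr[2], length.out = resolution)
  y <- seq(yr[1], yr[2], length.out = resolution)
  pts <- matrix(0, nrow = resolution^2, ncol = k)
  pts[, others] <- rep(lev, each = resolution^2)
  gr <- expand.grid(x = x, y = y)
  pts[, i] <- gr$x
  pts[, j] <- gr$y
  z <- matrix(predict(fit, pts), nrow = resolution)
  structure(
    list(factor_i = factors[[i]]$name, factor_j = factors[[j]]$name,
         x = x, y = y, z = z, fixed = lev),
    class = "surface_grid"
  )
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %s x %s, %d x %d points; fixed: %s\n",
              x$factor_i, x$factor_j, length(x$x), length(x$y),
              paste(sprintf("%s=%g", names(x$fixed), x$fixed),
                    collapse = ", ")))
  invisible(x)
}
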