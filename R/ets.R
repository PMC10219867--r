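#' Specify a Holt-Winters forecasting model
#'
#' The three seasonal exponential-smoothing variants used by the early
#' warning system: additive Holt-Winters (`"additive"`, AHWM),
#' multiplicative Holt-Winters (`"multiplicative"`, MHWM) and damped-trend
#' additive Holt-Winters (`"damped"`, HWDM). All share a level, a trend and
#' `m` seasonal indices; the damped variant attenuates the trend by a
#' factor `phi` per step so long-horizon forecasts stay bounded.
#'
#' @param variant One of `"additive"`, `"multiplicative"`, `"damped"`.
#' @param m Seasonal period in hours; 24 encodes the diurnal cycle.
#' @param trend Logical; keep the trend component (default `TRUE`).
#' @return An object of class `ets_spec`.
#' @export
#' @examples
#' ets_spec("additive")
#' ets_spec("damped", m = 24)
ets_spec <- function(variant = c("additive", "multiplicative", "damped"),
                     m = 24, trend = TRUE) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(m), m >= 2, m == as.integer(m))
  structure(list(variant = variant, m = as.integer(m), trend = isTRUE(trend)),
            class = "ets_spec")
}

#' @export
print.ets_spec <- function(x, ...) {
  cat("<ets_spec> ", x$variant, " Holt-Winters, m = ", x$m,
      if (!x$trend) ", no trend" else "", "\n", sep = "")
  invisible(x)
}

#' Smoothing parameters for a Holt-Winters model
#'
#' @param alpha Level smoothing weight in \[0, 1\].
#' @param beta Trend smoothing weight in \[0, 1\].
#' @param gamma Seasonal smoothing weight in \[0, 1\].
#' @param phi Trend damping factor in \[0.8, 0.98\] (damped variant only;
#'   `NULL` otherwise).
#' @return An object of class `ets_params`.
#' @export
ets_params <- function(alpha, beta, gamma, phi = NULL) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1,
            gamma >= 0, gamma <= 1)
  if (!is.null(phi)) stopifnot(phi >= 0.8, phi <= 0.98)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, phi = phi),
            class = "ets_params")
}

series_values <- function(series) {
  if (is.data.frame(series)) as_hourly_series(series)$value else as.numeric(series)
}

#' Heuristic initial states for Holt-Winters smoothing
#'
#' Seasonal-average initialisation: the level is the mean of the first
#' season, the trend the per-step difference between the first two seasonal
#' means, and each seasonal index the average per-position deviation from
#' its season's mean over all complete seasons (differences for the
#' additive/damped variants, ratios for the multiplicative one), normalised
#' to sum to zero (additive) or average to one (multiplicative).
#'
#' @param series An hourly series (or bare numeric vector) with at least
#'   `2 * m` contiguous observations.
#' @param spec An [ets_spec()].
#' @return A list with components `level`, `trend` and `seasonal` (length
#'   `m`, ordered so that `seasonal[1]` applies to the first observation).
#' @export
ets_init <- function(series, spec) {
  y <- series_values(series)
  m <- spec$m
  if (length(y) < 2 * m) {
    stop("insufficient history: need at least ", 2 * m,
         " observations to initialise (got ", length(y), ")", call. = FALSE)
  }
  mult <- spec$variant == "multiplicative"
  if (mult && any(y <= 0)) {
    stop("multiplicative model requires strictly positive training values",
         call. = FALSE)
  }
  n_seasons <- length(y) %/% m
  ymat <- matrix(y[seq_len(n_seasons * m)], nrow = m)
  season_means <- colMeans(ymat)
  level <- season_means[1]
  trend <- if (spec$trend) (season_means[2] - season_means[1]) / m else 0
  dev <- if (mult) sweep(ymat, 2, season_means, "/")
         else      sweep(ymat, 2, season_means, "-")
  s <- rowMeans(dev)
  s <- if (mult) s / mean(s) else s - mean(s)
  list(level = unname(level), trend = unname(trend), seasonal = unname(s))
}

#' Run the Holt-Winters smoothing recursions with fixed parameters
#'
#' Applies the variant's level/trend/seasonal update equations over the
#' series, producing the full state trajectory and the one-step-ahead
#' fitted values and residuals.
#'
#' @param series Hourly series or numeric vector.
#' @param spec An [ets_spec()].
#' @param params An [ets_params()].
#' @param init Initial states as returned by [ets_init()].
#' @return A tibble with one row per observation and columns `level`,
#'   `trend`, `seasonal` (the index updated at that step), `fitted` and
#'   `residual`; the final `m` seasonal indices are attached as attribute
#'   `"s_final"` and the residual sum of squares as `"sse"`.
#' @export
ets_smooth <- function(series, spec, params, init) {
  y <- series_values(series)
  mult <- spec$variant == "multiplicative"
  phi <- effective_phi(spec, params)
  res <- ets_filter_cpp(y, spec$m, params$alpha, params$beta, params$gamma,
                        phi, init$level, init$trend, init$seasonal, mult)
  out <- tibble::tibble(
    level = res$level, trend = res$trend,
    seasonal = res$seasonal[(spec$m + 1):(spec$m + length(y))],
    fitted = res$fitted, residual = res$residuals
  )
  attr(out, "s_final") <- res$s_final
  attr(out, "sse") <- res$sse
  out
}

effective_phi <- function(spec, params) {
  if (spec$variant == "damped") {
    if (is.null(params$phi)) stop("damped spec requires phi", call. = FALSE)
    params$phi
  } else 1
}

# fixed deterministic multi-start grid (alpha, beta, gamma[, phi])
ets_start_grid <- function(damped) {
  g <- rbind(c(0.20, 0.05, 0.10), c(0.50, 0.01, 0.30), c(0.80, 0.10, 0.05),
             c(0.30, 0.001, 0.50), c(0.10, 0.20, 0.20), c(0.60, 0.05, 0.60))
  if (damped) cbind(g, phi = c(0.90, 0.95, 0.90, 0.95, 0.90, 0.95)) else g
}

#' Fit a Holt-Winters model by maximum likelihood
#'
#' Smoothing weights are estimated by maximising the Gaussian one-step
#' likelihood, equivalently minimising the sum of squared one-step
#' residuals, over the bounded parameter box (`alpha, beta, gamma` in
#' \[0, 1\]; `phi` in \[0.8, 0.98\] for the damped variant) with L-BFGS-B
#' from a fixed grid of six starting points. Initial states come from the
#' heuristic in [ets_init()] and the model carries its final smoothed state
#' so forecasts originate from the last training hour.
#'
#' Multiplicative fits on series containing zeros add an offset of 0.5 to
#' the training values; forecasts subtract it again and are floored at 0.
#'
#' @param series Hourly series tibble (or numeric vector).
#' @param spec An [ets_spec()].
#' @return An object of class `ed_ets`.
#' @export
#' @examples
#' ed <- simulate_ed(n_days = 30, seed = 1)
#' fit <- ets_fit(ed$arrivals, ets_spec("additive"))
#' glance(fit)
ets_fit <- function(series, spec) {
  is_df <- is.data.frame(series)
  if (is_df) series <- as_hourly_series(series)
  y_raw <- series_values(series)
  m <- spec$m
  if (length(y_raw) < 2 * m) {
    stop("insufficient history: need at least ", 2 * m, " observations",
         call. = FALSE)
  }
  mult <- spec$variant == "multiplicative"
  damped <- spec$variant == "damped"
  offset <- if (mult && any(y_raw <= 0)) 0.5 else 0
  y <- y_raw + offset

  init <- ets_init(y, spec)
  obj <- function(p) {
    phi <- if (damped) p[4] else 1
    ets_sse_cpp(y, m, p[1], p[2], p[3], phi,
                init$level, init$trend, init$seasonal, mult)
  }
  starts <- ets_start_grid(damped)
  lower <- c(1e-4, 0, 1e-4, if (damped) 0.80)
  upper <- c(0.9999, 0.9999, 0.9999, if (damped) 0.98)
  best <- NULL
  diagnostics <- character()
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 200)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
    } else if (is.null(best) || fit$value < best$value) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("ets fitting failed on all starts: ",
         paste(unique(diagnostics), collapse = "; "), call. = FALSE)
  }
  p <- best$par
  params <- ets_params(p[1], p[2], p[3], if (damped) p[4] else NULL)
  traj <- ets_smooth(y, spec, params, init)
  n <- length(y)
  sse <- attr(traj, "sse")
  sigma2 <- sse / n
  params$sigma2 <- sigma2
  loglik <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf

  structure(list(
    spec = spec, params = params, init = init,
    state = list(level = traj$level[n], trend = traj$trend[n],
                 seasonal = attr(traj, "s_final")),
    offset = offset, n_train = n, sse = sse, loglik = loglik,
    train_end = if (is_df) series$timestamp[nrow(series)] else NA
  ), class = "ed_ets")
}

#' Point forecasts from a fitted Holt-Winters model
#'
#' Forecast equations at horizon `k` from the final state
#' (level `l`, trend `b`, seasonal index `s` at the matching position):
#' additive `l + k b + s`; multiplicative `(l + k b) * s`; damped
#' `l + (phi + ... + phi^k) b + s`. Count forecasts are floored at 0 (and
#' any multiplicative training offset is removed first); no rounding is
#' applied so forecasts remain continuous scores.
#'
#' @param object A fitted `ed_ets` model.
#' @param h Forecast horizon in hours (default 24).
#' @return A tibble with columns `horizon` (1..h) and `yhat`.
#' @export
ets_forecast <- function(object, h = 24) {
  stopifnot(inherits(object, "ed_ets"), h >= 1)
  forecast_from_state(object$spec, object$params, object$state, h,
                      offset = object$offset)
}

# forecast h steps ahead from an arbitrary state
forecast_from_state <- function(spec, params, state, h, offset = 0) {
  k <- seq_len(h)
  m <- spec$m
  s <- state$seasonal[((k - 1) %% m) + 1]
  yhat <- switch(spec$variant,
    additive = state$level + k * state$trend + s,
    multiplicative = (state$level + k * state$trend) * s,
    damped = {
      phi <- params$phi
      damp <- phi * (1 - phi^k) / (1 - phi)
      state$level + damp * state$trend + s
    }
  )
  tibble::tibble(horizon = k, yhat = pmax(yhat - offset, 0))
}

#' @export
#' @param ... Unused.
#' @rdname ets_forecast
predict.ed_ets <- function(object, h = 24, ...) ets_forecast(object, h)

#' @export
print.ed_ets <- function(x, ...) {
  cat("<ed_ets> ", x$spec$variant, " Holt-Winters, m = ", x$spec$m,
      ", n = ", x$n_train, "\n", sep = "")
  cat(sprintf("  alpha = %.4f, beta = %.4f, gamma = %.4f%s\n",
              x$params$alpha, x$params$beta, x$params$gamma,
              if (!is.null(x$params$phi))
                sprintf(", phi = %.4f", x$params$phi) else ""))
  cat(sprintf("  sigma^2 = %.4f, log-lik = %.2f\n", x$params$sigma2, x$loglik))
  invisible(x)
}

#' Tidy a fitted Holt-Winters model
#'
#' @param x An `ed_ets` object.
#' @param ... Unused.
#' @return One row per smoothing parameter with columns `term` and
#'   `estimate`.
#' @export
tidy.ed_ets <- function(x, ...) {
  p <- x$params
  terms <- c("alpha", "beta", "gamma", if (!is.null(p$phi)) "phi")
  tibble::tibble(term = terms,
                 estimate = unlist(p[terms], use.names = FALSE))
}

#' @rdname tidy.ed_ets
#' @return `glance()` returns a one-row model summary.
#' @export
glance.ed_ets <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant, m = x$spec$m,
                 n_train = x$n_train, sigma2 = x$params$sigma2,
                 sse = x$sse, logLik = x$loglik)
}
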