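#' Build an hourly forecast-origin schedule
#'
#' Origins are every observed hour after a warm-up period long enough to
#' initialise the seasonal smoothers (14 days by default, comfortably more
#' than the two full seasonal cycles the initialisation needs).
#'
#' @param series An hourly series spanning the study period.
#' @param warmup_days Days at the start never used as forecast origins.
#' @return A POSIXct vector of origins.
#' @export
forecast_schedule <- function(series, warmup_days = 14) {
  series <- as_hourly_series(series)
  start <- series$timestamp[1] + warmup_days * 86400
  series$timestamp[series$timestamp >= start]
}

#' The three deployed Holt-Winters model specifications
#'
#' @param m Seasonal period (hours).
#' @return A named list of [ets_spec()]s: `AHWM` (additive), `MHWM`
#'   (multiplicative) and `HWDM` (damped additive trend).
#' @export
default_models <- function(m = 24) {
  list(AHWM = ets_spec("additive", m = m),
       MHWM = ets_spec("multiplicative", m = m),
       HWDM = ets_spec("damped", m = m))
}

#' Run the prospective forecasting engine
#'
#' Emulates the deployed early-warning loop: at every forecast origin each
#' model is trained on all history available strictly up to that origin and
#' issues 24 hourly point forecasts, which are appended to a prediction
#' store. Parameters are re-estimated every `refit_stride` hours; between
#' refits the smoothing states are advanced observation by observation with
#' the last fitted parameters, so forecasts always start from the most
#' recent state. Origins that cannot be served (insufficient history, a
#' missing origin hour, a fitting failure) are skipped and logged, and the
#' run continues — mirroring how the live system behaved across downtime.
#'
#' @param data Named list of hourly series by target, e.g.
#'   `list(arrivals = ..., occupancy = ...)`.
#' @param models Named list of [ets_spec()]s; names become `model_id`s.
#'   Defaults to the three Holt-Winters variants (AHWM, MHWM, HWDM).
#' @param origins POSIXct forecast origins; defaults to
#'   [forecast_schedule()] on the first target.
#' @param refit_stride Hours between full parameter re-estimations
#'   (1 = refit every hour, as deployed; 24 keeps desk-scale runs cheap).
#' @param h Forecast horizon in hours (24).
#' @param warmup_days Warm-up passed to [forecast_schedule()] when
#'   `origins` is `NULL`.
#' @param max_gap Longest gap (hours) interpolated in training series; see
#'   [prepare_training()].
#' @param quiet Suppress progress messages.
#' @return A list of class `prospective_run` with elements `store` (tibble:
#'   `origin`, `model_id`, `target`, `horizon`, `yhat`, `created_at`) and
#'   `skips` (tibble: `origin`, `model_id`, `target`, `reason`).
#' @export
#' @examples
#' ed <- simulate_ed(n_days = 35, seed = 7)
#' run <- run_prospective(ed["occupancy"], models = default_models()["AHWM"],
#'                        refit_stride = 24 * 7)
#' nrow(run$store)
run_prospective <- function(data, models = default_models(),
                            origins = NULL, refit_stride = 1, h = 24,
                            warmup_days = 14, max_gap = 6, quiet = TRUE) {
  stopifnot(is.list(data), length(data) >= 1, !is.null(names(data)),
            is.list(models), !is.null(names(models)), refit_stride >= 1)
  data <- lapply(data, as_hourly_series)
  if (is.null(origins)) origins <- forecast_schedule(data[[1]], warmup_days)
  origins <- sort(unique(origins))
  if (length(origins) == 0) stop("empty origin schedule", call. = FALSE)

  # time-based refit blocks over the origin schedule
  block_id <- floor(as.numeric(origins - origins[1], units = "hours") /
                    refit_stride)
  blocks <- split(origins, block_id)

  stores <- list(); skips <- list()
  for (target in names(data)) {
    series <- data[[target]]
    for (model_id in names(models)) {
      spec <- models[[model_id]]
      for (blk in blocks) {
        res <- forecast_block(series, spec, blk, h, max_gap)
        if (nrow(res$store)) {
          res$store$model_id <- model_id
          res$store$target <- target
          stores[[length(stores) + 1L]] <- res$store
        }
        if (nrow(res$skips)) {
          res$skips$model_id <- model_id
          res$skips$target <- target
          skips[[length(skips) + 1L]] <- res$skips
        }
      }
      if (!quiet) {
        message(sprintf("[%s] %s/%s: done", format(Sys.time(), "%H:%M:%S"),
                        target, model_id))
      }
    }
  }
  store <- if (length(stores)) dplyr::bind_rows(stores) else empty_store()
  skip_log <- if (length(skips)) dplyr::bind_rows(skips) else empty_skips()
  store <- dplyr::select(store, "origin", "model_id", "target", "horizon",
                         "yhat", "created_at")
  structure(list(store = store,
                 skips = dplyr::select(skip_log, "origin", "model_id",
                                       "target", "reason")),
            class = "prospective_run")
}

empty_store <- function() {
  tibble::tibble(origin = as.POSIXct(character(), tz = "UTC"),
                 model_id = character(), target = character(),
                 horizon = integer(), yhat = numeric(),
                 created_at = as.POSIXct(character(), tz = "UTC"))
}

empty_skips <- function() {
  tibble::tibble(origin = as.POSIXct(character(), tz = "UTC"),
                 model_id = character(), target = character(),
                 reason = character())
}

# fit at the block's first origin, then advance states causally through the
# block and forecast from the state at each origin
forecast_block <- function(series, spec, block_origins, h, max_gap) {
  r <- block_origins[1]
  skip_all <- function(reason) {
    list(store = empty_store()[, c("origin", "horizon", "yhat", "created_at")],
         skips = tibble::tibble(origin = block_origins, reason = reason))
  }
  hist <- series[series$timestamp <= r, ]
  prep <- prepare_training(hist, max_gap = max_gap)
  if (nrow(prep) < 2 * spec$m) return(skip_all("insufficient_history"))
  fit <- tryCatch(ets_fit(prep[, c("timestamp", "value")], spec),
                  error = function(e) e)
  if (inherits(fit, "error")) return(skip_all("fitting_failure"))

  # extend the prepared history through the block on a contiguous grid,
  # interpolating interior holes; trailing unobserved hours stay NA
  block_end <- block_origins[length(block_origins)]
  grid <- seq(prep$timestamp[1], block_end, by = "hour")
  idx <- match(as.numeric(grid), as.numeric(series$timestamp))
  v <- series$value[idx]
  observed <- !is.na(idx)
  np <- nrow(prep)
  v[seq_len(np)] <- prep$value
  last_obs <- max(which(!is.na(v)))
  if (any(is.na(v[seq_len(last_obs)]))) v[seq_len(last_obs)] <- approx_fill(v[seq_len(last_obs)])

  y <- v[seq_len(last_obs)] + fit$offset
  traj <- ets_smooth(y, spec, fit$params, fit$init)
  seas_pad <- c(fit$init$seasonal, traj$seasonal)
  m <- spec$m

  o_idx <- match(as.numeric(block_origins), as.numeric(grid))
  records <- vector("list", length(block_origins))
  skip_o <- character(0); skip_t <- as.POSIXct(character(), tz = "UTC")
  for (j in seq_along(block_origins)) {
    i <- o_idx[j]
    if (is.na(i) || i > last_obs || !observed[i]) {
      skip_t <- c(skip_t, block_origins[j]); skip_o <- c(skip_o, "origin_missing")
      next
    }
    state <- list(level = traj$level[i], trend = traj$trend[i],
                  seasonal = seas_pad[(i + 1):(i + m)])
    fc <- forecast_from_state(spec, fit$params, state, h, offset = fit$offset)
    records[[j]] <- tibble::tibble(origin = block_origins[j],
                                   horizon = fc$horizon, yhat = fc$yhat,
                                   created_at = block_origins[j])
  }
  store <- dplyr::bind_rows(records)
  if (nrow(store) == 0) {
    store <- empty_store()[, c("origin", "horizon", "yhat", "created_at")]
  }
  list(store = store,
       skips = tibble::tibble(origin = skip_t, reason = skip_o))
}

#' @export
print.prospective_run <- function(x, ...) {
  cat("<prospective_run> ", nrow(x$store), " forecast records, ",
      nrow(x$skips), " skipped origins\n", sep = "")
  invisible(x)
}

store_key <- function(store) {
  paste(as.numeric(store$origin), store$model_id, store$target,
        store$horizon, sep = "|")
}

#' Persist and reload the prediction store
#'
#' The store is a flat append-only CSV with fixed column order `origin,
#' model_id, target, horizon, yhat, created_at`. Writing is idempotent:
#' records whose (origin, model_id, target, horizon) key is already present
#' in the file are not appended again, so re-running a completed schedule
#' adds zero rows.
#'
#' @param store A prediction-store tibble (from [run_prospective()]).
#' @param path CSV file path.
#' @return `write_prediction_store()` invisibly returns the number of rows
#'   appended; `read_prediction_store()` returns the store tibble.
#' @export
write_prediction_store <- function(store, path) {
  new <- store
  if (file.exists(path)) {
    old <- read_prediction_store(path)
    new <- store[!(store_key(store) %in% store_key(old)), ]
    if (nrow(new) == 0) return(invisible(0L))
  }
  out <- data.frame(
    origin = format(new$origin, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    model_id = new$model_id, target = new$target, horizon = new$horizon,
    yhat = new$yhat,
    created_at = format(new$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
  invisible(nrow(new))
}

#' @rdname write_prediction_store
#' @export
read_prediction_store <- function(path) {
  if (!file.exists(path)) stop("prediction store not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("origin", "model_id", "target", "horizon", "yhat",
                "created_at")
  if (!all(required %in% names(df))) {
    stop("malformed prediction store: missing columns", call. = FALSE)
  }
  bad <- which(is.na(suppressWarnings(as.numeric(df$yhat))) |
                 is.na(suppressWarnings(as.integer(df$horizon))) |
                 df$horizon < 1)
  if (length(bad)) {
    stop("corrupted prediction store row at line ", bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  tibble::tibble(
    origin = as.POSIXct(df$origin, tz = "UTC",
                        format = "%Y-%m-%dT%H:%M:%SZ"),
    model_id = df$model_id, target = df$target,
    horizon = as.integer(df$horizon), yhat = as.numeric(df$yhat),
    created_at = as.POSIXct(df$created_at, tz = "UTC",
                            format = "%Y-%m-%dT%H:%M:%SZ")
  )
}

#' Align predictions with realised actuals and crowding labels
#'
#' Inner-joins every forecast record with the actual value observed at
#' `origin + horizon` and, for occupancy, the hourly crowding label; rows
#' whose target hour was never observed are dropped and counted, following
#' the study convention that downtime hours are excluded from evaluation
#' rather than imputed.
#'
#' @param store Prediction-store tibble.
#' @param actuals Named list of hourly series (must contain every target in
#'   the store; crowding labels come from `actuals$occupancy`).
#' @param scheme A [crowding_scheme()], required when occupancy labels are
#'   wanted.
#' @return A tibble with columns `origin`, `model_id`, `target`, `horizon`,
#'   `yhat`, `y_actual`, `hour_label`, `origin_hour`; the number of dropped
#'   records is attached as attribute `"dropped"`.
#' @export
align_predictions <- function(store, actuals, scheme = NULL) {
  stopifnot(is.list(actuals), !is.null(names(actuals)))
  actuals <- lapply(actuals, as_hourly_series)
  labels <- NULL
  if (!is.null(scheme) && "occupancy" %in% names(actuals)) {
    labels <- label_hours(actuals$occupancy, scheme)
  }
  if (nrow(store) == 0) {
    out <- dplyr::mutate(empty_store()[, c("origin", "model_id", "target",
                                           "horizon", "yhat")],
                         y_actual = numeric(), hour_label = integer(),
                         origin_hour = integer())
    attr(out, "dropped") <- 0L
    return(out)
  }
  rows <- store |>
    dplyr::mutate(target_time = .data$origin + 3600 * .data$horizon,
                  origin_hour = lubridate::hour(.data$origin))
  pieces <- lapply(split(rows, rows$target), function(part) {
    tt <- part$target[1]
    if (!tt %in% names(actuals)) {
      stop("no actuals supplied for target '", tt, "'", call. = FALSE)
    }
    act <- actuals[[tt]]
    part$y_actual <- act$value[match(as.numeric(part$target_time),
                                     as.numeric(act$timestamp))]
    if (!is.null(labels)) {
      part$hour_label <- labels$crowded[match(as.numeric(part$target_time),
                                              as.numeric(labels$timestamp))]
    } else {
      part$hour_label <- NA_integer_
    }
    part
  })
  joined <- dplyr::bind_rows(pieces)
  dropped <- sum(is.na(joined$y_actual))
  out <- joined |>
    dplyr::filter(!is.na(.data$y_actual)) |>
    dplyr::select("origin", "model_id", "target", "horizon", "yhat",
                  "y_actual", "hour_label", "origin_hour") |>
    dplyr::arrange(.data$origin, .data$model_id, .data$target, .data$horizon)
  attr(out, "dropped") <- dropped
  out
}
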