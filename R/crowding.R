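#' Daily peak occupancy
#'
#' The crowding definition is anchored on daily peak occupancy (DPO): the
#' highest occupancy recorded during each calendar day (00:00-23:00 UTC).
#' Days with fewer than 24 observed hours are flagged incomplete and
#' excluded from threshold estimation, since their observed maximum may
#' understate the true peak.
#'
#' @param occupancy An hourly occupancy series.
#' @return A tibble with one row per day: `day` (Date), `peak`,
#'   `peak_hour` (hour-of-day of the maximum, first hour on ties) and
#'   `complete` (all 24 hours observed).
#' @export
#' @examples
#' ed <- simulate_ed(n_days = 10, seed = 1)
#' daily_peak_occupancy(ed$occupancy)
daily_peak_occupancy <- function(occupancy) {
  occupancy <- as_hourly_series(occupancy)
  if (nrow(occupancy) == 0) {
    return(tibble::tibble(day = as.Date(character()), peak = numeric(),
                          peak_hour = integer(), complete = logical()))
  }
  occupancy |>
    dplyr::mutate(day = as.Date(.data$timestamp, tz = "UTC"),
                  hour = lubridate::hour(.data$timestamp)) |>
    dplyr::group_by(day = .data$day) |>
    dplyr::summarise(
      peak = max(.data$value),
      peak_hour = .data$hour[which.max(.data$value)],
      complete = dplyr::n() == 24L,
      .groups = "drop"
    )
}

#' Crowding threshold from the DPO distribution
#'
#' The operational threshold is the nearest-rank `q`-th percentile of the
#' daily-peak-occupancy distribution over complete days: with the peaks
#' sorted, the value at rank `ceiling(q * n)`. A day whose peak reaches
#' this value is crowded, so at most a `1 - q` fraction of days (less under
#' ties) is labelled crowded.
#'
#' @param dpo A DPO table from [daily_peak_occupancy()].
#' @param q Quantile defining the crowded class (default 0.75: the most
#'   crowded quartile of days).
#' @return The threshold (scalar).
#' @export
crowding_threshold <- function(dpo, q = 0.75) {
  stopifnot(q > 0, q < 1)
  peaks <- dpo$peak[dpo$complete]
  if (length(peaks) < 8) {
    stop("insufficient data: need at least 8 complete days to estimate the ",
         "crowding threshold (got ", length(peaks), ")", call. = FALSE)
  }
  sort(peaks)[ceiling(q * length(peaks))]
}

#' Crowding scheme
#'
#' Bundles the quartile level, the derived occupancy threshold and the
#' forecast-window length used to label hours and 24-hour windows as
#' crowded. Comparison is `occupancy >= threshold` ("reaches" the most
#' crowded quartile).
#'
#' @param threshold Occupancy threshold (patients).
#' @param quantile Quantile the threshold was derived from.
#' @param window Forecast window length in hours (default 24).
#' @return An object of class `crowding_scheme`.
#' @export
crowding_scheme <- function(threshold, quantile = 0.75, window = 24) {
  stopifnot(threshold > 0, quantile > 0, quantile < 1, window >= 1)
  structure(list(threshold = threshold, quantile = quantile,
                 window = as.integer(window)),
            class = "crowding_scheme")
}

#' @export
print.crowding_scheme <- function(x, ...) {
  cat("<crowding_scheme> occupancy >= ", x$threshold,
      " (q = ", x$quantile, "), window = ", x$window, " h\n", sep = "")
  invisible(x)
}

#' Derive a crowding scheme from an occupancy series
#'
#' Convenience wrapper: DPO table, nearest-rank threshold, scheme.
#'
#' @inheritParams daily_peak_occupancy
#' @inheritParams crowding_threshold
#' @inheritParams crowding_scheme
#' @return A `crowding_scheme`.
#' @export
derive_crowding_scheme <- function(occupancy, q = 0.75, window = 24) {
  theta <- crowding_threshold(daily_peak_occupancy(occupancy), q)
  crowding_scheme(theta, quantile = q, window = window)
}

#' Per-hour binary crowding labels
#'
#' @param occupancy An hourly occupancy series (gaps allowed; missing hours
#'   get missing labels downstream).
#' @param scheme A [crowding_scheme()].
#' @return The series with an added integer column `crowded`
#'   (1 if `value >= threshold`).
#' @export
label_hours <- function(occupancy, scheme) {
  occupancy <- as_hourly_series(occupancy)
  dplyr::mutate(occupancy,
                crowded = as.integer(.data$value >= scheme$threshold))
}

#' Binary crowding label for forecast windows
#'
#' A forecast window starting at `origin` is crowded if any of the hours
#' `origin + 1 .. origin + W` is crowded. Windows in which some hourly
#' labels are missing are labelled crowded if any observed hour is crowded,
#' and missing otherwise (never 0): downtime must not create false
#' negatives.
#'
#' @param hour_labels Output of [label_hours()].
#' @param origins POSIXct vector of window origins.
#' @param window Window length `W` in hours (default 24).
#' @return A tibble with columns `origin` and `window_crowded`
#'   (1, 0 or `NA`).
#' @export
label_windows <- function(hour_labels, origins, window = 24) {
  key <- as.numeric(hour_labels$timestamp)
  lab <- hour_labels$crowded
  out <- vapply(as.numeric(origins), function(o) {
    idx <- match(o + 3600 * seq_len(window), key)
    w <- lab[idx]
    if (any(w == 1, na.rm = TRUE)) 1L
    else if (!anyNA(idx) && !anyNA(w)) 0L
    else NA_integer_
  }, integer(1))
  tibble::tibble(origin = origins, window_crowded = out)
}
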