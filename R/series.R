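#' Hourly series utilities
#'
#' An hourly series is a tibble with a POSIXct `timestamp` column (UTC, on
#' the hour) and a non-negative numeric `value` column. Timestamps are
#' strictly increasing; missing hours are simply absent rows (gaps), which
#' downstream code either interpolates or drops according to its gap policy.
#'
#' @name hourly-series
NULL

#' Validate and normalise an hourly series
#'
#' Coerces a data frame with `timestamp` and `value` columns into the
#' canonical hourly-series form: POSIXct UTC timestamps aligned to the hour,
#' strictly increasing, with non-negative values.
#'
#' @param x A data frame with columns `timestamp` and `value`.
#' @return A tibble with columns `timestamp` (POSIXct, UTC) and `value`.
#' @export
#' @examples
#' as_hourly_series(data.frame(
#'   timestamp = as.POSIXct("2022-01-01 00:00", tz = "UTC") + 3600 * 0:5,
#'   value = c(3, 2, 4, 1, 0, 2)
#' ))
as_hourly_series <- function(x) {
  stopifnot(is.data.frame(x), all(c("timestamp", "value") %in% names(x)))
  ts <- if (is.character(x$timestamp) || is.factor(x$timestamp)) {
    lubridate::ymd_hms(as.character(x$timestamp), tz = "UTC", quiet = TRUE)
  } else {
    as.POSIXct(x$timestamp, tz = "UTC")
  }
  attr(ts, "tzone") <- "UTC"
  v <- as.numeric(x$value)
  if (anyNA(ts)) stop("unparseable timestamps in hourly series", call. = FALSE)
  if (any(as.numeric(ts) %% 3600 != 0)) {
    stop("timestamps must fall exactly on the hour", call. = FALSE)
  }
  ord <- order(ts)
  ts <- ts[ord]; v <- v[ord]
  if (anyDuplicated(as.numeric(ts))) {
    stop("duplicate timestamps in hourly series", call. = FALSE)
  }
  if (any(v < 0, na.rm = TRUE)) stop("series values must be >= 0", call. = FALSE)
  tibble::tibble(timestamp = ts, value = v)
}

#' Prepare a contiguous training series
#'
#' Regularises an hourly series for model training: gaps of at most
#' `max_gap` missing hours are filled by linear interpolation between their
#' bounding observations; if a longer outage is present, only the longest
#' contiguous trailing run after the last such outage is kept, so that the
#' seasonal index alignment of the smoother is never corrupted by a long
#' hole.
#'
#' @param series An hourly series (see [as_hourly_series()]).
#' @param max_gap Largest run of consecutive missing hours that is
#'   interpolated rather than treated as an outage (default 6).
#' @return A gap-free hourly series tibble with an additional logical
#'   column `observed` (FALSE for interpolated rows).
#' @export
prepare_training <- function(series, max_gap = 6) {
  series <- as_hourly_series(series)
  n <- nrow(series)
  if (n == 0) {
    return(tibble::tibble(timestamp = series$timestamp, value = numeric(),
                          observed = logical()))
  }
  full <- seq(series$timestamp[1], series$timestamp[n], by = "hour")
  idx <- match(as.numeric(full), as.numeric(series$timestamp))
  v <- series$value[idx]
  observed <- !is.na(idx)

  # locate runs of missing hours
  if (any(!observed)) {
    r <- rle(observed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    long_end <- 0L
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] && r$lengths[k] > max_gap) long_end <- ends[k]
    }
    if (long_end > 0L) {
      keep <- (long_end + 1L):length(full)
      full <- full[keep]; v <- v[keep]; observed <- observed[keep]
    }
    if (any(!observed)) {
      v <- approx_fill(v)
    }
  }
  tibble::tibble(timestamp = full, value = v, observed = observed)
}

# linear interpolation of interior NAs (no leading/trailing NAs expected)
approx_fill <- function(v) {
  i <- which(!is.na(v))
  stats::approx(i, v[i], xout = seq_along(v))$y
}

#' Read / write series CSV files
#'
#' Series files have two columns, `timestamp` (ISO-8601, hourly) and
#' `value`; lines starting with `#` are treated as provenance comments and
#' ignored on read.
#'
#' @param path File path.
#' @return `read_series_csv()` returns an hourly series tibble.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  as_hourly_series(df)
}

#' @rdname read_series_csv
#' @param series An hourly series tibble.
#' @param comments Character vector written as `#`-prefixed header lines
#'   (provenance: seed, generator parameters).
#' @export
write_series_csv <- function(series, path, comments = character()) {
  series <- as_hourly_series(series)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  out <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    value = series$value
  )
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
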