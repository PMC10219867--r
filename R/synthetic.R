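#' Default synthetic emergency department profile
#'
#' Calibrated generator settings reproducing the diurnal structure of a
#' large combined ED: a nonhomogeneous Poisson arrival intensity with a
#' trough of ~2 patients/hour at 05:00-07:00 rising to a peak of 13 at
#' 16:00; i.i.d. log-normal day-surge multipliers (mean 1) applied to the
#' afternoon/evening intensities (12:00-23:00), which create the day-to-day
#' variability in daily peak occupancy that makes the most-crowded-quartile
#' definition non-degenerate; and a log-normal length-of-stay distribution
#' (median 5 h, log-sd 0.8, capped at 48 h) through which occupancy emerges
#' from arrivals as an infinite-server queue. With these defaults the
#' expected occupancy profile troughs near 23-27 patients at 06:00-08:00,
#' peaks near 73 at 17:00-18:00, and roughly 3% of hours land above the
#' crowding threshold, all of them in the afternoon or evening.
#'
#' Because the day surges are independent across days and only touch hours
#' from noon on, the history available at midnight carries no information
#' about the coming day's surge; any forecaster's per-origin (PPO) skill at
#' origin 00:00 is therefore structurally pinned to chance.
#'
#' @param lambda Numeric length-24 vector of baseline arrival intensities
#'   (patients/hour) by hour of day.
#' @param surge_sd Log-sd of the day-surge multiplier.
#' @param surge_hours Hours of day (0-23) the surge applies to.
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters
#'   (hours).
#' @param los_cap Maximum length of stay in hours.
#' @return An object of class `ed_profile`.
#' @export
#' @examples
#' prof <- ed_profile()
#' prof$lambda[17] # intensity at 16:00
ed_profile <- function(lambda = c(3.0, 2.6, 2.3, 2.1, 2.0, 2.0, 2.0, 2.6,
                                  5.0, 8.5, 10.8, 11.8, 12.2, 12.4, 12.5,
                                  12.6, 13.0, 12.0, 10.0, 7.5, 5.8, 4.6,
                                  3.8, 3.2),
                       surge_sd = 0.15, surge_hours = 12:23,
                       los_meanlog = log(5), los_sdlog = 0.8,
                       los_cap = 48) {
  stopifnot(length(lambda) == 24, all(lambda >= 0), surge_sd >= 0,
            all(surge_hours %in% 0:23), los_cap > 0)
  structure(list(lambda = lambda, surge_sd = surge_sd,
                 surge_hours = as.integer(surge_hours),
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 los_cap = los_cap),
            class = "ed_profile")
}

#' @export
print.ed_profile <- function(x, ...) {
  cat("<ed_profile> lambda peak ", max(x$lambda), "/h at ",
      which.max(x$lambda) - 1, ":00, surge sd ", x$surge_sd,
      " on hours ", min(x$surge_hours), "-", max(x$surge_hours),
      ", LOS median ", round(exp(x$los_meanlog), 1), " h\n", sep = "")
  invisible(x)
}

#' Simulate hourly ED arrivals
#'
#' Nonhomogeneous Poisson counts: `arrivals_t ~ Poisson(lambda[hour(t)] *
#' surge(day(t)))`, with the log-normal surge multiplier (mean 1, log-sd
#' `surge_sd`) drawn independently per day and applied only on
#' `surge_hours`.
#'
#' @param profile An [ed_profile()].
#' @param n_days Number of simulated days.
#' @param seed Integer seed; identical seeds give identical series.
#' @param start First hour of the simulation (POSIXct or parseable string,
#'   UTC midnight recommended).
#' @return An hourly series tibble; the per-day surge multipliers are
#'   attached as attribute `"day_effects"`.
#' @export
simulate_arrivals <- function(profile = ed_profile(), n_days, seed,
                              start = "2022-01-01") {
  stopifnot(n_days >= 0)
  start <- as.POSIXct(start, tz = "UTC")
  n <- n_days * 24L
  ts <- start + 3600 * (seq_len(n) - 1)
  hrs <- rep(0:23, n_days)
  day <- rep(seq_len(n_days), each = 24L)
  withr::with_seed(seed, {
    effects <- exp(rnorm(n_days, -profile$surge_sd^2 / 2, profile$surge_sd))
    intensity <- profile$lambda[hrs + 1] *
      ifelse(hrs %in% profile$surge_hours, effects[day], 1)
    counts <- rpois(n, intensity)
  })
  out <- tibble::tibble(timestamp = ts, value = as.numeric(counts))
  attr(out, "day_effects") <- if (n_days > 0) effects else numeric()
  out
}

#' Simulate ED occupancy from arrivals
#'
#' Infinite-server queue: each arriving patient gets a uniform arrival
#' offset within their hour and an independent log-normal length of stay
#' (capped at `los_cap`); occupancy at the top of each hour is the number
#' of patients who have arrived and not yet departed. No capacity
#' constraint is imposed, so occupancy inherits the arrival seasonality
#' with a lag set by the stay distribution.
#'
#' @param arrivals An hourly arrivals series (integer counts).
#' @param profile An [ed_profile()] supplying the stay distribution.
#' @param seed Integer seed.
#' @return An hourly occupancy series aligned with `arrivals`.
#' @export
simulate_occupancy <- function(arrivals, profile = ed_profile(), seed) {
  arrivals <- as_hourly_series(arrivals)
  n <- nrow(arrivals)
  if (n == 0 || sum(arrivals$value) == 0) {
    return(tibble::tibble(timestamp = arrivals$timestamp,
                          value = numeric(n)))
  }
  counts <- as.integer(arrivals$value)
  total <- sum(counts)
  slot <- rep.int(seq_len(n) - 1L, counts)
  withr::with_seed(seed, {
    at <- slot + runif(total)
    los <- pmin(rlnorm(total, profile$los_meanlog, profile$los_sdlog),
                profile$los_cap)
  })
  # occupancy sampled at integer hours u = 1..n-1 relative to slot 0 start:
  # patient present at u iff at <= u < at + los
  first <- ceiling(at)
  last <- ceiling(at + los) - 1
  diffs <- numeric(n + 2L)
  ok <- last >= first & first <= (n - 1L)
  f <- pmin(first[ok], n - 1L) + 1L   # index into hours 0..n-1 (1-based)
  l <- pmin(last[ok], n - 1L) + 1L
  for (i in seq_along(f)) {
    diffs[f[i]] <- diffs[f[i]] + 1
    diffs[l[i] + 1L] <- diffs[l[i] + 1L] - 1
  }
  occ <- cumsum(diffs)[seq_len(n)]
  tibble::tibble(timestamp = arrivals$timestamp, value = occ)
}

#' Simulate a complete synthetic ED
#'
#' Convenience wrapper producing mutually consistent arrivals and
#' occupancy series from one profile and one seed.
#'
#' @inheritParams simulate_arrivals
#' @return A list with hourly series `arrivals` and `occupancy`.
#' @export
#' @examples
#' ed <- simulate_ed(n_days = 60, seed = 42)
#' range(ed$occupancy$value)
simulate_ed <- function(n_days, seed, profile = ed_profile(),
                        start = "2022-01-01") {
  arrivals <- simulate_arrivals(profile, n_days, seed, start)
  occupancy <- simulate_occupancy(arrivals, profile, seed + 1L)
  list(arrivals = arrivals, occupancy = occupancy)
}

#' Remove hours from a series to emulate system downtime
#'
#' Deletes rows to a target missing fraction using the two failure modes a
#' deployed system exhibits: long scheduled outages (contiguous blocks) and
#' sporadic single missing hours. By default 80% of the missing budget is
#' spent on one or more contiguous blocks and the rest on scattered hours.
#'
#' @param series An hourly series.
#' @param fraction Target missing fraction in \[0, 0.5\].
#' @param seed Integer seed.
#' @param block_share Share of missing hours allocated to contiguous
#'   blocks.
#' @param block_hours Length of each outage block (hours).
#' @return A copy of `series` with rows removed; the count is attached as
#'   attribute `"n_removed"`.
#' @export
inject_gaps <- function(series, fraction, seed, block_share = 0.8,
                        block_hours = 168) {
  stopifnot(fraction >= 0, fraction <= 0.5)
  series <- as_hourly_series(series)
  n <- nrow(series)
  target <- round(fraction * n)
  if (target == 0) {
    out <- series
    attr(out, "n_removed") <- 0L
    return(out)
  }
  drop <- withr::with_seed(seed, {
    n_block_hours <- round(block_share * target)
    n_blocks <- max(0L, floor(n_block_hours / block_hours))
    dropped <- integer(0)
    if (n_blocks > 0) {
      starts <- sample(seq_len(max(1L, n - block_hours)), n_blocks)
      dropped <- unique(unlist(lapply(starts, function(s)
        s:min(s + block_hours - 1L, n))))
    }
    remaining <- setdiff(seq_len(n), dropped)
    extra <- max(0L, target - length(dropped))
    c(dropped, sample(remaining, min(extra, length(remaining))))
  })
  out <- series[-drop, ]
  attr(out, "n_removed") <- length(drop)
  out
}
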