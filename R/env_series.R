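# Point-series SST utilities: rolling means, daily climatology, monthly
# anomalies, trip-window SST, alongshore velocity rotation. Series are
# tibbles `date, value` with missing values explicit as NA.

#' Centred rolling mean of a daily series
#'
#' The window is centred (an even width reaches `floor((w-1)/2)` days back
#' and `floor(w/2)` forward), edges use the truncated window, and missing
#' values are skipped within each window, so the smoothed series is defined
#' wherever any window value exists.
#'
#' @param series Tibble `date, value` (dates unique; gaps allowed and
#'   treated as missing days).
#' @param window_days Window width, days.
#' @return Tibble `date, value, smoothed` on the full daily grid from the
#'   first to the last date.
#' @export
rolling_mean <- function(series, window_days = 10) {
  stopifnot(window_days >= 1, all(c("date", "value") %in% names(series)))
  if (nrow(series) == 0) abort("empty series")
  if (anyDuplicated(series$date)) abort("duplicate dates in series")
  full <- tibble(date = seq(min(series$date), max(series$date), by = "day")) %>%
    left_join(series[c("date", "value")], by = "date") %>%
    arrange(.data$date)
  full$smoothed <- zoo::rollapply(full$value, width = window_days,
    FUN = function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
    partial = TRUE, align = "center"
  )
  full
}

#' Daily climatology across years
#'
#' Mean of the series for each calendar day across the supplied years;
#' Feb 29 is averaged over leap years only.
#'
#' @param series Tibble `date, value` spanning one or more years.
#' @return Tibble `month, day, value` (the per-calendar-day means).
#' @export
climatology <- function(series) {
  series %>%
    mutate(
      month = as.integer(format(.data$date, "%m")),
      day = as.integer(format(.data$date, "%d"))
    ) %>%
    group_by(.data$month, .data$day) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    arrange(.data$month, .data$day)
}

#' Monthly anomaly relative to reference years
#'
#' The month's mean in the given year minus the mean of that month's means
#' across the reference years (the three study years, in the source
#' analysis). Calendar-month daily means ignore missing days.
#'
#' @param series Tibble `date, value`.
#' @param month Month (1-12).
#' @param year Year of interest.
#' @param reference_years Years over which the cross-year monthly mean is
#'   taken (should include `year`).
#' @return Anomaly in the series' units (degrees C for SST).
#' @export
monthly_anomaly <- function(series, month, year, reference_years) {
  s <- series %>%
    mutate(
      m = as.integer(format(.data$date, "%m")),
      y = as.integer(format(.data$date, "%Y"))
    ) %>%
    filter(.data$m == month, .data$y %in% reference_years)
  by_year <- s %>%
    group_by(.data$y) %>%
    summarise(mu = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (!year %in% by_year$y || nrow(by_year) < length(reference_years)) {
    abort("month missing from a reference year")
  }
  by_year$mu[by_year$y == year] - mean(by_year$mu)
}

#' SST over a foraging trip's dates
#'
#' Trips of up to four days get the mean over a four-day window centred on
#' the trip midpoint (midpoint-1 ... midpoint+2 days; the even window cannot
#' be centred symmetrically, and this convention is configurable via
#' `window_offsets`); longer trips get the mean over the trip days. Missing
#' days are skipped.
#'
#' @param series Tibble `date, value`.
#' @param trip_start_date,trip_end_date Trip dates (inclusive).
#' @param window_offsets Day offsets around the midpoint for short trips.
#' @return Mean SST, degrees C.
#' @export
trip_sst <- function(series, trip_start_date, trip_end_date,
                     window_offsets = -1:2) {
  d0 <- as.Date(trip_start_date)
  d1 <- as.Date(trip_end_date)
  stopifnot(d1 >= d0)
  len <- as.integer(d1 - d0) + 1L
  days <- if (len <= 4) {
    d0 + floor((len - 1) / 2) + window_offsets
  } else {
    seq(d0, d1, by = "day")
  }
  v <- series$value[series$date %in% days]
  if (all(is.na(v)) || length(v) == 0) abort("no SST available in the trip window")
  mean(v, na.rm = TRUE)
}

#' Rotate velocity components into alongshore/cross-shore axes
#'
#' Standard 2-D rotation of eastward (`u`) and northward (`v`) components
#' onto a coastline oriented `angle_deg` east of north (19 degrees for this
#' coast). Magnitude is preserved.
#'
#' @param u,v Eastward and northward velocity, m/s.
#' @param angle_deg Coastline orientation, degrees east of north.
#' @return Tibble `alongshore, cross_shore` in m/s.
#' @export
rotate_alongshore <- function(u, v, angle_deg = 19) {
  stopifnot(all(is.finite(u)), all(is.finite(v)))
  th <- angle_deg * pi / 180
  tibble(
    alongshore = u * sin(th) + v * cos(th),
    cross_shore = u * cos(th) - v * sin(th)
  )
}
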