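# Windowed prey-capture and catch-per-unit-effort metrics. Trips are cut
# into consecutive non-overlapping windows from the trip start; a trailing
# partial window is dropped so short denominators cannot inflate rates.

#' Cut a trip into fixed-length windows and accumulate effort and captures
#'
#' @param dives Dive tibble for one trip with `start_s`, `end_s` (seconds
#'   from trip start).
#' @param capture_times Numeric vector of capture event times, s.
#' @param trip_duration_s Total trip duration, s.
#' @param minutes Window length, minutes.
#' @param start_time Optional POSIXct trip start; if given, each window
#'   carries its midpoint clock time (needed for night filtering).
#' @param allow_partial If the trip is shorter than one window, return the
#'   single partial window (flagged) instead of erroring.
#' @return Tibble `window_id, start_s, end_s, mid_s, n_captures, dive_s`
#'   (+ `mid_time` when `start_time` is given). Dive seconds are the overlap
#'   of each dive with the window, so effort is conserved across windows.
#' @export
segment_windows <- function(dives, capture_times, trip_duration_s,
                            minutes = 90, start_time = NULL,
                            allow_partial = FALSE) {
  win_s <- minutes * 60
  n_win <- floor(trip_duration_s / win_s)
  if (n_win < 1) {
    if (!allow_partial) {
      abort("trip is shorter than one window (set allow_partial to override)")
    }
    n_win <- 1
    win_s <- trip_duration_s
  }
  starts <- (seq_len(n_win) - 1) * win_s
  ends <- starts + win_s
  n_cap <- vapply(
    seq_len(n_win),
    function(i) sum(capture_times >= starts[i] & capture_times < ends[i]),
    integer(1)
  )
  dive_s <- vapply(seq_len(n_win), function(i) {
    sum(pmax(0, pmin(dives$end_s, ends[i]) - pmax(dives$start_s, starts[i])))
  }, numeric(1))
  out <- tibble(
    window_id = seq_len(n_win), start_s = starts, end_s = ends,
    mid_s = (starts + ends) / 2, n_captures = n_cap, dive_s = dive_s
  )
  if (!is.null(start_time)) out$mid_time <- start_time + out$mid_s
  out
}

#' Remove windows whose midpoint falls at night
#'
#' Penguins do not forage after dark, so night windows carry no effort and
#' are excluded. A window is "night" when its midpoint clock time falls
#' between sunset and the next sunrise according to the per-date sun table.
#' Single-day (daylight) trips pass through unchanged by construction.
#'
#' @param windows Window tibble from [segment_windows()] including
#'   `mid_time`.
#' @param sun_table Tibble `date, sunrise_h, sunset_h` covering the trip
#'   dates (see [sun_table()]).
#' @return The daylight subset of `windows`.
#' @export
filter_night <- function(windows, sun_table) {
  if (!"mid_time" %in% names(windows)) {
    abort("windows need mid_time; pass start_time to segment_windows()")
  }
  date <- as.Date(windows$mid_time, tz = "UTC")
  i <- match(date, sun_table$date)
  if (any(is.na(i))) abort("sun table does not cover all trip dates")
  h <- as.numeric(windows$mid_time - as.POSIXct(date, tz = "UTC"), units = "hours")
  night <- h < sun_table$sunrise_h[i] | h >= sun_table$sunset_h[i]
  windows[!night, , drop = FALSE]
}

#' Catch per unit effort of each window
#'
#' CPUE is captures per minute spent diving below the threshold within the
#' window. Windows with zero dive time have no defined effort: they return
#' `NA` and are excluded from trip-level CPUE means (but still count toward
#' capture-count means).
#'
#' @param windows Window tibble from [segment_windows()].
#' @return `windows` with a `cpue_per_min` column appended.
#' @export
window_cpue <- function(windows) {
  mutate(
    windows,
    cpue_per_min = ifelse(.data$dive_s > 0,
      .data$n_captures / (.data$dive_s / 60), NA_real_
    )
  )
}

#' Trip-level foraging metrics
#'
#' Arithmetic means of per-window captures and CPUE over the usable
#' (daylight, complete) windows of a trip.
#'
#' @param windows Window tibble (night-filtered if the trip spans nights).
#' @return One-row tibble `n_windows, mean_captures, mean_cpue`.
#' @export
trip_summary <- function(windows) {
  if (nrow(windows) < 1) abort("no usable windows")
  w <- window_cpue(windows)
  tibble(
    n_windows = nrow(w),
    mean_captures = mean(w$n_captures),
    mean_cpue = mean(w$cpue_per_min, na.rm = TRUE)
  )
}

#' Choose the CPUE window length that stabilises trip means
#'
#' For each candidate window length, computes every trip's mean CPUE and
#' then the standard deviation of those trip means across trips; the
#' candidate minimising that SD is returned (ties broken toward the smaller
#' window). Candidates longer than every trip are skipped with a warning.
#'
#' @param trips A list of per-trip lists, each with elements `dives`,
#'   `capture_times`, `duration_s`, and optionally `start_time`.
#' @param candidates Candidate window lengths, minutes.
#' @param sun_table Optional sun table for night filtering of multi-day
#'   trips.
#' @return A list of class `window_opt`: `minutes` (chosen) and `table`
#'   (tibble `minutes, sd_cpue, n_trips`).
#' @export
optimize_window <- function(trips,
                            candidates = c(1, 5, 10, 20, 30, 45, 60, 90, 120, 240),
                            sun_table = NULL) {
  if (length(trips) < 2) abort("window optimisation needs at least 2 trips")
  rows <- purrr::map_dfr(candidates, function(m) {
    means <- purrr::map_dbl(trips, function(tr) {
      if (tr$duration_s < m * 60) return(NA_real_)
      w <- segment_windows(tr$dives, tr$capture_times, tr$duration_s,
        minutes = m, start_time = tr$start_time
      )
      if (!is.null(sun_table) && "mid_time" %in% names(w)) {
        w <- filter_night(w, sun_table)
      }
      if (nrow(w) == 0) return(NA_real_)
      trip_summary(w)$mean_cpue
    })
    tibble(
      minutes = m,
      sd_cpue = if (sum(!is.na(means)) >= 2) sd(means, na.rm = TRUE) else NA_real_,
      n_trips = sum(!is.na(means))
    )
  })
  if (any(rows$n_trips == 0)) {
    warn(paste(
      "window candidates exceeding every trip duration skipped:",
      paste(rows$minutes[rows$n_trips == 0], collapse = ", ")
    ))
  }
  usable <- filter(rows, !is.na(.data$sd_cpue))
  if (nrow(usable) == 0) abort("no candidate window usable on these trips")
  best <- usable$minutes[order(usable$sd_cpue, usable$minutes)][1]
  structure(list(minutes = best, table = rows), class = "window_opt")
}
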