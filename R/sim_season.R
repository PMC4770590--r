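#' Simulate a complete study season
#'
#' Runs the full generator chain — SST fields, prey fields, one trip per
#' configured foraging day (track + two-mode dive record + ground truth) —
#' under a single master seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_season` with elements `config`, `sst`
#'   (see [simulate_sst_fields()]), `trips` (list of per-trip lists with
#'   `track` and `dive_series`), and pooled truth tables `dives`,
#'   `captures`, `trip_meta`.
#' @export
simulate_season <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sst <- simulate_sst_fields(config)
  dates <- config$start_date + ((seq_len(config$n_trips) - 1L) %% config$n_days)

  trips <- vector("list", config$n_trips)
  for (i in seq_len(config$n_trips)) {
    trip_id <- sprintf("trip%02d", i)
    day_field <- filter(sst$fields, .data$date == dates[i])
    prey <- simulate_prey_field(day_field, config)
    track <- simulate_trip_track(config, prey, dates[i], trip_id)
    lookup <- make_sst_lookup(day_field, config)
    ds <- simulate_dive_series(track, prey, config, sst_lookup = lookup)
    trips[[i]] <- list(track = track, dive_series = ds)
  }
  dives <- bind_rows(purrr::map(trips, ~ .x$dive_series$dives))
  captures <- bind_rows(purrr::map(trips, ~ .x$dive_series$captures))
  trip_meta <- tibble(
    trip_id = purrr::map_chr(trips, ~ .x$track$trip_id),
    date = as.Date(purrr::map_dbl(trips, ~ as.numeric(.x$track$date))),
    start_time = as.POSIXct(
      purrr::map_dbl(trips, ~ as.numeric(.x$track$start_time)),
      origin = "1970-01-01", tz = "UTC"
    ),
    duration_s = purrr::map_dbl(trips, ~ max(.x$track$path$t_s)),
    multi_day = purrr::map_lgl(trips, ~ config$trip_hours > 14)
  )
  structure(
    list(
      config = config, sst = sst, trips = trips,
      dives = dives, captures = captures, trip_meta = trip_meta
    ),
    class = "sim_season"
  )
}

# fast nearest-cell SST lookup for one day's field
make_sst_lookup <- function(day_field, config) {
  m <- matrix(NA_real_, config$grid_nx, config$grid_ny)
  m[cbind(day_field$ix + 1L, day_field$iy + 1L)] <- day_field$sst_c
  function(x, y) {
    cell <- sim_grid_cell_at(config, x, y)
    m[cbind(cell$ix + 1L, cell$iy + 1L)]
  }
}
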