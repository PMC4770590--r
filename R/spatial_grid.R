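# The 1 km^2 analysis grid: a colony-centred azimuthal-equidistant plane cut
# into half-open square cells [x, x+cell), indexed 0-based from the
# south-west corner, row-major. Distortion over a <=25 km foraging range is
# negligible.

#' Define the colony-centred analysis grid
#'
#' @param colony_lat,colony_lon Colony coordinates, decimal degrees.
#' @param extent_n_km,extent_s_km,extent_e_km,extent_w_km Grid extents from
#'   the colony, km. The study system bounds single-day trips to ~25 km
#'   north/south and east; the eastern (shelf-edge) extent is configurable
#'   because bathymetry is not part of the package.
#' @param cell_km Cell edge length, km.
#' @return A list of class `grid_spec` with origin, dimensions and colony
#'   coordinates.
#' @export
grid_spec <- function(colony_lat = -36.253, colony_lon = 150.227,
                      extent_n_km = 25, extent_s_km = 25,
                      extent_e_km = 25, extent_w_km = 25,
                      cell_km = 1) {
  stopifnot(cell_km > 0, extent_n_km > 0, extent_s_km > 0, extent_e_km > 0)
  nx <- as.integer(ceiling((extent_e_km + extent_w_km) / cell_km))
  ny <- as.integer(ceiling((extent_n_km + extent_s_km) / cell_km))
  structure(
    list(
      colony_lat = colony_lat, colony_lon = colony_lon,
      x0 = -extent_w_km, y0 = -extent_s_km,
      nx = nx, ny = ny, cell_km = cell_km
    ),
    class = "grid_spec"
  )
}

#' Map planar positions to grid cell indices
#'
#' Cells are half-open (`[x, x + cell)`), 0-based from the south-west
#' corner. Positions outside the grid get `NA` indices.
#'
#' @param x_km,y_km Planar colony-centred coordinates, km.
#' @param grid A [grid_spec()].
#' @return Tibble `ix, iy` (integer, `NA` outside the grid).
#' @export
cell_index <- function(x_km, y_km, grid) {
  ix <- floor((x_km - grid$x0) / grid$cell_km)
  iy <- floor((y_km - grid$y0) / grid$cell_km)
  outside <- ix < 0 | ix >= grid$nx | iy < 0 | iy >= grid$ny
  ix[outside] <- NA_integer_
  iy[outside] <- NA_integer_
  tibble(ix = as.integer(ix), iy = as.integer(iy))
}

#' Regularise a GPS track by linear interpolation at a fixed time step
#'
#' Interpolation at 10 min homogenises heterogeneous fix intervals and
#' equalises sampling between resting (many surface fixes) and diving (GPS
#' gaps): at the study species' 1.8 m/s transit speed a bird moves ~1 km per
#' 10 min, so cells merely transited receive about one count.
#'
#' @param track GPS tibble `t_s, lat_dd, lon_dd` (plus anything else).
#' @param grid A [grid_spec()] supplying the projection centre.
#' @param step_s Interpolation step, s.
#' @return Tibble `t_s, x_km, y_km, lat_dd, lon_dd, ix, iy` at times
#'   `t0, t0+step, ..., <= t_end`.
#' @export
interpolate_positions <- function(track, grid, step_s = 600) {
  if (nrow(track) < 2) abort("need at least 2 fixes to interpolate")
  p <- lonlat_to_planar(track$lat_dd, track$lon_dd, grid$colony_lat, grid$colony_lon)
  tt <- seq(min(track$t_s), max(track$t_s), by = step_s)
  x <- approx(track$t_s, p$x_km, xout = tt)$y
  y <- approx(track$t_s, p$y_km, xout = tt)$y
  ll <- planar_to_lonlat(x, y, grid$colony_lat, grid$colony_lon)
  ci <- cell_index(x, y, grid)
  tibble(
    t_s = tt, x_km = x, y_km = y,
    lat_dd = ll$lat_dd, lon_dd = ll$lon_dd, ix = ci$ix, iy = ci$iy
  )
}

#' Bin positions onto the grid
#'
#' @param positions Tibble with `ix, iy` (e.g. from
#'   [interpolate_positions()]); `NA` cells are counted to an outside sink.
#' @param grid A [grid_spec()].
#' @return Tibble of all `nx * ny` cells: `ix, iy, count, presence`, with
#'   attribute `outside_n` (positions falling off the grid). In-grid counts
#'   plus the sink equal the number of positions.
#' @export
bin_positions <- function(positions, grid) {
  all_cells <- tidyr::expand_grid(
    iy = seq_len(grid$ny) - 1L,
    ix = seq_len(grid$nx) - 1L
  ) %>% select("ix", "iy")
  inside <- filter(positions, !is.na(.data$ix), !is.na(.data$iy))
  outside_n <- nrow(positions) - nrow(inside)
  if (outside_n > 0) {
    warn(sprintf("%d position(s) outside the grid counted to the sink", outside_n))
  }
  counts <- inside %>%
    dplyr::count(.data$ix, .data$iy, name = "count")
  out <- all_cells %>%
    left_join(counts, by = c("ix", "iy")) %>%
    mutate(
      count = tidyr::replace_na(.data$count, 0L),
      presence = .data$count > 0
    )
  attr(out, "outside_n") <- outside_n
  out
}

#' Per-cell mean SST over the tracked days
#'
#' Averages gridded SST over exactly the days on which animals were tracked
#' (not the full date range). Cloud-masked (`NA`) values are skipped per
#' cell; a cell masked on every tracked day stays missing.
#'
#' @param sst_stack An `sst_stack` (from [simulate_sst_fields()] or
#'   [read_sst_stack()]).
#' @param tracked_dates Dates to average over (must be in the stack).
#' @return Tibble `ix, iy, sst_c, n_days`.
#' @export
mean_sst_by_cell <- function(sst_stack, tracked_dates) {
  tracked_dates <- as.Date(tracked_dates)
  if (length(tracked_dates) == 0) abort("empty tracked date set")
  have <- unique(sst_stack$fields$date)
  if (!all(tracked_dates %in% have)) abort("tracked dates missing from the SST stack")
  sst_stack$fields %>%
    filter(.data$date %in% tracked_dates) %>%
    group_by(.data$ix, .data$iy) %>%
    summarise(
      n_days = sum(!is.na(.data$sst_c)),
      sst_c = if (any(!is.na(.data$sst_c))) mean(.data$sst_c, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) %>%
    select("ix", "iy", "sst_c", "n_days")
}

#' Spatial SST anomaly
#'
#' Each cell's deviation from the mean SST over all non-missing cells, plus
#' the binary warmer/cooler-than-mean variant. Anomalies sum to zero over
#' non-missing cells by construction.
#'
#' @param cell_means Tibble with `sst_c` per cell (see
#'   [mean_sst_by_cell()]).
#' @return Input with `anomaly_c` and factor `anomaly_bin`
#'   (`cooler`/`warmer`) appended.
#' @export
sst_anomaly <- function(cell_means) {
  if (all(is.na(cell_means$sst_c))) abort("all cells missing")
  mu <- mean(cell_means$sst_c, na.rm = TRUE)
  mutate(
    cell_means,
    anomaly_c = .data$sst_c - mu,
    anomaly_bin = factor(
      ifelse(.data$anomaly_c > 0, "warmer", "cooler"),
      levels = c("cooler", "warmer")
    )
  )
}

#' Geolocate capture events along a track
#'
#' Positions each capture by linear interpolation of the GPS track on a 1 s
#' lattice (capture times are snapped to the nearest second first), the
#' resolution at which the accelerometry and GPS records are integrated.
#'
#' @param track GPS tibble `t_s, lat_dd, lon_dd`.
#' @param capture_times Capture event times, s (within the track span).
#' @param grid A [grid_spec()].
#' @return Tibble `t_s, x_km, y_km, lat_dd, lon_dd, ix, iy`.
#' @export
locate_captures <- function(track, capture_times, grid) {
  tc <- round(capture_times)
  if (any(tc < min(track$t_s) | tc > max(track$t_s))) {
    abort("capture time outside the track span")
  }
  p <- lonlat_to_planar(track$lat_dd, track$lon_dd, grid$colony_lat, grid$colony_lon)
  x <- approx(track$t_s, p$x_km, xout = tc)$y
  y <- approx(track$t_s, p$y_km, xout = tc)$y
  ll <- planar_to_lonlat(x, y, grid$colony_lat, grid$colony_lon)
  ci <- cell_index(x, y, grid)
  tibble(
    t_s = tc, x_km = x, y_km = y,
    lat_dd = ll$lat_dd, lon_dd = ll$lon_dd, ix = ci$ix, iy = ci$iy
  )
}

#' Per-cell capture counts
#'
#' @param capture_positions Tibble with `ix, iy` from [locate_captures()].
#' @param grid A [grid_spec()].
#' @return List: `cells` (all grid cells with `captures` counts) and
#'   `occupied` (the cells-with-captures-only view used for response-curve
#'   fitting).
#' @export
capture_density <- function(capture_positions, grid) {
  binned <- bin_positions(capture_positions, grid) %>%
    rename(captures = "count") %>%
    select("ix", "iy", "captures")
  list(cells = binned, occupied = filter(binned, .data$captures > 0))
}

#' Trip-decile SST and capture profiles
#'
#' Splits each trip into ten equal-time bins; per bin, the mean SST of the
#' cells visited (via the per-cell tracked-day SST means) and the number of
#' captures; finally averages bin values across the trips of a sampling
#' period.
#'
#' @param positions_by_trip Tibble of interpolated positions for all trips
#'   with columns `trip_id, t_s, ix, iy`.
#' @param cell_means Per-cell SST means (`ix, iy, sst_c`).
#' @param captures_by_trip Tibble `trip_id, t_s` of capture events (times on
#'   the same clock as positions); may be empty.
#' @return Tibble `decile (1-10), mean_sst_c, mean_captures`.
#' @export
decile_profile <- function(positions_by_trip, cell_means, captures_by_trip = NULL) {
  n_pos <- dplyr::count(positions_by_trip, .data$trip_id)
  if (any(n_pos$n < 10)) abort("a trip is too short to span 10 positions")
  per_trip <- positions_by_trip %>%
    group_by(.data$trip_id) %>%
    mutate(
      frac = (.data$t_s - min(.data$t_s)) /
        pmax(max(.data$t_s) - min(.data$t_s), 1),
      decile = pmin(floor(.data$frac * 10) + 1L, 10L)
    ) %>%
    ungroup()
  sst_part <- per_trip %>%
    left_join(cell_means, by = c("ix", "iy")) %>%
    group_by(.data$trip_id, .data$decile) %>%
    summarise(sst_c = mean(.data$sst_c, na.rm = TRUE), .groups = "drop")
  if (!is.null(captures_by_trip) && nrow(captures_by_trip) > 0) {
    spans <- positions_by_trip %>%
      group_by(.data$trip_id) %>%
      summarise(t0 = min(.data$t_s), t1 = max(.data$t_s), .groups = "drop")
    caps <- captures_by_trip %>%
      left_join(spans, by = "trip_id") %>%
      mutate(decile = pmin(
        floor((.data$t_s - .data$t0) / pmax(.data$t1 - .data$t0, 1) * 10) + 1L,
        10L
      )) %>%
      dplyr::count(.data$trip_id, .data$decile, name = "captures")
  } else {
    caps <- tibble(trip_id = character(), decile = integer(), captures = integer())
  }
  grid_td <- tidyr::expand_grid(
    trip_id = unique(positions_by_trip$trip_id), decile = 1:10
  )
  grid_td %>%
    left_join(sst_part, by = c("trip_id", "decile")) %>%
    left_join(caps, by = c("trip_id", "decile")) %>%
    mutate(captures = tidyr::replace_na(.data$captures, 0L)) %>%
    group_by(.data$decile) %>%
    summarise(
      mean_sst_c = mean(.data$sst_c, na.rm = TRUE),
      mean_captures = mean(.data$captures),
      .groups = "drop"
    )
}

#' Per-trip capture depth means and SST/tag-temperature pairs
#'
#' Summarises where in the water column prey is taken: the mean capture
#' depth per trip, and paired records of cell SST versus tag temperature at
#' the moment of capture (a near 1:1 relationship indicates a well-mixed
#' column with no thermocline decoupling).
#'
#' @param captures Tibble `trip_id, depth_m, temp_c, ix, iy` of capture
#'   events with tag depth/temperature and grid cell.
#' @param cell_means Per-cell SST means (`ix, iy, sst_c`).
#' @return List: `by_trip` (tibble `trip_id, mean_depth_m, n_captures`) and
#'   `temperature_pairs` (tibble `sst_c, capture_temp_c`).
#' @export
capture_depth_summary <- function(captures, cell_means) {
  by_trip <- captures %>%
    group_by(.data$trip_id) %>%
    summarise(
      mean_depth_m = mean(.data$depth_m),
      n_captures = dplyr::n(), .groups = "drop"
    )
  pairs <- captures %>%
    left_join(cell_means, by = c("ix", "iy")) %>%
    filter(!is.na(.data$sst_c)) %>%
    select(sst_c = "sst_c", capture_temp_c = "temp_c")
  list(by_trip = by_trip, temperature_pairs = pairs)
}
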