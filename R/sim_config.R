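#' Configuration for the synthetic study-season generator
#'
#' Collects every tunable of the synthetic data generator in one validated
#' list. Defaults emulate the study system: a colony-centred 50 x 50 km grid
#' of 1 km^2 cells, logger sampling at 10 s above 1.5 m and 30 Hz below,
#' a dome-shaped prey response to SST peaking at 20 degrees C, episodic
#' warm-water intrusions, and single-day central-place trips travelling at
#' 1.8 m/s within ~25 km of the colony.
#'
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param grid_nx,grid_ny Grid dimensions (cells); the colony sits at the
#'   grid centre.
#' @param cell_km Cell edge length, km.
#' @param colony_lat,colony_lon Colony coordinates, decimal degrees.
#' @param start_date First simulated calendar day (`Date` or string).
#' @param n_days Number of simulated days.
#' @param n_trips Number of foraging trips in a season.
#' @param base_sst_c Spatially averaged SST on day 1, degrees C.
#' @param merid_gradient_c_per_km Northward SST gradient (warm poleward
#'   intrusion source lies north), degrees C per km.
#' @param zonal_gradient_c_per_km Eastward (offshore) SST gradient.
#' @param trend_c_per_day Linear seasonal warming, degrees C per day.
#' @param sst_noise_sd Per-cell, per-day Gaussian SST noise sd (degrees C);
#'   0 keeps fields deterministic apart from intrusions.
#' @param intrusion_amp_c Peak amplitude of a warm intrusion, degrees C.
#' @param intrusion_rate_per_day Expected number of intrusion onsets per day.
#' @param intrusion_duration_d Duration of each square-pulse intrusion, days.
#' @param intrusion_sigma_km Gaussian spatial footprint sd of an intrusion.
#' @param intrusion_center Optional fixed `c(x_km, y_km)` footprint centre;
#'   `NULL` draws a centre in the offshore (eastern) half per event.
#' @param offshore_km,inshore_km Distance east (positive) / west (negative)
#'   of the colony at which the offshore and inshore point series are read.
#' @param thermal_opt_c SST at which prey density peaks, degrees C.
#' @param thermal_width_c Gaussian width of the prey-SST dome, degrees C.
#' @param capture_rate_scale Capture rate at the thermal optimum,
#'   events per minute of diving.
#' @param trip_speed_ms Transit swimming speed, m/s.
#' @param trip_hours Trip duration, hours (values > 14 span nights and give
#'   multi-day trips).
#' @param max_range_km Distance at which a trip turns for home.
#' @param ars_enabled Switch for area-restricted search behaviour.
#' @param ars_quantile Prey-density quantile above which ARS is triggered.
#' @param ars_speed_factor Speed multiplier during ARS.
#' @param taxis_gain Strength of heading bias up the local prey-density
#'   gradient (0 disables); foragers orient toward richer patches, which is
#'   what makes habitat preference visible in presence/absence data.
#' @param turn_sd_deg Per-second heading noise while transiting, degrees.
#' @param ars_turn_sd_deg Heading noise during ARS, degrees.
#' @param gps_interval_s GPS fix interval, s (loggers used 7-115 s).
#' @param gps_noise_m GPS positional error sd, m (logger precision is not
#'   documented; 25 m is a typical figure for this tag class and is
#'   configurable).
#' @param dive_threshold_m Depth separating the two logger modes, m.
#' @param shallow_dt_s Sampling period in shallow mode, s.
#' @param dive_hz Sampling rate in dive mode, Hz.
#' @param sunrise_h,sunset_h Local sunrise/sunset, fractional hours. Used to
#'   build the per-date sun table; a day/night cut is all the analysis needs.
#' @param dusk_buffer_h Diving ceases this many hours before sunset (birds
#'   wind down foraging at dusk), hours.
#' @param trip_start_h Local hour at which trips begin.
#' @param hurdle_zero_beta Length-2 `(intercept, slope per degree C)` of the
#'   habitat-presence (zero part) process used in habitat simulations.
#' @param hurdle_count_beta Same for the positive-count process.
#' @param thermocline_c_per_m Temperature decrease with depth; 0 gives a
#'   well-mixed column so tag temperature tracks surface SST.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       grid_nx = 50L, grid_ny = 50L, cell_km = 1,
                       colony_lat = -36.253, colony_lon = 150.227,
                       start_date = "2013-09-01", n_days = 30L,
                       n_trips = 30L,
                       base_sst_c = 20, merid_gradient_c_per_km = 0.03,
                       zonal_gradient_c_per_km = 0.02,
                       trend_c_per_day = 0.03, sst_noise_sd = 0,
                       intrusion_amp_c = 3, intrusion_rate_per_day = 0.08,
                       intrusion_duration_d = 3L, intrusion_sigma_km = 15,
                       intrusion_center = NULL,
                       offshore_km = 5.5, inshore_km = -3,
                       thermal_opt_c = 20, thermal_width_c = 1.5,
                       capture_rate_scale = 1.2,
                       trip_speed_ms = 1.8, trip_hours = 7,
                       max_range_km = 22,
                       ars_enabled = TRUE, ars_quantile = 0.7,
                       ars_speed_factor = 0.35, taxis_gain = 0.3,
                       turn_sd_deg = 3, ars_turn_sd_deg = 45,
                       gps_interval_s = 30, gps_noise_m = 25,
                       dive_threshold_m = 1.5, shallow_dt_s = 10,
                       dive_hz = 30,
                       sunrise_h = 6, sunset_h = 20, dusk_buffer_h = 1,
                       trip_start_h = 6,
                       hurdle_zero_beta = c(3.654, -0.28),
                       hurdle_count_beta = c(1.276, -0.02),
                       thermocline_c_per_m = 0) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  cfg$seed <- as.integer(seed)
  stopifnot(
    cfg$cell_km > 0, cfg$grid_nx >= 1, cfg$grid_ny >= 1,
    cfg$n_days >= 1, cfg$thermal_width_c > 0,
    cfg$dive_hz > 1 / cfg$shallow_dt_s,
    cfg$dive_threshold_m > 0, cfg$trip_speed_ms > 0,
    length(cfg$hurdle_zero_beta) == 2, length(cfg$hurdle_count_beta) == 2,
    cfg$sunset_h > cfg$sunrise_h
  )
  if (cfg$trip_hours * 3600 * cfg$trip_speed_ms < 2000) {
    abort("trip cannot fit a meaningful out-and-back path at this speed/duration")
  }
  structure(cfg, class = "sim_config")
}

#' Per-date sunrise/sunset table
#'
#' A fixed daily day/night cut (default 0600-2000 local) supplied as a
#' table, avoiding any ephemeris dependency.
#'
#' @param config A [sim_config()].
#' @param dates Dates to cover; defaults to the configured season.
#' @return Tibble with columns `date`, `sunrise_h`, `sunset_h`.
#' @export
sun_table <- function(config, dates = NULL) {
  if (is.null(dates)) {
    dates <- config$start_date + seq_len(config$n_days) - 1L
  }
  tibble(
    date = as.Date(dates),
    sunrise_h = config$sunrise_h,
    sunset_h = config$sunset_h
  )
}

# cell centres of the simulation grid, colony at the grid centre
sim_grid_centers <- function(config) {
  nx <- config$grid_nx
  ny <- config$grid_ny
  half_x <- nx * config$cell_km / 2
  half_y <- ny * config$cell_km / 2
  tidyr::expand_grid(iy = seq_len(ny) - 1L, ix = seq_len(nx) - 1L) %>%
    mutate(
      x_km = (.data$ix + 0.5) * config$cell_km - half_x,
      y_km = (.data$iy + 0.5) * config$cell_km - half_y
    ) %>%
    select("ix", "iy", "x_km", "y_km")
}

# nearest sim-grid cell to a planar point
sim_grid_cell_at <- function(config, x_km, y_km) {
  half_x <- config$grid_nx * config$cell_km / 2
  half_y <- config$grid_ny * config$cell_km / 2
  ix <- pmin(pmax(floor((x_km + half_x) / config$cell_km), 0), config$grid_nx - 1)
  iy <- pmin(pmax(floor((y_km + half_y) / config$cell_km), 0), config$grid_ny - 1)
  list(ix = as.integer(ix), iy = as.integer(iy))
}

# deterministic per-stage RNG streams derived from the master seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset) %% .Machine$integer.max)
}
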