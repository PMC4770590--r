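#' Simulate daily gridded SST fields with warm-water intrusions
#'
#' Builds a deterministic base field (meridional + zonal gradient plus a
#' linear seasonal trend) and superimposes stochastic warm intrusions:
#' square pulses in time with a Gaussian spatial footprint, emulating pulses
#' of warm water penetrating the study region from offshore. Point series
#' are read at designated offshore and inshore cells.
#'
#' @param config A [sim_config()].
#' @return A list of class `sst_stack` with elements
#'   \describe{
#'     \item{fields}{tibble `date, ix, iy, x_km, y_km, sst_c`}
#'     \item{offshore,inshore}{daily point series tibbles `date, sst_c`}
#'     \item{truth}{per-day bookkeeping: `date, intrusion` (logical) and the
#'       intrusion contribution `offshore_delta_c` at the offshore cell}
#'     \item{meta}{grid origin/size metadata}
#'   }
#' @export
simulate_sst_fields <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  dates <- config$start_date + seq_len(config$n_days) - 1L
  cells <- sim_grid_centers(config)

  base_day1 <- config$base_sst_c +
    config$merid_gradient_c_per_km * cells$y_km +
    config$zonal_gradient_c_per_km * cells$x_km

  # intrusion events: Poisson onsets, square pulse in time
  n_events <- rpois(1, config$intrusion_rate_per_day * config$n_days)
  events <- tibble(
    onset = if (n_events > 0) sample.int(config$n_days, n_events, replace = TRUE) else integer(),
    cx = numeric(n_events), cy = numeric(n_events)
  )
  if (n_events > 0) {
    if (is.null(config$intrusion_center)) {
      half_x <- config$grid_nx * config$cell_km / 2
      half_y <- config$grid_ny * config$cell_km / 2
      events$cx <- runif(n_events, 0, half_x) # offshore (eastern) half
      events$cy <- runif(n_events, -half_y, half_y)
    } else {
      events$cx <- config$intrusion_center[1]
      events$cy <- config$intrusion_center[2]
    }
  }

  off_cell <- sim_grid_cell_at(config, config$offshore_km, 0)
  in_cell <- sim_grid_cell_at(config, config$inshore_km, 0)
  off_xy <- cells %>% filter(.data$ix == off_cell$ix, .data$iy == off_cell$iy)

  day_tbls <- vector("list", config$n_days)
  offshore_delta <- numeric(config$n_days)
  intrusion_day <- logical(config$n_days)
  for (d in seq_len(config$n_days)) {
    sst <- base_day1 + config$trend_c_per_day * (d - 1)
    active <- which(events$onset <= d & d < events$onset + config$intrusion_duration_d)
    for (e in active) {
      r2 <- (cells$x_km - events$cx[e])^2 + (cells$y_km - events$cy[e])^2
      bump <- config$intrusion_amp_c * exp(-r2 / (2 * config$intrusion_sigma_km^2))
      sst <- sst + bump
      offshore_delta[d] <- offshore_delta[d] + config$intrusion_amp_c *
        exp(-((off_xy$x_km - events$cx[e])^2 + (off_xy$y_km - events$cy[e])^2) /
          (2 * config$intrusion_sigma_km^2))
    }
    intrusion_day[d] <- length(active) > 0
    if (config$sst_noise_sd > 0) {
      sst <- sst + rnorm(length(sst), 0, config$sst_noise_sd)
    }
    day_tbls[[d]] <- mutate(cells, date = dates[d], sst_c = sst)
  }
  fields <- bind_rows(day_tbls) %>% select("date", "ix", "iy", "x_km", "y_km", "sst_c")

  point_series <- function(cell) {
    fields %>%
      filter(.data$ix == cell$ix, .data$iy == cell$iy) %>%
      select("date", "sst_c")
  }
  structure(
    list(
      fields = fields,
      offshore = point_series(off_cell),
      inshore = point_series(in_cell),
      truth = tibble(
        date = dates, intrusion = intrusion_day,
        offshore_delta_c = offshore_delta
      ),
      meta = list(
        colony_lat = config$colony_lat, colony_lon = config$colony_lon,
        nx = config$grid_nx, ny = config$grid_ny, cell_km = config$cell_km,
        origin_x_km = -config$grid_nx * config$cell_km / 2,
        origin_y_km = -config$grid_ny * config$cell_km / 2
      )
    ),
    class = "sst_stack"
  )
}

#' Derive a relative prey-density field from SST
#'
#' Encodes the assumed unimodal (Gaussian-in-temperature) prey response that
#' the downstream smooth regression is expected to recover:
#' `density = capture_rate_scale * exp(-(SST - opt)^2 / (2 width^2))`,
#' in capture events per minute of diving.
#'
#' @param sst_field A tibble containing an `sst_c` column (e.g. one day of
#'   `simulate_sst_fields()$fields`).
#' @param config A [sim_config()].
#' @return The input tibble with a `density` column appended.
#' @export
simulate_prey_field <- function(sst_field, config) {
  stopifnot(is.data.frame(sst_field), "sst_c" %in% names(sst_field))
  if (any(!is.finite(sst_field$sst_c))) abort("SST must be finite")
  mutate(
    as_tibble(sst_field),
    density = config$capture_rate_scale *
      exp(-(.data$sst_c - config$thermal_opt_c)^2 / (2 * config$thermal_width_c^2))
  )
}
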