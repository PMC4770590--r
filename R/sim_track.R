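#' Simulate one central-place foraging trip
#'
#' A correlated random walk at 1 Hz from the colony: outbound transit at the
#' configured speed with weak heading noise, switching to area-restricted
#' search (slower, much more tortuous) inside high-prey cells, then homing
#' back to the colony so the trip both starts and ends there. Displacement
#' is capped near the single-day range (~25 km). GPS fixes are noisy
#' subsamples of the true 1 Hz path.
#'
#' @param config A [sim_config()].
#' @param prey_field One day's prey field from [simulate_prey_field()]
#'   (columns `ix, iy, density`).
#' @param trip_date Calendar date of the trip.
#' @param trip_id Identifier stored in the outputs.
#' @return A list of class `sim_trip`:
#'   \describe{
#'     \item{gps}{tibble `trip_id, t_s, time, lat_dd, lon_dd` of noisy fixes}
#'     \item{path}{true 1 Hz path `t_s, x_km, y_km`}
#'     \item{trip_id, date, start_time}{metadata; `start_time` is POSIXct UTC}
#'   }
#' @export
simulate_trip_track <- function(config, prey_field, trip_date,
                                trip_id = "trip01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1000L + sum(utf8ToInt(trip_id))))

  daylight_h <- config$sunset_h - config$sunrise_h
  if (config$trip_hours <= 14 && config$trip_hours > daylight_h) {
    abort("trip cannot fit within daylight at the configured duration")
  }
  n_s <- as.integer(round(config$trip_hours * 3600))
  dens <- matrix(0, config$grid_nx, config$grid_ny)
  dens[cbind(prey_field$ix + 1L, prey_field$iy + 1L)] <- prey_field$density
  ars_thr <- quantile(prey_field$density, config$ars_quantile, names = FALSE)
  # central-difference prey gradient for taxis (zero on uniform fields)
  gx <- (dens[c(2:nrow(dens), nrow(dens)), ] - dens[c(1, 1:(nrow(dens) - 1)), ]) / 2
  gy <- (dens[, c(2:ncol(dens), ncol(dens))] - dens[, c(1, 1:(ncol(dens) - 1))]) / 2

  v_kms <- config$trip_speed_ms / 1000
  x <- numeric(n_s + 1)
  y <- numeric(n_s + 1)
  heading <- runif(1, 0, 2 * pi)
  turn_sd <- config$turn_sd_deg * pi / 180
  ars_turn_sd <- config$ars_turn_sd_deg * pi / 180
  t_turn <- n_s / 2
  homing <- FALSE
  for (t in seq_len(n_s)) {
    cell <- sim_grid_cell_at(config, x[t], y[t])
    in_ars <- config$ars_enabled && dens[cell$ix + 1L, cell$iy + 1L] > ars_thr
    d_home <- sqrt(x[t]^2 + y[t]^2)
    if (!homing && (t >= t_turn || d_home >= config$max_range_km)) homing <- TRUE
    if (homing && d_home < 0.05) { # arrived: hold position at the colony
      x[t + 1] <- x[t]
      y[t + 1] <- y[t]
      next
    }
    sdv <- if (in_ars && !homing) ars_turn_sd else turn_sd
    heading <- heading + rnorm(1, 0, sdv)
    if (!homing && config$taxis_gain > 0) {
      g1 <- gx[cell$ix + 1L, cell$iy + 1L]
      g2 <- gy[cell$ix + 1L, cell$iy + 1L]
      if (abs(g1) + abs(g2) > 1e-12) {
        bearing_g <- atan2(g1, g2)
        dg <- ((bearing_g - heading + pi) %% (2 * pi)) - pi
        heading <- heading + config$taxis_gain * dg
      }
    }
    if (homing) {
      bearing_home <- atan2(-x[t], -y[t])
      dh <- ((bearing_home - heading + pi) %% (2 * pi)) - pi
      gain <- if (d_home < 2) 0.5 else 0.05
      heading <- heading + gain * dh
    }
    speed <- if (in_ars && !homing) v_kms * config$ars_speed_factor else v_kms
    x[t + 1] <- x[t] + speed * sin(heading)
    y[t + 1] <- y[t] + speed * cos(heading)
    r <- sqrt(x[t + 1]^2 + y[t + 1]^2)
    if (r > 25) { # hard cap at the single-day range
      x[t + 1] <- x[t + 1] * 25 / r
      y[t + 1] <- y[t + 1] * 25 / r
      homing <- TRUE
    }
  }
  path <- tibble(t_s = 0:n_s, x_km = x, y_km = y)

  fix_t <- seq(0, n_s, by = config$gps_interval_s)
  noise <- config$gps_noise_m / 1000
  fx <- x[fix_t + 1] + rnorm(length(fix_t), 0, noise)
  fy <- y[fix_t + 1] + rnorm(length(fix_t), 0, noise)
  ll <- planar_to_lonlat(fx, fy, config$colony_lat, config$colony_lon)
  start_time <- as.POSIXct(trip_date, tz = "UTC") + config$trip_start_h * 3600
  gps <- tibble(
    trip_id = trip_id, t_s = fix_t, time = start_time + fix_t,
    lat_dd = ll$lat_dd, lon_dd = ll$lon_dd
  )
  structure(
    list(
      gps = gps, path = path, trip_id = trip_id,
      date = as.Date(trip_date), start_time = start_time
    ),
    class = "sim_trip"
  )
}
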