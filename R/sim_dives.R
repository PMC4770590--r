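# Synthetic two-mode dive records.
#
# Depth/acceleration/temperature are emitted exactly as the loggers record
# them: every 10 s while at the surface (shallow mode) and at 30 Hz during
# dives (dive mode), with a sample emitted at the exact threshold-crossing
# instant so dive boundaries are well defined at both rates. Capture-positive
# dives are drawn systematically longer, deeper, with longer bottom phases,
# more bottom-phase undulations and faster vertical rates, and each capture
# injects a short high-frequency surge/heave burst at a recorded time.

# analytic first/last attainment of the bottom-phase depth criterion for a
# trapezoidal dive profile; used both to build profiles and to record truth
.dive_phase_times <- function(dur, maxd, bottom_t, threshold, bottom_frac = 0.85) {
  desc_t <- (dur - bottom_t) / 2
  crit <- bottom_frac * maxd
  t_first <- desc_t * (crit - threshold) / (maxd - threshold)
  t_last <- dur - desc_t * (crit - threshold) / (maxd - threshold)
  list(desc_t = desc_t, t_first = t_first, t_last = t_last)
}

#' Simulate a two-mode accelerometry record along a trip
#'
#' Walks the true 1 Hz path of a simulated trip, scheduling dives during
#' daylight with capture probability driven by the local prey density, and
#' emits the full logger record plus ground truth (per-dive labels and
#' capture times/positions).
#'
#' @param track A `sim_trip` from [simulate_trip_track()].
#' @param prey_field One day's prey field (columns `ix, iy, density`),
#'   density in captures per minute of diving.
#' @param config A [sim_config()].
#' @param sst_lookup Optional function `(x_km, y_km) -> surface temp`;
#'   defaults to a constant 18 degrees C.
#' @return A list of class `sim_dive_series`:
#'   \describe{
#'     \item{accel}{tibble `t_s, depth_m, ax_g, ay_g, az_g, temp_c, mode`}
#'     \item{dives}{ground-truth dive table with the six signature features,
#'       `n_captures` and logical `capture`}
#'     \item{captures}{tibble `dive_id, t_s, x_km, y_km, depth_m, temp_c`}
#'   }
#' @export
simulate_dive_series <- function(track, prey_field, config, sst_lookup = NULL) {
  stopifnot(inherits(track, "sim_trip"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2000L + sum(utf8ToInt(track$trip_id))))
  if (is.null(sst_lookup)) sst_lookup <- function(x, y) rep(18, length(x))

  dens <- matrix(0, config$grid_nx, config$grid_ny)
  dens[cbind(prey_field$ix + 1L, prey_field$iy + 1L)] <- prey_field$density

  thr <- config$dive_threshold_m
  dt <- 1 / config$dive_hz
  n_s <- max(track$path$t_s)
  px <- track$path$x_km
  py <- track$path$y_km
  start_h <- config$trip_start_h

  # birds stop diving a little before sunset (dusk taper) and raft overnight,
  # so windows straddling dusk carry almost no dive effort
  is_night <- function(t) {
    h <- (start_h + t / 3600) %% 24
    h < config$sunrise_h | h >= config$sunset_h - config$dusk_buffer_h
  }

  acc_t <- list(); acc_d <- list(); acc_ax <- list(); acc_ay <- list()
  acc_az <- list(); acc_tc <- list(); acc_mode <- list()
  dive_rows <- list()
  cap_rows <- list()
  emit_surface <- function(t0, t1) {
    if (t1 - t0 < config$shallow_dt_s) return(invisible())
    from <- ceiling(t0 / config$shallow_dt_s) * config$shallow_dt_s
    if (from > t1) return(invisible())
    ts <- seq(from, t1, by = config$shallow_dt_s)
    ts <- ts[ts > t0 + 0.5 & ts < t1 - 0.5]
    if (!length(ts)) return(invisible())
    k <- length(ts)
    i <- pmin(floor(ts), n_s) + 1L
    temp <- sst_lookup(px[i], py[i]) + rnorm(k, 0, 0.05)
    j <- length(acc_t) + 1L
    acc_t[[j]] <<- ts
    acc_d[[j]] <<- runif(k, 0, 0.4)
    acc_ax[[j]] <<- rnorm(k, 0, 0.12)
    acc_ay[[j]] <<- rnorm(k, 0, 0.12)
    acc_az[[j]] <<- 1 + rnorm(k, 0, 0.12) # resting heave near +1 g
    acc_tc[[j]] <<- temp
    acc_mode[[j]] <<- rep("shallow", k)
  }

  t <- 0
  dive_id <- 0L
  while (t < n_s - 90) {
    if (is_night(t)) { # raft at the surface overnight
      h <- (start_h + t / 3600) %% 24
      wait <- if (h >= config$sunset_h - config$dusk_buffer_h) {
        (24 - h + config$sunrise_h) * 3600
      } else {
        (config$sunrise_h - h) * 3600
      }
      t_end <- min(t + wait, n_s)
      emit_surface(t, t_end)
      t <- t_end
      next
    }
    surf <- 10 + stats::rexp(1, 1 / 35)
    t_dive <- t + surf
    if (t_dive > n_s - 90 || is_night(t_dive)) {
      emit_surface(t, min(t_dive, n_s))
      t <- t_dive
      next
    }
    emit_surface(t, t_dive)

    cell <- sim_grid_cell_at(config, px[floor(t_dive) + 1L], py[floor(t_dive) + 1L])
    rate <- dens[cell$ix + 1L, cell$iy + 1L] # captures per min diving
    p_cap <- 1 - exp(-rate * 25 / 60)
    capture <- runif(1) < p_cap
    if (capture) {
      dur <- max(12, rnorm(1, 35, 7))
      maxd <- max(4, rnorm(1, 10, 3))
      vert_rate <- max(0.6, rnorm(1, 1.4, 0.2)) # m/s descent/ascent
      n_u <- 2L + rpois(1, 2)
      n_cap <- 1L + rpois(1, min(rate, 2) * 0.8)
    } else {
      dur <- max(8, rnorm(1, 20, 5))
      maxd <- max(3, rnorm(1, 8, 2.5))
      vert_rate <- max(0.4, rnorm(1, 0.95, 0.15))
      n_u <- rpois(1, 0.4)
      n_cap <- 0L
    }
    desc_t <- min((maxd - thr) / vert_rate, 0.4 * dur)
    bottom_t <- dur - 2 * desc_t
    ph <- .dive_phase_times(dur, maxd, bottom_t, thr)
    amp <- runif(1, 0.8, 1.3)
    amp <- min(amp, 0.14 * maxd) # keep wiggles above the 85% depth criterion
    if (amp < 0.55) n_u <- 0L

    k <- round(dur / dt)
    tt <- seq(0, k) * dt
    tt[length(tt)] <- dur
    depth <- numeric(length(tt))
    seg1 <- tt <= ph$desc_t
    seg3 <- tt >= dur - ph$desc_t
    seg2 <- !seg1 & !seg3
    depth[seg1] <- thr + (maxd - thr) * tt[seg1] / ph$desc_t
    depth[seg3] <- thr + (maxd - thr) * (dur - tt[seg3]) / ph$desc_t
    if (any(seg2)) {
      s <- (tt[seg2] - ph$desc_t) / bottom_t
      depth[seg2] <- maxd - if (n_u > 0) amp * (1 - cos(2 * pi * n_u * s)) / 2 else 0
    }
    noise_scale <- pmin(1, pmax(0, (depth - 2))) * 0.05
    depth <- depth + rnorm(length(depth), 0, 1) * noise_scale
    depth[1] <- thr
    depth[length(depth)] <- thr

    flap <- 0.30 * sin(2 * pi * 1.5 * tt) * as.numeric(seg1 | seg3)
    ax <- rnorm(length(tt), 0, 0.12) + flap
    ay <- rnorm(length(tt), 0, 0.12)
    az <- rnorm(length(tt), 0, 0.12) + 0.8 * flap

    cap_times <- numeric(0)
    if (n_cap > 0) {
      n_cap <- min(n_cap, max(1L, floor(bottom_t / 2.5)))
      lo <- ph$desc_t + 0.5
      hi <- ph$desc_t + bottom_t - 0.5
      cap_times <- lo + (seq_len(n_cap) - 0.5) / n_cap * (hi - lo) +
        runif(n_cap, -0.2, 0.2)
      for (tc in cap_times) {
        w <- abs(tt - tc) < 0.25
        burst <- 1.6 * sin(2 * pi * 8 * (tt[w] - tc)) *
          cos(pi * (tt[w] - tc) / 0.5)
        ax[w] <- ax[w] + burst
        az[w] <- az[w] + 0.9 * burst
      }
    }
    ax <- pmin(pmax(ax, -2), 2)
    ay <- pmin(pmax(ay, -2), 2)
    az <- pmin(pmax(az, -2), 2)

    i <- pmin(floor(t_dive + tt), n_s) + 1L
    temp <- sst_lookup(px[i], py[i]) - config$thermocline_c_per_m * depth +
      rnorm(length(tt), 0, 0.05)

    dive_id <- dive_id + 1L
    id <- sprintf("%s_d%04d", track$trip_id, dive_id)
    j <- length(acc_t) + 1L
    acc_t[[j]] <- t_dive + tt
    acc_d[[j]] <- depth
    acc_ax[[j]] <- ax
    acc_ay[[j]] <- ay
    acc_az[[j]] <- az
    acc_tc[[j]] <- temp
    acc_mode[[j]] <- rep("dive", length(tt))

    dive_rows[[dive_id]] <- tibble(
      trip_id = track$trip_id, dive_id = id,
      start_s = t_dive, end_s = t_dive + dur, duration_s = dur,
      max_depth_m = maxd, bottom_s = ph$t_last - ph$t_first,
      undulations = n_u,
      descent_ms = (maxd - thr) / ph$t_first,
      ascent_ms = (maxd - thr) / (dur - ph$t_last),
      n_captures = length(cap_times), capture = length(cap_times) > 0
    )
    if (length(cap_times)) {
      ci <- pmin(floor(t_dive + cap_times), n_s) + 1L
      di <- approx(tt, depth, xout = cap_times)$y
      cap_rows[[length(cap_rows) + 1L]] <- tibble(
        trip_id = track$trip_id, dive_id = id,
        t_s = t_dive + cap_times,
        x_km = px[ci], y_km = py[ci],
        depth_m = di,
        temp_c = sst_lookup(px[ci], py[ci]) - config$thermocline_c_per_m * di
      )
    }
    t <- t_dive + dur
  }
  emit_surface(t, n_s)

  accel <- tibble(
    t_s = unlist(acc_t), depth_m = unlist(acc_d),
    ax_g = unlist(acc_ax), ay_g = unlist(acc_ay), az_g = unlist(acc_az),
    temp_c = unlist(acc_tc), mode = unlist(acc_mode)
  ) %>% arrange(.data$t_s)

  structure(
    list(
      accel = accel,
      dives = if (dive_id > 0) bind_rows(dive_rows) else tibble(),
      captures = if (length(cap_rows)) bind_rows(cap_rows) else
        tibble(
          trip_id = character(), dive_id = character(), t_s = numeric(),
          x_km = numeric(), y_km = numeric(), depth_m = numeric(),
          temp_c = numeric()
        ),
      trip_id = track$trip_id
    ),
    class = "sim_dive_series"
  )
}
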