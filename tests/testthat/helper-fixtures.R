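# Shared fixtures and independent oracles. Expensive fixtures are built once
# per test run and memoised.

fix_seed <- 42L

.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Two 12 h trips over a warm (near-optimal SST) uniform field: plenty of
# dives with a realistic capture fraction. Trip 1 trains the classifier,
# trip 2 is held out.
dive_season <- function() {
  fixture("dive_season", function() {
    cfg <- sim_config(
      seed = fix_seed, n_days = 2, n_trips = 2, trip_hours = 12,
      base_sst_c = 20, merid_gradient_c_per_km = 0,
      zonal_gradient_c_per_km = 0, trend_c_per_day = 0,
      intrusion_rate_per_day = 0
    )
    season <- simulate_season(cfg)
    per_trip <- lapply(season$trips, function(tr) {
      accel <- tr$dive_series$accel
      dives <- segment_dives(accel, cfg$dive_threshold_m)
      feats <- compute_dive_features(dives, accel)
      truth_n <- vapply(seq_len(nrow(dives)), function(i) {
        sum(tr$dive_series$captures$t_s >= dives$start_s[i] &
          tr$dive_series$captures$t_s <= dives$end_s[i])
      }, numeric(1))
      list(
        accel = accel, dives = dives, feats = feats, truth_n = truth_n,
        truth_dives = tr$dive_series$dives,
        captures = tr$dive_series$captures
      )
    })
    list(config = cfg, season = season, per_trip = per_trip)
  })
}

dive_model <- function() {
  fixture("dive_model", function() {
    fx <- dive_season()
    train_capture_classifier(
      fx$per_trip[[1]]$feats,
      fx$per_trip[[1]]$truth_n > 0
    )
  })
}

# Brute-force threshold-scan segmentation oracle: a plain linear walk over
# samples, independent of the rle-based implementation.
brute_segment <- function(t, d, thr = 1.5, min_samples = 2L) {
  runs <- list()
  run <- integer(0)
  for (i in seq_along(d)) {
    if (d[i] > thr) {
      run <- c(run, i)
    } else {
      if (length(run) >= min_samples) runs[[length(runs) + 1L]] <- run
      run <- integer(0)
    }
  }
  if (length(run) >= min_samples) runs[[length(runs) + 1L]] <- run
  if (!length(runs)) {
    return(tibble::tibble(
      start_s = numeric(), end_s = numeric(),
      i_first = integer(), i_last = integer()
    ))
  }
  do.call(rbind, lapply(runs, function(idx) {
    i1 <- idx[1]
    i2 <- idx[length(idx)]
    s <- if (i1 == 1) t[1] else {
      t[i1 - 1] + (thr - d[i1 - 1]) / (d[i1] - d[i1 - 1]) * (t[i1] - t[i1 - 1])
    }
    e <- if (i2 == length(d)) t[i2] else {
      t[i2] + (d[i2] - thr) / (d[i2] - d[i2 + 1]) * (t[i2 + 1] - t[i2])
    }
    data.frame(start_s = s, end_s = e, i_first = i1, i_last = i2)
  }))
}

# random depth series exercising threshold crossings, exact-threshold
# samples and irregular time steps
random_depth_series <- function(n = 60) {
  t <- cumsum(runif(n, 0.5, 2))
  d <- pmax(0, cumsum(rnorm(n, 0, 1.2)))
  d[sample.int(n, 3)] <- 1.5
  list(t = t, d = d)
}

# a straight constant-speed GPS track east of the colony
straight_track <- function(speed_ms = 1.8, duration_s = 3600, fix_s = 60,
                           colony_lat = -36.253, colony_lon = 150.227) {
  t <- seq(0, duration_s, by = fix_s)
  ll <- planar_to_lonlat(speed_ms * t / 1000, 0, colony_lat, colony_lon)
  tibble::tibble(t_s = t, lat_dd = ll$lat_dd, lon_dd = ll$lon_dd)
}
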