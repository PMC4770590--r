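# The 1 km^2 analysis grid: projection, interpolation, binning, cell SST,
# capture geolocation, decile profiles, distances.

gr <- grid_spec()

test_that("projection round-trips within 1 m out to 50 km", {
  set.seed(fix_seed)
  x <- runif(200, -50, 50)
  y <- runif(200, -50, 50)
  ll <- planar_to_lonlat(x, y, gr$colony_lat, gr$colony_lon)
  back <- lonlat_to_planar(ll$lat_dd, ll$lon_dd, gr$colony_lat, gr$colony_lon)
  expect_lt(max(abs(back$x_km - x)), 1e-3)
  expect_lt(max(abs(back$y_km - y)), 1e-3)
})

test_that("interpolation yields the expected positions and matches a segment oracle", {
  # two fixes 20 min apart -> positions at 0, 10, 20 min
  tr <- straight_track(duration_s = 1200, fix_s = 1200)
  pos <- interpolate_positions(tr, gr)
  expect_identical(nrow(pos), 3L)

  # brute-force per-segment linear evaluation on an irregular random track
  set.seed(fix_seed)
  t <- cumsum(runif(20, 30, 115))
  xx <- cumsum(rnorm(20, 0, 0.4))
  yy <- cumsum(rnorm(20, 0, 0.4))
  ll <- planar_to_lonlat(xx, yy, gr$colony_lat, gr$colony_lon)
  trk <- tibble::tibble(t_s = t, lat_dd = ll$lat_dd, lon_dd = ll$lon_dd)
  pos2 <- interpolate_positions(trk, gr, step_s = 60)
  for (i in seq_len(nrow(pos2))) {
    j <- findInterval(pos2$t_s[i], t, rightmost.closed = TRUE)
    j <- min(max(j, 1), length(t) - 1)
    fr <- (pos2$t_s[i] - t[j]) / (t[j + 1] - t[j])
    expect_equal(pos2$x_km[i], xx[j] + fr * (xx[j + 1] - xx[j]), tolerance = 1e-6)
    expect_equal(pos2$y_km[i], yy[j] + fr * (yy[j + 1] - yy[j]), tolerance = 1e-6)
  }
  expect_error(interpolate_positions(trk[1, ], gr), "2 fixes")
})

test_that("position binning is conservative and transects leave 1-2 counts per cell", {
  one <- tibble::tibble(ix = 3L, iy = 4L)
  cells <- bin_positions(one, gr)
  expect_identical(cells$count[cells$ix == 3 & cells$iy == 4], 1L)
  expect_identical(sum(cells$count), 1L)
  expect_true(all(cells$presence == (cells$count > 0)))

  # straight transect at 1.8 m/s, 10-min steps (1.08 km spacing)
  tr <- straight_track(duration_s = 3600 * 3, fix_s = 60)
  pos <- interpolate_positions(tr, gr)
  binned <- bin_positions(pos, gr)
  expect_identical(sum(binned$count), nrow(pos))
  traversed <- binned$count[binned$count > 0]
  expect_true(all(traversed %in% c(1L, 2L)))

  expect_warning(
    out <- bin_positions(tibble::tibble(ix = c(1L, NA), iy = c(1L, NA)), gr),
    "outside"
  )
  expect_identical(attr(out, "outside_n"), 1L)
  # re-binning the derived presence field is idempotent
  again <- bin_positions(pos, gr)
  expect_identical(again$presence, binned$presence)
})

test_that("per-cell SST means honour tracked dates and cloud masks", {
  mk_stack <- function(vals_by_day) {
    fields <- purrr::imap_dfr(vals_by_day, function(v, i) {
      tibble::tibble(
        date = as.Date("2013-09-01") + (as.integer(i) - 1),
        ix = c(0L, 1L), iy = 0L, sst_c = v
      )
    })
    structure(list(fields = fields), class = "sst_stack")
  }
  # day constants {3,4,6,8,11}: mean over exactly the tracked days
  st <- mk_stack(list(`1` = c(3, 3), `2` = c(4, 4), `3` = c(6, 6), `4` = c(8, 8), `5` = c(11, 11)))
  m <- mean_sst_by_cell(st, as.Date("2013-09-01") + 0:4)
  expect_equal(m$sst_c, rep(mean(c(3, 4, 6, 8, 11)), 2))
  single <- mean_sst_by_cell(st, as.Date("2013-09-03"))
  expect_equal(single$sst_c, c(6, 6))

  # cell masked on 2 of 5 days: mean of the unmasked three
  st2 <- mk_stack(list(`1` = c(3, NA), `2` = c(4, NA), `3` = c(6, 6), `4` = c(8, 8), `5` = c(11, 11)))
  m2 <- mean_sst_by_cell(st2, as.Date("2013-09-01") + 0:4)
  expect_equal(m2$sst_c[m2$ix == 1], mean(c(6, 8, 11)))
  expect_identical(m2$n_days[m2$ix == 1], 3L)
  expect_error(mean_sst_by_cell(st, as.Date("2020-01-01")), "missing")
  expect_error(mean_sst_by_cell(st, as.Date(character())), "empty")
})

test_that("SST anomalies centre on zero with a binary variant", {
  u <- tibble::tibble(ix = 0:3, iy = 0L, sst_c = rep(17, 4))
  expect_equal(sst_anomaly(u)$anomaly_c, rep(0, 4))
  two <- tibble::tibble(ix = 0:1, iy = 0L, sst_c = c(18, 20))
  a <- sst_anomaly(two)
  expect_equal(a$anomaly_c, c(-1, 1))
  expect_identical(as.character(a$anomaly_bin), c("cooler", "warmer"))
  set.seed(fix_seed)
  r <- tibble::tibble(ix = 1:100, iy = 0L, sst_c = rnorm(100, 18, 2))
  r$sst_c[sample(100, 10)] <- NA
  expect_lt(abs(sum(sst_anomaly(r)$anomaly_c, na.rm = TRUE)), 1e-9)
  expect_error(sst_anomaly(tibble::tibble(sst_c = NA_real_)), "missing")
})

test_that("capture geolocation interpolates on the 1 s lattice", {
  tr <- straight_track(duration_s = 600, fix_s = 60)
  p <- lonlat_to_planar(tr$lat_dd, tr$lon_dd, gr$colony_lat, gr$colony_lon)
  at_fix <- locate_captures(tr, 120, gr)
  expect_equal(at_fix$x_km, p$x_km[tr$t_s == 120], tolerance = 1e-9)
  midway <- locate_captures(tr, 90, gr)
  expect_equal(midway$x_km, mean(p$x_km[tr$t_s %in% c(60, 120)]), tolerance = 1e-9)
  expect_error(locate_captures(tr, 9999, gr), "outside")
})

test_that("generator captures geolocate within GPS noise of the true positions", {
  fx <- dive_season()
  tr <- fx$season$trips[[2]]
  caps <- tr$dive_series$captures
  pos <- locate_captures(tr$track$gps, caps$t_s, gr)
  err_km <- sqrt((pos$x_km - caps$x_km)^2 + (pos$y_km - caps$y_km)^2)
  # a few noisy fixes bracket each capture: allow a few multiples of sigma
  expect_lt(stats::quantile(err_km, 0.95), 6 * fx$config$gps_noise_m / 1000)
})

test_that("capture density counts conserve and expose an occupied-cells view", {
  none <- capture_density(tibble::tibble(ix = integer(), iy = integer()), gr)
  expect_identical(nrow(none$occupied), 0L)
  three <- capture_density(tibble::tibble(ix = c(2L, 2L, 2L), iy = c(5L, 5L, 5L)), gr)
  expect_identical(three$occupied$captures, 3L)
  expect_identical(sum(three$cells$captures), 3L)
})

test_that("decile profiles average per-trip bins and track mid-trip structure", {
  # two-trip toy on a known SST surface, hand-computed
  cm <- tidyr::expand_grid(ix = 0:49, iy = 0:49) %>%
    dplyr::mutate(sst_c = 15 + ix * 0.1)
  pos <- dplyr::bind_rows(
    tibble::tibble(trip_id = "a", t_s = seq(0, 900, by = 100),
      ix = 0:9 * 2L, iy = 0L),
    tibble::tibble(trip_id = "b", t_s = seq(0, 900, by = 100),
      ix = rep(4L, 10), iy = 0L)
  )
  pr <- decile_profile(pos, cm)
  want_a <- 15 + (0:9 * 2) * 0.1
  want_b <- rep(15.4, 10)
  expect_equal(pr$mean_sst_c, (want_a + want_b) / 2)
  expect_equal(pr$mean_captures, rep(0, 10))

  # flat field -> flat profile
  flat <- dplyr::mutate(cm, sst_c = 17)
  expect_equal(decile_profile(pos, flat)$mean_sst_c, rep(17, 10))

  # a cold patch visited mid-trip shows as an SST dip where captures peak
  pos_c <- tibble::tibble(trip_id = "c", t_s = seq(0, 1900, by = 100),
    ix = c(0:9, 9:0) * 2L, iy = 0L)
  caps <- tibble::tibble(trip_id = "c", t_s = c(800, 860, 900))
  cold <- dplyr::mutate(cm, sst_c = 15 + ix * 0.1 - ifelse(ix >= 16, 3, 0))
  pr2 <- decile_profile(pos_c, cold, caps)
  expect_identical(which.min(pr2$mean_sst_c), which.max(pr2$mean_captures))
  expect_lt(pr2$mean_sst_c[5], pr2$mean_sst_c[1])
  expect_error(
    decile_profile(tibble::tibble(trip_id = "x", t_s = 1:5, ix = 1L, iy = 1L), cm),
    "10 positions"
  )
})

test_that("colony distances use the haversine and agree with an ellipsoidal oracle", {
  expect_equal(colony_distance(gr$colony_lat, gr$colony_lon, gr$colony_lat, gr$colony_lon), 0)
  one_deg <- colony_distance(gr$colony_lat + 1, gr$colony_lon, gr$colony_lat, gr$colony_lon)
  expect_equal(one_deg, 6371 * pi / 180, tolerance = 1e-6)
  set.seed(fix_seed)
  x <- runif(100, -25, 25)
  y <- runif(100, -25, 25)
  ll <- planar_to_lonlat(x, y, gr$colony_lat, gr$colony_lon)
  mine <- colony_distance(ll$lat_dd, ll$lon_dd, gr$colony_lat, gr$colony_lon)
  oracle <- geosphere::distGeo(
    cbind(gr$colony_lon, gr$colony_lat), cbind(ll$lon_dd, ll$lat_dd)
  ) / 1000
  expect_lt(max(abs(mine - oracle) / oracle), 0.005)
})

test_that("habitat preference for cold water shows up in presence fractions", {
  cfg <- sim_config(
    seed = 6L, n_trips = 5, n_days = 5, base_sst_c = 20,
    thermal_opt_c = 18.5, merid_gradient_c_per_km = 0.05,
    trend_c_per_day = 0, trip_hours = 5
  )
  season <- simulate_season(cfg)
  grid <- penguinforage:::grid_from_config(cfg)
  pos <- purrr::map_dfr(season$trips, function(t) {
    interpolate_positions(t$track$gps, grid)
  })
  cells <- bin_positions(pos, grid)
  cs <- sst_anomaly(mean_sst_by_cell(season$sst, unique(season$trip_meta$date)))
  j <- dplyr::left_join(cells, cs, by = c("ix", "iy"))
  frac <- tapply(j$presence, j$anomaly_bin, mean)
  expect_gt(frac[["cooler"]], frac[["warmer"]])
})

test_that("capture depth means and SST/tag-temperature pairs summarise correctly", {
  cm <- tibble::tibble(ix = c(1L, 2L), iy = 0L, sst_c = c(18, 20))
  caps <- tibble::tibble(
    trip_id = c("a", "a", "b"), depth_m = c(5, 5, 5),
    temp_c = c(18.1, 18.2, 19.9), ix = c(1L, 1L, 2L), iy = 0L
  )
  s <- capture_depth_summary(caps, cm)
  expect_equal(s$by_trip$mean_depth_m, c(5, 5))
  expect_equal(s$temperature_pairs$sst_c, c(18, 18, 20))

  # generator without a thermocline: tag temperature tracks cell SST 1:1
  # a static field (no trend/intrusions) so tracked-day cell means coincide
  # with the water the tag actually swam through
  cfg <- sim_config(
    seed = 9L, n_trips = 4, n_days = 4, trip_hours = 5,
    merid_gradient_c_per_km = 0.08, trend_c_per_day = 0,
    intrusion_rate_per_day = 0, thermal_opt_c = 18.5
  )
  season <- simulate_season(cfg)
  grid <- penguinforage:::grid_from_config(cfg)
  cmm <- mean_sst_by_cell(season$sst, unique(season$trip_meta$date))
  ci <- cell_index(season$captures$x_km, season$captures$y_km, grid)
  caps2 <- dplyr::bind_cols(season$captures, ci)
  s2 <- capture_depth_summary(caps2, cmm)
  expect_gt(nrow(s2$temperature_pairs), 30)
  f <- linfit(s2$temperature_pairs$sst_c, s2$temperature_pairs$capture_temp_c)
  expect_lt(abs(f$slope - 1), 0.15)
})
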