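# End-to-end orchestration: simulate a season, classify dives, compute
# windowed foraging metrics, grid habitat use, fit the statistical models,
# and write a reproducible report bundle stamped with the config hash and
# seed. All randomness flows from the config seed, and no output embeds a
# wall-clock time, so re-running with the same config overwrites
# byte-identical artefacts.

# analysis grid congruent with the simulation grid
grid_from_config <- function(config) {
  grid_spec(
    colony_lat = config$colony_lat, colony_lon = config$colony_lon,
    extent_n_km = config$grid_ny * config$cell_km / 2,
    extent_s_km = config$grid_ny * config$cell_km / 2,
    extent_e_km = config$grid_nx * config$cell_km / 2,
    extent_w_km = config$grid_nx * config$cell_km / 2,
    cell_km = config$cell_km
  )
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$start_date <- format(cfg$start_date)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  file_checksum(tmp)$checksums[1]
}

# per-dive truth labels for segmented dives: a dive is capture-positive if a
# ground-truth capture time falls inside its boundaries
label_dives <- function(dives, capture_times) {
  vapply(seq_len(nrow(dives)), function(i) {
    sum(capture_times >= dives$start_s[i] & capture_times <= dives$end_s[i])
  }, numeric(1))
}

#' Run the complete analysis on a synthetic season
#'
#' Sequences every stage: simulate -> segment + classify dives -> windowed
#' CPUE metrics (night-filtered) and window optimisation -> spatial gridding
#' with per-cell SST and hurdle models (SST vs anomaly predictors compared
#' by AIC) -> geolocated captures, capture-density smooth, trip-decile
#' profiles and capture summaries -> temporal smooths of foraging success
#' against trip SST. Artefacts (CSV tables, JSON fits, a markdown report, a
#' checksummed manifest carrying the config hash and seed) are written to
#' `out_dir`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param window_minutes CPUE window length, minutes.
#' @param train_frac Fraction of trips whose dives train the classifier.
#' @return Invisibly, a list with every intermediate table and fit.
#' @export
run_all <- function(config, out_dir, window_minutes = 90, train_frac = 0.6) {
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
    message(sprintf(
      "stage %-12s %6.1f s", name,
      as.numeric(Sys.time() - t0, units = "secs")
    ))
    r
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  season <- stage("simulate", simulate_season(config))
  grid <- grid_from_config(config)
  suns <- sun_table(config, dates = seq(config$start_date - 1,
    config$start_date + config$n_days + 2, by = "day"
  ))

  ## --- dive segmentation, features, truth labels
  per_trip <- stage("dives", purrr::map(season$trips, function(tr) {
    accel <- tr$dive_series$accel
    dives <- segment_dives(accel, config$dive_threshold_m)
    feats <- compute_dive_features(dives, accel)
    truth_n <- label_dives(dives, tr$dive_series$captures$t_s)
    list(
      trip_id = tr$track$trip_id, accel = accel, dives = dives,
      features = feats, truth_n = truth_n
    )
  }))

  ## --- classifier: train on the first trips, detect everywhere
  det <- stage("classify", {
    n_train <- max(1L, ceiling(train_frac * length(per_trip)))
    train_feats <- bind_rows(purrr::map(per_trip[1:n_train], "features"))
    train_labels <- unlist(purrr::map(per_trip[1:n_train], "truth_n")) > 0
    model <- train_capture_classifier(train_feats, train_labels)
    events <- purrr::map_dfr(per_trip, function(pt) {
      ev <- detect_captures(pt$dives, pt$accel, model, features = pt$features)
      if (nrow(ev)) mutate(ev, trip_id = pt$trip_id, .before = 1) else
        tibble(trip_id = character(), dive_id = character(),
          t_s = numeric(), score = numeric())
    })
    pred_by_dive <- purrr::map(per_trip, function(pt) {
      pt$dives$dive_id %in% events$dive_id[events$trip_id == pt$trip_id]
    })
    held <- setdiff(seq_along(per_trip), 1:n_train)
    idx <- if (length(held)) held else seq_along(per_trip)
    metrics <- classifier_metrics(
      unlist(pred_by_dive[idx]),
      unlist(purrr::map(per_trip[idx], "truth_n")) > 0
    )
    list(model = model, events = events, metrics = metrics)
  })

  ## --- windowed foraging metrics
  metrics <- stage("metrics", {
    trip_inputs <- purrr::map(seq_along(per_trip), function(i) {
      pt <- per_trip[[i]]
      meta <- season$trip_meta[i, ]
      caps <- det$events$t_s[det$events$trip_id == pt$trip_id]
      list(
        trip_id = pt$trip_id,
        dives = pt$dives, capture_times = caps,
        duration_s = meta$duration_s, start_time = meta$start_time
      )
    })
    trip_metrics <- purrr::map_dfr(seq_along(trip_inputs), function(i) {
      tr <- trip_inputs[[i]]
      w <- segment_windows(tr$dives, tr$capture_times, tr$duration_s,
        minutes = window_minutes, start_time = tr$start_time
      ) %>% filter_night(suns)
      dplyr::bind_cols(
        tibble(trip_id = tr$trip_id, date = season$trip_meta$date[i]),
        trip_summary(w)
      )
    })
    opt <- optimize_window(trip_inputs[seq_len(min(8, length(trip_inputs)))],
      sun_table = suns
    )
    list(trip_metrics = trip_metrics, window_opt = opt, trip_inputs = trip_inputs)
  })

  ## --- spatial habitat use: binned positions, cell SST, hurdle models
  spatial <- stage("grid", {
    positions <- purrr::map_dfr(season$trips, function(tr) {
      interpolate_positions(tr$track$gps, grid) %>%
        mutate(trip_id = tr$track$trip_id, .before = 1)
    })
    cells <- bin_positions(positions, grid)
    cell_sst <- mean_sst_by_cell(season$sst, unique(season$trip_meta$date)) %>%
      sst_anomaly()
    cells <- left_join(cells, cell_sst, by = c("ix", "iy"))
    fit_or_null <- function(counts, covariate) {
      tryCatch(hurdle_fit(counts, covariate),
        error = function(e) hurdle_fit(counts, covariate, family = "poisson")
      )
    }
    fits <- list(
      sst = fit_or_null(cells$count, cells$sst_c),
      anomaly = fit_or_null(cells$count, cells$anomaly_c),
      anomaly_bin = fit_or_null(cells$count, as.numeric(cells$anomaly_bin) - 1)
    )
    list(
      positions = positions, cells = cells,
      hurdle_fits = fits, hurdle_aic = aic_compare(fits)
    )
  })

  ## --- spatial prey-capture success
  success <- stage("success", {
    cap_pos <- purrr::map_dfr(seq_along(season$trips), function(i) {
      tr <- season$trips[[i]]
      ev <- det$events %>% filter(.data$trip_id == tr$track$trip_id)
      if (nrow(ev) == 0) return(tibble())
      pt <- per_trip[[i]]
      pos <- locate_captures(tr$track$gps, ev$t_s, grid)
      pos %>% mutate(
        trip_id = tr$track$trip_id, .before = 1
      ) %>% mutate(
        depth_m = approx(pt$accel$t_s, pt$accel$depth_m, xout = ev$t_s)$y,
        temp_c = approx(pt$accel$t_s, pt$accel$temp_c, xout = ev$t_s)$y,
        dist_km = colony_distance(.data$lat_dd, .data$lon_dd,
          grid$colony_lat, grid$colony_lon)
      )
    })
    dens <- capture_density(cap_pos, grid)
    cell_sst <- select(spatial$cells, "ix", "iy", "sst_c")
    occ <- left_join(dens$occupied, cell_sst, by = c("ix", "iy")) %>%
      filter(!is.na(.data$sst_c))
    density_gam <- if (nrow(occ) > 12) {
      gam_fit(occ$sst_c, occ$captures)
    }
    profile <- decile_profile(
      spatial$positions, cell_sst,
      select(cap_pos, "trip_id", "t_s")
    )
    depth_summary <- capture_depth_summary(cap_pos, cell_sst)
    dist_by_trip <- cap_pos %>%
      group_by(.data$trip_id) %>%
      summarise(mean_dist_km = mean(.data$dist_km), .groups = "drop")
    list(
      capture_positions = cap_pos, density = dens, density_gam = density_gam,
      profile = profile, depth_summary = depth_summary,
      dist_by_trip = dist_by_trip
    )
  })

  ## --- temporal: trip SST and success smooths, offshore series
  temporal <- stage("temporal", {
    smoothed <- rolling_mean(
      rename(season$sst$offshore, value = "sst_c"),
      window_days = 10
    )
    tm <- metrics$trip_metrics %>%
      mutate(trip_sst_c = purrr::map_dbl(.data$date, function(d) {
        trip_sst(rename(season$sst$offshore, value = "sst_c"), d, d)
      }))
    gam_caps <- if (nrow(tm) > 12) gam_fit(tm$trip_sst_c, tm$mean_captures)
    gam_cpue <- if (nrow(tm) > 12) gam_fit(tm$trip_sst_c, tm$mean_cpue)
    list(
      offshore_smoothed = smoothed, trip_metrics_sst = tm,
      gam_captures = gam_caps, gam_cpue = gam_cpue
    )
  })

  ## --- write the bundle
  res <- list(
    config = config, window_minutes = window_minutes, season = season,
    classifier = det, metrics = metrics,
    spatial = spatial, success = success, temporal = temporal
  )
  stage("report", write_report_bundle(res, out_dir))
  message(sprintf(
    "run_all completed in %.1f s", as.numeric(Sys.time() - t_all, units = "secs")
  ))
  invisible(res)
}

write_report_bundle <- function(res, out_dir) {
  hash <- config_hash(res$config)
  seed <- res$config$seed
  w <- function(df, f) {
    readr::write_csv(df, file.path(out_dir, f))
    f
  }
  files <- c(
    w(res$metrics$trip_metrics, "trip_metrics.csv"),
    w(res$metrics$window_opt$table, "window_optimisation.csv"),
    w(res$spatial$cells %>%
      select("ix", "iy", "count", "presence", "sst_c", "anomaly_c"),
      "cells.csv"),
    w(res$success$capture_positions, "capture_positions.csv"),
    w(res$success$profile, "decile_profile.csv"),
    w(res$success$depth_summary$by_trip, "capture_depth_by_trip.csv"),
    w(res$temporal$trip_metrics_sst, "trip_metrics_sst.csv"),
    w(res$temporal$offshore_smoothed, "offshore_sst_smoothed.csv")
  )
  write_classifier(res$classifier$model, file.path(out_dir, "classifier.json"))
  fits <- list(
    classifier_metrics = res$classifier$metrics,
    window_minutes_chosen = res$metrics$window_opt$minutes,
    hurdle = purrr::map(res$spatial$hurdle_fits, function(f) {
      list(tidy = tidy(f), glance = glance(f))
    }),
    hurdle_aic = res$spatial$hurdle_aic,
    gam_captures = if (!is.null(res$temporal$gam_captures)) {
      list(tidy = tidy(res$temporal$gam_captures),
        glance = glance(res$temporal$gam_captures))
    },
    gam_cpue = if (!is.null(res$temporal$gam_cpue)) {
      list(tidy = tidy(res$temporal$gam_cpue),
        glance = glance(res$temporal$gam_cpue))
    },
    capture_density_gam = if (!is.null(res$success$density_gam)) {
      list(tidy = tidy(res$success$density_gam),
        glance = glance(res$success$density_gam))
    }
  )
  jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  files <- c(files, "classifier.json", "fits.json")

  rpt <- file.path(out_dir, "report.md")
  fmt_fit <- function(name, f) {
    if (is.null(f)) return(sprintf("## %s\n\n(not fitted: too few cells)\n", name))
    sprintf(
      "## %s\n\nedf %.2f, R^2 %.3f, F %.2f, p %.3g; smooth argmax %.2f degC\n",
      name, f$edf, f$r_squared, f$f_value, f$p_value, f$argmax
    )
  }
  lines <- c(
    "# Synthetic season analysis report",
    sprintf("config hash: %s", hash),
    sprintf("seed: %d; trips: %d; window: %g min",
      seed, res$config$n_trips, res$window_minutes),
    "",
    "## Capture detection (held-out dive-level validation)",
    sprintf(
      "TP %d FP %d TN %d FN %d; FPR %.4f; sensitivity %.4f",
      res$classifier$metrics$tp, res$classifier$metrics$fp,
      res$classifier$metrics$tn, res$classifier$metrics$fn,
      res$classifier$metrics$fpr, res$classifier$metrics$sensitivity
    ),
    "",
    "## Window optimisation",
    sprintf("chosen window: %g min", res$metrics$window_opt$minutes),
    "",
    "## Trip metrics (mean over daylight windows)",
    sprintf(
      "trips %d; mean captures/window %.2f; mean CPUE %.3f per min diving",
      nrow(res$metrics$trip_metrics),
      mean(res$metrics$trip_metrics$mean_captures),
      mean(res$metrics$trip_metrics$mean_cpue)
    ),
    "",
    "## Habitat use (hurdle models, AIC ranking)",
    paste(utils::capture.output(as.data.frame(res$spatial$hurdle_aic)),
      collapse = "\n"),
    sprintf(
      "best predictor: %s; zero-part SST slope %.4f (SE %.4f); count-part %.4f (SE %.4f)",
      res$spatial$hurdle_aic$model[1],
      res$spatial$hurdle_fits$sst$zero$estimate[2],
      res$spatial$hurdle_fits$sst$zero$se[2],
      res$spatial$hurdle_fits$sst$count$estimate[2],
      res$spatial$hurdle_fits$sst$count$se[2]
    ),
    sprintf(
      "empty cells: %.1f%%",
      100 * mean(!res$spatial$cells$presence)
    ),
    "",
    fmt_fit("Capture density vs cell SST", res$success$density_gam),
    fmt_fit("Prey per window vs trip SST", res$temporal$gam_captures),
    fmt_fit("CPUE vs trip SST", res$temporal$gam_cpue),
    "## Trip-decile profile",
    paste(utils::capture.output(as.data.frame(res$success$profile)),
      collapse = "\n"),
    "",
    "## Capture depth / distance",
    sprintf(
      "mean capture depth %.2f m; mean capture distance from colony %.2f km",
      mean(res$success$depth_summary$by_trip$mean_depth_m),
      mean(res$success$dist_by_trip$mean_dist_km)
    )
  )
  writeLines(lines, rpt)
  files <- c(files, "report.md")

  paths <- file.path(out_dir, files)
  ck <- file_checksum(paths)
  jsonlite::write_json(
    list(
      config_hash = hash, seed = seed, algorithm = ck$algorithm,
      files = tibble(file = files, checksum = ck$checksums)
    ),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
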