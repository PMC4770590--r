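# Plain-text fixture sets: GPS CSVs, accelerometry CSVs, an SST stack as
# CSV-per-day plus JSON metadata, ground-truth JSON, and a SHA-256 manifest.

file_checksum <- function(paths) {
  sha <- Sys.which("sha256sum")
  if (nzchar(sha)) {
    out <- system2(sha, shQuote(paths), stdout = TRUE)
    list(algorithm = "sha256", checksums = sub(" .*$", "", out))
  } else {
    list(algorithm = "md5", checksums = unname(tools::md5sum(paths)))
  }
}

#' Write a synthetic season to disk as a plain-text fixture set
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param season Optionally a pre-built [simulate_season()] result for the
#'   same config, to avoid re-simulation.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`): file names, checksums, seed.
#' @export
write_fixture_set <- function(config, out_dir, season = NULL) {
  if (is.null(season)) season <- simulate_season(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("cannot create output directory")
  sst_dir <- file.path(out_dir, "sst")
  dir.create(sst_dir, showWarnings = FALSE)

  files <- character(0)
  for (tr in season$trips) {
    id <- tr$track$trip_id
    gps_path <- file.path(out_dir, paste0("gps_", id, ".csv"))
    readr::write_csv(
      tr$track$gps %>%
        mutate(timestamp_iso8601 = format(.data$time, "%Y-%m-%dT%H:%M:%SZ")) %>%
        select("timestamp_iso8601", "lat_dd", "lon_dd"),
      gps_path
    )
    accel_path <- file.path(out_dir, paste0("accel_", id, ".csv"))
    readr::write_csv(tr$dive_series$accel, accel_path)
    files <- c(files, gps_path, accel_path)
  }

  for (d in unique(season$sst$fields$date)) {
    day <- filter(season$sst$fields, .data$date == d)
    p <- file.path(sst_dir, paste0("sst_", format(as.Date(d, origin = "1970-01-01")), ".csv"))
    readr::write_csv(select(day, "ix", "iy", "sst_c"), p)
    files <- c(files, p)
  }
  meta_path <- file.path(sst_dir, "sst_meta.json")
  jsonlite::write_json(
    c(season$sst$meta, list(dates = format(unique(season$sst$fields$date)))),
    meta_path,
    auto_unbox = TRUE, digits = NA
  )
  files <- c(files, meta_path)

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(
      trip_meta = season$trip_meta %>%
        mutate(
          date = format(.data$date),
          start_time = format(.data$start_time, "%Y-%m-%dT%H:%M:%SZ")
        ),
      dives = season$dives,
      captures = season$captures,
      sst_days = season$sst$truth %>% mutate(date = format(.data$date)),
      offshore = season$sst$offshore %>% mutate(date = format(.data$date)),
      inshore = season$sst$inshore %>% mutate(date = format(.data$date))
    ),
    truth_path,
    auto_unbox = TRUE, digits = NA
  )
  files <- c(files, truth_path)

  ck <- file_checksum(files)
  manifest <- list(
    seed = season$config$seed,
    n_trips = season$config$n_trips,
    algorithm = ck$algorithm,
    files = tibble(
      file = basename(files),
      path = sub(paste0("^", out_dir, "/?"), "", files),
      checksum = ck$checksums
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

#' Read a GPS track CSV
#'
#' Expects columns `timestamp_iso8601, lat_dd, lon_dd`.
#'
#' @param path CSV file path.
#' @param trip_id Identifier attached to the returned track.
#' @return Tibble `trip_id, t_s, time, lat_dd, lon_dd` with `t_s` seconds
#'   since the first fix.
#' @export
read_gps <- function(path, trip_id = basename(path)) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("timestamp_iso8601", "lat_dd", "lon_dd")
  if (!all(need %in% names(x))) abort("GPS file missing required columns")
  time <- as.POSIXct(x$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (any(is.na(time))) abort("unparseable timestamps in GPS file")
  if (any(diff(as.numeric(time)) <= 0)) abort("GPS times must be strictly increasing")
  tibble(
    trip_id = trip_id, t_s = as.numeric(time) - as.numeric(time[1]),
    time = time, lat_dd = x$lat_dd, lon_dd = x$lon_dd
  )
}

#' Read an SST stack written as CSV-per-day plus JSON metadata
#'
#' @param dir Directory containing `sst_YYYY-MM-DD.csv` files and
#'   `sst_meta.json`.
#' @return A list of class `sst_stack` with `fields` and `meta` (point
#'   series are not part of the on-disk stack).
#' @export
read_sst_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "sst_meta.json"), simplifyVector = TRUE)
  fields <- purrr::map_dfr(meta$dates, function(d) {
    readr::read_csv(file.path(dir, paste0("sst_", d, ".csv")),
      show_col_types = FALSE
    ) %>%
      mutate(date = as.Date(d), .before = 1)
  })
  fields <- fields %>% mutate(
    x_km = meta$origin_x_km + (.data$ix + 0.5) * meta$cell_km,
    y_km = meta$origin_y_km + (.data$iy + 0.5) * meta$cell_km
  )
  structure(list(fields = fields, meta = meta), class = "sst_stack")
}
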