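# Dive segmentation, the six-feature signature, and capture detection.

test_that("read_accel validates structure and infers mode from depth", {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    t_s = c(0, 1, 2), depth_m = c(0.2, 1.4, 2.1),
    ax_g = 0, ay_g = 0, az_g = 1, temp_c = 18
  ), f)
  a <- read_accel(f)
  expect_identical(a$mode, c("shallow", "shallow", "dive"))

  empty <- tempfile(fileext = ".csv")
  writeLines("t_s,depth_m,ax_g,ay_g,az_g,temp_c", empty)
  expect_error(read_accel(empty), "empty")

  bad <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t_s = c(0, 1, 1), depth_m = 0, ax_g = 0,
    ay_g = 0, az_g = 0, temp_c = 18), bad)
  expect_error(read_accel(bad), "increasing")

  miss <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(t_s = 0:1, depth_m = 0), miss)
  expect_error(read_accel(miss), "missing columns")
  unlink(c(f, empty, bad, miss))
})

test_that("fixture accelerometry reads back with the generator's sample count", {
  fx <- dive_season()
  d <- file.path(tempdir(), "readback")
  unlink(d, recursive = TRUE)
  cfg_small <- sim_config(seed = 21L, n_days = 1, n_trips = 1, trip_hours = 4,
    grid_nx = 12L, grid_ny = 12L, max_range_km = 4)
  season <- simulate_season(cfg_small)
  write_fixture_set(cfg_small, d, season = season)
  a <- read_accel(file.path(d, "accel_trip01.csv"))
  expect_identical(nrow(a), nrow(season$trips[[1]]$dive_series$accel))
  unlink(d, recursive = TRUE)
})

test_that("segmentation matches hand-worked threshold crossings", {
  expect_identical(
    nrow(segment_dives(tibble::tibble(t_s = 0:5, depth_m = c(0, 1, 1.5, 1.2, 0.4, 0)))),
    0L
  )
  # depth 0,0,2,3,2,0 at 1 Hz: crossings interpolate to 1.75 s and 4.25 s
  d <- segment_dives(tibble::tibble(t_s = 0:5, depth_m = c(0, 0, 2, 3, 2, 0)))
  expect_identical(nrow(d), 1L)
  expect_equal(d$start_s, 1.75)
  expect_equal(d$end_s, 4.25)
  expect_equal(d$duration_s, 2.5)
})

test_that("segmentation equals the brute-force threshold scan on random series", {
  set.seed(fix_seed)
  for (r in 1:250) {
    s <- random_depth_series()
    got <- segment_dives(tibble::tibble(t_s = s$t, depth_m = s$d))
    want <- brute_segment(s$t, s$d)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
      expect_identical(got$i_first, as.integer(want$i_first))
      expect_identical(got$i_last, as.integer(want$i_last))
    }
  }
})

test_that("segmented boundaries match generator dives exactly", {
  fx <- dive_season()
  pt <- fx$per_trip[[1]]
  expect_identical(nrow(pt$dives), nrow(pt$truth_dives))
  expect_equal(pt$dives$start_s, pt$truth_dives$start_s, tolerance = 1e-9)
  expect_equal(pt$dives$end_s, pt$truth_dives$end_s, tolerance = 1e-9)
})

test_that("features of a symmetric V-dive follow the closed form", {
  # 1 m/s to 10 m from the 1.5 m threshold, sampled at 2 Hz
  t <- seq(0, 17, by = 0.5)
  depth <- 1.5 + pmin(t, 17 - t)
  a <- tibble::tibble(t_s = t, depth_m = depth)
  d <- segment_dives(a)
  f <- compute_dive_features(d, a)
  expect_equal(f$duration_s, 17)
  expect_equal(f$max_depth_m, 10)
  # bottom phase: depth >= 8.5 m, i.e. t in [7, 10]
  expect_equal(f$bottom_s, 3)
  expect_identical(f$undulations, 0L)
  expect_equal(f$descent_ms, 8.5 / 7)
  expect_equal(f$ascent_ms, 8.5 / 7)
})

test_that("injected bottom-phase wiggles are counted as undulations", {
  t <- seq(0, 40, by = 0.1)
  bottom <- t >= 10 & t <= 30
  depth <- 1.5 + pmin(t, 40 - t) * 0.85
  depth[bottom] <- 10 - 1 * (1 - cos(2 * pi * 3 * (t[bottom] - 10) / 20)) / 2
  a <- tibble::tibble(t_s = t, depth_m = pmin(depth, 10))
  d <- segment_dives(a)
  f <- compute_dive_features(d, a)
  expect_identical(f$undulations, 3L)
  # sub-threshold (0.3 m) wiggles are not counted
  depth2 <- a$depth_m
  depth2[bottom] <- 10 - 0.3 * (1 - cos(2 * pi * 5 * (t[bottom] - 10) / 20)) / 2
  f2 <- compute_dive_features(d, tibble::tibble(t_s = t, depth_m = depth2))
  expect_identical(f2$undulations, 0L)
})

test_that("generator dives yield features near their generating parameters", {
  fx <- dive_season()
  pt <- fx$per_trip[[1]]
  f <- compute_dive_features(pt$dives, pt$accel)
  td <- pt$truth_dives
  expect_equal(f$duration_s, td$duration_s, tolerance = 1e-6)
  expect_lt(max(abs(f$max_depth_m - td$max_depth_m)), 0.3)
  expect_lt(stats::median(abs(f$bottom_s - td$bottom_s)), 0.5)
  expect_gt(stats::cor(f$undulations, td$undulations), 0.9)
})

test_that("capture dives rank higher on every signature feature", {
  fx <- dive_season()
  f <- dplyr::bind_rows(lapply(fx$per_trip, function(p) p$feats))
  lab <- unlist(lapply(fx$per_trip, function(p) p$truth_n)) > 0
  for (col in c("duration_s", "max_depth_m", "bottom_s", "undulations",
    "descent_ms", "ascent_ms")) {
    w <- stats::wilcox.test(f[[col]][lab], f[[col]][!lab], alternative = "greater")
    expect_lt(w$p.value, 1e-6)
  }
})

test_that("total dive time is invariant to resampling the shallow mode", {
  fx <- dive_season()
  a <- fx$per_trip[[1]]$accel
  d1 <- segment_dives(a)
  sh <- which(a$mode == "shallow")
  drop <- sh[seq(1, length(sh), by = 2)]
  a2 <- a[-drop, ]
  d2 <- segment_dives(a2)
  expect_identical(nrow(d1), nrow(d2))
  expect_equal(sum(d1$duration_s), sum(d2$duration_s), tolerance = 1e-9)
})

test_that("a separable toy problem is classified perfectly", {
  set.seed(fix_seed)
  n <- 60
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  f <- tibble::tibble(
    duration_s = ifelse(lab, 40, 15) + rnorm(n),
    max_depth_m = ifelse(lab, 15, 6) + rnorm(n),
    bottom_s = ifelse(lab, 18, 5) + rnorm(n),
    undulations = ifelse(lab, 4, 0),
    descent_ms = ifelse(lab, 1.5, 0.9) + rnorm(n, 0, 0.05),
    ascent_ms = ifelse(lab, 1.5, 0.9) + rnorm(n, 0, 0.05)
  )
  m <- train_capture_classifier(f, lab)
  expect_identical(classify_dives(m, f)$gate, lab)
  expect_error(train_capture_classifier(f, rep(TRUE, n)), "both")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  fx <- dive_season()
  f <- fx$per_trip[[1]]$feats
  set.seed(fix_seed)
  lab <- sample(fx$per_trip[[1]]$truth_n > 0)
  half <- seq_len(nrow(f) %/% 2)
  m <- train_capture_classifier(f[half, ], lab[half])
  pred <- classify_dives(m, f[-half, ])$gate
  acc <- mean(pred == lab[-half])
  expect_gt(acc, 0.35)
  expect_lt(acc, 0.65)
})

test_that("classifier JSON round-trips and reproduces scores", {
  m <- dive_model()
  p <- tempfile(fileext = ".json")
  write_classifier(m, p)
  m2 <- read_classifier(p)
  f <- dive_season()$per_trip[[2]]$feats
  expect_equal(classify_dives(m2, f)$score, classify_dives(m, f)$score,
    tolerance = 1e-12)
  unlink(p)
})

test_that("burst detection resolves separated bursts and gates negatives", {
  # hand-built dive: 30 Hz, two bursts 3 s apart
  hz <- 30
  t <- seq(0, 20, by = 1 / hz)
  depth <- 1.5 + 8 * sin(pi * t / 20)
  ax <- rnorm(length(t), 0, 0.05)
  az <- rnorm(length(t), 0, 0.05)
  for (tc in c(9, 12)) {
    w <- abs(t - tc) < 0.25
    ax[w] <- ax[w] + 1.8 * sin(2 * pi * 8 * (t[w] - tc))
  }
  a <- tibble::tibble(t_s = t, depth_m = depth, ax_g = ax, ay_g = 0, az_g = az,
    temp_c = 18, mode = "dive")
  d <- segment_dives(a)
  f <- compute_dive_features(d, a)
  gate_open <- structure(list(
    features = penguinforage:::.signature_cols,
    center = setNames(rep(0, 6), penguinforage:::.signature_cols),
    scale = setNames(rep(1, 6), penguinforage:::.signature_cols),
    weights = setNames(rep(0, 6), penguinforage:::.signature_cols),
    bias = 1, burst_threshold_g = 1, refractory_s = 1, highpass_s = 1 / 3
  ), class = "capture_classifier")
  ev <- detect_captures(d, a, gate_open, features = f)
  expect_identical(nrow(ev), 2L)
  expect_equal(sort(ev$t_s), c(9, 12), tolerance = 0.3)

  gate_shut <- gate_open
  gate_shut$bias <- -1
  expect_identical(nrow(detect_captures(d, a, gate_shut, features = f)), 0L)
  expect_error(detect_captures(d, a, list()), "not fitted")
})

test_that("confusion-matrix arithmetic matches hand computation", {
  perfect <- classifier_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$sensitivity, 1)

  allpos <- classifier_metrics(rep(TRUE, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$fpr, 1)

  # TP=8 FP=1 TN=99 FN=2
  truth <- c(rep(TRUE, 10), rep(FALSE, 100))
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), TRUE, rep(FALSE, 99))
  m <- classifier_metrics(pred, truth)
  expect_equal(m$fpr, 0.01)
  expect_equal(m$sensitivity, 0.8)
  expect_error(classifier_metrics(TRUE, c(TRUE, FALSE)), "length")
})
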