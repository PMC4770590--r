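#' Read and validate a two-mode accelerometry record
#'
#' Expects columns `t_s, depth_m, ax_g, ay_g, az_g, temp_c, mode`. If the
#' mode column is absent it is inferred from depth (`dive` at or below the
#' 1.5 m threshold boundary, i.e. depth >= threshold; `shallow` otherwise).
#'
#' @param path CSV file path.
#' @param threshold_m Mode-switching depth, m.
#' @return A validated tibble (times strictly increasing, accelerations
#'   within +/-2 g).
#' @export
read_accel <- function(path, threshold_m = 1.5) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(x) == 0) abort("empty accelerometry file")
  need <- c("t_s", "depth_m", "ax_g", "ay_g", "az_g", "temp_c")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste("accelerometry file missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(diff(x$t_s) <= 0)) abort("accelerometry times must be strictly increasing")
  if (any(abs(c(x$ax_g, x$ay_g, x$az_g)) > 2 + 1e-9)) {
    abort("acceleration outside the +/-2 g logger range")
  }
  if (!"mode" %in% names(x)) {
    x$mode <- ifelse(x$depth_m >= threshold_m, "dive", "shallow")
  }
  as_tibble(x)
}

#' Segment a depth record into dives at a threshold
#'
#' Dives are maximal intervals with depth strictly above the threshold.
#' Boundary times are placed by linear interpolation between the bracketing
#' samples (a sample emitted exactly at the threshold is the boundary
#' itself). Excursions shorter than `min_samples` consecutive
#' above-threshold samples are ignored.
#'
#' @param accel Accelerometry tibble with `t_s` and `depth_m`.
#' @param threshold_m Dive threshold, m (1.5 for these loggers).
#' @param min_samples Minimum above-threshold samples for a dive.
#' @return Tibble of class `dive_table`: `dive_id, start_s, end_s,
#'   duration_s, i_first, i_last` (`i_*` index the above-threshold samples
#'   in `accel`). Attributes record the threshold.
#' @export
segment_dives <- function(accel, threshold_m = 1.5, min_samples = 2L) {
  stopifnot(is.data.frame(accel), all(c("t_s", "depth_m") %in% names(accel)))
  d <- accel$depth_m
  t <- accel$t_s
  above <- d > threshold_m
  out <- tibble(
    dive_id = character(), start_s = numeric(), end_s = numeric(),
    duration_s = numeric(), i_first = integer(), i_last = integer()
  )
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_samples
    i_first <- starts[keep]
    i_last <- ends[keep]
    if (length(i_first)) {
      n <- length(d)
      prev <- pmax(i_first - 1L, 1L)
      nxt <- pmin(i_last + 1L, n)
      start_s <- ifelse(
        i_first == 1L, t[i_first],
        t[prev] + (threshold_m - d[prev]) / (d[i_first] - d[prev]) *
          (t[i_first] - t[prev])
      )
      end_s <- ifelse(
        i_last == n, t[i_last],
        t[i_last] + (d[i_last] - threshold_m) / (d[i_last] - d[nxt]) *
          (t[nxt] - t[i_last])
      )
      out <- tibble(
        dive_id = sprintf("d%04d", seq_along(i_first)),
        start_s = start_s, end_s = end_s, duration_s = end_s - start_s,
        i_first = i_first, i_last = i_last
      )
    }
  }
  attr(out, "threshold_m") <- threshold_m
  class(out) <- c("dive_table", class(out))
  out
}

# alternating local extremes of a series, endpoints included
turning_points <- function(v) {
  dv <- diff(v)
  dv_nz <- dv[dv != 0]
  if (length(dv_nz) < 1) return(v[1])
  vals <- cumsum(c(v[1], dv_nz))
  s <- sign(dv_nz)
  turns <- which(diff(s) != 0)
  c(vals[1], vals[turns + 1L], vals[length(vals)])
}

# Count depth undulations of at least `min_m` within a (bottom-phase) depth
# vector. An undulation is a rise off the bottom and return: a local minimum
# of depth (down-positive) with excursion amplitude of at least `min_m` on
# both sides. Sensor noise creates sub-threshold turning points, so counting
# uses hysteresis: a dip only arms once depth has fallen `min_m` below the
# running maximum, and only counts once it has risen `min_m` above the dip.
count_undulations <- function(depth, min_m = 0.5) {
  if (length(depth) < 3) return(0L)
  tp <- turning_points(depth)
  count <- 0L
  ref <- tp[1] # deepest point since the last counted dip
  armed <- FALSE
  cur_min <- tp[1]
  for (v in tp[-1]) {
    if (!armed) {
      if (v > ref) {
        ref <- v
      } else if (ref - v >= min_m) {
        armed <- TRUE
        cur_min <- v
      }
    } else {
      if (v < cur_min) {
        cur_min <- v
      } else if (v - cur_min >= min_m) {
        count <- count + 1L
        armed <- FALSE
        ref <- v
      }
    }
  }
  count
}

#' Extract the six-feature prey-capture signature from dives
#'
#' For each segmented dive: duration (boundary difference), maximum depth,
#' bottom time (time between the first and last sample at or above
#' `bottom_frac` of maximum depth), the number of bottom-phase depth
#' undulations of amplitude at least `undulation_min_m`, and descent/ascent
#' rates measured as depth change from the threshold to maximum depth over
#' the respective phase duration.
#'
#' @param dives A `dive_table` from [segment_dives()] (one or more rows).
#' @param accel The accelerometry tibble the dives were segmented from.
#' @param bottom_frac Fraction of maximum depth defining the bottom phase.
#' @param undulation_min_m Minimum undulation amplitude, m.
#' @return Tibble `dive_id, duration_s, max_depth_m, bottom_s, undulations,
#'   descent_ms, ascent_ms`.
#' @export
compute_dive_features <- function(dives, accel, bottom_frac = 0.85,
                                  undulation_min_m = 0.5) {
  stopifnot(inherits(dives, "dive_table") || is.data.frame(dives))
  thr <- attr(dives, "threshold_m") %||% 1.5
  n <- nrow(dives)
  maxd <- numeric(n)
  bottom_s <- numeric(n)
  und <- integer(n)
  desc <- numeric(n)
  asc <- numeric(n)
  td <- accel$t_s
  dd <- accel$depth_m
  for (k in seq_len(n)) {
    i1 <- dives$i_first[k]
    i2 <- dives$i_last[k]
    if (i2 - i1 < 1L) abort("degenerate one-sample dive")
    d <- dd[i1:i2]
    t <- td[i1:i2]
    m <- max(d)
    in_bottom <- which(d >= bottom_frac * m)
    b1 <- in_bottom[1]
    b2 <- in_bottom[length(in_bottom)]
    maxd[k] <- m
    bottom_s[k] <- t[b2] - t[b1]
    und[k] <- count_undulations(d[b1:b2], undulation_min_m)
    # a dive reaching max depth in its first sample has an unresolvably
    # short phase; bound by half the local sample interval
    half_dt <- min(diff(t)) / 2
    desc[k] <- (m - thr) / max(t[b1] - dives$start_s[k], half_dt)
    asc[k] <- (m - thr) / max(dives$end_s[k] - t[b2], half_dt)
  }
  tibble(
    dive_id = dives$dive_id,
    duration_s = dives$end_s - dives$start_s,
    max_depth_m = maxd, bottom_s = bottom_s, undulations = und,
    descent_ms = desc, ascent_ms = asc
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
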