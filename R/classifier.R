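# Prey-capture detection: a max-margin linear gate on the six dive-signature
# features, followed by a within-dive acceleration-burst detector (moving-
# mean high-pass of surge and heave, L2 magnitude, threshold + refractory
# merging). Events are reported only in gate-positive dives.

#' Train the dive-level capture classifier
#'
#' Standardises the six signature features and fits a regularised max-margin
#' linear separator (a linear support vector machine). The within-dive burst
#' threshold and refractory period used by [detect_captures()] are stored
#' with the model.
#'
#' @param features Tibble from [compute_dive_features()] (columns
#'   `duration_s, max_depth_m, bottom_s, undulations, descent_ms,
#'   ascent_ms`).
#' @param labels Logical vector: did the dive contain a capture.
#' @param cost Soft-margin cost parameter.
#' @param burst_threshold_g Threshold on high-passed surge/heave magnitude, g.
#' @param refractory_s Bursts closer than this are merged into one event, s.
#' @param highpass_s Moving-mean high-pass window, s (1/3 s passes
#'   components above about 3 Hz).
#' @return A list of class `capture_classifier`: standardisation parameters,
#'   linear weights and bias, and burst-detector settings.
#' @export
train_capture_classifier <- function(features, labels, cost = 1,
                                     burst_threshold_g = 1,
                                     refractory_s = 1,
                                     highpass_s = 1 / 3) {
  feats <- .signature_cols
  stopifnot(all(feats %in% names(features)), nrow(features) == length(labels))
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) abort("need both capture and non-capture dives")
  x <- as.matrix(features[feats])
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- e1071::svm(z, factor(labels, levels = c(FALSE, TRUE)),
    kernel = "linear", cost = cost, scale = FALSE
  )
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the score so capture dives are positive
  sc <- drop(z %*% w) + b
  if (mean(sc[labels]) < mean(sc[!labels])) {
    w <- -w
    b <- -b
  }
  structure(
    list(
      features = feats, center = center, scale = scale,
      weights = w, bias = b,
      burst_threshold_g = burst_threshold_g,
      refractory_s = refractory_s, highpass_s = highpass_s
    ),
    class = "capture_classifier"
  )
}

.signature_cols <- c(
  "duration_s", "max_depth_m", "bottom_s", "undulations",
  "descent_ms", "ascent_ms"
)

#' Dive-level classifier scores and gate decisions
#'
#' @param model A `capture_classifier`.
#' @param features Feature tibble as in [train_capture_classifier()].
#' @return Tibble `score, gate` (gate is `score > 0`).
#' @export
classify_dives <- function(model, features) {
  stopifnot(inherits(model, "capture_classifier"))
  x <- as.matrix(features[model$features])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  score <- drop(z %*% model$weights) + model$bias
  tibble(score = score, gate = score > 0)
}

# centred moving-mean high-pass over a window of n samples (cumsum-based;
# truncated windows at the edges)
highpass <- function(v, n) {
  n <- max(1L, as.integer(n))
  N <- length(v)
  i <- seq_len(N)
  lo <- pmax(1L, i - ((n - 1L) %/% 2L))
  hi <- pmin(N, i + (n %/% 2L))
  cs <- c(0, cumsum(v))
  v - (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect prey-capture events within dives
#'
#' Gate-positive dives (classifier score > 0) are scanned for
#' surge-plus-heave bursts: both axes are high-passed with a moving-mean
#' subtraction, the L2 magnitude is thresholded, and supra-threshold samples
#' closer than the refractory period are merged into single events timed at
#' the magnitude peak.
#'
#' @param dives A `dive_table` from [segment_dives()].
#' @param accel The accelerometry tibble the dives index into.
#' @param model A fitted `capture_classifier`.
#' @param features Optional precomputed feature tibble (row order matching
#'   `dives`); computed if omitted.
#' @return Tibble of class `capture_events`: `dive_id, t_s, score`.
#' @export
detect_captures <- function(dives, accel, model, features = NULL) {
  if (!inherits(model, "capture_classifier")) abort("model is not fitted")
  if (is.null(features)) features <- compute_dive_features(dives, accel)
  gate <- classify_dives(model, features)
  out <- list()
  for (i in seq_len(nrow(dives))) {
    if (!gate$gate[i]) next
    idx <- dives$i_first[i]:dives$i_last[i]
    t <- accel$t_s[idx]
    if (length(t) < 3) next
    dt <- median(diff(t))
    n_hp <- round(model$highpass_s / dt)
    mag <- sqrt(highpass(accel$ax_g[idx], n_hp)^2 +
      highpass(accel$az_g[idx], n_hp)^2)
    hit <- which(mag > model$burst_threshold_g)
    if (!length(hit)) next
    gap <- c(Inf, diff(t[hit]))
    cluster <- cumsum(gap > model$refractory_s)
    th <- t[hit]
    mh <- mag[hit]
    ev_t <- vapply(
      split(seq_along(th), cluster),
      function(j) th[j][which.max(mh[j])], numeric(1)
    )
    out[[length(out) + 1L]] <- tibble(
      dive_id = dives$dive_id[i], t_s = unname(ev_t), score = gate$score[i]
    )
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(dive_id = character(), t_s = numeric(), score = numeric())
  class(res) <- c("capture_events", class(res))
  res
}

#' Confusion-matrix summary for dive-level capture predictions
#'
#' @param predicted,truth Logical vectors of equal length.
#' @return One-row tibble `tp, fp, tn, fn, fpr, sensitivity, specificity,
#'   accuracy` (FPR = FP/(FP+TN)).
#' @export
classifier_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("label sets differ in length")
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  fn <- sum(!predicted & truth)
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    accuracy = (tp + tn) / length(truth)
  )
}

#' Serialise a capture classifier to JSON
#'
#' @param model A `capture_classifier`.
#' @param path Output file.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "capture_classifier"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a capture classifier from JSON
#'
#' @param path JSON file written by [write_classifier()].
#' @return A `capture_classifier`.
#' @export
read_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$center <- setNames(as.numeric(m$center), m$features)
  m$scale <- setNames(as.numeric(m$scale), m$features)
  m$weights <- setNames(as.numeric(m$weights), names(m$weights))
  structure(m, class = "capture_classifier")
}
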