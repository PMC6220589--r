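# Preprocessing pipelines: scale the SDFs, measure them, z-score each
# feature across the sample, and compute pairwise distances. The full grid
# is 6 scalings x 4 measurements x 2 metrics = 48 pipelines.

#' Names of the built-in SDF scaling methods
#'
#' Three are fixed by the analysis design (`none`, `z_baseline` relative to
#' the baseline epoch's mean and SD, `z_whole` relative to the whole
#' trial); the remaining three round out the six-method registry
#' (baseline subtraction, peak normalization, min-max to `[0, 1]`). The
#' consensus stage is agnostic to the particular set.
#' @export
scaler_names <- function() {
  c("none", "z_baseline", "z_whole", "baseline_subtract", "peak_norm", "minmax")
}

#' @rdname scaler_names
#' @export
measurement_names <- function() c("mean", "slope", "mean_and_slope", "sdf")

#' @rdname scaler_names
#' @export
metric_names <- function() c("euclidean", "correlation")

#' Enumerate the preprocessing-pipeline grid
#'
#' @return tibble with columns `pipeline` (id), `scaler`, `measurement`,
#'   `metric`; 48 rows under the defaults.
#' @export
pipeline_grid <- function(scalers = scaler_names(),
                          measurements = measurement_names(),
                          metrics = metric_names()) {
  g <- tidyr::expand_grid(scaler = scalers, measurement = measurements,
                          metric = metrics)
  g$pipeline <- paste(g$scaler, g$measurement, g$metric, sep = "+")
  g[, c("pipeline", "scaler", "measurement", "metric")]
}

#' Scale spike density functions
#'
#' Applies one of the per-unit scaling transforms to every unit's pair of
#' aligned SDFs. All transforms are deterministic per unit and use no
#' cross-unit information. Units whose scale is degenerate (zero baseline
#' SD under `z_baseline`, an all-constant SDF under `z_whole`/`minmax`, a
#' non-positive trial maximum under `peak_norm`) are set to zero and listed
#' in the `degenerate_units` attribute of the result.
#'
#' @param sdf_set a `fef_sdf_set` (a single `fef_sdf` is also accepted).
#' @param method one of [scaler_names()].
#' @return a `fef_sdf_set` with scaled `stim`/`sacc` matrices.
#' @export
scale_sdf <- function(sdf_set, method = scaler_names()) {
  method <- match.arg(method)
  single <- inherits(sdf_set, "fef_sdf")
  if (single) sdf_set <- sdf_single_to_set(sdf_set)
  x <- sdf_set
  n <- length(x$unit_ids)
  both <- cbind(x$stim, x$sacc)
  ns <- ncol(x$stim)
  degenerate <- character(0)

  for (i in seq_len(n)) {
    v <- both[i, ]
    sc <- switch(method,
      none = v,
      z_baseline = {
        m <- x$baseline_mean[i]; s <- x$baseline_sd[i]
        if (!is.finite(s) || s == 0) { degenerate <- c(degenerate, x$unit_ids[i]); v * 0 }
        else (v - m) / s
      },
      z_whole = {
        m <- mean(v); s <- stats::sd(v)
        if (!is.finite(s) || s == 0) { degenerate <- c(degenerate, x$unit_ids[i]); v * 0 }
        else (v - m) / s
      },
      baseline_subtract = v - x$baseline_mean[i],
      peak_norm = {
        mx <- max(v)
        if (mx <= 0) { degenerate <- c(degenerate, x$unit_ids[i]); v * 0 }
        else v / mx
      },
      minmax = {
        rng <- range(v)
        if (diff(rng) == 0) { degenerate <- c(degenerate, x$unit_ids[i]); v * 0 }
        else (v - rng[1]) / diff(rng)
      })
    both[i, ] <- sc
  }
  x$stim <- both[, seq_len(ns), drop = FALSE]
  x$sacc <- both[, -seq_len(ns), drop = FALSE]
  attr(x, "scaler") <- method
  attr(x, "degenerate_units") <- degenerate
  if (single) return(sdf_set_to_single(x))
  x
}

sdf_single_to_set <- function(s) {
  structure(list(unit_ids = s$unit_id,
                 stim = matrix(s$stim, nrow = 1),
                 sacc = matrix(s$sacc, nrow = 1),
                 stim_time = s$stim_time, sacc_time = s$sacc_time,
                 n_trials_used = s$n_trials_used,
                 baseline_mean = s$baseline_mean,
                 baseline_sd = s$baseline_sd,
                 dropped = character(0)), class = "fef_sdf_set")
}

sdf_set_to_single <- function(x) {
  structure(list(unit_id = x$unit_ids[1],
                 stim = x$stim[1, ], sacc = x$sacc[1, ],
                 stim_time = x$stim_time, sacc_time = x$sacc_time,
                 n_trials_used = x$n_trials_used[1],
                 baseline_mean = x$baseline_mean[1],
                 baseline_sd = x$baseline_sd[1]), class = "fef_sdf")
}

#' The six measurement epochs
#'
#' Half-open `[start, end)` intervals in ms: the pre-stimulus baseline
#' (-200, -100), early (50, 100) and late (100, 150) visual epochs
#' anchored to stimulus onset, early (-100, -50) and late (-50, 0)
#' presaccadic epochs and the postsaccadic epoch (50, 100) anchored to the
#' saccade.
#' @return tibble `epoch`, `anchor`, `start`, `end`.
#' @export
epoch_set <- function() {
  tibble::tribble(
    ~epoch, ~anchor, ~start, ~end,
    "baseline",       "stimulus", -200, -100,
    "early_visual",   "stimulus",   50,  100,
    "late_visual",    "stimulus",  100,  150,
    "early_presacc",  "saccade",  -100,  -50,
    "late_presacc",   "saccade",   -50,    0,
    "postsacc",       "saccade",    50,  100
  )
}

epoch_values <- function(sdf_set, anchor, start, end) {
  if (anchor == "stimulus") {
    idx <- sdf_set$stim_time >= start & sdf_set$stim_time < end
    sdf_set$stim[, idx, drop = FALSE]
  } else {
    idx <- sdf_set$sacc_time >= start & sdf_set$sacc_time < end
    sdf_set$sacc[, idx, drop = FALSE]
  }
}

#' Measure response features from scaled SDFs
#'
#' `mean` takes the mean rate in each of the six epochs (6 features);
#' `slope` the change across each epoch, computed as the mean over the last
#' `slope_window` ms minus the mean over the first `slope_window` ms
#' (6 features); `mean_and_slope` concatenates means then slopes (12); and
#' `sdf` uses every sample of the stimulus-aligned (-200..300 ms) and
#' saccade-aligned (-300..200 ms) SDFs (1002 features).
#'
#' @param sdf_set a (scaled) `fef_sdf_set`.
#' @param measurement one of [measurement_names()].
#' @param epochs an [epoch_set()].
#' @param slope_window endpoint-window width for the slope measurement, ms.
#' @return numeric matrix units x features with provenance column names.
#' @export
measure_features <- function(sdf_set, measurement = measurement_names(),
                             epochs = epoch_set(), slope_window = 10) {
  measurement <- match.arg(measurement)
  check_epoch_coverage(sdf_set, epochs)
  mean_mat <- function() {
    m <- vapply(seq_len(nrow(epochs)), function(i) {
      rowMeans(epoch_values(sdf_set, epochs$anchor[i], epochs$start[i],
                            epochs$end[i]))
    }, numeric(length(sdf_set$unit_ids)))
    m <- matrix(m, nrow = length(sdf_set$unit_ids))
    colnames(m) <- paste0("mean:", epochs$epoch)
    m
  }
  slope_mat <- function() {
    m <- vapply(seq_len(nrow(epochs)), function(i) {
      head_m <- rowMeans(epoch_values(sdf_set, epochs$anchor[i],
                                      epochs$start[i],
                                      epochs$start[i] + slope_window))
      tail_m <- rowMeans(epoch_values(sdf_set, epochs$anchor[i],
                                      epochs$end[i] - slope_window,
                                      epochs$end[i]))
      tail_m - head_m
    }, numeric(length(sdf_set$unit_ids)))
    m <- matrix(m, nrow = length(sdf_set$unit_ids))
    colnames(m) <- paste0("slope:", epochs$epoch)
    m
  }
  out <- switch(measurement,
    mean = mean_mat(),
    slope = slope_mat(),
    mean_and_slope = cbind(mean_mat(), slope_mat()),
    sdf = {
      m <- cbind(sdf_set$stim, sdf_set$sacc)
      colnames(m) <- c(paste0("sdf:stim:", sdf_set$stim_time),
                       paste0("sdf:sacc:", sdf_set$sacc_time))
      m
    })
  rownames(out) <- sdf_set$unit_ids
  out
}

check_epoch_coverage <- function(sdf_set, epochs) {
  for (i in seq_len(nrow(epochs))) {
    tm <- if (epochs$anchor[i] == "stimulus") sdf_set$stim_time
          else sdf_set$sacc_time
    if (epochs$start[i] < min(tm) || epochs$end[i] > max(tm) + 1) {
      stop_bad_arg("SDF window does not cover epoch '%s' [%g, %g)",
                   epochs$epoch[i], epochs$start[i], epochs$end[i])
    }
  }
}

#' z-score each feature across the sample
#'
#' Every column is centred and scaled to unit SD across units so all
#' epochs, means, and slopes weigh equally; constant columns map to zeros
#' (keeping them inert under Euclidean distance).
#'
#' @param features units x features matrix.
#' @return matrix of the same shape.
#' @export
zscore_across_sample <- function(features) {
  if (nrow(features) < 2L) stop_bad_arg("need at least 2 units to z-score")
  m <- colMeans(features)
  s <- apply(features, 2, stats::sd)
  out <- sweep(features, 2, m)
  keep <- is.finite(s) & s > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, s[keep], "/")
  out[, !keep] <- 0
  out
}

#' Pairwise distance matrix between units
#'
#' Euclidean distance in feature space, or correlation distance
#' `1 - Pearson rho` (range `[0, 2]`). Feature vectors with zero variance
#' have undefined correlation; their distance to every other unit is set to
#' the maximum (2) and they are listed in the `flagged_units` attribute.
#'
#' @param features units x features matrix (no missing values).
#' @param metric `"euclidean"` or `"correlation"`.
#' @return symmetric matrix of class `fef_dist` with zero diagonal and a
#'   `metric` attribute.
#' @export
pairwise_distance <- function(features, metric = metric_names()) {
  metric <- match.arg(metric)
  if (anyNA(features)) stop_bad_arg("feature matrix contains missing values")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(features, method = "euclidean"))
    flagged <- character(0)
  } else {
    sds <- apply(features, 1, stats::sd)
    flat <- sds == 0
    d <- matrix(2, nrow(features), nrow(features))
    if (any(!flat)) {
      ok <- which(!flat)
      d[ok, ok] <- 1 - stats::cor(t(features[ok, , drop = FALSE]))
    }
    diag(d) <- 0
    flagged <- rownames(features)[flat] %||% which(flat)
  }
  rownames(d) <- colnames(d) <- rownames(features)
  attr(d, "metric") <- metric
  attr(d, "flagged_units") <- flagged
  class(d) <- c("fef_dist", class(d))
  d
}

#' Mean cross-unit skewness of scaled SDFs
#'
#' At every time point of the concatenated aligned SDFs, the sample
#' skewness of the scaled values across units is computed; the mean over
#' time points summarizes how equitable the scaling is for cross-unit
#' comparison (smaller is better).
#'
#' @param sdf_set a (scaled) `fef_sdf_set` with at least 3 units.
#' @return scalar skewness index.
#' @export
skewness_index <- function(sdf_set) {
  if (length(sdf_set$unit_ids) < 3L) {
    stop_bad_arg("skewness index requires at least 3 units")
  }
  both <- cbind(sdf_set$stim, sdf_set$sacc)
  mean(apply(both, 2, sample_skewness), na.rm = TRUE)
}

#' Run the full preprocessing grid to distance matrices
#'
#' For each pipeline in the grid: scale the SDFs, measure features,
#' z-score each feature across the sample, and compute the pairwise
#' distance matrix. Scaled sets and feature matrices are cached across
#' pipelines sharing them.
#'
#' @param sdf_set a `fef_sdf_set`.
#' @param grid a [pipeline_grid()].
#' @param epochs an [epoch_set()].
#' @return named list of `fef_dist` matrices, one per pipeline row.
#' @export
compute_pipeline_distances <- function(sdf_set, grid = pipeline_grid(),
                                       epochs = epoch_set()) {
  scaled_cache <- list()
  feat_cache <- list()
  out <- vector("list", nrow(grid))
  names(out) <- grid$pipeline
  for (i in seq_len(nrow(grid))) {
    sc <- grid$scaler[i]
    if (is.null(scaled_cache[[sc]])) scaled_cache[[sc]] <- scale_sdf(sdf_set, sc)
    key <- paste(sc, grid$measurement[i])
    if (is.null(feat_cache[[key]])) {
      feat_cache[[key]] <- zscore_across_sample(
        measure_features(scaled_cache[[sc]], grid$measurement[i], epochs))
    }
    d <- pairwise_distance(feat_cache[[key]], grid$metric[i])
    attr(d, "pipeline") <- grid$pipeline[i]
    out[[i]] <- d
  }
  out
}
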