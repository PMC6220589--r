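#' Spike width of a mean action-potential waveform
#'
#' Width is the time between the initial trough and the following peak for
#' negative-leading spikes, or between the initial peak and the following
#' trough for positive-leading spikes. Polarity is decided by which global
#' extremum occurs first.
#'
#' @param waveforms matrix (one row per spike) with a `time_us` attribute,
#'   or a mean-waveform vector plus `sample_us`.
#' @param sample_us sampling period in microseconds (used when `waveforms`
#'   lacks a `time_us` attribute).
#' @return width in microseconds.
#' @export
spike_width <- function(waveforms, sample_us = attr(waveforms, "sample_us") %||% 25) {
  m <- if (is.matrix(waveforms)) colMeans(waveforms) else as.numeric(waveforms)
  t_us <- attr(waveforms, "time_us") %||% ((seq_along(m) - 1L) * sample_us)
  i_min <- which.min(m); i_max <- which.max(m)
  if (i_min < i_max) {
    j <- i_min + which.max(m[i_min:length(m)]) - 1L   # trough then peak
    t_us[j] - t_us[i_min]
  } else {
    j <- i_max + which.min(m[i_max:length(m)]) - 1L   # peak then trough
    t_us[j] - t_us[i_max]
  }
}

# CV2 / LV / LVR terms operate on consecutive ISI pairs within a trial.
isi_pairs <- function(unit) {
  out <- lapply(unit$trials$spikes, function(s) {
    if (length(s) < 3L) return(NULL)
    isi <- diff(s)
    cbind(isi[-length(isi)], isi[-1])
  })
  do.call(rbind, out)
}

#' Biophysical spike-train features of a unit
#'
#' Computes the interspike-interval variability metrics (CV, CV2, LV, and
#' LVR with a 5 ms refractory constant), the Fano factor of spike counts in
#' 100 ms bins, and the spike width of the mean waveform. Each metric is
#' about 1 for a stationary Poisson process. Metrics whose data are
#' insufficient (fewer than 2 ISIs, or no waveforms) are `NA`, never
#' fabricated.
#'
#' @param unit a `fef_unit`.
#' @param refractory_ms LVR refractory constant, ms.
#' @param fano_bin_ms Fano-factor bin width, ms.
#' @return one-row tibble: `unit_id`, `spike_width_us`, `cv`, `cv2`, `lv`,
#'   `lvr`, `fano`.
#' @export
biophysical_features <- function(unit, refractory_ms = 5, fano_bin_ms = 100) {
  isis <- unit_isis(unit)
  cv <- if (length(isis) >= 2L) stats::sd(isis) / mean(isis) else NA_real_

  pr <- isi_pairs(unit)
  cv2 <- lv <- lvr <- NA_real_
  if (!is.null(pr) && nrow(pr) >= 1L) {
    s <- pr[, 1] + pr[, 2]
    d <- pr[, 1] - pr[, 2]
    cv2 <- mean(2 * abs(d) / s)
    lv <- mean(3 * (d / s)^2)
    lvr <- mean(3 * (1 - 4 * pr[, 1] * pr[, 2] / s^2) *
                  (1 + 4 * refractory_ms / s))
  }

  fano <- fano_factor(unit, fano_bin_ms)
  width <- if (!is.null(unit$waveforms)) spike_width(unit$waveforms) else NA_real_

  tibble::tibble(unit_id = unit$unit_id, spike_width_us = width,
                 cv = cv, cv2 = cv2, lv = lv, lvr = lvr, fano = fano)
}

# Spike-count variance / mean over fixed bins pooled across trials, using
# the time span common to all trials so every trial contributes the same
# bins.
fano_factor <- function(unit, bin_ms = 100) {
  tr <- unit$trials
  if (nrow(tr) == 0L) return(NA_real_)
  t_end <- min(tr$saccade_ms + 200)
  nb <- floor(t_end / bin_ms)
  if (nb < 1L) return(NA_real_)
  counts <- unlist(lapply(tr$spikes, function(s) {
    tabulate(pmin(pmax(floor(s / bin_ms) + 1L, 0L), nb)[s < nb * bin_ms & s >= 0],
             nbins = nb)
  }))
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  stats::var(counts) / m
}

#' Mean epoch responses at the eight target locations
#'
#' @param unit a `fef_unit`.
#' @param epoch `"visual"` (50-150 ms after stimulus onset) or
#'   `"movement"` (the 50 ms preceding saccade initiation).
#' @param n_locations task locations.
#' @return tibble `location` (index), `angle_deg`, `rate` (spikes/s,
#'   averaged over correct trials at that location).
#' @export
location_responses <- function(unit, epoch = c("visual", "movement"),
                               n_locations = 8L) {
  epoch <- match.arg(epoch)
  tr <- unit$trials[unit$trials$correct, ]
  win <- if (epoch == "visual") c(50, 150) else c(-50, 0)
  ref <- if (epoch == "visual") tr$stimulus_onset_ms else tr$saccade_ms
  rate_i <- vapply(seq_len(nrow(tr)), function(i) {
    rel <- tr$spikes[[i]] - ref[i]
    sum(rel >= win[1] & rel < win[2]) / diff(win) * 1000
  }, numeric(1))
  out <- tibble::tibble(location = tr$target_location, rate = rate_i)
  out <- dplyr::summarise(dplyr::group_by(out, .data$location),
                          rate = mean(.data$rate), .groups = "drop")
  out$angle_deg <- out$location * (360 / n_locations)
  out[, c("location", "angle_deg", "rate")]
}

#' Fit a circular-domain Gaussian response field
#'
#' Fits `rate(theta) = b + a * exp(-d(theta, mu)^2 / (2 * sigma^2))`, with
#' `d` the angular distance on the circle, to the mean responses at the
#' eight target locations, by least squares with multi-start over candidate
#' centres. Fits with r-squared below 0.5 are flagged invalid, as are
#' degenerate (all-equal) response sets for which r-squared is undefined.
#'
#' @param responses tibble from [location_responses()] (columns `angle_deg`,
#'   `rate`) or a numeric vector of 8 rates at 45-degree spacing.
#' @param epoch label carried into the result.
#' @return one-row tibble of class `fef_tuning_fit`: `epoch`,
#'   `max_response`, `preferred_location` (degrees), `tuning_width`
#'   (degrees), `r2`, `valid`.
#' @export
fit_response_field <- function(responses, epoch = "visual") {
  if (is.numeric(responses)) {
    responses <- tibble::tibble(
      angle_deg = (seq_along(responses) - 1) * 360 / length(responses),
      rate = responses)
  }
  th <- responses$angle_deg
  y <- responses$rate
  sst <- sum((y - mean(y))^2)
  bad <- tibble::tibble(epoch = epoch, max_response = NA_real_,
                        preferred_location = NA_real_,
                        tuning_width = NA_real_, r2 = NA_real_,
                        valid = FALSE)
  if (length(y) < 4L || sst == 0) return(bad)

  sse_fn <- function(p) {
    mu <- p[3] %% 360
    sig <- exp(p[4])
    pred <- p[1] + p[2] * exp(-0.5 * (ang_dist(th, mu) / sig)^2)
    sum((y - pred)^2)
  }
  best <- NULL
  for (mu0 in th) {
    for (sig0 in c(30, 60, 90)) {
      p0 <- c(min(y), max(y) - min(y), mu0, log(sig0))
      fit <- stats::optim(p0, sse_fn, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  r2 <- 1 - best$value / sst
  p <- best$par
  tibble::tibble(epoch = epoch,
                 max_response = p[1] + p[2],
                 preferred_location = p[3] %% 360,
                 tuning_width = exp(p[4]),
                 r2 = r2,
                 valid = is.finite(r2) && r2 >= 0.5)
}
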