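#' Screening thresholds for unit isolation quality
#'
#' Defaults follow the recording-quality cascade: waveform SNR at or above
#' a system-dependent minimum, at most 10% of interspike intervals under
#' 2 ms, mean baseline discharge of at least 5 spikes/s (baseline epoch:
#' -200 to -100 ms before stimulus onset), and a spike density function
#' with nonzero values in both the visual (50-150 ms post-stimulus) and
#' perisaccadic (-50 to +50 ms around the saccade) epochs.
#'
#' @param min_snr minimum waveform signal-to-noise ratio.
#' @param max_isi_violation maximum tolerated fraction of ISIs below
#'   `isi_threshold_ms`.
#' @param isi_threshold_ms refractory bound, ms.
#' @param min_baseline_rate spikes/s.
#' @export
screening_config <- function(min_snr = 2.5,
                             max_isi_violation = 0.10,
                             isi_threshold_ms = 2,
                             min_baseline_rate = 5) {
  list(min_snr = min_snr, max_isi_violation = max_isi_violation,
       isi_threshold_ms = isi_threshold_ms,
       min_baseline_rate = min_baseline_rate)
}

#' Waveform signal-to-noise ratio
#'
#' Peak-to-trough voltage difference of the mean action-potential waveform
#' divided by the SD of the concatenated waveform residuals.
#'
#' @param waveforms matrix, one row per spike.
#' @return scalar SNR.
#' @export
waveform_snr <- function(waveforms) {
  m <- colMeans(waveforms)
  resid <- sweep(waveforms, 2, m)
  (max(m) - min(m)) / stats::sd(as.vector(resid))
}

unit_isis <- function(unit) {
  unlist(lapply(unit$trials$spikes, function(s) if (length(s) > 1) diff(s)),
         use.names = FALSE)
}

# Mean rate (spikes/s) in a stimulus-anchored epoch across correct trials.
epoch_rate <- function(unit, start, end, anchor = "stimulus") {
  tr <- unit$trials[unit$trials$correct, ]
  if (nrow(tr) == 0L) return(NA_real_)
  ref <- if (anchor == "stimulus") tr$stimulus_onset_ms else tr$saccade_ms
  counts <- vapply(seq_len(nrow(tr)), function(i) {
    rel <- tr$spikes[[i]] - ref[i]
    sum(rel >= start & rel < end)
  }, numeric(1))
  mean(counts) / (end - start) * 1000
}

#' Screen one unit against the isolation-quality criteria
#'
#' Each criterion is evaluated independently and every failure is listed in
#' `reasons`; `included` is true iff all applicable criteria pass. Units
#' without waveforms skip the SNR criterion (noted in `reasons` as
#' `"snr_unavailable"`, which does not exclude the unit). Screening never
#' throws on a bad unit.
#'
#' @param unit a `fef_unit`.
#' @param thresholds a [screening_config()].
#' @param sdf optional precomputed `fef_sdf` used for the nonzero-epoch
#'   checks; computed on the fly when absent (and skipped, without
#'   exclusion, if no stable estimate exists — the SDF stage drops such
#'   units itself).
#' @return one-row tibble: `unit_id`, `snr`, `isi_violation_fraction`,
#'   `baseline_rate`, `nonzero_visual_epoch`, `nonzero_perisaccadic_epoch`,
#'   `included`, `reasons` (comma-joined).
#' @export
screen_unit <- function(unit, thresholds = screening_config(), sdf = NULL) {
  reasons <- character(0)

  snr <- NA_real_
  if (is.null(unit$waveforms)) {
    reasons <- c(reasons, "snr_unavailable")
  } else {
    snr <- waveform_snr(unit$waveforms)
    if (snr < thresholds$min_snr) reasons <- c(reasons, "snr")
  }

  isis <- unit_isis(unit)
  isi_frac <- if (length(isis)) mean(isis < thresholds$isi_threshold_ms) else NA_real_
  if (is.finite(isi_frac) && isi_frac > thresholds$max_isi_violation) {
    reasons <- c(reasons, "isi")
  }

  base <- epoch_rate(unit, -200, -100, "stimulus")
  if (!is.finite(base) || base < thresholds$min_baseline_rate) {
    reasons <- c(reasons, "baseline_rate")
  }

  if (is.null(sdf)) {
    sdf <- tryCatch(compute_sdf(unit), fef_unstable_sdf = function(e) NULL,
                    error = function(e) NULL)
  }
  nz_vis <- NA; nz_peri <- NA
  if (!is.null(sdf)) {
    vis_idx <- sdf$stim_time >= 50 & sdf$stim_time < 150
    peri_idx <- sdf$sacc_time >= -50 & sdf$sacc_time < 50
    nz_vis <- any(sdf$stim[vis_idx] > 0)
    nz_peri <- any(sdf$sacc[peri_idx] > 0)
    if (!nz_vis && !nz_peri) reasons <- c(reasons, "zero_epochs")
  }

  excluding <- setdiff(reasons, "snr_unavailable")
  tibble::tibble(
    unit_id = unit$unit_id,
    snr = snr,
    isi_violation_fraction = isi_frac,
    baseline_rate = base,
    nonzero_visual_epoch = nz_vis,
    nonzero_perisaccadic_epoch = nz_peri,
    included = length(excluding) == 0L,
    reasons = paste(reasons, collapse = ",")
  )
}

#' Screen a whole population
#'
#' @param population `fef_population` or list of `fef_unit`s.
#' @inheritParams screen_unit
#' @return tibble with one [screen_unit()] row per unit.
#' @export
screen_population <- function(population, thresholds = screening_config()) {
  units <- if (inherits(population, "fef_population")) population$units
           else population
  dplyr::bind_rows(lapply(units, screen_unit, thresholds = thresholds))
}
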