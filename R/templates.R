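#' Build firing-rate templates for the planted response archetypes
#'
#' A rate template describes one functional archetype of frontal eye field
#' activity during a memory-guided saccade: a baseline rate, a visual
#' transient locked to stimulus onset, optional sustained delay-period
#' activity, a presaccadic ramp with either a "clipped" (abrupt) or slow
#' postsaccadic return to baseline, an optional postsaccadic transient, and
#' optional perisaccadic suppression. Visual and delay terms are anchored to
#' stimulus onset; motor, transient and suppression terms to saccade
#' initiation. The trial rate is the rectified sum of all terms.
#'
#' With `config = "default"` the built-in library returns one template per
#' consensus functional category: two visual-only cells distinguished by
#' peak latency (74 vs 136 ms, the latter with delay activity), four
#' visuomovement cells crossing early/late visual peaks (70 vs 161 ms) with
#' clipped vs unclipped saccadic discharge and with/without delay activity,
#' a visual cell with a strong postsaccadic transient, a near-pure movement
#' cell with slow postsaccadic decay, a visual-"off" cell with a clipped
#' presaccadic ramp, and a fixation-like cell sharply suppressed around the
#' saccade.
#'
#' @param config either the string `"default"` for the built-in archetype
#'   library, or a data frame / tibble with one row per template supplying
#'   any subset of the template fields (missing fields take the neutral
#'   defaults of [rate_template()]).
#' @return A tibble of class `fef_templates`, one row per template.
#' @examples
#' tpl <- make_category_templates()
#' nrow(tpl)
#' @export
make_category_templates <- function(config = "default") {
  if (is.character(config) && length(config) == 1L && config == "default") {
    return(default_template_library())
  }
  if (!is.data.frame(config)) {
    stop_bad_arg("`config` must be \"default\" or a data frame of template fields")
  }
  rows <- lapply(seq_len(nrow(config)), function(i) {
    do.call(rate_template, as.list(config[i, , drop = FALSE]))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fef_templates", class(out))
  out
}

#' Construct a single rate template
#'
#' All rate and width parameters are magnitudes (>= 0); the sign of the
#' visual response is carried by `visual_sign` so that "off" cells (a dip in
#' rate after stimulus onset) are representable without negative rate
#' parameters. See [make_category_templates()] for the meaning of each term.
#'
#' @param name label for the archetype.
#' @param baseline_rate tonic rate, spikes/s.
#' @param visual_peak_rate,visual_peak_latency,visual_width amplitude
#'   (spikes/s), peak time (ms after stimulus onset) and Gaussian width (ms)
#'   of the visual transient.
#' @param visual_sign `+1` for an excitatory transient, `-1` for an "off"
#'   (suppressive) visual response.
#' @param delay_rate sustained rate (spikes/s) from the end of the visual
#'   transient until the saccade.
#' @param ramp_onset,ramp_peak_rate,ramp_peak_time presaccadic ramp: onset
#'   (ms before saccade, positive), peak amplitude (spikes/s) and peak time
#'   (ms relative to saccade; negative = before).
#' @param clipped if `TRUE` the saccadic discharge collapses to baseline
#'   within ~10 ms of its peak; otherwise it decays with `postsacc_tau`.
#' @param postsacc_tau exponential decay constant (ms) of unclipped
#'   saccadic discharge.
#' @param postsacc_transient_rate,postsacc_transient_latency amplitude and
#'   latency (ms after saccade) of a postsaccadic burst.
#' @param suppression_depth,suppression_width perisaccadic suppression:
#'   depth (spikes/s, subtracted) and Gaussian width (ms) centred on the
#'   saccade.
#' @param spike_width_us action-potential trough-to-peak width, microseconds.
#' @param polarity `"negative-leading"` or `"positive-leading"` waveform.
#' @param tuning_width Gaussian receptive-field width (degrees) used to
#'   attenuate modulation at non-preferred target locations.
#' @return one-row tibble of class `fef_templates`.
#' @export
rate_template <- function(name = "template",
                          baseline_rate = 10,
                          visual_peak_rate = 0,
                          visual_peak_latency = 100,
                          visual_width = 20,
                          visual_sign = 1,
                          delay_rate = 0,
                          ramp_onset = 100,
                          ramp_peak_rate = 0,
                          ramp_peak_time = 0,
                          clipped = TRUE,
                          postsacc_tau = 80,
                          postsacc_transient_rate = 0,
                          postsacc_transient_latency = 40,
                          suppression_depth = 0,
                          suppression_width = 50,
                          spike_width_us = 250,
                          polarity = "negative-leading",
                          tuning_width = 60) {
  for (nm in c("baseline_rate", "visual_peak_rate", "visual_width",
               "delay_rate", "ramp_onset", "ramp_peak_rate", "postsacc_tau",
               "postsacc_transient_rate", "postsacc_transient_latency",
               "suppression_depth", "suppression_width", "tuning_width")) {
    assert_scalar_number(get(nm), nm, min = 0)
  }
  assert_scalar_number(visual_peak_latency, "visual_peak_latency", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(spike_width_us, "spike_width_us", min = 0,
                       strict_min = TRUE)
  if (!visual_sign %in% c(-1, 1)) stop_bad_arg("`visual_sign` must be +1 or -1")
  polarity <- match.arg(polarity, c("negative-leading", "positive-leading"))
  out <- tibble::tibble(
    name = as.character(name),
    baseline_rate = baseline_rate,
    visual_peak_rate = visual_peak_rate,
    visual_peak_latency = visual_peak_latency,
    visual_width = visual_width,
    visual_sign = visual_sign,
    delay_rate = delay_rate,
    ramp_onset = ramp_onset,
    ramp_peak_rate = ramp_peak_rate,
    ramp_peak_time = ramp_peak_time,
    clipped = isTRUE(clipped),
    postsacc_tau = postsacc_tau,
    postsacc_transient_rate = postsacc_transient_rate,
    postsacc_transient_latency = postsacc_transient_latency,
    suppression_depth = suppression_depth,
    suppression_width = suppression_width,
    spike_width_us = spike_width_us,
    polarity = polarity,
    tuning_width = tuning_width
  )
  class(out) <- c("fef_templates", class(out))
  out
}

default_template_library <- function() {
  out <- dplyr::bind_rows(
    rate_template("vis_early", baseline_rate = 10, visual_peak_rate = 80,
                  visual_peak_latency = 74, visual_width = 15),
    rate_template("vis_late_delay", baseline_rate = 10, visual_peak_rate = 70,
                  visual_peak_latency = 136, visual_width = 22,
                  delay_rate = 25, suppression_depth = 6,
                  suppression_width = 40),
    rate_template("vm_early_clipped", baseline_rate = 10,
                  visual_peak_rate = 70, visual_peak_latency = 70,
                  visual_width = 15, ramp_onset = 100, ramp_peak_rate = 60,
                  ramp_peak_time = 0, clipped = TRUE),
    rate_template("vm_late_unclipped", baseline_rate = 10,
                  visual_peak_rate = 70, visual_peak_latency = 161,
                  visual_width = 25, ramp_onset = 120, ramp_peak_rate = 60,
                  ramp_peak_time = 20, clipped = FALSE, postsacc_tau = 70),
    rate_template("vis_postsacc", baseline_rate = 10, visual_peak_rate = 30,
                  visual_peak_latency = 80, visual_width = 18,
                  postsacc_transient_rate = 70,
                  postsacc_transient_latency = 45),
    rate_template("vm_clipped_nodelay", baseline_rate = 10,
                  visual_peak_rate = 25, visual_peak_latency = 140,
                  visual_width = 25, ramp_onset = 100, ramp_peak_rate = 70,
                  ramp_peak_time = 0, clipped = TRUE),
    rate_template("vm_clipped_delay", baseline_rate = 10,
                  visual_peak_rate = 25, visual_peak_latency = 140,
                  visual_width = 25, delay_rate = 18, ramp_onset = 100,
                  ramp_peak_rate = 70, ramp_peak_time = 0, clipped = TRUE),
    rate_template("mov_unclipped", baseline_rate = 10, visual_peak_rate = 8,
                  visual_peak_latency = 110, visual_width = 25,
                  ramp_onset = 150, ramp_peak_rate = 65, ramp_peak_time = 40,
                  clipped = FALSE, postsacc_tau = 130,
                  spike_width_us = 266),
    rate_template("vis_off_clipped", baseline_rate = 22,
                  visual_peak_rate = 16, visual_peak_latency = 90,
                  visual_width = 30, visual_sign = -1, ramp_onset = 120,
                  ramp_peak_rate = 50, ramp_peak_time = -10, clipped = TRUE,
                  spike_width_us = 174),
    rate_template("fix_suppressed", baseline_rate = 30, visual_peak_rate = 0,
                  suppression_depth = 26, suppression_width = 60)
  )
  class(out) <- c("fef_templates", class(out))
  out
}

#' Evaluate a template's firing rate on a trial
#'
#' Composes the stimulus-anchored (visual transient, delay) and
#' saccade-anchored (ramp, postsaccadic discharge/transient, suppression)
#' terms for one trial and rectifies at zero.
#'
#' @param template one-row template tibble (see [rate_template()]).
#' @param t times (ms, trial clock) at which to evaluate.
#' @param stim_time,sacc_time stimulus onset and saccade initiation on the
#'   trial clock (ms).
#' @param gain multiplicative gain applied to all modulation terms (not the
#'   baseline); used for receptive-field attenuation and unit-level
#'   variability.
#' @return numeric vector of rates, spikes/s, same length as `t`.
#' @export
template_rate <- function(template, t, stim_time, sacc_time, gain = 1) {
  tpl <- as.list(template[1, ])
  ts <- t - stim_time   # stimulus clock
  tm <- t - sacc_time   # saccade clock

  r <- rep(tpl$baseline_rate, length(t))

  if (tpl$visual_peak_rate > 0) {
    vis <- tpl$visual_peak_rate *
      exp(-0.5 * ((ts - tpl$visual_peak_latency) / tpl$visual_width)^2)
    vis[ts < 0] <- 0
    r <- r + gain * tpl$visual_sign * vis
  }

  if (tpl$delay_rate > 0) {
    # sustained activity bridging the visual transient and the saccade
    on_t <- tpl$visual_peak_latency + tpl$visual_width
    rise <- 1 / (1 + exp(-(ts - on_t) / 15))
    fall <- 1 / (1 + exp(tm / 15))
    r <- r + gain * tpl$delay_rate * rise * fall
  }

  if (tpl$ramp_peak_rate > 0) {
    ramp <- numeric(length(t))
    up <- tm >= -tpl$ramp_onset & tm <= tpl$ramp_peak_time
    ramp[up] <- tpl$ramp_peak_rate *
      (tm[up] + tpl$ramp_onset) / (tpl$ramp_onset + tpl$ramp_peak_time)
    post <- tm > tpl$ramp_peak_time
    if (isTRUE(tpl$clipped)) {
      # collapse to baseline within 10 ms of the peak
      dp <- tm[post] - tpl$ramp_peak_time
      ramp[post] <- tpl$ramp_peak_rate * pmax(0, 1 - dp / 10)
    } else {
      ramp[post] <- tpl$ramp_peak_rate *
        exp(-(tm[post] - tpl$ramp_peak_time) / tpl$postsacc_tau)
    }
    r <- r + gain * ramp
  }

  if (tpl$postsacc_transient_rate > 0) {
    tr <- tpl$postsacc_transient_rate *
      exp(-0.5 * ((tm - tpl$postsacc_transient_latency) / 15)^2)
    tr[tm < 0] <- 0
    r <- r + gain * tr
  }

  if (tpl$suppression_depth > 0) {
    r <- r - gain * tpl$suppression_depth *
      exp(-0.5 * (tm / tpl$suppression_width)^2)
  }

  pmax(r, 0)
}
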