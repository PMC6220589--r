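#' Describe a synthetic population of task-aligned units
#'
#' Bundles everything needed to generate a seeded population with planted
#' category structure: the template library, units per template, the
#' right-skewed per-unit trial-count distribution (discretized log-normal
#' pinned at the target median and truncated to `[min, max]`), the
#' memory-guided-saccade task geometry (eight target locations at 45deg
#' spacing, 8deg eccentricity, 300-800 ms variable delay), and the
#' unit-to-unit variability applied around each template.
#'
#' @param templates tibble of rate templates ([make_category_templates()]).
#' @param units_per_template units simulated per template.
#' @param trial_counts `(min, median, max)` per-unit counts of
#'   receptive-field trials.
#' @param delay_range uniform delay between stimulus onset and the go
#'   signal, ms.
#' @param n_locations,eccentricity task geometry (locations on a circle).
#' @param trials_per_other_location trials simulated at each non-preferred
#'   location (feeds response-field fits only; the SDF uses RF trials).
#' @param p_error probability a trial is flagged incorrect.
#' @param unit_gain_sd,baseline_sd log-normal SDs of per-unit modulation
#'   gain and baseline scaling.
#' @param latency_jitter_sd SD (ms) of per-unit visual peak-latency jitter.
#' @param waveform_n,waveform_noise_sd spikes per simulated waveform matrix
#'   and per-sample noise SD (uV).
#' @param seed integer RNG seed for the whole population.
#' @return list of class `fef_population_spec`.
#' @export
population_spec <- function(templates = make_category_templates(),
                            units_per_template = 20,
                            trial_counts = c(min = 4, median = 34, max = 317),
                            delay_range = c(300, 800),
                            n_locations = 8,
                            eccentricity = 8,
                            trials_per_other_location = 3,
                            p_error = 0.05,
                            unit_gain_sd = 0.15,
                            baseline_sd = 0.15,
                            latency_jitter_sd = 5,
                            waveform_n = 150,
                            waveform_noise_sd = 10,
                            seed = 1L) {
  if (!is.data.frame(templates) || nrow(templates) < 1L) {
    stop_bad_arg("`templates` must contain at least one rate template")
  }
  if (units_per_template < 1L) stop_bad_arg("`units_per_template` must be >= 1")
  tc <- unname(trial_counts)
  if (length(tc) != 3L || !(tc[1] <= tc[2] && tc[2] <= tc[3])) {
    stop_bad_arg("`trial_counts` must satisfy min <= median <= max")
  }
  structure(list(
    templates = templates,
    units_per_template = as.integer(units_per_template),
    trial_counts = c(min = tc[1], median = tc[2], max = tc[3]),
    delay_range = delay_range,
    n_locations = as.integer(n_locations),
    eccentricity = eccentricity,
    trials_per_other_location = as.integer(trials_per_other_location),
    p_error = p_error,
    unit_gain_sd = unit_gain_sd,
    baseline_sd = baseline_sd,
    latency_jitter_sd = latency_jitter_sd,
    waveform_n = as.integer(waveform_n),
    waveform_noise_sd = waveform_noise_sd,
    seed = as.integer(seed)
  ), class = "fef_population_spec")
}

# Right-skewed trial counts: log-normal with median pinned to the target,
# rounded and truncated to [min, max].
draw_trial_counts <- function(n, counts, sdlog = 0.8) {
  x <- round(stats::rlnorm(n, meanlog = log(counts[["median"]]), sdlog = sdlog))
  pmin(pmax(x, counts[["min"]]), counts[["max"]])
}

#' Simulate one unit's task-aligned spike trains
#'
#' Trials follow the memory-guided saccade timeline: fixation from t = 0,
#' stimulus flash at 500 ms, a variable delay drawn uniformly from
#' `delay_range`, then a saccade 150-250 ms after the go signal. Spikes are
#' an inhomogeneous Poisson realization of the template's trial rate,
#' generated by thinning. `n_trials` trials are placed at the unit's
#' receptive-field location; modulation at other locations is attenuated by
#' the template's Gaussian tuning.
#'
#' @param template one-row rate template.
#' @param n_trials number of receptive-field trials (>= 1).
#' @param seed integer seed; identical inputs give identical output.
#' @param rf_location receptive-field location index, `0 .. n_locations-1`.
#' @param delay_range,n_locations task parameters.
#' @param trials_per_other_location trials at each non-RF location.
#' @param p_error probability a trial is flagged incorrect.
#' @param waveform_n,waveform_noise_sd if `waveform_n > 0`, a waveform
#'   matrix is attached via [simulate_waveforms()].
#' @return object of class `fef_unit`: a list with `unit_id`, `rf_location`,
#'   a `trials` tibble (one row per trial, spike times in a list column),
#'   optional `waveforms` matrix (uV, one row per spike), and
#'   `ground_truth_label`.
#' @export
simulate_unit <- function(template, n_trials, seed,
                          rf_location = 0L,
                          delay_range = c(300, 800),
                          n_locations = 8L,
                          trials_per_other_location = 0L,
                          p_error = 0,
                          waveform_n = 0L,
                          waveform_noise_sd = 10,
                          unit_id = template$name[1]) {
  if (n_trials < 1L) stop_bad_arg("`n_trials` must be >= 1")
  with_seed(seed, {
    locs <- c(rep(rf_location, n_trials),
              rep(setdiff(seq_len(n_locations) - 1L, rf_location),
                  each = trials_per_other_location))
    n_all <- length(locs)
    stim <- rep(500, n_all)
    delay <- stats::runif(n_all, delay_range[1], delay_range[2])
    rt <- stats::runif(n_all, 150, 250)
    sacc <- stim + delay + rt
    correct <- stats::runif(n_all) >= p_error
    ang <- ang_dist(locs * (360 / n_locations),
                    rf_location * (360 / n_locations))
    gain <- exp(-0.5 * (ang / template$tuning_width[1])^2)

    spikes <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      spikes[[i]] <- draw_poisson_spikes(template, stim[i], sacc[i], gain[i])
    }
    wf <- NULL
    if (waveform_n > 0L) {
      wf <- simulate_waveforms(template, waveform_n, waveform_noise_sd,
                               seed = child_seed(seed, 104729L))
    }
    structure(list(
      unit_id = as.character(unit_id),
      rf_location = as.integer(rf_location),
      ground_truth_label = template$name[1],
      trials = tibble::tibble(
        trial_id = seq_len(n_all),
        target_location = as.integer(locs),
        stimulus_onset_ms = stim,
        saccade_ms = sacc,
        correct = correct,
        spikes = spikes
      ),
      waveforms = wf
    ), class = "fef_unit")
  })
}

# Inhomogeneous Poisson spike times on [0, sacc + 400] by thinning.
draw_poisson_spikes <- function(template, stim, sacc, gain) {
  t_end <- sacc + 400
  # rate upper bound: baseline plus the sum of all excitatory magnitudes
  rmax <- template$baseline_rate[1] + gain *
    (template$visual_peak_rate[1] + template$delay_rate[1] +
     template$ramp_peak_rate[1] + template$postsacc_transient_rate[1])
  rmax <- max(rmax, 1e-9)
  n_cand <- stats::rpois(1, rmax * t_end / 1000)
  if (n_cand == 0L) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, t_end))
  keep <- stats::runif(n_cand) <
    template_rate(template, cand, stim, sacc, gain) / rmax
  unique(cand[keep])
}

#' Simulate a population with planted category labels
#'
#' Realizes `units_per_template` units per template under the spec's task
#' parameters. Each unit perturbs its template (log-normal modulation gain
#' and baseline scaling, Gaussian jitter of the visual peak latency) so that
#' within-category units vary the way repeated recordings of one functional
#' type do, then draws its trial count from the skewed distribution and its
#' receptive field uniformly among the locations.
#'
#' @param spec a [population_spec()].
#' @return list of class `fef_population` with elements `units` (list of
#'   `fef_unit`) and `truth` (tibble `unit_id`, `label` of class
#'   `fef_categorization`).
#' @export
simulate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "fef_population_spec"))
  tpls <- spec$templates
  n_units <- nrow(tpls) * spec$units_per_template
  units <- vector("list", n_units)
  ids <- character(n_units)
  labels <- character(n_units)
  k <- 0L
  with_seed(spec$seed, {
    counts <- draw_trial_counts(n_units, spec$trial_counts)
    rfs <- sample.int(spec$n_locations, n_units, replace = TRUE) - 1L
    gains <- stats::rlnorm(n_units, 0, spec$unit_gain_sd)
    bases <- stats::rlnorm(n_units, 0, spec$baseline_sd)
    lat_jit <- stats::rnorm(n_units, 0, spec$latency_jitter_sd)
    for (ti in seq_len(nrow(tpls))) {
      for (ui in seq_len(spec$units_per_template)) {
        k <- k + 1L
        tpl <- tpls[ti, ]
        tpl$baseline_rate <- tpl$baseline_rate * bases[k]
        tpl$visual_peak_rate <- tpl$visual_peak_rate * gains[k]
        tpl$delay_rate <- tpl$delay_rate * gains[k]
        tpl$ramp_peak_rate <- tpl$ramp_peak_rate * gains[k]
        tpl$postsacc_transient_rate <- tpl$postsacc_transient_rate * gains[k]
        # suppression is bounded by the cell's own baseline, so its depth
        # scales with the baseline rather than the excitatory gain
        tpl$suppression_depth <- tpl$suppression_depth * bases[k]
        tpl$visual_peak_latency <- max(1, tpl$visual_peak_latency + lat_jit[k])
        id <- sprintf("u%03d_%s", k, tpls$name[ti])
        units[[k]] <- simulate_unit(
          tpl, counts[k], seed = child_seed(spec$seed, k),
          rf_location = rfs[k], delay_range = spec$delay_range,
          n_locations = spec$n_locations,
          trials_per_other_location = spec$trials_per_other_location,
          p_error = spec$p_error,
          waveform_n = spec$waveform_n,
          waveform_noise_sd = spec$waveform_noise_sd,
          unit_id = id
        )
        units[[k]]$ground_truth_label <- tpls$name[ti]
        ids[k] <- id
        labels[k] <- tpls$name[ti]
      }
    }
  })
  truth <- new_categorization(tibble::tibble(unit_id = ids, label = labels),
                              provenance = "truth")
  structure(list(units = units, truth = truth, spec = spec),
            class = "fef_population")
}

#' @export
print.fef_population <- function(x, ...) {
  cat(sprintf("<fef_population> %d units, %d planted categories, seed %d\n",
              length(x$units), length(unique(x$truth$label)), x$spec$seed))
  invisible(x)
}

#' Simulate action-potential waveforms
#'
#' Generates `n_spikes` noisy realizations of a biphasic waveform whose
#' leading and trailing deflections are separated by the template's spike
#' width. Negative-leading spikes have a 100 uV trough followed by a 50 uV
#' peak (peak-to-trough amplitude 150 uV); positive-leading spikes are the
#' mirror image, so the width is measured peak-to-trough instead.
#'
#' @param template one-row rate template (uses `spike_width_us`, `polarity`).
#' @param n_spikes rows of the returned matrix (>= 1).
#' @param noise_sd per-sample Gaussian noise SD, uV (> 0; use a tiny value
#'   for a near-noiseless waveform).
#' @param seed integer seed.
#' @param sample_us sampling period, microseconds (40 kHz default).
#' @return numeric matrix `n_spikes x n_samples` with attributes
#'   `sample_us` and `time_us`.
#' @export
simulate_waveforms <- function(template, n_spikes, noise_sd = 10, seed = 1L,
                               sample_us = 25) {
  if (n_spikes < 1L) stop_bad_arg("`n_spikes` must be >= 1")
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_bad_arg("`noise_sd` must be > 0")
  }
  width <- template$spike_width_us[1]
  t_us <- seq(0, 400 + width + 600, by = sample_us)
  first_at <- 400
  shape <- -100 * exp(-0.5 * ((t_us - first_at) / 60)^2) +
    50 * exp(-0.5 * ((t_us - first_at - width) / 110)^2)
  if (template$polarity[1] == "positive-leading") shape <- -shape
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n_spikes * length(t_us), 0, noise_sd),
                    nrow = n_spikes)
    w <- matrix(rep(shape, each = n_spikes), nrow = n_spikes) + noise
    attr(w, "sample_us") <- sample_us
    attr(w, "time_us") <- t_us
    w
  })
}
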