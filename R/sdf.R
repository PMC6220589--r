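#' Postsynaptic-potential spike density kernel
#'
#' Causal kernel resembling the postsynaptic influence of a spike: an
#' exponential growth phase (time constant `growth_tau`) multiplied by an
#' exponential decay (`decay_tau`), zero for t < 0, sampled at 1 ms and
#' normalized to unit area so that convolution yields rates in spikes/s.
#'
#' @param growth_tau,decay_tau time constants, ms (both > 0).
#' @param support kernel length, ms; defaults to the point where the tail
#'   is negligible.
#' @return numeric kernel values at t = 0, 1, ... ms, class `fef_kernel`.
#' @export
sdf_kernel <- function(growth_tau = 1, decay_tau = 20,
                       support = ceiling(8 * decay_tau + 5 * growth_tau)) {
  assert_scalar_number(growth_tau, "growth_tau", min = 0, strict_min = TRUE)
  assert_scalar_number(decay_tau, "decay_tau", min = 0, strict_min = TRUE)
  t <- 0:support
  k <- (1 - exp(-t / growth_tau)) * exp(-t / decay_tau)
  k <- k / sum(k)
  structure(k, growth_tau = growth_tau, decay_tau = decay_tau,
            class = "fef_kernel")
}

# Convolve one trial's spike train with the kernel over the grid
# [grid_start, grid_end] (ms relative to the alignment event). Spikes are
# binned at 1 ms and each contributes an exact translated copy of the
# kernel, so the result carries no FFT round-off.
convolve_counts <- function(spike_rel, kernel, grid_start, grid_end) {
  support <- length(kernel) - 1L
  k <- unclass(kernel)
  out <- numeric(grid_end - grid_start + 1L)
  for (sb in floor(spike_rel)) {
    lo <- max(grid_start, sb)
    hi <- min(grid_end, sb + support)
    if (hi < lo) next
    seg <- (lo:hi) - grid_start + 1L
    out[seg] <- out[seg] + k[(lo:hi) - sb + 1L]
  }
  out
}

#' Compute a unit's stimulus- and saccade-aligned spike density functions
#'
#' Convolves each eligible trial's spike train with the kernel and averages
#' across trials, in spikes/s at 1 ms resolution. Eligible trials are
#' correct, have the target at the unit's receptive-field location, and
#' contain at least `min_spikes` spikes; trials failing any filter
#' contribute nothing. With zero eligible trials the estimate is unstable
#' and an error of class `fef_unstable_sdf` is signalled (callers drop the
#' unit). An optional split-half reliability gate (Pearson r of SDFs from
#' two random halves of the trials) can enforce estimate stability; it is
#' off by default.
#'
#' @param unit a `fef_unit`.
#' @param kernel an [sdf_kernel()].
#' @param rf_location receptive-field location filter (defaults to the
#'   unit's own).
#' @param stim_window,sacc_window alignment windows, ms (inclusive ends;
#'   the defaults give 501 samples each).
#' @param min_spikes minimum spikes per eligible trial.
#' @param reliability_threshold if non-`NULL`, minimum split-half Pearson r.
#' @return object of class `fef_sdf`: list with `stim`, `sacc` rate
#'   vectors, their time axes, `n_trials_used`, and baseline statistics
#'   (mean and SD of the stimulus-aligned SDF over the baseline epoch,
#'   -200 to -100 ms).
#' @export
compute_sdf <- function(unit, kernel = sdf_kernel(),
                        rf_location = unit$rf_location,
                        stim_window = c(-200, 300),
                        sacc_window = c(-300, 200),
                        min_spikes = 5,
                        reliability_threshold = NULL) {
  tr <- unit$trials
  n_sp <- vapply(tr$spikes, length, integer(1))
  elig <- which(tr$correct & tr$target_location == rf_location &
                n_sp >= min_spikes)
  if (length(elig) == 0L) {
    stop(structure(class = c("fef_unstable_sdf", "error", "condition"),
                   list(message = sprintf(
                     "unit %s: no eligible trials; spike density estimate is unstable",
                     unit$unit_id), call = NULL)))
  }
  one_side <- function(rows, align, win) {
    acc <- numeric(win[2] - win[1] + 1L)
    for (i in rows) {
      rel <- tr$spikes[[i]] - align[i]
      acc <- acc + convolve_counts(rel, kernel, win[1], win[2])
    }
    1000 * acc / length(rows)
  }
  stim <- one_side(elig, tr$stimulus_onset_ms, stim_window)
  sacc <- one_side(elig, tr$saccade_ms, sacc_window)

  if (!is.null(reliability_threshold) && length(elig) >= 4L) {
    h <- seq_along(elig) %% 2L == 0L
    s1 <- one_side(elig[h], tr$stimulus_onset_ms, stim_window)
    s2 <- one_side(elig[!h], tr$stimulus_onset_ms, stim_window)
    r <- suppressWarnings(stats::cor(s1, s2))
    if (!is.finite(r) || r < reliability_threshold) {
      stop(structure(class = c("fef_unstable_sdf", "error", "condition"),
                     list(message = sprintf(
                       "unit %s: split-half reliability %.2f below threshold",
                       unit$unit_id, r), call = NULL)))
    }
  }

  stim_time <- stim_window[1]:stim_window[2]
  base_idx <- stim_time >= -200 & stim_time < -100
  structure(list(
    unit_id = unit$unit_id,
    stim = stim, sacc = sacc,
    stim_time = stim_time,
    sacc_time = sacc_window[1]:sacc_window[2],
    n_trials_used = length(elig),
    baseline_mean = mean(stim[base_idx]),
    baseline_sd = stats::sd(stim[base_idx])
  ), class = "fef_sdf")
}

#' Compute spike density functions for a whole population
#'
#' Applies [compute_sdf()] to every unit, collecting stable estimates into
#' aligned matrices and recording units dropped as unstable.
#'
#' @param population a `fef_population` or list of `fef_unit`s.
#' @inheritParams compute_sdf
#' @return object of class `fef_sdf_set`: list with `stim` and `sacc`
#'   (units x time matrices, spikes/s), `unit_ids`, time axes,
#'   `n_trials_used`, `baseline_mean`, `baseline_sd`, and `dropped`
#'   (unit ids whose estimate was unstable).
#' @export
compute_sdf_set <- function(population, kernel = sdf_kernel(),
                            stim_window = c(-200, 300),
                            sacc_window = c(-300, 200),
                            min_spikes = 5,
                            reliability_threshold = NULL) {
  units <- if (inherits(population, "fef_population")) population$units
           else population
  res <- list(); dropped <- character(0)
  for (u in units) {
    s <- tryCatch(
      compute_sdf(u, kernel, stim_window = stim_window,
                  sacc_window = sacc_window, min_spikes = min_spikes,
                  reliability_threshold = reliability_threshold),
      fef_unstable_sdf = function(e) NULL)
    if (is.null(s)) dropped <- c(dropped, u$unit_id) else res[[u$unit_id]] <- s
  }
  if (length(res) == 0L) stop_bad_arg("no unit yielded a stable SDF estimate")
  structure(list(
    unit_ids = names(res),
    stim = do.call(rbind, lapply(res, `[[`, "stim")),
    sacc = do.call(rbind, lapply(res, `[[`, "sacc")),
    stim_time = res[[1]]$stim_time,
    sacc_time = res[[1]]$sacc_time,
    n_trials_used = vapply(res, `[[`, integer(1), "n_trials_used"),
    baseline_mean = vapply(res, `[[`, numeric(1), "baseline_mean"),
    baseline_sd = vapply(res, `[[`, numeric(1), "baseline_sd"),
    dropped = dropped
  ), class = "fef_sdf_set")
}

#' @export
print.fef_sdf_set <- function(x, ...) {
  cat(sprintf("<fef_sdf_set> %d units, stim [%d, %d] ms, sacc [%d, %d] ms, %d dropped\n",
              length(x$unit_ids), min(x$stim_time), max(x$stim_time),
              min(x$sacc_time), max(x$sacc_time), length(x$dropped)))
  invisible(x)
}

#' Tidy a spike-density set into a long tibble
#'
#' @param x a `fef_sdf_set`.
#' @param ... unused.
#' @return tibble with columns `unit_id`, `alignment` (`"stimulus"` or
#'   `"saccade"`), `time_ms`, `rate`.
#' @export
tidy.fef_sdf_set <- function(x, ...) {
  n <- length(x$unit_ids)
  dplyr::bind_rows(
    tibble::tibble(
      unit_id = rep(x$unit_ids, each = length(x$stim_time)),
      alignment = "stimulus",
      time_ms = rep(x$stim_time, n),
      rate = as.vector(t(x$stim))),
    tibble::tibble(
      unit_id = rep(x$unit_ids, each = length(x$sacc_time)),
      alignment = "saccade",
      time_ms = rep(x$sacc_time, n),
      rate = as.vector(t(x$sacc)))
  )
}

#' Plot population spike density functions
#'
#' One panel per alignment; optionally averaged within categories.
#'
#' @param object a `fef_sdf_set`.
#' @param categorization optional `fef_categorization` to average within.
#' @param ... unused.
#' @export
autoplot.fef_sdf_set <- function(object, categorization = NULL, ...) {
  df <- tidy.fef_sdf_set(object)
  df$alignment <- factor(df$alignment, c("stimulus", "saccade"))
  if (!is.null(categorization)) {
    df <- dplyr::inner_join(df, categorization, by = "unit_id")
    df <- dplyr::summarise(
      dplyr::group_by(df, .data$label, .data$alignment, .data$time_ms),
      rate = mean(.data$rate), .groups = "drop")
    ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$rate,
                                     colour = .data$label)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~alignment, scales = "free_x") +
      ggplot2::labs(x = "time (ms)", y = "rate (spikes/s)",
                    colour = "category")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$rate,
                                     group = .data$unit_id)) +
      ggplot2::geom_line(alpha = 0.2) +
      ggplot2::facet_wrap(~alignment, scales = "free_x") +
      ggplot2::labs(x = "time (ms)", y = "rate (spikes/s)")
  }
}
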