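test_that("the SDF kernel is causal, non-negative and unit-area", {
  k <- sdf_kernel(1, 20)
  expect_true(all(k >= 0))
  expect_equal(sum(k), 1)
  expect_equal(k[1], 0)  # zero at t = 0: strictly causal rise
  expect_error(sdf_kernel(0, 20), "growth_tau")
  expect_error(sdf_kernel(1, -1), "decay_tau")
})

test_that("a single spike reproduces the translated kernel", {
  k <- sdf_kernel(1, 20)
  u <- make_unit(list(c(550)))  # one spike 50 ms after stimulus onset
  s <- compute_sdf(u, k, min_spikes = 1)
  idx <- which(s$stim_time >= 50)[seq_along(k)]
  idx <- idx[!is.na(idx)]
  expect_equal(s$stim[idx], 1000 * unclass(k)[seq_along(idx)],
               tolerance = 1e-12)
  expect_true(all(s$stim[s$stim_time < 50] == 0))
  expect_true(all(s$stim[s$stim_time >= 50 + length(k)] == 0))
  expect_equal(s$n_trials_used, 1L)
})

test_that("SDF mass is conserved and sparse trials are filtered", {
  k <- sdf_kernel()
  sp <- c(520, 560, 580, 640, 700, 830)
  u <- make_unit(list(sp), stim = 500, sacc = 1100)
  s <- compute_sdf(u, k, stim_window = c(-400, 800), min_spikes = 1)
  expect_equal(sum(s$stim) / 1000, length(sp), tolerance = 1e-6)

  # a 4-spike trial contributes nothing when min_spikes = 5
  u2 <- make_unit(list(sp, c(510, 520, 530, 540)))
  s_both <- compute_sdf(u2)
  s_one <- compute_sdf(make_unit(list(sp)))
  expect_equal(s_both$stim, s_one$stim)
  expect_equal(s_both$n_trials_used, 1L)

  # incorrect trials and wrong-location trials are excluded
  u3 <- make_unit(list(sp, sp), correct = c(TRUE, FALSE))
  expect_equal(compute_sdf(u3)$n_trials_used, 1L)
  u4 <- make_unit(list(sp, sp), location = c(0L, 3L))
  expect_equal(compute_sdf(u4)$n_trials_used, 1L)

  # zero eligible trials: unstable-estimate signal
  u5 <- make_unit(list(c(510, 520)))
  expect_error(compute_sdf(u5), class = "fef_unstable_sdf")
})

test_that("a homogeneous unit's SDF stays within sampling error of its rate", {
  tpl <- rate_template(baseline_rate = 30, visual_peak_rate = 0,
                       ramp_peak_rate = 0)
  u <- simulate_unit(tpl, n_trials = 500, seed = 6)
  s <- compute_sdf(u)
  # per-sample SE from the empirical spread of single-trial SDFs
  singles <- vapply(which(vapply(u$trials$spikes, length, 0L) >= 5),
                    function(i) {
    ui <- make_unit(u$trials$spikes[i], stim = u$trials$stimulus_onset_ms[i],
                    sacc = u$trials$saccade_ms[i])
    compute_sdf(ui, min_spikes = 1)$stim
  }, numeric(501))
  se <- apply(singles, 1, sd) / sqrt(ncol(singles))
  expect_true(all(abs(s$stim - 30) <= 4 * se))
  expect_gte(mean(abs(s$stim - 30) <= 3 * se), 0.95)
})

test_that("population SDF sets collect stable units and drop unstable ones", {
  pop <- small_population()
  sdfs <- compute_sdf_set(pop)
  expect_equal(length(sdfs$unit_ids) + length(sdfs$dropped), 36)
  expect_equal(ncol(sdfs$stim), 501)
  expect_equal(ncol(sdfs$sacc), 501)
  expect_true(all(sdfs$stim >= 0))
  td <- tidy(sdfs)
  expect_equal(nrow(td), length(sdfs$unit_ids) * 1002)
})

test_that("screening applies each exclusion criterion independently", {
  # 11% of ISIs under 2 ms -> excluded for refractory violations
  base <- cumsum(rep(50, 100))
  violent <- sort(c(base, base[1:13] + 1))  # 13 of 112 ISIs < 2 ms
  u <- make_unit(list(violent), stim = 2000, sacc = 4000)
  res <- screen_unit(u)
  expect_false(res$included)
  expect_match(res$reasons, "isi")

  # baseline rate just under 5 spikes/s -> excluded
  trials <- lapply(1:100, function(i) {
    if (i <= 49) c(1810) else numeric(0)
  })
  u2 <- make_unit(trials, stim = 2000, sacc = 3000)
  r2 <- screen_unit(u2)
  expect_equal(r2$baseline_rate, 4.9, tolerance = 1e-9)
  expect_false(r2$included)
  expect_match(r2$reasons, "baseline_rate")

  # SNR from the stated definition
  tpl <- rate_template()
  w <- simulate_waveforms(tpl, 2000, noise_sd = 10, seed = 5)
  m <- colMeans(w)
  resid_sd <- sd(as.vector(sweep(w, 2, m)))
  expect_equal(waveform_snr(w), (max(m) - min(m)) / resid_sd)

  # missing waveforms skip the SNR criterion without excluding the unit
  ok_train <- lapply(1:30, function(i) seq(100, 2900, by = 50) + i / 7)
  u3 <- make_unit(ok_train, stim = 2000, sacc = 2800)
  r3 <- screen_unit(u3)
  expect_true(r3$included)
  expect_match(r3$reasons, "snr_unavailable")
})

test_that("relaxing screening thresholds never excludes an included unit", {
  pop <- small_population(seed = 77)
  strict <- screening_config(min_snr = 5, max_isi_violation = 0.02,
                             min_baseline_rate = 8)
  lenient <- screening_config(min_snr = 1, max_isi_violation = 0.5,
                              min_baseline_rate = 0.5)
  s1 <- screen_population(pop, strict)
  s2 <- screen_population(pop, lenient)
  expect_true(all(!s1$included | s2$included))
})

test_that("variability metrics hit their analytic anchors", {
  # perfectly regular train: cv = lv = 0, deterministic counts: fano = 0
  reg <- make_unit(lapply(1:20, function(i) seq(25, 1975, by = 50)),
                   stim = 1000, sacc = 1800)
  f <- biophysical_features(reg)
  expect_equal(f$cv, 0)
  expect_equal(f$lv, 0)
  expect_equal(f$cv2, 0)
  expect_equal(f$fano, 0)

  # long stationary Poisson train: cv, cv2, lv, fano near 1
  tpl <- rate_template(baseline_rate = 40, visual_peak_rate = 0,
                       ramp_peak_rate = 0)
  u <- simulate_unit(tpl, n_trials = 200, seed = 13)
  expect_gt(sum(vapply(u$trials$spikes, length, 0L)), 1e4)
  fp <- biophysical_features(u)
  expect_equal(fp$cv, 1, tolerance = 0.1)
  expect_equal(fp$cv2, 1, tolerance = 0.1)
  expect_equal(fp$lv, 1, tolerance = 0.1)
  expect_equal(fp$fano, 1, tolerance = 0.1)

  # too few spikes: flagged missing, not fabricated
  tiny <- make_unit(list(c(500)))
  ft <- biophysical_features(tiny)
  expect_true(is.na(ft$cv) && is.na(ft$lv))
})

test_that("spike width is a direct extremum-to-extremum measurement", {
  t_us <- seq(0, 1000, by = 25)
  m <- -exp(-0.5 * ((t_us - 300) / 40)^2) + 0.5 * exp(-0.5 * ((t_us - 550) / 60)^2)
  attr(m, "time_us") <- t_us
  expect_equal(spike_width(m), 250)
})

test_that("Gaussian response fields are recovered and gated on r2", {
  th <- seq(0, 315, by = 45)
  y <- 5 + 40 * exp(-0.5 * (fefclust:::ang_dist(th, 90) / 60)^2)
  fit <- fit_response_field(y)
  expect_true(fit$valid)
  expect_lt(abs(fit$preferred_location - 90), 1)
  expect_lt(abs(fit$tuning_width - 60) / 60, 0.05)
  expect_equal(fit$max_response, 45, tolerance = 0.05)

  flat <- fit_response_field(rep(7, 8))
  expect_false(flat$valid)

  peaky <- c(2, 2, 2, 30, 2, 2, 2, 2)
  fitp <- fit_response_field(peaky)
  expect_lt(fefclust:::ang_dist(fitp$preferred_location, 135), 23)
})

test_that("location responses feed tuning fits from simulated units", {
  tpl <- make_category_templates()[1, ]
  u <- simulate_unit(tpl, n_trials = 60, seed = 21, rf_location = 2L,
                     trials_per_other_location = 40)
  lr <- location_responses(u, "visual")
  expect_equal(nrow(lr), 8)
  expect_equal(lr$location[which.max(lr$rate)], 2L)
})
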