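test_that("default template library matches the described archetypes", {
  tpl <- make_category_templates()
  expect_equal(nrow(tpl), 10)
  expect_equal(anyDuplicated(tpl$name), 0L)

  vis_early <- tpl[tpl$name == "vis_early", ]
  expect_equal(vis_early$visual_peak_latency, 74)
  expect_equal(vis_early$ramp_peak_rate, 0)

  vis_late <- tpl[tpl$name == "vis_late_delay", ]
  expect_equal(vis_late$visual_peak_latency, 136)
  expect_gt(vis_late$delay_rate, 0)

  expect_equal(tpl$visual_peak_latency[tpl$name == "vm_early_clipped"], 70)
  expect_equal(tpl$visual_peak_latency[tpl$name == "vm_late_unclipped"], 161)

  fix <- tpl[tpl$name == "fix_suppressed", ]
  expect_gt(fix$suppression_depth, 0)
  expect_equal(fix$visual_peak_rate, 0)
})

test_that("templates reject negative rates and degenerate ones are constant", {
  expect_error(rate_template(baseline_rate = -1), "baseline_rate")
  expect_error(rate_template(visual_peak_latency = -5), "visual_peak_latency")
  expect_error(rate_template(spike_width_us = 0), "spike_width_us")

  flat <- rate_template(baseline_rate = 17, visual_peak_rate = 0,
                        delay_rate = 0, ramp_peak_rate = 0,
                        postsacc_transient_rate = 0, suppression_depth = 0)
  r <- template_rate(flat, seq(0, 2000, by = 7), 500, 1200)
  expect_true(all(r == 17))
})

test_that("template evaluation is rectified and anchors terms correctly", {
  tpl <- rate_template(baseline_rate = 5, visual_peak_rate = 0,
                       suppression_depth = 50, suppression_width = 40)
  r <- template_rate(tpl, seq(0, 2000), 500, 1200)
  expect_true(all(r >= 0))
  expect_equal(r[1201], 0)  # fully suppressed at the saccade

  # visual transient is stimulus-anchored: peak tracks stimulus time
  vis <- rate_template(baseline_rate = 5, visual_peak_rate = 60,
                       visual_peak_latency = 80, visual_width = 10)
  for (stim in c(400, 700)) {
    r <- template_rate(vis, seq(0, 2000), stim, stim + 600)
    expect_equal(which.max(r) - 1, stim + 80, tolerance = 1e-9)
  }
})

test_that("simulate_unit is deterministic under a fixed seed", {
  tpl <- make_category_templates()[3, ]
  u1 <- simulate_unit(tpl, n_trials = 20, seed = 7, waveform_n = 20)
  u2 <- simulate_unit(tpl, n_trials = 20, seed = 7, waveform_n = 20)
  expect_identical(u1, u2)
  u3 <- simulate_unit(tpl, n_trials = 20, seed = 8, waveform_n = 20)
  expect_false(identical(u1$trials$spikes, u3$trials$spikes))
})

test_that("constant-rate unit recovers its rate and task delays stay in range", {
  tpl <- rate_template(baseline_rate = 20, visual_peak_rate = 0,
                       ramp_peak_rate = 0)
  u <- simulate_unit(tpl, n_trials = 500, seed = 3)
  # law of large numbers on Poisson counts over the whole trial
  spans <- u$trials$saccade_ms + 400
  counts <- vapply(u$trials$spikes, length, numeric(1))
  expected <- 20 * spans / 1000
  z <- (sum(counts) - sum(expected)) / sqrt(sum(expected))
  expect_lt(abs(z), 3)

  # saccade = stimulus + delay (uniform 300..800) + reaction time (150..250)
  u2 <- simulate_unit(tpl, n_trials = 1000, seed = 4)
  stim_to_sacc <- u2$trials$saccade_ms - u2$trials$stimulus_onset_ms
  expect_true(all(stim_to_sacc >= 300 + 150 & stim_to_sacc <= 800 + 250))
})

test_that("spike times are strictly increasing within each trial", {
  tpl <- make_category_templates()[4, ]
  u <- simulate_unit(tpl, n_trials = 50, seed = 11)
  for (sp in u$trials$spikes) {
    if (length(sp) > 1) expect_true(all(diff(sp) > 0))
  }
  expect_true(all(u$trials$saccade_ms > u$trials$stimulus_onset_ms))
})

test_that("trial-averaged rate tracks the template rate function", {
  # PSTH recovery: stimulus-aligned 10 ms bins within sampling error of the
  # per-trial template rate, for a transient and a ramping archetype
  for (row in c(1, 3)) {
    tpl <- make_category_templates()[row, ]
    u <- simulate_unit(tpl, n_trials = 500, seed = 20 + row)
    edges <- seq(-200, 300, by = 10)
    nb <- length(edges) - 1
    obs <- matrix(0, 500, nb)
    expd <- matrix(0, 500, nb)
    for (i in seq_len(500)) {
      rel <- u$trials$spikes[[i]] - u$trials$stimulus_onset_ms[i]
      obs[i, ] <- vapply(seq_len(nb), function(b)
        sum(rel >= edges[b] & rel < edges[b + 1]), numeric(1))
      tt <- u$trials$stimulus_onset_ms[i] + (edges[-length(edges)] + 5)
      expd[i, ] <- template_rate(tpl, tt, u$trials$stimulus_onset_ms[i],
                                 u$trials$saccade_ms[i]) * 10 / 1000
    }
    se <- apply(obs, 2, sd) / sqrt(500)
    dev <- abs(colMeans(obs) - colMeans(expd))
    expect_true(all(dev <= 4 * pmax(se, 1e-3)))
    expect_gte(mean(dev <= 3 * pmax(se, 1e-3)), 0.9)
  }
})

test_that("simulate_population bookkeeping and trial-count range hold", {
  tpls <- make_category_templates()[c(1, 10), ]
  spec <- population_spec(templates = tpls, units_per_template = 15,
                          trial_counts = c(min = 5, median = 12, max = 40),
                          trials_per_other_location = 0, waveform_n = 0,
                          seed = 9)
  pop <- simulate_population(spec)
  expect_length(pop$units, 30)
  expect_equal(sort(as.integer(table(pop$truth$label))), c(15L, 15L))

  pop2 <- simulate_population(population_spec(
    templates = tpls, units_per_template = 15,
    trial_counts = c(min = 5, median = 12, max = 40),
    trials_per_other_location = 0, waveform_n = 0, seed = 10))
  expect_identical(pop$truth$label, pop2$truth$label)
  expect_false(identical(pop$units[[1]]$trials$spikes,
                         pop2$units[[1]]$trials$spikes))

  # the default skewed trial-count distribution respects the printed range
  counts <- fefclust:::draw_trial_counts(466, c(min = 4, median = 34, max = 317))
  expect_true(all(counts >= 4 & counts <= 317))
  expect_lt(abs(stats::median(counts) - 34), 8)

  expect_error(population_spec(templates = tpls[0, ]), "template")
  expect_error(population_spec(templates = tpls, units_per_template = 0),
               "units_per_template")
})

test_that("waveform widths, polarity and SNR behave as specified", {
  tpl <- rate_template(spike_width_us = 250)
  # near-noiseless: measured width equals the template width to one sample
  w <- simulate_waveforms(tpl, n_spikes = 5, noise_sd = 1e-6, seed = 1)
  expect_lte(abs(spike_width(w) - 250), 25)

  wide <- rate_template(spike_width_us = 400)
  w2 <- simulate_waveforms(wide, n_spikes = 5, noise_sd = 1e-6, seed = 1)
  expect_lte(abs(spike_width(w2) - 400), 25)

  # positive-leading spikes are measured peak-to-trough
  pos <- rate_template(spike_width_us = 300, polarity = "positive-leading")
  wp <- simulate_waveforms(pos, n_spikes = 5, noise_sd = 1e-6, seed = 1)
  m <- colMeans(wp)
  expect_lt(which.max(m), which.min(m))
  expect_lte(abs(spike_width(wp) - 300), 25)

  # peak-trough 150 uV over 10 uV residuals gives SNR near 15
  w3 <- simulate_waveforms(tpl, n_spikes = 2000, noise_sd = 10, seed = 2)
  expect_equal(waveform_snr(w3), 15, tolerance = 0.05)

  expect_error(simulate_waveforms(tpl, 10, noise_sd = 0), "noise_sd")
  expect_error(simulate_waveforms(tpl, 0, noise_sd = 5), "n_spikes")
})

test_that("planted templates are more similar within than between", {
  demo <- demo_analysis(1L)
  zs <- scale_sdf(demo$sdfs, "z_whole")
  X <- cbind(zs$stim, zs$sacc)
  lab <- demo$pop$truth$label[match(zs$unit_ids, demo$pop$truth$unit_id)]
  cors <- stats::cor(t(X))
  same <- outer(lab, lab, "==")
  diag(same) <- NA
  expect_gt(mean(cors[same & upper.tri(cors)], na.rm = TRUE),
            mean(cors[!same & upper.tri(cors)], na.rm = TRUE))
})
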