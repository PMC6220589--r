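# Shared fixtures, built in code. The full-size default population is
# expensive, so it is computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Full default-conditions population with its pipeline products.
demo_analysis <- function(seed = 1L) {
  key <- paste0("demo", seed)
  if (is.null(.fixture_env[[key]])) {
    pop <- simulate_population(population_spec(seed = seed))
    sdfs <- compute_sdf_set(pop)
    dists <- compute_pipeline_distances(sdfs)
    C <- build_consensus_matrix(dists)
    cons <- consensus_categories(C)
    .fixture_env[[key]] <- list(pop = pop, sdfs = sdfs, dists = dists,
                                C = C, cons = cons)
  }
  .fixture_env[[key]]
}

# A small fast population: 3 well-separated archetypes, 12 units each.
small_population <- function(seed = 42L, units_per_template = 12L) {
  tpls <- make_category_templates()[c(1, 3, 10), ]
  simulate_population(population_spec(
    templates = tpls, units_per_template = units_per_template,
    trial_counts = c(min = 8, median = 20, max = 60),
    trials_per_other_location = 0, p_error = 0,
    waveform_n = 30, seed = seed))
}

# Construct a unit from explicit per-trial spike times.
make_unit <- function(spike_list, stim = 500, sacc = 1100, correct = TRUE,
                      location = 0L, unit_id = "u1", waveforms = NULL,
                      rf_location = 0L) {
  n <- length(spike_list)
  structure(list(
    unit_id = unit_id, rf_location = as.integer(rf_location),
    ground_truth_label = NA_character_,
    trials = tibble::tibble(
      trial_id = seq_len(n),
      target_location = rep_len(as.integer(location), n),
      stimulus_onset_ms = rep_len(stim, n),
      saccade_ms = rep_len(sacc, n),
      correct = rep_len(correct, n),
      spikes = spike_list),
    waveforms = waveforms), class = "fef_unit")
}

# Construct an SDF set directly from rate matrices.
make_sdf_set <- function(stim, sacc, ids = paste0("u", seq_len(nrow(stim))),
                         stim_time = -200:300, sacc_time = -300:200) {
  base_idx <- stim_time >= -200 & stim_time < -100
  structure(list(
    unit_ids = ids,
    stim = `rownames<-`(stim, ids), sacc = `rownames<-`(sacc, ids),
    stim_time = stim_time, sacc_time = sacc_time,
    n_trials_used = rep(10L, nrow(stim)),
    baseline_mean = apply(stim[, base_idx, drop = FALSE], 1, mean),
    baseline_sd = apply(stim[, base_idx, drop = FALSE], 1, stats::sd),
    dropped = character(0)), class = "fef_sdf_set")
}

# Construct a single fef_sdf from rate vectors.
make_sdf <- function(stim, sacc, stim_time = -200:300, sacc_time = -300:200,
                     unit_id = "u1") {
  base_idx <- stim_time >= -200 & stim_time < -100
  structure(list(unit_id = unit_id, stim = stim, sacc = sacc,
                 stim_time = stim_time, sacc_time = sacc_time,
                 n_trials_used = 10L,
                 baseline_mean = mean(stim[base_idx]),
                 baseline_sd = stats::sd(stim[base_idx])),
            class = "fef_sdf")
}

# A categorization from a plain label vector.
make_cat <- function(labels, ids = paste0("u", seq_along(labels))) {
  new_categorization(tibble::tibble(unit_id = ids, label = as.character(labels)))
}

# Random symmetric distance matrix with zero diagonal.
random_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 10)
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("u", seq_len(n))
  m
}

# Well-separated Gaussian blobs in feature space.
blob_features <- function(centers, per = 12, sd = 0.3, dims = 4, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(per * dims, mean = rep(centers[i, ], each = per), sd = sd),
           nrow = per)
  }))
  rownames(X) <- paste0("u", seq_len(nrow(X)))
  labels <- rep(paste0("blob", seq_len(nrow(centers))), each = per)
  list(X = X, labels = labels)
}
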