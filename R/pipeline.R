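#' Configuration for a full analysis run
#'
#' Collects every tunable of the end-to-end analysis: the input (a
#' synthetic [population_spec()] or a spike-table path), the SDF kernel,
#' screening thresholds, the preprocessing grid, epochs, consensus
#' membership criteria, resampling counts, the RNG seed, and an optional
#' output directory for the report bundle. Fully serializable to YAML; a
#' run archives its config verbatim in the bundle.
#'
#' @param population a [population_spec()], or `NULL` with `input_path`.
#' @param input_path optional spike-table CSV ([read_spike_table()]).
#' @param units_meta_path optional per-unit metadata CSV for `input_path`.
#' @param kernel_growth_tau,kernel_decay_tau SDF kernel time constants, ms.
#' @param screening a [screening_config()].
#' @param grid a [pipeline_grid()].
#' @param criteria a [membership_criteria()].
#' @param ari_shuffles,chi2_shuffles,crossval_shuffles permutation counts.
#' @param crossval_components component counts for the accuracy curve.
#' @param seed integer seed for every stochastic step.
#' @param output_dir when non-`NULL`, the report bundle is written there.
#' @export
analysis_config <- function(population = population_spec(),
                            input_path = NULL,
                            units_meta_path = NULL,
                            kernel_growth_tau = 1,
                            kernel_decay_tau = 20,
                            screening = screening_config(),
                            grid = pipeline_grid(),
                            criteria = membership_criteria(),
                            ari_shuffles = 1000,
                            chi2_shuffles = 1000,
                            crossval_shuffles = 1000,
                            crossval_components = 1:100,
                            seed = 1L,
                            output_dir = NULL) {
  structure(list(
    population = population, input_path = input_path,
    units_meta_path = units_meta_path,
    kernel_growth_tau = kernel_growth_tau,
    kernel_decay_tau = kernel_decay_tau,
    screening = screening, grid = grid, criteria = criteria,
    ari_shuffles = ari_shuffles, chi2_shuffles = chi2_shuffles,
    crossval_shuffles = crossval_shuffles,
    crossval_components = crossval_components,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "fef_analysis_config")
}

#' Run the full consensus-clustering analysis
#'
#' Executes the whole pipeline: unit screening, spike density estimation,
#' the 48 preprocessing pipelines, the z-scored median composite matrix
#' and consensus categories, the traditional baseline classification, the
#' categorization-quality statistics (penalized RoV, ARI with permutation
#' inference, signed chi-square with bootstrap z), biophysical feature
#' tests across consensus categories, and leave-one-out cross-validation
#' with its label-shuffle control. With `output_dir` set, writes the
#' report bundle (categorizations, matrices, dendrogram, reports, config,
#' and a log with the per-stage unit-exclusion cascade and seed).
#'
#' @param config an [analysis_config()].
#' @return object of class `fef_analysis` collecting every stage's result.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  log_lines <- c(sprintf("fefclust %s | R %s | seed %d",
                         as.character(utils::packageVersion("fefclust")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         config$seed))
  units <- if (!is.null(config$input_path)) {
    meta <- if (!is.null(config$units_meta_path)) {
      utils::read.csv(config$units_meta_path, stringsAsFactors = FALSE)
    }
    read_spike_table(config$input_path, meta)
  } else {
    simulate_population(config$population)$units
  }
  log_lines <- c(log_lines, sprintf("units in: %d", length(units)))

  screen <- screen_population(units, config$screening)
  if (any(grepl("snr_unavailable", screen$reasons))) {
    log_lines <- c(log_lines, "waveforms absent for some units: SNR screen skipped")
  }
  for (reason in c("snr", "isi", "baseline_rate", "zero_epochs")) {
    n_r <- sum(vapply(strsplit(screen$reasons, ","),
                      function(r) reason %in% r, logical(1)))
    log_lines <- c(log_lines, sprintf("excluded by %s: %d", reason, n_r))
  }
  keep_ids <- screen$unit_id[screen$included]
  units <- units[vapply(units, function(u) u$unit_id %in% keep_ids, logical(1))]
  log_lines <- c(log_lines, sprintf("units after screening: %d", length(units)))
  if (length(units) < config$criteria$min_members) {
    stop_bad_arg("only %d units survive screening (< min_members %d); aborting",
                 length(units), config$criteria$min_members)
  }

  kernel <- sdf_kernel(config$kernel_growth_tau, config$kernel_decay_tau)
  sdfs <- compute_sdf_set(units, kernel)
  log_lines <- c(log_lines,
                 sprintf("unstable SDF estimates dropped: %d", length(sdfs$dropped)))

  dists <- compute_pipeline_distances(sdfs, config$grid)
  C <- build_consensus_matrix(dists)
  cons <- consensus_categories(C, config$criteria)
  traditional <- classify_traditional_set(sdfs)

  zwhole <- scale_sdf(sdfs, "z_whole")
  sdf_base <- cbind(zwhole$stim, zwhole$sacc)
  rownames(sdf_base) <- zwhole$unit_ids
  rov_consensus <- rov(cons$categorization, sdf_base)
  rov_traditional <- rov(traditional, sdf_base)

  ari <- adjusted_rand(traditional, cons$categorization,
                       shuffles = config$ari_shuffles,
                       seed = child_seed(config$seed, 1L))
  chi2 <- signed_chi2(traditional, cons$categorization,
                      shuffles = config$chi2_shuffles,
                      seed = child_seed(config$seed, 2L))

  feats <- dplyr::bind_rows(lapply(units, biophysical_features))
  tuning <- dplyr::bind_rows(lapply(units, function(u) {
    v <- fit_response_field(location_responses(u, "visual"), "visual")
    m <- fit_response_field(location_responses(u, "movement"), "movement")
    tibble::tibble(unit_id = u$unit_id,
                   visual_tuning_width = ifelse(v$valid, v$tuning_width, NA),
                   visual_max_response = ifelse(v$valid, v$max_response, NA),
                   movement_tuning_width = ifelse(m$valid, m$tuning_width, NA),
                   movement_max_response = ifelse(m$valid, m$max_response, NA))
  }))
  feats <- dplyr::left_join(feats, tuning, by = "unit_id")
  feature_tests <- category_feature_tests(cons$categorization, feats)

  crossval <- loo_accuracy_curve(C, cons$categorization,
                                 config$crossval_components)
  shuffle <- shuffle_control(C, cons$categorization,
                             n_components = crossval$peak_components,
                             shuffles = config$crossval_shuffles,
                             seed = child_seed(config$seed, 3L))

  result <- structure(list(
    config = config, screen = screen, sdfs = sdfs,
    pipeline_distances = dists, consensus_matrix = C,
    consensus = cons, traditional = traditional,
    rov_consensus = rov_consensus, rov_traditional = rov_traditional,
    ari = ari, chi2 = chi2, features = feats,
    feature_tests = feature_tests,
    crossval = crossval, shuffle = shuffle,
    log = log_lines
  ), class = "fef_analysis")

  if (!is.null(config$output_dir)) write_bundle(result, config$output_dir)
  result
}

#' @export
print.fef_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "<fef_analysis> %d units | consensus k = %d (%.1f%% uncategorized)\n",
    "  RoV: consensus %.2f, traditional %.2f | ARI %.3f (p = %.3g)\n",
    "  LOO peak accuracy %.1f%% at %d components (shuffle mean %.1f%%)\n"),
    length(x$sdfs$unit_ids), x$consensus$k,
    100 * uncategorized_fraction(x$consensus$categorization),
    x$rov_consensus$penalized, x$rov_traditional$penalized,
    x$ari$ari, x$ari$p_value,
    100 * x$crossval$peak_accuracy, x$crossval$peak_components,
    100 * x$shuffle$shuffle_mean))
  invisible(x)
}

write_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdir <- file.path(dir, "pipeline_matrices")
  dir.create(pdir, showWarnings = FALSE)
  for (nm in names(result$pipeline_distances)) {
    write_matrix_csv(result$pipeline_distances[[nm]],
                     file.path(pdir, paste0(gsub("[^A-Za-z0-9_+-]", "_", nm),
                                            ".csv")))
  }
  write_matrix_csv(result$consensus_matrix,
                   file.path(dir, "consensus_matrix.csv"))
  write_categorization(result$consensus$categorization,
                       file.path(dir, "consensus_categories.csv"))
  write_categorization(result$traditional,
                       file.path(dir, "traditional_categories.csv"))
  tree_newick(result$consensus$tree, file.path(dir, "consensus_dendrogram.nwk"))
  utils::write.csv(result$screen, file.path(dir, "screening.csv"),
                   row.names = FALSE)
  utils::write.csv(result$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$feature_tests, file.path(dir, "feature_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(result$crossval$curve, file.path(dir, "accuracy_curve.csv"),
                   row.names = FALSE)
  write_matrix_csv(result$crossval$misclassification,
                   file.path(dir, "misclassification.csv"))
  report <- list(
    consensus_k = result$consensus$k,
    uncategorized_fraction =
      uncategorized_fraction(result$consensus$categorization),
    rov = list(consensus = result$rov_consensus$penalized,
               traditional = result$rov_traditional$penalized),
    ari = list(value = result$ari$ari, p = result$ari$p_value),
    crossval = list(peak_accuracy = result$crossval$peak_accuracy,
                    peak_components = result$crossval$peak_components,
                    shuffle_mean = result$shuffle$shuffle_mean,
                    shuffle_p = result$shuffle$p_value))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  cfg_list <- list(
    seed = cfg$seed,
    kernel = list(growth_tau = cfg$kernel_growth_tau,
                  decay_tau = cfg$kernel_decay_tau),
    screening = cfg$screening,
    criteria = cfg$criteria,
    shuffles = list(ari = cfg$ari_shuffles, chi2 = cfg$chi2_shuffles,
                    crossval = cfg$crossval_shuffles),
    synthetic = is.null(cfg$input_path),
    input_path = cfg$input_path %||% "",
    n_pipelines = nrow(cfg$grid))
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  writeLines(result$log, file.path(dir, "log.txt"))
  invisible(dir)
}
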