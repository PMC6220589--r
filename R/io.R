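# On-disk formats: a delimited spike-event table (one row per spike;
# columns unit_id, trial_id, target_location, stimulus_onset_ms,
# saccade_ms, correct, spike_time_ms; times in ms on the trial clock,
# 0-based location indices), a two-column ground-truth CSV, square
# distance-matrix CSVs with a unit-id header row/column, and Newick
# dendrograms.

#' Write and read the spike-event table
#'
#' One row per spike. Trials that contain no spikes are preserved as a
#' single row with an empty `spike_time_ms` field so the trial structure
#' survives the round trip.
#'
#' @param population a `fef_population` or list of `fef_unit`s.
#' @param path CSV path.
#' @export
write_spike_table <- function(population, path) {
  units <- if (inherits(population, "fef_population")) population$units
           else population
  rows <- lapply(units, function(u) {
    tr <- u$trials
    dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(i) {
      sp <- tr$spikes[[i]]
      tibble::tibble(
        unit_id = u$unit_id,
        trial_id = tr$trial_id[i],
        target_location = tr$target_location[i],
        stimulus_onset_ms = tr$stimulus_onset_ms[i],
        saccade_ms = tr$saccade_ms[i],
        correct = tr$correct[i],
        spike_time_ms = if (length(sp)) sp else NA_real_)
    }))
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_spike_table
#' @param units_meta optional tibble (`unit_id`, `rf_location`, optionally
#'   `ground_truth_label`) giving per-unit metadata the spike table does
#'   not carry; without it the receptive field defaults to each unit's
#'   modal target location.
#' @return `read_spike_table()` returns a list of `fef_unit`s.
#' @export
read_spike_table <- function(path, units_meta = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$correct <- as.logical(df$correct)
  units <- lapply(split(df, df$unit_id), function(ud) {
    trs <- split(ud, ud$trial_id)
    tr <- dplyr::bind_rows(lapply(trs, function(td) {
      sp <- td$spike_time_ms[is.finite(td$spike_time_ms)]
      tibble::tibble(trial_id = td$trial_id[1],
                     target_location = td$target_location[1],
                     stimulus_onset_ms = td$stimulus_onset_ms[1],
                     saccade_ms = td$saccade_ms[1],
                     correct = td$correct[1],
                     spikes = list(sort(sp)))
    }))
    tr <- tr[order(tr$trial_id), ]
    id <- ud$unit_id[1]
    rf <- NULL; gt <- NA_character_
    if (!is.null(units_meta) && id %in% units_meta$unit_id) {
      row <- units_meta[units_meta$unit_id == id, ]
      rf <- row$rf_location[1]
      if ("ground_truth_label" %in% names(row)) gt <- row$ground_truth_label[1]
    }
    if (is.null(rf)) {
      tab <- table(tr$target_location)
      rf <- as.integer(names(tab)[which.max(tab)])
    }
    structure(list(unit_id = id, rf_location = as.integer(rf),
                   ground_truth_label = gt, trials = tr, waveforms = NULL),
              class = "fef_unit")
  })
  unname(units)
}

#' Write/read a categorization as a two-column CSV
#' @param cat a `fef_categorization`.
#' @param path CSV path.
#' @export
write_categorization <- function(cat, path) {
  utils::write.csv(as.data.frame(cat[, c("unit_id", "label")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_categorization
#' @param provenance provenance tag for the reconstructed object.
#' @export
read_categorization <- function(path, provenance = "file") {
  new_categorization(utils::read.csv(path, stringsAsFactors = FALSE),
                     provenance = provenance)
}

#' Write/read a square distance matrix CSV with unit-id headers
#' @param m matrix with dimnames.
#' @param path CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
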