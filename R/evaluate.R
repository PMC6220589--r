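#' Traditional visual/movement/visuomovement classification
#'
#' A unit has visual activity if its mean rate 50-150 ms after stimulus
#' onset exceeds the baseline mean by more than 6 baseline SDs; it has
#' movement activity if its mean rate in the 100 ms preceding the saccade
#' exceeds the same bound *and* the SDF correlates positively with time
#' over the final 20 ms before the saccade (so elevated delay activity
#' without presaccadic ramping does not count as movement-related).
#' Visual-only units are `"visual"`, movement-only `"movement"`, both
#' `"visuomovement"`, neither `"uncategorized"`. Fixation and postsaccadic
#' activity are not tested.
#'
#' @param sdf a `fef_sdf` (baseline mean/SD are taken from it).
#' @param n_sd threshold in baseline SDs.
#' @return label string; `NA` if the baseline SD is zero (classification
#'   impossible).
#' @export
classify_traditional <- function(sdf, n_sd = 6) {
  if (!is.finite(sdf$baseline_sd) || sdf$baseline_sd == 0) return(NA_character_)
  thr <- sdf$baseline_mean + n_sd * sdf$baseline_sd
  vis <- mean(sdf$stim[sdf$stim_time >= 50 & sdf$stim_time < 150]) > thr
  pre_idx <- sdf$sacc_time >= -100 & sdf$sacc_time < 0
  ramp_idx <- sdf$sacc_time >= -20 & sdf$sacc_time < 0
  ramp_cor <- suppressWarnings(
    stats::cor(sdf$sacc[ramp_idx], sdf$sacc_time[ramp_idx]))
  mov <- mean(sdf$sacc[pre_idx]) > thr && is.finite(ramp_cor) && ramp_cor > 0
  if (vis && mov) "visuomovement"
  else if (vis) "visual"
  else if (mov) "movement"
  else "uncategorized"
}

#' Traditional classification for a population
#'
#' @param sdf_set a `fef_sdf_set`.
#' @inheritParams classify_traditional
#' @return `fef_categorization` (provenance `"traditional"`); units with a
#'   zero baseline SD are labelled uncategorized and listed in the
#'   `flagged_units` attribute.
#' @export
classify_traditional_set <- function(sdf_set, n_sd = 6) {
  n <- length(sdf_set$unit_ids)
  labels <- character(n)
  flagged <- character(0)
  for (i in seq_len(n)) {
    s <- structure(list(
      stim = sdf_set$stim[i, ], sacc = sdf_set$sacc[i, ],
      stim_time = sdf_set$stim_time, sacc_time = sdf_set$sacc_time,
      baseline_mean = sdf_set$baseline_mean[i],
      baseline_sd = sdf_set$baseline_sd[i]), class = "fef_sdf")
    lab <- classify_traditional(s, n_sd)
    if (is.na(lab)) {
      flagged <- c(flagged, sdf_set$unit_ids[i])
      lab <- "uncategorized"
    }
    labels[i] <- lab
  }
  out <- new_categorization(
    tibble::tibble(unit_id = sdf_set$unit_ids, label = labels),
    provenance = "traditional")
  attr(out, "flagged_units") <- flagged
  out
}

#' Penalized ratio-of-variances categorization quality index
#'
#' For each category and time point, the within-category variance of the
#' (scaled) spike density values is divided by the variance of the
#' category-mean SDF across time points (the category's modulation
#' strength). Ratios are averaged over time, then over categories, and the
#' grand average is multiplied by the square root of the number of
#' categories as an oversplitting penalty. Smaller values indicate better
#' categorization. Categories whose mean is constant in time have an
#' undefined ratio; they are excluded from the grand mean with a warning.
#'
#' @param cat a `fef_categorization`; uncategorized units are excluded.
#' @param sdf_values units x time matrix of scaled SDF samples (row names
#'   are unit ids); conventionally the concatenated stimulus- and
#'   saccade-aligned samples on the 1002-point analysis base.
#' @return object of class `fef_rov`: list with `per_category` tibble
#'   (`label`, `n_members`, `modulation_strength`, `mean_ratio`),
#'   `grand_mean`, `n_categories`, `penalized`, `undefined_categories`.
#' @export
rov <- function(cat, sdf_values) {
  labs <- setdiff(unique(cat$label), "uncategorized")
  rows <- list()
  undefined <- character(0)
  for (lab in labs) {
    ids <- cat$unit_id[cat$label == lab]
    idx <- match(ids, rownames(sdf_values))
    if (anyNA(idx)) stop_bad_arg("category '%s' has units without SDF rows", lab)
    X <- sdf_values[idx, , drop = FALSE]
    xbar <- colMeans(X)
    ms <- mean((xbar - mean(xbar))^2)          # Nt-normalized time variance
    if (ms == 0) {
      undefined <- c(undefined, lab)
      warning(sprintf("category '%s' has a time-constant mean; RoV undefined",
                      lab), call. = FALSE)
      next
    }
    within_t <- colMeans(sweep(X, 2, xbar)^2)  # per-time within variance
    rows[[length(rows) + 1L]] <- tibble::tibble(
      label = lab, n_members = length(idx), modulation_strength = ms,
      mean_ratio = mean(within_t / ms))
  }
  per_cat <- dplyr::bind_rows(rows)
  n_cat <- length(labs)
  grand <- if (nrow(per_cat)) mean(per_cat$mean_ratio) else NA_real_
  structure(list(
    per_category = per_cat,
    grand_mean = grand,
    n_categories = n_cat,
    penalized = sqrt(n_cat) * grand,
    undefined_categories = undefined
  ), class = "fef_rov")
}

#' @export
glance.fef_rov <- function(x, ...) {
  tibble::tibble(penalized_rov = x$penalized, grand_mean = x$grand_mean,
                 n_categories = x$n_categories,
                 n_undefined = length(x$undefined_categories))
}

#' @export
tidy.fef_rov <- function(x, ...) x$per_category

align_partitions <- function(a, b) {
  m <- dplyr::inner_join(tibble::as_tibble(a[, c("unit_id", "label")]),
                         tibble::as_tibble(b[, c("unit_id", "label")]),
                         by = "unit_id", suffix = c("_a", "_b"))
  if (nrow(m) != nrow(a) || nrow(m) != nrow(b)) {
    stop_bad_arg("categorizations must cover the same unit set")
  }
  m
}

ari_from_labels <- function(la, lb) {
  tab <- table(la, lb)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(NA_real_)
  (sum_ij - expected) / denom
}

#' Adjusted Rand Index with permutation inference
#'
#' Chance-corrected pairwise co-membership agreement between two
#' categorizations of the same units. The `"uncategorized"` label is
#' treated as an ordinary category. Significance is assessed by shuffling
#' each labelling independently and recomputing; `p` is the proportion of
#' shuffled ARIs exceeding the observed ARI (no +1 correction).
#'
#' @param a,b `fef_categorization`s over the same unit set.
#' @param shuffles number of label permutations.
#' @param seed RNG seed.
#' @return tibble of class `fef_ari`: `ari`, `p_value`, `shuffles`, with
#'   the shuffled values in attribute `shuffled`.
#' @export
adjusted_rand <- function(a, b, shuffles = 1000, seed = 1L) {
  m <- align_partitions(a, b)
  obs <- ari_from_labels(m$label_a, m$label_b)
  shuf <- with_seed(seed, {
    vapply(seq_len(shuffles), function(i) {
      ari_from_labels(sample(m$label_a), sample(m$label_b))
    }, numeric(1))
  })
  out <- tibble::tibble(ari = obs,
                        p_value = mean(shuf > obs, na.rm = TRUE),
                        shuffles = as.integer(shuffles))
  attr(out, "shuffled") <- shuf
  class(out) <- c("fef_ari", class(out))
  out
}

#' Signed chi-square overlap of two categorization schemes
#'
#' For every category pair (i, j) of schemes a and b, computes
#' `(O - E) / E`, where O is the observed co-assignment count and E the
#' count expected from the schemes' marginal probabilities. Positive
#' values mark over-represented pairings, negative values
#' under-represented ones. Each labelling is shuffled independently and
#' the statistic recomputed to yield a bootstrap z-score per cell. Cells
#' with E = 0 are undefined and masked as `NA`.
#'
#' @inheritParams adjusted_rand
#' @return object of class `fef_chi2`: list with `signed`, `z`,
#'   `observed`, `expected` matrices (rows = categories of `a`).
#' @export
signed_chi2 <- function(a, b, shuffles = 1000, seed = 1L) {
  m <- align_partitions(a, b)
  la <- factor(m$label_a); lb <- factor(m$label_b)
  stat <- function(xa, xb) {
    O <- table(xa, xb)
    n <- sum(O)
    E <- outer(rowSums(O), colSums(O)) / n
    S <- (O - E) / E
    S[E == 0] <- NA
    unclass(S)
  }
  obs <- stat(la, lb)
  shuf <- with_seed(seed, {
    array(vapply(seq_len(shuffles),
                 function(i) stat(sample(la), sample(lb)),
                 obs),
          dim = c(dim(obs), shuffles))
  })
  mu <- apply(shuf, c(1, 2), mean)
  sdv <- apply(shuf, c(1, 2), stats::sd)
  z <- (obs - mu) / sdv
  O <- table(la, lb)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  structure(list(signed = obs, z = z, observed = unclass(O), expected = E,
                 shuffles = shuffles),
            class = "fef_chi2")
}

#' @export
tidy.fef_chi2 <- function(x, ...) {
  dn <- dimnames(x$signed)
  grid <- expand.grid(category_a = dn[[1]], category_b = dn[[2]],
                      stringsAsFactors = FALSE)
  tibble::tibble(grid,
                 observed = as.vector(x$observed),
                 expected = as.vector(x$expected),
                 signed_chi2 = as.vector(x$signed),
                 z = as.vector(x$z))
}

#' @export
autoplot.fef_chi2 <- function(object, ...) {
  df <- tidy.fef_chi2(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$category_b, .data$category_a,
                                   fill = .data$signed_chi2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "scheme b", y = "scheme a", fill = "(O - E)/E")
}

#' Kruskal-Wallis tests of unit features across categories
#'
#' Omnibus Kruskal-Wallis test per feature across all real categories
#' (uncategorized units excluded, missing values dropped per feature),
#' plus optional follow-up tests restricted to declared super-groups of
#' categories (e.g., the visual, visuomovement, and movement families).
#'
#' @param cat a `fef_categorization`.
#' @param features tibble with `unit_id` and numeric feature columns.
#' @param factors feature column names to test (default: all numeric).
#' @param supergroups named list of character vectors of category labels.
#' @return tibble: `scope` (`"omnibus"` or the super-group name),
#'   `factor`, `statistic` (H), `df`, `p_value`, `n`.
#' @export
category_feature_tests <- function(cat, features, factors = NULL,
                                   supergroups = NULL) {
  df <- dplyr::inner_join(tibble::as_tibble(cat[, c("unit_id", "label")]),
                          features, by = "unit_id")
  df <- df[df$label != "uncategorized", ]
  if (is.null(factors)) {
    factors <- names(features)[vapply(features, is.numeric, logical(1))]
    factors <- setdiff(factors, "unit_id")
  }
  run_kw <- function(sub, scope) {
    dplyr::bind_rows(lapply(factors, function(f) {
      x <- sub[[f]]; g <- sub$label
      keep <- is.finite(x)
      x <- x[keep]; g <- factor(g[keep])
      groups_ok <- sum(table(g) >= 2) >= 2
      if (!groups_ok || length(unique(x)) < 2) {
        return(tibble::tibble(scope = scope, factor = f,
                              statistic = NA_real_, df = NA_integer_,
                              p_value = NA_real_, n = length(x)))
      }
      kw <- stats::kruskal.test(x, g)
      tibble::tibble(scope = scope, factor = f,
                     statistic = unname(kw$statistic),
                     df = as.integer(kw$parameter),
                     p_value = kw$p.value, n = length(x))
    }))
  }
  out <- run_kw(df, "omnibus")
  for (nm in names(supergroups)) {
    out <- dplyr::bind_rows(out, run_kw(df[df$label %in% supergroups[[nm]], ], nm))
  }
  out
}
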