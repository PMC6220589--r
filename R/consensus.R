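#' Build the z-scored median composite distance matrix
#'
#' Each per-pipeline distance matrix is z-scored internally (over its
#' off-diagonal upper-triangle entries, correcting for the absolute scale
#' differences between pipelines), then the composite entry for every unit
#' pair is the median across pipelines, which prevents skewing by
#' nonoptimal pipelines. The diagonal is set to the composite minimum so a
#' unit remains nearest to itself under linkage even though composite
#' entries are signed z-scores.
#'
#' @param matrices list of distance matrices sharing one unit set (order
#'   and names must agree).
#' @return matrix of class `fef_consensus` with attribute `n_pipelines`.
#' @export
build_consensus_matrix <- function(matrices) {
  if (length(matrices) < 1L) stop_bad_arg("need at least one distance matrix")
  ref <- rownames(matrices[[1]])
  n <- nrow(matrices[[1]])
  for (m in matrices) {
    if (nrow(m) != n || !identical(rownames(m), ref)) {
      stop_bad_arg("all distance matrices must share the same unit set")
    }
  }
  ut <- upper.tri(matrix(0, n, n))
  z_entries <- vapply(matrices, function(m) {
    v <- unclass(m)[ut]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) v * 0 else (v - mean(v)) / s
  }, numeric(sum(ut)))
  z_entries <- matrix(z_entries, ncol = length(matrices))
  med <- apply(z_entries, 1, stats::median)

  C <- matrix(0, n, n, dimnames = list(ref, ref))
  C[ut] <- med
  C <- C + t(C)
  diag(C) <- min(med)
  attr(C, "n_pipelines") <- length(matrices)
  class(C) <- c("fef_consensus", class(C))
  C
}

#' Membership criteria for consensus category selection
#'
#' @param min_members minimum units per category (default 10).
#' @param max_uncategorized_fraction maximum fraction of units left
#'   uncategorized (default 0.10).
#' @param k_max largest number of categories considered (default 20).
#' @export
membership_criteria <- function(min_members = 10,
                                max_uncategorized_fraction = 0.10,
                                k_max = 20) {
  stopifnot(min_members > 0, max_uncategorized_fraction > 0, k_max > 0)
  list(min_members = min_members,
       max_uncategorized_fraction = max_uncategorized_fraction,
       k_max = as.integer(k_max))
}

#' Extract consensus categories from the composite matrix
#'
#' Agglomerates the composite matrix with the group-average linkage, then
#' evaluates candidate cuts for k = 1..k_max and keeps the categorization
#' with the largest k satisfying both membership criteria: every category
#' has at least `min_members` units and at most
#' `max_uncategorized_fraction` of units remain uncategorized. If no k
#' qualifies, the root categorization (k = 1) is returned with a
#' `criteria_unmet` warning flag.
#'
#' @param C a `fef_consensus` matrix (any distance matrix works).
#' @param criteria a [membership_criteria()].
#' @return list of class `fef_consensus_fit`: `categorization` (a
#'   `fef_categorization`, provenance `"consensus"`), `tree` (`fef_tree`),
#'   `k`, `criteria`, `flag` (`NA` or `"criteria_unmet"`), and
#'   `candidates` (tibble of every k examined with its uncategorized
#'   fraction and minimum category size).
#' @export
consensus_categories <- function(C, criteria = membership_criteria()) {
  tree <- agglomerate(C)
  rows <- list()
  best <- NULL
  for (k in seq_len(criteria$k_max)) {
    ct <- cut_categories(tree, k, criteria$min_members)
    if (is.na(attr(ct, "cut_step"))) next
    uf <- uncategorized_fraction(ct)
    sizes <- table(ct$label[ct$label != "uncategorized"])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      k = k, uncategorized_fraction = uf,
      min_category_size = as.integer(min(sizes)),
      satisfies = uf <= criteria$max_uncategorized_fraction)
    if (uf <= criteria$max_uncategorized_fraction) best <- ct
  }
  flag <- NA_character_
  if (is.null(best)) {
    best <- cut_categories(tree, 1L, 1L)
    flag <- "criteria_unmet"
  }
  attr(best, "provenance") <- "consensus"
  structure(list(
    categorization = best,
    tree = tree,
    k = n_categories(best),
    criteria = criteria,
    flag = flag,
    candidates = dplyr::bind_rows(rows)
  ), class = "fef_consensus_fit")
}

#' @export
print.fef_consensus_fit <- function(x, ...) {
  cat(sprintf("<fef_consensus_fit> k = %d, %.1f%% uncategorized%s\n",
              x$k, 100 * uncategorized_fraction(x$categorization),
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
tidy.fef_consensus_fit <- function(x, ...) {
  tibble::as_tibble(x$categorization)
}

#' @export
glance.fef_consensus_fit <- function(x, ...) {
  g <- glance.fef_categorization(x$categorization)
  g$flag <- x$flag
  g
}

#' Plot the consensus dendrogram with category colours
#' @param object a `fef_consensus_fit`.
#' @param ... unused.
#' @export
autoplot.fef_consensus_fit <- function(object, ...) {
  hc <- as.hclust.fef_tree(object$tree)
  ord <- hc$labels[hc$order]
  df <- tibble::as_tibble(object$categorization)
  df$unit_id <- factor(df$unit_id, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit_id, y = 1,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = "units (dendrogram order)", y = NULL,
                  fill = "category")
}

#' Tidy a consensus (or distance) matrix into unit pairs
#' @param x a `fef_consensus` or `fef_dist` matrix.
#' @param ... unused.
#' @export
tidy.fef_consensus <- function(x, ...) {
  m <- unclass(x)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(unit_a = rownames(m)[ut[, 1]],
                 unit_b = colnames(m)[ut[, 2]],
                 distance = m[ut])
}

#' @export
tidy.fef_dist <- tidy.fef_consensus
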