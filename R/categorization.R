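#' Categorization objects
#'
#' A categorization is a tibble with columns `unit_id` and `label`, where
#' the distinguished label `"uncategorized"` marks units absorbed by no
#' category. `k` counts the distinct real (non-uncategorized) labels;
#' `provenance` records which scheme produced it (a pipeline id,
#' `"consensus"`, `"traditional"`, or `"truth"`).
#'
#' @param x data frame with columns `unit_id`, `label`.
#' @param provenance character scalar.
#' @return tibble of class `fef_categorization`.
#' @export
new_categorization <- function(x, provenance = "unknown") {
  stopifnot(is.data.frame(x), all(c("unit_id", "label") %in% names(x)))
  out <- tibble::as_tibble(x[, c("unit_id", "label")])
  out$unit_id <- as.character(out$unit_id)
  out$label <- as.character(out$label)
  attr(out, "provenance") <- provenance
  class(out) <- c("fef_categorization", class(out))
  out
}

#' Number of real categories in a categorization
#' @param cat a `fef_categorization`.
#' @export
n_categories <- function(cat) {
  length(setdiff(unique(cat$label), "uncategorized"))
}

#' Fraction of units left uncategorized
#' @param cat a `fef_categorization`.
#' @export
uncategorized_fraction <- function(cat) {
  mean(cat$label == "uncategorized")
}

#' @export
glance.fef_categorization <- function(x, ...) {
  sizes <- table(x$label[x$label != "uncategorized"])
  tibble::tibble(
    k = n_categories(x),
    n_units = nrow(x),
    uncategorized_fraction = uncategorized_fraction(x),
    min_category_size = if (length(sizes)) min(sizes) else NA_integer_,
    provenance = attr(x, "provenance") %||% "unknown"
  )
}
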