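# Leave-one-out validation of consensus categories with a linear
# least-squares classifier on principal components of the composite
# distance matrix.

one_hot <- function(y_factor) {
  Y <- matrix(0, length(y_factor), nlevels(y_factor))
  Y[cbind(seq_along(y_factor), as.integer(y_factor))] <- 1
  Y
}

# Exact leave-one-out predictions of a one-hot linear least-squares
# classifier (intercept + scores). Uses the hat-matrix identity
# yhat_loo = (yhat - h * y) / (1 - h), algebraically identical to
# refitting with each unit held out.
loo_predict_linear <- function(scores, y_factor) {
  Z <- cbind(1, scores)
  qrZ <- qr(Z)
  Q <- qr.Q(qrZ)
  h <- rowSums(Q^2)
  Y <- one_hot(y_factor)
  Fhat <- Q %*% (t(Q) %*% Y)
  denom <- pmax(1 - h, 1e-12)
  Floo <- (Fhat - h * Y) / denom
  levels(y_factor)[max.col(Floo, ties.method = "first")]
}

refit_loo_predict <- function(scores, y_factor) {
  # explicit per-fold refit; reference implementation used by tests
  Z <- cbind(1, scores)
  Y <- one_hot(y_factor)
  n <- nrow(Z)
  out <- character(n)
  for (i in seq_len(n)) {
    B <- qr.coef(qr(Z[-i, , drop = FALSE]), Y[-i, , drop = FALSE])
    B[is.na(B)] <- 0
    out[i] <- levels(y_factor)[max.col(rbind(Z[i, ] %*% B),
                                       ties.method = "first")]
  }
  out
}

#' Leave-one-out accuracy of a linear classifier on composite components
#'
#' Principal components are computed once from the labelled units' rows of
#' the composite distance matrix (each unit's vector of composite
#' distances to all units, column-centred). For every component count, a
#' multiclass linear least-squares classifier (one-hot labels regressed on
#' the component scores, no regularization; prediction by argmax of the
#' fitted scores, ties to the lowest category index) is evaluated with
#' every labelled unit held out once. Uncategorized units are excluded.
#'
#' @param C composite (`fef_consensus`) or any distance matrix with unit
#'   ids as dimnames.
#' @param labels a `fef_categorization`.
#' @param components component counts to evaluate; counts beyond the
#'   matrix rank are truncated with a warning.
#' @param pca_per_fold if `TRUE`, recompute the principal components
#'   within every fold (slower; the default follows the
#'   components-first-then-folds order).
#' @return object of class `fef_crossval`: list with `curve` (tibble
#'   `n_components`, `accuracy`, `cum_var_explained`), `peak_accuracy`,
#'   `peak_components`, `predictions` (tibble at the peak),
#'   `misclassification` (row = consensus category, column = predicted,
#'   % of row count), `n_units`, `flag`.
#' @export
loo_accuracy_curve <- function(C, labels, components = 1:100,
                               pca_per_fold = FALSE) {
  keep <- labels$unit_id[labels$label != "uncategorized"]
  idx <- match(keep, rownames(C))
  if (anyNA(idx)) stop_bad_arg("labels refer to units missing from the matrix")
  y <- factor(labels$label[labels$label != "uncategorized"])
  flag <- NA_character_
  if (nlevels(y) < 2L) flag <- "single_class"
  X <- unclass(C)[idx, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > 1e-10
  rank <- sum(pos)
  cum_var <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  if (max(components) > rank) {
    warning(sprintf("component range truncated to matrix rank %d", rank),
            call. = FALSE)
    components <- components[components <= rank]
  }
  acc <- vapply(components, function(nc) {
    pred <- if (pca_per_fold) {
      refit_loo_predict_pca(X, y, nc)
    } else {
      loo_predict_linear(pc$x[, seq_len(nc), drop = FALSE], y)
    }
    mean(pred == as.character(y))
  }, numeric(1))
  peak_i <- which.max(acc)
  peak_nc <- components[peak_i]
  pred_peak <- loo_predict_linear(pc$x[, seq_len(peak_nc), drop = FALSE], y)

  lev <- levels(y)
  mis <- 100 * prop.table(table(factor(as.character(y), lev),
                                factor(pred_peak, lev)), margin = 1)
  structure(list(
    curve = tibble::tibble(n_components = components, accuracy = acc,
                           cum_var_explained = cum_var[components]),
    peak_accuracy = acc[peak_i],
    peak_components = peak_nc,
    predictions = tibble::tibble(unit_id = keep,
                                 consensus = as.character(y),
                                 predicted = pred_peak),
    misclassification = unclass(mis),
    n_units = length(keep),
    flag = flag
  ), class = "fef_crossval")
}

refit_loo_predict_pca <- function(X, y, nc) {
  n <- nrow(X)
  out <- character(n)
  for (i in seq_len(n)) {
    pc <- stats::prcomp(X[-i, , drop = FALSE], center = TRUE)
    tr_scores <- pc$x[, seq_len(nc), drop = FALSE]
    te_score <- scale(X[i, , drop = FALSE], center = pc$center,
                      scale = FALSE) %*% pc$rotation[, seq_len(nc), drop = FALSE]
    Z <- cbind(1, tr_scores)
    Y <- one_hot(y[-i])
    B <- qr.coef(qr(Z), Y)
    B[is.na(B)] <- 0
    out[i] <- levels(y)[max.col(cbind(1, te_score) %*% B,
                                ties.method = "first")]
  }
  out
}

#' @export
print.fef_crossval <- function(x, ...) {
  cat(sprintf("<fef_crossval> peak accuracy %.1f%% at %d components (%d units)\n",
              100 * x$peak_accuracy, x$peak_components, x$n_units))
  invisible(x)
}

#' @export
tidy.fef_crossval <- function(x, ...) x$curve

#' @export
glance.fef_crossval <- function(x, ...) {
  tibble::tibble(peak_accuracy = x$peak_accuracy,
                 peak_components = x$peak_components,
                 n_units = x$n_units, flag = x$flag)
}

#' @export
autoplot.fef_crossval <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$n_components, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_components, linetype = 2) +
    ggplot2::labs(x = "principal components", y = "LOO accuracy")
}

#' Label-shuffle control for the leave-one-out classifier
#'
#' Repeats the leave-one-out evaluation at a fixed component count with
#' the category assignments randomly permuted, yielding the chance
#' accuracy distribution; `p` is the proportion of shuffled accuracies at
#' or above the observed accuracy at that component count.
#'
#' @inheritParams loo_accuracy_curve
#' @param n_components component count used for every shuffle.
#' @param shuffles number of permutations.
#' @param seed RNG seed.
#' @return tibble of class `fef_shuffle`: `observed_accuracy`,
#'   `shuffle_mean`, `shuffle_sd`, `shuffle_min`, `shuffle_max`,
#'   `p_value`, `shuffles`; shuffled accuracies in attribute `shuffled`.
#' @export
shuffle_control <- function(C, labels, n_components = 8, shuffles = 1000,
                            seed = 1L) {
  keep <- labels$unit_id[labels$label != "uncategorized"]
  idx <- match(keep, rownames(C))
  y <- factor(labels$label[labels$label != "uncategorized"])
  X <- unclass(C)[idx, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nc <- min(n_components, sum(pc$sdev > 1e-10))
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  observed <- mean(loo_predict_linear(scores, y) == as.character(y))
  shuf <- with_seed(seed, {
    vapply(seq_len(shuffles), function(i) {
      ys <- factor(sample(as.character(y)), levels(y))
      mean(loo_predict_linear(scores, ys) == as.character(ys))
    }, numeric(1))
  })
  out <- tibble::tibble(
    observed_accuracy = observed,
    shuffle_mean = mean(shuf),
    shuffle_sd = stats::sd(shuf),
    shuffle_min = min(shuf),
    shuffle_max = max(shuf),
    p_value = mean(shuf >= observed),
    shuffles = as.integer(shuffles))
  attr(out, "shuffled") <- shuf
  class(out) <- c("fef_shuffle", class(out))
  out
}
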