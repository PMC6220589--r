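#' Agglomerative clustering with group-average linkage
#'
#' Starting from one group per unit, repeatedly merges the two groups with
#' the smallest inter-group distance, where the distance between groups is
#' the arithmetic mean of all cross-group member pairwise distances (a
#' weighted average, so similarity is not skewed by uneven group sizes).
#' Ties are broken deterministically in favour of the pair containing the
#' lexicographically smallest original unit indices. The full merge history
#' (heights and memberships) is recorded.
#'
#' @param D symmetric distance matrix (`fef_dist` or plain matrix) with
#'   finite entries, n >= 2.
#' @return object of class `fef_tree`: list with hclust-style `merge`
#'   (n-1 x 2; negative entries are leaves), `height`, `labels`, and `n`.
#' @export
agglomerate <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_bad_arg("`D` must be square")
  if (any(!is.finite(D))) stop_bad_arg("`D` contains non-finite entries")
  n <- nrow(D)
  if (n < 2L) stop_bad_arg("need at least 2 units to agglomerate")
  labels <- rownames(D) %||% as.character(seq_len(n))

  d <- D
  diag(d) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)          # hclust code of each active group
  sig <- seq_len(n)            # smallest original member, for tie-breaks
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    mval <- min(sub)
    hits <- which(sub == mval, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    # deterministic tie-break on the original-unit signatures of the pair
    key_lo <- pmin(sig[idx[hits[, 1]]], sig[idx[hits[, 2]]])
    key_hi <- pmax(sig[idx[hits[, 1]]], sig[idx[hits[, 2]]])
    pick <- order(key_lo, key_hi)[1]
    i <- idx[hits[pick, 1]]; j <- idx[hits[pick, 2]]

    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- mval

    # Lance-Williams update for group-average linkage: the merged group's
    # distance to k is the size-weighted mean of the members' distances.
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      d[i, others] <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[others, i] <- d[i, others]
    }
    size[i] <- size[i] + size[j]
    sig[i] <- min(sig[i], sig[j])
    node[i] <- step
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = height, labels = labels, n = n),
            class = "fef_tree")
}

#' @export
print.fef_tree <- function(x, ...) {
  cat(sprintf("<fef_tree> %d leaves, %d merges, heights [%.3g, %.3g]\n",
              x$n, length(x$height), min(x$height), max(x$height)))
  invisible(x)
}

# Membership snapshots: row m+1 gives the group id of each unit after m
# merges (0 = no merges). Groups are numbered by their smallest original
# member.
all_memberships <- function(tree) {
  n <- tree$n
  M <- matrix(0L, n, n)
  g <- seq_len(n)
  M[1, ] <- g
  grp <- vector("list", nrow(tree$merge))
  for (s in seq_len(n - 1L)) {
    members <- unlist(lapply(tree$merge[s, ], function(code) {
      if (code < 0) -code else grp[[code]]
    }))
    grp[[s]] <- members
    g[members] <- min(g[members])
    M[s + 1L, ] <- g
  }
  M
}

# Group membership vector after `m` merges.
membership_at <- function(tree, m) all_memberships(tree)[m + 1L, ]

#' Convert a merge tree to an hclust object
#' @param x a `fef_tree`.
#' @param ... unused.
#' @export
as.hclust.fef_tree <- function(x, ...) {
  # leaf ordering by recursive traversal of the merge matrix
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(x$merge[code, 1]), walk(x$merge[code, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = walk(nrow(x$merge)),
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "user"),
            class = "hclust")
}

#' Export a merge tree as a Newick string
#'
#' Branch lengths are derived from merge heights. Heights on a composite
#' z-score scale can be negative; they are shifted to a non-negative scale
#' for export.
#' @param tree a `fef_tree`.
#' @param file optional path; when given, writes the Newick file.
#' @export
tree_newick <- function(tree, file = NULL) {
  hc <- as.hclust.fef_tree(tree)
  shift <- min(0, min(hc$height))
  hc$height <- hc$height - shift + 1e-9
  ph <- ape::as.phylo(hc)
  if (is.null(file)) ape::write.tree(ph) else ape::write.tree(ph, file = file)
}

#' Cut a merge tree into k categories under a membership floor
#'
#' Walks the merge history from the final agglomeration back toward the
#' start and returns the most recent partition state containing exactly
#' `k` groups of at least `min_members` units. Units outside those groups
#' are labelled `"uncategorized"`. If no state qualifies, every unit is
#' uncategorized (k = 0): absence is a valid result.
#'
#' @param tree a `fef_tree`.
#' @param k requested number of categories (>= 1).
#' @param min_members minimum category size.
#' @return a `fef_categorization` with attribute `cut_step` (number of
#'   merges applied at the returned state, `NA` if none qualified).
#' @export
cut_categories <- function(tree, k, min_members = 10) {
  if (k < 1L) stop_bad_arg("`k` must be >= 1")
  n <- tree$n
  M <- all_memberships(tree)
  for (m in (n - 1L):0) {
    g <- M[m + 1L, ]
    sizes <- table(g)
    big <- names(sizes)[sizes >= min_members]
    if (length(big) == k) {
      lab <- ifelse(g %in% as.integer(big),
                    paste0("C", match(g, sort(as.integer(big)))),
                    "uncategorized")
      out <- new_categorization(
        tibble::tibble(unit_id = tree$labels, label = lab),
        provenance = "cut")
      attr(out, "cut_step") <- m
      return(out)
    }
    if (m == 0L) break
  }
  out <- new_categorization(
    tibble::tibble(unit_id = tree$labels, label = "uncategorized"),
    provenance = "cut")
  attr(out, "cut_step") <- NA_integer_
  out
}

#' Intracluster dispersion of a categorization
#'
#' Sum over categories of the mean within-category pairwise distance
#' weighted by category size (the gap statistic's W up to a constant);
#' uncategorized units are excluded.
#'
#' @param D distance matrix with unit ids as dimnames.
#' @param cat a `fef_categorization`.
#' @export
intracluster_dispersion <- function(D, cat) {
  D <- unclass(D)
  total <- 0
  for (lab in setdiff(unique(cat$label), "uncategorized")) {
    ids <- cat$unit_id[cat$label == lab]
    idx <- match(ids, rownames(D))
    if (length(idx) < 2L) next
    sub <- D[idx, idx]
    total <- total + length(idx) * mean(sub[upper.tri(sub)])
  }
  total
}

#' Select the number of categories by the gap procedure
#'
#' Compares the reduction in intracluster dispersion on the data against
#' randomized null sets with no intrinsic clustering (uniform samples
#' within the per-dimension range of the features). The strict rule picks
#' the first k whose gap exceeds the next k's gap minus its null SD; the
#' lenient variant reports every k meeting that criterion as a candidate
#' for inspection. When no usable null can be built (features absent, or a
#' degenerate null), the fallback identifies the inflection of the
#' dispersion curve (largest second difference).
#'
#' @param features units x dims matrix; when `NULL`, `D` must be given and
#'   the inflection fallback is used.
#' @param D optional precomputed distance matrix (built from `features`
#'   with `metric` when absent).
#' @param metric metric for feature-space distances.
#' @param k_range candidate k values, within 1..20.
#' @param min_members membership floor passed to [cut_categories()].
#' @param n_null number of null reference sets.
#' @param seed RNG seed for the nulls.
#' @return object of class `fef_gap`: list with `curve` (tibble per k:
#'   `k`, `W_obs`, `null_mean`, `null_sd`, `gap`, `gap_sd`), `candidates`,
#'   `inflection_k`, `chosen_k`, `method`.
#' @export
gap_select_k <- function(features = NULL, D = NULL,
                         metric = "euclidean", k_range = 1:10,
                         min_members = 10, n_null = 20, seed = 1L) {
  if (any(k_range < 1) || any(k_range > 20)) {
    stop_bad_arg("`k_range` must lie within [1, 20]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (is.null(D)) {
    if (is.null(features)) stop_bad_arg("supply `features` or `D`")
    if (is.null(rownames(features))) {
      rownames(features) <- as.character(seq_len(nrow(features)))
    }
    D <- pairwise_distance(features, metric)
  }
  w_curve <- function(Dm) {
    tr <- agglomerate(Dm)
    vapply(k_range, function(k) {
      ct <- cut_categories(tr, k, min_members)
      if (is.na(attr(ct, "cut_step"))) NA_real_
      else intracluster_dispersion(Dm, ct)
    }, numeric(1))
  }
  W_obs <- w_curve(D)
  # ks with no qualifying cut (or zero dispersion) drop out of the
  # comparison rather than voiding the whole procedure
  usable <- is.finite(W_obs) & W_obs > 0

  null_ok <- !is.null(features) && sum(usable) >= 2L
  null_mean <- null_sd <- gap <- gap_sd <- rep(NA_real_, length(k_range))
  if (null_ok) {
    logW_null <- with_seed(seed, {
      rng_lo <- apply(features, 2, min)
      rng_hi <- apply(features, 2, max)
      t(vapply(seq_len(n_null), function(b) {
        nf <- vapply(seq_along(rng_lo),
                     function(j) stats::runif(nrow(features), rng_lo[j], rng_hi[j]),
                     numeric(nrow(features)))
        nf <- matrix(nf, nrow = nrow(features))
        rownames(nf) <- rownames(features)
        log(w_curve(pairwise_distance(nf, metric)))
      }, numeric(length(k_range))))
    })
    usable <- usable & apply(logW_null, 2, function(x) all(is.finite(x)))
    if (sum(usable) < 2L) {
      null_ok <- FALSE
    } else {
      u <- usable
      null_mean[u] <- exp(colMeans(logW_null[, u, drop = FALSE]))
      null_sd[u] <- apply(exp(logW_null[, u, drop = FALSE]), 2, stats::sd)
      gap[u] <- colMeans(logW_null[, u, drop = FALSE]) - log(W_obs[u])
      gap_sd[u] <- apply(logW_null[, u, drop = FALSE], 2, stats::sd) *
        sqrt(1 + 1 / n_null)
    }
  }

  # inflection: largest second difference of the dispersion-vs-k curve,
  # over the contiguous leading stretch where dispersion is defined
  inflection_k <- NA_integer_
  fin <- which(is.finite(W_obs))
  if (length(fin) >= 3L) {
    lead <- fin[seq_len(which.max(diff(c(fin, Inf)) > 1))]
    if (length(lead) >= 3L) {
      d2 <- diff(diff(W_obs[lead]))
      inflection_k <- k_range[lead][which.max(d2) + 1L]
    }
  }

  candidates <- integer(0)
  chosen <- NA_integer_
  method <- "inflection"
  if (null_ok) {
    u <- which(usable)
    ok <- gap_strict_candidates(gap[u], gap_sd[u], k_range[u])
    candidates <- ok
    if (length(ok)) {
      chosen <- ok[1]
      method <- "strict"
    }
  }
  if (is.na(chosen)) chosen <- inflection_k
  if (is.na(chosen) && any(is.finite(W_obs))) {
    # neither rule resolves (e.g. too few usable ks): prefer parsimony
    chosen <- k_range[which(is.finite(W_obs))[1]]
    method <- "parsimony"
  }

  structure(list(
    curve = tibble::tibble(k = k_range, W_obs = W_obs,
                           null_mean = null_mean, null_sd = null_sd,
                           gap = gap, gap_sd = gap_sd),
    candidates = candidates,
    inflection_k = inflection_k,
    chosen_k = chosen,
    method = method
  ), class = "fef_gap")
}

# k values satisfying gap(k) >= gap(k+1) - sd(k+1); the last k qualifies
# vacuously only if its gap is defined, and is excluded.
gap_strict_candidates <- function(gap, gap_sd, k_range) {
  nk <- length(k_range)
  if (nk < 2L) return(integer(0))
  ok <- which(gap[-nk] >= gap[-1] - gap_sd[-1])
  k_range[ok]
}

#' @export
tidy.fef_gap <- function(x, ...) x$curve

#' @export
glance.fef_gap <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, method = x$method,
                 n_candidates = length(x$candidates),
                 inflection_k = x$inflection_k)
}

#' @export
autoplot.fef_gap <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$gap_sd,
                                          ymax = .data$gap + .data$gap_sd)) +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::labs(x = "number of categories k", y = "gap statistic")
}
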