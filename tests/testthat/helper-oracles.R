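# Independent brute-force oracles. These deliberately re-derive each
# quantity by explicit loops over the definitions, sharing no code with the
# implementation paths they check.

# Naive agglomeration: at every step, the inter-group distance is the mean
# of all cross-group leaf pairwise distances, recomputed from scratch by a
# double loop. Ties go to the pair with the smallest original indices.
oracle_linkage <- function(D) {
  n <- nrow(D)
  groups <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(groups) > 1L) {
    best <- NULL
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        tot <- 0
        for (x in groups[[i]]) for (y in groups[[j]]) tot <- tot + D[x, y]
        d <- tot / (length(groups[[i]]) * length(groups[[j]]))
        key <- c(min(min(groups[[i]]), min(groups[[j]])),
                 max(min(groups[[i]]), min(groups[[j]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(d = d, i = i, j = j, key = key)
        }
      }
    }
    merged <- sort(c(groups[[best$i]], groups[[best$j]]))
    groups <- c(groups[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$d)
    memb <- integer(n)
    for (g in groups) memb[g] <- min(g)
    partitions[[length(partitions) + 1L]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# ARI by explicit enumeration of all unit pairs.
oracle_ari <- function(la, lb) {
  n <- length(la)
  a11 <- a10 <- a01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- la[i] == la[j]; sb <- lb[i] == lb[j]
      if (sa && sb) a11 <- a11 + 1
      else if (sa) a10 <- a10 + 1
      else if (sb) a01 <- a01 + 1
    }
  }
  np <- n * (n - 1) / 2
  expected <- (a11 + a10) * (a11 + a01) / np
  maxi <- ((a11 + a10) + (a11 + a01)) / 2
  if (maxi == expected) return(NA_real_)
  (a11 - expected) / (maxi - expected)
}

# Penalized ratio of variances by explicit loops over categories, time
# points and members.
oracle_rov <- function(labels, X) {
  cats <- setdiff(unique(labels), "uncategorized")
  per_cat <- numeric(0)
  for (cl in cats) {
    rows <- which(labels == cl)
    Nt <- ncol(X)
    xbar <- numeric(Nt)
    for (t in seq_len(Nt)) xbar[t] <- mean(X[rows, t])
    ms <- 0
    for (t in seq_len(Nt)) ms <- ms + (xbar[t] - mean(xbar))^2
    ms <- ms / Nt
    if (ms == 0) next
    ratios <- numeric(Nt)
    for (t in seq_len(Nt)) {
      w <- 0
      for (i in rows) w <- w + (X[i, t] - xbar[t])^2
      ratios[t] <- (w / length(rows)) / ms
    }
    per_cat <- c(per_cat, mean(ratios))
  }
  sqrt(length(cats)) * mean(per_cat)
}

# Signed chi-square cells by explicit loops.
oracle_signed_chi2 <- function(la, lb) {
  ca <- sort(unique(la)); cb <- sort(unique(lb))
  n <- length(la)
  S <- matrix(NA_real_, length(ca), length(cb), dimnames = list(ca, cb))
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      O <- sum(la == ca[i] & lb == cb[j])
      E <- n * (sum(la == ca[i]) / n) * (sum(lb == cb[j]) / n)
      if (E > 0) S[i, j] <- (O - E) / E
    }
  }
  S
}

# Kruskal-Wallis H from ranks, no ties assumed.
oracle_kruskal_h <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  h <- 0
  for (cl in unique(g)) {
    rs <- sum(r[g == cl])
    h <- h + rs^2 / sum(g == cl)
  }
  12 / (n * (n + 1)) * h - 3 * (n + 1)
}

# Per-timepoint cross-unit skewness, averaged, by explicit loops.
oracle_skewness_index <- function(mat) {
  vals <- numeric(ncol(mat))
  for (t in seq_len(ncol(mat))) {
    x <- mat[, t]
    m <- mean(x); s <- sqrt(mean((x - m)^2))
    vals[t] <- if (s == 0) 0 else mean((x - m)^3) / s^3
  }
  mean(vals)
}
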