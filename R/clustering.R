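# How many behavior partitions? Gap statistic, elbow and silhouette on the
# (z-scored) metric table, combined by majority vote. k-means is the
# clustering engine throughout: the three diagnostics are all classically
# paired with it.

# z-score columns; zero-variance columns become 0.
zscore <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)
}

#' k-means partition of a metric table
#'
#' Features are z-scored internally; the best of `n_restarts` random starts
#' by total within-cluster sum of squares is returned. Deterministic given
#' `seed`.
#'
#' @param table Numeric data frame or matrix (rows = tracks).
#' @param k Number of clusters, `1 <= k <= nrow(table)`.
#' @param n_restarts Random restarts; default 25.
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @return List with `assignments` (integer vector), `centers` (k x p matrix
#'   in z-score space), `wss` (total within-cluster sum of squares).
#' @export
kmeans_partition <- function(table, k, n_restarts = 25, seed = NULL) {
  x <- zscore(table)
  if (k < 1 || k > nrow(x)) stopf("k must be in [1, nrow(table)]")
  if (k == nrow(x)) {
    # every point its own cluster: exact, and stats::kmeans refuses k = n
    return(list(assignments = seq_len(nrow(x)), centers = x, wss = 0))
  }
  with_seed(seed, {
    fit <- suppressWarnings(
      kmeans(x, centers = k, nstart = n_restarts, iter.max = 100))
    list(assignments = unname(fit$cluster), centers = fit$centers,
         wss = fit$tot.withinss)
  })
}

#' Gap statistic for the number of clusters
#'
#' For each k, Gap(k) = mean_b log W*_kb - log W_k, where W_k is the
#' within-cluster sum of squares of [kmeans_partition()] on the z-scored
#' data and the W*_kb come from B reference datasets drawn uniformly over
#' the per-feature observed ranges. The reported choice is the smallest k
#' with Gap(k) >= Gap(k+1) - SE(k+1) (the classical one-standard-error
#' rule); if no k satisfies it, `k_max` is chosen.
#'
#' @param table Numeric data frame or matrix.
#' @param k_max Largest k tested.
#' @param B Number of reference datasets; default 50.
#' @param seed Integer seed.
#' @param n_restarts k-means restarts per fit; default 10.
#' @return List with `gap` (data frame `k`, `gap`, `se`, `log_w`) and
#'   `chosen_k`.
#' @export
gap_statistic <- function(table, k_max, B = 50, seed = NULL,
                          n_restarts = 10) {
  if (k_max < 1) stopf("k_max must be >= 1")
  if (B < 2) stopf("B must be >= 2")
  x <- zscore(table)
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    stopf("degenerate table: all rows identical")
  }
  rng <- apply(x, 2, range)
  with_seed(seed, {
    log_w <- vapply(seq_len(k_max), function(k) {
      log(suppressWarnings(
        kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
      )$tot.withinss)
    }, numeric(1))
    log_w_star <- matrix(NA_real_, nrow = B, ncol = k_max)
    for (b in seq_len(B)) {
      ref <- vapply(seq_len(ncol(x)), function(j)
        runif(nrow(x), rng[1, j], rng[2, j]), numeric(nrow(x)))
      for (k in seq_len(k_max)) {
        log_w_star[b, k] <- log(suppressWarnings(
          kmeans(ref, centers = k, nstart = n_restarts, iter.max = 100)
        )$tot.withinss)
      }
    }
    gap <- colMeans(log_w_star) - log_w
    se <- apply(log_w_star, 2, sd) * sqrt(1 + 1 / B)
    chosen <- k_max
    for (k in seq_len(k_max - 1)) {
      if (gap[k] >= gap[k + 1] - se[k + 1]) { chosen <- k; break }
    }
    list(gap = data.frame(k = seq_len(k_max), gap = gap, se = se,
                          log_w = log_w),
         chosen_k = chosen)
  })
}

#' Silhouette and elbow diagnostics over a range of k
#'
#' Mean silhouette width (from [cluster::silhouette()]) per k >= 2, and the
#' within-cluster sum-of-squares curve with its elbow located by maximum
#' distance to the chord joining the curve's endpoints (Kneedle-style
#' maximum curvature).
#'
#' @param table Numeric data frame or matrix.
#' @param k_range Integer vector of k values (silhouette is only defined for
#'   k >= 2).
#' @param n_restarts k-means restarts; default 25.
#' @param seed Integer seed.
#' @return List with `wss` (data frame `k`, `wss`), `silhouette` (data frame
#'   `k`, `mean_width`; k >= 2 only), `elbow_k`, `silhouette_k`.
#' @export
silhouette_and_elbow <- function(table, k_range, n_restarts = 25,
                                 seed = NULL) {
  x <- zscore(table)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > nrow(x)) {
    stopf("k_range must lie within [1, nrow(table)]")
  }
  with_seed(seed, {
    d <- dist(x)
    wss <- numeric(length(k_range))
    sil <- rep(NA_real_, length(k_range))
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      fit <- suppressWarnings(
        kmeans(x, centers = k, nstart = n_restarts, iter.max = 100))
      wss[i] <- fit$tot.withinss
      if (k >= 2) {
        sil[i] <- mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
      }
    }
    # elbow: farthest point below the chord from first to last (k, wss)
    elbow_k <- k_range[1]
    if (length(k_range) >= 3) {
      p1 <- c(k_range[1], wss[1])
      p2 <- c(k_range[length(k_range)], wss[length(wss)])
      v <- p2 - p1
      dist_to_chord <- vapply(seq_along(k_range), function(i) {
        w <- c(k_range[i], wss[i]) - p1
        abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
      }, numeric(1))
      elbow_k <- k_range[which.max(dist_to_chord)]
    }
    sil_ok <- which(!is.na(sil))
    silhouette_k <- if (length(sil_ok) > 0) {
      k_range[sil_ok[which.max(sil[sil_ok])]]
    } else {
      NA_integer_
    }
    list(wss = data.frame(k = k_range, wss = wss),
         silhouette = data.frame(k = k_range[sil_ok],
                                 mean_width = sil[sil_ok]),
         elbow_k = elbow_k, silhouette_k = silhouette_k)
  })
}

#' Consensus choice of the number of behavior partitions
#'
#' Runs the gap statistic, elbow and silhouette diagnostics and combines
#' their votes: majority wins; with three distinct votes the priority is
#' gap > silhouette > elbow.
#'
#' @param table Numeric metric data frame (no id column).
#' @param k_range Candidate k values; default 1:10.
#' @param B Gap-statistic reference sets; default 50.
#' @param seed Integer seed.
#' @return List of class `bb_k_selection`: `votes` (named integer vector),
#'   `consensus_k`, plus the per-method reports (`gap`, `wss`,
#'   `silhouette`).
#' @export
select_k <- function(table, k_range = 1:10, B = 50, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  gs <- gap_statistic(table, k_max = max(k_range), B = B,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  se_el <- silhouette_and_elbow(table, k_range,
                                seed = if (is.null(seed)) NULL
                                       else derive_seed(seed, 2))
  votes <- c(gap = gs$chosen_k, silhouette = se_el$silhouette_k,
             elbow = se_el$elbow_k)
  structure(
    list(votes = votes, consensus_k = select_k_consensus(votes),
         gap = gs$gap, wss = se_el$wss, silhouette = se_el$silhouette),
    class = "bb_k_selection")
}

#' Combine the three k votes
#'
#' @param votes Named integer vector with entries `gap`, `silhouette`,
#'   `elbow`.
#' @return The majority k; if all three differ, the gap statistic's vote
#'   (priority gap > silhouette > elbow).
#' @export
select_k_consensus <- function(votes) {
  need <- c("gap", "silhouette", "elbow")
  if (!all(need %in% names(votes))) {
    stopf("votes must name gap, silhouette and elbow")
  }
  v <- votes[need]
  v <- v[!is.na(v)]
  tab <- table(v)
  if (max(tab) >= 2) {
    as.integer(names(tab)[which.max(tab)])
  } else {
    as.integer(votes[["gap"]])
  }
}

#' @export
print.bb_k_selection <- function(x, ...) {
  cat("<bb_k_selection>\n  votes:",
      paste(sprintf("%s = %s", names(x$votes), x$votes), collapse = ", "),
      sprintf("\n  consensus k = %d\n", x$consensus_k))
  invisible(x)
}
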