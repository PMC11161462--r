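# Deployment-level bait-attraction analysis: hourly activity/interest
# series per deployment and rank-based comparison of bait types.

#' Hourly activity and interest series of one deployment
#'
#' Bins a deployment's tracks into hour-of-deployment bins. A track counts
#' as active in every hour bin its frame span touches (so a split track's
#' fragments each count — mirroring how fragmented tracking inflates
#' counts), and as interested in those bins when its predicted label is
#' Interested.
#'
#' @param tracks Track table of the deployment.
#' @param predictions Data frame with `track_id` and `label`
#'   (Interested/Uninterested), e.g. from [predict_interest()]. Every
#'   prediction must refer to a track present in `tracks`.
#' @param meta A [deployment_meta()].
#' @param fps Frames per second used to convert frame indices to time.
#' @return Data frame with one row per hour bin: `bait_type`, `day_id`,
#'   `hour_bin` (0-based), `n_tracks_active`, `n_tracks_interested`.
#' @export
hourly_aggregate <- function(tracks, predictions, meta, fps = 5) {
  tracks <- as_track_table(tracks)
  stopifnot(inherits(meta, "bb_deployment_meta"))
  unknown <- setdiff(predictions$track_id, tracks$track_id)
  if (length(unknown) > 0) {
    stopf("prediction for unknown track id %s", unknown[1])
  }
  n_bins <- ceiling(meta$duration_h)
  bins <- data.frame(bait_type = meta$bait_type, day_id = meta$day_id,
                     hour_bin = seq_len(n_bins) - 1L,
                     n_tracks_active = 0L, n_tracks_interested = 0L,
                     stringsAsFactors = FALSE)
  if (nrow(tracks) == 0) return(bins)
  label_of <- setNames(predictions$label, predictions$track_id)
  for (id in unique(tracks$track_id)) {
    fr <- range(tracks$frame_index[tracks$track_id == id])
    h0 <- floor(fr[1] / (fps * 3600))
    h1 <- floor(fr[2] / (fps * 3600))
    touched <- intersect(h0:h1, bins$hour_bin)
    if (length(touched) == 0) next
    sel <- bins$hour_bin %in% touched
    bins$n_tracks_active[sel] <- bins$n_tracks_active[sel] + 1L
    if (identical(unname(label_of[as.character(id)]), "Interested")) {
      bins$n_tracks_interested[sel] <- bins$n_tracks_interested[sel] + 1L
    }
  }
  bins
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] (rank-based H with tie
#' correction, chi-squared reference with g - 1 degrees of freedom), with
#' the degenerate all-identical case defined as H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return List `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stopf("every group must be non-empty")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn post-hoc pairwise comparisons
#'
#' Pairwise z statistics from mean ranks with the tie correction
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' where \eqn{T = \sum (t^3 - t) / (12 (N - 1))} sums over tie groups;
#' two-sided p values adjusted by the chosen method.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust Multiplicity adjustment: `"holm"` (default),
#'   `"bonferroni"` or `"bh"` (Benjamini-Hochberg).
#' @return Data frame `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = c("holm", "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stopf("need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- base::table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    denom <- sqrt((N * (N + 1) / 12 - tie_corr) *
                    (1 / n_i[[i]] + 1 / n_i[[j]]))
    z <- if (denom > 0) (mean_rank[[i]] - mean_rank[[j]]) / denom else 0
    data.frame(group1 = i, group2 = j, z = z,
               p_raw = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_raw, method = adjust)
  rownames(out) <- NULL
  out
}

#' Compare bait types from hourly interest series
#'
#' Builds one observation group per bait type — by default the total
#' interested-track count of each deployment (a small-sample rank test over
#' trials), alternatively every hourly count — and runs the Kruskal-Wallis
#' test plus Dunn post-hoc pairwise comparisons.
#'
#' @param hourly Data frame as returned by (rows of) [hourly_aggregate()]
#'   over several deployments; needs columns `bait_type`, `day_id`,
#'   `n_tracks_interested`.
#' @param contrast `"per_deployment_total"` (default) or `"per_hour"`.
#' @param adjust Dunn adjustment method, default `"holm"`.
#' @return List of class `bb_bait_comparison`: `kw` (`H`, `df`, `p`),
#'   `dunn` (pair table), `groups` (the observation groups used).
#' @export
compare_baits <- function(hourly,
                          contrast = c("per_deployment_total", "per_hour"),
                          adjust = "holm") {
  contrast <- match.arg(contrast)
  need <- c("bait_type", "day_id", "n_tracks_interested")
  missing_cols <- setdiff(need, names(hourly))
  if (length(missing_cols) > 0) {
    stopf("hourly table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  baits <- unique(hourly$bait_type)
  if (length(baits) < 2) stopf("need >= 2 bait types to compare")
  groups <- lapply(setNames(baits, baits), function(bt) {
    sub <- hourly[hourly$bait_type == bt, , drop = FALSE]
    if (contrast == "per_deployment_total") {
      as.numeric(tapply(sub$n_tracks_interested, sub$day_id, sum))
    } else {
      as.numeric(sub$n_tracks_interested)
    }
  })
  structure(
    list(kw = kruskal_wallis(groups),
         dunn = dunn_posthoc(groups, adjust = adjust),
         groups = groups, contrast = contrast),
    class = "bb_bait_comparison")
}

#' @export
print.bb_bait_comparison <- function(x, ...) {
  cat(sprintf("<bb_bait_comparison> (%s) Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
              x$contrast, x$kw$H, x$kw$df, x$kw$p))
  print(x$dunn, digits = 4)
  invisible(x)
}
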