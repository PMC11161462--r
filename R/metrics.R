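# Stimulus-relative trajectory metrics.
#
# Per-step series (Fig.-style quantities measured against the bait point B):
#   d1   step length, px
#   dx, dy signed coordinate changes, px
#   d2   distance from the fish centroid to B, px (defined at every point)
#   alpha absolute movement angle, atan2(dy, dx) in image coordinates
#   turn  wrapped difference of consecutive alphas
#   beta  unsigned angular offset between the step heading and the bearing
#         to B, in [0, pi]
#   R2n  squared net displacement from the track's first point, px^2
#   in_P indicator that the centroid lies in the proximity zone
# The per-track feature vector is a fixed, versioned registry of exactly 104
# named scalars: 10 base series x 9 generic aggregations + 14 track-level
# scalars.

METRIC_BASE_SERIES <- c("d1", "speed", "d2", "dx", "dy", "cos_alpha",
                        "abs_turn", "beta", "R2n", "bbox_area")
METRIC_AGGREGATIONS <- c("mean", "sd", "min", "max", "median", "q10", "q90",
                         "first", "last")
METRIC_SCALARS <- c("n_points", "duration_s", "path_length",
                    "net_displacement", "straightness", "f", "n_P_entries",
                    "longest_P_bout_s", "time_to_first_P_s", "start_d2",
                    "end_d2", "mean_copresent_fish", "max_copresent_fish",
                    "frac_in_A")

#' The versioned metric registry
#'
#' Names and order of the 104 per-track behavioral metrics: the 10 base
#' series (`d1`, `speed`, `d2`, `dx`, `dy`, `cos_alpha`, `abs_turn`, `beta`,
#' `R2n`, `bbox_area`) crossed with 9 aggregations (`mean`, `sd`, `min`,
#' `max`, `median`, `q10`, `q90`, `first`, `last`), plus 14 track-level
#' scalars. Stable across runs; version `"catalog-v1"` is attached as an
#' attribute.
#'
#' @return Character vector of length 104 with attribute `version`.
#' @export
metric_registry <- function() {
  nm <- c(as.vector(t(outer(METRIC_BASE_SERIES, METRIC_AGGREGATIONS,
                            paste, sep = "_"))),
          METRIC_SCALARS)
  attr(nm, "version") <- "catalog-v1"
  nm
}

#' Per-step kinematic and stimulus-relative series of one track
#'
#' @param track Track table rows of a single track (>= 2 detections; the
#'   turning-angle series additionally needs >= 3).
#' @param scene A [scene()].
#' @return A data frame with one row per detection: `frame_index`, `x`, `y`,
#'   `d2`, `in_P`, `in_A`, `R2n`, and step quantities aligned to the arriving
#'   point (`NA` on the first row): `d1`, `dx`, `dy`, `alpha`, `turn`,
#'   `beta`, `dframes`.
#' @details For a zero-length step, `alpha` is undefined and is carried
#'   forward from the previous defined step (0 by convention if the first
#'   step has zero length). `beta` is measured against the bearing to the
#'   bait from the step's starting point. Frame gaps are reported in
#'   `dframes`; `d1`, `dx`, `dy` are the raw displacements over the gap, and
#'   the speed metric divides by `dframes`.
#' @export
compute_step_series <- function(track, scene) {
  track <- as_track_table(track)
  if (length(unique(track$track_id)) > 1) {
    stopf("compute_step_series expects a single track")
  }
  n <- nrow(track)
  if (n < 2) stopf("track too short: need >= 2 detections, got %d", n)
  x <- (track$x1 + track$x2) / 2
  y <- (track$y1 + track$y2) / 2
  B <- scene$bait_point
  A <- scene$annotation_area
  d2 <- sqrt((x - B[1])^2 + (y - B[2])^2)
  in_P <- d2 <= scene$proximity_radius
  in_A <- x >= A[1] & x <= A[3] & y >= A[2] & y <= A[4]
  R2n <- (x - x[1])^2 + (y - y[1])^2
  dx <- c(NA, diff(x))
  dy <- c(NA, diff(y))
  d1 <- sqrt(dx^2 + dy^2)
  dframes <- c(NA, diff(track$frame_index))
  alpha <- rep(NA_real_, n)
  prev_alpha <- 0
  for (t in 2:n) {
    if (d1[t] > 0) prev_alpha <- atan2(dy[t], dx[t])
    alpha[t] <- prev_alpha
  }
  turn <- rep(NA_real_, n)
  if (n >= 3) turn[3:n] <- wrap_angle(alpha[3:n] - alpha[2:(n - 1)])
  bearing <- atan2(B[2] - y, B[1] - x)  # bearing to bait from each point
  beta <- rep(NA_real_, n)
  beta[2:n] <- abs(wrap_angle(alpha[2:n] - bearing[1:(n - 1)]))
  data.frame(frame_index = track$frame_index, x = x, y = y, d2 = d2,
             in_P = in_P, in_A = in_A, R2n = R2n, d1 = d1, dx = dx, dy = dy,
             alpha = alpha, turn = turn, beta = beta, dframes = dframes)
}

# The 9 generic aggregations; empty series -> zeros, length-1 -> sd 0.
aggregate9 <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) return(setNames(numeric(9), METRIC_AGGREGATIONS))
  qs <- unname(quantile(v, c(0.1, 0.9), names = FALSE, type = 7))
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
    min = min(v), max = max(v), median = median(v),
    q10 = qs[1], q90 = qs[2], first = v[1], last = v[length(v)])
}

# Runs of TRUE in a logical vector -> lengths (in points).
run_lengths_true <- function(flag) {
  r <- rle(flag)
  r$lengths[r$values]
}

# Frame span (min, max) per track id; rownames are track ids.
cohort_spans <- function(cohort) {
  if (is.null(cohort)) return(NULL)
  cohort <- as_track_table(cohort)
  if (nrow(cohort) == 0) return(matrix(numeric(0), ncol = 2))
  t(vapply(split(cohort$frame_index, cohort$track_id), range, numeric(2)))
}

#' The 104-metric feature vector of one track
#'
#' @param track Track table rows of a single track (>= 2 detections).
#' @param scene A [scene()].
#' @param cohort Optional track table of the whole deployment, used only for
#'   co-presence counts (how many other tracks' frame spans overlap this
#'   track's frames).
#' @return Named numeric vector of length 104 in [metric_registry()] order;
#'   all values finite.
#' @details Conventions keeping every value finite: the standard deviation
#'   of a length-1 series is 0; the turning-angle aggregates of a
#'   2-detection track are 0; a track that never enters the proximity zone
#'   gets `time_to_first_P_s = duration_s + 1`; `straightness` is 0 when the
#'   path length is 0.
#' @export
compute_metric_vector <- function(track, scene, cohort = NULL) {
  ss <- compute_step_series(track, scene)
  track <- as_track_table(track)
  fps <- scene$fps
  n <- nrow(ss)
  steps <- 2:n
  series <- list(
    d1 = ss$d1[steps],
    speed = ss$d1[steps] * fps / ss$dframes[steps],
    d2 = ss$d2,
    dx = ss$dx[steps],
    dy = ss$dy[steps],
    cos_alpha = cos(ss$alpha[steps]),
    abs_turn = if (n >= 3) abs(ss$turn[3:n]) else numeric(0),
    beta = ss$beta[steps],
    R2n = ss$R2n,
    bbox_area = (track$x2 - track$x1) * (track$y2 - track$y1)
  )
  agg <- unlist(lapply(METRIC_BASE_SERIES, function(b) {
    v <- aggregate9(series[[b]])
    setNames(v, paste(b, METRIC_AGGREGATIONS, sep = "_"))
  }))
  duration_s <- (ss$frame_index[n] - ss$frame_index[1]) / fps
  path_length <- sum(ss$d1[steps])
  net_displacement <- sqrt(ss$R2n[n])
  f <- mean(ss$in_P)
  entries <- sum(diff(c(FALSE, ss$in_P)) == 1)
  bouts <- run_lengths_true(ss$in_P)
  longest_P_bout_s <- if (length(bouts) > 0) max(bouts) / fps else 0
  time_to_first_P_s <- if (any(ss$in_P)) {
    (ss$frame_index[which(ss$in_P)[1]] - ss$frame_index[1]) / fps
  } else {
    duration_s + 1
  }
  copresent <- c(mean = 0, max = 0)
  spans <- if (is.matrix(cohort)) cohort else cohort_spans(cohort)
  if (!is.null(spans) && nrow(spans) > 0) {
    own_id <- track$track_id[1]
    spans <- spans[rownames(spans) != as.character(own_id), , drop = FALSE]
    if (nrow(spans) > 0) {
      counts <- vapply(ss$frame_index, function(fr)
        sum(spans[, 1] <= fr & spans[, 2] >= fr), numeric(1))
      copresent <- c(mean = mean(counts), max = max(counts))
    }
  }
  scalars <- c(
    n_points = n,
    duration_s = duration_s,
    path_length = path_length,
    net_displacement = net_displacement,
    straightness = if (path_length > 0) net_displacement / path_length else 0,
    f = f,
    n_P_entries = entries,
    longest_P_bout_s = longest_P_bout_s,
    time_to_first_P_s = time_to_first_P_s,
    start_d2 = ss$d2[1],
    end_d2 = ss$d2[n],
    mean_copresent_fish = unname(copresent["mean"]),
    max_copresent_fish = unname(copresent["max"]),
    frac_in_A = mean(ss$in_A)
  )
  out <- c(agg, scalars)
  stopifnot(identical(names(out), as.vector(metric_registry())),
            all(is.finite(out)))
  out
}

#' Metric table of a whole track set
#'
#' Computes the 104-metric vector for every track with at least two
#' detections; shorter tracks are dropped with a warning giving the count.
#'
#' @param tracks A track table.
#' @param scene A [scene()].
#' @param copresence Use the full track set as co-presence cohort
#'   (default TRUE).
#' @return Data frame with `track_id` plus the 104 registry columns, one row
#'   per surviving track. Attribute `n_dropped_short` records how many
#'   tracks were too short.
#' @export
compute_metric_table <- function(tracks, scene, copresence = TRUE) {
  tracks <- as_track_table(tracks)
  ids <- unique(tracks$track_id)
  sizes <- table(tracks$track_id)
  short <- as.integer(names(sizes)[sizes < 2])
  if (length(short) > 0) {
    warnf("dropping %d single-detection track(s)", length(short))
  }
  keep <- setdiff(ids, short)
  spans <- if (copresence) cohort_spans(tracks) else NULL
  by_id <- split(tracks, tracks$track_id)
  rows <- lapply(keep, function(id) {
    compute_metric_vector(by_id[[as.character(id)]], scene, spans)
  })
  out <- if (length(rows) > 0) {
    cbind(data.frame(track_id = keep),
          as.data.frame(do.call(rbind, rows)))
  } else {
    empty <- as.data.frame(matrix(numeric(0), ncol = 104,
                                  dimnames = list(NULL, metric_registry())))
    cbind(data.frame(track_id = integer(0)), empty)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped_short") <- length(short)
  attr(out, "registry_version") <- attr(metric_registry(), "version")
  out
}
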