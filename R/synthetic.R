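# Synthetic fish-track generator: biased correlated random walks per behavior
# archetype, plus a tracker-imperfection model (dropouts, splits, jitter,
# confidence noise, clutter). All quantitative kinematics are package
# constants chosen to produce the qualitative trajectory shapes of each
# behavior; none are field measurements.

#' Kinematic parameters of one behavior archetype
#'
#' Tracks are biased correlated random walks: at each frame the heading gets
#' a wrapped-normal increment (sd `turn_sd`) plus `bait_bias` times the
#' wrapped angular difference between the bearing-to-bait and the current
#' heading; the step length is truncated-normal(`speed_mean`, `speed_sd`),
#' floored at zero. Positive `bait_bias` attracts toward the bait point,
#' negative repels. `dwell_frames` frames of near-zero speed are spent inside
#' the proximity zone (feeding-type behaviors). `event` adds a scripted rule:
#' `"startle"` (on first entry into the proximity zone, turn by more than
#' 2pi/3 and triple the speed for 10 frames, then avoid the bait),
#' `"retreat_after_dwell"` (once the dwell budget is spent, flip to bait
#' avoidance), `"burst"` (periodic short sprints).
#'
#' @param archetype One of the eight fine-scale behaviors
#'   (see [finescale_behaviors()]).
#' @param speed_mean,speed_sd Step length distribution, px per frame.
#' @param turn_sd Turning-angle spread, radians.
#' @param bait_bias Weight in \[-1, 1\] of the pull toward (or push away
#'   from) the bait.
#' @param dwell_frames Frames of near-zero speed spent inside the proximity
#'   zone.
#' @param event Scripted event rule, `"none"`, `"startle"`,
#'   `"retreat_after_dwell"` or `"burst"`.
#' @param box_size Side of the synthesized square bounding box, px.
#' @return A list of class `bb_archetype_params`.
#' @export
archetype_params <- function(archetype,
                             speed_mean, speed_sd, turn_sd, bait_bias,
                             dwell_frames = 0L, event = "none",
                             box_size = 40) {
  archetype <- match.arg(archetype, finescale_behaviors())
  defaults <- archetype_defaults()[[archetype]]
  if (missing(speed_mean)) speed_mean <- defaults$speed_mean
  if (missing(speed_sd)) speed_sd <- defaults$speed_sd
  if (missing(turn_sd)) turn_sd <- defaults$turn_sd
  if (missing(bait_bias)) bait_bias <- defaults$bait_bias
  if (missing(dwell_frames) && !is.null(defaults$dwell_frames)) {
    dwell_frames <- defaults$dwell_frames
  }
  if (missing(event) && !is.null(defaults$event)) event <- defaults$event
  if (speed_mean <= 0) stopf("speed_mean must be > 0")
  if (speed_sd < 0 || turn_sd < 0) stopf("speed_sd and turn_sd must be >= 0")
  if (abs(bait_bias) > 1) stopf("bait_bias must be in [-1, 1]")
  if (dwell_frames < 0) stopf("dwell_frames must be >= 0")
  event <- match.arg(event, c("none", "startle", "retreat_after_dwell",
                              "burst"))
  structure(
    list(archetype = archetype, speed_mean = speed_mean, speed_sd = speed_sd,
         turn_sd = turn_sd, bait_bias = bait_bias,
         dwell_frames = as.integer(dwell_frames), event = event,
         box_size = box_size),
    class = "bb_archetype_params"
  )
}

#' Default kinematics for the eight behavior archetypes
#'
#' Package constants (px per frame at 5 fps in a 1920 x 1080 frame), chosen
#' so that each archetype's trajectory shape matches its behavioral
#' description: feeding-type behaviors approach the bait and dwell; exploring
#' wanders near the bait without settling; passing crosses the frame in a
#' near-straight line; startle approaches, spooks on first proximity-zone
#' entry and leaves; burst swimming alternates cruising with sprints;
#' fleeing heads away from the bait.
#'
#' @return Named list (one entry per archetype) of parameter lists.
#' @export
archetype_defaults <- function() {
  list(
    Feeding       = list(speed_mean = 20, speed_sd = 6,  turn_sd = 0.55,
                         bait_bias = 0.90, dwell_frames = 200L, event = "none"),
    Biting        = list(speed_mean = 22, speed_sd = 7,  turn_sd = 0.55,
                         bait_bias = 0.85, dwell_frames = 120L,
                         event = "retreat_after_dwell"),
    Nibble        = list(speed_mean = 20, speed_sd = 6,  turn_sd = 0.60,
                         bait_bias = 0.85, dwell_frames = 160L,
                         event = "retreat_after_dwell"),
    Exploring     = list(speed_mean = 18, speed_sd = 6,  turn_sd = 0.80,
                         bait_bias = 0.80, dwell_frames = 0L, event = "none"),
    Passing       = list(speed_mean = 55, speed_sd = 7,  turn_sd = 0.07,
                         bait_bias = 0.00, dwell_frames = 0L, event = "none"),
    Startle       = list(speed_mean = 45, speed_sd = 7,  turn_sd = 0.12,
                         bait_bias = 0.25, dwell_frames = 0L,
                         event = "startle"),
    BurstSwimming = list(speed_mean = 50, speed_sd = 10, turn_sd = 0.10,
                         bait_bias = 0.00, dwell_frames = 0L, event = "burst"),
    Fleeing       = list(speed_mean = 52, speed_sd = 8,  turn_sd = 0.10,
                         bait_bias = -0.90, dwell_frames = 0L, event = "none")
  )
}

#' Bundle a track table with its behavior labels
#'
#' @param tracks A track table (see [as_track_table()]).
#' @param labels Data frame with columns `track_id`, `fine_label`,
#'   `principal_label`, `source_track_id`, `clutter`. Clutter tracks carry
#'   `NA` labels and `clutter = TRUE`.
#' @return A list of class `bb_labeled_tracks`.
#' @export
labeled_tracks <- function(tracks, labels) {
  tracks <- as_track_table(tracks)
  need <- c("track_id", "fine_label", "principal_label", "source_track_id",
            "clutter")
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols) > 0) {
    stopf("labels missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)[need]
  real <- !labels$clutter
  mismatch <- which(real & labels$principal_label !=
                      map_finescale_to_parent(labels$fine_label))
  if (length(mismatch) > 0) {
    stopf("principal_label does not match parent of fine_label for track %d",
          labels$track_id[mismatch[1]])
  }
  if (!setequal(unique(tracks$track_id), labels$track_id)) {
    stopf("labels and tracks must cover the same track ids")
  }
  structure(list(tracks = tracks, labels = labels),
            class = "bb_labeled_tracks")
}

#' @export
print.bb_labeled_tracks <- function(x, ...) {
  cat(sprintf("<bb_labeled_tracks> %d tracks, %d detections (%d clutter tracks)\n",
              nrow(x$labels), nrow(x$tracks), sum(x$labels$clutter)))
  if (any(!x$labels$clutter)) {
    print(table(x$labels$fine_label[!x$labels$clutter]))
  }
  invisible(x)
}

# One biased-correlated-random-walk trajectory; uses the ambient RNG.
simulate_track_impl <- function(scene, params, n_frames, track_id,
                                entry_frame, start = NULL, heading = NULL) {
  B <- scene$bait_point
  W <- scene$frame_width
  H <- scene$frame_height
  pos <- if (is.null(start)) {
    c(runif(1, 0.05 * W, 0.95 * W), runif(1, 0.05 * H, 0.95 * H))
  } else {
    as.numeric(start)
  }
  if (is.null(heading)) heading <- runif(1, -pi, pi)
  xs <- ys <- numeric(n_frames)
  dwell_left <- params$dwell_frames
  had_dwell <- params$dwell_frames > 0
  bias <- params$bait_bias
  startled <- FALSE
  sprint_left <- 0L
  for (t in seq_len(n_frames)) {
    xs[t] <- pos[1]
    ys[t] <- pos[2]
    if (t == n_frames) break
    d_to_B <- sqrt(sum((pos - B)^2))
    in_P <- d_to_B <= scene$proximity_radius
    speed_mult <- 1
    if (params$event == "startle" && in_P && !startled) {
      startled <- TRUE
      heading <- heading + sample(c(-1, 1), 1) * runif(1, 2 * pi / 3, pi)
      sprint_left <- 10L
      bias <- -0.7
    }
    if (sprint_left > 0) {
      speed_mult <- 3
      sprint_left <- sprint_left - 1L
    }
    if (params$event == "burst" && (t %% 25L) < 6L) speed_mult <- 2.5
    dwelling <- in_P && dwell_left > 0
    if (dwelling) {
      dwell_left <- dwell_left - 1L
      if (dwell_left == 0L && params$event == "retreat_after_dwell") {
        bias <- -0.6
      }
      step_len <- max(0, rnorm(1, 4, 2))  # slow milling at the bait
    } else {
      step_len <- max(0, rnorm(1, params$speed_mean * speed_mult,
                               params$speed_sd))
    }
    bearing <- atan2(B[2] - pos[2], B[1] - pos[1])
    heading <- heading + rnorm(1, 0, params$turn_sd) +
      bias * wrap_angle(bearing - heading)
    heading <- wrap_angle(heading)
    pos <- pos + step_len * c(cos(heading), sin(heading))
    # reflect at the frame borders, flipping the matching heading component
    if (pos[1] < 0) { pos[1] <- -pos[1]; heading <- wrap_angle(pi - heading) }
    if (pos[1] > W) { pos[1] <- 2 * W - pos[1]; heading <- wrap_angle(pi - heading) }
    if (pos[2] < 0) { pos[2] <- -pos[2]; heading <- wrap_angle(-heading) }
    if (pos[2] > H) { pos[2] <- 2 * H - pos[2]; heading <- wrap_angle(-heading) }
    pos[1] <- min(max(pos[1], 0), W)
    pos[2] <- min(max(pos[2], 0), H)
  }
  half <- params$box_size / 2
  data.frame(
    track_id = as.integer(track_id),
    frame_index = as.integer(entry_frame + seq_len(n_frames) - 1L),
    x1 = xs - half, y1 = ys - half, x2 = xs + half, y2 = ys + half,
    class_label = "fish", confidence = 1,
    stringsAsFactors = FALSE
  )
}

#' Simulate one labeled fish track
#'
#' Generates a biased correlated random walk for one behavior archetype (see
#' [archetype_params()] for the movement model) and synthesizes fixed-size
#' square bounding boxes around the positions. Deterministic given `seed`.
#'
#' @param scene A [scene()].
#' @param params An [archetype_params()] (or an archetype name, which uses
#'   the defaults).
#' @param n_frames Number of frames (>= 3).
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @param track_id,entry_frame Identity and first frame index of the track.
#' @param start Optional starting position `(x, y)`; default uniform in the
#'   frame.
#' @param heading Optional initial heading in radians; default uniform.
#' @return A `bb_labeled_tracks` with a single track.
#' @export
simulate_track <- function(scene, params, n_frames, seed = NULL,
                           track_id = 1L, entry_frame = 0L, start = NULL,
                           heading = NULL) {
  if (is.character(params)) params <- archetype_params(params)
  if (!inherits(params, "bb_archetype_params")) {
    stopf("params must be archetype_params() or an archetype name")
  }
  if (n_frames < 3) stopf("n_frames must be >= 3")
  tr <- with_seed(seed, simulate_track_impl(scene, params, n_frames,
                                            track_id, entry_frame,
                                            start, heading))
  labeled_tracks(
    tr,
    data.frame(track_id = as.integer(track_id),
               fine_label = params$archetype,
               principal_label = map_finescale_to_parent(params$archetype),
               source_track_id = as.integer(track_id),
               clutter = FALSE, stringsAsFactors = FALSE)
  )
}

#' Tracker-imperfection parameters
#'
#' @param p_miss Per-frame detection dropout probability.
#' @param p_split Per-frame probability that the tracker starts a new track
#'   id (track fragmentation).
#' @param jitter_sd Isotropic Gaussian bounding-box-center noise, px.
#' @param conf_fish `c(a, b)` of the Beta distribution that per-detection
#'   confidences of true fish are redrawn from, or `NULL` to keep the
#'   original confidences.
#' @param p_spurious Expected number of short non-fish clutter tracks per
#'   true track (clutter count is Poisson with this rate times the number of
#'   tracks).
#' @param conf_clutter `c(a, b)` Beta parameters for clutter confidences;
#'   the default Beta(1, 8) leaves ~95% of clutter tracks below the 0.89
#'   maximum-confidence filter.
#' @param clutter_len `c(min, max)` clutter track length in frames.
#' @return A list of class `bb_corruption_params`. The default is the
#'   identity corruption (no change).
#' @export
corruption_params <- function(p_miss = 0, p_split = 0, jitter_sd = 0,
                              conf_fish = NULL, p_spurious = 0,
                              conf_clutter = c(1, 8),
                              clutter_len = c(5L, 15L)) {
  if (p_miss < 0 || p_miss > 1 || p_split < 0 || p_split > 1) {
    stopf("p_miss and p_split must be in [0, 1]")
  }
  if (p_spurious < 0) stopf("p_spurious must be >= 0")
  if (jitter_sd < 0) stopf("jitter_sd must be >= 0")
  structure(
    list(p_miss = p_miss, p_split = p_split, jitter_sd = jitter_sd,
         conf_fish = conf_fish, p_spurious = p_spurious,
         conf_clutter = conf_clutter, clutter_len = as.integer(clutter_len)),
    class = "bb_corruption_params"
  )
}

#' Default (moderate) tracker-imperfection parameters
#'
#' The study conditions emulated by the package's tests: occasional missed
#' detections, occasional track splits, small box jitter, realistic
#' confidence noise (fish confidences from Beta(5, 2), so virtually every
#' real track has at least one detection above 0.89), and low-confidence
#' clutter tracks.
#'
#' @return A `bb_corruption_params`.
#' @export
default_corruption <- function() {
  corruption_params(p_miss = 0.05, p_split = 0.005, jitter_sd = 2,
                    conf_fish = c(5, 2), p_spurious = 0.2)
}

corrupt_tracks_impl <- function(lt, scene, corruption) {
  tracks <- lt$tracks
  labels <- lt$labels
  out_rows <- list()
  out_labels <- list()
  next_id <- if (nrow(tracks) > 0) max(tracks$track_id) + 1L else 1L
  for (sid in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == sid, , drop = FALSE]
    lab <- labels[labels$track_id == sid, , drop = FALSE]
    keep <- runif(nrow(tr)) >= corruption$p_miss
    tr <- tr[keep, , drop = FALSE]
    if (nrow(tr) == 0) next
    split_here <- c(FALSE, runif(nrow(tr) - 1) < corruption$p_split)
    frag <- cumsum(split_here)
    ids <- integer(nrow(tr))
    ids[frag == 0] <- sid
    for (fg in setdiff(unique(frag), 0)) {
      ids[frag == fg] <- next_id
      next_id <- next_id + 1L
    }
    tr$track_id <- ids
    if (corruption$jitter_sd > 0) {
      jx <- rnorm(nrow(tr), 0, corruption$jitter_sd)
      jy <- rnorm(nrow(tr), 0, corruption$jitter_sd)
      tr$x1 <- tr$x1 + jx; tr$x2 <- tr$x2 + jx
      tr$y1 <- tr$y1 + jy; tr$y2 <- tr$y2 + jy
    }
    if (!is.null(corruption$conf_fish)) {
      tr$confidence <- rbeta(nrow(tr), corruption$conf_fish[1],
                             corruption$conf_fish[2])
    }
    out_rows[[length(out_rows) + 1L]] <- tr
    for (id in unique(ids)) {
      out_labels[[length(out_labels) + 1L]] <- data.frame(
        track_id = id, fine_label = lab$fine_label,
        principal_label = lab$principal_label,
        source_track_id = lab$source_track_id, clutter = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  # spurious short clutter tracks (e.g. drifting debris), low confidence
  n_clutter <- if (corruption$p_spurious > 0 && nrow(labels) > 0) {
    rpois(1, corruption$p_spurious * length(unique(tracks$track_id)))
  } else {
    0L
  }
  if (n_clutter > 0) {
    fr_max <- max(1L, max(tracks$frame_index))
    for (i in seq_len(n_clutter)) {
      len <- sample1(seq(corruption$clutter_len[1], corruption$clutter_len[2]))
      f0 <- sample.int(max(1L, fr_max - len), 1) - 1L
      cx <- runif(1, 0, scene$frame_width)
      cy <- runif(1, 0, scene$frame_height)
      drift <- runif(1, -pi, pi)
      px <- cx + cumsum(rnorm(len, 5 * cos(drift), 3))
      py <- cy + cumsum(rnorm(len, 5 * sin(drift), 3))
      sz <- runif(1, 10, 30)
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        track_id = next_id, frame_index = f0 + seq_len(len) - 1L,
        x1 = px - sz / 2, y1 = py - sz / 2, x2 = px + sz / 2,
        y2 = py + sz / 2, class_label = "clutter",
        confidence = rbeta(len, corruption$conf_clutter[1],
                           corruption$conf_clutter[2]),
        stringsAsFactors = FALSE)
      out_labels[[length(out_labels) + 1L]] <- data.frame(
        track_id = next_id, fine_label = NA_character_,
        principal_label = NA_character_, source_track_id = NA_integer_,
        clutter = TRUE, stringsAsFactors = FALSE)
      next_id <- next_id + 1L
    }
  }
  if (length(out_rows) == 0) {
    return(labeled_tracks(tracks[0, , drop = FALSE], labels[0, , drop = FALSE]))
  }
  labeled_tracks(do.call(rbind, out_rows), do.call(rbind, out_labels))
}

#' Degrade labeled tracks with the tracker-imperfection model
#'
#' Applies per-detection dropout, track splitting (label and source id
#' propagate to every fragment), bounding-box jitter, confidence resampling,
#' and appends spurious clutter tracks. Distinct source tracks are never
#' merged. Deterministic given `seed`.
#'
#' @param lt A `bb_labeled_tracks`.
#' @param scene A [scene()] (frame bounds for clutter placement).
#' @param corruption A [corruption_params()].
#' @param seed Integer seed; `NULL` uses the ambient RNG state.
#' @return A `bb_labeled_tracks`.
#' @export
corrupt_tracks <- function(lt, scene, corruption = corruption_params(),
                           seed = NULL) {
  stopifnot(inherits(lt, "bb_labeled_tracks"),
            inherits(corruption, "bb_corruption_params"))
  with_seed(seed, corrupt_tracks_impl(lt, scene, corruption))
}

#' Simulate a multi-fish deployment
#'
#' Generates independent labeled tracks for a mixture of behavior archetypes
#' with staggered entry frames, then degrades them with the
#' tracker-imperfection model. Deterministic given `seed`.
#'
#' @param scene A [scene()].
#' @param mixture Named integer vector, archetype -> track count, e.g.
#'   `c(Feeding = 10, Passing = 10)`.
#' @param n_frames_range `c(min, max)` track length in frames (uniform).
#' @param corruption A [corruption_params()]; the default is the identity.
#' @param seed Integer seed.
#' @param horizon_frames Deployment length in frames over which entries are
#'   staggered.
#' @param params_overrides Optional named list archetype -> [archetype_params()]
#'   replacing the defaults.
#' @return List with elements `groundtruth` and `observed`, both
#'   `bb_labeled_tracks`. With the identity corruption, `observed` equals
#'   `groundtruth`.
#' @export
simulate_deployment <- function(scene, mixture,
                                n_frames_range = c(150L, 400L),
                                corruption = corruption_params(),
                                seed = NULL, horizon_frames = 3000L,
                                params_overrides = list()) {
  mixture <- mixture[mixture > 0]
  if (length(mixture) == 0) {
    empty <- labeled_tracks(
      data.frame(track_id = integer(0), frame_index = integer(0),
                 x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), class_label = character(0),
                 confidence = numeric(0)),
      data.frame(track_id = integer(0), fine_label = character(0),
                 principal_label = character(0),
                 source_track_id = integer(0), clutter = logical(0)))
    return(list(groundtruth = empty, observed = empty))
  }
  unknown <- setdiff(names(mixture), finescale_behaviors())
  if (length(unknown) > 0) {
    stopf("unknown archetype(s) in mixture: %s", paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    rows <- list()
    labs <- list()
    id <- 1L
    for (arc in names(mixture)) {
      par <- if (!is.null(params_overrides[[arc]])) {
        params_overrides[[arc]]
      } else {
        archetype_params(arc)
      }
      for (i in seq_len(mixture[[arc]])) {
        nf <- sample1(seq(n_frames_range[1], n_frames_range[2]))
        entry <- sample.int(max(1L, horizon_frames - nf), 1) - 1L
        tr <- simulate_track_impl(scene, par, nf, id, entry)
        rows[[length(rows) + 1L]] <- tr
        labs[[length(labs) + 1L]] <- data.frame(
          track_id = id, fine_label = arc,
          principal_label = map_finescale_to_parent(arc),
          source_track_id = id, clutter = FALSE, stringsAsFactors = FALSE)
        id <- id + 1L
      }
    }
    groundtruth <- labeled_tracks(do.call(rbind, rows), do.call(rbind, labs))
    observed <- corrupt_tracks_impl(groundtruth, scene, corruption)
    list(groundtruth = groundtruth, observed = observed)
  })
}

#' A balanced archetype mixture
#'
#' @param n_total Total number of tracks, spread as evenly as possible over
#'   the eight archetypes (remainder goes to the first archetypes in
#'   [finescale_behaviors()] order).
#' @return Named integer vector usable as `mixture` in
#'   [simulate_deployment()].
#' @export
balanced_mixture <- function(n_total) {
  k <- length(finescale_behaviors())
  base <- n_total %/% k
  extra <- n_total %% k
  setNames(as.integer(base + (seq_len(k) <= extra)), finescale_behaviors())
}
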