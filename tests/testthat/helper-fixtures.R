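# Shared fixtures. Heavy simulated objects are memoized so several test
# files can reuse them within one run.

test_scene <- function() {
  scene(bait_point = c(960, 620), proximity_radius = 150,
        annotation_area = c(100, 60, 1820, 1020),
        frame_width = 1920, frame_height = 1080, fps = 5)
}

# A tiny hand-written track table: one track along the x axis, one diagonal.
toy_tracks <- function() {
  as_track_table(data.frame(
    track_id = c(1L, 1L, 1L, 2L, 2L),
    frame_index = c(0L, 1L, 2L, 0L, 1L),
    x1 = c(0, 10, 20, 100, 103),
    y1 = c(0, 0, 0, 100, 104),
    x2 = c(10, 20, 30, 110, 113),
    y2 = c(10, 10, 10, 110, 114),
    class_label = "fish",
    confidence = c(0.5, 0.95, 0.7, 0.88, 0.88)))
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

# Default-condition deployment: 300 tracks over the eight archetypes with
# the moderate tracker-imperfection model, confidence-filtered, with metric
# table and labels aligned.
fixture_deployment <- function(seed = 5) {
  memo(paste0("dep", seed), {
    sc <- test_scene()
    sim <- simulate_deployment(sc, balanced_mixture(300),
                               corruption = default_corruption(),
                               seed = seed)
    kept <- filter_tracks_by_confidence(sim$observed$tracks)
    metrics <- suppressWarnings(compute_metric_table(kept, sc))
    labels <- sim$observed$labels[
      match(metrics$track_id, sim$observed$labels$track_id), ]
    fish <- !labels$clutter
    list(scene = sc, sim = sim, tracks = kept, metrics = metrics,
         labels = labels, fish = fish)
  })
}

# Correlation-filtered feature table of the fixture deployment (fish only).
fixture_features <- function(seed = 5) {
  memo(paste0("feat", seed), {
    d <- fixture_deployment(seed)
    cf <- suppressWarnings(
      correlation_filter(d$metrics[d$fish, -1], 0.90))
    list(table = cf$table, labels = d$labels$principal_label[d$fish])
  })
}

track_cols <- function() {
  c("track_id", "frame_index", "x1", "y1", "x2", "y2", "class_label",
    "confidence")
}

# z-score used when checking clustering against references
zscore_test <- function(x) scale(as.matrix(x))
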