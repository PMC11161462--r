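test_that("generation is deterministic given the seed", {
  sc <- test_scene()
  a <- simulate_deployment(sc, balanced_mixture(20),
                           corruption = default_corruption(), seed = 42)
  b <- simulate_deployment(sc, balanced_mixture(20),
                           corruption = default_corruption(), seed = 42)
  expect_identical(a$groundtruth$tracks, b$groundtruth$tracks)
  expect_identical(a$observed$tracks, b$observed$tracks)
  expect_identical(a$observed$labels, b$observed$labels)
})

test_that("every generated label obeys the 8-to-2 parent mapping", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, balanced_mixture(40),
                             corruption = default_corruption(), seed = 2)
  for (lt in list(sim$groundtruth, sim$observed)) {
    real <- !lt$labels$clutter
    expect_equal(lt$labels$principal_label[real],
                 map_finescale_to_parent(lt$labels$fine_label[real]))
  }
})

test_that("zero corruption leaves observed identical to groundtruth", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, c(Passing = 3), seed = 4)
  expect_identical(sim$observed$tracks, sim$groundtruth$tracks)
  expect_identical(sim$observed$labels, sim$groundtruth$labels)
  expect_equal(nrow(sim$observed$labels), 3)
  expect_equal(sort(unique(sim$observed$labels$source_track_id)), 1:3)
})

test_that("an empty mixture yields empty outputs", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, c(Passing = 0), seed = 1)
  expect_equal(nrow(sim$groundtruth$tracks), 0)
  expect_equal(nrow(sim$observed$labels), 0)
})

test_that("a straight-line archetype walks a straight centroid path", {
  sc <- test_scene()
  par <- archetype_params("Passing", speed_mean = 30, speed_sd = 0,
                          turn_sd = 0, bait_bias = 0)
  lt <- simulate_track(sc, par, n_frames = 20, seed = 6,
                       start = c(200, 500), heading = 0.3)
  ce <- track_centroids(lt$tracks)
  # collinearity: cross products of consecutive displacement vectors vanish
  dx <- diff(ce$x); dy <- diff(ce$y)
  cross <- head(dx, -1) * tail(dy, -1) - head(dy, -1) * tail(dx, -1)
  expect_lt(max(abs(cross)), 1e-6)
})

test_that("feeding dwells in the proximity zone for most of the track", {
  sc <- test_scene()
  par <- archetype_params("Feeding", bait_bias = 0.8, dwell_frames = 100L)
  f_vals <- vapply(1:5, function(s) {
    lt <- simulate_track(sc, par, n_frames = 200, seed = s)
    compute_metric_vector(lt$tracks, sc)[["f"]]
  }, numeric(1))
  expect_true(all(f_vals >= 0.5))
})

test_that("fleeing started inside the proximity zone ends farther from the bait", {
  sc <- test_scene()
  away <- vapply(1:100, function(s) {
    lt <- simulate_track(sc, "Fleeing", n_frames = 100, seed = s,
                         start = sc$bait_point + c(50, 0))
    ss <- compute_step_series(lt$tracks, sc)
    ss$d2[nrow(ss)] > ss$d2[1]
  }, logical(1))
  expect_gte(sum(away), 95)
})

test_that("split-only corruption conserves detections and source labels", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, balanced_mixture(10), seed = 9,
                             n_frames_range = c(200L, 300L))
  corr <- corruption_params(p_split = 0.02)
  obs <- corrupt_tracks(sim$groundtruth, sc, corr, seed = 10)
  expect_equal(nrow(obs$tracks), nrow(sim$groundtruth$tracks))
  expect_gt(nrow(obs$labels), nrow(sim$groundtruth$labels))
  # each fragment carries its source's fine label
  src <- sim$groundtruth$labels
  for (i in seq_len(nrow(obs$labels))) {
    expect_equal(obs$labels$fine_label[i],
                 src$fine_label[src$track_id == obs$labels$source_track_id[i]])
  }
})

test_that("fragment count grows like the geometric splitting expectation", {
  sc <- test_scene()
  n_frames <- 200L
  p_split <- 0.01
  sim <- simulate_deployment(sc, c(Passing = 5), seed = 12,
                             n_frames_range = c(n_frames, n_frames))
  frag_counts <- vapply(1:200, function(s) {
    obs <- corrupt_tracks(sim$groundtruth, sc,
                          corruption_params(p_split = p_split), seed = s)
    nrow(obs$labels) / 5
  }, numeric(1))
  expected <- 1 + (n_frames - 1) * p_split
  expect_equal(mean(frag_counts), expected, tolerance = 0.05)
})

test_that("dropout removes the binomially expected number of detections", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, c(Passing = 10), seed = 20,
                             n_frames_range = c(500L, 500L))
  obs <- corrupt_tracks(sim$groundtruth, sc,
                        corruption_params(p_miss = 0.2), seed = 21)
  n <- 10 * 500
  expect_lt(abs(nrow(obs$tracks) - 0.8 * n), 3 * sqrt(n * 0.2 * 0.8))
})

test_that("spurious clutter tracks are flagged and mostly fall below 0.89", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, balanced_mixture(40), seed = 30,
                             corruption = corruption_params(p_spurious = 2))
  lab <- sim$observed$labels
  expect_gt(sum(lab$clutter), 0)
  expect_true(all(is.na(lab$fine_label[lab$clutter])))
  mx <- track_max_confidence(sim$observed$tracks)
  clutter_mx <- mx[as.character(lab$track_id[lab$clutter])]
  expect_gt(mean(clutter_mx < 0.89), 0.8)
})

test_that("interested and uninterested tracks separate on three summary metrics", {
  # nearest-centroid oracle on (mean d2, f, mean d1): downstream recovery
  # tests are well-posed only if this brute-force baseline succeeds
  sc <- test_scene()
  sim <- simulate_deployment(sc, balanced_mixture(400), seed = 11)
  mt <- compute_metric_table(sim$groundtruth$tracks, sc)
  lab <- sim$groundtruth$labels$principal_label[
    match(mt$track_id, sim$groundtruth$labels$track_id)]
  X <- scale(mt[, c("d2_mean", "f", "d1_mean")])
  cen <- sapply(as.data.frame(X), tapply, lab, mean)
  dI <- rowSums((X - matrix(cen["Interested", ], nrow(X), 3, byrow = TRUE))^2)
  dU <- rowSums((X - matrix(cen["Uninterested", ], nrow(X), 3, byrow = TRUE))^2)
  pred <- ifelse(dI < dU, "Interested", "Uninterested")
  expect_gte(mean(pred == lab), 0.85)
})
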