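# Step-series and metric-catalog checks against closed forms and a
# first-principles re-computation.

# Build a track table from bare centroid coordinates (10 px square boxes).
track_from_xy <- function(x, y, frame_index = seq_along(x) - 1L, id = 1L) {
  as_track_table(data.frame(
    track_id = id, frame_index = frame_index,
    x1 = x - 5, y1 = y - 5, x2 = x + 5, y2 = y + 5,
    class_label = "fish", confidence = 1))
}

test_that("step series matches the 3-4-5 closed form", {
  sc <- test_scene()
  ss <- compute_step_series(track_from_xy(c(0, 3), c(0, 4) + 5), sc)
  # +5 keeps boxes in frame; displacement is still (3, 4)
  expect_equal(ss$d1[2], 5)
  expect_equal(ss$dx[2], 3)
  expect_equal(ss$dy[2], 4)
  expect_equal(ss$R2n[2], 25)
  expect_equal(ss$R2n[1], 0)
})

test_that("relative angle hits its definitional extremes", {
  sc <- scene(bait_point = c(1000, 500), proximity_radius = 100)
  toward <- compute_step_series(track_from_xy(c(500, 600), c(500, 500)), sc)
  expect_equal(toward$beta[2], 0)
  away <- compute_step_series(track_from_xy(c(500, 400), c(500, 500)), sc)
  expect_equal(away$beta[2], pi)
})

test_that("step identities hold on random walks", {
  sc <- test_scene()
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- cumsum(c(runif(1, 200, 1700), rnorm(n - 1, 0, 20)))
    y <- cumsum(c(runif(1, 200, 900), rnorm(n - 1, 0, 20)))
    x <- pmin(pmax(x, 6), sc$frame_width - 6)
    y <- pmin(pmax(y, 6), sc$frame_height - 6)
    ss <- compute_step_series(track_from_xy(x, y), sc)
    expect_equal(ss$d1[-1]^2, ss$dx[-1]^2 + ss$dy[-1]^2, tolerance = 1e-9)
    expect_equal(ss$R2n, (x - x[1])^2 + (y - y[1])^2, tolerance = 1e-9)
    expect_true(all(ss$beta[-1] >= 0 & ss$beta[-1] <= pi))
    expect_true(all(ss$d2 >= 0))
  }
})

test_that("proximity fraction spans its indicator bounds", {
  sc <- scene(bait_point = c(960, 540), proximity_radius = 200)
  inside <- track_from_xy(960 + c(0, 10, -10, 5), 540 + c(5, -5, 0, 10))
  expect_equal(compute_metric_vector(inside, sc)[["f"]], 1)
  outside <- track_from_xy(c(100, 120, 140, 160), c(100, 100, 100, 100))
  expect_equal(compute_metric_vector(outside, sc)[["f"]], 0)
})

test_that("the metric vector has exactly the 104 registry names, all finite", {
  sc <- test_scene()
  lt <- simulate_track(sc, "Exploring", n_frames = 50, seed = 14)
  mv <- compute_metric_vector(lt$tracks, sc)
  expect_length(mv, 104)
  expect_identical(names(mv), as.vector(metric_registry()))
  expect_true(all(is.finite(mv)))
  expect_identical(attr(metric_registry(), "version"), "catalog-v1")
})

test_that("degenerate tracks follow the documented conventions", {
  sc <- test_scene()
  # stationary after the first step: straightness net/path, path = d1(1)
  tr <- track_from_xy(c(500, 530, 530, 530), c(500, 540, 540, 540))
  mv <- compute_metric_vector(tr, sc)
  expect_equal(mv[["path_length"]], 50)
  expect_equal(mv[["net_displacement"]], 50)
  expect_equal(mv[["straightness"]], 1)
  # constant distance to bait
  sc2 <- scene(bait_point = c(500, 500), proximity_radius = 50)
  circ <- track_from_xy(500 + 100 * cos(seq(0, 1, 0.25)),
                        500 + 100 * sin(seq(0, 1, 0.25)))
  expect_equal(compute_metric_vector(circ, sc2)[["d2_mean"]], 100)
  # never enters P: finite coding duration_s + 1
  far <- track_from_xy(c(100, 110, 120), c(100, 100, 100))
  mvf <- compute_metric_vector(far, sc2)
  expect_equal(mvf[["time_to_first_P_s"]], mvf[["duration_s"]] + 1)
  # single-detection track is rejected
  expect_error(compute_metric_vector(track_from_xy(500, 500), sc),
               "track too short")
})

test_that("aggregations equal a first-principles recomputation", {
  sc <- test_scene()
  set.seed(41)
  for (rep in 1:10) {
    x <- runif(5, 100, 1800)
    y <- runif(5, 100, 1000)
    tr <- track_from_xy(x, y)
    mv <- compute_metric_vector(tr, sc)
    # oracle: recompute d1 aggregates directly from coordinates
    d1 <- sqrt(diff(x)^2 + diff(y)^2)
    expect_equal(mv[["d1_mean"]], mean(d1), tolerance = 1e-12)
    expect_equal(mv[["d1_sd"]], sd(d1), tolerance = 1e-12)
    expect_equal(mv[["d1_min"]], min(d1))
    expect_equal(mv[["d1_max"]], max(d1))
    expect_equal(mv[["d1_median"]], median(d1))
    expect_equal(mv[["d1_q10"]], unname(quantile(d1, 0.1)))
    expect_equal(mv[["d1_q90"]], unname(quantile(d1, 0.9)))
    expect_equal(mv[["d1_first"]], d1[1])
    expect_equal(mv[["d1_last"]], d1[4])
    d2 <- sqrt((x - sc$bait_point[1])^2 + (y - sc$bait_point[2])^2)
    expect_equal(mv[["d2_mean"]], mean(d2), tolerance = 1e-12)
    expect_equal(mv[["start_d2"]], d2[1])
    expect_equal(mv[["end_d2"]], d2[5])
    expect_equal(mv[["net_displacement"]],
                 sqrt((x[5] - x[1])^2 + (y[5] - y[1])^2))
    expect_equal(mv[["straightness"]],
                 mv[["net_displacement"]] / sum(d1))
  }
})

test_that("metrics are invariant to joint translation and rotation about the bait", {
  base_sc <- scene(bait_point = c(600, 400), proximity_radius = 120,
                   frame_width = 4000, frame_height = 4000,
                   annotation_area = c(0, 0, 4000, 4000))
  set.seed(7)
  x <- 600 + cumsum(c(100, rnorm(7, 0, 30)))
  y <- 400 + cumsum(c(50, rnorm(7, 0, 30)))
  mv <- compute_metric_vector(track_from_xy(x, y), base_sc)
  # translation of track, bait and annotation area together
  sh <- c(250, 180)
  sc_t <- scene(bait_point = c(600, 400) + sh, proximity_radius = 120,
                frame_width = 4000, frame_height = 4000,
                annotation_area = c(0, 0, 4000, 4000))
  mv_t <- compute_metric_vector(track_from_xy(x + sh[1], y + sh[2]), sc_t)
  expect_equal(mv_t, mv, tolerance = 1e-9)
  # rotation about B: bait-relative and length metrics unchanged;
  # absolute-angle aggregates may differ
  th <- 0.7
  xr <- 600 + cos(th) * (x - 600) - sin(th) * (y - 400)
  yr <- 400 + sin(th) * (x - 600) + cos(th) * (y - 400)
  mv_r <- compute_metric_vector(track_from_xy(xr, yr), base_sc)
  invariant <- c(outer(c("d1", "d2", "beta", "R2n", "abs_turn"),
                       c("mean", "sd", "min", "max", "median", "q10", "q90",
                         "first", "last"), paste, sep = "_"),
                 "f", "path_length", "net_displacement", "straightness",
                 "n_P_entries")
  expect_equal(mv_r[invariant], mv[invariant], tolerance = 1e-9)
})

test_that("the metric table is one row per valid track and order-invariant", {
  sc <- test_scene()
  sim <- simulate_deployment(sc, balanced_mixture(10), seed = 55)
  tr <- sim$groundtruth$tracks
  mt <- compute_metric_table(tr, sc)
  expect_equal(dim(mt), c(10, 105))
  # shuffling detection rows changes nothing (tables are re-sorted)
  shuffled <- tr[sample(nrow(tr)), ]
  mt2 <- compute_metric_table(shuffled, sc)
  expect_equal(mt2, mt, ignore_attr = TRUE)
  # single-detection tracks are dropped with a warning, counted
  one <- tr[1, ]
  one$track_id <- 999L
  expect_warning(mt3 <- compute_metric_table(rbind(tr, one), sc),
                 "single-detection")
  expect_equal(nrow(mt3), 10)
  expect_equal(attr(mt3, "n_dropped_short"), 1)
})

test_that("co-presence counts overlap of frame spans in the cohort", {
  sc <- test_scene()
  t1 <- track_from_xy(c(200, 210, 220), c(200, 200, 200),
                      frame_index = 0:2, id = 1L)
  t2 <- track_from_xy(c(400, 410), c(400, 400), frame_index = 1:2, id = 2L)
  t3 <- track_from_xy(c(600, 610), c(600, 600), frame_index = 10:11, id = 3L)
  cohort <- rbind(t1, t2, t3)
  mv <- compute_metric_vector(t1, sc, cohort)
  expect_equal(mv[["max_copresent_fish"]], 1)   # t2 overlaps frames 1-2
  expect_equal(mv[["mean_copresent_fish"]], 2 / 3)
})
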