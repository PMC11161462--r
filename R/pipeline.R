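# End-to-end orchestration: simulate -> filter -> extract -> select ->
# cluster -> train -> predict -> analyze, from one config with one master
# seed. Every stage gets a seed derived deterministically from the master
# seed, so stages are individually reproducible from their on-disk inputs.

#' Default pipeline configuration
#'
#' A small synthetic experiment mirroring the study design: four bait types
#' over four trial days (one 9-h deployment per bait per day), the raw bait
#' attracting more interested fish than the bio-baits, moderate tracker
#' imperfections, and desk-scale selection/clustering settings.
#'
#' @param master_seed Master seed, default 1.
#' @param out_dir Output directory for stage artifacts (`NULL` for none).
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(master_seed = 1, out_dir = NULL) {
  interested <- c(Feeding = 6, Biting = 4, Nibble = 4, Exploring = 5)
  uninterested <- c(Passing = 6, Startle = 4, BurstSwimming = 4, Fleeing = 5)
  deployments <- list()
  for (day in 1:4) {
    for (bt in c("raw", "C17", "C600", "Lactips")) {
      boost <- if (bt == "raw") 2 else 1
      deployments[[length(deployments) + 1L]] <- list(
        bait_type = bt, day_id = day,
        mixture = c(round(interested * boost), uninterested))
    }
  }
  list(
    scene = list(bait_point = c(960, 620), proximity_radius = 150,
                 frame_width = 1920, frame_height = 1080, fps = 5),
    deployments = deployments,
    n_frames_range = c(150L, 400L),
    horizon_frames = 162000L,  # 9 h at 5 fps
    duration_h = 9,
    corruption = "default",
    confidence_threshold = 0.89,
    selection = list(r_threshold = 0.90, rfe_iterations = 0L),
    cluster = list(k_range = 1:6, B = 20),
    classifier = list(cv_k = 5, interest_threshold = 0.52),
    analysis = list(contrast = "per_deployment_total", adjust = "holm"),
    master_seed = master_seed,
    out_dir = out_dir
  )
}

pipeline_write <- function(obj, out_dir, file) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, file)
  if (grepl("\\.csv$", file)) {
    write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}

#' Run the full behavior-recognition pipeline
#'
#' Executes, in order: per-deployment track simulation and corruption,
#' the maximum-confidence track filter, metric extraction, correlation
#' filtering (plus Random-Forest recursive feature elimination when
#' `selection$rfe_iterations > 0`), cluster-number consensus, stratified
#' cross-validation and training of the principal classifier, per-track
#' interest prediction, hourly aggregation and bait comparison. All
#' randomness derives from `master_seed`; rerunning an identical config
#' reproduces identical outputs.
#'
#' @param config A config list as produced by [default_pipeline_config()]
#'   (any subset of fields may be overridden), or a path to a YAML file of
#'   the same shape.
#' @return List of class `bb_pipeline_result`: `metrics`, `labels`,
#'   `selection`, `kselect`, `cv`, `model`, `predictions`, `hourly`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  sc <- if (inherits(config$scene, "bb_scene")) config$scene
        else do.call(scene, config$scene)
  corruption <- if (identical(config$corruption, "default")) {
    default_corruption()
  } else if (identical(config$corruption, "none")) {
    corruption_params()
  } else if (inherits(config$corruption, "bb_corruption_params")) {
    config$corruption
  } else {
    do.call(corruption_params, config$corruption)
  }
  seed0 <- config$master_seed
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(master_seed = seed0, stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    manifest$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    val
  }

  # -- simulate + filter + extract, per deployment -------------------------
  per_dep <- t_stage("simulate_extract", {
    lapply(seq_along(config$deployments), function(i) {
      dep <- config$deployments[[i]]
      sim <- simulate_deployment(
        sc, mixture = unlist(dep$mixture),
        n_frames_range = config$n_frames_range,
        corruption = corruption,
        seed = derive_seed(seed0, 10 + i),
        horizon_frames = config$horizon_frames)
      kept <- filter_tracks_by_confidence(sim$observed$tracks,
                                          config$confidence_threshold)
      metrics <- suppressWarnings(compute_metric_table(kept, sc))
      labels <- sim$observed$labels
      labels <- labels[match(metrics$track_id, labels$track_id), ]
      list(meta = deployment_meta(dep$bait_type, dep$day_id,
                                  duration_h = config$duration_h),
           tracks = kept, metrics = metrics, labels = labels)
    })
  })
  metrics_all <- do.call(rbind, lapply(per_dep, `[[`, "metrics"))
  labels_all <- do.call(rbind, lapply(per_dep, `[[`, "labels"))
  fish <- !labels_all$clutter & !is.na(labels_all$principal_label)
  pipeline_write(metrics_all, out_dir, "metrics.csv")
  pipeline_write(labels_all, out_dir, "labels.csv")

  # -- feature selection ---------------------------------------------------
  selection <- t_stage("select", {
    feats <- metrics_all[fish, setdiff(names(metrics_all), "track_id"),
                         drop = FALSE]
    cf <- suppressWarnings(
      correlation_filter(feats, config$selection$r_threshold))
    sel <- list(kept_features = names(cf$table),
                dropped = cf$report, rfe = NULL)
    if (config$selection$rfe_iterations > 0) {
      rfe <- rfe_select(cf$table, labels_all$principal_label[fish],
                        n_iterations = config$selection$rfe_iterations,
                        seed = derive_seed(seed0, 2))
      sel$rfe <- rfe
      sel$kept_features <- rfe$selected_features
    }
    sel
  })
  pipeline_write(list(kept_features = selection$kept_features,
                      n_dropped_by_correlation = nrow(selection$dropped)),
                 out_dir, "selection.json")

  # -- cluster-number consensus -------------------------------------------
  kselect <- t_stage("cluster", {
    feats <- metrics_all[fish, selection$kept_features, drop = FALSE]
    select_k(feats, k_range = config$cluster$k_range,
             B = config$cluster$B, seed = derive_seed(seed0, 3))
  })
  pipeline_write(list(votes = as.list(kselect$votes),
                      consensus_k = kselect$consensus_k),
                 out_dir, "kselect.json")

  # -- classifier: CV + final model + predictions --------------------------
  feats_fish <- metrics_all[fish, selection$kept_features, drop = FALSE]
  y_fish <- labels_all$principal_label[fish]
  cv <- t_stage("cv", kfold_cv(
    feats_fish, y_fish, task = "principal", k = config$classifier$cv_k,
    interest_threshold = config$classifier$interest_threshold,
    seed = derive_seed(seed0, 4)))
  model <- t_stage("train", train_rf(
    feats_fish, y_fish, task = "principal",
    interest_threshold = config$classifier$interest_threshold,
    seed = derive_seed(seed0, 5)))
  predictions <- predict_interest(
    model, metrics_all[, c("track_id", selection$kept_features)])
  pipeline_write(predictions, out_dir, "predictions.csv")

  # -- deployment analysis -------------------------------------------------
  analysis <- t_stage("analyze", {
    hourly <- do.call(rbind, lapply(per_dep, function(d) {
      ids <- d$metrics$track_id
      hourly_aggregate(d$tracks[d$tracks$track_id %in% ids, , drop = FALSE],
                       predictions[predictions$track_id %in% ids, ,
                                   drop = FALSE],
                       d$meta, fps = sc$fps)
    }))
    list(hourly = hourly,
         comparison = compare_baits(hourly,
                                    contrast = config$analysis$contrast,
                                    adjust = config$analysis$adjust))
  })
  pipeline_write(analysis$hourly, out_dir, "hourly.csv")
  pipeline_write(list(kw = analysis$comparison$kw,
                      dunn = analysis$comparison$dunn),
                 out_dir, "analysis.json")

  manifest$counts <- list(
    n_tracks = nrow(labels_all), n_fish_tracks = sum(fish),
    n_features_kept = length(selection$kept_features),
    consensus_k = kselect$consensus_k,
    cv_accuracy = cv$pooled$accuracy)
  pipeline_write(manifest, out_dir, "manifest.json")
  structure(
    list(metrics = metrics_all, labels = labels_all, selection = selection,
         kselect = kselect, cv = cv, model = model,
         predictions = predictions, hourly = analysis$hourly,
         comparison = analysis$comparison, manifest = manifest),
    class = "bb_pipeline_result")
}

#' @export
print.bb_pipeline_result <- function(x, ...) {
  cat("<bb_pipeline_result>\n")
  cat(sprintf("  tracks: %d (%d fish), features kept: %d\n",
              x$manifest$counts$n_tracks, x$manifest$counts$n_fish_tracks,
              x$manifest$counts$n_features_kept))
  cat(sprintf("  consensus k = %d; pooled CV accuracy = %.3f\n",
              x$kselect$consensus_k, x$cv$pooled$accuracy))
  cat(sprintf("  bait comparison: H = %.3f, p = %.4g\n",
              x$comparison$kw$H, x$comparison$kw$p))
  invisible(x)
}

#' Sweep the interest decision threshold
#'
#' Re-labels the model's interest probabilities at each threshold in the
#' grid and evaluates against the true labels — the utility behind choosing
#' a decision threshold such as 0.52 (the point below which
#' misclassifications prevail).
#'
#' @param model A principal-task `bb_behavior_model`.
#' @param table Feature data frame (with the model's features).
#' @param truth True principal labels, one per row.
#' @param grid Thresholds to evaluate; default `seq(0.05, 0.95, by = 0.05)`.
#' @return List with `sweep` (data frame `threshold`, `accuracy`,
#'   `precision`, `recall`, `f1`, `n_interested`) and `best_threshold`
#'   (accuracy-maximizing; among ties, the threshold closest to the
#'   balanced operating point 0.5).
#' @export
threshold_sweep <- function(model, table, truth,
                            grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(grid) == 0) stopf("empty threshold grid")
  prob <- predict_interest(model, table)$prob_interested
  rows <- lapply(grid, function(th) {
    lab <- ifelse(prob >= th, "Interested", "Uninterested")
    ev <- evaluate(lab, truth, positive_class = "Interested")
    data.frame(threshold = th, accuracy = ev$accuracy,
               precision = ev$precision, recall = ev$recall, f1 = ev$f1,
               n_interested = sum(lab == "Interested"))
  })
  sweep <- do.call(rbind, rows)
  top <- which(sweep$accuracy == max(sweep$accuracy))
  best <- top[which.min(abs(sweep$threshold[top] - 0.5))]
  list(sweep = sweep, best_threshold = sweep$threshold[best])
}
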