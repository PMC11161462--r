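# Track tables: the package's detection container.
#
# A track table is a data.frame with one row per detection and columns
#   track_id (integer), frame_index (integer >= 0),
#   x1, y1, x2, y2 (pixels, closed bbox, origin top-left, y down),
#   class_label (character), confidence (in [0, 1]).
# Rows are kept sorted by (track_id, frame_index). Extra columns are carried
# through untouched.

TRACK_COLUMNS <- c("track_id", "frame_index", "x1", "y1", "x2", "y2",
                   "class_label", "confidence")

#' Assemble and validate a track table
#'
#' @param df Data frame with at least the track-table columns `track_id`,
#'   `frame_index`, `x1`, `y1`, `x2`, `y2`, `class_label`, `confidence`.
#' @return The validated, (track_id, frame_index)-sorted data frame.
#' @details Invariants enforced: frame indices non-negative and unique within
#'   a track, bounding boxes with positive width and height, confidences in
#'   \[0, 1\]. Frame gaps within a track are allowed (tracker dropouts);
#'   downstream per-step quantities account for the gap.
#' @export
as_track_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stopf("track table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df$track_id <- as.integer(df$track_id)
  df$frame_index <- as.integer(df$frame_index)
  df$class_label <- as.character(df$class_label)
  for (col in c("x1", "y1", "x2", "y2", "confidence")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (nrow(df) > 0) {
    bad <- which(!(df$x2 > df$x1 & df$y2 > df$y1))
    if (length(bad) > 0) {
      stopf("invalid bbox (needs x1 < x2 and y1 < y2) at row %d", bad[1])
    }
    bad <- which(df$confidence < 0 | df$confidence > 1 | is.na(df$confidence))
    if (length(bad) > 0) stopf("confidence outside [0, 1] at row %d", bad[1])
    bad <- which(df$frame_index < 0 | is.na(df$frame_index))
    if (length(bad) > 0) stopf("negative or missing frame_index at row %d", bad[1])
    dup <- duplicated(df[c("track_id", "frame_index")])
    if (any(dup)) {
      stopf("duplicate (track_id, frame_index) pair at row %d: (%d, %d)",
            which(dup)[1], df$track_id[which(dup)[1]],
            df$frame_index[which(dup)[1]])
    }
    df <- df[order(df$track_id, df$frame_index), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read tracks from a detection file
#'
#' Two dialects are supported. `viame_csv` is a flat CSV with columns
#' `track_id, frame_index, x1, y1, x2, y2, class_label, confidence` (header
#' row, UTF-8); unknown columns are preserved. `coco_json` is the standard
#' COCO annotation layout (`images`, `annotations` with `bbox = [x, y, w, h]`
#' and `category_id`, `categories`) extended with per-annotation `track_id`
#' and `score`.
#'
#' @param path File path.
#' @param format `"viame_csv"` or `"coco_json"`.
#' @return A validated track table (see [as_track_table()]), grouped by track
#'   id with detections frame-sorted.
#' @export
read_tracks <- function(path, format = c("viame_csv", "coco_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "viame_csv") {
    df <- tryCatch(
      read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stopf("malformed CSV %s: %s", path, conditionMessage(e))
    )
    missing_cols <- setdiff(TRACK_COLUMNS, names(df))
    if (length(missing_cols) > 0) {
      stopf("%s: missing column(s) %s", path,
            paste(missing_cols, collapse = ", "))
    }
    as_track_table(df)
  } else {
    js <- tryCatch(
      jsonlite::read_json(path, simplifyVector = FALSE),
      error = function(e) stopf("malformed JSON %s: %s", path, conditionMessage(e))
    )
    if (is.null(js$annotations) || is.null(js$images)) {
      stopf("%s: not a COCO annotation file (needs images + annotations)", path)
    }
    frame_of_image <- vapply(js$images, function(im) {
      if (!is.null(im$frame_index)) as.integer(im$frame_index)
      else as.integer(im$id) - 1L
    }, integer(1))
    names(frame_of_image) <- vapply(js$images, function(im)
      as.character(im$id), character(1))
    label_of_cat <- character(0)
    if (!is.null(js$categories)) {
      label_of_cat <- vapply(js$categories, function(cc)
        as.character(cc$name), character(1))
      names(label_of_cat) <- vapply(js$categories, function(cc)
        as.character(cc$id), character(1))
    }
    rows <- lapply(seq_along(js$annotations), function(i) {
      an <- js$annotations[[i]]
      if (is.null(an$bbox) || length(an$bbox) != 4 || is.null(an$track_id) ||
          is.null(an$image_id)) {
        stopf("%s: malformed annotation record %d", path, i)
      }
      b <- as.numeric(an$bbox)
      lab <- if (!is.null(an$category_id) &&
                 as.character(an$category_id) %in% names(label_of_cat)) {
        label_of_cat[[as.character(an$category_id)]]
      } else {
        "fish"
      }
      fr <- frame_of_image[[as.character(an$image_id)]]
      if (is.null(fr)) stopf("%s: annotation %d references unknown image", path, i)
      data.frame(track_id = as.integer(an$track_id), frame_index = fr,
                 x1 = b[1], y1 = b[2], x2 = b[1] + b[3], y2 = b[2] + b[4],
                 class_label = lab,
                 confidence = if (is.null(an$score)) 1 else as.numeric(an$score),
                 stringsAsFactors = FALSE)
    })
    as_track_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  }
}

#' Write tracks to a detection file
#'
#' Inverse of [read_tracks()]; both dialects round-trip all typed fields
#' losslessly.
#'
#' @param tracks A track table.
#' @param path Output file path.
#' @param format `"viame_csv"` or `"coco_json"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, format = c("viame_csv", "coco_json")) {
  format <- match.arg(format)
  tracks <- as_track_table(tracks)
  if (format == "viame_csv") {
    write.csv(tracks, path, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  } else {
    frames <- sort(unique(tracks$frame_index))
    images <- lapply(frames, function(fr) {
      list(id = fr + 1L, frame_index = fr,
           file_name = sprintf("frame_%06d.png", fr))
    })
    labels <- sort(unique(tracks$class_label))
    categories <- lapply(seq_along(labels), function(i) {
      list(id = i, name = labels[i])
    })
    cat_id <- setNames(seq_along(labels), labels)
    annotations <- lapply(seq_len(nrow(tracks)), function(i) {
      r <- tracks[i, ]
      list(id = i, image_id = r$frame_index + 1L,
           category_id = unname(cat_id[[r$class_label]]),
           bbox = c(r$x1, r$y1, r$x2 - r$x1, r$y2 - r$y1),
           track_id = r$track_id, score = r$confidence)
    })
    jsonlite::write_json(
      list(images = images, annotations = annotations,
           categories = categories),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Per-track maximum detection confidence
#'
#' The tracker attributes an object's highest classification probability over
#' all instances of its track; this returns that maximum per track.
#'
#' @param tracks A track table.
#' @return Named numeric vector, names = track ids.
#' @export
track_max_confidence <- function(tracks) {
  tracks <- as_track_table(tracks)
  if (nrow(tracks) == 0) return(setNames(numeric(0), character(0)))
  tapply(tracks$confidence, tracks$track_id, max)
}

#' Filter tracks on maximum detection confidence
#'
#' Keeps exactly the tracks whose maximum detection confidence reaches the
#' threshold. A single robust detection along a track is taken as sufficient
#' evidence that the whole track is a fish, so the max (not the mean) is
#' thresholded; the default 0.89 discards most non-fish clutter such as
#' drifting plant debris.
#'
#' @param tracks A track table.
#' @param threshold Confidence threshold in \[0, 1\], default 0.89.
#' @return The filtered track table (row order preserved).
#' @export
filter_tracks_by_confidence <- function(tracks, threshold = 0.89) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  tracks <- as_track_table(tracks)
  if (nrow(tracks) == 0) return(tracks)
  mx <- track_max_confidence(tracks)
  keep_ids <- as.integer(names(mx)[mx >= threshold])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bounding-box centroids of every detection
#'
#' The package's position proxy for a fish is the center of its bounding box.
#'
#' @param tracks A track table.
#' @return Data frame `track_id, frame_index, x, y`, frame-ordered within
#'   track.
#' @export
track_centroids <- function(tracks) {
  tracks <- as_track_table(tracks)
  data.frame(track_id = tracks$track_id, frame_index = tracks$frame_index,
             x = (tracks$x1 + tracks$x2) / 2,
             y = (tracks$y1 + tracks$y2) / 2)
}
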