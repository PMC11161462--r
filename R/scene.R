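#' Describe the geometry of one bait-camera deployment
#'
#' A scene fixes everything positional that trajectory metrics are measured
#' against: the bait point \eqn{B}, the proximity-to-bait zone \eqn{P} (the
#' closed disc of radius `proximity_radius` around \eqn{B}), the annotation
#' area \eqn{A} (the rectangle inside which fish were annotated), the frame
#' size, and the frame rate of the subsampled video.
#'
#' Coordinates are 0-based pixels with the origin at the top-left corner and
#' the y axis pointing down (image convention). Rectangles are closed real
#' rectangles `(x1, y1, x2, y2)` with `x1 < x2`, `y1 < y2`.
#'
#' @param bait_point Numeric length-2, pixel coordinates of the bait point B.
#' @param proximity_radius Radius of the proximity zone P in pixels (> 0).
#'   When a bait bounding box is known, twice its diagonal is a sensible
#'   scale-free choice; see [proximity_radius_from_bait_bbox()].
#' @param annotation_area Numeric length-4 `(x1, y1, x2, y2)`, the annotation
#'   rectangle A, contained in the frame.
#' @param frame_width,frame_height Frame size in pixels.
#' @param fps Frames per second of the (subsampled) video; default 5.
#' @return An object of class `bb_scene`.
#' @examples
#' sc <- scene(bait_point = c(960, 620), proximity_radius = 150)
#' sc
#' @export
scene <- function(bait_point = c(960, 620),
                  proximity_radius = 150,
                  annotation_area = NULL,
                  frame_width = 1920,
                  frame_height = 1080,
                  fps = 5) {
  if (length(bait_point) != 2 || !is.numeric(bait_point)) {
    stopf("bait_point must be a numeric (x, y) pair")
  }
  if (!is.numeric(proximity_radius) || proximity_radius <= 0) {
    stopf("proximity_radius must be > 0")
  }
  if (fps <= 0) stopf("fps must be > 0")
  if (frame_width <= 0 || frame_height <= 0) stopf("frame size must be positive")
  if (bait_point[1] < 0 || bait_point[1] > frame_width ||
      bait_point[2] < 0 || bait_point[2] > frame_height) {
    stopf("bait_point must lie inside the frame")
  }
  if (is.null(annotation_area)) {
    annotation_area <- c(0, 0, frame_width, frame_height)
  }
  a <- as.numeric(annotation_area)
  if (length(a) != 4 || a[1] >= a[3] || a[2] >= a[4]) {
    stopf("annotation_area must be (x1, y1, x2, y2) with x1 < x2, y1 < y2")
  }
  if (a[1] < 0 || a[2] < 0 || a[3] > frame_width || a[4] > frame_height) {
    stopf("annotation_area must be contained in the frame")
  }
  structure(
    list(
      bait_point = as.numeric(bait_point),
      proximity_radius = as.numeric(proximity_radius),
      annotation_area = a,
      frame_width = as.numeric(frame_width),
      frame_height = as.numeric(frame_height),
      fps = as.numeric(fps)
    ),
    class = "bb_scene"
  )
}

#' @export
print.bb_scene <- function(x, ...) {
  cat("<bb_scene>\n")
  cat(sprintf("  frame: %g x %g px @ %g fps\n",
              x$frame_width, x$frame_height, x$fps))
  cat(sprintf("  bait point B: (%g, %g); proximity radius: %g px\n",
              x$bait_point[1], x$bait_point[2], x$proximity_radius))
  cat(sprintf("  annotation area A: (%g, %g) - (%g, %g)\n",
              x$annotation_area[1], x$annotation_area[2],
              x$annotation_area[3], x$annotation_area[4]))
  invisible(x)
}

#' Default proximity-zone radius from the bait bounding box
#'
#' The study's figures draw the proximity zone but never give its size; the
#' package default ties it to the apparent bait size: twice the diagonal of
#' the bait's bounding box.
#'
#' @param bbox Numeric length-4 `(x1, y1, x2, y2)` bait bounding box.
#' @param factor Multiplier on the diagonal, default 2.
#' @return Radius in pixels.
#' @export
proximity_radius_from_bait_bbox <- function(bbox, factor = 2) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stopf("bbox must be (x1, y1, x2, y2) with positive width and height")
  }
  factor * sqrt((bbox[3] - bbox[1])^2 + (bbox[4] - bbox[2])^2)
}

#' Read a scene or deployment metadata from a YAML config
#'
#' @param path YAML file with keys mirroring [scene()] arguments
#'   (`bait_point`, `proximity_radius`, `annotation_area`, `frame_width`,
#'   `frame_height`, `fps`).
#' @return A `bb_scene`.
#' @export
read_scene <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scene, cfg[intersect(names(cfg), names(formals(scene)))])
}

#' Deployment metadata
#'
#' One deployment is a continuous multi-hour immersion of a baited camera
#' rig (nominally 9 h, bounded by battery and storage).
#'
#' @param bait_type One of `"raw"`, `"C17"`, `"C600"`, `"Lactips"`.
#' @param day_id Integer trial day.
#' @param start_time `POSIXct` deployment start (defaults to epoch; only
#'   differences matter for hourly binning).
#' @param duration_h Deployment duration in hours (> 0), default 9.
#' @return An object of class `bb_deployment_meta`.
#' @export
deployment_meta <- function(bait_type = c("raw", "C17", "C600", "Lactips"),
                            day_id = 1L,
                            start_time = as.POSIXct("2020-07-20 10:00:00",
                                                    tz = "UTC"),
                            duration_h = 9) {
  bait_type <- match.arg(bait_type)
  if (duration_h <= 0) stopf("duration_h must be > 0")
  structure(
    list(bait_type = bait_type, day_id = as.integer(day_id),
         start_time = start_time, duration_h = as.numeric(duration_h)),
    class = "bb_deployment_meta"
  )
}

#' Read deployment metadata entries from a YAML file
#'
#' @param path YAML file holding a list of deployment entries with keys
#'   `bait_type`, `day_id`, `start_time`, `duration_h`.
#' @return A list of `bb_deployment_meta`.
#' @export
read_deployment_meta <- function(path) {
  entries <- yaml::read_yaml(path)
  lapply(entries, function(e) {
    if (!is.null(e$start_time)) {
      e$start_time <- as.POSIXct(e$start_time, tz = "UTC")
    }
    do.call(deployment_meta, e[intersect(names(e),
                                         names(formals(deployment_meta)))])
  })
}
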