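# The tracked object is a constellation of keypoints around a reference
# center (the R-table of the Generalized Hough Transform). Each model
# keypoint stores its distance d_i to the center and the angle of the
# keypoint-to-center vector measured relative to the keypoint's own
# orientation, which makes the stored geometry rotation-covariant. A binary
# voting state per keypoint records whether it supported the detected center
# in the current frame; a negative streak counter makes "remove negative
# features" during model adaptation well defined.

#' Build the keypoint object model from a template frame
#'
#' Detects keypoints inside the initial bounding box and enrolls them with
#' their distance and relative angle to the box center. All voting states
#' start positive; the initial scale is 1 and the initial rotation 0.
#'
#' @param image Template frame, color array `[h, w, 3]` in `[0, 1]`.
#' @param bbox Initial bounding box, a [ght_rect()] `(u', v', w, h)` around
#'   the instrument head. The box may (and should) be slightly larger than
#'   the object; background features are suppressed later through
#'   segmentation-based vote weights, not at enrollment.
#' @param params Detector settings ([keypoint_params()]).
#' @return An object of class `ght_object_model`.
#' @export
build_model <- function(image, bbox, params = keypoint_params()) {
  kp <- detect_keypoints(image, region = bbox, params = params)
  if (length(kp) == 0L) {
    stop("build_model: no keypoints detected inside the bounding box")
  }
  center <- rect_center(bbox)
  du <- center["u"] - kp$u
  dv <- center["v"] - kp$v
  structure(list(
    keypoints = kp,
    center_distance = as.numeric(sqrt(du^2 + dv^2)),
    center_angle = wrap_angle(atan2(dv, du) - kp$orientation),
    voting_state = rep(1L, length(kp)),
    negative_streak = rep(0L, length(kp)),
    reference_center = center,
    bbox_size = c(w = unname(bbox["w"]), h = unname(bbox["h"])),
    current_scale = 1.0,
    current_rotation = 0.0,
    enrollment_size = length(kp)
  ), class = "ght_object_model")
}

#' @export
print.ght_object_model <- function(x, ...) {
  cat(sprintf(paste0("<ght_object_model: %d keypoints (%d positive), ",
                     "center (%.1f, %.1f), scale %.3f, rotation %.1f deg>\n"),
              length(x$keypoints), sum(x$voting_state),
              x$reference_center["u"], x$reference_center["v"],
              x$current_scale, x$current_rotation * 180 / pi))
  invisible(x)
}

#' Match the object model against frame keypoints
#'
#' Nearest-neighbour descriptor matching with Lowe's ratio test, enforced
#' one-to-one (greedy by ascending descriptor distance). The vote weight of
#' each matched pair is the segmentation-model foreground weight of the
#' matched frame keypoint.
#'
#' @param model A `ght_object_model`.
#' @param frame_keypoints `ght_keypoints` detected in the current frame.
#' @param weights Per-frame-keypoint foreground weights in `[0, 1]`
#'   (see [keypoint_weights()]); defaults to 1 for all.
#' @param ratio Lowe ratio-test threshold.
#' @return An object of class `ght_matchset`: a list with integer vectors
#'   `model_index`, `frame_index`, numeric `u`, `v`, `orientation` (of the
#'   matched frame keypoint), `weight`, `distance`. An empty match set is a
#'   valid result and signals possible loss of the target.
#' @export
match_model <- function(model, frame_keypoints, weights = NULL, ratio = 0.8) {
  kp <- frame_keypoints
  n <- length(model$keypoints); m <- length(kp)
  if (!is.null(weights)) {
    stopifnot(length(weights) == m)
    if (m > 0 && (any(weights < -1e-9) || any(weights > 1 + 1e-9))) {
      stop("match_model: weights must lie in [0, 1]")
    }
  }
  if (m == 0L || n == 0L) return(empty_matchset())
  if (ncol(model$keypoints$descriptors) != ncol(kp$descriptors)) {
    stop("match_model: descriptor lengths disagree")
  }
  if (is.null(weights)) weights <- rep(1, m)
  # descriptors are L2-normalized: dist^2 = 2 - 2 * dot
  dots <- model$keypoints$descriptors %*% t(kp$descriptors)
  d2 <- pmax(2 - 2 * dots, 0)
  best <- max.col(-d2, ties.method = "first")
  d1 <- d2[cbind(seq_len(n), best)]
  if (m >= 2L) {
    d2nd <- vapply(seq_len(n), function(i) min(d2[i, -best[i]]), numeric(1))
  } else {
    d2nd <- rep(Inf, n)
  }
  pass <- sqrt(d1) < ratio * sqrt(d2nd)
  cand <- which(pass)
  if (length(cand) == 0L) return(empty_matchset())
  # greedy one-to-one: best (smallest distance) claim on each frame keypoint
  ord <- cand[order(d1[cand])]
  taken <- logical(m)
  keep <- integer(0)
  for (i in ord) {
    j <- best[i]
    if (!taken[j]) { taken[j] <- TRUE; keep <- c(keep, i) }
  }
  keep <- sort(keep)
  j <- best[keep]
  structure(list(model_index = keep, frame_index = j,
                 u = kp$u[j], v = kp$v[j], orientation = kp$orientation[j],
                 weight = weights[j], distance = sqrt(d1[keep])),
            class = "ght_matchset")
}

empty_matchset <- function() {
  structure(list(model_index = integer(0), frame_index = integer(0),
                 u = numeric(0), v = numeric(0), orientation = numeric(0),
                 weight = numeric(0), distance = numeric(0)),
            class = "ght_matchset")
}

#' @export
length.ght_matchset <- function(x) length(x$model_index)

#' @export
print.ght_matchset <- function(x, ...) {
  cat(sprintf("<ght_matchset: %d matches>\n", length(x)))
  invisible(x)
}

#' @export
as_tibble.ght_matchset <- function(x, ...) {
  tibble::tibble(model_index = x$model_index, frame_index = x$frame_index,
                 u = x$u, v = x$v, orientation = x$orientation,
                 weight = x$weight, distance = x$distance)
}

#' Serialize an object model to JSON
#'
#' The descriptor matrix is stored row-major with an explicit shape header so
#' a tracking session can be resumed or inspected outside R.
#'
#' @param model A `ght_object_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_object_model <- function(model, path) {
  kp <- model$keypoints
  obj <- list(
    format = "ghtrack-object-model",
    version = 1L,
    descriptor_shape = dim(kp$descriptors),
    descriptors_row_major = as.numeric(t(kp$descriptors)),
    u = kp$u, v = kp$v, orientation = kp$orientation, scale = kp$scale,
    response = kp$response,
    center_distance = model$center_distance,
    center_angle = model$center_angle,
    voting_state = model$voting_state,
    negative_streak = model$negative_streak,
    reference_center = as.numeric(model$reference_center),
    bbox_size = as.numeric(model$bbox_size),
    current_scale = model$current_scale,
    current_rotation = model$current_rotation,
    enrollment_size = model$enrollment_size
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an object model written by [write_object_model()]
#'
#' @param path Path to the JSON archive.
#' @return A `ght_object_model`.
#' @export
read_object_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ghtrack-object-model")) {
    stop("read_object_model: not an object-model archive")
  }
  sh <- as.integer(obj$descriptor_shape)
  desc <- matrix(obj$descriptors_row_major, nrow = sh[1], ncol = sh[2],
                 byrow = TRUE)
  kp <- new_keypoints(obj$u, obj$v, obj$orientation, obj$scale, obj$response,
                      desc)
  structure(list(
    keypoints = kp,
    center_distance = as.numeric(obj$center_distance),
    center_angle = as.numeric(obj$center_angle),
    voting_state = as.integer(obj$voting_state),
    negative_streak = as.integer(obj$negative_streak),
    reference_center = c(u = obj$reference_center[1],
                         v = obj$reference_center[2]),
    bbox_size = c(w = obj$bbox_size[1], h = obj$bbox_size[2]),
    current_scale = obj$current_scale,
    current_rotation = obj$current_rotation,
    enrollment_size = as.integer(obj$enrollment_size)
  ), class = "ght_object_model")
}
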