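# Per-frame orchestration. Every frame runs the fixed pipeline
# detect -> match -> weight -> vote -> find center -> classify ->
# estimate scale/rotation -> adaptation decision -> histogram update.
# Tracking is by detection: the whole frame is searched every time, so the
# tracker can recover from total failure without drift.

#' Tracker configuration
#'
#' @param detector Keypoint detector settings ([keypoint_params()]).
#' @param match_ratio Lowe ratio-test threshold for descriptor matching.
#' @param weight_threshold Minimum segmentation weight for a keypoint to
#'   participate in voting (and to qualify as an update candidate).
#' @param thickness_ratio Voting ring thickness ratio `c(lo, hi)`.
#' @param smooth_sigma Accumulator Gaussian smoothing, pixels.
#' @param classify_tolerance Radial slack for positive classification, px.
#' @param stay_prob Temporal stay-probability of the segmentation filter.
#' @param delta Histogram update factor.
#' @param patch_half_width Minimum half-width of the weight patch, px (grows
#'   with detector scale).
#' @param min_matches Minimum number of vote-eligible matches for a
#'   detection to be trusted in normal mode.
#' @param count_threshold Candidate-count threshold for a model update;
#'   `NULL` means `max(5, 10%` of the model size`)`.
#' @param removal_streak Negative-streak length at which a model keypoint
#'   becomes removable.
#' @param min_model_frac Never prune the model below this fraction of its
#'   enrollment size.
#' @param max_model_size Hard cap on model size.
#' @param reacquire_matches Minimum matches to leave reset mode.
#' @param reacquire_peak_frac Minimum accumulator peak to leave reset mode,
#'   as a fraction of the template self-match peak.
#' @return A list of class `ght_config`.
#' @export
ght_config <- function(detector = keypoint_params(), match_ratio = 0.8,
                       weight_threshold = 0.5,
                       thickness_ratio = c(0.95, 1.05), smooth_sigma = 2,
                       classify_tolerance = 2, stay_prob = 0.6, delta = 0.1,
                       patch_half_width = 4, min_matches = 4L,
                       count_threshold = NULL, removal_streak = 5L,
                       min_model_frac = 0.5, max_model_size = 600L,
                       reacquire_matches = 8L, reacquire_peak_frac = 0.25) {
  structure(list(detector = detector, match_ratio = match_ratio,
                 weight_threshold = weight_threshold,
                 thickness_ratio = thickness_ratio,
                 smooth_sigma = smooth_sigma,
                 classify_tolerance = classify_tolerance,
                 stay_prob = stay_prob, delta = delta,
                 patch_half_width = patch_half_width,
                 min_matches = as.integer(min_matches),
                 count_threshold = count_threshold,
                 removal_streak = as.integer(removal_streak),
                 min_model_frac = min_model_frac,
                 max_model_size = as.integer(max_model_size),
                 reacquire_matches = as.integer(reacquire_matches),
                 reacquire_peak_frac = reacquire_peak_frac),
            class = "ght_config")
}

# Axis-aligned bounding box of the template rectangle at pose (u, v, th, s).
pose_bbox <- function(center, bbox_size, scale, rotation) {
  w <- bbox_size[1] * scale; h <- bbox_size[2] * scale
  half_u <- (w * abs(cos(rotation)) + h * abs(sin(rotation))) / 2
  half_v <- (w * abs(sin(rotation)) + h * abs(cos(rotation))) / 2
  ght_rect(center[1] - half_u, center[2] - half_v, 2 * half_u, 2 * half_v)
}

#' Initialize a tracker from the first frame
#'
#' Builds the keypoint model from the bounding box, computes the template
#' self-match accumulator peak (the re-acquisition reference), and
#' initializes the segmentation model from the hull of the enrolled
#' keypoints (all positive on the template frame).
#'
#' @param frame Template frame, `[h, w, 3]` array in `[0, 1]`.
#' @param bbox Initial bounding box ([ght_rect()]).
#' @param config A [ght_config()].
#' @return A tracker state of class `ght_tracker`, to be advanced with
#'   [track_frame()].
#' @export
ght_tracker <- function(frame, bbox, config = ght_config()) {
  model <- build_model(frame, bbox, config$detector)
  ms0 <- match_model(model, model$keypoints, ratio = config$match_ratio)
  acc0 <- cast_votes(ms0, model, config$weight_threshold,
                     extent = c(dim(frame)[2], dim(frame)[1]),
                     prev_scale = 1,
                     thickness_ratio = config$thickness_ratio)
  fc0 <- find_center(acc0, config$smooth_sigma)
  template_peak <- if (is.null(fc0)) 0 else fc0$peak
  seg <- init_segmentation(frame, cbind(model$keypoints$u, model$keypoints$v),
                           bbox, config$stay_prob, config$delta)
  center <- rect_center(bbox)
  structure(list(model = model, seg = seg, config = config,
                 mode = "NORMAL",
                 pose = c(u = unname(center["u"]), v = unname(center["v"]),
                          theta = 0, scale = 1),
                 template_peak = template_peak,
                 frame_index = 1L,
                 width = dim(frame)[2], height = dim(frame)[1]),
            class = "ght_tracker")
}

#' @export
print.ght_tracker <- function(x, ...) {
  cat(sprintf("<ght_tracker: frame %d, mode %s, model %d keypoints>\n",
              x$frame_index, x$mode, length(x$model$keypoints)))
  invisible(x)
}

no_detection_record <- function(frame_index, mode, matches = 0L, peak = 0,
                                model_size = NA_integer_) {
  tibble::tibble(frame = frame_index, u = NA_real_, v = NA_real_,
                 theta = NA_real_, scale = NA_real_, mode = mode,
                 matches = as.integer(matches), peak = peak,
                 model_size = model_size)
}

pose_record <- function(frame_index, pose, mode, matches, peak, model_size) {
  tibble::tibble(frame = frame_index, u = unname(pose["u"]),
                 v = unname(pose["v"]), theta = unname(pose["theta"]),
                 scale = unname(pose["scale"]), mode = mode,
                 matches = as.integer(matches), peak = peak,
                 model_size = as.integer(model_size))
}

#' Track the object in one new frame
#'
#' Advances the tracker through the fixed per-frame pipeline and returns
#' the updated state plus the trajectory record for this frame. In normal
#' mode a failed detection (no eligible votes, an empty accumulator, or an
#' adaptation decision of reset) reports no-detection and switches the
#' tracker to reset mode with the model and segmentation frozen; in reset
#' mode each frame attempts whole-frame re-detection.
#'
#' @param state A `ght_tracker` state.
#' @param frame The next frame image.
#' @return A list: `state` (advanced tracker) and `record` (one-row tibble
#'   `frame`, `u`, `v`, `theta`, `scale`, `mode`, `matches`, `peak`,
#'   `model_size`; pose columns `NA` on no-detection).
#' @export
track_frame <- function(state, frame) {
  cfg <- state$config
  state$frame_index <- state$frame_index + 1L
  t_idx <- state$frame_index

  if (state$mode == "RESET") {
    rd <- redetect(state$model, frame, state$seg, state$template_peak, cfg)
    if (is.null(rd)) {
      return(list(state = state,
                  record = no_detection_record(t_idx, "RESET",
                                               model_size = length(state$model$keypoints))))
    }
    state$mode <- "NORMAL"
    state$model <- rd$model
    state$model$current_scale <- unname(rd$pose["scale"])
    state$model$current_rotation <- unname(rd$pose["theta"])
    state$pose <- rd$pose
    # trusted again: persist the posterior and adapt histograms
    state$seg$prev_posterior <- rd$map
    pos_uv <- cbind(rd$match_set$u[rd$positive], rd$match_set$v[rd$positive])
    bt <- pose_bbox(rd$pose[c("u", "v")], state$model$bbox_size,
                    rd$pose["scale"], rd$pose["theta"])
    state$seg <- update_histograms(state$seg, frame, pos_uv, bt)
    return(list(state = state,
                record = pose_record(t_idx, rd$pose, "NORMAL", rd$matches,
                                     rd$peak, length(state$model$keypoints))))
  }

  kp <- detect_keypoints(frame, params = cfg$detector)
  pm <- posterior_map(state$seg, frame)
  w <- keypoint_weights(pm$map, kp$u, kp$v, cfg$patch_half_width,
                        kp_scale = kp$scale)
  ms <- match_model(state$model, kp, w, ratio = cfg$match_ratio)
  n_eligible <- sum(ms$weight > cfg$weight_threshold)
  lost <- function(matches) {
    state$mode <- "RESET"
    list(state = state,
         record = no_detection_record(t_idx, "RESET", matches,
                                      model_size = length(state$model$keypoints)))
  }
  if (length(ms) == 0L || n_eligible < cfg$min_matches) {
    return(lost(length(ms)))
  }
  acc <- cast_votes(ms, state$model, cfg$weight_threshold,
                    extent = c(state$width, state$height),
                    prev_scale = state$model$current_scale,
                    thickness_ratio = cfg$thickness_ratio)
  fc <- find_center(acc, cfg$smooth_sigma)
  if (is.null(fc)) return(lost(length(ms)))

  cl <- classify_votes(ms, state$model, fc$center, cfg$classify_tolerance,
                       cfg$weight_threshold, state$model$current_scale,
                       cfg$thickness_ratio)
  state$model <- cl$model
  sr <- estimate_scale_rotation(ms, cl$positive, fc$center, state$model)
  pose <- c(u = unname(fc$center[1]), v = unname(fc$center[2]),
            theta = sr$rotation, scale = sr$scale)
  bt <- pose_bbox(pose[c("u", "v")], state$model$bbox_size, pose["scale"],
                  pose["theta"])

  pos_uv <- cbind(ms$u[cl$positive], ms$v[cl$positive])
  hull_pos <- if (nrow(pos_uv) >= 3L) convex_hull(pos_uv[, 1], pos_uv[, 2])
              else NULL
  center_inside <- !is.null(hull_pos) &&
    points_in_convex_poly(pose["u"], pose["v"], hull_pos)

  if (!center_inside) {
    cand <- collect_candidates(kp, bt, pm$map, cfg$weight_threshold,
                               cfg$patch_half_width)
    cthr <- if (is.null(cfg$count_threshold)) {
      max(5L, ceiling(0.1 * length(state$model$keypoints)))
    } else cfg$count_threshold
    decision <- adaptation_decision(pose[c("u", "v")], cand, cthr)
    if (decision == "RESET") return(lost(length(ms)))
    if (decision == "UPDATE") {
      state$model <- apply_update(state$model, cand, pose[c("u", "v")],
                                  unname(pose["scale"]),
                                  unname(pose["theta"]),
                                  cfg$removal_streak, cfg$min_model_frac,
                                  cfg$max_model_size)
    }
  }

  state$model$current_scale <- unname(pose["scale"])
  state$model$current_rotation <- unname(pose["theta"])
  state$pose <- pose
  state$seg <- pm$model   # persist the posterior recursion
  state$seg <- update_histograms(state$seg, frame, pos_uv, bt)
  list(state = state,
       record = pose_record(t_idx, pose, "NORMAL", length(ms), fc$peak,
                            length(state$model$keypoints)))
}

# Normalize the many accepted frame sources to list(n, get(t)).
frame_source <- function(frames) {
  if (inherits(frames, "ght_sequence")) {
    return(list(n = frames$n_frames, get = frames$frame))
  }
  if (is.function(frames)) {
    n <- attr(frames, "n_frames")
    if (is.null(n)) stop("frame function needs an 'n_frames' attribute")
    return(list(n = n, get = frames))
  }
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    files <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames in ", frames)
    return(list(n = length(files), get = function(t) read_frame(files[t])))
  }
  if (is.list(frames)) {
    return(list(n = length(frames), get = function(t) frames[[t]]))
  }
  stop("unsupported frame source")
}

#' Track an object through a whole sequence
#'
#' Initializes the tracker from the first frame and the given bounding box,
#' then advances frame by frame. Optionally lifts each detected 2D pose to
#' a 3D pose initialization through a pinhole camera model. Deterministic:
#' identical inputs give identical trajectories.
#'
#' @param frames A `ght_sequence`, a directory of PNG frames, a list of
#'   image arrays, or a `function(t)` with an `n_frames` attribute.
#' @param init_bbox Bounding box on frame 1 ([ght_rect()]).
#' @param config A [ght_config()].
#' @param camera Optional [camera_model()] for 3D lifting.
#' @param z0 Metric depth of the object at enrollment (required with
#'   `camera`).
#' @param refine_3d Optional `function(pose3d, frame)` hook representing an
#'   external 3D refinement stage; the default passes the initialization
#'   through unchanged.
#' @return An object of class `ght_track`: list with `records` (tibble, one
#'   row per frame), `state` (final tracker state), and `config`.
#' @export
run_sequence <- function(frames, init_bbox, config = ght_config(),
                         camera = NULL, z0 = NULL, refine_3d = NULL) {
  src <- frame_source(frames)
  stopifnot(src$n >= 1L)
  if (!is.null(camera) && is.null(z0)) stop("z0 is required with a camera")
  first <- src$get(1L)
  state <- ght_tracker(first, init_bbox, config)
  records <- vector("list", src$n)
  records[[1]] <- pose_record(1L, state$pose, "NORMAL",
                              length(state$model$keypoints),
                              state$template_peak,
                              length(state$model$keypoints))
  pose3d_prev <- c(x = 0, y = 0, z = if (is.null(z0)) NA_real_ else z0,
                   phi = 0, psi = 0, theta_hat = 0)
  lift <- function(rec, frame) {
    if (is.null(camera)) return(rec)
    if (is.na(rec$u)) {
      rec[c("x", "y", "z", "phi", "psi", "theta_hat")] <- NA_real_
      return(rec)
    }
    p3 <- lift_to_3d(c(u = rec$u, v = rec$v, theta = rec$theta,
                       scale = rec$scale),
                     camera, z0, pose3d_prev)
    if (!is.null(refine_3d)) p3 <- refine_3d(p3, frame)
    pose3d_prev <<- p3
    rec$x <- unname(p3["x"]); rec$y <- unname(p3["y"])
    rec$z <- unname(p3["z"])
    rec$phi <- unname(p3["phi"]); rec$psi <- unname(p3["psi"])
    rec$theta_hat <- unname(p3["theta_hat"])
    rec
  }
  if (!is.null(camera)) {
    records[[1]] <- lift(records[[1]], first)
  }
  if (src$n > 1L) {
    for (t in 2:src$n) {
      step <- tryCatch({
        frame <- src$get(t)
        s <- track_frame(state, frame)
        s$record <- lift(s$record, frame)
        s
      }, error = function(e) {
        warning(sprintf("frame %d unreadable (%s); recorded as no-detection",
                        t, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(step)) {
        state$frame_index <- state$frame_index + 1L
        records[[t]] <- no_detection_record(t, state$mode,
                                            model_size = length(state$model$keypoints))
      } else {
        state <- step$state
        records[[t]] <- step$record
      }
    }
  }
  structure(list(records = dplyr::bind_rows(records), state = state,
                 config = config),
            class = "ght_track")
}

#' @export
print.ght_track <- function(x, ...) {
  n <- nrow(x$records)
  det <- sum(!is.na(x$records$u))
  cat(sprintf("<ght_track: %d frames, %d detections (%.1f%%)>\n",
              n, det, 100 * det / n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-frame trajectory of a tracked sequence
#'
#' @param x A `ght_track`.
#' @param ... Unused.
#' @return The per-frame records tibble.
#' @export
tidy.ght_track <- function(x, ...) x$records

#' One-row summary of a tracked sequence
#'
#' @param x A `ght_track`.
#' @param ... Unused.
#' @return A one-row tibble: frame count, detection count and rate, mean
#'   match count, mean accumulator peak, final mode and model size.
#' @export
glance.ght_track <- function(x, ...) {
  r <- x$records
  det <- !is.na(r$u)
  tibble::tibble(n_frames = nrow(r), n_detected = sum(det),
                 detection_rate = mean(det),
                 mean_matches = mean(r$matches),
                 mean_peak = mean(r$peak),
                 final_mode = r$mode[nrow(r)],
                 final_model_size = r$model_size[nrow(r)])
}

#' Plot a tracked trajectory
#'
#' Draws the tracked center path in image coordinates (v axis reversed to
#' match the image convention), optionally against ground truth.
#'
#' @param object A `ght_track`.
#' @param truth Optional ground-truth tibble with `u`, `v` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ght_track <- function(object, truth = NULL, ...) {
  r <- object$records
  p <- ggplot2::ggplot(r[!is.na(r$u), ], ggplot2::aes(x = u, y = v)) +
    ggplot2::geom_path(color = "steelblue") +
    ggplot2::geom_point(size = 0.6, color = "steelblue") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "u (px)", y = "v (px)",
                  title = "Tracked center trajectory")
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_path(data = truth, ggplot2::aes(x = u, y = v),
                                color = "gray40", linetype = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a trajectory CSV
#'
#' Columns `frame,u,v,theta,scale,mode,matches,peak` plus
#' `x,y,z,phi,psi,theta_hat` when 3D lifting was enabled; missed detections
#' are encoded as empty fields; angles in radians.
#'
#' @param x A `ght_track` or its records tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  r <- if (inherits(x, "ght_track")) x$records else x
  cols <- c("frame", "u", "v", "theta", "scale", "mode", "matches", "peak")
  extra <- c("x", "y", "z", "phi", "psi", "theta_hat")
  cols <- c(cols, intersect(extra, names(r)))
  utils::write.csv(r[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A tibble with empty fields read back as `NA`.
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path, na.strings = c("", "NA")))
}
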