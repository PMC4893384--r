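# Model adaptation and reset. The model is only touched when the voted
# center falls outside the convex hull of the positive keypoints — the
# signature of appearance change, out-of-plane rotation, or the object
# leaving the view. The keypoints inside the detected box are then screened
# by their segmentation weight: if the center sits inside the hull of these
# candidates (and there are enough of them) the model absorbs them and
# sheds persistently negative features; if the center falls outside, the
# object is most likely gone and the tracker enters reset mode, where the
# model and segmentation are frozen and every frame attempts a whole-frame
# re-detection until the object is matched again.

#' Collect candidate keypoints for a model update
#'
#' @param frame_keypoints `ght_keypoints` of the current frame.
#' @param bbox Detected object box B_t ([ght_rect()]).
#' @param prob_map Foreground posterior map of the frame.
#' @param weight_threshold Minimum foreground weight (same threshold as
#'   voting participation).
#' @param patch_half_width Patch half-width for [keypoint_weights()].
#' @return A list of class `ght_candidates`: `keypoints` (subset of the
#'   frame keypoints), `weight`, and `index` into `frame_keypoints`.
#' @export
collect_candidates <- function(frame_keypoints, bbox, prob_map,
                               weight_threshold = 0.5,
                               patch_half_width = 4) {
  inb <- which(points_in_rect(frame_keypoints$u, frame_keypoints$v, bbox))
  if (length(inb) > 0L) {
    w <- keypoint_weights(prob_map, frame_keypoints$u[inb],
                          frame_keypoints$v[inb], patch_half_width,
                          kp_scale = frame_keypoints$scale[inb])
    sel <- w > weight_threshold
    inb <- inb[sel]; w <- w[sel]
  } else {
    w <- numeric(0)
  }
  structure(list(keypoints = subset_keypoints(frame_keypoints, inb),
                 weight = w, index = inb),
            class = "ght_candidates")
}

#' @export
length.ght_candidates <- function(x) length(x$index)

#' Decide between model update, hold, and reset
#'
#' Invoked when the voted center fell outside the hull of the positive
#' keypoints. `UPDATE` when the center lies inside the hull of the
#' candidates and there are more than `count_threshold` of them; `RESET`
#' when the center is outside the candidate hull (or the hull is
#' degenerate, fewer than 3 candidates); `HOLD` otherwise (center inside
#' but too few candidates to trust an update).
#'
#' @param center Detected center `c(u, v)`.
#' @param candidates A `ght_candidates` set.
#' @param count_threshold Minimum candidate count for an update.
#' @return One of `"UPDATE"`, `"RESET"`, `"HOLD"`.
#' @export
adaptation_decision <- function(center, candidates, count_threshold = 5L) {
  if (length(candidates) < 3L) return("RESET")
  hull <- convex_hull(candidates$keypoints$u, candidates$keypoints$v)
  if (is.null(hull)) return("RESET")
  inside <- points_in_convex_poly(center[1], center[2], hull)
  if (!inside) return("RESET")
  if (length(candidates) > count_threshold) "UPDATE" else "HOLD"
}

#' Absorb candidate keypoints into the model and prune negative features
#'
#' Candidates are enrolled in template units: distances to the detected
#' center are divided by the current scale, and the center angle is stored
#' relative to each keypoint's own orientation (which makes it independent
#' of the current rotation). Near-duplicates of existing model keypoints
#' (descriptor distance < 0.4 and template distance within 3 px) are
#' rejected. Model keypoints whose negative streak has reached
#' `removal_streak` are deleted, but never below `min_frac` of the
#' enrollment size; if the model would exceed `max_size`, the
#' lowest-response new candidates are dropped first.
#'
#' @param model A `ght_object_model`.
#' @param candidates A `ght_candidates` set (decision was `UPDATE`).
#' @param center Detected center `c(u, v)`.
#' @param scale,rotation Current pose estimates s_t, theta_t.
#' @param removal_streak Consecutive-negative-frames threshold for removal.
#' @param min_frac Minimum model size as a fraction of enrollment size.
#' @param max_size Hard cap on model size.
#' @return The updated `ght_object_model`.
#' @export
apply_update <- function(model, candidates, center, scale, rotation,
                         removal_streak = 5L, min_frac = 0.5,
                         max_size = 600L) {
  ck <- candidates$keypoints
  n_cand <- length(ck)
  if (n_cand > 0L) {
    du <- center[1] - ck$u; dv <- center[2] - ck$v
    d_new <- sqrt(du^2 + dv^2) / scale
    a_new <- wrap_angle(atan2(dv, du) - ck$orientation)
    # reject near-duplicates of existing model keypoints
    dots <- ck$descriptors %*% t(model$keypoints$descriptors)
    dmin <- sqrt(pmax(2 - 2 * apply(dots, 1, max), 0))
    nn <- max.col(dots, ties.method = "first")
    dup <- dmin < 0.4 & abs(d_new - model$center_distance[nn]) < 3
    keep <- which(!dup)
    # respect the size cap, strongest responses first
    room <- max_size - length(model$keypoints)
    if (length(keep) > room) {
      keep <- keep[order(-ck$response[keep])][seq_len(max(room, 0L))]
      keep <- sort(keep)
    }
    if (length(keep) > 0L) {
      kk <- subset_keypoints(ck, keep)
      model$keypoints <- new_keypoints(
        c(model$keypoints$u, kk$u), c(model$keypoints$v, kk$v),
        c(model$keypoints$orientation, kk$orientation),
        c(model$keypoints$scale, kk$scale),
        c(model$keypoints$response, kk$response),
        rbind(model$keypoints$descriptors, kk$descriptors))
      model$center_distance <- c(model$center_distance, d_new[keep])
      model$center_angle <- c(model$center_angle, a_new[keep])
      model$voting_state <- c(model$voting_state, rep(1L, length(keep)))
      model$negative_streak <- c(model$negative_streak,
                                 rep(0L, length(keep)))
    }
  }
  # prune persistently negative features, guarding the minimum size
  stale <- which(model$negative_streak >= removal_streak)
  min_size <- max(3L, ceiling(min_frac * model$enrollment_size))
  n_removable <- max(0L, length(model$keypoints) - min_size)
  if (length(stale) > n_removable) {
    stale <- stale[order(-model$negative_streak[stale])][seq_len(n_removable)]
  }
  if (length(stale) > 0L) {
    keep <- setdiff(seq_along(model$center_distance), stale)
    model$keypoints <- subset_keypoints(model$keypoints, keep)
    model$center_distance <- model$center_distance[keep]
    model$center_angle <- model$center_angle[keep]
    model$voting_state <- model$voting_state[keep]
    model$negative_streak <- model$negative_streak[keep]
  }
  model
}

#' Attempt whole-frame re-detection in reset mode
#'
#' Runs the full detect/match/vote pipeline over the entire frame. The
#' tracker returns to normal mode only when enough model keypoints match
#' and the (smoothed) accumulator peak reaches a fraction of the
#' template-frame self-match peak; otherwise no pose is reported and the
#' tracker stays in reset mode.
#'
#' @param model A `ght_object_model` (frozen during reset).
#' @param frame Current frame image.
#' @param seg_model The (frozen) `ght_segmentation`.
#' @param template_peak Accumulator peak of the template self-match, the
#'   re-acquisition reference.
#' @param config Tracker configuration ([ght_config()]).
#' @return `NULL` when the object is not re-acquired, otherwise a list with
#'   `pose` (`u`, `v`, `theta`, `scale`), `matches`, `peak`, `model`
#'   (voting states refreshed), and `map` (posterior map used).
#' @export
redetect <- function(model, frame, seg_model, template_peak,
                     config = ght_config()) {
  kp <- detect_keypoints(frame, params = config$detector)
  if (length(kp) == 0L) return(NULL)
  pm <- posterior_map(seg_model, frame)   # frozen: posterior not persisted
  w <- keypoint_weights(pm$map, kp$u, kp$v, config$patch_half_width,
                        kp_scale = kp$scale)
  ms <- match_model(model, kp, w, ratio = config$match_ratio)
  if (length(ms) < config$reacquire_matches) return(NULL)
  acc <- cast_votes(ms, model, config$weight_threshold,
                    extent = c(ncol(pm$map), nrow(pm$map)),
                    prev_scale = model$current_scale,
                    thickness_ratio = config$thickness_ratio)
  fc <- find_center(acc, config$smooth_sigma)
  if (is.null(fc)) return(NULL)
  if (sum(ms$weight > config$weight_threshold) < config$reacquire_matches ||
      fc$peak < config$reacquire_peak_frac * template_peak) {
    return(NULL)
  }
  cl <- classify_votes(ms, model, fc$center, config$classify_tolerance,
                       config$weight_threshold, model$current_scale,
                       config$thickness_ratio)
  sr <- estimate_scale_rotation(ms, cl$positive, fc$center, cl$model)
  list(pose = c(u = unname(fc$center[1]), v = unname(fc$center[2]),
                theta = sr$rotation, scale = sr$scale),
       matches = length(ms), peak = fc$peak, model = cl$model,
       map = pm$map, match_set = ms, positive = cl$positive)
}
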