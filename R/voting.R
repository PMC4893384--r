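# Rotation-invariant annulus voting. A matched keypoint does not know the
# object's current in-plane rotation, but it does know its template distance
# d_i to the reference center, so the center must lie on a circle of radius
# d_i * s_{t-1} around the keypoint. Each eligible keypoint therefore votes
# for a thin ring (thickness ratio r_d around that radius, absorbing
# per-frame scale change and mild out-of-plane effects), and the rings of
# all inliers intersect at the true center regardless of rotation. Scale and
# rotation are estimated afterwards from the positive keypoints only.

#' Radial voting interval for one keypoint
#'
#' @param center_distance Template distance d_i of the keypoint to the
#'   reference center, pixels.
#' @param prev_scale Scale estimate of the previous frame, s_{t-1}.
#' @param thickness_ratio Ring thickness ratio `c(lo, hi)`; default
#'   `c(0.95, 1.05)`.
#' @return `c(r_min, r_max)` in pixels. A zero distance gives `c(0, 0)`, a
#'   point vote at the keypoint itself.
#' @export
vote_radius <- function(center_distance, prev_scale,
                        thickness_ratio = c(0.95, 1.05)) {
  stopifnot(center_distance >= 0, prev_scale > 0)
  center_distance * prev_scale * thickness_ratio
}

# Effective annulus half-thickness used when rasterizing to integer cells:
# never below half a cell diagonal, which guarantees that every cell the
# continuous ring passes through (in particular the one containing the true
# center) receives the vote even for degenerate ring thickness.
annulus_halfwidth <- function(r_interval) {
  max((r_interval[2] - r_interval[1]) / 2, sqrt(2) / 2)
}

#' Cast weighted annulus votes into an accumulator
#'
#' Each match whose foreground weight exceeds `weight_threshold` deposits a
#' total mass equal to its weight, shared uniformly over the integer cells of
#' the ring of [vote_radius()] centered at the keypoint's frame position
#' (cells whose distance to the keypoint lies within half a ring thickness,
#' at least half a cell diagonal, of the ring's mid radius). Votes falling outside
#' the image are clipped, so total accumulator mass can be below the summed
#' weights. Near and far keypoints have equal influence: the per-cell share
#' shrinks as the ring perimeter grows.
#'
#' @param matches A `ght_matchset` (see [match_model()]).
#' @param model The `ght_object_model` the matches refer to.
#' @param weight_threshold Minimum vote weight for participation (default
#'   0.5).
#' @param extent Accumulator extent `c(width, height)` in pixels (bin size
#'   1 px).
#' @param prev_scale Previous-frame scale estimate; defaults to the model's
#'   current scale.
#' @param thickness_ratio Ring thickness ratio passed to [vote_radius()].
#' @return An object of class `ght_accumulator`: list with `grid`
#'   (`[height, width]` matrix) and `bin_size` (1).
#' @export
cast_votes <- function(matches, model, weight_threshold = 0.5,
                       extent, prev_scale = model$current_scale,
                       thickness_ratio = c(0.95, 1.05)) {
  width <- as.integer(extent[1]); height <- as.integer(extent[2])
  grid <- matrix(0, height, width)
  elig <- which(matches$weight > weight_threshold)
  for (k in elig) {
    d_i <- model$center_distance[matches$model_index[k]]
    w <- matches$weight[k]
    u0 <- matches$u[k]; v0 <- matches$v[k]
    if (d_i <= 0) {
      ui <- round(u0); vi <- round(v0)
      if (ui >= 0 && ui < width && vi >= 0 && vi < height) {
        grid[vi + 1, ui + 1] <- grid[vi + 1, ui + 1] + w
      }
      next
    }
    r <- vote_radius(d_i, prev_scale, thickness_ratio)
    rc <- mean(r); hw <- annulus_halfwidth(r)
    rmin <- rc - hw; rmax <- rc + hw
    ulo <- floor(u0 - rmax); uhi <- ceiling(u0 + rmax)
    vlo <- floor(v0 - rmax); vhi <- ceiling(v0 + rmax)
    uu <- ulo:uhi; vv <- vlo:vhi
    du2 <- (uu - u0)^2
    dv2 <- (vv - v0)^2
    dist <- sqrt(outer(dv2, du2, "+"))
    on_ring <- dist >= rmin & dist <= rmax
    n_cells <- sum(on_ring)
    if (n_cells == 0L) next
    share <- w / n_cells
    sel <- which(on_ring, arr.ind = TRUE)
    cu <- uu[sel[, 2]]; cv <- vv[sel[, 1]]
    ok <- cu >= 0 & cu < width & cv >= 0 & cv < height
    if (!any(ok)) next
    idx <- cbind(cv[ok] + 1L, cu[ok] + 1L)
    grid[idx] <- grid[idx] + share
  }
  structure(list(grid = grid, bin_size = 1), class = "ght_accumulator")
}

#' @export
print.ght_accumulator <- function(x, ...) {
  cat(sprintf("<ght_accumulator: %dx%d, total mass %.3f, peak %.4f>\n",
              ncol(x$grid), nrow(x$grid), sum(x$grid), max(x$grid)))
  invisible(x)
}

#' Export an accumulator as a grayscale PNG heat map
#'
#' @param acc A `ght_accumulator`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accumulator_png <- function(acc, path) {
  g <- acc$grid
  m <- max(g)
  if (m > 0) g <- g / m
  write_frame(g, path)
}

#' Locate the voted object center
#'
#' Gaussian-smooths the accumulator (annuli intersect in thin arcs, so the
#' raw argmax is brittle) and returns the maximal cell, with ties broken by
#' the smallest (v, u) lexicographically. Optionally refines to sub-pixel
#' position by parabolic interpolation around the peak.
#'
#' @param acc A `ght_accumulator`.
#' @param smooth_sigma Gaussian smoothing in pixels (0 to disable).
#' @param refine If `TRUE`, add parabolic sub-pixel refinement.
#' @return `NULL` when the accumulator is empty (no-detection), otherwise a
#'   list with `cell` (integer argmax, 0-based `c(u, v)`), `center`
#'   (possibly refined `c(u, v)`), and `peak` (smoothed peak value).
#' @export
find_center <- function(acc, smooth_sigma = 2, refine = TRUE) {
  if (sum(acc$grid) <= 0) return(NULL)
  g <- if (smooth_sigma > 0) gaussian_blur(acc$grid, smooth_sigma) else acc$grid
  mx <- max(g)
  hits <- which(g == mx, arr.ind = TRUE)
  ord <- order(hits[, 1], hits[, 2])
  best <- hits[ord[1], ]
  vi <- best[1]; ui <- best[2]
  cell <- c(u = unname(ui) - 1, v = unname(vi) - 1)
  center <- cell
  if (refine) {
    nr <- nrow(g); nc <- ncol(g)
    if (ui > 1 && ui < nc) {
      den <- g[vi, ui - 1] - 2 * g[vi, ui] + g[vi, ui + 1]
      if (abs(den) > 1e-15) {
        off <- 0.5 * (g[vi, ui - 1] - g[vi, ui + 1]) / den
        center["u"] <- center["u"] + min(max(off, -0.5), 0.5)
      }
    }
    if (vi > 1 && vi < nr) {
      den <- g[vi - 1, ui] - 2 * g[vi, ui] + g[vi + 1, ui]
      if (abs(den) > 1e-15) {
        off <- 0.5 * (g[vi - 1, ui] - g[vi + 1, ui]) / den
        center["v"] <- center["v"] + min(max(off, -0.5), 0.5)
      }
    }
  }
  list(cell = cell, center = center, peak = mx)
}

#' Classify keypoints as positive or negative after voting
#'
#' A model keypoint is positive in this frame iff it participated in the
#' voting (matched, with weight above the threshold) and its ring actually
#' passes through the detected center: the distance from the matched frame
#' position to the center is within the ring half-thickness plus a small
#' tolerance of the ring mid-radius. Negative streak counters are advanced
#' for all other model keypoints (including unmatched ones).
#'
#' @param matches A `ght_matchset`.
#' @param model The `ght_object_model`.
#' @param center Detected center `c(u, v)`.
#' @param tolerance Extra radial slack in pixels beyond the ring
#'   half-thickness (default 2).
#' @param weight_threshold Voting participation threshold.
#' @param prev_scale Scale used when the votes were cast.
#' @param thickness_ratio Ring thickness ratio used when voting.
#' @return A list: `model` (voting states and negative streaks updated),
#'   `states` (0/1 per model keypoint), and `positive` (indices into
#'   `matches` of the positive pairs).
#' @export
classify_votes <- function(matches, model, center, tolerance = 2,
                           weight_threshold = 0.5,
                           prev_scale = model$current_scale,
                           thickness_ratio = c(0.95, 1.05)) {
  n <- length(model$keypoints)
  states <- integer(n)
  pos_pairs <- integer(0)
  if (length(matches) > 0L) {
    d_i <- model$center_distance[matches$model_index]
    r_lo <- d_i * prev_scale * thickness_ratio[1]
    r_hi <- d_i * prev_scale * thickness_ratio[2]
    rc <- (r_lo + r_hi) / 2
    hw <- pmax((r_hi - r_lo) / 2, sqrt(2) / 2)
    dist <- sqrt((matches$u - center[1])^2 + (matches$v - center[2])^2)
    ok <- matches$weight > weight_threshold & abs(dist - rc) <= hw + tolerance
    states[matches$model_index[ok]] <- 1L
    pos_pairs <- which(ok)
  }
  model$voting_state <- states
  model$negative_streak <- ifelse(states == 1L, 0L,
                                  model$negative_streak + 1L)
  list(model = model, states = states, positive = pos_pairs)
}

#' Estimate scale and rotation from the positive keypoints
#'
#' After the center is found, the scale is the median over positive
#' keypoints of the ratio of their current distance to the center to their
#' template distance d_i; the rotation is the circular median of the change
#' in the geometric angle of the keypoint-to-center vector relative to its
#' template value. Keypoints closer than 1 px to the center are excluded
#' (their ratios and angles are numerically meaningless). With fewer than
#' two usable positives the previous estimates are carried over and flagged.
#'
#' @param matches A `ght_matchset`.
#' @param positive Indices into `matches` of positive pairs (from
#'   [classify_votes()]).
#' @param center Detected center `c(u, v)`.
#' @param model The `ght_object_model`.
#' @param prev `c(scale, rotation)` fallback values.
#' @return A list: `scale`, `rotation` (radians, wrapped to (-pi, pi]), and
#'   `carried` (`TRUE` when the fallback was used).
#' @export
estimate_scale_rotation <- function(matches, positive, center, model,
                                    prev = c(model$current_scale,
                                             model$current_rotation)) {
  if (length(positive) > 0L) {
    mi <- matches$model_index[positive]
    d_i <- model$center_distance[mi]
    usable <- d_i >= 1
    mi <- mi[usable]; sel <- positive[usable]
  } else {
    sel <- integer(0); mi <- integer(0)
  }
  if (length(sel) < 2L) {
    return(list(scale = prev[1], rotation = wrap_angle(prev[2]),
                carried = TRUE))
  }
  du <- center[1] - matches$u[sel]
  dv <- center[2] - matches$v[sel]
  dist <- sqrt(du^2 + dv^2)
  s_t <- stats::median(dist / model$center_distance[mi])
  beta_now <- atan2(dv, du)
  beta_tpl <- model$center_angle[mi] + model$keypoints$orientation[mi]
  theta_t <- circular_median(wrap_angle(beta_now - beta_tpl))
  list(scale = s_t, rotation = theta_t, carried = FALSE)
}
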