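# Global colour-histogram foreground/background model with a recursive
# Bayesian per-pixel posterior. Colour likelihoods are HSV histograms with
# 12 x 12 bins over hue x saturation for chromatic pixels and 8 value bins
# for achromatic pixels (saturation or value too low for hue to be
# meaningful); the two parts share one normalization, so each class
# likelihood is a single 152-bin distribution. The per-pixel foreground
# posterior is a two-class forward filter: the previous frame's posterior is
# propagated through a 2 x 2 temporal transition matrix and combined with the
# colour likelihood, then normalized against the symmetric background term.

N_HS_BINS <- 12L
N_V_BINS <- 8L
N_BINS <- N_HS_BINS * N_HS_BINS + N_V_BINS  # 152

SAT_THRESHOLD <- 0.10
VAL_THRESHOLD <- 0.15

# Map RGB pixels (3-column matrix or [h, w, 3] array, values in [0, 1]) to
# 1-based histogram bin indices.
hsv_bin_index <- function(img) {
  if (length(dim(img)) == 3L) {
    rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                 as.vector(img[, , 3]))
  } else {
    rgb <- t(img)
  }
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  chrom <- s > SAT_THRESHOLD & v > VAL_THRESHOLD
  hb <- pmin(floor(h * N_HS_BINS), N_HS_BINS - 1L)
  sb <- pmin(floor(s * N_HS_BINS), N_HS_BINS - 1L)
  vb <- pmin(floor(v * N_V_BINS), N_V_BINS - 1L)
  ifelse(chrom, hb * N_HS_BINS + sb + 1L, N_HS_BINS * N_HS_BINS + vb + 1L)
}

# Normalized 152-bin histogram from selected pixels (logical or index mask).
build_color_histogram <- function(bin_idx, mask) {
  counts <- tabulate(bin_idx[mask], nbins = N_BINS)
  tot <- sum(counts)
  if (tot == 0) return(rep(1 / N_BINS, N_BINS))
  counts / tot
}

# Background sampling annulus: between inner_factor x and outer_factor x the
# detected bbox, centered on it, clipped to the image.
background_mask <- function(bbox, width, height, inner_factor = 1.25,
                            outer_factor = 1.75) {
  ctr <- rect_center(bbox)
  inner <- ght_rect(ctr["u"] - bbox["w"] * inner_factor / 2,
                    ctr["v"] - bbox["h"] * inner_factor / 2,
                    bbox["w"] * inner_factor, bbox["h"] * inner_factor)
  outer <- ght_rect(ctr["u"] - bbox["w"] * outer_factor / 2,
                    ctr["v"] - bbox["h"] * outer_factor / 2,
                    bbox["w"] * outer_factor, bbox["h"] * outer_factor)
  uu <- rep(0:(width - 1L), each = height)
  vv <- rep(0:(height - 1L), times = width)
  m <- points_in_rect(uu, vv, outer) & !points_in_rect(uu, vv, inner)
  matrix(m, height, width)
}

#' Initialize the segmentation model from the first detection
#'
#' The foreground histogram is built from pixels inside the convex hull of
#' the positive keypoints (which contains fewer background pixels than the
#' bounding box); the background histogram from an annular region
#' surrounding the detected box. The per-pixel posterior starts
#' uninformative at 0.5.
#'
#' @param image Color frame `[h, w, 3]` in `[0, 1]`.
#' @param positive_uv Two-column matrix (u, v) of positive keypoint
#'   positions. If their hull is degenerate (fewer than 3 non-collinear
#'   points) the detected box itself is used as the foreground region.
#' @param detected_bbox [ght_rect()] around the detected object.
#' @param stay_prob Temporal transition stay-probability for both classes.
#' @param delta Histogram update factor (see [update_histograms()]).
#' @return An object of class `ght_segmentation`.
#' @export
init_segmentation <- function(image, positive_uv, detected_bbox,
                              stay_prob = 0.6, delta = 0.1) {
  stopifnot(stay_prob > 0, stay_prob < 1, delta > 0, delta < 1)
  height <- dim(image)[1]; width <- dim(image)[2]
  bins <- matrix(hsv_bin_index(image), height, width)
  hull <- convex_hull(positive_uv[, 1], positive_uv[, 2])
  if (!is.null(hull)) {
    fg_mask <- poly_mask(hull, width, height)
    if (!any(fg_mask)) hull <- NULL
  }
  if (is.null(hull)) {
    bb <- rect_clip(detected_bbox, width, height)
    fg_mask <- matrix(FALSE, height, width)
    if (!is.null(bb)) {
      uu <- rep(0:(width - 1L), each = height)
      vv <- rep(0:(height - 1L), times = width)
      fg_mask <- matrix(points_in_rect(uu, vv, bb), height, width)
    }
  }
  bg_mask <- background_mask(detected_bbox, width, height)
  structure(list(
    fg_hist = build_color_histogram(bins, fg_mask),
    bg_hist = build_color_histogram(bins, bg_mask),
    prev_posterior = matrix(0.5, height, width),
    stay_prob = stay_prob,
    delta = delta,
    width = width, height = height
  ), class = "ght_segmentation")
}

#' @export
print.ght_segmentation <- function(x, ...) {
  cat(sprintf("<ght_segmentation: %dx%d, stay_prob %.2f, delta %.2f>\n",
              x$width, x$height, x$stay_prob, x$delta))
  invisible(x)
}

#' Per-pixel foreground posterior for a new frame
#'
#' Two-class recursive Bayes filter: the previous posterior is propagated
#' through the temporal transition matrix (stay-probability on the
#' diagonal), multiplied by the class colour likelihood of the pixel, and
#' normalized so foreground and background posteriors sum to 1. When both
#' class likelihoods vanish for a pixel (an unseen colour), the propagated
#' prior is returned unchanged.
#'
#' @param model A `ght_segmentation`.
#' @param image Color frame with the same extent the model was built on.
#' @return A list: `map` (matrix of foreground posteriors, the new
#'   `prev_posterior`) and `model` (the model with `prev_posterior`
#'   advanced). Callers that only probe the filter can ignore `model`.
#' @export
posterior_map <- function(model, image) {
  height <- dim(image)[1]; width <- dim(image)[2]
  if (height != model$height || width != model$width) {
    stop("posterior_map: frame extent does not match the model")
  }
  bins <- hsv_bin_index(image)
  l_fg <- model$fg_hist[bins]
  l_bg <- model$bg_hist[bins]
  prior <- as.vector(model$prev_posterior)
  a <- model$stay_prob
  pred_fg <- a * prior + (1 - a) * (1 - prior)
  pred_bg <- (1 - a) * prior + a * (1 - prior)
  num_fg <- l_fg * pred_fg
  num_bg <- l_bg * pred_bg
  z <- num_fg + num_bg
  post <- ifelse(z > 1e-12, num_fg / z, pred_fg)
  map <- matrix(post, height, width)
  model$prev_posterior <- map
  list(map = map, model = model)
}

#' Adapt the colour histograms toward the current frame
#'
#' Exponential forgetting with update factor `delta`: the new class
#' likelihood is `delta` times the histogram of the current frame's trusted
#' region plus `1 - delta` times the previous likelihood. The trusted
#' foreground region is the convex hull of the positive keypoints; the
#' background region is the annulus surrounding the detected box. An empty
#' region leaves the corresponding histogram unchanged for that frame.
#'
#' @param model A `ght_segmentation`.
#' @param image Current frame.
#' @param positive_hull Two-column matrix of hull vertices (u, v), or a raw
#'   point set whose hull is taken; `NULL` for no foreground update.
#' @param detected_bbox Detected object box for the background annulus.
#' @param delta Optional override of the model's update factor.
#' @return The updated `ght_segmentation`.
#' @export
update_histograms <- function(model, image, positive_hull, detected_bbox,
                              delta = model$delta) {
  height <- dim(image)[1]; width <- dim(image)[2]
  bins <- matrix(hsv_bin_index(image), height, width)
  hull <- if (is.null(positive_hull)) NULL else
    convex_hull(positive_hull[, 1], positive_hull[, 2])
  if (!is.null(hull)) {
    fg_mask <- poly_mask(hull, width, height)
    if (any(fg_mask)) {
      h_new <- build_color_histogram(bins, fg_mask)
      fg <- delta * h_new + (1 - delta) * model$fg_hist
      model$fg_hist <- fg / sum(fg)
    }
  }
  if (!is.null(detected_bbox)) {
    bg_mask <- background_mask(detected_bbox, width, height)
    if (any(bg_mask)) {
      h_new <- build_color_histogram(bins, bg_mask)
      bg <- delta * h_new + (1 - delta) * model$bg_hist
      model$bg_hist <- bg / sum(bg)
    }
  }
  model
}

#' Foreground vote weight of a keypoint
#'
#' The weight is the mean foreground posterior over the square patch
#' centered on the keypoint, clipped at image borders (the mean is over the
#' valid intersection only).
#'
#' @param prob_map Matrix of per-pixel foreground posteriors.
#' @param u,v Keypoint position (0-based).
#' @param patch_half_width Half-width of the square patch in pixels.
#' @return A weight in `[0, 1]`.
#' @export
keypoint_weight <- function(prob_map, u, v, patch_half_width = 4) {
  keypoint_weights(prob_map, u, v, patch_half_width)
}

#' Foreground vote weights for many keypoints
#'
#' Vectorized form of [keypoint_weight()]. The patch half-width scales with
#' the detector scale of each keypoint when `kp_scale` is given.
#'
#' @param prob_map Matrix of per-pixel foreground posteriors.
#' @param u,v Keypoint positions (0-based).
#' @param patch_half_width Half-width(s) of the square patch; recycled.
#' @param kp_scale Optional detector scales; when given, the half-width is
#'   `max(patch_half_width, 1.5 * kp_scale)` per keypoint.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
keypoint_weights <- function(prob_map, u, v, patch_half_width = 4,
                             kp_scale = NULL) {
  n <- length(u)
  if (n == 0L) return(numeric(0))
  hw <- rep(patch_half_width, length.out = n)
  if (!is.null(kp_scale)) hw <- pmax(hw, 1.5 * kp_scale)
  hw <- as.integer(round(hw))
  nr <- nrow(prob_map); nc <- ncol(prob_map)
  out <- numeric(n)
  ui <- round(u); vi <- round(v)
  for (i in seq_len(n)) {
    u0 <- max(ui[i] - hw[i], 0); u1 <- min(ui[i] + hw[i], nc - 1L)
    v0 <- max(vi[i] - hw[i], 0); v1 <- min(vi[i] + hw[i], nr - 1L)
    if (u1 < u0 || v1 < v0) { out[i] <- 0; next }
    out[i] <- mean(prob_map[(v0 + 1L):(v1 + 1L), (u0 + 1L):(u1 + 1L)])
  }
  out
}
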