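# Shared fixtures and independent oracles. Fixtures are generated in code;
# oracles are deliberately naive (dense scans, scalar loops) so they share
# no code path with the implementation they check.

# High-contrast checkerboard patch on a flat background.
fx_checkerboard <- function() {
  img <- array(0.5, dim = c(120, 160, 3))
  for (i in 0:7) for (j in 0:7) {
    val <- if ((i + j) %% 2 == 0) 0.9 else 0.1
    img[40 + i * 8 + 1:8 - 1, 48 + j * 8 + 1:8 - 1, ] <- val
  }
  img
}

# Hand-built object model from explicit keypoint geometry (no detector).
fx_synthetic_model <- function(u, v, center, orientation = NULL,
                               seed = 99L) {
  n <- length(u)
  set.seed(seed)
  if (is.null(orientation)) orientation <- runif(n, -pi, pi)
  desc <- matrix(rnorm(n * 128), n, 128)
  desc <- desc / sqrt(rowSums(desc^2))
  kp <- ghtrack:::new_keypoints(u, v, orientation, rep(1.3, n),
                                rep(1, n), desc)
  du <- center[1] - u; dv <- center[2] - v
  structure(list(
    keypoints = kp,
    center_distance = sqrt(du^2 + dv^2),
    center_angle = ghtrack:::wrap_angle(atan2(dv, du) - orientation),
    voting_state = rep(1L, n),
    negative_streak = rep(0L, n),
    reference_center = c(u = center[1], v = center[2]),
    bbox_size = c(w = 2 * max(abs(du)) + 10, h = 2 * max(abs(dv)) + 10),
    current_scale = 1.0, current_rotation = 0.0,
    enrollment_size = n
  ), class = "ght_object_model")
}

# Hand-built match set at explicit frame positions.
fx_matchset <- function(model_index, u, v, weight = 1,
                        orientation = rep(0, length(u))) {
  n <- length(u)
  structure(list(model_index = as.integer(model_index),
                 frame_index = seq_len(n),
                 u = u, v = v, orientation = orientation,
                 weight = rep(weight, length.out = n),
                 distance = rep(0, n)),
            class = "ght_matchset")
}

# Place the model's keypoints at a rigid pose (rotation about the center,
# uniform scale, translation of the center) and return the match set.
fx_posed_matches <- function(model, center_new, theta = 0, scale = 1,
                             weight = 1) {
  c0 <- model$reference_center
  du <- model$keypoints$u - c0["u"]; dv <- model$keypoints$v - c0["v"]
  u <- center_new[1] + scale * (cos(theta) * du - sin(theta) * dv)
  v <- center_new[2] + scale * (sin(theta) * du + cos(theta) * dv)
  fx_matchset(seq_along(u), u, v, weight,
              orientation = ghtrack:::wrap_angle(model$keypoints$orientation + theta))
}

# Exhaustive accumulator scan: for every keypoint, decide ring membership
# per cell over an extended grid, normalize by the ring's full cell count,
# then keep the in-image part. Independent of the rasterizer.
oracle_accumulator <- function(matches, model, weight_threshold, extent,
                               prev_scale = 1, ratio = c(0.95, 1.05)) {
  width <- extent[1]; height <- extent[2]
  grid <- matrix(0, height, width)
  for (k in seq_along(matches$model_index)) {
    if (matches$weight[k] <= weight_threshold) next
    d_i <- model$center_distance[matches$model_index[k]]
    u0 <- matches$u[k]; v0 <- matches$v[k]
    if (d_i <= 0) {
      ui <- round(u0); vi <- round(v0)
      if (ui >= 0 && ui < width && vi >= 0 && vi < height)
        grid[vi + 1, ui + 1] <- grid[vi + 1, ui + 1] + matches$weight[k]
      next
    }
    r <- ratio * d_i * prev_scale
    rc <- mean(r); hw <- max((r[2] - r[1]) / 2, sqrt(2) / 2)
    pad <- ceiling(rc + hw) + 1
    n_cells <- 0L
    hits <- NULL
    for (cu in floor(u0 - pad):ceiling(u0 + pad)) {
      for (cv in floor(v0 - pad):ceiling(v0 + pad)) {
        dist <- sqrt((cu - u0)^2 + (cv - v0)^2)
        if (abs(dist - rc) <= hw) {
          n_cells <- n_cells + 1L
          if (cu >= 0 && cu < width && cv >= 0 && cv < height)
            hits <- rbind(hits, c(cv + 1, cu + 1))
        }
      }
    }
    if (n_cells > 0L && !is.null(hits))
      grid[hits] <- grid[hits] + matches$weight[k] / n_cells
  }
  grid
}

# Argmax with the smallest-(v, u) tie rule, written independently.
oracle_argmax <- function(grid) {
  mx <- max(grid)
  best <- NULL
  for (vi in seq_len(nrow(grid))) {
    for (ui in seq_len(ncol(grid))) {
      if (grid[vi, ui] == mx) { best <- c(u = ui - 1, v = vi - 1); break }
    }
    if (!is.null(best)) break
  }
  best
}

# Classic vector voting (each keypoint votes for one predicted center using
# its stored angle and current orientation) as a test oracle.
oracle_vector_votes <- function(matches, model, weight_threshold, extent) {
  width <- extent[1]; height <- extent[2]
  grid <- matrix(0, height, width)
  for (k in seq_along(matches$model_index)) {
    if (matches$weight[k] <= weight_threshold) next
    i <- matches$model_index[k]
    ang <- model$center_angle[i] + matches$orientation[k]
    d_i <- model$center_distance[i]
    cu <- round(matches$u[k] + d_i * cos(ang))
    cv <- round(matches$v[k] + d_i * sin(ang))
    if (cu >= 0 && cu < width && cv >= 0 && cv < height)
      grid[cv + 1, cu + 1] <- grid[cv + 1, cu + 1] + matches$weight[k]
  }
  grid
}

# Scalar two-class forward filter (one pixel, one step).
oracle_bayes_step <- function(l_fg, l_bg, prior_fg, stay) {
  pred_fg <- stay * prior_fg + (1 - stay) * (1 - prior_fg)
  pred_bg <- (1 - stay) * prior_fg + stay * (1 - prior_fg)
  num_fg <- l_fg * pred_fg
  num_bg <- l_bg * pred_bg
  z <- num_fg + num_bg
  if (z > 1e-12) num_fg / z else pred_fg
}

# Single-colour segmentation model built from explicit histograms.
fx_segmentation <- function(fg_hist, bg_hist, prior, stay = 0.6,
                            delta = 0.1) {
  structure(list(fg_hist = fg_hist, bg_hist = bg_hist,
                 prev_posterior = prior, stay_prob = stay, delta = delta,
                 width = ncol(prior), height = nrow(prior)),
            class = "ght_segmentation")
}

# Uniform-colour image helper (r, g, b in [0, 1]).
fx_flat_image <- function(height, width, rgb) {
  array(rep(rgb, each = height * width), dim = c(height, width, 3))
}

# Short cached tracking fixtures (built once per test run).
.fx_cache <- new.env(parent = emptyenv())

fx_cached <- function(key, build) {
  hit <- .fx_cache[[key]]
  if (is.null(hit)) {
    hit <- build()
    .fx_cache[[key]] <- hit
  }
  hit
}

fx_template_sequence <- function() {
  fx_cached("template_seq", function() {
    cfg <- sequence_config(tibble::tibble(frame = 1:3, u = 160, v = 120,
                                          theta = 0, scale = 1),
                           noise_sd = 0, seed = 11)
    generate_sequence(cfg)
  })
}

fx_template_model <- function() {
  fx_cached("template_model", function() {
    sq <- fx_template_sequence()
    build_model(sq$frame(1), ght_rect(115, 75, 90, 90))
  })
}
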