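# Ground-truthed synthetic sequences for the four standard challenge
# regimes: occlusion by a second instrument, occlusion by tissue, full
# out-of-view excursions, and long-term drift in translation, in-plane
# rotation and scale. A rigid, corner-rich textured target moves over a
# smooth textured background following an exact per-frame pose program;
# rendering is bilinear, so ground truth (the continuous pose) is accurate
# to within ~0.5 px of rasterization. Foreground and background palettes
# are separable in HSV by default (distinct hue modes) so the segmentation
# model has a known optimum; a "camouflage" palette overlaps them for
# stress testing.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

hsv_to_rgb_array <- function(h, s, v, height, width) {
  cols <- grDevices::col2rgb(grDevices::hsv(pmin(pmax(h, 0), 1),
                                            pmin(pmax(s, 0), 1),
                                            pmin(pmax(v, 0), 1))) / 255
  array(c(matrix(cols[1, ], height, width),
          matrix(cols[2, ], height, width),
          matrix(cols[3, ], height, width)),
        dim = c(height, width, 3L))
}

# Corner- and blob-rich value texture: a block mosaic plus contrast dots.
value_texture <- function(size, n_dots = round(size * size / 180),
                          block = 8L) {
  nb <- ceiling(size / block)
  blocks <- matrix(stats::runif(nb * nb, 0.25, 0.95), nb, nb)
  val <- blocks[cbind(rep(ceiling(seq_len(size) / block), times = size),
                      rep(ceiling(seq_len(size) / block), each = size))]
  val <- matrix(val, size, size)
  for (i in seq_len(n_dots)) {
    cu <- stats::runif(1, 3, size - 4); cv <- stats::runif(1, 3, size - 4)
    r <- stats::runif(1, 1.5, 3.5)
    lum <- sample(c(0.05, 1), 1)
    ui <- max(1, floor(cu - r)):min(size, ceiling(cu + r))
    vi <- max(1, floor(cv - r)):min(size, ceiling(cv + r))
    d2 <- outer((vi - cv)^2, (ui - cu)^2, "+")
    val[vi, ui][d2 <= r^2] <- lum
  }
  val
}

make_target_texture <- function(size, palette) {
  val <- value_texture(size)
  hue_base <- if (palette == "camouflage") 0.04 else 0.58
  h <- hue_base + matrix(stats::runif(size * size, -0.03, 0.03), size, size)
  s <- matrix(stats::runif(size * size, 0.55, 0.85), size, size)
  hsv_to_rgb_array(as.vector(h), as.vector(s), as.vector(val), size, size)
}

make_background_texture <- function(width, height, palette) {
  # smooth blobs: coarse noise, heavy blur, bilinear upsample
  ch <- max(6L, height %/% 8L); cw <- max(8L, width %/% 8L)
  coarse <- gaussian_blur(matrix(stats::runif(ch * cw), ch, cw), 1.5)
  uu <- rep(seq(0, cw - 1, length.out = width), each = height)
  vv <- rep(seq(0, ch - 1, length.out = height), times = width)
  field <- matrix(bilinear_sample(coarse, uu, vv), height, width)
  field <- (field - min(field)) / max(1e-9, diff(range(field)))
  hue_base <- 0.03
  h <- hue_base + 0.05 * field
  s <- 0.45 + 0.25 * field
  v <- 0.35 + 0.35 * field
  hsv_to_rgb_array(as.vector(h), as.vector(s), as.vector(v), height, width)
}

make_occluder_texture <- function(type, size) {
  if (type == "patch") {
    # achromatic instrument-like patch: textured grays
    val <- value_texture(size)
    h <- matrix(0.6, size, size)
    s <- matrix(stats::runif(size * size, 0, 0.06), size, size)
    hsv_to_rgb_array(as.vector(h), as.vector(s), as.vector(val), size, size)
  } else {
    # tissue-coloured blob (matches the background palette)
    val <- 0.35 + 0.4 * gaussian_blur(matrix(stats::runif(size^2), size, size), 3)
    h <- matrix(stats::runif(size * size, 0.02, 0.07), size, size)
    s <- matrix(stats::runif(size * size, 0.5, 0.7), size, size)
    hsv_to_rgb_array(as.vector(h), as.vector(s), as.vector(val), size, size)
  }
}

# Elliptical alpha for blob occluders, square for patch occluders.
occluder_alpha <- function(type, size) {
  if (type == "patch") return(matrix(1, size, size))
  c0 <- (size - 1) / 2
  d2 <- outer(((seq_len(size) - 1 - c0) / (0.5 * size))^2,
              ((seq_len(size) - 1 - c0) / (0.42 * size))^2, "+")
  (d2 <= 1) * 1
}

# Composite a textured patch at pose (u, v, theta, scale) onto img in place.
# Returns list(img, mask): mask is the logical coverage (alpha > 0.5) of the
# patch on the image canvas.
compose_patch <- function(img, tex, alpha_tpl, u, v, theta, scale) {
  height <- dim(img)[1]; width <- dim(img)[2]
  ts <- dim(tex)[1]
  tc <- (ts - 1) / 2
  half <- ceiling(ts / 2 * scale * sqrt(2)) + 2
  u0 <- max(0, floor(u - half)); u1 <- min(width - 1, ceiling(u + half))
  v0 <- max(0, floor(v - half)); v1 <- min(height - 1, ceiling(v + half))
  mask <- matrix(FALSE, height, width)
  if (u1 < u0 || v1 < v0) return(list(img = img, mask = mask))
  uu <- rep(u0:u1, each = v1 - v0 + 1L)
  vv <- rep(v0:v1, times = u1 - u0 + 1L)
  ct <- cos(theta); st <- sin(theta)
  xr <- (ct * (uu - u) + st * (vv - v)) / scale + tc
  yr <- (-st * (uu - u) + ct * (vv - v)) / scale + tc
  # alpha template padded with a zero ring -> soft 1-px edge under bilinear
  pad <- matrix(0, ts + 2, ts + 2)
  pad[2:(ts + 1), 2:(ts + 1)] <- alpha_tpl
  a <- bilinear_sample(pad, xr + 1, yr + 1)
  inside <- a > 1e-3
  if (any(inside)) {
    xi <- pmin(pmax(xr[inside], 0), ts - 1)
    yi <- pmin(pmax(yr[inside], 0), ts - 1)
    ai <- a[inside]
    rows <- vv[inside] + 1L; cols <- uu[inside] + 1L
    for (c3 in 1:3) {
      tv <- bilinear_sample(tex[, , c3], xi, yi)
      idx <- cbind(rows, cols, rep(c3, length(rows)))
      img[idx] <- (1 - ai) * img[idx] + ai * tv
    }
    cover <- inside & a > 0.5
    mask[cbind(vv[cover] + 1L, uu[cover] + 1L)] <- TRUE
  }
  list(img = img, mask = mask)
}

# Rasterized coverage count of the target at a pose on an unbounded canvas,
# used as the denominator of the visibility fraction.
patch_area_cells <- function(ts, scale, theta) {
  half <- ceiling(ts / 2 * scale * sqrt(2)) + 2
  uu <- rep(-half:half, each = 2 * half + 1L)
  vv <- rep(-half:half, times = 2 * half + 1L)
  tc <- (ts - 1) / 2
  ct <- cos(theta); st <- sin(theta)
  xr <- (ct * uu + st * vv) / scale + tc
  yr <- (-st * uu + ct * vv) / scale + tc
  pad <- matrix(0, ts + 2, ts + 2)
  pad[2:(ts + 1), 2:(ts + 1)] <- 1
  sum(bilinear_sample(pad, xr + 1, yr + 1) > 0.5)
}

#' Assemble a synthetic sequence configuration
#'
#' @param poses Tibble/data frame with columns `frame`, `u`, `v`, `theta`,
#'   `scale`: the exact per-frame pose program of the target center.
#' @param width,height Frame size in pixels.
#' @param target_size Side length of the square target patch, pixels.
#' @param palette `"separable"` (target and background occupy distinct hue
#'   modes) or `"camouflage"` (overlapping palettes, for stress tests).
#' @param occluder `NULL`, or a list with `type` (`"patch"` or `"blob"`),
#'   `size`, and `poses` (tibble `frame`, `u`, `v`; `NA` when absent).
#' @param noise_sd Additive Gaussian noise, per-channel standard deviation.
#' @param seed Integer seed controlling textures and noise.
#' @return A list of class `ght_sequence_config`.
#' @export
sequence_config <- function(poses, width = 320L, height = 240L,
                            target_size = 80L, palette = "separable",
                            occluder = NULL, noise_sd = 0.01, seed = 1L) {
  stopifnot(all(c("frame", "u", "v", "theta", "scale") %in% names(poses)),
            all(poses$scale > 0), target_size < min(width, height))
  structure(list(poses = tibble::as_tibble(poses), width = as.integer(width),
                 height = as.integer(height),
                 target_size = as.integer(target_size),
                 palette = match.arg(palette, c("separable", "camouflage")),
                 occluder = occluder, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ght_sequence_config")
}

#' Generate a ground-truthed synthetic sequence
#'
#' Deterministic for a fixed configuration: textures are drawn from the
#' config seed and per-frame noise from a seed derived from it, so the same
#' config always yields identical pixels. Frames are rendered on demand via
#' the returned `frame(t)` closure (so long sequences do not need to fit in
#' memory); ground truth, including the occlusion-aware visibility fraction,
#' is computed up front.
#'
#' @param config A [sequence_config()] (or [preset()]) object.
#' @return An object of class `ght_sequence`: list with `config`, `truth`
#'   (tibble `frame`, `u`, `v`, `theta`, `scale`, `visibility`, `in_view`)
#'   and `frame(t)` returning the RGB array of frame `t`.
#' @export
generate_sequence <- function(config) {
  cfg <- config
  tex <- with_seed(cfg$seed, list(
    target = make_target_texture(cfg$target_size, cfg$palette),
    background = make_background_texture(cfg$width, cfg$height, cfg$palette),
    occluder = if (!is.null(cfg$occluder))
      make_occluder_texture(cfg$occluder$type, cfg$occluder$size)
  ))
  alpha_t <- matrix(1, cfg$target_size, cfg$target_size)
  alpha_o <- if (!is.null(cfg$occluder))
    occluder_alpha(cfg$occluder$type, cfg$occluder$size)
  n <- nrow(cfg$poses)

  render_masks <- function(t) {
    p <- cfg$poses[t, ]
    bg <- tex$background
    out <- compose_patch(bg, tex$target, alpha_t, p$u, p$v, p$theta, p$scale)
    occ_mask <- NULL
    if (!is.null(cfg$occluder)) {
      op <- cfg$occluder$poses[t, ]
      if (!is.na(op$u)) {
        oc <- compose_patch(out$img, tex$occluder, alpha_o, op$u, op$v, 0, 1)
        out$img <- oc$img
        occ_mask <- oc$mask
      }
    }
    list(img = out$img, target_mask = out$mask, occ_mask = occ_mask)
  }

  visibility <- numeric(n)
  for (t in seq_len(n)) {
    p <- cfg$poses[t, ]
    half <- ceiling(cfg$target_size / 2 * p$scale * sqrt(2)) + 2
    occ_active <- !is.null(cfg$occluder) && !is.na(cfg$occluder$poses$u[t])
    if (!occ_active && p$u - half >= 0 && p$u + half < cfg$width &&
        p$v - half >= 0 && p$v + half < cfg$height) {
      visibility[t] <- 1   # fully inside, nothing in front of it
      next
    }
    total <- patch_area_cells(cfg$target_size, p$scale, p$theta)
    rm_ <- render_masks(t)
    vis_mask <- rm_$target_mask
    if (!is.null(rm_$occ_mask)) vis_mask <- vis_mask & !rm_$occ_mask
    visibility[t] <- min(1, sum(vis_mask) / max(1, total))
  }
  truth <- tibble::tibble(frame = cfg$poses$frame, u = cfg$poses$u,
                          v = cfg$poses$v, theta = cfg$poses$theta,
                          scale = cfg$poses$scale, visibility = visibility,
                          in_view = visibility > 0.05)

  frame_fun <- function(t) {
    stopifnot(t >= 1, t <= n)
    img <- render_masks(t)$img
    if (cfg$noise_sd > 0) {
      fs <- (as.numeric(cfg$seed %% 100000L) * 20011 + t * 7919) %% 2147483647
      img <- img + with_seed(as.integer(fs),
                             array(stats::rnorm(length(img), 0, cfg$noise_sd),
                                   dim = dim(img)))
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    img
  }

  structure(list(config = cfg, truth = truth, frame = frame_fun,
                 n_frames = n),
            class = "ght_sequence")
}

#' @export
print.ght_sequence <- function(x, ...) {
  cat(sprintf("<ght_sequence: %d frames %dx%d, palette %s, occluder %s>\n",
              x$n_frames, x$config$width, x$config$height, x$config$palette,
              if (is.null(x$config$occluder)) "none" else x$config$occluder$type))
  invisible(x)
}

#' Write sequence frames and ground truth to disk
#'
#' Frames go to zero-padded numbered PNG files, ground truth to
#' `ground_truth.csv` with columns `frame,u,v,theta,scale,visibility,in_view`.
#'
#' @param seq A `ght_sequence`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  width <- nchar(as.character(seq$n_frames))
  for (t in seq_len(seq$n_frames)) {
    write_frame(seq$frame(t),
                file.path(dir, sprintf(paste0("frame_%0", max(width, 4), "d.png"), t)))
  }
  utils::write.csv(seq$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# ---- motion programs -------------------------------------------------------

#' Smooth drift motion program
#'
#' Sinusoidal drift in all pose components, emulating slow instrument motion
#' over a long sequence.
#'
#' @param n Number of frames.
#' @param center `c(u, v)` mean position.
#' @param amp_u,amp_v Translation amplitudes, pixels.
#' @param amp_theta Rotation amplitude, radians (0 for translation-only).
#' @param amp_scale Peak scale increase above 1 (0 for fixed scale).
#' @param period Frames per full oscillation.
#' @return Pose tibble for [sequence_config()].
#' @export
motion_drift <- function(n, center, amp_u = 40, amp_v = 25,
                         amp_theta = 20 * pi / 180, amp_scale = 0.25,
                         period = 600) {
  t <- seq_len(n)
  tibble::tibble(
    frame = t,
    u = center[1] + amp_u * sin(2 * pi * t / period),
    v = center[2] + amp_v * sin(2 * pi * t / (period * 0.73) + 1),
    theta = amp_theta * sin(2 * pi * t / (period * 1.31)),
    scale = 1 + amp_scale * (1 - cos(2 * pi * t / (period * 1.57))) / 2)
}

#' In-plane rotation sweep program
#'
#' @param center `c(u, v)` fixed position.
#' @param step_deg Rotation increment per frame, degrees.
#' @param max_deg Final rotation, degrees.
#' @return Pose tibble covering 0 to `max_deg` degrees.
#' @export
motion_rotation_sweep <- function(center, step_deg = 5, max_deg = 350) {
  theta <- seq(0, max_deg, by = step_deg) * pi / 180
  tibble::tibble(frame = seq_along(theta), u = center[1], v = center[2],
                 theta = theta, scale = 1)
}

#' Geometric scale ramp program
#'
#' @param n Number of frames.
#' @param center `c(u, v)` fixed position.
#' @param s_end Final scale (geometric ramp from 1).
#' @return Pose tibble.
#' @export
motion_scale_ramp <- function(n, center, s_end = 1.5) {
  tibble::tibble(frame = seq_len(n), u = center[1], v = center[2], theta = 0,
                 scale = s_end^((seq_len(n) - 1) / (n - 1)))
}

# ---- presets ---------------------------------------------------------------

#' Canonical challenge-regime configurations
#'
#' Four regimes mirror the standard ex vivo evaluation designs:
#' `instrument_occlusion` (a second rigid instrument-like patch sweeps over
#' the target), `tissue_occlusion` (a tissue-coloured blob covers the
#' target), `out_of_view` (the target fully leaves the frame for 30 frames
#' and returns), and `long_term` (2000 frames of slow drift in all of u, v,
#' rotation and scale).
#'
#' @param name One of `"instrument_occlusion"`, `"tissue_occlusion"`,
#'   `"out_of_view"`, `"long_term"`.
#' @param seed Integer seed.
#' @param n_frames Optional frame-count override.
#' @param rotate,zoom Include the rotation / scale components of the motion
#'   program (`long_term` only).
#' @param palette Palette passed to [sequence_config()].
#' @return A `ght_sequence_config`.
#' @export
preset <- function(name, seed = 1L, n_frames = NULL, rotate = TRUE,
                   zoom = TRUE, palette = "separable") {
  name <- match.arg(name, c("instrument_occlusion", "tissue_occlusion",
                            "out_of_view", "long_term"))
  width <- 320L; height <- 240L; ts <- 80L
  ctr <- c(width / 2, height / 2)
  if (name == "long_term") {
    n <- if (is.null(n_frames)) 2000L else as.integer(n_frames)
    poses <- motion_drift(n, ctr,
                          amp_theta = if (rotate) 20 * pi / 180 else 0,
                          amp_scale = if (zoom) 0.25 else 0)
    return(sequence_config(poses, width, height, ts, palette, NULL,
                           noise_sd = 0.01, seed = seed))
  }
  if (name == "out_of_view") {
    n <- if (is.null(n_frames)) 160L else as.integer(n_frames)
    # piecewise path: drift right, fully exit for 30 frames, re-enter
    u <- numeric(n); v <- rep(ctr[2], n)
    out_u <- width + 80   # fully outside for an 80-px target
    seg <- function(a, b, k) seq(a, b, length.out = k)
    u[1:50] <- seg(ctr[1], width - 30, 50)
    u[51:70] <- seg(width - 30, out_u, 20)
    u[71:100] <- out_u
    u[101:115] <- seg(out_u, ctr[1], 15)
    if (n > 115) u[116:n] <- ctr[1]
    poses <- tibble::tibble(frame = seq_len(n), u = u, v = v, theta = 0,
                            scale = 1)
    return(sequence_config(poses, width, height, ts, palette, NULL,
                           noise_sd = 0.01, seed = seed))
  }
  n <- if (is.null(n_frames)) 150L else as.integer(n_frames)
  t <- seq_len(n)
  poses <- tibble::tibble(frame = t,
                          u = ctr[1] + 25 * sin(2 * pi * t / 300),
                          v = ctr[2] + 15 * sin(2 * pi * t / 210 + 1),
                          theta = 0, scale = 1)
  if (name == "instrument_occlusion") {
    osize <- 90L
    ou <- rep(NA_real_, n)
    sweep_t <- intersect(40:110, t)   # occluder window, clipped to n
    full <- seq(-60, width + 60, length.out = 71)
    ou[sweep_t] <- full[sweep_t - 39L]
    occ <- list(type = "patch", size = osize,
                poses = tibble::tibble(frame = t, u = ou,
                                       v = rep(ctr[2] + 5, n)))
  } else {
    osize <- 110L
    ou <- rep(NA_real_, n); ov <- rep(NA_real_, n)
    path_u <- c(seq(-70, ctr[1], length.out = 21),
                rep(ctr[1], 25),
                seq(ctr[1], -70, length.out = 20))
    win <- intersect(50:115, t)
    ou[win] <- path_u[win - 49L]
    ov[win] <- ctr[2] - 5
    occ <- list(type = "blob", size = osize,
                poses = tibble::tibble(frame = t, u = ou, v = ov))
  }
  sequence_config(poses, width, height, ts, palette, occ, noise_sd = 0.01,
                  seed = seed)
}
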