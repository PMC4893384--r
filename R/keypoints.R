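# Scale-space keypoint detection with gradient-orientation descriptors.
#
# The tracker is feature-based: it needs repeatable, rotation- and
# scale-covariant interest points with descriptors that can be matched across
# frames. We detect extrema of a difference-of-Gaussians (DoG) stack computed
# at a fixed ladder of smoothing scales, assign each keypoint a dominant
# gradient orientation, and describe it with the standard 4 x 4 spatial x 8
# orientation-bin histogram of gradients sampled in the keypoint's own
# (rotated, scale-normalized) frame. Everything is vectorized per pyramid
# level so whole-frame detection stays fast in plain R.

#' Keypoint detector settings
#'
#' @param n_levels Number of smoothing levels in the scale ladder.
#' @param sigma0 Base smoothing scale in pixels.
#' @param sigma_ratio Multiplicative step between consecutive levels.
#' @param contrast_threshold Minimum absolute DoG response for an extremum.
#' @param edge_ratio Maximum principal-curvature ratio (Harris-style edge
#'   rejection on the DoG Hessian).
#' @param max_keypoints Keep at most this many keypoints, strongest first.
#' @return A list of detector settings.
#' @export
keypoint_params <- function(n_levels = 7L, sigma0 = 1.3, sigma_ratio = 1.32,
                            contrast_threshold = 0.012, edge_ratio = 10,
                            max_keypoints = 300L) {
  list(n_levels = as.integer(n_levels), sigma0 = sigma0,
       sigma_ratio = sigma_ratio, contrast_threshold = contrast_threshold,
       edge_ratio = edge_ratio, max_keypoints = as.integer(max_keypoints))
}

scale_ladder <- function(p) p$sigma0 * p$sigma_ratio^(seq_len(p$n_levels) - 1L)

# Incrementally blurred grayscale stack plus per-level gradients (lazy).
build_scale_space <- function(gray, p) {
  sigmas <- scale_ladder(p)
  levels <- vector("list", p$n_levels)
  levels[[1]] <- gaussian_blur(gray, sigmas[1])
  for (k in 2:p$n_levels) {
    dsig <- sqrt(sigmas[k]^2 - sigmas[k - 1]^2)
    levels[[k]] <- gaussian_blur(levels[[k - 1]], dsig)
  }
  list(levels = levels, sigmas = sigmas)
}

# 3D (u, v, sigma) local extrema of the DoG stack with contrast and edge tests.
dog_extrema <- function(ss, p) {
  nl <- length(ss$levels)
  dog <- lapply(seq_len(nl - 1L), function(k) ss$levels[[k + 1L]] - ss$levels[[k]])
  out <- list()
  nr <- nrow(dog[[1]]); nc <- ncol(dog[[1]])
  for (k in 2:(length(dog) - 1L)) {
    d <- dog[[k]]
    lo <- dog[[k - 1L]]; hi <- dog[[k + 1L]]
    idx <- which(abs(d) > p$contrast_threshold)
    if (length(idx) == 0L) next
    # interior only (neighbor index arithmetic must stay in bounds)
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    ok <- i > 1L & i < nr & j > 1L & j < nc
    idx <- idx[ok]
    if (length(idx) == 0L) next
    val <- d[idx]
    pos <- val > 0
    is_ext <- rep(TRUE, length(idx))
    for (off in c(-nr - 1L, -nr, -nr + 1L, -1L, 1L, nr - 1L, nr, nr + 1L)) {
      nb <- d[idx + off]
      is_ext <- is_ext & ifelse(pos, val > nb, val < nb)
    }
    for (off in c(-nr - 1L, -nr, -nr + 1L, -1L, 0L, 1L, nr - 1L, nr, nr + 1L)) {
      nlo <- lo[idx + off]; nhi <- hi[idx + off]
      is_ext <- is_ext & ifelse(pos, val > nlo & val > nhi,
                                val < nlo & val < nhi)
    }
    idx <- idx[is_ext]
    if (length(idx) == 0L) next
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    cand <- cbind(i, j)
    dxx <- d[idx + nr] + d[idx - nr] - 2 * d[idx]
    dyy <- d[idx + 1L] + d[idx - 1L] - 2 * d[idx]
    dxy <- (d[idx + nr + 1L] + d[idx - nr - 1L] - d[idx + nr - 1L] - d[idx - nr + 1L]) / 4
    tr <- dxx + dyy; det <- dxx * dyy - dxy^2
    r <- p$edge_ratio
    ok <- det > 0 & (tr^2 / det) < ((r + 1)^2 / r)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) next
    idx <- idx[ok]
    # parabolic sub-pixel refinement along u and v
    du_off <- (d[idx - nr] - d[idx + nr]) / (2 * (d[idx - nr] - 2 * d[idx] + d[idx + nr]))
    dv_off <- (d[idx - 1L] - d[idx + 1L]) / (2 * (d[idx - 1L] - 2 * d[idx] + d[idx + 1L]))
    du_off[!is.finite(du_off)] <- 0; dv_off[!is.finite(dv_off)] <- 0
    du_off <- pmin(pmax(du_off, -0.5), 0.5); dv_off <- pmin(pmax(dv_off, -0.5), 0.5)
    out[[length(out) + 1L]] <- data.frame(
      u = (cand[, 2] - 1) + du_off, v = (cand[, 1] - 1) + dv_off,
      level = k, scale = ss$sigmas[k], response = abs(d[idx]))
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Dominant gradient orientation for all keypoints of one pyramid level.
assign_orientations <- function(level_img, kps, sigma) {
  g <- image_gradient(level_img)
  r <- max(3L, round(2.5 * sigma))
  offs <- expand.grid(du = -r:r, dv = -r:r)
  wg <- exp(-(offs$du^2 + offs$dv^2) / (2 * (1.5 * sigma)^2))
  nk <- nrow(kps); np <- nrow(offs)
  nr <- nrow(level_img); nc <- ncol(level_img)
  uu <- pmin(pmax(round(rep(kps$u, each = np) + offs$du), 0), nc - 1)
  vv <- pmin(pmax(round(rep(kps$v, each = np) + offs$dv), 0), nr - 1)
  idx <- vv + 1 + uu * nr
  gx <- g$gx[idx]; gy <- g$gy[idx]
  mag <- sqrt(gx^2 + gy^2) * rep(wg, times = nk)
  ang <- atan2(gy, gx)            # (-pi, pi]
  bin <- floor((ang + pi) / (2 * pi) * 36) %% 36
  kp_id <- rep(seq_len(nk) - 1L, each = np)
  hist_idx <- kp_id * 36L + bin + 1L   # 1-based compact index
  h <- numeric(nk * 36L)
  s <- rowsum(mag, hist_idx, reorder = TRUE)
  h[sort(unique(hist_idx))] <- s
  hmat <- matrix(h, nrow = 36L)        # [bin, keypoint]
  # circular smoothing (twice, 1-2-1 kernel)
  for (rep_i in 1:2) {
    hmat <- (hmat[c(36L, 1:35), , drop = FALSE] + 2 * hmat +
             hmat[c(2:36, 1L), , drop = FALSE]) / 4
  }
  peak <- max.col(t(hmat), ties.method = "first")
  # parabolic interpolation around the peak bin
  ori <- numeric(nk)
  for (i in seq_len(nk)) {
    b <- peak[i]
    hm <- hmat[if (b == 1L) 36L else b - 1L, i]
    h0 <- hmat[b, i]
    hp <- hmat[if (b == 36L) 1L else b + 1L, i]
    denom <- hm - 2 * h0 + hp
    off <- if (abs(denom) > 1e-12) 0.5 * (hm - hp) / denom else 0
    off <- min(max(off, -0.5), 0.5)
    ori[i] <- wrap_angle((b - 1 + 0.5 + off) / 36 * 2 * pi - pi)
  }
  ori
}

# SIFT-style 4x4x8 descriptors for all keypoints of one pyramid level.
# Sample grid: 16 x 16 points spaced 0.75 * sigma in the keypoint frame.
compute_descriptors <- function(level_img, kps, sigma) {
  g <- image_gradient(level_img)
  spacing <- 0.75 * sigma
  # sample positions in cell units: 16 points spanning [-2, 2) cells
  cu <- (seq_len(16) - 8.5) / 4          # -1.875 .. 1.875 cell units
  grid <- expand.grid(x = cu, y = cu)
  np <- nrow(grid); nk <- nrow(kps)
  wg <- exp(-(grid$x^2 + grid$y^2) / (2 * 1.5^2))   # Gaussian over window
  cosA <- cos(kps$orientation); sinA <- sin(kps$orientation)
  # rotated sample offsets in pixels (4 cell units across = 16 samples)
  gx_pix <- rep(grid$x, times = nk) * 4 * spacing
  gy_pix <- rep(grid$y, times = nk) * 4 * spacing
  ca <- rep(cosA, each = np); sa <- rep(sinA, each = np)
  su <- rep(kps$u, each = np) + ca * gx_pix - sa * gy_pix
  sv <- rep(kps$v, each = np) + sa * gx_pix + ca * gy_pix
  gxs <- bilinear_sample(g$gx, su, sv)
  gys <- bilinear_sample(g$gy, su, sv)
  # rotate gradients into the keypoint frame
  rgx <- ca * gxs + sa * gys
  rgy <- -sa * gxs + ca * gys
  mag <- sqrt(rgx^2 + rgy^2) * rep(wg, times = nk)
  obin <- (atan2(rgy, rgx) + pi) / (2 * pi) * 8   # [0, 8]
  # trilinear soft assignment: spatial bilinear over 4x4 cells, linear over 8
  cx <- rep(grid$x, times = nk) + 1.5   # cell coords 0..3 (centers)
  cy <- rep(grid$y, times = nk) + 1.5
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  o0 <- floor(obin); fo <- obin - o0
  kp_id <- rep(seq_len(nk) - 1L, each = np)
  des <- numeric(nk * 128L)
  for (dx in 0:1) for (dy in 0:1) for (do in 0:1) {
    xs <- x0 + dx; ys <- y0 + dy
    os <- (o0 + do) %% 8
    w <- mag * (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (do) fo else 1 - fo)
    ok <- xs >= 0 & xs <= 3 & ys >= 0 & ys <= 3 & w > 0
    if (!any(ok)) next
    idx <- kp_id[ok] * 128L + (ys[ok] * 4L + xs[ok]) * 8L + os[ok] + 1L
    s <- rowsum(w[ok], idx, reorder = TRUE)
    ii <- sort(unique(idx))
    des[ii] <- des[ii] + s
  }
  D <- matrix(des, nrow = 128L)   # [feature, keypoint]
  # normalize, clip at 0.2, renormalize (illumination robustness)
  nrm <- sqrt(colSums(D^2)); nrm[nrm < 1e-12] <- 1
  D <- sweep(D, 2, nrm, "/")
  D[D > 0.2] <- 0.2
  nrm <- sqrt(colSums(D^2)); nrm[nrm < 1e-12] <- 1
  t(sweep(D, 2, nrm, "/"))        # [keypoint, 128]
}

#' Detect scale-space keypoints in an image
#'
#' Finds difference-of-Gaussians extrema over a ladder of smoothing scales,
#' assigns each a dominant gradient orientation, and computes a 128-element
#' gradient-orientation descriptor in the keypoint's rotated, scale-normalized
#' frame. Deterministic: identical input yields identical output.
#'
#' @param image Color array `[h, w, 3]` or grayscale matrix, values in `[0, 1]`.
#' @param region Optional [ght_rect()]; only keypoints inside it are returned
#'   (detection itself runs on the full image so descriptors are unaffected
#'   by the crop).
#' @param params Settings from [keypoint_params()].
#' @return An object of class `ght_keypoints`: a list with numeric vectors
#'   `u`, `v` (0-based sub-pixel positions), `orientation` (radians),
#'   `scale`, `response`, and a `[n, 128]` `descriptors` matrix.
#' @export
detect_keypoints <- function(image, region = NULL, params = keypoint_params()) {
  if (is.null(image) || length(image) == 0L || any(dim(image)[1:2] < 8L)) {
    stop("detect_keypoints: image is empty or too small")
  }
  gray <- to_gray(image)
  ss <- build_scale_space(gray, params)
  kps <- dog_extrema(ss, params)
  if (is.null(kps) || nrow(kps) == 0L) return(empty_keypoints())
  if (nrow(kps) > params$max_keypoints) {
    kps <- kps[order(-kps$response), , drop = FALSE][seq_len(params$max_keypoints), ]
  }
  kps <- kps[order(kps$level, kps$v, kps$u), , drop = FALSE]
  kps$orientation <- 0
  desc <- matrix(0, nrow(kps), 128L)
  for (k in unique(kps$level)) {
    sel <- which(kps$level == k)
    lvl <- ss$levels[[k]]
    kps$orientation[sel] <- assign_orientations(lvl, kps[sel, ], ss$sigmas[k])
    desc[sel, ] <- compute_descriptors(lvl, kps[sel, ], ss$sigmas[k])
  }
  if (!is.null(region)) {
    keep <- points_in_rect(kps$u, kps$v, region)
    kps <- kps[keep, , drop = FALSE]
    desc <- desc[keep, , drop = FALSE]
  }
  new_keypoints(kps$u, kps$v, kps$orientation, kps$scale, kps$response, desc)
}

new_keypoints <- function(u, v, orientation, scale, response, descriptors) {
  structure(list(u = as.numeric(u), v = as.numeric(v),
                 orientation = as.numeric(orientation),
                 scale = as.numeric(scale), response = as.numeric(response),
                 descriptors = descriptors),
            class = "ght_keypoints")
}

empty_keypoints <- function() {
  new_keypoints(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
                matrix(0, 0L, 128L))
}

#' @export
length.ght_keypoints <- function(x) length(x$u)

#' @export
print.ght_keypoints <- function(x, ...) {
  cat(sprintf("<ght_keypoints: %d keypoints, descriptor length %d>\n",
              length(x), ncol(x$descriptors)))
  invisible(x)
}

subset_keypoints <- function(kp, idx) {
  new_keypoints(kp$u[idx], kp$v[idx], kp$orientation[idx], kp$scale[idx],
                kp$response[idx], kp$descriptors[idx, , drop = FALSE])
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.ght_keypoints <- function(x, ...) {
  tibble::tibble(u = x$u, v = x$v, orientation = x$orientation,
                 scale = x$scale, response = x$response)
}
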