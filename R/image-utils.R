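# Low-level image helpers shared by the detector, segmentation model and
# renderer. Images are numeric arrays [height, width] (grayscale) or
# [height, width, 3] (RGB), values in [0, 1]. User-facing pixel coordinates
# are 0-based with (u, v) = (column, row); array element [v + 1, u + 1].

#' Read a frame image from a PNG file
#'
#' @param path Path to a PNG file.
#' @return Numeric array `[height, width, 3]` with values in `[0, 1]`.
#' @export
read_frame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a frame image to a PNG file
#'
#' @param img Numeric array `[height, width]` or `[height, width, 3]`, values
#'   clipped to `[0, 1]` before writing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' Export a probability map as an 8-bit grayscale PNG
#'
#' Pixel value is `round(255 * p)`; useful for visually debugging the
#' segmentation posterior.
#'
#' @param prob_map Matrix of per-pixel probabilities in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probability_png <- function(prob_map, path) {
  write_frame(round(255 * prob_map) / 255, path)
}

to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Shift a matrix by (dv, du) with edge replication.
shift_mat <- function(m, dv, du) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dv, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - du, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Banded convolution matrix for one image axis, edge-replicated boundary;
# memoized because the scale-space ladder reuses the same (n, sigma) pairs
# on every frame.
.blur_cache <- new.env(parent = emptyenv())

blur_band_matrix <- function(n, sigma) {
  key <- paste0(n, "_", format(sigma, digits = 12))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in seq_along(k)) {
    src <- pmin(pmax(i + o - 1L - r, 1L), n)
    idx <- cbind(i, src)
    K[idx] <- K[idx] + k[o]
  }
  .blur_cache[[key]] <- K
  K
}

# Separable Gaussian blur (edge-replicated) as two banded matrix products.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  Kv <- blur_band_matrix(nrow(m), sigma)
  Ku <- blur_band_matrix(ncol(m), sigma)
  Kv %*% m %*% t(Ku)
}

# Central-difference gradients; returns list(gx, gy) matching m's extent.
image_gradient <- function(m) {
  gx <- 0.5 * (shift_mat(m, 0L, -1L) - shift_mat(m, 0L, 1L))
  gy <- 0.5 * (shift_mat(m, -1L, 0L) - shift_mat(m, 1L, 0L))
  list(gx = gx, gy = gy)
}

# Bilinear sample of matrix m at 0-based continuous coords (u, v); points
# outside the image are clamped to the border.
bilinear_sample <- function(m, u, v) {
  nr <- nrow(m); nc <- ncol(m)
  u <- pmin(pmax(u, 0), nc - 1)
  v <- pmin(pmax(v, 0), nr - 1)
  u0 <- floor(u); v0 <- floor(v)
  du <- u - u0; dv <- v - v0
  u0 <- pmin(u0, nc - 2); v0 <- pmin(v0, nr - 2)
  u0[is.na(u0)] <- 0; v0[is.na(v0)] <- 0
  i00 <- v0 + 1 + u0 * nr
  m00 <- m[i00]; m01 <- m[i00 + nr]; m10 <- m[i00 + 1]; m11 <- m[i00 + nr + 1]
  (1 - dv) * ((1 - du) * m00 + du * m01) + dv * ((1 - du) * m10 + du * m11)
}

#' Construct a rectangle
#'
#' Rectangles are half-open: pixel (u, v) is inside iff
#' `u0 <= u < u0 + w` and `v0 <= v < v0 + h`, in 0-based coordinates.
#'
#' @param u0,v0 Top-left corner (0-based, column/row).
#' @param w,h Width and height in pixels.
#' @return A named numeric vector of class `ght_rect`.
#' @export
ght_rect <- function(u0, v0, w, h) {
  stopifnot(w > 0, h > 0)
  structure(c(u0 = unname(u0), v0 = unname(v0), w = unname(w),
              h = unname(h)), class = "ght_rect")
}

rect_center <- function(r) c(u = unname(r["u0"] + r["w"] / 2),
                             v = unname(r["v0"] + r["h"] / 2))

rect_clip <- function(r, width, height) {
  u0 <- max(r["u0"], 0); v0 <- max(r["v0"], 0)
  u1 <- min(r["u0"] + r["w"], width); v1 <- min(r["v0"] + r["h"], height)
  if (u1 <= u0 || v1 <= v0) return(NULL)
  ght_rect(u0, v0, u1 - u0, v1 - v0)
}

points_in_rect <- function(u, v, r) {
  u >= r["u0"] & u < r["u0"] + r["w"] & v >= r["v0"] & v < r["v0"] + r["h"]
}

# Convex hull (0-based coords) of a point set; returns NULL when degenerate
# (fewer than 3 distinct non-collinear points).
convex_hull <- function(u, v) {
  pts <- unique(cbind(u, v))
  if (nrow(pts) < 3L) return(NULL)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  if (nrow(hull) < 3L) return(NULL)
  # chull returns clockwise order in plot coords; area check guards collinear
  x <- hull[, 1]; y <- hull[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area < 1e-9) return(NULL)
  hull
}

# Vectorized point-in-convex-polygon: all cross products one sign (or zero).
points_in_convex_poly <- function(u, v, hull) {
  n <- nrow(hull)
  inside_pos <- rep(TRUE, length(u))
  inside_neg <- rep(TRUE, length(u))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hull[j, 1] - hull[i, 1]) * (v - hull[i, 2]) -
          (hull[j, 2] - hull[i, 2]) * (u - hull[i, 1])
    inside_pos <- inside_pos & cr >= -1e-9
    inside_neg <- inside_neg & cr <= 1e-9
  }
  inside_pos | inside_neg
}

# Logical mask [height, width] of pixels whose centers fall inside the hull.
poly_mask <- function(hull, width, height) {
  mask <- matrix(FALSE, height, width)
  u0 <- max(0L, floor(min(hull[, 1]))); u1 <- min(width - 1L, ceiling(max(hull[, 1])))
  v0 <- max(0L, floor(min(hull[, 2]))); v1 <- min(height - 1L, ceiling(max(hull[, 2])))
  if (u1 < u0 || v1 < v0) return(mask)
  uu <- rep(u0:u1, each = v1 - v0 + 1L)
  vv <- rep(v0:v1, times = u1 - u0 + 1L)
  ok <- points_in_convex_poly(uu, vv, hull)
  mask[cbind(vv[ok] + 1L, uu[ok] + 1L)] <- TRUE
  mask
}

# Wrap angle to (-pi, pi].
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

# Circular median: angle minimizing summed absolute circular deviation.
circular_median <- function(a) {
  if (length(a) == 1L) return(wrap_angle(a))
  best <- a[1]; best_cost <- Inf
  for (cand in a) {
    cost <- sum(abs(wrap_angle(a - cand)))
    if (cost < best_cost) { best_cost <- cost; best <- cand }
  }
  wrap_angle(best)
}
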