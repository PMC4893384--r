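# 2D -> 3D pose initialization. The 2D tracker recovers (u, v, theta, s);
# a pinhole camera plus the metric depth of the object at enrollment turn
# that into an initialization of the full 3D pose (x, y, z, phi, psi,
# theta_hat) for a downstream model-based 3D tracker: the center pixel is
# ray-cast to depth z_ref / s (apparent size scales inversely with depth),
# the in-plane rotation initializes theta_hat directly, and the two
# out-of-plane rotations - which the 2D tracker cannot observe - are
# retained from the previous frame. The external 3D refinement stage is a
# pluggable hook; a pass-through ships as default (see run_sequence()).

#' Pinhole camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels.
#' @return A list of class `ght_camera`.
#' @export
camera_model <- function(fx, fy, cx, cy) {
  stopifnot(fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy), class = "ght_camera")
}

#' Read camera intrinsics from a plain-text config
#'
#' Accepts `key = value` or `key: value` lines with keys `fx`, `fy`, `cx`,
#' `cy`.
#'
#' @param path Path to the text file.
#' @return A `ght_camera`.
#' @export
read_camera <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*(fx|fy|cx|cy)\\s*[:=]\\s*([-0-9.eE+]+)", ln))[[1]]
    if (length(m) == 3L) vals[[m[2]]] <- as.numeric(m[3])
  }
  if (!all(c("fx", "fy", "cx", "cy") %in% names(vals))) {
    stop("camera config must define fx, fy, cx, cy")
  }
  camera_model(vals$fx, vals$fy, vals$cx, vals$cy)
}

#' Lift a 2D pose to a 3D pose initialization
#'
#' Ray-casts the tracked center through the camera at depth `z_ref / s`
#' (the object was at depth `z_ref` when its scale was 1; a larger apparent
#' scale means it is nearer). `theta` initializes `theta_hat` directly; the
#' out-of-plane rotations `phi`, `psi` are copied from the previous 3D
#' pose. The scale `s` is cumulative relative to the enrollment frame, not
#' a frame-to-frame ratio.
#'
#' @param pose2d Named vector with `u`, `v`, `theta`, `scale`.
#' @param camera A [camera_model()].
#' @param z_ref Metric depth at enrollment (`scale` = 1); `> 0`.
#' @param prev_pose3d Previous 3D pose (named vector with `phi`, `psi`);
#'   defaults to zero rotations.
#' @return Named numeric vector `c(x, y, z, phi, psi, theta_hat)`.
#' @export
lift_to_3d <- function(pose2d, camera, z_ref,
                       prev_pose3d = c(phi = 0, psi = 0)) {
  s <- unname(pose2d["scale"])
  if (!is.finite(s) || s <= 0) stop("lift_to_3d: invalid scale")
  stopifnot(z_ref > 0)
  z <- z_ref / s
  x <- (unname(pose2d["u"]) - camera$cx) * z / camera$fx
  y <- (unname(pose2d["v"]) - camera$cy) * z / camera$fy
  c(x = x, y = y, z = z,
    phi = unname(prev_pose3d["phi"]), psi = unname(prev_pose3d["psi"]),
    theta_hat = unname(pose2d["theta"]))
}

#' Project a 3D position back to pixel coordinates
#'
#' Exact pinhole inversion of [lift_to_3d()], used to verify consistency.
#'
#' @param pose3d Named vector with `x`, `y`, `z`.
#' @param camera A [camera_model()].
#' @return `c(u, v)` in pixels.
#' @export
project_point <- function(pose3d, camera) {
  z <- unname(pose3d["z"])
  stopifnot(z > 0)
  c(u = unname(pose3d["x"]) * camera$fx / z + camera$cx,
    v = unname(pose3d["y"]) * camera$fy / z + camera$cy)
}
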