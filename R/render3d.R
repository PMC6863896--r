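# Rotation matrix acting on physical (x, y, z) column vectors; angles in
# degrees, applied in the fixed order x, then y, then z.
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Maximum-intensity projection along the axial view axis of the volume
# rotated rigidly about its physical centroid. Sampling grid = the input
# grid zero-padded (per axis, in whole voxels) to cover the rotation
# sphere, so an identity rotation samples exactly at voxel centers and
# the frame equals the plain axial MIP up to zero padding. Trilinear
# interpolation, zero fill outside the volume.
rotated_mip <- function(arr, spacing, angles_deg, block = 8L) {
  d <- dim(arr)
  extent <- (d - 1) * spacing
  centroid <- extent / 2                      # (z, x, y) um
  r <- sqrt(sum((extent / 2)^2))
  pad <- pmax(0L, ceiling((r - extent / 2) / spacing))
  dout <- d + 2L * pad

  Rinv <- t(rotation_matrix(angles_deg))      # inverse of a rotation
  nz <- dout[1]
  uz <- ((seq_len(nz) - 1L) - pad[1]) * spacing[1] - centroid[1]
  ux_all <- ((seq_len(dout[2]) - 1L) - pad[2]) * spacing[2] - centroid[2]
  uy_all <- ((seq_len(dout[3]) - 1L) - pad[3]) * spacing[3] - centroid[3]

  img <- matrix(0, dout[2], dout[3])
  for (k0 in seq(1L, dout[3], by = block)) {
    k1 <- min(k0 + block - 1L, dout[3])
    nk <- k1 - k0 + 1L
    # Output physical offsets (x, y, z) for this block, z fastest.
    gx <- rep(ux_all, each = nz, times = nk)
    gy <- rep(uy_all[k0:k1], each = nz * dout[2])
    gz <- rep(uz, times = dout[2] * nk)
    sx <- Rinv[1, 1] * gx + Rinv[1, 2] * gy + Rinv[1, 3] * gz
    sy <- Rinv[2, 1] * gx + Rinv[2, 2] * gy + Rinv[2, 3] * gz
    sz_ <- Rinv[3, 1] * gx + Rinv[3, 2] * gy + Rinv[3, 3] * gz
    # Back to fractional 1-based voxel indices (z, x, y).
    fi <- (sz_ + centroid[1]) / spacing[1] + 1
    fj <- (sx + centroid[2]) / spacing[2] + 1
    fk <- (sy + centroid[3]) / spacing[3] + 1
    vals <- trilinear_sample(arr, fi, fj, fk)
    m <- matrix(vals, nz, dout[2] * nk)
    acc <- m[1, ]
    if (nz > 1) for (z in 2:nz) acc <- pmax(acc, m[z, ])
    img[, k0:k1] <- matrix(acc, dout[2], nk)
  }
  img
}

# Trilinear interpolation of a 3D array at fractional 1-based indices,
# zero outside.
trilinear_sample <- function(arr, fi, fj, fk) {
  d <- dim(arr)
  i0 <- floor(fi); j0 <- floor(fj); k0 <- floor(fk)
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  gather <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- numeric(length(i))
    if (any(ok))
      out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
    out
  }
  v <- (1 - wi) * (1 - wj) * (1 - wk) * gather(i0,     j0,     k0) +
       wi       * (1 - wj) * (1 - wk) * gather(i0 + 1, j0,     k0) +
       (1 - wi) * wj       * (1 - wk) * gather(i0,     j0 + 1, k0) +
       wi       * wj       * (1 - wk) * gather(i0 + 1, j0 + 1, k0) +
       (1 - wi) * (1 - wj) * wk       * gather(i0,     j0,     k0 + 1) +
       wi       * (1 - wj) * wk       * gather(i0 + 1, j0,     k0 + 1) +
       (1 - wi) * wj       * wk       * gather(i0,     j0 + 1, k0 + 1) +
       wi       * wj       * wk       * gather(i0 + 1, j0 + 1, k0 + 1)
  v
}

#' Render one rotational frame
#'
#' Rotates the volume(s) rigidly about the physical centroid by
#' `(theta_x, theta_y, theta_z)` (applied in that fixed order, trilinear
#' interpolation, spacing-aware so anisotropic voxels rotate without
#' distortion) and max-projects along the axial view axis. In `merged`
#' mode the structural MIP is composited in grayscale (white signal) and
#' the flow MIP in magenta, blended by per-pixel maximum. At identity
#' rotation the flow channel equals the plain axial MIP exactly (up to
#' the zero-padding border that keeps the frame size angle-independent).
#'
#' @param flow Flow volume ([octa_volume()] or array).
#' @param struct Structural volume (required for `mode = "merged"`).
#' @param angles_deg Rotation angles `(theta_x, theta_y, theta_z)` in
#'   degrees about the horizontal, vertical, and axial axes.
#' @param mode `"flow_only"` (grayscale) or `"merged"`.
#' @param spacing Voxel spacing override.
#' @return RGB array `(x, y, 3)` with values in `[0, 1]`; the input
#'   volumes are not modified. Multiply by 255 for gray levels.
#' @export
render_frame <- function(flow, struct = NULL, angles_deg = c(0, 0, 0),
                         mode = c("flow_only", "merged"), spacing = NULL) {
  mode <- match.arg(mode)
  f <- vol_data(flow)
  sp <- vol_spacing(flow, spacing)
  if (mode == "merged" && is.null(struct))
    stop("merged mode requires a structural volume")
  fm <- rotated_mip(f, sp, angles_deg) / 255
  if (mode == "flow_only") {
    out <- array(0, c(dim(fm), 3L))
    out[, , 1] <- fm; out[, , 2] <- fm; out[, , 3] <- fm
    return(out)
  }
  st <- vol_data(struct)
  if (!all(dim(st) == dim(f))) stop("flow and struct shapes differ")
  sm <- rotated_mip(st, sp, angles_deg) / 255
  out <- array(0, c(dim(fm), 3L))
  out[, , 1] <- pmax(sm, fm)   # magenta flow = (1, 0, 1)
  out[, , 2] <- sm
  out[, , 3] <- pmax(sm, fm)
  out
}

#' Render a rotation series
#'
#' `n_frames` frames at equally spaced angles over 360 degrees about one
#' axis, written as `frame_0000.png`, `frame_0001.png`, ... Frames are
#' deterministic functions of (volume, angles).
#'
#' @param flow,struct,mode,spacing As in [render_frame()].
#' @param axis `"x"`, `"y"`, or `"z"`.
#' @param n_frames Number of frames (>= 1); frame `i` is at
#'   `(i - 1) * 360 / n_frames` degrees.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
render_rotation_series <- function(flow, struct = NULL, axis = c("y", "x", "z"),
                                   n_frames = 36L, out_dir,
                                   mode = c("flow_only", "merged"),
                                   spacing = NULL) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  ai <- match(axis, c("x", "y", "z"))
  paths <- character(n_frames)
  for (i in seq_len(n_frames)) {
    ang <- c(0, 0, 0)
    ang[ai] <- (i - 1) * 360 / n_frames
    frame <- render_frame(flow, struct, angles_deg = ang, mode = mode,
                          spacing = spacing)
    paths[i] <- file.path(out_dir, sprintf("frame_%04d.png", i - 1))
    write_frame_png(frame, paths[i])
  }
  invisible(paths)
}

#' Write a rendered frame as PNG
#'
#' @param frame RGB array from [render_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(aperm(frame, c(2, 1, 3)), path)
  invisible(path)
}
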