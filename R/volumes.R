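#' OCTA / OCT volume container
#'
#' A volume is a 3D array of 8-bit intensities in canonical axis order
#' `(z, x, y)`: the first axis is axial depth (increasing toward the
#' choroid), the second horizontal, the third vertical. Flow volumes hold
#' OCTA decorrelation values, structural volumes hold OCT reflectivity;
#' both live on the same grid with voxel spacing `(dz, dx, dy)` in
#' micrometers.
#'
#' @param data 3D numeric/integer array with values in `[0, 255]`.
#' @param spacing Numeric length-3 vector `(dz, dx, dy)` in um/voxel,
#'   all positive. Default `c(2, 10, 10)` corresponds to a 3 x 3 mm,
#'   300 x 300 A-scan macular cube; the axial sampling is instrument
#'   configuration, not a measurement, and every physical-unit output in
#'   the package consumes `spacing` rather than assuming isotropy.
#' @param kind `"flow"` or `"struct"`.
#' @return An object of class `octa_volume`: a list with elements `data`
#'   (integer array), `spacing`, and `kind`.
#' @examples
#' v <- flow_volume(array(0L, c(4, 4, 4)))
#' dim(v$data)
#' @export
octa_volume <- function(data, spacing = c(2, 10, 10), kind = c("flow", "struct")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array")
  if (anyNA(data) || min(data) < 0 || max(data) > 255)
    stop("voxel values must lie in [0, 255]")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers (dz, dx, dy) in um/voxel")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = as.numeric(spacing), kind = kind),
            class = "octa_volume")
}

#' @rdname octa_volume
#' @export
flow_volume <- function(data, spacing = c(2, 10, 10)) {
  octa_volume(data, spacing, kind = "flow")
}

#' @rdname octa_volume
#' @export
struct_volume <- function(data, spacing = c(2, 10, 10)) {
  octa_volume(data, spacing, kind = "struct")
}

#' @export
print.octa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<octa_volume: %s, %d x %d x %d (z,x,y), spacing %.3g/%.3g/%.3g um>\n",
              x$kind, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Accept either an octa_volume or a bare array; return the array.
vol_data <- function(vol) {
  if (inherits(vol, "octa_volume")) vol$data else vol
}

vol_spacing <- function(vol, spacing = NULL) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (inherits(vol, "octa_volume")) vol$spacing else c(2, 10, 10)
}

#' Read a headerless 8-bit raw volume
#'
#' Raw exports are plain byte streams with no header; the caller supplies
#' the grid shape. Bytes are laid out with the first (axial) index varying
#' fastest, i.e. one A-scan after another, matching [write_raw_volume()].
#'
#' @param path File path.
#' @param shape Integer length-3 vector `(z, x, y)`.
#' @param spacing Voxel spacing `(dz, dx, dy)` in um; see [octa_volume()].
#' @param kind `"flow"` or `"struct"`.
#' @return An [octa_volume()].
#' @export
read_raw_volume <- function(path, shape, spacing = c(2, 10, 10),
                            kind = c("flow", "struct")) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape <= 0))
    stop("`shape` must be three positive integers (z, x, y)")
  expected <- prod(shape)
  actual <- file.size(path)
  if (is.na(actual)) stop(sprintf("cannot read '%s'", path))
  if (actual != expected)
    stop(sprintf("raw volume size mismatch for '%s': expected %d bytes (%d x %d x %d), got %d",
                 path, expected, shape[1], shape[2], shape[3], actual))
  bytes <- readBin(path, what = "integer", n = expected, size = 1L, signed = FALSE)
  octa_volume(array(bytes, dim = shape), spacing = spacing, kind = kind)
}

#' Write a volume as a headerless 8-bit raw file
#'
#' @param vol An [octa_volume()] (or bare uint8 array).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_volume <- function(vol, path) {
  data <- vol_data(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(as.vector(data)), con)
  invisible(path)
}

#' Re-orient a volume grid into canonical axial-first order
#'
#' Imported cubes may carry the axial direction on any axis and in either
#' sense. `reorient` permutes (and optionally flips) the axes so that the
#' first dimension is axial depth with pixel number increasing toward the
#' choroid, the second horizontal and the third vertical.
#'
#' @param x 3D array or [octa_volume()].
#' @param perm Integer permutation of `1:3`: output axis `i` is input axis
#'   `perm[i]` (the semantics of [aperm()]).
#' @param flip Logical length-3: reverse output axis `i` after permutation.
#' @param spacing Spacing of the *output* `(dz, dx, dy)`; defaults to the
#'   input volume's spacing permuted by `perm` when `x` is an
#'   `octa_volume`, else `c(2, 10, 10)`.
#' @param kind Volume kind for the result.
#' @return An [octa_volume()] in canonical `(z, x, y)` order.
#' @examples
#' a <- array(seq_len(24), c(2, 3, 4)) - 1
#' v <- reorient(a, perm = c(3, 1, 2))  # axial was the last axis
#' dim(v$data)
#' @export
reorient <- function(x, perm = c(1, 2, 3), flip = c(FALSE, FALSE, FALSE),
                     spacing = NULL, kind = c("flow", "struct")) {
  kind <- match.arg(kind)
  perm <- as.integer(perm)
  if (length(perm) != 3 || !setequal(perm, 1:3))
    stop("`perm` must be a permutation of 1:3")
  if (length(flip) != 3 || !is.logical(flip))
    stop("`flip` must be three logicals")
  arr <- vol_data(x)
  if (is.null(spacing)) {
    spacing <- if (inherits(x, "octa_volume")) x$spacing[perm] else c(2, 10, 10)
  }
  out <- aperm(arr, perm)
  idx <- lapply(seq_len(3), function(i) {
    if (flip[i]) rev(seq_len(dim(out)[i])) else seq_len(dim(out)[i])
  })
  out <- out[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  octa_volume(out, spacing = spacing, kind = kind)
}

#' Invert a reorientation
#'
#' Returns the `perm`/`flip` pair that undoes [reorient()], so that
#' `reorient(reorient(x, perm, flip)$data, inv$perm, inv$flip)` recovers
#' the original grid exactly.
#'
#' @param perm,flip As in [reorient()].
#' @return List with elements `perm` and `flip`.
#' @export
invert_orientation <- function(perm, flip = c(FALSE, FALSE, FALSE)) {
  perm <- as.integer(perm)
  if (length(perm) != 3 || !setequal(perm, 1:3))
    stop("`perm` must be a permutation of 1:3")
  # Forward: out = flip_out(aperm(in, perm)). Inverse: permute by order(perm),
  # flipping the axes that were flipped, expressed in input-axis positions.
  inv_perm <- order(perm)
  inv_flip <- flip[inv_perm]
  list(perm = inv_perm, flip = inv_flip)
}

#' Read / write a volume as a multi-page 8-bit TIFF stack
#'
#' Page `i` of the stack is the en face plane at depth `i`
#' (`vol$data[i, , ]`). Round trips are lossless for 8-bit data.
#'
#' @param path TIFF file path.
#' @param spacing,kind As in [octa_volume()].
#' @return [read_tiff_stack()]: an [octa_volume()]; [write_tiff_stack()]:
#'   `path`, invisibly.
#' @export
read_tiff_stack <- function(path, spacing = c(2, 10, 10),
                            kind = c("flow", "struct")) {
  kind <- match.arg(kind)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    bits <- attr(pages[[i]], "bits.per.sample")
    if ((!is.null(bits) && bits != 8) || max(pages[[i]]) > 255)
      stop(sprintf(paste0("page %d of '%s' is not 8-bit; convert the stack to ",
                          "8-bit first (e.g. rescale to [0,255] and requantize)"),
                   i, path))
    if (length(dim(pages[[i]])) != 2)
      stop(sprintf("page %d of '%s' is not single-channel grayscale", i, path))
  }
  nz <- length(pages)
  nx <- nrow(pages[[1]])
  ny <- ncol(pages[[1]])
  data <- array(0L, c(nz, nx, ny))
  for (i in seq_len(nz)) data[i, , ] <- pages[[i]]
  octa_volume(data, spacing = spacing, kind = kind)
}

#' @rdname read_tiff_stack
#' @param vol An [octa_volume()] (or bare uint8 array).
#' @export
write_tiff_stack <- function(vol, path) {
  data <- vol_data(vol)
  pages <- lapply(seq_len(dim(data)[1]), function(i) {
    m <- data[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(data)[2])
    m / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}
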