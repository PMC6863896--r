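#' Retinal layer surfaces
#'
#' Per-A-scan depth maps of the three surfaces the pipeline consumes: the
#' outer boundary of the deep vascular complex (DVC), the retinal pigment
#' epithelium (RPE), and Bruch's membrane (BM). Depths are fractional
#' axial voxel indices (first axial sample = 1, increasing toward the
#' choroid); convert to micrometers by multiplying by `dz`. Surfaces are
#' inputs to the pipeline — the package does not segment structural OCT.
#'
#' @param dvc_outer,rpe,bm Numeric matrices over `(x, y)`, the lateral
#'   grid of the paired volumes, with `1 <= dvc_outer < rpe <= bm` at
#'   every A-scan.
#' @return Object of class `layer_surfaces`.
#' @export
layer_surfaces <- function(dvc_outer, rpe, bm) {
  if (!all(dim(dvc_outer) == dim(rpe)) || !all(dim(rpe) == dim(bm)))
    stop("surface maps must share the same lateral shape")
  if (any(dvc_outer < 1) || any(dvc_outer >= rpe) || any(rpe > bm))
    stop("surfaces must satisfy 1 <= dvc_outer < rpe <= bm at every (x, y)")
  structure(list(dvc_outer = dvc_outer, rpe = rpe, bm = bm),
            class = "layer_surfaces")
}

#' @export
print.layer_surfaces <- function(x, ...) {
  cat(sprintf("<layer_surfaces: %d x %d A-scans, mean depths dvc=%.1f rpe=%.1f bm=%.1f vox>\n",
              nrow(x$dvc_outer), ncol(x$dvc_outer),
              mean(x$dvc_outer), mean(x$rpe), mean(x$bm)))
  invisible(x)
}

# Check surfaces against a volume's grid.
validate_surfaces <- function(surfaces, vol) {
  d <- dim(vol_data(vol))
  if (!all(dim(surfaces$dvc_outer) == d[2:3]))
    stop(sprintf("surface maps are %d x %d but the volume lateral grid is %d x %d",
                 nrow(surfaces$dvc_outer), ncol(surfaces$dvc_outer), d[2], d[3]))
  if (any(surfaces$bm >= d[1]))
    stop("Bruch's membrane surface extends beyond the axial extent of the volume")
  invisible(TRUE)
}

#' Read / write layer surfaces as CSV
#'
#' Long format with one row per A-scan: columns `x`, `y` (1-based lateral
#' voxel indices), `dvc_outer`, `rpe`, `bm` (fractional axial voxel
#' depths).
#'
#' @param path CSV path.
#' @return [read_surfaces_csv()]: a [layer_surfaces()];
#'   [write_surfaces_csv()]: `path`, invisibly.
#' @export
read_surfaces_csv <- function(path) {
  df <- read.csv(path)
  need <- c("x", "y", "dvc_outer", "rpe", "bm")
  if (!all(need %in% names(df)))
    stop(sprintf("surface CSV must have columns %s", paste(need, collapse = ", ")))
  nx <- max(df$x); ny <- max(df$y)
  mk <- function(col) {
    m <- matrix(NA_real_, nx, ny)
    m[cbind(df$x, df$y)] <- df[[col]]
    if (anyNA(m)) stop("surface CSV does not cover the full lateral grid")
    m
  }
  layer_surfaces(mk("dvc_outer"), mk("rpe"), mk("bm"))
}

#' @rdname read_surfaces_csv
#' @param surfaces A [layer_surfaces()].
#' @export
write_surfaces_csv <- function(surfaces, path) {
  nx <- nrow(surfaces$dvc_outer); ny <- ncol(surfaces$dvc_outer)
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  df <- data.frame(grid,
                   dvc_outer = surfaces$dvc_outer[as.matrix(grid)],
                   rpe = surfaces$rpe[as.matrix(grid)],
                   bm = surfaces$bm[as.matrix(grid)])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Small separable box smoothing of a 2D map (used for the RPE-fit surface).
smooth_surface <- function(m, half_width = 5L) {
  if (half_width < 1) return(m)
  k <- rep(1, 2L * half_width + 1L)
  sm1 <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], half_width), v, rep(v[n], half_width))
    as.numeric(stats::filter(padded, k / length(k), sides = 2))[
      (half_width + 1L):(half_width + n)]
  }
  m2 <- apply(m, 2, sm1)
  t(apply(m2, 1, sm1))
}
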