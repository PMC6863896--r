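# Independent oracles used by the tests. These deliberately use the most
# direct (brute-force) formulation of each quantity, not the package's
# algorithms.

# Connected-component labeling by explicit flood fill (queue-based).
# `offsets`: matrix of neighbor index offsets, one row per neighbor.
flood_label <- function(mask, offsets) {
  d <- dim(mask)
  lab <- array(0L, d)
  nd <- nrow(offsets)
  idx_ok <- function(p) all(p >= 1) && all(p <= d)
  nextlab <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    p0 <- coords[r, ]
    if (lab[matrix(p0, 1)] != 0L) next
    nextlab <- nextlab + 1L
    queue <- list(p0)
    lab[matrix(p0, 1)] <- nextlab
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nd)) {
        pn <- p + offsets[q, ]
        if (!idx_ok(pn)) next
        pm <- matrix(pn, 1)
        if (mask[pm] && lab[pm] == 0L) {
          lab[pm] <- nextlab
          queue[[length(queue) + 1]] <- pn
        }
      }
    }
  }
  lab
}

offsets_4 <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))

# Projection-tail field by direct double summation of the closed form:
# tail(z) = alpha * refl(z)/255 * sum_{z' < z} flow(z') * exp(-(z-z')*dz/tau),
# zero where reflectivity is at/below the background level.
tail_oracle <- function(clean, refl, alpha, tau_um, dz_um, bg_level) {
  d <- dim(clean)
  out <- array(0, d)
  for (x in seq_len(d[2])) for (y in seq_len(d[3])) {
    for (z in seq_len(d[1])) {
      if (refl[z, x, y] <= bg_level) next
      zp <- seq_len(z - 1L)
      if (length(zp) == 0) next
      acc <- sum(clean[zp, x, y] * exp(-(z - zp) * dz_um / tau_um))
      out[z, x, y] <- alpha * (refl[z, x, y] / 255) * acc
    }
  }
  out
}

# Single-A-scan oracle for the windowed projection-removal contract,
# written as direct sums (no running recursion): at each window top z0,
# A(z) = sum_{z' < z} val(z') * exp(-(z - z')*dz/tau) with val(z') the
# finalized corrected value for z' < z0 and the current partially
# corrected value inside the window; corrections are averaged over the
# windows covering each depth.
par_column_oracle <- function(flow, refl, h, s, alpha, tau_um, dz_um,
                              eps = 1, clamp = TRUE) {
  nz <- length(flow)
  corr_sum <- numeric(nz)
  corr_cnt <- integer(nz)
  gate <- alpha * pmax(refl, eps) / 255
  partial <- function(z) {
    v <- flow[z] - if (corr_cnt[z] > 0) corr_sum[z] / corr_cnt[z] else 0
    if (clamp) v <- max(v, 0)
    v
  }
  for (z0 in seq(1, nz, by = s)) {
    for (z in z0:min(z0 + h - 1, nz)) {
      acc <- 0
      for (zp in seq_len(z - 1)) {
        acc <- acc + partial(zp) * exp(-(z - zp) * dz_um / tau_um)
      }
      corr_sum[z] <- corr_sum[z] + gate[z] * acc
      corr_cnt[z] <- corr_cnt[z] + 1L
    }
  }
  out <- vapply(seq_len(nz), partial, numeric(1))
  out <- round(out)
  out <- pmin(pmax(out, 0), 255)
  if (clamp) out <- pmin(out, flow)
  out
}

# Compact phantom used throughout the lesion tests: same anatomy as the
# full cube, smaller lateral grid for speed.
small_phantom_spec <- function(lesions, seed = 1L, ...) {
  phantom_spec(shape = c(128, 100, 100), lesions = lesions, seed = seed, ...)
}
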