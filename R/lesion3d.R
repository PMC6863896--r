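#' Detect type 3 lesions in a corrected OCTA volume
#'
#' Restricts flow to the intraretinal/sub-RPE zone between the DVC outer
#' boundary (exclusive) and Bruch's membrane (inclusive), thresholds it,
#' labels 26-connected components, and keeps components that (i) contain
#' at least `min_voxels` voxels, (ii) contact the DVC boundary (come
#' within one voxel of it), and (iii) extend at least `min_depth_um`
#' below it. A component with several distinct DVC contact points — the
#' configuration in which separate intraretinal lesions join one vascular
#' trunk — is split into one record per origin by geodesic partition of
#' its voxels, all records sharing a `merge_group`.
#'
#' Each record carries a centerline skeleton: the minimal-physical-length
#' in-mask path from the origin (the contact voxel of minimum depth, ties
#' broken by lowest x then y) to the terminus (the in-mask voxel at
#' maximal geodesic distance from the origin), plus the mean
#' distance-to-background radius along it.
#'
#' @param corrected Corrected flow volume ([octa_volume()] or array).
#' @param surfaces [layer_surfaces()] aligned with the volume.
#' @param threshold Flow threshold (0-255); voxels strictly above are
#'   candidate lesion voxels.
#' @param min_voxels Minimum component size.
#' @param min_depth_um Minimum extension below the DVC boundary (um).
#' @param spacing Voxel spacing override.
#' @return List of `lesion_record` objects (possibly empty).
#' @export
detect_lesions <- function(corrected, surfaces, threshold = 60,
                           min_voxels = 20L, min_depth_um = 20,
                           spacing = NULL) {
  f <- vol_data(corrected)
  sp <- vol_spacing(corrected, spacing)
  validate_surfaces(surfaces, f)
  d <- dim(f)

  zone <- array(FALSE, d)
  for (z in seq_len(d[1]))
    zone[z, , ] <- z > surfaces$dvc_outer & z <= surfaces$bm
  mask <- f > threshold & zone
  if (!any(mask)) return(list())

  lab <- array(.cc_label_3d(as.logical(mask), d, 26L), d)
  ncomp <- max(lab)
  records <- list()
  for (comp in seq_len(ncomp)) {
    vox <- which(lab == comp, arr.ind = TRUE)
    if (nrow(vox) < min_voxels) next
    dvc_at <- surfaces$dvc_outer[vox[, 2:3, drop = FALSE]]
    depth_vox <- vox[, 1] - dvc_at
    contact <- depth_vox <= 1
    if (!any(contact)) next
    if (max(depth_vox) * sp[1] < min_depth_um) next

    recs <- split_component(vox, contact, comp, sp)
    records <- c(records, recs)
  }
  # Renumber sequentially, keep merge groups stable per source component.
  for (i in seq_along(records)) records[[i]]$id <- i
  records
}

# Split one component by its DVC contact clusters; build a lesion_record
# per origin with skeleton and radius profile.
split_component <- function(vox, contact, comp_id, sp) {
  bb_lo <- apply(vox, 2, min)
  bb_hi <- apply(vox, 2, max)
  bdim <- bb_hi - bb_lo + 1L
  rel <- sweep(vox, 2, bb_lo - 1L)      # 1-based within bbox
  bmask <- array(FALSE, bdim)
  bmask[rel] <- TRUE
  flat <- function(r) r[, 1] + bdim[1] * (r[, 2] - 1L) + bdim[1] * bdim[2] * (r[, 3] - 1L)

  # Cluster contact voxels (26-connectivity within the bbox).
  cmask <- array(FALSE, bdim)
  cmask[rel[contact, , drop = FALSE]] <- TRUE
  clab <- array(.cc_label_3d(as.logical(cmask), bdim, 26L), bdim)
  n_origin <- max(clab)

  origin_of_cluster <- function(k) {
    cv <- vox[contact, , drop = FALSE][clab[rel[contact, , drop = FALSE]] == k, ,
                                       drop = FALSE]
    cv <- cv[order(cv[, 1], cv[, 2], cv[, 3]), , drop = FALSE]
    cv[1, ]
  }
  origins <- lapply(seq_len(n_origin), origin_of_cluster)

  if (n_origin == 1) {
    assign_lab <- rep(1L, nrow(vox))
  } else {
    seeds_rel <- rel[contact, , drop = FALSE]
    seed_lab <- clab[seeds_rel]
    geo <- .geodesic_paths(as.logical(bmask), bdim, sp,
                           flat(seeds_rel), as.integer(seed_lab))
    assign_lab <- geo$label[flat(rel)]
    assign_lab[assign_lab == 0] <- 1L  # unreachable pockets: fold into first
  }

  lapply(seq_len(n_origin), function(k) {
    sel <- assign_lab == k
    sub_vox <- vox[sel, , drop = FALSE]
    rec <- build_record(sub_vox, origins[[k]], sp)
    rec$merge_group <- comp_id
    rec$n_origins_in_component <- n_origin
    rec
  })
}

# Moving-average smoothing of an n x 3 polyline (endpoint-replicated).
smooth_polyline <- function(P, window = 5L) {
  n <- nrow(P)
  w <- min(window, if (n %% 2 == 1) n else n - 1L)
  if (w < 3) return(P)
  hw <- (w - 1L) %/% 2L
  out <- P
  for (j in 1:3) {
    v <- c(rep(P[1, j], hw), P[, j], rep(P[n, j], hw))
    out[, j] <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))[
      (hw + 1L):(hw + n)]
  }
  out
}

polyline_length <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums(diff(P)^2)))
}

# Build a lesion_record: skeleton path origin -> farthest voxel, physical
# length, mean distance-to-background radius along the skeleton.
build_record <- function(vox, origin, sp) {
  bb_lo <- apply(vox, 2, min)
  bb_hi <- apply(vox, 2, max)
  bdim <- bb_hi - bb_lo + 1L
  rel <- sweep(vox, 2, bb_lo - 1L)
  bmask <- array(FALSE, bdim)
  bmask[rel] <- TRUE
  flat <- function(r) r[, 1] + bdim[1] * (r[, 2] - 1L) + bdim[1] * bdim[2] * (r[, 3] - 1L)
  unflat <- function(fidx) {
    f0 <- fidx - 1L
    cbind(f0 %% bdim[1] + 1L,
          (f0 %/% bdim[1]) %% bdim[2] + 1L,
          f0 %/% (bdim[1] * bdim[2]) + 1L)
  }

  orel <- matrix(origin - bb_lo + 1L, 1)
  geo <- .geodesic_paths(as.logical(bmask), bdim, sp, flat(orel), 1L)
  # Centerline: geodesic-distance shells from the origin, each represented
  # by the shell's sub-voxel voxel centroid. For a tube this traces the
  # axis; for a bulb, its axis of symmetry. (A raw shortest-path backtrace
  # zigzags off-center among lattice near-ties on the anisotropic grid and
  # biases both the radius profile and the principal axis; snapping the
  # centroids to voxel centers would re-introduce lateral jitter.)
  geod <- geo$dist[flat(rel)]
  reach <- is.finite(geod)
  rel_um <- sweep(rel - 1L, 2, sp, "*")           # bbox-local (z,x,y) um
  bin_w <- max(sp)
  bins <- floor(geod[reach] / bin_w)
  skel_loc_um <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- which(reach)[bins == b]
    colMeans(rel_um[sel, , drop = FALSE])
  }))
  skel_vox <- sweep(round(sweep(skel_loc_um, 2, sp, "/")) + 1L,
                    2, bb_lo - 1L, "+")           # snapped, for reporting
  skel_raw_um <- sweep(skel_loc_um, 2, (bb_lo - 1L) * sp, "+")

  # Light smoothing removes residual jitter before length and axis
  # estimation.
  skel_um <- smooth_polyline(skel_raw_um, window = 3L)
  length_um <- polyline_length(skel_um)

  # Radius profile: physical distance from each skeleton sample to the
  # nearest background voxel center in the padded bounding box. The path
  # tips touch the mask boundary, so their radii are boundary artifacts;
  # the profile is trimmed before averaging.
  pad <- 1L
  pdim <- bdim + 2L * pad
  pmask <- array(FALSE, pdim)
  pmask[(pad + 1):(pad + bdim[1]), (pad + 1):(pad + bdim[2]),
        (pad + 1):(pad + bdim[3])] <- bmask
  bg <- which(!pmask, arr.ind = TRUE)
  bg_um <- sweep(sweep(bg, 2, pad) - 1L, 2, sp, "*")  # bbox-local um
  radii <- vapply(seq_len(nrow(skel_loc_um)), function(i) {
    dd <- sweep(bg_um, 2, skel_loc_um[i, ])
    sqrt(min(rowSums(dd^2)))
  }, numeric(1))
  m <- length(radii)
  if (m >= 7) {
    tr <- ceiling(0.15 * m)
    radii <- radii[(tr + 1):(m - tr)]
  }

  structure(list(
    id = NA_integer_,
    voxels = vox,
    origin = origin,
    terminus = skel_vox[nrow(skel_vox), ],
    skeleton_vox = skel_vox,
    skeleton_um = skel_um,
    length_um = length_um,
    mean_radius_um = mean(radii),
    spacing = sp,
    merge_group = NA_integer_,
    n_origins_in_component = 1L), class = "lesion_record")
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf("<lesion_record %s: %d voxels, L=%.1f um, r=%.1f um, origin (z=%d,x=%d,y=%d)%s>\n",
              ifelse(is.na(x$id), "?", x$id), nrow(x$voxels), x$length_um,
              x$mean_radius_um, x$origin[1], x$origin[2], x$origin[3],
              if (x$n_origins_in_component > 1)
                sprintf(", merge group %d", x$merge_group) else ""))
  invisible(x)
}

#' Classify a lesion as saccular or filiform
#'
#' Operationalizes the two observed 3D morphologies with a scale-free
#' elongation statistic `E = L / (2 * rbar)`, where `L` is the physical
#' skeleton length and `rbar` the mean distance-transform radius along
#' the skeleton. Thread-like (filiform) lesions have large `E`; bulb-like
#' (saccular) lesions small `E`. The default critical value 3 sits
#' between the two regimes (an isolated sphere measures about 2, a long
#' uniform tube well above 5).
#'
#' @param record A `lesion_record`.
#' @param e_crit Critical elongation: filiform iff `E >= e_crit`.
#' @return `"saccular"` or `"filiform"`, with the elongation in
#'   `attr(, "elongation")`.
#' @export
classify_shape <- function(record, e_crit = 3) {
  stopifnot(inherits(record, "lesion_record"))
  if (nrow(record$voxels) < 2 || record$length_um <= 0)
    stop("degenerate lesion mask: cannot classify a single-voxel lesion")
  e <- record$length_um / (2 * record$mean_radius_um)
  out <- if (e >= e_crit) "filiform" else "saccular"
  attr(out, "elongation") <- e
  out
}

#' Lesion orientation relative to the Bruch's membrane plane
#'
#' The principal axis is the first principal component of the physical
#' skeleton coordinates (oriented to grow downward). The local BM
#' reference plane is the least-squares plane of the BM surface in a
#' lateral window around the lesion origin; the xy-plane through the
#' origin is taken parallel to it. Inclination is the angle between the
#' principal axis and that plane (0 = in-plane, 90 = perpendicular);
#' axis angles are the angles to the three Cartesian axes (x horizontal,
#' y vertical, z axial) from direction cosines, folded to `[0, 90]`.
#'
#' @param record A `lesion_record`.
#' @param surfaces [layer_surfaces()].
#' @param window_um Lateral half-window for the local BM plane fit (um).
#' @return List: `inclination_deg`, `axis_angles_deg` (named x, y, z),
#'   `axis` (unit vector, physical (x, y, z)), and `degenerate` (`TRUE`
#'   when the PCA fit was ill-conditioned and the endpoint-to-endpoint
#'   vector was used instead).
#' @export
orientation <- function(record, surfaces, window_um = 200) {
  stopifnot(inherits(record, "lesion_record"))
  sk <- record$skeleton_um                      # (z, x, y) um
  if (nrow(sk) < 2) stop("skeleton must have at least 2 voxels")
  P <- cbind(x = sk[, 2], y = sk[, 3], z = sk[, 1])
  degenerate <- FALSE
  axis <- tryCatch({
    pc <- prcomp(P, center = TRUE)
    if (pc$sdev[1] <= 1e-9) stop("collinear")
    pc$rotation[, 1]
  }, error = function(e) {
    degenerate <<- TRUE
    v <- P[nrow(P), ] - P[1, ]
    v / sqrt(sum(v^2))
  })
  if (axis[3] < 0) axis <- -axis               # downward growth

  sp <- record$spacing
  ox <- (record$origin[2] - 1) * sp[2]
  oy <- (record$origin[3] - 1) * sp[3]
  nx <- nrow(surfaces$bm); ny <- ncol(surfaces$bm)
  xg <- (seq_len(nx) - 1) * sp[2]
  yg <- (seq_len(ny) - 1) * sp[3]
  xi <- which(abs(xg - ox) <= window_um)
  yi <- which(abs(yg - oy) <= window_um)
  bmw <- surfaces$bm[xi, yi, drop = FALSE] * sp[1]   # depth in um
  gw <- expand.grid(x = xg[xi], y = yg[yi])
  # Least-squares plane depth = a + b x + c y; normal prop to (b, c, -1).
  fit <- stats::lm.fit(cbind(1, gw$x, gw$y), as.vector(bmw))
  b <- fit$coefficients[2]; c <- fit$coefficients[3]
  if (anyNA(c(b, c))) { b <- 0; c <- 0 }
  nrm <- c(b, c, -1)
  nrm <- nrm / sqrt(sum(nrm^2))

  cosang <- abs(sum(axis * nrm))
  inclination <- 90 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ax_angles <- acos(pmin(abs(axis), 1)) * 180 / pi
  names(ax_angles) <- c("x", "y", "z")
  list(inclination_deg = as.numeric(inclination),
       axis_angles_deg = ax_angles,
       axis = axis,
       degenerate = degenerate)
}

#' Does a lesion contact the sub-RPE space?
#'
#' `TRUE` iff any mask voxel lies at or below the RPE surface at its
#' A-scan.
#'
#' @param record A `lesion_record`.
#' @param surfaces [layer_surfaces()].
#' @return Logical flag.
#' @export
sub_rpe_contact <- function(record, surfaces) {
  stopifnot(inherits(record, "lesion_record"))
  rpe_at <- surfaces$rpe[record$voxels[, 2:3, drop = FALSE]]
  any(record$voxels[, 1] >= rpe_at)
}

#' Characterize detected lesions
#'
#' Runs [classify_shape()], [orientation()] and [sub_rpe_contact()] on
#' every record and assembles the per-lesion table (one row per record).
#'
#' @param records List of `lesion_record` from [detect_lesions()].
#' @param surfaces [layer_surfaces()].
#' @param e_crit Critical elongation for [classify_shape()].
#' @param window_um BM plane window for [orientation()].
#' @return A `data.frame` with columns id, merge_group, n_voxels,
#'   origin/terminus indices, length_um, mean_radius_um, elongation,
#'   shape_class, inclination_deg, angle_x/y/z_deg, reaches_sub_rpe,
#'   degenerate_axis.
#' @export
characterize_lesions <- function(records, surfaces, e_crit = 3,
                                 window_um = 200) {
  if (length(records) == 0) {
    return(data.frame(id = integer(0), merge_group = integer(0),
                      n_voxels = integer(0), origin_z = integer(0),
                      origin_x = integer(0), origin_y = integer(0),
                      terminus_z = integer(0), length_um = numeric(0),
                      mean_radius_um = numeric(0), elongation = numeric(0),
                      shape_class = character(0), inclination_deg = numeric(0),
                      angle_x_deg = numeric(0), angle_y_deg = numeric(0),
                      angle_z_deg = numeric(0), reaches_sub_rpe = logical(0),
                      degenerate_axis = logical(0)))
  }
  rows <- lapply(records, function(rec) {
    sh <- classify_shape(rec, e_crit = e_crit)
    ori <- orientation(rec, surfaces, window_um = window_um)
    data.frame(id = rec$id, merge_group = rec$merge_group,
               n_voxels = nrow(rec$voxels),
               origin_z = rec$origin[1], origin_x = rec$origin[2],
               origin_y = rec$origin[3], terminus_z = rec$terminus[1],
               length_um = rec$length_um, mean_radius_um = rec$mean_radius_um,
               elongation = attr(sh, "elongation"),
               shape_class = as.character(sh),
               inclination_deg = ori$inclination_deg,
               angle_x_deg = unname(ori$axis_angles_deg["x"]),
               angle_y_deg = unname(ori$axis_angles_deg["y"]),
               angle_z_deg = unname(ori$axis_angles_deg["z"]),
               reaches_sub_rpe = sub_rpe_contact(rec, surfaces),
               degenerate_axis = ori$degenerate)
  })
  do.call(rbind, rows)
}

#' End-to-end volume analysis
#'
#' Convenience pipeline: volumetric projection removal, 3D lesion
#' detection and characterization, and the 2D comparator count on the
#' outer-retina en face slab at the same threshold.
#'
#' @param flow,struct Paired volumes.
#' @param surfaces [layer_surfaces()].
#' @param params [par_params()] for projection removal.
#' @param threshold Flow threshold used for both 3D detection and 2D
#'   counting.
#' @param min_voxels,min_depth_um Passed to [detect_lesions()].
#' @param min_area_2d Minimum 2D component area (pixels).
#' @return List: `corrected` volume, `records`, `table`
#'   (per-lesion data.frame), `n_3d`, `enface` (outer-retina slab),
#'   `n_2d`.
#' @export
analyze_volume <- function(flow, struct, surfaces, params = par_params(),
                           threshold = 60, min_voxels = 20L,
                           min_depth_um = 20, min_area_2d = 3L) {
  corrected <- remove_projection(flow, struct, params)
  records <- detect_lesions(corrected, surfaces, threshold = threshold,
                            min_voxels = min_voxels,
                            min_depth_um = min_depth_um)
  tab <- characterize_lesions(records, surfaces)
  enface <- enface_projection(corrected, surfaces, slab = "outer_retina",
                              reducer = "max")
  cnt2d <- count_2d_lesions(enface, threshold = threshold,
                            min_area = min_area_2d)
  list(corrected = corrected, records = records, table = tab,
       n_3d = length(records), enface = enface, n_2d = cnt2d$count)
}

#' Write a lesion table as CSV
#'
#' @param table Data frame from [characterize_lesions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesion_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
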