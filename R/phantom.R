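#' Synthetic macular OCT/OCTA phantom specification
#'
#' Describes a 3 x 3 mm macular cube with a layered retina, two retinal
#' vascular plexuses, planted type 3 neovascular lesions growing downward
#' from the deep vascular complex (DVC), decorrelation-tail projection
#' artifacts beneath flowing vessels, and speckle/background noise.
#' [generate_phantom()] turns a spec into paired structural/flow volumes
#' plus a ground-truth record.
#'
#' Layer depths are given in micrometers from the first axial sample.
#' Defaults place the inner limiting membrane at 30 um, the DVC outer
#' boundary at 160 um, the RPE at 230 um and Bruch's membrane at 236 um —
#' a compact but anatomically ordered retina that fits a 160-sample,
#' 2 um/voxel axial window with choroid below.
#'
#' The projection-tail model is a reflectivity-gated exponential-decay
#' accumulation of the overlying flow: at axial sample `z`,
#' `tail(z) = alpha * refl(z)/255 * sum_{z'<z} flow(z') * exp(-(z-z')*dz/tau)`,
#' applied only where reflectivity exceeds the background level. This
#' reproduces the defining OCTA artifact — spurious flow cast onto bright
#' posterior layers (notably the RPE) beneath true vessels — in a closed
#' form that independent oracles can evaluate.
#'
#' @param shape Volume shape `(z, x, y)` in voxels.
#' @param spacing Voxel spacing `(dz, dx, dy)` in um.
#' @param layers Named list of layer depths in um: `ilm`, `dvc_outer`,
#'   `rpe`, `bm`, plus RPE band thickness `rpe_band`.
#' @param ped Optional pigment epithelial detachment: list with
#'   `center_um` (x, y), `radius_um`, `height_um`; lifts the RPE as a
#'   Gaussian dome off Bruch's membrane.
#' @param vessels List of plexus vessels (see [phantom_vessel()]); `NULL`
#'   uses a default grid of superficial and deep vessels.
#' @param lesions List of planted lesions (see [plant_lesion()]).
#' @param tail List `alpha` (dimensionless amplitude) and `tau_um`
#'   (decay constant, um).
#' @param noise List `speckle_sd` (multiplicative SD on signal voxels),
#'   `background_rate` (probability of a spurious low-flow background
#'   voxel), `background_max` (maximum spurious value).
#' @param struct_levels Reflectivity levels (0-255) for `background`,
#'   `inner` retina, `outer` retina, `rpe`, `ped_interior`, `choroid`.
#' @param seed RNG seed; together with the spec it fully determines the
#'   generated volumes.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 150, 150),
                         spacing = c(2, 10, 10),
                         layers = list(ilm = 30, dvc_outer = 160, rpe = 230,
                                       bm = 236, rpe_band = 6),
                         ped = NULL,
                         vessels = NULL,
                         lesions = list(),
                         tail = list(alpha = 0.08, tau_um = 150),
                         noise = list(speckle_sd = 0.05,
                                      background_rate = 0.001,
                                      background_max = 50),
                         struct_levels = list(background = 20, inner = 90,
                                              outer = 55, rpe = 220,
                                              ped_interior = 45, choroid = 100),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8))
    stop("`shape` must be three integers >= 8")
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  stopifnot(layers$ilm < layers$dvc_outer, layers$dvc_outer < layers$rpe,
            layers$rpe <= layers$bm,
            layers$bm < (shape[1] - 1) * spacing[1])
  if (tail$alpha < 0 || tail$tau_um <= 0)
    stop("tail parameters must satisfy alpha >= 0, tau_um > 0")
  if (is.null(vessels)) vessels <- default_phantom_vessels(shape, spacing)
  structure(list(shape = shape, spacing = as.numeric(spacing), layers = layers,
                 ped = ped, vessels = vessels, lesions = lesions, tail = tail,
                 noise = noise, struct_levels = struct_levels,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Define a plexus vessel for the phantom
#'
#' Vessels are straight tubes at a fixed depth. Superficial vessels run in
#' the inner retina (default depth 60 um), deep vessels just above the DVC
#' outer boundary (default 145 um, so the tube stays anterior to the
#' boundary at the default 12 um radius).
#'
#' @param from_um,to_um Lateral endpoints `(x, y)` in um.
#' @param plexus `"superficial"` or `"deep"`.
#' @param depth_um Depth in um; default by plexus.
#' @param radius_um Tube radius in um.
#' @param intensity Flow value (0-255).
#' @return A vessel description list.
#' @export
phantom_vessel <- function(from_um, to_um, plexus = c("superficial", "deep"),
                           depth_um = NULL, radius_um = NULL, intensity = 200) {
  plexus <- match.arg(plexus)
  if (is.null(depth_um)) depth_um <- if (plexus == "superficial") 60 else 145
  if (is.null(radius_um)) radius_um <- if (plexus == "superficial") 15 else 12
  list(from_um = as.numeric(from_um), to_um = as.numeric(to_um),
       plexus = plexus, depth_um = depth_um, radius_um = radius_um,
       intensity = intensity)
}

# Default plexuses: a grid of superficial and deep vessels spanning the cube.
default_phantom_vessels <- function(shape, spacing) {
  ex <- (shape[2] - 1) * spacing[2]
  ey <- (shape[3] - 1) * spacing[3]
  v <- list()
  for (f in c(0.2, 0.45, 0.7, 0.9)) {
    v[[length(v) + 1]] <- phantom_vessel(c(0, f * ey), c(ex, f * ey), "superficial")
    v[[length(v) + 1]] <- phantom_vessel(c(f * ex, 0), c(f * ex, ey), "superficial")
  }
  for (f in c(0.3, 0.55, 0.8)) {
    v[[length(v) + 1]] <- phantom_vessel(c(0, f * ey), c(ex, f * ey), "deep")
    v[[length(v) + 1]] <- phantom_vessel(c(f * ex, 0), c(f * ex, ey), "deep")
  }
  v
}

#' Plant a type 3 lesion in the phantom
#'
#' Lesions originate on the DVC outer boundary and grow downward along a
#' straight direction with positive axial component. Filiform lesions are
#' constant-radius tubes; saccular lesions are a short stalk ending in a
#' spheroidal bulb. Geometry defaults are chosen so that planted shapes
#' are well separated by the elongation statistic (construction aspect
#' ratios: filiform about 5-9, saccular about 1.1-1.3) and so that
#' `reaches_sub_rpe` lesions terminate inside the thin sub-RPE space
#' (between RPE and Bruch's membrane) while truncated ("nascent") lesions
#' stop well short of the RPE.
#'
#' @param origin_um Lateral origin `(x, y)` in um on the DVC boundary.
#' @param shape `"filiform"` or `"saccular"`.
#' @param reaches_sub_rpe Should the lesion cross the RPE surface?
#' @param incl_deg Planted inclination to the BM-parallel plane, degrees;
#'   defaults: filiform 45 (reaching) / 34 (nascent), saccular 75 / 50.
#' @param azimuth_deg Lateral growth direction, degrees from +x.
#' @param radius_um Tube/stalk radius; defaults 8 (reaching filiform),
#'   9 (nascent filiform), 10 (saccular stalk).
#' @param length_um Path length from origin to terminus (bulb center for
#'   saccular); default derived from `incl_deg` and the reach flag for the
#'   default layer depths.
#' @param bulb_radius_um Saccular bulb radius (default 30).
#' @param intensity Flow value (0-255). The default 90 is deliberately
#'   below the plexus vessel value: capillary tufts carry slower flow
#'   (lower decorrelation) than the parent vessels, and it keeps the
#'   lesion signal plus its own projection tail within the 8-bit range
#'   even through the bulb on the bright RPE.
#' @param merge_group Optional integer: lesions sharing a group id are
#'   expected to join one vascular trunk (see [merged_lesion_group()]).
#' @return A lesion description list.
#' @export
plant_lesion <- function(origin_um, shape = c("filiform", "saccular"),
                         reaches_sub_rpe = TRUE, incl_deg = NULL,
                         azimuth_deg = 0, radius_um = NULL, length_um = NULL,
                         bulb_radius_um = 30, intensity = 90,
                         merge_group = NA_integer_) {
  shape <- match.arg(shape)
  # Depth of the sub-RPE target below the DVC boundary for default layers
  # (rpe 230 - dvc 160 = 70 um); reaching lesions aim 3 um past the RPE,
  # nascent ones stop >= 8 um short.
  reach_depth <- 73
  stop_depth <- 62
  if (is.null(incl_deg)) {
    incl_deg <- if (shape == "filiform") {
      if (reaches_sub_rpe) 45 else 34
    } else {
      if (reaches_sub_rpe) 75 else 50
    }
  }
  if (incl_deg <= 0 || incl_deg > 90) stop("`incl_deg` must lie in (0, 90]")
  sz <- sin(incl_deg * pi / 180)
  if (is.null(radius_um))
    radius_um <- if (shape == "saccular") 10 else if (reaches_sub_rpe) 8 else 9
  if (is.null(length_um)) {
    length_um <- if (shape == "filiform") {
      if (reaches_sub_rpe) reach_depth / sz else min(95, stop_depth / sz)
    } else {
      if (reaches_sub_rpe) (reach_depth - bulb_radius_um) / sz
      else min(35, (stop_depth - bulb_radius_um) / sz)
    }
  }
  az <- azimuth_deg * pi / 180
  direction <- c(cos(incl_deg * pi / 180) * cos(az),
                 cos(incl_deg * pi / 180) * sin(az),
                 sz)  # (dx, dy, dz), unit, physical um
  list(origin_um = as.numeric(origin_um), shape = shape,
       reaches_sub_rpe = reaches_sub_rpe, direction = direction,
       incl_deg = incl_deg, azimuth_deg = azimuth_deg,
       length_um = length_um, radius_um = radius_um,
       bulb_radius_um = if (shape == "saccular") bulb_radius_um else NA_real_,
       intensity = intensity, merge_group = merge_group)
}

#' Construct lesions that merge into a single vascular trunk
#'
#' Builds one lesion per origin, each directed at a common junction point
#' in the outer retina, plus a shared trunk continuing from the junction
#' toward the sub-RPE space. Mirrors the observed configuration of several
#' distinct intraretinal lesions joining one trunk; the detector should
#' report one record per origin sharing a `merge_group`.
#'
#' @param origins_um List/matrix of lateral origins `(x, y)` in um.
#' @param junction_um Junction point `(x, y, depth-below-DVC)` in um.
#' @param group Integer group id.
#' @param radius_um Tube radius of members and trunk.
#' @param trunk_depth_um Depth below the DVC reached by the trunk terminus
#'   (default 73, i.e. just past the RPE for default layers).
#' @param intensity Flow value.
#' @return List of lesion descriptions (members carry `trunk` on the
#'   first member).
#' @export
merged_lesion_group <- function(origins_um, junction_um, group = 1L,
                                radius_um = 9, trunk_depth_um = 73,
                                intensity = 90) {
  if (is.matrix(origins_um))
    origins_um <- lapply(seq_len(nrow(origins_um)), function(i) origins_um[i, ])
  jl <- as.numeric(junction_um)  # (x, y, depth below DVC)
  members <- lapply(origins_um, function(o) {
    o <- as.numeric(o)
    d3 <- c(jl[1] - o[1], jl[2] - o[2], jl[3])
    len <- sqrt(sum(d3^2))
    if (d3[3] <= 0) stop("junction must lie below the DVC boundary")
    dir <- d3 / len
    incl <- asin(dir[3]) * 180 / pi
    az <- atan2(dir[2], dir[1]) * 180 / pi
    plant_lesion(o, shape = "filiform",
                 reaches_sub_rpe = trunk_depth_um >= 70,
                 incl_deg = incl, azimuth_deg = az, radius_um = radius_um,
                 length_um = len, intensity = intensity, merge_group = group)
  })
  # Shared trunk: straight continuation from the junction toward the RPE,
  # attached to the first member for labeling purposes.
  members[[1]]$trunk <- list(from_depth_um = jl[3], to_depth_um = trunk_depth_um,
                             at_um = jl[1:2], radius_um = radius_um,
                             intensity = intensity)
  members
}

#' Randomized phantom specification
#'
#' Places `n_lesions` lesions with random lateral origins (minimum
#' separation 320 um, 250 um edge margin), random azimuths, and shapes /
#' reach flags drawn to mirror the observed cohort mix (about a quarter
#' saccular; most lesions reaching the sub-RPE space). With
#' `merged_pair = TRUE` two additional converging lesions are planted
#' whose en face footprints overlap (the 2D-undercount mechanism).
#'
#' @param n_lesions Number of laterally separated lesions.
#' @param seed RNG seed (also stored in the spec).
#' @param shape,spacing Volume geometry.
#' @param p_saccular Probability a lesion is saccular (default 9/35).
#' @param p_reach Probability a lesion reaches the sub-RPE space.
#' @param merged_pair Add a converging two-lesion merge group?
#' @param ... Passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(n_lesions = 3, seed = 1L,
                                shape = c(160, 150, 150),
                                spacing = c(2, 10, 10),
                                p_saccular = 9 / 35, p_reach = 0.7,
                                merged_pair = FALSE, ...) {
  ex <- (shape[2] - 1) * spacing[2]
  ey <- (shape[3] - 1) * spacing[3]
  margin <- 250
  min_sep <- 320
  with_seed(seed + 77000L, {
    pts <- matrix(numeric(0), 0, 2)
    n_groups <- n_lesions + as.integer(merged_pair)
    tries <- 0
    while (nrow(pts) < n_groups && tries < 5000) {
      cand <- c(runif(1, margin, ex - margin), runif(1, margin, ey - margin))
      if (nrow(pts) == 0 || min(sqrt(rowSums(sweep(pts, 2, cand)^2))) >= min_sep)
        pts <- rbind(pts, cand)
      tries <- tries + 1
    }
    if (nrow(pts) < n_groups)
      stop("could not place lesions with the required separation")
    lesions <- list()
    for (i in seq_len(n_lesions)) {
      sac <- runif(1) < p_saccular
      reach <- runif(1) < p_reach
      incl <- if (sac) {
        if (reach) runif(1, 72, 82) else runif(1, 45, 58)
      } else {
        if (reach) runif(1, 36, 58) else runif(1, 30, 38)
      }
      lesions[[i]] <- plant_lesion(pts[i, ],
                                   shape = if (sac) "saccular" else "filiform",
                                   reaches_sub_rpe = reach, incl_deg = incl,
                                   azimuth_deg = runif(1, 0, 360))
    }
    if (merged_pair) {
      o <- pts[n_groups, ]
      # Two origins 120 um apart converging on a junction between them.
      og <- list(o + c(-60, 0), o + c(60, 0))
      jn <- c(o[1], o[2], 40)
      lesions <- c(lesions, merged_lesion_group(og, jn, group = 1L))
    }
    phantom_spec(shape = shape, spacing = spacing, lesions = lesions,
                 seed = seed, ...)
  })
}

# Evaluate code with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- rasterization helpers (physical um coordinates, axis order z,x,y) ----

# Voxel center of 1-based index i along an axis with spacing s: (i-1)*s um.

# Paint a tube (segment p0->p1, radius r) into `arr` (max-combined); also
# record voxel flat indices into the label array when lab/id given.
paint_tube <- function(arr, p0, p1, radius, value, spacing, lab = NULL, id = NULL) {
  d <- dim(arr)
  lo <- pmin(p0, p1) - radius
  hi <- pmax(p0, p1) + radius
  i0 <- pmax(1L, floor(lo / spacing) + 1L)
  i1 <- pmin(d, ceiling(hi / spacing) + 1L)
  if (any(i0 > i1)) return(list(arr = arr, lab = lab))
  zi <- i0[1]:i1[1]; xi <- i0[2]:i1[2]; yi <- i0[3]:i1[3]
  g <- expand.grid(z = zi, x = xi, y = yi)
  P <- cbind((g$z - 1) * spacing[1], (g$x - 1) * spacing[2], (g$y - 1) * spacing[3])
  u <- p1 - p0
  L2 <- sum(u^2)
  V <- sweep(P, 2, p0)
  tpar <- if (L2 > 0) pmin(1, pmax(0, as.vector(V %*% u) / L2))
          else numeric(nrow(P))
  closest <- outer(tpar, u)
  D2 <- rowSums((V - closest)^2)
  sel <- D2 <= radius^2
  if (any(sel)) {
    idx <- cbind(g$z[sel], g$x[sel], g$y[sel])
    arr[idx] <- pmax(arr[idx], value)
    if (!is.null(lab)) lab[idx] <- id
  }
  list(arr = arr, lab = lab)
}

paint_sphere <- function(arr, center, radius, value, spacing, lab = NULL, id = NULL) {
  paint_tube(arr, center, center, radius, value, spacing, lab, id)
}

# Does the capsule/sphere geometry fit inside the volume extent?
geometry_inside <- function(points, radius, extent) {
  lo <- apply(rbind(points), 2, min) - radius
  hi <- apply(rbind(points), 2, max) + radius
  all(lo >= 0) && all(hi <= extent)
}

# ---- generation ----

#' Generate a synthetic macular OCT/OCTA phantom
#'
#' Renders the structural volume as reflectivity bands (RPE brightest),
#' rasterizes plexus vessels and planted lesions into a clean flow volume,
#' adds closed-form projection tails and noise, and returns the paired
#' volumes together with the ground truth every downstream test uses.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `struct` ([struct_volume()]), `flow`
#'   ([flow_volume()]), and `truth` — a `phantom_truth` object holding the
#'   clean (tail- and noise-free) flow array, the tail field, a per-lesion
#'   label array, the [layer_surfaces()], and per-lesion truth rows
#'   (see [truth_lesion_table()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  sp <- spec$spacing
  extent <- (d - 1) * sp
  L <- spec$layers
  lv <- spec$struct_levels

  # Surfaces (um), lifted RPE under an optional PED dome.
  nx <- d[2]; ny <- d[3]
  xg <- ((seq_len(nx)) - 1) * sp[2]
  yg <- ((seq_len(ny)) - 1) * sp[3]
  rpe_um <- matrix(L$rpe, nx, ny)
  if (!is.null(spec$ped)) {
    r2 <- outer((xg - spec$ped$center_um[1])^2, (yg - spec$ped$center_um[2])^2, "+")
    rpe_um <- rpe_um - spec$ped$height_um * exp(-r2 / spec$ped$radius_um^2)
    if (any(rpe_um <= L$dvc_outer))
      stop("PED height lifts the RPE above the DVC boundary")
  }
  bm_um <- matrix(L$bm, nx, ny)
  dvc_um <- matrix(L$dvc_outer, nx, ny)
  surfaces <- layer_surfaces(dvc_um / sp[1] + 1, rpe_um / sp[1] + 1,
                             bm_um / sp[1] + 1)

  # Structural reflectivity bands.
  struct <- array(0, d)
  for (z in seq_len(d[1])) {
    zu <- (z - 1) * sp[1]
    m <- matrix(lv$background, nx, ny)
    m[zu >= L$ilm & zu < dvc_um] <- lv$inner
    m[zu >= dvc_um & zu < rpe_um] <- lv$outer
    m[zu >= rpe_um & zu < rpe_um + L$rpe_band] <- lv$rpe
    m[zu >= rpe_um + L$rpe_band & zu < bm_um] <- lv$ped_interior
    m[zu >= bm_um] <- lv$choroid
    struct[z, , ] <- m
  }

  # Clean flow: plexus vessels then lesions.
  clean <- array(0, d)
  lesion_labels <- array(0L, d)
  for (v in spec$vessels) {
    p0 <- c(v$depth_um, v$from_um)
    p1 <- c(v$depth_um, v$to_um)
    p0[2:3] <- pmin(pmax(p0[2:3], 0), extent[2:3])
    p1[2:3] <- pmin(pmax(p1[2:3], 0), extent[2:3])
    clean <- paint_tube(clean, p0, p1, v$radius_um, v$intensity, sp)$arr
  }

  truth_rows <- list()
  for (i in seq_along(spec$lesions)) {
    le <- spec$lesions[[i]]
    oxy <- le$origin_um
    ix <- pmin(pmax(round(oxy[1] / sp[2]) + 1, 1), nx)
    iy <- pmin(pmax(round(oxy[2] / sp[3]) + 1, 1), ny)
    oz <- dvc_um[ix, iy]
    p0 <- c(oz, oxy[1], oxy[2])                       # (z, x, y) um
    dirzxy <- c(le$direction[3], le$direction[1], le$direction[2])
    p1 <- p0 + dirzxy * le$length_um
    rmax <- max(le$radius_um, le$bulb_radius_um, na.rm = TRUE)
    if (!geometry_inside(rbind(p0, p1), rmax, extent))
      stop(sprintf("lesion %d extends outside the volume", i))
    if (le$shape == "saccular") {
      res <- paint_tube(clean, p0, p1, le$radius_um, le$intensity, sp,
                        lesion_labels, i)
      clean <- res$arr; lesion_labels <- res$lab
      res <- paint_sphere(clean, p1, le$bulb_radius_um, le$intensity, sp,
                          lesion_labels, i)
      clean <- res$arr; lesion_labels <- res$lab
    } else {
      res <- paint_tube(clean, p0, p1, le$radius_um, le$intensity, sp,
                        lesion_labels, i)
      clean <- res$arr; lesion_labels <- res$lab
    }
    if (!is.null(le$trunk)) {
      tr <- le$trunk
      t0 <- c(L$dvc_outer + tr$from_depth_um, tr$at_um)
      t1 <- c(L$dvc_outer + tr$to_depth_um, tr$at_um)
      if (!geometry_inside(rbind(t0, t1), tr$radius_um, extent))
        stop(sprintf("lesion %d trunk extends outside the volume", i))
      res <- paint_tube(clean, t0, t1, tr$radius_um, tr$intensity, sp,
                        lesion_labels, i)
      clean <- res$arr; lesion_labels <- res$lab
    }
    truth_rows[[i]] <- list(lesion = le, origin_zxy_um = p0, terminus_zxy_um = p1)
  }

  # Projection tails: decayed accumulation of the clean flow, gated by
  # reflectivity above background.
  tail_field <- array(0, d)
  decay <- exp(-sp[1] / spec$tail$tau_um)
  A <- matrix(0, nx, ny)
  for (z in seq_len(d[1])) {
    refl <- struct[z, , ]
    tl <- spec$tail$alpha * (refl / 255) * A
    tl[refl <= lv$background] <- 0
    tail_field[z, , ] <- tl
    A <- decay * (A + clean[z, , ])
  }

  # Noise + quantization.
  flow_sig <- clean + tail_field
  flow <- with_seed(spec$seed, {
    f <- flow_sig
    if (spec$noise$speckle_sd > 0) {
      pos <- f > 0
      f[pos] <- f[pos] * (1 + rnorm(sum(pos), 0, spec$noise$speckle_sd))
    }
    if (spec$noise$background_rate > 0) {
      bg <- runif(length(f)) < spec$noise$background_rate & f == 0
      f[bg] <- runif(sum(bg), 5, spec$noise$background_max)
    }
    st <- struct
    if (spec$noise$speckle_sd > 0)
      st <- st * (1 + rnorm(length(st), 0, spec$noise$speckle_sd))
    list(flow = f, struct = st)
  })
  struct_noisy <- pmin(pmax(round(flow$struct), 0), 255)
  flow_noisy <- pmin(pmax(round(flow$flow), 0), 255)

  truth <- structure(list(
    clean = pmin(pmax(round(clean), 0), 255),
    tail = tail_field,
    lesion_labels = lesion_labels,
    surfaces = surfaces,
    rows = truth_rows,
    spacing = sp,
    spec = spec), class = "phantom_truth")

  list(struct = struct_volume(array(struct_noisy, d), sp),
       flow = flow_volume(array(flow_noisy, d), sp),
       truth = truth)
}

#' Ground-truth lesion table of a phantom
#'
#' One row per planted lesion with the quantities the 3D characterization
#' should recover: origin/terminus voxel positions, true inclination to
#' the locally flat BM-parallel plane (degrees), planted shape class and
#' construction aspect ratio, sub-RPE contact, and merge group.
#'
#' @param truth `phantom_truth` from [generate_phantom()].
#' @return A `data.frame`.
#' @export
truth_lesion_table <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  sp <- truth$spacing
  rows <- lapply(seq_along(truth$rows), function(i) {
    tr <- truth$rows[[i]]
    le <- tr$lesion
    dirp <- le$direction / sqrt(sum(le$direction^2))  # (dx, dy, dz) physical
    incl <- asin(abs(dirp[3])) * 180 / pi
    # Sub-RPE contact from the realized mask: any voxel at/below the RPE.
    vox <- which(truth$lesion_labels == i, arr.ind = TRUE)
    reaches <- FALSE
    if (nrow(vox) > 0) {
      rpe_at <- truth$surfaces$rpe[vox[, 2:3, drop = FALSE]]
      reaches <- any(vox[, 1] >= rpe_at)
    }
    planted_e <- if (le$shape == "filiform") {
      le$length_um / (2 * le$radius_um)
    } else {
      (le$length_um + le$bulb_radius_um) / (2 * le$bulb_radius_um)
    }
    data.frame(id = i,
               shape = le$shape,
               origin_z = tr$origin_zxy_um[1] / sp[1] + 1,
               origin_x = tr$origin_zxy_um[2] / sp[2] + 1,
               origin_y = tr$origin_zxy_um[3] / sp[3] + 1,
               terminus_z = tr$terminus_zxy_um[1] / sp[1] + 1,
               length_um = le$length_um,
               radius_um = le$radius_um,
               bulb_radius_um = le$bulb_radius_um,
               inclination_deg = incl,
               planted_elongation = planted_e,
               reaches_sub_rpe = reaches,
               merge_group = le$merge_group,
               n_voxels = nrow(vox))
  })
  do.call(rbind, rows)
}
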