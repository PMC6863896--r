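# Hand-built isotropic test volume: surfaces in voxel units, spacing 2 um.
iso_vol <- function(arr) flow_volume(arr, spacing = c(2, 2, 2))
iso_surf <- function(nx, ny, dvc = 6, rpe = 50, bm = 55) {
  layer_surfaces(matrix(dvc, nx, ny), matrix(rpe, nx, ny), matrix(bm, nx, ny))
}

test_that("planted lesions are recovered with their origins", {
  spec <- small_phantom_spec(list(
    plant_lesion(c(300, 300), "filiform", azimuth_deg = 0),
    plant_lesion(c(650, 350), "saccular", reaches_sub_rpe = FALSE,
                 azimuth_deg = 90),
    plant_lesion(c(400, 700), "filiform", reaches_sub_rpe = FALSE,
                 azimuth_deg = 200)), seed = 41)
  ph <- generate_phantom(spec)
  corr <- remove_projection(ph$flow, ph$struct,
                            par_params(alpha = spec$tail$alpha,
                                       tau_um = spec$tail$tau_um))
  recs <- detect_lesions(corr, ph$truth$surfaces)
  expect_length(recs, 3)
  tt <- truth_lesion_table(ph$truth)
  for (i in 1:3) {
    d2 <- vapply(recs, function(r)
      sum((r$origin[2:3] - c(tt$origin_x[i], tt$origin_y[i]))^2), numeric(1))
    j <- which.min(d2)
    expect_lte(abs(recs[[j]]$origin[2] - tt$origin_x[i]), 1.5)
    expect_lte(abs(recs[[j]]$origin[3] - tt$origin_y[i]), 1.5)
    expect_lte(abs(recs[[j]]$origin[1] - tt$origin_z[i]), 1.5)
  }
  # Disjoint lesions do not share merge groups.
  expect_length(unique(vapply(recs, `[[`, integer(1), "merge_group")), 3)
})

test_that("flow confined to the DVC band yields no lesion records", {
  spec <- small_phantom_spec(list(), seed = 7)   # vessels only
  ph <- generate_phantom(spec)
  recs <- detect_lesions(ph$truth$clean, ph$truth$surfaces,
                         spacing = spec$spacing)
  expect_length(recs, 0)
  # And an empty volume is an empty list, not an error.
  empty <- flow_volume(array(0L, c(128, 100, 100)))
  expect_length(detect_lesions(empty, ph$truth$surfaces), 0)
})

test_that("lesions merging into one trunk split into records sharing a merge group", {
  lesions <- merged_lesion_group(
    list(c(380, 500), c(500, 620), c(620, 500)),
    junction_um = c(500, 500, 40), group = 1L)
  spec <- small_phantom_spec(lesions, seed = 17)
  ph <- generate_phantom(spec)
  corr <- remove_projection(ph$flow, ph$struct,
                            par_params(alpha = spec$tail$alpha,
                                       tau_um = spec$tail$tau_um))
  recs <- detect_lesions(corr, ph$truth$surfaces)
  expect_length(recs, 3)
  groups <- vapply(recs, `[[`, integer(1), "merge_group")
  expect_length(unique(groups), 1)
  expect_true(all(vapply(recs, `[[`, integer(1),
                         "n_origins_in_component") == 3))
})

test_that("elongation separates tubes from bulb-dominated lesions by construction", {
  # Straight vertical tube, 100 um long, 5 um radius -> strongly filiform.
  arr <- array(0L, c(60, 30, 30))
  for (z in 7:57) {
    for (x in 13:17) for (y in 13:17) {
      if ((x - 15)^2 + (y - 15)^2 <= (5 / 2)^2) arr[z, x, y] <- 200L
    }
  }
  recs <- detect_lesions(iso_vol(arr), iso_surf(30, 30), min_voxels = 10)
  expect_length(recs, 1)
  cls <- classify_shape(recs[[1]])
  expect_equal(as.character(cls), "filiform")
  expect_gt(attr(cls, "elongation"), 5)

  # Short stalk ending in a dominant bulb -> saccular.
  arr2 <- array(0L, c(60, 40, 40))
  cz <- 20; cx <- 20; cy <- 20; R <- 8   # 16 um bulb radius
  for (z in 7:(cz + R)) for (x in (cx - R):(cx + R)) for (y in (cy - R):(cy + R)) {
    in_bulb <- (z - cz)^2 + (x - cx)^2 + (y - cy)^2 <= R^2
    in_stalk <- z <= cz & abs(x - cx) <= 2 & abs(y - cy) <= 2
    if (in_bulb || in_stalk) arr2[z, x, y] <- 200L
  }
  recs2 <- detect_lesions(iso_vol(arr2), iso_surf(40, 40), min_voxels = 10)
  expect_length(recs2, 1)
  cls2 <- classify_shape(recs2[[1]])
  expect_equal(as.character(cls2), "saccular")
  expect_lt(attr(cls2, "elongation"), 3)

  # Degenerate single-voxel record cannot be classified.
  bad <- structure(list(voxels = matrix(c(5L, 5L, 5L), 1),
                        length_um = 0, mean_radius_um = 1),
                   class = "lesion_record")
  expect_error(classify_shape(bad), "degenerate")
})

test_that("orientation recovers perpendicular, in-plane and oblique axes", {
  # Vertical tube on a flat BM: inclination 90.
  arr <- array(0L, c(60, 30, 30))
  arr[7:50, 14:16, 14:16] <- 200L
  recs <- detect_lesions(iso_vol(arr), iso_surf(30, 30), min_voxels = 10)
  ori <- orientation(recs[[1]], iso_surf(30, 30))
  expect_gt(ori$inclination_deg, 85)
  expect_lt(ori$axis_angles_deg["z"], 5)

  # Horizontal tube just below the DVC: inclination near 0.
  arr2 <- array(0L, c(60, 40, 40))
  arr2[7:9, 5:35, 19:21] <- 200L
  recs2 <- detect_lesions(iso_vol(arr2), iso_surf(40, 40),
                          min_voxels = 10, min_depth_um = 2)
  ori2 <- orientation(recs2[[1]], iso_surf(40, 40))
  expect_lt(ori2$inclination_deg, 5)
  expect_lt(ori2$axis_angles_deg["x"], 10)

  # Planted 35-degree lesion on a flat BM recovered within 5 degrees.
  spec <- small_phantom_spec(list(
    plant_lesion(c(500, 500), "filiform", reaches_sub_rpe = FALSE,
                 incl_deg = 35, azimuth_deg = 55)), seed = 19)
  ph <- generate_phantom(spec)
  corr <- remove_projection(ph$flow, ph$struct,
                            par_params(alpha = spec$tail$alpha,
                                       tau_um = spec$tail$tau_um))
  recs3 <- detect_lesions(corr, ph$truth$surfaces)
  ori3 <- orientation(recs3[[1]], ph$truth$surfaces)
  expect_lt(abs(ori3$inclination_deg - 35), 5)
})

test_that("sub-RPE contact flags reflect the planted geometry", {
  spec <- small_phantom_spec(list(
    plant_lesion(c(350, 350), "filiform", reaches_sub_rpe = TRUE),
    plant_lesion(c(650, 650), "filiform", reaches_sub_rpe = FALSE)), seed = 23)
  ph <- generate_phantom(spec)
  corr <- remove_projection(ph$flow, ph$struct,
                            par_params(alpha = spec$tail$alpha,
                                       tau_um = spec$tail$tau_um))
  recs <- detect_lesions(corr, ph$truth$surfaces)
  expect_length(recs, 2)
  flags <- vapply(recs, sub_rpe_contact, logical(1),
                  surfaces = ph$truth$surfaces)
  xs <- vapply(recs, function(r) r$origin[2], numeric(1))
  expect_true(flags[which.min(abs(xs - 36))])    # origin 350 um -> x ~ 36
  expect_false(flags[which.min(abs(xs - 66))])
})

test_that("shape classification is invariant to rotation about the axial axis", {
  for (shp in c("filiform", "saccular")) {
    cls <- character(0)
    for (az in c(0, 137)) {
      spec <- small_phantom_spec(list(
        plant_lesion(c(500, 500), shp, reaches_sub_rpe = FALSE,
                     azimuth_deg = az)), seed = 29)
      ph <- generate_phantom(spec)
      corr <- remove_projection(ph$flow, ph$struct,
                                par_params(alpha = spec$tail$alpha,
                                           tau_um = spec$tail$tau_um))
      recs <- detect_lesions(corr, ph$truth$surfaces)
      expect_length(recs, 1)
      cls <- c(cls, as.character(classify_shape(recs[[1]])))
    }
    expect_equal(cls[1], cls[2])
    expect_equal(cls[1], shp)
  }
})

test_that("the 3D count is never below the 2D en face count on phantoms", {
  for (sd in c(3, 19)) {
    spec <- small_phantom_spec(list(
      plant_lesion(c(350, 350), "filiform"),
      plant_lesion(c(650, 650), "filiform", reaches_sub_rpe = FALSE,
                   azimuth_deg = 180)), seed = sd)
    ph <- generate_phantom(spec)
    res <- analyze_volume(ph$flow, ph$struct, ph$truth$surfaces)
    expect_gte(res$n_3d, res$n_2d)
  }
})
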