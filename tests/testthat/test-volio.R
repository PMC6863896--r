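test_that("raw volumes round-trip bit-exactly and honor the byte layout", {
  tmp <- tempfile(fileext = ".raw")
  on.exit(unlink(tmp))

  # Identity layout: bytes 0..7 into a 2x2x2 grid, axial index fastest.
  writeBin(as.raw(0:7), tmp)
  v <- read_raw_volume(tmp, shape = c(2, 2, 2))
  expect_equal(v$data[1, 1, 1], 0L)
  expect_equal(v$data[2, 2, 2], 7L)
  expect_equal(v$data[2, 1, 1], 1L)  # axial-fastest

  # Round trip on a random volume.
  set.seed(42)
  arr <- array(sample(0:255, 5 * 4 * 3, replace = TRUE), c(5, 4, 3))
  v2 <- flow_volume(arr)
  write_raw_volume(v2, tmp)
  back <- read_raw_volume(tmp, shape = c(5, 4, 3))
  expect_identical(back$data, v2$data)

  # Re-serializing gives identical bytes.
  tmp2 <- tempfile(fileext = ".raw")
  on.exit(unlink(tmp2), add = TRUE)
  write_raw_volume(back, tmp2)
  expect_identical(readBin(tmp, "raw", 100), readBin(tmp2, "raw", 100))

  # All-zero volume: exactly prod(shape) zero bytes.
  write_raw_volume(flow_volume(array(0L, c(4, 4, 4))), tmp)
  expect_equal(file.size(tmp), 64)
  expect_true(all(readBin(tmp, "raw", 64) == as.raw(0)))
})

test_that("raw reader rejects size mismatches with the byte counts", {
  tmp <- tempfile(fileext = ".raw")
  on.exit(unlink(tmp))
  writeBin(as.raw(seq_len(100) %% 256), tmp)
  expect_error(read_raw_volume(tmp, shape = c(2, 2, 2)),
               "expected 8 bytes.*got 100")
})

test_that("reorient matches the exhaustive index oracle and inverts cleanly", {
  a <- array(seq_len(3 * 4 * 5), c(3, 4, 5))

  # Identity permutation leaves the grid unchanged.
  expect_identical(reorient(a, perm = c(1, 2, 3))$data, a)

  # Axial on the last axis; permutation (3,1,2): voxel (i,j,k) of the
  # input must land at (k,i,j). Checked voxel by voxel.
  out <- reorient(a, perm = c(3, 1, 2))$data
  expect_equal(dim(out), c(5, 3, 4))
  for (i in 1:3) for (j in 1:4) for (k in 1:5)
    expect_equal(out[k, i, j], a[i, j, k])

  # Double flip on z is the identity.
  f1 <- reorient(a, flip = c(TRUE, FALSE, FALSE))$data
  f2 <- reorient(f1, flip = c(TRUE, FALSE, FALSE))$data
  expect_identical(f2, a)

  expect_error(reorient(a, perm = c(1, 1, 3)), "permutation")
})

test_that("reorient composed with its inverse is the identity on random grids", {
  set.seed(7)
  for (rep in 1:8) {
    arr <- array(sample(0:255, 3 * 4 * 5, replace = TRUE), c(3, 4, 5))
    perm <- sample(1:3)
    flip <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    fwd <- reorient(arr, perm = perm, flip = flip)$data
    inv <- invert_orientation(perm, flip)
    back <- reorient(fwd, perm = inv$perm, flip = inv$flip)$data
    expect_identical(back, arr)
  }
})

test_that("TIFF stacks round-trip losslessly with one page per depth", {
  set.seed(11)
  arr <- array(sample(0:255, 6 * 8 * 7, replace = TRUE), c(6, 8, 7))
  v <- flow_volume(arr)
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  write_tiff_stack(v, tmp)
  back <- read_tiff_stack(tmp)
  expect_identical(back$data, v$data)

  # Page count equals the axial extent.
  pages <- tiff::readTIFF(tmp, all = TRUE)
  expect_length(pages, 6)
  # Page i is the en face plane at depth i.
  expect_equal(round(pages[[3]] * 255), arr[3, , ], ignore_attr = TRUE)

  # raw -> tiff -> raw chain is bit-identical.
  rawf <- tempfile(fileext = ".raw")
  on.exit(unlink(rawf), add = TRUE)
  write_raw_volume(back, rawf)
  again <- read_raw_volume(rawf, shape = dim(arr))
  expect_identical(again$data, arr + 0L)

  # Single-page stack -> volume with z = 1.
  v1 <- flow_volume(array(5L, c(1, 4, 4)))
  write_tiff_stack(v1, tmp)
  expect_equal(dim(read_tiff_stack(tmp)$data), c(1, 4, 4))
})

test_that("layer surfaces validate ordering and round-trip through CSV", {
  nx <- 6; ny <- 5
  s <- layer_surfaces(matrix(10, nx, ny), matrix(20.5, nx, ny),
                      matrix(22, nx, ny))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_surfaces_csv(s, tmp)
  back <- read_surfaces_csv(tmp)
  expect_equal(back$rpe, s$rpe)
  expect_equal(back$bm, s$bm)

  expect_error(layer_surfaces(matrix(20, 2, 2), matrix(10, 2, 2),
                              matrix(30, 2, 2)), "dvc_outer < rpe")
})
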