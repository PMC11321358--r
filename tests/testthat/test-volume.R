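straight_path <- function() polyline3(rbind(c(10, 25, 25), c(50, 25, 25)))

test_that("rasterization marks exactly the voxels within the tube radius", {
  path <- straight_path()
  vol <- empty_volume(c(0, 0, 0), c(60, 50, 50), spacing = 1, background = 40)
  ras <- rasterize_nerve(path, vol)
  idx <- which(ras$data == 900, arr.ind = TRUE)
  d <- points_polyline_distance(voxel_to_world(ras, idx), path)
  expect_true(all(d <= 2.5))
  # no voxel within the radius was missed
  all_idx <- which(ras$data != 900, arr.ind = TRUE)
  d_out <- points_polyline_distance(voxel_to_world(ras, all_idx), path)
  expect_true(all(d_out > 2.5))
  # background preserved away from the tube
  expect_equal(ras$data[1, 1, 1], 40)
  # labeled count matches the analytic cylinder-plus-caps volume within
  # discretization error
  expected <- pi * 2.5^2 * 40 + 4 / 3 * pi * 2.5^3
  expect_lt(abs(nrow(idx) - expected) / expected, 0.1)
})

test_that("rasterization is idempotent and rejects out-of-bounds paths", {
  path <- straight_path()
  vol <- empty_volume(c(0, 0, 0), c(60, 50, 50), spacing = 1, background = 40)
  once <- rasterize_nerve(path, vol)
  twice <- rasterize_nerve(path, once)
  expect_identical(once$data, twice$data)
  expect_error(
    rasterize_nerve(polyline3(rbind(c(1, 25, 25), c(50, 25, 25))), vol),
    "exits the volume")
})

test_that("threshold segmentation recovers exactly the written voxel set", {
  vol <- empty_volume(c(0, 0, 0), c(30, 30, 30), spacing = 1, background = 0)
  expect_equal(nrow(segment_hu_threshold(vol)$indices), 0L)
  ras <- rasterize_nerve(polyline3(rbind(c(10, 15, 15), c(20, 15, 15))), vol)
  seg <- segment_hu_threshold(ras)
  written <- which(ras$data == 900, arr.ind = TRUE)
  expect_equal(nrow(seg$indices), nrow(written))
  expect_true(all(ras$data[seg$indices] == 900))
  expect_equal(nrow(segment_hu_threshold(ras, hu_min = 901)$indices), 0L)
})

test_that("centerline extraction flags degenerate and disconnected input", {
  vol <- empty_volume(c(0, 0, 0), c(10, 10, 10), spacing = 1)
  single <- voxel_set(matrix(c(3L, 3L, 3L), 1), vol)
  out <- extract_centerline(single)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_equal(nrow(out), 1L)

  two_blobs <- voxel_set(rbind(c(1L, 1L, 1L), c(9L, 9L, 9L)), vol)
  expect_error(extract_centerline(two_blobs), "2 components")
})

test_that("centerline of straight and curved tubes stays within a voxel diagonal", {
  path <- straight_path()
  vol <- empty_volume(c(0, 0, 0), c(60, 50, 50), spacing = 1, background = 40)
  seg <- segment_hu_threshold(rasterize_nerve(path, vol))
  cl <- extract_centerline(seg)
  expect_lt(polyline_hausdorff(path, cl), sqrt(3))
  # collinearity with the generating line
  dev <- points_polyline_distance(unclass(cl), path)
  expect_lt(max(dev), sqrt(3) / 2)

  # smooth curve, curvature radius 20 mm
  tt <- seq(0, 1, length.out = 40)
  curved <- polyline3(cbind(30 + 20 * sin(2 * tt), 25 + 20 * (1 - cos(2 * tt)), 25 + 10 * tt))
  vol2 <- empty_volume(c(5, 5, 5), c(75, 70, 50), spacing = 1, background = 40)
  cl2 <- extract_centerline(segment_hu_threshold(rasterize_nerve(curved, vol2)))
  expect_lt(polyline_hausdorff(curved, cl2), sqrt(3))
})

test_that("round-trip distance error is bounded and shrinks with voxel size", {
  path <- straight_path()
  sites <- rbind(c(30, 45, 25), c(5, 25, 55), c(55, 45, 45))
  errs <- vapply(c(2, 1, 0.5, 0.25), function(sp) {
    vol <- empty_volume(c(0, 0, 0), c(60, 50, 50), spacing = sp, background = 40)
    max(roundtrip_distance_error(path, vol, sites)$error_mm)
  }, numeric(1))
  diag_mm <- sqrt(3) * c(2, 1, 0.5, 0.25)
  expect_true(all(errs <= diag_mm))
  expect_lte(errs[4], 0.5)              # fine-resolution limit
  expect_lt(errs[4], errs[1])           # coarse-to-fine improvement

  vol <- empty_volume(c(0, 0, 0), c(60, 50, 50), spacing = 1, background = 40)
  empty_sites <- roundtrip_distance_error(path, vol, matrix(numeric(0), 0, 3))
  expect_length(empty_sites$error_mm, 0)
})

test_that("volumes and voxel sets survive their file formats", {
  vol <- empty_volume(c(0, 0, 0), c(12, 10, 8), spacing = c(1, 1.5, 2), background = -1000)
  vol$data[3, 4, 2] <- 900
  tmp <- tempfile(fileext = ".nii.gz")
  write_hu_volume(vol, tmp)
  back <- read_hu_volume(tmp)
  expect_equal(dim(back$data), dim(vol$data))
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_equal(back$data[3, 4, 2], 900)

  seg <- segment_hu_threshold(vol)
  tmp2 <- tempfile(fileext = ".csv")
  write_voxel_set_csv(seg, tmp2)
  expect_equal(as.integer(as.matrix(utils::read.csv(tmp2))), as.integer(seg$indices))
})
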