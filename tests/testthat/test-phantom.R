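test_that("phantom generation is deterministic and labels are complete", {
  spec <- phantom_spec(voxel_size = 1.5, grid_shape = c(38, 35, 32))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_setequal(unique(as.vector(fx_phantom()$volume$labels)), 0:5)
})

test_that("voxelised tissue volumes match the analytic ground truth", {
  ph <- fx_phantom()
  vv <- voxel_volumes(ph$volume)
  gt <- ph$ground_truth$volumes_cm3 * 1000
  cavity_vox <- vv[["fat"]] + vv[["muscle"]] + vv[["bulbus"]]
  expect_lt(abs(cavity_vox / gt[["cavity"]] - 1), 0.02)
  expect_lt(abs(vv[["bulbus"]] / gt[["bulbus"]] - 1), 0.02)
  # sector areas are positive and sum to the tissue-contact wall area
  sa <- ph$ground_truth$sector_areas_cm2
  expect_true(all(sa > 0))
  expect_equal(sum(sa), ph$ground_truth$total_wall_area_cm2)
})

test_that("a 12 mm bulbus voxelised at 0.5 mm recovers the sphere volume", {
  spec <- phantom_spec(voxel_size = 0.5, grid_shape = c(112, 104, 96),
                       bulbus_radius = 12, bulbus_center = c(0, 27, 0))
  ph <- generate_phantom(spec)
  vb <- voxel_volumes(ph$volume)[["bulbus"]]
  expect_lt(abs(vb / (4 / 3 * pi * 12^3) - 1), 0.02)
})

test_that("muscle_count = 0 leaves no muscle voxels", {
  spec <- phantom_spec(voxel_size = 1.5, grid_shape = c(38, 35, 32),
                       muscle_count = 0L)
  ph <- generate_phantom(spec)
  expect_false(any(ph$volume$labels == 3L))
  expect_equal(unname(ph$ground_truth$volumes_cm3[["muscle"]]), 0)
})

test_that("halving the voxel size reduces the volume error of every tissue", {
  coarse <- generate_phantom(phantom_spec(voxel_size = 1.0))
  fine <- generate_phantom(phantom_spec(voxel_size = 0.5,
                                        grid_shape = c(112, 104, 96)))
  gt <- coarse$ground_truth$volumes_cm3 * 1000
  for (t in c("fat", "muscle", "bulbus", "bone", "temporalis")) {
    e1 <- abs(voxel_volumes(coarse$volume)[[t]] - gt[[t]])
    e2 <- abs(voxel_volumes(fine$volume)[[t]] - gt[[t]])
    expect_lt(e2, e1)
  }
})

test_that("bone seals the orbit: no fat-to-background path avoids bone", {
  spec <- phantom_spec(voxel_size = 1.5, grid_shape = c(38, 35, 32))
  ph <- generate_phantom(spec)
  expect_true(cavity_sealed(ph$volume))
  # breaching the wall breaks the seal (sanity of the checker itself)
  breached <- ph$volume
  lab <- breached$labels
  lab[lab == 1L] <- 0L
  breached$labels <- lab
  expect_false(cavity_sealed(breached))
})

test_that("geometrically inconsistent specs are rejected with diagnostics", {
  expect_error(phantom_spec(bulbus_radius = 18), "bulbus")
  expect_error(phantom_spec(wall_region_angles = c(lateral = 120, floor = 90,
                                                   medial = 90, roof = 90)),
               "360")
  expect_error(phantom_spec(voxel_size = -1), "non-positive")
  expect_error(phantom_spec(grid_shape = c(20, 20, 20)),
               "grid does not contain")
})

test_that("labelmap NIfTI round-trip is exact", {
  spec <- phantom_spec(voxel_size = 1.5, grid_shape = c(38, 35, 32))
  ph <- generate_phantom(spec)
  f <- tempfile(fileext = ".nii.gz")
  save_labelmap(ph$volume, f)
  back <- load_labelmap(f)
  expect_identical(back$labels, ph$volume$labels)
  expect_identical(back$voxel_size, ph$volume$voxel_size)
  expect_identical(back$origin, ph$volume$origin)
})

test_that("unknown label codes are rejected and empty volumes warned about", {
  arr <- array(0L, c(6, 6, 6)); arr[3, 3, 3] <- 9L
  expect_error(label_volume(arr, 1), "9")
  expect_warning(label_volume(array(0L, c(6, 6, 6)), 1), "no tissue labels")
})

test_that("phantom specs round-trip through YAML", {
  spec <- phantom_spec(voxel_size = 1.5, grid_shape = c(38, 35, 32),
                       bulbus_radius = 9.5)
  f <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, f)
  back <- read_phantom_spec(f)
  expect_equal(back, spec)
})
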