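test_that("a voxelised sphere surface recovers the analytic area and volume", {
  vol <- sphere_volume(r = 12, h = 0.5)
  sm <- extract_surfaces(vol, 4L)
  expect_true(surface_is_closed(sm))
  expect_lt(abs(surface_area(sm) / (4 * pi * 12^2) - 1), 0.03)
  expect_lt(abs(surface_enclosed_volume(sm) / (4 / 3 * pi * 12^3) - 1), 0.02)
})

test_that("a full cube mask yields a closed box with the right volume", {
  vol <- cube_volume(h = 0.5)
  sm <- extract_surfaces(vol, 2L)
  expect_true(surface_is_closed(sm))
  expect_gte(nrow(sm$triangles), 12L)
  expect_lt(abs(surface_enclosed_volume(sm) / 1000 - 1), 0.02)
})

test_that("requesting an absent label is an error naming the label", {
  vol <- cube_volume()
  expect_error(extract_surfaces(vol, 5L), "5")
})

test_that("extracted surfaces are outward oriented", {
  # positive enclosed volume is the divergence-theorem signature of
  # outward orientation
  vol <- sphere_volume(r = 8, h = 1)
  sm <- extract_surfaces(vol, 4L)
  expect_gt(surface_enclosed_volume(sm), 0)
})
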