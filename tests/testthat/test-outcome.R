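slab_sdf <- function(p) p[, 3] - 10   # cavity = half space z <= 10

test_that("zero displacement releases zero volume", {
  bm <- tet_mesh_box(c(20, 20, 10), c(8, 8, 4))
  expect_equal(released_volume(bm, zero_field(bm), slab_sdf, pitch = 0.5), 0)
  expect_equal(proptosis_change(fx_mesh2(), zero_field(fx_mesh2())), 0)
})

test_that("a rigidly translated slab releases area times travel", {
  bm <- tet_mesh_box(c(20, 20, 10), c(8, 8, 4))
  fld <- uniform_field(bm, c(0, 0, 5))   # A = 4 cm^2, t = 0.5 cm -> 2 cm^3
  expect_lt(abs(released_volume(bm, fld, slab_sdf, pitch = 0.5) / 2 - 1), 0.01)
  expect_lt(abs(released_volume(bm, fld, slab_sdf, mode = "flux") / 2 - 1), 0.01)
  expect_lt(abs(released_volume_bruteforce(bm, fld, slab_sdf, pitch = 0.5) / 2 - 1),
            0.01)
})

test_that("the voxel estimate self-converges under pitch refinement", {
  m <- fx_mesh2()
  fld <- fx_lava_field()
  reg <- fx_phantom()$ground_truth$orbit_region
  v1 <- released_volume(m, fld, reg, pitch = 1.0)
  v2 <- released_volume(m, fld, reg, pitch = 0.5)
  expect_lt(abs(v1 / v2 - 1), 0.01)
})

test_that("rasterisation and brute-force counting agree on the phantom", {
  m <- fx_mesh2()
  fld <- fx_lava_field()
  reg <- fx_phantom()$ground_truth$orbit_region
  v_fast <- released_volume(m, fld, reg, pitch = 1.0)
  v_brute <- released_volume_bruteforce(m, fld, reg, pitch = 1.0)
  expect_lt(abs(v_fast / v_brute - 1), 0.01)
})

test_that("released volume is non-decreasing in intraorbital pressure", {
  fit <- fx_fit()
  vols <- vapply(c(0.1, 0.25, 0.4), function(p) {
    plan <- fit$plan; plan$pressure_kPa <- p
    fld <- simulate_scenario(fit$mesh, plan,
                             orbdecomp:::materials_from_params(
                               c(E_muscle_ratio = 4, nu = 0.45)),
                             n_steps = 2)
    released_volume(fit$mesh, fld, fit$region, mode = "sample")
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("proptosis change matches direct front-pole tracking", {
  m <- fx_mesh2()
  # uniform posterior translation of everything: bulbus recedes by 2 mm
  expect_equal(proptosis_change(m, uniform_field(m, c(0, -2, 0))), 2)
  # oracle on a mixed field: brute force over bulbus nodes
  fld <- fx_lava_field()
  bn <- unique(as.vector(m$tets[m$tet_label == 4L, ]))
  oracle <- max(m$nodes[bn, 2]) - max(m$nodes[bn, 2] + fld$u[bn, 2])
  expect_equal(proptosis_change(m, fld), oracle, tolerance = 1e-12)
})

test_that("comparison arithmetic is exact", {
  rep1 <- structure(list(scenario = "a", area_cm2 = 10, released_cm3 = 2,
                         volume_per_area = 0.2, proptosis_mm = 1,
                         per_tissue_cm3 = list()), class = "outcome_report")
  rep2 <- rep1; rep2$scenario <- "b"
  cmp <- compare_scenarios(list(rep1, rep2))
  expect_equal(unname(cmp$ratio_of_ratios["a", "b"]), 1)
  rep3 <- rep1; rep3$scenario <- "c"; rep3$area_cm2 <- 20
  rep3$volume_per_area <- rep3$released_cm3 / rep3$area_cm2
  cmp2 <- compare_scenarios(list(rep1, rep3))
  expect_equal(unname(cmp2$ratio_of_ratios["c", "a"]), 0.5)
  expect_error(compare_scenarios(list(rep1)), "two")
})

test_that("outcome reports carry consistent ratios and breakdowns", {
  m <- fx_mesh2()
  rep <- outcome_report("lava", m, fx_lava_field(),
                        fx_phantom()$ground_truth$orbit_region, pitch = 1.0)
  expect_equal(rep$volume_per_area, rep$released_cm3 / rep$area_cm2)
  expect_gte(rep$released_cm3, 0)
  expect_equal(sum(unlist(rep$per_tissue_cm3)), rep$released_cm3,
               tolerance = 1e-9)
})

test_that("field/mesh mismatches are rejected", {
  bm <- tet_mesh_box(c(10, 10, 10), 2)
  bad <- displacement_field(matrix(0, 5, 3))
  expect_error(released_volume(bm, bad, slab_sdf), "nodes")
})
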