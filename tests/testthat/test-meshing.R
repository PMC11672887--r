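test_that("an all-fat cube labelmap meshes to the exact volume", {
  vol <- cube_volume(h = 0.5)
  mesh <- build_tet_mesh(vol)
  expect_lt(abs(sum(tet_volumes(mesh)) / 1000 - 1), 0.01)
  expect_true(all(tet_volumes(mesh) > 0))
})

test_that("every boundary facet of the phantom mesh carries exactly one tag", {
  mesh <- fx_mesh2()
  expect_equal(length(mesh$boundary$tag), nrow(mesh$boundary$facets))
  expect_true(all(mesh$boundary$tag %in%
                    c("LATERAL_WALL", "FLOOR_WALL", "MEDIAL_WALL",
                      "ROOF_WALL", "APEX_FIXED", "ANTERIOR_FREE")))
  # the facet set covers the mesh boundary exactly once
  bf <- orbdecomp:::boundary_faces(mesh$nodes, mesh$tets)
  expect_equal(nrow(bf$facets), nrow(mesh$boundary$facets))
})

test_that("refinement increases node count and decreases max tet volume", {
  ph <- fx_phantom()
  coarse <- build_tet_mesh(ph$volume, target_edge = 4)
  fine <- fx_mesh2()
  expect_gt(nrow(fine$nodes), nrow(coarse$nodes))
  expect_lt(max(tet_volumes(fine)), max(tet_volumes(coarse)))
})

test_that("per-tissue mesh volumes track the voxel volumes at default resolution", {
  mesh <- fx_mesh1()
  mv <- mesh_tissue_volumes(mesh)
  vv <- voxel_volumes(fx_phantom()$volume)
  for (t in c("fat", "muscle", "bulbus"))
    expect_lt(abs(mv[[t]] / vv[[t]] - 1), 0.03)
})

test_that("tet labels agree with the labelmap at tet centroids", {
  mesh <- fx_mesh1()
  tt <- mesh$tets
  cen <- (mesh$nodes[tt[, 1], ] + mesh$nodes[tt[, 2], ] +
            mesh$nodes[tt[, 3], ] + mesh$nodes[tt[, 4], ]) / 4
  lab <- orbdecomp:::label_at(fx_phantom()$volume, cen)
  expect_gte(mean(lab == mesh$tet_label), 0.99)
})

test_that("mesh_quality reports the regular tetrahedron exactly", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  q <- mesh_quality(list(nodes = v, tets = matrix(c(1, 2, 4, 3), 1)))
  expect_equal(q$min_dihedral_deg, acos(1 / 3) * 180 / pi, tolerance = 1e-10)
  expect_equal(q$max_aspect, 1, tolerance = 1e-10)
  expect_equal(q$n_inverted, 0L)
})

test_that("inverted tets are detected and rejected", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  q <- mesh_quality(list(nodes = v, tets = matrix(c(1, 3, 2, 4), 1)))
  expect_equal(q$n_inverted, 1L)
  expect_error(tissue_mesh(v, matrix(c(1, 3, 2, 4), 1), 2L,
                           boundary = list(facets = matrix(1:3, 1),
                                           tag = "APEX_FIXED", tet = 1L)),
               "non-positive")
})

test_that("the accepted phantom mesh has no inverted tets", {
  q <- mesh_quality(fx_mesh2())
  expect_equal(q$n_inverted, 0L)
  expect_gt(q$min_dihedral_deg, 1)
})

test_that("structured box and shell fixtures are valid and exactly sized", {
  bm <- tet_mesh_box(c(10, 10, 10), 4)
  expect_equal(sum(tet_volumes(bm)), 1000)
  expect_equal(sort(unique(bm$boundary$tag)),
               sort(c("MEDIAL_WALL", "LATERAL_WALL", "APEX_FIXED",
                      "ANTERIOR_FREE", "FLOOR_WALL", "ROOF_WALL")))
  sh <- tet_mesh_sphere_shell(10, 20, n = 8, nr = 4)
  expect_true(all(tet_volumes(sh) > 0))
  expect_setequal(unique(sh$boundary$tag),
                  c("INNER", "OUTER", "SYMM_X", "SYMM_Y", "SYMM_Z"))
  # octant shell volume converges to pi/6 (b^3 - a^3) from below
  expect_lt(abs(sum(tet_volumes(sh)) / (pi / 6 * (20^3 - 10^3)) - 1), 0.05)
})
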