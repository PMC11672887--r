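mats_unit <- material_params(E = c(fat = 1), nu = c(fat = 0.3))

test_that("the assembled operator is symmetric and linear in E", {
  bm <- tet_mesh_box(c(10, 10, 10), 2)
  K1 <- assemble(bm, mats_unit)$K
  expect_lt(max(abs(K1 - Matrix::t(K1))), 1e-12 * max(abs(K1@x)))
  K2 <- assemble(bm, material_params(E = c(fat = 2), nu = c(fat = 0.3)))$K
  expect_equal(as.matrix(K2), 2 * as.matrix(K1), tolerance = 1e-12)
})

test_that("the unconstrained stiffness has exactly the six rigid-body modes", {
  bm <- tet_mesh_box(c(10, 8, 12), 2)          # 81 dof
  sys <- assemble(bm, mats_unit)
  ev <- eigen(as.matrix(sys$K), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6L)
})

test_that("zero loads and zero Dirichlet give the zero field", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  bnodes <- sort(unique(as.vector(bm$boundary$facets)))
  bc <- bc_fix_nodes(boundary_conditions(bm), bnodes, c(0, 0, 0))
  fld <- solve_elastic(assemble(bm, mats_unit), bc, bm)
  expect_equal(max(abs(fld$u)), 0)
})

test_that("affine Dirichlet data is reproduced exactly at interior nodes", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  A <- matrix(c(0.01, 0.002, 0, 0.003, -0.01, 0.004, 0, 0.005, 0.02),
              3, 3, byrow = TRUE)
  b <- c(0.1, -0.2, 0.05)
  uaff <- t(A %*% t(bm$nodes)) + matrix(b, nrow(bm$nodes), 3, byrow = TRUE)
  bnodes <- sort(unique(as.vector(bm$boundary$facets)))
  bc <- bc_fix_nodes(boundary_conditions(bm), bnodes, uaff[bnodes, ])
  fld <- solve_elastic(assemble(bm, mats_unit), bc, bm)
  expect_lt(max(abs(fld$u - uaff)) / max(abs(uaff)), 1e-10)
})

test_that("an unconstrained solve names the free rigid-body mode", {
  bm <- tet_mesh_box(c(10, 10, 10), 2)
  bc <- boundary_conditions(bm)  # nothing fixed
  bc <- bc_pressure(bc, seq_len(nrow(bm$boundary$facets)), 0.1)
  # CHOLMOD emits its own non-positive-definite warning before our error
  suppressWarnings(
    expect_error(solve_elastic(assemble(bm, mats_unit), bc, bm),
                 "singular|rigid-body"))
})

test_that("Dirichlet values are reproduced exactly under loads", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  tg <- bm$boundary$tag
  fixed <- sort(unique(as.vector(bm$boundary$facets[tg == "APEX_FIXED", ])))
  bc <- bc_fix_nodes(boundary_conditions(bm), fixed, c(0.5, 0, -0.25))
  bc <- bc_pressure(bc, which(tg == "ANTERIOR_FREE"), 0.2)
  fld <- solve_elastic(assemble(bm, mats_unit), bc, bm)
  expect_equal(fld$u[fixed, ],
               matrix(c(0.5, 0, -0.25), length(fixed), 3, byrow = TRUE),
               tolerance = 1e-14)
  expect_gte(strain_energy(assemble(bm, mats_unit), fld), 0)
})

test_that("one incremental step reproduces the plain solve", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  tg <- bm$boundary$tag
  fixed <- sort(unique(as.vector(bm$boundary$facets[tg == "APEX_FIXED", ])))
  bc <- bc_fix_nodes(boundary_conditions(bm), fixed, c(0, 0, 0))
  bc <- bc_pressure(bc, which(tg == "ANTERIOR_FREE"), 0.05)
  one <- solve_incremental(bm, mats_unit, bc, n_steps = 1)
  direct <- solve_elastic(assemble(bm, mats_unit), bc, bm)
  expect_equal(one$u, direct$u, tolerance = 1e-12)
})

test_that("incremental and single-step solves agree in the small-load limit", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  tg <- bm$boundary$tag
  fixed <- sort(unique(as.vector(bm$boundary$facets[tg == "APEX_FIXED", ])))
  rel_gap <- function(p) {
    bc <- bc_fix_nodes(boundary_conditions(bm), fixed, c(0, 0, 0))
    bc <- bc_pressure(bc, which(tg == "ANTERIOR_FREE"), p)
    u1 <- solve_incremental(bm, mats_unit, bc, n_steps = 1)$u
    u10 <- solve_incremental(bm, mats_unit, bc, n_steps = 10)$u
    max(abs(u10 - u1)) / max(abs(u1))
  }
  expect_lt(rel_gap(0.002), rel_gap(0.2))
  expect_lt(rel_gap(0.002), 0.01)
})

test_that("the incremental solution self-converges as steps double", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  tg <- bm$boundary$tag
  fixed <- sort(unique(as.vector(bm$boundary$facets[tg == "APEX_FIXED", ])))
  bc <- bc_fix_nodes(boundary_conditions(bm), fixed, c(0, 0, 0))
  bc <- bc_pressure(bc, which(tg == "ANTERIOR_FREE"), 0.3)
  u <- lapply(c(5, 10, 20), function(k)
    solve_incremental(bm, mats_unit, bc, n_steps = k)$u)
  d1 <- max(abs(u[[2]] - u[[1]]))
  d2 <- max(abs(u[[3]] - u[[2]]))
  expect_lt(d2, d1)
})

test_that("solutions scale with p/E and are invariant to joint rescaling", {
  bm <- tet_mesh_box(c(10, 10, 10), 3)
  tg <- bm$boundary$tag
  fixed <- sort(unique(as.vector(bm$boundary$facets[tg == "APEX_FIXED", ])))
  solve_p_E <- function(p, E) {
    m <- material_params(E = c(fat = E), nu = c(fat = 0.3))
    bc <- bc_fix_nodes(boundary_conditions(bm), fixed, c(0, 0, 0))
    bc <- bc_pressure(bc, which(tg == "ANTERIOR_FREE"), p)
    solve_elastic(assemble(bm, m), bc, bm)$u
  }
  u <- solve_p_E(0.1, 1)
  expect_equal(solve_p_E(0.2, 2), u, tolerance = 1e-10)    # joint rescale
  expect_equal(solve_p_E(0.2, 1), 2 * u, tolerance = 1e-10) # linear in p
  # pure Dirichlet loading is independent of the global E scale
  uaff <- 0.01 * bm$nodes
  bnodes <- sort(unique(as.vector(bm$boundary$facets)))
  dir_solve <- function(E) {
    m <- material_params(E = c(fat = E), nu = c(fat = 0.3))
    bc <- bc_fix_nodes(boundary_conditions(bm), bnodes, uaff[bnodes, ])
    solve_elastic(assemble(bm, m), bc, bm)$u
  }
  expect_equal(dir_solve(1), dir_solve(10), tolerance = 1e-10)
})

test_that("missing materials and high Poisson ratios are handled", {
  expect_error(assemble(fx_mesh2(), material_params(E = c(fat = 1),
                                                    nu = c(fat = 0.3))),
               "muscle")
  expect_message(material_params(E = c(fat = 1), nu = c(fat = 0.495)),
                 "capping")
})

test_that("scenario simulation composes its steps as documented", {
  m <- fx_mesh2()
  mats <- material_params()
  # resection at zero pressure gives the zero field
  p0 <- surgical_plan("RESECTION", fx_floor(), pressure_kPa = 0, id = "p0")
  expect_equal(max(abs(simulate_scenario(m, p0, mats, n_steps = 2)$u)), 0)
  # identity valgization with zero pressure gives the zero field
  id0 <- surgical_plan("VALGIZATION", fx_lateral(), shift_mm = 0,
                       angle_deg = 0, pressure_kPa = 0, id = "id0")
  expect_equal(max(abs(simulate_scenario(m, id0, mats, n_steps = 2)$u)), 0)
  # step (i) alone equals an incremental solve with the step-(i) BCs
  lv <- surgical_plan("VALGIZATION", fx_lateral(), shift_mm = 2.5,
                      angle_deg = 30, pressure_kPa = 0, id = "step1")
  cp <- compile_boundary_conditions(m, lv)
  direct <- solve_incremental(m, mats, cp$steps[[1]], n_steps = 4)
  full <- simulate_scenario(m, lv, mats, n_steps = 4)
  expect_equal(full$u, direct$u, tolerance = 1e-9)
})
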