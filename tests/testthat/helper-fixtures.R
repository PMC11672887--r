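# Shared fixtures, built once per test run and memoised.

.fx <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# default phantom at 1 mm voxels (the package default)
fx_phantom <- function() memo("phantom", function() generate_phantom(phantom_spec()))

# simulation mesh at 2 mm cells on the default phantom
fx_mesh2 <- function() memo("mesh2", function() {
  build_tet_mesh(fx_phantom()$volume, target_edge = 2)
})

# default-resolution mesh (1 mm cells)
fx_mesh1 <- function() memo("mesh1", function() {
  build_tet_mesh(fx_phantom()$volume)
})

fx_lateral <- function() memo("lateral", function() {
  select_wall_fragment(fx_mesh2(), "LATERAL_WALL")
})

fx_floor <- function() memo("floor", function() {
  suppressMessages(select_wall_fragment(fx_mesh2(), "FLOOR_WALL"))
})

fx_lava_plan <- function() memo("lava_plan", function() {
  surgical_plan("VALGIZATION", fx_lateral(), shift_mm = 2.5, angle_deg = 30,
                pressure_kPa = 1.2, id = "lava")
})

fx_twowall_plan <- function() memo("twowall_plan", function() {
  surgical_plan("RESECTION", list(fx_lateral(), fx_floor()),
                pressure_kPa = 1.2, id = "twowall")
})

fx_lava_field <- function() memo("lava_field", function() {
  simulate_scenario(fx_mesh2(), fx_lava_plan(), material_params(), n_steps = 10)
})

fx_twowall_field <- function() memo("twowall_field", function() {
  simulate_scenario(fx_mesh2(), fx_twowall_plan(), material_params(), n_steps = 10)
})

# coarse phantom + mesh for the inverse-problem experiments
fx_fit <- function() memo("fit", function() {
  spec <- phantom_spec(voxel_size = 2, grid_shape = c(28, 26, 24))
  ph <- generate_phantom(spec)
  mesh <- build_tet_mesh(ph$volume, target_edge = 4)
  # calibration probe: the window is fully open (no temporalis blocking),
  # so the observation actually carries information about the parameters
  attr(mesh, "source_volume") <- NULL
  frag <- suppressMessages(select_wall_fragment(
    mesh, "LATERAL_WALL", extent_spec = list(y_range = c(6, 36))))
  plan <- surgical_plan("RESECTION", frag, pressure_kPa = 1, id = "fitprobe")
  list(ph = ph, mesh = mesh, plan = plan,
       region = ph$ground_truth$orbit_region,
       truth = c(p_over_E_fat = 0.4, E_muscle_ratio = 4, nu = 0.45))
})

# sphere-in-a-box labelmap (bulbus label), voxel h, radius r
sphere_volume <- function(r = 12, h = 0.5, n = ceiling(2 * (r + 3) / h)) {
  ax <- (seq_len(n) - 0.5) * h - n * h / 2
  arr <- array(0L, c(n, n, n))
  disk2 <- outer(ax^2, ax^2, `+`)
  for (k in seq_len(n)) arr[, , k] <- (disk2 + ax[k]^2 < r^2) * 4L
  label_volume(arr, h, origin = rep(-n * h / 2, 3))
}

# all-fat cube labelmap, edge 10 mm at voxel h
cube_volume <- function(h = 0.5) {
  nv <- round(10 / h)
  pad <- 3L
  n <- nv + 2L * pad
  arr <- array(0L, c(n, n, n))
  arr[(pad + 1):(pad + nv), (pad + 1):(pad + nv), (pad + 1):(pad + nv)] <- 2L
  label_volume(arr, h, origin = c(0, 0, 0))
}

# uniform-translation displacement field
uniform_field <- function(mesh, t) {
  displacement_field(matrix(rep(t, each = nrow(mesh$nodes)), ncol = 3))
}

zero_field <- function(mesh) uniform_field(mesh, c(0, 0, 0))
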