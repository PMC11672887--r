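# Linear elastostatics on labelled tetrahedral meshes.
#
# The displacement form of isotropic linear elasticity (Lame-Navier) is
# discretised with linear (P1) tetrahedra.  Per-tet material parameters
# come from the tissue label.  The assembled stiffness is symmetric
# positive semi-definite with the 6-dimensional rigid-body null space;
# Dirichlet constraints are eliminated by reduction and the reduced system
# is solved by sparse Cholesky factorisation (deterministic ordering).
# Units: mm for lengths/displacements, kPa for moduli, pressures and
# tractions (forces in kPa*mm^2).

#' Per-tissue elastic material parameters
#'
#' @param E named vector of Young's moduli (kPa) keyed by tissue name
#'   (`fat`, `muscle`, `bulbus`).
#' @param nu named vector of Poisson ratios (same names, or a single value
#'   recycled).
#' @param nu_cap upper cap applied to Poisson ratios; values above the cap
#'   are reduced (with a message) to avoid volumetric locking of P1
#'   elements.
#' @return Object of class `material_params`.
#' @export
material_params <- function(E = c(fat = 3, muscle = 12, bulbus = 90),
                            nu = c(fat = 0.45, muscle = 0.45, bulbus = 0.45),
                            nu_cap = 0.49) {
  if (length(nu) == 1L && is.null(names(nu)))
    nu <- stats::setNames(rep(nu, length(E)), names(E))
  if (any(E <= 0)) stopf("Young's moduli must be positive")
  if (any(nu < 0)) stopf("Poisson ratios must be non-negative")
  capped <- nu > nu_cap
  if (any(capped)) {
    message(sprintf("capping Poisson ratio at %.3g for: %s", nu_cap,
                    paste(names(nu)[capped], collapse = ", ")))
    nu[capped] <- nu_cap
  }
  structure(list(E = E, nu = nu, nu_cap = nu_cap), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("material_params:\n")
  for (nm in names(x$E))
    cat(sprintf("  %-8s E = %8.3g kPa   nu = %.3g\n", nm, x$E[[nm]],
                x$nu[[if (nm %in% names(x$nu)) nm else 1L]]))
  invisible(x)
}

# per-tet (E, nu) vectors for a mesh
tet_materials <- function(mesh, materials) {
  nm <- names(TISSUE_LABELS)[match(mesh$tet_label, TISSUE_LABELS)]
  missing <- setdiff(unique(nm), names(materials$E))
  if (length(missing))
    stopf("no material parameters for tissue label(s): %s",
          paste(missing, collapse = ", "))
  nu <- materials$nu
  if (is.null(names(nu))) nu <- stats::setNames(rep(nu[[1]], length(materials$E)),
                                               names(materials$E))
  list(E = unname(materials$E[nm]), nu = unname(nu[nm]))
}

#' Assemble the P1 elasticity stiffness operator
#'
#' @param mesh a `tissue_mesh`.
#' @param materials a [material_params()] covering every tissue present.
#' @param nodes optional node coordinates overriding `mesh$nodes` (used by
#'   the incremental solver after geometry updates).
#' @return Object of class `elastic_system`: sparse symmetric stiffness
#'   `K` (3n x 3n), `ndof`, and the per-tet volumes used.
#' @export
assemble <- function(mesh, materials, nodes = mesh$nodes) {
  tm <- tet_materials(mesh, materials)
  lambda <- tm$E * tm$nu / ((1 + tm$nu) * (1 - 2 * tm$nu))
  mu <- tm$E / (2 * (1 + tm$nu))

  tt <- mesh$tets
  a <- nodes[tt[, 1], , drop = FALSE]; b <- nodes[tt[, 2], , drop = FALSE]
  c <- nodes[tt[, 3], , drop = FALSE]; d <- nodes[tt[, 4], , drop = FALSE]
  e1 <- b - a; e2 <- c - a; e3 <- d - a
  detJ <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
    e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
    e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  if (any(detJ <= 0)) stopf("assemble: %d inverted tet(s)", sum(detJ <= 0))
  vol <- detJ / 6

  # rows of inv(J)^T: gradients of barycentric coordinates 2..4
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  g2 <- cross(e2, e3) / detJ
  g3 <- cross(e3, e1) / detJ
  g4 <- cross(e1, e2) / detJ
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)            # each m x 3

  n <- nrow(nodes); ndof <- 3L * n
  K <- NULL
  for (p in 1:4) for (q in 1:4) {
    gp <- G[[p]]; gq <- G[[q]]
    dot_pq <- rowSums(gp * gq)
    ii <- jj <- xx <- vector("list", 9L); s <- 0L
    for (i in 1:3) for (j in 1:3) {
      s <- s + 1L
      val <- vol * (lambda * gp[, i] * gq[, j] + mu * gq[, i] * gp[, j] +
                      (if (i == j) mu * dot_pq else 0))
      ii[[s]] <- 3L * (tt[, p] - 1L) + i
      jj[[s]] <- 3L * (tt[, q] - 1L) + j
      xx[[s]] <- val
    }
    Kpq <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                x = unlist(xx), dims = c(ndof, ndof))
    K <- if (is.null(K)) Kpq else K + Kpq
  }
  structure(list(K = K, ndof = ndof, n_nodes = n, tet_volumes = vol),
            class = "elastic_system")
}

#' @export
print.elastic_system <- function(x, ...) {
  cat(sprintf("elastic_system: %d dof (%d nodes), nnz = %d\n",
              x$ndof, x$n_nodes, length(x$K@x)))
  invisible(x)
}

# --- boundary conditions -------------------------------------------------

#' Boundary conditions for an elastic solve
#'
#' A container assembled with the `bc_*` helpers: per-dof Dirichlet values,
#' follower pressure loads on boundary facets (traction `p` times the
#' current outward facet normal), fixed facet tractions, and an optional
#' uniform body force per unit volume.
#'
#' @param mesh the `tissue_mesh` the conditions refer to.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(mesh) {
  structure(list(n_nodes = nrow(mesh$nodes),
                 dirichlet_dofs = integer(0), dirichlet_vals = numeric(0),
                 pressure_facets = integer(0), pressure_values = numeric(0),
                 traction_facets = integer(0),
                 traction_values = matrix(0, 0, 3),
                 body_force = NULL),
            class = "boundary_conditions")
}

#' @rdname boundary_conditions
#' @param bc a `boundary_conditions` object.
#' @param nodes node indices.
#' @param values prescribed displacement: a single 3-vector, or an
#'   n x 3 matrix (one row per node), mm.
#' @param comps which components (1 = x, 2 = y, 3 = z) to constrain.
#' @export
bc_fix_nodes <- function(bc, nodes, values = c(0, 0, 0), comps = 1:3) {
  if (is.null(dim(values)))
    values <- matrix(values, nrow = length(nodes), ncol = 3, byrow = TRUE)
  for (cmp in comps) {
    bc$dirichlet_dofs <- c(bc$dirichlet_dofs, 3L * (nodes - 1L) + cmp)
    bc$dirichlet_vals <- c(bc$dirichlet_vals, values[, cmp])
  }
  # later assignments win for repeated dofs
  keep <- !duplicated(rev(bc$dirichlet_dofs))
  ord <- rev(seq_along(bc$dirichlet_dofs))[keep]
  ord <- sort(ord)
  bc$dirichlet_dofs <- bc$dirichlet_dofs[ord]
  bc$dirichlet_vals <- bc$dirichlet_vals[ord]
  bc
}

#' @rdname boundary_conditions
#' @param facets boundary facet indices (rows of `mesh$boundary$facets`).
#' @param p pressure (kPa); the applied traction is `p` times the outward
#'   facet normal, re-evaluated on the current geometry (follower load).
#' @export
bc_pressure <- function(bc, facets, p) {
  bc$pressure_facets <- c(bc$pressure_facets, facets)
  bc$pressure_values <- c(bc$pressure_values, rep(p, length(facets)))
  bc
}

#' @rdname boundary_conditions
#' @param tractions f x 3 matrix of fixed traction vectors (kPa).
#' @export
bc_traction <- function(bc, facets, tractions) {
  if (is.null(dim(tractions)))
    tractions <- matrix(tractions, nrow = length(facets), ncol = 3, byrow = TRUE)
  bc$traction_facets <- c(bc$traction_facets, facets)
  bc$traction_values <- rbind(bc$traction_values, tractions)
  bc
}

#' @rdname boundary_conditions
#' @param f body force per unit volume (kPa/mm), 3-vector.
#' @export
bc_body_force <- function(bc, f) { bc$body_force <- as.numeric(f); bc }

#' @export
print.boundary_conditions <- function(x, ...) {
  cat(sprintf("boundary_conditions: %d Dirichlet dofs, %d pressure facets, %d traction facets%s\n",
              length(x$dirichlet_dofs), length(x$pressure_facets),
              length(x$traction_facets),
              if (!is.null(x$body_force)) ", body force" else ""))
  invisible(x)
}

# consistent nodal load vector from Neumann data on the given geometry
load_vector <- function(mesh, bc, nodes = mesh$nodes) {
  f <- numeric(3L * nrow(nodes))
  if (length(bc$pressure_facets)) {
    fs <- mesh$boundary$facets[bc$pressure_facets, , drop = FALSE]
    nrm <- tri_normal(nodes[fs[, 1], , drop = FALSE],
                      nodes[fs[, 2], , drop = FALSE],
                      nodes[fs[, 3], , drop = FALSE])
    ar <- row_norms(nrm) / 2
    unit <- nrm / pmax(row_norms(nrm), 1e-300)
    trac <- unit * bc$pressure_values
    for (v in 1:3) {
      idx <- 3L * (fs[, v] - 1L)
      for (cmp in 1:3) {
        w <- ar / 3 * trac[, cmp]
        agg <- rowsum(w, idx + cmp)
        f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  if (length(bc$traction_facets)) {
    fs <- mesh$boundary$facets[bc$traction_facets, , drop = FALSE]
    ar <- tri_area(nodes[fs[, 1], , drop = FALSE], nodes[fs[, 2], , drop = FALSE],
                   nodes[fs[, 3], , drop = FALSE])
    for (v in 1:3) {
      idx <- 3L * (fs[, v] - 1L)
      for (cmp in 1:3) {
        w <- ar / 3 * bc$traction_values[, cmp]
        agg <- rowsum(w, idx + cmp)
        f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  if (!is.null(bc$body_force)) {
    tt <- mesh$tets
    vol <- tet_volume_signed(nodes[tt[, 1], , drop = FALSE],
                             nodes[tt[, 2], , drop = FALSE],
                             nodes[tt[, 3], , drop = FALSE],
                             nodes[tt[, 4], , drop = FALSE])
    for (v in 1:4) {
      idx <- 3L * (tt[, v] - 1L)
      for (cmp in 1:3) {
        w <- vol / 4 * bc$body_force[cmp]
        agg <- rowsum(w, idx + cmp)
        f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1]
      }
    }
  }
  f
}

#' Displacement field
#'
#' @param u n x 3 matrix of nodal displacements (mm).
#' @param steps optional list of per-step displacement increments.
#' @param residual relative residual of the final linear solve.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(u, steps = NULL, residual = NA_real_) {
  structure(list(u = u, steps = steps, residual = residual),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mags <- row_norms(x$u)
  cat(sprintf("displacement_field: %d nodes, |u| max %.3g mm, mean %.3g mm",
              nrow(x$u), max(mags), mean(mags)))
  if (!is.null(x$steps)) cat(sprintf(", %d steps", length(x$steps)))
  cat(sprintf(" (solver residual %.2g)\n", x$residual))
  invisible(x)
}

# names of the 6 rigid-body modes, used in singular-system diagnostics
rigid_body_modes <- function(nodes) {
  n <- nrow(nodes)
  ctr <- colMeans(nodes)
  x <- sweep(nodes, 2L, ctr)
  modes <- list(
    "translation x" = cbind(1, 0, 0)[rep(1, n), ],
    "translation y" = cbind(0, 1, 0)[rep(1, n), ],
    "translation z" = cbind(0, 0, 1)[rep(1, n), ],
    "rotation about x" = cbind(0, -x[, 3], x[, 2]),
    "rotation about y" = cbind(x[, 3], 0, -x[, 1]),
    "rotation about z" = cbind(-x[, 2], x[, 1], 0))
  lapply(modes, function(m) as.numeric(t(m)))
}

#' Solve the constrained elastic system
#'
#' Eliminates Dirichlet dofs, factorises the reduced stiffness (sparse
#' Cholesky) and returns the displacement field.  Dirichlet values are
#' reproduced exactly; the relative residual of the reduced system is
#' checked against `tol`.
#'
#' @param system an `elastic_system` from [assemble()].
#' @param bc a `boundary_conditions`.
#' @param mesh the mesh (needed to integrate Neumann loads).
#' @param nodes geometry on which loads are evaluated (defaults to the
#'   mesh nodes).
#' @param tol relative residual tolerance.
#' @return A `displacement_field`.
#' @export
solve_elastic <- function(system, bc, mesh, nodes = mesh$nodes, tol = 1e-9) {
  K <- system$K
  ndof <- system$ndof
  f <- load_vector(mesh, bc, nodes)
  fixed <- bc$dirichlet_dofs
  if (anyDuplicated(fixed)) stopf("duplicate Dirichlet dofs")
  free <- setdiff(seq_len(ndof), fixed)
  u <- numeric(ndof)
  u[fixed] <- bc$dirichlet_vals
  rhs <- f[free]
  if (length(fixed))
    rhs <- rhs - as.numeric(K[free, fixed, drop = FALSE] %*% u[fixed])
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e) e)
  if (inherits(ch, "error")) {
    # identify an unconstrained rigid-body mode for the diagnostic
    modes <- rigid_body_modes(nodes)
    for (nm in names(modes)) {
      v <- modes[[nm]][free]
      if (sqrt(sum(v^2)) < 1e-12) next
      v <- v / sqrt(sum(v^2))
      r <- as.numeric(Kff %*% v)
      if (sqrt(sum(r^2)) < 1e-8 * max(abs(Kff@x)))
        stopf("singular elastic system: rigid-body mode '%s' is unconstrained", nm)
    }
    stopf("singular elastic system: insufficient Dirichlet constraints")
  }
  uf <- as.numeric(Matrix::solve(ch, rhs))
  u[free] <- uf
  res <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  ref <- max(sqrt(sum(rhs^2)), 1e-300)
  rel <- res / ref
  if (length(rhs) && sqrt(sum(rhs^2)) > 0 && rel > tol)
    warnf("solver residual %.2g exceeds tolerance %.2g", rel, tol)
  displacement_field(matrix(u, ncol = 3, byrow = TRUE), residual = rel)
}

#' Strain energy of a displacement field
#'
#' @param system an `elastic_system`; @param field a `displacement_field`.
#' @return 0.5 u' K u (kPa mm^3), non-negative.
#' @export
strain_energy <- function(system, field) {
  u <- as.numeric(t(field$u))
  as.numeric(0.5 * (u %*% (system$K %*% u)))
}

#' Incremental (piecewise-linear) elastic solve
#'
#' Applies the prescribed displacements and loads in `n_steps` equal
#' increments, re-assembling the stiffness on the updated geometry after
#' every step.  With `n_steps = 1` this reduces to a single linear solve
#' on the original geometry.
#'
#' @param mesh a `tissue_mesh`.
#' @param materials a `material_params`.
#' @param bc total boundary conditions (full Dirichlet values and loads).
#' @param n_steps number of equal increments (>= 1).
#' @return A `displacement_field` with per-step increments in `$steps`.
#' @export
solve_incremental <- function(mesh, materials, bc, n_steps = 10L) {
  if (n_steps < 1L) stopf("n_steps must be >= 1")
  nodes <- mesh$nodes
  total <- matrix(0, nrow(nodes), 3L)
  steps <- vector("list", n_steps)
  res <- NA_real_
  for (s in seq_len(n_steps)) {
    inc <- bc
    inc$dirichlet_vals <- bc$dirichlet_vals / n_steps
    inc$pressure_values <- bc$pressure_values / n_steps
    if (length(bc$traction_facets))
      inc$traction_values <- bc$traction_values / n_steps
    if (!is.null(bc$body_force)) inc$body_force <- bc$body_force / n_steps
    sys <- assemble(mesh, materials, nodes = nodes)
    fld <- solve_elastic(sys, inc, mesh, nodes = nodes)
    nodes_new <- nodes + fld$u
    v <- tet_volumes(mesh, nodes_new)
    if (any(v <= 0))
      stopf("element inversion during incremental update at step %d (tet %d)",
            s, which(v <= 0)[1])
    nodes <- nodes_new
    total <- total + fld$u
    steps[[s]] <- fld$u
    res <- fld$residual
  }
  displacement_field(total, steps = steps, residual = res)
}

# --- verification benchmark ---------------------------------------------

#' Pressurised thick-walled sphere benchmark
#'
#' Solves the internally pressurised thick spherical shell on a structured
#' octant mesh and compares the radial displacement with the closed form
#' `u(r) = p a^3 / (E (b^3 - a^3)) [(1 - 2 nu) r + (1 + nu) b^3 / (2 r^2)]`.
#'
#' @param a,b inner/outer radii (mm); @param p internal pressure (kPa).
#' @param E,nu material parameters.
#' @param levels list of `c(n, nr)` angular/radial subdivisions, coarse to
#'   fine.
#' @return data.frame with one row per level: nodes, dofs and relative L2
#'   error of the radial displacement at the nodes.
#' @export
lame_sphere_benchmark <- function(a = 10, b = 20, p = 1, E = 10, nu = 0.3,
                                  levels = list(c(8L, 4L), c(16L, 8L),
                                                c(32L, 16L))) {
  mats <- material_params(E = c(fat = E), nu = c(fat = nu))
  out <- lapply(levels, function(lv) {
    mesh <- tet_mesh_sphere_shell(a, b, n = lv[1], nr = lv[2])
    tg <- mesh$boundary$tag
    bc <- boundary_conditions(mesh)
    nn <- nrow(mesh$nodes)
    near0 <- function(v) abs(v) < 1e-7 * b
    bc <- bc_fix_nodes(bc, which(near0(mesh$nodes[, 1])), comps = 1L)
    bc <- bc_fix_nodes(bc, which(near0(mesh$nodes[, 2])), comps = 2L)
    bc <- bc_fix_nodes(bc, which(near0(mesh$nodes[, 3])), comps = 3L)
    # internal pressure pushes the inner surface outward: the solid's
    # outward normal there points to the centre, so apply -p
    bc <- bc_pressure(bc, which(tg == "INNER"), -p)
    sys <- assemble(mesh, mats)
    fld <- solve_elastic(sys, bc, mesh)
    r <- row_norms(mesh$nodes)
    ur_num <- rowSums(fld$u * mesh$nodes) / r
    ur_ex <- p * a^3 / (E * (b^3 - a^3)) * ((1 - 2 * nu) * r +
                                              (1 + nu) * b^3 / (2 * r^2))
    err <- sqrt(sum((ur_num - ur_ex)^2) / sum(ur_ex^2))
    data.frame(n = lv[1], nr = lv[2], nodes = nn, dofs = 3L * nn,
               rel_l2_error = err)
  })
  do.call(rbind, out)
}
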