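# Surgical plans and their compilation into boundary conditions.
#
# A wall fragment is a contiguous set of wall-tagged boundary facets of the
# tissue mesh (bone itself is never meshed; the wall exists as facet tags).
# Two scenarios are supported:
#   RESECTION   - the fragment is removed; the window becomes a pressure
#                 (Neumann) surface.  Window facets backed by the
#                 temporalis muscle stay fixed: the muscle herniates into
#                 the defect and blocks outflow there.
#   VALGIZATION - the fragment swings outward about a hinge on its
#                 anterior edge (plus a lateral shift along its mean
#                 outward normal).  Step (i) drags the adjacent soft
#                 tissue kinematically with the fragment; step (ii)
#                 releases the fragment's rim band (the gap around the
#                 displaced plate) and applies intraorbital pressure
#                 there, while tissue backed by the plate stays pinned.

WALL_TAGS <- c("LATERAL_WALL", "FLOOR_WALL", "MEDIAL_WALL", "ROOF_WALL")

#' Select a contiguous wall fragment on the mesh boundary
#'
#' @param mesh a `tissue_mesh`.
#' @param wall_tag one of LATERAL_WALL, FLOOR_WALL, MEDIAL_WALL, ROOF_WALL.
#' @param extent_spec optional list restricting the selection: `y_range`
#'   (anterior coordinate interval, mm) and/or `phi_range` (angular
#'   interval about the orbital axis, degrees).
#' @return Object of class `wall_fragment`: facet indices, hinge axis
#'   (point + unit direction on the anterior edge), area (cm^2), mean
#'   outward normal, and the facet node set.
#' @export
select_wall_fragment <- function(mesh, wall_tag, extent_spec = NULL) {
  if (!wall_tag %in% mesh$boundary$tag)
    stopf("wall tag '%s' not present on the mesh boundary", wall_tag)
  sel <- which(mesh$boundary$tag == wall_tag)
  if (!is.null(extent_spec)) {
    cen <- boundary_facet_centroids(mesh)[sel, , drop = FALSE]
    keep <- rep(TRUE, length(sel))
    if (!is.null(extent_spec$y_range))
      keep <- keep & cen[, 2] >= extent_spec$y_range[1] &
        cen[, 2] <= extent_spec$y_range[2]
    if (!is.null(extent_spec$phi_range)) {
      phi <- atan2(cen[, 3], cen[, 1]) * 180 / pi
      keep <- keep & phi >= extent_spec$phi_range[1] &
        phi <= extent_spec$phi_range[2]
    }
    sel <- sel[keep]
  }
  if (!length(sel)) stopf("empty wall-fragment selection (%s)", wall_tag)

  facets <- mesh$boundary$facets[sel, , drop = FALSE]
  comp <- facet_components(facets)
  if (max(comp) > 1L) {
    # tolerate tiny satellite patches from tag discretisation noise, but
    # reject selections that are genuinely split
    ar_all <- boundary_facet_areas(mesh)[sel]
    carea <- tapply(ar_all, comp, sum)
    main <- as.integer(names(which.max(carea)))
    if (any(carea[-main] > 0.02 * sum(carea)))
      stopf("wall-fragment selection is disconnected (%d components)", max(comp))
    message(sprintf("dropping %d satellite facet(s) (%.2g%% of area) from %s selection",
                    sum(comp != main), 100 * sum(carea[-main]) / sum(carea),
                    wall_tag))
    sel <- sel[comp == main]
    facets <- mesh$boundary$facets[sel, , drop = FALSE]
  }

  ar <- boundary_facet_areas(mesh)[sel]
  nrm <- boundary_facet_normals(mesh)[sel, , drop = FALSE]
  mean_nrm <- colSums(nrm * ar)
  mean_nrm <- mean_nrm / sqrt(sum(mean_nrm^2))

  # effective area: facet areas projected onto the smooth tissue surface
  # (signed-distance gradient).  Snapped lattice boundaries carry small
  # tangential folds whose raw triangle areas overcount the patch; the
  # signed projection cancels them.
  ar_eff <- ar
  sdf <- attr(mesh, "sdf_field")
  if (!is.null(sdf)) {
    cen <- boundary_facet_centroids(mesh)[sel, , drop = FALSE]
    g <- sdf_gradient_at(sdf, cen)
    ar_eff <- ar * rowSums(nrm * g)
  }

  hinge <- fragment_hinge(mesh, facets)
  structure(list(facets = sel, wall_tag = wall_tag,
                 nodes = sort(unique(as.vector(facets))),
                 area_cm2 = sum(ar_eff) / 100,
                 normal = mean_nrm,
                 hinge_point = hinge$point, hinge_dir = hinge$dir),
            class = "wall_fragment")
}

#' @export
print.wall_fragment <- function(x, ...) {
  cat(sprintf("wall_fragment (%s): %d facets, %d nodes, area %.2f cm^2\n",
              x$wall_tag, length(x$facets), length(x$nodes), x$area_cm2))
  cat(sprintf("  hinge: point (%.1f, %.1f, %.1f), direction (%.2f, %.2f, %.2f)\n",
              x$hinge_point[1], x$hinge_point[2], x$hinge_point[3],
              x$hinge_dir[1], x$hinge_dir[2], x$hinge_dir[3]))
  invisible(x)
}

# connected components of a facet set under shared-edge adjacency
facet_components <- function(facets) {
  nf <- nrow(facets)
  e <- rbind(facets[, 1:2], facets[, 2:3], facets[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  fid <- rep(seq_len(nf), 3L)
  parent <- seq_len(nf)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  sp <- split(fid, key)
  for (grp in sp) {
    if (length(grp) > 1L) {
      r <- find(grp[1])
      for (g in grp[-1]) parent[find(g)] <- r
    }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  match(roots, unique(roots))
}

# boundary edges of the patch whose midpoints lie in the anterior band;
# hinge = centroid + principal direction of their endpoints
fragment_hinge <- function(mesh, facets) {
  e <- rbind(facets[, 1:2], facets[, 2:3], facets[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- !(key %in% key[duplicated(key)])
  be <- e[once, , drop = FALSE]
  if (!nrow(be)) stopf("fragment has no boundary edges (closed patch?)")
  midy <- (mesh$nodes[be[, 1], 2] + mesh$nodes[be[, 2], 2]) / 2
  yr <- range(midy)
  band <- midy >= yr[2] - 0.12 * max(yr[2] - yr[1], 1e-9) - 1e-9
  pts <- mesh$nodes[unique(as.vector(be[band, , drop = FALSE])), , drop = FALSE]
  ctr <- colMeans(pts)
  if (nrow(pts) >= 2L) {
    pc <- eigen(stats::cov(pts), symmetric = TRUE)
    dirv <- pc$vectors[, 1]
  } else dirv <- c(0, 0, 1)
  list(point = ctr, dir = dirv / sqrt(sum(dirv^2)))
}

#' Rigid valgization transform of a wall fragment
#'
#' Rotation by `angle` degrees about the fragment's hinge axis (sign chosen
#' so the fragment swings outward) composed with a translation `shift` mm
#' along the fragment's mean outward normal.
#'
#' @param fragment a `wall_fragment`.
#' @param shift lateral shift, mm (>= 0).
#' @param angle hinge rotation, degrees (0 <= angle < 90).
#' @param mesh the mesh the fragment refers to (for the outward test).
#' @return Object of class `rigid_transform` with rotation `R`, offset `t`
#'   (so points map as `x R' + t`), and the 4 x 4 matrix.
#' @export
make_valgization <- function(fragment, shift, angle, mesh = NULL) {
  if (shift < 0) stopf("valgization shift must be >= 0")
  if (angle < 0 || angle >= 90) stopf("valgization angle must be in [0, 90)")
  u <- fragment$hinge_dir; p0 <- fragment$hinge_point
  rot <- function(theta) {
    ct <- cos(theta); st <- sin(theta)
    ux <- u[1]; uy <- u[2]; uz <- u[3]
    matrix(c(ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
             uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
             uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)),
           3, 3, byrow = TRUE)
  }
  theta <- angle * pi / 180
  R <- rot(theta)
  # pick the rotation sense that moves the fragment outward
  ctr <- fragment$hinge_point  # fallback
  if (!is.null(mesh)) {
    fac <- mesh$boundary$facets[fragment$facets, , drop = FALSE]
    ctr <- colMeans(mesh$nodes[unique(as.vector(fac)), , drop = FALSE])
  }
  disp <- as.numeric(R %*% (ctr - p0)) + p0 - ctr
  if (theta > 0 && sum(disp * fragment$normal) < 0) R <- rot(-theta)
  t_off <- p0 - as.numeric(R %*% p0) + shift * fragment$normal
  M <- diag(4); M[1:3, 1:3] <- R; M[1:3, 4] <- t_off
  structure(list(R = R, t = t_off, matrix = M), class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`; @param pts n x 3 matrix.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(transform$R), 2L, transform$t, `+`)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform:\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Surgical plan
#'
#' @param scenario "RESECTION" or "VALGIZATION".
#' @param fragments list of `wall_fragment` objects (RESECTION may carry
#'   several, e.g. lateral + floor; VALGIZATION uses the first).
#' @param shift_mm,angle_deg valgization parameters (must be absent/zero
#'   for RESECTION plans).
#' @param pressure_kPa uniform intraorbital pressure driving outflow.
#' @param contact_tol_mm nodes within this distance of the fragment follow
#'   it kinematically during valgization.
#' @param drag_taper Lipschitz cap on the kinematic drag: the prescribed
#'   displacement magnitude of a contact node is limited to its distance
#'   from the fragment rim divided by `drag_taper`.  Tissue at the
#'   osteotomy edge is tethered to the intact wall, so the relocation must
#'   go to zero there; the cap keeps the prescribed field continuous and
#'   prevents element inversion at the rim.  `Inf` disables the taper
#'   (every contact node follows the plate exactly).
#' @param body_force optional uniform body force per unit volume
#'   (kPa/mm 3-vector) as an alternative loading mode; default off.
#' @param id optional scenario label used in reports.
#' @return Object of class `surgical_plan`.
#' @export
surgical_plan <- function(scenario = c("RESECTION", "VALGIZATION"),
                          fragments, shift_mm = 0, angle_deg = 0,
                          pressure_kPa = 1.2, contact_tol_mm = 1.0,
                          drag_taper = 1.5, body_force = NULL, id = NULL) {
  scenario <- match.arg(scenario)
  if (inherits(fragments, "wall_fragment")) fragments <- list(fragments)
  if (!length(fragments)) stopf("plan needs at least one wall fragment")
  if (scenario == "RESECTION" && (shift_mm != 0 || angle_deg != 0))
    stopf("RESECTION plans carry no valgization transform parameters")
  if (shift_mm < 0) stopf("shift must be >= 0")
  if (angle_deg < 0 || angle_deg >= 90) stopf("angle must be in [0, 90)")
  if (pressure_kPa < 0) stopf("pressure must be >= 0")
  structure(list(scenario = scenario, fragments = fragments,
                 shift_mm = shift_mm, angle_deg = angle_deg,
                 pressure_kPa = pressure_kPa,
                 contact_tol_mm = contact_tol_mm,
                 drag_taper = drag_taper,
                 body_force = body_force,
                 id = id %||% tolower(scenario)),
            class = "surgical_plan")
}

#' @export
print.surgical_plan <- function(x, ...) {
  cat(sprintf("surgical_plan '%s' (%s)\n", x$id, x$scenario))
  for (fr in x$fragments)
    cat(sprintf("  fragment %s: %.2f cm^2\n", fr$wall_tag, fr$area_cm2))
  if (x$scenario == "VALGIZATION")
    cat(sprintf("  shift %.2f mm, angle %.1f deg, contact tol %.2f mm\n",
                x$shift_mm, x$angle_deg, x$contact_tol_mm))
  cat(sprintf("  intraorbital pressure %.3g kPa\n", x$pressure_kPa))
  invisible(x)
}

# facets of the fragment backed by the temporalis muscle (ray through the
# bone hits label 5); these stay fixed in RESECTION scenarios
temporalis_backed <- function(mesh, fragment, volume) {
  if (is.null(volume)) return(rep(FALSE, length(fragment$facets)))
  cen <- boundary_facet_centroids(mesh)[fragment$facets, , drop = FALSE]
  nrm <- boundary_facet_normals(mesh)[fragment$facets, , drop = FALSE]
  geo <- volume$geometry
  wt <- geo$wall_thickness %||% 2
  off <- (geo$temporalis$offset %||% 0.5)
  h0 <- volume$voxel_size
  depth <- wt + off + 3 * h0
  blocked <- rep(FALSE, nrow(cen))
  for (dd in seq(0.5 * h0, depth, by = h0)) {
    lb <- label_at(volume, cen + dd * nrm)
    blocked <- blocked | lb == 5L
  }
  blocked
}

# nodes within tol of the fragment's node set (chunked distance search)
nodes_near_fragment <- function(mesh, fragment, tol) {
  fp <- mesh$nodes[fragment$nodes, , drop = FALSE]
  out <- logical(nrow(mesh$nodes))
  out[fragment$nodes] <- TRUE
  if (tol <= 0) return(which(out))
  chunk <- 2000L
  for (s in seq(1L, nrow(mesh$nodes), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(mesh$nodes))
    sub <- mesh$nodes[idx, , drop = FALSE]
    d2 <- outer(rowSums(sub^2), rowSums(fp^2), `+`) - 2 * sub %*% t(fp)
    out[idx] <- out[idx] | apply(d2, 1L, min) <= tol^2
  }
  which(out)
}

# rim nodes of a fragment patch: nodes on patch boundary edges
fragment_rim_nodes <- function(mesh, fragment) {
  facets <- mesh$boundary$facets[fragment$facets, , drop = FALSE]
  e <- rbind(facets[, 1:2], facets[, 2:3], facets[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- !(key %in% key[duplicated(key)])
  sort(unique(as.vector(e[once, , drop = FALSE])))
}

#' Compile a surgical plan into per-step boundary conditions
#'
#' RESECTION compiles to a single step: fragment facets carry the
#' intraorbital pressure (except temporalis-backed facets, which remain
#' fixed), all other wall facets and the apex are fixed, the anterior
#' surface is traction-free.  VALGIZATION compiles to two steps: (i) the
#' soft-tissue nodes in contact with the fragment receive the rigid
#' valgization displacement, and (ii) the rim band of the displaced plate
#' (where the plate has moved further than the contact tolerance from its
#' seat) is released and pressurised while plate-backed tissue stays
#' pinned.
#'
#' @param mesh a `tissue_mesh`.
#' @param plan a `surgical_plan`.
#' @param volume optional source `label_volume` (enables temporalis
#'   blocking; defaults to the labelmap the mesh was built from).
#' @return Object of class `compiled_plan`: list of `boundary_conditions`
#'   in `$steps` plus bookkeeping (contact and window sets, transform).
#' @export
compile_boundary_conditions <- function(mesh, plan,
                                        volume = attr(mesh, "source_volume")) {
  tags <- mesh$boundary$tag
  frag_facets <- unlist(lapply(plan$fragments, `[[`, "facets"))
  if (anyDuplicated(frag_facets)) {
    dup <- frag_facets[duplicated(frag_facets)][1]
    node <- mesh$boundary$facets[dup, 1]
    stopf("Dirichlet/Neumann conflict: facet %d (node %d) belongs to more than one fragment",
          dup, node)
  }
  apex_nodes <- sort(unique(as.vector(
    mesh$boundary$facets[tags == "APEX_FIXED", , drop = FALSE])))
  wall_sel <- tags %in% WALL_TAGS
  wall_sel[frag_facets] <- FALSE
  wall_nodes <- sort(unique(as.vector(
    mesh$boundary$facets[wall_sel, , drop = FALSE])))

  base_bc <- function() {
    bc <- boundary_conditions(mesh)
    bc <- bc_fix_nodes(bc, apex_nodes, c(0, 0, 0))
    bc <- bc_fix_nodes(bc, wall_nodes, c(0, 0, 0))
    if (!is.null(plan$body_force)) bc <- bc_body_force(bc, plan$body_force)
    bc
  }

  if (plan$scenario == "RESECTION") {
    bc <- base_bc()
    blocked_all <- c()
    open_facets <- c()
    for (fr in plan$fragments) {
      blk <- temporalis_backed(mesh, fr, volume)
      blocked <- fr$facets[blk]
      open_facets <- c(open_facets, fr$facets[!blk])
      blocked_all <- c(blocked_all, blocked)
    }
    if (length(blocked_all)) {
      bnodes <- sort(unique(as.vector(
        mesh$boundary$facets[blocked_all, , drop = FALSE])))
      bc <- bc_fix_nodes(bc, bnodes, c(0, 0, 0))
    }
    # pressure on window facets; loads on Dirichlet dofs are discarded in
    # the solve, which resolves the shared rim nodes in favour of bone
    bc <- bc_pressure(bc, open_facets, plan$pressure_kPa)
    return(structure(list(scenario = "RESECTION", steps = list(bc),
                          window_facets = open_facets,
                          blocked_facets = blocked_all, plan = plan),
                     class = "compiled_plan"))
  }

  # VALGIZATION
  fr <- plan$fragments[[1]]
  trans <- make_valgization(fr, plan$shift_mm, plan$angle_deg, mesh)
  contact <- nodes_near_fragment(mesh, fr, plan$contact_tol_mm)
  disp <- apply_transform(trans, mesh$nodes[contact, , drop = FALSE]) -
    mesh$nodes[contact, , drop = FALSE]
  rim0 <- fragment_rim_nodes(mesh, fr)
  if (is.finite(plan$drag_taper) && length(rim0)) {
    rp <- mesh$nodes[rim0, , drop = FALSE]
    cn <- mesh$nodes[contact, , drop = FALSE]
    d2 <- outer(rowSums(cn^2), rowSums(rp^2), `+`) - 2 * cn %*% t(rp)
    d_rim <- sqrt(pmax(apply(d2, 1L, min), 0))
    cap <- d_rim / plan$drag_taper
    m <- row_norms(disp)
    scale <- ifelse(m > cap & m > 0, cap / pmax(m, 1e-300), 1)
    disp <- disp * scale
  }

  # kinematic-consistency filter: a tet whose four nodes are all
  # prescribed can be inverted outright by incompatible drag values (the
  # elastic solve has no freedom left there).  Such contact nodes are
  # released, largest drag first, until every fully-prescribed tet stays
  # valid along the whole drag path.
  presc <- matrix(0, nrow(mesh$nodes), 3)
  presc[contact, ] <- disp
  fixed_flag <- rep(FALSE, nrow(mesh$nodes))
  fixed_flag[c(contact, wall_nodes, apex_nodes)] <- TRUE
  keep <- rep(TRUE, length(contact))
  for (round in 1:25) {
    act <- rep(FALSE, nrow(mesh$nodes))
    act[c(contact[keep], wall_nodes, apex_nodes)] <- TRUE
    tt <- mesh$tets
    allD <- act[tt[, 1]] & act[tt[, 2]] & act[tt[, 3]] & act[tt[, 4]]
    if (!any(allD)) break
    pk <- presc
    pk[contact[!keep], ] <- 0
    sub <- tt[allD, , drop = FALSE]
    minv <- rep(Inf, nrow(sub))
    for (s in seq(0.2, 1, by = 0.2)) {
      xs <- mesh$nodes + s * pk
      minv <- pmin(minv, tet_volume_signed(xs[sub[, 1], , drop = FALSE],
                                           xs[sub[, 2], , drop = FALSE],
                                           xs[sub[, 3], , drop = FALSE],
                                           xs[sub[, 4], , drop = FALSE]))
    }
    v0 <- tet_volumes(mesh)[allD]
    bad <- which(minv <= 0.05 * v0)
    if (!length(bad)) break
    bad_nodes <- unique(as.vector(sub[bad, , drop = FALSE]))
    bad_contact <- intersect(bad_nodes, contact[keep])
    bad_contact <- setdiff(bad_contact, c(wall_nodes, apex_nodes))
    if (!length(bad_contact)) break
    mags <- row_norms(presc[bad_contact, , drop = FALSE])
    drop_node <- bad_contact[which.max(mags)]
    keep[match(drop_node, contact)] <- FALSE
  }
  contact <- contact[keep]
  disp <- disp[keep, , drop = FALSE]

  # contact drag first, then intact bone: shared rim nodes stay with bone
  bc1 <- boundary_conditions(mesh)
  bc1 <- bc_fix_nodes(bc1, contact, disp)
  bc1 <- bc_fix_nodes(bc1, wall_nodes, c(0, 0, 0))
  bc1 <- bc_fix_nodes(bc1, apex_nodes, c(0, 0, 0))
  if (!is.null(plan$body_force)) bc1 <- bc_body_force(bc1, plan$body_force)

  rim <- rim0
  gap <- row_norms(apply_transform(trans, mesh$nodes[rim, , drop = FALSE]) -
                     mesh$nodes[rim, , drop = FALSE])
  released <- rim[gap > plan$contact_tol_mm]
  # intact bone keeps the rim nodes it shares with untouched wall facets
  released <- setdiff(released, wall_nodes)
  pinned <- setdiff(contact, released)

  fac <- mesh$boundary$facets[fr$facets, , drop = FALSE]
  window <- fr$facets[rowSums(matrix(fac %in% released, ncol = 3)) > 0]

  bc2 <- base_bc()
  bc2 <- bc_fix_nodes(bc2, pinned, c(0, 0, 0))
  bc2 <- bc_pressure(bc2, window, plan$pressure_kPa)

  structure(list(scenario = "VALGIZATION", steps = list(bc1, bc2),
                 transform = trans, contact_nodes = contact,
                 released_nodes = released, window_facets = window,
                 plan = plan),
            class = "compiled_plan")
}

#' @export
print.compiled_plan <- function(x, ...) {
  cat(sprintf("compiled_plan (%s): %d step(s)\n", x$scenario, length(x$steps)))
  if (x$scenario == "VALGIZATION")
    cat(sprintf("  %d contact nodes, %d released rim nodes, %d window facets\n",
                length(x$contact_nodes), length(x$released_nodes),
                length(x$window_facets)))
  else
    cat(sprintf("  %d window facets, %d temporalis-blocked facets\n",
                length(x$window_facets), length(x$blocked_facets)))
  invisible(x)
}

#' Simulate a surgical scenario
#'
#' Runs the compiled plan on the mesh: RESECTION is a single (incremental)
#' pressure solve; VALGIZATION runs step (i) kinematic valgization followed
#' by step (ii) pressure-driven outflow on the updated geometry.  The
#' returned field is the accumulated displacement.
#'
#' @param mesh a `tissue_mesh`.
#' @param plan a `surgical_plan`.
#' @param materials a `material_params`.
#' @param n_steps increments per simulation step (piecewise-linear regime).
#' @param volume optional source labelmap (see
#'   [compile_boundary_conditions()]).
#' @return A `displacement_field`; attribute `compiled` holds the compiled
#'   plan.
#' @export
simulate_scenario <- function(mesh, plan, materials, n_steps = 10L,
                              volume = attr(mesh, "source_volume")) {
  cp <- compile_boundary_conditions(mesh, plan, volume)
  if (cp$scenario == "RESECTION") {
    fld <- solve_incremental(mesh, materials, cp$steps[[1]], n_steps)
    attr(fld, "compiled") <- cp
    return(fld)
  }
  fld1 <- solve_incremental(mesh, materials, cp$steps[[1]], n_steps)
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes + fld1$u
  fld2 <- solve_incremental(mesh2, materials, cp$steps[[2]], n_steps)
  total <- displacement_field(fld1$u + fld2$u,
                              steps = c(fld1$steps, fld2$steps),
                              residual = fld2$residual)
  attr(total, "compiled") <- cp
  total
}
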