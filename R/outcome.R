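# Outcome metrics: released intraorbital tissue volume, volume-per-area
# efficiency, proptosis change, and scenario comparison reports.
#
# "Released volume" is operationalised as the volume of deformed tissue
# lying outside the original bony cavity, measured by rasterising the
# deformed tetrahedral mesh on a fine voxel grid and counting voxel
# centres whose cavity signed distance is positive.  A surface-flux mode
# (integral of u . n over the original cavity-adjacent boundary) is
# provided as an independent cross-check of the same quantity.

#' Released intraorbital tissue volume
#'
#' @param mesh a `tissue_mesh`.
#' @param field a `displacement_field` on the mesh.
#' @param orbit_region cavity descriptor: a function mapping an n x 3
#'   matrix of world points to signed distances (negative inside the
#'   original bony cavity), e.g. `ground_truth$orbit_region` from
#'   [generate_phantom()].
#' @param pitch voxel pitch (mm) of the rasterisation.
#' @param mode `"voxel"` (default) rasterises the deformed mesh;
#'   `"flux"` integrates the outward normal displacement over the
#'   wall-adjacent boundary (first-order in the displacement);
#'   `"sample"` estimates the outside fraction of every deformed tet from
#'   a fixed barycentric quadrature set (fast, used inside the inverse
#'   loop where only consistency matters).
#' @param per_tissue also return the per-tissue breakdown.
#' @return Released volume in cm^3 (named list when `per_tissue`).
#' @export
released_volume <- function(mesh, field, orbit_region, pitch = 0.5,
                            mode = c("voxel", "flux", "sample"),
                            per_tissue = FALSE) {
  mode <- match.arg(mode)
  if (nrow(field$u) != nrow(mesh$nodes))
    stopf("displacement field has %d nodes but mesh has %d",
          nrow(field$u), nrow(mesh$nodes))
  if (mode == "sample") {
    out_frac <- function(nodes) {
      tt <- mesh$tets
      v <- abs(tet_volumes(mesh, nodes))
      # fixed symmetric barycentric sample set (deterministic)
      W <- rbind(c(0.58, 0.14, 0.14, 0.14), c(0.14, 0.58, 0.14, 0.14),
                 c(0.14, 0.14, 0.58, 0.14), c(0.14, 0.14, 0.14, 0.58),
                 c(0.25, 0.25, 0.25, 0.25),
                 c(0.40, 0.40, 0.10, 0.10), c(0.10, 0.40, 0.40, 0.10),
                 c(0.10, 0.10, 0.40, 0.40))
      outside <- 0
      for (r in seq_len(nrow(W))) {
        pts <- W[r, 1] * nodes[tt[, 1], , drop = FALSE] +
          W[r, 2] * nodes[tt[, 2], , drop = FALSE] +
          W[r, 3] * nodes[tt[, 3], , drop = FALSE] +
          W[r, 4] * nodes[tt[, 4], , drop = FALSE]
        outside <- outside + (orbit_region(pts) > 0)
      }
      sum(v * outside / nrow(W)) / 1000
    }
    # released volume is measured relative to the undeformed baseline: the
    # discretised rest mesh protrudes marginally past the analytic cavity
    return(max(out_frac(mesh$nodes + field$u) - out_frac(mesh$nodes), 0))
  }
  if (mode == "flux") {
    tags <- mesh$boundary$tag
    sel <- which(tags != "APEX_FIXED")
    f <- mesh$boundary$facets[sel, , drop = FALSE]
    ar <- boundary_facet_areas(mesh)[sel]
    nrm <- boundary_facet_normals(mesh)[sel, , drop = FALSE]
    ubar <- (field$u[f[, 1], , drop = FALSE] + field$u[f[, 2], , drop = FALSE] +
               field$u[f[, 3], , drop = FALSE]) / 3
    flux <- sum(pmax(rowSums(ubar * nrm), 0) * ar)
    return(flux / 1000)
  }
  out_by_label <- function(nodes) {
    occ <- rasterize_mesh(mesh, nodes, pitch)
    outside <- orbit_region(occ$centers) > 0
    tapply(outside, factor(occ$label, levels = DEFORMABLE_LABELS), sum) *
      pitch^3 / 1000
  }
  # subtract the undeformed baseline (the discretised rest mesh protrudes
  # marginally past the analytic cavity boundary)
  v <- out_by_label(mesh$nodes + field$u) - out_by_label(mesh$nodes)
  v[is.na(v)] <- 0
  v <- pmax(v, 0)
  if (per_tissue) {
    nm <- names(TISSUE_LABELS)[match(as.integer(names(v)), TISSUE_LABELS)]
    out <- as.list(v); names(out) <- nm
    return(c(list(total = sum(v)), out))
  }
  sum(v)
}

# Rasterise a tet mesh: voxel centres covered by the mesh, with the label
# of the covering tet.  Deterministic; ties resolved by tet order.
rasterize_mesh <- function(mesh, nodes, pitch) {
  lo <- apply(nodes, 2L, min) - pitch
  hi <- apply(nodes, 2L, max) + pitch
  nvx <- pmax(ceiling((hi - lo) / pitch), 1L)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(nvx[a]) - 0.5) * pitch)
  occ <- array(0L, dim = nvx)

  tt <- mesh$tets
  a <- nodes[tt[, 1], , drop = FALSE]; b <- nodes[tt[, 2], , drop = FALSE]
  c <- nodes[tt[, 3], , drop = FALSE]; d <- nodes[tt[, 4], , drop = FALSE]
  for (t in seq_len(nrow(tt))) {
    P <- rbind(a[t, ], b[t, ], c[t, ], d[t, ])
    i0 <- pmax(1L, ceiling((apply(P, 2, min) - lo) / pitch - 0.5) + 1L)
    i1 <- pmin(nvx, floor((apply(P, 2, max) - lo) / pitch - 0.5) + 1L)
    if (any(i1 < i0)) next
    xs <- ax[[1]][i0[1]:i1[1]]; ys <- ax[[2]][i0[2]:i1[2]]
    zs <- ax[[3]][i0[3]:i1[3]]
    g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    M <- cbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])
    bary <- t(solve(M, t(sweep(g, 2L, P[1, ]))))
    inside <- bary[, 1] >= -1e-12 & bary[, 2] >= -1e-12 & bary[, 3] >= -1e-12 &
      rowSums(bary) <= 1 + 1e-12
    if (!any(inside)) next
    gi <- as.matrix(expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2],
                                k = i0[3]:i1[3]))[inside, , drop = FALSE]
    occ[gi] <- mesh$tet_label[t]
  }
  filled <- which(occ > 0L)
  gi <- arrayInd(filled, .dim = nvx)
  centers <- cbind(ax[[1]][gi[, 1]], ax[[2]][gi[, 2]], ax[[3]][gi[, 3]])
  list(centers = centers, label = occ[filled], dim = nvx, origin = lo,
       pitch = pitch)
}

#' Brute-force released-volume oracle
#'
#' Independent check of [released_volume()]: loops over candidate voxel
#' centres outside the cavity and tests membership in the deformed mesh by
#' barycentric point-in-tet queries (different code path from the
#' per-tet rasterisation).
#'
#' @inheritParams released_volume
#' @return Released volume in cm^3.
#' @export
released_volume_bruteforce <- function(mesh, field, orbit_region, pitch = 0.5) {
  v1 <- outside_volume_bruteforce(mesh, mesh$nodes + field$u, orbit_region, pitch)
  v0 <- outside_volume_bruteforce(mesh, mesh$nodes, orbit_region, pitch)
  max(v1 - v0, 0)
}

outside_volume_bruteforce <- function(mesh, nodes, orbit_region, pitch) {
  lo <- apply(nodes, 2L, min) - pitch
  hi <- apply(nodes, 2L, max) + pitch
  nvx <- pmax(ceiling((hi - lo) / pitch), 1L)
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(nvx[a]) - 0.5) * pitch)
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  g <- g[orbit_region(g) > 0, , drop = FALSE]   # only candidates outside
  tt <- mesh$tets
  count <- 0L
  covered <- rep(FALSE, nrow(g))
  for (t in seq_len(nrow(tt))) {
    P <- nodes[tt[t, ], , drop = FALSE]
    cand <- which(!covered &
                    g[, 1] >= min(P[, 1]) & g[, 1] <= max(P[, 1]) &
                    g[, 2] >= min(P[, 2]) & g[, 2] <= max(P[, 2]) &
                    g[, 3] >= min(P[, 3]) & g[, 3] <= max(P[, 3]))
    if (!length(cand)) next
    M <- cbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])
    bary <- t(solve(M, t(sweep(g[cand, , drop = FALSE], 2L, P[1, ]))))
    inside <- bary[, 1] >= -1e-12 & bary[, 2] >= -1e-12 &
      bary[, 3] >= -1e-12 & rowSums(bary) <= 1 + 1e-12
    covered[cand[inside]] <- TRUE
  }
  sum(covered) * pitch^3 / 1000
}

#' Proptosis change
#'
#' Change of the anterior-most bulbus surface coordinate along the
#' anterior (+y) axis; positive when the bulbus recedes posteriorly.
#'
#' @param mesh a `tissue_mesh` with bulbus tets.
#' @param field a `displacement_field`.
#' @return Proptosis change in mm.
#' @export
proptosis_change <- function(mesh, field) {
  bt <- mesh$tets[mesh$tet_label == TISSUE_LABELS[["bulbus"]], , drop = FALSE]
  if (!nrow(bt)) stopf("mesh has no bulbus tets")
  bn <- unique(as.vector(bt))
  y0 <- max(mesh$nodes[bn, 2])
  y1 <- max(mesh$nodes[bn, 2] + field$u[bn, 2])
  y0 - y1
}

#' Outcome report for one simulated scenario
#'
#' @param scenario_id label for the scenario.
#' @param mesh,field,orbit_region as in [released_volume()].
#' @param area_cm2 affected wall area; defaults to the summed fragment
#'   areas recorded in the field's compiled plan.
#' @param pitch rasterisation pitch (mm).
#' @return Object of class `outcome_report` with affected area (cm^2),
#'   released volume (cm^3), volume per area (cm), proptosis change (mm)
#'   and the per-tissue displaced-volume breakdown.
#' @export
outcome_report <- function(scenario_id, mesh, field, orbit_region,
                           area_cm2 = NULL, pitch = 0.5) {
  cp <- attr(field, "compiled")
  if (is.null(area_cm2)) {
    if (is.null(cp)) stopf("area_cm2 missing and field carries no compiled plan")
    area_cm2 <- sum(vapply(cp$plan$fragments, `[[`, numeric(1), "area_cm2"))
  }
  rv <- released_volume(mesh, field, orbit_region, pitch = pitch,
                        per_tissue = TRUE)
  structure(list(scenario = scenario_id,
                 area_cm2 = area_cm2,
                 released_cm3 = rv$total,
                 volume_per_area = rv$total / area_cm2,
                 proptosis_mm = proptosis_change(mesh, field),
                 per_tissue_cm3 = rv[names(rv) != "total"]),
            class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("outcome_report '%s'\n", x$scenario))
  cat(sprintf("  affected area    %8.2f cm^2\n", x$area_cm2))
  cat(sprintf("  released volume  %8.2f cm^3\n", x$released_cm3))
  cat(sprintf("  volume per area  %8.3f cm^3/cm^2\n", x$volume_per_area))
  cat(sprintf("  proptosis change %8.2f mm\n", x$proptosis_mm))
  bt <- x$per_tissue_cm3
  if (length(bt))
    cat(sprintf("  by tissue: %s\n",
                paste(sprintf("%s %.2f", names(bt), unlist(bt)), collapse = ", ")))
  invisible(x)
}

#' Compare scenario outcome reports
#'
#' @param reports list of at least two `outcome_report`s.
#' @return Object of class `outcome_comparison`: a data.frame `table` with
#'   per-scenario area, volume, ratio, and a matrix `ratio_of_ratios`
#'   (pairwise volume-per-area ratios, rows over columns).
#' @export
compare_scenarios <- function(reports) {
  if (length(reports) < 2L) stopf("need at least two reports to compare")
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(scenario = r$scenario, area_cm2 = r$area_cm2,
               released_cm3 = r$released_cm3,
               volume_per_area = r$volume_per_area,
               proptosis_mm = r$proptosis_mm,
               stringsAsFactors = FALSE)))
  rr <- outer(tab$volume_per_area, tab$volume_per_area, `/`)
  dimnames(rr) <- list(tab$scenario, tab$scenario)
  structure(list(table = tab, ratio_of_ratios = rr),
            class = "outcome_comparison")
}

#' @export
print.outcome_comparison <- function(x, ...) {
  cat("Scenario comparison\n")
  print(x$table, row.names = FALSE)
  cat("volume-per-area ratios (row / column):\n")
  print(round(x$ratio_of_ratios, 3))
  invisible(x)
}

#' Write an outcome comparison to CSV / JSON
#'
#' @param comparison an `outcome_comparison`.
#' @param csv,json optional output paths.
#' @return The comparison, invisibly.
#' @export
write_comparison <- function(comparison, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(comparison$table, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(table = comparison$table,
                              ratio_of_ratios = comparison$ratio_of_ratios),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(comparison)
}
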