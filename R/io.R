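# Mesh / field / plan serialisation: ASCII VTU (VTK XML UnstructuredGrid)
# and PVD time series for external visualisation, ASCII STL for surfaces,
# YAML for surgical plan specifications.

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

#' Write a tetrahedral mesh (and optional fields) as ASCII VTU
#'
#' @param mesh a `tissue_mesh`.
#' @param path output file (.vtu).
#' @param nodes node coordinates to write (e.g. deformed), defaults to the
#'   mesh nodes.
#' @param point_data named list of per-node scalars (length n) or vector
#'   fields (n x 3 matrices).
#' @param cell_data named list of per-tet scalars.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, nodes = mesh$nodes,
                      point_data = list(), cell_data = list()) {
  n <- nrow(nodes); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(nodes, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1L, paste, collapse = " "), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(as.character(seq_len(m) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('        </DataArray>')
  w('      </Cells>')
  cell_data <- c(list(tissue = as.numeric(mesh$tet_label)), cell_data)
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      nc <- if (is.null(dim(val))) 1L else ncol(val)
      w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, nc))
      if (nc == 1L) writeLines(fmt_num(val), con)
      else writeLines(apply(val, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('      <CellData>')
  for (nm in names(cell_data)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
    writeLines(fmt_num(cell_data[[nm]]), con)
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a displacement time series as VTU files plus a PVD index
#'
#' One VTU per step (deformed geometry with the accumulated displacement
#' as point data) referenced from a ParaView .pvd collection file.
#'
#' @param mesh a `tissue_mesh`; @param field a `displacement_field` with
#'   per-step increments; @param basename output basename (without
#'   extension).
#' @return The .pvd path, invisibly.
#' @export
write_vtu_series <- function(mesh, field, basename) {
  steps <- field$steps %||% list(field$u)
  acc <- matrix(0, nrow(mesh$nodes), 3)
  files <- character(length(steps))
  for (s in seq_along(steps)) {
    acc <- acc + steps[[s]]
    files[s] <- sprintf("%s_%03d.vtu", basename, s)
    write_vtu(mesh, files[s], nodes = mesh$nodes + acc,
              point_data = list(displacement = acc))
  }
  pvd <- paste0(basename, ".pvd")
  con <- file(pvd, "w")
  writeLines(c('<?xml version="1.0"?>',
               '<VTKFile type="Collection" version="0.1">',
               '  <Collection>',
               sprintf('    <DataSet timestep="%d" file="%s"/>',
                       seq_along(files), basename(files)),
               '  </Collection>', '</VTKFile>'), con)
  close(con)
  invisible(pvd)
}

#' Write a triangle surface as ASCII STL
#'
#' @param mesh a `surface_mesh` (or any list with `vertices` and
#'   `triangles`); @param path output path; @param name solid name.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  v <- mesh$vertices; tr <- mesh$triangles
  nrm <- tri_normal(v[tr[, 1], , drop = FALSE], v[tr[, 2], , drop = FALSE],
                    v[tr[, 3], , drop = FALSE])
  nrm <- nrm / pmax(row_norms(nrm), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (t in seq_len(nrow(tr))) {
    writeLines(c(sprintf("  facet normal %s", paste(fmt_num(nrm[t, ]), collapse = " ")),
                 "    outer loop",
                 sprintf("      vertex %s", paste(fmt_num(v[tr[t, 1], ]), collapse = " ")),
                 sprintf("      vertex %s", paste(fmt_num(v[tr[t, 2], ]), collapse = " ")),
                 sprintf("      vertex %s", paste(fmt_num(v[tr[t, 3], ]), collapse = " ")),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Export a wall fragment (original and displaced) as STL
#'
#' @param mesh a `tissue_mesh`; @param fragment a `wall_fragment`;
#' @param transform optional `rigid_transform` applied to the copy written
#'   to `displaced_path`.
#' @param path,displaced_path output files.
#' @return `path`, invisibly.
#' @export
write_fragment_stl <- function(mesh, fragment, path, transform = NULL,
                               displaced_path = NULL) {
  fac <- mesh$boundary$facets[fragment$facets, , drop = FALSE]
  used <- sort(unique(as.vector(fac)))
  remap <- match(fac, used)
  dim(remap) <- dim(fac)
  sm <- list(vertices = mesh$nodes[used, , drop = FALSE], triangles = remap)
  write_stl(sm, path, name = tolower(fragment$wall_tag))
  if (!is.null(transform) && !is.null(displaced_path)) {
    sm$vertices <- apply_transform(transform, sm$vertices)
    write_stl(sm, displaced_path, name = paste0(tolower(fragment$wall_tag),
                                                "_displaced"))
  }
  invisible(path)
}

# --- plan specifications (YAML) -----------------------------------------

#' Read / write surgical plan specifications as YAML
#'
#' A plan specification names the scenario, the wall fragments (by tag and
#' optional extent) and the load parameters; it is realised against a
#' concrete mesh with [realize_plan()].
#'
#' @param spec a plan-specification list (`scenario`, `pressure_kPa`,
#'   `fragments` = list of `wall_tag`/`y_range`/`phi_range`, and for
#'   valgization `shift_mm`, `angle_deg`, `contact_tol_mm`, `drag_taper`).
#' @param path YAML file path.
#' @return `read_plan_spec()` returns the specification list.
#' @export
write_plan_spec <- function(spec, path) {
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_plan_spec
#' @export
read_plan_spec <- function(path) {
  if (!file.exists(path)) stopf("plan spec not found: %s", path)
  yaml::read_yaml(path)
}

#' @rdname write_plan_spec
#' @param mesh the `tissue_mesh` to realise the plan against.
#' @export
realize_plan <- function(spec, mesh) {
  frags <- lapply(spec$fragments, function(fs) {
    extent <- NULL
    if (!is.null(fs$y_range) || !is.null(fs$phi_range))
      extent <- list(y_range = unlist(fs$y_range),
                     phi_range = unlist(fs$phi_range))
    select_wall_fragment(mesh, fs$wall_tag, extent)
  })
  surgical_plan(scenario = spec$scenario, fragments = frags,
                shift_mm = spec$shift_mm %||% 0,
                angle_deg = spec$angle_deg %||% 0,
                pressure_kPa = spec$pressure_kPa %||% 1.2,
                contact_tol_mm = spec$contact_tol_mm %||% 1.0,
                drag_taper = spec$drag_taper %||% 1.5,
                id = spec$id %||% tolower(spec$scenario))
}
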