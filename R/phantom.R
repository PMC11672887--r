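# Parametric synthetic orbital phantom.
#
# The phantom emulates the output of a segmented orbital CT: a conical bony
# orbit (apex posterior, rim anterior) whose cavity is filled with fat,
# rectus-like muscle bodies and a spherical bulbus, an anterior bony
# membrane sealing the aperture (orbital-septum stand-in), and a temporalis
# body lying outside the lateral wall.  All tissue regions are defined
# analytically, so exact volumes and wall-sector areas are available as
# ground truth for every downstream stage.

#' Specification of a synthetic orbital phantom
#'
#' Defines the geometry of the synthetic orbit.  The orbit is a truncated
#' cone with its apex at the world origin and its axis along +y (anterior);
#' x points laterally, z superiorly.  All lengths are in mm.
#'
#' @param voxel_size edge length of a (cubic) voxel, mm.
#' @param grid_shape integer vector of three grid dimensions.
#' @param origin world position (mm) of the corner of voxel (0,0,0).
#' @param orbit_apex_depth height of the orbital cone (apex to rim), mm.
#' @param orbit_rim_radius cone radius at the anterior rim, mm.
#' @param orbit_apex_radius cone radius at the (truncated) apex, mm.
#' @param bulbus_radius radius of the spherical bulbus (globe), mm.
#' @param bulbus_center world position of the bulbus center, mm.
#' @param muscle_count number of rectus-like muscle bodies (cylinders
#'   parallel to the orbital axis, evenly spaced around it).
#' @param muscle_radius radius of each muscle cylinder, mm.
#' @param muscle_offset distance of muscle axes from the orbital axis, mm.
#' @param temporalis_offset clearance between the outer bone surface and the
#'   temporalis body, mm.
#' @param temporalis_thickness radial thickness of the temporalis body, mm.
#' @param wall_thickness perpendicular thickness of the bony wall shell, mm.
#' @param wall_region_angles named numeric vector of angular extents
#'   (degrees) of the lateral, floor, medial and roof wall sectors; must sum
#'   to 360.  The lateral sector is centred on +x, and sectors follow in
#'   the order lateral, roof, medial, floor going from +x towards +z.
#' @param seed integer seed recorded with the spec (the generator itself is
#'   deterministic; the seed is carried so that downstream sampling tied to
#'   a phantom is reproducible).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size = 1.0,
                         grid_shape = c(56L, 52L, 48L),
                         origin = c(-24, -4, -24),
                         orbit_apex_depth = 42,
                         orbit_rim_radius = 19,
                         orbit_apex_radius = 3,
                         bulbus_radius = 10.5,
                         bulbus_center = c(0, 29, 0),
                         muscle_count = 4L,
                         muscle_radius = 2.0,
                         muscle_offset = 4.0,
                         temporalis_offset = 0.5,
                         temporalis_thickness = 8,
                         wall_thickness = 2.0,
                         wall_region_angles = c(lateral = 121, floor = 90,
                                                medial = 59, roof = 90),
                         seed = 1L) {
  spec <- list(voxel_size = voxel_size,
               grid_shape = as.integer(grid_shape),
               origin = as.numeric(origin),
               orbit_apex_depth = orbit_apex_depth,
               orbit_rim_radius = orbit_rim_radius,
               orbit_apex_radius = orbit_apex_radius,
               bulbus_radius = bulbus_radius,
               bulbus_center = as.numeric(bulbus_center),
               muscle_count = as.integer(muscle_count),
               muscle_radius = muscle_radius,
               muscle_offset = muscle_offset,
               temporalis_offset = temporalis_offset,
               temporalis_thickness = temporalis_thickness,
               wall_thickness = wall_thickness,
               wall_region_angles = wall_region_angles,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

# Cone radius at height y above the apex (linear taper), clamped outside.
cone_radius <- function(spec, y) {
  s <- (spec$orbit_rim_radius - spec$orbit_apex_radius) / spec$orbit_apex_depth
  spec$orbit_apex_radius + s * pmin(pmax(y, 0), spec$orbit_apex_depth)
}

cone_half_angle <- function(spec) {
  atan2(spec$orbit_rim_radius - spec$orbit_apex_radius, spec$orbit_apex_depth)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Synthetic orbital phantom spec\n")
  cat(sprintf("  grid %d x %d x %d at %.3g mm voxels\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3], x$voxel_size))
  cat(sprintf("  orbit: depth %.3g mm, rim radius %.3g mm, apex radius %.3g mm\n",
              x$orbit_apex_depth, x$orbit_rim_radius, x$orbit_apex_radius))
  cat(sprintf("  bulbus: r = %.3g mm at (%.3g, %.3g, %.3g)\n",
              x$bulbus_radius, x$bulbus_center[1], x$bulbus_center[2],
              x$bulbus_center[3]))
  cat(sprintf("  muscles: %d, r = %.3g mm; wall thickness %.3g mm\n",
              x$muscle_count, x$muscle_radius, x$wall_thickness))
  invisible(x)
}

validate_phantom_spec <- function(spec) {
  lens <- c(voxel_size = spec$voxel_size,
            orbit_apex_depth = spec$orbit_apex_depth,
            orbit_rim_radius = spec$orbit_rim_radius,
            orbit_apex_radius = spec$orbit_apex_radius,
            bulbus_radius = spec$bulbus_radius,
            muscle_radius = spec$muscle_radius,
            wall_thickness = spec$wall_thickness)
  if (any(lens <= 0))
    stopf("phantom spec invariant violated: non-positive length(s): %s",
          paste(names(lens)[lens <= 0], collapse = ", "))
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 8L))
    stopf("phantom spec invariant violated: grid_shape must be 3 integers >= 8")
  if (abs(sum(spec$wall_region_angles) - 360) > 1e-9)
    stopf("phantom spec invariant violated: wall sectors must partition 360 degrees (sum = %g)",
          sum(spec$wall_region_angles))
  need <- c("lateral", "floor", "medial", "roof")
  if (!all(need %in% names(spec$wall_region_angles)))
    stopf("phantom spec invariant violated: wall_region_angles must name %s",
          paste(need, collapse = ", "))

  # bulbus strictly inside the orbital cone (and clear of the anterior
  # membrane slab, which occupies the last wall_thickness of the cone)
  bc <- spec$bulbus_center
  rho <- sqrt(bc[1]^2 + bc[3]^2)
  alpha <- cone_half_angle(spec)
  clear <- (cone_radius(spec, bc[2]) - rho) * cos(alpha)
  if (clear <= spec$bulbus_radius ||
      bc[2] - spec$bulbus_radius <= 0 ||
      bc[2] + spec$bulbus_radius >= spec$orbit_apex_depth - spec$wall_thickness)
    stopf(paste0("phantom spec invariant violated: bulbus (r = %g mm at y = %g)",
                 " does not fit strictly inside the orbital cone"),
          spec$bulbus_radius, bc[2])

  # grid must contain orbit + temporalis
  t_r <- spec$wall_thickness / cos(alpha)
  ext_hi <- c(spec$orbit_rim_radius + t_r + spec$temporalis_offset +
                spec$temporalis_thickness,
              spec$orbit_apex_depth,
              spec$orbit_rim_radius + t_r)
  ext_lo <- c(-(spec$orbit_rim_radius + t_r), -spec$wall_thickness,
              -(spec$orbit_rim_radius + t_r))
  hi <- spec$origin + spec$grid_shape * spec$voxel_size
  if (any(spec$origin > ext_lo) || any(hi < ext_hi))
    stopf("phantom spec invariant violated: grid does not contain the orbit plus temporalis body")

  # muscles must fit in the cavity, clear of each other and of the bulbus
  if (spec$muscle_count > 0L) {
    mg <- muscle_geometry(spec)
    if (mg$y1 <= mg$y0)
      stopf("phantom spec invariant violated: no room for muscle bodies between apex and bulbus")
    if (spec$muscle_count > 1L) {
      gap <- 2 * spec$muscle_offset * sin(pi / spec$muscle_count)
      if (gap < 2 * spec$muscle_radius)
        stopf("phantom spec invariant violated: muscle bodies overlap (spacing %.2g < diameter %.2g)",
              gap, 2 * spec$muscle_radius)
    }
    need_r <- (spec$muscle_offset + spec$muscle_radius) / cos(alpha) +
      spec$muscle_radius * 0  # perpendicular clearance handled below
    r0 <- cone_radius(spec, mg$y0)
    if ((r0 - spec$muscle_offset) * cos(alpha) < spec$muscle_radius)
      stopf("phantom spec invariant violated: muscle bodies poke through the orbital wall near the apex")
  }
  invisible(spec)
}

# muscle cylinder extents: from just anterior of the apex to 1 mm short of
# the bulbus back pole, so cylinders are exact (no spherical clipping)
muscle_geometry <- function(spec) {
  alpha <- cone_half_angle(spec)
  # smallest y where the cylinder fits inside the cone
  s <- (spec$orbit_rim_radius - spec$orbit_apex_radius) / spec$orbit_apex_depth
  r_need <- spec$muscle_offset + spec$muscle_radius / cos(alpha)
  y0 <- max(0, (r_need - spec$orbit_apex_radius) / s) + 0.6
  y1 <- spec$bulbus_center[2] - spec$bulbus_radius - 1.3
  # ring rotated 10 degrees off the coordinate axes so that cylinder cross
  # sections are in generic position with respect to the voxel grid
  angles <- 2 * pi * (seq_len(max(spec$muscle_count, 0L)) - 1L) /
    max(spec$muscle_count, 1L) + 10 * pi / 180
  list(y0 = y0, y1 = y1,
       centers = cbind(spec$muscle_offset * cos(angles),
                       spec$muscle_offset * sin(angles)))
}

# angular extent [lo, hi) of each wall sector, degrees in (-180, 180] wrapped;
# returned as a data.frame with columns sector, lo, hi (lo may exceed hi when
# the sector wraps across +/-180)
wall_sector_table <- function(wall_region_angles) {
  ext <- wall_region_angles[c("lateral", "roof", "medial", "floor")]
  lo <- -ext[["lateral"]] / 2 + c(0, cumsum(ext))[1:4]
  hi <- lo + ext
  data.frame(sector = c("LATERAL_WALL", "ROOF_WALL", "MEDIAL_WALL", "FLOOR_WALL"),
             lo = as.numeric(lo), hi = as.numeric(hi),
             stringsAsFactors = FALSE)
}

# sector name for angles phi (degrees, atan2(z, x))
wall_sector_of <- function(phi, wall_region_angles) {
  tab <- wall_sector_table(wall_region_angles)
  phi <- (phi - tab$lo[1]) %% 360 + tab$lo[1]   # wrap into [lo_lateral, +360)
  out <- character(length(phi))
  for (r in seq_len(nrow(tab))) {
    sel <- phi >= tab$lo[r] - 1e-12 & phi < tab$hi[r]
    out[sel] <- tab$sector[r]
  }
  out[out == ""] <- tab$sector[nrow(tab)]
  out
}

#' Generate a synthetic orbital labelmap with analytic ground truth
#'
#' Produces a voxel labelmap emulating a segmented orbital CT together with
#' the exact (analytic) volumes and wall-sector areas of the generating
#' geometry.  The generator is fully deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return A list with components `volume` (a `label_volume`) and
#'   `ground_truth` (a `phantom_ground_truth`: analytic per-tissue volumes
#'   in cm^3, wall-sector areas in cm^2, and the orbital-cavity
#'   signed-distance descriptor, negative inside).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$grid_shape
  ax <- grid_axes(d, spec$voxel_size, spec$origin)
  x <- ax[[1]]; y <- ax[[2]]; z <- ax[[3]]
  nx <- d[1]; ny <- d[2]; nz <- d[3]

  alpha <- cone_half_angle(spec)
  t_r <- spec$wall_thickness / cos(alpha)   # radial thickness of the shell
  wt <- spec$wall_thickness
  depth <- spec$orbit_apex_depth

  # 2D fields in (x, z) replicated over y slices keeps memory modest
  rho <- sqrt(outer(x^2, z^2, `+`))         # nx x nz
  labels <- array(0L, dim = d)
  r_y <- cone_radius(spec, y)

  bc <- spec$bulbus_center
  rb2 <- spec$bulbus_radius^2
  mg <- if (spec$muscle_count > 0L) muscle_geometry(spec) else NULL

  tseg <- temporalis_geometry(spec)
  phi <- outer(x, z, function(xx, zz) atan2(zz, xx)) * 180 / pi  # nx x nz

  for (j in seq_len(ny)) {
    yj <- y[j]
    sl <- matrix(0L, nx, nz)
    if (yj > 0 && yj < depth) {
      inside <- rho < r_y[j]
      shell <- !inside & rho < r_y[j] + t_r
      sl[shell] <- 1L
      if (yj >= depth - wt) {
        sl[inside] <- 1L                     # anterior membrane slab
      } else {
        sl[inside] <- 2L                     # fat (overwritten below)
        if (!is.null(mg) && yj >= mg$y0 && yj <= mg$y1) {
          for (k in seq_len(spec$muscle_count)) {
            cc <- mg$centers[k, ]
            msk <- outer((x - cc[1])^2, (z - cc[2])^2, `+`) < spec$muscle_radius^2
            sl[msk & inside] <- 3L
          }
        }
        dy2 <- (yj - bc[2])^2
        if (dy2 < rb2) {
          bmask <- outer((x - bc[1])^2, (z - bc[3])^2, `+`) < rb2 - dy2
          sl[bmask] <- 4L
        }
      }
    } else if (yj <= 0 && yj >= -wt) {
      sl[rho < spec$orbit_apex_radius + t_r] <- 1L   # posterior cap
    }
    # temporalis: exterior body over the lateral sector
    if (yj >= tseg$y0 && yj <= tseg$y1) {
      r_in <- r_y[j] + t_r + spec$temporalis_offset
      tm <- rho >= r_in & rho < r_in + spec$temporalis_thickness &
        phi >= tseg$phi_lo & phi <= tseg$phi_hi
      sl[tm & sl == 0L] <- 5L
    }
    labels[, j, ] <- sl
  }

  volume <- label_volume(labels, spec$voxel_size, spec$origin,
                         geometry = phantom_geometry(spec))
  list(volume = volume, ground_truth = phantom_ground_truth(spec))
}

temporalis_geometry <- function(spec) {
  sect <- wall_sector_table(spec$wall_region_angles)
  lat <- sect[sect$sector == "LATERAL_WALL", ]
  list(y0 = 0.15 * spec$orbit_apex_depth,
       y1 = 0.75 * spec$orbit_apex_depth,
       phi_lo = lat$lo * 0.85, phi_hi = lat$hi * 0.85)
}

# compact geometric descriptor attached to phantom labelmaps so that the
# mesher and surgery modules can classify wall sectors without the spec
phantom_geometry <- function(spec) {
  list(apex_y = 0,
       rim_y = spec$orbit_apex_depth,
       apex_radius = spec$orbit_apex_radius,
       rim_radius = spec$orbit_rim_radius,
       wall_thickness = spec$wall_thickness,
       wall_region_angles = spec$wall_region_angles,
       temporalis = temporalis_geometry(spec))
}

frustum_volume <- function(r0, r1, h) pi * h * (r0^2 + r0 * r1 + r1^2) / 3

#' @rdname generate_phantom
#' @details `phantom_ground_truth()` computes the exact tissue volumes and
#'   wall-sector areas implied by a spec without voxelising anything.
#' @export
phantom_ground_truth <- function(spec) {
  depth <- spec$orbit_apex_depth; wt <- spec$wall_thickness
  alpha <- cone_half_angle(spec)
  t_r <- wt / cos(alpha)
  r_at <- function(yy) cone_radius(spec, yy)

  cone_all <- frustum_volume(spec$orbit_apex_radius, spec$orbit_rim_radius, depth)
  membrane <- frustum_volume(r_at(depth - wt), spec$orbit_rim_radius, wt)
  cavity <- cone_all - membrane
  bulbus <- 4 / 3 * pi * spec$bulbus_radius^3
  muscle <- 0
  if (spec$muscle_count > 0L) {
    mg <- muscle_geometry(spec)
    muscle <- spec$muscle_count * pi * spec$muscle_radius^2 * (mg$y1 - mg$y0)
  }
  fat <- cavity - bulbus - muscle

  shell <- frustum_volume(spec$orbit_apex_radius + t_r,
                          spec$orbit_rim_radius + t_r, depth) - cone_all
  cap <- pi * (spec$orbit_apex_radius + t_r)^2 * wt
  bone <- shell + cap + membrane

  tg <- temporalis_geometry(spec)
  # temporalis: angular sector of an annulus with y-dependent inner radius
  frac <- (tg$phi_hi - tg$phi_lo) / 360
  r_in0 <- r_at(tg$y0) + t_r + spec$temporalis_offset
  r_in1 <- r_at(tg$y1) + t_r + spec$temporalis_offset
  th <- spec$temporalis_thickness
  ann <- function(ri) pi * ((ri + th)^2 - ri^2)
  # annulus area is linear in the inner radius, which varies linearly in y,
  # so the trapezoid rule is exact
  temporalis <- frac * (tg$y1 - tg$y0) * (ann(r_in0) + ann(r_in1)) / 2

  # wall area in contact with orbital tissue: the cone flank between the
  # apex plane and the anterior membrane (the rim ring covered by the
  # membrane is not part of any osteotomy fragment)
  y_top <- depth - wt
  slant <- sqrt(y_top^2 + (r_at(y_top) - spec$orbit_apex_radius)^2)
  lat_area_total <- pi * (spec$orbit_apex_radius + r_at(y_top)) * slant
  sector_areas <- spec$wall_region_angles / 360 * lat_area_total

  sdf <- make_cone_sdf(spec)

  structure(list(
    volumes_cm3 = c(fat = fat, muscle = muscle, bulbus = bulbus,
                    bone = bone, temporalis = temporalis, cavity = cavity) / 1000,
    sector_areas_cm2 = sector_areas / 100,
    total_wall_area_cm2 = lat_area_total / 100,
    orbit_region = sdf,
    cone = list(apex_y = 0, rim_y = depth,
                apex_radius = spec$orbit_apex_radius,
                rim_radius = spec$orbit_rim_radius,
                half_angle = alpha)),
    class = "phantom_ground_truth")
}

# signed distance (negative inside) to the original orbital cavity: the full
# truncated cone from apex plane to rim plane
make_cone_sdf <- function(spec) {
  depth <- spec$orbit_apex_depth
  alpha <- cone_half_angle(spec)
  force(spec)
  function(pts) {
    pts <- rbind(pts)  # accept vectors
    rho <- sqrt(pts[, 1]^2 + pts[, 3]^2)
    y <- pts[, 2]
    d_lat <- (rho - cone_radius(spec, y)) * cos(alpha)
    pmax(d_lat, -y, y - depth)
  }
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat("Phantom ground truth (analytic)\n")
  v <- x$volumes_cm3
  cat(sprintf("  volumes [cm^3]: fat %.2f, muscle %.2f, bulbus %.2f, cavity %.2f\n",
              v["fat"], v["muscle"], v["bulbus"], v["cavity"]))
  a <- x$sector_areas_cm2
  cat(sprintf("  wall sectors [cm^2]: %s\n",
              paste(sprintf("%s %.2f", names(a), a), collapse = ", ")))
  invisible(x)
}

#' Labelled voxel volume
#'
#' Container for a 3D tissue labelmap.  Labels must be codes from
#' [TISSUE_LABELS].
#'
#' @param labels 3D integer array of label codes.
#' @param voxel_size voxel edge length, mm.
#' @param origin world coordinates (mm) of the corner of voxel (0,0,0).
#' @param geometry optional orbital geometry descriptor (attached by
#'   [generate_phantom()]; used for wall-sector classification).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size, origin = c(0, 0, 0),
                         geometry = NULL) {
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(TISSUE_LABELS))
  if (length(bad))
    stopf("unknown label code(s): %s", paste(sort(bad), collapse = ", "))
  if (all(labels == 0L))
    warnf("label volume contains no tissue labels")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), geometry = geometry),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels at %.3g mm\n",
              d[1], d[2], d[3], x$voxel_size))
  tab <- table(factor(x$labels, levels = TISSUE_LABELS,
                      labels = names(TISSUE_LABELS)))
  v <- as.numeric(tab) * x$voxel_size^3 / 1000
  for (i in seq_along(tab))
    if (tab[i] > 0)
      cat(sprintf("  %-10s %8d voxels  %8.2f cm^3\n",
                  names(tab)[i], as.integer(tab[i]), v[i]))
  invisible(x)
}

#' Per-tissue voxel volumes
#'
#' @param volume a `label_volume`.
#' @return Named numeric vector of tissue volumes in mm^3 (voxel counts
#'   times voxel volume).
#' @export
voxel_volumes <- function(volume) {
  tab <- table(factor(volume$labels, levels = TISSUE_LABELS,
                      labels = names(TISSUE_LABELS)))
  as.numeric(tab) * volume$voxel_size^3 -> v
  names(v) <- names(tab)
  v
}

#' @export
plot.label_volume <- function(x, axis = 3L, slice = NULL, ...) {
  d <- dim(x$labels)
  slice <- slice %||% (d[axis] %/% 2L)
  sl <- switch(axis,
               x$labels[slice, , ], x$labels[, slice, ], x$labels[, , slice])
  cols <- c("white", "grey40", "gold", "firebrick", "steelblue", "tan")
  graphics::image(z = sl, col = cols, zlim = c(-0.5, 5.5),
                  useRaster = TRUE, asp = 1,
                  main = sprintf("labelmap slice %d (axis %d)", slice, axis), ...)
  invisible(x)
}

#' Read and write labelmaps as NIfTI-1
#'
#' Labelmaps are stored as integer NIfTI-1 volumes; the voxel size and world
#' origin are carried in the sform (code 2).  `save_labelmap()` then
#' `load_labelmap()` reproduces labels, voxel size and origin exactly for
#' values representable in single precision.
#'
#' @param volume a `label_volume`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `load_labelmap()` returns a `label_volume`; `save_labelmap()`
#'   returns `path` invisibly.
#' @export
save_labelmap <- function(volume, path) {
  img <- RNifti::asNifti(volume$labels, datatype = "int16", internal = FALSE)
  m <- diag(c(rep(volume$voxel_size, 3), 1))
  m[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname save_labelmap
#' @export
load_labelmap <- function(path) {
  if (!file.exists(path)) stopf("labelmap file not found: %s", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  x <- RNifti::xform(img, useQuaternionFirst = FALSE)
  labels <- array(as.integer(img), dim = dim(img))
  label_volume(labels, voxel_size = x[1, 1], origin = x[1:3, 4])
}

#' Serialize a phantom spec to YAML
#'
#' @param spec a `phantom_spec`; @param path file path.
#' @return `read_phantom_spec()` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  lst <- unclass(spec)
  lst$wall_region_angles <- as.list(spec$wall_region_angles)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$wall_region_angles <- unlist(lst$wall_region_angles)
  do.call(phantom_spec, lst)
}

# 6-connected flood fill over passable voxels from seed labels; returns a
# logical array of reached voxels.  Used to verify that the bony shell seals
# the intraorbital tissues.
flood_fill6 <- function(labels, seed_labels, blocked_labels) {
  passable <- !(labels %in% blocked_labels)
  dim(passable) <- dim(labels)
  reach <- labels %in% seed_labels
  dim(reach) <- dim(labels)
  d <- dim(labels)
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & passable
    grown <- grown | reach
    if (identical(grown, reach)) break
    reach <- grown
  }
  reach
}

#' Check that intraorbital tissue is sealed by bone
#'
#' Performs a 6-connected flood fill from fat voxels through any non-bone
#' voxels and reports whether the background is reachable without crossing
#' bone.
#'
#' @param volume a `label_volume`.
#' @return TRUE if no fat-to-background path avoids bone.
#' @export
cavity_sealed <- function(volume) {
  reach <- flood_fill6(volume$labels, seed_labels = 2L, blocked_labels = 1L)
  !any(reach & volume$labels == 0L)
}
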