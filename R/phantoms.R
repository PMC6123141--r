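# Synthetic phantoms: dose grids, contoured structures and analytic truth.
# These are the package's ground-truth fixtures; every shape has a closed-form
# volume and, for uniform / z-gradient dose models, closed-form dose summaries.

#' Dose grid container
#'
#' A 3-D dose array with DICOM-style geometry: `origin` is the patient-space
#' coordinate (mm) of the first voxel center, `pixel_spacing` is `c(dx, dy)`
#' in mm, and `z_offsets` are per-plane offsets (mm) from `origin[3]`. Stored
#' values times `dose_scaling` are dose in Gy; in-memory phantoms use
#' `dose_scaling = 1` with values already in Gy.
#'
#' @param values numeric 3-D array indexed `[i, j, k]` for x, y, z.
#' @param origin numeric length-3, mm.
#' @param pixel_spacing numeric length-2 `c(dx, dy)`, mm.
#' @param z_offsets numeric, strictly monotone plane offsets in mm; one per
#'   plane of `values`.
#' @param dose_scaling Gy per stored unit.
#' @param units dose units; only `"GY"` is supported.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, pixel_spacing, z_offsets,
                      dose_scaling = 1, units = "GY") {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L,
            length(origin) == 3L,
            length(pixel_spacing) == 2L,
            length(z_offsets) == dim(values)[3L])
  if (!identical(toupper(units), "GY"))
    stop("dose units must be GY, got: ", units)
  if (length(z_offsets) > 1L) {
    dz <- diff(z_offsets)
    if (!(all(dz > 0) || all(dz < 0)))
      stop("z_offsets must be strictly monotone")
    if (z_offsets[2] < z_offsets[1]) {  # normalize to increasing z
      values <- values[, , rev(seq_along(z_offsets)), drop = FALSE]
      z_offsets <- rev(z_offsets)
    }
  }
  if (min(values) * dose_scaling < 0) stop("scaled dose must be >= 0")
  structure(list(values = values, origin = as.numeric(origin),
                 pixel_spacing = as.numeric(pixel_spacing),
                 z_offsets = as.numeric(z_offsets),
                 dose_scaling = dose_scaling, units = "GY"),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %.3g x %.3g mm, %d planes\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2], d[3]))
  cat(sprintf("  dose range %.3f - %.3f Gy (scaling %.4g)\n",
              min(x$values) * x$dose_scaling, max(x$values) * x$dose_scaling,
              x$dose_scaling))
  invisible(x)
}

# Scaled dose values in Gy.
dose_values <- function(grid) grid$values * grid$dose_scaling

# Voxel-center coordinate axes in mm.
grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$pixel_spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$pixel_spacing[2],
       z = grid$origin[3] + grid$z_offsets)
}

# Per-plane slab thickness: forward gap, last plane reuses the previous gap.
plane_thickness <- function(z) {
  n <- length(z)
  if (n == 1L) return(NA_real_)
  g <- diff(z)
  c(g, g[n - 1L])
}

#' ROI planar contours
#'
#' Per-slice closed planar rings in patient coordinates (mm), the geometry
#' representation every downstream computation consumes. Rings on the same
#' slice follow the DICOM convention: a ring inside the region accumulated so
#' far is a hole, a ring outside is an island.
#'
#' @param roi_name raw structure name as stored.
#' @param roi_type interpreted type (`PTV`, `ORGAN`, `EXTERNAL`, ...).
#' @param slices list of `list(z =, rings = list(list(x =, y =)))`.
#' @return object of class `roi_contours`.
#' @export
roi_contours <- function(roi_name, roi_type, slices) {
  keep <- list()
  for (s in slices) {
    rings <- Filter(function(r) length(r$x) >= 3L, s$rings)
    if (length(rings) < length(s$rings))
      warning(sprintf("ROI '%s': dropped %d ring(s) with < 3 points at z=%.3f",
                      roi_name, length(s$rings) - length(rings), s$z))
    if (length(rings)) keep[[length(keep) + 1L]] <- list(z = s$z, rings = rings)
  }
  if (length(keep)) {
    ord <- order(vapply(keep, function(s) s$z, 0))
    keep <- keep[ord]
  }
  for (s in keep)
    for (r in s$rings)
      if (!all(is.finite(r$x)) || !all(is.finite(r$y)) || !is.finite(s$z))
        stop("ROI '", roi_name, "': non-finite contour coordinates")
  structure(list(roi_name = roi_name, roi_type = toupper(roi_type),
                 slices = keep),
            class = "roi_contours")
}

#' @export
print.roi_contours <- function(x, ...) {
  nr <- sum(vapply(x$slices, function(s) length(s$rings), 0L))
  cat(sprintf("<roi_contours> '%s' [%s]: %d slice(s), %d ring(s)\n",
              x$roi_name, x$roi_type, length(x$slices), nr))
  invisible(x)
}

## ---- shape and dose-model constructors --------------------------------

#' Phantom shape primitives
#'
#' Constructors for the analytic shapes a phantom structure can take. All
#' dimensions in mm. `shape_ring` is a tube (outer cylinder minus coaxial
#' inner cylinder); `shape_two_islands` is two disjoint parallel cylinders
#' delineated within a single ROI (one ROI, two rings per slice).
#'
#' @param r,r_out,r_in radii (mm).
#' @param a,b,c box edge lengths along x, y, z (mm).
#' @param h height along z (mm).
#' @param sep center-to-center x separation of the two islands (mm).
#' @name phantom_shapes
#' @export
shape_sphere <- function(r) list(kind = "sphere", r = r)
#' @rdname phantom_shapes
#' @export
shape_box <- function(a, b, c) list(kind = "box", a = a, b = b, c = c)
#' @rdname phantom_shapes
#' @export
shape_cylinder <- function(r, h) list(kind = "cylinder", r = r, h = h)
#' @rdname phantom_shapes
#' @export
shape_ring <- function(r_out, r_in, h) {
  stopifnot(r_out > r_in)
  list(kind = "ring", r_out = r_out, r_in = r_in, h = h)
}
#' @rdname phantom_shapes
#' @export
shape_two_islands <- function(r, h, sep) {
  stopifnot(sep > 2 * r)
  list(kind = "two_islands", r = r, h = h, sep = sep)
}

#' Phantom dose models
#'
#' `dose_uniform`: constant dose everywhere. `dose_z_gradient`: dose =
#' `slope * (z - z_floor)` (Gy, z in mm, `z_floor` the lowest grid plane),
#' linear along z and non-negative. `dose_spherical_falloff`:
#' `d0 * 2^-((r/r50)^2)` with `r` the distance from `center`; `r50` is the
#' radius at which dose has fallen to half of `d0`.
#'
#' @param dose,d0 dose levels in Gy.
#' @param slope Gy per mm.
#' @param center length-3 mm.
#' @param r50 half-dose radius, mm.
#' @name dose_models
#' @export
dose_uniform <- function(dose) list(kind = "uniform", dose = dose)
#' @rdname dose_models
#' @export
dose_z_gradient <- function(slope) list(kind = "z_gradient", slope = slope)
#' @rdname dose_models
#' @export
dose_spherical_falloff <- function(center, d0, r50)
  list(kind = "spherical_falloff", center = center, d0 = d0, r50 = r50)

#' Declare a phantom structure
#'
#' @param name ROI name.
#' @param roi_type interpreted type (PTV, ORGAN, EXTERNAL, ...).
#' @param shape a [phantom_shapes] object.
#' @param center length-3 center in mm.
#' @export
structure_spec <- function(name, roi_type, shape, center = c(0, 0, 0)) {
  list(name = name, roi_type = roi_type, shape = shape,
       center = as.numeric(center))
}

#' Plan metadata for synthetic filesets
#'
#' Everything the RT Plan / Structure writer needs beyond geometry. The
#' treatment-site point of interest is written as a POI named `"tx: <site>"`
#' so the ingest convention can be exercised end to end.
#'
#' @param mrn medical record number.
#' @param rx list of fraction groups, each `list(fxs =, fx_dose =, name =)`
#'   (dose in Gy); `rx_percent` optional, defaults 100.
#' @param beams list of beams, each a list with `name`, `energy` (MV),
#'   `mu`, `gantry_start`, `gantry_end`, `ssd` (mm) and optional fields; beams
#'   are assigned to fraction groups round-robin by `fx_group`.
#' @param brachy if TRUE the plan is written as a brachytherapy plan: no
#'   beams, `tx_time` recorded.
#' @param ... see argument list.
#' @export
plan_meta <- function(mrn = "PH000001",
                      patient_name = "Phantom^Test",
                      birthdate = "1960-01-01",
                      sex = "O",
                      physician = "AB",
                      tx_site = "Phantom",
                      plan_label = "PhantomPlan",
                      sim_date = "2024-03-01",
                      rx = list(list(fxs = 30, fx_dose = 2, name = "initial")),
                      beams = list(
                        list(name = "Beam1", energy = 6, mu = 120,
                             gantry_start = 181, gantry_end = 179,
                             ssd = 920, fx_group = 1),
                        list(name = "Beam2", energy = 6, mu = 110,
                             gantry_start = 179, gantry_end = 181,
                             ssd = 915, fx_group = 1)),
                      machine = "LINAC1",
                      tx_modality = "Photon arc",
                      orientation = "HFS",
                      brachy = FALSE,
                      tx_time = NA_real_,
                      ...) {
  if (brachy) beams <- list()
  list(mrn = mrn, patient_name = patient_name, birthdate = birthdate,
       sex = sex, physician = physician, tx_site = tx_site,
       plan_label = plan_label, sim_date = sim_date, rx = rx, beams = beams,
       machine = machine, tx_modality = tx_modality,
       orientation = orientation, brachy = brachy, tx_time = tx_time, ...)
}

#' Specify a synthetic phantom
#'
#' The specification fixes everything: grid geometry, the analytic dose
#' model, the contoured structures and the plan metadata. `seed` pins every
#' stochastic choice (DICOM UIDs); geometry and dose are fully deterministic.
#'
#' @param grid_shape integer length-3, voxels along x, y, z.
#' @param spacing numeric length-3 `c(dx, dy, dz)` in mm.
#' @param origin first-voxel-center coordinate; default centers the grid on
#'   the patient origin.
#' @param dose_model a [dose_models] object.
#' @param structures list of [structure_spec()] entries.
#' @param plan_meta a [plan_meta()] list.
#' @param vertex_spacing maximum spacing between consecutive contour
#'   vertices, mm.
#' @param seed integer seed for UID generation.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 20),
                         spacing = c(2, 2, 2),
                         origin = NULL,
                         dose_model = dose_uniform(60),
                         structures = list(
                           structure_spec("PTV", "PTV", shape_sphere(25))),
                         plan_meta = NULL,
                         vertex_spacing = 1,
                         seed = 1L) {
  if (is.null(plan_meta)) plan_meta <- rtdvh::plan_meta()
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (is.null(origin)) origin <- -(grid_shape - 1) * spacing / 2
  spec <- list(grid_shape = grid_shape, spacing = spacing,
               origin = as.numeric(origin), dose_model = dose_model,
               structures = structures, plan_meta = plan_meta,
               vertex_spacing = vertex_spacing, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

## ---- contour generation -----------------------------------------------

# Circle ring with vertex spacing <= vs mm.
circle_ring <- function(cx, cy, rad, vs) {
  n <- max(12L, ceiling(2 * pi * rad / vs))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + rad * cos(th), y = cy + rad * sin(th))
}

# Axis-aligned rectangle ring densified to vertex spacing <= vs mm.
rect_ring <- function(cx, cy, wx, wy, vs) {
  x0 <- cx - wx / 2; x1 <- cx + wx / 2
  y0 <- cy - wy / 2; y1 <- cy + wy / 2
  seg <- function(ax, ay, bx, by) {
    n <- max(1L, ceiling(sqrt((bx - ax)^2 + (by - ay)^2) / vs))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    list(x = ax + t * (bx - ax), y = ay + t * (by - ay))
  }
  p <- list(seg(x0, y0, x1, y0), seg(x1, y0, x1, y1),
            seg(x1, y1, x0, y1), seg(x0, y1, x0, y0))
  list(x = unlist(lapply(p, `[[`, "x")), y = unlist(lapply(p, `[[`, "y")))
}

# Rings of one structure on the plane at height z, or NULL if it misses.
shape_rings_at_z <- function(shape, center, z, vs) {
  dz <- z - center[3]
  switch(shape$kind,
    sphere = {
      if (abs(dz) >= shape$r) return(NULL)
      rad <- sqrt(shape$r^2 - dz^2)
      if (rad < 0.5) return(NULL)
      list(circle_ring(center[1], center[2], rad, vs))
    },
    box = {
      if (abs(dz) > shape$c / 2) return(NULL)
      list(rect_ring(center[1], center[2], shape$a, shape$b, vs))
    },
    cylinder = {
      if (abs(dz) > shape$h / 2) return(NULL)
      list(circle_ring(center[1], center[2], shape$r, vs))
    },
    ring = {
      if (abs(dz) > shape$h / 2) return(NULL)
      list(circle_ring(center[1], center[2], shape$r_out, vs),
           circle_ring(center[1], center[2], shape$r_in, vs))
    },
    two_islands = {
      if (abs(dz) > shape$h / 2) return(NULL)
      list(circle_ring(center[1] - shape$sep / 2, center[2], shape$r, vs),
           circle_ring(center[1] + shape$sep / 2, center[2], shape$r, vs))
    },
    stop("unknown shape kind: ", shape$kind))
}

# Closed-form volume in cm^3.
shape_volume_cc <- function(shape) {
  v_mm3 <- switch(shape$kind,
    sphere = 4 / 3 * pi * shape$r^3,
    box = shape$a * shape$b * shape$c,
    cylinder = pi * shape$r^2 * shape$h,
    ring = pi * (shape$r_out^2 - shape$r_in^2) * shape$h,
    two_islands = 2 * pi * shape$r^2 * shape$h)
  v_mm3 / MM3_PER_CM3
}

# z extent of a shape about its center.
shape_half_height <- function(shape) {
  switch(shape$kind,
    sphere = shape$r,
    box = shape$c / 2,
    cylinder = , ring = , two_islands = shape$h / 2)
}

# Radial extent in the xy plane.
shape_xy_extent <- function(shape) {
  switch(shape$kind,
    sphere = c(shape$r, shape$r),
    box = c(shape$a / 2, shape$b / 2),
    cylinder = c(shape$r, shape$r),
    ring = c(shape$r_out, shape$r_out),
    two_islands = c(shape$sep / 2 + shape$r, shape$r))
}

# Analytic dose summary over a shape (continuous ideal, not voxelized).
shape_dose_truth <- function(shape, center, model, z_floor = 0) {
  hh <- shape_half_height(shape)
  switch(model$kind,
    uniform = list(min = model$dose, mean = model$dose, max = model$dose),
    z_gradient = list(min = model$slope * (center[3] - hh - z_floor),
                      mean = model$slope * (center[3] - z_floor),
                      max = model$slope * (center[3] + hh - z_floor)),
    list(min = NA_real_, mean = NA_real_, max = NA_real_))
}

#' Build a phantom: dose grid, contours, analytic truth
#'
#' Generates the dose array from the spec's analytic dose model, contours
#' each structure as dense planar rings on the grid's z planes (vertex
#' spacing at most `vertex_spacing` mm), and tabulates closed-form truth:
#' volume, dose summaries where the model admits them, and surface gaps for
#' concentric same-center sphere pairs.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `grid` ([dose_grid]), `rois` (list of
#'   [roi_contours]), `truth` (data.frame) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  ax <- list(x = spec$origin[1] + (seq_len(d[1]) - 1) * spec$spacing[1],
             y = spec$origin[2] + (seq_len(d[2]) - 1) * spec$spacing[2],
             z = spec$origin[3] + (seq_len(d[3]) - 1) * spec$spacing[3])

  # structures must lie within the grid
  for (st in spec$structures) {
    hh <- shape_half_height(st$shape); ext <- shape_xy_extent(st$shape)
    lo <- c(st$center[1] - ext[1], st$center[2] - ext[2], st$center[3] - hh)
    hi <- c(st$center[1] + ext[1], st$center[2] + ext[2], st$center[3] + hh)
    gmin <- c(min(ax$x), min(ax$y), min(ax$z)) - spec$spacing / 2
    gmax <- c(max(ax$x), max(ax$y), max(ax$z)) + spec$spacing / 2
    if (any(lo < gmin) || any(hi > gmax))
      stop("structure '", st$name, "' extends outside the dose grid")
  }

  m <- spec$dose_model
  vals <- switch(m$kind,
    uniform = array(m$dose, dim = d),
    z_gradient = {
      a <- array(0, dim = d)
      for (k in seq_len(d[3])) a[, , k] <- m$slope * (ax$z[k] - min(ax$z))
      a
    },
    spherical_falloff = {
      a <- array(0, dim = d)
      dx2 <- (ax$x - m$center[1])^2
      dy2 <- (ax$y - m$center[2])^2
      for (k in seq_len(d[3])) {
        r2 <- outer(dx2, dy2, `+`) + (ax$z[k] - m$center[3])^2
        a[, , k] <- m$d0 * 2^(-(r2 / m$r50^2))
      }
      a
    },
    stop("unknown dose model: ", m$kind))

  grid <- dose_grid(vals, spec$origin, spec$spacing[1:2],
                    (seq_len(d[3]) - 1) * spec$spacing[3])

  rois <- lapply(spec$structures, function(st) {
    slices <- list()
    for (z in ax$z) {
      rings <- shape_rings_at_z(st$shape, st$center, z, spec$vertex_spacing)
      if (!is.null(rings))
        slices[[length(slices) + 1L]] <- list(z = z, rings = rings)
    }
    if (!length(slices))
      stop("structure '", st$name, "' intersects no grid plane")
    roi_contours(st$name, st$roi_type, slices)
  })
  names(rois) <- vapply(spec$structures, `[[`, "", "name")

  truth <- do.call(rbind, lapply(spec$structures, function(st) {
    ds <- shape_dose_truth(st$shape, st$center, m, z_floor = min(ax$z))
    data.frame(name = st$name, roi_type = toupper(st$roi_type),
               volume_cc = shape_volume_cc(st$shape),
               dose_min = ds$min, dose_mean = ds$mean, dose_max = ds$max,
               stringsAsFactors = FALSE)
  }))

  # analytic surface gaps for concentric sphere pairs
  gaps <- list()
  ns <- length(spec$structures)
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) for (j in seq(i + 1L, ns)) {
      a <- spec$structures[[i]]; b <- spec$structures[[j]]
      if (a$shape$kind == "sphere" && b$shape$kind == "sphere" &&
          all(a$center == b$center))
        gaps[[length(gaps) + 1L]] <- data.frame(
          roi_a = a$name, roi_b = b$name,
          gap_mm = abs(a$shape$r - b$shape$r), stringsAsFactors = FALSE)
    }
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else NULL

  list(grid = grid, rois = rois,
       truth = list(structures = truth, gaps = gaps), spec = spec)
}
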