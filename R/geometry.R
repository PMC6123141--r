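# Planar polygon geometry: the DICOM ring/island convention, union of PTVs,
# PTV overlap volume, and brute-force ROI-to-PTV surface distances.
# 2-D boolean operations are executed by polyclip (Clipper); all the
# conventions -- even-odd hole/island folding, per-slice union, slice
# thickness handling, distance summaries -- live here.

# Remove consecutive duplicate vertices and an explicitly closed last point.
clean_ring <- function(r, tol = 1e-9) {
  x <- r$x; y <- r$y
  n <- length(x)
  if (n >= 2 && abs(x[1] - x[n]) < tol && abs(y[1] - y[n]) < tol) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n >= 2) {
    keep <- c(TRUE, abs(diff(x)) > tol | abs(diff(y)) > tol)
    x <- x[keep]; y <- y[keep]
  }
  list(x = x, y = y)
}

# Canonicalize a ring collection under the even-odd rule into oriented
# Clipper rings (outers counter-clockwise, holes clockwise).
canonical_region <- function(rings) {
  rings <- Filter(function(r) length(r$x) >= 3L, lapply(rings, clean_ring))
  if (!length(rings)) return(list())
  out <- tryCatch(
    polyclip::polyclip(rings, rings, op = "union",
                       fillA = "evenodd", fillB = "evenodd"),
    error = function(e) NULL)
  if (is.null(out)) {
    # repair self-intersections ring by ring, then retry
    rings <- unlist(lapply(rings, function(r)
      tryCatch(polyclip::polysimplify(list(r), filltype = "evenodd"),
               error = function(e) {
                 warning("dropping unrepairable ring"); NULL
               })), recursive = FALSE)
    if (!length(rings)) return(list())
    out <- polyclip::polyclip(rings, rings, op = "union",
                              fillA = "evenodd", fillB = "evenodd")
  }
  out
}

region_area_mm2 <- function(region) {
  if (!length(region)) return(0)
  sum(vapply(region, function(r) ring_signed_area(r$x, r$y), 0))
}

#' Fold ROI contours into per-slice polygon regions
#'
#' Applies the DICOM multi-contour convention slice by slice: rings are
#' accumulated in order, a ring lying inside the cumulative region subtracts
#' area (a hole, e.g. a ring structure), a ring outside adds area (an
#' island, e.g. both lungs in one ROI). Self-intersecting rings are repaired
#' by even-odd resimplification; rings that remain degenerate are dropped
#' with a warning.
#'
#' @param roi a [roi_contours] object.
#' @return object of class `slice_polygons`: per-z canonical ring sets with
#'   cached areas (mm^2).
#' @export
build_slice_polygons <- function(roi) {
  stopifnot(inherits(roi, "roi_contours"))
  slices <- list()
  for (s in roi$slices) {
    reg <- canonical_region(s$rings)
    if (!length(reg)) {
      warning(sprintf("ROI '%s': slice z=%.3f has no valid region",
                      roi$roi_name, s$z))
      next
    }
    slices[[z_key(s$z)]] <- list(rings = reg,
                                 area_mm2 = region_area_mm2(reg))
  }
  new_slice_polygons(slices, source = roi$roi_name)
}

new_slice_polygons <- function(slices, source) {
  z <- as.numeric(names(slices))
  ord <- order(z)
  structure(list(slices = slices[ord], z = z[ord], source = source),
            class = "slice_polygons")
}

#' @export
print.slice_polygons <- function(x, ...) {
  cat(sprintf("<slice_polygons> '%s': %d slice(s), volume %.3f cm^3\n",
              paste(x$source, collapse = "+"), length(x$z),
              slice_volume_cc(x)))
  invisible(x)
}

# Per-slice thickness (mm) from this region's own z keys; forward gap, last
# slice reuses the previous gap. Single slice -> NA (caller decides).
slice_thickness <- function(sp) plane_thickness(sp$z)

#' Slice-sum volume of a polygon region
#'
#' Sum over slices of area times slice thickness (forward gap; the last
#' slice reuses the previous gap), in cm^3. For a single-slice region
#' `fallback_mm` supplies the thickness.
#'
#' @param sp a `slice_polygons` object.
#' @param fallback_mm thickness to use when the region has a single slice.
#' @export
slice_volume_cc <- function(sp, fallback_mm = NA_real_) {
  if (!length(sp$z)) return(0)
  th <- slice_thickness(sp)
  if (all(is.na(th))) th <- rep(fallback_mm, length(sp$z))
  areas <- vapply(sp$slices, `[[`, 0, "area_mm2")
  sum(areas * th) / MM3_PER_CM3
}

#' Union of all PTVs
#'
#' Per-slice geometric union of every input region, keyed on the merged set
#' of z values, yielding the combined PTV used by overlap and distance
#' computations. Inputs are expected to be all ROIs whose type begins with
#' PTV.
#'
#' @param ptvs list of `slice_polygons`.
#' @return a `slice_polygons` region.
#' @export
union_ptvs <- function(ptvs) {
  if (!length(ptvs)) stop("no PTV found")
  stopifnot(all(vapply(ptvs, inherits, TRUE, "slice_polygons")))
  if (length(ptvs) == 1L) return(ptvs[[1L]])
  keys <- sort(unique(unlist(lapply(ptvs, function(p) names(p$slices)))))
  slices <- list()
  for (k in keys) {
    reg <- NULL
    for (p in ptvs) {
      r <- p$slices[[k]]
      if (is.null(r)) next
      reg <- if (is.null(reg)) r$rings
             else polyclip::polyclip(reg, r$rings, op = "union",
                                     fillA = "nonzero", fillB = "nonzero")
    }
    if (length(reg))
      slices[[k]] <- list(rings = reg, area_mm2 = region_area_mm2(reg))
  }
  new_slice_polygons(slices,
                     source = unlist(lapply(ptvs, `[[`, "source")))
}

#' PTV overlap volume
#'
#' For each slice shared by both regions, the area of the 2-D intersection
#' is multiplied by the slice thickness (taken from the ROI's own z
#' spacing: the gap to the adjacent slice, the last slice reusing the
#' previous gap) and the products are summed. Returned in cm^3.
#'
#' @param ptv combined-PTV `slice_polygons`.
#' @param roi the other region.
#' @return overlap volume, cm^3.
#' @export
overlap_volume <- function(ptv, roi) {
  stopifnot(inherits(ptv, "slice_polygons"), inherits(roi, "slice_polygons"))
  if (!length(ptv$z) || !length(roi$z)) stop("empty region")
  th <- slice_thickness(roi)
  if (all(is.na(th))) {
    fb <- stats::median(slice_thickness(ptv), na.rm = TRUE)
    if (is.na(fb)) stop("cannot determine slice thickness")
    warning("single-slice ROI: falling back to PTV median slice spacing")
    th <- rep(fb, length(roi$z))
  }
  names(th) <- names(roi$slices)
  total_mm3 <- 0
  for (k in intersect(names(roi$slices), names(ptv$slices))) {
    inter <- polyclip::polyclip(ptv$slices[[k]]$rings, roi$slices[[k]]$rings,
                                op = "intersection",
                                fillA = "nonzero", fillB = "nonzero")
    if (length(inter))
      total_mm3 <- total_mm3 + region_area_mm2(inter) * th[[k]]
  }
  total_mm3 / MM3_PER_CM3
}

# All boundary vertices of a region as an n x 3 matrix (mm).
boundary_points <- function(sp) {
  pts <- lapply(seq_along(sp$slices), function(i) {
    z <- sp$z[i]
    do.call(rbind, lapply(sp$slices[[i]]$rings, function(r)
      cbind(r$x, r$y, rep(z, length(r$x)))))
  })
  m <- do.call(rbind, pts)
  colnames(m) <- c("x", "y", "z")
  m
}

#' ROI-to-PTV surface distances
#'
#' Brute-force 3-D Euclidean distances between every boundary vertex of the
#' ROI and every boundary vertex of the PTV, summarized as min, mean,
#' median and max, reported in cm. Boundary points are the contour vertices
#' as stored (no resampling), so the minimum is resolved to the vertex
#' spacing. Pair counts above `max_pairs` are refused unless `force = TRUE`.
#'
#' @param ptv combined-PTV `slice_polygons`.
#' @param roi the other region.
#' @param force evaluate even when the pair count exceeds `max_pairs`.
#' @param max_pairs refusal threshold (default 1e7).
#' @return object of class `geometry_summary` with fields `dist_min`,
#'   `dist_mean`, `dist_median`, `dist_max` (cm).
#' @export
surface_distances <- function(ptv, roi, force = FALSE, max_pairs = 1e7) {
  p1 <- boundary_points(ptv)
  p2 <- boundary_points(roi)
  npair <- as.double(nrow(p1)) * nrow(p2)
  if (npair == 0) stop("empty region")
  if (npair > max_pairs && !force)
    stop(sprintf("%.3g point pairs exceed the %.3g limit; use force = TRUE",
                 npair, max_pairs))
  # chunk over ROI points; accumulate the full distance multiset
  dists <- numeric(0)
  chunk <- max(1L, floor(5e6 / nrow(p1)))
  for (start in seq(1L, nrow(p2), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(p2))
    d2 <- outer(p1[, 1], p2[idx, 1], `-`)^2 +
          outer(p1[, 2], p2[idx, 2], `-`)^2 +
          outer(p1[, 3], p2[idx, 3], `-`)^2
    dists <- c(dists, sqrt(as.numeric(d2)))
  }
  geometry_summary(dist_min = min(dists) / MM_PER_CM,
                   dist_mean = mean(dists) / MM_PER_CM,
                   dist_median = stats::median(dists) / MM_PER_CM,
                   dist_max = max(dists) / MM_PER_CM)
}

#' Geometry summary container
#'
#' @param dist_min,dist_mean,dist_median,dist_max distances in cm.
#' @param ptv_overlap overlap volume in cm^3.
#' @export
geometry_summary <- function(dist_min = NA_real_, dist_mean = NA_real_,
                             dist_median = NA_real_, dist_max = NA_real_,
                             ptv_overlap = NA_real_) {
  structure(list(dist_min = dist_min, dist_mean = dist_mean,
                 dist_median = dist_median, dist_max = dist_max,
                 ptv_overlap = ptv_overlap),
            class = "geometry_summary")
}

#' @export
print.geometry_summary <- function(x, ...) {
  cat(sprintf("<geometry_summary> dist min/mean/median/max = %.2f/%.2f/%.2f/%.2f cm, overlap %.3f cm^3\n",
              x$dist_min, x$dist_mean, x$dist_median, x$dist_max,
              x$ptv_overlap))
  invisible(x)
}

#' Geometry metrics of every ROI against the combined PTV
#'
#' Builds the PTV union from all PTV-typed ROIs, then computes, for each
#' other ROI, the overlap volume and (unless the ROI is of external/skin
#' type and not explicitly forced) the surface-distance summaries.
#'
#' @param rois list of [roi_contours].
#' @param force_distance_for character vector of ROI names for which the
#'   distance computation runs even if the type is EXTERNAL/SKIN or the
#'   pair-count guard would refuse.
#' @return named list of [geometry_summary()] per non-PTV ROI, with the
#'   combined PTV attached as attribute `ptv_union`.
#' @export
ptv_geometry <- function(rois, force_distance_for = character(0)) {
  types <- vapply(rois, `[[`, "", "roi_type")
  is_ptv <- startsWith(toupper(types), "PTV")
  if (!any(is_ptv)) stop("no PTV found")
  ptv_regions <- lapply(rois[is_ptv], build_slice_polygons)
  ptv <- union_ptvs(ptv_regions)
  out <- list()
  for (roi in rois[!is_ptv]) {
    reg <- build_slice_polygons(roi)
    ov <- overlap_volume(ptv, reg)
    skip_dist <- toupper(roi$roi_type) %in% c("EXTERNAL", "SKIN") &&
      !(roi$roi_name %in% force_distance_for)
    gs <- if (skip_dist) geometry_summary(ptv_overlap = ov)
    else {
      g <- tryCatch(
        surface_distances(ptv, reg,
                          force = roi$roi_name %in% force_distance_for),
        error = function(e) {
          warning(sprintf("distance skipped for '%s': %s",
                          roi$roi_name, conditionMessage(e)))
          geometry_summary()
        })
      g$ptv_overlap <- ov
      g
    }
    out[[roi$roi_name]] <- gs
  }
  attr(out, "ptv_union") <- ptv
  out
}
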