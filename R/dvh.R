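# DVH computation: contour rasterization onto the dose grid, cumulative /
# differential histograms, and D/V endpoint evaluation.

#' Rasterize a contoured structure onto a dose grid
#'
#' A voxel belongs to the structure iff its center lies inside the slice's
#' polygon set under the even-odd rule (holes subtract, islands add). Each
#' contour slice is assigned to the nearest grid plane, provided the gap is
#' at most half the local plane spacing; slices falling farther from every
#' plane are skipped. No partial-volume weighting is applied, so the masked
#' volume depends on grid resolution and converges to the true volume as the
#' grid is refined.
#'
#' @param roi a [roi_contours] object.
#' @param grid a [dose_grid].
#' @return object of class `voxel_mask`: linear voxel indices into the grid
#'   array plus the voxel volume (mm^3).
#' @export
rasterize_structure <- function(roi, grid) {
  stopifnot(inherits(roi, "roi_contours"), inherits(grid, "dose_grid"))
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  half_gap <- plane_thickness(ax$z) / 2
  if (all(is.na(half_gap))) half_gap <- rep(Inf, length(ax$z))

  plane_sets <- vector("list", d[3])   # logical xy masks per plane
  for (s in roi$slices) {
    k <- which.min(abs(ax$z - s$z))
    if (abs(ax$z[k] - s$z) > half_gap[k] + 1e-9) next
    # restrict point-in-polygon tests to the rings' bounding box
    bx <- range(unlist(lapply(s$rings, `[[`, "x")))
    by <- range(unlist(lapply(s$rings, `[[`, "y")))
    ii <- which(ax$x >= bx[1] - 1e-9 & ax$x <= bx[2] + 1e-9)
    jj <- which(ax$y >= by[1] - 1e-9 & ax$y <= by[2] + 1e-9)
    if (!length(ii) || !length(jj)) next
    px <- rep(ax$x[ii], times = length(jj))
    py <- rep(ax$y[jj], each = length(ii))
    ins <- points_in_rings(px, py, s$rings)
    if (!any(ins)) next
    m <- plane_sets[[k]]
    if (is.null(m)) m <- matrix(FALSE, d[1], d[2])
    sub <- m[ii, jj, drop = FALSE]
    sub[matrix(ins, length(ii), length(jj))] <- TRUE
    m[ii, jj] <- sub
    plane_sets[[k]] <- m
  }

  idx <- integer(0)
  nxy <- d[1] * d[2]
  for (k in seq_len(d[3])) {
    m <- plane_sets[[k]]
    if (!is.null(m) && any(m)) idx <- c(idx, which(m) + (k - 1L) * nxy)
  }
  dz <- plane_thickness(ax$z)
  voxel_mm3 <- grid$pixel_spacing[1] * grid$pixel_spacing[2] *
    (if (all(is.na(dz))) NA_real_ else stats::median(dz, na.rm = TRUE))
  if (!length(idx))
    warning(sprintf("ROI '%s' rasterizes to an empty mask", roi$roi_name))
  structure(list(indices = idx, dims = d, voxel_mm3 = voxel_mm3,
                 roi_name = roi$roi_name),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> '%s': %d voxels (%.3f cm^3)\n", x$roi_name,
              length(x$indices), length(x$indices) * x$voxel_mm3 / MM3_PER_CM3))
  invisible(x)
}

#' Volume of a voxel mask in cm^3
#' @param mask a `voxel_mask` from [rasterize_structure()].
#' @export
mask_volume_cc <- function(mask) length(mask$indices) * mask$voxel_mm3 / MM3_PER_CM3

#' Compute a dose-volume histogram from a voxel mask
#'
#' Builds the differential histogram of masked voxel doses at a fixed bin
#' width (bin `i` covers `[(i-1) w, i w)`) and the cumulative DVH
#' `cumulative[i]` = volume receiving at least the bin's lower-edge dose.
#' Alongside the bin counts, the mass-weighted mean dose of each occupied bin
#' is retained so that histogram-based statistics (mean dose, gEUD)
#' reproduce the voxel-level values to machine precision rather than to half
#' a bin width.
#'
#' @param mask a `voxel_mask` from [rasterize_structure()].
#' @param grid the [dose_grid] the mask refers to.
#' @param bin_width histogram bin width in Gy (default 0.01).
#' @param rx_dose optional prescription dose in Gy for relative scaling.
#' @return object of class `dvh`.
#' @export
compute_dvh <- function(mask, grid, bin_width = 0.01, rx_dose = NA_real_) {
  stopifnot(inherits(mask, "voxel_mask"), inherits(grid, "dose_grid"))
  if (!length(mask$indices)) stop("zero-volume ROI: empty voxel mask")
  doses <- dose_values(grid)[mask$indices]
  vox_cc <- mask$voxel_mm3 / MM3_PER_CM3
  nbin <- max(1L, floor(max(doses) / bin_width) + 1L)
  bin <- pmin(floor(doses / bin_width) + 1L, nbin)
  counts <- tabulate(bin, nbins = nbin)
  diff_cc <- counts * vox_cc
  bin_mean <- rep(NA_real_, nbin)
  occ <- counts > 0L
  sums <- vapply(split(doses, bin), sum, 0)
  bin_mean[as.integer(names(sums))] <- sums / counts[as.integer(names(sums))]
  cumulative <- rev(cumsum(rev(diff_cc)))
  structure(list(bin_width = bin_width,
                 diff_counts = diff_cc,
                 bin_dose_mean = bin_mean,
                 cumulative = cumulative,
                 volume = length(doses) * vox_cc,
                 min_dose = min(doses),
                 mean_dose = mean(doses),
                 max_dose = max(doses),
                 rx_dose = rx_dose),
            class = "dvh")
}

#' Construct a DVH directly from bin volumes
#'
#' Used when deserializing stored DVHs or building toy histograms in
#' analyses; `diff_counts` are per-bin absolute volumes in cm^3.
#'
#' @param diff_counts per-bin volume, cm^3.
#' @param bin_width Gy.
#' @param rx_dose optional Gy.
#' @param min_dose,mean_dose,max_dose optional dose summaries; derived from
#'   bin centers when missing.
#' @export
dvh_from_diff <- function(diff_counts, bin_width = 0.01, rx_dose = NA_real_,
                          min_dose = NULL, mean_dose = NULL, max_dose = NULL) {
  stopifnot(all(diff_counts >= 0), sum(diff_counts) > 0)
  centers <- (seq_along(diff_counts) - 0.5) * bin_width
  vol <- sum(diff_counts)
  occ <- which(diff_counts > 0)
  structure(list(bin_width = bin_width,
                 diff_counts = diff_counts,
                 bin_dose_mean = ifelse(diff_counts > 0, centers, NA_real_),
                 cumulative = rev(cumsum(rev(diff_counts))),
                 volume = vol,
                 min_dose = min_dose %||% centers[occ[1]],
                 mean_dose = mean_dose %||% sum(diff_counts * centers) / vol,
                 max_dose = max_dose %||% centers[occ[length(occ)]],
                 rx_dose = rx_dose),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> volume %.3f cm^3, dose %.2f / %.2f / %.2f Gy (min/mean/max), bin %.3g Gy\n",
              x$volume, x$min_dose, x$mean_dose, x$max_dose, x$bin_width))
  invisible(x)
}

# Cumulative volume evaluated at the bin edges 0, w, 2w, ..., nw.
dvh_edge_curve <- function(dvh) {
  n <- length(dvh$cumulative)
  list(dose = (seq_len(n + 1L) - 1L) * dvh$bin_width,
       vol = c(dvh$cumulative, 0))
}

#' DVH endpoint specification
#'
#' Describes a dosimetric (`D`) or volumetric (`V`) endpoint: `D_95%`
#' (`endpoint_spec("D", 95, "%")`), `D_2cc`, `V_20Gy`, `V_50%` and so on.
#' Output may be absolute (Gy or cm^3) or relative (% of prescription dose
#' for D, % of structure volume for V).
#'
#' @param kind `"D"` or `"V"`.
#' @param value positive number.
#' @param value_units for D: `"%"` or `"cc"`; for V: `"%"` (of rx dose) or
#'   `"Gy"`.
#' @param output_units `"abs"` or `"rel"`.
#' @export
endpoint_spec <- function(kind, value, value_units,
                          output_units = c("abs", "rel")) {
  kind <- toupper(kind)
  output_units <- match.arg(output_units)
  stopifnot(kind %in% c("D", "V"), value > 0)
  ok <- if (kind == "D") c("%", "cc") else c("%", "Gy")
  if (!value_units %in% ok)
    stop(kind, " endpoints take value_units in {", paste(ok, collapse = ", "), "}")
  structure(list(kind = kind, value = value, value_units = value_units,
                 output_units = output_units),
            class = "endpoint_spec")
}

#' Parse endpoint strings like "D95%", "D2cc", "V20Gy", "V50%"
#'
#' A trailing `:rel` requests relative output (`"D95%:rel"`).
#' @param text character vector of endpoint strings.
#' @return list of [endpoint_spec()] objects.
#' @export
parse_endpoint <- function(text) {
  lapply(text, function(s) {
    raw <- gsub("[ _]", "", s)
    out <- "abs"
    if (grepl(":rel$", raw, ignore.case = TRUE)) {
      out <- "rel"; raw <- sub(":rel$", "", raw, ignore.case = TRUE)
    }
    m <- regmatches(raw, regexec("^([DdVv])([0-9.]+)(%|cc|Gy|gy)$", raw))[[1]]
    if (!length(m)) stop("cannot parse endpoint: '", s, "'")
    units <- m[4]; if (tolower(units) == "gy") units <- "Gy"
    endpoint_spec(toupper(m[2]), as.numeric(m[3]), units, out)
  })
}

# Label such as "D_95%" / "V_20Gy" for table headers.
endpoint_label <- function(spec) {
  sprintf("%s_%g%s%s", spec$kind, spec$value, spec$value_units,
          if (spec$output_units == "rel") "_rel" else "")
}

#' Dose at volume (D endpoints)
#'
#' Largest dose `D` such that the cumulative volume at `D` still covers the
#' requested volume, linearly interpolated between bin edges; ties on a flat
#' cumulative segment resolve toward the higher dose.
#'
#' @param dvh a `dvh`.
#' @param spec an [endpoint_spec()] with `kind == "D"`.
#' @return dose in Gy, or % of prescription dose for relative output.
#' @export
dose_at_volume <- function(dvh, spec) {
  stopifnot(inherits(dvh, "dvh"), inherits(spec, "endpoint_spec"),
            spec$kind == "D")
  target <- if (spec$value_units == "%") {
    if (spec$value <= 0 || spec$value > 100)
      stop("percent volume must be in (0, 100]")
    spec$value / 100 * dvh$volume
  } else {
    if (spec$value > dvh$volume + 1e-12)
      stop(sprintf("requested %.3f cc exceeds structure volume %.3f cc",
                   spec$value, dvh$volume))
    spec$value
  }
  ec <- dvh_edge_curve(dvh)
  ge <- which(ec$vol >= target - 1e-12)
  i <- ge[length(ge)]                      # last edge still covering target
  d <- if (i == length(ec$dose)) {
    ec$dose[i]
  } else {
    drop <- ec$vol[i] - ec$vol[i + 1L]
    if (drop <= 0) ec$dose[i]
    else ec$dose[i] + dvh$bin_width * (ec$vol[i] - target) / drop
  }
  if (spec$output_units == "rel") {
    if (is.na(dvh$rx_dose)) stop("relative dose output needs rx_dose")
    100 * d / dvh$rx_dose
  } else d
}

#' Volume at dose (V endpoints)
#'
#' Cumulative volume at the requested dose, linearly interpolated between
#' bin edges. Percent dose specs are interpreted as % of the prescription
#' dose.
#'
#' @param dvh a `dvh`.
#' @param spec an [endpoint_spec()] with `kind == "V"`.
#' @return volume in cm^3, or % of structure volume for relative output.
#' @export
volume_at_dose <- function(dvh, spec) {
  stopifnot(inherits(dvh, "dvh"), inherits(spec, "endpoint_spec"),
            spec$kind == "V")
  d <- if (spec$value_units == "%") {
    if (is.na(dvh$rx_dose)) stop("percent dose specs need rx_dose")
    spec$value / 100 * dvh$rx_dose
  } else spec$value
  if (d < 0) stop("dose must be >= 0")
  ec <- dvh_edge_curve(dvh)
  v <- if (d >= ec$dose[length(ec$dose)]) 0
       else stats::approx(ec$dose, ec$vol, xout = d, method = "linear")$y
  if (spec$output_units == "rel") 100 * v / dvh$volume else v
}

#' Evaluate an endpoint on a DVH
#'
#' Dispatches to [dose_at_volume()] or [volume_at_dose()].
#' @param dvh a `dvh`.
#' @param spec an [endpoint_spec()].
#' @export
evaluate_endpoint <- function(dvh, spec) {
  if (spec$kind == "D") dose_at_volume(dvh, spec) else volume_at_dose(dvh, spec)
}

#' Export DVHs as CSV
#'
#' One row per ROI: identifiers, volume, dose summaries, then the cumulative
#' bin volumes (cm^3) at the fixed bin width.
#'
#' @param dvhs named list of `dvh` objects.
#' @param meta data.frame with one row per DVH: `mrn`, `study_uid`,
#'   `roi_name` (and any extra columns, carried through).
#' @param path output file.
#' @export
export_dvhs_csv <- function(dvhs, meta, path) {
  stopifnot(length(dvhs) == nrow(meta))
  nmax <- max(vapply(dvhs, function(d) length(d$cumulative), 0L))
  rows <- lapply(seq_along(dvhs), function(i) {
    d <- dvhs[[i]]
    cum <- c(d$cumulative, rep(0, nmax - length(d$cumulative)))
    cbind(meta[i, , drop = FALSE],
          data.frame(volume_cc = d$volume, min_dose = d$min_dose,
                     mean_dose = d$mean_dose, max_dose = d$max_dose,
                     bin_width = d$bin_width),
          as.data.frame(as.list(stats::setNames(
            cum, sprintf("bin_%d", seq_len(nmax))))))
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
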