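# DICOM RT fileset discovery and parsing into domain records.

#' Discover and group DICOM RT filesets
#'
#' Scans a directory (recursively; files need not be organized), groups
#' DICOM files by study instance UID and selects, per modality, the
#' instance with the latest timestamp (instance creation date+time, file
#' modification time when absent). Groups missing any of RT Plan, RT
#' Structure Set or RT Dose are reported via the `"incomplete"` attribute,
#' not returned. Unreadable or non-DICOM files are skipped with a warning.
#'
#' @param directory path to scan.
#' @return list of `plan_fileset` objects (fields `mrn`, `study_uid`,
#'   `plan_file`, `structure_file`, `dose_file`, `extra_files`), with
#'   attribute `"incomplete"` describing rejected groups.
#' @export
discover_filesets <- function(directory) {
  stopifnot(dir.exists(directory))
  files <- sort(list.files(directory, recursive = TRUE, full.names = TRUE))
  info <- list()
  for (f in files) {
    ds <- tryCatch(dcm_read_file(f), error = function(e) {
      warning(sprintf("skipping '%s': %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(ds)) next
    da <- ds_get1(ds, "InstanceCreationDate", NA)
    tm <- ds_get1(ds, "InstanceCreationTime", "000000")
    stamp <- if (!is.na(da))
      as.POSIXct(paste0(da, substr(paste0(tm, "000000"), 1, 6)),
                 format = "%Y%m%d%H%M%S", tz = "UTC")
    else file.mtime(f)
    info[[length(info) + 1L]] <- list(
      path = f,
      mrn = ds_get1(ds, "PatientID", NA),
      study_uid = ds_get1(ds, "StudyInstanceUID", NA),
      modality = ds_get1(ds, "Modality", NA),
      stamp = stamp)
  }
  if (!length(info)) {
    out <- list()
    attr(out, "incomplete") <- list()
    return(out)
  }
  uids <- vapply(info, `[[`, "", "study_uid")
  out <- list()
  incomplete <- list()
  for (uid in unique(uids)) {
    grp <- info[uids == uid]
    pick <- function(modality) {
      cand <- Filter(function(g) identical(g$modality, modality), grp)
      if (!length(cand)) return(NULL)
      stamps <- do.call(c, lapply(cand, `[[`, "stamp"))
      cand[[order(stamps, vapply(cand, `[[`, "", "path"),
                  decreasing = TRUE)[1]]]
    }
    p <- pick("RTPLAN"); s <- pick("RTSTRUCT"); d <- pick("RTDOSE")
    if (is.null(p) || is.null(s) || is.null(d)) {
      missing <- c("RTPLAN", "RTSTRUCT", "RTDOSE")[
        c(is.null(p), is.null(s), is.null(d))]
      incomplete[[uid]] <- list(study_uid = uid, missing = missing,
                                files = vapply(grp, `[[`, "", "path"))
      next
    }
    chosen <- c(p$path, s$path, d$path)
    fs <- structure(list(
      mrn = p$mrn,
      study_uid = uid,
      plan_file = p$path,
      structure_file = s$path,
      dose_file = d$path,
      extra_files = setdiff(vapply(grp, `[[`, "", "path"), chosen)),
      class = "plan_fileset")
    out[[length(out) + 1L]] <- fs
  }
  attr(out, "incomplete") <- incomplete
  out
}

#' @export
print.plan_fileset <- function(x, ...) {
  cat(sprintf("<plan_fileset> MRN %s, study %s (%d extra file(s))\n",
              x$mrn, x$study_uid, length(x$extra_files)))
  invisible(x)
}

# Wrapped angular sweep statistics over control-point values.
angle_stats <- function(vals) {
  if (!length(vals)) return(list(start = NA_real_, end = NA_real_,
                                 min = NA_real_, max = NA_real_,
                                 range = NA_real_))
  sweep <- if (length(vals) > 1) {
    d <- diff(vals)
    d <- ((d + 180) %% 360) - 180
    sum(abs(d))
  } else 0
  list(start = vals[1], end = vals[length(vals)],
       min = min(vals), max = max(vals), range = sweep)
}

#' Parse ROI contours from a fileset's structure file
#'
#' Every ROI with closed planar contour data is returned as
#' [roi_contours]; the interpreted type comes from the RT ROI observations,
#' except that any ROI whose name begins with "ITV" (case-insensitive) is
#' typed ITV regardless of the file. Point-only ROIs (POIs) are excluded
#' from the geometry list but returned in the `"points"` attribute (name ->
#' xyz) for treatment-site and prescription parsing.
#'
#' @param fs a `plan_fileset` (or a path to an RT Structure Set).
#' @return list of [roi_contours] with attribute `"points"`.
#' @export
parse_structures <- function(fs) {
  path <- if (inherits(fs, "plan_fileset")) fs$structure_file else fs
  ds <- dcm_read_file(path)
  roi_names <- list()
  for (item in ds_get(ds, "StructureSetROISequence") %||% list())
    roi_names[[as.character(ds_get1(item, "ROINumber"))]] <-
      ds_get1(item, "ROIName", "")
  roi_types <- list()
  for (item in ds_get(ds, "RTROIObservationsSequence") %||% list())
    roi_types[[as.character(ds_get1(item, "ReferencedROINumber"))]] <-
      ds_get1(item, "RTROIInterpretedType", "")

  rois <- list()
  points <- list()
  for (item in ds_get(ds, "ROIContourSequence") %||% list()) {
    num <- as.character(ds_get1(item, "ReferencedROINumber"))
    name <- roi_names[[num]] %||% paste0("ROI", num)
    type <- roi_types[[num]] %||% ""
    slices <- list()   # z key -> list of rings
    only_points <- TRUE
    for (ct in ds_get(item, "ContourSequence") %||% list()) {
      gtype <- toupper(ds_get1(ct, "ContourGeometricType", ""))
      xyz <- ds_get(ct, "ContourData")
      if (is.null(xyz) || length(xyz) %% 3 != 0) next
      m <- matrix(xyz, nrow = 3)
      if (gtype == "POINT" || ncol(m) == 1L) {
        points[[name]] <- m[, 1]
        next
      }
      only_points <- FALSE
      z <- m[3, 1]
      k <- z_key(z)
      ring <- list(x = m[1, ], y = m[2, ])
      if (is.null(slices[[k]]))
        slices[[k]] <- list(z = z, rings = list(ring))
      else slices[[k]]$rings <- c(slices[[k]]$rings, list(ring))
    }
    if (only_points || !length(slices)) next
    if (grepl("^itv", name, ignore.case = TRUE)) type <- "ITV"
    rois[[name]] <- roi_contours(name, type, unname(slices))
  }
  attr(rois, "points") <- points
  rois
}

#' Parse the dose grid from a fileset's dose file
#'
#' @param fs a `plan_fileset` (or a path to an RT Dose file).
#' @return a [dose_grid]; stored integer values with the file's dose
#'   scaling. Dose units other than Gy are rejected.
#' @export
parse_dose <- function(fs) {
  path <- if (inherits(fs, "plan_fileset")) fs$dose_file else fs
  ds <- dcm_read_file(path)
  units <- toupper(ds_get1(ds, "DoseUnits", ""))
  if (units != "GY")
    stop("unsupported dose units '", units, "' (only GY): ", path)
  iop <- ds_get(ds, "ImageOrientationPatient") %||% c(1, 0, 0, 0, 1, 0)
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("only axis-aligned dose grids are supported: ", path)
  rows <- ds_get1(ds, "Rows"); cols <- ds_get1(ds, "Columns")
  nframes <- as.integer(ds_get1(ds, "NumberOfFrames", 1))
  ps <- ds_get(ds, "PixelSpacing")          # (row spacing dy, col spacing dx)
  offsets <- as.numeric(ds_get(ds, "GridFrameOffsetVector") %||% 0)
  scaling <- as.numeric(ds_get1(ds, "DoseGridScaling", 1))
  bits <- as.integer(ds_get1(ds, "BitsAllocated", 16))
  pix <- ds_get(ds, "PixelData")
  vals <- switch(as.character(bits),
                 "16" = raw_u16(pix),
                 "32" = raw_u32(pix),
                 stop("unsupported BitsAllocated ", bits))
  if (length(vals) != cols * rows * nframes)
    stop("pixel data size mismatch in ", path)
  arr <- array(vals, dim = c(cols, rows, nframes))  # x fastest within a row
  dose_grid(arr,
            origin = as.numeric(ds_get(ds, "ImagePositionPatient")),
            pixel_spacing = c(ps[2], ps[1]),
            z_offsets = offsets,
            dose_scaling = scaling)
}

# POI-encoded prescription hook for planning systems that omit
# prescription attributes:
#   "rx<group>: <name>:<fxs>x<fx_dose>:<rx_percent>%"
parse_rx_poi <- function(poi_names) {
  pat <- "^\\s*rx(\\d+)\\s*:\\s*(.+?)\\s*:\\s*(\\d+)\\s*x\\s*([0-9.]+)\\s*:\\s*([0-9.]+)\\s*%\\s*$"
  hits <- grepl(pat, poi_names, ignore.case = TRUE)
  if (!any(hits)) return(NULL)
  m <- regmatches(poi_names[hits], regexec(pat, poi_names[hits],
                                           ignore.case = TRUE))
  out <- lapply(m, function(g)
    list(group = as.integer(g[2]), name = g[3], fxs = as.integer(g[4]),
         fx_dose = as.numeric(g[5]), rx_percent = as.numeric(g[6])))
  stats::setNames(out, vapply(out, function(x) as.character(x$group), ""))
}

#' Parse plan, prescription and beam records from a fileset
#'
#' Extracts one plan record, one prescription record per fraction group and
#' one beam record per beam. The treatment site is the text following a
#' `"tx:"`-prefixed point-of-interest name in the structure set
#' (case-insensitive, whitespace-tolerant), falling back to the plan label.
#' Brachytherapy plans yield no beam records but populate everything else.
#'
#' @param fs a `plan_fileset`.
#' @return list with data.frames `plan`, `rxs`, `beams`.
#' @export
parse_plan <- function(fs) {
  stopifnot(inherits(fs, "plan_fileset"))
  plan <- dcm_read_file(fs$plan_file)
  struct <- dcm_read_file(fs$structure_file)
  dose <- dcm_read_file(fs$dose_file)

  mrn <- ds_get1(plan, "PatientID", NA)
  study_uid <- ds_get1(plan, "StudyInstanceUID", NA)
  if (is.na(mrn) || is.na(study_uid))
    stop("missing Patient ID or study instance UID in ", fs$plan_file)

  pois <- attr(parse_structures(fs), "points")
  poi_names <- names(pois) %||% character(0)
  tx_hit <- grepl("^\\s*tx\\s*:", poi_names, ignore.case = TRUE)
  plan_label <- ds_get1(plan, "RTPlanLabel",
                        ds_get1(plan, "RTPlanName", NA))
  tx_site <- if (any(tx_hit))
    trimws(sub("^\\s*tx\\s*:\\s*", "", poi_names[tx_hit][1],
               ignore.case = TRUE))
  else plan_label
  rx_pois <- parse_rx_poi(poi_names)

  stamp_of <- function(ds, date_name, time_name) {
    da <- ds_get1(ds, date_name, NA)
    tm <- ds_get1(ds, time_name, "000000")
    if (is.na(da)) return(NA_character_)
    sprintf("%s %s:%s:%s", dicom_date_to_iso(da),
            substr(tm, 1, 2), substr(tm, 3, 4), substr(tm, 5, 6))
  }

  fx_groups <- ds_get(plan, "FractionGroupSequence") %||% list()
  dose_refs <- ds_get(plan, "DoseReferenceSequence") %||% list()
  beam_items <- ds_get(plan, "BeamSequence") %||% list()
  brachy <- !is.null(ds_get(plan, "BrachyTreatmentType")) ||
    any(vapply(fx_groups, function(g)
      as.numeric(ds_get1(g, "NumberOfBrachyApplicationSetups", 0)) > 0, TRUE))

  # referenced beam dose / meterset by beam number, plus group membership
  beam_ref <- list()
  for (i in seq_along(fx_groups)) {
    for (r in ds_get(fx_groups[[i]], "ReferencedBeamSequence") %||% list()) {
      bn <- as.character(ds_get1(r, "ReferencedBeamNumber"))
      beam_ref[[bn]] <- list(group = i,
                             dose = as.numeric(ds_get1(r, "BeamDose", NA)),
                             mu = as.numeric(ds_get1(r, "BeamMeterset", NA)))
    }
  }

  rx_rows <- lapply(seq_along(fx_groups), function(i) {
    g <- fx_groups[[i]]
    fxs <- as.integer(ds_get1(g, "NumberOfFractionsPlanned", NA))
    refs <- Filter(function(b) b$group == i, beam_ref)
    fx_dose <- if (length(refs))
      sum(vapply(refs, `[[`, 0, "dose"), na.rm = TRUE)
    else if (i <= length(dose_refs)) {
      tpd <- as.numeric(ds_get1(dose_refs[[i]], "TargetPrescriptionDose", NA))
      if (!is.na(tpd) && !is.na(fxs) && fxs > 0) tpd / fxs else NA_real_
    } else NA_real_
    name <- if (i <= length(dose_refs))
      ds_get1(dose_refs[[i]], "DoseReferenceDescription",
              sprintf("FxGrp %d", i))
    else sprintf("FxGrp %d", i)
    rx_percent <- 100
    hook <- rx_pois[[as.character(i)]]
    if (!is.null(hook)) {
      fxs <- hook$fxs; fx_dose <- hook$fx_dose
      rx_percent <- hook$rx_percent; name <- hook$name
    }
    data.frame(mrn = mrn, study_uid = study_uid,
               import_timestamp = NA_character_,
               fxs = fxs, fx_dose = fx_dose, fx_group_name = name,
               fx_group_number = i, fx_group_count = length(fx_groups),
               norm_method = if (i <= length(dose_refs))
                 ds_get1(dose_refs[[i]], "DoseReferenceType", NA)
               else NA_character_,
               norm_object = if (i <= length(dose_refs))
                 ds_get1(dose_refs[[i]], "DoseReferenceStructureType", NA)
               else NA_character_,
               rx_dose = fxs * fx_dose, rx_percent = rx_percent,
               stringsAsFactors = FALSE)
  })
  rxs <- do.call(rbind, rx_rows) %||%
    data.frame(mrn = character(0))

  beams <- if (brachy || !length(beam_items)) NULL else {
    do.call(rbind, lapply(beam_items, function(b) {
      bn <- as.character(ds_get1(b, "BeamNumber"))
      ref <- beam_ref[[bn]] %||% list(group = NA, dose = NA, mu = NA)
      cps <- ds_get(b, "ControlPointSequence") %||% list()
      num <- function(name) as.numeric(unlist(lapply(cps, ds_get1, name, NA)))
      gantry <- angle_stats(stats::na.omit(num("GantryAngle")))
      coll <- angle_stats(stats::na.omit(num("BeamLimitingDeviceAngle")))
      couch <- angle_stats(stats::na.omit(num("PatientSupportAngle")))
      energies <- stats::na.omit(num("NominalBeamEnergy"))
      ssds <- stats::na.omit(num("SourceToSurfaceDistance"))
      iso <- NULL
      for (cp in cps) {
        v <- ds_get(cp, "IsocenterPosition")
        if (!is.null(v)) { iso <- v; break }
      }
      spots <- stats::na.omit(num("NumberOfScanSpotPositions"))
      ncp <- as.integer(ds_get1(b, "NumberOfControlPoints", length(cps)))
      mu <- ref$mu
      grp_fxs <- if (!is.na(ref$group))
        as.integer(ds_get1(fx_groups[[ref$group]],
                           "NumberOfFractionsPlanned", NA))
      else NA_integer_
      data.frame(
        mrn = mrn, study_uid = study_uid,
        import_timestamp = NA_character_,
        beam_name = ds_get1(b, "BeamName", NA),
        beam_number = as.integer(bn),
        beam_dose = ref$dose,
        beam_mu = mu,
        mu_per_degree = if (!is.na(gantry$range) && gantry$range > 0)
          mu / gantry$range else NA_real_,
        mu_per_control_point = if (!is.na(mu) && ncp > 0) mu / ncp
          else NA_real_,
        control_point_count = ncp,
        energy_min = if (length(energies)) min(energies) else NA_real_,
        energy_max = if (length(energies)) max(energies) else NA_real_,
        radiation_type = ds_get1(b, "RadiationType", NA),
        beam_type = ds_get1(b, "BeamType", NA),
        fx_count = grp_fxs,
        fx_group_beam_count = if (!is.na(ref$group))
          as.integer(ds_get1(fx_groups[[ref$group]], "NumberOfBeams", NA))
        else NA_integer_,
        fx_group_number = ref$group,
        gantry_rot_dir = {
          gd <- unlist(lapply(cps, ds_get1, "GantryRotationDirection", NA))
          gd <- gd[!is.na(gd)]
          if (length(gd)) gd[1] else NA_character_
        },
        collimator_rot_dir = NA_character_,
        couch_rot_dir = NA_character_,
        gantry_start = gantry$start, gantry_end = gantry$end,
        gantry_min = gantry$min, gantry_max = gantry$max,
        gantry_range = gantry$range,
        collimator_start = coll$start, collimator_end = coll$end,
        collimator_min = coll$min, collimator_max = coll$max,
        collimator_range = coll$range,
        couch_start = couch$start, couch_end = couch$end,
        couch_min = couch$min, couch_max = couch$max,
        couch_range = couch$range,
        isocenter_x = (iso %||% rep(NA_real_, 3))[1],
        isocenter_y = (iso %||% rep(NA_real_, 3))[2],
        isocenter_z = (iso %||% rep(NA_real_, 3))[3],
        scan_spot_count = if (length(spots)) sum(spots) else NA_real_,
        scan_mode = {
          sm <- unlist(lapply(cps, ds_get1, "ScanMode", NA))
          sm <- sm[!is.na(sm)]
          if (length(sm)) sm[1] else ds_get1(b, "ScanMode", NA)
        },
        ssd = if (length(ssds)) mean(ssds) else NA_real_,
        treatment_machine = ds_get1(b, "TreatmentMachineName", NA),
        stringsAsFactors = FALSE)
    }))
  }
  if (is.null(beams))
    beams <- data.frame(mrn = character(0), study_uid = character(0))

  # treatment time (brachytherapy): total channel dwell time
  tx_time <- NA_real_
  if (brachy) {
    secs <- 0
    for (setup in ds_get(plan, "ApplicationSetupSequence") %||% list())
      for (ch in ds_get(setup, "ChannelSequence") %||% list())
        secs <- secs + as.numeric(ds_get1(ch, "ChannelTotalTime", 0))
    tx_time <- secs
  }

  radiation_types <- toupper(unique(stats::na.omit(
    if (nrow(beams)) beams$radiation_type else character(0))))
  tx_modality <- if (brachy) "Brachytherapy"
    else if ("PROTON" %in% radiation_types) "Proton"
    else if ("ELECTRON" %in% radiation_types) "Electron"
    else if (nrow(beams) && any(beams$gantry_range > 1, na.rm = TRUE))
      "Photon arc"
    else "Photon 3D"

  ps <- ds_get(dose, "PixelSpacing")
  offsets <- as.numeric(ds_get(dose, "GridFrameOffsetVector") %||% NA)
  dz <- if (length(offsets) > 1) unique(round(diff(offsets), 3))[1] else NA
  grid_res <- if (!is.null(ps)) sprintf("%g,%g,%g mm", ps[2], ps[1], dz)
              else NA_character_

  birth <- dicom_date_to_iso(ds_get1(plan, "PatientBirthDate", NA))
  simd <- dicom_date_to_iso(ds_get1(plan, "StudyDate", NA))

  orientation <- {
    setup <- ds_get(plan, "PatientSetupSequence") %||% list()
    if (length(setup)) ds_get1(setup[[1]], "PatientPosition", NA)
    else NA_character_
  }

  plan_row <- data.frame(
    mrn = mrn, study_uid = study_uid,
    import_timestamp = NA_character_,
    age_at_study = floor_years_between(birth, simd),
    baseline = FALSE,
    birthdate = birth,
    dose_grid_resolution = grid_res,
    dose_timestamp = stamp_of(dose, "InstanceCreationDate",
                              "InstanceCreationTime"),
    fractions = if (nrow(rxs)) sum(rxs$fxs, na.rm = TRUE) else NA_integer_,
    heterogeneity_correction = paste(
      ds_get(dose, "TissueHeterogeneityCorrection") %||% NA, collapse = ","),
    total_mu = if (nrow(beams)) sum(beams$beam_mu, na.rm = TRUE) else NA_real_,
    patient_sex = ds_get1(plan, "PatientSex", NA),
    patient_orientation = orientation,
    physician = ds_get1(plan, "ReferringPhysicianName", NA),
    plan_timestamp = stamp_of(plan, "RTPlanDate", "RTPlanTime") %||%
      stamp_of(plan, "InstanceCreationDate", "InstanceCreationTime"),
    rx_dose = if (nrow(rxs)) sum(rxs$rx_dose, na.rm = TRUE) else NA_real_,
    sim_study_date = simd,
    structure_timestamp = stamp_of(struct, "StructureSetDate",
                                   "StructureSetTime") %||%
      stamp_of(struct, "InstanceCreationDate", "InstanceCreationTime"),
    tps_manufacturer = ds_get1(plan, "Manufacturer", NA),
    tps_name = ds_get1(plan, "ManufacturerModelName", NA),
    tps_version = ds_get1(plan, "SoftwareVersions", NA),
    tx_modality = tx_modality,
    tx_site = tx_site,
    tx_time = tx_time,
    stringsAsFactors = FALSE)

  list(plan = plan_row, rxs = rxs, beams = beams)
}
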