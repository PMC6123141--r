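# Writers for standards-conformant synthetic RT Plan / Structure Set /
# Dose filesets built from a phantom. One study instance UID spans the
# three files; UIDs are pinned by the phantom seed so regeneration is
# byte-stable.

phantom_uid <- function(seed, k)
  sprintf("1.2.826.0.1.3680043.9.7432.%d.%d", seed, k)

dicom_datetime <- function(x) {
  # "YYYY-MM-DD HH:MM:SS" or Date-like -> list(date = DA, time = TM)
  s <- format(x)
  s <- gsub("[-: ]", "", s)
  if (nchar(s) == 8) s <- paste0(s, "120000")
  list(date = substr(s, 1, 8), time = substr(s, 9, 14))
}

common_patient_ds <- function(ds, pm, seed, dt) {
  ds <- ds_set(ds, "SpecificCharacterSet", "ISO_IR 100")
  ds <- ds_set(ds, "InstanceCreationDate", dt$date)
  ds <- ds_set(ds, "InstanceCreationTime", dt$time)
  ds <- ds_set(ds, "PatientName", pm$patient_name)
  ds <- ds_set(ds, "PatientID", pm$mrn)
  ds <- ds_set(ds, "PatientBirthDate", iso_to_dicom_date(pm$birthdate))
  ds <- ds_set(ds, "PatientSex", pm$sex)
  ds <- ds_set(ds, "StudyDate", iso_to_dicom_date(pm$sim_date))
  ds <- ds_set(ds, "StudyTime", "090000")
  ds <- ds_set(ds, "StudyID", "1")
  ds <- ds_set(ds, "StudyInstanceUID", phantom_uid(seed, 1))
  ds <- ds_set(ds, "FrameOfReferenceUID", phantom_uid(seed, 2))
  ds <- ds_set(ds, "Manufacturer", "rtdvh synthetic")
  ds <- ds_set(ds, "ManufacturerModelName", "rtdvh phantom writer")
  ds <- ds_set(ds, "SoftwareVersions", "0.1.0")
  ds
}

build_rtplan_ds <- function(phantom, pm, seed, dt, instance_index = 1L) {
  ds <- dcm_ds(SOPClassUID = SOP_RTPLAN,
               SOPInstanceUID = phantom_uid(seed, 10 + instance_index),
               Modality = "RTPLAN",
               SeriesInstanceUID = phantom_uid(seed, 3),
               SeriesNumber = 1)
  ds <- common_patient_ds(ds, pm, seed, dt)
  ds <- ds_set(ds, "ReferringPhysicianName", pm$physician)
  ds <- ds_set(ds, "RTPlanLabel", pm$plan_label)
  ds <- ds_set(ds, "RTPlanName", pm$plan_label)
  ds <- ds_set(ds, "RTPlanDate", iso_to_dicom_date(pm$sim_date))
  ds <- ds_set(ds, "RTPlanTime", "110000")
  ds <- ds_set(ds, "RTPlanGeometry", "PATIENT")
  ds <- ds_set(ds, "PatientSetupSequence", list(
    dcm_ds(PatientSetupNumber = 1, PatientPosition = pm$orientation)))

  n_groups <- length(pm$rx)
  beam_groups <- if (length(pm$beams))
    vapply(pm$beams, function(b) as.integer(b$fx_group %||% 1L), 1L)
  else integer(0)

  dose_refs <- lapply(seq_len(n_groups), function(i) {
    g <- pm$rx[[i]]
    dcm_ds(DoseReferenceDescription = g$name %||% sprintf("FxGrp %d", i),
           DoseReferenceType = "TARGET",
           DoseReferenceStructureType = "SITE",
           TargetPrescriptionDose = g$fxs * g$fx_dose)
  })
  ds <- ds_set(ds, "DoseReferenceSequence", dose_refs)

  fx_groups <- lapply(seq_len(n_groups), function(i) {
    g <- pm$rx[[i]]
    item <- dcm_ds(FractionGroupNumber = i,
                   NumberOfFractionsPlanned = g$fxs)
    if (pm$brachy) {
      item <- ds_set(item, "NumberOfBeams", 0)
      item <- ds_set(item, "NumberOfBrachyApplicationSetups", 1)
    } else {
      in_grp <- which(beam_groups == i)
      item <- ds_set(item, "NumberOfBeams", length(in_grp))
      mu <- vapply(pm$beams[in_grp], function(b) b$mu, 0)
      refs <- lapply(seq_along(in_grp), function(j) {
        b <- pm$beams[[in_grp[j]]]
        dcm_ds(ReferencedBeamNumber = in_grp[j],
               BeamDose = g$fx_dose * mu[j] / sum(mu),
               BeamMeterset = b$mu)
      })
      item <- ds_set(item, "ReferencedBeamSequence", refs)
    }
    item
  })
  ds <- ds_set(ds, "FractionGroupSequence", fx_groups)

  if (pm$brachy) {
    ds <- ds_set(ds, "BrachyTreatmentType", "HDR")
    ds <- ds_set(ds, "ApplicationSetupSequence", list(
      dcm_ds(ApplicationSetupNumber = 1,
             ChannelSequence = list(
               dcm_ds(ChannelNumber = 1,
                      ChannelTotalTime = pm$tx_time %||% 300)))))
  } else {
    beams <- lapply(seq_along(pm$beams), function(j) {
      b <- pm$beams[[j]]
      iso <- b$isocenter %||% c(0, 0, 0)
      coll <- b$collimator %||% 0
      couch <- b$couch %||% 0
      arc <- !isTRUE(all.equal(b$gantry_start, b$gantry_end))
      cp0 <- dcm_ds(ControlPointIndex = 0,
                    NominalBeamEnergy = b$energy,
                    GantryAngle = b$gantry_start,
                    GantryRotationDirection = if (arc) "CW" else "NONE",
                    BeamLimitingDeviceAngle = coll,
                    PatientSupportAngle = couch,
                    IsocenterPosition = iso,
                    SourceToSurfaceDistance = b$ssd,
                    CumulativeMetersetWeight = 0)
      cp1 <- dcm_ds(ControlPointIndex = 1,
                    GantryAngle = b$gantry_end,
                    SourceToSurfaceDistance = b$ssd_end %||% b$ssd,
                    CumulativeMetersetWeight = 1)
      dcm_ds(BeamNumber = j,
             BeamName = b$name,
             BeamType = if (arc) "DYNAMIC" else "STATIC",
             RadiationType = toupper(b$radiation_type %||% "PHOTON"),
             TreatmentMachineName = pm$machine,
             FinalCumulativeMetersetWeight = 1,
             NumberOfControlPoints = 2,
             ControlPointSequence = list(cp0, cp1))
    })
    ds <- ds_set(ds, "BeamSequence", beams)
  }
  ds
}

build_rtstruct_ds <- function(phantom, pm, seed, dt, instance_index = 1L) {
  ds <- dcm_ds(SOPClassUID = SOP_RTSTRUCT,
               SOPInstanceUID = phantom_uid(seed, 20 + instance_index),
               Modality = "RTSTRUCT",
               SeriesInstanceUID = phantom_uid(seed, 4),
               SeriesNumber = 1)
  ds <- common_patient_ds(ds, pm, seed, dt)
  ds <- ds_set(ds, "StructureSetLabel", pm$plan_label)
  ds <- ds_set(ds, "StructureSetDate", iso_to_dicom_date(pm$sim_date))
  ds <- ds_set(ds, "StructureSetTime", "100000")

  rois <- phantom$rois
  pois <- list(list(name = paste0("tx: ", pm$tx_site), point = c(0, 0, 0),
                    type = "MARKER"))
  for (p in pm$pois %||% list()) {
    p$type <- p$type %||% "MARKER"
    pois[[length(pois) + 1L]] <- p
  }
  n_roi <- length(rois)

  roi_seq <- c(
    lapply(seq_len(n_roi), function(i)
      dcm_ds(ROINumber = i, ROIName = rois[[i]]$roi_name)),
    lapply(seq_along(pois), function(i)
      dcm_ds(ROINumber = n_roi + i, ROIName = pois[[i]]$name)))
  ds <- ds_set(ds, "StructureSetROISequence", roi_seq)

  contour_seq <- c(
    lapply(seq_len(n_roi), function(i) {
      roi <- rois[[i]]
      items <- list()
      for (s in roi$slices) for (r in s$rings) {
        n <- length(r$x)
        items[[length(items) + 1L]] <- dcm_ds(
          ContourGeometricType = "CLOSED_PLANAR",
          NumberOfContourPoints = n,
          ContourData = as.numeric(rbind(r$x, r$y, rep(s$z, n))))
      }
      dcm_ds(ReferencedROINumber = i, ContourSequence = items)
    }),
    lapply(seq_along(pois), function(i)
      dcm_ds(ReferencedROINumber = n_roi + i,
             ContourSequence = list(dcm_ds(
               ContourGeometricType = "POINT",
               NumberOfContourPoints = 1,
               ContourData = as.numeric(pois[[i]]$point))))))
  ds <- ds_set(ds, "ROIContourSequence", contour_seq)

  obs_seq <- c(
    lapply(seq_len(n_roi), function(i)
      dcm_ds(ObservationNumber = i, ReferencedROINumber = i,
             RTROIInterpretedType = toupper(rois[[i]]$roi_type))),
    lapply(seq_along(pois), function(i)
      dcm_ds(ObservationNumber = n_roi + i, ReferencedROINumber = n_roi + i,
             RTROIInterpretedType = toupper(pois[[i]]$type))))
  ds <- ds_set(ds, "RTROIObservationsSequence", obs_seq)
  ds
}

build_rtdose_ds <- function(phantom, pm, seed, dt, instance_index = 1L) {
  grid <- phantom$grid
  d <- dim(grid$values)
  gy <- dose_values(grid)
  maxdose <- max(gy)
  scaling <- if (maxdose > 0) maxdose / 65530 else 1
  ints <- round(gy / scaling)
  pix <- u16_raw(as.vector(ints))   # frame-major, rows = y, cols = x

  ds <- dcm_ds(SOPClassUID = SOP_RTDOSE,
               SOPInstanceUID = phantom_uid(seed, 30 + instance_index),
               Modality = "RTDOSE",
               SeriesInstanceUID = phantom_uid(seed, 5),
               SeriesNumber = 1)
  ds <- common_patient_ds(ds, pm, seed, dt)
  ds <- ds_set(ds, "ImagePositionPatient", grid$origin)
  ds <- ds_set(ds, "ImageOrientationPatient", c(1, 0, 0, 0, 1, 0))
  ds <- ds_set(ds, "PixelSpacing",
               c(grid$pixel_spacing[2], grid$pixel_spacing[1]))  # row, col
  ds <- ds_set(ds, "Rows", d[2])
  ds <- ds_set(ds, "Columns", d[1])
  ds <- ds_set(ds, "NumberOfFrames", d[3])
  ds <- ds_set(ds, "GridFrameOffsetVector", grid$z_offsets)
  ds <- ds_set(ds, "DoseGridScaling", scaling)
  ds <- ds_set(ds, "DoseUnits", "GY")
  ds <- ds_set(ds, "DoseType", "PHYSICAL")
  ds <- ds_set(ds, "DoseSummationType", "PLAN")
  ds <- ds_set(ds, "TissueHeterogeneityCorrection",
               pm$heterogeneity %||% "IMAGE")
  ds <- ds_set(ds, "SamplesPerPixel", 1)
  ds <- ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds <- ds_set(ds, "BitsAllocated", 16)
  ds <- ds_set(ds, "BitsStored", 16)
  ds <- ds_set(ds, "HighBit", 15)
  ds <- ds_set(ds, "PixelRepresentation", 0)
  ds <- ds_set(ds, "ReferencedRTPlanSequence", list(
    dcm_ds(ReferencedSOPClassUID = SOP_RTPLAN,
           ReferencedSOPInstanceUID = phantom_uid(seed, 11))))
  ds[[tag_of("PixelData")]] <- list(vr = "OW", value = pix)
  ds
}

#' Write a phantom as a DICOM RT fileset
#'
#' Produces a standards-conformant RT Plan, RT Structure Set and RT Dose
#' file sharing one study instance UID, re-ingestable by
#' [discover_filesets()] and the parsers. The structure set carries a
#' `"tx: <site>"` point of interest so the treatment-site convention can be
#' exercised; dose is quantized to 16 bits with the scale factor stored in
#' the file.
#'
#' @param phantom result of [make_phantom()].
#' @param out_dir output directory (created if needed).
#' @param plan_meta optional [plan_meta()] override (defaults to the
#'   phantom spec's).
#' @param instance_datetime creation timestamp for the instances
#'   (`"YYYY-MM-DD HH:MM:SS"`); defaults to the sim date at noon.
#' @param modalities subset of `c("plan", "struct", "dose")` to write.
#' @param instance_index distinguishes repeated instances of the same
#'   modality (new SOP instance UIDs and file names, same study UID).
#' @return named character vector of the paths written.
#' @export
write_dicom_rt <- function(phantom, out_dir, plan_meta = NULL,
                           instance_datetime = NULL,
                           modalities = c("plan", "struct", "dose"),
                           instance_index = 1L) {
  pm <- plan_meta %||% phantom$spec$plan_meta
  seed <- phantom$spec$seed
  dt <- dicom_datetime(instance_datetime %||% paste(pm$sim_date, "12:00:00"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sfx <- if (instance_index > 1L) sprintf("_%d", instance_index) else ""
  out <- character(0)
  if ("plan" %in% modalities) {
    p <- file.path(out_dir, sprintf("RP.%s%s.dcm", pm$mrn, sfx))
    dcm_write_file(build_rtplan_ds(phantom, pm, seed, dt, instance_index), p)
    out["plan"] <- p
  }
  if ("struct" %in% modalities) {
    p <- file.path(out_dir, sprintf("RS.%s%s.dcm", pm$mrn, sfx))
    dcm_write_file(build_rtstruct_ds(phantom, pm, seed, dt, instance_index), p)
    out["struct"] <- p
  }
  if ("dose" %in% modalities) {
    p <- file.path(out_dir, sprintf("RD.%s%s.dcm", pm$mrn, sfx))
    dcm_write_file(build_rtdose_ds(phantom, pm, seed, dt, instance_index), p)
    out["dose"] <- p
  }
  out
}
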