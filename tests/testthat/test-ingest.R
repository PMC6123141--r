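# DICOM write -> discover -> parse round trips and ingest conventions.

two_roi_phantom <- function(seed = 3, tx = "Larynx", brachy = FALSE,
                            rx = list(list(fxs = 30, fx_dose = 2,
                                           name = "initial"),
                                      list(fxs = 5, fx_dose = 2,
                                           name = "boost"))) {
  make_phantom(phantom_spec(
    grid_shape = c(26, 26, 18), spacing = c(2, 2, 2),
    dose_model = dose_uniform(60),
    structures = list(
      structure_spec("PTV", "PTV", shape_sphere(12)),
      structure_spec("ITV_primary", "ORGAN", shape_sphere(8)),
      structure_spec("node", "ORGAN", shape_ring(10, 6, 12),
                     center = c(0, 12, 0))),
    plan_meta = plan_meta(tx_site = tx, rx = rx, brachy = brachy,
                          tx_time = if (brachy) 412 else NA_real_,
                          beams = if (brachy) list() else list(
                            list(name = "Arc1", energy = 6, mu = 200,
                                 gantry_start = 181, gantry_end = 179,
                                 ssd = 900, fx_group = 1),
                            list(name = "AP", energy = 10, mu = 90,
                                 gantry_start = 0, gantry_end = 0,
                                 ssd = 950, fx_group = 2))),
    seed = seed))
}

test_that("discovery groups by study UID and picks the latest timestamp", {
  dir <- withr::local_tempdir()
  ph <- two_roi_phantom(seed = 21)
  write_dicom_rt(ph, dir, instance_datetime = "2024-03-01 12:00:00")
  fss <- discover_filesets(dir)
  expect_length(fss, 1)
  expect_equal(fss[[1]]$mrn, "PH000001")
  expect_length(fss[[1]]$extra_files, 0)

  # a second, later RT Dose instance for the same study wins
  write_dicom_rt(ph, dir, instance_datetime = "2024-03-02 09:00:00",
                 modalities = "dose", instance_index = 2L)
  fss2 <- discover_filesets(dir)
  expect_length(fss2, 1)
  expect_match(fss2[[1]]$dose_file, "_2")
  expect_length(fss2[[1]]$extra_files, 1)
  expect_match(fss2[[1]]$extra_files, "RD\\.PH000001\\.dcm")
})

test_that("incomplete groups are reported, not returned; junk is skipped", {
  dir <- withr::local_tempdir()
  ph <- two_roi_phantom(seed = 22)
  write_dicom_rt(ph, dir, modalities = c("plan", "dose"))
  writeLines("not dicom at all", file.path(dir, "junk.txt"))
  expect_warning(discover_filesets(dir), "skipping")
  fss <- suppressWarnings(discover_filesets(dir))
  expect_length(fss, 0)
  inc <- attr(fss, "incomplete")
  expect_length(inc, 1)
  expect_equal(inc[[1]]$missing, "RTSTRUCT")
})

test_that("grouping is invariant to discovery order", {
  dir <- withr::local_tempdir()
  for (s in c(31, 32)) write_dicom_rt(two_roi_phantom(seed = s),
                                      file.path(dir, paste0("s", s)))
  fss <- discover_filesets(dir)
  expect_length(fss, 2)
  # renaming files to reverse lexicographic order must not change grouping
  key <- function(fs) fs[c("mrn", "study_uid")]
  uids <- sort(vapply(fss, `[[`, "", "study_uid"))
  dir2 <- withr::local_tempdir()
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  for (i in seq_along(files))
    file.copy(files[i], file.path(dir2, sprintf("zz_%02d.dcm",
                                                length(files) - i)))
  fss2 <- discover_filesets(dir2)
  expect_equal(sort(vapply(fss2, `[[`, "", "study_uid")), uids)
})

test_that("structure parsing honors ITV naming, rings and POIs", {
  dir <- withr::local_tempdir()
  write_dicom_rt(two_roi_phantom(seed = 23), dir)
  fs <- discover_filesets(dir)[[1]]
  rois <- parse_structures(fs)
  # ITV_primary was written as ORGAN but must come back typed ITV
  expect_equal(rois$ITV_primary$roi_type, "ITV")
  expect_equal(rois$PTV$roi_type, "PTV")
  # ring structure: two rings per slice, order preserved (outer first)
  rings <- rois$node$slices[[1]]$rings
  expect_length(rings, 2)
  r_out <- max(sqrt(rings[[1]]$x^2 + (rings[[1]]$y - 12)^2))
  r_in <- max(sqrt(rings[[2]]$x^2 + (rings[[2]]$y - 12)^2))
  expect_gt(r_out, r_in)
  # POI list carries the tx site marker, excluded from geometry
  expect_true(any(grepl("^tx:", names(attr(rois, "points")))))
  expect_false(any(grepl("^tx:", names(rois))))
})

test_that("plan parsing extracts site, prescriptions and arc SSD", {
  dir <- withr::local_tempdir()
  write_dicom_rt(two_roi_phantom(seed = 24, tx = "Larynx"), dir)
  fs <- discover_filesets(dir)[[1]]
  pp <- parse_plan(fs)
  expect_equal(pp$plan$tx_site, "Larynx")
  expect_equal(nrow(pp$rxs), 2)
  expect_equal(pp$rxs$rx_dose, c(60, 10))
  expect_equal(pp$plan$rx_dose, 70)   # composite = sum of groups
  expect_equal(pp$rxs$fx_group_number, c(1, 2))
  expect_true(all(pp$rxs$fx_group_number <= pp$rxs$fx_group_count))
  expect_equal(pp$plan$fractions, 35)
  expect_equal(nrow(pp$beams), 2)
  arc <- pp$beams[pp$beams$beam_name == "Arc1", ]
  expect_equal(arc$ssd, 900)           # mean over control points
  expect_equal(arc$gantry_range, 2)
  expect_equal(arc$mu_per_degree, 200 / 2)
  expect_true(is.na(pp$beams$mu_per_degree[pp$beams$beam_name == "AP"]))
  expect_equal(pp$plan$tx_modality, "Photon arc")
  expect_equal(pp$plan$age_at_study, 64)
})

test_that("brachytherapy plans populate all tables except beams", {
  dir <- withr::local_tempdir()
  write_dicom_rt(two_roi_phantom(seed = 25, brachy = TRUE,
                                 rx = list(list(fxs = 5, fx_dose = 6,
                                                name = "hdr"))), dir)
  fs <- discover_filesets(dir)[[1]]
  pp <- parse_plan(fs)
  expect_equal(nrow(pp$beams), 0)
  expect_equal(nrow(pp$rxs), 1)
  expect_equal(pp$rxs$rx_dose, 30)
  expect_equal(pp$plan$tx_modality, "Brachytherapy")
  expect_equal(pp$plan$tx_time, 412)
})

test_that("POI-encoded prescriptions override fraction-group data", {
  ph <- two_roi_phantom(seed = 26,
                        rx = list(list(fxs = 30, fx_dose = 2)))
  ph$spec$plan_meta$pois <- list(
    list(name = "rx1: SIB plan:33x2.12:97%", point = c(0, 0, 0)))
  dir <- withr::local_tempdir()
  write_dicom_rt(ph, dir)
  pp <- parse_plan(discover_filesets(dir)[[1]])
  expect_equal(pp$rxs$fxs, 33)
  expect_equal(pp$rxs$fx_dose, 2.12)
  expect_equal(pp$rxs$rx_percent, 97)
  expect_equal(pp$rxs$fx_group_name, "SIB plan")
})

test_that("dose parsing rejects non-Gy units and round-trips values", {
  dir <- withr::local_tempdir()
  ph <- two_roi_phantom(seed = 27)
  paths <- write_dicom_rt(ph, dir)
  g <- parse_dose(discover_filesets(dir)[[1]])
  expect_equal(dim(g$values), dim(ph$grid$values))
  expect_lte(max(abs(dose_values(g) - dose_values(ph$grid))),
             g$dose_scaling)
  expect_equal(g$z_offsets, ph$grid$z_offsets)
  expect_equal(g$pixel_spacing, ph$grid$pixel_spacing)

  # flip the units tag to RELATIVE and expect refusal
  ds <- rtdvh:::dcm_read_file(paths[["dose"]])
  ds <- rtdvh:::ds_set(ds, "DoseUnits", "RELATIVE")
  bad <- file.path(dir, "bad_dose.dcm")
  rtdvh:::dcm_write_file(ds, bad)
  expect_error(parse_dose(bad), "RELATIVE")
})

test_that("contours and metadata round-trip exactly", {
  dir <- withr::local_tempdir()
  ph <- two_roi_phantom(seed = 28)
  write_dicom_rt(ph, dir)
  fs <- discover_filesets(dir)[[1]]
  rois <- parse_structures(fs)
  for (nm in names(ph$rois)) {
    a <- ph$rois[[nm]]$slices; b <- rois[[nm]]$slices
    expect_equal(vapply(a, `[[`, 0, "z"), vapply(b, `[[`, 0, "z"))
    for (i in seq_along(a)) for (j in seq_along(a[[i]]$rings)) {
      expect_equal(a[[i]]$rings[[j]]$x, b[[i]]$rings[[j]]$x,
                   tolerance = 1e-7)
      expect_equal(a[[i]]$rings[[j]]$y, b[[i]]$rings[[j]]$y,
                   tolerance = 1e-7)
    }
  }
})
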