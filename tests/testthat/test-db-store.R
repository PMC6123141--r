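# Five-table schema, transactional import, duplicate guard, query layer.

make_bundle <- function(seed = 51, mrn = "P1", physician = "AB",
                        tx_site = "Larynx", rx_dose = 60) {
  dir <- tempfile()
  ph <- make_phantom(phantom_spec(
    grid_shape = c(24, 24, 14), spacing = c(2, 2, 2),
    dose_model = dose_uniform(rx_dose),
    structures = list(structure_spec("PTV", "PTV", shape_sphere(10)),
                      structure_spec("cord", "ORGAN",
                                     shape_cylinder(4, 20), c(18, 0, 0))),
    plan_meta = plan_meta(mrn = mrn, physician = physician,
                          tx_site = tx_site,
                          rx = list(list(fxs = 30, fx_dose = rx_dose / 30,
                                         name = "initial"))),
    seed = seed))
  write_dicom_rt(ph, dir)
  fs <- discover_filesets(dir)[[1]]
  process_fileset(fs)
}

local_db <- function(env = parent.frame()) {
  con <- db_connect(":memory:")
  withr::defer(DBI::dbDisconnect(con), envir = env)
  initialize_schema(con)
  con
}

test_that("schema creation is idempotent and refuses incompatible tables", {
  con <- local_db()
  expect_setequal(DBI::dbListTables(con),
                  c("plans", "rxs", "beams", "dvhs", "dicom_files"))
  expect_silent(initialize_schema(con))   # second call is a no-op

  con2 <- db_connect(":memory:")
  withr::defer(DBI::dbDisconnect(con2))
  DBI::dbExecute(con2, "CREATE TABLE plans (wrong TEXT)")
  expect_error(initialize_schema(con2), "incompatible")
})

test_that("import is transactional, conserves rows and guards duplicates", {
  con <- local_db()
  b <- make_bundle()
  res <- import_fileset(con, b)
  expect_true(res$imported)
  counts <- vapply(c("plans", "rxs", "beams", "dvhs", "dicom_files"),
                   function(tb) DBI::dbGetQuery(
                     con, paste("SELECT COUNT(*) n FROM", tb))$n, 0)
  expect_equal(unname(counts), c(1, nrow(b$rxs), nrow(b$beams),
                                 nrow(b$dvhs), 1))

  res2 <- import_fileset(con, b)   # duplicate study refused
  expect_false(res2$imported)
  expect_match(res2$reason, "already imported")
  counts2 <- DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM plans")$n
  expect_equal(counts2, 1)

  # a bundle violating an invariant rolls back completely
  bad <- make_bundle(seed = 52, mrn = "P2")
  bad$dvhs$roi_volume[1] <- -1
  expect_error(import_fileset(con, bad), "roi_volume")
  expect_equal(DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM plans")$n, 1)
  expect_equal(DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM dvhs")$n,
               nrow(b$dvhs))

  # one import timestamp across all rows of the import
  stamps <- unlist(lapply(c("plans", "rxs", "beams", "dvhs"), function(tb)
    DBI::dbGetQuery(con, paste("SELECT DISTINCT import_timestamp FROM",
                               tb))[[1]]))
  expect_length(unique(stamps), 1)
})

test_that("stored numerics round-trip bit-identically", {
  con <- local_db()
  b <- make_bundle(seed = 53)
  import_fileset(con, b)
  got <- DBI::dbGetQuery(con, "SELECT * FROM dvhs ORDER BY roi_name")
  ord <- order(b$dvhs$roi_name)
  expect_identical(got$roi_volume, b$dvhs$roi_volume[ord])
  expect_identical(got$mean_dose, b$dvhs$mean_dose[ord])
  expect_identical(got$dist_min, b$dvhs$dist_min[ord])
  # serialized DVH curve reconstructs the cumulative values
  d <- rtdvh:::deserialize_dvh(got$dvh[1], got$bin_width[1])
  orig <- rtdvh:::deserialize_dvh(b$dvhs$dvh[ord][1], got$bin_width[1])
  expect_equal(d$cumulative, orig$cumulative)
  # contour serialization round-trips coordinates to 1e-3 mm
  roi <- rtdvh:::deserialize_contours(got$roi_coordinates[1], "x", "ORGAN")
  expect_s3_class(roi, "roi_contours")
  expect_gt(length(roi$slices), 2)
})

test_that("query combines OR within a category, AND across, ranges inclusive", {
  con <- local_db()
  import_fileset(con, make_bundle(seed = 54, mrn = "P1", physician = "AB",
                                  tx_site = "Brain", rx_dose = 50))
  import_fileset(con, make_bundle(seed = 55, mrn = "P2", physician = "CD",
                                  tx_site = "Brain", rx_dose = 60))
  import_fileset(con, make_bundle(seed = 56, mrn = "P3", physician = "EF",
                                  tx_site = "Larynx", rx_dose = 70))

  s1 <- execute_query(con, query_filter(
    selection = list(physician = "AB", tx_site = "Brain")))
  expect_equal(unique(s1$dvhs$mrn), "P1")

  s2 <- execute_query(con, query_filter(
    selection = list(physician = c("AB", "CD"))))
  expect_setequal(unique(s2$dvhs$mrn), c("P1", "P2"))

  s3 <- execute_query(con, query_filter(
    ranges = list(list(category = "rx_dose", min = 59, max = 61))))
  expect_equal(unique(s3$dvhs$mrn), "P2")
  expect_equal(unique(s3$plans$rx_dose), 60)

  # beam-table range filters select whole studies via EXISTS
  s4 <- execute_query(con, query_filter(
    ranges = list(list(category = "beam_mu", min = 115, max = 125))))
  expect_setequal(unique(s4$dvhs$mrn), c("P1", "P2", "P3"))

  expect_error(query_filter(selection = list(nope = "x")), "unknown")
  expect_error(query_filter(ranges = list(list(category = "nope",
                                               min = 0, max = 1))),
               "unknown")

  # results independent of insertion order: same filter, fresh db reversed
  con2 <- local_db()
  import_fileset(con2, make_bundle(seed = 56, mrn = "P3", physician = "EF",
                                   tx_site = "Larynx", rx_dose = 70))
  import_fileset(con2, make_bundle(seed = 55, mrn = "P2", physician = "CD",
                                   tx_site = "Brain", rx_dose = 60))
  import_fileset(con2, make_bundle(seed = 54, mrn = "P1", physician = "AB",
                                   tx_site = "Brain", rx_dose = 50))
  s2b <- execute_query(con2, query_filter(
    selection = list(physician = c("AB", "CD"))))
  expect_equal(s2b$dvhs$roi_name, s2$dvhs$roi_name)
  expect_equal(s2b$dvhs$mrn, s2$dvhs$mrn)
})

test_that("single-cell edits apply, log, and reject unknown targets", {
  con <- local_db()
  b <- make_bundle(seed = 57)
  import_fileset(con, b)
  uid <- b$plan$study_uid
  update_record(con, "plans", uid, "P1", "baseline", TRUE)
  s <- execute_query(con, query_filter(selection = list(baseline = TRUE)))
  expect_equal(unique(s$dvhs$study_uid), uid)

  update_record(con, "plans", uid, "P1", "physician", "ZZ")
  s2 <- execute_query(con, query_filter(selection = list(physician = "ZZ")))
  expect_equal(nrow(s2$plans), 1)

  expect_error(update_record(con, "plans", "no-such-uid", "P1",
                             "physician", "QQ"), "no row")
  expect_error(update_record(con, "plans", uid, "P1", "nope", 1),
               "unknown column")
  expect_error(update_record(con, "dvhs", uid, "P1", "roi_type", "X"),
               "roi_name")
})

test_that("referential integrity holds for all imported rows", {
  con <- local_db()
  import_fileset(con, make_bundle(seed = 58, mrn = "P8"))
  orphans <- DBI::dbGetQuery(con, "
    SELECT COUNT(*) n FROM (
      SELECT mrn, study_uid FROM dvhs
      UNION ALL SELECT mrn, study_uid FROM rxs
      UNION ALL SELECT mrn, study_uid FROM beams) t
    WHERE NOT EXISTS (SELECT 1 FROM plans p
                      WHERE p.mrn = t.mrn AND p.study_uid = t.study_uid)")
  expect_equal(orphans$n, 0)
})
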