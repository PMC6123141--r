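# Five-table relational store (DVHs, Plans, Rxs, Beams, DICOM file
# catalog), linked by MRN + study instance UID, plus the query layer.
# The embedded engine is SQLite via DBI; the shipped DDL
# (inst/extdata/schema.sql) is portable to server engines.

db_schema <- list(
  plans = c(
    mrn = "TEXT", study_uid = "TEXT", import_timestamp = "TEXT",
    age_at_study = "REAL", baseline = "INTEGER", birthdate = "TEXT",
    dose_grid_resolution = "TEXT", dose_timestamp = "TEXT",
    fractions = "INTEGER", heterogeneity_correction = "TEXT",
    total_mu = "REAL", patient_sex = "TEXT", patient_orientation = "TEXT",
    physician = "TEXT", plan_timestamp = "TEXT", rx_dose = "REAL",
    sim_study_date = "TEXT", structure_timestamp = "TEXT",
    tps_manufacturer = "TEXT", tps_name = "TEXT", tps_version = "TEXT",
    tx_modality = "TEXT", tx_site = "TEXT", tx_time = "REAL"),
  rxs = c(
    mrn = "TEXT", study_uid = "TEXT", import_timestamp = "TEXT",
    fxs = "INTEGER", fx_dose = "REAL", fx_group_name = "TEXT",
    fx_group_number = "INTEGER", fx_group_count = "INTEGER",
    norm_method = "TEXT", norm_object = "TEXT", rx_dose = "REAL",
    rx_percent = "REAL"),
  beams = c(
    mrn = "TEXT", study_uid = "TEXT", import_timestamp = "TEXT",
    beam_name = "TEXT", beam_number = "INTEGER", beam_dose = "REAL",
    beam_mu = "REAL", mu_per_degree = "REAL",
    mu_per_control_point = "REAL", control_point_count = "INTEGER",
    energy_min = "REAL", energy_max = "REAL", radiation_type = "TEXT",
    beam_type = "TEXT", fx_count = "INTEGER",
    fx_group_beam_count = "INTEGER", fx_group_number = "INTEGER",
    gantry_rot_dir = "TEXT", collimator_rot_dir = "TEXT",
    couch_rot_dir = "TEXT",
    gantry_start = "REAL", gantry_end = "REAL", gantry_min = "REAL",
    gantry_max = "REAL", gantry_range = "REAL",
    collimator_start = "REAL", collimator_end = "REAL",
    collimator_min = "REAL", collimator_max = "REAL",
    collimator_range = "REAL",
    couch_start = "REAL", couch_end = "REAL", couch_min = "REAL",
    couch_max = "REAL", couch_range = "REAL",
    isocenter_x = "REAL", isocenter_y = "REAL", isocenter_z = "REAL",
    scan_spot_count = "REAL", scan_mode = "TEXT", ssd = "REAL",
    treatment_machine = "TEXT"),
  dvhs = c(
    mrn = "TEXT", study_uid = "TEXT", import_timestamp = "TEXT",
    roi_name = "TEXT", roi_type = "TEXT", institutional_roi = "TEXT",
    physician_roi = "TEXT", roi_volume = "REAL", min_dose = "REAL",
    mean_dose = "REAL", max_dose = "REAL", bin_width = "REAL",
    dvh = "TEXT", roi_coordinates = "TEXT", dist_min = "REAL",
    dist_mean = "REAL", dist_median = "REAL", dist_max = "REAL",
    ptv_overlap = "REAL"),
  dicom_files = c(
    mrn = "TEXT", study_uid = "TEXT", folder = "TEXT",
    plan_file = "TEXT", structure_file = "TEXT", dose_file = "TEXT"))

#' Open a database connection
#'
#' @param path SQLite database file, or `":memory:"`.
#' @return a DBI connection.
#' @export
db_connect <- function(path = ":memory:") {
  if (path != ":memory:" && !dir.exists(dirname(path)))
    dir.create(dirname(path), recursive = TRUE)
  DBI::dbConnect(RSQLite::SQLite(), path)
}

schema_ddl <- function() {
  vapply(names(db_schema), function(tb) {
    cols <- db_schema[[tb]]
    sprintf("CREATE TABLE %s (\n  %s\n);", tb,
            paste(sprintf("%s %s", names(cols), cols), collapse = ",\n  "))
  }, "")
}

#' Create the five-table schema
#'
#' Creates the DVHs, Plans, Rxs (prescriptions), Beams and DICOM file
#' catalog tables if absent. Idempotent on a database that already holds
#' the schema; a table of the same name with different columns raises an
#' error (no silent migration).
#'
#' @param con DBI connection from [db_connect()].
#' @export
initialize_schema <- function(con) {
  for (tb in names(db_schema)) {
    if (DBI::dbExistsTable(con, tb)) {
      have <- DBI::dbListFields(con, tb)
      want <- names(db_schema[[tb]])
      if (!setequal(have, want))
        stop(sprintf("table '%s' exists with incompatible columns", tb))
    } else {
      DBI::dbExecute(con, schema_ddl()[[tb]])
    }
  }
  invisible(con)
}

## ---- serialization ----------------------------------------------------

# Cumulative DVH as comma-separated cm^3 values at the stored bin width.
serialize_dvh <- function(dvh) paste(sprintf("%.9g", dvh$cumulative),
                                     collapse = ",")

deserialize_dvh <- function(text, bin_width, min_dose = NULL,
                            mean_dose = NULL, max_dose = NULL,
                            rx_dose = NA_real_) {
  cum <- as.numeric(strsplit(text, ",")[[1]])
  diffs <- cum - c(cum[-1], 0)
  diffs[diffs < 0] <- 0
  dvh_from_diff(diffs, bin_width = bin_width, rx_dose = rx_dose,
                min_dose = min_dose, mean_dose = mean_dose,
                max_dose = max_dose)
}

# Contours as per-slice text blocks: "z: x,y;x,y;..." (one line per ring).
serialize_contours <- function(roi) {
  lines <- character(0)
  for (s in roi$slices) for (r in s$rings)
    lines <- c(lines, sprintf("%.3f: %s", s$z,
                              paste(sprintf("%.3f,%.3f", r$x, r$y),
                                    collapse = ";")))
  paste(lines, collapse = "\n")
}

deserialize_contours <- function(text, roi_name = "roi", roi_type = "") {
  lines <- strsplit(text, "\n")[[1]]
  slices <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    z <- as.numeric(parts[1])
    xy <- do.call(rbind, lapply(strsplit(strsplit(parts[2], ";")[[1]], ","),
                                as.numeric))
    k <- z_key(z)
    ring <- list(x = xy[, 1], y = xy[, 2])
    if (is.null(slices[[k]])) slices[[k]] <- list(z = z, rings = list(ring))
    else slices[[k]]$rings <- c(slices[[k]]$rings, list(ring))
  }
  roi_contours(roi_name, roi_type, unname(slices))
}

## ---- import -----------------------------------------------------------

#' Import a parsed fileset bundle
#'
#' Writes the plan, prescription, beam and DVH rows plus the file-catalog
#' entry in a single all-or-nothing transaction, stamping every row with
#' one import timestamp. A study instance UID already present in the
#' database is refused (duplicate guard): importing two plans for one CT
#' study would duplicate DVH data, so a re-import requires deleting the
#' first. When `import_root` is given, the source files are moved to
#' `<import_root>/<mrn>/<study_uid>/`.
#'
#' @param con DBI connection with the schema in place.
#' @param bundle list with `plan`, `rxs`, `beams` (data.frames from
#'   [parse_plan()]), `dvhs` (data.frame of DVH rows) and `files` (the
#'   `plan_fileset`).
#' @param import_root optional directory files are organized under.
#' @return list with `imported` (logical), `reason`, and row counts.
#' @export
import_fileset <- function(con, bundle, import_root = NULL) {
  uid <- bundle$plan$study_uid[1]
  mrn <- bundle$plan$mrn[1]
  dup <- DBI::dbGetQuery(con, paste0(
    "SELECT COUNT(*) AS n FROM plans WHERE study_uid = ",
    DBI::dbQuoteLiteral(con, uid)))$n
  dup <- dup + DBI::dbGetQuery(con, paste0(
    "SELECT COUNT(*) AS n FROM dicom_files WHERE study_uid = ",
    DBI::dbQuoteLiteral(con, uid)))$n
  if (dup > 0) {
    rtdvh_log("import refused (duplicate study %s)", uid)
    return(list(imported = FALSE,
                reason = sprintf("study %s already imported", uid)))
  }
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  fill <- function(df, table) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df$import_timestamp <- stamp
    want <- names(db_schema[[table]])
    for (w in setdiff(want, names(df))) df[[w]] <- NA
    df[, want, drop = FALSE]
  }
  folder <- if (!is.null(import_root))
    file.path(import_root, mrn, uid) else dirname(bundle$files$plan_file)
  catalog <- data.frame(
    mrn = mrn, study_uid = uid, folder = folder,
    plan_file = basename(bundle$files$plan_file),
    structure_file = basename(bundle$files$structure_file),
    dose_file = basename(bundle$files$dose_file),
    stringsAsFactors = FALSE)

  DBI::dbWithTransaction(con, {
    DBI::dbAppendTable(con, "plans", fill(bundle$plan, "plans"))
    rx <- fill(bundle$rxs, "rxs")
    if (!is.null(rx)) DBI::dbAppendTable(con, "rxs", rx)
    bm <- fill(bundle$beams, "beams")
    if (!is.null(bm)) DBI::dbAppendTable(con, "beams", bm)
    dv <- fill(bundle$dvhs, "dvhs")
    if (is.null(dv)) stop("bundle carries no DVH rows")
    if (any(!is.finite(dv$roi_volume)) || any(dv$roi_volume <= 0))
      stop("DVH rows with nonpositive roi_volume")
    DBI::dbAppendTable(con, "dvhs", dv)
    DBI::dbAppendTable(con, "dicom_files", catalog)
  })

  if (!is.null(import_root)) {
    dir.create(folder, recursive = TRUE, showWarnings = FALSE)
    src <- c(bundle$files$plan_file, bundle$files$structure_file,
             bundle$files$dose_file, bundle$files$extra_files)
    for (f in src) {
      dest <- file.path(folder, basename(f))
      if (normalizePath(dirname(f)) != normalizePath(folder)) {
        file.copy(f, dest, overwrite = FALSE)
        unlink(f)
      }
    }
  }
  rtdvh_log("imported study %s (mrn %s): %d rx, %d beams, %d rois",
            uid, mrn, nrow(bundle$rxs %||% data.frame()),
            nrow(bundle$beams %||% data.frame()), nrow(bundle$dvhs))
  list(imported = TRUE, reason = NULL,
       counts = c(plans = 1L, rxs = nrow(bundle$rxs %||% data.frame()),
                  beams = nrow(bundle$beams %||% data.frame()),
                  dvhs = nrow(bundle$dvhs)))
}

## ---- query layer ------------------------------------------------------

selection_categories <- c(
  baseline = "plans.baseline",
  beam_type = "beams.beam_type",
  collimator_rotation = "beams.collimator_rot_dir",
  couch_rotation = "beams.couch_rot_dir",
  dose_grid_resolution = "plans.dose_grid_resolution",
  gantry_rotation = "beams.gantry_rot_dir",
  heterogeneity_correction = "plans.heterogeneity_correction",
  mrn = "plans.mrn",
  norm_method = "rxs.norm_method",
  patient_orientation = "plans.patient_orientation",
  patient_sex = "plans.patient_sex",
  physician = "plans.physician",
  institutional_roi = "dvhs.institutional_roi",
  physician_roi = "dvhs.physician_roi",
  roi_type = "dvhs.roi_type",
  radiation_type = "beams.radiation_type",
  scan_mode = "beams.scan_mode",
  treatment_machine = "beams.treatment_machine",
  tx_modality = "plans.tx_modality",
  tx_site = "plans.tx_site")

range_categories <- c(
  age = "plans.age_at_study",
  beam_dose = "beams.beam_dose",
  beam_energy = "beams.energy_max",
  beam_mu = "beams.beam_mu",
  birthdate = "plans.birthdate",
  collimator_angle = "beams.collimator_start",
  couch_angle = "beams.couch_start",
  ptv_distance = "dvhs.dist_min",
  fx_dose = "rxs.fx_dose",
  gantry_angle = "beams.gantry_start",
  fractions = "plans.fractions",
  roi_min_dose = "dvhs.min_dose",
  roi_mean_dose = "dvhs.mean_dose",
  roi_max_dose = "dvhs.max_dose",
  roi_volume = "dvhs.roi_volume",
  rx_dose = "plans.rx_dose",
  rx_isodose = "rxs.rx_percent",
  scan_spots = "beams.scan_spot_count",
  sim_date = "plans.sim_study_date",
  ssd = "beams.ssd",
  total_mu = "plans.total_mu",
  tx_time = "plans.tx_time")

#' Build a query filter
#'
#' Selection filters match discrete values (repeating a category ORs its
#' values; distinct categories AND); range filters are inclusive
#' `min <= value <= max`. Category names follow the searchable-category
#' vocabulary (see [query_categories()]).
#'
#' @param selection named list: category -> vector of accepted values.
#' @param ranges list of `list(category =, min =, max =)`.
#' @return object of class `query_filter`.
#' @export
query_filter <- function(selection = list(), ranges = list()) {
  for (cat in names(selection))
    if (!cat %in% names(selection_categories))
      stop("unknown selection category '", cat, "'. Options: ",
           paste(names(selection_categories), collapse = ", "))
  for (r in ranges)
    if (!r$category %in% names(range_categories))
      stop("unknown range category '", r$category, "'. Options: ",
           paste(names(range_categories), collapse = ", "))
  structure(list(selection = selection, ranges = ranges),
            class = "query_filter")
}

#' List the searchable categories
#'
#' @return list with `selection` and `range` category names.
#' @export
query_categories <- function() {
  list(selection = names(selection_categories),
       range = names(range_categories))
}

# WHERE fragment for one category; conditions on rxs/beams become EXISTS
# subqueries correlated on (mrn, study_uid).
category_condition <- function(con, colref, clause) {
  parts <- strsplit(colref, ".", fixed = TRUE)[[1]]
  tb <- parts[1]; col <- parts[2]
  if (tb %in% c("plans", "dvhs")) {
    sprintf("(%s)", gsub("\\{col\\}", sprintf("%s.%s", tb, col), clause))
  } else {
    inner <- gsub("\\{col\\}", sprintf("%s.%s", tb, col), clause)
    sprintf(paste0("EXISTS (SELECT 1 FROM %s WHERE %s.study_uid = ",
                   "plans.study_uid AND %s.mrn = plans.mrn AND (%s))"),
            tb, tb, tb, inner)
  }
}

#' Execute a query against the database
#'
#' Returns the sample: DVH rows joined with their plan context, plus the
#' prescription and beam rows of the matched studies. Selection filters OR
#' within a repeated category and AND across categories; range filters are
#' inclusive.
#'
#' @param con DBI connection.
#' @param filter a [query_filter()].
#' @return object of class `record_sample` with data.frames `dvhs`
#'   (joined with plans), `plans`, `rxs`, `beams`.
#' @export
execute_query <- function(con, filter) {
  stopifnot(inherits(filter, "query_filter"))
  conds <- character(0)
  for (cat in unique(names(filter$selection))) {
    vals <- unlist(filter$selection[names(filter$selection) == cat],
                   use.names = FALSE)
    colref <- selection_categories[[cat]]
    if (cat == "baseline")
      vals <- as.integer(as.logical(vals))
    lits <- vapply(vals, function(v)
      as.character(DBI::dbQuoteLiteral(con, v)), "")
    conds <- c(conds, category_condition(
      con, colref, sprintf("{col} IN (%s)", paste(lits, collapse = ", "))))
  }
  rng_cats <- vapply(filter$ranges, `[[`, "", "category")
  for (cat in unique(rng_cats)) {
    rs <- filter$ranges[rng_cats == cat]
    colref <- range_categories[[cat]]
    ors <- vapply(rs, function(r)
      sprintf("{col} BETWEEN %s AND %s",
              DBI::dbQuoteLiteral(con, r$min),
              DBI::dbQuoteLiteral(con, r$max)), "")
    conds <- c(conds, category_condition(
      con, colref, paste(ors, collapse = " OR ")))
  }
  where <- if (length(conds)) paste("WHERE", paste(conds, collapse = "\n  AND "))
           else ""
  plan_cols <- setdiff(names(db_schema$plans),
                       c("mrn", "study_uid", "import_timestamp"))
  sql <- sprintf(
    "SELECT dvhs.*, %s FROM dvhs
       JOIN plans ON plans.mrn = dvhs.mrn AND plans.study_uid = dvhs.study_uid
     %s ORDER BY dvhs.mrn, dvhs.study_uid, dvhs.roi_name",
    paste(sprintf("plans.%s", plan_cols), collapse = ", "), where)
  dvh_rows <- DBI::dbGetQuery(con, sql)
  uids <- unique(dvh_rows$study_uid)
  fetch <- function(tb) {
    if (!length(uids))
      return(DBI::dbGetQuery(con, sprintf("SELECT * FROM %s WHERE 0", tb)))
    lits <- paste(vapply(uids, function(u)
      as.character(DBI::dbQuoteLiteral(con, u)), ""), collapse = ", ")
    DBI::dbGetQuery(con, sprintf(
      "SELECT * FROM %s WHERE study_uid IN (%s)", tb, lits))
  }
  structure(list(dvhs = dvh_rows, plans = fetch("plans"),
                 rxs = fetch("rxs"), beams = fetch("beams")),
            class = "record_sample")
}

#' @export
print.record_sample <- function(x, ...) {
  cat(sprintf("<record_sample> %d DVH row(s) across %d plan(s)\n",
              nrow(x$dvhs), nrow(x$plans)))
  invisible(x)
}

# Rebuild dvh objects (with plan rx dose) from a record sample.
sample_dvhs <- function(sample) {
  rows <- sample$dvhs
  out <- lapply(seq_len(nrow(rows)), function(i)
    deserialize_dvh(rows$dvh[i], rows$bin_width[i],
                    min_dose = rows$min_dose[i],
                    mean_dose = rows$mean_dose[i],
                    max_dose = rows$max_dose[i],
                    rx_dose = rows$rx_dose[i]))
  names(out) <- sprintf("%s|%s", rows$mrn, rows$roi_name)
  out
}

#' Edit one cell of a stored record
#'
#' Administrator-style single-cell update keyed by study UID and MRN (plus
#' ROI name for the DVHs table); the edit is audit-logged.
#'
#' @param con DBI connection.
#' @param table one of the five table names.
#' @param study_uid,mrn row keys.
#' @param column column to update.
#' @param value new value.
#' @param roi_name required for the `dvhs` table.
#' @export
update_record <- function(con, table, study_uid, mrn, column, value,
                          roi_name = NULL) {
  if (!table %in% names(db_schema)) stop("unknown table '", table, "'")
  if (!column %in% names(db_schema[[table]]))
    stop(sprintf("unknown column '%s' in table '%s'", column, table))
  if (is.logical(value)) value <- as.integer(value)
  extra <- if (table == "dvhs") {
    if (is.null(roi_name)) stop("dvhs updates need roi_name")
    sprintf(" AND roi_name = %s", DBI::dbQuoteLiteral(con, roi_name))
  } else ""
  n <- DBI::dbExecute(con, sprintf(
    "UPDATE %s SET %s = %s WHERE study_uid = %s AND mrn = %s%s",
    table, column, DBI::dbQuoteLiteral(con, value),
    DBI::dbQuoteLiteral(con, study_uid), DBI::dbQuoteLiteral(con, mrn),
    extra))
  if (n == 0)
    stop(sprintf("no row in '%s' for study %s / mrn %s", table, study_uid, mrn))
  rtdvh_log("update %s.%s = %s for study %s", table, column,
            paste(value, collapse = ","), study_uid)
  invisible(n)
}

#' Export a query result as CSV files
#'
#' Writes one CSV per table view (`dvhs.csv`, `plans.csv`, `rxs.csv`,
#' `beams.csv`) into `dir`.
#'
#' @param sample a `record_sample`.
#' @param dir output directory.
#' @export
export_sample_csv <- function(sample, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("dvhs", "plans", "rxs", "beams"))
    utils::write.csv(sample[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
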