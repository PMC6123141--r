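# ROI name management: physician-specific variation maps rolling up to
# institutional categories, ignore lists, and PTV ordering by D95.

# Reserved physician_roi value marking an ignored variation in map files.
IGNORE_MARK <- "<ignore>"

#' Normalize an ROI name for lookup
#'
#' Lowercases, collapses every run of non-alphanumeric characters to a
#' single space and trims, so "Cochlea_L", "cochlea  l" and "Cochlea-L"
#' all key the same map entry.
#'
#' @param name character vector of raw ROI names.
#' @export
normalize_roi_name <- function(name) {
  x <- tolower(name)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Create a physician ROI mapping
#'
#' @param physician physician initials the map belongs to.
#' @param entries named character vector: normalized variation ->
#'   physician ROI.
#' @param rollup named character vector: physician ROI -> institutional ROI
#'   (missing physician ROIs are institutionally uncategorized).
#' @param ignored character vector of normalized variations to ignore.
#' @export
roi_mapping <- function(physician, entries = character(0),
                        rollup = character(0), ignored = character(0)) {
  names(entries) <- normalize_roi_name(names(entries) %||% character(0))
  ignored <- normalize_roi_name(ignored)
  if (length(intersect(names(entries), ignored)))
    stop("a variation cannot be both mapped and ignored")
  structure(list(physician = physician, entries = entries,
                 rollup = rollup, ignored = ignored),
            class = "roi_mapping")
}

#' @export
print.roi_mapping <- function(x, ...) {
  cat(sprintf("<roi_mapping> physician %s: %d variation(s), %d ignored\n",
              x$physician, length(x$entries), length(x$ignored)))
  invisible(x)
}

#' Categorize a raw ROI name
#'
#' Normalizes the name and looks it up in the physician's map. Unknown
#' names are reported uncategorized, never guessed; ignored names are
#' flagged so they stay out of the uncategorized listing.
#'
#' @param m a [roi_mapping()].
#' @param raw_name raw ROI name from a structure set.
#' @return list with `status` (`"mapped"`, `"uncategorized"` or
#'   `"ignored"`), `physician_roi` and `institutional_roi` (both
#'   `"uncategorized"` unless mapped).
#' @export
categorize_roi <- function(m, raw_name) {
  stopifnot(inherits(m, "roi_mapping"))
  key <- normalize_roi_name(raw_name)
  if (key %in% m$ignored)
    return(list(status = "ignored", physician_roi = "ignored",
                institutional_roi = "ignored"))
  if (!key %in% names(m$entries))
    return(list(status = "uncategorized", physician_roi = "uncategorized",
                institutional_roi = "uncategorized"))
  proi <- unname(m$entries[[key]])
  iroi <- if (proi %in% names(m$rollup)) unname(m$rollup[[proi]])
          else "uncategorized"
  list(status = "mapped", physician_roi = proi, institutional_roi = iroi)
}

#' Add, ignore or unignore an ROI name variation
#'
#' @param m a [roi_mapping()].
#' @param action `"add"`, `"ignore"` or `"unignore"`.
#' @param variation raw or normalized variation text.
#' @param physician_roi target physician ROI (required for `"add"`).
#' @param institutional_roi optional institutional rollup for the physician
#'   ROI, recorded when given.
#' @return the updated mapping.
#' @export
manage_variation <- function(m, action = c("add", "ignore", "unignore"),
                             variation, physician_roi = NULL,
                             institutional_roi = NULL) {
  stopifnot(inherits(m, "roi_mapping"))
  action <- match.arg(action)
  key <- normalize_roi_name(variation)
  if (action == "add") {
    if (is.null(physician_roi)) stop("add requires a physician_roi")
    if (key %in% names(m$entries) &&
        !identical(unname(m$entries[[key]]), physician_roi))
      stop(sprintf("variation '%s' already maps to '%s'",
                   key, m$entries[[key]]))
    m$entries[[key]] <- physician_roi
    m$ignored <- setdiff(m$ignored, key)
    if (!is.null(institutional_roi)) m$rollup[[physician_roi]] <- institutional_roi
  } else if (action == "ignore") {
    if (key %in% names(m$entries))
      stop(sprintf("variation '%s' is mapped; remove the mapping first", key))
    m$ignored <- union(m$ignored, key)
  } else {
    m$ignored <- setdiff(m$ignored, key)
  }
  m
}

#' Read / write physician ROI map files
#'
#' Plain-text, diff-able format: one file per physician named
#' `<initials>.tsv` with tab-separated columns
#' `variation`, `physician_roi`, `institutional_roi`. Ignored variations
#' carry the reserved physician ROI `<ignore>`.
#'
#' @param dir directory of per-physician map files.
#' @param physician initials (file stem).
#' @name roi_map_io
#' @export
read_roi_map <- function(dir, physician) {
  path <- file.path(dir, paste0(physician, ".tsv"))
  if (!file.exists(path)) return(roi_mapping(physician))
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  ign <- tb$variation[tb$physician_roi == IGNORE_MARK]
  tb <- tb[tb$physician_roi != IGNORE_MARK, , drop = FALSE]
  entries <- stats::setNames(tb$physician_roi, tb$variation)
  ru <- tb[nzchar(tb$institutional_roi), , drop = FALSE]
  rollup <- stats::setNames(ru$institutional_roi, ru$physician_roi)
  rollup <- rollup[!duplicated(names(rollup))]
  roi_mapping(physician, entries, rollup, ign)
}

#' @rdname roi_map_io
#' @param m a [roi_mapping()] to persist.
#' @export
write_roi_map <- function(m, dir) {
  stopifnot(inherits(m, "roi_mapping"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- data.frame(
    variation = c(names(m$entries), m$ignored),
    physician_roi = c(unname(m$entries), rep(IGNORE_MARK, length(m$ignored))),
    institutional_roi = c(vapply(unname(m$entries), function(p)
      if (p %in% names(m$rollup)) unname(m$rollup[[p]]) else "", ""),
      rep("", length(m$ignored))),
    stringsAsFactors = FALSE)
  rows <- rows[order(rows$variation), , drop = FALSE]
  utils::write.table(rows, file.path(dir, paste0(m$physician, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(m)
}

#' Order multiple PTVs by D95
#'
#' Assigns the conventional labels PTV1..PTVn, PTV1 being the volume with
#' the highest D95 (the highest-dose target first); ties break toward the
#' larger volume, then lexicographic name.
#'
#' @param ptv_dvhs named list of `dvh` objects (names are ROI names).
#' @return named character vector ROI name -> label.
#' @export
order_ptvs <- function(ptv_dvhs) {
  stopifnot(length(ptv_dvhs) >= 1L)
  d95 <- vapply(ptv_dvhs, function(d)
    dose_at_volume(d, endpoint_spec("D", 95, "%")), 0)
  vol <- vapply(ptv_dvhs, `[[`, 0, "volume")
  nm <- names(ptv_dvhs)
  ord <- order(-d95, -vol, nm)
  stats::setNames(sprintf("PTV%d", order(ord)), nm)
}
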