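# Shared internal helpers: unit conversions, logging, small numerics.

MM3_PER_CM3 <- 1000
MM_PER_CM <- 10

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# Signed area of a closed ring (shoelace); positive for counter-clockwise.
ring_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Even-odd point-in-polygon over a collection of rings (crossing number).
# `rings` is a list of list(x=, y=); px/py are vectors of query points.
# Returns logical vector; points exactly on an edge may fall on either side.
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    x <- r$x; y <- r$y
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
      crosses <- ((yi > py) != (yj > py))
      if (any(crosses)) {
        xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
        flip <- xint > px[crosses]
        idx <- which(crosses)[flip]
        inside[idx] <- !inside[idx]
      }
    }
  }
  inside
}

# log-sum-exp, used for numerically stable generalized power means
logsumexp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

# Structured log line; sink controlled by option so the CLI can audit runs.
rtdvh_log <- function(fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  sprintf(fmt, ...))
  path <- getOption("rtdvh.log_file", NULL)
  if (!is.null(path))
    tryCatch({
      if (!dir.exists(dirname(path)))
        dir.create(dirname(path), recursive = TRUE)
      cat(line, "\n", file = path, append = TRUE, sep = "")
    }, error = function(e) NULL, warning = function(w) NULL)
  invisible(line)
}

# Snap z coordinates to 1e-3 mm so floating z values key slices reliably.
snap_z <- function(z) round(z, 3)
z_key <- function(z) sprintf("%.3f", snap_z(z))

# ISO date helpers for DICOM DA ("YYYYMMDD") values.
dicom_date_to_iso <- function(da) {
  if (is.null(da) || !nzchar(da)) return(NA_character_)
  da <- gsub("[^0-9]", "", da)
  if (nchar(da) < 8) return(NA_character_)
  sprintf("%s-%s-%s", substr(da, 1, 4), substr(da, 5, 6), substr(da, 7, 8))
}

iso_to_dicom_date <- function(iso) gsub("-", "", iso)

# Whole years elapsed between two ISO dates (age at study).
floor_years_between <- function(birth_iso, study_iso) {
  if (is.na(birth_iso) || is.na(study_iso)) return(NA_real_)
  b <- as.Date(birth_iso); s <- as.Date(study_iso)
  if (is.na(b) || is.na(s)) return(NA_real_)
  yrs <- as.integer(format(s, "%Y")) - as.integer(format(b, "%Y"))
  if (format(s, "%m%d") < format(b, "%m%d")) yrs <- yrs - 1L
  as.numeric(yrs)
}
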