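# DICOM element-level reader and writer (little endian, explicit and
# implicit VR). Covers the subset of the standard the RT Plan / Structure
# Set / Dose pipeline needs: flat elements, nested sequences with defined
# or undefined lengths, and OW pixel data. No installed R package provides
# DICOM I/O, so this layer is implemented here from the encoding rules.

STR_VRS <- c("SH", "LO", "CS", "PN", "DA", "TM", "ST", "LT", "AE", "AS",
             "UT", "UC")
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN", "UC", "UR")

u16_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(as.integer(rbind(x %% 256, (x %/% 256) %% 256)))
}
u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(as.integer(rbind(x %% 256, (x %/% 256) %% 256,
                          (x %/% 65536) %% 256, (x %/% 16777216) %% 256)))
}
raw_u16 <- function(r) {
  m <- matrix(as.integer(r), nrow = 2)
  m[1, ] + 256 * m[2, ]
}
raw_u32 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 4)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

format_ds <- function(x) {
  s <- vapply(x, function(v) {
    out <- sprintf("%.10g", v)
    if (nchar(out) > 16) out <- sprintf("%.8g", v)
    out
  }, "")
  paste(s, collapse = "\\")
}

# Encode one element's value field as raw bytes (padded to even length).
encode_value <- function(vr, value) {
  bytes <- switch(vr,
    UI = charToRaw(paste(as.character(value), collapse = "\\")),
    DS = charToRaw(format_ds(value)),
    IS = charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\")),
    US = u16_raw(value),
    UL = u32_raw(value),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OW = , OB = as.raw(value),
    {
      if (!vr %in% STR_VRS) stop("cannot encode VR ", vr)
      charToRaw(paste(as.character(value), collapse = "\\"))
    })
  if (length(bytes) %% 2 == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else
           if (vr %in% c("OB", "OW")) as.raw(0L) else charToRaw(" ")
    bytes <- c(bytes, pad)
  }
  bytes
}

# Encode a full element (explicit VR little endian).
encode_element <- function(tag, vr, value) {
  grp <- strtoi(substr(tag, 1, 4), 16L)
  ele <- strtoi(substr(tag, 5, 8), 16L)
  if (vr == "SQ") {
    items <- lapply(value, function(item_ds) {
      body <- encode_dataset(item_ds)
      c(u16_raw(0xFFFE), u16_raw(0xE000), u32_raw(length(body)), body)
    })
    val <- do.call(c, c(items, list(raw(0))))
    header <- c(u16_raw(grp), u16_raw(ele), charToRaw("SQ"), as.raw(c(0, 0)),
                u32_raw(length(val)))
    return(c(header, val))
  }
  val <- encode_value(vr, value)
  if (vr %in% LONG_VRS) {
    c(u16_raw(grp), u16_raw(ele), charToRaw(vr), as.raw(c(0, 0)),
      u32_raw(length(val)), val)
  } else {
    if (length(val) > 65534) stop("value too long for short-form VR ", vr)
    c(u16_raw(grp), u16_raw(ele), charToRaw(vr), u16_raw(length(val)), val)
  }
}

# Encode a dataset: named list tag -> list(vr, value), in tag order.
encode_dataset <- function(ds) {
  tags <- sort(names(ds))
  do.call(c, c(lapply(tags, function(t)
    encode_element(t, ds[[t]]$vr, ds[[t]]$value)), list(raw(0))))
}

#' Write a DICOM dataset to file
#'
#' Writes the 128-byte preamble, "DICM" marker, a file meta group and the
#' dataset in explicit-VR little-endian transfer syntax.
#'
#' @param ds dataset: named list mapping 8-hex-digit tags to
#'   `list(vr =, value =)`; sequences hold lists of nested datasets.
#' @param path output path.
#' @return `path`, invisibly.
#' @keywords internal
dcm_write_file <- function(ds, path) {
  sop_class <- ds[[tag_of("SOPClassUID")]]$value
  sop_inst <- ds[[tag_of("SOPInstanceUID")]]$value
  if (is.null(sop_class) || is.null(sop_inst))
    stop("dataset must carry SOPClassUID and SOPInstanceUID")
  meta <- list()
  meta[["00020001"]] <- list(vr = "OB", value = as.raw(c(0, 1)))
  meta[["00020002"]] <- list(vr = "UI", value = sop_class)
  meta[["00020003"]] <- list(vr = "UI", value = sop_inst)
  meta[["00020010"]] <- list(vr = "UI", value = TS_EXPLICIT_LE)
  meta[["00020012"]] <- list(vr = "UI", value = "1.2.826.0.1.3680043.9.7432.1")
  meta_body <- encode_dataset(meta)
  grp_len <- encode_element("00020000", "UL", length(meta_body))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grp_len, meta_body, encode_dataset(ds)), con)
  invisible(path)
}

## ---- reading ----------------------------------------------------------

decode_value <- function(vr, bytes) {
  if (!length(bytes)) return(switch(vr, SQ = list(), NULL))
  switch(vr,
    UI = , DS = , IS = {
      s <- strsplit(trimws(rawToChar(bytes[bytes != as.raw(0)])),
                    "\\\\")[[1]]
      if (vr == "UI") s else as.numeric(s)
    },
    US = raw_u16(bytes),
    UL = raw_u32(bytes),
    FL = readBin(bytes, "numeric", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    OW = , OB = , UN = bytes,
    {
      s <- sub(" +$", "", rawToChar(bytes[bytes != as.raw(0)]))
      strsplit(s, "\\\\")[[1]]
    })
}

# Parse elements of `buf` in [pos, end]; returns list(ds=, pos=).
# `stop_tag` ("FFFEE00D"/"FFFEE0DD") ends an undefined-length scope.
parse_dataset <- function(buf, pos, end, explicit, stop_tag = NULL) {
  ds <- list()
  while (pos + 7 <= end) {
    grp <- raw_u16(buf[pos:(pos + 1)]); ele <- raw_u16(buf[(pos + 2):(pos + 3)])
    tag <- sprintf("%04X%04X", grp, ele)
    pos <- pos + 4
    if (grp == 0xFFFE) {            # delimiter items carry a 4-byte length
      len <- raw_u32(buf[pos:(pos + 3)]); pos <- pos + 4
      if (!is.null(stop_tag) && tag == stop_tag) return(list(ds = ds, pos = pos))
      stop("unexpected delimiter ", tag)
    }
    if (explicit) {
      vr <- rawToChar(buf[pos:(pos + 1)]); pos <- pos + 2
      if (vr %in% LONG_VRS) {
        len <- raw_u32(buf[(pos + 2):(pos + 5)]); pos <- pos + 6
      } else {
        len <- raw_u16(buf[pos:(pos + 1)]); pos <- pos + 2
      }
    } else {
      len <- raw_u32(buf[pos:(pos + 3)]); pos <- pos + 4
      de <- dict_by_tag(tag)
      vr <- if (!is.null(de)) de$vr else "UN"
    }
    if (vr == "SQ" || (len == 4294967295 && vr == "UN")) {
      if (len == 4294967295) {      # undefined length: delimited items
        items <- list()
        repeat {
          itag <- sprintf("%04X%04X", raw_u16(buf[pos:(pos + 1)]),
                          raw_u16(buf[(pos + 2):(pos + 3)]))
          ilen <- raw_u32(buf[(pos + 4):(pos + 7)])
          pos <- pos + 8
          if (itag == "FFFEE0DD") break
          if (itag != "FFFEE000") stop("malformed sequence at ", tag)
          if (ilen == 4294967295) {
            r <- parse_dataset(buf, pos, end, explicit, stop_tag = "FFFEE00D")
            items[[length(items) + 1L]] <- r$ds; pos <- r$pos
          } else {
            r <- parse_dataset(buf, pos, pos + ilen - 1, explicit)
            items[[length(items) + 1L]] <- r$ds; pos <- pos + ilen
          }
        }
        ds[[tag]] <- list(vr = "SQ", value = items)
      } else {
        stop_at <- pos + len - 1
        items <- list()
        while (pos < stop_at) {
          itag <- sprintf("%04X%04X", raw_u16(buf[pos:(pos + 1)]),
                          raw_u16(buf[(pos + 2):(pos + 3)]))
          ilen <- raw_u32(buf[(pos + 4):(pos + 7)])
          pos <- pos + 8
          if (itag != "FFFEE000") stop("malformed sequence at ", tag)
          if (ilen == 4294967295) {
            r <- parse_dataset(buf, pos, end, explicit, stop_tag = "FFFEE00D")
            items[[length(items) + 1L]] <- r$ds; pos <- r$pos
          } else {
            r <- parse_dataset(buf, pos, pos + ilen - 1, explicit)
            items[[length(items) + 1L]] <- r$ds; pos <- pos + ilen
          }
        }
        ds[[tag]] <- list(vr = "SQ", value = items)
      }
    } else {
      bytes <- if (len > 0) buf[pos:(pos + len - 1)] else raw(0)
      pos <- pos + len
      ds[[tag]] <- list(vr = vr, value = decode_value(vr, bytes))
    }
  }
  list(ds = ds, pos = pos)
}

#' Read a DICOM file
#'
#' Accepts explicit- and implicit-VR little-endian transfer syntaxes.
#' Returns the parsed dataset with the file meta group attached as an
#' attribute. Non-DICOM files (no DICM marker) raise an error.
#'
#' @param path file to read.
#' @return named list of elements (see [dcm_write_file()] for the layout).
#' @keywords internal
dcm_read_file <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133
  # file meta group is always explicit VR LE; read its group length first
  grp <- raw_u16(buf[pos:(pos + 1)]); ele <- raw_u16(buf[(pos + 2):(pos + 3)])
  if (grp != 2L || ele != 0L) stop("missing file meta group length in ", path)
  meta_len <- raw_u32(buf[(pos + 8):(pos + 11)])
  pos <- pos + 12
  meta <- parse_dataset(buf, pos, pos + meta_len - 1, explicit = TRUE)$ds
  pos <- pos + meta_len
  ts <- meta[[tag_of("TransferSyntaxUID")]]$value %||% TS_EXPLICIT_LE
  explicit <- switch(ts,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported transfer syntax ", ts, " in ", path))
  ds <- parse_dataset(buf, pos, length(buf), explicit)$ds
  attr(ds, "meta") <- meta
  attr(ds, "transfer_syntax") <- ts
  ds
}

## ---- dataset convenience accessors ------------------------------------

# Get an attribute's value by dictionary name (NULL if absent).
ds_get <- function(ds, name) {
  el <- ds[[tag_of(name)]]
  if (is.null(el)) NULL else el$value
}

ds_get1 <- function(ds, name, default = NA) {
  v <- ds_get(ds, name)
  if (is.null(v) || !length(v)) default else v[[1]]
}

# Set an attribute by name (VR from the dictionary).
ds_set <- function(ds, name, value) {
  tag <- tag_of(name)
  de <- dict_by_tag(tag)
  ds[[tag]] <- list(vr = de$vr, value = value)
  ds
}

# Build a dataset from name = value pairs.
dcm_ds <- function(...) {
  args <- list(...)
  ds <- list()
  for (nm in names(args)) ds <- ds_set(ds, nm, args[[nm]])
  ds
}
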