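# In-memory DICOM dataset model and a Part-10 Explicit VR Little Endian
# reader/writer.  The subset covers the VRs used by the exported object
# types; unsupported constructs fail loudly rather than guessing.
#
# A dataset is an ordered named list of elements keyed "GGGGEEEE"; each
# element is list(vr = <2-char VR>, value = <decoded R value>).  Sequences
# (VR SQ) hold a list of child datasets as their value.

TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"  # Explicit VR Little Endian
IMPLEMENTATION_UID <- "1.2.826.0.1.3680043.9.7432.0.1"

.vr_long_form <- c("OB", "OW", "OF", "OD", "SQ", "UC", "UR", "UT", "UN")
.vr_string <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                "PN", "SH", "ST", "TM", "UC", "UR", "UT", "UI")

#' Create an empty DICOM dataset
#'
#' Datasets are ordered maps from tag (`"GGGGEEEE"` hex) to a `(vr, value)`
#' pair; sequence elements carry a list of child datasets as their value.
#'
#' @return An object of class `dicom_dataset`.
#' @export
dcm_dataset <- function() {
  structure(list(elements = list()), class = "dicom_dataset")
}

canon_tag <- function(tag) {
  tag <- gsub("[(),\\s]", "", toupper(tag))
  if (!grepl("^[0-9A-F]{8}$", tag)) stop("malformed DICOM tag: ", tag)
  tag
}

#' Set an element of a DICOM dataset
#' @param ds A `dicom_dataset`.
#' @param tag Tag as `"GGGGEEEE"` (hex, case-insensitive).
#' @param vr Two-letter value representation code.
#' @param value Element value; for `vr = "SQ"`, a list of child datasets.
#' @return The modified dataset.
#' @export
dcm_set <- function(ds, tag, vr, value) {
  tag <- canon_tag(tag)
  ds$elements[[tag]] <- list(vr = vr, value = value)
  ds
}

#' Get an element value from a DICOM dataset
#' @inheritParams dcm_set
#' @param default Returned when the tag is absent.
#' @export
dcm_get <- function(ds, tag, default = NULL) {
  el <- ds$elements[[canon_tag(tag)]]
  if (is.null(el)) default else el$value
}

#' @rdname dcm_get
#' @export
dcm_has <- function(ds, tag) !is.null(ds$elements[[canon_tag(tag)]])

#' @export
print.dicom_dataset <- function(x, ...) {
  cat("<dicom_dataset> ", length(x$elements), " elements\n", sep = "")
  for (tag in names(x$elements)) {
    el <- x$elements[[tag]]
    val <- if (inherits(el$value, "tm_query")) {
      sprintf("<query: %s>", el$value$query)
    } else if (inherits(el$value, "tm_sequence")) {
      "<sequence template with queries>"
    } else if (identical(el$vr, "SQ")) {
      sprintf("<sequence of %d item(s)>", length(el$value))
    } else if (is.raw(el$value)) {
      sprintf("<%d bytes>", length(el$value))
    } else paste(utils::head(el$value, 4), collapse = "\\")
    cat(sprintf("  (%s,%s) %s %s\n", substr(tag, 1, 4), substr(tag, 5, 8),
                el$vr, val))
  }
  invisible(x)
}

# ---- encoding -------------------------------------------------------------

encode_string_value <- function(vr, value) {
  s <- paste(as.character(value), collapse = "\\")
  r <- charToRaw(enc2utf8(s))
  if (length(r) %% 2L == 1L)
    r <- c(r, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  r
}

encode_value <- function(vr, value) {
  if (inherits(value, "tm_query") || inherits(value, "tm_sequence"))
    stop("cannot encode an unevaluated query placeholder (VR ", vr, ")")
  if (vr %in% .vr_string) return(encode_string_value(vr, value))
  switch(vr,
    US = pack_u16(value),
    SS = pack_s16(value),
    UL = pack_u32(value),
    SL = pack_u32(ifelse(value < 0, value + 4294967296, value)),
    FL = pack_f32(value),
    FD = pack_f64(value),
    OB = , OW = , OF = , UN = {
      r <- as.raw(value)
      if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
      r
    },
    stop("unsupported VR for encoding: ", vr)
  )
}

encode_element <- function(tag, vr, body) {
  group <- strtoi(substr(tag, 1, 4), 16L)
  elem <- strtoi(substr(tag, 5, 8), 16L)
  hdr <- c(pack_u16(group), pack_u16(elem), charToRaw(vr))
  if (vr %in% .vr_long_form) {
    c(hdr, as.raw(c(0L, 0L)), pack_u32(length(body)), body)
  } else {
    if (length(body) > 65535)
      stop("value too long for short-form VR ", vr, " at tag ", tag)
    c(hdr, pack_u16(length(body)), body)
  }
}

encode_dataset <- function(ds) {
  tags <- names(ds$elements)
  ord <- order(vapply(tags, function(t) strtoi(substr(t, 1, 4), 16L), 0) * 65536 +
               vapply(tags, function(t) strtoi(substr(t, 5, 8), 16L), 0))
  parts <- lapply(tags[ord], function(tag) {
    el <- ds$elements[[tag]]
    if (identical(el$vr, "SQ")) {
      items <- lapply(el$value, function(item) {
        body <- encode_dataset(item)
        c(pack_u16(0xFFFE), pack_u16(0xE000), pack_u32(length(body)), body)
      })
      body <- do.call(c, c(items, list(raw(0))))
      encode_element(tag, "SQ", body)
    } else {
      encode_element(tag, el$vr, encode_value(el$vr, el$value))
    }
  })
  do.call(c, c(parts, list(raw(0))))
}

#' Write a dataset as a DICOM Part-10 file
#'
#' Writes the standard 128-byte preamble, `DICM` marker and file meta group,
#' then the dataset in Explicit VR Little Endian transfer syntax with
#' elements in ascending tag order and defined-length sequences.
#'
#' @param ds A `dicom_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dcm_write_file <- function(ds, path) {
  sop_class <- dcm_get(ds, "00080016", default = "")[1]
  sop_inst <- dcm_get(ds, "00080018", default = "")[1]
  meta <- dcm_dataset()
  meta <- dcm_set(meta, "00020001", "OB", as.raw(c(0L, 1L)))
  meta <- dcm_set(meta, "00020002", "UI", sop_class)
  meta <- dcm_set(meta, "00020003", "UI", sop_inst)
  meta <- dcm_set(meta, "00020010", "UI", TRANSFER_SYNTAX_ELE)
  meta <- dcm_set(meta, "00020012", "UI", IMPLEMENTATION_UID)
  meta_bytes <- encode_dataset(meta)
  grouplen <- encode_element("00020000", "UL", pack_u32(length(meta_bytes)))
  body <- encode_dataset(ds)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(grouplen, meta_bytes, body), con)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

decode_value <- function(vr, body) {
  if (vr %in% .vr_string) {
    s <- rawToChar(body[body != as.raw(0L)])
    s <- sub("[ ]+$", "", s)
    if (!nzchar(s)) return(character(0))
    return(strsplit(s, "\\", fixed = TRUE)[[1]])
  }
  switch(vr,
    US = unpack_u16(body),
    SS = unpack_s16(body),
    UL = unpack_u32(body),
    SL = { v <- unpack_u32(body); ifelse(v > 2147483647, v - 4294967296, v) },
    FL = unpack_f32(body),
    FD = unpack_f64(body),
    OB = , OW = , OF = , UN = body,
    stop("unsupported VR for decoding: ", vr)
  )
}

new_reader <- function(bytes) {
  env <- new.env(parent = emptyenv())
  env$bytes <- bytes
  env$pos <- 1L
  env
}
rd_take <- function(rd, n) {
  if (rd$pos + n - 1L > length(rd$bytes)) stop("unexpected end of DICOM stream")
  out <- rd$bytes[rd$pos:(rd$pos + n - 1L)]
  rd$pos <- rd$pos + n
  out
}
rd_u16 <- function(rd) unpack_u16(rd_take(rd, 2L))
rd_u32 <- function(rd) unpack_u32(rd_take(rd, 4L))

parse_dataset <- function(rd, end_pos) {
  ds <- dcm_dataset()
  while (rd$pos < end_pos) {
    group <- rd_u16(rd)
    elem <- rd_u16(rd)
    if (group == 0xFFFE) {
      if (elem == 0xE00D || elem == 0xE0DD) { rd_u32(rd); next }
      stop("unexpected item tag outside sequence")
    }
    vr <- rawToChar(rd_take(rd, 2L))
    len <- if (vr %in% .vr_long_form) { rd_take(rd, 2L); rd_u32(rd) } else rd_u16(rd)
    tag <- sprintf("%04X%04X", group, elem)
    if (identical(vr, "SQ")) {
      if (len == 4294967295) stop("undefined-length sequences are not supported")
      sq_end <- rd$pos + len
      items <- list()
      while (rd$pos < sq_end) {
        ig <- rd_u16(rd); ie <- rd_u16(rd)
        if (ig != 0xFFFE || ie != 0xE000) stop("malformed sequence item in ", tag)
        ilen <- rd_u32(rd)
        if (ilen == 4294967295) stop("undefined-length items are not supported")
        items[[length(items) + 1L]] <- parse_dataset(rd, rd$pos + ilen)
      }
      ds$elements[[tag]] <- list(vr = "SQ", value = items)
    } else {
      if (len == 4294967295) stop("undefined-length element not supported at ", tag)
      ds$elements[[tag]] <- list(vr = vr, value = decode_value(vr, rd_take(rd, len)))
    }
  }
  ds
}

#' Read a DICOM Part-10 file
#'
#' Parses the file meta group, verifies the transfer syntax is Explicit VR
#' Little Endian, and decodes the dataset.  Only defined-length sequences
#' are supported; anything else is an error, never a guess.
#'
#' @param path File to read.
#' @return A `dicom_dataset` (file meta group attached as attribute `meta`).
#' @export
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  rd <- new_reader(bytes)
  rd$pos <- 133L
  # file meta: first element is the group length
  g <- rd_u16(rd); e <- rd_u16(rd)
  if (g != 2L || e != 0L) stop("missing file meta group length in ", path)
  vr <- rawToChar(rd_take(rd, 2L))
  len <- rd_u16(rd)
  meta_len <- unpack_u32(rd_take(rd, len))
  meta <- parse_dataset(rd, rd$pos + meta_len)
  ts <- dcm_get(meta, "00020010", default = "")[1]
  if (!identical(ts, TRANSFER_SYNTAX_ELE))
    stop("unsupported transfer syntax ", ts, " in ", path)
  ds <- parse_dataset(rd, length(bytes) + 1L)
  attr(ds, "meta") <- meta
  ds
}

#' Structural equality of two datasets (tags, VRs and decoded values)
#' @param a,b `dicom_dataset` objects.
#' @export
dcm_equal <- function(a, b) {
  ta <- sort(names(a$elements)); tb <- sort(names(b$elements))
  if (!identical(ta, tb)) return(FALSE)
  for (tag in ta) {
    ea <- a$elements[[tag]]; eb <- b$elements[[tag]]
    if (!identical(ea$vr, eb$vr)) return(FALSE)
    if (identical(ea$vr, "SQ")) {
      if (length(ea$value) != length(eb$value)) return(FALSE)
      for (i in seq_along(ea$value))
        if (!dcm_equal(ea$value[[i]], eb$value[[i]])) return(FALSE)
    } else if (!isTRUE(all.equal(ea$value, eb$value, tolerance = 0))) {
      if (!identical(as.character(ea$value), as.character(eb$value)))
        return(FALSE)
    }
  }
  TRUE
}
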