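# Loading and indexing of tomo-lite patient archives: XML master files plus
# flat sibling binary payloads named <UID>.img / .bin / .dpe (raw headerless
# little-endian).  Payload reads are lazy; a missing binary is flagged, not
# fatal, so incomplete historic archives still load.

.version_labels <- c("V3", "V4_0", "V4_2PLUS")

#' Storage version of a vendor-style archive
#'
#' Three storage generations are distinguished; the only raw-format change
#' between them is the plan-sinogram layout, so the version governs the
#' sinogram decoding path.  Versions are ordered `V3 < V4_0 < V4_2PLUS`.
#'
#' @param label One of `"V3"`, `"V4_0"`, `"V4_2PLUS"`.
#' @export
storage_version <- function(label) {
  label <- match.arg(label, .version_labels)
  structure(label, class = "storage_version")
}

#' @export
Ops.storage_version <- function(e1, e2) {
  r1 <- match(unclass(e1), .version_labels)
  r2 <- match(unclass(e2), .version_labels)
  get(.Generic)(r1, r2)
}

#' @export
print.storage_version <- function(x, ...) {
  cat("<storage_version> ", unclass(x), "\n", sep = ""); invisible(x)
}

version_from_marker <- function(marker) {
  if (is.null(marker) || is.na(marker) || !nzchar(marker))
    stop("archive declares no storage-version marker")
  if (startsWith(marker, "3.")) return(storage_version("V3"))
  if (startsWith(marker, "4.0")) return(storage_version("V4_0"))
  if (startsWith(marker, "4.")) return(storage_version("V4_2PLUS"))
  stop("unknown storage version marker: '", marker, "'")
}

.dtype_size <- c(float32 = 4L, float64 = 8L, int16 = 2L, uint16 = 2L)

#' A 6-degree-of-freedom positional correction record
#'
#' Couch/gantry correction applied after registering a daily
#' image-guidance scan to the plan CT.  Normally linked to its scan by
#' UID; `linked_scan_uid = NA` models a record whose link was lost.
#'
#' @param record_uid UID of the correction record.
#' @param linked_scan_uid UID of the image-guidance scan, or `NA`.
#' @param timestamp POSIXct or ISO-8601 string, seconds precision.
#' @param translations `(lateral, longitudinal, vertical)` in mm.
#' @param rotations `(roll, pitch, yaw)` in degrees.
#' @export
correlation_record <- function(record_uid, linked_scan_uid = NA_character_,
                               timestamp, translations, rotations) {
  if (!is.na(linked_scan_uid) && !is_valid_uid(linked_scan_uid))
    stop("linked_scan_uid is not a syntactically valid UID: ", linked_scan_uid)
  if (!inherits(timestamp, "POSIXct"))
    timestamp <- iso_to_posix(as.character(timestamp))
  stopifnot(length(translations) == 3, length(rotations) == 3)
  structure(list(record_uid = record_uid, linked_scan_uid = linked_scan_uid,
                 timestamp = timestamp,
                 translations = as.numeric(translations),
                 rotations = as.numeric(rotations)),
            class = "correlation_record")
}

parse_blob_refs <- function(doc, dir, patient_id) {
  nodes <- xml2::xml_find_all(doc, ".//*[arrayHeader and dbInfo/databaseUID]")
  if (length(nodes) == 0)
    return(data.frame(uid = character(0), kind = character(0),
                      dtype = character(0), rows = integer(0),
                      cols = integer(0), slices = integer(0),
                      byte_length = numeric(0), path = character(0),
                      missing = logical(0), found_bytes = numeric(0),
                      patient_id = character(0), stringsAsFactors = FALSE))
  uid <- xml2::xml_text(xml2::xml_find_first(nodes, "dbInfo/databaseUID"))
  hdr <- xml2::xml_find_first(nodes, "arrayHeader")
  dtype <- xml2::xml_attr(hdr, "dtype")
  bad <- !dtype %in% names(.dtype_size)
  if (any(bad)) stop("unsupported blob dtype: ", dtype[bad][1])
  rows <- as.integer(xml2::xml_attr(hdr, "dimY"))
  cols <- as.integer(xml2::xml_attr(hdr, "dimX"))
  slices <- as.integer(xml2::xml_attr(hdr, "dimZ"))
  kind <- xml2::xml_attr(hdr, "kind")
  byte_length <- .dtype_size[dtype] * as.numeric(rows) * cols * slices
  path <- file.path(dir, paste0(uid, ".", kind))
  found <- file.exists(path)
  found_bytes <- ifelse(found, file.size(path), NA_real_)
  data.frame(uid = uid, kind = kind, dtype = dtype, rows = rows, cols = cols,
             slices = slices, byte_length = byte_length, path = path,
             missing = !found, found_bytes = found_bytes,
             patient_id = patient_id, stringsAsFactors = FALSE)
}

#' Load and index a tomo-lite patient archive
#'
#' Parses every `patient.xml` master document under `path` (either a single
#' patient directory or a directory of patient directories), builds the
#' UID-to-binary index from the `arrayHeader`/`dbInfo` fragments, and
#' detects the storage version.  Binary payloads are not read — resolution
#' is lazy via [resolve_uid()] / [read_blob()].  Missing payload files are
#' recorded in the index (`missing` flag), never fatal; an unreadable or
#' absent master document is fatal.
#'
#' @param path Archive root directory.
#' @return A `vendor_archive`: patients, binary index, storage version.
#' @export
load_archive <- function(path) {
  if (!dir.exists(path)) stop("archive path does not exist: ", path)
  dirs <- if (file.exists(file.path(path, "patient.xml"))) {
    path
  } else {
    sub <- list.dirs(path, recursive = FALSE)
    sub[file.exists(file.path(sub, "patient.xml"))]
  }
  if (length(dirs) == 0)
    stop("no patient.xml master document found under ", path)
  patients <- list()
  index <- list()
  markers <- character(0)
  for (d in sort(dirs)) {
    xml_path <- file.path(d, "patient.xml")
    doc <- tryCatch(xml2::read_xml(xml_path),
                    error = function(e) stop("malformed master XML in ",
                                             xml_path, ": ", conditionMessage(e)))
    pid <- xml2::xml_text(xml2::xml_find_first(doc, "/fullPatient/briefPatient/patientID"))
    marker <- xml2::xml_attr(xml2::xml_find_first(doc, "/fullPatient"), "formatVersion")
    markers <- c(markers, marker)
    patients[[pid]] <- list(id = pid, dir = d, doc = doc, marker = marker)
    index[[length(index) + 1L]] <- parse_blob_refs(doc, d, pid)
  }
  index <- do.call(rbind, index)
  if (anyDuplicated(index$uid))
    stop("duplicate binary UID in archive: ",
         index$uid[duplicated(index$uid)][1])
  arch <- structure(list(root_path = path, patients = patients,
                         binary_index = index,
                         patient_ids = names(patients),
                         markers = markers,
                         audit = new.env(parent = emptyenv())),
                    class = "vendor_archive")
  arch$audit$reads <- character(0)
  arch$version <- detect_storage_version(arch)
  arch
}

#' Detect the storage version declared by an archive
#'
#' Reads the `fullPatient/@formatVersion` marker: prefix `"3."` maps to
#' `V3`, `"4.0"` to `V4_0`, any other `"4."` to `V4_2PLUS`.  A missing or
#' unrecognized marker, or disagreeing markers across patients, is an
#' explicit error — the version is never silently defaulted.
#'
#' @param archive A `vendor_archive` (or a list with a `markers` field).
#' @return A [storage_version()].
#' @export
detect_storage_version <- function(archive) {
  versions <- unique(vapply(archive$markers,
                            function(m) unclass(version_from_marker(m)),
                            character(1), USE.NAMES = FALSE))
  if (length(versions) != 1)
    stop("archive mixes storage versions: ", paste(versions, collapse = ", "))
  storage_version(versions)
}

#' @export
print.vendor_archive <- function(x, ...) {
  cat("<vendor_archive> ", length(x$patients), " patient(s), ",
      nrow(x$binary_index), " binary blob(s) (", sum(x$binary_index$missing),
      " missing), version ", unclass(x$version), "\n", sep = "")
  invisible(x)
}

#' Resolve a UID to its binary-blob descriptor
#'
#' Returns the descriptor (dtype, shape, path) without reading the payload.
#' An unresolved UID raises a missing-blob error carrying the UID; a
#' payload file whose on-disk size disagrees with
#' `element-size(dtype) * prod(shape)` raises a length-mismatch error.
#'
#' @param archive A `vendor_archive`.
#' @param uid The DICOM UID of the payload.
#' @return A `binary_blob` descriptor.
#' @export
resolve_uid <- function(archive, uid) {
  i <- match(uid, archive$binary_index$uid)
  if (is.na(i) || archive$binary_index$missing[i])
    stop("missing blob: no binary payload for UID ", uid)
  row <- archive$binary_index[i, ]
  if (!is.na(row$found_bytes) && row$found_bytes != row$byte_length)
    stop("length mismatch for UID ", uid, ": expected ", row$byte_length,
         " bytes, found ", row$found_bytes)
  structure(c(as.list(row), list(audit = archive$audit)), class = "binary_blob")
}

#' Read a binary blob payload
#'
#' Decodes the little-endian payload into the declared dtype and shape
#' (rows x columns x slices, column-major; a single slice yields a matrix).
#' Values round-trip bit-identically; `NaN` passes through (with a note).
#'
#' @param blob A `binary_blob` from [resolve_uid()].
#' @return Numeric array with attribute `dtype`.
#' @export
read_blob <- function(blob) {
  stopifnot(inherits(blob, "binary_blob"))
  if (!file.exists(blob$path)) stop("missing blob file: ", blob$path)
  if (file.size(blob$path) != blob$byte_length)
    stop("length mismatch for UID ", blob$uid, ": expected ", blob$byte_length,
         " bytes, found ", file.size(blob$path))
  if (!is.null(blob$audit)) blob$audit$reads <- c(blob$audit$reads, blob$uid)
  n <- blob$rows * blob$cols * blob$slices
  v <- switch(blob$dtype,
    float32 = readBin(blob$path, "double", n = n, size = 4L, endian = "little"),
    float64 = readBin(blob$path, "double", n = n, size = 8L, endian = "little"),
    int16 = readBin(blob$path, "integer", n = n, size = 2L, signed = TRUE,
                    endian = "little"),
    uint16 = readBin(blob$path, "integer", n = n, size = 2L, signed = FALSE,
                     endian = "little"))
  if (anyNA(v) || any(is.nan(v)))
    message("read_blob: NaN values present in ", blob$uid, " (passed through)")
  out <- if (blob$slices == 1L) {
    matrix(v, nrow = blob$rows, ncol = blob$cols)
  } else {
    array(v, dim = c(blob$rows, blob$cols, blob$slices))
  }
  attr(out, "dtype") <- blob$dtype
  out
}

#' Write a binary blob payload (tomo-lite convention)
#'
#' Column-major little-endian serialization of an array; inverse of
#' [read_blob()].  Used by the synthetic generator and round-trip tests.
#'
#' @param values Numeric array.
#' @param dtype One of `"float32"`, `"float64"`, `"int16"`, `"uint16"`.
#' @param path Output path.
#' @export
write_blob <- function(values, dtype, path) {
  v <- as.vector(values)
  bytes <- switch(dtype,
    float32 = pack_f32(v),
    float64 = pack_f64(v),
    int16 = pack_s16(v),
    uint16 = pack_u16(v),
    stop("unsupported dtype: ", dtype))
  writeBin(bytes, path)
  invisible(path)
}

patient_doc <- function(archive, patient_id) {
  p <- archive$patients[[patient_id]]
  if (is.null(p)) stop("unknown patient: ", patient_id)
  p$doc
}

#' Extract positional-correction records for one patient
#'
#' Reads the `fullCorrelationDataArray` fragment into
#' [correlation_record()] objects (a missing `linkedScanUID` child becomes
#' `NA`, modelling a lost link).
#'
#' @param archive A `vendor_archive`.
#' @param patient_id Patient identifier.
#' @export
archive_corrections <- function(archive, patient_id) {
  doc <- patient_doc(archive, patient_id)
  nodes <- xml2::xml_find_all(doc, "//fullCorrelationDataArray/fullCorrelationData")
  child_num <- function(n, name)
    as.numeric(xml2::xml_text(xml2::xml_find_first(n, name)))
  lapply(nodes, function(n) {
    link <- xml2::xml_text(xml2::xml_find_first(n, "linkedScanUID"))
    correlation_record(
      record_uid = xml2::xml_text(xml2::xml_find_first(n, "dbInfo/databaseUID")),
      linked_scan_uid = if (is.na(link)) NA_character_ else link,
      timestamp = xml2::xml_text(xml2::xml_find_first(n, "timestamp")),
      translations = c(child_num(n, "lateral"), child_num(n, "longitudinal"),
                       child_num(n, "vertical")),
      rotations = c(child_num(n, "roll"), child_num(n, "pitch"),
                    child_num(n, "yaw")))
  })
}

#' Image-guidance scans (UID + acquisition time) for one patient
#' @inheritParams archive_corrections
#' @return Data frame with `scan_uid`, `datetime`, `fraction`.
#' @export
archive_scans <- function(archive, patient_id) {
  doc <- patient_doc(archive, patient_id)
  nodes <- xml2::xml_find_all(
    doc, "//fullImageDataArray/fullImageData[imageType='MVCT']")
  data.frame(
    scan_uid = vapply(nodes, function(n)
      xml2::xml_text(xml2::xml_find_first(n, "dbInfo/databaseUID")), ""),
    datetime = iso_to_posix(vapply(nodes, function(n)
      xml2::xml_text(xml2::xml_find_first(n, "acquisitionDateTime")), "")),
    fraction = vapply(nodes, function(n)
      as.integer(xml2::xml_text(xml2::xml_find_first(n, "fractionNumber"))), 0L),
    stringsAsFactors = FALSE)
}
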