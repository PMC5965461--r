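# Object builders: one specialization per exported DICOM-RT type.  The
# TagMap engine fills the metadata; each variant hook then applies its
# raw-data transformation (export padding for CT/MVCT, 16-bit quantization
# with DoseGridScaling for doses, the sinogram pipeline for plans, detector
# rescaling for delivery sinograms) and attaches the payload.

CORR_PRIVATE_CREATOR <- "TAGMAP-CORR"
CORR_GROUP <- "7771"
QA_PRIVATE_CREATOR <- "TAGMAP-QA"

xp_text <- function(doc, q) xml2::xml_text(xml2::xml_find_first(doc, q))
xp_num <- function(doc, q) as.numeric(xp_text(doc, q))

pack_frames_u16 <- function(arr) {
  # DICOM pixel data: row-major within each frame, frames concatenated
  if (length(dim(arr)) == 2) return(pack_u16(as.vector(t(arr))))
  do.call(c, lapply(seq_len(dim(arr)[3]),
                    function(k) pack_u16(as.vector(t(arr[, , k])))))
}

set_image_module <- function(ds, rows, cols) {
  ds <- dcm_set(ds, "00280002", "US", 1L)
  ds <- dcm_set(ds, "00280004", "CS", "MONOCHROME2")
  ds <- dcm_set(ds, "00280010", "US", rows)
  ds <- dcm_set(ds, "00280011", "US", cols)
  ds <- dcm_set(ds, "00280100", "US", 16L)
  ds <- dcm_set(ds, "00280101", "US", 16L)
  ds <- dcm_set(ds, "00280102", "US", 15L)
  ds <- dcm_set(ds, "00280103", "US", 0L)
  ds
}

# the payload reference lives in the PixelData entry: its TagMap query
# returns the blob UID, which evaluation annotates with `blob_uid`
find_blob_element <- function(ds) {
  el <- ds$elements[["7FE00010"]]
  if (is.null(el)) return(NULL)
  uid <- attr(el$value, "blob_uid")
  if (is.null(uid)) return(NULL)
  list(tag = "7FE00010", uid = uid)
}

add_failure <- function(ds, tag, reason) {
  attr(ds, "failures") <- c(attr(ds, "failures"), tag)
  attr(ds, "completeness") <- "INCOMPLETE"
  attr(ds, "failure_reasons") <- c(attr(ds, "failure_reasons"), reason)
  # a failed payload element must not carry its unresolved reference into
  # the written file
  if (!is.null(ds$elements[[tag]]) && ds$elements[[tag]]$vr %in% c("OW", "OB"))
    ds$elements[[tag]]$value <- raw(0)
  ds
}

#' Build one DICOM object from a TagMap
#'
#' Checks that the archive's storage version lies in the TagMap's scope
#' (before any evaluation), evaluates the TagMap against the patient's
#' master document, and dispatches to the variant hook named by the
#' TagMap's target type.  A missing binary payload degrades the object to
#' `INCOMPLETE` rather than failing the build.
#'
#' @param tagmap A [parse_tagmap()] result.
#' @param archive A `vendor_archive`.
#' @param ctx [binding_context()] whose `user_inputs` must name
#'   `patientID` plus any selectors the TagMap's queries use
#'   (`scanUID`, `fraction`, `doseUID`, ...).
#' @return An evaluated `dicom_dataset` with attributes `variant`,
#'   `completeness`, `failures`.
#' @export
build_object <- function(tagmap, archive, ctx) {
  if (!unclass(archive$version) %in% tagmap$version_scope)
    stop("version mismatch: TagMap is scoped to ",
         paste(tagmap$version_scope, collapse = "/"),
         " but the archive is ", unclass(archive$version))
  pid <- ctx$user_inputs$patientID
  if (is.null(pid)) stop("binding context must carry a patientID input")
  backend <- xpath_backend(archive, pid)
  ds <- evaluate(build_skeleton(tagmap), backend, ctx, tagmap$target_type)
  ds <- dcm_set(ds, "00080016", "UI", sop_class_for_variant(tagmap$target_type))
  if (!dcm_has(ds, "00080060"))
    ds <- dcm_set(ds, "00080060", "CS", .modality_for_variant[[tagmap$target_type]])
  ds <- apply_variant_hook(ds, tagmap$target_type, archive, ctx)
  attr(ds, "variant") <- tagmap$target_type
  ds
}

apply_variant_hook <- function(ds, variant, archive, ctx) {
  doc <- patient_doc(archive, ctx$user_inputs$patientID)
  switch(variant,
    CT = , MVCT = hook_ct_image(ds, archive),
    RTDOSE = , QADOSE = hook_dose(ds, archive, variant),
    RTPLAN = hook_rtplan(ds, archive, doc),
    DELIVERY_SINOGRAM = hook_delivery(ds, archive),
    RTSTRUCT = ds,
    RTRECORD = ds,
    stop("no builder for variant ", variant))
}

# derived series UID keeps non-image objects in their own series while
# staying deterministic under assign_uids
derived_series_uid <- function(ds) {
  sop <- dcm_get(ds, "00080018", default = NULL)
  if (!is.null(sop) && !dcm_has(ds, "0020000E"))
    ds <- dcm_set(ds, "0020000E", "UI", paste0(sop[1], ".1"))
  ds
}

hook_ct_image <- function(ds, archive) {
  blob <- find_blob_element(ds)
  if (is.null(blob))
    return(add_failure(ds, "7FE00010", "no pixel payload reference"))
  img <- tryCatch(read_blob(resolve_uid(archive, blob$uid)),
                  error = function(e) e)
  if (inherits(img, "error"))
    return(add_failure(ds, "7FE00010", conditionMessage(img)))
  padded <- pad_for_export(img, pad_value = 0)
  ds <- set_image_module(ds, nrow(padded), ncol(padded))
  if (!dcm_has(ds, "00281053")) ds <- dcm_set(ds, "00281053", "DS", format_ds(1))
  ds$elements[[blob$tag]] <- list(vr = "OW", value = pack_frames_u16(padded))
  ds
}

hook_dose <- function(ds, archive, variant) {
  blob <- find_blob_element(ds)
  if (is.null(blob))
    return(add_failure(ds, "7FE00010", "no dose payload reference"))
  field <- tryCatch(read_blob(resolve_uid(archive, blob$uid)),
                    error = function(e) e)
  if (inherits(field, "error"))
    return(add_failure(ds, "7FE00010", conditionMessage(field)))
  sf <- compute_scale_factor(field)
  sd <- quantize_dose(field, sf)
  dims <- dim(sd$voxels16)
  if (length(dims) == 2) dims <- c(dims, 1L)
  ds <- set_image_module(ds, dims[1], dims[2])
  ds <- dcm_set(ds, "00280008", "IS", as.character(dims[3]))
  ds <- dcm_set(ds, "30040002", "CS", "GY")
  ds <- dcm_set(ds, "30040004", "CS", "PHYSICAL")
  if (!dcm_has(ds, "3004000A"))
    ds <- dcm_set(ds, "3004000A", "CS",
                  if (variant == "QADOSE") "FRACTION" else "PLAN")
  dz <- attr(field, "grid_dz") %||% 2.5
  ds <- dcm_set(ds, "3004000C", "DS", format_ds((seq_len(dims[3]) - 1) * dz))
  ds <- dcm_set(ds, "3004000E", "DS", format_ds(sf))
  ds$elements[[blob$tag]] <- list(vr = "OW", value = pack_frames_u16(sd$voxels16))
  if (variant == "QADOSE") {
    ds <- dcm_set(ds, paste0("77730010"), "LO", QA_PRIVATE_CREATOR)
    ds <- dcm_set(ds, paste0("77731001"), "LO", "QADOSE")
  }
  ds <- derived_series_uid(ds)
  ds
}

hook_rtplan <- function(ds, archive, doc) {
  frag <- "/fullPatient/fullPlanDataArray/fullPlanData/planSinogram"
  sino_uid <- xp_text(doc, paste0(frag, "/dbInfo/databaseUID"))
  n_proj <- as.integer(xp_num(doc, paste0(frag, "/nProjections")))
  tau <- xp_num(doc, paste0(frag, "/projectionDuration"))
  warmup <- xp_num(doc, paste0(frag, "/warmupDuration"))
  raw <- tryCatch(suppressMessages(read_blob(resolve_uid(archive, sino_uid))),
                  error = function(e) e)
  if (inherits(raw, "error"))
    return(add_failure(ds, SINOGRAM_PRIVATE_TAG, conditionMessage(raw)))
  layout <- detect_sinogram_version(raw, archive$version)
  sg3 <- if (layout == "V3-layout") {
    plan_sinogram_v3(raw)
  } else {
    open_leaves <- as.integer(strsplit(
      xp_text(doc, paste0(frag, "/openLeafIndices")), "\\s+")[[1]])
    sg4 <- plan_sinogram_v4(raw, open_leaves, warmup_s = warmup,
                            projection_duration_s = tau)
    decode_sinogram_v4(sg4, n_proj)
  }
  ds <- dcm_set(ds, SINOGRAM_CREATOR_TAG, "LO", SINOGRAM_PRIVATE_CREATOR)
  ds <- dcm_set(ds, SINOGRAM_PRIVATE_TAG, "OB", encode_plan_sinogram_dicom(sg3))
  ds <- derived_series_uid(ds)
  ds
}

hook_delivery <- function(ds, archive) {
  blob <- find_blob_element(ds)
  if (is.null(blob))
    return(add_failure(ds, "7FE00010", "no detector payload reference"))
  det <- tryCatch(read_blob(resolve_uid(archive, blob$uid)),
                  error = function(e) e)
  if (inherits(det, "error"))
    return(add_failure(ds, "7FE00010", conditionMessage(det)))
  slope <- if (max(det) > 0) max(det) / 65535 else 1
  pix <- pmin(pmax(round_half_up(det / slope), 0), 65535)
  ds <- set_image_module(ds, nrow(det), ncol(det))
  ds <- dcm_set(ds, "00281052", "DS", format_ds(0))
  ds <- dcm_set(ds, "00281053", "DS", format_ds(slope))
  ds$elements[[blob$tag]] <- list(vr = "OW", value = pack_frames_u16(pix))
  ds <- derived_series_uid(ds)
  ds
}

#' Build a QADose object for one fraction
#'
#' An RT-Dose-shaped dataset holding the dose recalculated on a daily
#' image-guidance scan; its referenced image sequence points at the MVCT
#' series of that fraction, not the plan CT, and the quantization contract
#' is identical to RT-Dose.  A missing recalculated dose yields an
#' `INCOMPLETE` object with the reason recorded.
#'
#' @param tagmap The QADose TagMap.
#' @param archive A `vendor_archive`.
#' @param patient_id Patient identifier.
#' @param fraction Fraction number of the daily scan.
#' @export
build_qadose <- function(tagmap, archive, patient_id, fraction) {
  ctx <- binding_context(list(patientID = patient_id, fraction = fraction))
  build_object(tagmap, archive, ctx)
}

#' Build a delivery-sinogram image for one fraction
#'
#' RT-Image-shaped dataset whose pixel grid is detector channels (rows) by
#' projections (columns); float detector values are packed to 16 bits with
#' `RescaleSlope = max / 65535`, intercept 0, so the payload is recovered
#' within slope/2.
#'
#' @inheritParams build_qadose
#' @export
build_delivery_sinogram <- function(tagmap, archive, patient_id, fraction) {
  ctx <- binding_context(list(patientID = patient_id, fraction = fraction))
  build_object(tagmap, archive, ctx)
}

#' Embed a positional correction into an MVCT dataset as private tags
#'
#' Writes the full correction block (translations, rotations, timestamp,
#' link method) under the reserved private creator `"TAGMAP-CORR"` in
#' group 7771; public elements are untouched.  An `UNLINKED` record writes
#' no block (logged).
#'
#' @param mvct An MVCT `dicom_dataset`.
#' @param record A [correlation_record()].
#' @param method `"UID"`, `"TIMESTAMP"` or `"UNLINKED"`.
#' @export
embed_corrections <- function(mvct, record, method) {
  if (!identical(attr(mvct, "variant"), "MVCT"))
    stop("corrections embed into MVCT objects only")
  if (identical(method, "UNLINKED")) {
    message("embed_corrections: record ", record$record_uid,
            " is UNLINKED; no private block written")
    return(mvct)
  }
  mvct <- dcm_set(mvct, paste0(CORR_GROUP, "0010"), "LO", CORR_PRIVATE_CREATOR)
  mvct <- dcm_set(mvct, paste0(CORR_GROUP, "1001"), "DS",
                  format_ds(record$translations))
  mvct <- dcm_set(mvct, paste0(CORR_GROUP, "1002"), "DS",
                  format_ds(record$rotations))
  mvct <- dcm_set(mvct, paste0(CORR_GROUP, "1003"), "DT",
                  format(record$timestamp, "%Y%m%d%H%M%S", tz = "UTC"))
  mvct <- dcm_set(mvct, paste0(CORR_GROUP, "1004"), "LO", method)
  mvct
}

# ---- UID assignment and reference graph -----------------------------------

collect_uid_values <- function(ds) {
  out <- character(0)
  for (tag in names(ds$elements)) {
    el <- ds$elements[[tag]]
    if (identical(el$vr, "SQ")) {
      for (item in el$value) out <- c(out, collect_uid_values(item))
    } else if (identical(el$vr, "UI")) {
      out <- c(out, as.character(el$value))
    }
  }
  out
}

remap_uid_values <- function(ds, map) {
  for (tag in names(ds$elements)) {
    el <- ds$elements[[tag]]
    if (identical(el$vr, "SQ")) {
      ds$elements[[tag]]$value <- lapply(el$value, remap_uid_values, map = map)
    } else if (identical(el$vr, "UI")) {
      v <- as.character(el$value)
      hit <- v %in% names(map)
      v[hit] <- unname(map[v[hit]])
      ds$elements[[tag]]$value <- v
    }
  }
  ds
}

collect_refs <- function(ds) {
  refs <- character(0)
  for (tag in names(ds$elements)) {
    el <- ds$elements[[tag]]
    if (identical(el$vr, "SQ")) {
      for (item in el$value) refs <- c(refs, collect_refs(item))
    } else if (tag == "00081155") {
      refs <- c(refs, as.character(el$value))
    }
  }
  refs
}

.image_variants <- c("CT", "MVCT", "DELIVERY_SINOGRAM")

#' Check that every cross-object UID reference resolves within a set
#'
#' The testable core of "correctly linked" export: every referenced SOP
#' instance (0008,1155), and every frame-of-reference UID claimed by a
#' non-image object, must be defined by some object in the set (SOP
#' instance, series, study, or an image's frame of reference).
#'
#' @param objects List of built `dicom_dataset`s.
#' @return Data frame of dangling references (zero rows when closed).
#' @export
uid_reference_graph <- function(objects) {
  defined <- character(0)
  for (obj in objects) {
    defined <- c(defined,
                 dcm_get(obj, "00080018", default = character(0)),
                 dcm_get(obj, "0020000D", default = character(0)),
                 dcm_get(obj, "0020000E", default = character(0)))
    if (identical(attr(obj, "variant"), "CT") ||
        identical(attr(obj, "variant"), "MVCT"))
      defined <- c(defined, dcm_get(obj, "00200052", default = character(0)))
  }
  dangling <- list()
  for (i in seq_along(objects)) {
    obj <- objects[[i]]
    refs <- collect_refs(obj)
    if (!attr(obj, "variant") %in% .image_variants)
      refs <- c(refs, dcm_get(obj, "00200052", default = character(0)))
    bad <- setdiff(refs, defined)
    if (length(bad))
      dangling[[length(dangling) + 1L]] <- data.frame(
        source = rep(names(objects)[i] %||% as.character(i), length(bad)),
        target = bad, stringsAsFactors = FALSE)
  }
  if (length(dangling)) do.call(rbind, dangling)
  else data.frame(source = character(0), target = character(0))
}

#' Deterministically reassign UIDs over one patient's export
#'
#' Every non-standard UID value (archive-derived identifiers; standard SOP
#' Class / transfer-syntax UIDs under `1.2.840.10008` are left alone) is
#' replaced by `<namespace_root>.<seed>.<h1>.<h2>` where `h1`, `h2` are
#' 32-bit FNV-1a digests of the source UID and seed.  The same source UID
#' maps to the same new UID everywhere, so every cross-reference keeps
#' resolving; repeated export with the same seed is byte-stable.  A
#' dangling reference (an object referencing a UID no object defines) is
#' an error listing source and target.
#'
#' @param objects Named list of built `dicom_dataset`s for one patient.
#' @param namespace_root UID prefix for the derived identifiers.
#' @param seed Deterministic token mixed into the digest.
#' @return The objects with rewritten UIDs.
#' @export
assign_uids <- function(objects, namespace_root = "1.2.826.0.1.3680043.9.7432",
                        seed = 1L) {
  uids <- unique(unlist(lapply(objects, collect_uid_values)))
  uids <- uids[!startsWith(uids, "1.2.840.10008")]
  map <- vapply(uids, derive_uid, "", namespace_root = namespace_root,
                seed = seed)
  if (anyDuplicated(map)) stop("UID digest collision; change namespace seed")
  objects <- lapply(objects, remap_uid_values, map = map)
  g <- uid_reference_graph(objects)
  if (nrow(g) > 0)
    stop("dangling UID reference(s): ",
         paste(sprintf("%s -> %s", g$source, g$target), collapse = "; "))
  objects
}

#' Write a built object as a DICOM Part-10 file
#'
#' Explicit VR Little Endian with standard preamble and file meta group.
#' Under the `"strict"` policy an `INCOMPLETE` object is not written (and
#' reported); the default `"lenient"` policy writes it with its
#' completeness recorded by the caller's QA report.
#'
#' @param obj A built `dicom_dataset`.
#' @param path Output file path.
#' @param policy `"lenient"` or `"strict"`.
#' @return `TRUE` if the file was written, `FALSE` if suppressed.
#' @export
write_dicom <- function(obj, path, policy = c("lenient", "strict")) {
  policy <- match.arg(policy)
  if (identical(attr(obj, "completeness"), "INCOMPLETE") && policy == "strict") {
    message("write_dicom: INCOMPLETE object suppressed under strict policy: ",
            path)
    return(invisible(FALSE))
  }
  dcm_write_file(obj, path)
  invisible(TRUE)
}
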