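# Batch, unattended export with QA accounting.  One failing patient never
# aborts the batch: each patient directory is loaded and exported inside
# its own error boundary, and the report keeps the complete / "needs
# additional processing" bookkeeping for every run.

.supported_types <- c("CT", "MVCT", "RTPLAN", "RTDOSE", "RTSTRUCT",
                      "QADOSE", "DELIVERY_SINOGRAM")

#' Describe a batch export job
#'
#' @param archive Archive root directory (one patient directory per
#'   patient, each holding `patient.xml`).
#' @param out Output root; one directory per patient is created.
#' @param patients `"all"` or a character vector of patient IDs.
#' @param types Object types to export (subset of the supported variants).
#' @param tagmap_dir Directory of TagMap XML files (`<TYPE>.xml`); defaults
#'   to the maps shipped with the package.
#' @param seed Integer seed for deterministic UID derivation.
#' @param policy `"lenient"` writes INCOMPLETE objects (recorded in the QA
#'   report); `"strict"` suppresses them.
#' @param relink_tolerance_s Timestamp-fallback tolerance for correction
#'   relinking, seconds.
#' @param namespace_root UID prefix for derived identifiers.
#' @export
export_job <- function(archive, out, patients = "all",
                       types = .supported_types,
                       tagmap_dir = system.file("tagmaps", package = "tagmapr"),
                       seed = 1L, policy = c("lenient", "strict"),
                       relink_tolerance_s = 120,
                       namespace_root = "1.2.826.0.1.3680043.9.7432") {
  policy <- match.arg(policy)
  unknown <- setdiff(types, .supported_types)
  if (length(unknown))
    stop("configuration error: unknown object type(s): ",
         paste(unknown, collapse = ", "))
  structure(list(archive = archive, out = out, patients = patients,
                 types = types, tagmap_dir = tagmap_dir, seed = seed,
                 policy = policy, relink_tolerance_s = relink_tolerance_s,
                 namespace_root = namespace_root), class = "export_job")
}

log_line <- function(..., pid = NULL) {
  scope <- if (is.null(pid)) "" else paste0("[", pid, "] ")
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), scope, ...)
}

#' Run a batch export job
#'
#' Processes every selected patient unattended; configuration errors
#' (unparseable TagMaps, unknown types, absent archive root) are fatal
#' before any processing, but any failure inside one patient is caught,
#' logged and reported while the batch continues.  Writes the per-patient
#' DICOM trees, a per-patient `manifest.json` QA report, and a
#' machine-readable `export_report.json` at the output root.
#'
#' @param job An [export_job()].
#' @return An `export_report` list: `patients` data frame and `aggregate`
#'   counts (`processed = complete + incomplete` always holds).
#' @export
run_export <- function(job) {
  stopifnot(inherits(job, "export_job"))
  if (!dir.exists(job$archive))
    stop("configuration error: archive root not found: ", job$archive)
  tagmaps <- lapply(stats::setNames(job$types, job$types), function(ty) {
    f <- file.path(job$tagmap_dir, paste0(ty, ".xml"))
    if (!file.exists(f)) stop("configuration error: no TagMap for type ", ty,
                              " in ", job$tagmap_dir)
    parse_tagmap(f)
  })
  pdirs <- if (file.exists(file.path(job$archive, "patient.xml"))) {
    job$archive
  } else {
    d <- list.dirs(job$archive, recursive = FALSE)
    sort(d[file.exists(file.path(d, "patient.xml"))])
  }
  if (!identical(job$patients, "all"))
    pdirs <- pdirs[basename(pdirs) %in% job$patients]
  dir.create(job$out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (pdir in pdirs) {
    pid_guess <- basename(pdir)
    res <- tryCatch(export_one_patient(pdir, tagmaps, job),
                    error = function(e) {
                      log_line("FAILED: ", conditionMessage(e), pid = pid_guess)
                      list(patient_id = pid_guess, status = "failed",
                           error = conditionMessage(e), objects_written = 0L,
                           complete = 0L, incomplete = 0L,
                           relink_uid = 0L, relink_timestamp = 0L,
                           relink_unlinked = 0L)
                    })
    rows[[length(rows) + 1L]] <- res
  }
  patients <- do.call(rbind, lapply(rows, function(r)
    data.frame(patient_id = r$patient_id, status = r$status,
               objects_written = r$objects_written, complete = r$complete,
               incomplete = r$incomplete, relink_uid = r$relink_uid,
               relink_timestamp = r$relink_timestamp,
               relink_unlinked = r$relink_unlinked,
               error = r$error %||% NA_character_, stringsAsFactors = FALSE)))
  ok <- patients$status == "exported"
  dataset_complete <- ok & patients$incomplete == 0L
  aggregate <- list(
    selected = nrow(patients),
    processed = sum(ok),
    complete = sum(dataset_complete),
    incomplete = sum(ok & patients$incomplete > 0L),
    failed = sum(!ok),
    seed = job$seed)
  report <- structure(list(patients = patients, aggregate = aggregate),
                      class = "export_report")
  jsonlite::write_json(list(patients = patients, aggregate = aggregate),
                       file.path(job$out, "export_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report
}

#' @export
print.export_report <- function(x, ...) {
  a <- x$aggregate
  cat("<export_report> ", a$processed, "/", a$selected, " patients processed (",
      a$complete, " complete, ", a$incomplete,
      " needing additional processing, ", a$failed, " failed)\n", sep = "")
  invisible(x)
}

export_one_patient <- function(pdir, tagmaps, job) {
  arch <- load_archive(pdir)
  pid <- arch$patient_ids[1]
  log_line("loaded archive (version ", unclass(arch$version), ")", pid = pid)
  objects <- list()
  add <- function(name, obj) objects[[name]] <<- obj
  base_ctx <- function(...) binding_context(c(list(patientID = pid), list(...)))
  scans <- archive_scans(arch, pid)
  if ("CT" %in% names(tagmaps))
    add("CT", build_object(tagmaps$CT, arch, base_ctx()))
  relink <- NULL
  if ("MVCT" %in% names(tagmaps)) {
    corrections <- archive_corrections(arch, pid)
    relink <- suppressWarnings(
      relink_corrections(corrections, scans, job$relink_tolerance_s))
    for (i in seq_len(nrow(scans))) {
      mv <- build_object(tagmaps$MVCT, arch, base_ctx(scanUID = scans$scan_uid[i]))
      hit <- which(relink$scan_uid == scans$scan_uid[i])
      if (length(hit) == 1)
        mv <- suppressMessages(
          embed_corrections(mv, corrections[[hit]], relink$method[hit]))
      add(paste0("MVCT_", scans$fraction[i]), mv)
    }
  }
  if ("RTPLAN" %in% names(tagmaps))
    add("RTPLAN", build_object(tagmaps$RTPLAN, arch, base_ctx()))
  if ("RTDOSE" %in% names(tagmaps))
    add("RTDOSE", build_object(tagmaps$RTDOSE, arch, base_ctx()))
  if ("RTSTRUCT" %in% names(tagmaps))
    add("RTSTRUCT", build_object(tagmaps$RTSTRUCT, arch, base_ctx()))
  for (ty in intersect(c("QADOSE", "DELIVERY_SINOGRAM"), names(tagmaps)))
    for (f in scans$fraction)
      add(paste0(ty, "_", f),
          build_object(tagmaps[[ty]], arch, base_ctx(fraction = f)))
  objects <- assign_uids(objects, job$namespace_root, job$seed)
  outdir <- file.path(job$out, pid)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  for (name in names(objects)) {
    obj <- objects[[name]]
    modality <- dcm_get(obj, "00080060", default = "UN")[1]
    sop <- dcm_get(obj, "00080018", default = "unknown")[1]
    fname <- paste0(modality, ".", sop, ".dcm")
    ok <- write_dicom(obj, file.path(outdir, fname), policy = job$policy)
    written[[name]] <- list(
      file = if (ok) fname else NA_character_,
      variant = attr(obj, "variant"),
      completeness = attr(obj, "completeness") %||% "COMPLETE",
      failures = as.list(attr(obj, "failures") %||% character(0)))
  }
  comp <- vapply(written, function(w) identical(w$completeness, "COMPLETE"), TRUE)
  relink_counts <- if (is.null(relink)) c(UID = 0L, TIMESTAMP = 0L, UNLINKED = 0L)
    else vapply(c("UID", "TIMESTAMP", "UNLINKED"),
                function(m) sum(relink$method == m), 0L)
  qa <- list(patient_id = pid, seed = job$seed,
             objects = written,
             relink_methods = as.list(relink_counts))
  jsonlite::write_json(qa, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(sum(comp), " complete / ", sum(!comp),
           " incomplete object(s) written", pid = pid)
  list(patient_id = pid, status = "exported", error = NULL,
       objects_written = length(written),
       complete = sum(comp), incomplete = sum(!comp),
       relink_uid = unname(relink_counts["UID"]),
       relink_timestamp = unname(relink_counts["TIMESTAMP"]),
       relink_unlinked = unname(relink_counts["UNLINKED"]))
}

#' Validate an export tree
#'
#' Reparses every written DICOM file, checks UID reference-graph closure
#' per patient, and (when the generator's ground-truth manifest is given)
#' cross-checks key values: padded CT dimensions and the maximum dose
#' reconstructed from `DoseGridScaling`.
#'
#' @param out_root Output root of a completed [run_export()].
#' @param manifest Optional generator manifest list.
#' @return Data frame with one row per file: `file`, `pass`, `reason`.
#' @export
validate_outputs <- function(out_root, manifest = NULL) {
  pdirs <- list.dirs(out_root, recursive = FALSE)
  rows <- list()
  for (pdir in pdirs) {
    pid <- basename(pdir)
    files <- list.files(pdir, pattern = "\\.dcm$", full.names = TRUE)
    objs <- list()
    for (f in files) {
      ds <- tryCatch(dcm_read_file(f), error = function(e) e)
      if (inherits(ds, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          file = f, pass = FALSE, reason = conditionMessage(ds))
        next
      }
      sop_class <- dcm_get(ds, "00080016", default = "")[1]
      attr(ds, "variant") <- if (sop_class == "1.2.840.10008.5.1.4.1.1.2") "CT"
        else if (sop_class == "1.2.840.10008.5.1.4.1.1.481.1") "DELIVERY_SINOGRAM"
        else "OTHER"
      objs[[f]] <- ds
      reason <- ""
      if (!is.null(manifest)) {
        pm <- manifest$patients[[pid]]
        if (!is.null(pm)) reason <- check_against_manifest(ds, pm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        file = f, pass = !nzchar(reason),
        reason = if (nzchar(reason)) reason else NA_character_)
    }
    if (length(objs)) {
      g <- uid_reference_graph(objs)
      if (nrow(g) > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          file = file.path(pdir, "<uid-graph>"), pass = FALSE,
          reason = paste(sprintf("%s -> %s", g$source, g$target),
                         collapse = "; "))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(file = character(0), pass = logical(0),
                         reason = character(0))
  rownames(out) <- NULL
  out
}

check_against_manifest <- function(ds, pm) {
  sop_class <- dcm_get(ds, "00080016", default = "")[1]
  if (sop_class == "1.2.840.10008.5.1.4.1.1.2" &&
      identical(dcm_get(ds, "0008103E", default = "")[1], "Planning CT")) {
    side <- max(pm$plan_ct$rows, pm$plan_ct$cols)
    if (dcm_get(ds, "00280010") != side || dcm_get(ds, "00280011") != side)
      return(sprintf("plan CT not padded to %d x %d", side, side))
  }
  if (sop_class == "1.2.840.10008.5.1.4.1.1.481.2") {
    sf <- as.numeric(dcm_get(ds, "3004000E"))
    maxes <- vapply(pm$doses, function(d) as.numeric(d$max_dose), 0)
    if (!any(abs(65535 * sf - maxes) <= maxes * 1e-6 + 1e-9))
      return("DoseGridScaling does not reconstruct any manifest max dose")
  }
  ""
}
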