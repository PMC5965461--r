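# Synthetic tomo-lite archive generator: the test bed for the whole export
# pipeline.  Emits archives in all three storage-version variants together
# with a ground-truth manifest, plus a matched relational (CSV) fixture for
# the SQL backend.  Image content is geometric phantoms and dose grids are
# smooth Gaussian-sum fields: assertions downstream are structural and
# numeric, not anatomical.

.first_names <- c("ANN", "BORIS", "CARLA", "DEREK", "EVA", "FRED", "GRETA",
                  "HUGO", "IRIS", "JACK")
.last_names <- c("SMITH", "JONES", "TAYLOR", "BROWN", "WILSON", "EVANS",
                 "THOMAS", "ROBERTS", "JOHNSON", "LEWIS")

#' Specification for a synthetic tomo-lite archive
#'
#' The defaults describe one realistic patient: a 256 x 256 planning CT
#' enlarged to 384 x 284 by the couch insertion (width 384, 28 couch rows),
#' daily MVCT image guidance with one 6-DoF correction per scan (a fifth of
#' which have lost their UID link), a 50-projection plan sinogram with
#' leaves 11-52 open, per-fraction adaptive doses and 640-channel delivery
#' sinograms.  The seed fully determines the generated bytes.
#'
#' @param n_patients Number of patients.
#' @param n_fractions Treatment fractions (MVCT scans) per patient.
#' @param version Storage version label: `"V3"`, `"V4_0"` or `"V4_2PLUS"`.
#' @param couch_scenario One of `"none"`, `"vertical"`, `"horizontal"`,
#'   `"both"` — which dimensions the couch insertion enlarges.
#' @param base_image_shape `(rows, cols)` of the pre-insertion planning CT.
#' @param target_width Post-insertion width in pixels.
#' @param couch_height_px Couch rows appended by the insertion.
#' @param dose_shape `(rows, cols, slices)` of dose grids.
#' @param n_projections Plan-sinogram projections.
#' @param projection_duration_s Seconds per projection.
#' @param warmup_s Beam warm-up before projection 1 (seconds).
#' @param open_leaves 1-based indices of MLC leaves that ever open.
#' @param n_channels Detector channels of the delivery sinogram.
#' @param broken_link_fraction Fraction of corrections with the scan-UID
#'   link removed.
#' @param scan_interval_s Time between consecutive MVCT scans (seconds).
#' @param correction_jitter_s Max |offset| of a correction timestamp from
#'   its scan's acquisition time (seconds).
#' @param include_adaptive_dose,include_delivery_sinogram Emit the
#'   per-fraction hidden-data payloads.
#' @param seed Integer seed; determines every byte of the output.
#' @export
archive_spec <- function(n_patients = 1L, n_fractions = 3L,
                         version = "V4_2PLUS", couch_scenario = "both",
                         base_image_shape = c(256L, 256L),
                         target_width = 384L, couch_height_px = 28L,
                         dose_shape = c(32L, 32L, 16L),
                         n_projections = 50L, projection_duration_s = 0.4,
                         warmup_s = 10, open_leaves = 11:52,
                         n_channels = 640L, broken_link_fraction = 0.2,
                         scan_interval_s = 86400, correction_jitter_s = 30,
                         include_adaptive_dose = TRUE,
                         include_delivery_sinogram = TRUE, seed = 1L) {
  couch_scenario <- match.arg(couch_scenario,
                              c("none", "vertical", "horizontal", "both"))
  version <- match.arg(version, c("V3", "V4_0", "V4_2PLUS"))
  structure(as.list(environment()), class = "archive_spec")
}

.version_marker <- c(V3 = "3.1.4", V4_0 = "4.0.2", V4_2PLUS = "4.2.1")

fmt_num <- function(x) formatC(x, digits = 12, format = "g", width = 0)
fmt_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

ellipse_phantom <- function(rows, cols, body_value, couch_value = NULL) {
  r <- matrix(seq_len(rows), rows, cols)
  c_ <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  img <- matrix(0, rows, cols)
  inside <- ((r - rows / 2) / (rows * 0.38))^2 +
    ((c_ - cols / 2) / (cols * 0.42))^2 <= 1
  img[inside] <- body_value
  if (!is.null(couch_value)) {
    n_couch <- max(2L, rows %/% 32L)
    img[(rows - n_couch + 1):rows, ] <- couch_value
  }
  img
}

gaussian_sum_field <- function(shape, n_gauss = 3L) {
  r <- shape[1]; c_ <- shape[2]; s <- shape[3]
  field <- array(0, dim = shape)
  gr <- slice.index(field, 1); gc <- slice.index(field, 2)
  gs <- slice.index(field, 3)
  for (g in seq_len(n_gauss)) {
    ctr <- c(stats::runif(1, 0.25, 0.75) * r, stats::runif(1, 0.25, 0.75) * c_,
             stats::runif(1, 0.25, 0.75) * s)
    sig <- c(stats::runif(1, 0.1, 0.3) * r, stats::runif(1, 0.1, 0.3) * c_,
             stats::runif(1, 0.15, 0.4) * s)
    amp <- stats::runif(1, 0.3, 1)
    field <- field + amp * exp(-(((gr - ctr[1]) / sig[1])^2 +
                                 ((gc - ctr[2]) / sig[2])^2 +
                                 ((gs - ctr[3]) / sig[3])^2) / 2)
  }
  field
}

as_f32 <- function(x) {
  out <- unpack_f32(pack_f32(as.vector(x)))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

smooth_fractions <- function(n_projections, open_leaves) {
  fr <- matrix(0, n_projections, MLC_N_LEAVES)
  k <- seq_len(n_projections)
  for (leaf in open_leaves) {
    amp <- stats::runif(1, 0.3, 0.95)
    phase <- stats::runif(1, 0, pi)
    f <- amp * (0.15 + 0.85 * sin(pi * k / n_projections + phase)^2)
    fr[, leaf] <- pmin(pmax(f, 0.01), 1)
  }
  as_f32(fr)
}

#' Synthetic dose grid: smooth Gaussian-sum field at float32 precision
#'
#' Sum of three randomly placed 3-D Gaussians, rescaled so the hottest
#' voxel equals `max_dose`, then rounded to float32 (the precision dose
#' grids are archived at).  Used to exercise the 16-bit quantization
#' across dose magnitudes.
#'
#' @param shape `(rows, cols, slices)` of the grid.
#' @param max_dose Maximum voxel dose in Gy.
#' @return Numeric array with `max(out)` equal to float32(`max_dose`).
#' @export
synthetic_dose_grid <- function(shape = c(32L, 32L, 32L), max_dose = 60) {
  field <- gaussian_sum_field(as.integer(shape))
  as_f32(field / max(field) * max_dose)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic tomo-lite archive with ground-truth manifest
#'
#' Writes one directory per patient (a `patient.xml` master document plus
#' flat `<UID>.img/.bin/.dpe` binaries) and a `manifest.json` at the root
#' recording every generated UID, dtype, shape and key value (maximum
#' doses, open leaves, true scan links, correction vectors, timestamps) so
#' that any exported DICOM value can be verified against it.
#'
#' @param spec An [archive_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir` and the `manifest` list.
#' @export
generate_archive <- function(spec, dir) {
  stopifnot(inherits(spec, "archive_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- with_seed(spec$seed, {
    pats <- list()
    for (p in seq_len(spec$n_patients))
      pats[[sprintf("TL%04d", p)]] <- generate_patient(spec, dir, p)
    list(seed = spec$seed, version = spec$version,
         n_patients = spec$n_patients, patients = pats)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, manifest = manifest))
}

generate_patient <- function(spec, root, p) {
  pid <- sprintf("TL%04d", p)
  pdir <- file.path(root, pid)
  dir.create(pdir, showWarnings = FALSE)
  first <- .first_names[(p - 1L) %% length(.first_names) + 1L]
  last <- .last_names[(p - 1L) %% length(.last_names) + 1L]
  uid_counter <- 0L
  new_uid <- function() {
    uid_counter <<- uid_counter + 1L
    sprintf("1.2.826.0.1.3680043.9.7432.%d.%d.%d", spec$seed, p, uid_counter)
  }
  t0 <- iso_to_posix("2011-03-01T09:00:00") + (p - 1) * 86400

  study_uid <- new_uid(); frame_uid <- new_uid()
  ct_series_uid <- new_uid(); ct_uid <- new_uid()

  # plan CT: phantom with scanner couch, then treatment-couch insertion
  rows0 <- spec$base_image_shape[1]; cols0 <- spec$base_image_shape[2]
  base_img <- ellipse_phantom(rows0, cols0, body_value = 1064,
                              couch_value = 1300)
  cs <- switch(spec$couch_scenario,
    none = couch_spec(cols0, 0L, pad_value = 0),
    vertical = couch_spec(cols0, spec$couch_height_px,
                          couch_profile = round(seq(1150, 1250,
                            length.out = spec$couch_height_px)), pad_value = 0),
    horizontal = couch_spec(spec$target_width, 0L, pad_value = 0),
    both = couch_spec(spec$target_width, spec$couch_height_px,
                      couch_profile = round(seq(1150, 1250,
                        length.out = spec$couch_height_px)), pad_value = 0))
  cs$isocenter_px <- c(rows0 %/% 2L, cols0 %/% 2L)
  ct_img <- insert_couch(base_img, cs)
  write_blob(ct_img, "uint16", file.path(pdir, paste0(ct_uid, ".img")))

  xml <- c(sprintf('<fullPatient formatVersion="%s">',
                   .version_marker[[spec$version]]),
           "  <briefPatient>",
           sprintf("    <patientID>%s</patientID>", pid),
           sprintf("    <patientName>%s^%s</patientName>", last, first),
           sprintf("    <patientBirthDate>%s</patientBirthDate>",
                   format(as.Date("1940-01-01") + p * 137, "%Y-%m-%d")),
           sprintf("    <patientSex>%s</patientSex>", c("F", "M")[p %% 2 + 1]),
           "  </briefPatient>",
           "  <fullImageDataArray>")
  image_fragment <- function(uid, type, img, dt, series_uid, fraction, iso) {
    c("    <fullImageData>",
      sprintf("      <dbInfo><databaseUID>%s</databaseUID></dbInfo>", uid),
      sprintf("      <imageType>%s</imageType>", type),
      sprintf("      <acquisitionDateTime>%s</acquisitionDateTime>", fmt_iso(dt)),
      sprintf("      <studyUID>%s</studyUID>", study_uid),
      sprintf("      <seriesUID>%s</seriesUID>", series_uid),
      sprintf("      <frameOfReferenceUID>%s</frameOfReferenceUID>", frame_uid),
      sprintf("      <fractionNumber>%d</fractionNumber>", fraction),
      sprintf('      <arrayHeader dtype="uint16" dimX="%d" dimY="%d" dimZ="1" kind="img"/>',
              ncol(img), nrow(img)),
      "      <pixelSpacing>0.754 0.754</pixelSpacing>",
      "      <sliceThickness>2.5</sliceThickness>",
      "      <rescaleIntercept>-1024</rescaleIntercept>",
      sprintf("      <isocenterRow>%d</isocenterRow>", iso[1]),
      sprintf("      <isocenterCol>%d</isocenterCol>", iso[2]),
      "    </fullImageData>")
  }
  iso_ct <- attr(ct_img, "isocenter_px")
  xml <- c(xml, image_fragment(ct_uid, "KVCT", ct_img, t0, ct_series_uid, 0L,
                               iso_ct))

  mvct <- list()
  for (f in seq_len(spec$n_fractions)) {
    muid <- new_uid(); mseries <- new_uid()
    mimg <- ellipse_phantom(rows0, cols0, body_value = 1054)
    write_blob(mimg, "uint16", file.path(pdir, paste0(muid, ".img")))
    mdt <- t0 + f * spec$scan_interval_s
    xml <- c(xml, image_fragment(muid, "MVCT", mimg, mdt, mseries, f,
                                 c(rows0 %/% 2L, cols0 %/% 2L)))
    mvct[[f]] <- list(uid = muid, series_uid = mseries, fraction = f,
                      rows = nrow(mimg), cols = ncol(mimg),
                      datetime = fmt_iso(mdt))
  }
  xml <- c(xml, "  </fullImageDataArray>")

  # doses -------------------------------------------------------------------
  plan_uid <- new_uid()
  xml <- c(xml, "  <fullDoseDataArray>")
  doses <- list()
  dose_fragment <- function(uid, type, field, ref_series, fraction) {
    c("    <fullDoseData>",
      sprintf("      <dbInfo><databaseUID>%s</databaseUID></dbInfo>", uid),
      sprintf("      <doseType>%s</doseType>", type),
      sprintf("      <referencedPlanUID>%s</referencedPlanUID>", plan_uid),
      sprintf("      <referencedSeriesUID>%s</referencedSeriesUID>", ref_series),
      sprintf("      <fractionNumber>%d</fractionNumber>", fraction),
      sprintf('      <arrayHeader dtype="float32" dimX="%d" dimY="%d" dimZ="%d" kind="bin"/>',
              dim(field)[2], dim(field)[1], dim(field)[3]),
      "      <gridSpacing>2.5 2.5 2.5</gridSpacing>",
      "      <gridOrigin>-40 -40 -20</gridOrigin>",
      "    </fullDoseData>")
  }
  make_dose <- function(type, ref_series, fraction) {
    uid <- new_uid()
    max_dose <- stats::runif(1, 0.5, 80)
    field <- gaussian_sum_field(spec$dose_shape)
    field <- as_f32(field / max(field) * max_dose)
    write_blob(field, "float32", file.path(pdir, paste0(uid, ".bin")))
    doses[[length(doses) + 1L]] <<- list(
      uid = uid, type = type, fraction = fraction, max_dose = max(field),
      sf = max(field) / 65535, dim = dim(field),
      referenced_plan = plan_uid, referenced_series = ref_series)
    dose_fragment(uid, type, field, ref_series, fraction)
  }
  xml <- c(xml, make_dose("PLAN", ct_series_uid, 0L))
  if (spec$include_adaptive_dose)
    for (f in seq_len(spec$n_fractions))
      xml <- c(xml, make_dose("QA", mvct[[f]]$series_uid, f))
  xml <- c(xml, "  </fullDoseDataArray>")

  # plan + sinograms ---------------------------------------------------------
  sino_uid <- new_uid()
  fr <- smooth_fractions(spec$n_projections, spec$open_leaves)
  sg3 <- plan_sinogram_v3(fr)
  if (spec$version == "V3") {
    write_blob(fr, "float32", file.path(pdir, paste0(sino_uid, ".bin")))
    sino_dims <- c(nrow(fr), MLC_N_LEAVES)
    sino_dtype <- "float32"
    open_attr <- character(0)
  } else {
    sg4 <- encode_sinogram_v4(sg3, warmup_s = spec$warmup_s,
                              projection_duration_s = spec$projection_duration_s)
    write_blob(sg4$events, "float64", file.path(pdir, paste0(sino_uid, ".bin")))
    sino_dims <- dim(sg4$events)
    sino_dtype <- "float64"
    open_attr <- sprintf("        <openLeafIndices>%s</openLeafIndices>",
                         paste(sg4$open_leaf_indices, collapse = " "))
  }
  xml <- c(xml, "  <fullPlanDataArray>", "    <fullPlanData>",
           sprintf("      <dbInfo><databaseUID>%s</databaseUID></dbInfo>", plan_uid),
           sprintf("      <planLabel>HELICAL_%d</planLabel>", p),
           sprintf("      <planDateTime>%s</planDateTime>", fmt_iso(t0)),
           sprintf("      <frameOfReferenceUID>%s</frameOfReferenceUID>", frame_uid),
           sprintf("      <referencedSeriesUID>%s</referencedSeriesUID>", ct_series_uid),
           "      <planSinogram>",
           sprintf("        <dbInfo><databaseUID>%s</databaseUID></dbInfo>", sino_uid),
           sprintf('        <arrayHeader dtype="%s" dimX="%d" dimY="%d" dimZ="1" kind="bin"/>',
                   sino_dtype, sino_dims[2], sino_dims[1]),
           sprintf("        <nProjections>%d</nProjections>", spec$n_projections),
           sprintf("        <projectionDuration>%s</projectionDuration>",
                   fmt_num(spec$projection_duration_s)),
           sprintf("        <warmupDuration>%s</warmupDuration>",
                   fmt_num(spec$warmup_s)),
           open_attr,
           "      </planSinogram>")
  delivery <- list()
  if (spec$include_delivery_sinogram) {
    xml <- c(xml, "      <deliverySinogramArray>")
    for (f in seq_len(spec$n_fractions)) {
      duid <- new_uid()
      det <- as_f32(matrix(stats::runif(spec$n_channels * spec$n_projections,
                                        0.01, 1.2),
                           spec$n_channels, spec$n_projections))
      write_blob(det, "float32", file.path(pdir, paste0(duid, ".dpe")))
      xml <- c(xml, "        <deliverySinogram>",
               sprintf("          <dbInfo><databaseUID>%s</databaseUID></dbInfo>", duid),
               sprintf("          <fractionNumber>%d</fractionNumber>", f),
               sprintf('          <arrayHeader dtype="float32" dimX="%d" dimY="%d" dimZ="1" kind="dpe"/>',
                       spec$n_projections, spec$n_channels),
               "        </deliverySinogram>")
      delivery[[f]] <- list(uid = duid, fraction = f,
                            channels = spec$n_channels,
                            projections = spec$n_projections,
                            max_value = max(det))
    }
    xml <- c(xml, "      </deliverySinogramArray>")
  }
  struct_uid <- new_uid()
  xml <- c(xml, "      <structureSet>",
           sprintf("        <dbInfo><databaseUID>%s</databaseUID></dbInfo>", struct_uid),
           '        <roi number="1" name="BODY"/>',
           '        <roi number="2" name="PTV"/>',
           "      </structureSet>",
           "    </fullPlanData>", "  </fullPlanDataArray>")

  # corrections ---------------------------------------------------------------
  n_corr <- spec$n_fractions
  n_broken <- round(n_corr * spec$broken_link_fraction)
  broken <- if (n_broken > 0) sample(n_corr, n_broken) else integer(0)
  xml <- c(xml, "  <fullCorrelationDataArray>")
  corrections <- list()
  for (f in seq_len(n_corr)) {
    cuid <- new_uid()
    ts <- iso_to_posix(mvct[[f]]$datetime) +
      round(stats::runif(1, -spec$correction_jitter_s, spec$correction_jitter_s))
    tr <- round(stats::runif(3, -5, 5), 2)
    rot <- round(stats::runif(3, -3, 3), 2)
    link_line <- if (f %in% broken) character(0) else
      sprintf("      <linkedScanUID>%s</linkedScanUID>", mvct[[f]]$uid)
    xml <- c(xml, "    <fullCorrelationData>",
             sprintf("      <dbInfo><databaseUID>%s</databaseUID></dbInfo>", cuid),
             link_line,
             sprintf("      <timestamp>%s</timestamp>", fmt_iso(ts)),
             sprintf("      <lateral>%s</lateral>", fmt_num(tr[1])),
             sprintf("      <longitudinal>%s</longitudinal>", fmt_num(tr[2])),
             sprintf("      <vertical>%s</vertical>", fmt_num(tr[3])),
             sprintf("      <roll>%s</roll>", fmt_num(rot[1])),
             sprintf("      <pitch>%s</pitch>", fmt_num(rot[2])),
             sprintf("      <yaw>%s</yaw>", fmt_num(rot[3])),
             "    </fullCorrelationData>")
    corrections[[f]] <- list(uid = cuid, true_scan_uid = mvct[[f]]$uid,
                             link_broken = f %in% broken,
                             timestamp = fmt_iso(ts),
                             translations = tr, rotations = rot)
  }
  xml <- c(xml, "  </fullCorrelationDataArray>", "</fullPatient>")
  writeLines(xml, file.path(pdir, "patient.xml"))

  list(patient_id = pid, first_name = first, last_name = last,
       version = spec$version, study_uid = study_uid, frame_uid = frame_uid,
       plan_ct = list(uid = ct_uid, series_uid = ct_series_uid,
                      rows = nrow(ct_img), cols = ncol(ct_img),
                      scenario = spec$couch_scenario,
                      isocenter = as.integer(iso_ct), datetime = fmt_iso(t0)),
       mvct = mvct,
       plan = list(uid = plan_uid, sinogram_uid = sino_uid,
                   struct_uid = struct_uid,
                   n_projections = spec$n_projections,
                   projection_duration_s = spec$projection_duration_s,
                   warmup_s = spec$warmup_s,
                   open_leaves = as.integer(spec$open_leaves),
                   layout = if (spec$version == "V3") "V3" else "V4",
                   sinogram_rows = sino_dims[1],
                   leaf_total_open_s = colSums(fr) * spec$projection_duration_s),
       doses = doses, delivery = delivery, corrections = corrections)
}

#' Generate the relational fixture matching an archive
#'
#' Emits CSV tables `Patient`, `DCMStudy`, `DCMSeries`, `TreatmentList`
#' whose rows are consistent with the archive generated from the same
#' seed, so the SQL and XPath backends can be driven from the same ground
#' truth.  DICOM UIDs serve as the foreign keys (`DCMStudy_ID`,
#' `ImageSeriesUID`) so that staged evaluation can bind earlier-resolved
#' tags directly.
#'
#' @param manifest Manifest list from [generate_archive()].
#' @param dir Output directory for the CSV tables.
#' @export
generate_sql_fixture <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- manifest$patients
  patient <- data.frame(
    ID = vapply(pats, `[[`, "", "patient_id"),
    Pat_ID1 = seq_along(pats),
    FIRST_NAME = vapply(pats, `[[`, "", "first_name"),
    LAST_NAME = vapply(pats, `[[`, "", "last_name"),
    stringsAsFactors = FALSE)
  study <- data.frame(
    Pat_ID1 = seq_along(pats),
    StudyInstanceUID = vapply(pats, `[[`, "", "study_uid"),
    stringsAsFactors = FALSE)
  series <- data.frame(
    DCMStudy_ID = vapply(pats, `[[`, "", "study_uid"),
    SeriesInstanceUID = vapply(pats, function(p) p$plan_ct$series_uid, ""),
    stringsAsFactors = FALSE)
  treatment <- data.frame(
    ID = vapply(pats, `[[`, "", "patient_id"),
    ImageSeriesUID = vapply(pats, function(p) p$plan_ct$series_uid, ""),
    PlanInstanceUID = vapply(pats, function(p) p$plan$uid, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(patient, file.path(dir, "Patient.csv"), row.names = FALSE)
  utils::write.csv(study, file.path(dir, "DCMStudy.csv"), row.names = FALSE)
  utils::write.csv(series, file.path(dir, "DCMSeries.csv"), row.names = FALSE)
  utils::write.csv(treatment, file.path(dir, "TreatmentList.csv"),
                   row.names = FALSE)
  invisible(dir)
}
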