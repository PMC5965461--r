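tm_path <- function(ty) system.file("tagmaps", paste0(ty, ".xml"),
                                    package = "tagmapr")

build_one <- function(ty, arch, ...) {
  ctx <- binding_context(c(list(patientID = arch$patient_ids[1]), list(...)))
  build_object(parse_tagmap(tm_path(ty)), arch, ctx)
}

test_that("RT-Dose objects carry DoseGridScaling = max dose / 65535 and bounded error", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 61L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  ds <- build_one("RTDOSE", arch)
  expect_identical(attr(ds, "completeness"), "COMPLETE")
  plan_dose <- pm$doses[[1]]
  sf <- as.numeric(dcm_get(ds, "3004000E"))
  expect_equal(sf, plan_dose$max_dose / 65535, tolerance = 1e-9)
  expect_identical(as.integer(dcm_get(ds, "00280008")), plan_dose$dim[3])
  # reconstructed voxels match the archived grid within SF/2 (0.001% of max)
  pix <- unpack_u16(dcm_get(ds, "7FE00010"))
  orig <- read_blob(resolve_uid(arch, plan_dose$uid))
  recon <- array(NA_real_, dim = dim(orig))
  for (k in seq_len(dim(orig)[3]))
    recon[, , k] <- matrix(pix[((k - 1) * prod(dim(orig)[1:2]) + 1):
                               (k * prod(dim(orig)[1:2]))],
                           nrow = dim(orig)[1], byrow = TRUE)
  expect_lte(max(abs(recon * sf - orig)), sf / 2)
  expect_lte(max(abs(recon * sf - orig)) / max(orig) * 100, 0.001)
  # the dose references the plan object
  item <- dcm_get(ds, "300C0002")[[1]]
  expect_identical(as.character(dcm_get(item, "00081155")), pm$plan$uid)
  unlink(dir, recursive = TRUE)
})

test_that("stored plan-CT slices export padded to square with inherited pixels intact", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 62L, base_image_shape = c(40L, 40L),
                    target_width = 56L, couch_height_px = 6L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  ds <- build_one("CT", arch)
  side <- max(pm$plan_ct$rows, pm$plan_ct$cols)   # stored 46 x 56 -> 56 x 56
  expect_identical(as.integer(dcm_get(ds, "00280010")), side)
  expect_identical(as.integer(dcm_get(ds, "00280011")), side)
  pix <- matrix(unpack_u16(dcm_get(ds, "7FE00010")), side, side, byrow = TRUE)
  stored <- read_blob(resolve_uid(arch, pm$plan_ct$uid))
  expect_identical(pix[seq_len(nrow(stored)), seq_len(ncol(stored))],
                   stored[, ])
  # MVCT build selected by scan UID
  mv <- build_one("MVCT", arch, scanUID = pm$mvct[[1]]$uid)
  expect_identical(as.character(dcm_get(mv, "00080018")), pm$mvct[[1]]$uid)
  expect_identical(dcm_get(mv, "0008103E"), "MVCT")
  unlink(dir, recursive = TRUE)
})

test_that("a version-scoped TagMap refuses a foreign-version archive before evaluating", {
  dir <- tempfile()
  make_archive(dir, seed = 63L, version = "V4_2PLUS")
  arch <- load_archive(dir)
  v3only <- parse_tagmap(
    "<dicom target='RTPLAN' versions='V3'><attr tag='300A0002' vr='SH' src='literal'>X</attr></dicom>")
  expect_error(build_object(v3only, arch,
                            binding_context(list(patientID = "TL0001"))),
               "version mismatch")
  unlink(dir, recursive = TRUE)
})

test_that("QADose references the fraction's MVCT series and degrades to INCOMPLETE", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 64L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  qd <- build_qadose(parse_tagmap(tm_path("QADOSE")), arch, "TL0001", 2L)
  expect_identical(attr(qd, "completeness"), "COMPLETE")
  ref <- dcm_get(dcm_get(qd, "00081140")[[1]], "00081155")
  expect_identical(as.character(ref), pm$mvct[[2]]$series_uid)
  qa_dose <- Filter(function(d) d$type == "QA" && d$fraction == 2, pm$doses)[[1]]
  sf <- as.numeric(dcm_get(qd, "3004000E"))
  expect_equal(65535 * sf, qa_dose$max_dose, tolerance = 1e-9)
  # no adaptive dose stored -> INCOMPLETE with reasons recorded
  dir2 <- tempfile()
  make_archive(dir2, seed = 65L, include_adaptive_dose = FALSE)
  arch2 <- load_archive(dir2)
  qd2 <- suppressMessages(
    build_qadose(parse_tagmap(tm_path("QADOSE")), arch2, "TL0001", 1L))
  expect_identical(attr(qd2, "completeness"), "INCOMPLETE")
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("delivery sinograms export channels x projections with bounded rescale error", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 66L, n_fractions = 1L, n_channels = 640L,
                    n_projections = 200L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  ds <- build_delivery_sinogram(parse_tagmap(tm_path("DELIVERY_SINOGRAM")),
                                arch, "TL0001", 1L)
  expect_identical(as.integer(dcm_get(ds, "00280010")), 640L)
  expect_identical(as.integer(dcm_get(ds, "00280011")), 200L)
  slope <- as.numeric(dcm_get(ds, "00281053"))
  expect_equal(65535 * slope, pm$delivery[[1]]$max_value, tolerance = 1e-9)
  pix <- matrix(unpack_u16(dcm_get(ds, "7FE00010")), 640, 200, byrow = TRUE)
  det <- read_blob(resolve_uid(arch, pm$delivery[[1]]$uid))
  # slope is carried in a 10-significant-digit decimal string; its rounding
  # adds up to max(det) * 1e-9 on top of the slope/2 quantization bound
  expect_lte(max(abs(pix * slope - det)), slope / 2 + max(det) * 1e-9)
  # absent .dpe payload -> INCOMPLETE
  file.remove(file.path(dir, "TL0001", paste0(pm$delivery[[1]]$uid, ".dpe")))
  arch2 <- load_archive(dir)
  ds2 <- build_delivery_sinogram(parse_tagmap(tm_path("DELIVERY_SINOGRAM")),
                                 arch2, "TL0001", 1L)
  expect_identical(attr(ds2, "completeness"), "INCOMPLETE")
  unlink(dir, recursive = TRUE)
})

test_that("corrections embed as a private block and survive a write/read cycle", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 67L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  mv <- build_one("MVCT", arch, scanUID = pm$mvct[[1]]$uid)
  rec <- correlation_record("1.9.9", pm$mvct[[1]]$uid,
                            "2011-03-02T09:16:40", c(1.2, -3.4, 0),
                            c(0.5, -0.25, 1))
  before <- names(mv$elements)
  out <- embed_corrections(mv, rec, "TIMESTAMP")
  expect_identical(dcm_get(out, "77710010"), "TAGMAP-CORR")
  expect_identical(dcm_get(out, "77711004"), "TIMESTAMP")
  for (tag in before)   # public elements untouched
    expect_identical(out$elements[[tag]], mv$elements[[tag]])
  path <- tempfile(fileext = ".dcm")
  dcm_write_file(out, path)
  back <- dcm_read_file(path)
  expect_identical(as.numeric(dcm_get(back, "77711001")), c(1.2, -3.4, 0))
  expect_identical(as.numeric(dcm_get(back, "77711002")), c(0.5, -0.25, 1))
  expect_identical(dcm_get(back, "77711003"), "20110302091640")
  # UNLINKED records write no block
  none <- suppressMessages(embed_corrections(mv, rec, "UNLINKED"))
  expect_false(dcm_has(none, "77710010"))
  expect_error(embed_corrections(
    build_one("RTPLAN", arch), rec, "UID"), "MVCT")
  unlink(dir, recursive = TRUE)
})

test_that("UID assignment is deterministic, closed over references, and catches danglers", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 68L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  objs <- list(
    CT = build_one("CT", arch),
    MVCT = build_one("MVCT", arch, scanUID = pm$mvct[[1]]$uid),
    RTPLAN = build_one("RTPLAN", arch),
    RTDOSE = build_one("RTDOSE", arch),
    RTSTRUCT = build_one("RTSTRUCT", arch))
  a <- assign_uids(objs, seed = 5L)
  expect_identical(nrow(uid_reference_graph(a)), 0L)
  b <- assign_uids(objs, seed = 5L)
  expect_identical(
    sort(unlist(lapply(a, function(o) dcm_get(o, "00080018")))),
    sort(unlist(lapply(b, function(o) dcm_get(o, "00080018")))))
  c_ <- assign_uids(objs, seed = 6L)
  expect_false(any(dcm_get(a$CT, "00080018") == dcm_get(c_$CT, "00080018")))
  # standard SOP class UIDs are never remapped
  item <- dcm_get(a$RTDOSE, "300C0002")[[1]]
  expect_identical(dcm_get(item, "00081150"), "1.2.840.10008.5.1.4.1.1.481.5")
  # removing the referenced plan leaves the dose dangling
  expect_error(assign_uids(objs[c("CT", "RTDOSE")], seed = 5L),
               "dangling UID reference")
  unlink(dir, recursive = TRUE)
})

test_that("strict export policy suppresses INCOMPLETE objects", {
  dir <- tempfile()
  make_archive(dir, seed = 69L, include_adaptive_dose = FALSE)
  arch <- load_archive(dir)
  qd <- suppressMessages(
    build_qadose(parse_tagmap(tm_path("QADOSE")), arch, "TL0001", 1L))
  path <- tempfile(fileext = ".dcm")
  expect_false(suppressMessages(write_dicom(qd, path, policy = "strict")))
  expect_false(file.exists(path))
  expect_true(write_dicom(qd, path, policy = "lenient"))
  expect_true(file.exists(path))
  unlink(dir, recursive = TRUE)
})
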