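record_map_path <- function(which = "sql")
  system.file("tagmaps", paste0("RTRECORD.", which, ".xml"), package = "tagmapr")

test_that("the treatment-record TagMap parses: order, classification, one-item template", {
  tm <- parse_tagmap(record_map_path("sql"))
  expect_identical(tm$target_type, "RTRECORD")
  expect_identical(vapply(tm$entries, `[[`, "", "tag"),
                   c("00100010", "0020000D", "0020000E", "300C0002"))
  expect_true(all(vapply(tm$entries[1:3], `[[`, TRUE, "is_query")))
  sq <- tm$entries[[4]]
  expect_identical(sq$vr, "SQ")
  expect_length(sq$children, 2)
  expect_false(sq$children[[1]]$is_query)   # constant SOP Class UID
  expect_identical(sq$children[[1]]$payload, "1.2.840.10008.5.1.4.1.1.481.5")
  expect_true(sq$children[[2]]$is_query)
  expect_identical(sq$children[[2]]$params, c("input:patientID", "tag:0020000E"))
})

test_that("TagMap parse errors name the offending construct", {
  expect_length(parse_tagmap("<dicom target='RTRECORD'/>")$entries, 0)
  expect_error(parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='00100010' vr='PN'>A</attr><attr tag='00100010' vr='PN'>B</attr></dicom>"),
    "duplicate tag 00100010")
  expect_error(parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='XYZ' vr='PN'>A</attr></dicom>"),
    "malformed DICOM tag")
  expect_error(parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='300C0002' vr='SQ'><item/><item/></attr></dicom>"),
    "exactly one <item>")
  expect_error(parse_tagmap("<tagmap/>"), "root element must be <dicom>")
})

test_that("skeletons keep literals final and queries as placeholders", {
  tm <- parse_tagmap(record_map_path("sql"))
  sk <- build_skeleton(tm)
  expect_s3_class(sk$elements[["00100010"]]$value, "tm_query")
  expect_s3_class(sk$elements[["300C0002"]]$value, "tm_sequence")
  lit <- parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='00080060' vr='CS' src='literal'>CT</attr></dicom>")
  sk2 <- build_skeleton(lit)
  expect_identical(dcm_get(sk2, "00080060"), "CT")
  expect_length(build_skeleton(parse_tagmap("<dicom target='RTRECORD'/>"))$elements, 0)
})

test_that("sequence expansion copies the template with $i bound 1-based", {
  tm <- parse_tagmap(paste0(
    "<dicom target='RTRECORD'><attr tag='30060020' vr='SQ' count='count(//roi)'>",
    "<item><attr tag='30060022' vr='IS'>//roi[$i]/@number</attr></item>",
    "</attr></dicom>"))
  entry <- tm$entries[[1]]
  items <- expand_sequence(entry, 3)
  expect_length(items, 3)
  expect_identical(vapply(items, function(it) it[[1]]$payload, ""),
                   sprintf("//roi[%d]/@number", 1:3))
  expect_length(expand_sequence(entry, 0), 0)
  expect_length(expand_sequence(entry, 1), 1)   # the stated default count
  expect_error(expand_sequence(entry, -2), "negative")
})

test_that("XPath evaluation fills manifest values, marks payload UIDs, flags Type-1 gaps", {
  dir <- tempfile()
  g <- make_archive(dir, seed = 21L)
  arch <- load_archive(dir)
  pm <- g$manifest$patients$TL0001
  tm <- parse_tagmap(system.file("tagmaps", "CT.xml", package = "tagmapr"))
  ctx <- binding_context(list(patientID = "TL0001"))
  ds <- evaluate(build_skeleton(tm), xpath_backend(arch, "TL0001"), ctx, "CT")
  expect_identical(attr(ds, "completeness"), "COMPLETE")
  expect_identical(dcm_get(ds, "00100010"), paste0(pm$last_name, "^", pm$first_name))
  expect_identical(dcm_get(ds, "0020000D"), pm$study_uid)
  expect_identical(as.character(dcm_get(ds, "00080018")), pm$plan_ct$uid)
  expect_identical(attr(dcm_get(ds, "7FE00010"), "blob_uid"), pm$plan_ct$uid)
  # skeleton of only literals returns unchanged
  lit <- parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='00080060' vr='CS' src='literal'>CT</attr></dicom>")
  sk <- build_skeleton(lit)
  expect_true(dcm_equal(evaluate(sk, xpath_backend(arch, "TL0001"),
                                 binding_context(), "RTRECORD"), sk))
  # a query missing its target degrades to INCOMPLETE with one recorded failure
  bad <- parse_tagmap(
    "<dicom target='CT'><attr tag='00080018' vr='UI'>/fullPatient/noSuchNode/uid</attr></dicom>")
  ds2 <- evaluate(build_skeleton(bad), xpath_backend(arch, "TL0001"),
                  binding_context(), "CT")
  expect_identical(attr(ds2, "completeness"), "INCOMPLETE")
  expect_identical(attr(ds2, "failures"), "00080018")
  unlink(dir, recursive = TRUE)
})

test_that("the SQL subset evaluates joins, placeholders and row-count contracts", {
  be <- sql_backend(list(
    Patient = data.frame(ID = c("P1", "P2"), Pat_ID1 = c("1", "2"),
                         FIRST_NAME = c("Ann", "Ben"),
                         LAST_NAME = c("Smith", "Stone")),
    DCMStudy = data.frame(Pat_ID1 = c("1", "2"),
                          StudyInstanceUID = c("1.2.3.10", "1.2.3.20"))))
  out <- evaluate_sql("SELECT FIRST_NAME, LAST_NAME FROM Patient WHERE Patient.ID = ?",
                      list("P1"), be)
  expect_identical(unlist(out, use.names = FALSE), c("Ann", "Smith"))
  # PN coercion: two name columns concatenate family-name first
  expect_identical(coerce_vr(unlist(out), "PN", "00100010"), "Smith^Ann")
  out2 <- evaluate_sql(
    "SELECT s.StudyInstanceUID FROM DCMStudy S INNER JOIN Patient P ON P.Pat_ID1 AND P.ID = ?",
    list("P2"), be)
  expect_identical(out2$StudyInstanceUID, "1.2.3.20")
  expect_error(evaluate_sql("SELECT ID FROM Patient WHERE ID = ?", list(), be),
               "binding count mismatch")
  expect_error(evaluate_sql("DROP TABLE Patient", list(), be), "unsupported SQL")
  # >1 row where the engine expects a scalar
  tm <- parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='00100020' vr='LO' src='query'>SELECT ID FROM Patient</attr></dicom>")
  expect_error(evaluate(build_skeleton(tm), be, binding_context(), "RTRECORD"),
               "2 rows")
})

test_that("staged evaluation chains patient->study->series->plan and both backends agree", {
  dir <- tempfile(); sqldir <- tempfile()
  g <- make_archive(dir, seed = 33L)
  generate_sql_fixture(g$manifest, sqldir)
  pm <- g$manifest$patients$TL0001
  ctx <- binding_context(list(patientID = "TL0001"))
  sql_ds <- evaluate(build_skeleton(parse_tagmap(record_map_path("sql"))),
                     sql_backend(sqldir), ctx, "RTRECORD")
  expect_identical(attr(sql_ds, "completeness"), "COMPLETE")
  expect_identical(dcm_get(sql_ds, "0020000D"), pm$study_uid)
  expect_identical(dcm_get(sql_ds, "0020000E"), pm$plan_ct$series_uid)
  item <- dcm_get(sql_ds, "300C0002")[[1]]
  expect_identical(dcm_get(item, "00081150"), "1.2.840.10008.5.1.4.1.1.481.5")
  expect_identical(dcm_get(item, "00081155"), pm$plan$uid)
  # the same records served over XPath yield an identical dataset
  arch <- load_archive(dir)
  x_ds <- evaluate(build_skeleton(parse_tagmap(record_map_path("xpath"))),
                   xpath_backend(arch, "TL0001"),
                   binding_context(list(patientID = "TL0001")), "RTRECORD")
  expect_true(dcm_equal(sql_ds, x_ds))
  # binding an unresolved tag is an explicit staging error
  broken <- parse_tagmap(
    "<dicom target='RTRECORD'><attr tag='0020000E' vr='UI' params='tag:0020000D' src='query'>SELECT SeriesInstanceUID FROM DCMSeries D WHERE D.DCMStudy_ID = ?</attr></dicom>")
  expect_error(evaluate(build_skeleton(broken), sql_backend(sqldir),
                        binding_context(), "RTRECORD"), "unresolved tag")
  unlink(c(dir, sqldir), recursive = TRUE)
})

test_that("evaluation is deterministic and independent of non-dependent entry order", {
  dir <- tempfile()
  make_archive(dir, seed = 55L)
  arch <- load_archive(dir)
  tm <- parse_tagmap(system.file("tagmaps", "CT.xml", package = "tagmapr"))
  ev <- function(t) evaluate(build_skeleton(t), xpath_backend(arch, "TL0001"),
                             binding_context(list(patientID = "TL0001")), "CT")
  a <- ev(tm); b <- ev(tm)
  expect_true(dcm_equal(a, b))
  # the CT map has no tag: dependencies; reverse its entry order
  tm_rev <- tm
  tm_rev$entries <- rev(tm$entries)
  c_ <- ev(tm_rev)
  for (tag in names(a$elements))
    expect_identical(as.character(dcm_get(a, tag)),
                     as.character(dcm_get(c_, tag)))
  unlink(dir, recursive = TRUE)
})
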