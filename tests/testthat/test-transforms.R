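test_that("scale factor follows its definition and handles degenerate grids", {
  for (k in c(1e-4, 0.5, 1, 2.37)) {
    g <- array(c(0, 1, 65535 * k), dim = c(3, 1, 1))
    expect_equal(compute_scale_factor(g), k)
  }
  zero <- array(0, dim = c(4, 4, 2))
  expect_identical(compute_scale_factor(zero), 1)
  sd0 <- quantize_dose(zero, compute_scale_factor(zero))
  expect_true(all(sd0$voxels16 == 0))
  expect_error(compute_scale_factor(array(c(1, -0.1), 2)), "negative")
  expect_error(compute_scale_factor(array(c(1, NaN), 2)), "non-finite")
})

test_that("vectorized quantization is bit-identical to a per-voxel loop", {
  set.seed(42)
  for (rep in 1:5) {
    g <- array(runif(6 * 5 * 4, 0, 70), dim = c(6, 5, 4))
    sf <- compute_scale_factor(g)
    sd <- quantize_dose(g, sf)
    expect_identical(as.vector(sd$voxels16), as.vector(quantize_oracle(g, sf)))
  }
  # hottest voxel hits the top of the 16-bit range exactly
  g <- array(c(13.1, 26.2, 65.5), 3)
  sd <- quantize_dose(g, compute_scale_factor(g))
  expect_identical(max(sd$voxels16), 65535)
  expect_equal(dequantize_dose(sd)[3], 65.5)
})

test_that("quantization round-trip error stays below SF/2 and 0.001% of max dose", {
  set.seed(7)
  for (rep in 1:20) {
    g <- synthetic_dose_grid(c(16L, 16L, 8L), max_dose = runif(1, 0.05, 80))
    sf <- compute_scale_factor(g)
    err <- max(abs(dequantize_dose(quantize_dose(g, sf)) - g))
    expect_lte(err, sf / 2)
    expect_lte(err / max(g) * 100, 0.001)
  }
})

test_that("sinogram layout detection cross-checks dtype against archive version", {
  f32 <- matrix(runif(64 * 5), 5, 64); attr(f32, "dtype") <- "float32"
  f64 <- matrix(runif(10), 2, 5); attr(f64, "dtype") <- "float64"
  expect_identical(detect_sinogram_version(f32, storage_version("V3")), "V3-layout")
  expect_identical(detect_sinogram_version(f64, storage_version("V4_2PLUS")), "V4-layout")
  expect_identical(detect_sinogram_version(f64, storage_version("V4_0")), "V4-layout")
  expect_error(detect_sinogram_version(f64, storage_version("V3")), "inconsistent")
  expect_error(detect_sinogram_version(f32, storage_version("V4_2PLUS")), "inconsistent")
})

test_that("event-list decoding matches exact geometry and the 1 ms sampling oracle", {
  # one leaf open exactly one full projection window
  ev <- matrix(c(10.4, 10.8), nrow = 2)
  sg <- plan_sinogram_v4(ev, 20L, warmup_s = 10, projection_duration_s = 0.4)
  fr <- decode_sinogram_v4(sg, 4L)$fractions
  expect_equal(fr[2, 20], 1.0)
  expect_equal(sum(fr), 1.0)
  # all 64 leaves present, closed ones zero; height = 2 x open leaves
  set.seed(31)
  base <- plan_sinogram_v3(local({
    m <- matrix(0, 12, 64); m[, 11:52] <- runif(12 * 42, 0.05, 1); m
  }))
  sg4 <- encode_sinogram_v4(base, warmup_s = 10, projection_duration_s = 0.5)
  expect_identical(nrow(sg4$events), 84L)
  dec <- decode_sinogram_v4(sg4, 12L)
  expect_true(all(dec$fractions[, c(1:10, 53:64)] == 0))
  expect_equal(dec$fractions, base$fractions, tolerance = 1e-9)
  # random event sets vs brute-force time sampling
  oracle <- sampling_oracle(sg4, 12L)
  expect_lt(max(abs(dec$fractions - oracle)), 2 * 0.001 / 0.5)
  # malformed event lists fail loudly
  late <- matrix(c(10.0, 30.0), nrow = 2)
  expect_error(decode_sinogram_v4(
    plan_sinogram_v4(late, 1L, 10, 0.4), 4L), "beyond treatment end")
  expect_error(plan_sinogram_v4(matrix(c(10.0, 10.5, 10.3, 10.8), nrow = 2),
                                1L, 10, 0.4), "interleave")
})

test_that("per-leaf open time is conserved through decoding", {
  set.seed(13)
  m <- matrix(0, 10, 64); m[, 15:40] <- runif(260, 0, 1)
  sg3 <- plan_sinogram_v3(m)
  tau <- 0.3
  sg4 <- encode_sinogram_v4(sg3, warmup_s = 10, projection_duration_s = tau)
  dec <- decode_sinogram_v4(sg4, 10L)
  total_from_events <- vapply(seq_along(sg4$open_leaf_indices), function(k) {
    op <- sg4$events[2 * k - 1, ]; cl <- sg4$events[2 * k, ]
    sum(cl - op, na.rm = TRUE)
  }, 0)
  total_from_fractions <- colSums(dec$fractions)[sg4$open_leaf_indices] * tau
  expect_equal(total_from_fractions, total_from_events, tolerance = 1e-6)
})

test_that("sinogram payload encoding round-trips, including through an RT-Plan file", {
  set.seed(5)
  m <- matrix(0, 8, 64); m[, 11:52] <- runif(8 * 42)
  m <- matrix(unpack_f32(pack_f32(m)), 8, 64)   # float32-representable
  sg3 <- plan_sinogram_v3(m)
  payload <- encode_plan_sinogram_dicom(sg3)
  expect_identical(decode_plan_sinogram_payload(payload, 8L)$fractions, m)
  # v4 composition: encode(decode(v4)) equals direct encode of the fractions
  sg4 <- encode_sinogram_v4(sg3, 10, 0.4)
  expect_equal(encode_plan_sinogram_dicom(decode_sinogram_v4(sg4, 8L)),
               payload)
  # through a written file under the private creator block
  ds <- dcm_set(dcm_dataset(), "00080018", "UI", "1.2.3.4")
  ds <- dcm_set(ds, "300D0010", "LO", "TAGMAP-TOMO")
  ds <- dcm_set(ds, "300D10A7", "OB", payload)
  path <- tempfile(fileext = ".dcm")
  dcm_write_file(ds, path)
  reread <- dcm_get(dcm_read_file(path), "300D10A7")
  expect_identical(decode_plan_sinogram_payload(reread, 8L)$fractions, m)
  expect_error(plan_sinogram_v3(matrix(1.2, 4, 64)), "\\[0, 1\\]")
})

test_that("couch insertion reshapes the canvas and never alters inherited pixels", {
  img <- matrix(sample(0:2000, 256 * 256, replace = TRUE), 256, 256)
  spec <- couch_spec(384L, 28L, couch_profile = rep(1200, 28),
                     isocenter_px = c(128, 128))
  out <- insert_couch(img, spec)
  expect_identical(dim(out), c(284L, 384L))
  off <- attr(out, "block_offset")
  expect_identical(out[1:256, off["col"] + (1:256)], img)
  expect_identical(attr(out, "isocenter_px"), c(128, 128 + off[["col"]]))
  # zero enhancement is the identity
  none <- insert_couch(img, couch_spec(256L, 0L))
  expect_identical(none[, ], img[, ])
  # all four scenarios follow the stated dimension arithmetic
  dims <- list(none = c(40L, 40L), vertical = c(46L, 40L),
               horizontal = c(40L, 56L), both = c(46L, 56L))
  small <- matrix(1:1600, 40, 40)
  for (sc in names(dims)) {
    s <- switch(sc,
      none = couch_spec(40L, 0L), vertical = couch_spec(40L, 6L),
      horizontal = couch_spec(56L, 0L), both = couch_spec(56L, 6L))
    expect_identical(dim(insert_couch(small, s)), dims[[sc]])
  }
  expect_error(insert_couch(img, couch_spec(100L, 0L)), "target_width")
  expect_error(insert_couch(img, couch_spec(256L, 0L,
                                            isocenter_px = c(500, 10))),
               "isocenter")
})

test_that("export padding squares the image, top-aligned, pads below and right", {
  img <- matrix(sample(0:2000, 284 * 384, replace = TRUE), 284, 384)
  out <- pad_for_export(img)
  expect_identical(dim(out), c(384L, 384L))
  expect_identical(out[1:284, ], img)              # top-aligned, bit-identical
  expect_true(all(out[285:384, ] == 0))            # pad rows below
  sq <- matrix(1:16, 4, 4)
  expect_identical(pad_for_export(sq)[, ], sq)     # already square: unchanged
  set.seed(9)
  for (rep in 1:10) {
    h <- sample(5:40, 1); w <- sample(5:40, 1)
    m <- matrix(rnorm(h * w), h, w)
    o <- pad_for_export(m, pad_value = -1)
    side <- max(h, w)
    expect_identical(dim(o), c(side, side))
    off <- attr(o, "block_offset")
    expect_identical(o[1:h, off[["col"]] + (1:w)], m)
    expect_equal(sum(o == -1) + h * w, side * side)
  }
})

test_that("correction relinking: UID kept, fallback within tolerance, ties and conflicts unlinked", {
  scans <- data.frame(
    scan_uid = sprintf("1.2.3.%d", 1:5),
    datetime = iso_to_posix("2011-03-02T09:00:00") + (0:4) * 300)
  rec <- function(uid, link, t_off) correlation_record(
    uid, link, iso_to_posix("2011-03-02T09:00:00") + t_off,
    c(1, 2, 3), c(0, 0, 0))
  out <- relink_corrections(list(
    rec("c1", "1.2.3.9", 0),                  # intact link kept verbatim
    rec("c2", NA, 310),                       # near scan 2 (300 s)
    rec("c3", NA, 36000)),                    # 10 h away from everything
    scans, tolerance_s = 120)
  expect_identical(out$method, c("UID", "TIMESTAMP", "UNLINKED"))
  expect_identical(out$scan_uid[1:2], c("1.2.3.9", "1.2.3.2"))
  # exact tie between two scans
  tie <- relink_corrections(list(rec("c4", NA, 150)), scans, 400)
  expect_identical(tie$method, "UNLINKED")
  # two corrections nearest to the same scan: injectivity demotes both
  conflict <- suppressWarnings(relink_corrections(
    list(rec("c5", NA, 290), rec("c6", NA, 315)), scans, 120))
  expect_identical(conflict$method, c("UNLINKED", "UNLINKED"))
})

test_that("relinking equals the brute-force nearest-in-time oracle on random instances", {
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    scans <- data.frame(
      scan_uid = sprintf("1.2.9.%d", seq_len(n)),
      datetime = iso_to_posix("2011-03-02T08:00:00") +
        sort(sample.int(100000, n)))
    m <- sample(1:20, 1)
    corr <- lapply(seq_len(m), function(i) {
      broken <- runif(1) < 0.6
      k <- sample.int(n, 1)
      correlation_record(sprintf("c%d", i),
                         if (broken) NA_character_ else scans$scan_uid[k],
                         scans$datetime[k] + round(runif(1, -200, 200)),
                         runif(3, -5, 5), runif(3, -3, 3))
    })
    got <- suppressWarnings(relink_corrections(corr, scans, tolerance_s = 120))
    want <- relink_oracle(corr, scans, tolerance_s = 120)
    expect_identical(got, want)
  }
})
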