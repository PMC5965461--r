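# Numeric transformations applied between vendor-style raw storage and
# DICOM-RT: 16-bit dose quantization, plan-sinogram decoding across the two
# storage generations, couch-insertion / export padding of plan CT images,
# and timestamp-fallback relinking of image-guidance corrections.

MLC_N_LEAVES <- 64L

# round half away from zero; doses are non-negative so this is floor(x + 0.5)
round_half_up <- function(x) floor(x + 0.5)

#' Scale factor for 16-bit dose storage
#'
#' The scale factor (Gy per integer unit) is the ratio of the maximum voxel
#' dose to the maximum of the unsigned 16-bit range, `SF = max(D) / 65535`,
#' so that quantizing by division maps the hottest voxel to 65535.  An
#' all-zero grid returns the sentinel `SF = 1`.
#'
#' @param grid Numeric array of absorbed dose in Gy; finite, non-negative.
#' @return Scalar scale factor in Gy.
#' @export
compute_scale_factor <- function(grid) {
  if (any(!is.finite(grid))) stop("dose grid contains non-finite values")
  if (any(grid < 0)) stop("dose grid contains negative values")
  m <- max(grid)
  if (m == 0) 1 else m / 65535
}

#' Quantize and dequantize a dose grid
#'
#' `quantize_dose` packs a float dose grid into unsigned 16-bit integers:
#' `D16 = round(D / SF)` (round half away from zero), clamped to
#' `[0, 65535]`.  `dequantize_dose` reconstructs `D16 * SF`.  The round-trip
#' error is bounded by `SF / 2`, i.e. at most 1/131070 (0.00076%) of the
#' maximum dose when SF is computed by [compute_scale_factor()].
#'
#' @param grid Numeric dose array (Gy).
#' @param sf Positive scale factor (Gy per integer unit).
#' @return `quantize_dose`: a `scaled_dose` (list of integer array
#'   `voxels16` and `scale_factor`); `dequantize_dose`: the numeric array.
#' @export
quantize_dose <- function(grid, sf) {
  if (!is.numeric(sf) || length(sf) != 1 || !is.finite(sf) || sf <= 0)
    stop("scale factor must be a single positive number")
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("dose grid must be finite and non-negative")
  v <- round_half_up(grid / sf)
  clamped <- v > 65535 | v < 0
  if (any(clamped)) {
    message("quantize_dose: ", sum(clamped), " voxel(s) clamped to 16-bit range")
    v <- pmin(pmax(v, 0), 65535)
  }
  storage.mode(v) <- "double"  # keeps 0..65535 exactly; dim preserved
  structure(list(voxels16 = v, scale_factor = sf), class = "scaled_dose")
}

#' @rdname quantize_dose
#' @param sd A `scaled_dose` object.
#' @export
dequantize_dose <- function(sd) {
  stopifnot(inherits(sd, "scaled_dose"))
  sd$voxels16 * sd$scale_factor
}

# ---- plan sinograms -------------------------------------------------------

#' Plan sinogram containers
#'
#' `plan_sinogram_v3` holds per-projection leaf-open-time fractions (one row
#' per projection, 64 columns, values in `[0, 1]`).  `plan_sinogram_v4`
#' holds the later storage generation: cumulative open/close event times in
#' seconds since beam-on (including warm-up) for the leaves that ever open,
#' two rows per open leaf (odd row = opening times, even row = closing
#' times, `NaN`-padded), plus the projection duration and leading warm-up.
#'
#' @param fractions Numeric matrix, `n_projections x 64`, values in `[0,1]`.
#' @export
plan_sinogram_v3 <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != MLC_N_LEAVES)
    stop("plan sinogram must have ", MLC_N_LEAVES, " leaf columns")
  if (any(!is.finite(fractions)) || any(fractions < 0 | fractions > 1))
    stop("open-time fractions must lie in [0, 1]")
  structure(list(fractions = fractions), class = "plan_sinogram_v3")
}

#' @rdname plan_sinogram_v3
#' @param events Numeric matrix `2 * n_open_leaves x n_events` of cumulative
#'   seconds, `NaN`-padded on the right.
#' @param open_leaf_indices Sorted 1-based indices of leaves that ever open.
#' @param warmup_s Leading beam warm-up offset in seconds (default 10).
#' @param projection_duration_s Seconds per projection (control point).
#' @export
plan_sinogram_v4 <- function(events, open_leaf_indices, warmup_s = 10,
                             projection_duration_s) {
  events <- as.matrix(events)
  open_leaf_indices <- as.integer(open_leaf_indices)
  if (is.unsorted(open_leaf_indices, strictly = TRUE) ||
      any(open_leaf_indices < 1L | open_leaf_indices > MLC_N_LEAVES))
    stop("open_leaf_indices must be strictly increasing within 1..64")
  if (nrow(events) != 2L * length(open_leaf_indices))
    stop("event matrix must have 2 rows per open leaf (got ", nrow(events),
         " rows for ", length(open_leaf_indices), " leaves)")
  for (k in seq_along(open_leaf_indices)) {
    op <- events[2L * k - 1L, ]; cl <- events[2L * k, ]
    op <- op[is.finite(op)]; cl <- cl[is.finite(cl)]
    if (length(op) != length(cl))
      stop("leaf ", open_leaf_indices[k], ": unbalanced open/close events")
    inter <- as.vector(rbind(op, cl))
    if (length(inter) && is.unsorted(inter))
      stop("leaf ", open_leaf_indices[k],
           ": open/close times must interleave and be non-decreasing")
  }
  structure(list(events = events, open_leaf_indices = open_leaf_indices,
                 warmup_s = warmup_s,
                 projection_duration_s = projection_duration_s),
            class = "plan_sinogram_v4")
}

#' Classify a raw plan-sinogram blob by storage generation
#'
#' The early storage generation keeps per-projection fractions as float32;
#' the later one keeps cumulative event times as float64.  The dtype-based
#' classification is cross-checked against the archive's declared storage
#' version; any disagreement is an error, never a guess.
#'
#' @param raw A numeric grid with a `dtype` attribute (`"float32"` or
#'   `"float64"`), as returned by [read_blob()].
#' @param declared The archive [storage_version()].
#' @return `"V3-layout"` or `"V4-layout"`.
#' @export
detect_sinogram_version <- function(raw, declared) {
  if (length(raw) == 0) stop("empty sinogram blob")
  dtype <- attr(raw, "dtype") %||% stop("sinogram blob lacks a dtype attribute")
  layout <- switch(dtype, float32 = "V3-layout", float64 = "V4-layout",
                   stop("sinogram dtype must be float32 or float64, got ", dtype))
  expected <- if (declared == "V3") "V3-layout" else "V4-layout"
  if (layout != expected)
    stop("sinogram dtype ", dtype, " is inconsistent with declared storage ",
         "version ", unclass(declared))
  layout
}

#' Decode a cumulative-event plan sinogram to per-projection fractions
#'
#' Projection `k` (1-based) spans the half-open window
#' `[warmup + (k-1) * tau, warmup + k * tau)`.  Each open leaf's fraction in
#' a projection is the total overlap of its open intervals with that window
#' divided by `tau`; leaves absent from `open_leaf_indices` (closed for the
#' whole treatment) get fraction 0 everywhere.  The output always carries
#' all 64 leaves.
#'
#' @param sg A [plan_sinogram_v4()].
#' @param n_projections Number of projections (from plan metadata, not
#'   inferred from the blob).
#' @return A [plan_sinogram_v3()].
#' @export
decode_sinogram_v4 <- function(sg, n_projections) {
  stopifnot(inherits(sg, "plan_sinogram_v4"))
  tau <- sg$projection_duration_s
  t_end <- sg$warmup_s + n_projections * tau
  fr <- matrix(0, nrow = n_projections, ncol = MLC_N_LEAVES)
  w0 <- sg$warmup_s + (seq_len(n_projections) - 1) * tau
  w1 <- w0 + tau
  for (k in seq_along(sg$open_leaf_indices)) {
    leaf <- sg$open_leaf_indices[k]
    op <- sg$events[2L * k - 1L, ]; cl <- sg$events[2L * k, ]
    keep <- is.finite(op) & is.finite(cl)
    op <- op[keep]; cl <- cl[keep]
    if (length(op) == 0) next
    if (any(cl > t_end + 1e-9))
      stop("leaf ", leaf, ": event time ", max(cl), " s beyond treatment end ",
           t_end, " s")
    if (any(op[-1] < cl[-length(cl)] - 1e-12))
      stop("leaf ", leaf, ": overlapping open intervals")
    acc <- numeric(n_projections)
    for (j in seq_along(op)) {
      ov <- pmin(cl[j], w1) - pmax(op[j], w0)
      acc <- acc + pmax(ov, 0)
    }
    fr[, leaf] <- pmin(acc / tau, 1)
  }
  plan_sinogram_v3(fr)
}

#' Encode per-projection fractions as a cumulative event list
#'
#' Generator-side inverse of [decode_sinogram_v4()]: each nonzero fraction
#' `f` in projection `k` becomes one open interval of length `f * tau`
#' centred in that projection window.  Used to emit the later-generation
#' storage variant of a known delivery.
#'
#' @param sg3 A [plan_sinogram_v3()].
#' @inheritParams plan_sinogram_v4
#' @export
encode_sinogram_v4 <- function(sg3, warmup_s = 10, projection_duration_s) {
  stopifnot(inherits(sg3, "plan_sinogram_v3"))
  fr <- sg3$fractions
  tau <- projection_duration_s
  open_leaves <- which(colSums(fr) > 0)
  if (length(open_leaves) == 0) stop("no leaf ever opens")
  per_leaf <- lapply(open_leaves, function(leaf) {
    ks <- which(fr[, leaf] > 0)
    w0 <- warmup_s + (ks - 1) * tau
    f <- fr[ks, leaf]
    list(open = w0 + (1 - f) * tau / 2, close = w0 + (1 + f) * tau / 2)
  })
  n_ev <- max(vapply(per_leaf, function(x) length(x$open), 0L))
  events <- matrix(NaN, nrow = 2L * length(open_leaves), ncol = n_ev)
  for (k in seq_along(per_leaf)) {
    ne <- length(per_leaf[[k]]$open)
    events[2L * k - 1L, seq_len(ne)] <- per_leaf[[k]]$open
    events[2L * k, seq_len(ne)] <- per_leaf[[k]]$close
  }
  plan_sinogram_v4(events, open_leaves, warmup_s, tau)
}

#' Serialize plan-sinogram fractions for the RT-Plan private tag
#'
#' The per-projection fractions are stored row-major (projection by
#' projection, 64 float32 values each) in the private data element
#' (300D,10A7), reserved under the private creator `"TAGMAP-TOMO"` at
#' (300D,0010).  `decode_plan_sinogram_payload` inverts the encoding.
#'
#' @param sg3 A [plan_sinogram_v3()].
#' @return Raw vector payload.
#' @export
encode_plan_sinogram_dicom <- function(sg3) {
  stopifnot(inherits(sg3, "plan_sinogram_v3"))
  pack_f32(as.vector(t(sg3$fractions)))
}

#' @rdname encode_plan_sinogram_dicom
#' @param payload Raw vector from the private element.
#' @param n_projections Number of projections.
#' @export
decode_plan_sinogram_payload <- function(payload, n_projections) {
  v <- unpack_f32(payload)
  if (length(v) != n_projections * MLC_N_LEAVES)
    stop("sinogram payload length ", length(v), " does not match ",
         n_projections, " projections x 64 leaves")
  plan_sinogram_v3(matrix(v, nrow = n_projections, ncol = MLC_N_LEAVES,
                          byrow = TRUE))
}

SINOGRAM_PRIVATE_CREATOR <- "TAGMAP-TOMO"
SINOGRAM_PRIVATE_TAG <- "300D10A7"
SINOGRAM_CREATOR_TAG <- "300D0010"

# ---- plan CT reshaping ----------------------------------------------------

#' Couch-insertion specification
#'
#' Describes how a planning-CT slice is enlarged when the diagnostic
#' scanner's couch image is replaced by the (wider, taller) treatment
#' couch: the canvas grows to `target_width` columns and gains
#' `couch_height_px` rows below, the couch attenuation profile is written
#' into the appended rows, and the isocenter pixel must stay inside the
#' result.
#'
#' @param target_width Output width in pixels (>= source width).
#' @param couch_height_px Rows appended below the image.
#' @param couch_profile Numeric vector of length `couch_height_px`; stored
#'   values written across the appended rows (recycled over columns).
#' @param pad_value Stored pixel value used for padding.
#' @param isocenter_px `(row, col)` of the treatment isocenter in the input.
#' @export
couch_spec <- function(target_width, couch_height_px,
                       couch_profile = numeric(couch_height_px),
                       pad_value = 0, isocenter_px = NULL) {
  if (couch_height_px > 0 && length(couch_profile) != couch_height_px)
    stop("couch_profile must have couch_height_px values")
  structure(list(target_width = as.integer(target_width),
                 couch_height_px = as.integer(couch_height_px),
                 couch_profile = couch_profile, pad_value = pad_value,
                 isocenter_px = isocenter_px),
            class = "couch_spec")
}

#' Insert the treatment couch into a planning-CT slice
#'
#' Enlarges the slice canvas per the [couch_spec()]: columns are padded
#' symmetrically (extra column to the right), rows for the couch are
#' appended below, and the couch profile is written into the appended
#' rows.  The inherited pixel block is never altered; its offset and the
#' shifted isocenter are recorded as attributes `block_offset` and
#' `isocenter_px`.
#'
#' @param image Numeric matrix of stored pixel values (rows x columns).
#' @param spec A [couch_spec()].
#' @return The enlarged matrix.
#' @export
insert_couch <- function(image, spec) {
  stopifnot(inherits(spec, "couch_spec"))
  h <- nrow(image); w <- ncol(image)
  if (spec$target_width < w)
    stop("target_width (", spec$target_width, ") smaller than image width (", w, ")")
  out_h <- h + spec$couch_height_px
  out_w <- spec$target_width
  left <- (out_w - w) %/% 2L
  out <- matrix(spec$pad_value, nrow = out_h, ncol = out_w)
  out[seq_len(h), left + seq_len(w)] <- image
  if (spec$couch_height_px > 0)
    out[h + seq_len(spec$couch_height_px), left + seq_len(w)] <-
      matrix(spec$couch_profile, nrow = spec$couch_height_px, ncol = w)
  if (is.integer(image) && all(out == round(out)))
    storage.mode(out) <- "integer"
  iso <- spec$isocenter_px
  if (!is.null(iso)) {
    iso <- c(iso[1], iso[2] + left)
    if (iso[1] < 1 || iso[1] > out_h || iso[2] < 1 || iso[2] > out_w)
      stop("isocenter falls outside the enlarged image")
  }
  attr(out, "block_offset") <- c(row = 0L, col = left)
  attr(out, "isocenter_px") <- iso
  out
}

#' Pad an image to a square for DICOM export
#'
#' Export-time reshaping: the slice is padded to
#' `max(rows, cols) x max(rows, cols)`.  Content stays top-aligned (pad
#' rows are appended below); when columns must grow, padding is split
#' equally with the extra column on the right.  Inherited pixels are
#' bit-identical; pad pixels carry `pad_value` (default 0, the stored
#' value of -1024 HU under the intercept used for CT export).
#'
#' @param image Numeric matrix of stored pixel values.
#' @param pad_value Stored value for padding pixels.
#' @return Square matrix with attribute `block_offset`.
#' @export
pad_for_export <- function(image, pad_value = 0) {
  h <- nrow(image); w <- ncol(image)
  side <- max(h, w)
  out <- matrix(pad_value, nrow = side, ncol = side)
  if (is.integer(image) && pad_value == round(pad_value))
    storage.mode(out) <- "integer"
  left <- (side - w) %/% 2L
  out[seq_len(h), left + seq_len(w)] <- image
  attr(out, "block_offset") <- c(row = 0L, col = left)
  out
}

# ---- correction relinking -------------------------------------------------

#' Relink positional corrections to image-guidance scans
#'
#' Corrections normally reference their scan via a UID; when that link was
#' lost (recording continued while the unit/database communication was
#' down), the fallback locates the scan by acquisition time.  A correction
#' with an intact UID keeps it (method `"UID"`); otherwise the nearest scan
#' within `tolerance_s` is assigned (method `"TIMESTAMP"`).  Exact-tie
#' candidates, no scan within tolerance, or two corrections competing for
#' the same scan all demote to `"UNLINKED"` — the mapping over timestamp
#' matches is kept injective so one scan never absorbs two corrections.
#'
#' @param corrections List of [correlation_record()] objects.
#' @param scans Data frame with columns `scan_uid` and `datetime`
#'   (POSIXct or ISO-8601 strings).
#' @param tolerance_s Maximum |time difference| in seconds for a fallback
#'   match (default 120).
#' @return Data frame with columns `record_uid`, `scan_uid`, `method`.
#' @export
relink_corrections <- function(corrections, scans, tolerance_s = 120) {
  stopifnot(is.data.frame(scans), all(c("scan_uid", "datetime") %in% names(scans)))
  times <- scans$datetime
  if (!inherits(times, "POSIXct")) times <- iso_to_posix(as.character(times))
  n <- length(corrections)
  out <- data.frame(record_uid = character(n), scan_uid = NA_character_,
                    method = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rec <- corrections[[i]]
    out$record_uid[i] <- rec$record_uid
    if (!is.null(rec$linked_scan_uid) && !is.na(rec$linked_scan_uid)) {
      out$scan_uid[i] <- rec$linked_scan_uid
      out$method[i] <- "UID"
      next
    }
    ts <- rec$timestamp
    if (!inherits(ts, "POSIXct")) ts <- iso_to_posix(as.character(ts))
    d <- abs(as.numeric(difftime(times, ts, units = "secs")))
    if (length(d) == 0 || min(d) > tolerance_s) {
      out$method[i] <- "UNLINKED"
      next
    }
    best <- which(abs(d - min(d)) < 1e-9)
    if (length(best) > 1) {
      out$method[i] <- "UNLINKED"  # ambiguous tie
    } else {
      out$scan_uid[i] <- scans$scan_uid[best]
      out$method[i] <- "TIMESTAMP"
    }
  }
  # injectivity over TIMESTAMP matches: conflicts demote both
  ts_idx <- which(out$method == "TIMESTAMP")
  dup_scans <- unique(out$scan_uid[ts_idx][duplicated(out$scan_uid[ts_idx])])
  if (length(dup_scans)) {
    clash <- ts_idx[out$scan_uid[ts_idx] %in% dup_scans]
    warning(length(clash), " correction(s) competed for the same scan; unlinked")
    out$scan_uid[clash] <- NA_character_
    out$method[clash] <- "UNLINKED"
  }
  out
}
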