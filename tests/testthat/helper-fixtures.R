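# Shared fixtures: all archives are generated in code at test time.

tiny_spec <- function(...) {
  args <- list(n_patients = 1L, n_fractions = 2L,
               base_image_shape = c(48L, 48L), target_width = 64L,
               couch_height_px = 6L, dose_shape = c(12L, 12L, 6L),
               n_projections = 16L, n_channels = 24L, seed = 101L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(archive_spec, args)
}

make_archive <- function(dir, ...) generate_archive(tiny_spec(...), dir)

# relative-path -> md5 map of every file under root
tree_hashes <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- substring(files, nchar(root) + 2L)
  h
}

# independent DICOM reader oracle: returns c(parsed_ok, total)
pydicom_parse_count <- function(root) {
  code <- c(
    "import sys, glob, pydicom",
    "files = glob.glob(sys.argv[1] + '/**/*.dcm', recursive=True)",
    "ok = 0",
    "for f in files:",
    "    try:",
    "        d = pydicom.dcmread(f)",
    "        _ = d.SOPClassUID; _ = d.SOPInstanceUID",
    "        ok += 1",
    "    except Exception as e:",
    "        print('FAIL', f, e)",
    "print(ok, len(files))")
  tf <- tempfile(fileext = ".py")
  writeLines(code, tf)
  out <- system2("python", c(tf, root), stdout = TRUE)
  as.integer(strsplit(out[length(out)], " ")[[1]])
}

# brute-force per-voxel quantization oracle
quantize_oracle <- function(grid, sf) {
  out <- grid
  for (i in seq_along(grid)) {
    v <- floor(grid[i] / sf + 0.5)
    out[i] <- min(max(v, 0), 65535)
  }
  out
}

# 1 ms time-sampling oracle for cumulative-event sinogram decoding
sampling_oracle <- function(sg4, n_projections, dt = 0.001) {
  tau <- sg4$projection_duration_s
  fr <- matrix(0, n_projections, 64)
  for (k in seq_along(sg4$open_leaf_indices)) {
    leaf <- sg4$open_leaf_indices[k]
    op <- sg4$events[2 * k - 1, ]; cl <- sg4$events[2 * k, ]
    keep <- is.finite(op) & is.finite(cl)
    op <- op[keep]; cl <- cl[keep]
    for (p in seq_len(n_projections)) {
      w0 <- sg4$warmup_s + (p - 1) * tau
      ts <- seq(w0 + dt / 2, w0 + tau - dt / 2, by = dt)
      open <- vapply(ts, function(t) any(op <= t & t < cl), TRUE)
      fr[p, leaf] <- mean(open)
    }
  }
  fr
}

# brute-force nearest-in-time relinking oracle (tolerance, ties, injectivity)
relink_oracle <- function(corrections, scans, tolerance_s) {
  n <- length(corrections)
  assigned <- rep(NA_character_, n)
  method <- character(n)
  for (i in seq_len(n)) {
    rec <- corrections[[i]]
    if (!is.na(rec$linked_scan_uid)) {
      assigned[i] <- rec$linked_scan_uid; method[i] <- "UID"; next
    }
    d <- abs(as.numeric(difftime(scans$datetime, rec$timestamp, units = "secs")))
    if (min(d) > tolerance_s) { method[i] <- "UNLINKED"; next }
    best <- which(abs(d - min(d)) < 1e-9)
    if (length(best) > 1) { method[i] <- "UNLINKED"; next }
    assigned[i] <- scans$scan_uid[best]; method[i] <- "TIMESTAMP"
  }
  ts <- which(method == "TIMESTAMP")
  dup <- unique(assigned[ts][duplicated(assigned[ts])])
  clash <- ts[assigned[ts] %in% dup]
  assigned[clash] <- NA_character_
  method[clash] <- "UNLINKED"
  data.frame(record_uid = vapply(corrections, `[[`, "", "record_uid"),
             scan_uid = assigned, method = method, stringsAsFactors = FALSE)
}
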