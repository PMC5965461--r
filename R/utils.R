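# Low-level byte packing, hashing and date helpers shared across modules.
# All binary I/O in the package is little-endian.

pack_u16 <- function(v) {
  v <- as.numeric(v)
  if (any(v < 0 | v > 65535)) stop("pack_u16: value out of uint16 range")
  as.raw(rbind(v %% 256, v %/% 256))
}

unpack_u16 <- function(r) {
  i <- as.integer(r)
  i[c(TRUE, FALSE)] + 256L * i[c(FALSE, TRUE)]
}

pack_s16 <- function(v) {
  v <- as.numeric(v)
  if (any(v < -32768 | v > 32767)) stop("pack_s16: value out of int16 range")
  pack_u16(ifelse(v < 0, v + 65536, v))
}

unpack_s16 <- function(r) {
  u <- unpack_u16(r)
  ifelse(u > 32767, u - 65536, u)
}

pack_u32 <- function(v) {
  v <- as.numeric(v)
  if (any(v < 0 | v > 4294967295)) stop("pack_u32: value out of uint32 range")
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; b3 <- v %/% 256
  as.raw(rbind(b0, b1, b2, b3))
}

unpack_u32 <- function(r) {
  i <- as.numeric(as.integer(r))
  i[c(TRUE, FALSE, FALSE, FALSE)] +
    256 * i[c(FALSE, TRUE, FALSE, FALSE)] +
    65536 * i[c(FALSE, FALSE, TRUE, FALSE)] +
    16777216 * i[c(FALSE, FALSE, FALSE, TRUE)]
}

pack_f32 <- function(v) writeBin(as.double(v), raw(), size = 4L, endian = "little")
unpack_f32 <- function(r) readBin(r, "double", n = length(r) %/% 4L, size = 4L,
                                  endian = "little")
pack_f64 <- function(v) writeBin(as.double(v), raw(), size = 8L, endian = "little")
unpack_f64 <- function(r) readBin(r, "double", n = length(r) %/% 8L, size = 8L,
                                  endian = "little")

# 32-bit FNV-1a over the UTF-8 bytes of a string, carried in doubles with the
# multiply done in 16-bit halves so no intermediate exceeds 2^53.
fnv1a32 <- function(s) {
  b <- as.integer(charToRaw(enc2utf8(s)))
  hi <- 0x8422  # 2166136261 = 0x84222325
  lo <- 0x2325
  for (byte in b) {
    lo <- bitwXor(lo, byte)
    # multiply (hi*2^16 + lo) by 16777619 = 256*2^16 + 403, mod 2^32
    p_lo <- lo * 403
    cross <- lo * 256 + hi * 403 + p_lo %/% 65536
    lo <- p_lo %% 65536
    hi <- cross %% 65536
  }
  hi * 65536 + lo
}

# Deterministic UID derivation: namespace root + seed + two independent
# 32-bit digests of the source UID.  Stays within the 64-character UID limit
# for roots up to ~26 characters.
derive_uid <- function(source_uid, namespace_root, seed) {
  h1 <- fnv1a32(paste0(source_uid, "|", seed))
  h2 <- fnv1a32(paste0(seed, "#", source_uid))
  uid <- sprintf("%s.%d.%.0f.%.0f", namespace_root, as.integer(seed), h1, h2)
  if (nchar(uid) > 64) stop("derived UID exceeds 64 characters: ", uid)
  uid
}

is_valid_uid <- function(uid) {
  length(uid) == 1 && !is.na(uid) && nchar(uid) <= 64 &&
    grepl("^[0-9]+(\\.[0-9]+)+$", uid)
}

# ISO-8601 (tomo-lite) <-> DICOM DA/TM/DT
iso_to_posix <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  dateonly <- is.na(out) & !is.na(x)
  if (any(dateonly))
    out[dateonly] <- as.POSIXct(x[dateonly], format = "%Y-%m-%d", tz = "UTC")
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable ISO-8601 timestamp: ", paste(x[is.na(out)], collapse = ", "))
  out
}
iso_to_da <- function(x) format(iso_to_posix(x), "%Y%m%d")
iso_to_tm <- function(x) format(iso_to_posix(x), "%H%M%S")
iso_to_dt <- function(x) format(iso_to_posix(x), "%Y%m%d%H%M%S")

# Decimal String formatting: <= 16 chars per DICOM DS
format_ds <- function(x) {
  s <- vapply(as.numeric(x), function(v) {
    out <- formatC(v, digits = 10, format = "g", width = 0)
    if (nchar(out) > 16) out <- formatC(v, digits = 8, format = "g", width = 0)
    out
  }, character(1))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
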