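# Minimal DICOM support: uncompressed single-frame monochrome images in the
# explicit- or implicit-VR little-endian transfer syntaxes, which covers MR
# exports in practice. No installed R package parses DICOM, hence this
# reader/writer; scope is deliberately narrow (no sequences, no compressed
# pixel data, no anonymization tooling).

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_uint <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1L))

# Parse one explicit/implicit-VR element starting at offset `i` (1-based).
# Returns list(group, elem, vr, value_raw, next_offset).
dcm_element <- function(buf, i, explicit) {
  group <- dcm_uint(buf[i:(i + 1L)])
  elem <- dcm_uint(buf[(i + 2L):(i + 3L)])
  if (explicit) {
    vr <- rawToChar(buf[(i + 4L):(i + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- dcm_uint(buf[(i + 8L):(i + 11L)])
      val_at <- i + 12L
    } else {
      len <- dcm_uint(buf[(i + 6L):(i + 7L)])
      val_at <- i + 8L
    }
  } else {
    vr <- ""
    len <- dcm_uint(buf[(i + 4L):(i + 7L)])
    val_at <- i + 8L
  }
  if (len == 4294967295)
    stop_mriqa("DICOM element (", sprintf("%04x,%04x", group, elem),
               ") has undefined length; sequences are not supported")
  value <- if (len > 0) buf[val_at:(val_at + len - 1L)] else raw(0)
  list(group = group, elem = elem, vr = vr, value = value,
       next_offset = val_at + len)
}

dcm_str <- function(x) {
  # strip trailing NUL/space padding before conversion
  while (length(x) && x[length(x)] %in% as.raw(c(0L, 32L)))
    x <- x[-length(x)]
  rawToChar(x)
}

read_dicom <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  i <- 1L
  ts <- TS_IMPLICIT_LE
  if (length(buf) > 132L && rawToChar(buf[129:132]) == "DICM") {
    i <- 133L
    # File meta group (0002,xxxx) is always explicit little-endian.
    while (i + 7L <= length(buf)) {
      el <- dcm_element(buf, i, explicit = TRUE)
      if (el$group != 2L) break
      if (el$elem == 16L) ts <- dcm_str(el$value)  # (0002,0010)
      i <- el$next_offset
    }
  }
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE))
    stop_mriqa("unsupported DICOM transfer syntax '", ts, "' in ", path,
               " (only uncompressed little-endian is supported)")
  explicit <- ts == TS_EXPLICIT_LE
  meta <- list(rows = NA, cols = NA, bits = 16L, samples = 1L,
               slope = 1, intercept = 0, signed = 0L,
               patient_id = "", body_part = "")
  pixel_raw <- NULL
  while (i + 7L <= length(buf)) {
    el <- dcm_element(buf, i, explicit)
    key <- sprintf("%04x,%04x", el$group, el$elem)
    switch(key,
      "0010,0020" = meta$patient_id <- dcm_str(el$value),
      "0018,0015" = meta$body_part <- dcm_str(el$value),
      "0028,0002" = meta$samples <- dcm_uint(el$value),
      "0028,0010" = meta$rows <- dcm_uint(el$value),
      "0028,0011" = meta$cols <- dcm_uint(el$value),
      "0028,0100" = meta$bits <- dcm_uint(el$value),
      "0028,0103" = meta$signed <- dcm_uint(el$value),
      "0028,1052" = meta$intercept <- as.numeric(dcm_str(el$value)),
      "0028,1053" = meta$slope <- as.numeric(dcm_str(el$value)),
      "7fe0,0010" = pixel_raw <- el$value,
      NULL)
    i <- el$next_offset
  }
  if (is.null(pixel_raw)) stop_mriqa("no PixelData in DICOM file ", path)
  if (meta$samples != 1L)
    stop_mriqa("colour (multi-sample) DICOM rejected: ", path,
               " -- MR images are single-channel")
  if (meta$bits != 16L)
    stop_mriqa("only 16-bit DICOM pixel data is supported (got ",
               meta$bits, " bits): ", path)
  if (is.na(meta$rows) || is.na(meta$cols))
    stop_mriqa("DICOM file lacks Rows/Columns: ", path)
  v <- readBin(pixel_raw, "integer", n = meta$rows * meta$cols, size = 2L,
               signed = meta$signed == 1L, endian = "little")
  if (meta$signed != 1L) v <- ifelse(v < 0, v + 65536, v)  # size-2 unsigned fix
  px <- matrix(v, nrow = meta$rows, ncol = meta$cols, byrow = TRUE)
  # Canonicalize vendor dialects: apply rescale, clip to the 16-bit range.
  px <- pmin(pmax(px * meta$slope + meta$intercept, 0), 65535)
  if (nzchar(meta$patient_id)) attr(px, "group_id") <- meta$patient_id
  if (nzchar(meta$body_part)) attr(px, "body_part") <- meta$body_part
  px
}

dcm_pad <- function(x) if (length(x) %% 2L == 1L) c(x, as.raw(0L)) else x

dcm_raw_uint16 <- function(x) as.raw(c(x %% 256L, x %/% 256L))
dcm_raw_uint32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, x %/% 16777216))
}

dcm_write_element <- function(group, elem, vr, value) {
  value <- dcm_pad(value)
  head <- c(dcm_raw_uint16(group), dcm_raw_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0L, 0L)), dcm_raw_uint32(length(value)), value)
  else
    c(head, dcm_raw_uint16(length(value)), value)
}

write_dicom <- function(px, path, id = "image", group_id = NULL,
                        body_part = "") {
  h <- nrow(px); w <- ncol(px)
  v <- as.integer(t(px))  # row-major
  pix <- writeBin(v, raw(), size = 2L, endian = "little")
  # readBin/writeBin with size 2 truncate to the low 16 bits, which is what
  # the unsigned representation needs.
  meta <- c(
    dcm_write_element(2L, 16L, "UI", charToRaw(TS_EXPLICIT_LE)))
  meta <- c(dcm_write_element(2L, 0L, "UL", dcm_raw_uint32(length(meta))), meta)
  body <- c(
    dcm_write_element(0x0008L, 0x0060L, "CS", charToRaw("MR")),
    dcm_write_element(0x0010L, 0x0020L, "LO",
                      charToRaw(if (is.null(group_id)) id else group_id)),
    if (nzchar(body_part))
      dcm_write_element(0x0018L, 0x0015L, "CS", charToRaw(body_part)),
    dcm_write_element(0x0028L, 0x0002L, "US", dcm_raw_uint16(1L)),
    dcm_write_element(0x0028L, 0x0004L, "CS", charToRaw("MONOCHROME2")),
    dcm_write_element(0x0028L, 0x0010L, "US", dcm_raw_uint16(h)),
    dcm_write_element(0x0028L, 0x0011L, "US", dcm_raw_uint16(w)),
    dcm_write_element(0x0028L, 0x0100L, "US", dcm_raw_uint16(16L)),
    dcm_write_element(0x0028L, 0x0101L, "US", dcm_raw_uint16(16L)),
    dcm_write_element(0x0028L, 0x0102L, "US", dcm_raw_uint16(15L)),
    dcm_write_element(0x0028L, 0x0103L, "US", dcm_raw_uint16(0L)),
    dcm_write_element(0x7fe0L, 0x0010L, "OW", pix))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), path)
  invisible(path)
}
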