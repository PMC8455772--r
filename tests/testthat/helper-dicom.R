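# test-only writer for tiny explicit-VR little-endian DICOM files

dcm_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, x %/% 16777216))

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_u16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", dcm_u16(x))

# pixels: integer matrix (row-major in the file)
write_test_dicom <- function(path, pixels, spacing = NULL,
                             imager_spacing = NULL, view = "AP",
                             photometric = "MONOCHROME2",
                             patient_id = "TESTPAT") {
  px <- as.integer(t(pixels))
  pxraw <- writeBin(px, raw(), size = 2, endian = "little")
  body <- c(
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_str(0x0010, 0x0020, "LO", patient_id),
    if (!is.null(imager_spacing))
      dcm_str(0x0018, 0x1164, "DS",
              sprintf("%g\\%g", imager_spacing[1], imager_spacing[2])),
    if (!is.null(view)) dcm_str(0x0018, 0x5101, "CS", view),
    dcm_str(0x0028, 0x0004, "CS", photometric),
    dcm_us(0x0028, 0x0010, nrow(pixels)),
    dcm_us(0x0028, 0x0011, ncol(pixels)),
    if (!is.null(spacing))
      dcm_str(0x0028, 0x0030, "DS", sprintf("%g\\%g", spacing[1], spacing[2])),
    dcm_us(0x0028, 0x0100, 16L),
    dcm_element(0x7FE0, 0x0010, "OW", pxraw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(body, con)
  invisible(path)
}
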