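# Readers and writers: 16-bit PGM + JSON sidecar for synthetic exams,
# a minimal DICOM reader (explicit VR little endian, uncompressed
# monochrome), and the manifest CSV shared with the training harness.

#' One radiograph with metadata and optional ground truth
#'
#' @param exam_id,patient_id Identifier strings.
#' @param image Numeric matrix of pixel values.
#' @param spacing A `pixel_spacing` or `NULL`.
#' @param view `"FRONTAL"`, `"OTHER"` or `"UNKNOWN"`.
#' @param label Optional ETT presence (logical).
#' @param carina,tip Optional ORIGINAL-frame `landmark`s.
#' @param report_text Optional free-text report.
#' @return An `exam_record`.
#' @export
exam_record <- function(exam_id, patient_id, image, spacing = NULL,
                        view = "UNKNOWN", label = NULL, carina = NULL,
                        tip = NULL, report_text = NULL) {
  view <- match.arg(view, c("FRONTAL", "OTHER", "UNKNOWN"))
  if (!is.matrix(image)) ettc_error("image must be a matrix", "ettc_input_error")
  if (!is.null(tip) && (is.null(label) || !isTRUE(label))) {
    ettc_error("an ETT tip landmark requires label = TRUE", "ettc_input_error")
  }
  structure(list(exam_id = exam_id, patient_id = patient_id, image = image,
                 spacing = spacing, view = view, label = label,
                 carina = carina, tip = tip, report_text = report_text),
            class = "exam_record")
}

#' Read / write 16-bit binary PGM (P5)
#'
#' Images are stored as big-endian 16-bit samples with `maxval` 65535; the
#' unit-scale intensities are mapped linearly from `[lo, hi]`. Reading
#' reconstructs `lo + v * (hi - lo) / 65535` exactly, so
#' read -> write -> read is lossless.
#'
#' @param path File path.
#' @param image Numeric matrix.
#' @param lo,hi Intensity range mapped onto 0..65535 (values clamped).
#' @return `read_pgm`: the reconstructed matrix with attributes `lo`, `hi`.
#' @export
write_pgm <- function(image, path, lo = -0.5, hi = 1.5) {
  v <- round((pmin(pmax(image, lo), hi) - lo) / (hi - lo) * 65535)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n65535\n", ncol(image), nrow(image)), con,
            eos = NULL)
  writeBin(as.integer(t(v)), con, size = 2, endian = "big")
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path, lo = -0.5, hi = 1.5) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: 4 whitespace-separated tokens, then exactly one whitespace byte
  tok <- character(0); cur <- ""
  while (length(tok) < 4) {
    ch <- readBin(con, "raw", 1)
    if (length(ch) == 0) ettc_error(sprintf("%s: truncated PGM header", path),
                                    "ettc_io_error")
    if (rawToChar(ch) %in% c(" ", "\n", "\t", "\r")) {
      if (nzchar(cur)) { tok <- c(tok, cur); cur <- "" }
    } else {
      cur <- paste0(cur, rawToChar(ch))
    }
  }
  if (tok[1] != "P5") {
    ettc_error(sprintf("%s: not a binary PGM", path), "ettc_io_error")
  }
  dims <- as.integer(tok[2:3])
  maxval <- as.integer(tok[4])
  v <- readBin(con, "integer", n = dims[1] * dims[2], size = 2,
               signed = FALSE, endian = "big")
  m <- matrix(lo + v * (hi - lo) / maxval, nrow = dims[2], byrow = TRUE)
  attr(m, "lo") <- lo; attr(m, "hi") <- hi
  m
}

#' Write a synthetic exam as PGM + JSON sidecar
#'
#' The in-memory image is replaced by its 16-bit quantization before
#' writing, so the on-disk pair is the authoritative record and
#' [read_synth()] round-trips exactly.
#'
#' @param exam A `synth_exam` (from [render_exam()]).
#' @param dir Output directory.
#' @return Base path (without extension), invisibly.
#' @export
write_synth_exam <- function(exam, dir) {
  base <- file.path(dir, exam$exam_id)
  write_pgm(exam$image, paste0(base, ".pgm"))
  side <- list(
    exam_id = exam$exam_id, patient_id = exam$patient_id,
    rows = nrow(exam$image), cols = ncol(exam$image),
    spacing_row_mm = exam$spacing$row_mm_per_px,
    spacing_col_mm = exam$spacing$col_mm_per_px,
    view = "FRONTAL",
    ett_present = exam$ett_present,
    carina = c(exam$carina$y, exam$carina$x),
    ett_tip = if (is.null(exam$ett_tip)) NULL else c(exam$ett_tip$y, exam$ett_tip$x),
    distance_cm = if (is.finite(exam$distance_cm)) exam$distance_cm else NULL,
    report_text = exam$report_text)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' Read a synthetic exam (PGM + JSON sidecar)
#'
#' @param pgm_path Path to the image; the sidecar defaults to the same base
#'   name with extension `.json`.
#' @param sidecar_path Optional explicit sidecar path.
#' @return An `exam_record` with the same semantics as [read_dicom()].
#' @export
read_synth <- function(pgm_path, sidecar_path = sub("\\.pgm$", ".json", pgm_path)) {
  if (!file.exists(sidecar_path)) {
    ettc_error(sprintf("missing sidecar %s", sidecar_path), "ettc_io_error")
  }
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  img <- read_pgm(pgm_path)
  if (nrow(img) != side$rows || ncol(img) != side$cols) {
    ettc_error("sidecar/image dimension mismatch", "ettc_io_error")
  }
  label <- isTRUE(side$ett_present)
  tip <- NULL
  if (!is.null(side$ett_tip)) {
    if (!label) ettc_error("sidecar has an ETT tip but ett_present is false",
                           "ettc_io_error")
    tip <- landmark(side$ett_tip[1], side$ett_tip[2], "ORIGINAL")
  }
  exam_record(side$exam_id, side$patient_id, img,
              spacing = pixel_spacing(side$spacing_row_mm, side$spacing_col_mm),
              view = side$view %||% "UNKNOWN", label = label,
              carina = landmark(side$carina[1], side$carina[2], "ORIGINAL"),
              tip = tip, report_text = side$report_text)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- minimal DICOM (explicit VR little endian, uncompressed monochrome) ---

.dcm_tag <- function(group, elem) sprintf("%04X%04X", group, elem)
.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Read a DICOM radiograph
#'
#' Minimal reader for uncompressed monochrome files in the explicit VR
#' little endian transfer syntax (the only one supported: no codec library
#' exists in this stack). Pixel spacing is taken from PixelSpacing
#' (0028,0030), falling back to ImagerPixelSpacing (0018,1164), else absent;
#' the view is FRONTAL when ViewPosition (0018,5101) is AP or PA; a
#' MONOCHROME1 photometric interpretation is inverted to the MONOCHROME2
#' convention (higher value = brighter).
#'
#' @param path DICOM file path.
#' @return An `exam_record` (no ground truth fields).
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    ettc_error(sprintf("%s: not a DICOM part-10 file", path), "ettc_io_error")
  }
  pos <- 133L
  elems <- list()
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2)
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8); vstart <- pos + 12
    } else {
      len <- u16(pos + 6); vstart <- pos + 8
    }
    if (!grepl("^[A-Z]{2}$", vr)) {
      ettc_error(sprintf("%s: unsupported (implicit VR?) encoding at byte %d",
                         path, pos), "ettc_io_error")
    }
    if (vstart + len - 1 > length(raw)) {
      ettc_error(sprintf("%s: truncated element", path), "ettc_io_error")
    }
    val <- raw[vstart:(vstart + len - 1)]
    elems[[.dcm_tag(group, elem)]] <- list(vr = vr, value = val)
    pos <- vstart + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  getstr <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(e$value))
  }
  ts <- getstr(.dcm_tag(0x0002, 0x0010))
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
    ettc_error(sprintf("%s: unsupported transfer syntax %s", path, ts),
               "ettc_io_error")
  }
  getu16 <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    u <- e$value
    as.integer(u[1]) + 256L * as.integer(u[2])
  }
  rows <- getu16(.dcm_tag(0x0028, 0x0010))
  cols <- getu16(.dcm_tag(0x0028, 0x0011))
  bits <- getu16(.dcm_tag(0x0028, 0x0100)) %||% 16L
  px <- elems[[.dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(px) || is.null(rows) || is.null(cols)) {
    ettc_error(sprintf("%s: missing pixel data or dimensions", path),
               "ettc_io_error")
  }
  if (bits == 16) {
    v <- readBin(px$value, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
  } else if (bits == 8) {
    v <- as.integer(px$value[seq_len(rows * cols)])
  } else {
    ettc_error(sprintf("%s: unsupported BitsAllocated %d", path, bits),
               "ettc_io_error")
  }
  img <- matrix(as.numeric(v), nrow = rows, byrow = TRUE)
  photometric <- getstr(.dcm_tag(0x0028, 0x0004)) %||% "MONOCHROME2"
  if (photometric == "MONOCHROME1") img <- max(img) - img
  sp_str <- getstr(.dcm_tag(0x0028, 0x0030)) %||% getstr(.dcm_tag(0x0018, 0x1164))
  spacing <- NULL
  if (!is.null(sp_str) && nzchar(sp_str)) {
    parts <- as.numeric(strsplit(sp_str, "\\\\")[[1]])
    if (length(parts) == 2 && all(is.finite(parts))) {
      spacing <- pixel_spacing(parts[1], parts[2])
    }
  }
  viewpos <- getstr(.dcm_tag(0x0018, 0x5101))
  view <- if (is.null(viewpos)) "UNKNOWN"
          else if (toupper(viewpos) %in% c("AP", "PA")) "FRONTAL" else "OTHER"
  pid <- getstr(.dcm_tag(0x0010, 0x0020)) %||% "UNKNOWN"
  exam_record(basename(path), pid, img, spacing = spacing, view = view)
}

#' Read / write the cohort manifest CSV
#'
#' Schema: `exam_id, patient_id, path, label, carina_y, carina_x, tip_y,
#' tip_x, spacing_row_mm, spacing_col_mm, report_text`.
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @return `read_manifest`: the data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
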