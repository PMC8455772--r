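# Coordinate frames and invertible per-axis affine maps between them.
#
# Every landmark travels through four frames:
#   ORIGINAL -> PADDED -> MODEL -> CROP
# (native detector grid, square zero-padded grid, resampled network input,
# and the hard-attention crop around the predicted carina). All maps are
# per-axis affine (y' = y * scale_y + offset_y) and exactly invertible.

FRAMES <- c("ORIGINAL", "PADDED", "MODEL", "CROP")

ettc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ettc_error")))
}

#' Physical pixel spacing
#'
#' Millimeters per pixel along image rows and columns, as carried by the
#' DICOM `PixelSpacing`/`ImagerPixelSpacing` attributes. Required to convert
#' pixel distances into centimeters.
#'
#' @param row_mm_per_px Millimeters per pixel along rows (y). Positive finite.
#' @param col_mm_per_px Millimeters per pixel along columns (x); defaults to
#'   `row_mm_per_px` (isotropic).
#' @return A `pixel_spacing` object.
#' @export
pixel_spacing <- function(row_mm_per_px, col_mm_per_px = row_mm_per_px) {
  if (!is.finite(row_mm_per_px) || !is.finite(col_mm_per_px) ||
      row_mm_per_px <= 0 || col_mm_per_px <= 0) {
    ettc_error("pixel spacing must be strictly positive and finite",
               "ettc_input_error")
  }
  structure(list(row_mm_per_px = as.numeric(row_mm_per_px),
                 col_mm_per_px = as.numeric(col_mm_per_px)),
            class = "pixel_spacing")
}

#' A landmark coordinate tagged with its frame
#'
#' Coordinates are 0-based `(y, x)` = (row, column) with the origin at the
#' top-left pixel center.
#'
#' @param y,x Row and column coordinate in pixels (finite numerics).
#' @param frame One of `"ORIGINAL"`, `"PADDED"`, `"MODEL"`, `"CROP"`.
#' @return A `landmark` object with fields `y`, `x`, `frame`.
#' @export
landmark <- function(y, x, frame) {
  frame <- match.arg(frame, FRAMES)
  if (!is.finite(y) || !is.finite(x)) {
    ettc_error("landmark coordinates must be finite", "ettc_input_error")
  }
  structure(list(y = as.numeric(y), x = as.numeric(x), frame = frame),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark y=%.4f x=%.4f frame=%s>\n", x$y, x$x, x$frame))
  invisible(x)
}

#' Invertible per-axis affine map between two frames
#'
#' @param scale_y,scale_x Unitless per-axis scales (nonzero).
#' @param offset_y,offset_x Offsets in destination-frame pixels.
#' @param src_frame,dst_frame Frame identifiers.
#' @return An `affine_map` object.
#' @export
affine_map <- function(scale_y = 1, scale_x = 1, offset_y = 0, offset_x = 0,
                       src_frame = "ORIGINAL", dst_frame = "MODEL") {
  src_frame <- match.arg(src_frame, FRAMES)
  dst_frame <- match.arg(dst_frame, FRAMES)
  if (scale_y == 0 || scale_x == 0 ||
      !all(is.finite(c(scale_y, scale_x, offset_y, offset_x)))) {
    ettc_error("affine map scales must be nonzero and all terms finite",
               "ettc_input_error")
  }
  structure(list(scale_y = as.numeric(scale_y), scale_x = as.numeric(scale_x),
                 offset_y = as.numeric(offset_y), offset_x = as.numeric(offset_x),
                 src_frame = src_frame, dst_frame = dst_frame),
            class = "affine_map")
}

#' Invert an affine map
#' @param m An `affine_map`.
#' @return The inverse map (dst -> src).
#' @export
invert_map <- function(m) {
  affine_map(1 / m$scale_y, 1 / m$scale_x,
             -m$offset_y / m$scale_y, -m$offset_x / m$scale_x,
             src_frame = m$dst_frame, dst_frame = m$src_frame)
}

#' Compose two affine maps (apply `m1`, then `m2`)
#' @param m1,m2 `affine_map`s with `m1$dst_frame == m2$src_frame`.
#' @return The composite map from `m1$src_frame` to `m2$dst_frame`.
#' @export
compose_maps <- function(m1, m2) {
  if (m1$dst_frame != m2$src_frame) {
    ettc_error(sprintf("cannot compose %s->%s with %s->%s",
                       m1$src_frame, m1$dst_frame, m2$src_frame, m2$dst_frame),
               "ettc_frame_error")
  }
  affine_map(m1$scale_y * m2$scale_y, m1$scale_x * m2$scale_x,
             m1$offset_y * m2$scale_y + m2$offset_y,
             m1$offset_x * m2$scale_x + m2$offset_x,
             src_frame = m1$src_frame, dst_frame = m2$dst_frame)
}

#' Map a landmark through an affine map
#'
#' `map_point` applies the map (source to destination frame); `unmap_point`
#' applies its inverse. The landmark's frame must match the corresponding end
#' of the map.
#'
#' @param p A `landmark`.
#' @param m An `affine_map`.
#' @return The transformed `landmark`, re-tagged with the new frame.
#' @export
map_point <- function(p, m) {
  if (p$frame != m$src_frame) {
    ettc_error(sprintf("landmark in frame %s but map expects %s",
                       p$frame, m$src_frame), "ettc_frame_error")
  }
  landmark(p$y * m$scale_y + m$offset_y, p$x * m$scale_x + m$offset_x,
           m$dst_frame)
}

#' @rdname map_point
#' @export
unmap_point <- function(p, m) {
  if (p$frame != m$dst_frame) {
    ettc_error(sprintf("landmark in frame %s but inverse map expects %s",
                       p$frame, m$dst_frame), "ettc_frame_error")
  }
  map_point(p, invert_map(m))
}

#' Zero-padding map to a square canvas
#'
#' Pads the shorter axis until the matrix is square. Under the default
#' pad-right/bottom placement the ORIGINAL and PADDED coordinates coincide
#' (identity map); symmetric placement shifts coordinates by half the pad.
#'
#' @param h,w Image height and width in pixels (>= 1).
#' @param placement `"bottomright"` (default) or `"symmetric"`.
#' @return A list with `map` (ORIGINAL -> PADDED `affine_map`), `side`
#'   (padded side length) and per-axis integer pad amounts.
#' @export
pad_to_square_map <- function(h, w, placement = c("bottomright", "symmetric")) {
  placement <- match.arg(placement)
  if (h < 1 || w < 1) {
    ettc_error("image dimensions must be >= 1", "ettc_input_error")
  }
  side <- max(h, w)
  if (placement == "bottomright") {
    off <- c(0, 0)
  } else {
    off <- c((side - h) %/% 2, (side - w) %/% 2)
  }
  list(map = affine_map(1, 1, off[1], off[2], "ORIGINAL", "PADDED"),
       side = as.integer(side),
       pad_top = as.integer(off[1]), pad_left = as.integer(off[2]),
       pad_bottom = as.integer(side - h - off[1]),
       pad_right = as.integer(side - w - off[2]))
}

#' Resampling map between two grid sizes
#'
#' @param src_h,src_w,dst_h,dst_w Source and destination dimensions (>= 1).
#' @param src_frame,dst_frame Frame tags for the returned map.
#' @param spacing Optional `pixel_spacing` of the source grid; when given the
#'   effective spacing of the destination grid is returned alongside.
#' @return A list with `map` and (if `spacing` given) `spacing`: the
#'   effective destination spacing, satisfying
#'   `spacing_eff * dst = spacing * src` per axis exactly.
#' @export
resample_map <- function(src_h, src_w, dst_h, dst_w,
                         src_frame = "PADDED", dst_frame = "MODEL",
                         spacing = NULL) {
  if (min(src_h, src_w, dst_h, dst_w) < 1) {
    ettc_error("grid dimensions must be >= 1", "ettc_input_error")
  }
  m <- affine_map(dst_h / src_h, dst_w / src_w, 0, 0, src_frame, dst_frame)
  out <- list(map = m)
  if (!is.null(spacing)) {
    out$spacing <- pixel_spacing(spacing$row_mm_per_px * src_h / dst_h,
                                 spacing$col_mm_per_px * src_w / dst_w)
  }
  out
}

#' Hard-attention crop window around the carina
#'
#' Builds the rectangular stage-2/3 attention window: a 2:1
#' (height-to-width) rectangle spanning `frac_h` and `frac_w` of the model
#' input, centered on the (predicted or ground-truth) carina. Bounds are
#' half-open MODEL-frame pixel indices and may extend beyond the image;
#' extraction zero-fills (see [extract_crop()]).
#'
#' @param carina A `landmark` in the MODEL frame.
#' @param model_h,model_w Model-input dimensions (512 x 512 by default
#'   upstream).
#' @param frac_h,frac_w Window fractions of the model input (defaults 0.50
#'   and 0.25, i.e. 256 x 128 from a 512 input).
#' @param out_h,out_w Output matrix shape after resampling; `NULL` (default)
#'   keeps the window's own size, so a 512 model input yields a 256 x 128
#'   crop with identity resampling.
#' @param v_offset_frac Vertical offset of the window center as a fraction of
#'   the window height (0 = symmetric about the carina; negative shifts the
#'   window up toward the ETT).
#' @return A `crop_window` with half-open bounds, output shape and the
#'   MODEL -> CROP `affine_map` in `$map`.
#' @export
crop_window_for_carina <- function(carina, model_h, model_w,
                                   frac_h = 0.50, frac_w = 0.25,
                                   out_h = NULL, out_w = NULL,
                                   v_offset_frac = 0) {
  if (!inherits(carina, "landmark") || carina$frame != "MODEL") {
    ettc_error("carina must be a landmark in the MODEL frame",
               "ettc_frame_error")
  }
  win_h <- round(frac_h * model_h)
  win_w <- round(frac_w * model_w)
  cy <- carina$y + v_offset_frac * win_h
  cx <- carina$x
  row_start <- round(cy - win_h / 2)
  col_start <- round(cx - win_w / 2)
  if (is.null(out_h)) out_h <- win_h
  if (is.null(out_w)) out_w <- win_w
  w <- structure(list(row_start = row_start, row_stop = row_start + win_h,
                      col_start = col_start, col_stop = col_start + win_w,
                      out_h = as.integer(out_h), out_w = as.integer(out_w)),
                 class = "crop_window")
  w$map <- affine_map(out_h / win_h, out_w / win_w,
                      -row_start * out_h / win_h, -col_start * out_w / win_w,
                      src_frame = "MODEL", dst_frame = "CROP")
  w
}

#' Normalize landmark coordinates to the unit square
#'
#' The regression networks are trained against normalized coordinates
#' `(y/h, x/w)`; `denormalize_coords` maps a network output back to pixels.
#'
#' @param p A `landmark`.
#' @param h,w Frame dimensions in pixels (>= 1).
#' @return `normalize_coords`: numeric `c(ny, nx)`.
#' @export
normalize_coords <- function(p, h, w) {
  if (h < 1 || w < 1) ettc_error("dimensions must be >= 1", "ettc_input_error")
  c(p$y / h, p$x / w)
}

#' @rdname normalize_coords
#' @param ny,nx Normalized coordinates.
#' @param frame Frame tag for the reconstructed landmark.
#' @export
denormalize_coords <- function(ny, nx, h, w, frame) {
  if (h < 1 || w < 1) ettc_error("dimensions must be >= 1", "ettc_input_error")
  landmark(ny * h, nx * w, frame)
}

#' Physical distance between two landmarks in centimeters
#'
#' Scales each pixel axis by its millimeter spacing before taking the
#' Euclidean norm (correct for anisotropic spacing), then converts to cm.
#'
#' @param p1,p2 `landmark`s in the same frame.
#' @param spacing The effective `pixel_spacing` of that frame, or `NULL`.
#' @param allow_pixels If `TRUE` and `spacing` is `NULL`, returns the pixel
#'   Euclidean distance with attribute `units = "px"` instead of erroring.
#' @return Distance in centimeters (or pixels under the fallback).
#' @export
distance_cm <- function(p1, p2, spacing, allow_pixels = FALSE) {
  if (p1$frame != p2$frame) {
    ettc_error(sprintf("landmarks in different frames (%s vs %s)",
                       p1$frame, p2$frame), "ettc_frame_error")
  }
  dy <- p1$y - p2$y
  dx <- p1$x - p2$x
  if (is.null(spacing)) {
    if (!allow_pixels) {
      ettc_error("no pixel spacing available; pass allow_pixels = TRUE for a pixel-unit fallback",
                 "ettc_spacing_error")
    }
    return(structure(sqrt(dy^2 + dx^2), units = "px"))
  }
  sqrt((dy * spacing$row_mm_per_px)^2 + (dx * spacing$col_mm_per_px)^2) / 10
}
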