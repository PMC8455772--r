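# Image-side preprocessing (pad -> resample -> z-score) and training-time
# augmentation. Every geometric change to the pixels is mirrored by the
# corresponding affine map so landmarks stay consistent.

#' Augmentation parameters
#'
#' Training-time augmentation draws (a) a normalization jitter that rescales
#' the stored z-score statistics by a factor uniform in
#' `[jitter_lo, jitter_hi]` and (b) a geometric translation + scale whose
#' worst image-corner displacement is bounded by `max_disp_px` pixels.
#'
#' @param jitter_lo,jitter_hi Bounds on the normalization-statistics scale
#'   factor (defaults 0.90 and 1.10).
#' @param max_disp_px Maximum corner displacement in pixels (default 14).
#' @return An `augment_params` object.
#' @export
augment_params <- function(jitter_lo = 0.90, jitter_hi = 1.10, max_disp_px = 14) {
  if (!(jitter_lo > 0 && jitter_lo <= jitter_hi) || max_disp_px < 0) {
    ettc_error("need 0 < jitter_lo <= jitter_hi and max_disp_px >= 0",
               "ettc_input_error")
  }
  structure(list(jitter_lo = jitter_lo, jitter_hi = jitter_hi,
                 max_disp_px = max_disp_px),
            class = "augment_params")
}

#' Pad, resample and z-score a radiograph
#'
#' Zero-pads the image to a square (pad right/bottom by default, so ORIGINAL
#' and PADDED coordinates coincide), resamples to
#' `model_size x model_size` (bilinear) and applies per-image z-score
#' normalization. A constant image (zero standard deviation) is normalized
#' with `sd = 1` and flagged.
#'
#' @param image Numeric matrix (rows x cols), finite values.
#' @param spacing Optional `pixel_spacing` of the input grid.
#' @param model_size Side length of the model input (default 512).
#' @param placement Padding placement, see [pad_to_square_map()].
#' @return A list: `image` (model-size matrix, z-scored), `map`
#'   (ORIGINAL -> MODEL composite `affine_map`), `pad` (pad record),
#'   `spacing` (effective MODEL-frame `pixel_spacing`, `NULL` if no input
#'   spacing), `mu`, `sigma` (the statistics used), `constant` flag.
#' @export
preprocess <- function(image, spacing = NULL, model_size = 512,
                       placement = "bottomright") {
  if (!is.matrix(image) || nrow(image) < 1 || ncol(image) < 1) {
    ettc_error("image must be a non-empty numeric matrix", "ettc_input_error")
  }
  if (!all(is.finite(image))) {
    ettc_error("image contains non-finite values", "ettc_input_error")
  }
  h <- nrow(image); w <- ncol(image)
  pad <- pad_to_square_map(h, w, placement)
  side <- pad$side
  rs <- resample_map(side, side, model_size, model_size,
                     src_frame = "PADDED", dst_frame = "MODEL",
                     spacing = spacing)
  # sample the padded plane directly: model index i sits at padded position
  # i * side/model, i.e. ORIGINAL position i * side/model - pad offset
  # (zero-filled outside the original matrix).
  step <- side / model_size
  out <- cpp_affine_sample(image, model_size, model_size,
                           -pad$map$offset_y, step,
                           -pad$map$offset_x, step,
                           side - 1 - pad$map$offset_y,
                           side - 1 - pad$map$offset_x)
  mu <- mean(out)
  sigma <- stats::sd(as.numeric(out))
  constant <- !is.finite(sigma) || sigma == 0
  if (constant) {
    sigma <- 1
    warning("constant image: z-score falls back to sd = 1")
  }
  list(image = (out - mu) / sigma,
       map = compose_maps(pad$map, rs$map),
       pad = pad,
       spacing = rs$spacing,
       mu = mu, sigma = sigma, constant = constant)
}

#' Draw one augmentation transform
#'
#' Translation per axis is integer-uniform on `[-max_disp_px, max_disp_px]`
#' and the scale factor uniform on `[1 - m/(side/2), 1 + m/(side/2)]` (about
#' the image center), rejection-resampled jointly until the largest Euclidean
#' displacement of the four image corners is at most `max_disp_px`; the
#' normalization jitter factor is uniform on `[jitter_lo, jitter_hi]`.
#' Consumes the R RNG stream.
#'
#' @param params An `augment_params`.
#' @param h,w Frame dimensions the transform applies to.
#' @return A list `t_y`, `t_x`, `scale`, `jitter`, `center_y`, `center_x`,
#'   `max_corner_disp`.
#' @export
draw_augment_transform <- function(params, h, w) {
  m <- params$max_disp_px
  side <- max(h, w)
  cy <- h / 2; cx <- w / 2
  r <- if (side > 0) m / (side / 2) else 0
  corners <- rbind(c(0, 0), c(0, w), c(h, 0), c(h, w))
  repeat {
    t_y <- if (m > 0) sample.int(2 * m + 1, 1) - m - 1 else 0
    t_x <- if (m > 0) sample.int(2 * m + 1, 1) - m - 1 else 0
    s <- runif(1, 1 - r, 1 + r)
    dy <- (s - 1) * (corners[, 1] - cy) + t_y
    dx <- (s - 1) * (corners[, 2] - cx) + t_x
    disp <- max(sqrt(dy^2 + dx^2))
    if (disp <= m + 1e-12) break
  }
  list(t_y = t_y, t_x = t_x, scale = s,
       jitter = runif(1, params$jitter_lo, params$jitter_hi),
       center_y = cy, center_x = cx, max_corner_disp = disp)
}

#' Apply translation/scale/normalization-jitter augmentation
#'
#' The geometric transform maps source position `p` to
#' `scale * (p - center) + center + t`; the image is warped accordingly
#' (bilinear, zero-filled) and every landmark is moved by the same forward
#' transform. Intensity statistics are re-applied with the jittered
#' `mu`, `sigma` when `stats` is supplied.
#'
#' @param image Numeric matrix (typically the z-scored MODEL-frame image).
#' @param landmarks A list of `landmark`s (may be empty).
#' @param params An `augment_params`.
#' @param stats Optional list with `mu`, `sigma`: the z-score statistics the
#'   image was normalized with; the jitter rescales both.
#' @param transform Optional pre-drawn transform (from
#'   [draw_augment_transform()]); default draws a fresh one from the R RNG.
#' @return A list: `image`, `landmarks` (transformed, same frames),
#'   `transform` (the applied record).
#' @export
augment <- function(image, landmarks = list(), params = augment_params(),
                    stats = NULL, transform = NULL) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(transform)) transform <- draw_augment_transform(params, h, w)
  s <- transform$scale; cy <- transform$center_y; cx <- transform$center_x
  # inverse map for resampling: src = (dst - c - t)/s + c
  ay <- (0 - cy - transform$t_y) / s + cy
  ax <- (0 - cx - transform$t_x) / s + cx
  out <- cpp_affine_sample(image, h, w, ay, 1 / s, ax, 1 / s)
  if (!is.null(stats)) {
    f <- transform$jitter
    # image holds (I - mu)/sigma; re-normalize with (f*mu, f*sigma)
    out <- (out * stats$sigma + stats$mu - f * stats$mu) / (f * stats$sigma)
  }
  lms <- lapply(landmarks, function(p) {
    landmark(s * (p$y - cy) + cy + transform$t_y,
             s * (p$x - cx) + cx + transform$t_x, p$frame)
  })
  list(image = out, landmarks = lms, transform = transform)
}

#' Extract (and resample) a crop window from an image
#'
#' Samples the half-open window `[row_start, row_stop) x [col_start,
#' col_stop)` on a regular `out_h x out_w` grid (bilinear); window regions
#' outside the image are zero-filled. When the window lies fully inside the
#' image and matches the output shape the extraction is an exact sub-grid
#' copy.
#'
#' @param image Numeric matrix in the frame the window refers to.
#' @param window A `crop_window` (or any list with the same bound fields).
#' @return An `out_h x out_w` numeric matrix.
#' @export
extract_crop <- function(image, window) {
  win_h <- window$row_stop - window$row_start
  win_w <- window$col_stop - window$col_start
  cpp_affine_sample(image, window$out_h, window$out_w,
                    window$row_start, win_h / window$out_h,
                    window$col_start, win_w / window$out_w)
}

#' Re-express a MODEL-frame crop window in another frame
#'
#' Maps the window bounds through `m` (e.g. the inverse of the
#' PADDED -> MODEL resample map) so the crop can be extracted from a
#' higher-resolution grid; the output shape is preserved.
#'
#' @param window A `crop_window` with MODEL-frame bounds.
#' @param m An `affine_map` whose source frame is MODEL.
#' @return A list with transformed bounds and the same `out_h`, `out_w`.
#' @export
window_in_frame <- function(window, m) {
  list(row_start = window$row_start * m$scale_y + m$offset_y,
       row_stop = window$row_stop * m$scale_y + m$offset_y,
       col_start = window$col_start * m$scale_x + m$offset_x,
       col_stop = window$col_stop * m$scale_x + m$offset_x,
       out_h = window$out_h, out_w = window$out_w)
}
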