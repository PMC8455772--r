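# End-to-end inference: coarse carina -> hard-attention crop -> ETT
# classification -> refined carina + tip -> tip-carina distance in cm.

#' Stage 1: coarse carina localization
#'
#' Denormalizes the 2-logit regression output to MODEL-frame pixels and
#' clamps it into the image bounds.
#'
#' @param net The stage-1 `cxr_net`.
#' @param model_image Preprocessed model-input matrix.
#' @return A MODEL-frame `landmark`.
#' @export
run_stage1 <- function(net, model_image) {
  p <- forward_network(net, model_image)
  h <- nrow(model_image); w <- ncol(model_image)
  landmark(min(max(p[1, 1] * h, 0), h - 1e-9),
           min(max(p[1, 2] * w, 0), w - 1e-9), "MODEL")
}

#' Stage 2: ETT presence probability
#'
#' @param net The stage-2 `cxr_net`.
#' @param crop_image Extracted attention crop.
#' @return Softmax probability of the ETT-present class (class 1).
#' @export
run_stage2 <- function(net, crop_image) {
  logits <- forward_network(net, crop_image)
  unname(softmax(logits[1, ])[2])
}

#' Stage 3: refined carina and distal ETT tip
#'
#' Both points are denormalized in the CROP frame and mapped back to the
#' MODEL frame through the window's affine map.
#'
#' @param net The stage-3 `cxr_net` (4-dim regression head).
#' @param crop_image Extracted attention crop.
#' @param window The `crop_window` the crop was taken from.
#' @return A list with MODEL-frame `landmark`s `carina` and `tip`.
#' @export
run_stage3 <- function(net, crop_image, window) {
  p <- forward_network(net, crop_image)
  oh <- window$out_h; ow <- window$out_w
  ck <- denormalize_coords(p[1, 1], p[1, 2], oh, ow, "CROP")
  tk <- denormalize_coords(p[1, 3], p[1, 4], oh, ow, "CROP")
  list(carina = unmap_point(ck, window$map), tip = unmap_point(tk, window$map))
}

#' Run the full cascade on one exam
#'
#' Stage order: preprocess, coarse carina, crop, presence classification,
#' and (for ETT-positive calls) refinement + tip localization. The
#' tip-carina distance is computed in the ORIGINAL frame with the exam's
#' native pixel spacing; when spacing is missing the distance is omitted
#' unless `allow_pixel_units = TRUE`, in which case a pixel-unit value is
#' reported in `distance_px`.
#'
#' @param models Named list with `stage1`, `stage2`, `stage3` `cxr_net`s
#'   (`stage3` may be `NULL` when never needed).
#' @param exam An `exam_record` or `synth_exam` (needs `$image`).
#' @param config A `cascade_config` (threshold, crop geometry, model size).
#' @param allow_pixel_units Permit pixel-unit distances without spacing.
#' @return A `cascade_prediction`: ids, `carina_coarse`, `ett_probability`,
#'   `ett_present`, `carina_refined`, `ett_tip`, `tip_carina_distance_cm`
#'   (the landmark fields in both MODEL and ORIGINAL frames), `frames` (the
#'   ORIGINAL -> MODEL map and crop window used).
#' @export
run_cascade <- function(models, exam, config = cascade_config(),
                        allow_pixel_units = FALSE) {
  if (is.null(exam$image)) ettc_error("exam has no pixel data", "ettc_input_error")
  stopifnot(inherits(config, "cascade_config"))
  pre <- preprocess(exam$image, exam$spacing, config$model_size)
  to_orig <- invert_map(pre$map)

  coarse <- run_stage1(models$stage1, pre$image)
  crop <- cascade_crop(exam$image, pre, coarse, config)
  prob <- run_stage2(models$stage2, crop$image)
  present <- prob >= config$threshold

  refined <- NULL; tip <- NULL
  if ((present || config$refine_without_ett) && !is.null(models$stage3)) {
    r3 <- run_stage3(models$stage3, crop$image, crop$window)
    refined <- r3$carina
    if (present) tip <- r3$tip
  }
  carina_final <- refined %||% coarse

  dist_cm <- NA_real_; dist_px <- NA_real_
  if (present && !is.null(tip)) {
    tip_o <- unmap_point(tip, pre$map)
    car_o <- unmap_point(carina_final, pre$map)
    if (!is.null(exam$spacing)) {
      dist_cm <- distance_cm(tip_o, car_o, exam$spacing)
    } else if (allow_pixel_units) {
      dist_px <- as.numeric(distance_cm(tip_o, car_o, NULL, allow_pixels = TRUE))
    } else {
      ettc_error("exam has no pixel spacing; pass allow_pixel_units = TRUE for a pixel-unit distance",
                 "ettc_spacing_error")
    }
  }

  structure(list(
    exam_id = exam$exam_id %||% NA_character_,
    patient_id = exam$patient_id %||% NA_character_,
    carina_coarse = coarse,
    carina_coarse_orig = unmap_point(coarse, pre$map),
    ett_probability = prob,
    ett_present = present,
    carina_refined = refined,
    carina_final_orig = unmap_point(carina_final, pre$map),
    ett_tip = tip,
    ett_tip_orig = if (is.null(tip)) NULL else unmap_point(tip, pre$map),
    tip_carina_distance_cm = dist_cm,
    tip_carina_distance_px = dist_px,
    frames = list(map = pre$map, window = crop$window,
                  spacing_model = pre$spacing)),
    class = "cascade_prediction")
}

#' Tabulate cascade predictions
#'
#' One row per exam with ORIGINAL-frame coordinates, suitable for the
#' prediction CSV.
#'
#' @param preds List of `cascade_prediction`s.
#' @return A data frame.
#' @export
predictions_to_df <- function(preds) {
  do.call(rbind, lapply(preds, function(p) {
    data.frame(
      exam_id = p$exam_id, patient_id = p$patient_id,
      ett_probability = p$ett_probability,
      ett_present = p$ett_present,
      carina_y = p$carina_final_orig$y, carina_x = p$carina_final_orig$x,
      tip_y = if (is.null(p$ett_tip_orig)) NA_real_ else p$ett_tip_orig$y,
      tip_x = if (is.null(p$ett_tip_orig)) NA_real_ else p$ett_tip_orig$x,
      distance_cm = p$tip_carina_distance_cm,
      stringsAsFactors = FALSE)
  }))
}

#' Write predictions as CSV or JSON (with frame provenance)
#'
#' @param preds List of `cascade_prediction`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(preds, path) {
  write.csv(predictions_to_df(preds), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
write_predictions_json <- function(preds, path) {
  ser <- lapply(preds, function(p) {
    out <- unclass(p)
    out$frames <- list(map = unclass(p$frames$map),
                       window = unclass(p$frames$window[
                         c("row_start", "row_stop", "col_start", "col_stop",
                           "out_h", "out_w")]))
    lapply(out, function(v) if (inherits(v, "landmark")) unclass(v) else v)
  })
  jsonlite::write_json(list(schema = "ettcascade/predictions/v1",
                            predictions = ser),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
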