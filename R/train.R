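# Stage-wise training with the fixed 3 + 1 epoch schedule and
# patient-grouped five-fold cross-validation.

#' Training schedule
#'
#' Adam with learning rate 5e-4 and batch size 12 for 3 epochs, then one
#' fine-tuning epoch at the learning rate divided by 10 (4 epochs total).
#'
#' @param lr_initial Initial learning rate (default 5e-4).
#' @param batch_size Mini-batch size (default 12).
#' @param epochs_initial Epochs at `lr_initial` (default 3).
#' @param epochs_finetune Epochs at `lr_finetune` (default 1).
#' @param lr_finetune Fine-tuning learning rate (default `lr_initial / 10`).
#' @param seed RNG seed for shuffling and augmentation (default 1).
#' @return A `train_schedule`.
#' @export
train_schedule <- function(lr_initial = 5e-4, batch_size = 12,
                           epochs_initial = 3, epochs_finetune = 1,
                           lr_finetune = lr_initial / 10, seed = 1) {
  stopifnot(lr_initial > 0, lr_finetune > 0, batch_size >= 1,
            epochs_initial >= 0, epochs_finetune >= 0)
  structure(list(lr_initial = lr_initial, batch_size = as.integer(batch_size),
                 epochs_initial = as.integer(epochs_initial),
                 epochs_finetune = as.integer(epochs_finetune),
                 lr_finetune = lr_finetune, seed = as.integer(seed)),
            class = "train_schedule")
}

#' Cascade geometry settings shared by training and inference
#'
#' @param model_size Stage-1 model input side length (default 512).
#' @param frac_h,frac_w Crop-window fractions of the model input (defaults
#'   0.50 / 0.25).
#' @param v_offset_frac Vertical crop offset, see [crop_window_for_carina()].
#' @param threshold Stage-2 decision threshold (default 0.5).
#' @param refine_without_ett Run the stage-3 refinement even when the
#'   classifier calls the exam ETT-negative (default FALSE: the coarse
#'   carina is final for negatives).
#' @return A `cascade_config`.
#' @export
cascade_config <- function(model_size = 512, frac_h = 0.50, frac_w = 0.25,
                           v_offset_frac = 0, threshold = 0.5,
                           refine_without_ett = FALSE) {
  structure(list(model_size = as.integer(model_size), frac_h = frac_h,
                 frac_w = frac_w, v_offset_frac = v_offset_frac,
                 threshold = threshold,
                 refine_without_ett = refine_without_ett),
            class = "cascade_config")
}

#' Write / read a training configuration as a YAML-style key/value file
#'
#' Flat `key: value` lines covering the schedule, cascade geometry and
#' augmentation bounds, so a run is reproducible from its config file.
#'
#' @param schedule A `train_schedule`.
#' @param cascade A `cascade_config`.
#' @param aug An `augment_params` or `NULL`.
#' @param path Output file.
#' @return `read_train_config`: a list with `schedule`, `cascade`, `aug`.
#' @export
write_train_config <- function(schedule, cascade, aug, path) {
  kv <- c(lapply(unclass(schedule), identity),
          setNames(unclass(cascade), paste0("cascade_", names(unclass(cascade)))),
          if (!is.null(aug))
            setNames(unclass(aug), paste0("aug_", names(unclass(aug)))))
  writeLines(sprintf("%s: %s", names(kv),
                     vapply(kv, function(v) format(v, digits = 17), character(1))),
             path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  v <- setNames(lapply(vals, function(x) {
    if (x %in% c("TRUE", "FALSE")) return(as.logical(x))
    num <- suppressWarnings(as.numeric(x))
    if (is.na(num)) x else num
  }), keys)
  sched <- train_schedule(v$lr_initial, v$batch_size, v$epochs_initial,
                          v$epochs_finetune, v$lr_finetune, v$seed)
  casc <- cascade_config(v$cascade_model_size, v$cascade_frac_h,
                         v$cascade_frac_w, v$cascade_v_offset_frac,
                         v$cascade_threshold,
                         isTRUE(v$cascade_refine_without_ett))
  aug <- if (!is.null(v$aug_max_disp_px)) {
    augment_params(v$aug_jitter_lo, v$aug_jitter_hi, v$aug_max_disp_px)
  }
  list(schedule = sched, cascade = casc, aug = aug)
}

#' Patient-grouped fold assignment
#'
#' Patients are shuffled with `seed` and dealt round-robin over `k` folds,
#' so fold patient counts differ by at most one and every exam of a patient
#' lands in that patient's fold.
#'
#' @param manifest Data frame with `exam_id` and `patient_id` columns.
#' @param k Number of folds (default 5).
#' @param seed Shuffle seed.
#' @return A `fold_assignment`: named integer vectors `exam_fold` and
#'   `patient_fold` (folds are 0-based).
#' @export
make_folds <- function(manifest, k = 5, seed = 1) {
  stopifnot(all(c("exam_id", "patient_id") %in% names(manifest)))
  patients <- unique(as.character(manifest$patient_id))
  if (k > length(patients)) {
    ettc_error(sprintf("k = %d folds but only %d patients", k, length(patients)),
               "ettc_input_error")
  }
  shuffled <- withr_seed(seed, sample(patients))
  patient_fold <- setNames((seq_along(shuffled) - 1L) %% k, shuffled)
  exam_fold <- patient_fold[as.character(manifest$patient_id)]
  names(exam_fold) <- as.character(manifest$exam_id)
  structure(list(exam_fold = exam_fold, patient_fold = patient_fold, k = k),
            class = "fold_assignment")
}

#' Write / read a fold assignment CSV
#' @param folds A `fold_assignment`.
#' @param path CSV path.
#' @return `read_folds`: the `fold_assignment`.
#' @export
write_folds <- function(folds, path) {
  write.csv(data.frame(exam_id = names(folds$exam_fold),
                       fold = as.integer(folds$exam_fold)), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds
#' @param manifest Manifest data frame (to recover patient grouping).
#' @export
read_folds <- function(path, manifest) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  exam_fold <- setNames(as.integer(df$fold), df$exam_id)
  pid <- manifest$patient_id[match(df$exam_id, manifest$exam_id)]
  patient_fold <- exam_fold[!duplicated(pid)]
  names(patient_fold) <- pid[!duplicated(pid)]
  structure(list(exam_fold = exam_fold, patient_fold = patient_fold,
                 k = length(unique(df$fold))),
            class = "fold_assignment")
}

# exam -> stage-1 training record (model image + normalized carina target)
prepare_stage1_record <- function(exam, model_size) {
  pre <- preprocess(exam$image, exam$spacing, model_size)
  rec <- list(x = pre$image, stats = list(mu = pre$mu, sigma = pre$sigma),
              map = pre$map, spacing = pre$spacing)
  if (!is.null(exam$carina)) {
    cm <- map_point(exam$carina, pre$map)
    rec$carina_model <- cm
    rec$y <- normalize_coords(cm, model_size, model_size)
  }
  rec
}

#' Build stage-2/3 training crops from ground-truth carinas
#'
#' Crops are centered on the ground-truth carina plus Gaussian jitter
#' (sigma `jitter_sigma_px` in MODEL pixels, emulating stage-1 error) and
#' extracted from the padded original-resolution grid, so each crop pixel
#' keeps the native physical size. Stage-3 targets are re-expressed as
#' CROP-frame normalized coordinates. Consumes the R RNG stream.
#'
#' @param exams List of exams (`synth_exam` or `exam_record`) with
#'   ground-truth carina.
#' @param config A `cascade_config`.
#' @param jitter_sigma_px Center jitter sigma in MODEL-frame pixels
#'   (default 8).
#' @return List of crop records: `x` (crop matrix), `label`, `y`
#'   (normalized `c(carina_y, carina_x, tip_y, tip_x)` or `NULL`), `window`,
#'   `stats`, `spacing` (ORIGINAL-frame).
#' @export
make_stage23_crops <- function(exams, config = cascade_config(),
                               jitter_sigma_px = 8) {
  lapply(exams, function(exam) {
    if (is.null(exam$carina)) {
      ettc_error("make_stage23_crops needs ground-truth carina",
                 "ettc_input_error")
    }
    pre <- preprocess(exam$image, exam$spacing, config$model_size)
    cm <- map_point(exam$carina, pre$map)
    center <- landmark(cm$y + rnorm(1, 0, jitter_sigma_px),
                       cm$x + rnorm(1, 0, jitter_sigma_px), "MODEL")
    crop <- cascade_crop(exam$image, pre, center, config)
    rec <- list(x = crop$image, label = exam$ett_present %||% exam$label,
                window = crop$window,
                stats = list(mu = pre$mu, sigma = pre$sigma),
                spacing = exam$spacing)
    if (isTRUE(rec$label) && !is.null(exam$ett_tip %||% exam$tip)) {
      tip <- exam$ett_tip %||% exam$tip
      ck <- map_point(map_point(exam$carina, pre$map), crop$window$map)
      tk <- map_point(map_point(tip, pre$map), crop$window$map)
      rec$y <- c(normalize_coords(ck, crop$window$out_h, crop$window$out_w),
                 normalize_coords(tk, crop$window$out_h, crop$window$out_w))
    }
    rec
  })
}

# build the attention window around a MODEL-frame center and extract the
# crop from the original-resolution (zero-padded) grid
cascade_crop <- function(image, pre, center_model, config) {
  side <- pre$pad$side
  up <- side / config$model_size
  window <- crop_window_for_carina(center_model, config$model_size,
                                   config$model_size,
                                   frac_h = config$frac_h,
                                   frac_w = config$frac_w,
                                   out_h = round(config$frac_h * config$model_size * up),
                                   out_w = round(config$frac_w * config$model_size * up),
                                   v_offset_frac = config$v_offset_frac)
  # window bounds in ORIGINAL pixels (pad is zero-fill, sampling handles it)
  to_orig <- invert_map(pre$map)
  worig <- window_in_frame(window, to_orig)
  oz <- (image - pre$mu) / pre$sigma
  list(image = extract_crop(oz, worig), window = window)
}

#' Train one cascade stage
#'
#' Runs `epochs_initial` epochs at the initial learning rate followed by
#' `epochs_finetune` at the fine-tuning rate, with per-sample augmentation
#' redrawn every epoch. Stage 1 consumes full exams; stages 2-3 consume
#' crop records from [make_stage23_crops()] (stage 3 uses only ETT-positive
#' crops with coordinate targets).
#'
#' @param stage `"stage1"`, `"stage2"` or `"stage3"`.
#' @param data For stage 1: a list of exams with ground-truth carina. For
#'   stages 2-3: crop records.
#' @param config The stage's `backbone_config`.
#' @param schedule A `train_schedule`.
#' @param aug An `augment_params`, or `NULL` to disable augmentation.
#' @param cascade A `cascade_config` (stage 1 only, for the model size;
#'   defaults to `config$input_h`).
#' @param init_seed Weight-init seed (default `schedule$seed`).
#' @return A list: `net` (trained `cxr_net`), `log` (data frame of epoch,
#'   lr, mean loss).
#' @export
train_stage <- function(stage = c("stage1", "stage2", "stage3"), data,
                        config, schedule = train_schedule(),
                        aug = augment_params(), cascade = NULL,
                        init_seed = schedule$seed) {
  stage <- match.arg(stage)
  if (length(data) == 0) ettc_error("empty training set", "ettc_input_error")
  model_size <- config$input_h

  if (stage == "stage1") {
    samples <- lapply(data, prepare_stage1_record, model_size = model_size)
    if (any(vapply(samples, function(s) is.null(s$y), logical(1)))) {
      ettc_error("stage 1 training needs ground-truth carinas", "ettc_input_error")
    }
  } else if (stage == "stage2") {
    samples <- lapply(data, function(r) {
      if (is.null(r$label)) ettc_error("stage 2 needs presence labels",
                                       "ettc_input_error")
      list(x = r$x, label = as.integer(r$label), stats = r$stats)
    })
  } else {
    samples <- Filter(function(r) !is.null(r$y), data)
    if (length(samples) == 0) {
      ettc_error("stage 3 needs ETT-positive crops with coordinate targets",
                 "ettc_input_error")
    }
  }
  dims <- dim(samples[[1]]$x)
  if (dims[1] != config$input_h || dims[2] != config$input_w) {
    ettc_error(sprintf("%s data is %dx%d but config expects %dx%d",
                       stage, dims[1], dims[2], config$input_h, config$input_w),
               "ettc_input_error")
  }

  net <- build_network(config, seed = init_seed)
  n <- length(samples)
  bs <- schedule$batch_size
  log <- list()
  epochs <- c(rep(schedule$lr_initial, schedule$epochs_initial),
              rep(schedule$lr_finetune, schedule$epochs_finetune))
  withr_seed(schedule$seed, {
    for (ep in seq_along(epochs)) {
      lr <- epochs[ep]
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        nb <- length(idx)
        xb <- array(0, c(dims[1], dims[2], nb))
        yb <- if (config$head_type == "regression") {
          matrix(0, nb, config$head_dim)
        } else integer(nb)
        for (j in seq_len(nb)) {
          s <- samples[[idx[j]]]
          if (!is.null(aug)) {
            lms <- if (stage == "stage1") {
              list(denormalize_coords(s$y[1], s$y[2], dims[1], dims[2], "MODEL"))
            } else if (stage == "stage3") {
              list(denormalize_coords(s$y[1], s$y[2], dims[1], dims[2], "CROP"),
                   denormalize_coords(s$y[3], s$y[4], dims[1], dims[2], "CROP"))
            } else list()
            a <- augment(s$x, lms, aug, stats = s$stats)
            xb[, , j] <- a$image
            if (config$head_type == "regression") {
              yb[j, ] <- unlist(lapply(a$landmarks, normalize_coords,
                                       h = dims[1], w = dims[2]))
            } else yb[j] <- s$label
          } else {
            xb[, , j] <- s$x
            if (config$head_type == "regression") {
              yb[j, ] <- if (stage == "stage1") s$y else s$y
            } else yb[j] <- s$label
          }
        }
        losses <- c(losses, cnet_train_batch(net$ptr, xb, yb, lr))
      }
      log[[ep]] <- data.frame(epoch = ep, lr = lr, mean_loss = mean(losses))
    }
  })
  list(net = net, log = do.call(rbind, log))
}

#' Patient-grouped cross-validation of the full cascade
#'
#' For each fold, trains all three stages on the training patients and runs
#' the cascade on the held-out exams; asserts that no test patient appears
#' in training.
#'
#' @param exams List of exams with ground truth.
#' @param configs Named list of `backbone_config`s
#'   (`stage1`, `stage2`, `stage3`).
#' @param cascade A `cascade_config`.
#' @param schedule A `train_schedule`.
#' @param aug An `augment_params` or `NULL`.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return A list of per-fold results, each with `predictions` (data frame
#'   from [run_cascade()] over the test exams) and `fold` index.
#' @export
cross_validate <- function(exams, configs, cascade = cascade_config(),
                           schedule = train_schedule(), aug = augment_params(),
                           k = 5, seed = 1) {
  manifest <- data.frame(
    exam_id = vapply(exams, `[[`, character(1), "exam_id"),
    patient_id = vapply(exams, `[[`, character(1), "patient_id"))
  folds <- make_folds(manifest, k, seed)
  lapply(seq_len(k) - 1L, function(f) {
    test_idx <- which(folds$exam_fold[manifest$exam_id] == f)
    train_idx <- setdiff(seq_along(exams), test_idx)
    stopifnot(!any(manifest$patient_id[train_idx] %in%
                     manifest$patient_id[test_idx]))
    models <- train_cascade(exams[train_idx], configs, cascade, schedule, aug)
    preds <- lapply(exams[test_idx], function(e)
      run_cascade(models, e, cascade))
    list(fold = f, predictions = preds, models = models)
  })
}

#' Train all three cascade stages
#'
#' @inheritParams cross_validate
#' @param exams Training exams with ground truth.
#' @return Named list of trained `cxr_net`s (`stage1`, `stage2`, `stage3`)
#'   with attribute `logs`.
#' @export
train_cascade <- function(exams, configs, cascade = cascade_config(),
                          schedule = train_schedule(), aug = augment_params()) {
  s1 <- train_stage("stage1", exams, configs$stage1, schedule, aug)
  crops <- withr_seed(schedule$seed + 1,
                      make_stage23_crops(exams, cascade))
  s2 <- train_stage("stage2", crops, configs$stage2, schedule, aug)
  s3 <- train_stage("stage3", crops, configs$stage3, schedule, aug)
  models <- list(stage1 = s1$net, stage2 = s2$net, stage3 = s3$net)
  attr(models, "logs") <- list(stage1 = s1$log, stage2 = s2$log, stage3 = s3$log)
  models
}
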