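test_that("train_schedule encodes the 3+1 epoch protocol", {
  s <- train_schedule()
  expect_equal(s$lr_initial, 5e-4)
  expect_equal(s$batch_size, 12L)
  expect_equal(s$epochs_initial + s$epochs_finetune, 4L)
  expect_equal(s$lr_finetune, s$lr_initial / 10)
})

test_that("make_folds groups patients and balances fold sizes", {
  man <- data.frame(
    exam_id = sprintf("E%02d", 1:23),
    patient_id = c(rep("A", 3), rep("B", 2), LETTERS[3:20]))
  folds <- make_folds(man, k = 5, seed = 1)
  # every exam follows its patient
  expect_true(all(folds$exam_fold == folds$patient_fold[man$patient_id]))
  # patient A's 3 exams in a single fold
  expect_equal(length(unique(folds$exam_fold[man$patient_id == "A"])), 1L)
  # fold patient counts differ by <= 1
  counts <- table(folds$patient_fold)
  expect_lte(diff(range(counts)), 1)
  expect_equal(sum(counts), 20)
  # deterministic under seed, different otherwise
  expect_identical(folds$patient_fold, make_folds(man, 5, seed = 1)$patient_fold)
  expect_false(identical(folds$patient_fold,
                         make_folds(man, 5, seed = 2)$patient_fold))

  ten <- data.frame(exam_id = paste0("E", 1:10), patient_id = paste0("P", 1:10))
  f10 <- make_folds(ten, k = 5, seed = 3)
  expect_true(all(table(f10$patient_fold) == 2))

  expect_error(make_folds(ten, k = 11), class = "ettc_input_error")
})

test_that("fold files round-trip", {
  man <- data.frame(exam_id = paste0("E", 1:8),
                    patient_id = rep(paste0("P", 1:4), each = 2))
  folds <- make_folds(man, k = 2, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_folds(folds, path)
  back <- read_folds(path, man)
  expect_equal(back$exam_fold, folds$exam_fold)
  expect_equal(back$k, 2L)
})

test_that("training config files round-trip", {
  sched <- train_schedule(lr_initial = 2e-4, batch_size = 6, seed = 11)
  casc <- cascade_config(model_size = 128, threshold = 0.4,
                         refine_without_ett = TRUE)
  aug <- augment_params(0.92, 1.08, 10)
  path <- tempfile(fileext = ".yml")
  write_train_config(sched, casc, aug, path)
  back <- read_train_config(path)
  expect_equal(back$schedule$lr_initial, 2e-4)
  expect_equal(back$schedule$lr_finetune, 2e-5)
  expect_equal(back$schedule$batch_size, 6L)
  expect_equal(back$cascade$model_size, 128L)
  expect_equal(back$cascade$threshold, 0.4)
  expect_true(back$cascade$refine_without_ett)
  expect_equal(back$aug$max_disp_px, 10)

  write_train_config(sched, casc, NULL, path)
  expect_null(read_train_config(path)$aug)
})

test_that("stage-2/3 crops are centered on the (jittered) ground truth", {
  set.seed(50)
  p <- synth_params(image_h = 128, image_w = 128)
  ex <- render_exam(p, ett_present = TRUE)
  cfg <- cascade_config(model_size = 64)

  crops0 <- make_stage23_crops(list(ex), cfg, jitter_sigma_px = 0)
  r <- crops0[[1]]
  # zero jitter: the ground-truth carina sits at the crop center, up to the
  # half-pixel rounding of the window start (one crop pixel here)
  expect_lt(abs(r$y[1] - 0.5), 0.017)
  expect_lt(abs(r$y[2] - 0.5), 0.017)
  expect_equal(dim(r$x), c(r$window$out_h, r$window$out_w))
  expect_equal(r$window$out_h / r$window$out_w, 2)

  # jitter spread: ~99.7% of draws below 3 sigma
  draws <- replicate(1000, rnorm(1, 0, 8))
  expect_gt(mean(abs(draws) < 24), 0.985)
})

test_that("crop targets are consistent with the geometry maps", {
  set.seed(51)
  p <- synth_params(image_h = 128, image_w = 128)
  ex <- render_exam(p, ett_present = TRUE)
  cfg <- cascade_config(model_size = 64)
  r <- make_stage23_crops(list(ex), cfg, jitter_sigma_px = 5)[[1]]
  # invert the stored maps: normalized CROP target -> ORIGINAL landmark
  pre <- preprocess(ex$image, ex$spacing, 64)
  ck <- denormalize_coords(r$y[1], r$y[2], r$window$out_h, r$window$out_w, "CROP")
  back <- unmap_point(unmap_point(ck, r$window$map), pre$map)
  expect_equal(back$y, ex$carina$y, tolerance = 1e-9)
  expect_equal(back$x, ex$carina$x, tolerance = 1e-9)
})

test_that("train_stage runs the schedule and reduces loss on easy data", {
  set.seed(52)
  p <- synth_params(image_h = 64, image_w = 64, noise_sd = 0.02,
                    distractor_prob = 0)
  man <- generate_dataset(24, c(1, 1), p, seed = 53)
  exams <- attr(man, "exams")
  cfg <- backbone_config(c(2, 2), c(6, 8), "regression", 2,
                         input_h = 32, input_w = 32)
  sch <- train_schedule(seed = 2)
  fit <- train_stage("stage1", exams, cfg, sch)
  expect_equal(nrow(fit$log), 4L)  # 3 + 1 epochs
  expect_equal(fit$log$lr, c(rep(5e-4, 3), 5e-5))
  expect_lt(fit$log$mean_loss[4], fit$log$mean_loss[1])
  # at most one non-monotone step across epochs
  expect_lte(sum(diff(fit$log$mean_loss) > 0), 1)

  expect_error(train_stage("stage1", list(), cfg, sch),
               class = "ettc_input_error")
})

test_that("training is reproducible under the schedule seed", {
  set.seed(54)
  p <- synth_params(image_h = 64, image_w = 64)
  man <- generate_dataset(10, c(1, 1), p, seed = 55)
  exams <- attr(man, "exams")
  cfg <- backbone_config(c(1, 1), c(4, 6), "regression", 2,
                         input_h = 32, input_w = 32)
  sch <- train_schedule(epochs_initial = 1, epochs_finetune = 0, seed = 9)
  f1 <- train_stage("stage1", exams, cfg, sch)
  f2 <- train_stage("stage1", exams, cfg, sch)
  expect_equal(f1$log$mean_loss, f2$log$mean_loss, tolerance = 1e-4)
})

test_that("cross-validation never leaks a test patient into training", {
  set.seed(56)
  p <- synth_params(image_h = 64, image_w = 64)
  man <- generate_dataset(10, c(1, 2), p, seed = 57)
  exams <- attr(man, "exams")
  manifest <- data.frame(
    exam_id = vapply(exams, `[[`, character(1), "exam_id"),
    patient_id = vapply(exams, `[[`, character(1), "patient_id"))
  folds <- make_folds(manifest, k = 5, seed = 1)
  for (f in 0:4) {
    test_pat <- manifest$patient_id[folds$exam_fold[manifest$exam_id] == f]
    train_pat <- manifest$patient_id[folds$exam_fold[manifest$exam_id] != f]
    expect_length(intersect(test_pat, train_pat), 0)
  }
})
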