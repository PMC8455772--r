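# cascade plumbing tests use tiny constant-output networks (head W = 0)
# so stage behavior is exactly controlled without training

tiny_models <- function(model_size = 64, prob_logits = c(0, 0),
                        s3 = c(0.5, 0.5, 0.25, 0.5)) {
  crop_h <- model_size / 2; crop_w <- model_size / 4
  list(
    stage1 = make_const_net(
      backbone_config(c(1, 1), c(3, 4), "regression", 2,
                      input_h = model_size, input_w = model_size),
      c(0.5, 0.5)),
    stage2 = make_const_net(
      backbone_config(c(1, 1), c(3, 4), "classification", 2,
                      input_h = crop_h, input_w = crop_w),
      prob_logits),
    stage3 = make_const_net(
      backbone_config(c(1, 1), c(3, 4), "regression", 4,
                      input_h = crop_h, input_w = crop_w),
      s3))
}

synth_64 <- function(seed, ett = TRUE) {
  withr_seed <- ettcascade:::withr_seed
  withr_seed(seed, render_exam(synth_params(image_h = 64, image_w = 64),
                               "P1", "E1", ett_present = ett))
}

test_that("run_stage1 denormalizes and clamps into frame bounds", {
  cfg <- backbone_config(c(1, 1), c(3, 4), "regression", 2,
                         input_h = 64, input_w = 64)
  img <- rand_image(64)
  p <- run_stage1(make_const_net(cfg, c(0.5, 0.5)), img)
  expect_equal(c(p$y, p$x), c(32, 32))
  expect_equal(p$frame, "MODEL")
  # out-of-range outputs are clamped, not errors
  p2 <- run_stage1(make_const_net(cfg, c(-0.3, 1.4)), img)
  expect_gte(p2$y, 0); expect_lt(p2$x, 64)

  # (0.5, 0.5) on a 512 input maps to (256, 256)
  cfg512 <- backbone_config(c(1, 1), c(2, 2), "regression", 2,
                            input_h = 512, input_w = 512)
  p3 <- run_stage1(make_const_net(cfg512, c(0.5, 0.5)), rand_image(512))
  expect_equal(c(p3$y, p3$x), c(256, 256))
})

test_that("run_stage2 emits a softmax probability", {
  cfg <- tiny_cls_config(h = 32, w = 16)
  expect_equal(run_stage2(make_const_net(cfg, c(0, 0)), rand_image(32, 16)), 0.5)
  expect_gt(run_stage2(make_const_net(cfg, c(-3, 3)), rand_image(32, 16)), 0.99)
  for (lg in list(c(1, 2), c(-5, 0.3), c(4, 4))) {
    pr <- run_stage2(make_const_net(cfg, lg), rand_image(32, 16))
    expect_gte(pr, 0); expect_lte(pr, 1)
  }
})

test_that("run_stage3 unmaps crop coordinates through the window", {
  w <- crop_window_for_carina(landmark(300, 256, "MODEL"), 512, 512)
  cfg <- backbone_config(c(1, 1), c(2, 3), "regression", 4,
                         input_h = 256, input_w = 128)
  # normalized (0.5, 0.5) = crop pixel (128, 64) -> MODEL (300, 256)
  net <- make_const_net(cfg, c(0.5, 0.5, 0.25, 0.5))
  r <- run_stage3(net, rand_image(256, 128), w)
  expect_equal(c(r$carina$y, r$carina$x), c(300, 256))
  expect_equal(r$carina$frame, "MODEL")
  # crop (64, 64) -> MODEL row 172 + 64 = 236
  expect_equal(c(r$tip$y, r$tip$x), c(236, 256))
  # refined carina lies inside the window by construction of the map
  expect_gte(r$carina$y, w$row_start); expect_lt(r$carina$y, w$row_stop)
})

test_that("cascade gates stage 3 on the classifier decision", {
  ex <- synth_64(60)
  cfg <- cascade_config(model_size = 64)
  neg <- run_cascade(tiny_models(64, prob_logits = c(5, -5)), ex, cfg)
  expect_false(neg$ett_present)
  expect_null(neg$ett_tip)
  expect_null(neg$carina_refined)        # coarse carina is final
  expect_true(is.na(neg$tip_carina_distance_cm))
  expect_lt(neg$ett_probability, 0.5)

  pos <- run_cascade(tiny_models(64, prob_logits = c(-5, 5)), ex, cfg)
  expect_true(pos$ett_present)
  expect_false(is.null(pos$ett_tip))
  expect_true(is.finite(pos$tip_carina_distance_cm))
  expect_gte(pos$tip_carina_distance_cm, 0)

  # configurable always-refine for negatives
  cfg2 <- cascade_config(model_size = 64, refine_without_ett = TRUE)
  neg2 <- run_cascade(tiny_models(64, prob_logits = c(5, -5)), ex, cfg2)
  expect_false(neg2$ett_present)
  expect_false(is.null(neg2$carina_refined))
  expect_null(neg2$ett_tip)
})

test_that("cascade predictions satisfy their invariants on random batches", {
  set.seed(61)
  cfg <- cascade_config(model_size = 64)
  for (i in 1:10) {
    ex <- synth_64(1000 + i, ett = runif(1) < 0.5)
    models <- tiny_models(64, prob_logits = rnorm(2, sd = 2))
    pr <- run_cascade(models, ex, cfg)
    expect_identical(pr$ett_present, pr$ett_probability >= cfg$threshold)
    expect_identical(is.finite(pr$tip_carina_distance_cm), !is.null(pr$ett_tip))
    expect_equal(pr$carina_coarse$frame, "MODEL")
    # frame provenance: reported ORIGINAL points fall inside the image
    expect_gte(pr$carina_coarse_orig$y, 0)
    expect_lt(pr$carina_coarse_orig$y, nrow(ex$image))
    expect_gte(pr$carina_coarse_orig$x, 0)
    expect_lt(pr$carina_coarse_orig$x, ncol(ex$image))
    expect_equal(pr$carina_coarse_orig$frame, "ORIGINAL")
  }
})

test_that("inference is deterministic for fixed checkpoints", {
  ex <- synth_64(62)
  models <- tiny_models(64, prob_logits = c(-1, 1))
  cfg <- cascade_config(model_size = 64)
  a <- run_cascade(models, ex, cfg)
  b <- run_cascade(models, ex, cfg)
  expect_identical(predictions_to_df(list(a)), predictions_to_df(list(b)))
})

test_that("missing spacing is gated behind allow_pixel_units", {
  ex <- synth_64(63)
  ex$spacing <- NULL
  models <- tiny_models(64, prob_logits = c(-5, 5))
  cfg <- cascade_config(model_size = 64)
  expect_error(run_cascade(models, ex, cfg), class = "ettc_spacing_error")
  pr <- run_cascade(models, ex, cfg, allow_pixel_units = TRUE)
  expect_true(is.na(pr$tip_carina_distance_cm))
  expect_true(is.finite(pr$tip_carina_distance_px))
})

test_that("prediction writers emit the documented schemas", {
  ex <- synth_64(64)
  models <- tiny_models(64, prob_logits = c(-2, 2))
  pr <- run_cascade(models, ex, cascade_config(model_size = 64))
  df <- predictions_to_df(list(pr))
  expect_named(df, c("exam_id", "patient_id", "ett_probability", "ett_present",
                     "carina_y", "carina_x", "tip_y", "tip_x", "distance_cm"))
  csvp <- tempfile(fileext = ".csv")
  write_predictions_csv(list(pr), csvp)
  expect_equal(nrow(read.csv(csvp)), 1)
  jsp <- tempfile(fileext = ".json")
  write_predictions_json(list(pr), jsp)
  parsed <- jsonlite::read_json(jsp, simplifyVector = TRUE)
  expect_equal(parsed$schema, "ettcascade/predictions/v1")
  expect_equal(parsed$predictions$ett_probability[1], pr$ett_probability)
})

test_that("exams without pixel data are rejected", {
  models <- tiny_models(64)
  expect_error(run_cascade(models, list(spacing = pixel_spacing(0.7)),
                           cascade_config(model_size = 64)),
               class = "ettc_input_error")
})
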