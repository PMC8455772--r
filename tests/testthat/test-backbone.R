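test_that("default configuration matches the published topology", {
  for (stage in c("stage1", "stage2", "stage3")) {
    cfg <- default_config(stage)
    expect_equal(sum(cfg$n_blocks), 30L)              # 30 conv blocks
    expect_equal(length(cfg$n_blocks) - 1L, 7L)       # 7 stride-2 subsamplings
    expect_equal(cfg$channels[1], 48L)
    expect_equal(cfg$channels[length(cfg$channels)], 128L)
    expect_equal(cfg$n_blocks[1], 5L)                 # 5 blocks before 1st subsample
    expect_equal(cfg$n_blocks[2], 4L)                 # 4 before the 2nd
    expect_false(is.unsorted(cfg$channels))
  }
  s1 <- default_config("stage1")
  expect_equal(c(s1$input_h, s1$input_w), c(512L, 512L))
  expect_equal(s1$head_dim, 2L)
  s2 <- default_config("stage2")
  expect_equal(c(s2$input_h, s2$input_w), c(256L, 128L))
  expect_equal(s2$head_type, "classification")
  s3 <- default_config("stage3")
  expect_equal(s3$head_dim, 4L)
})

test_that("instantiated default backbone reports the published structure", {
  net <- build_network(default_config("stage1"), seed = 1)
  info <- network_info(net)
  expect_equal(info$n_blocks, 30L)
  expect_equal(info$n_stride2, 7L)
  expect_equal(info$block_channels[1], 48L)
  expect_equal(info$block_channels[30], 128L)
  # 5 blocks at level 1 (before the first subsample), 4 at level 2
  expect_equal(sum(info$block_level == 1), 5L)
  expect_equal(sum(info$block_level == 2), 4L)
  # stride-2 blocks are exactly the level entries
  expect_equal(which(info$block_stride == 2), c(6L, 10L, 14L, 18L, 22L, 25L, 28L))
  # final feature map: 512 / 2^7 = 4
  expect_equal(c(info$feat_h, info$feat_w), c(4L, 4L))

  info23 <- network_info(build_network(default_config("stage3"), seed = 1))
  expect_equal(c(info23$feat_h, info23$feat_w), c(2L, 1L))  # 256/2^7, 128/2^7
})

test_that("forward pass shape follows ceil(h / 2^subsamplings)", {
  # an 8-level (7-subsampling) config small enough to run: channels constant
  cfg <- backbone_config(rep(1L, 8), rep(3L, 8), "regression", 2,
                         input_h = 128, input_w = 128)
  net <- build_network(cfg, seed = 2)
  info <- network_info(net)
  expect_equal(c(info$feat_h, info$feat_w), c(1L, 1L))
  out <- forward_network(net, rand_image(128), train = TRUE)
  expect_equal(dim(out), c(1L, 2L))

  cfg2 <- tiny_cls_config(h = 24, w = 12)
  info2 <- network_info(build_network(cfg2, 1))
  expect_equal(c(info2$feat_h, info2$feat_w), c(12L, 6L))

  expect_error(backbone_config(rep(1L, 8), rep(3L, 8), "regression", 2,
                               input_h = 64, input_w = 512),
               class = "ettc_config_error")
})

test_that("weight initialization is seed-deterministic", {
  cfg <- tiny_reg_config()
  a <- cnet_state(build_network(cfg, seed = 7))
  b <- cnet_state(build_network(cfg, seed = 7))
  d <- cnet_state(build_network(cfg, seed = 8))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("one optimization step changes every parameter tensor", {
  set.seed(10)
  cfg <- tiny_reg_config()
  net <- build_network(cfg, seed = 3)
  before <- cnet_state(net)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  train_network_batch(net, x, matrix(runif(8), 4, 2), lr = 1e-3)
  after <- cnet_state(net)
  param_names <- grep("^(W|gamma|beta|headW|headb)", names(before), value = TRUE)
  for (nm in param_names) {
    expect_false(identical(before[[nm]], after[[nm]]), info = nm)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  for (cfg in list(tiny_reg_config(), tiny_cls_config())) {
    net <- build_network(cfg, seed = 4)
    x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
    y <- if (cfg$head_type == "regression") matrix(runif(6), 3, 2) else c(0L, 1L, 1L)
    g <- ettcascade:::cnet_grad(net$ptr, x, y, TRUE)
    st <- cnet_state(net)
    eps <- 1e-6
    for (nm in c("W0", "W2", "gamma1", "beta3", "headW", "headb")) {
      i <- sample(length(st[[nm]]), 1)
      st2 <- st; st2[[nm]][i] <- st2[[nm]][i] + eps
      cnet_restore(net, st2)
      lp <- ettcascade:::cnet_loss(net$ptr, x, y, TRUE)
      st2[[nm]][i] <- st2[[nm]][i] - 2 * eps
      cnet_restore(net, st2)
      lm <- ettcascade:::cnet_loss(net$ptr, x, y, TRUE)
      cnet_restore(net, st)
      expect_lt(abs((lp - lm) / (2 * eps) - g[[nm]][i]),
                1e-4 * max(1, abs(g[[nm]][i])))
    }
  }
})

test_that("regression loss is the MSE of the raw logits", {
  expect_identical(regression_loss(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(regression_loss(c(0.5, 0.5), c(0.25, 0.75)), 0.0625)
  a <- runif(4); b <- runif(4)
  expect_equal(regression_loss(a, b), regression_loss(b, a))
  expect_error(regression_loss(1:3, 1:2), class = "ettc_input_error")
})

test_that("classification loss is binary softmax cross-entropy", {
  expect_equal(classification_loss(c(0, 0), 0), log(2))
  expect_equal(classification_loss(c(10, -10), 0), log(1 + exp(-20)))
  expect_equal(classification_loss(c(10, -10), 0), 2.061154e-09,
               tolerance = 1e-6)
  for (i in 1:20) {
    lg <- rnorm(2, sd = 5)
    expect_gte(classification_loss(lg, sample(0:1, 1)), 0)
  }
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
})

test_that("checkpoints round-trip through disk", {
  set.seed(12)
  net <- build_network(tiny_reg_config(), seed = 5)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  train_network_batch(net, x, matrix(runif(4), 2, 2), 1e-3)
  base <- file.path(tempdir(), "ckpt_test")
  save_checkpoint(net, base)
  expect_true(file.exists(paste0(base, ".json")))
  net2 <- load_checkpoint(base)
  expect_equal(forward_network(net2, x), forward_network(net, x))
  expect_equal(net2$config$n_blocks, net$config$n_blocks)
})

test_that("reduced test-scale config keeps the structural invariants", {
  cfg <- test_scale_config("stage1")
  expect_equal(sum(cfg$n_blocks), 10L)
  expect_equal(length(cfg$n_blocks), 4L)
  info <- network_info(build_network(cfg, 1))
  expect_equal(info$n_blocks, 10L)
  expect_equal(info$n_stride2, 3L)
  expect_false(is.unsorted(info$block_channels))
})
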