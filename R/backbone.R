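# Backbone construction: declarative topology -> Rcpp network handle.

#' Declarative backbone topology
#'
#' The shared backbone is a stack of conv blocks (3x3 convolution, batch
#' normalization, LeakyReLU) organised in resolution levels. Every level
#' after the first is entered through a stride-2 convolution that performs
#' the subsampling and carries the channel increase; stride-2 blocks count
#' toward the block total.
#'
#' @param n_blocks Integer vector: conv blocks per resolution level (first
#'   level at full resolution).
#' @param channels Integer vector, same length: channel depth per level,
#'   positive and non-decreasing.
#' @param head `"regression"` (linear coordinate readout) or
#'   `"classification"` (2-way softmax).
#' @param head_dim Output dimension: 2 for a single landmark or binary
#'   logits, 4 for the carina+tip refinement head.
#' @param input_h,input_w Input matrix shape in pixels.
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.3).
#' @param head_style `"pool"` (default for regression: linear readout over
#'   a coarsely average-pooled final feature map), `"flatten"` (no pooling)
#'   or `"gap"` (global average pooling, default for classification).
#' @param pool_grid Target grid of the `"pool"` head (per axis, capped at
#'   the feature-map size; default 4).
#' @return A `backbone_config`.
#' @export
backbone_config <- function(n_blocks, channels, head = c("regression", "classification"),
                            head_dim = 2, input_h = 512, input_w = 512,
                            leaky_slope = 0.3, head_style = NULL,
                            pool_grid = 4) {
  head <- match.arg(head)
  n_blocks <- as.integer(n_blocks)
  channels <- as.integer(channels)
  if (length(n_blocks) != length(channels) || length(n_blocks) < 1) {
    ettc_error("n_blocks and channels must be equal-length non-empty vectors",
               "ettc_config_error")
  }
  if (any(n_blocks < 1) || any(channels < 1) || is.unsorted(channels)) {
    ettc_error("channel counts must be positive and non-decreasing, blocks >= 1 per level",
               "ettc_config_error")
  }
  n_sub <- length(n_blocks) - 1L
  if (min(input_h, input_w) < 2^n_sub) {
    ettc_error(sprintf("input %dx%d too small for %d subsamplings (needs >= %d px per axis)",
                       input_h, input_w, n_sub, 2^n_sub), "ettc_config_error")
  }
  if (is.null(head_style)) {
    head_style <- if (head == "regression") "pool" else "gap"
  }
  head_style <- match.arg(head_style, c("pool", "flatten", "gap"))
  structure(list(n_blocks = n_blocks, channels = channels,
                 head_type = head, head_dim = as.integer(head_dim),
                 input_h = as.integer(input_h), input_w = as.integer(input_w),
                 leaky_slope = leaky_slope, head_style = head_style,
                 pool_grid = as.integer(pool_grid)),
            class = "backbone_config")
}

#' Default full-scale backbone configuration per cascade stage
#'
#' Eight resolution levels with blocks `[5, 4, 4, 4, 4, 3, 3, 3]` (30 conv
#' blocks in total, 7 of them stride-2 level entries) and channel schedule
#' `[48, 56, 64, 76, 88, 100, 114, 128]`. Stage 1 regresses the carina on
#' the 512 x 512 model input; stage 2 classifies ETT presence on the
#' 256 x 128 crop; stage 3 regresses refined carina + ETT tip (4 outputs)
#' on the same crop.
#'
#' @param stage `"stage1"`, `"stage2"` or `"stage3"`.
#' @return A `backbone_config`.
#' @export
default_config <- function(stage = c("stage1", "stage2", "stage3")) {
  stage <- match.arg(stage)
  blocks <- c(5L, 4L, 4L, 4L, 4L, 3L, 3L, 3L)
  chans <- c(48L, 56L, 64L, 76L, 88L, 100L, 114L, 128L)
  switch(stage,
    stage1 = backbone_config(blocks, chans, "regression", 2, 512, 512),
    stage2 = backbone_config(blocks, chans, "classification", 2, 256, 128),
    stage3 = backbone_config(blocks, chans, "regression", 4, 256, 128))
}

#' Reduced test-scale configuration (CPU-trainable)
#'
#' Four levels, blocks `[4, 2, 2, 2]` (10 blocks, 3 stride-2), channels
#' `[12, 16, 24, 32]`. Stage 1 runs on a 128 x 128 model input; stages 2-3
#' on the matching 128 x 64 crop. Structural invariants (stride-2 level
#' entries, channel growth, head wiring) are identical to the full scale.
#'
#' @inheritParams default_config
#' @return A `backbone_config`.
#' @export
test_scale_config <- function(stage = c("stage1", "stage2", "stage3")) {
  stage <- match.arg(stage)
  blocks <- c(4L, 2L, 2L, 2L)
  chans <- c(12L, 16L, 24L, 32L)
  switch(stage,
    stage1 = backbone_config(blocks, chans, "regression", 2, 128, 128),
    stage2 = backbone_config(blocks, chans, "classification", 2, 128, 64),
    stage3 = backbone_config(blocks, chans, "regression", 4, 128, 64))
}

#' Build (and Xavier-initialize) a network from a configuration
#'
#' @param config A `backbone_config`.
#' @param seed Integer seed for the Xavier-uniform weight initialization;
#'   two builds with the same seed have identical parameters.
#' @return A `cxr_net` handle.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  ptr <- cnet_create(unclass(config), as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "cxr_net")
}

#' Introspect a built network
#'
#' @param net A `cxr_net`.
#' @return A list with block/stride-2 counts, per-block level/stride/channel
#'   vectors, final feature-map shape and parameter count.
#' @export
network_info <- function(net) {
  cnet_info(net$ptr)
}

#' @export
print.cxr_net <- function(x, ...) {
  info <- network_info(x)
  cat(sprintf("<cxr_net %s head, %d blocks (%d stride-2), channels %d..%d, input %dx%d>\n",
              x$config$head_type, info$n_blocks, info$n_stride2,
              min(info$block_channels), max(info$block_channels),
              x$config$input_h, x$config$input_w))
  invisible(x)
}

as_batch <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(length(dim(x)) == 3)
  x
}

#' Forward pass
#'
#' @param net A `cxr_net`.
#' @param x A single image matrix or an `(H, W, N)` array matching the
#'   configured input shape.
#' @param train Use batch statistics in the batch-norm layers (training
#'   mode). Default `FALSE`: inference with running statistics.
#' @return An `N x head_dim` matrix of raw logits.
#' @export
forward_network <- function(net, x, train = FALSE) {
  x <- as_batch(x)
  if (dim(x)[1] != net$config$input_h || dim(x)[2] != net$config$input_w) {
    ettc_error(sprintf("input %dx%d does not match configured %dx%d",
                       dim(x)[1], dim(x)[2],
                       net$config$input_h, net$config$input_w),
               "ettc_input_error")
  }
  cnet_forward(net$ptr, x, train)
}

#' One Adam training step on a mini-batch
#'
#' @inheritParams forward_network
#' @param y Targets: an `N x head_dim` matrix of normalized coordinates
#'   (regression) or an integer vector of 0/1 labels (classification).
#' @param lr Learning rate.
#' @return The mini-batch loss (invisible).
#' @export
train_network_batch <- function(net, x, y, lr) {
  x <- as_batch(x)
  if (net$config$head_type == "regression") {
    y <- matrix(as.numeric(y), nrow = dim(x)[3])
    stopifnot(ncol(y) == net$config$head_dim)
  } else {
    y <- as.integer(y)
    stopifnot(all(y %in% c(0L, 1L)), length(y) == dim(x)[3])
  }
  invisible(cnet_train_batch(net$ptr, x, y, lr))
}

#' Mean-squared-error regression loss
#'
#' The regression heads emit raw linear logits trained against normalized
#' coordinates in `[0, 1]`.
#'
#' @param pred,target Equal-length numeric vectors (or matrices).
#' @return Mean of squared differences.
#' @export
regression_loss <- function(pred, target) {
  if (length(pred) != length(target)) {
    ettc_error("pred and target lengths differ", "ettc_input_error")
  }
  mean((as.numeric(pred) - as.numeric(target))^2)
}

#' Binary softmax cross-entropy loss
#'
#' @param logits Numeric 2-vector of class logits.
#' @param label Class index, 0 or 1.
#' @return `-log softmax(logits)[label + 1]`.
#' @export
classification_loss <- function(logits, label) {
  stopifnot(length(logits) == 2, label %in% c(0, 1), all(is.finite(logits)))
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  lse - logits[label + 1]
}

#' Softmax over a logit vector
#' @param logits Numeric vector.
#' @return Probabilities summing to 1.
#' @export
softmax <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Save / load a network checkpoint
#'
#' Weights and optimizer-independent state are written as an RDS blob next
#' to a plain-text JSON record of the `backbone_config`, so a checkpoint is
#' self-describing.
#'
#' @param net A `cxr_net`.
#' @param path Base path without extension; writes `<path>.rds` and
#'   `<path>.json`.
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: a
#'   rebuilt `cxr_net`.
#' @export
save_checkpoint <- function(net, path) {
  state <- cnet_get_state(net$ptr)
  cfg <- unclass(net$config)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  saveRDS(state, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- backbone_config(cfg$n_blocks, cfg$channels, cfg$head_type,
                            cfg$head_dim, cfg$input_h, cfg$input_w,
                            cfg$leaky_slope, cfg$head_style,
                            cfg$pool_grid %||% 4)
  net <- build_network(config, seed = 0L)
  cnet_set_state(net$ptr, readRDS(paste0(path, ".rds")))
  net
}
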