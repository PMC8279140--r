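#' Declarative description of one backbone U-Net
#'
#' @param backbone One of `"resnet50"`, `"densenet169"`, `"se_resnext50"`,
#'   `"efficientnet_b4"`, `"se_resnext101"`, `"efficientnet_b3"`, `"tiny"`.
#' @param decoder_channels Five decoder block widths, deep to shallow
#'   (default halving 256 to 16).
#' @param decoder_batchnorm Use batch normalization in the decoder blocks.
#'   The published presets disable it for DenseNet169 only.
#' @param pretrained Accept externally loaded backbone weights (the builder
#'   always initializes randomly; weights can be injected afterwards via
#'   `net_set_params()`-style snapshots).
#' @param input_channels Number of input channels (3: replicated grayscale).
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(backbone,
                              decoder_channels = c(256L, 128L, 64L, 32L, 16L),
                              decoder_batchnorm = TRUE,
                              pretrained = FALSE,
                              input_channels = 3L) {
  backbones <- c("resnet50", "densenet169", "se_resnext50", "efficientnet_b4",
                 "se_resnext101", "efficientnet_b3", "tiny")
  if (!backbone %in% backbones) stop("unsupported backbone: ", backbone)
  stopifnot(length(decoder_channels) == 5L, all(decoder_channels >= 1))
  structure(list(backbone = backbone,
                 decoder_channels = as.integer(decoder_channels),
                 decoder_batchnorm = isTRUE(decoder_batchnorm),
                 pretrained = isTRUE(pretrained),
                 input_channels = as.integer(input_channels)),
            class = "architecture_spec")
}

#' Published architecture presets
#'
#' `resnet50_unet`, `densenet169_unet`, `se_resnext50_unet` and
#' `efficientnetb4_unet` are the four ensemble members; `se_resnext101_unet`
#' and `efficientnetb3_unet` are optional variants. `tiny_unet` is a small
#' five-stage plain-convolution backbone for CPU-scale training experiments.
#'
#' @param name Preset name.
#' @return An `architecture_spec`.
#' @export
bunet_preset <- function(name) {
  switch(name,
    resnet50_unet = architecture_spec("resnet50"),
    densenet169_unet = architecture_spec("densenet169", decoder_batchnorm = FALSE),
    se_resnext50_unet = architecture_spec("se_resnext50"),
    efficientnetb4_unet = architecture_spec("efficientnet_b4"),
    se_resnext101_unet = architecture_spec("se_resnext101"),
    efficientnetb3_unet = architecture_spec("efficientnet_b3"),
    tiny_unet = architecture_spec("tiny",
                                  decoder_channels = c(40L, 32L, 24L, 16L, 8L)),
    stop("unknown preset: ", name))
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("architecture_spec:", x$backbone,
      "| decoder", paste(x$decoder_channels, collapse = "-"),
      "| decoder BN:", x$decoder_batchnorm, "\n")
  invisible(x)
}

# --- backbone graph builders ----------------------------------------------
# Each returns list(bottleneck = node, skips = c(4 node names, deep->shallow:
# /16, /8, /4, /2)).

build_resnet_family <- function(B, blocks, se = FALSE, groups = 1L,
                                width_ratio = 0.25) {
  x <- nb_cba(B, "stem", "input", 64L, k = 7L, stride = 2L)
  stem_act <- x
  x <- nb_maxpool(B, "stem_pool", x, k = 3L, stride = 2L)
  outs <- c(256L, 512L, 1024L, 2048L)
  stage_out <- character(4L)
  for (st in 1:4) {
    o <- outs[st]
    mid <- if (groups > 1L) o %/% 2L else as.integer(o * width_ratio)
    for (b in seq_len(blocks[st])) {
      pre <- sprintf("s%db%d", st, b)
      s <- if (st > 1L && b == 1L) 2L else 1L
      inx <- x
      y <- nb_cba(B, paste0(pre, "_1"), inx, mid, k = 1L)
      y <- nb_cba(B, paste0(pre, "_2"), y, mid, k = 3L, stride = s,
                  groups = groups)
      y <- nb_cba(B, paste0(pre, "_3"), y, o, k = 1L, act = NULL)
      if (se) {
        g <- nb_gap(B, paste0(pre, "_se_gap"), y)
        r <- max(1L, o %/% 16L)
        g <- nb_conv(B, paste0(pre, "_se_fc1"), g, r, k = 1L, bias = TRUE)
        g <- nb_act(B, paste0(pre, "_se_relu"), g, "relu")
        g <- nb_conv(B, paste0(pre, "_se_fc2"), g, o, k = 1L, bias = TRUE)
        g <- nb_act(B, paste0(pre, "_se_sig"), g, "sigmoid")
        y <- nb_mul(B, paste0(pre, "_se_mul"), c(y, g))
      }
      if (b == 1L) {
        sh <- nb_cba(B, paste0(pre, "_down"), inx, o, k = 1L, stride = s,
                     act = NULL)
      } else sh <- inx
      y <- nb_add_op(B, paste0(pre, "_add"), c(y, sh))
      x <- nb_act(B, paste0(pre, "_out"), y, "relu")
    }
    stage_out[st] <- x
  }
  list(bottleneck = stage_out[4L],
       skips = c(stage_out[3L], stage_out[2L], stage_out[1L], stem_act))
}

build_densenet169 <- function(B) {
  growth <- 32L
  x <- nb_cba(B, "stem", "input", 64L, k = 7L, stride = 2L)
  stem_act <- x
  x <- nb_maxpool(B, "stem_pool", x, k = 3L, stride = 2L)
  layers <- c(6L, 12L, 32L, 32L)
  ch <- 64L
  trans_tap <- character(3L)
  for (blk in 1:4) {
    for (l in seq_len(layers[blk])) {
      pre <- sprintf("d%dl%d", blk, l)
      y <- nb_bn(B, paste0(pre, "_bn1"), x)
      y <- nb_act(B, paste0(pre, "_relu1"), y)
      y <- nb_conv(B, paste0(pre, "_conv1"), y, 4L * growth, k = 1L, bias = FALSE)
      y <- nb_bn(B, paste0(pre, "_bn2"), y)
      y <- nb_act(B, paste0(pre, "_relu2"), y)
      y <- nb_conv(B, paste0(pre, "_conv2"), y, growth, k = 3L, bias = FALSE)
      x <- nb_concat(B, paste0(pre, "_cat"), c(x, y))
      ch <- ch + growth
    }
    if (blk < 4L) {
      pre <- sprintf("t%d", blk)
      y <- nb_bn(B, paste0(pre, "_bn"), x)
      y <- nb_act(B, paste0(pre, "_relu"), y)
      ch <- ch %/% 2L
      y <- nb_conv(B, paste0(pre, "_conv"), y, ch, k = 1L, bias = FALSE)
      trans_tap[blk] <- y  # compressed features at pre-pool resolution
      x <- nb_avgpool(B, paste0(pre, "_pool"), y, k = 2L, stride = 2L)
    }
  }
  x <- nb_bn(B, "final_bn", x)
  x <- nb_act(B, "final_relu", x)
  list(bottleneck = x,
       skips = c(trans_tap[3L], trans_tap[2L], trans_tap[1L], stem_act))
}

effnet_round_filters <- function(f, wc, divisor = 8L) {
  f <- f * wc
  nf <- max(divisor, as.integer(f + divisor / 2) %/% divisor * divisor)
  if (nf < 0.9 * f) nf <- nf + divisor
  as.integer(nf)
}

effnet_round_repeats <- function(r, dc) as.integer(ceiling(r * dc))

build_efficientnet <- function(B, width_coef, depth_coef) {
  base <- list(e = c(1, 6, 6, 6, 6, 6, 6),
               out = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
               r = c(1L, 2L, 2L, 3L, 3L, 4L, 1L),
               k = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
               s = c(1L, 2L, 2L, 2L, 1L, 2L, 1L))
  stem_f <- effnet_round_filters(32L, width_coef)
  x <- nb_cba(B, "stem", "input", stem_f, k = 3L, stride = 2L, act = "swish")
  ch <- stem_f
  taps <- character(0)
  for (st in 1:7) {
    out <- effnet_round_filters(base$out[st], width_coef)
    reps <- effnet_round_repeats(base$r[st], depth_coef)
    for (b in seq_len(reps)) {
      pre <- sprintf("mb%db%d", st, b)
      s <- if (b == 1L) base$s[st] else 1L
      inx <- x
      in_ch <- ch
      exp_ch <- as.integer(in_ch * base$e[st])
      y <- inx
      if (base$e[st] != 1) {
        y <- nb_cba(B, paste0(pre, "_exp"), y, exp_ch, k = 1L, act = "swish")
      }
      if (b == 1L && s == 2L) taps <- c(taps, y)  # pre-downsample expansion
      y <- nb_cba(B, paste0(pre, "_dw"), y, exp_ch, k = base$k[st], stride = s,
                  groups = exp_ch, act = "swish")
      se_ch <- max(1L, as.integer(in_ch * 0.25))
      g <- nb_gap(B, paste0(pre, "_se_gap"), y)
      g <- nb_conv(B, paste0(pre, "_se_fc1"), g, se_ch, k = 1L, bias = TRUE)
      g <- nb_act(B, paste0(pre, "_se_swish"), g, "swish")
      g <- nb_conv(B, paste0(pre, "_se_fc2"), g, exp_ch, k = 1L, bias = TRUE)
      g <- nb_act(B, paste0(pre, "_se_sig"), g, "sigmoid")
      y <- nb_mul(B, paste0(pre, "_se_mul"), c(y, g))
      y <- nb_cba(B, paste0(pre, "_proj"), y, out, k = 1L, act = NULL)
      if (s == 1L && in_ch == out) {
        y <- nb_add_op(B, paste0(pre, "_add"), c(y, inx))
      }
      x <- y
      ch <- out
    }
  }
  head_f <- effnet_round_filters(1280L, width_coef)
  x <- nb_cba(B, "top", x, head_f, k = 1L, act = "swish")
  # taps were recorded shallow->deep at /2, /4, /8, /16; decoder wants deep->shallow
  list(bottleneck = x, skips = rev(taps))
}

# Downsampling via 2x2 max-pooling and stride-1 3x3 convolutions: the spatial
# layout is left-right symmetric (no one-sided stride-2 padding), keeping the
# tiny model cheap and its geometry simple for CPU-scale experiments.
build_tiny_backbone <- function(B) {
  x <- nb_cba(B, "stem", "input", 16L, k = 3L)
  ch <- c(20L, 24L, 32L, 40L, 48L)
  taps <- character(0)
  for (i in 1:5) {
    x <- nb_maxpool(B, sprintf("pool%d", i), x, k = 2L, stride = 2L, pad = "valid")
    x <- nb_cba(B, sprintf("down%d", i), x, ch[i], k = 3L)
    if (i < 5L) taps <- c(taps, x)
  }
  list(bottleneck = x, skips = rev(taps))
}

build_decoder <- function(B, bottleneck, skips, channels, use_bn) {
  x <- bottleneck
  for (i in 1:5) {
    pre <- sprintf("dec%d", i)
    x <- nb_upsample(B, paste0(pre, "_up"), x, 2L)
    if (i <= 4L) x <- nb_concat(B, paste0(pre, "_cat"), c(x, skips[i]))
    x <- nb_cba(B, paste0(pre, "_a"), x, channels[i], k = 3L, bn = use_bn)
    x <- nb_cba(B, paste0(pre, "_b"), x, channels[i], k = 3L, bn = use_bn)
  }
  x <- nb_conv(B, "head_conv", x, 1L, k = 3L, bias = TRUE)
  nb_act(B, "head_sigmoid", x, "sigmoid")
}

#' Build a backbone U-Net from an architecture specification
#'
#' The encoder is the named classification backbone truncated before global
#' pooling and classifier; the decoder has five blocks of nearest-neighbour
#' 2x upsampling, skip concatenation (first four blocks), and two 3x3
#' convolution + (optional BN) + ReLU layers; the head is a 3x3 convolution
#' to one channel with a sigmoid, so an H x W x 3 input (H, W divisible by
#' 32) maps to an H x W probability map.
#'
#' @param spec An [architecture_spec()] or preset name for [bunet_preset()].
#' @param seed Optional integer seed for the random weight initialization.
#' @return A `bunet_network` handle.
#' @export
build_bunet <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- bunet_preset(spec)
  stopifnot(inherits(spec, "architecture_spec"))
  build <- function() {
    B <- new_builder(spec$input_channels)
    enc <- switch(spec$backbone,
      resnet50 = build_resnet_family(B, c(3L, 4L, 6L, 3L)),
      se_resnext50 = build_resnet_family(B, c(3L, 4L, 6L, 3L), se = TRUE,
                                         groups = 32L),
      se_resnext101 = build_resnet_family(B, c(3L, 4L, 23L, 3L), se = TRUE,
                                          groups = 32L),
      densenet169 = build_densenet169(B),
      efficientnet_b4 = build_efficientnet(B, 1.4, 1.8),
      efficientnet_b3 = build_efficientnet(B, 1.2, 1.4),
      tiny = build_tiny_backbone(B))
    out <- build_decoder(B, enc$bottleneck, enc$skips, spec$decoder_channels,
                         spec$decoder_batchnorm)
    pstore <- new.env(parent = emptyenv())
    for (nm in names(B$params)) assign(nm, B$params[[nm]], envir = pstore)
    structure(list(nodes = B$nodes, order = names(B$nodes), pstore = pstore,
                   channels = B$channels, input = "input", output = out,
                   spec = spec,
                   meta = list(decoder_blocks = 5L, skip_concats = 4L,
                               skip_taps = enc$skips, bottleneck = enc$bottleneck,
                               divisor = 32L)),
              class = "bunet_network")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Total trainable parameter count of a network
#'
#' Counts convolution weights/biases and batch-norm scale/shift; running
#' statistics are not trainable and are excluded.
#'
#' @param net A `bunet_network`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "bunet_network"))
  tot <- 0
  for (nm in ls(net$pstore)) {
    p <- get(nm, envir = net$pstore)
    for (tn in intersect(trainable_names, names(p))) tot <- tot + length(p[[tn]])
  }
  tot
}

#' @export
print.bunet_network <- function(x, ...) {
  cat("bunet_network:", x$spec$backbone, "|", length(x$order), "nodes |",
      format(count_parameters(x), big.mark = ","), "trainable parameters\n")
  invisible(x)
}

as_input_tensor <- function(x) {
  if (inherits(x, "model_input")) x <- x$tensor
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, dim = c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, dim = c(d, 1L))
  x
}

#' Run a network on an image tensor
#'
#' @param object A `bunet_network`.
#' @param x A `model_input`, an H x W x 3 array, or an H x W x 3 x N batch.
#' @param ... Unused.
#' @return An H x W probability matrix (or H x W x N array for batches).
#' @export
predict.bunet_network <- function(object, x, ...) {
  x <- as_input_tensor(x)
  d <- dim(x)
  if (d[1L] %% object$meta$divisor != 0L || d[2L] %% object$meta$divisor != 0L) {
    stop("input spatial size must be divisible by ", object$meta$divisor)
  }
  if (d[3L] != object$spec$input_channels) {
    stop("expected ", object$spec$input_channels, " input channels")
  }
  y <- net_forward(object, x, train = FALSE)
  if (d[4L] == 1L) matrix(y, nrow = dim(y)[1L], ncol = dim(y)[2L])
  else array(y, dim = dim(y)[c(1L, 2L, 4L)])
}

flip_lr <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) x[, d[2L]:1, drop = FALSE]
  else if (length(d) == 3L) x[, d[2L]:1, , drop = FALSE]
  else x[, d[2L]:1, , , drop = FALSE]
}

#' Horizontal-flip equivariance probe
#'
#' Measures `mean |unflip(f(flip(x))) - f(x)|` — a sanity probe for test-time
#' augmentation: exactly 0 for a constant-output network, near 0 for
#' horizontally symmetric inputs, finite otherwise. No training side effects.
#'
#' @param net A `bunet_network`.
#' @param image Input image (matrix, array, or `model_input`).
#' @return Non-negative discrepancy score.
#' @export
flip_equivariance_probe <- function(net, image) {
  x <- as_input_tensor(image)
  p1 <- net_forward(net, x, train = FALSE)
  p2 <- net_forward(net, flip_lr(x), train = FALSE)
  mean(abs(flip_lr(p2) - p1))
}
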