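#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[y log p + (1 - y) log(1 - p)]`. Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pred Predicted probabilities (vector, matrix or array).
#' @param truth Ground-truth values in \{0, 1\}, same length.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  stopifnot(length(pred) == length(truth), all(truth %in% c(0, 1)))
  p <- pmin(pmax(as.numeric(pred), 1e-7), 1 - 1e-7)
  y <- as.numeric(truth)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + s) / (sum(p) + sum(y) + s)` with smoothing `s` added
#' to numerator and denominator for stability on empty masks. Lies in
#' \[0, 1\]; 0 for a perfect binary prediction.
#'
#' @inheritParams bce_loss
#' @param smooth Smoothing constant (default 1).
#' @return Scalar in \[0, 1\].
#' @export
dice_loss <- function(pred, truth, smooth = 1) {
  if (length(pred) == 0L) stop("empty input")
  if (!identical(dim(pred), dim(truth)) && length(pred) != length(truth)) {
    stop("shape mismatch between prediction and truth")
  }
  p <- as.numeric(pred); y <- as.numeric(truth)
  1 - (2 * sum(p * y) + smooth) / (sum(p) + sum(y) + smooth)
}

#' Combined BCE-Dice loss (sum of the two terms)
#' @inheritParams dice_loss
#' @export
bce_dice_loss <- function(pred, truth, smooth = 1) {
  bce_loss(pred, truth) + dice_loss(pred, truth, smooth)
}

# Gradient of the combined loss w.r.t. the predicted probabilities.
bce_dice_grad <- function(pred, truth, smooth = 1) {
  p <- pmin(pmax(as.numeric(pred), 1e-7), 1 - 1e-7)
  y <- as.numeric(truth)
  n <- length(p)
  g_bce <- (-y / p + (1 - y) / (1 - p)) / n
  den <- sum(p) + sum(y) + smooth
  num <- 2 * sum(p * y) + smooth
  g_dice <- -(2 * y * den - num) / (den * den)
  g <- g_bce + g_dice
  dim(g) <- dim(pred)
  g
}

#' Cosine annealing learning-rate schedule
#'
#' One half-cosine cycle over the whole run:
#' `lr_end + (lr_start - lr_end) * (1 + cos(pi * step / total_steps)) / 2`.
#'
#' @param step Current step in `[0, total_steps]`.
#' @param total_steps Schedule length (> 0).
#' @param lr_start,lr_end Schedule endpoints.
#' @return Learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, lr_start, lr_end) {
  if (total_steps <= 0) stop("total_steps must be positive")
  stopifnot(step >= 0, step <= total_steps)
  lr_end + 0.5 * (lr_start - lr_end) * (1 + cos(pi * step / total_steps))
}

#' Training recipe
#'
#' @param optimizer `"sgd_momentum"` or `"adam"`.
#' @param lr_start,lr_end Cosine schedule endpoints (`lr_start > lr_end > 0`).
#' @param batch_size Images per optimization step.
#' @param epochs Number of epochs.
#' @param swa_last_k Number of final epoch checkpoints averaged by SWA.
#' @param momentum SGD momentum (0.9).
#' @return A `train_recipe`.
#' @export
train_recipe <- function(optimizer = c("adam", "sgd_momentum"),
                         lr_start = 1e-4, lr_end = 1e-6,
                         batch_size = 4L, epochs = 10L, swa_last_k = 1L,
                         momentum = 0.9) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr_start > lr_end, lr_end > 0, batch_size >= 1, epochs >= 1,
            swa_last_k >= 1, swa_last_k <= epochs)
  structure(list(optimizer = optimizer, momentum = momentum,
                 lr_start = lr_start, lr_end = lr_end,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 swa_last_k = as.integer(swa_last_k)),
            class = "train_recipe")
}

#' Published training recipes
#'
#' The four selected experiment configurations: `exp1` ResNet50-UNet (SGD,
#' momentum 0.9, 1e-3 to 1e-5, batch 10, 60 epochs, SWA over the last 5),
#' `exp2` DenseNet169-UNet (Adam, 1e-4 to 1e-6, batch 6, 80 epochs, SWA 4),
#' `exp4` SE-ResNeXt50-UNet (Adam, 1e-4 to 1e-6, batch 6, 80 epochs, SWA 3),
#' `exp7` EfficientNetB4-UNet (Adam, 1e-4 to 1e-6, batch 4, 80 epochs,
#' SWA 4). `tiny` is a desk-scale recipe for the tiny preset.
#'
#' @param name Recipe name.
#' @return A [train_recipe()].
#' @export
train_recipe_preset <- function(name) {
  switch(name,
    exp1 = train_recipe("sgd_momentum", 1e-3, 1e-5, 10L, 60L, 5L),
    exp2 = train_recipe("adam", 1e-4, 1e-6, 6L, 80L, 4L),
    exp4 = train_recipe("adam", 1e-4, 1e-6, 6L, 80L, 3L),
    exp7 = train_recipe("adam", 1e-4, 1e-6, 4L, 80L, 4L),
    tiny = train_recipe("adam", 3e-3, 1e-5, 4L, 30L, 3L),
    stop("unknown recipe preset: ", name))
}

stack_batch <- function(inputs) {
  d <- dim(inputs[[1L]]$tensor)
  x <- array(0, dim = c(d, length(inputs)))
  for (i in seq_along(inputs)) x[, , , i] <- inputs[[i]]$tensor
  x
}

#' Train a backbone U-Net with BCE-Dice loss
#'
#' Runs the recipe's optimizer under a per-epoch cosine annealing schedule,
#' optionally augmenting each training pair per step, logs per-epoch loss and
#' IoU (predictions binarized at 0.5) on the training and optional validation
#' split, and retains parameter checkpoints for the last `swa_last_k` epochs.
#' Deterministic for a fixed seed. A non-finite loss aborts with a diagnostic.
#'
#' @param model A `bunet_network`.
#' @param data List of `model_input`s with non-null masks.
#' @param recipe A [train_recipe()].
#' @param aug Optional [augmentation_config()] applied per sample per epoch.
#' @param validation Optional list of `model_input`s for validation metrics.
#' @param seed Integer seed controlling shuffling, augmentation draws.
#' @param verbose Print one line per epoch.
#' @return A `trained_bunet`: list with the trained `net`, per-epoch `log`
#'   data.frame, and `checkpoints` (last `swa_last_k` parameter snapshots,
#'   oldest first).
#' @export
train_bunet <- function(model, data, recipe, aug = NULL, validation = NULL,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "bunet_network"), inherits(recipe, "train_recipe"))
  if (length(data) == 0L) stop("empty dataset")
  if (any(vapply(data, function(d) is.null(d$mask), TRUE))) {
    stop("all training inputs need masks")
  }
  opt <- make_optimizer(recipe$optimizer, momentum = recipe$momentum)
  n <- length(data)
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_loss = numeric(0), train_iou = numeric(0),
                    val_loss = numeric(0), val_iou = numeric(0))
  checkpoints <- list()
  with_seed(seed, {
    for (epoch in seq_len(recipe$epochs)) {
      lr_now <- cosine_lr(epoch - 1L, max(recipe$epochs - 1L, 1L),
                          recipe$lr_start, recipe$lr_end)
      ord <- sample.int(n)
      losses <- numeric(0)
      ious <- numeric(0)
      for (b0 in seq(1L, n, by = recipe$batch_size)) {
        idx <- ord[b0:min(b0 + recipe$batch_size - 1L, n)]
        batch <- data[idx]
        if (!is.null(aug)) {
          batch <- lapply(batch, function(d) {
            augment_pair(d, aug, rng_state = sample.int(.Machine$integer.max, 1L))
          })
        }
        x <- stack_batch(batch)
        fw <- net_forward(model, x, train = TRUE, update_bn_stats = TRUE)
        p <- fw$out
        gout <- array(0, dim = dim(p))
        bl <- numeric(length(batch))
        for (i in seq_along(batch)) {
          pi <- p[, , 1L, i]
          yi <- batch[[i]]$mask
          bl[i] <- bce_dice_loss(pi, yi)
          gout[, , 1L, i] <- bce_dice_grad(pi, yi) / length(batch)
          ious <- c(ious, iou(binarize(pi, 0.5), yi))
        }
        loss <- mean(bl)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (batch starting %d): %g",
                       epoch, b0, loss))
        }
        losses <- c(losses, loss)
        gp <- net_backward(model, fw$vals, fw$caches, gout)
        opt$step(model, gp, lr_now)
      }
      vl <- NA_real_; vi <- NA_real_
      if (!is.null(validation) && length(validation) > 0L) {
        vres <- evaluate_inputs(model, validation)
        vl <- vres$loss; vi <- vres$iou
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr_now,
                                   train_loss = mean(losses),
                                   train_iou = mean(ious),
                                   val_loss = vl, val_iou = vi))
      if (epoch > recipe$epochs - recipe$swa_last_k) {
        checkpoints[[length(checkpoints) + 1L]] <- net_param_snapshot(model)
      }
      if (verbose) {
        message(sprintf("epoch %3d lr %.2e loss %.4f iou %.4f", epoch, lr_now,
                        mean(losses), mean(ious)))
      }
    }
  })
  structure(list(net = model, recipe = recipe, log = log,
                 checkpoints = checkpoints, seed = seed),
            class = "trained_bunet")
}

evaluate_inputs <- function(model, inputs) {
  losses <- numeric(length(inputs))
  ious <- numeric(length(inputs))
  for (i in seq_along(inputs)) {
    p <- predict(model, inputs[[i]])
    losses[i] <- bce_dice_loss(p, inputs[[i]]$mask)
    ious[i] <- iou(binarize(p, 0.5), inputs[[i]]$mask)
  }
  list(loss = mean(losses), iou = mean(ious))
}

#' Average parameter checkpoints (terminal stochastic weight averaging)
#'
#' Element-wise arithmetic mean of all weight tensors across checkpoints.
#' With a single monotone cosine schedule, averaging the last few epoch
#' checkpoints is the applicable form of stochastic weight averaging. After
#' installing averaged weights into a network with batch normalization, the
#' running statistics must be refreshed over training data
#' ([apply_swa()] does both).
#'
#' @param checkpoints List of parameter snapshots of identical structure.
#' @return One parameter snapshot.
#' @export
swa_average <- function(checkpoints) {
  stopifnot(length(checkpoints) >= 1L)
  ref <- checkpoints[[1L]]
  out <- ref
  for (ck in checkpoints[-1L]) {
    if (!identical(lapply(ck, function(p) lapply(p, dim)),
                   lapply(ref, function(p) lapply(p, dim)))) {
      stop("checkpoint structure mismatch")
    }
  }
  for (nm in names(ref)) {
    for (tn in names(ref[[nm]])) {
      acc <- ref[[nm]][[tn]]
      for (ck in checkpoints[-1L]) acc <- acc + ck[[nm]][[tn]]
      out[[nm]][[tn]] <- acc / length(checkpoints)
    }
  }
  out
}

# Recompute batch-norm running statistics as the average of per-batch
# statistics over the given data (needed after weight averaging).
bn_refresh <- function(net, data, batch_size = 4L) {
  has_bn <- any(vapply(net$nodes, function(nd) nd$op == "bn", TRUE))
  if (!has_bn) return(invisible(net))
  stats_env <- new.env(parent = emptyenv())
  n <- length(data)
  for (b0 in seq(1L, n, by = batch_size)) {
    x <- stack_batch(data[b0:min(b0 + batch_size - 1L, n)])
    net_forward(net, x, train = FALSE, stats_env = stats_env)
  }
  for (nm in ls(stats_env)) {
    acc <- get(nm, envir = stats_env)
    p <- get(nm, envir = net$pstore)
    p$rmean <- acc$m / acc$n
    p$rvar <- acc$v / acc$n
    assign(nm, p, envir = net$pstore)
  }
  invisible(net)
}

#' Install SWA-averaged weights into a trained model
#'
#' @param fit A `trained_bunet` from [train_bunet()].
#' @param data Training inputs used to refresh batch-norm statistics.
#' @return The `trained_bunet` with averaged weights installed in `fit$net`.
#' @export
apply_swa <- function(fit, data) {
  stopifnot(inherits(fit, "trained_bunet"))
  avg <- swa_average(fit$checkpoints)
  net_set_params(fit$net, avg)
  bn_refresh(fit$net, data, fit$recipe$batch_size)
  fit
}

#' Save/load network weights
#'
#' Serializes the architecture spec plus a parameter snapshot (RDS, R's
#' native serialization); loading rebuilds the graph and installs weights.
#'
#' @param net A `bunet_network`.
#' @param path File path.
#' @export
save_network <- function(net, path) {
  saveRDS(list(spec = net$spec, params = net_param_snapshot(net)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  net <- build_bunet(obj$spec, seed = 0L)
  net_set_params(net, obj$params)
  net
}
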