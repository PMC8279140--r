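test_that("BCE loss matches its closed forms", {
  expect_lt(bce_loss(1 - 1e-9, 1), 1e-6)
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(c(0.5, 0.5), c(0, 1)), log(2))
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("soft Dice loss matches direct evaluation of the formula", {
  m <- random_mask(10, 10, 0.4)
  expect_equal(dice_loss(m, m), 0)  # the smoothing cancels exactly when X == Y
  n <- 400
  expect_gt(dice_loss(rep(1 - 1e-9, n), rep(0, n)), 0.99)
  # p = 0.5 everywhere, all-ones truth: 1 - 2(0.5N)/(0.5N + N) -> 1/3
  N <- 3000
  expect_equal(dice_loss(rep(0.5, N), rep(1, N)), 1/3, tolerance = 1e-3)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape mismatch")
})

test_that("BCE-Dice is the sum of its terms and worsens with error", {
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50, 0.05, 0.95)
    y <- rbinom(50, 1, 0.5)
    expect_equal(bce_dice_loss(p, y), bce_loss(p, y) + dice_loss(p, y))
    # push one prediction away from its label: the loss never decreases
    j <- sample(50, 1)
    p2 <- p
    p2[j] <- if (y[j] == 1) p[j] - 0.04 else p[j] + 0.04
    expect_gte(bce_dice_loss(p2, y), bce_dice_loss(p, y))
  }
})

test_that("the loss gradient matches finite differences on a 3x3 map", {
  set.seed(2)
  p <- matrix(runif(9, 0.1, 0.9), 3, 3)
  y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  g <- bce_dice_grad(p, y)
  eps <- 1e-6
  for (i in 1:9) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    expect_equal(g[i], (bce_dice_loss(pp, y) - bce_dice_loss(pm, y)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("the cosine schedule hits the published endpoints", {
  expect_equal(cosine_lr(0, 100, 1e-3, 1e-5), 1e-3)
  expect_equal(cosine_lr(100, 100, 1e-3, 1e-5), 1e-5)
  expect_equal(cosine_lr(50, 100, 1e-3, 1e-5), (1e-3 + 1e-5) / 2)
  expect_equal(cosine_lr(0, 80, 1e-4, 1e-6), 1e-4)
  expect_equal(cosine_lr(80, 80, 1e-4, 1e-6), 1e-6)
  expect_error(cosine_lr(0, 0, 1e-3, 1e-5), "positive")
  # single cycle: monotone non-increasing over the run
  lrs <- sapply(0:60, cosine_lr, total_steps = 60, lr_start = 1e-3, lr_end = 1e-5)
  expect_true(all(diff(lrs) <= 0))
})

test_that("the published recipes are wired as in the training table", {
  r1 <- train_recipe_preset("exp1")
  expect_equal(r1$optimizer, "sgd_momentum"); expect_equal(r1$momentum, 0.9)
  expect_equal(c(r1$lr_start, r1$lr_end), c(1e-3, 1e-5))
  expect_equal(c(r1$batch_size, r1$epochs, r1$swa_last_k), c(10, 60, 5))
  r2 <- train_recipe_preset("exp2")
  expect_equal(r2$optimizer, "adam")
  expect_equal(c(r2$lr_start, r2$lr_end, r2$batch_size, r2$epochs, r2$swa_last_k),
               c(1e-4, 1e-6, 6, 80, 4))
  r4 <- train_recipe_preset("exp4")
  expect_equal(c(r4$batch_size, r4$epochs, r4$swa_last_k), c(6, 80, 3))
  r7 <- train_recipe_preset("exp7")
  expect_equal(c(r7$batch_size, r7$epochs, r7$swa_last_k), c(4, 80, 4))
  expect_error(train_recipe("adam", 1e-5, 1e-3), "lr_start > lr_end")
  expect_error(train_recipe("adam", 1e-3, 1e-5, epochs = 5, swa_last_k = 9))
})

test_that("SWA averaging equals the per-tensor mean oracle", {
  net <- build_bunet("tiny_unet", seed = 9)
  ck1 <- pneumoseg:::net_param_snapshot(net)
  expect_equal(swa_average(list(ck1, ck1, ck1)), ck1)
  neg <- lapply(ck1, function(p) lapply(p, function(t) -t))
  zero <- swa_average(list(ck1, neg))
  expect_equal(max(abs(unlist(zero))), 0)
  # three random checkpoints vs independent sum/3
  mk <- function(s) lapply(ck1, function(p) lapply(p, function(t) {
    r <- rnorm(length(t), sd = 0.1)
    dim(r) <- dim(t)
    r
  }))
  set.seed(10)
  cks <- lapply(1:3, mk)
  avg <- swa_average(cks)
  for (nm in sample(names(ck1), 3)) {
    for (tn in names(ck1[[nm]])) {
      want <- (cks[[1]][[nm]][[tn]] + cks[[2]][[nm]][[tn]] + cks[[3]][[nm]][[tn]]) / 3
      expect_equal(as.vector(avg[[nm]][[tn]]), as.vector(want))
    }
  }
  bad <- ck1; bad[["head_conv"]][["w"]] <- NULL
  expect_error(swa_average(list(ck1, bad)), "structure mismatch")
})

test_that("short training runs are deterministic and keep swa_last_k checkpoints", {
  data <- smoke_corpus()[1:4]
  rec <- train_recipe("adam", 1e-3, 1e-5, batch_size = 2L, epochs = 3L,
                      swa_last_k = 2L)
  f1 <- train_bunet(build_bunet("tiny_unet", seed = 13), data, rec, seed = 5)
  f2 <- train_bunet(build_bunet("tiny_unet", seed = 13), data, rec, seed = 5)
  expect_identical(f1$log, f2$log)
  expect_length(f1$checkpoints, 2L)
  f3 <- train_bunet(build_bunet("tiny_unet", seed = 13), data, rec, seed = 6)
  expect_false(identical(f1$log$train_loss, f3$log$train_loss))
  expect_error(train_bunet(build_bunet("tiny_unet", seed = 13), list(), rec),
               "empty dataset")
})

test_that("SWA-averaged weights with refreshed BN stats still predict", {
  data <- smoke_corpus()[1:4]
  rec <- train_recipe("adam", 1e-3, 1e-5, batch_size = 2L, epochs = 3L,
                      swa_last_k = 3L)
  fit <- train_bunet(build_bunet("tiny_unet", seed = 14), data, rec, seed = 5)
  fit <- apply_swa(fit, data)
  avg <- swa_average(fit$checkpoints)
  got <- pneumoseg:::net_param_snapshot(fit$net)
  expect_equal(got[["head_conv"]]$w, avg[["head_conv"]]$w)
  p <- predict(fit$net, data[[1]])
  expect_true(all(p > 0 & p < 1))
})
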