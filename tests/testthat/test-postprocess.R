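test_that("binarization uses the strict greater-than boundary", {
  m <- matrix(c(0.74, 0.73, 0.1, 0.9), 2, 2)
  b <- binarize(m, 0.73)
  expect_equal(as.vector(b), c(1L, 0L, 0L, 1L))
  expect_true(all(binarize(matrix(0.2, 4, 4), 0.5) == 0L))
  expect_error(binarize(m, 0))
})

test_that("small-object removal honours the strict size boundary per mode", {
  m <- matrix(0L, 20, 20)
  m[2:4, 2:4] <- 1L           # 9-pixel component
  m[10:15, 10:15] <- 1L       # 36-pixel component
  out <- remove_small(m, 9, "component")   # == r_th: erased
  expect_equal(sum(out), 36)
  out <- remove_small(m, 8, "component")   # 9 > 8: kept
  expect_equal(sum(out), 45)
  expect_identical(remove_small(m, NA, "component"), m)
  # whole-mask mode erases everything or nothing
  expect_equal(sum(remove_small(m, 45, "whole_mask")), 0)
  expect_equal(sum(remove_small(m, 44, "whole_mask")), 45)
  # idempotence
  r1 <- remove_small(m, 9, "component")
  expect_identical(remove_small(r1, 9, "component"), r1)
})

test_that("component removal agrees with a labelling oracle at scale", {
  set.seed(31)
  m <- matrix(0L, 64, 64)
  m[2:11, 2:11] <- 1L          # 100 px
  m[20:63, 20:63] <- 1L        # 1936 px
  out <- remove_small(m, 1024, "component")
  expect_equal(sum(out), 1936)
  expect_true(all(out[20:63, 20:63] == 1L))
})

test_that("the threshold grid enumerates 70 x 5 = 350 candidates", {
  g <- threshold_grid()
  expect_equal(length(unique(g$b_th)), 70)
  expect_equal(sort(unique(g$b_th))[1:3], c(0.20, 0.21, 0.22))
  expect_equal(max(g$b_th), 0.89)
  expect_equal(sum(is.na(g$r_th)) > 0, TRUE)
  expect_equal(length(unique(g$r_th)), 5)
  expect_setequal(unique(g$r_th[!is.na(g$r_th)]), c(1024, 2048, 3072, 4096))
  expect_equal(nrow(g), 350)
})

test_that("grid search recovers a planted binarization threshold", {
  cfg <- phantom_config(image_size = 96, n_images = 10, positive_fraction = 0.8,
                        lesion_area_range = c(0.01, 0.06), noise_sd = 5, seed = 21)
  corpus <- generate_corpus(cfg)
  maps <- generate_probability_maps(corpus$masks, blur_sd = 2, noise_sd = 0.15,
                                    seed = 3)$model1
  truths <- lapply(maps, binarize, b_th = 0.42)
  res <- tune_thresholds(maps, truths)
  expect_equal(nrow(res$table), 350)
  expect_true(res$best$b_th %in% c(0.41, 0.42))
  expect_true(is.na(res$best$r_th))
  expect_gt(res$best$score, 0.999)
})

test_that("ties break toward the least aggressive post-processing", {
  empty <- list(matrix(0, 32, 32), matrix(0, 32, 32))
  truths <- list(matrix(0L, 32, 32), matrix(0L, 32, 32))
  res <- tune_thresholds(empty, truths)
  expect_equal(res$best$b_th, 0.20)
  expect_true(is.na(res$best$r_th))
  expect_true(all(res$table$score == 1))
  expect_error(tune_thresholds(list(), list()), "empty validation set")
})

test_that("foreground shrinks monotonically as the binarization threshold rises", {
  set.seed(33)
  m <- matrix(runif(64 * 64), 64, 64)
  counts <- sapply(seq(0.2, 0.89, by = 0.03), function(t) sum(binarize(m, t)))
  expect_true(all(diff(counts) <= 0))
})

test_that("weighted ensembling normalizes and averages pixelwise", {
  a <- matrix(0.2, 8, 8); b <- matrix(0.8, 8, 8)
  cfg <- ensemble_config(c(m1 = 1, m2 = 1))
  expect_true(all(ensemble_average(list(m1 = a, m2 = b), cfg) == 0.5))
  expect_true(all(ensemble_average(list(m1 = a, m2 = a), cfg) == 0.2))
  # the published prose weights sum to 1.2 and normalize to 1/3,1/3,1/6,1/6
  pw <- ensemble_weights_preset("prose")
  expect_equal(sum(pw$members), 1.2)
  expect_equal(unname(pw$members / sum(pw$members)),
               c(1/3, 1/3, 1/6, 1/6))
  gb <- ensemble_weights_preset("grid_best")
  expect_equal(unname(gb$members), c(0.4, 0.4, 0.1, 0.1))
  expect_error(ensemble_config(c(x = -1)), "positive")
  expect_error(ensemble_average(list(m1 = a, m2 = matrix(0.5, 4, 4)), cfg),
               "dimension mismatch")
  # output bounded by the member extremes
  set.seed(5)
  ms <- list(m1 = matrix(runif(64), 8, 8), m2 = matrix(runif(64), 8, 8))
  e <- ensemble_average(ms, cfg)
  expect_true(all(e >= pmin(ms$m1, ms$m2) - 1e-12 & e <= pmax(ms$m1, ms$m2) + 1e-12))
})

test_that("TTA prediction is convex and symmetric where it must be", {
  net <- build_bunet("tiny_unet", seed = 15)
  set.seed(16)
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  t1 <- tta_predict(net, x)
  p1 <- predict(net, x)
  flip_lr <- pneumoseg:::flip_lr
  pf <- flip_lr(predict(net, flip_lr(x)))
  expect_true(all(t1 >= pmin(p1, pf) - 1e-12 & t1 <= pmax(p1, pf) + 1e-12))
  # horizontally symmetric input -> symmetric TTA map (by construction)
  xs <- (x + flip_lr(x)) / 2
  ts <- tta_predict(net, xs)
  expect_equal(ts, flip_lr(ts))
  # constant-output model -> TTA output equals that constant
  p <- get("head_conv", envir = net$pstore); p$w[] <- 0; p$b[] <- -0.5
  assign("head_conv", p, envir = net$pstore)
  expect_equal(unique(as.vector(tta_predict(net, x))), 1 / (1 + exp(0.5)))
})

test_that("submissions round-trip and reject duplicates", {
  m1 <- random_mask(32, 32, 0.1)
  m2 <- matrix(0L, 32, 32)
  f <- tempfile(fileext = ".csv")
  write_submission(list(img_a = m1, img_b = m2), f)
  txt <- readLines(f)
  expect_equal(txt[1], "ImageId,EncodedPixels")
  expect_equal(length(txt), 3)
  ann <- read_annotations(f)
  expect_identical(mask_from_annotations(ann, "img_a", 32, 32), m1)
  expect_equal(ann$EncodedPixels[ann$ImageId == "img_b"], "-1")
  expect_error(write_submission(list(a = m1, a = m2), f), "duplicate")
  expect_error(write_submission(list(m1), f), "named")
})

test_that("the full pipeline maps a synthetic batch to a valid submission", {
  cfg <- phantom_config(image_size = 128, n_images = 6, positive_fraction = 0.5,
                        noise_sd = 6, seed = 8)
  corpus <- generate_corpus(cfg)
  maps <- generate_probability_maps(corpus$masks, blur_sd = 1, noise_sd = 0.08,
                                    seed = 4, models = c("m1", "m2"))
  cfge <- ensemble_config(c(m1 = 0.6, m2 = 0.4))
  final <- lapply(names(corpus$masks), function(id) {
    em <- ensemble_average(list(m1 = maps$m1[[id]], m2 = maps$m2[[id]]), cfge)
    postprocess_map(em, b_th = 0.5, r_th = 16, target_size = 256L)
  })
  names(final) <- names(corpus$masks)
  f <- tempfile(fileext = ".csv")
  write_submission(final, f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 6)
  for (id in ann$ImageId) {
    m <- mask_from_annotations(ann, id, 256, 256)  # decodes within bounds
    expect_true(all(m %in% c(0L, 1L)))
  }
  # both post-processing orders produce binary masks at target resolution
  alt <- postprocess_map(maps$m1[[1]], 0.5, r_th = NA, target_size = 256L,
                         threshold_at = "model")
  expect_equal(dim(alt), c(256, 256))
  expect_true(all(alt %in% c(0L, 1L)))
})
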