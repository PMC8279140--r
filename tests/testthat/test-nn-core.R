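# The convolution kernels and backward passes are the numerical foundation of
# every network here, so they are checked against a direct-loop oracle and
# central finite differences on small tensors.

cpp_conv_fwd <- pneumoseg:::cpp_conv2d_fwd
cpp_conv_bwd <- pneumoseg:::cpp_conv2d_bwd
pad_amounts <- pneumoseg:::pad_amounts
out_size <- pneumoseg:::out_size

test_that("convolution forward matches the direct-loop oracle", {
  set.seed(21)
  cases <- list(
    list(H = 5, W = 7, C = 3, N = 2, k = 3, s = 1, g = 1, Co = 4, pad = "same"),
    list(H = 6, W = 6, C = 3, N = 1, k = 3, s = 2, g = 1, Co = 2, pad = "same"),
    list(H = 7, W = 5, C = 4, N = 2, k = 1, s = 1, g = 1, Co = 5, pad = "valid"),
    list(H = 6, W = 6, C = 4, N = 1, k = 3, s = 1, g = 2, Co = 6, pad = "same"),
    list(H = 8, W = 8, C = 4, N = 1, k = 5, s = 2, g = 4, Co = 4, pad = "same"))
  for (cs in cases) {
    x <- array(rnorm(cs$H * cs$W * cs$C * cs$N), dim = c(cs$H, cs$W, cs$C, cs$N))
    w <- array(rnorm(cs$k^2 * (cs$C / cs$g) * cs$Co),
               dim = c(cs$k, cs$k, cs$C / cs$g, cs$Co))
    b <- rnorm(cs$Co)
    ph <- pad_amounts(cs$H, cs$k, cs$s, cs$pad)
    pw <- pad_amounts(cs$W, cs$k, cs$s, cs$pad)
    Ho <- out_size(cs$H, cs$k, cs$s, ph); Wo <- out_size(cs$W, cs$k, cs$s, pw)
    got <- cpp_conv_fwd(x, dim(x), w, dim(w), b, cs$s, cs$s, ph[1], pw[1],
                        Ho, Wo, cs$g)
    want <- oracle_conv(x, w, b, cs$s, ph[1], pw[1], Ho, Wo, cs$g)
    expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)
  }
})

test_that("convolution backward matches central finite differences", {
  set.seed(22)
  x <- array(rnorm(5 * 5 * 2 * 2), dim = c(5, 5, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), dim = c(3, 3, 2, 3))
  ph <- pad_amounts(5, 3, 1, "same"); Ho <- out_size(5, 3, 1, ph)
  fwd <- function(x, w) cpp_conv_fwd(x, dim(x), w, dim(w), NULL, 1, 1,
                                     ph[1], ph[1], Ho, Ho, 1)
  y <- fwd(x, w)
  gy <- array(rnorm(length(y)), dim = dim(y))
  loss <- function(x, w) sum(fwd(x, w) * gy)
  r <- cpp_conv_bwd(x, dim(x), w, dim(w), gy, FALSE, 1, 1, ph[1], ph[1],
                    Ho, Ho, 1)
  eps <- 1e-6
  for (i in sample(length(x), 8)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(r$gx[i], (loss(xp, w) - loss(xm, w)) / (2 * eps), tolerance = 1e-5)
  }
  for (i in sample(length(w), 8)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    expect_equal(r$gw[i], (loss(x, wp) - loss(x, wm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("pooling and upsampling kernels agree with hand-computed cases", {
  x <- array(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16),
             dim = c(4, 4, 1, 1))
  mp <- pneumoseg:::cpp_maxpool_fwd(x, dim(x), 2, 2, 2, 2, 0, 0, 2, 2)
  expect_equal(as.vector(mp$y), c(6, 8, 14, 16))
  ap <- pneumoseg:::cpp_avgpool_fwd(x, dim(x), 2, 2, 2, 2, 0, 0, 2, 2)
  expect_equal(as.vector(ap), c(3.5, 5.5, 11.5, 13.5))
  up <- pneumoseg:::cpp_upsample_nn_fwd(array(c(1, 2, 3, 4), dim = c(2, 2, 1, 1)),
                                        c(2L, 2L, 1L, 1L), 2L)
  expect_equal(up[, , 1, 1], matrix(c(1, 1, 2, 2, 1, 1, 2, 2, 3, 3, 4, 4, 3, 3, 4, 4), 4, 4))
  # adjoints: <A x, y> == <x, At y> for random vectors
  set.seed(9)
  gy <- array(rnorm(4), dim = c(2, 2, 1, 1))
  gx <- pneumoseg:::cpp_maxpool_bwd(gy, mp$argmax, dim(x), dim(gy))
  expect_equal(sum(gx * x), sum(gy * mp$y))
  gxa <- pneumoseg:::cpp_avgpool_bwd(gy, dim(x), 2, 2, 2, 2, 0, 0, 2, 2)
  expect_equal(sum(gxa * x), sum(gy * ap))
})

test_that("a whole tiny network backpropagates consistently with finite differences", {
  net <- build_bunet("tiny_unet", seed = 31)
  set.seed(32)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  y <- random_mask(32, 32, 0.3)
  # both the analytic pass and the finite differences use train-mode forward
  # (batch statistics), so the BN backward's statistics terms are exercised
  loss_of <- function() {
    p <- pneumoseg:::net_forward(net, x, train = TRUE)$out
    bce_dice_loss(p[, , 1, 1], y)
  }
  fw <- pneumoseg:::net_forward(net, x, train = TRUE)
  gout <- array(bce_dice_grad(fw$out[, , 1, 1], y), dim = dim(fw$out))
  gp <- pneumoseg:::net_backward(net, fw$vals, fw$caches, gout)
  eps <- 1e-5
  for (nodename in c("head_conv", "dec5_a_conv")) {
    p <- get(nodename, envir = net$pstore)
    for (i in sample(length(p$w), 3)) {
      w0 <- p$w[i]
      p$w[i] <- w0 + eps; assign(nodename, p, envir = net$pstore)
      lp <- loss_of()
      p$w[i] <- w0 - eps; assign(nodename, p, envir = net$pstore)
      lm <- loss_of()
      p$w[i] <- w0; assign(nodename, p, envir = net$pstore)
      expect_equal(gp[[nodename]]$w[i], (lp - lm) / (2 * eps), tolerance = 5e-2)
    }
  }
})

test_that("8-connected labelling matches a union-find oracle", {
  # diagonal pixels belong to one 8-connected component
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L
  lab <- pneumoseg:::cpp_label8(m)
  expect_equal(max(lab), 1L)
  set.seed(44)
  for (i in 1:25) {
    m <- random_mask(12, 12, runif(1, 0.1, 0.5))
    lab <- pneumoseg:::cpp_label8(m)
    sizes <- sort(tabulate(lab[lab > 0]))
    expect_equal(sizes, oracle_component_sizes(m))
  }
})
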