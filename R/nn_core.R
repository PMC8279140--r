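# A small static computational-graph engine for the backbone U-Nets.
#
# Tensors are R arrays with dim c(H, W, C, N). A network is an ordered list of
# nodes (conv / bn / act / pools / upsample / concat / add / mul / gap), each
# naming its input nodes. Parameters live in an environment (net$pstore), one
# named list of tensors per parameterized node, so batch-norm running-stat
# updates and optimizer steps persist. Convolutions run through the im2col
# kernels in src/. Forward has an inference mode that frees intermediates as
# soon as no later node needs them, and a training mode retaining the values
# and caches needed by the hand-derived backward passes.

new_builder <- function(input_channels = 3L) {
  B <- new.env(parent = emptyenv())
  B$nodes <- list()
  B$params <- list()
  B$channels <- c(input = input_channels)
  B$nodes[["input"]] <- list(name = "input", op = "input", inputs = character(0),
                             cfg = list())
  B
}

nb_add <- function(B, name, op, inputs, cfg = list(), channels, params = NULL) {
  stopifnot(is.null(B$nodes[[name]]), all(inputs %in% names(B$nodes)))
  B$nodes[[name]] <- list(name = name, op = op, inputs = inputs, cfg = cfg)
  B$channels[[name]] <- channels
  if (!is.null(params)) B$params[[name]] <- params
  name
}

nb_conv <- function(B, name, input, filters, k = 3L, stride = 1L, groups = 1L,
                    bias = TRUE, pad = "same") {
  cin <- B$channels[[input]]
  stopifnot(cin %% groups == 0L, filters %% groups == 0L)
  cin_g <- cin %/% groups
  w <- array(rnorm(k * k * cin_g * filters, sd = sqrt(2 / (k * k * cin_g))),
             dim = c(k, k, cin_g, filters))
  p <- list(w = w)
  if (bias) p$b <- numeric(filters)
  nb_add(B, name, "conv", input,
         cfg = list(k = as.integer(k), stride = as.integer(stride),
                    groups = as.integer(groups), pad = pad, bias = bias),
         channels = filters, params = p)
}

nb_bn <- function(B, name, input, eps = 1e-3, momentum = 0.9) {
  C <- B$channels[[input]]
  nb_add(B, name, "bn", input, cfg = list(eps = eps, momentum = momentum),
         channels = C,
         params = list(gamma = rep(1, C), beta = numeric(C),
                       rmean = numeric(C), rvar = rep(1, C)))
}

nb_act <- function(B, name, input, fun = "relu") {
  nb_add(B, name, "act", input, cfg = list(fun = fun),
         channels = B$channels[[input]])
}

nb_maxpool <- function(B, name, input, k = 3L, stride = 2L, pad = "same") {
  nb_add(B, name, "maxpool", input,
         cfg = list(k = as.integer(k), stride = as.integer(stride), pad = pad),
         channels = B$channels[[input]])
}

nb_avgpool <- function(B, name, input, k = 2L, stride = 2L, pad = "valid") {
  nb_add(B, name, "avgpool", input,
         cfg = list(k = as.integer(k), stride = as.integer(stride), pad = pad),
         channels = B$channels[[input]])
}

nb_gap <- function(B, name, input) {
  nb_add(B, name, "gap", input, channels = B$channels[[input]])
}

nb_upsample <- function(B, name, input, factor = 2L) {
  nb_add(B, name, "upsample", input, cfg = list(factor = as.integer(factor)),
         channels = B$channels[[input]])
}

nb_concat <- function(B, name, inputs) {
  nb_add(B, name, "concat", inputs,
         channels = sum(vapply(inputs, function(i) B$channels[[i]], 0L)))
}

nb_add_op <- function(B, name, inputs) {
  nb_add(B, name, "add", inputs, channels = B$channels[[inputs[1L]]])
}

nb_mul <- function(B, name, inputs) {  # inputs = c(x, gate); gate is 1x1xCxN
  nb_add(B, name, "mul", inputs, channels = B$channels[[inputs[1L]]])
}

# conv + optional BN + activation, the standard composite block
nb_cba <- function(B, prefix, input, filters, k = 3L, stride = 1L, groups = 1L,
                   bn = TRUE, act = "relu") {
  x <- nb_conv(B, paste0(prefix, "_conv"), input, filters, k = k,
               stride = stride, groups = groups, bias = !bn)
  if (bn) x <- nb_bn(B, paste0(prefix, "_bn"), x)
  if (!is.null(act)) x <- nb_act(B, paste0(prefix, "_", act), x, fun = act)
  x
}

pad_amounts <- function(H, k, s, pad) {
  if (pad == "valid") return(c(0L, 0L))
  tot <- max((ceiling(H / s) - 1L) * s + k - H, 0L)
  pt <- tot %/% 2L
  as.integer(c(pt, tot - pt))
}

out_size <- function(H, k, s, pads) as.integer((H + pads[1L] + pads[2L] - k) %/% s + 1L)

# Last position at which each node's value is still needed (for freeing).
plan_last_use <- function(nodes, order) {
  pos <- stats::setNames(seq_along(order), order)
  last <- pos
  for (nm in order) {
    for (inp in nodes[[nm]]$inputs) last[inp] <- max(last[inp], pos[nm])
  }
  last
}

act_forward <- function(fun, x) {
  switch(fun,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         swish = x / (1 + exp(-x)),
         stop("unknown activation ", fun))
}

# per-channel sums of an (H,W,C,N) array -> C x N matrix
channel_sums <- function(x, HW, C, N) {
  matrix(colSums(matrix(x, nrow = HW)), nrow = C, ncol = N)
}

get_params <- function(net, nm) {
  if (exists(nm, envir = net$pstore, inherits = FALSE)) {
    get(nm, envir = net$pstore)
  } else NULL
}

# stats_env, when given, accumulates per-BN batch statistics (for the
# post-averaging running-stat refresh).
net_forward <- function(net, x, train = FALSE, update_bn_stats = FALSE,
                        stats_env = NULL) {
  stopifnot(length(dim(x)) == 4L)
  vals <- new.env(parent = emptyenv())
  caches <- if (train) new.env(parent = emptyenv()) else NULL
  assign("input", x, envir = vals)
  order <- net$order
  last <- if (!train) plan_last_use(net$nodes, order) else NULL
  use_batch_stats <- train || !is.null(stats_env)
  pos <- 0L
  for (nm in order) {
    pos <- pos + 1L
    node <- net$nodes[[nm]]
    if (node$op == "input") next
    ins <- lapply(node$inputs, get, envir = vals)
    p <- get_params(net, nm)
    cfg <- node$cfg
    y <- switch(node$op,
      conv = {
        xx <- ins[[1L]]; d <- dim(xx)
        ph <- pad_amounts(d[1L], cfg$k, cfg$stride, cfg$pad)
        pw <- pad_amounts(d[2L], cfg$k, cfg$stride, cfg$pad)
        Ho <- out_size(d[1L], cfg$k, cfg$stride, ph)
        Wo <- out_size(d[2L], cfg$k, cfg$stride, pw)
        cpp_conv2d_fwd(xx, d, p$w, dim(p$w),
                       if (cfg$bias) p$b else NULL,
                       cfg$stride, cfg$stride, ph[1L], pw[1L], Ho, Wo, cfg$groups)
      },
      bn = {
        xx <- ins[[1L]]; d <- dim(xx)
        HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
        if (use_batch_stats) {
          neff <- HW * N
          m <- rowSums(channel_sums(xx, HW, C, N)) / neff
          v <- pmax(rowSums(channel_sums(xx * xx, HW, C, N)) / neff - m * m, 0)
          if (update_bn_stats) {
            mom <- cfg$momentum
            p$rmean <- mom * p$rmean + (1 - mom) * m
            p$rvar <- mom * p$rvar + (1 - mom) * v
            assign(nm, p, envir = net$pstore)
          }
          if (!is.null(stats_env)) {
            acc <- if (exists(nm, envir = stats_env, inherits = FALSE)) {
              get(nm, envir = stats_env)
            } else list(m = 0, v = 0, n = 0L)
            assign(nm, list(m = acc$m + m, v = acc$v + v, n = acc$n + 1L),
                   envir = stats_env)
          }
        } else {
          m <- p$rmean; v <- p$rvar
        }
        invsd <- 1 / sqrt(v + cfg$eps)
        sc <- p$gamma * invsd
        off <- p$beta - m * sc
        yy <- xx * rep(sc, each = HW) + rep(off, each = HW)
        dim(yy) <- d
        if (train) {
          xhat <- (xx - rep(m, each = HW)) * rep(invsd, each = HW)
          dim(xhat) <- d
          assign(nm, list(xhat = xhat, invsd = invsd), envir = caches)
        }
        yy
      },
      act = {
        yy <- act_forward(cfg$fun, ins[[1L]])
        if (train && cfg$fun == "swish") {
          assign(nm, list(s = 1 / (1 + exp(-ins[[1L]]))), envir = caches)
        }
        yy
      },
      maxpool = {
        xx <- ins[[1L]]; d <- dim(xx)
        ph <- pad_amounts(d[1L], cfg$k, cfg$stride, cfg$pad)
        pw <- pad_amounts(d[2L], cfg$k, cfg$stride, cfg$pad)
        Ho <- out_size(d[1L], cfg$k, cfg$stride, ph)
        Wo <- out_size(d[2L], cfg$k, cfg$stride, pw)
        r <- cpp_maxpool_fwd(xx, d, cfg$k, cfg$k, cfg$stride, cfg$stride,
                             ph[1L], pw[1L], Ho, Wo)
        if (train) assign(nm, list(argmax = r$argmax, xdim = d), envir = caches)
        r$y
      },
      avgpool = {
        xx <- ins[[1L]]; d <- dim(xx)
        ph <- pad_amounts(d[1L], cfg$k, cfg$stride, cfg$pad)
        pw <- pad_amounts(d[2L], cfg$k, cfg$stride, cfg$pad)
        Ho <- out_size(d[1L], cfg$k, cfg$stride, ph)
        Wo <- out_size(d[2L], cfg$k, cfg$stride, pw)
        if (train) assign(nm, list(xdim = d, ph = ph, pw = pw, Ho = Ho, Wo = Wo),
                          envir = caches)
        cpp_avgpool_fwd(xx, d, cfg$k, cfg$k, cfg$stride, cfg$stride,
                        ph[1L], pw[1L], Ho, Wo)
      },
      gap = {
        xx <- ins[[1L]]; d <- dim(xx)
        HW <- d[1L] * d[2L]
        m <- channel_sums(xx, HW, d[3L], d[4L]) / HW
        array(m, dim = c(1L, 1L, d[3L], d[4L]))
      },
      upsample = cpp_upsample_nn_fwd(ins[[1L]], dim(ins[[1L]]), cfg$factor),
      concat = {
        d1 <- dim(ins[[1L]])
        cs <- vapply(ins, function(a) dim(a)[3L], 0L)
        yy <- array(0, dim = c(d1[1L], d1[2L], sum(cs), d1[4L]))
        off <- 0L
        for (j in seq_along(ins)) {
          yy[, , (off + 1L):(off + cs[j]), ] <- ins[[j]]
          off <- off + cs[j]
        }
        yy
      },
      add = ins[[1L]] + ins[[2L]],
      mul = {
        xx <- ins[[1L]]; g <- ins[[2L]]
        d <- dim(xx); HW <- d[1L] * d[2L]
        yy <- xx * rep(as.vector(g), each = HW)
        dim(yy) <- d
        yy
      },
      stop("unknown op ", node$op))
    assign(nm, y, envir = vals)
    if (!train) {
      for (inp in node$inputs) {
        if (last[inp] <= pos && inp != net$output) rm(list = inp, envir = vals)
      }
    }
  }
  if (train) list(out = get(net$output, envir = vals), vals = vals, caches = caches)
  else get(net$output, envir = vals)
}

net_backward <- function(net, vals, caches, gout) {
  grads <- new.env(parent = emptyenv())
  gparams <- list()
  assign(net$output, gout, envir = grads)
  accum <- function(nm, g) {
    if (exists(nm, envir = grads, inherits = FALSE)) {
      assign(nm, get(nm, envir = grads) + g, envir = grads)
    } else assign(nm, g, envir = grads)
  }
  for (nm in rev(net$order)) {
    node <- net$nodes[[nm]]
    if (node$op == "input") next
    if (!exists(nm, envir = grads, inherits = FALSE)) next
    gy <- get(nm, envir = grads)
    rm(list = nm, envir = grads)
    cfg <- node$cfg
    p <- get_params(net, nm)
    switch(node$op,
      conv = {
        xx <- get(node$inputs[1L], envir = vals)
        d <- dim(xx)
        ph <- pad_amounts(d[1L], cfg$k, cfg$stride, cfg$pad)
        pw <- pad_amounts(d[2L], cfg$k, cfg$stride, cfg$pad)
        dy <- dim(gy)
        r <- cpp_conv2d_bwd(xx, d, p$w, dim(p$w), gy, cfg$bias,
                            cfg$stride, cfg$stride, ph[1L], pw[1L],
                            dy[1L], dy[2L], cfg$groups)
        gp <- list(w = r$gw)
        if (cfg$bias) gp$b <- r$gb
        gparams[[nm]] <- gp
        accum(node$inputs[1L], r$gx)
      },
      bn = {
        cc <- get(nm, envir = caches)
        d <- dim(gy); HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
        neff <- HW * N
        dgamma <- rowSums(channel_sums(gy * cc$xhat, HW, C, N))
        dbeta <- rowSums(channel_sums(gy, HW, C, N))
        sc <- p$gamma * cc$invsd
        gx <- rep(sc, each = HW) *
          (gy - rep(dbeta / neff, each = HW) -
             cc$xhat * rep(dgamma / neff, each = HW))
        dim(gx) <- d
        gparams[[nm]] <- list(gamma = dgamma, beta = dbeta)
        accum(node$inputs[1L], gx)
      },
      act = {
        y <- get(nm, envir = vals)
        gx <- switch(cfg$fun,
          relu = gy * (y > 0),
          sigmoid = gy * y * (1 - y),
          swish = {
            s <- get(nm, envir = caches)$s
            gy * (s + y * (1 - s))  # y = x*s => dy/dx = s + x*s*(1-s)
          })
        accum(node$inputs[1L], gx)
      },
      maxpool = {
        cc <- get(nm, envir = caches)
        accum(node$inputs[1L], cpp_maxpool_bwd(gy, cc$argmax, cc$xdim, dim(gy)))
      },
      avgpool = {
        cc <- get(nm, envir = caches)
        accum(node$inputs[1L],
              cpp_avgpool_bwd(gy, cc$xdim, cfg$k, cfg$k, cfg$stride, cfg$stride,
                              cc$ph[1L], cc$pw[1L], cc$Ho, cc$Wo))
      },
      gap = {
        xx <- get(node$inputs[1L], envir = vals)
        d <- dim(xx); HW <- d[1L] * d[2L]
        gx <- array(rep(as.vector(gy) / HW, each = HW), dim = d)
        accum(node$inputs[1L], gx)
      },
      upsample = {
        xdim <- dim(get(node$inputs[1L], envir = vals))
        accum(node$inputs[1L], cpp_upsample_nn_bwd(gy, xdim, cfg$factor))
      },
      concat = {
        off <- 0L
        for (inp in node$inputs) {
          ci <- dim(get(inp, envir = vals))[3L]
          accum(inp, gy[, , (off + 1L):(off + ci), , drop = FALSE])
          off <- off + ci
        }
      },
      add = {
        accum(node$inputs[1L], gy)
        accum(node$inputs[2L], gy)
      },
      mul = {
        xx <- get(node$inputs[1L], envir = vals)
        g <- get(node$inputs[2L], envir = vals)
        d <- dim(xx); HW <- d[1L] * d[2L]; C <- d[3L]; N <- d[4L]
        gx <- gy * rep(as.vector(g), each = HW)
        dim(gx) <- d
        accum(node$inputs[1L], gx)
        gg <- channel_sums(gy * xx, HW, C, N)
        accum(node$inputs[2L], array(gg, dim = c(1L, 1L, C, N)))
      })
  }
  gparams
}

trainable_names <- c("w", "b", "gamma", "beta")

# Snapshot of all parameters (a deep, plain-list copy).
net_param_snapshot <- function(net) {
  out <- list()
  for (nm in ls(net$pstore)) out[[nm]] <- get(nm, envir = net$pstore)
  out
}

net_set_params <- function(net, params) {
  for (nm in names(params)) assign(nm, params[[nm]], envir = net$pstore)
  invisible(net)
}

make_optimizer <- function(kind = c("sgd_momentum", "adam"), momentum = 0.9,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  st <- new.env(parent = emptyenv())
  st$v <- list(); st$m <- list(); st$t <- 0L
  step <- function(net, gparams, lr_now) {
    st$t <- st$t + 1L
    for (nm in names(gparams)) {
      p <- get(nm, envir = net$pstore)
      for (tn in names(gparams[[nm]])) {
        key <- paste0(nm, ".", tn)
        g <- gparams[[nm]][[tn]]
        if (kind == "sgd_momentum") {
          v <- if (is.null(st$v[[key]])) 0 else st$v[[key]]
          v <- momentum * v - lr_now * g
          st$v[[key]] <- v
          p[[tn]] <- p[[tn]] + v
        } else {
          m <- if (is.null(st$m[[key]])) 0 else st$m[[key]]
          v <- if (is.null(st$v[[key]])) 0 else st$v[[key]]
          m <- beta1 * m + (1 - beta1) * g
          v <- beta2 * v + (1 - beta2) * g * g
          st$m[[key]] <- m; st$v[[key]] <- v
          p[[tn]] <- p[[tn]] - lr_now * (m / (1 - beta1^st$t)) /
            (sqrt(v / (1 - beta2^st$t)) + eps)
        }
      }
      assign(nm, p, envir = net$pstore)
    }
    invisible(net)
  }
  list(kind = kind, step = step, state = st)
}
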