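#' Training-time augmentation configuration
#'
#' The augmentation menu applied to image/mask pairs during training:
#' horizontal flip; shift-scale-rotate with rotations up to 20 degrees; one of
#' elastic transform, optical distortion, grid distortion; one of random
#' contrast, random brightness, random gamma; and (for the ResNet50-UNet
#' recipe only) random crops that are resized back to the model input size.
#' Geometric transforms are applied identically to image and mask; intensity
#' transforms touch the image only. Application probabilities and distortion
#' magnitudes are conventional defaults, all overridable.
#'
#' @param horizontal_flip_p,shift_scale_rotate_p,distortion_group_p,intensity_group_p
#'   Application probabilities in \[0, 1\].
#' @param max_rotation_deg Rotation limit in degrees (default 20).
#' @param shift_limit,scale_limit Shift fraction and scale deviation limits.
#' @param elastic_alpha,elastic_sigma Elastic displacement magnitude (pixels)
#'   and smoothing sigma (pixels).
#' @param optical_k Radial distortion coefficient limit.
#' @param grid_steps,grid_limit Grid distortion cell count and stretch limit.
#' @param contrast_limit,brightness_limit,gamma_range Intensity transform limits.
#' @param random_crop_enabled Enable random area crops (resized back).
#' @param random_crop_area_range Crop area fraction interval in (0, 1\].
#' @param seed Default RNG seed used when [augment_pair()] is called without one.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(horizontal_flip_p = 0.5,
                                max_rotation_deg = 20,
                                shift_scale_rotate_p = 0.5,
                                shift_limit = 0.0625,
                                scale_limit = 0.1,
                                distortion_group_p = 0.5,
                                elastic_alpha = 20,
                                elastic_sigma = 6,
                                optical_k = 0.3,
                                grid_steps = 5L,
                                grid_limit = 0.3,
                                intensity_group_p = 0.5,
                                contrast_limit = 0.2,
                                brightness_limit = 0.2,
                                gamma_range = c(0.8, 1.25),
                                random_crop_enabled = FALSE,
                                random_crop_area_range = c(0.81, 1.0),
                                seed = NULL) {
  p <- c(horizontal_flip_p, shift_scale_rotate_p, distortion_group_p,
         intensity_group_p)
  stopifnot(all(p >= 0 & p <= 1), max_rotation_deg >= 0,
            length(random_crop_area_range) == 2L,
            random_crop_area_range[1] > 0, random_crop_area_range[2] <= 1,
            random_crop_area_range[1] <= random_crop_area_range[2])
  structure(as.list(environment()), class = "augmentation_config")
}

#' Augmentation presets per model
#'
#' Random crop is enabled only for the ResNet50-UNet recipe; all other models
#' share the common menu.
#'
#' @param model_name One of `"resnet50_unet"`, `"densenet169_unet"`,
#'   `"se_resnext50_unet"`, `"efficientnetb4_unet"`, `"se_resnext101_unet"`,
#'   `"efficientnetb3_unet"`, `"tiny_unet"`.
#' @return An [augmentation_config()].
#' @export
build_train_augmentation <- function(model_name) {
  known <- c("resnet50_unet", "densenet169_unet", "se_resnext50_unet",
             "efficientnetb4_unet", "se_resnext101_unet", "efficientnetb3_unet",
             "tiny_unet")
  if (!model_name %in% known) {
    stop("unknown model name: ", model_name,
         " (expected one of ", paste(known, collapse = ", "), ")")
  }
  augmentation_config(random_crop_enabled = model_name == "resnet50_unet")
}

# --- coordinate remapping helpers -----------------------------------------

# Reflect-101 fold of (possibly fractional) 1-based coordinates into [1, n].
reflect101 <- function(x, n) {
  if (n == 1L) return(rep(1, length(x)))
  p <- 2 * (n - 1)
  m <- (x - 1) %% p
  m <- ifelse(m > (n - 1), p - m, m)
  m + 1
}

remap_bilinear <- function(img, rs, cs) {
  h <- nrow(img); w <- ncol(img)
  rs <- reflect101(rs, h); cs <- reflect101(cs, w)
  r0 <- pmin(floor(rs), h - 1L); c0 <- pmin(floor(cs), w - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- rs - r0; fc <- cs - c0
  v00 <- img[cbind(r0, c0)]; v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]; v11 <- img[cbind(r0 + 1, c0 + 1)]
  out <- (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
  matrix(out, h, w)
}

remap_nearest <- function(img, rs, cs) {
  h <- nrow(img); w <- ncol(img)
  rs <- pmin(pmax(round(reflect101(rs, h)), 1), h)
  cs <- pmin(pmax(round(reflect101(cs, w)), 1), w)
  matrix(img[cbind(rs, cs)], h, w)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  # the Gaussian brush must fit inside the image
  sigma <- min(sigma, (min(dim(m)) - 1) / 7)
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

# Output-pixel coordinate grids (vectors of length H*W, column-major).
coord_grid <- function(h, w) {
  list(r = rep(seq_len(h), times = w), c = rep(seq_len(w), each = h))
}

#' Apply stochastic augmentation to an image/mask pair
#'
#' Deterministic for a fixed `rng_state`: running twice with the same state
#' yields bitwise-identical outputs. The mask (when present) is warped with
#' nearest-neighbour sampling and therefore stays binary; output dimensions
#' always equal input dimensions.
#'
#' @param input A `model_input` (see [to_model_input()]).
#' @param cfg An [augmentation_config()].
#' @param rng_state Integer seed for this draw (defaults to `cfg$seed`).
#' @return An augmented `model_input`.
#' @export
augment_pair <- function(input, cfg, rng_state = cfg$seed) {
  stopifnot(inherits(input, "model_input"), inherits(cfg, "augmentation_config"))
  if (is.null(rng_state)) stop("augment_pair needs an rng_state (or cfg$seed)")
  h <- dim(input$tensor)[1]; w <- dim(input$tensor)[2]
  if (!is.null(input$mask) && !identical(dim(input$mask), c(h, w))) {
    stop("image and mask dimensions differ")
  }
  with_seed(rng_state, {
    chans <- lapply(seq_len(dim(input$tensor)[3]), function(k) input$tensor[, , k])
    mask <- input$mask

    if (runif(1) < cfg$horizontal_flip_p) {
      chans <- lapply(chans, function(m) m[, w:1, drop = FALSE])
      if (!is.null(mask)) mask <- mask[, w:1, drop = FALSE]
    }

    if (runif(1) < cfg$shift_scale_rotate_p) {
      ang <- runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg) * pi / 180
      scl <- 1 + runif(1, -cfg$scale_limit, cfg$scale_limit)
      shr <- runif(1, -cfg$shift_limit, cfg$shift_limit) * h
      shc <- runif(1, -cfg$shift_limit, cfg$shift_limit) * w
      g <- coord_grid(h, w)
      rc <- (h + 1) / 2; cc <- (w + 1) / 2
      dr <- g$r - rc - shr; dc <- g$c - cc - shc
      rs <- (cos(-ang) * dr - sin(-ang) * dc) / scl + rc
      cs <- (sin(-ang) * dr + cos(-ang) * dc) / scl + cc
      chans <- lapply(chans, remap_bilinear, rs = rs, cs = cs)
      if (!is.null(mask)) mask <- remap_nearest(mask, rs, cs)
    }

    if (runif(1) < cfg$distortion_group_p) {
      which_d <- sample.int(3L, 1L)
      g <- coord_grid(h, w)
      if (which_d == 1L) {  # elastic
        dr <- gaussian_blur(matrix(rnorm(h * w), h, w), cfg$elastic_sigma)
        dc <- gaussian_blur(matrix(rnorm(h * w), h, w), cfg$elastic_sigma)
        nrm <- max(sd(dr), 1e-12)
        rs <- g$r + as.vector(dr) / nrm * cfg$elastic_alpha / 10
        cs <- g$c + as.vector(dc) / nrm * cfg$elastic_alpha / 10
      } else if (which_d == 2L) {  # optical (radial)
        k <- runif(1, -cfg$optical_k, cfg$optical_k)
        rc <- (h + 1) / 2; cc <- (w + 1) / 2
        u <- (g$r - rc) / (h / 2); v <- (g$c - cc) / (w / 2)
        f <- 1 + k * (u * u + v * v)
        rs <- rc + (g$r - rc) * f
        cs <- cc + (g$c - cc) * f
      } else {  # grid
        warp_axis <- function(n) {
          steps <- 1 + runif(cfg$grid_steps, -cfg$grid_limit, cfg$grid_limit)
          src <- cumsum(c(0, steps)) / sum(steps) * (n - 1) + 1
          out <- seq(1, n, length.out = cfg$grid_steps + 1L)
          stats::approx(out, src, xout = seq_len(n))$y
        }
        rs <- rep(warp_axis(h), times = w)
        cs <- rep(warp_axis(w), each = h)
      }
      chans <- lapply(chans, remap_bilinear, rs = rs, cs = cs)
      if (!is.null(mask)) mask <- remap_nearest(mask, rs, cs)
    }

    if (runif(1) < cfg$intensity_group_p) {
      which_i <- sample.int(3L, 1L)
      # one parameter draw shared by all three (identical) channels
      par <- switch(which_i,
                    1 + runif(1, -cfg$contrast_limit, cfg$contrast_limit),
                    runif(1, -cfg$brightness_limit, cfg$brightness_limit),
                    runif(1, cfg$gamma_range[1], cfg$gamma_range[2]))
      chans <- lapply(chans, function(m) {
        m <- switch(which_i,
                    (m - mean(m)) * par + mean(m),
                    m + par,
                    pmax(m, 0)^par)
        pmin(pmax(m, 0), 1)
      })
    }

    if (cfg$random_crop_enabled) {
      a <- runif(1, cfg$random_crop_area_range[1], cfg$random_crop_area_range[2])
      side <- sqrt(a)
      ch <- max(1L, round(h * side)); cw <- max(1L, round(w * side))
      top <- sample.int(h - ch + 1L, 1L); left <- sample.int(w - cw + 1L, 1L)
      chans <- lapply(chans, function(m) {
        resize_matrix(m[top:(top + ch - 1L), left:(left + cw - 1L)], h, w, "bilinear")
      })
      if (!is.null(mask)) {
        mask <- resize_matrix(mask[top:(top + ch - 1L), left:(left + cw - 1L)],
                              h, w, "none")
        mask <- (mask > 0.5) + 0L
        dim(mask) <- c(h, w)
      }
    }

    tensor <- array(unlist(chans, use.names = FALSE), dim = dim(input$tensor))
    if (!is.null(mask)) {
      mask <- (mask > 0.5) + 0L
      dim(mask) <- c(h, w)
    }
    structure(list(tensor = pmin(pmax(tensor, 0), 1), mask = mask,
                   image_id = input$image_id),
              class = "model_input")
  })
}
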