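#' Synthetic chest-phantom corpus configuration
#'
#' The generator emulates the statistics the pipeline cares about — grayscale
#' lung-field phantoms with thin crescent-shaped pleural lesions occupying a
#' small fraction of pixels, a ~22% positive prevalence matching the real
#' corpus, and annotations stored one RLE string per lesion component — with
#' no attempt at radiographic realism.
#'
#' @param image_size Side length in pixels.
#' @param n_images Number of images.
#' @param positive_fraction Fraction of images with lesions (default 0.22,
#'   the prevalence of the real training corpus).
#' @param lesion_area_range Per-image foreground fraction interval
#'   (default 0.005 to 0.08).
#' @param noise_sd Additive Gaussian pixel noise, grayscale units.
#' @param seed Corpus seed; identical configs yield byte-identical corpora.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L, n_images = 16L,
                           positive_fraction = 0.22,
                           lesion_area_range = c(0.005, 0.08),
                           noise_sd = 8, seed = 1L) {
  stopifnot(image_size >= 32L, n_images >= 1L,
            positive_fraction >= 0, positive_fraction <= 1,
            length(lesion_area_range) == 2L, lesion_area_range[1] > 0,
            lesion_area_range[2] <= 0.25, noise_sd >= 0)
  if (lesion_area_range[1] * image_size^2 < 4) {
    stop("infeasible lesion area for this image size")
  }
  structure(list(image_size = as.integer(image_size),
                 n_images = as.integer(n_images),
                 positive_fraction = positive_fraction,
                 lesion_area_range = lesion_area_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Crescent hugging a lung-ellipse boundary: normalized elliptical radius in
# [1 - t, 1] within an angular window. Area is monotone in t, so t is found
# by bisection against the pixel target.
crescent_mask <- function(S, r0, c0, a, b, theta0, phi, target_px) {
  g <- coord_grid(S, S)
  dr <- (g$r - r0) / a
  dc <- (g$c - c0) / b
  rho <- sqrt(dr * dr + dc * dc)
  ang <- atan2(dc, -dr)
  dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
  in_window <- dang <= phi / 2
  area_at <- function(t) sum(rho <= 1 & rho >= 1 - t & in_window)
  lo <- 0.01; hi <- 0.6
  if (area_at(hi) < target_px) {
    t <- hi
  } else {
    for (i in 1:18) {
      mid <- (lo + hi) / 2
      if (area_at(mid) < target_px) lo <- mid else hi <- mid
    }
    t <- hi
  }
  m <- (rho <= 1 & rho >= 1 - t & in_window) + 0L
  matrix(m, S, S)
}

ellipse_mask <- function(S, r0, c0, a, b) {
  g <- coord_grid(S, S)
  dr <- (g$r - r0) / a
  dc <- (g$c - c0) / b
  matrix((dr * dr + dc * dc <= 1) + 0L, S, S)
}

#' Generate a deterministic synthetic phantom corpus
#'
#' Each positive image contains 1–3 crescent-shaped lesion components hugging
#' a simulated lung-field boundary; negatives carry the all-`"-1"`
#' annotation. Masks, annotation CSV rows (one RLE string per component) and
#' images are mutually consistent under the RLE codec.
#'
#' @param cfg A [phantom_config()].
#' @param out_dir Optional directory; when given, images (PNG), masks (PNG)
#'   and `annotations.csv` are written in the layout the real dataset uses.
#' @param dicom Also write each image as a minimal DICOM file.
#' @return A `phantom_corpus`: list with `images` (list of `image_record`),
#'   `masks` (named list of binary matrices), `annotations` (data.frame),
#'   and `config`.
#' @export
generate_corpus <- function(cfg, out_dir = NULL, dicom = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  S <- cfg$image_size
  n <- cfg$n_images
  with_seed(cfg$seed, {
    n_pos <- round(cfg$positive_fraction * n)
    pos <- rep(FALSE, n)
    if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
    ids <- sprintf("phantom_%03d", seq_len(n))
    thorax <- ellipse_mask(S, 0.52 * S, 0.50 * S, 0.46 * S, 0.42 * S)
    lungs <- list(l = c(r0 = 0.46 * S, c0 = 0.32 * S, a = 0.30 * S, b = 0.15 * S),
                  r = c(r0 = 0.46 * S, c0 = 0.68 * S, a = 0.30 * S, b = 0.15 * S))
    lung_masks <- lapply(lungs, function(p) {
      ellipse_mask(S, p["r0"], p["c0"], p["a"], p["b"])
    })
    images <- vector("list", n)
    masks <- stats::setNames(vector("list", n), ids)
    ann_id <- character(0); ann_px <- character(0)
    for (i in seq_len(n)) {
      img <- 35 + 120 * thorax - 55 * lung_masks$l - 55 * lung_masks$r
      img <- img + outer(seq(0, 12, length.out = S), seq(-6, 6, length.out = S), "+")
      mask <- matrix(0L, S, S)
      if (pos[i]) {
        A <- runif(1, cfg$lesion_area_range[1], cfg$lesion_area_range[2])
        target_px <- A * S * S
        k <- min(3L, max(1L, ceiling(A / 0.03)))
        sides <- sample(names(lungs), k, replace = k > 2L)
        for (j in seq_len(k)) {
          p <- lungs[[sides[j]]]
          cm <- crescent_mask(S, p["r0"], p["c0"], p["a"], p["b"],
                              theta0 = runif(1, -pi, pi),
                              phi = runif(1, pi / 3, 2 * pi / 3),
                              target_px = target_px / k)
          mask <- (mask | cm) + 0L
        }
        dim(mask) <- c(S, S)
        img <- img - 30 * mask  # pleural air: locally lucent
      }
      img <- img + matrix(rnorm(S * S, sd = cfg$noise_sd), S, S)
      img <- round(pmin(pmax(img, 0), 255))
      storage.mode(img) <- "integer"
      images[[i]] <- structure(list(image_id = ids[i], pixels = img,
                                    source_kind = "synthetic",
                                    native_size = c(S, S)),
                               class = "image_record")
      masks[[i]] <- mask
      if (sum(mask) == 0L) {
        ann_id <- c(ann_id, ids[i]); ann_px <- c(ann_px, "-1")
      } else {
        lab <- cpp_label8(mask)
        for (comp in seq_len(max(lab))) {
          cmask <- (lab == comp) + 0L
          dim(cmask) <- c(S, S)
          ann_id <- c(ann_id, ids[i])
          ann_px <- c(ann_px, encode_rle(cmask))
        }
      }
    }
    ann <- data.frame(ImageId = ann_id, EncodedPixels = ann_px,
                      stringsAsFactors = FALSE)
    corpus <- structure(list(images = images, masks = masks, annotations = ann,
                             config = cfg),
                        class = "phantom_corpus")
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
      dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n)) {
        png::writePNG(images[[i]]$pixels / 255,
                      file.path(out_dir, "images", paste0(ids[i], ".png")))
        write_mask_png(masks[[i]],
                       file.path(out_dir, "masks", paste0(ids[i], ".png")))
        if (dicom) {
          dir.create(file.path(out_dir, "dicom"), showWarnings = FALSE)
          write_dicom(images[[i]]$pixels,
                      file.path(out_dir, "dicom", paste0(ids[i], ".dcm")),
                      image_id = ids[i])
        }
      }
      write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE,
                quote = FALSE)
    }
    corpus
  })
}

#' Synthetic per-model probability maps
#'
#' For each model name, emits `clip(blur(mask) + noise)` per image —
#' probability maps whose agreement with the masks degrades as `noise_sd`
#' grows, the fixture for post-processing and ensembling experiments.
#'
#' @param masks Named list of binary masks.
#' @param blur_sd Gaussian blur sigma in pixels (0 = no blur).
#' @param noise_sd Additive Gaussian noise on the \[0, 1\] probability scale.
#' @param seed RNG seed.
#' @param models Character vector of model names (one map set each).
#' @return Named list (per model) of named lists of probability matrices.
#' @export
generate_probability_maps <- function(masks, blur_sd = 1.5, noise_sd = 0.1,
                                      seed = 1L, models = "model1") {
  stopifnot(length(masks) >= 1L)
  with_seed(seed, {
    out <- stats::setNames(vector("list", length(models)), models)
    for (mn in models) {
      maps <- lapply(masks, function(m) {
        base <- if (blur_sd > 0) gaussian_blur(m + 0, blur_sd) else m + 0
        if (noise_sd > 0) {
          base <- base + matrix(rnorm(length(m), sd = noise_sd), nrow(m), ncol(m))
        }
        pmin(pmax(base, 0), 1)
      })
      out[[mn]] <- maps
    }
    out
  })
}
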