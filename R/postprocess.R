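#' Horizontal-flip test-time augmentation
#'
#' Averages the model's prediction on the image and the horizontally flipped
#' image (prediction flipped back): `(f(x) + unflip(f(flip(x)))) / 2`.
#'
#' @param model A `bunet_network`.
#' @param image A `model_input`, matrix or H x W x 3 array.
#' @return Probability matrix in \[0, 1\].
#' @export
tta_predict <- function(model, image) {
  x <- as_input_tensor(image)
  p1 <- predict(model, x)
  p2 <- predict(model, flip_lr(x))
  (p1 + flip_lr(p2)) / 2
}

#' Binarize a probability map
#'
#' Strict inequality: pixels with probability greater than `b_th` become 1,
#' pixels equal to or below `b_th` become 0.
#'
#' @param map Probability matrix.
#' @param b_th Binarization threshold in (0, 1).
#' @return Integer binary matrix.
#' @export
binarize <- function(map, b_th) {
  stopifnot(b_th > 0, b_th < 1)
  m <- (map > b_th) + 0L
  dim(m) <- dim(map)
  m
}

#' Remove small objects from a binary mask
#'
#' Component mode (default): 8-connected components whose pixel size is not
#' larger than `r_th` are erased (strict "larger than": a component of
#' exactly `r_th` pixels is removed). Whole-mask mode: the entire mask is
#' erased when its total foreground does not exceed `r_th`.
#'
#' @param mask Binary matrix.
#' @param r_th Removal threshold in pixels; `NA` or 0 disables removal.
#' @param mode `"component"` or `"whole_mask"`.
#' @return Binary matrix.
#' @export
remove_small <- function(mask, r_th, mode = c("component", "whole_mask")) {
  mode <- match.arg(mode)
  check_binary_mask(mask)
  if (is.na(r_th) || r_th <= 0) return(mask)
  if (mode == "whole_mask") {
    if (sum(mask) <= r_th) return(matrix(0L, nrow(mask), ncol(mask)))
    return(mask)
  }
  mm <- mask
  storage.mode(mm) <- "integer"
  lab <- cpp_label8(mm)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes > r_th
  out <- (lab > 0L & keep[pmax(lab, 1L)]) + 0L
  dim(out) <- dim(mask)
  out
}

#' The dual-threshold search grid
#'
#' 70 binarization thresholds (0.20, 0.21, ..., 0.89 — "0.2 to 0.9" with an
#' exclusive upper bound is the only reading consistent with 70 values at
#' step 0.01) crossed with 5 removal options (none, 1024, 2048, 3072, 4096
#' pixels): 350 candidates.
#'
#' @return Data.frame with columns `b_th` and `r_th` (`NA` = no removal).
#' @export
threshold_grid <- function() {
  b <- round(0.20 + 0.01 * (0:69), 2)
  r <- c(NA, 1024, 2048, 3072, 4096)
  expand.grid(b_th = b, r_th = r, KEEP.OUT.ATTRS = FALSE)
}

#' Joint grid search over binarization and removal thresholds
#'
#' Evaluates the objective (default: macro mean per-image IoU with the
#' both-empty-equals-1 convention) for every grid point over a validation
#' set of probability maps and ground-truth masks; deterministic.
#' Ties break toward the least aggressive post-processing: highest
#' objective, then lowest `b_th`, then no removal, then smallest `r_th`.
#'
#' @param prob_maps List of probability matrices.
#' @param truths List of binary matrices, aligned with `prob_maps`.
#' @param grid Candidate data.frame (default [threshold_grid()]).
#' @param objective Function `(preds, truths) -> scalar` to maximize;
#'   default mean per-image [iou()].
#' @param mode Removal mode passed to [remove_small()].
#' @return List with `best` (list `b_th`, `r_th`, `score`) and `table`
#'   (the grid with a `score` column, one row per grid point).
#' @export
tune_thresholds <- function(prob_maps, truths, grid = threshold_grid(),
                            objective = NULL,
                            mode = c("component", "whole_mask")) {
  mode <- match.arg(mode)
  if (length(prob_maps) == 0L) stop("empty validation set")
  stopifnot(length(prob_maps) == length(truths))
  if (is.null(objective)) {
    objective <- function(preds, truths) mean(mapply(iou, preds, truths))
  }
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    preds <- lapply(prob_maps, function(m) {
      remove_small(binarize(m, grid$b_th[g]), grid$r_th[g], mode)
    })
    score[g] <- objective(preds, truths)
  }
  tab <- cbind(grid, score = score)
  ord <- order(-score, grid$b_th, !is.na(grid$r_th),
               ifelse(is.na(grid$r_th), 0, grid$r_th))
  best <- tab[ord[1L], ]
  list(best = list(b_th = best$b_th, r_th = best$r_th, score = best$score),
       table = tab)
}

#' Ensemble configuration
#'
#' Member weights for probability-map averaging. The published best weights
#' are available as presets: `"prose"` — 40% EfficientNetB4-UNet, 40%
#' SE-ResNeXt50-UNet, 20% DenseNet169-UNet, 20% ResNet50-UNet (sum 1.2,
#' normalized before use); `"grid_best"` — the top validation grid row
#' (10/10/40/40 for ResNet50/DenseNet169/SE-ResNeXt50/EfficientNetB4).
#'
#' @param members Named numeric vector of positive weights.
#' @param normalize Normalize weights to sum to 1 before averaging (default
#'   TRUE; an unnormalized weighted average could push probabilities above 1
#'   and would change the meaning of binarization thresholds).
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(members, normalize = TRUE) {
  stopifnot(is.numeric(members), length(members) >= 1L)
  if (any(members <= 0)) stop("ensemble weights must be positive")
  structure(list(members = members, normalize = isTRUE(normalize)),
            class = "ensemble_config")
}

#' @rdname ensemble_config
#' @param name Preset name: `"prose"` or `"grid_best"`.
#' @export
ensemble_weights_preset <- function(name = c("prose", "grid_best")) {
  name <- match.arg(name)
  w <- switch(name,
    prose = c(efficientnetb4_unet = 0.4, se_resnext50_unet = 0.4,
              densenet169_unet = 0.2, resnet50_unet = 0.2),
    grid_best = c(efficientnetb4_unet = 0.4, se_resnext50_unet = 0.4,
                  densenet169_unet = 0.1, resnet50_unet = 0.1))
  ensemble_config(w)
}

#' Weighted average of probability maps
#'
#' Pixelwise `sum(w_i * map_i)` with weights normalized to sum to 1.
#'
#' @param maps List of probability matrices sharing dimensions; names are
#'   matched against `cfg$members` when both are named.
#' @param cfg An [ensemble_config()].
#' @return Probability matrix in \[0, 1\].
#' @export
ensemble_average <- function(maps, cfg) {
  stopifnot(inherits(cfg, "ensemble_config"), length(maps) >= 1L)
  w <- cfg$members
  if (!is.null(names(maps)) && !is.null(names(w))) {
    if (!all(names(maps) %in% names(w))) stop("unmatched ensemble member names")
    w <- w[names(maps)]
  }
  stopifnot(length(w) == length(maps))
  if (cfg$normalize) w <- w / sum(w)
  d <- dim(maps[[1L]])
  out <- matrix(0, d[1L], d[2L])
  for (i in seq_along(maps)) {
    if (!identical(dim(maps[[i]]), d)) stop("ensemble map dimension mismatch")
    out <- out + w[i] * maps[[i]]
  }
  pmin(pmax(out, 0), 1)
}

#' Post-process one probability map to a final binary mask
#'
#' Default order (`threshold_at = "native"`): upscale the probability map to
#' the submission resolution, then binarize and remove small objects, so the
#' removal threshold counts native-resolution pixels. The alternative order
#' (`"model"`) binarizes at model resolution and upscales the binary mask
#' with nearest-neighbour interpolation.
#'
#' @param map Probability matrix (model resolution).
#' @param b_th,r_th Thresholds (see [binarize()], [remove_small()]).
#' @param target_size Submission resolution (default 1024).
#' @param mode Removal mode.
#' @param threshold_at `"native"` or `"model"`.
#' @return Binary matrix at `target_size`.
#' @export
postprocess_map <- function(map, b_th, r_th = NA, target_size = 1024L,
                            mode = c("component", "whole_mask"),
                            threshold_at = c("native", "model")) {
  mode <- match.arg(mode)
  threshold_at <- match.arg(threshold_at)
  if (threshold_at == "native") {
    m <- binarize(upscale_probability(map, target_size), b_th)
  } else {
    m <- binarize(map, b_th)
    m <- resize_matrix(m, target_size, target_size, "none")
    m <- (m > 0.5) + 0L
    dim(m) <- c(target_size, target_size)
  }
  remove_small(m, r_th, mode)
}

#' Write a submission CSV
#'
#' One row per image (`ImageId,EncodedPixels`); empty masks are written as
#' `"-1"`. Every row round-trips through [decode_rle()].
#'
#' @param masks Named list of binary masks (names are image ids).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_submission <- function(masks, path) {
  ids <- names(masks)
  if (is.null(ids) || any(ids == "")) stop("masks must be a named list")
  if (anyDuplicated(ids)) stop("duplicate image_id in submission: ",
                               ids[duplicated(ids)][1L])
  df <- data.frame(ImageId = ids,
                   EncodedPixels = vapply(masks, encode_rle, ""),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
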