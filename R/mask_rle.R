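#' Relative run-length mask codec
#'
#' The SIIM-ACR pneumothorax annotations store binary masks as a *relative*
#' run-length encoding: the string is a whitespace-separated list of integer
#' tokens in (start, length) pairs, where the first start is an absolute flat
#' pixel index and every later start is an offset ("gap") counted from the end
#' of the previous run. The sentinel `"-1"` denotes an empty mask.
#'
#' Flat pixel indices follow the challenge reference encoder: column-major
#' flattening with 0-based indices. Both the flattening order and the index
#' base are configurable because the published worked example (gaps close to
#' `width - 2`) cannot distinguish the dialects on its own.
#'
#' @param rle A single RLE string (or `"-1"`).
#' @param width,height Mask dimensions in pixels.
#' @param order Flattening order, `"column"` (default) or `"row"`.
#' @param base Index base of the first token, `0` (default) or `1`.
#' @param image_id Optional identifier used to label error messages.
#' @return `decode_rle()`: an integer `height x width` matrix of 0/1.
#' @examples
#' m <- decode_rle("0 3", 4, 4)
#' encode_rle(m)
#' @export
decode_rle <- function(rle, width, height, order = c("column", "row"),
                       base = 0L, image_id = NULL) {
  order <- match.arg(order)
  stopifnot(length(rle) == 1L, width >= 1, height >= 1)
  who <- if (is.null(image_id)) "" else sprintf(" [image %s]", image_id)
  rle <- trimws(rle)
  if (rle == "-1" || rle == "") {
    return(matrix(0L, nrow = height, ncol = width))
  }
  tok <- strsplit(rle, "\\s+")[[1]]
  num <- suppressWarnings(as.numeric(tok))
  if (anyNA(num) || any(num < 0) || any(num != floor(num))) {
    stop("malformed RLE: tokens must be non-negative integers (or the string \"-1\")", who)
  }
  if (length(num) %% 2L != 0L) {
    stop("malformed RLE: odd token count (", length(num), ")", who)
  }
  offs <- num[seq(1L, length(num), by = 2L)]
  lens <- num[seq(2L, length(num), by = 2L)]
  npix <- as.double(width) * height
  mask <- matrix(0L, nrow = height, ncol = width)
  pos <- offs[1L] - base  # absolute 0-based start of run 1
  runs <- length(offs)
  idx_all <- vector("list", runs)
  for (k in seq_len(runs)) {
    if (k > 1L) pos <- pos + offs[k]  # gap from the end of the previous run
    if (lens[k] > 0) {
      last <- pos + lens[k] - 1
      if (pos < 0 || last >= npix) {
        stop(sprintf("RLE run %d out of bounds: pixels [%d, %d] for a %dx%d mask",
                     k, pos, last, width, height), who)
      }
      idx_all[[k]] <- seq(pos, last)
    }
    pos <- pos + lens[k]
  }
  idx <- unlist(idx_all, use.names = FALSE)
  if (order == "column") {
    mask[idx + 1L] <- 1L
  } else {
    tm <- matrix(0L, nrow = width, ncol = height)
    tm[idx + 1L] <- 1L
    mask <- t(tm)
    storage.mode(mask) <- "integer"
  }
  mask
}

#' @rdname decode_rle
#' @param mask A binary `height x width` matrix (values 0/1).
#' @return `encode_rle()`: a single RLE string; the empty mask encodes to `"-1"`.
#' @export
encode_rle <- function(mask, order = c("column", "row"), base = 0L) {
  order <- match.arg(order)
  check_binary_mask(mask)
  m <- if (order == "column") mask else t(mask)
  idx <- which(m != 0) - 1L  # 0-based flat indices, ascending
  if (length(idx) == 0L) return("-1")
  brk <- which(diff(idx) > 1L)
  starts <- idx[c(1L, brk + 1L)]
  ends <- idx[c(brk, length(idx))]
  lens <- ends - starts + 1L
  k <- length(starts)
  first <- starts[1L] + base
  gaps <- if (k > 1L) starts[-1L] - (starts[-k] + lens[-k]) else integer(0)
  tokens <- c(rbind(c(first, gaps), lens))
  paste(format(tokens, scientific = FALSE, trim = TRUE), collapse = " ")
}

#' Merge several binary masks by pixelwise logical OR
#'
#' Images annotated with several RLE strings (multiple pneumothorax
#' components) are merged into one union mask at load time.
#'
#' @param masks A list of binary matrices sharing dimensions.
#' @return A single binary matrix.
#' @export
merge_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1L]])
  out <- matrix(0L, d[1L], d[2L])
  for (m in masks) {
    if (!identical(dim(m), d)) {
      stop("merge_masks: dimension mismatch (", paste(dim(m), collapse = "x"),
           " vs ", paste(d, collapse = "x"), ")")
    }
    check_binary_mask(m)
    out <- out | (m != 0)
  }
  storage.mode(out) <- "integer"
  out
}

#' Convert between flat pixel indices and (row, col) coordinates
#'
#' @param flat_index Vector of flat pixel indices (in the configured base).
#' @inheritParams decode_rle
#' @return A two-column matrix of 0-based `(row, col)` pairs.
#' @export
index_to_rowcol <- function(flat_index, width, height,
                            order = c("column", "row"), base = 0L) {
  order <- match.arg(order)
  i <- flat_index - base
  if (any(i < 0 | i >= as.double(width) * height)) {
    stop("flat index out of range for a ", width, "x", height, " mask")
  }
  if (order == "column") {
    cbind(row = i %% height, col = i %/% height)
  } else {
    cbind(row = i %/% width, col = i %% width)
  }
}

#' @rdname index_to_rowcol
#' @param row,col 0-based coordinates.
#' @export
rowcol_to_index <- function(row, col, width, height,
                            order = c("column", "row"), base = 0L) {
  order <- match.arg(order)
  if (any(row < 0 | row >= height | col < 0 | col >= width)) {
    stop("row/col out of range for a ", width, "x", height, " mask")
  }
  i <- if (order == "column") row + height * col else col + width * row
  i + base
}

check_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask == 0 | mask == 1)) stop("mask must contain only 0 and 1")
  invisible(TRUE)
}

#' Read an annotation CSV (ImageId, EncodedPixels)
#'
#' One row per RLE string; `"-1"` (with leading-space tolerance) means no
#' pneumothorax. Malformed records fail loudly naming the image.
#'
#' @param path CSV file path.
#' @return A data.frame with character columns `ImageId` and `EncodedPixels`.
#' @export
read_annotations <- function(path) {
  ann <- read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("ImageId", "EncodedPixels")
  if (!all(need %in% names(ann))) {
    stop("annotation CSV must have columns ImageId and EncodedPixels")
  }
  ann$EncodedPixels <- trimws(ann$EncodedPixels)
  ann[, need]
}

#' Decode all annotation rows of one image into a merged binary mask
#'
#' @param ann Annotation data.frame from [read_annotations()].
#' @param image_id Image identifier to look up.
#' @inheritParams decode_rle
#' @return A binary `height x width` matrix (all-zero for `"-1"` rows).
#' @export
mask_from_annotations <- function(ann, image_id, width = 1024L, height = 1024L,
                                  order = c("column", "row"), base = 0L) {
  order <- match.arg(order)
  rows <- ann[ann$ImageId == image_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no annotation rows for image ", image_id)
  masks <- lapply(rows$EncodedPixels, decode_rle, width = width, height = height,
                  order = order, base = base, image_id = image_id)
  merge_masks(masks)
}
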