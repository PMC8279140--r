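#' Read a single-frame 8-bit grayscale DICOM radiograph
#'
#' A deliberately narrow DICOM reader covering the uncompressed single-frame
#' 8-bit explicit-VR-little-endian files this pipeline consumes (and which
#' [write_dicom()] produces). Photometric interpretation MONOCHROME1 is
#' inverted to MONOCHROME2 polarity. Anything else (compressed transfer
#' syntaxes, multi-frame, >8 bit) errors out.
#'
#' @param path File path.
#' @param image_id Optional identifier override; defaults to the SOP Instance
#'   UID when present, else the file name without extension.
#' @return An `image_record`: list with `image_id`, `pixels` (H x W integer
#'   matrix in \[0, 255\]), `source_kind`, `native_size`.
#' @export
read_dicom <- function(path, image_id = NULL) {
  raw <- tryCatch(readBin(path, "raw", n = file.info(path)$size),
                  error = function(e) stop("unreadable DICOM file: ", path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop("unreadable DICOM file (missing DICM magic): ", path)
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  pos <- 133L
  elems <- list()
  while (pos + 8L <= length(raw) + 1L) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) stop("unsupported DICOM encoding (implicit VR?): ", path)
    if (vr %in% long_vrs) {
      len <- sum(as.integer(raw[(pos + 8L):(pos + 11L)]) * c(1, 256, 65536, 16777216))
      vpos <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      vpos <- pos + 8L
    }
    if (vpos + len - 1L > length(raw)) stop("unreadable DICOM file (truncated): ", path)
    key <- sprintf("%04x,%04x", grp, ele)
    elems[[key]] <- list(vr = vr, value = raw[vpos:(vpos + len - 1L)][seq_len(len)])
    pos <- vpos + len
    if (key == "7fe0,0010") break
  }
  getstr <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    trimws(gsub("\\x00", "", rawToChar(e$value)))
  }
  getus <- function(key) {
    e <- elems[[key]]
    if (is.null(e)) return(NULL)
    as.integer(e$value[1L]) + 256L * as.integer(e$value[2L])
  }
  rows <- getus("0028,0010"); cols <- getus("0028,0011")
  bits <- getus("0028,0100")
  if (is.null(elems[["7fe0,0010"]])) stop("DICOM file has no pixel data: ", path)
  if (is.null(rows) || is.null(cols)) stop("DICOM file lacks Rows/Columns: ", path)
  if (!is.null(bits) && bits != 8L) stop("only 8-bit DICOM pixel data is supported: ", path)
  px <- elems[["7fe0,0010"]]$value
  if (length(px) < rows * cols) stop("unreadable DICOM file (pixel data truncated): ", path)
  # pixel data is stored row-major (one image row after another)
  m <- t(matrix(as.integer(px[seq_len(rows * cols)]), nrow = cols, ncol = rows))
  photo <- getstr("0028,0004")
  if (!is.null(photo) && photo == "MONOCHROME1") m <- 255L - m
  if (is.null(image_id)) {
    image_id <- getstr("0008,0018")
    if (is.null(image_id) || image_id == "") {
      image_id <- sub("\\.[^.]*$", "", basename(path))
    }
  }
  structure(list(image_id = image_id, pixels = m, source_kind = "dicom",
                 native_size = c(rows, cols)),
            class = "image_record")
}

#' Write a minimal single-frame 8-bit DICOM file
#'
#' Counterpart of [read_dicom()], used by the synthetic fixture generator.
#'
#' @param pixels H x W integer matrix in \[0, 255\].
#' @param path Output path.
#' @param image_id Stored as the SOP Instance UID.
#' @param photometric `"MONOCHROME2"` (default) or `"MONOCHROME1"`.
#' @export
write_dicom <- function(pixels, path, image_id = "img",
                        photometric = "MONOCHROME2") {
  stopifnot(is.matrix(pixels), all(pixels >= 0 & pixels <= 255))
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))
    r
  }
  short_el <- function(grp, ele, vr, val) {
    c(u16(grp), u16(ele), charToRaw(vr), u16(length(val)), val)
  }
  long_el <- function(grp, ele, vr, val) {
    c(u16(grp), u16(ele), charToRaw(vr), as.raw(c(0, 0)), u32(length(val)), val)
  }
  ts <- pad("1.2.840.10008.1.2.1")
  meta <- c(short_el(2L, 16L, "UI", ts))
  meta <- c(short_el(2L, 0L, "UL", u32(length(meta))), meta)
  h <- nrow(pixels); w <- ncol(pixels)
  px <- as.raw(as.integer(t(pixels)))  # row-major
  body <- c(
    short_el(8L, 24L, "UI", pad(image_id)),
    short_el(40L, 2L, "US", u16(1L)),
    short_el(40L, 4L, "CS", pad(photometric)),
    short_el(40L, 16L, "US", u16(h)),
    short_el(40L, 17L, "US", u16(w)),
    short_el(40L, 256L, "US", u16(8L)),
    short_el(40L, 257L, "US", u16(8L)),
    short_el(40L, 259L, "US", u16(0L)),
    long_el(0x7fe0L, 16L, "OB", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Read a grayscale PNG radiograph into an image record
#' @inheritParams read_dicom
#' @return An `image_record` (see [read_dicom()]).
#' @export
read_image_png <- function(path, image_id = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(image_id = image_id, pixels = m, source_kind = "png",
                 native_size = dim(m)),
            class = "image_record")
}

#' Write/read binary masks as 8-bit PNG (foreground 255, background 0)
#' @param mask Binary H x W matrix.
#' @param path File path.
#' @export
write_mask_png <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- (a > 0.5) + 0L
  dim(m) <- dim(a)
  m
}

# Resize a matrix; filter "bilinear" or "none" (nearest neighbour).
resize_matrix <- function(m, height, width, filter = "bilinear") {
  if (nrow(m) == height && ncol(m) == width) return(m)
  r <- EBImage::resize(m, w = height, h = width, filter = filter)
  matrix(as.numeric(r), nrow = height, ncol = width)
}

#' Prepare a network input from an image record
#'
#' Replicates the grayscale image to three identical channels, resizes with
#' bilinear interpolation, and rescales intensities to \[0, 1\]. A ground-truth
#' mask, when supplied, is resized with nearest-neighbour interpolation so it
#' stays strictly binary.
#'
#' @param rec An `image_record`.
#' @param mask Optional binary mask at the record's native size.
#' @param target_size Output side length in pixels (default 512).
#' @return A `model_input`: list with `tensor` (H x W x 3 array in \[0, 1\]),
#'   `mask` (binary matrix or `NULL`) and `image_id`.
#' @export
to_model_input <- function(rec, mask = NULL, target_size = 512L) {
  stopifnot(inherits(rec, "image_record"), target_size >= 1)
  if (!is.null(mask)) {
    check_binary_mask(mask)
    if (!identical(dim(mask), dim(rec$pixels))) {
      stop("mask/image size mismatch for image ", rec$image_id)
    }
  }
  img <- resize_matrix(rec$pixels / 255, target_size, target_size, "bilinear")
  img <- pmin(pmax(img, 0), 1)
  tensor <- array(img, dim = c(target_size, target_size, 3L))
  if (!is.null(mask)) {
    mask <- resize_matrix(mask, target_size, target_size, "none")
    mask <- (mask > 0.5) + 0L
    dim(mask) <- c(target_size, target_size)
  }
  structure(list(tensor = tensor, mask = mask, image_id = rec$image_id),
            class = "model_input")
}

#' Bilinearly upscale a probability map
#'
#' Used to bring 512 x 512 network outputs back to the native 1,024 x 1,024
#' resolution before thresholding, so removal thresholds count
#' native-resolution pixels.
#'
#' @param map Matrix of probabilities in \[0, 1\].
#' @param target_size Output side length.
#' @return Matrix of probabilities in \[0, 1\].
#' @export
upscale_probability <- function(map, target_size) {
  stopifnot(all(map >= 0 & map <= 1))
  out <- resize_matrix(map, target_size, target_size, "bilinear")
  pmin(pmax(out, 0), 1)
}

#' Store/load probability maps as 16-bit TIFF
#'
#' Maps are quantized to 16 bits (`k / 65535`); the quantized values
#' round-trip exactly.
#'
#' @param map Probability matrix in \[0, 1\].
#' @param path File path.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(all(map >= 0 & map <= 1))
  tiff::writeTIFF(map, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
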