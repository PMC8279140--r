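#' Load an image directory plus annotation CSV as model inputs
#'
#' File discovery is driven by the annotation CSV: for every distinct
#' `ImageId` the loader reads `<id>.png` or `<id>.dcm` from `images_dir`,
#' decodes and merges that image's RLE rows at native resolution, and builds
#' a [to_model_input()] pair at `target_size`.
#'
#' @param images_dir Directory holding the images.
#' @param annotations Annotation CSV path or data.frame (see
#'   [read_annotations()]); `NULL` loads images without masks.
#' @param target_size Model input side length.
#' @param ids Optional subset of image ids.
#' @return Named list of `model_input`s.
#' @export
load_dataset <- function(images_dir, annotations = NULL, target_size = 512L,
                         ids = NULL) {
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- if (is.character(annotations)) read_annotations(annotations) else annotations
  }
  if (is.null(ids)) {
    ids <- if (!is.null(ann)) unique(ann$ImageId) else {
      unique(sub("\\.(png|dcm)$", "", list.files(images_dir, "\\.(png|dcm)$")))
    }
  }
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    png_path <- file.path(images_dir, paste0(id, ".png"))
    dcm_path <- file.path(images_dir, paste0(id, ".dcm"))
    rec <- if (file.exists(png_path)) read_image_png(png_path, id)
           else if (file.exists(dcm_path)) read_dicom(dcm_path, id)
           else stop("no image file found for ", id, " in ", images_dir)
    mask <- NULL
    if (!is.null(ann)) {
      mask <- mask_from_annotations(ann, id, width = ncol(rec$pixels),
                                    height = nrow(rec$pixels))
    }
    out[[id]] <- to_model_input(rec, mask, target_size = target_size)
  }
  out
}
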