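test_that("phantom corpora are byte-identical for identical configs", {
  cfg <- phantom_config(image_size = 64, n_images = 6, seed = 7)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$masks, b$masks)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))
  expect_identical(a$annotations, b$annotations)
  d <- generate_corpus(phantom_config(image_size = 64, n_images = 6, seed = 8))
  expect_false(identical(a$annotations, d$annotations))
})

test_that("a zero positive fraction yields only -1 annotations", {
  cfg <- phantom_config(image_size = 64, n_images = 5, positive_fraction = 0)
  corpus <- generate_corpus(cfg)
  expect_true(all(corpus$annotations$EncodedPixels == "-1"))
  expect_true(all(sapply(corpus$masks, sum) == 0))
})

test_that("annotations decode back to exactly the saved masks", {
  cfg <- phantom_config(image_size = 96, n_images = 8, positive_fraction = 0.6,
                        seed = 3)
  corpus <- generate_corpus(cfg)
  for (id in names(corpus$masks)) {
    expect_identical(mask_from_annotations(corpus$annotations, id, 96, 96),
                     corpus$masks[[id]])
  }
  # positives with several components have one RLE row per component
  npos_rows <- table(corpus$annotations$ImageId)
  ncomp <- sapply(names(corpus$masks), function(id) {
    max(pneumoseg:::cpp_label8(corpus$masks[[id]]))
  })
  for (id in names(ncomp)) {
    expect_equal(unname(npos_rows[id]), max(1, ncomp[[id]]))
  }
})

test_that("corpus statistics track the config across seeds", {
  for (s in 1:5) {
    cfg <- phantom_config(image_size = 96, n_images = 10,
                          positive_fraction = 0.22, seed = s)
    corpus <- generate_corpus(cfg)
    npos <- sum(sapply(corpus$masks, sum) > 0)
    expect_lte(abs(npos - 0.22 * 10), 1)
    fracs <- sapply(corpus$masks, function(m) mean(m != 0))
    fracs <- fracs[fracs > 0]
    # per-image lesion fraction: inside the configured interval up to the
    # small slack left by component overlap and pixelation
    expect_true(all(fracs >= cfg$lesion_area_range[1] * 0.5))
    expect_true(all(fracs <= cfg$lesion_area_range[2] * 1.2))
  }
})

test_that("corpus files land on disk in the dataset layout", {
  cfg <- phantom_config(image_size = 64, n_images = 4, positive_fraction = 0.5,
                        seed = 2)
  dir <- tempfile()
  corpus <- generate_corpus(cfg, out_dir = dir, dicom = TRUE)
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  expect_length(list.files(file.path(dir, "images")), 4)
  expect_length(list.files(file.path(dir, "masks")), 4)
  rec <- read_dicom(file.path(dir, "dicom", "phantom_001.dcm"))
  expect_identical(rec$pixels, corpus$images[[1]]$pixels)
  png_rec <- read_image_png(file.path(dir, "images", "phantom_001.png"))
  expect_identical(png_rec$pixels, corpus$images[[1]]$pixels)
  m <- read_mask_png(file.path(dir, "masks", "phantom_002.png"))
  expect_identical(m, corpus$masks[[2]])
})

test_that("probability maps degrade monotonically with noise", {
  cfg <- phantom_config(image_size = 64, n_images = 30, positive_fraction = 0.7,
                        seed = 9)
  corpus <- generate_corpus(cfg)
  clean <- generate_probability_maps(corpus$masks, blur_sd = 0, noise_sd = 0,
                                     seed = 1)$model1
  for (id in names(corpus$masks)) {
    expect_identical(binarize(clean[[id]], 0.5), corpus$masks[[id]] + 0L)
  }
  m_lo <- generate_probability_maps(corpus$masks, blur_sd = 1, noise_sd = 0.05,
                                    seed = 2)$model1
  m_hi <- generate_probability_maps(corpus$masks, blur_sd = 1, noise_sd = 0.3,
                                    seed = 2)$model1
  iou_at <- function(maps) mean(mapply(function(p, y) iou(binarize(p, 0.5), y),
                                       maps, corpus$masks))
  expect_gt(iou_at(m_lo), iou_at(m_hi))
  # determinism
  again <- generate_probability_maps(corpus$masks, blur_sd = 1, noise_sd = 0.05,
                                     seed = 2)$model1
  expect_identical(m_lo, again)
})
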