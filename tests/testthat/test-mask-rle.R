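test_that("the published worked example decodes to the six stated pixels", {
  m <- decode_rle("247981 1 1022 2 1021 3", 1024, 1024)
  expect_identical(sort(which(m != 0) - 1L),
                   c(247981L, 249004L, 249005L, 250027L, 250028L, 250029L))
  expect_equal(sum(m), 1 + 2 + 3)  # foreground equals the sum of length tokens
  expect_identical(encode_rle(m), "247981 1 1022 2 1021 3")
})

test_that("the empty-mask sentinel and simple runs behave as specified", {
  expect_identical(decode_rle("-1", 1024, 1024), matrix(0L, 1024, 1024))
  expect_identical(decode_rle(" -1", 16, 16), matrix(0L, 16, 16))
  m <- decode_rle("0 3", 4, 4)
  expect_identical(which(m != 0) - 1L, c(0L, 1L, 2L))
  expect_identical(encode_rle(m), "0 3")
  expect_identical(encode_rle(matrix(0L, 8, 8)), "-1")
})

test_that("malformed and out-of-bounds RLE strings fail loudly", {
  expect_error(decode_rle("10 2 5", 16, 16), "odd token count")
  expect_error(decode_rle("1 2 x 4", 16, 16), "malformed")
  expect_error(decode_rle("250 10", 16, 16), "run 1 out of bounds")
  expect_error(decode_rle("0 2 100 200", 16, 16), "run 2 out of bounds")
  expect_error(decode_rle("10 -2 1 1", 16, 16), "malformed")
  expect_error(decode_rle("250 10", 16, 16, image_id = "abc"), "abc")
})

test_that("encode/decode round-trips agree with brute-force oracles", {
  set.seed(41)
  cases <- c(rep(16L, 60), rep(64L, 50), rep(1024L, 10))
  for (s in cases) {
    m <- if (s >= 1024L) sparse_random_mask(s, s) else random_mask(s, s, runif(1, 0.05, 0.6))
    r <- encode_rle(m)
    expect_identical(r, oracle_encode(m))
    expect_identical(decode_rle(r, s, s), m)
    expect_identical(oracle_decode(r, s, s), m)
  }
})

test_that("decoded foreground count equals the sum of the length tokens", {
  set.seed(5)
  for (i in 1:20) {
    m <- random_mask(32, 32, 0.3)
    r <- encode_rle(m)
    if (r == "-1") next
    tok <- as.numeric(strsplit(r, " ")[[1]])
    expect_equal(sum(decode_rle(r, 32, 32)), sum(tok[seq(2, length(tok), 2)]))
  }
})

test_that("row- and column-major dialects are conjugate by transpose", {
  set.seed(6)
  for (i in 1:10) {
    m <- random_mask(24, 24, 0.3)
    r <- encode_rle(m, order = "column")
    expect_identical(decode_rle(r, 24, 24, order = "row"), t(m))
    expect_identical(decode_rle(encode_rle(t(m), order = "row"), 24, 24,
                                order = "column"), m)
  }
  # 1-based dialect shifts every start token by one
  m <- decode_rle("0 3", 4, 4)
  expect_identical(encode_rle(m, base = 1L), "1 3")
  expect_identical(decode_rle("1 3", 4, 4, base = 1L), m)
})

test_that("flat-index/rowcol conversion is bijective and matches enumeration", {
  expect_equal(index_to_rowcol(0, 1024, 1024)[1, ], c(row = 0, col = 0))
  expect_equal(index_to_rowcol(1024 * 1024 - 1, 1024, 1024)[1, ],
               c(row = 1023, col = 1023))
  # brute-force flattener for the first two columns, column-major
  for (i in 0:2047) {
    rc <- index_to_rowcol(i, 1024, 1024)
    expect_equal(unname(rc[1, ]), c(i %% 1024, i %/% 1024))
    expect_equal(unname(rowcol_to_index(rc[1, 1], rc[1, 2], 1024, 1024)), i)
  }
  expect_equal(unname(index_to_rowcol(1024, 1024, 1024)[1, ]), c(0, 1))
  expect_equal(unname(index_to_rowcol(5, 4, 4, order = "row")[1, ]), c(1, 1))
  expect_error(index_to_rowcol(16, 4, 4), "out of range")
})

test_that("merge_masks is a pixelwise OR with the expected algebra", {
  set.seed(7)
  m <- random_mask(16, 16, 0.3)
  z <- matrix(0L, 16, 16)
  expect_identical(merge_masks(list(m, z)), m)
  expect_identical(merge_masks(list(m, m)), m)
  a <- z; a[1:3] <- 1L
  b <- z; b[10:13] <- 1L
  expect_equal(sum(merge_masks(list(a, b))), 7)
  expect_error(merge_masks(list(m, matrix(0L, 8, 8))), "dimension mismatch")
})

test_that("annotation CSVs read back with merging and the -1 convention", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("ImageId,EncodedPixels",
               "img1,0 3",
               "img1,20 2",
               "img2, -1"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 3)
  m1 <- mask_from_annotations(ann, "img1", 8, 8)
  expect_equal(sum(m1), 5)
  expect_identical(mask_from_annotations(ann, "img2", 8, 8), matrix(0L, 8, 8))
  expect_error(mask_from_annotations(ann, "nope", 8, 8), "no annotation rows")
})
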