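# Independent brute-force oracles used by the property tests. These scan
# masks pixel by pixel (or via base rle()) and share no code with the
# package's vectorized codecs.

random_mask <- function(h, w, p = 0.2) {
  m <- matrix(rbinom(h * w, 1L, p), h, w)
  storage.mode(m) <- "integer"
  m
}

sparse_random_mask <- function(h, w, n_runs = 20) {
  m <- matrix(0L, h, w)
  idx <- sort(sample.int(h * w, n_runs))
  for (i in idx) {
    len <- sample.int(50, 1)
    m[i:min(i + len - 1, h * w)] <- 1L
  }
  m
}

# Decode oracle: walk the token pairs, tracking the absolute cursor, and set
# pixels one (row, col) at a time via explicit index arithmetic.
oracle_decode <- function(rle, width, height) {
  m <- matrix(0L, height, width)
  rle <- trimws(rle)
  if (rle == "-1") return(m)
  tok <- as.numeric(strsplit(rle, "\\s+")[[1]])
  pos <- NA
  for (k in seq(1, length(tok), by = 2)) {
    pos <- if (k == 1) tok[1] else pos + tok[k]
    for (j in seq_len(tok[k + 1])) {
      i0 <- pos + j - 1  # 0-based column-major flat index
      m[(i0 %% height) + 1, (i0 %/% height) + 1] <- 1L
    }
    pos <- pos + tok[k + 1]
  }
  m
}

# Encode oracle: run extraction via base rle() on the flattened mask.
oracle_encode <- function(mask) {
  v <- as.integer(mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths  # 0-based run starts
  fg <- which(r$values == 1L)
  if (length(fg) == 0) return("-1")
  s <- starts0[fg]; l <- r$lengths[fg]
  toks <- numeric(0)
  for (i in seq_along(fg)) {
    off <- if (i == 1) s[1] else s[i] - (s[i - 1] + l[i - 1])
    toks <- c(toks, off, l[i])
  }
  paste(format(toks, scientific = FALSE, trim = TRUE), collapse = " ")
}

# Pixel-set metric oracles.
oracle_iou <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  u <- length(union(A, B))
  if (u == 0) 1 else length(intersect(A, B)) / u
}

oracle_dsc <- function(a, b) {
  A <- which(a != 0); B <- which(b != 0)
  den <- length(A) + length(B)
  if (den == 0) 1 else 2 * length(intersect(A, B)) / den
}

# Direct-loop convolution oracle for tiny tensors (same semantics as the
# package kernel: correlation, zero padding pt/pl, groups).
oracle_conv <- function(x, w, bias, stride, pt, pl, Ho, Wo, groups) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; cin_g <- dim(w)[3]; Cout <- dim(w)[4]
  cout_g <- Cout / groups
  y <- array(0, dim = c(Ho, Wo, Cout, N))
  for (n in 1:N) for (o in 1:Cout) {
    g <- (o - 1) %/% cout_g
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(bias)) 0 else bias[o]
      for (c in 1:cin_g) for (ki in 1:k) for (kj in 1:k) {
        hi <- (ho - 1) * stride - pt + ki
        wi <- (wo - 1) * stride - pl + kj
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[hi, wi, g * cin_g + c, n] * w[ki, kj, c, o]
        }
      }
      y[ho, wo, o, n] <- acc
    }
  }
  y
}

# Union-find 8-connected labelling oracle for small masks: returns sorted
# component sizes.
oracle_component_sizes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  parent <- seq_len(h * w)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  uni <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  for (r in 1:h) for (c in 1:w) {
    if (mask[r, c] == 0) next
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] != 0) {
        uni(r + (c - 1) * h, rr + (cc - 1) * h)
      }
    }
  }
  roots <- vapply(which(mask != 0), find, numeric(1))
  sort(as.integer(table(roots)))
}

# Shared tiny phantom corpus for the training/pipeline tests (built once).
smoke_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- phantom_config(image_size = 64, n_images = 8, positive_fraction = 1,
                            lesion_area_range = c(0.04, 0.12), noise_sd = 4,
                            seed = 7)
      cc <- generate_corpus(cfg)
      cache <<- lapply(seq_along(cc$images), function(i) {
        to_model_input(cc$images[[i]], cc$masks[[i]], target_size = 64L)
      })
    }
    cache
  }
})
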