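# Independent brute-force oracles and small fixture builders used across
# the test files. The oracles deliberately share no code with the package
# implementation: plain double loops over pixels.

# 2D correlation of a gray matrix with a small kernel, interior pixels only
oracle_conv_interior <- function(gray, kernel) {
  kr <- (nrow(kernel) - 1) / 2
  kc <- (ncol(kernel) - 1) / 2
  nr <- nrow(gray); nc <- ncol(gray)
  out <- matrix(NA_real_, nr, nc)
  for (i in (1 + kr):(nr - kr)) {
    for (j in (1 + kc):(nc - kc)) {
      acc <- 0
      for (a in -kr:kr) for (b in -kc:kc)
        acc <- acc + kernel[a + kr + 1, b + kc + 1] * gray[i + a, j + b]
      out[i, j] <- acc
    }
  }
  out
}

oracle_sobel_score <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- oracle_conv_interior(gray, kx)
  gy <- oracle_conv_interior(gray, ky)
  sum(sqrt(gx^2 + gy^2), na.rm = TRUE)
}

oracle_laplacian_score <- function(gray) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)
  sum(oracle_conv_interior(gray, k)^2, na.rm = TRUE)
}

# brute-force symmetric normalized GLCM at angle 0 plus its four statistics,
# by direct pair enumeration
oracle_glcm <- function(gray, mask, distance = 1, levels = 8) {
  q <- pmin(floor(pmin(pmax(gray, 0), 255) / 256 * levels), levels - 1)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(gray))) {
    for (cc in seq_len(ncol(gray) - distance)) {
      if (mask[r, cc] && mask[r, cc + distance]) {
        a <- q[r, cc] + 1; b <- q[r, cc + distance] + 1
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_glcm_stats <- function(p) {
  k <- nrow(p)
  eng <- 0; con <- 0; hom <- 0
  mi <- 0; mj <- 0
  for (i in 1:k) for (j in 1:k) {
    eng <- eng + p[i, j]^2
    con <- con + (i - j)^2 * p[i, j]
    hom <- hom + p[i, j] / (1 + abs(i - j))
    mi <- mi + i * p[i, j]; mj <- mj + j * p[i, j]
  }
  si2 <- 0; sj2 <- 0; cov <- 0
  for (i in 1:k) for (j in 1:k) {
    si2 <- si2 + (i - mi)^2 * p[i, j]
    sj2 <- sj2 + (j - mj)^2 * p[i, j]
    cov <- cov + (i - mi) * (j - mj) * p[i, j]
  }
  cor <- if (si2 == 0 || sj2 == 0) 0 else cov / sqrt(si2 * sj2)
  c(energy = eng, contrast = con, correlation = cor, homogeneity = hom)
}

# constant-color RGB image builder
const_rgb <- function(nr, nc, rgb) {
  img <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# small synthetic scene with constant-color structures: identical left and
# right cord patches so max/min feature pairs coincide exactly
toy_scene <- function() {
  img <- const_rgb(40, 40, c(180, 110, 100))
  regions <- list(
    glottis = matrix(FALSE, 40, 40),
    left_vc = matrix(FALSE, 40, 40),
    right_vc = matrix(FALSE, 40, 40),
    arytenoid = matrix(FALSE, 40, 40)
  )
  regions$glottis[15:30, 18:23] <- TRUE
  regions$left_vc[15:30, 8:13] <- TRUE
  regions$right_vc[15:30, 27:32] <- TRUE
  regions$arytenoid[3:10, 10:30] <- TRUE
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[regions$glottis] <- c(40, 20, 20)[ch]
    plane[regions$left_vc] <- c(220, 170, 160)[ch]
    plane[regions$right_vc] <- c(220, 170, 160)[ch]
    plane[regions$arytenoid] <- c(210, 190, 180)[ch]
    img[, , ch] <- plane
  }
  list(image = img, regions = regions)
}

# cached default phantom segmentation (reused within a test file run)
.lq_test_cache <- new.env(parent = emptyenv())

segmented_phantom <- function(seed = 1, lpr = FALSE) {
  key <- sprintf("seg_%d_%d", seed, lpr)
  if (is.null(.lq_test_cache[[key]])) {
    ph <- make_phantom(phantom_params(seed = seed, lpr = lpr))
    comp <- suppressWarnings(histogram_shift(ph$image))
    regions <- segment_regions(comp)
    .lq_test_cache[[key]] <- list(phantom = ph, compensated = comp,
                                  regions = regions)
  }
  .lq_test_cache[[key]]
}
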