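# Internal raster / numeric helpers shared by the pipeline stages.
# Images are numeric arrays dim (rows, cols, 3) in [0, 255]; gray images are
# numeric matrices; binary masks are logical matrices. All indexing is (row, col).

#' Signal a classed error
#'
#' @param msg message
#' @param class condition class (in addition to `lq_error`)
#' @noRd
lq_stop <- function(msg, class = "lq_invalid_input") {
  stop(structure(
    class = c(class, "lq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate code with a temporary RNG state
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' stream afterwards, so generators do not perturb user code.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_rgb_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
is_gray_image <- function(x) is.matrix(x) && is.numeric(x)
is_mask <- function(x) is.matrix(x) && is.logical(x)

check_rgb <- function(image) {
  if (!is_rgb_image(image) || any(dim(image)[1:2] < 1L))
    lq_stop("expected an RGB image array with dim (rows, cols, 3)")
  invisible(image)
}

check_gray <- function(gray, min_dim = c(1L, 1L)) {
  if (!is_gray_image(gray))
    lq_stop("expected a numeric gray-level matrix")
  if (nrow(gray) < min_dim[1] || ncol(gray) < min_dim[2])
    lq_stop(sprintf("gray image must be at least %dx%d", min_dim[1], min_dim[2]))
  invisible(gray)
}

#' Shift a matrix by (dr, dc), sampling source pixel (r + dr, c + dc)
#'
#' `pad = "replicate"` clamps indices at the border; `pad = "zero"` fills with
#' `fill` (0 for numeric, FALSE for logical).
#' @noRd
shift_mat <- function(m, dr, dc, pad = c("replicate", "zero"), fill = NULL) {
  pad <- match.arg(pad)
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) + dr
  ci <- seq_len(nc) + dc
  if (pad == "replicate") {
    m[clamp(ri, 1L, nr), clamp(ci, 1L, nc), drop = FALSE]
  } else {
    if (is.null(fill)) fill <- if (is.logical(m)) FALSE else 0
    out <- matrix(fill, nr, nc)
    rok <- ri >= 1L & ri <= nr
    cok <- ci >= 1L & ci <= nc
    out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
    out
  }
}

#' Symmetric separable convolution (replicate padding)
#'
#' Kernel must be odd-length and symmetric. Paired shifts are summed as
#' (left + right) so a mirrored input yields a bitwise-mirrored output,
#' which keeps left/right symmetry tests exact in floating point.
#' @noRd
conv_sep_sym <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  k0 <- kernel[r + 1L]
  # columns pass
  out <- k0 * m
  if (r > 0) for (j in seq_len(r)) {
    kj <- kernel[r + 1L + j]
    out <- out + kj * (shift_mat(m, 0L, -j) + shift_mat(m, 0L, j))
  }
  m2 <- out
  out <- k0 * m2
  if (r > 0) for (j in seq_len(r)) {
    kj <- kernel[r + 1L + j]
    out <- out + kj * (shift_mat(m2, -j, 0L) + shift_mat(m2, j, 0L))
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of a gray matrix (no-op for sigma <= 0)
#' @noRd
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep_sym(m, gaussian_kernel(sigma))
}

blur_rgb <- function(image, sigma) {
  if (sigma <= 0) return(image)
  out <- image
  for (ch in 1:3) out[, , ch] <- gaussian_blur(image[, , ch], sigma)
  out
}

#' 3x3 binary erosion / dilation (square structuring element)
#' @noRd
erode3 <- function(mask, passes = 1L) {
  for (p in seq_len(passes)) {
    out <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out & shift_mat(mask, dr, dc, pad = "zero", fill = FALSE)
    }
    mask <- out
  }
  mask
}

dilate3 <- function(mask, passes = 1L) {
  for (p in seq_len(passes)) {
    out <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out | shift_mat(mask, dr, dc, pad = "zero", fill = FALSE)
    }
    mask <- out
  }
  mask
}

#' Bilinear sample of a matrix at continuous (x = col, y = row) positions
#'
#' Coordinates are 1-based pixel centers; positions are clamped to the image.
#' @noRd
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- clamp(x, 1, nc); y <- clamp(y, 1, nr)
  x0 <- clamp(floor(x), 1, nc); x1 <- clamp(x0 + 1, 1, nc)
  y0 <- clamp(floor(y), 1, nr); y1 <- clamp(y0 + 1, 1, nr)
  fx <- x - x0; fy <- y - y0
  v00 <- m[cbind(y0, x0)]; v01 <- m[cbind(y0, x1)]
  v10 <- m[cbind(y1, x0)]; v11 <- m[cbind(y1, x1)]
  (v00 * (1 - fx) + v01 * fx) * (1 - fy) + (v10 * (1 - fx) + v11 * fx) * fy
}

#' Rasterize a closed polygon into a logical mask (even-odd scanline fill)
#'
#' `px` are x (column) and `py` y (row) vertex coordinates, 1-based pixel
#' centers; the polygon is closed implicitly. A pixel is inside when its
#' center passes the even-odd rule.
#' @noRd
fill_polygon <- function(px, py, nrow, ncol) {
  n <- length(px)
  mask <- matrix(FALSE, nrow, ncol)
  if (n < 3L) return(mask)
  x1 <- px; y1 <- py
  x2 <- px[c(2:n, 1L)]; y2 <- py[c(2:n, 1L)]
  r0 <- max(1L, ceiling(min(py))); r1 <- min(nrow, floor(max(py)))
  if (r0 > r1) return(mask)
  for (y0 in r0:r1) {
    sel <- (y1 <= y0 & y2 > y0) | (y2 <= y0 & y1 > y0)
    if (!any(sel)) next
    t <- (y0 - y1[sel]) / (y2[sel] - y1[sel])
    xs <- sort(x1[sel] + t * (x2[sel] - x1[sel]))
    i <- 1L
    while (i + 1L <= length(xs)) {
      a <- ceiling(xs[i] - 1e-9); b <- floor(xs[i + 1L] + 1e-9)
      a <- max(a, 1L); b <- min(b, ncol)
      if (a <= b) mask[y0, a:b] <- TRUE
      i <- i + 2L
    }
  }
  mask
}

#' Signed polygon area (shoelace); positive for counter-clockwise in (x, y)
#' @noRd
polygon_area <- function(px, py) {
  n <- length(px)
  x2 <- px[c(2:n, 1L)]; y2 <- py[c(2:n, 1L)]
  0.5 * sum(px * y2 - x2 * py)
}

#' Connected components of a binary mask (8-connectivity, run-based)
#'
#' Returns a list with `labels` (integer matrix, 0 = background) and
#' `components`, a data.frame ordered by decreasing area with columns
#' id, area, centroid_r, centroid_c, bbox_aspect (bbox width / height).
#' @noRd
label_components_mask <- function(mask) {
  if (!is_mask(mask)) lq_stop("expected a logical mask matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  parent <- integer(0)
  findp <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  prev <- integer(0)  # run ids of previous row
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) { prev <- integer(0); next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    s <- starts[rl$values]; e <- ends[rl$values]
    ids <- length(run_row) + seq_along(s)
    run_row <- c(run_row, rep.int(r, length(s)))
    run_s <- c(run_s, s); run_e <- c(run_e, e)
    parent <- c(parent, ids)
    if (length(prev)) {
      for (i in seq_along(ids)) {
        for (j in prev) {
          # 8-connectivity: diagonal touch counts
          if (s[i] <= run_e[j] + 1L && e[i] >= run_s[j] - 1L) {
            ri <- findp(ids[i]); rj <- findp(j)
            if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
          }
        }
      }
    }
    prev <- ids
  }
  labels <- matrix(0L, nr, nc)
  if (!length(run_row)) {
    return(list(labels = labels, components = data.frame(
      id = integer(0), area = integer(0), centroid_r = numeric(0),
      centroid_c = numeric(0), bbox_aspect = numeric(0))))
  }
  roots <- vapply(seq_along(parent), findp, integer(1))
  comp_of <- match(roots, sort(unique(roots)))
  n_comp <- max(comp_of)
  area <- integer(n_comp)
  sum_r <- sum_c <- numeric(n_comp)
  min_r <- min_c <- rep.int(.Machine$integer.max, n_comp)
  max_r <- max_c <- rep.int(0L, n_comp)
  for (k in seq_along(run_row)) {
    g <- comp_of[k]
    len <- run_e[k] - run_s[k] + 1L
    area[g] <- area[g] + len
    sum_r[g] <- sum_r[g] + run_row[k] * len
    sum_c[g] <- sum_c[g] + (run_s[k] + run_e[k]) / 2 * len
    min_r[g] <- min(min_r[g], run_row[k]); max_r[g] <- max(max_r[g], run_row[k])
    min_c[g] <- min(min_c[g], run_s[k]);  max_c[g] <- max(max_c[g], run_e[k])
    labels[run_row[k], run_s[k]:run_e[k]] <- g
  }
  comps <- data.frame(
    id = seq_len(n_comp),
    area = area,
    centroid_r = sum_r / area,
    centroid_c = sum_c / area,
    bbox_aspect = (max_c - min_c + 1L) / (max_r - min_r + 1L)
  )
  comps <- comps[order(-comps$area, comps$id), , drop = FALSE]
  rownames(comps) <- NULL
  list(labels = labels, components = comps)
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) lq_stop("empty mask has no bounding box")
  c(r0 = min(idx[, 1]), r1 = max(idx[, 1]), c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) lq_stop("empty mask has no centroid")
  c(r = mean(idx[, 1]), c = mean(idx[, 2]))
}

#' Mirror an RGB image or mask left-right
#'
#' Convenience for symmetry checks: columns are reversed.
#'
#' @param x RGB image array, gray matrix or logical mask.
#' @return object of the same type with columns reversed.
#' @export
mirror_lr <- function(x) {
  if (is_rgb_image(x)) {
    x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  } else if (is.matrix(x)) {
    x[, rev(seq_len(ncol(x))), drop = FALSE]
  } else {
    lq_stop("mirror_lr expects an image array or matrix")
  }
}
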