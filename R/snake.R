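# Greedy active-contour model (snake) with entropy-difference adaptive stop.
#
# A snake is a closed parametric contour v(s) = (x(s), y(s)) evolved to
# minimize internal energy (elasticity + curvature, weights alpha and beta)
# plus external image energy E_image = -|grad I|^2, plus an optional
# constraint energy. Evolution is greedy neighborhood descent in the style
# of Williams & Shah: each control point in turn moves to the position in
# its (2r+1)^2 neighborhood that minimizes its exact local contribution to
# the total energy, so the total energy is non-increasing by construction.
# A signed-area pressure term (the constraint energy) selects the direction
# of evolution: gamma > 0 contracts the contour, gamma < 0 inflates it.
# The adaptive stopping rule tracks the Shannon entropy of the enclosed
# region per iteration and stops at the iteration (within [min_iter,
# max_iter]) where the entropy difference between successive iterations is
# minimal.

#' Construct a snake
#'
#' @param points numeric n x 2 matrix of (x = col, y = row) coordinates,
#'   1-based pixel centers, ordered along a closed non-self-intersecting
#'   contour (the closing edge is implicit). At least 4 points.
#' @param alpha elasticity weight (>= 0); penalizes stretching and, alone,
#'   contracts the contour.
#' @param beta curvature weight (>= 0); penalizes bending.
#' @param gamma pressure weight for the constraint energy
#'   `gamma * enclosed_area` (orientation-normalized): positive contracts,
#'   negative inflates, 0 disables.
#' @param search_radius greedy neighborhood half-width in pixels.
#' @return object of class `lq_snake`.
#' @export
snake <- function(points, alpha = 1, beta = 0.5, gamma = 0, search_radius = 1L) {
  if (!is.matrix(points) || ncol(points) != 2 || nrow(points) < 4)
    lq_stop("snake needs an n x 2 coordinate matrix with n >= 4")
  if (alpha < 0 || beta < 0) lq_stop("alpha and beta must be >= 0")
  a <- polygon_area(points[, 1], points[, 2])
  structure(list(points = unname(points), alpha = alpha, beta = beta,
                 gamma = gamma, search_radius = as.integer(search_radius),
                 orient = if (a >= 0) 1 else -1),
            class = "lq_snake")
}

#' @export
print.lq_snake <- function(x, ...) {
  cat(sprintf("<lq_snake> %d points, alpha=%g beta=%g gamma=%g r=%d\n",
              nrow(x$points), x$alpha, x$beta, x$gamma, x$search_radius))
  invisible(x)
}

#' Internal energy of a snake
#'
#' 1/2 * sum over points of alpha |v_s|^2 + beta |v_ss|^2 with cyclic
#' finite differences: v_s is the first difference to the successor and
#' v_ss the second central difference.
#'
#' @param sn `lq_snake`.
#' @return non-negative scalar.
#' @export
internal_energy <- function(sn) {
  if (!inherits(sn, "lq_snake")) lq_stop("expected an lq_snake")
  p <- sn$points
  n <- nrow(p)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  vs <- p[nxt, , drop = FALSE] - p
  vss <- p[nxt, , drop = FALSE] - 2 * p + p[prv, , drop = FALSE]
  0.5 * sum(sn$alpha * rowSums(vs^2) + sn$beta * rowSums(vss^2))
}

#' External (image) energy field
#'
#' E_image(x, y) = -|grad I(x, y)|^2 with central-difference gradients
#' (one-sided at the borders). The image is smoothed with a small Gaussian
#' before differentiation to widen the capture range of the edges; set
#' `smooth_sigma = 0` to disable.
#'
#' @param gray gray matrix, at least 3x3.
#' @param smooth_sigma Gaussian pre-smoothing scale (default 1).
#' @param con optional constraint map added to the external energy.
#' @return object of class `lq_energy_field` with elements `external`
#'   (matrix, everywhere <= 0) and `con` (matrix or NULL).
#' @export
external_energy_field <- function(gray, smooth_sigma = 1, con = NULL) {
  check_gray(gray, c(3L, 3L))
  gs <- gaussian_blur(gray, smooth_sigma)
  nr <- nrow(gs); nc <- ncol(gs)
  gx <- (gs[, c(2:nc, nc)] - gs[, c(1, 1:(nc - 1))]) /
    rep(c(1, rep(2, nc - 2), 1), each = nr)
  gy <- (gs[c(2:nr, nr), ] - gs[c(1, 1:(nr - 1)), ]) /
    rep(c(1, rep(2, nr - 2), 1), times = nc)
  structure(list(external = -(gx^2 + gy^2), con = con),
            class = "lq_energy_field")
}

# external + constraint energy sampled at continuous points
sample_external <- function(field, x, y) {
  e <- bilinear_sample(field$external, x, y)
  if (!is.null(field$con)) e <- e + bilinear_sample(field$con, x, y)
  e
}

#' Total snake energy
#'
#' Internal energy plus the external field bilinearly sampled at the control
#' points, plus the pressure (constraint) term `gamma * enclosed_area` when
#' `gamma != 0`. This is exactly the objective the greedy evolution
#' minimizes, so it is non-increasing across [evolve()] iterations.
#'
#' @param sn `lq_snake`.
#' @param field `lq_energy_field`.
#' @return scalar.
#' @export
total_energy <- function(sn, field) {
  if (!inherits(field, "lq_energy_field")) lq_stop("expected an lq_energy_field")
  e <- internal_energy(sn) +
    sum(sample_external(field, sn$points[, 1], sn$points[, 2]))
  if (sn$gamma != 0)
    e <- e + sn$gamma * sn$orient * polygon_area(sn$points[, 1], sn$points[, 2])
  e
}

# candidate offsets in row-major order (dy outer, dx inner)
candidate_offsets <- function(r) {
  dy <- rep(-r:r, each = 2L * r + 1L)
  dx <- rep(-r:r, times = 2L * r + 1L)
  cbind(dx, dy)
}

#' Evolve a snake by greedy energy minimization
#'
#' Each iteration visits every control point in order and moves it to the
#' neighborhood position minimizing its exact local contribution to the
#' total energy (elasticity/curvature terms involving the point, the
#' external energy at the point, and the pressure term). Ties keep the
#' current position; among strictly better candidates the lowest row-major
#' one wins, making evolution fully deterministic.
#'
#' @param sn `lq_snake`.
#' @param field `lq_energy_field` (dimensions bound the contour).
#' @param n_iter number of iterations (>= 1).
#' @return evolved `lq_snake`; attribute `energy_trace` holds the total
#'   energy after each iteration.
#' @export
evolve <- function(sn, field, n_iter) {
  if (!inherits(sn, "lq_snake")) lq_stop("expected an lq_snake")
  if (!inherits(field, "lq_energy_field")) lq_stop("expected an lq_energy_field")
  if (n_iter < 1) lq_stop("n_iter must be >= 1")
  nr <- nrow(field$external); nc <- ncol(field$external)
  off <- candidate_offsets(sn$search_radius)
  cur <- which(off[, 1] == 0L & off[, 2] == 0L)
  p <- sn$points
  n <- nrow(p)
  ga <- sn$gamma * sn$orient
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(n)) {
      ip <- if (i == 1L) n else i - 1L
      ipp <- if (ip == 1L) n else ip - 1L
      inx <- if (i == n) 1L else i + 1L
      inn <- if (inx == n) 1L else inx + 1L
      xp <- p[ip, 1]; yp <- p[ip, 2]
      xpp <- p[ipp, 1]; ypp <- p[ipp, 2]
      xn <- p[inx, 1]; yn <- p[inx, 2]
      xnn <- p[inn, 1]; ynn <- p[inn, 2]
      cx <- clamp(p[i, 1] + off[, 1], 1, nc)
      cy <- clamp(p[i, 2] + off[, 2], 1, nr)
      e <- 0.5 * sn$alpha * ((cx - xp)^2 + (cy - yp)^2 +
                             (xn - cx)^2 + (yn - cy)^2) +
        0.5 * sn$beta * ((xn - 2 * cx + xp)^2 + (yn - 2 * cy + yp)^2 +
                         (cx - 2 * xp + xpp)^2 + (cy - 2 * yp + ypp)^2 +
                         (xnn - 2 * xn + cx)^2 + (ynn - 2 * yn + cy)^2) +
        sample_external(field, cx, cy)
      if (ga != 0)
        e <- e + ga * 0.5 * (xp * cy - cx * yp + cx * yn - xn * cy)
      best <- which.min(e)
      if (e[best] < e[cur] - 1e-9) {
        p[i, 1] <- cx[best]; p[i, 2] <- cy[best]
      }
    }
    sn$points <- p
    trace[it] <- total_energy(sn, field)
  }
  attr(sn, "energy_trace") <- trace
  sn
}

#' Shannon entropy of the gray levels within a mask
#'
#' Base-2 entropy of the 256-bin gray-level histogram of the masked pixels
#' (values rounded and clamped to 0..255), with 0 log 0 = 0.
#'
#' @param gray gray matrix.
#' @param mask logical matrix of the same dimensions.
#' @return entropy in bits, in \[0, 8\].
#' @export
region_entropy <- function(gray, mask) {
  check_gray(gray)
  if (!is_mask(mask) || !all(dim(mask) == dim(gray)))
    lq_stop("mask must be a logical matrix matching the image")
  v <- gray[mask]
  if (!length(v)) lq_stop("region_entropy: empty mask")
  lev <- clamp(round(v), 0, 255)
  p <- tabulate(lev + 1L, nbins = 256L)
  p <- p[p > 0] / length(lev)
  -sum(p * log2(p))
}

#' Region enclosed by a snake as a binary mask
#' @param sn `lq_snake`.
#' @param nrow,ncol mask dimensions.
#' @return logical matrix.
#' @export
snake_mask <- function(sn, nrow, ncol) {
  fill_polygon(sn$points[, 1], sn$points[, 2], nrow, ncol)
}

#' Evolve with the entropy-difference adaptive stopping rule
#'
#' Runs [evolve()] one iteration at a time up to `max_iter`, recording per
#' iteration the entropy H_i of the range grown by that iteration (the
#' symmetric difference between the regions enclosed before and after the
#' iteration; 0 when the contour did not move). The stopping iteration n*
#' is the i in \[min_iter, max_iter\] minimizing |H_i - H_(i-1)| (ties
#' resolved to the smallest i): while the contour grows into new tissue
#' each ring carries the tissue's gray-level entropy, and once growth
#' stalls at the target boundary the rings empty and the entropy difference
#' collapses to zero.
#'
#' @param sn `lq_snake`.
#' @param field `lq_energy_field`.
#' @param gray gray matrix for the entropy computation.
#' @param min_iter,max_iter iteration bounds (defaults 13 and 41).
#' @return list with `snake` (state at n*), `n_star`, `entropy` (H_i per
#'   iteration), `entropy_diffs` (|H_i - H_(i-1)|, NA for i = 1) and
#'   `energy_trace`.
#' @export
adaptive_evolve <- function(sn, field, gray, min_iter = 13L, max_iter = 41L) {
  if (min_iter < 2) lq_stop("min_iter must be >= 2")
  if (max_iter < min_iter) lq_stop("max_iter must be >= min_iter")
  nr <- nrow(field$external); nc <- ncol(field$external)
  H <- rep(NA_real_, max_iter)
  energy <- numeric(max_iter)
  snapshots <- vector("list", max_iter)
  state <- sn
  last <- 0L
  prev_mask <- snake_mask(state, nr, nc)
  for (i in seq_len(max_iter)) {
    state <- evolve(state, field, 1L)
    energy[i] <- attr(state, "energy_trace")
    m <- snake_mask(state, nr, nc)
    if (!any(m)) {
      if (i < min_iter)
        lq_stop(sprintf("contour degenerated at iteration %d (before min_iter)", i),
                "lq_degenerate_contour")
      break
    }
    ring <- xor(m, prev_mask)
    H[i] <- if (any(ring)) region_entropy(gray, ring) else 0
    prev_mask <- m
    snapshots[[i]] <- state$points
    last <- i
  }
  if (last < min_iter)
    lq_stop("contour degenerated before min_iter", "lq_degenerate_contour")
  d <- c(NA_real_, abs(diff(H[seq_len(last)])))
  cand <- seq.int(min_iter, last)
  n_star <- cand[which.min(d[cand])]
  out <- state
  out$points <- snapshots[[n_star]]
  list(snake = out, n_star = n_star,
       entropy = H[seq_len(last)], entropy_diffs = d,
       energy_trace = energy[seq_len(last)])
}

# resample a closed polygon to n points equally spaced by arc length
resample_polygon <- function(px, py, n) {
  m <- length(px)
  x2 <- px[c(2:m, 1L)]; y2 <- py[c(2:m, 1L)]
  seg <- sqrt((x2 - px)^2 + (y2 - py)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1L]
  t <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  idx <- findInterval(t, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- ifelse(seg[idx] > 0, (t - cum[idx]) / seg[idx], 0)
  cbind(px[idx] + frac * (x2[idx] - px[idx]),
        py[idx] + frac * (y2[idx] - py[idx]))
}

#' Initialize a snake on the convex hull of a mask
#'
#' The mask is optionally dilated, the convex hull of its pixel centers is
#' taken, and the hull polygon is resampled to `n_points` equally spaced
#' control points. Intended for contract-mode refinement of a candidate
#' component.
#'
#' @param mask logical matrix (non-empty).
#' @param n_points number of control points.
#' @param dilate_passes 3x3 dilation passes before taking the hull.
#' @param ... passed to [snake()].
#' @return `lq_snake`.
#' @export
mask_to_snake <- function(mask, n_points = 80L, dilate_passes = 0L, ...) {
  if (!is_mask(mask) || !any(mask)) lq_stop("mask_to_snake: empty mask")
  if (dilate_passes > 0) mask <- dilate3(mask, dilate_passes)
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  h <- grDevices::chull(x, y)
  pts <- resample_polygon(x[h], y[h], n_points)
  snake(pts, ...)
}
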