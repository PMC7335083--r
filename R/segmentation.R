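# Automatic segmentation of the glottis, arytenoid cartilage and vocal cords.
#
# The glottis is the darkest structure: global-histogram thresholding at the
# lower bound TH = mu - sigma followed by structure rules (area, centroid
# position, bounding-box aspect ratio) selects it directly. The arytenoid
# cartilage is found among the bright regions (binarize at mu + k sigma,
# erode, largest component, structure rules) and refined with a contracting
# snake. The vocal cords are grown from the bright ridge between the
# dilated glottis boundary and the valley separating each cord from the
# false vocal cord, using an inflating snake stopped by the entropy-
# difference rule. Dice similarity quantifies agreement with ground truth.

#' Lower threshold of the gray-level histogram
#'
#' TH = mu - sigma (population sd), clamped to \[0, 255\]. Pixels below TH
#' are "relatively dark" and glottis candidates.
#'
#' @param gray gray matrix.
#' @return scalar threshold.
#' @export
glottis_threshold <- function(gray) {
  check_gray(gray)
  mu <- mean(gray)
  sigma <- sqrt(mean((gray - mu)^2))
  clamp(mu - sigma, 0, 255)
}

#' Binarize dark pixels
#' @param gray gray matrix.
#' @param th threshold; pixels strictly below are selected.
#' @return logical mask.
#' @export
binarize_dark <- function(gray, th) {
  check_gray(gray)
  gray < th
}

#' Binarize bright pixels
#'
#' Pixels strictly above mu + k sigma (population statistics of the whole
#' image).
#'
#' @param gray gray matrix.
#' @param k sd multiplier (default 0.5).
#' @return logical mask.
#' @export
binarize_bright <- function(gray, k = 0.5) {
  check_gray(gray)
  mu <- mean(gray)
  sigma <- sqrt(mean((gray - mu)^2))
  gray > mu + k * sigma
}

#' Connected components of a mask
#'
#' 8-connectivity labeling. Components are returned in decreasing area
#' order with centroid (row, col) and bounding-box aspect ratio
#' (width / height).
#'
#' @param mask logical matrix.
#' @return data.frame with columns id, area, centroid_r, centroid_c,
#'   bbox_aspect; attribute `labels` holds the integer label matrix.
#' @export
label_components <- function(mask) {
  res <- label_components_mask(mask)
  out <- res$components
  attr(out, "labels") <- res$labels
  out
}

#' Structure rules for component discrimination
#'
#' @param min_area_frac minimum component area as a fraction of the image.
#' @param centroid_zone c(r0, r1, c0, c1) in normalized \[0, 1\] image
#'   coordinates; the component centroid must fall inside.
#' @param aspect_min,aspect_max admissible bounding-box width/height range.
#' @return object of class `lq_structure_rules`.
#' @export
structure_rules <- function(min_area_frac = 0.005,
                            centroid_zone = c(0, 1, 0, 1),
                            aspect_min = 1e-6, aspect_max = Inf) {
  if (aspect_min >= aspect_max) lq_stop("aspect_min must be < aspect_max")
  if (any(centroid_zone < 0) || any(centroid_zone > 1))
    lq_stop("centroid_zone must be within [0, 1]")
  structure(list(min_area_frac = min_area_frac, centroid_zone = centroid_zone,
                 aspect_min = aspect_min, aspect_max = aspect_max),
            class = "lq_structure_rules")
}

#' Default rules for the glottis
#'
#' Central 50% centroid zone in both axes; wide ("east-west") regions
#' rejected via aspect_max = 2 since the glottis is a tall inverted
#' triangle.
#' @return `lq_structure_rules`.
#' @export
glottis_rules <- function() {
  structure_rules(min_area_frac = 0.005, centroid_zone = c(0.25, 0.75, 0.25, 0.75),
                  aspect_min = 1e-6, aspect_max = 2)
}

#' Default rules for the arytenoid cartilage
#'
#' Centroid in the upper 40% of rows; tall ("south-north") regions rejected
#' via aspect_min = 1 since the block is a wide rectangle.
#' @return `lq_structure_rules`.
#' @export
arytenoid_rules <- function() {
  structure_rules(min_area_frac = 0.005, centroid_zone = c(0, 0.4, 0.05, 0.95),
                  aspect_min = 1, aspect_max = Inf)
}

#' Filter components by structure rules and pick the largest survivor
#'
#' @param components data.frame from [label_components()].
#' @param rules `lq_structure_rules`.
#' @param image_dims c(rows, cols).
#' @return the selected component (one-row data.frame) or NULL when none
#'   survives.
#' @export
apply_structure_rules <- function(components, rules, image_dims) {
  if (!inherits(rules, "lq_structure_rules")) lq_stop("expected lq_structure_rules")
  if (!nrow(components)) return(NULL)
  nr <- image_dims[1]; nc <- image_dims[2]
  z <- rules$centroid_zone
  ok <- components$area >= rules$min_area_frac * nr * nc &
    components$centroid_r >= z[1] * nr & components$centroid_r <= z[2] * nr &
    components$centroid_c >= z[3] * nc & components$centroid_c <= z[4] * nc &
    components$bbox_aspect >= rules$aspect_min &
    components$bbox_aspect <= rules$aspect_max
  surv <- components[ok, , drop = FALSE]
  if (!nrow(surv)) return(NULL)
  surv[which.max(surv$area), , drop = FALSE]
}

#' Segment the glottis
#'
#' Gray conversion, lower-bound threshold, dark binarization, component
#' labeling and glottis structure rules; returns the mask of the selected
#' component.
#'
#' @param image (compensated) RGB array.
#' @param rules structure rules (default [glottis_rules()]).
#' @return logical mask.
#' @export
segment_glottis <- function(image, rules = glottis_rules()) {
  check_rgb(image)
  gray <- rgb_to_gray(image)
  th <- glottis_threshold(gray)
  comps <- label_components(binarize_dark(gray, th))
  sel <- apply_structure_rules(comps, rules, dim(gray))
  if (is.null(sel)) lq_stop("glottis not found", "lq_not_found")
  attr(comps, "labels") == sel$id
}

#' Segment the arytenoid cartilage
#'
#' Bright binarization, one-pass 3x3 erosion, largest component, arytenoid
#' structure rules, then snake refinement: a contour initialized on the
#' convex hull of the dilated candidate contracts onto the block's edges
#' and the filled polygon is returned.
#'
#' @param image (compensated) RGB array.
#' @param rules structure rules (default [arytenoid_rules()]).
#' @param k bright-threshold sd multiplier.
#' @param n_points,n_iter snake discretization and iteration count.
#' @return logical mask; attribute `candidate` holds the pre-snake
#'   candidate mask.
#' @export
segment_arytenoid <- function(image, rules = arytenoid_rules(), k = 0.5,
                              n_points = 80L, n_iter = 20L) {
  check_rgb(image)
  gray <- rgb_to_gray(image)
  comps <- label_components(erode3(binarize_bright(gray, k), 1L))
  if (!nrow(comps)) lq_stop("arytenoid not found", "lq_not_found")
  largest <- comps[1, , drop = FALSE]
  sel <- apply_structure_rules(largest, rules, dim(gray))
  if (is.null(sel)) lq_stop("arytenoid not found", "lq_not_found")
  candidate <- attr(comps, "labels") == sel$id
  sn <- mask_to_snake(candidate, n_points = n_points, dilate_passes = 2L,
                      alpha = 1, beta = 0.5, gamma = 0, search_radius = 1L)
  field <- external_energy_field(gray)
  sn <- evolve(sn, field, n_iter)
  out <- snake_mask(sn, nrow(gray), ncol(gray))
  attr(out, "candidate") <- candidate
  out
}

# moving average of width 3 with replicated ends; (left + right) + center
# keeps mirrored profiles bitwise symmetric
ma3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  l <- v[c(1, 1:(n - 1))]
  r <- v[c(2:n, n)]
  ((l + r) + v) / 3
}

# scan a gray profile outward from the glottis edge: locate the cord ridge
# (first maximum), the valley beyond it (minimum after the ridge) and the
# cord's outer edge (half-prominence crossing of the ridge-to-valley
# descent).
# (first maximum) and the valley beyond it (minimum after the ridge).
# `cols` is the outward-ordered column sequence.
find_valley <- function(gray, row, cols, min_prominence = 20) {
  if (length(cols) < 3) return(NULL)
  prof <- ma3(gray[row, cols])
  peak <- which.max(prof)
  if (peak >= length(prof)) return(NULL)
  rest <- prof[(peak + 1L):length(prof)]
  valley <- peak + which.min(rest)
  # a genuine valley sits well below the cord ridge; plain noise does not
  if (prof[peak] - prof[valley] < min_prominence) return(NULL)
  half <- (prof[peak] + prof[valley]) / 2
  above <- which(prof[peak:valley] >= half)
  edge <- peak + max(above) - 1L
  edge <- min(edge + 1L, valley)
  list(ridge_col = cols[peak], valley_col = cols[valley],
       edge_col = cols[edge])
}

#' Segment the left and right vocal cords
#'
#' The glottis is dilated (3x3, 2 passes) and transected by the horizontal
#' line through its centroid. On each side the gray profile is scanned
#' outward for the bright cord ridge and the first valley beyond it (the
#' gap between cord and false cord). A thin snake initialized on the ridge,
#' spanning the glottis rows, is inflated with the pressure term and
#' stopped by the entropy-difference rule; the filled contour (minus the
#' glottis) is the cord mask. Left/right are assigned by centroid column
#' relative to the glottis centroid.
#'
#' @param image (compensated) RGB array.
#' @param glottis_mask logical glottis mask.
#' @param min_iter,max_iter adaptive iteration bounds (defaults 13 and 41).
#' @param gamma inflation pressure (negative expands; default -40).
#' @param beta bending stiffness of the cord snake (default 10; stiffer
#'   than the generic snake default so the converged contour stays put).
#' @param scan_range maximum outward scan distance in pixels.
#' @param n_points snake control points.
#' @return list with `left`, `right` (logical masks), `n_star` (named
#'   integer vector of adaptive iteration counts) and `valley_cols`.
#' @export
segment_vocal_cords <- function(image, glottis_mask,
                                min_iter = 13L, max_iter = 41L,
                                gamma = -40, beta = 10, search_radius = 1L, scan_range = 60L,
                                n_points = 100L) {
  check_rgb(image)
  if (!is_mask(glottis_mask) || !any(glottis_mask))
    lq_stop("glottis mask must be a non-empty logical matrix")
  gray <- rgb_to_gray(image)
  nr <- nrow(gray); nc <- ncol(gray)
  dil <- dilate3(glottis_mask, 2L)
  ctr <- mask_centroid(glottis_mask)
  rc <- clamp(round(ctr["r"]), 1, nr)
  bb <- mask_bbox(dil)
  gb <- mask_bbox(glottis_mask)  # row extent of the cords
  sides <- list(
    a = seq.int(min(bb["c1"] + 1L, nc), min(bb["c1"] + scan_range, nc)),
    b = seq.int(max(bb["c0"] - 1L, 1L), max(bb["c0"] - scan_range, 1L))
  )
  res <- list()
  for (nm in names(sides)) {
    v <- find_valley(gray, rc, sides[[nm]])
    if (is.null(v))
      lq_stop(sprintf("vocal cord not found (%s of glottis): no valley in scan range",
                      if (nm == "a") "right" else "left"), "lq_not_found")
    # constraint energy: the cord lies between the dilated glottis boundary
    # and the cord's outer edge (the half-prominence point of the descent
    # into the valley, where the region is slit), within the glottis row
    # extent; a high-energy wall outside that box keeps the inflating
    # contour anatomically confined (corner lobes would otherwise grow into
    # the featureless background).
    inner <- sides[[nm]][1]
    dir <- if (v$edge_col >= inner) 1L else -1L
    box_cols <- sort(c(inner, v$edge_col))
    con <- matrix(1e4, nr, nc)
    con[gb["r0"]:gb["r1"], box_cols[1]:box_cols[2]] <- 0
    field <- external_energy_field(gray, con = con)
    # initialization strip centered in the box, constructed outward from the
    # glottis so that mirrored images evolve bitwise-mirrored contours
    mid <- inner + dir * (abs(v$edge_col - inner) %/% 2L)
    near <- mid - 2L * dir; far <- mid + 2L * dir
    corners_x <- c(near, far, far, near)
    corners_y <- c(gb["r0"], gb["r0"], gb["r1"], gb["r1"])
    pts <- resample_polygon(corners_x, corners_y, n_points)
    # high bending stiffness keeps the converged contour from folding onto
    # the deepest gradient spots once the pressure is balanced by the edges
    sn <- snake(pts, alpha = 1, beta = beta, gamma = gamma, search_radius = search_radius)
    ad <- adaptive_evolve(sn, field, gray, min_iter = min_iter, max_iter = max_iter)
    mask <- snake_mask(ad$snake, nr, nc) & !glottis_mask
    res[[nm]] <- list(mask = mask, n_star = ad$n_star, valley_col = v$valley_col)
  }
  # assign left/right in image space by centroid column
  cols <- vapply(res, function(r) mask_centroid(r$mask)["c"], numeric(1))
  left_nm <- names(sides)[which.min(cols)]
  right_nm <- setdiff(names(sides), left_nm)
  list(left = res[[left_nm]]$mask,
       right = res[[right_nm]]$mask,
       n_star = c(left = res[[left_nm]]$n_star, right = res[[right_nm]]$n_star),
       valley_cols = c(left = res[[left_nm]]$valley_col,
                       right = res[[right_nm]]$valley_col))
}

#' Segment all four regions
#'
#' Runs glottis, arytenoid and vocal-cord segmentation and enforces
#' pairwise disjointness (cords minus glottis; arytenoid minus the rest).
#'
#' @param image (compensated) RGB array.
#' @param ... passed to [segment_vocal_cords()].
#' @return object of class `lq_regionset`: list of masks `glottis`,
#'   `left_vc`, `right_vc`, `arytenoid`; attribute `n_star` from the cord
#'   stage.
#' @export
segment_regions <- function(image, ...) {
  glottis <- segment_glottis(image)
  aryt <- segment_arytenoid(image)
  vc <- segment_vocal_cords(image, glottis, ...)
  left <- vc$left & !glottis
  right <- vc$right & !glottis
  aryt <- aryt & !(glottis | left | right)
  structure(list(glottis = glottis, left_vc = left, right_vc = right,
                 arytenoid = aryt),
            class = "lq_regionset", n_star = vc$n_star)
}

#' Dice similarity coefficient
#'
#' 2 |A intersect B| / (|A| + |B|); 1 when both masks are empty.
#'
#' @param a,b logical masks with identical dimensions.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!is_mask(a) || !is_mask(b)) lq_stop("dice expects logical masks")
  if (!all(dim(a) == dim(b))) lq_stop("dice: dimension mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
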