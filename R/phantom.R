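# Synthetic laryngeal phantoms.
#
# Clinical laryngoscopy data is not redistributable, so every pipeline stage
# is exercised on generated phantoms with pixel-level ground truth. A phantom
# mimics the eigenstructure the segmentation relies on: a dark inverted-
# triangle glottis near the image center, two bright columnar vocal cords
# flanking it, dark "valley" strips separating the cords from the false
# cords, a bright rectangular arytenoid-cartilage block in the upper image,
# and mucosa-colored background. Gaussian speckle gives the bright
# structures non-degenerate texture for the GLCM features; the LPR effect
# reddens the cords, shifts the arytenoid chroma and boosts cord contrast.

#' Phantom generation parameters
#'
#' All geometry defaults scale with the image size; the canonical frame is
#' 256x256. Row/column coordinates are 1-based pixel indices.
#'
#' @param rows,cols image dimensions in pixels.
#' @param glottis_geometry list with `top_left`, `top_right`, `apex`, each a
#'   c(row, col) vertex of the filled inverted triangle.
#' @param vocal_cord_geometry list with `rows` = c(r0, r1) shared by both
#'   cords, `left_cols`, `right_cols` (cord column ranges) and
#'   `left_valley_cols`, `right_valley_cols` (dark valley strips lateral to
#'   each cord).
#' @param arytenoid_geometry list with `rows`, `cols` ranges of the bright
#'   upper rectangle.
#' @param base_colors named list of length-3 RGB vectors for `background`,
#'   `glottis`, `vocal_cord`, `arytenoid`, `valley`.
#' @param lpr_effect list: `vc_red_shift` (additive R offset on the cords),
#'   `aryt_cb_shift`, `aryt_cr_shift` (additive chroma offsets on the
#'   arytenoid block), `vc_contrast_gain` (speckle amplitude multiplier in
#'   the cords). Applied only when `lpr = TRUE`, before noise.
#' @param lpr logical; should the LPR effect be applied?
#' @param noise_sd per-channel Gaussian noise sd (gray levels).
#' @param speckle_sd sd of the luminance speckle texturing the bright
#'   structures.
#' @param blur_sigma Gaussian blur scale applied to the rendered frame
#'   (0 = sharp).
#' @param illum_offset additive brightness offset (all channels), emulating
#'   lens/light-source variation.
#' @param seed RNG seed; generation is bitwise deterministic per seed.
#' @return object of class `lq_phantom_params`.
#' @export
phantom_params <- function(rows = 256, cols = 256,
                           glottis_geometry = NULL,
                           vocal_cord_geometry = NULL,
                           arytenoid_geometry = NULL,
                           base_colors = NULL,
                           lpr_effect = NULL,
                           lpr = FALSE,
                           noise_sd = 6,
                           speckle_sd = 7,
                           blur_sigma = 0,
                           illum_offset = 0,
                           seed = 1) {
  sr <- rows / 256; sc <- cols / 256
  px <- function(r, c) c(round(r * sr), round(c * sc))
  if (is.null(glottis_geometry))
    glottis_geometry <- list(top_left = px(90, 98), top_right = px(90, 158),
                             apex = px(190, 128))
  if (is.null(vocal_cord_geometry))
    vocal_cord_geometry <- list(
      rows = c(round(90 * sr), round(190 * sr)),
      left_cols = c(round(63 * sc), round(96 * sc)),
      right_cols = c(round(160 * sc), round(193 * sc)),
      left_valley_cols = c(round(52 * sc), round(58 * sc)),
      right_valley_cols = c(round(198 * sc), round(204 * sc))
    )
  if (is.null(arytenoid_geometry))
    arytenoid_geometry <- list(rows = c(round(20 * sr), round(60 * sr)),
                               cols = c(round(78 * sc), round(178 * sc)))
  if (is.null(base_colors))
    base_colors <- list(background = c(205, 120, 115),
                        glottis = c(45, 25, 25),
                        vocal_cord = c(235, 180, 170),
                        arytenoid = c(225, 195, 185),
                        valley = c(150, 75, 75))
  if (is.null(lpr_effect))
    lpr_effect <- list(vc_red_shift = 25, aryt_cb_shift = -12,
                       aryt_cr_shift = 12, vc_contrast_gain = 1.6)
  p <- structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    glottis_geometry = glottis_geometry,
    vocal_cord_geometry = vocal_cord_geometry,
    arytenoid_geometry = arytenoid_geometry,
    base_colors = base_colors,
    lpr_effect = lpr_effect,
    lpr = isTRUE(lpr),
    noise_sd = noise_sd, speckle_sd = speckle_sd,
    blur_sigma = blur_sigma, illum_offset = illum_offset,
    seed = seed
  ), class = "lq_phantom_params")
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  inb <- function(rc) all(rc >= 1) && rc[1] <= p$rows && rc[2] <= p$cols
  g <- p$glottis_geometry
  if (!inb(g$top_left) || !inb(g$top_right) || !inb(g$apex))
    lq_stop("glottis geometry outside image bounds", "lq_invalid_parameter")
  v <- p$vocal_cord_geometry
  rng_ok <- function(rng, lim) rng[1] >= 1 && rng[2] <= lim && rng[1] <= rng[2]
  if (!rng_ok(v$rows, p$rows) || !rng_ok(v$left_cols, p$cols) ||
      !rng_ok(v$right_cols, p$cols) || !rng_ok(v$left_valley_cols, p$cols) ||
      !rng_ok(v$right_valley_cols, p$cols))
    lq_stop("vocal cord geometry outside image bounds", "lq_invalid_parameter")
  a <- p$arytenoid_geometry
  if (!rng_ok(a$rows, p$rows) || !rng_ok(a$cols, p$cols))
    lq_stop("arytenoid geometry outside image bounds", "lq_invalid_parameter")
  if (a$rows[2] >= v$rows[1])
    lq_stop("arytenoid block overlaps the vocal-cord rows", "lq_invalid_parameter")
  if (p$noise_sd < 0 || p$blur_sigma < 0 || p$speckle_sd < 0)
    lq_stop("noise_sd, speckle_sd and blur_sigma must be >= 0", "lq_invalid_parameter")
  invisible(p)
}

rect_mask <- function(rows, cols, rrng, crng) {
  m <- matrix(FALSE, rows, cols)
  m[rrng[1]:rrng[2], crng[1]:crng[2]] <- TRUE
  m
}

#' Ground-truth region masks implied by phantom parameters
#' @param params `lq_phantom_params`.
#' @return list of logical masks: glottis, left_vc, right_vc, arytenoid.
#' @export
phantom_truth <- function(params) {
  g <- params$glottis_geometry
  v <- params$vocal_cord_geometry
  a <- params$arytenoid_geometry
  glottis <- fill_polygon(
    px = c(g$top_left[2], g$top_right[2], g$apex[2]),
    py = c(g$top_left[1], g$top_right[1], g$apex[1]),
    nrow = params$rows, ncol = params$cols)
  list(
    glottis = glottis,
    left_vc = rect_mask(params$rows, params$cols, v$rows, v$left_cols),
    right_vc = rect_mask(params$rows, params$cols, v$rows, v$right_cols),
    arytenoid = rect_mask(params$rows, params$cols, a$rows, a$cols)
  )
}

#' Render a synthetic laryngeal phantom
#'
#' Deterministic for a fixed seed. By construction the glottis is darker
#' than the rest of the image and the vocal cords and arytenoid block are
#' brighter than the background; when `params$lpr` is TRUE the hue/texture
#' shifts of `params$lpr_effect` are applied before noise.
#'
#' @param params `lq_phantom_params` from [phantom_params()].
#' @return object of class `lq_phantom`: list with `image` (8-bit RGB
#'   array), `truth` (region masks), `label` ("LPR"/"non-LPR"), `rsi`
#'   (integer symptom score, in \[13, 45\] for LPR else \[0, 12\]) and
#'   `params`.
#' @export
make_phantom <- function(params = phantom_params()) {
  validate_phantom_params(params)
  truth <- phantom_truth(params)
  v <- params$vocal_cord_geometry
  valley <- rect_mask(params$rows, params$cols, v$rows, v$left_valley_cols) |
    rect_mask(params$rows, params$cols, v$rows, v$right_valley_cols)
  bc <- params$base_colors
  img <- array(0, dim = c(params$rows, params$cols, 3))
  cords <- truth$left_vc | truth$right_vc
  for (ch in 1:3) {
    plane <- matrix(bc$background[ch], params$rows, params$cols)
    plane[valley] <- bc$valley[ch]
    plane[cords] <- bc$vocal_cord[ch]
    plane[truth$arytenoid] <- bc$arytenoid[ch]
    plane[truth$glottis] <- bc$glottis[ch]
    img[, , ch] <- plane
  }
  out <- with_seed(params$seed, {
    # luminance speckle: full amplitude on the bright textured structures,
    # reduced elsewhere so variance scores stay informative
    speckle <- matrix(stats::rnorm(params$rows * params$cols),
                      params$rows, params$cols)
    gain <- matrix(0.5, params$rows, params$cols)
    gain[truth$glottis] <- 0.25
    gain[valley] <- 0.25
    gain[truth$arytenoid] <- 1
    vc_gain <- if (params$lpr) params$lpr_effect$vc_contrast_gain else 1
    gain[cords] <- vc_gain
    for (ch in 1:3) img[, , ch] <- img[, , ch] + params$speckle_sd * gain * speckle
    if (params$lpr) {
      r <- img[, , 1]
      r[cords] <- r[cords] + params$lpr_effect$vc_red_shift
      img[, , 1] <- r
      ycc <- rgb_to_ycbcr(clamp(img, 0, 255))
      ycc$Cb[truth$arytenoid] <- ycc$Cb[truth$arytenoid] + params$lpr_effect$aryt_cb_shift
      ycc$Cr[truth$arytenoid] <- ycc$Cr[truth$arytenoid] + params$lpr_effect$aryt_cr_shift
      img <- ycbcr_to_rgb(ycc)
    }
    img <- blur_rgb(img, params$blur_sigma)
    img <- img + params$illum_offset
    if (params$noise_sd > 0) {
      noise <- array(stats::rnorm(length(img), sd = params$noise_sd), dim = dim(img))
      img <- img + noise
    } else {
      # keep the RNG stream aligned across noise settings
      invisible(stats::rnorm(length(img)))
    }
    rsi <- if (params$lpr) {
      bin <- sample.int(3, 1, prob = c(38, 54, 14) / 106)
      lo <- c(13, 21, 31)[bin]; hi <- c(20, 30, 45)[bin]
      lo + sample.int(hi - lo + 1L, 1) - 1L
    } else {
      sample.int(13L, 1) - 1L
    }
    list(image = round(clamp(img, 0, 255)), rsi = as.integer(rsi))
  })
  structure(list(image = out$image, truth = truth,
                 label = if (params$lpr) "LPR" else "non-LPR",
                 rsi = out$rsi, params = params),
            class = "lq_phantom")
}

#' @export
print.lq_phantom <- function(x, ...) {
  cat(sprintf("<lq_phantom> %dx%d, label = %s, rsi = %d\n",
              nrow(x$image), ncol(x$image), x$label, x$rsi))
  invisible(x)
}

#' Generate a frame stack with one sharp throat frame plus distractors
#'
#' The stack contains exactly one unblurred throat frame (the phantom
#' rendered from `params`), Gaussian-blurred copies of it, motion-smeared
#' copies, and low-red non-throat frames, in seeded random order. Because
#' the distractors are derived from the sharp frame, every focus score of a
#' blurred copy is strictly below the sharp frame's.
#'
#' @param params phantom parameters for the sharp frame.
#' @param n_frames expected stack size; must equal 1 plus the number of
#'   distractors (provided as a cross-check, may be NULL).
#' @param distractor_spec list: `blur_sigmas` (one blurred copy per sigma),
#'   `n_motion` and `motion_shift` (horizontal smear copies), `n_nonthroat`
#'   (gray-blue frames below the red threshold).
#' @return list with `frames` (list of RGB arrays), `truth_index` (1-based
#'   index of the sharp frame) and `kinds` (character vector).
#' @export
make_frame_stack <- function(params = phantom_params(), n_frames = NULL,
                             distractor_spec = list(blur_sigmas = c(2, 3, 4),
                                                    n_motion = 0,
                                                    motion_shift = 4,
                                                    n_nonthroat = 1)) {
  spec <- utils::modifyList(
    list(blur_sigmas = numeric(0), n_motion = 0L, motion_shift = 4L,
         n_nonthroat = 0L), distractor_spec)
  total <- 1L + length(spec$blur_sigmas) + spec$n_motion + spec$n_nonthroat
  if (!is.null(n_frames)) {
    if (n_frames < 1) lq_stop("n_frames must be >= 1", "lq_invalid_parameter")
    if (n_frames != total)
      lq_stop(sprintf("n_frames (%d) does not match distractor_spec (%d frames)",
                      n_frames, total), "lq_invalid_parameter")
  }
  sharp <- make_phantom(params)$image
  frames <- list(sharp)
  kinds <- "sharp"
  for (s in spec$blur_sigmas) {
    frames <- c(frames, list(blur_rgb(sharp, s)))
    kinds <- c(kinds, sprintf("blur_%g", s))
  }
  if (spec$n_motion > 0) for (i in seq_len(spec$n_motion)) {
    sm <- sharp
    for (k in seq_len(spec$motion_shift)) {
      sh <- sharp
      for (ch in 1:3) sh[, , ch] <- shift_mat(sharp[, , ch], 0L, k * i)
      sm <- sm + sh
    }
    frames <- c(frames, list(sm / (spec$motion_shift + 1)))
    kinds <- c(kinds, sprintf("motion_%d", i))
  }
  stack <- with_seed(params$seed, {
    if (spec$n_nonthroat > 0) for (i in seq_len(spec$n_nonthroat)) {
      nt <- array(0, dim = dim(sharp))
      base <- c(90, 95, 120)
      noise <- array(stats::rnorm(length(nt), sd = 8), dim = dim(nt))
      for (ch in 1:3) nt[, , ch] <- base[ch]
      nt <- round(clamp(nt + noise, 0, 255))
      frames <- c(frames, list(nt))
      kinds <- c(kinds, sprintf("nonthroat_%d", i))
    }
    ord <- sample.int(length(frames))
    list(frames = frames[ord], kinds = kinds[ord],
         truth_index = which(ord == 1L))
  })
  stack
}

#' Canonical names of the 36 hue/texture features
#'
#' Six chromatic channels (R, G, B, H, Cb, Cr) for the arytenoid cartilage,
#' max/min over the two vocal cords, vocal-cord-to-arytenoid ratios, and
#' four GLCM statistics (contrast, energy, correlation, homogeneity) for the
#' arytenoid plus max/min over the cords.
#'
#' @return character vector of length 36.
#' @export
lq_feature_names <- function() {
  hue <- c("R", "G", "B", "H", "Cb", "Cr")
  tex <- c("con", "eng", "cor", "hom")
  c(paste0("A_", hue),
    as.vector(t(outer(paste0("VC_", hue), c("max", "min"), paste))),
    paste0("VC/A_", hue),
    paste0("A_", tex),
    as.vector(t(outer(paste0("VC_", tex), c("max", "min"), paste))))
}

#' The five features selected for classification
#'
#' Arytenoid GLCM energy, arytenoid Cb and Cr, vocal-cord GLCM contrast
#' (max) and vocal-cord R channel (max): the features with the highest
#' Fisher scores on the clinical cohort.
#'
#' @return character vector of length 5.
#' @export
lq_selected_features <- function() {
  c("A_eng", "A_Cb", "A_Cr", "VC_con max", "VC_R max")
}

# Default per-feature mean shifts (in sd units) for the synthetic cohort:
# chosen so the two-class Fisher score f = delta^2 / 2 of each selected
# feature matches the scale reported for the clinical cohort.
default_cohort_effect <- function() {
  f <- c("A_eng" = 0.6568, "A_Cb" = 0.6425, "A_Cr" = 0.6409,
         "VC_con max" = 0.5241, "VC_R max" = 0.5213)
  sqrt(2 * f)
}

#' Generate a labeled synthetic feature cohort
#'
#' Draws all 36 features as standard normals per sample and adds class-mean
#' shifts (in sd units) to the LPR class on the specified features; all
#' other features have zero effect. RSI scores follow the inclusion rule:
#' non-LPR in \[0, 12\], LPR in \[13, 45\] with a 38/54/14 mix over the
#' primary/intermediate/severe bins.
#'
#' @param n_lpr,n_non class sample counts (both >= 1).
#' @param effect NULL for the calibrated defaults on the five selected
#'   features; a scalar applied to the five selected features; or a named
#'   vector of shifts over any of the 36 features.
#' @param seed RNG seed.
#' @return list with `features` (data.frame, 36 columns named as in
#'   [lq_feature_names()]), `labels` (factor LPR/non-LPR) and `rsi`
#'   (integer vector).
#' @export
make_feature_cohort <- function(n_lpr = 106, n_non = 246, effect = NULL, seed = 1) {
  if (n_lpr < 1 || n_non < 1)
    lq_stop("both class counts must be >= 1", "lq_invalid_parameter")
  nm <- lq_feature_names()
  shifts <- stats::setNames(numeric(36), nm)
  if (is.null(effect)) {
    eff <- default_cohort_effect()
  } else if (is.null(names(effect))) {
    if (length(effect) != 1) lq_stop("unnamed effect must be a scalar",
                                     "lq_invalid_parameter")
    eff <- stats::setNames(rep(effect, 5), lq_selected_features())
  } else {
    if (!all(names(effect) %in% nm))
      lq_stop("effect names must be feature names", "lq_invalid_parameter")
    eff <- effect
  }
  shifts[names(eff)] <- eff
  n <- n_lpr + n_non
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * 36), n, 36, dimnames = list(NULL, nm))
    lpr_rows <- seq_len(n_lpr)
    x[lpr_rows, ] <- x[lpr_rows, ] + rep(shifts, each = n_lpr)
    labels <- factor(c(rep("LPR", n_lpr), rep("non-LPR", n_non)),
                     levels = c("LPR", "non-LPR"))
    bins <- sample.int(3, n_lpr, replace = TRUE, prob = c(38, 54, 14) / 106)
    lo <- c(13, 21, 31)[bins]; hi <- c(20, 30, 45)[bins]
    rsi_lpr <- lo + floor(stats::runif(n_lpr) * (hi - lo + 1))
    rsi_non <- sample.int(13L, n_non, replace = TRUE) - 1L
    list(features = as.data.frame(x, check.names = FALSE),
         labels = labels,
         rsi = as.integer(c(rsi_lpr, rsi_non)))
  })
}

#' Generate a separable synthetic severity cohort
#'
#' Five features per sample (named as the selected features); class means
#' lie on the unit diagonal with adjacent classes `sep` sd apart, so the
#' three severity grades are well separated at the default sep = 4. The
#' class mix defaults to the 38/54/14 primary/intermediate/severe split.
#'
#' @param n integer vector of class counts (primary, intermediate, severe).
#' @param sep Euclidean distance between adjacent class means, in sd units.
#' @param seed RNG seed.
#' @return list with `features` (data.frame, 5 columns), `severity`
#'   (ordered factor) and `rsi` (integer vector within each class bin).
#' @export
make_severity_cohort <- function(n = c(38, 54, 14), sep = 4, seed = 1) {
  if (length(n) != 3 || any(n < 1))
    lq_stop("n must give three positive class counts", "lq_invalid_parameter")
  lv <- c("primary", "intermediate", "severe")
  u <- rep(1 / sqrt(5), 5)
  with_seed(seed, {
    total <- sum(n)
    x <- matrix(stats::rnorm(total * 5), total, 5,
                dimnames = list(NULL, lq_selected_features()))
    cls <- rep(seq_len(3), n)
    x <- x + outer((cls - 1) * sep, u)
    lo <- c(13, 21, 31)[cls]; hi <- c(20, 30, 45)[cls]
    rsi <- lo + floor(stats::runif(total) * (hi - lo + 1))
    list(features = as.data.frame(x, check.names = FALSE),
         severity = factor(lv[cls], levels = lv, ordered = TRUE),
         rsi = as.integer(rsi))
  })
}

#' Write a phantom sample to disk (frame + truth masks)
#'
#' @param phantom `lq_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame(phantom$image, file.path(dir, "frame.png"))
  for (nm in names(phantom$truth))
    write_mask(phantom$truth[[nm]], file.path(dir, paste0("mask_", nm, ".png")))
  meta <- list(label = phantom$label, rsi = phantom$rsi,
               seed = phantom$params$seed)
  jsonlite::write_json(meta, file.path(dir, "sample.json"), auto_unbox = TRUE)
  invisible(dir)
}
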