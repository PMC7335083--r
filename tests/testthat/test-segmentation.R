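# Thresholds, components, structure rules, region segmentation and DSC.

test_that("glottis_threshold is mu - sigma", {
  expect_equal(glottis_threshold(matrix(90, 6, 6)), 90)  # sigma = 0
  two <- matrix(c(100, 200), 10, 10)                     # mu 150, sigma 50
  expect_equal(glottis_threshold(two), 100)
})

test_that("binarization thresholds behave at the boundaries", {
  two <- matrix(c(100, 200), 10, 10)
  expect_false(any(binarize_dark(two, glottis_threshold(two))))  # none < 100
  expect_true(all(binarize_dark(matrix(50, 4, 4), 60)))
  expect_false(any(binarize_dark(matrix(50, 4, 4), 50)))
  expect_equal(sum(binarize_bright(two, k = 0.5)), sum(two == 200))
})

test_that("label_components reports area, centroid and aspect", {
  empty <- label_components(matrix(FALSE, 5, 5))
  expect_equal(nrow(empty), 0)
  sq <- matrix(FALSE, 20, 20); sq[5:14, 7:16] <- TRUE
  comps <- label_components(sq)
  expect_equal(comps$area, 100)
  expect_equal(comps$bbox_aspect, 1)
  expect_equal(comps$centroid_r, 9.5)
  expect_equal(comps$centroid_c, 11.5)
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE          # 16 px
  two[10:17, 10:15] <- TRUE      # 48 px
  comps2 <- label_components(two)
  expect_equal(comps2$area, c(48L, 16L))  # descending area
})

test_that("8-connectivity joins diagonal touches", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(label_components(m)), 1)
})

test_that("structure rules keep the anatomical candidate and drop imposters", {
  dims <- c(100, 100)
  central_tall <- matrix(FALSE, 100, 100); central_tall[30:70, 45:55] <- TRUE
  wide_bar <- matrix(FALSE, 100, 100); wide_bar[80:84, 10:90] <- TRUE
  comps <- label_components(central_tall | wide_bar)
  sel <- apply_structure_rules(comps, glottis_rules(), dims)
  expect_false(is.null(sel))
  expect_equal(sel$bbox_aspect, 11 / 41)  # the tall central region
  upper_rect <- matrix(FALSE, 100, 100); upper_rect[10:25, 25:75] <- TRUE
  tall_bar <- matrix(FALSE, 100, 100); tall_bar[5:80, 5:10] <- TRUE
  comps2 <- label_components(upper_rect | tall_bar)
  sel2 <- apply_structure_rules(comps2, arytenoid_rules(), dims)
  expect_false(is.null(sel2))
  expect_gt(sel2$bbox_aspect, 1)
  expect_null(apply_structure_rules(label_components(matrix(FALSE, 5, 5)),
                                    glottis_rules(), c(5, 5)))
})

test_that("dice matches its formula and basic identities", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(dice(a, b), 0)
  c1 <- matrix(FALSE, 20, 20); c1[1:10, 1:10] <- TRUE           # 100 px
  c2 <- matrix(FALSE, 20, 20); c2[1:10, 3:12] <- TRUE           # 100 px, 80 shared
  expect_equal(dice(c1, c2), 0.8)
  expect_equal(dice(c2, c1), 0.8)
  expect_equal(dice(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  expect_error(dice(a, matrix(TRUE, 5, 5)), class = "lq_invalid_input")
})

test_that("dice is invariant under joint translation", {
  a <- matrix(FALSE, 30, 30); a[5:12, 5:15] <- TRUE
  b <- matrix(FALSE, 30, 30); b[7:14, 8:16] <- TRUE
  a2 <- matrix(FALSE, 30, 30); a2[15:22, 10:20] <- TRUE
  b2 <- matrix(FALSE, 30, 30); b2[17:24, 13:21] <- TRUE
  expect_equal(dice(a2, b2), dice(a, b))
})

test_that("glottis segmentation recovers the phantom truth", {
  s <- segmented_phantom(seed = 1)
  expect_gte(dice(s$regions$glottis, s$phantom$truth$glottis), 0.85)
  # an image with no dark central region has no glottis
  expect_error(segment_glottis(const_rgb(64, 64, c(200, 120, 110))),
               class = "lq_not_found")
})

test_that("arytenoid segmentation recovers the block and snake refinement helps", {
  s <- segmented_phantom(seed = 1)
  aryt <- segment_arytenoid(s$compensated)
  truth <- s$phantom$truth$arytenoid
  expect_gte(dice(aryt, truth), 0.85)
  expect_gte(dice(aryt, truth), dice(attr(aryt, "candidate"), truth))
})

test_that("an image without the arytenoid block signals not-found", {
  ph <- make_phantom(phantom_params(seed = 3))
  img <- ph$image
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ph$truth$arytenoid] <- c(205, 120, 115)[ch]
    img[, , ch] <- plane
  }
  comp <- suppressWarnings(histogram_shift(img))
  expect_error(segment_arytenoid(comp), class = "lq_not_found")
})

test_that("vocal cord segmentation recovers both cords with adaptive stopping", {
  s <- segmented_phantom(seed = 1)
  expect_gte(dice(s$regions$left_vc, s$phantom$truth$left_vc), 0.85)
  expect_gte(dice(s$regions$right_vc, s$phantom$truth$right_vc), 0.85)
  ns <- attr(s$regions, "n_star")
  expect_true(all(ns >= 13 & ns <= 41))
})

test_that("cords without a valley signal not-found", {
  ph <- make_phantom(phantom_params(seed = 4))
  img <- ph$image
  flat <- ph$truth$left_vc | ph$truth$right_vc
  v <- ph$params$vocal_cord_geometry
  flat[v$rows[1]:v$rows[2], v$left_valley_cols[1]:v$left_valley_cols[2]] <- TRUE
  flat[v$rows[1]:v$rows[2], v$right_valley_cols[1]:v$right_valley_cols[2]] <- TRUE
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[flat] <- c(205, 120, 115)[ch]
    img[, , ch] <- plane
  }
  comp <- suppressWarnings(histogram_shift(img))
  gl <- segment_glottis(comp)
  expect_error(segment_vocal_cords(comp, gl), class = "lq_not_found")
})

test_that("mirroring the image swaps left and right cords exactly", {
  ph <- make_phantom(phantom_params(seed = 3))
  comp <- suppressWarnings(histogram_shift(ph$image))
  gl <- segment_glottis(comp)
  vc <- segment_vocal_cords(comp, gl)
  mcomp <- mirror_lr(comp)
  mgl <- segment_glottis(mcomp)
  expect_identical(mgl, mirror_lr(gl))
  mvc <- segment_vocal_cords(mcomp, mgl)
  expect_identical(mvc$left, mirror_lr(vc$right))
  expect_identical(mvc$right, mirror_lr(vc$left))
  expect_identical(unname(mvc$n_star), unname(vc$n_star[c("right", "left")]))
})

test_that("asymmetric cord widths yield different adaptive iteration counts", {
  p <- phantom_params(seed = 4)
  p$vocal_cord_geometry$left_cols <- c(73L, 96L)  # narrow left cord
  p$vocal_cord_geometry$left_valley_cols <- c(62L, 68L)
  ph <- make_phantom(p)
  comp <- suppressWarnings(histogram_shift(ph$image))
  vc <- segment_vocal_cords(comp, segment_glottis(comp))
  expect_false(vc$n_star["left"] == vc$n_star["right"])
  expect_gte(dice(vc$left, ph$truth$left_vc), 0.85)
  expect_gte(dice(vc$right, ph$truth$right_vc), 0.85)
})

test_that("segment_regions returns pairwise disjoint masks", {
  s <- segmented_phantom(seed = 1)
  r <- s$regions
  ms <- list(r$glottis, r$left_vc, r$right_vc, r$arytenoid)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(ms[[i]] & ms[[j]]))
  expect_true(all(vapply(ms, any, logical(1))))  # all non-empty
})
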