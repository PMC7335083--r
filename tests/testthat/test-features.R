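# Hue means, GLCM texture statistics and Fisher ranking.

test_that("mean_channel matches canonical colors", {
  m <- matrix(TRUE, 4, 4)
  red <- const_rgb(4, 4, c(255, 0, 0))
  expect_equal(mean_channel(red, m, "R"), 255)
  expect_equal(mean_channel(red, m, "H"), 0)
  green <- const_rgb(4, 4, c(0, 255, 0))
  expect_equal(mean_channel(green, m, "H"), 120)
  gray <- const_rgb(4, 4, c(90, 90, 90))
  expect_equal(mean_channel(gray, m, "Cb"), 128, tolerance = 1e-9)
  expect_equal(mean_channel(gray, m, "Cr"), 128, tolerance = 1e-9)
  expect_error(mean_channel(red, matrix(FALSE, 4, 4), "R"),
               class = "lq_invalid_input")
})

test_that("circular hue averaging has no 0/360 wrap artifact", {
  img <- const_rgb(2, 2, c(255, 0, 0))
  img[1, 1, ] <- c(255, 10, 0)   # hue slightly above 0
  img[2, 2, ] <- c(255, 0, 10)   # hue slightly below 360
  h <- mean_channel(img, matrix(TRUE, 2, 2), "H")
  expect_true(h < 5 || h > 355)  # near red, not near 180
})

test_that("GLCM of a constant region is a single unit entry", {
  g <- matrix(77, 16, 16)
  p <- glcm_matrix(g, matrix(TRUE, 16, 16))
  expect_equal(sum(p), 1)
  expect_equal(sum(p > 0), 1)
  expect_equal(glcm_energy(p), 1)
  expect_equal(glcm_contrast(p), 0)
  expect_equal(glcm_homogeneity(p), 1)
  expect_equal(glcm_correlation(p), 0)  # degenerate marginals
})

test_that("GLCM of a 2x2 checkerboard matches hand enumeration", {
  g <- matrix(c(0, 255, 255, 0), 2, 2)
  p <- glcm_matrix(g, matrix(TRUE, 2, 2), levels = 2)
  expect_equal(unclass(p)[1:2, 1:2], matrix(c(0, 0.5, 0.5, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(glcm_energy(p), 0.5)
  expect_equal(glcm_contrast(p), 1)
  expect_equal(glcm_homogeneity(p), 0.5)
})

test_that("GLCM statistics agree with brute-force pair enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
    m <- matrix(runif(36) < 0.75, 6, 6)
    m[, 1:2] <- TRUE  # guarantee at least one horizontal pair
    p <- glcm_matrix(g, m)
    o <- oracle_glcm(g, m)
    expect_equal(unclass(p), o, ignore_attr = TRUE, tolerance = 1e-12)
    os <- oracle_glcm_stats(o)
    expect_equal(glcm_energy(p), unname(os["energy"]))
    expect_equal(glcm_contrast(p), unname(os["contrast"]))
    expect_equal(glcm_correlation(p), unname(os["correlation"]))
    expect_equal(glcm_homogeneity(p), unname(os["homogeneity"]))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("GLCM statistics validate normalization", {
  bad <- matrix(0.4, 2, 2)
  expect_error(glcm_energy(bad), class = "lq_invalid_input")
  expect_error(glcm_matrix(matrix(1, 4, 4), matrix(FALSE, 4, 4)),
               class = "lq_invalid_input")
})

test_that("extract_features returns the 36 named features", {
  sc <- toy_scene()
  fv <- extract_features(sc$image, sc$regions)
  expect_length(fv, 36)
  expect_identical(names(fv), lq_feature_names())
  # identical cords: every max equals its min
  for (ch in c("R", "G", "B", "H", "Cb", "Cr", "con", "eng", "cor", "hom"))
    expect_equal(unname(fv[paste("VC", ch, "max", sep = "_")]),
                 unname(fv[paste("VC", ch, "min", sep = "_")]))
  expect_true(all(fv[c("A_eng", "VC_eng max", "VC_eng min")] >= 0 &
                  fv[c("A_eng", "VC_eng max", "VC_eng min")] <= 1))
  broken <- sc$regions; broken$arytenoid <- matrix(FALSE, 40, 40)
  expect_error(extract_features(sc$image, broken), "arytenoid",
               class = "lq_invalid_input")
})

test_that("the LPR red shift raises the vocal-cord R feature", {
  s0 <- make_phantom(phantom_params(seed = 6, lpr = FALSE))
  s1 <- make_phantom(phantom_params(seed = 6, lpr = TRUE))
  f0 <- extract_features(s0$image, s0$truth)
  f1 <- extract_features(s1$image, s1$truth)
  expect_gt(f1["VC_R max"], f0["VC_R max"])
})

test_that("hue features are invariant to the luma shift", {
  sc <- toy_scene()
  shifted <- suppressWarnings(histogram_shift(sc$image, target = 140))
  f0 <- extract_features(sc$image, sc$regions)
  f1 <- extract_features(shifted, sc$regions)
  for (nm in c("A_H", "A_Cb", "A_Cr"))
    expect_equal(unname(f1[nm]), unname(f0[nm]), tolerance = 0.5)
})

test_that("fisher_score matches its closed form", {
  lab <- rep(c("a", "b"), each = 3)
  expect_equal(fisher_score(c(1, 2, 3, 1, 2, 3), lab), 0)
  # class means 0 and 2, both sample variances 1 -> f = 4 / 2 = 2
  expect_equal(fisher_score(c(-1, 0, 1, 1, 2, 3), lab), 2)
  expect_error(fisher_score(1:6, rep("a", 6)), class = "lq_invalid_input")
})

test_that("fisher_score is invariant to affine feature rescaling", {
  set.seed(31)
  x <- rnorm(60)
  lab <- rep(c("a", "b"), each = 30)
  x[lab == "b"] <- x[lab == "b"] + 1
  f <- fisher_score(x, lab)
  expect_equal(fisher_score(2.7 * x - 13, lab), f)
  expect_equal(fisher_score(-0.4 * x + 2, lab), f)
})

test_that("rank_features finds a planted effect and is quiet under the null", {
  co <- make_feature_cohort(n_lpr = 200, n_non = 200,
                            effect = c("A_Cb" = 2), seed = 8)
  rk <- rank_features(co$features, co$labels)
  expect_identical(rk$scores$feature[1], "A_Cb")
  null <- make_feature_cohort(n_lpr = 200, n_non = 200, effect = 0, seed = 9)
  rk0 <- rank_features(null$features, null$labels)
  expect_lt(max(rk0$scores$f), 0.05)
  expect_equal(nrow(rank_features(co$features, co$labels, top_k = 36)$scores), 36)
  expect_length(rank_features(co$features, co$labels, top_k = 36)$selected, 36)
  expect_identical(rank_features(co$features, co$labels,
                                 use_paper_selection = TRUE)$selected,
                   lq_selected_features())
})
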