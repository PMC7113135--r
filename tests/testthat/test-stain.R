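test_that("CIELAB conversion hits the published sRGB/D65 reference values", {
  # reference Lab coordinates for standard patches (sRGB, D65)
  patches <- rbind(c(255, 255, 255), c(0, 0, 0), c(128, 128, 128),
                   c(255, 0, 0), c(0, 255, 0), c(0, 0, 255))
  ref <- rbind(c(100, 0, 0),
               c(0, 0, 0),
               c(53.585, 0, 0),
               c(53.2406, 80.0923, 67.2028),
               c(87.7351, -86.1830, 83.1797),
               c(32.2957, 79.1856, -107.8573))
  lab <- rgb_to_lab(slide_image(array(patches, c(6, 1, 3))))
  expect_true(max(abs(matrix(lab, 6, 3) - ref)) < 0.1)
  # neutral axis within 1e-3
  for (v in c(0, 128, 255)) {
    g <- rgb_to_lab(uniform_image(2, 2, c(v, v, v)))
    expect_lt(max(abs(g[, , 2:3])), 1e-3)
  }
  expect_equal(rgb_to_lab(uniform_image(1, 1, c(255, 255, 255)))[1, 1, 1], 100,
               tolerance = 1e-3)
})

test_that("stain estimation recovers forward-model stain vectors within 2 degrees", {
  st <- he_reference_stains()
  fx <- two_stain_fixture(60, seed = 42)
  img <- beer_lambert_image(fx$c_h, fx$c_e, st)
  est <- estimate_stains(img)
  expect_lt(angle_deg(est$M[, 1], st$M[, 1]), 2)
  expect_lt(angle_deg(est$M[, 2], st$M[, 2]), 2)
  # H/E ordering: hematoxylin carries the larger blue-channel OD weight
  expect_gt(est$M[3, 1], est$M[3, 2])

  # single stain plus small noise
  set.seed(7)
  c_h <- matrix(stats::runif(900, 0.3, 0.8), 30)
  img1 <- beer_lambert_image(c_h, matrix(0, 30, 30), st)
  px <- pmin(pmax(img1$pixels + array(sample(-1:1, 2700, TRUE), c(30, 30, 3)),
                  0L), 255L)
  est1 <- estimate_stains(slide_image(px))
  expect_lt(angle_deg(est1$M[, 1], st$M[, 1]), 2)
})

test_that("blank images raise an insufficient-tissue error", {
  expect_error(estimate_stains(uniform_image(50, 50, c(255, 255, 255))),
               "insufficient tissue")
})

test_that("deconvolution inverts the Beer-Lambert forward model", {
  st <- he_reference_stains()
  set.seed(3)
  c_h <- matrix(stats::runif(1600, 0.2, 0.7), 40)
  c_e <- matrix(stats::runif(1600, 0.2, 0.7), 40)
  img <- beer_lambert_image(c_h, c_e, st)
  he <- deconvolve(img, st)
  rel <- abs(he - array(c(c_h, c_e), c(40, 40, 2))) / array(c(c_h, c_e), c(40, 40, 2))
  expect_lt(mean(rel), 0.01)

  # all-white -> concentrations ~ 0
  he0 <- deconvolve(uniform_image(10, 10, c(255, 255, 255)), st)
  expect_lt(max(he0), 0.01)

  # pure hematoxylin -> eosin channel ~ 0
  hep <- deconvolve(beer_lambert_image(c_h, matrix(0, 40, 40), st), st)
  expect_lt(stats::quantile(hep[, , 2], 0.99), 0.02)

  # collinear stain matrix is rejected
  expect_error(stain_matrix(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)), "collinear")
})

test_that("deconvolve then reconstruct is identity on in-model images", {
  st <- he_reference_stains()
  set.seed(11)
  c_h <- matrix(stats::runif(400, 0.1, 0.8), 20)
  c_e <- matrix(stats::runif(400, 0.1, 0.6), 20)
  img <- beer_lambert_image(c_h, c_e, st)
  rt <- reconstruct_rgb(deconvolve(img, st), st)
  expect_lte(max(abs(rt$pixels - img$pixels)), 1L)
})

test_that("stain estimation is invariant to pixel shuffling", {
  st <- he_reference_stains()
  fx <- two_stain_fixture(40, seed = 9)
  img <- beer_lambert_image(fx$c_h, fx$c_e, st)
  set.seed(1)
  perm <- sample(40 * 40)
  shuf <- array(0L, dim(img$pixels))
  for (ch in 1:3) shuf[, , ch] <- matrix(img$pixels[, , ch][perm], 40)
  e1 <- estimate_stains(img)
  e2 <- estimate_stains(slide_image(shuf))
  expect_equal(e1$M, e2$M, tolerance = 1e-6)
})

test_that("normalization to a common reference aligns different stain bases", {
  st <- he_reference_stains()
  # identity: same stains, same maxima
  set.seed(5)
  c_h <- matrix(stats::runif(900, 0.2, 0.8), 30)
  c_e <- matrix(stats::runif(900, 0.2, 0.6), 30)
  img <- beer_lambert_image(c_h, c_e, st)
  idn <- normalize_stains(img, stains = st, reference = st)
  expect_lte(max(abs(idn$pixels - img$pixels)), 1L)

  # same concentration field under a different stain basis
  alt <- stain_matrix(c(0.55, 0.72, 0.42), c(0.15, 0.95, 0.27),
                      max_conc = st$max_conc)
  img_alt <- beer_lambert_image(c_h, c_e, alt)
  n1 <- normalize_stains(img, stains = st, reference = st)
  n2 <- normalize_stains(img_alt, stains = alt, reference = st)
  expect_lt(mean(abs(n1$pixels - n2$pixels)), 2)

  # all-white stays white
  w <- normalize_stains(uniform_image(8, 8, c(255, 255, 255)), stains = st,
                        reference = st)
  expect_true(all(w$pixels >= 254L))
})
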