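test_that("word tiling follows the grid arithmetic and discards partial tiles", {
  expect_equal(nrow(tile_words(uniform_image(360, 360, c(9, 9, 9)))), 9L)
  r <- tile_words(uniform_image(120, 120, c(0, 0, 0)))
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$x, r$y, r$w, r$h), c(0L, 0L, 120L, 120L))
  expect_equal(nrow(tile_words(uniform_image(500, 119, c(0, 0, 0)))), 0L)
  # scaled grid
  g <- tile_words(uniform_image(100, 75, c(1, 1, 1)), word_size = 25)
  expect_equal(nrow(g), 12L)
  expect_true(all(g$x %% 25 == 0 & g$y %% 25 == 0))
})

test_that("word tiles are pairwise disjoint and inside the image", {
  for (dims in list(c(360, 500), c(121, 241), c(77, 304))) {
    img <- uniform_image(dims[1], dims[2], c(5, 5, 5))
    r <- tile_words(img, word_size = 40)
    if (nrow(r) == 0L) next
    expect_true(all(r$x >= 0 & r$y >= 0 &
                    r$x + r$w <= dims[2] & r$y + r$h <= dims[1]))
    if (nrow(r) > 1L) {
      inter <- wsidiag:::rect_intersection_area(r, r)
      diag(inter) <- 0
      expect_true(all(inter == 0))
    }
  }
})

test_that("sliding windows advance by stride, clamp at borders and cover everything", {
  w <- sliding_windows(uniform_image(6000, 6000, c(0, 0, 0)))
  expect_equal(nrow(w), 9L)
  expect_equal(sort(unique(w$x)), c(0L, 1200L, 2400L))
  expect_equal(nrow(sliding_windows(uniform_image(3600, 3600, c(0, 0, 0)))), 1L)
  w2 <- sliding_windows(uniform_image(3600, 4000, c(0, 0, 0)))
  expect_equal(sort(w2$x), c(0L, 400L))
  expect_equal(nrow(w2), 2L)
  # full coverage + exact window size away from the undersized case
  for (dims in list(c(900, 700), c(650, 1321))) {
    img <- uniform_image(dims[1], dims[2], c(0, 0, 0))
    w3 <- sliding_windows(img, window = 300, overlap = 200)
    expect_false(attr(w3, "undersized"))
    expect_true(all(w3$w == 300 & w3$h == 300))
    covered <- matrix(FALSE, dims[1], dims[2])
    for (i in seq_len(nrow(w3)))
      covered[(w3$y[i] + 1):(w3$y[i] + 300), (w3$x[i] + 1):(w3$x[i] + 300)] <- TRUE
    expect_true(all(covered))
  }
})

test_that("an image smaller than the window yields one flagged whole-image window", {
  w <- sliding_windows(uniform_image(200, 5000, c(0, 0, 0)), window = 300,
                       overlap = 100)
  expect_true(attr(w, "undersized"))
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$w, w$h), c(5000L, 200L))
})

test_that("raster formats decode, replicate grayscale, and round-trip", {
  dir <- withr::local_tempdir()
  white <- uniform_image(2, 2, c(255, 255, 255))
  p <- file.path(dir, "white.png")
  save_image(white, p)
  expect_equal(load_image(p)$pixels, white$pixels)

  gray <- matrix(7L, 4, 5) / 255
  tp <- file.path(dir, "gray.tif")
  tiff::writeTIFF(gray, tp, bits.per.sample = 8L)
  g <- load_image(tp)
  expect_true(all(g$pixels == 7L))
  expect_equal(dim(g$pixels)[3], 3L)

  set.seed(1)
  noisy <- slide_image(array(sample(0:255, 60 * 3, TRUE), c(6, 10, 3)))
  for (ext in c("png", "tif", "bmp")) {
    f <- file.path(dir, paste0("rt.", ext))
    save_image(noisy, f)
    expect_equal(load_image(f)$pixels, noisy$pixels, info = ext)
  }

  lm <- matrix(sample(c(0L, 2:8), 35, TRUE), 5, 7)
  lf <- file.path(dir, "labels.png")
  save_label_map(lm, lf)
  expect_identical(load_label_map(lf), lm)
})

test_that("unreadable and unsupported files raise format errors naming the extension", {
  dir <- withr::local_tempdir()
  txt <- file.path(dir, "notes.txt")
  writeLines("not an image", txt)
  expect_error(load_image(txt), "txt")
  fake <- file.path(dir, "fake.png")
  writeLines("not a png", fake)
  expect_error(load_image(fake), "png")
  expect_error(load_image(file.path(dir, "absent.png")), "not found")
  expect_error(slide_image(array(0L, c(0, 4, 3))), "zero-area|dim")
})

test_that("non-x40 magnification is accepted with a warning", {
  expect_warning(slide_image(matrix(3L, 4, 4), magnification = 20), "x40")
  expect_silent(slide_image(matrix(3L, 4, 4), magnification = 40))
})

test_that("crop_rect honors the half-open 0-based convention", {
  px <- array(0L, c(10, 10, 3))
  px[3:5, 4:6, 1] <- 200L
  img <- slide_image(px)
  cr <- crop_rect(img, rect(3, 2, 3, 3))
  expect_equal(dim(cr$pixels), c(3L, 3L, 3L))
  expect_true(all(cr$pixels[, , 1] == 200L))
  expect_error(crop_rect(img, rect(8, 8, 5, 5)))
})
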