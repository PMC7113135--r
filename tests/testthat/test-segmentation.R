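test_that("SLIC respects color boundaries and partitions the raster", {
  px <- array(0L, c(60, 60, 3))
  px[, 1:30, ] <- 230L
  px[, 31:60, 1] <- 150L; px[, 31:60, 2] <- 40L; px[, 31:60, 3] <- 160L
  sp <- slic_superpixels(slide_image(px), n_segments = 2)
  expect_equal(max(sp) + 1L, 2L)
  for (s in 0:1) {
    m <- sp == s
    side <- max(sum(m[, 1:30]), sum(m[, 31:60])) / sum(m)
    expect_gte(side, 0.95)
  }
  # n_segments = 1: one segment covering everything
  expect_true(all(slic_superpixels(slide_image(px), n_segments = 1) == 0L))
  expect_error(slic_superpixels(slide_image(px), n_segments = 1e6),
               "exceeds")
})

test_that("SLIC superpixels are contiguous ids of 4-connected pixel sets", {
  roi <- generate_roi(synthetic_spec(size = c(120, 120), n_ducts = 1, seed = 8))
  sp <- slic_superpixels(roi$image, n_segments = 40)
  S <- max(sp) + 1L
  expect_setequal(unique(as.vector(sp)), 0:(S - 1L))
  expect_gte(S, 20L)
  expect_lte(S, 80L)
  # 4-connectivity per id via flood fill
  for (s in sample(0:(S - 1L), 5)) {
    m <- sp == s
    lab <- EBImage::bwlabel(m)
    expect_equal(max(lab), 1)
  }
})

test_that("majority vote matches the brute-force oracle and its invariants", {
  set.seed(13)
  for (i in 1:20) {
    fx <- random_label_sp(h = sample(6:14, 1), w = sample(6:14, 1),
                          n_sp = sample(3:8, 1))
    # overwrite with per-pixel noise so superpixels are mixed
    noisy <- fx$lab
    flip <- sample(length(noisy), length(noisy) %/% 3)
    noisy[flip] <- sample(tissue_codes(), length(flip), replace = TRUE)
    voted <- superpixel_majority_vote(noisy, fx$sp)
    expect_identical(as.vector(voted), as.vector(oracle_majority_vote(noisy, fx$sp)),
                     info = paste("case", i))
    # constant within superpixel; never introduces an absent class
    for (s in unique(as.vector(fx$sp))) {
      vals <- voted[fx$sp == s]
      expect_equal(length(unique(vals)), 1L)
      expect_true(vals[1] %in% noisy[fx$sp == s])
    }
  }
})

test_that("majority vote ties break to the lowest class code", {
  sp <- matrix(0L, 10, 10)
  lab <- matrix(c(rep(5L, 50), rep(2L, 50)), 10, 10)
  expect_true(all(superpixel_majority_vote(lab, sp) == 2L))
  lab2 <- matrix(c(rep(3L, 60), rep(4L, 40)), 10, 10)
  expect_true(all(superpixel_majority_vote(lab2, sp) == 3L))
  expect_error(superpixel_majority_vote(matrix(0L, 3, 3), matrix(0L, 4, 4)),
               "dimensions")
})

test_that("label rendering is a bijection over the palette", {
  set.seed(2)
  lab <- matrix(sample(tissue_codes(), 100, TRUE), 10, 10)
  img <- render_labels(lab)
  expect_identical(parse_rendered_labels(img), lab)
  expect_true(all(render_labels(matrix(0L, 3, 3))$pixels == 255L))
  r <- render_labels(matrix(8L, 3, 3))
  expect_true(all(r$pixels[, , 1] == 255L) && all(r$pixels[, , 2:3] == 0L))
  expect_error(render_labels(matrix(1L, 3, 3)), "invalid tissue label")
})

test_that("mean IOU is bounded and equals 1 on identical maps", {
  set.seed(3)
  a <- matrix(sample(tissue_codes(), 64, TRUE), 8, 8)
  b <- matrix(sample(tissue_codes(), 64, TRUE), 8, 8)
  expect_equal(mean_iou(a, a), 1)
  m <- mean_iou(a, b)
  expect_gte(m, 0); expect_lte(m, 1)
})

test_that("the classical pixel classifier learns separable tissue colors", {
  patches <- generate_segmentation_patches(12, size = 64, seed = 21)
  model <- build_segmentation_model(segmentation_config(backend = "classical",
                                                        patch_size = 64,
                                                        num_trees = 50))
  model <- train_pixel_classifier(patches[1:10], model, seed = 1)
  expect_false(is.null(model$forest))
  pred <- predict_pixel_labels(patches[[11]]$image, model)
  expect_true(all(pred %in% tissue_codes()))
  expect_gte(mean(pred == patches[[11]]$labels), 0.9)
  # determinism
  model2 <- train_pixel_classifier(patches[1:10],
                                   build_segmentation_model(
                                     segmentation_config(backend = "classical",
                                                         patch_size = 64,
                                                         num_trees = 50)),
                                   seed = 1)
  expect_identical(model$loss_trace, model2$loss_trace)
  expect_identical(pred, predict_pixel_labels(patches[[11]]$image, model2))
})

test_that("label codes outside the class set are rejected by name", {
  patches <- generate_segmentation_patches(1, size = 16, seed = 1)
  patches[[1]]$labels[1, 1] <- 1L
  model <- build_segmentation_model(segmentation_config(patch_size = 16))
  expect_error(suppressWarnings(train_pixel_classifier(patches, model)), "1")
  patches[[1]]$labels[1, 1] <- 9L
  expect_error(suppressWarnings(train_pixel_classifier(patches, model)), "9")
})

test_that("segment-then-vote recovers class-pure synthetic regions", {
  patches <- generate_segmentation_patches(14, size = 64, seed = 33)
  model <- train_pixel_classifier(
    patches[1:10],
    build_segmentation_model(segmentation_config(backend = "classical",
                                                 patch_size = 64,
                                                 num_trees = 50)),
    seed = 1)
  preds <- c(); truths <- c()
  for (p in patches[11:14]) {
    sp <- slic_superpixels(p$image, n_segments = 40)
    lab <- superpixel_majority_vote(predict_pixel_labels(p$image, model), sp)
    preds <- cbind(preds, lab); truths <- cbind(truths, p$labels)
  }
  expect_gte(mean_iou(preds, truths), 0.8)
})
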