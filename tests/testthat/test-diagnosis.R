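test_that("superpixel frequency counts one unit per superpixel", {
  # 10 superpixels as vertical strips: 4 background, 6 normal stroma
  sp <- matrix(rep(0:9, each = 10), 10, 10, byrow = TRUE)
  lab <- matrix(rep(c(rep(0L, 4), rep(4L, 6)), each = 10), 10, 10, byrow = TRUE)
  f <- superpixel_frequency(lab, sp)
  expect_equal(unname(f), c(0.4, 0, 0, 0.6, 0, 0, 0, 0))
  lab3 <- matrix(3L, 10, 10)
  expect_equal(unname(superpixel_frequency(lab3, sp)),
               c(0, 0, 1, 0, 0, 0, 0, 0))
  raw <- superpixel_frequency(lab, sp, normalize = FALSE)
  expect_equal(sum(raw), 10)
  expect_error(superpixel_frequency(matrix(0L, 0, 0), matrix(0L, 0, 0)),
               "empty")
})

test_that("frequency, adjacency and co-occurrence match brute force on random maps", {
  set.seed(17)
  for (i in 1:25) {
    fx <- random_label_sp(h = sample(5:12, 1), w = sample(5:12, 1),
                          n_sp = sample(2:7, 1))
    expect_equal(unname(superpixel_frequency(fx$lab, fx$sp)),
                 unname(oracle_frequency(fx$lab, fx$sp)), info = i)
    got <- superpixel_adjacency(fx$sp)
    want <- oracle_adjacency(fx$sp)
    expect_equal(unname(got), unname(want), info = i)
    M <- superpixel_cooccurrence(fx$lab, fx$sp)
    expect_equal(unname(M), unname(oracle_cooccurrence(fx$lab, fx$sp)),
                 info = i)
    expect_true(isSymmetric(unname(M)))
    # raw totals: 2 units per adjacency pair
    Mraw <- superpixel_cooccurrence(fx$lab, fx$sp, normalize = FALSE)
    expect_equal(sum(Mraw), 2 * nrow(want))
  }
})

test_that("adjacency handles the degenerate cases", {
  expect_equal(nrow(superpixel_adjacency(matrix(0L, 5, 5))), 0L)
  two <- matrix(rep(0:1, each = 10), 4, 5)
  expect_equal(superpixel_adjacency(two), matrix(c(0L, 1L), 1))
})

test_that("co-occurrence follows the symmetric counting convention", {
  sp <- matrix(rep(0:1, each = 8), 4, 4)
  lab <- matrix(rep(c(2L, 3L), each = 8), 4, 4)
  M <- superpixel_cooccurrence(lab, sp)
  expect_equal(M["2", "3"], 0.5)
  expect_equal(M["3", "2"], 0.5)
  expect_equal(sum(M), 1)
  # same class everywhere: mass on the diagonal cell only
  sp2 <- matrix(rep(0:3, each = 4), 4, 4)
  lab2 <- matrix(5L, 4, 4)
  M2 <- superpixel_cooccurrence(lab2, sp2)
  expect_equal(M2["5", "5"], 1)
  expect_equal(sum(M2 != 0), 1L)
})

test_that("mid-level features concatenate and split consistently", {
  f <- c(1, numeric(7))
  C <- matrix(0, 8, 8)
  v <- midlevel_features(f, C)
  expect_length(v, 72L)
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v != 0), 1L)
  set.seed(1)
  f2 <- stats::runif(8); C2 <- matrix(stats::runif(64), 8)
  v2 <- midlevel_features(f2, C2)
  back <- split_midlevel_features(v2)
  expect_equal(unname(back$freq), f2)
  expect_equal(unname(back$cooc), unname(C2))
})

test_that("ducts are connected epithelial components above the size floor", {
  ring <- generate_ring_roi(size = 160, seed = 2)
  ducts <- identify_ducts(ring$truth, ring$sp)
  expect_length(ducts, 1L)
  expect_setequal(ducts[[1]]$members, which(ring$sp_layer == 0) - 1L)
  # no epithelium -> no ducts
  lab0 <- matrix(4L, nrow(ring$sp), ncol(ring$sp))
  attr(lab0, "granularity") <- "superpixel"
  expect_length(identify_ducts(lab0, ring$sp), 0L)
})

test_that("two disjoint rings give two ducts", {
  roi <- generate_roi(synthetic_spec(size = c(260, 260), n_ducts = 2,
                                     class = "DCIS", seed = 12))
  sp <- slic_superpixels(roi$image, n_segments = 260)
  lab <- superpixel_majority_vote(roi$truth, sp)
  ducts <- identify_ducts(lab, sp)
  expect_length(ducts, 2L)
})

test_that("layer peeling reproduces the generator's ring indices exactly", {
  ring <- generate_ring_roi(size = 200, band_widths = c(14, 10, 10, 10, 10),
                            band_classes = c(0L, 0L, 3L, 4L, 5L), seed = 3)
  ducts <- identify_ducts(ring$truth, ring$sp)
  expect_length(ducts, 1L)
  d <- peel_layers(ducts[[1]], ring$truth, ring$sp, n_layers = 2)
  expect_setequal(d$inner[[1]], which(ring$sp_layer == -1) - 1L)
  expect_setequal(d$inner[[2]], which(ring$sp_layer == -2) - 1L)
  expect_setequal(d$outer[[1]], which(ring$sp_layer == 1) - 1L)
  expect_setequal(d$outer[[2]], which(ring$sp_layer == 2) - 1L)
  # layers are pairwise disjoint and exclude the duct members
  all_sets <- c(d$inner, d$outer, list(d$members))
  for (i in seq_along(all_sets))
    for (j in seq_len(i - 1L))
      expect_length(intersect(all_sets[[i]], all_sets[[j]]), 0L)
})

test_that("peeling truncates at the border and flags missing lumens", {
  # a duct with only one inner band available
  ring <- generate_ring_roi(size = 140, band_widths = c(10, 10, 10),
                            band_classes = c(0L, 3L, 4L), seed = 5)
  ducts <- identify_ducts(ring$truth, ring$sp)
  d <- peel_layers(ducts[[1]], ring$truth, ring$sp, n_layers = 3)
  expect_lte(length(d$inner), 2L)     # core + nothing deeper
  expect_gte(length(d$outer), 1L)
})

test_that("structure features assemble per-layer class histograms", {
  ring <- generate_ring_roi(size = 200, band_widths = c(14, 10, 10, 10, 10),
                            band_classes = c(0L, 0L, 3L, 4L, 5L), seed = 7)
  ducts <- identify_ducts(ring$truth, ring$sp)
  ducts <- lapply(ducts, peel_layers, lab = ring$truth, sp = ring$sp,
                  n_layers = 2)
  v <- structure_features(ducts, ring$truth, ring$sp, n_layers = 2)
  expect_length(v, 40L)
  m <- matrix(v, nrow = 5, byrow = TRUE)   # rows: inner_2, inner_1, duct, outer_1, outer_2
  codes <- as.character(tissue_codes())
  # hand-computed: each band is class-pure
  expect_equal(m[1, ], c(1, 0, 0, 0, 0, 0, 0, 0))        # core: background
  expect_equal(m[2, ], c(1, 0, 0, 0, 0, 0, 0, 0))        # lumen band
  expect_equal(m[3, ], c(0, 0, 1, 0, 0, 0, 0, 0))        # malignant ring
  expect_equal(m[4, ], c(0, 0, 0, 1, 0, 0, 0, 0))        # normal stroma
  expect_equal(m[5, ], c(0, 0, 0, 0, 1, 0, 0, 0))        # desmoplastic
  # averaging two identical ducts changes nothing
  v2 <- structure_features(c(ducts, ducts), ring$truth, ring$sp, n_layers = 2)
  expect_equal(as.numeric(v2), as.numeric(v))
  # no ducts: all-zero vector flagged with n_ducts = 0
  v0 <- structure_features(list(), ring$truth, ring$sp, n_layers = 2)
  expect_true(all(v0 == 0))
  expect_equal(attr(v0, "n_ducts"), 0L)
})

test_that("the cascade trains, short-circuits and is order invariant", {
  set.seed(30)
  centers <- rbind(benign = c(5, 0, 0), atypia = c(0, 5, 0),
                   DCIS = c(0, 0, 5), invasive = c(5, 5, 5))
  n <- 60
  y <- sample(rownames(centers), n, replace = TRUE)
  X <- centers[y, ] + matrix(stats::rnorm(3 * n, sd = 0.2), n)
  model <- train_cascade(X, y, seed = 1)
  pred <- apply(X, 1, function(x) classify_diagnosis(x, model)$label)
  expect_equal(mean(pred == y), 1)

  # stage short-circuit bookkeeping
  inv <- classify_diagnosis(centers["invasive", ], model)
  expect_equal(inv$label, "invasive")
  expect_true(is.na(inv$scores["benign_vs_proliferative"]))
  expect_true(is.na(inv$scores["dcis_vs_atypia"]))
  dc <- classify_diagnosis(centers["DCIS", ], model)
  expect_equal(dc$label, "DCIS")
  expect_false(any(is.na(dc$scores)))

  # order invariance with the same seed
  perm <- sample(n)
  model2 <- train_cascade(X[perm, ], y[perm], seed = 1)
  pred2 <- apply(X, 1, function(x) classify_diagnosis(x, model2)$label)
  expect_identical(pred, pred2)
  s1 <- classify_diagnosis(X[1, ], model)$scores
  s2 <- classify_diagnosis(X[1, ], model2)$scores
  expect_equal(s1, s2, tolerance = 1e-9)

  # errors
  expect_error(train_cascade(X[y != "atypia", ], y[y != "atypia"]),
               "atypia")
  expect_error(classify_diagnosis(c(1, 2), model), "feature length")
})
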