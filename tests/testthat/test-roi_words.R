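test_that("word descriptors are normalized histograms with the expected support", {
  # uniform color patch: single color bin with mass 1
  d <- word_descriptor(uniform_image(24, 24, c(100, 100, 100)))
  bins <- word_bins()
  color <- d[seq_len(bins$color_len)]
  tex <- d[bins$color_len + seq_len(bins$texture_len)]
  expect_equal(sum(color != 0), 1L)
  expect_equal(max(color), 1)
  # constant image: every interior pixel has the all-neighbors>=center
  # pattern (value 255), the last uniform code
  expect_equal(which(tex[1:59] != 0), 58L)
  expect_equal(which(tex[60:118] != 0), 58L)
  # any patch: both histograms sum to 1
  set.seed(2)
  rnd <- slide_image(array(sample(0:255, 24 * 24 * 3, TRUE), c(24, 24, 3)))
  d2 <- word_descriptor(rnd)
  expect_equal(sum(d2[seq_len(bins$color_len)]), 1)
  expect_equal(sum(d2[bins$color_len + seq_len(bins$texture_len)]), 1)
  expect_true(all(d2 >= 0))
})

test_that("wrong patch size raises a dimension error", {
  expect_error(word_descriptor(uniform_image(20, 24, c(1, 1, 1)),
                               word_size = 24), "word size")
  expect_error(word_descriptor(uniform_image(2, 2, c(1, 1, 1))), "too small")
})

test_that("batch descriptor extraction equals the single-patch computation", {
  roi <- generate_roi(synthetic_spec(size = c(96, 96), n_ducts = 1, seed = 4))
  words <- tile_words(roi$image, word_size = 24)
  batch <- extract_word_descriptors(roi$image, words)
  for (i in c(1L, 5L, nrow(words))) {
    single <- word_descriptor(crop_rect(roi$image, words[i, ]))
    expect_equal(batch[i, ], single, tolerance = 1e-12)
  }
})

test_that("k-means dictionary recovers well-separated cloud means", {
  set.seed(10)
  m1 <- c(rep(0.8, 5), rep(0.05, 5))
  m2 <- c(rep(0.05, 5), rep(0.8, 5))
  X <- rbind(matrix(rep(m1, 50), 50, byrow = TRUE),
             matrix(rep(m2, 50), 50, byrow = TRUE)) +
    matrix(stats::rnorm(1000, sd = 0.002), 100)
  dict <- build_dictionary(X, k = 2, seed = 1)
  d_to <- function(c1, m) sqrt(sum((c1 - m)^2))
  got <- dict$centroids
  expect_lt(min(d_to(got[1, ], m1), d_to(got[1, ], m2)), 0.01)
  expect_lt(min(d_to(got[2, ], m1), d_to(got[2, ], m2)), 0.01)
  expect_gt(d_to(got[1, ], got[2, ]), 0.5)

  # k = 1: centroid is the global mean
  d1 <- build_dictionary(X, k = 1, seed = 1)
  expect_equal(as.numeric(d1$centroids), colMeans(X), tolerance = 1e-9)

  expect_error(build_dictionary(X[1:5, ], k = 10), "insufficient")
})

test_that("word assignment matches the brute-force nearest-centroid scan", {
  set.seed(20)
  dict <- build_dictionary(matrix(stats::runif(40 * 6), 40), k = 8, seed = 3)
  # exact centroid maps to its own id
  expect_equal(assign_word(dict$centroids[4, ], dict), 4L)
  # equidistant descriptor takes the lowest index
  d0 <- (dict$centroids[1, ] + dict$centroids[2, ]) / 2
  ids <- assign_words(rbind(dict$centroids[1, ], dict$centroids[2, ]), dict)
  expect_equal(ids, c(1L, 2L))
  # brute force agreement on many random descriptors
  D <- matrix(stats::runif(200 * 6), 200)
  fast <- assign_words(D, dict)
  slow <- apply(D, 1, oracle_nearest_centroid, centroids = dict$centroids)
  expect_equal(fast, slow)
})

test_that("tie-breaking in assignment picks the lowest cluster id", {
  dict <- structure(list(centroids = rbind(c(0, 0), c(2, 0), c(1, 5), c(2, 0)),
                         k = 4L, seed = 1),
                    class = "visual_dictionary")
  # descriptor equidistant from centroids 2 and 4 (identical centroids)
  expect_equal(assign_word(c(2, 0), dict), 2L)
  expect_equal(assign_word(c(1, 0), dict), 1L)
})

test_that("bag histograms count contained words and normalize", {
  words <- tile_words(uniform_image(120, 120, c(0, 0, 0)), word_size = 40)
  b <- bag_histogram(rect(0, 0, 120, 120), words, rep(3L, 9), k = 4)
  expect_equal(b$hist, c(0, 0, 1, 0))
  b2 <- bag_histogram(rect(0, 0, 120, 120), words,
                      rep(c(1L, 2L), c(6, 3)), k = 4)
  expect_equal(b2$hist, c(2 / 3, 1 / 3, 0, 0))
  # raw counts
  b3 <- bag_histogram(rect(0, 0, 120, 120), words, rep(2L, 9), k = 4,
                      normalize = FALSE)
  expect_equal(sum(b3$hist), 9)
  # off-tissue window with no complete words
  expect_error(bag_histogram(rect(90, 90, 30, 30), words, rep(1L, 9), k = 4),
               "empty window")
})

test_that("bag histograms are additive over disjoint word sets before normalization", {
  set.seed(4)
  words <- tile_words(uniform_image(200, 400, c(0, 0, 0)), word_size = 40)
  assign <- sample.int(5, nrow(words), replace = TRUE)
  left <- rect(0, 0, 200, 200)
  right <- rect(200, 0, 200, 200)
  whole <- rect(0, 0, 400, 200)
  h <- function(r) bag_histogram(r, words, assign, k = 5, normalize = FALSE)$hist
  expect_equal(h(whole), h(left) + h(right))
})
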