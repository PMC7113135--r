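#' Histogram configuration for word descriptors
#'
#' Bin layout of the two per-word histograms: a joint CIELAB color
#' histogram with `l_bins * a_bins * b_bins` cells (L clamped to
#' \[0, 100\], a and b to \[-100, 100\]) and a texture histogram of
#' uniform local binary pattern codes (59 bins) computed on each of the
#' hematoxylin and eosin concentration channels.
#'
#' @param l_bins,a_bins,b_bins bins per CIELAB axis (default 8 each).
#' @return A list with the bin counts and derived descriptor lengths.
#' @export
word_bins <- function(l_bins = 8, a_bins = 8, b_bins = 8) {
  n_lbp <- lbp_n_bins_cpp()
  list(l_bins = l_bins, a_bins = a_bins, b_bins = b_bins,
       color_len = l_bins * a_bins * b_bins,
       texture_len = 2L * n_lbp,
       lbp_bins = n_lbp)
}

# flat 1-based color bin index per pixel; L fastest, then a, then b
lab_bin_index <- function(lab, bins) {
  cut01 <- function(v, lo, hi, n) {
    i <- floor((pmin(pmax(v, lo), hi) - lo) / (hi - lo) * n)
    pmin(i, n - 1L)
  }
  d <- dim(lab)
  m <- matrix(as.numeric(lab), ncol = 3L)
  iL <- cut01(m[, 1], 0, 100, bins$l_bins)
  ia <- cut01(m[, 2], -100, 100, bins$a_bins)
  ib <- cut01(m[, 3], -100, 100, bins$b_bins)
  idx <- 1L + iL + bins$l_bins * (ia + bins$a_bins * ib)
  matrix(as.integer(idx), d[1], d[2])
}

# Per-image feature planes shared by all words: color bin index and the
# two LBP code planes. LBP codes are valid away from the image border;
# because word histograms only use the word's interior ring, whole-image
# codes agree exactly with per-patch computation.
word_feature_planes <- function(img, stains, bins) {
  lab <- rgb_to_lab(img)
  he <- deconvolve(img, stains)
  list(color_idx = lab_bin_index(lab, bins),
       lbp_h = lbp_uniform_cpp(he[, , 1]),
       lbp_e = lbp_uniform_cpp(he[, , 2]))
}

word_descriptor_from_planes <- function(planes, r, bins) {
  rows <- (r$y + 1):(r$y + r$h)
  cols <- (r$x + 1):(r$x + r$w)
  color <- tabulate(planes$color_idx[rows, cols], nbins = bins$color_len)
  irows <- rows[-c(1L, length(rows))]
  icols <- cols[-c(1L, length(cols))]
  th <- tabulate(planes$lbp_h[irows, icols] + 1L, nbins = bins$lbp_bins)
  te <- tabulate(planes$lbp_e[irows, icols] + 1L, nbins = bins$lbp_bins)
  texture <- c(th, te)
  c(color / sum(color), texture / sum(texture))
}

#' Descriptor of a single visual word
#'
#' Concatenates an L1-normalized CIELAB color histogram with an
#' L1-normalized texture histogram of uniform LBP codes over the
#' hematoxylin and eosin channels. The LBP codes are computed on the
#' word's interior (pixels with a complete 8-neighborhood inside the
#' patch).
#'
#' @param patch a word-sized [slide_image()] or RGB array.
#' @param stains [stain_matrix()] used for the H&E channels.
#' @param bins a [word_bins()] configuration.
#' @param word_size when given, the patch must be exactly this size.
#' @return A numeric vector of length `color_len + texture_len`.
#' @export
word_descriptor <- function(patch, stains = he_reference_stains(),
                            bins = word_bins(), word_size = NULL) {
  px <- as_pixel_array(patch)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (!is.null(word_size) && (h != word_size || w != word_size))
    stop(sprintf("patch is %dx%d but the word size is %d", h, w, word_size))
  if (h < 3 || w < 3) stop("patch too small for texture codes (need >= 3x3)")
  planes <- word_feature_planes(slide_image(px), stains, bins)
  word_descriptor_from_planes(planes, rect(0, 0, w, h), bins)
}

#' Descriptors for all words of an image
#'
#' Batch form of [word_descriptor()]: computes the CIELAB and H&E feature
#' planes once for the whole image and histograms each word from them.
#' Identical to calling [word_descriptor()] on each cropped word.
#'
#' @param img a [slide_image()].
#' @param words rect data frame from [tile_words()].
#' @inheritParams word_descriptor
#' @return A matrix with one row per word.
#' @export
extract_word_descriptors <- function(img, words,
                                     stains = he_reference_stains(),
                                     bins = word_bins()) {
  planes <- word_feature_planes(img, stains, bins)
  out <- matrix(0, nrow = nrow(words), ncol = bins$color_len + bins$texture_len)
  for (i in seq_len(nrow(words)))
    out[i, ] <- word_descriptor_from_planes(planes, words[i, ], bins)
  out
}

#' Build the visual dictionary by k-means
#'
#' Clusters word descriptors with k-means (fixed seed) and stores the `k`
#' centroids, sorted lexicographically so the fitted dictionary is
#' independent of the clustering's internal label order.
#'
#' @param descriptors matrix of word descriptors (rows).
#' @param k dictionary size (default 64).
#' @param seed RNG seed for the k-means initialization.
#' @param iter_max,nstart k-means control.
#' @return An object of class `visual_dictionary`.
#' @export
build_dictionary <- function(descriptors, k = 64, seed = 1,
                             iter_max = 100, nstart = 5) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < k)
    stop(sprintf("insufficient samples: %d descriptors for k = %d",
                 nrow(descriptors), k))
  if (nrow(unique(descriptors)) < k)
    stop(sprintf("insufficient distinct descriptors (%d) for k = %d",
                 nrow(unique(descriptors)), k))
  set.seed(seed)
  km <- stats::kmeans(descriptors, centers = k, iter.max = iter_max,
                      nstart = nstart)
  centers <- km$centers
  ord <- do.call(order, as.data.frame(centers))
  structure(list(centroids = unname(centers[ord, , drop = FALSE]),
                 k = as.integer(k), seed = seed),
            class = "visual_dictionary")
}

#' @export
print.visual_dictionary <- function(x, ...) {
  cat(sprintf("<visual_dictionary k=%d, descriptor length %d>\n",
              x$k, ncol(x$centroids)))
  invisible(x)
}

#' Assign words to dictionary clusters
#'
#' Nearest centroid in Euclidean distance; ties go to the lowest cluster
#' id. Cluster ids are 1-based.
#'
#' @param descriptors a descriptor vector ([assign_word()]) or matrix of
#'   row descriptors ([assign_words()]).
#' @param dict a fitted [build_dictionary()].
#' @return Integer cluster id(s) in `1..k`.
#' @export
assign_words <- function(descriptors, dict) {
  D <- if (is.null(dim(descriptors))) matrix(descriptors, nrow = 1L)
       else as.matrix(descriptors)
  if (ncol(D) != ncol(dict$centroids))
    stop("descriptor length does not match dictionary")
  d2 <- matrix(0, nrow(D), dict$k)
  for (k in seq_len(dict$k))
    d2[, k] <- rowSums(sweep(D, 2L, dict$centroids[k, ], "-")^2)
  max.col(-d2, ties.method = "first")
}

#' @rdname assign_words
#' @export
assign_word <- function(descriptors, dict) assign_words(descriptors, dict)[1L]

#' Bag-of-words histogram of a window
#'
#' Counts the dictionary clusters of the words fully contained in the
#' window and (by default) L1-normalizes, since clamped border windows
#' hold fewer words.
#'
#' @param window a single [rect()].
#' @param word_rects rect data frame of word positions.
#' @param assignments integer cluster ids aligned with `word_rects`.
#' @param k dictionary size.
#' @param normalize L1-normalize the counts (default `TRUE`).
#' @return A list (`bag_feature`) with `window` and `hist`.
#' @export
bag_histogram <- function(window, word_rects, assignments, k,
                          normalize = TRUE) {
  if (nrow(word_rects) != length(assignments))
    stop("assignments do not align with word_rects")
  inside <- word_rects$x >= window$x & word_rects$y >= window$y &
    word_rects$x + word_rects$w <= window$x + window$w &
    word_rects$y + word_rects$h <= window$y + window$h
  if (!any(inside))
    stop("empty window: no complete word lies inside it")
  counts <- tabulate(assignments[inside], nbins = k)
  structure(list(window = window,
                 hist = if (normalize) counts / sum(counts) else counts),
            class = "bag_feature")
}
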