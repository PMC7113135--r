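#' Label sliding windows as positive/negative training examples
#'
#' Positive windows overlap a ground-truth ROI by at least `pos_overlap`
#' of their own area. Negative windows have zero ROI overlap but lie
#' near one: their center is within `near_margin` pixels of some ROI
#' rectangle. Remaining windows are used for neither class, which keeps
#' the negatives informative for the margin.
#'
#' @param roi_truth rect data frame of ground-truth ROIs.
#' @param windows rect data frame of analysis windows.
#' @param near_margin distance defining "near" (default 3600 px, one
#'   window).
#' @param pos_overlap minimum overlap fraction of the window's area for a
#'   positive label (default 0.5).
#' @return A list with integer index vectors `positive` and `negative`.
#' @export
make_training_pairs <- function(roi_truth, windows, near_margin = 3600,
                                pos_overlap = 0.5) {
  if (nrow(roi_truth) == 0L)
    return(list(positive = integer(0), negative = integer(0)))
  inter <- rect_intersection_area(windows, roi_truth)
  frac <- apply(inter, 1L, max) / (windows$w * windows$h)
  cx <- windows$x + windows$w / 2
  cy <- windows$y + windows$h / 2
  dist <- matrix(0, nrow(windows), nrow(roi_truth))
  for (j in seq_len(nrow(roi_truth))) {
    r <- roi_truth[j, ]
    dx <- pmax(r$x - cx, cx - (r$x + r$w), 0)
    dy <- pmax(r$y - cy, cy - (r$y + r$h), 0)
    dist[, j] <- sqrt(dx^2 + dy^2)
  }
  near <- apply(dist, 1L, min) <= near_margin
  list(positive = which(frac >= pos_overlap),
       negative = which(apply(inter, 1L, max) == 0 & near))
}

#' Train the ROI window classifier
#'
#' Binary margin classifier (linear-kernel support vector machine) on
#' bag-of-words histograms; positive examples are windows inside ROIs,
#' negatives are windows near but not inside them.
#'
#' @param positive,negative matrices of bag histograms (rows).
#' @param seed RNG seed (training is deterministic given it).
#' @param cost SVM cost parameter.
#' @return An object of class `window_classifier`.
#' @export
train_window_classifier <- function(positive, negative, seed = 1, cost = 1) {
  positive <- as.matrix(positive); negative <- as.matrix(negative)
  if (nrow(positive) < 1L || nrow(negative) < 1L)
    stop("degenerate training set: need at least one window of each class")
  x <- rbind(positive, negative)
  y <- factor(rep(c("roi", "background"), c(nrow(positive), nrow(negative))),
              levels = c("background", "roi"))
  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, x[1L, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (startsWith(colnames(dv)[1L], "roi")) 1 else -1
  structure(list(fit = fit, flip = flip, k = ncol(x), seed = seed),
            class = "window_classifier")
}

#' Score windows with a trained classifier
#'
#' @param clf a [train_window_classifier()] model.
#' @param bags matrix of bag histograms (rows).
#' @param threshold decision threshold for `is_roi` (default 0).
#' @return A data frame with `score` (signed margin, positive = ROI) and
#'   `is_roi`.
#' @export
predict_windows <- function(clf, bags, threshold = 0) {
  bags <- as.matrix(bags)
  if (ncol(bags) != clf$k) stop("bag histogram length mismatch")
  pr <- stats::predict(clf$fit, bags, decision.values = TRUE)
  score <- clf$flip * as.numeric(attr(pr, "decision.values"))
  data.frame(score = score, is_roi = score >= threshold)
}

# union of overlapping (or touching) positive windows into merged boxes
merge_overlapping_rects <- function(rects) {
  n <- nrow(rects)
  if (n == 0L) return(rect_df(integer(0), integer(0), integer(0), integer(0)))
  inter <- rect_intersection_area(rects, rects) > 0
  g <- igraph::graph_from_adjacency_matrix(inter, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- lapply(sort(unique(comp)), function(cid) {
    r <- rects[comp == cid, , drop = FALSE]
    x0 <- min(r$x); y0 <- min(r$y)
    rect_df(x0, y0, max(r$x + r$w) - x0, max(r$y + r$h) - y0)
  })
  do.call(rbind, out)
}

draw_box_outline <- function(px, r, color = c(255L, 0L, 0L), thick = 3L) {
  h <- dim(px)[1]; w <- dim(px)[2]
  x0 <- r$x + 1L; y0 <- r$y + 1L; x1 <- r$x + r$w; y1 <- r$y + r$h
  for (ch in 1:3) {
    for (t in seq_len(thick) - 1L) {
      rows <- c(min(y0 + t, h), max(y1 - t, 1L))
      cols <- c(min(x0 + t, w), max(x1 - t, 1L))
      px[rows, x0:x1, ch] <- color[ch]
      px[y0:y1, cols, ch] <- color[ch]
    }
  }
  px
}

#' Detect regions of interest on a slide
#'
#' Scores every sliding window's bag-of-words histogram with the trained
#' window classifier, merges overlapping positive windows into connected
#' boxes, and returns the boxes, per-window scores, cropped ROI images
#' and a red-box overlay visualization. Windows without a complete word
#' (e.g. off-tissue slivers) are treated as negative. Inference uses no
#' randomness: results are fully determined by the model and the input.
#'
#' @param img a [slide_image()].
#' @param dict a [build_dictionary()] visual dictionary.
#' @param clf a [train_window_classifier()] model.
#' @param word_size,window,overlap geometry parameters (defaults 120 /
#'   3600 / 2400 px).
#' @param stains,bins descriptor parameters, see [word_descriptor()].
#' @return A list: `boxes` (merged ROI rects), `windows` (all windows
#'   with `score`, `is_roi`), `rois` (cropped [slide_image()]s, one per
#'   merged box) and `overlay`.
#' @export
detect_rois <- function(img, dict, clf, word_size = 120, window = 3600,
                        overlap = 2400, stains = he_reference_stains(),
                        bins = word_bins()) {
  words <- tile_words(img, word_size)
  wins <- sliding_windows(img, window, overlap)
  if (nrow(words) > 0L) {
    desc <- extract_word_descriptors(img, words, stains, bins)
    assign <- assign_words(desc, dict)
  } else {
    assign <- integer(0)
  }
  bags <- matrix(0, nrow(wins), dict$k)
  has_words <- logical(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    b <- tryCatch(bag_histogram(wins[i, ], words, assign, dict$k),
                  error = function(e) NULL)
    if (!is.null(b)) { bags[i, ] <- b$hist; has_words[i] <- TRUE }
  }
  wins$score <- -Inf
  wins$is_roi <- FALSE
  if (any(has_words)) {
    pr <- predict_windows(clf, bags[has_words, , drop = FALSE])
    wins$score[has_words] <- pr$score
    wins$is_roi[has_words] <- pr$is_roi
  }
  boxes <- merge_overlapping_rects(wins[wins$is_roi, c("x", "y", "w", "h")])
  px <- as_pixel_array(img)
  overlay <- px
  rois <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    overlay <- draw_box_outline(overlay, boxes[i, ])
    rois[[i]] <- crop_rect(img, boxes[i, ])
  }
  list(boxes = boxes, windows = wins, rois = rois,
       overlay = slide_image(overlay))
}
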