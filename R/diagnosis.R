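#' Superpixel tissue-class frequency histogram
#'
#' Eight-bin histogram over the tissue palette, counting one unit per
#' superpixel (the labeling unit of the segmentation), indexed in class
#' code order (0, 2, 3, 4, 5, 6, 7, 8).
#'
#' @param lab a per-superpixel tissue label map.
#' @param sp the matching superpixel map.
#' @param normalize divide by the superpixel count (default `TRUE`).
#' @return A named numeric 8-vector.
#' @export
superpixel_frequency <- function(lab, sp, normalize = TRUE) {
  if (length(lab) == 0L || length(sp) == 0L) stop("empty label map")
  if (!all(dim(lab) == dim(sp)))
    stop("label map and superpixel map dimensions differ")
  check_label_codes(lab)
  cls <- superpixel_modal_class(lab, sp)
  counts <- tabulate(match(cls, tissue_codes()), nbins = 8L)
  names(counts) <- as.character(tissue_codes())
  if (normalize) counts / length(cls) else counts
}

#' Adjacent superpixel pairs
#'
#' Unordered pairs of distinct superpixel ids that share a pixel edge
#' (4-connectivity by default).
#'
#' @param sp a superpixel map.
#' @param connectivity 4 (default) or 8.
#' @return A two-column integer matrix of 0-based id pairs, each pair
#'   once with the smaller id first.
#' @export
superpixel_adjacency <- function(sp, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  m <- sp
  storage.mode(m) <- "integer"
  adjacency_pairs_cpp(m, diag8 = connectivity == 8)
}

#' Superpixel tissue-class co-occurrence matrix
#'
#' Entry (i, j) holds the frequency with which class-i superpixels touch
#' class-j superpixels. Counting is symmetric: each adjacent pair with
#' classes (a, b), a != b, adds one to (a, b) and one to (b, a); a
#' same-class pair adds two to its diagonal cell, so row sums stay
#' consistent with superpixel contact degrees. The matrix is optionally
#' L1-normalized.
#'
#' @inheritParams superpixel_frequency
#' @param normalize L1-normalize the matrix (default `TRUE`).
#' @param connectivity pixel connectivity for adjacency (default 4).
#' @return An 8 x 8 symmetric matrix with dimnames in class code order.
#' @export
superpixel_cooccurrence <- function(lab, sp, normalize = TRUE,
                                    connectivity = 4) {
  if (!all(dim(lab) == dim(sp)))
    stop("label map and superpixel map dimensions differ")
  check_label_codes(lab)
  codes <- tissue_codes()
  M <- matrix(0, 8L, 8L, dimnames = list(codes, codes))
  pairs <- superpixel_adjacency(sp, connectivity)
  if (nrow(pairs) > 0L) {
    cls <- superpixel_modal_class(lab, sp)
    a <- match(cls[pairs[, 1] + 1L], codes)
    b <- match(cls[pairs[, 2] + 1L], codes)
    for (i in seq_along(a)) {
      M[a[i], b[i]] <- M[a[i], b[i]] + 1
      M[b[i], a[i]] <- M[b[i], a[i]] + 1
    }
    if (normalize && sum(M) > 0) M <- M / sum(M)
  }
  M
}

#' Combined mid-level feature vector
#'
#' Concatenates the 8 superpixel frequency bins with the 64 co-occurrence
#' cells (row-major), the feature set of the mid-level diagnosis
#' classifier.
#'
#' @param freq a [superpixel_frequency()] 8-vector.
#' @param cooc a [superpixel_cooccurrence()] 8 x 8 matrix.
#' @return A numeric vector of length 72.
#' @export
midlevel_features <- function(freq, cooc) {
  stopifnot(length(freq) == 8L, all(dim(cooc) == c(8L, 8L)))
  codes <- as.character(tissue_codes())
  v <- c(as.numeric(freq), as.numeric(t(cooc)))
  names(v) <- c(paste0("freq_", codes),
                as.vector(t(outer(codes, codes,
                                  function(i, j) paste0("cooc_", i, "_", j)))))
  v
}

#' @rdname midlevel_features
#' @param v a 72-vector produced by [midlevel_features()].
#' @return `split_midlevel_features()` returns `list(freq, cooc)`.
#' @export
split_midlevel_features <- function(v) {
  stopifnot(length(v) == 72L)
  codes <- as.character(tissue_codes())
  list(freq = stats::setNames(as.numeric(v[1:8]), codes),
       cooc = matrix(as.numeric(v[9:72]), 8L, 8L, byrow = TRUE,
                     dimnames = list(codes, codes)))
}

#' Identify ducts as connected epithelial structures
#'
#' A duct is a connected component (under superpixel adjacency) of
#' epithelial superpixels — benign (code 2) or malignant (code 3)
#' epithelium — with at least `min_superpixels` members.
#'
#' @inheritParams superpixel_frequency
#' @param min_superpixels minimum component size (default 3).
#' @return A list of `duct_structure` objects holding the member
#'   superpixel ids (`members`, 0-based); layers are unset until
#'   [peel_layers()].
#' @export
identify_ducts <- function(lab, sp, min_superpixels = 3) {
  check_label_codes(lab)
  cls <- superpixel_modal_class(lab, sp)
  epi <- which(cls %in% c(2L, 3L)) - 1L          # 0-based ids
  if (length(epi) == 0L) return(list())
  pairs <- superpixel_adjacency(sp)
  keep <- pairs[, 1] %in% epi & pairs[, 2] %in% epi
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(pairs[keep, 1]),
                   to = as.character(pairs[keep, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(epi)))
  comp <- igraph::components(g)$membership
  ducts <- lapply(sort(unique(comp)), function(cid) {
    members <- as.integer(names(comp)[comp == cid])
    structure(list(id = NA_integer_, members = sort(members),
                   inner = NULL, outer = NULL),
              class = "duct_structure")
  })
  ducts <- Filter(function(d) length(d$members) >= min_superpixels, ducts)
  for (i in seq_along(ducts)) ducts[[i]]$id <- i
  ducts
}

# superpixels whose pixels are mostly inside the filled outline of the
# duct component but are not duct members
enclosed_superpixels <- function(duct, sp) {
  mask <- matrix(as.vector(sp) %in% duct$members, nrow(sp), ncol(sp))
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  inside <- filled & !mask
  if (!any(inside)) return(integer(0))
  S <- n_superpixels(sp)
  in_cnt <- tabulate(sp[inside] + 1L, nbins = S)
  tot_cnt <- tabulate(as.vector(sp) + 1L, nbins = S)
  which(in_cnt > tot_cnt / 2) - 1L
}

#' Peel superpixel layers around a duct
#'
#' Builds one-superpixel-wide layers inward (toward the lumen) and
#' outward (toward the stroma): the first inner layer holds non-duct
#' superpixels adjacent to the duct that lie in its enclosed region (the
#' filled outline of the duct component), deeper layers are adjacent to
#' the previous one; outer layers are built the same way outside the
#' enclosed region. Peeling stops early when a layer comes up empty.
#'
#' @param duct a duct from [identify_ducts()].
#' @param lab,sp the per-superpixel label map and superpixel map.
#' @param n_layers layers to peel on each side (default 2).
#' @return The duct with `inner` and `outer` set: lists of 0-based
#'   superpixel id vectors (possibly shorter than `n_layers`).
#' @export
peel_layers <- function(duct, lab, sp, n_layers = 2) {
  stopifnot(inherits(duct, "duct_structure"))
  pairs <- superpixel_adjacency(sp)
  S <- n_superpixels(sp)
  nbrs <- vector("list", S)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1] + 1L; b <- pairs[i, 2] + 1L
    nbrs[[a]] <- c(nbrs[[a]], b - 1L)
    nbrs[[b]] <- c(nbrs[[b]], a - 1L)
  }
  inside <- enclosed_superpixels(duct, sp)
  peel <- function(region) {
    layers <- list()
    assigned <- duct$members
    frontier <- duct$members
    for (l in seq_len(n_layers)) {
      cand <- unique(unlist(nbrs[frontier + 1L]))
      nxt <- sort(setdiff(intersect(cand, region), assigned))
      if (length(nxt) == 0L) break
      layers[[l]] <- nxt
      assigned <- c(assigned, nxt)
      frontier <- nxt
    }
    layers
  }
  all_ids <- seq_len(S) - 1L
  duct$inner <- peel(inside)
  duct$outer <- peel(setdiff(all_ids, c(inside, duct$members)))
  duct$enclosed_empty <- length(inside) == 0L
  duct
}

#' Duct-centric layered structure features
#'
#' For each peeled duct, an 8-bin tissue-class frequency histogram of the
#' superpixels in every layer, ordered
#' `inner_L .. inner_1, duct, outer_1 .. outer_L`, flattened to a
#' `(2 * n_layers + 1) * 8` vector; missing layers contribute all-zero
#' blocks. Multiple ducts in an ROI are averaged into one vector.
#'
#' @param ducts list of peeled ducts ([peel_layers()]).
#' @param lab,sp the per-superpixel label map and superpixel map.
#' @param n_layers layers per side (default 2).
#' @return A named numeric vector of length `(2 * n_layers + 1) * 8`;
#'   attribute `n_ducts` records how many ducts contributed (0 gives the
#'   all-zero vector).
#' @export
structure_features <- function(ducts, lab, sp, n_layers = 2) {
  codes <- tissue_codes()
  layer_names <- c(paste0("inner_", n_layers:1), "duct",
                   paste0("outer_", seq_len(n_layers)))
  nm <- as.vector(t(outer(layer_names, as.character(codes), paste, sep = "_c")))
  zero <- stats::setNames(numeric((2 * n_layers + 1) * 8), nm)
  if (length(ducts) == 0L) {
    attr(zero, "n_ducts") <- 0L
    return(zero)
  }
  cls <- superpixel_modal_class(lab, sp)
  hist8 <- function(ids) {
    if (length(ids) == 0L) return(numeric(8L))
    h <- tabulate(match(cls[ids + 1L], codes), nbins = 8L)
    h / sum(h)
  }
  vecs <- vapply(ducts, function(d) {
    blocks <- c(rev(c(d$inner, vector("list", n_layers - length(d$inner)))),
                list(d$members),
                c(d$outer, vector("list", n_layers - length(d$outer))))
    unlist(lapply(blocks, function(ids) hist8(if (is.null(ids)) integer(0) else ids)))
  }, numeric(length(zero)))
  out <- stats::setNames(rowMeans(vecs), nm)
  attr(out, "n_ducts") <- length(ducts)
  out
}

diagnosis_labels <- function() c("benign", "atypia", "DCIS", "invasive")

#' Train the cascaded diagnosis classifier
#'
#' Three binary margin classifiers (linear-kernel SVMs) arranged as a
#' tree: stage 1 separates invasive from everything else on all samples;
#' stage 2 separates benign from the proliferative pair (atypia, DCIS)
#' on the non-invasive samples; stage 3 separates DCIS from atypia.
#' Training is deterministic given the seed and invariant to sample
#' order.
#'
#' @param features matrix of ROI feature vectors (rows) — mid-level,
#'   structure, or their concatenation.
#' @param labels character vector in
#'   `c("benign", "atypia", "DCIS", "invasive")`; every class must be
#'   present.
#' @param seed RNG seed.
#' @param cost SVM cost parameter.
#' @return An object of class `cascade_model`.
#' @export
train_cascade <- function(features, labels, seed = 1, cost = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  missing <- setdiff(diagnosis_labels(), labels)
  if (length(missing) > 0L)
    stop("missing diagnosis class(es) in training labels: ",
         paste(missing, collapse = ", "))
  stage_fit <- function(x, pos) {
    # canonical sample order so the fit ignores input permutation
    ord <- do.call(order, as.data.frame(cbind(x, pos)))
    x <- x[ord, , drop = FALSE]; pos <- pos[ord]
    y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    set.seed(seed)
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(fit, x[1L, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    list(fit = fit, flip = if (startsWith(colnames(dv)[1L], "pos")) 1 else -1)
  }
  noninv <- labels != "invasive"
  prolif <- labels %in% c("atypia", "DCIS")
  structure(list(
    stage1 = stage_fit(features, labels == "invasive"),
    stage2 = stage_fit(features[noninv, , drop = FALSE],
                       labels[noninv] == "benign"),
    stage3 = stage_fit(features[prolif, , drop = FALSE],
                       labels[prolif] == "DCIS"),
    n_features = ncol(features), seed = seed),
    class = "cascade_model")
}

stage_score <- function(stage, x) {
  pr <- stats::predict(stage$fit, x, decision.values = TRUE)
  stage$flip * as.numeric(attr(pr, "decision.values"))
}

#' Classify an ROI with the diagnosis cascade
#'
#' Stage 1 positive short-circuits to invasive; otherwise stage 2
#' positive gives benign; otherwise stage 3 decides DCIS (positive)
#' versus atypia. Decision scores of the stages actually evaluated are
#' recorded (skipped stages are `NA`).
#'
#' @param features a single feature vector (or one-row matrix).
#' @param model a [train_cascade()] model.
#' @return A list (`diagnosis_result`): `label` and `scores`
#'   (`invasive_vs_rest`, `benign_vs_proliferative`, `dcis_vs_atypia`).
#' @export
classify_diagnosis <- function(features, model) {
  stopifnot(inherits(model, "cascade_model"))
  x <- matrix(as.numeric(features), nrow = 1L)
  if (ncol(x) != model$n_features)
    stop(sprintf("feature length %d does not match model (%d)",
                 ncol(x), model$n_features))
  scores <- c(invasive_vs_rest = NA_real_,
              benign_vs_proliferative = NA_real_,
              dcis_vs_atypia = NA_real_)
  scores[1] <- stage_score(model$stage1, x)
  if (scores[1] >= 0) {
    label <- "invasive"
  } else {
    scores[2] <- stage_score(model$stage2, x)
    if (scores[2] >= 0) {
      label <- "benign"
    } else {
      scores[3] <- stage_score(model$stage3, x)
      label <- if (scores[3] >= 0) "DCIS" else "atypia"
    }
  }
  structure(list(label = label, scores = scores), class = "diagnosis_result")
}

#' @export
print.diagnosis_result <- function(x, ...) {
  cat(sprintf("<diagnosis: %s>\n", x$label))
  s <- x$scores[!is.na(x$scores)]
  cat(paste(sprintf("  %s: %+.3f", names(s), s), collapse = "\n"), "\n")
  invisible(x)
}

#' Mid-level and structure features of a segmented ROI
#'
#' Convenience wrapper computing the configured feature set from a
#' per-superpixel label map.
#'
#' @param lab per-superpixel tissue label map.
#' @param sp superpixel map.
#' @param features `"midlevel"`, `"structure"` or `"both"`
#'   (concatenated).
#' @param n_layers structure-feature layers per side.
#' @param min_duct_superpixels duct size threshold.
#' @return A named numeric feature vector.
#' @export
roi_features <- function(lab, sp, features = c("both", "midlevel", "structure"),
                         n_layers = 2, min_duct_superpixels = 3) {
  features <- match.arg(features)
  out <- numeric(0)
  if (features %in% c("midlevel", "both")) {
    out <- c(out, midlevel_features(superpixel_frequency(lab, sp),
                                    superpixel_cooccurrence(lab, sp)))
  }
  if (features %in% c("structure", "both")) {
    ducts <- identify_ducts(lab, sp, min_superpixels = min_duct_superpixels)
    ducts <- lapply(ducts, peel_layers, lab = lab, sp = sp,
                    n_layers = n_layers)
    out <- c(out, structure_features(ducts, lab, sp, n_layers = n_layers))
  }
  out
}
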