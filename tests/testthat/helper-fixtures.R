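# shared fixture builders; everything is generated in code

uniform_image <- function(h, w, rgb) {
  px <- array(0L, c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  slide_image(px)
}

# Beer-Lambert forward model: render an image from known concentration
# fields under a known stain matrix (the independent oracle for the
# Macenko operations)
beer_lambert_image <- function(c_h, c_e, stains = he_reference_stains()) {
  reconstruct_rgb(array(c(c_h, c_e), c(dim(c_h), 2L)), stains)
}

# mixture with near-pure pixels of each stain, as in stained tissue
# where nuclei are H-dominant and stroma E-dominant
two_stain_fixture <- function(n_side = 60, seed = 42) {
  set.seed(seed)
  n <- n_side^2
  grp <- sample(1:3, n, replace = TRUE)
  c_h <- ifelse(grp == 1, stats::runif(n, 0.3, 0.8),
                ifelse(grp == 2, stats::runif(n, 0, 0.05),
                       stats::runif(n, 0.1, 0.6)))
  c_e <- ifelse(grp == 2, stats::runif(n, 0.3, 0.7),
                ifelse(grp == 1, stats::runif(n, 0, 0.05),
                       stats::runif(n, 0.1, 0.5)))
  list(c_h = matrix(c_h, n_side), c_e = matrix(c_e, n_side))
}

angle_deg <- function(a, b) acos(pmin(abs(sum(a * b)), 1)) * 180 / pi

# random small tissue label map + superpixel map pair for oracle tests
random_label_sp <- function(h = 12, w = 12, n_sp = 6) {
  sp <- matrix(sample.int(n_sp, h * w, replace = TRUE) - 1L, h, w)
  # make each id 4-connected is not required by the oracle ops; but ids
  # must be contiguous from 0
  ids <- sort(unique(as.vector(sp)))
  sp <- matrix(match(as.vector(sp), ids) - 1L, h, w)
  codes <- tissue_codes()
  lab_sp <- sample(codes, length(ids), replace = TRUE)
  lab <- matrix(lab_sp[sp + 1L], h, w)
  list(lab = lab, sp = sp)
}

# brute-force oracles -------------------------------------------------

oracle_nearest_centroid <- function(d, centroids) {
  best <- Inf; bi <- 0L
  for (k in seq_len(nrow(centroids))) {
    dist <- sum((d - centroids[k, ])^2)
    if (dist < best) { best <- dist; bi <- k }
  }
  bi
}

oracle_majority_vote <- function(lab, sp) {
  out <- lab
  for (s in sort(unique(as.vector(sp)))) {
    codes <- lab[sp == s]
    tab <- table(codes)
    win <- min(as.integer(names(tab)[tab == max(tab)]))
    out[sp == s] <- win
  }
  out
}

oracle_adjacency <- function(sp) {
  pairs <- character(0)
  h <- nrow(sp); w <- ncol(sp)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    a <- sp[y, x]
    if (x < w && sp[y, x + 1] != a)
      pairs <- c(pairs, paste(min(a, sp[y, x + 1]), max(a, sp[y, x + 1])))
    if (y < h && sp[y + 1, x] != a)
      pairs <- c(pairs, paste(min(a, sp[y + 1, x]), max(a, sp[y + 1, x])))
  }
  sorted <- sort(unique(pairs))
  if (length(sorted) == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, lapply(strsplit(sorted, " "), as.integer))
}

oracle_frequency <- function(lab, sp, normalize = TRUE) {
  codes <- tissue_codes()
  counts <- stats::setNames(numeric(8), as.character(codes))
  voted <- oracle_majority_vote(lab, sp)
  for (s in sort(unique(as.vector(sp)))) {
    cl <- voted[sp == s][1]
    counts[as.character(cl)] <- counts[as.character(cl)] + 1
  }
  if (normalize) counts / sum(counts) else counts
}

oracle_cooccurrence <- function(lab, sp, normalize = TRUE) {
  codes <- tissue_codes()
  M <- matrix(0, 8, 8, dimnames = list(codes, codes))
  voted <- oracle_majority_vote(lab, sp)
  cls_of <- function(s) voted[sp == s][1]
  pr <- oracle_adjacency(sp)
  for (i in seq_len(nrow(pr))) {
    a <- as.character(cls_of(pr[i, 1])); b <- as.character(cls_of(pr[i, 2]))
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  if (normalize && sum(M) > 0) M <- M / sum(M)
  M
}

# scaled detector geometry shared by the end-to-end tests: the same
# window/word and overlap/window ratios as the full-scale 120/3600/2400
# operating point, at one fifth the pixel budget per word
scaled_detector_config <- function(seed = 1) {
  pipeline_config(word_size = 24, window = 240, overlap = 160, k = 16,
                  seed = seed)
}

make_synthetic_slide <- function(seed, canvas = c(1200, 1200), n_blocks = 2) {
  classes <- c("benign", "atypia", "DCIS", "invasive")
  specs <- lapply(seq_len(n_blocks), function(i)
    synthetic_spec(size = c(300, 300),
                   class = classes[(seed * 3 + i) %% 4 + 1],
                   seed = seed * 10 + i))
  generate_slide(canvas = canvas, roi_specs = specs, seed = seed,
                 margin = 40)
}

window_detection_metrics <- function(det, truth_rects) {
  wins <- det$windows
  inter <- wsidiag:::rect_intersection_area(wins, truth_rects)
  frac <- apply(inter, 1, max) / (wins$w * wins$h)
  truth_pos <- frac >= 0.5
  pred <- wins$is_roi
  # windows partially overlapping a block are ambiguous and excluded
  # from precision, mirroring the in/near training label design
  decided <- truth_pos | frac == 0
  list(recall = sum(pred & truth_pos) / sum(truth_pos),
       precision = sum(pred & truth_pos) / max(1, sum(pred & decided)))
}
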