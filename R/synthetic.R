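# Deterministic synthetic H&E-like fixtures. The renderer paints each
# tissue class with a base color plus a class-specific sinusoidal texture
# and Gaussian noise, so color histograms, LBP texture histograms and the
# downstream classifiers all have real signal, while every pixel carries
# exact ground truth. This emulates composition and duct geometry, not
# nuclei-level histology.

synthetic_palette <- function() {
  data.frame(
    code = c(0L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    r = c(245, 140,  80, 235, 200, 220, 200, 170),
    g = c(243,  90,  60, 180, 140, 230,  60, 120),
    b = c(245, 180, 150, 200, 185, 205,  70, 110),
    sigma = c(3, 8, 8, 8, 8, 6, 8, 8),
    tex_freq = c(0, 0.25, 0.45, 0.08, 0.18, 0.03, 0.30, 0.12),
    tex_amp = c(0, 12, 12, 10, 10, 6, 10, 10),
    tex_angle = c(0, 0.4, 1.2, 0.0, 0.9, 0.2, 1.5, 0.6))
}

#' Specification of a synthetic ROI
#'
#' Describes one synthetic region: a stromal background with a
#' class-dependent desmoplastic fraction, `n_ducts` concentric-disk
#' ducts (lumen plus epithelial ring) and, per diagnosis class,
#' characteristic extras — necrotic lumen cores for DCIS, scattered
#' malignant epithelial islands for invasive.
#'
#' @param size `c(height, width)` in pixels (default 300 x 300).
#' @param class diagnosis label, one of `"benign"`, `"atypia"`,
#'   `"DCIS"`, `"invasive"`.
#' @param n_ducts number of ducts (default 3).
#' @param lumen_radius,ring_width duct geometry in pixels.
#' @param desmo_fraction fraction of stroma rendered as desmoplastic
#'   (default by class: benign 0.10, atypia 0.25, DCIS 0.45,
#'   invasive 0.65).
#' @param n_islands invasive only: number of scattered malignant
#'   epithelium islands (default 6).
#' @param secretion_prob probability a lumen holds secretion instead of
#'   background.
#' @param seed RNG seed; every artifact of the generator is a pure
#'   function of the spec (including its seed).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = c(300, 300),
                           class = c("benign", "atypia", "DCIS", "invasive"),
                           n_ducts = 3,
                           lumen_radius = 14,
                           ring_width = 8,
                           desmo_fraction = NULL,
                           n_islands = 6,
                           secretion_prob = 0.3,
                           seed = 1) {
  class <- match.arg(class)
  if (is.null(desmo_fraction))
    desmo_fraction <- c(benign = 0.10, atypia = 0.25,
                        DCIS = 0.45, invasive = 0.65)[[class]]
  stopifnot(lumen_radius >= 3, ring_width >= 3,
            desmo_fraction >= 0, desmo_fraction <= 1)
  structure(list(size = as.integer(size), class = class,
                 n_ducts = as.integer(n_ducts),
                 lumen_radius = lumen_radius, ring_width = ring_width,
                 desmo_fraction = desmo_fraction,
                 n_islands = as.integer(n_islands),
                 secretion_prob = secretion_prob, seed = seed),
            class = "synthetic_spec")
}

disk_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

# smooth random field in [0,1] for blobby desmoplasia placement
smooth_field <- function(h, w) {
  z <- matrix(stats::rnorm(h * w), h, w)
  k <- matrix(1, 9, 9) / 81
  z <- EBImage::filter2(z, k)
  z <- EBImage::filter2(z, k)
  (z - min(z)) / (max(z) - min(z) + 1e-12)
}

render_truth <- function(truth, seed) {
  set.seed(seed)
  pal <- synthetic_palette()
  h <- nrow(truth); w <- ncol(truth)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  yy <- matrix(seq_len(h), h, w)
  px <- array(0, c(h, w, 3L))
  i <- match(as.vector(truth), pal$code)
  base <- cbind(pal$r[i], pal$g[i], pal$b[i])
  tex <- pal$tex_amp[i] *
    sin(2 * pi * pal$tex_freq[i] *
        (as.vector(xx) * cos(pal$tex_angle[i]) +
         as.vector(yy) * sin(pal$tex_angle[i])))
  for (ch in 1:3) {
    v <- base[, ch] + tex + stats::rnorm(h * w, sd = pal$sigma[i])
    px[, , ch] <- matrix(pmin(pmax(round(v), 0), 255), h, w)
  }
  slide_image(px)
}

place_ducts <- function(h, w, n, radius, seed_offset, margin = 4) {
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > 500L)
      stop(sprintf("placement error: cannot fit %d ducts of radius %.0f in %dx%d",
                   n, radius, h, w))
    cy <- stats::runif(1, radius + margin, h - radius - margin)
    cx <- stats::runif(1, radius + margin, w - radius - margin)
    if (nrow(centers) == 0L ||
        all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) > 2 * radius + 6))
      centers <- rbind(centers, c(cy, cx))
  }
  centers
}

#' Generate one synthetic ROI with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_roi`: `image` ([slide_image()]),
#'   `truth` (per-pixel tissue label map), `ducts` (data frame of
#'   centers/radii), `class`, `spec`.
#' @export
generate_roi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  r_out <- spec$lumen_radius + spec$ring_width
  if (2 * (r_out + 4) > min(h, w))
    stop("placement error: ducts do not fit the image")
  set.seed(spec$seed)
  truth <- matrix(4L, h, w)
  # desmoplastic stroma as contiguous blobs hitting the requested fraction
  if (spec$desmo_fraction > 0) {
    f <- smooth_field(h, w)
    truth[f >= stats::quantile(f, 1 - spec$desmo_fraction)] <- 5L
  }
  epi_code <- if (spec$class %in% c("benign", "atypia")) 2L else 3L
  centers <- place_ducts(h, w, spec$n_ducts, r_out, spec$seed)
  lumen_secretion <- stats::runif(spec$n_ducts) < spec$secretion_prob
  for (i in seq_len(spec$n_ducts)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]
    ring <- disk_mask(h, w, cy, cx, r_out)
    lumen <- disk_mask(h, w, cy, cx, spec$lumen_radius)
    truth[ring] <- epi_code
    truth[lumen] <- if (lumen_secretion[i]) 6L else 0L
    if (spec$class == "DCIS")
      truth[disk_mask(h, w, cy, cx, spec$lumen_radius * 0.5)] <- 8L
  }
  if (spec$class == "invasive" && spec$n_islands > 0) {
    for (i in seq_len(spec$n_islands)) {
      ry <- stats::runif(1, 8, h - 8); rx <- stats::runif(1, 8, w - 8)
      rr <- stats::runif(1, 3, 6)
      m <- disk_mask(h, w, ry, rx, rr)
      m <- m & truth %in% c(4L, 5L)            # islands invade stroma only
      truth[m] <- 3L
    }
  }
  img <- render_truth(truth, spec$seed + 1L)
  structure(list(image = img,
                 truth = label_map(truth, granularity = "pixel"),
                 ducts = data.frame(cy = centers[, 1], cx = centers[, 2],
                                    lumen_radius = spec$lumen_radius,
                                    ring_outer = r_out),
                 class = spec$class, spec = spec),
            class = "synthetic_roi")
}

#' Generate a concentric-ring ROI with aligned superpixels
#'
#' A single centered duct drawn as exact concentric bands — core and
#' lumen band inside the epithelial ring, stromal bands outside — each
#' band split into angular sectors that double as a ground-truth
#' superpixel map. Because every band is one superpixel wide, the band
#' index is exactly the layer that [peel_layers()] should recover
#' (negative = inner, 0 = duct, positive = outer).
#'
#' @param size image side (square, default 200).
#' @param band_widths radii increments, innermost first:
#'   `core, inner band, duct ring, outer bands...` (default
#'   `c(14, 10, 10, 10, 10)`).
#' @param band_classes tissue code of each band (default: background
#'   core and lumen, malignant ring, normal then desmoplastic stroma).
#' @param n_sectors angular sectors per band (default 8).
#' @param seed render seed.
#' @return A list: `image`, `truth`, `sp` (superpixel map), `sp_layer`
#'   (per-superpixel layer index, `NA` for background superpixels
#'   beyond the bands), `sp_class`.
#' @export
generate_ring_roi <- function(size = 200,
                              band_widths = c(14, 10, 10, 10, 10),
                              band_classes = c(0L, 0L, 3L, 4L, 5L),
                              n_sectors = 8,
                              seed = 1) {
  stopifnot(length(band_widths) == length(band_classes))
  duct_band <- which(band_classes %in% c(2L, 3L))
  stopifnot(length(duct_band) == 1L)
  h <- w <- as.integer(size)
  cy <- cx <- (size + 1) / 2
  radii <- cumsum(band_widths)
  stopifnot(2 * (max(radii) + 2) < size)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
  theta <- atan2(yy - cy, xx - cx) + pi          # (0, 2*pi]
  band <- findInterval(rr, radii) + 1L           # 1..nb inside, nb+1 beyond
  nb <- length(radii)
  sector <- pmin(floor(theta / (2 * pi) * n_sectors), n_sectors - 1L)
  sp <- matrix(-1L, h, w)
  sp_layer <- integer(0); sp_class <- integer(0)
  next_id <- 0L
  for (b in seq_len(nb)) {
    in_band <- band == b
    secs <- if (b == 1L) 1L else n_sectors       # core disk is one superpixel
    for (s in seq_len(secs) - 1L) {
      m <- in_band & (if (secs == 1L) TRUE else sector == s)
      sp[m] <- next_id
      sp_layer <- c(sp_layer, b - duct_band)
      sp_class <- c(sp_class, band_classes[b])
      next_id <- next_id + 1L
    }
  }
  # background outside the bands: grid-block superpixels of normal stroma
  out_band <- band > nb
  block <- 2L * as.integer(ceiling(size / 8))
  gy <- (yy - 1L) %/% block; gx <- (xx - 1L) %/% block
  gid <- gy * ceiling(w / block) + gx
  for (g in sort(unique(gid[out_band]))) {
    m <- out_band & gid == g
    sp[m] <- next_id
    sp_layer <- c(sp_layer, NA_integer_)
    sp_class <- c(sp_class, 4L)
    next_id <- next_id + 1L
  }
  truth <- matrix(sp_class[sp + 1L], h, w)
  img <- render_truth(truth, seed)
  attr(sp, "n_superpixels") <- next_id
  list(image = img, truth = label_map(truth, granularity = "superpixel"),
       sp = sp, sp_layer = sp_layer, sp_class = sp_class)
}

#' Generate annotated patches for segmenter training
#'
#' Square patches tiled into class-pure Voronoi regions: each region is
#' painted as one randomly drawn tissue class with the standard
#' synthetic texture. Every patch comes with its exact per-pixel label
#' map, emulating expert pixel annotation.
#'
#' @param n number of patches.
#' @param size patch side in pixels (default 96).
#' @param n_regions Voronoi regions per patch (default 6).
#' @param classes tissue codes to draw from (default all 8).
#' @param seed RNG seed.
#' @return A list of `list(image = , labels = )` pairs.
#' @export
generate_segmentation_patches <- function(n, size = 96, n_regions = 6,
                                          classes = tissue_codes(),
                                          seed = 1) {
  stopifnot(n >= 1, size >= 8, n_regions >= 1)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sy <- stats::runif(n_regions, 1, size)
    sx <- stats::runif(n_regions, 1, size)
    # every patch carries several classes; all classes appear across patches
    cls <- c(classes[(i - 1L) %% length(classes) + 1L],
             sample(classes, n_regions - 1L, replace = TRUE))
    yy <- matrix(seq_len(size), size, size)
    xx <- matrix(seq_len(size), size, size, byrow = TRUE)
    nearest <- matrix(1L, size, size)
    best <- (yy - sy[1])^2 + (xx - sx[1])^2
    for (r in seq_len(n_regions)[-1]) {
      d <- (yy - sy[r])^2 + (xx - sx[r])^2
      upd <- d < best
      nearest[upd] <- r
      best[upd] <- d[upd]
    }
    truth <- matrix(cls[nearest], size, size)
    list(image = render_truth(truth, seed * 1000L + i),
         labels = label_map(truth, granularity = "pixel"))
  })
}

#' Generate a labeled synthetic dataset
#'
#' `4 * n_per_class` ROIs with per-class jitter of duct count, radii and
#' desmoplastic fraction; deterministic for a given seed.
#'
#' @param n_per_class ROIs per diagnosis class.
#' @param base_spec template [synthetic_spec()]; class, seed and the
#'   jittered fields are overridden per ROI.
#' @param seed dataset seed.
#' @return A list of `synthetic_roi` objects.
#' @export
generate_dataset <- function(n_per_class, base_spec = synthetic_spec(),
                             seed = 1) {
  stopifnot(n_per_class >= 1)
  rois <- list()
  base_desmo <- c(benign = 0.10, atypia = 0.25, DCIS = 0.45, invasive = 0.65)
  set.seed(seed)
  for (cls in diagnosis_labels()) {
    for (i in seq_len(n_per_class)) {
      sp <- base_spec
      sp$class <- cls
      sp$n_ducts <- if (cls == "invasive") sample(1:2, 1) else sample(2:3, 1)
      sp$lumen_radius <- base_spec$lumen_radius * stats::runif(1, 0.85, 1.15)
      sp$desmo_fraction <- min(1, max(0, base_desmo[[cls]] +
                                        stats::runif(1, -0.05, 0.05)))
      sp$seed <- seed * 10000L + match(cls, diagnosis_labels()) * 1000L + i
      rois[[length(rois) + 1L]] <- generate_roi(sp)
    }
  }
  rois
}

#' Split a dataset into disjoint train/test sets
#'
#' Stratified by diagnosis class; the split is a pure function of the
#' seed.
#'
#' @param rois list of `synthetic_roi` objects.
#' @param test_fraction fraction held out per class (default 0.25).
#' @param seed split seed.
#' @return `list(train = , test = )`, disjoint and exhaustive.
#' @export
split_dataset <- function(rois, test_fraction = 0.25, seed = 1) {
  classes <- vapply(rois, function(r) r$class, character(1))
  set.seed(seed)
  test_idx <- unlist(lapply(unique(classes), function(cls) {
    i <- which(classes == cls)
    sample(i, max(1L, round(length(i) * test_fraction)))
  }))
  list(train = rois[setdiff(seq_along(rois), test_idx)],
       test = rois[sort(test_idx)])
}

#' Generate a synthetic slide with tissue blocks on a white canvas
#'
#' Places rendered synthetic ROIs at non-overlapping random rectangles
#' on a blank white canvas, returning the slide and the ground-truth
#' rectangles for window labeling.
#'
#' @param canvas `c(height, width)` of the slide (default
#'   12000 x 12000).
#' @param roi_specs list of [synthetic_spec()]s, one tissue block each.
#' @param seed placement seed.
#' @param margin minimum distance from the border and between blocks.
#' @return A list: `image` ([slide_image()]), `roi_rects` (rect data
#'   frame), `rois` (the generated `synthetic_roi`s).
#' @export
generate_slide <- function(canvas = c(12000, 12000), roi_specs, seed = 1,
                           margin = 40) {
  h <- canvas[1]; w <- canvas[2]
  rois <- lapply(roi_specs, generate_roi)
  set.seed(seed)
  px <- array(255L, c(h, w, 3L))
  placed <- rect_df(integer(0), integer(0), integer(0), integer(0))
  for (roi in rois) {
    rh <- roi$image$height; rw <- roi$image$width
    ok <- FALSE
    for (try in 1:500) {
      x0 <- floor(stats::runif(1, margin, w - rw - margin))
      y0 <- floor(stats::runif(1, margin, h - rh - margin))
      cand <- rect_df(x0, y0, rw, rh)
      grown <- rect_df(max(x0 - margin, 0), max(y0 - margin, 0),
                       rw + 2 * margin, rh + 2 * margin)
      if (nrow(placed) == 0L ||
          all(rect_intersection_area(grown, placed) == 0)) {
        placed <- rbind(placed, cand)
        px[(y0 + 1):(y0 + rh), (x0 + 1):(x0 + rw), ] <- roi$image$pixels
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: ROI blocks overlap; enlarge the canvas")
  }
  list(image = slide_image(px), roi_rects = placed, rois = rois)
}
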