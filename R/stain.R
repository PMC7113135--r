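#' Convert an RGB image to CIELAB
#'
#' Standard sRGB decoding (IEC 61966-2-1) followed by the CIE 1976 L*a*b*
#' transform under the D65 white point. Neutral grays map to `a = b = 0`
#' and white to `L = 100`.
#'
#' @param img a [slide_image()] or `H x W x 3` array of 8-bit RGB.
#' @return An `H x W x 3` numeric array with channels (L, a, b).
#' @export
rgb_to_lab <- function(img) {
  px <- as_pixel_array(img)
  d <- dim(px)
  rgb <- matrix(as.numeric(px), ncol = 3L) / 255
  lab <- srgb_to_lab_matrix(rgb)
  array(lab, d)
}

# sRGB (D65) -> XYZ -> Lab on an N x 3 matrix in [0, 1]
srgb_to_lab_matrix <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3L, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1.00000, 1.08883)
  t_ <- sweep(xyz, 2L, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(t_ > eps, t_^(1 / 3), t_ / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Stain matrix for two-stain (H&E) deconvolution
#'
#' Holds the optical-density direction of each stain as a unit-norm,
#' non-negative 3-vector, plus a per-stain robust maximum concentration
#' used by [normalize_stains()].
#'
#' @param hematoxylin,eosin length-3 OD direction vectors (normalized
#'   internally; must be non-negative and linearly independent).
#' @param max_conc length-2 reference maximum concentrations
#'   (hematoxylin, eosin); may be `NA` when unknown.
#' @return An object of class `stain_matrix`: a 3 x 2 matrix `M` (columns
#'   hematoxylin, eosin) plus `max_conc`.
#' @export
stain_matrix <- function(hematoxylin, eosin, max_conc = c(NA_real_, NA_real_)) {
  M <- cbind(hematoxylin = hematoxylin / sqrt(sum(hematoxylin^2)),
             eosin = eosin / sqrt(sum(eosin^2)))
  if (any(M < -1e-9)) stop("stain vectors must have non-negative components")
  M[M < 0] <- 0
  cosang <- abs(sum(M[, 1] * M[, 2]))
  if (cosang > 1 - 1e-8)
    stop("degenerate stain matrix: stain vectors are collinear")
  structure(list(M = M, max_conc = as.numeric(max_conc)),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("<stain_matrix>\n")
  print(round(x$M, 4))
  cat("max concentrations:", round(x$max_conc, 4), "\n")
  invisible(x)
}

#' Package reference H&E stain matrix
#'
#' The widely used Ruifrok–Johnston H&E optical-density directions with
#' conventional robust maximum concentrations; serves as the common
#' normalization target and as the default basis for texture features.
#'
#' @return A [stain_matrix()].
#' @export
he_reference_stains <- function() {
  stain_matrix(hematoxylin = c(0.650, 0.704, 0.286),
               eosin = c(0.072, 0.990, 0.105),
               max_conc = c(1.9705, 1.0308))
}

# Beer-Lambert optical density; epsilon = 1 keeps log finite at I = 0.
rgb_to_od <- function(px) -log10((as.numeric(px) + 1) / 255)

od_to_rgb <- function(od) {
  i <- 255 * 10^(-od) - 1
  as.integer(round(pmin(pmax(i, 0), 255)))
}

#' Estimate H&E stain vectors by the Macenko procedure
#'
#' Converts pixels to optical density (`OD = -log10((I + 1) / 255)`),
#' discards background pixels whose OD vector norm falls below
#' `od_threshold`, takes the top two principal directions of the remaining OD
#' cloud, and returns the two robust extreme directions of the projected
#' angle distribution (at `angle_percentile` and its complement). The
#' vector with the larger blue-channel OD component is labeled
#' hematoxylin. Robust maximum concentrations (99th percentile) are
#' filled in from the same pixels.
#'
#' @param img a [slide_image()].
#' @param od_threshold background OD cut-off (default 0.15).
#' @param angle_percentile robust percentile for the extreme angles, in
#'   percent (default 1, i.e. 1st/99th).
#' @param min_tissue_pixels minimum number of above-threshold pixels
#'   required (default 100).
#' @return A [stain_matrix()].
#' @export
estimate_stains <- function(img, od_threshold = 0.15, angle_percentile = 1,
                            min_tissue_pixels = 100) {
  px <- as_pixel_array(img)
  od <- matrix(rgb_to_od(px), ncol = 3L)
  keep <- sqrt(rowSums(pmax(od, 0)^2)) > od_threshold
  if (sum(keep) < min_tissue_pixels)
    stop(sprintf(paste0("insufficient tissue: %d pixels above OD %.2f ",
                        "(need >= %d)"), sum(keep), od_threshold,
                 min_tissue_pixels))
  X <- od[keep, , drop = FALSE]
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  basis <- ev$vectors[, 1:2, drop = FALSE]
  # deterministic orientation: principal axes point into the OD cloud
  for (j in 1:2) if (sum(X %*% basis[, j]) < 0) basis[, j] <- -basis[, j]
  p <- X %*% basis
  phi <- atan2(p[, 2], p[, 1])
  qs <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
                        names = FALSE)
  v1 <- basis %*% c(cos(qs[1]), sin(qs[1]))
  v2 <- basis %*% c(cos(qs[2]), sin(qs[2]))
  clean <- function(v) { v <- pmax(as.numeric(v), 0); v / sqrt(sum(v^2)) }
  v1 <- clean(v1); v2 <- clean(v2)
  # hematoxylin absorbs more in the blue channel
  if (v1[3] >= v2[3]) { h <- v1; e <- v2 } else { h <- v2; e <- v1 }
  st <- stain_matrix(h, e)
  conc <- matrix(he_concentrations(od, st), ncol = 2L)
  st$max_conc <- apply(conc, 2L, stats::quantile, probs = 0.99, names = FALSE)
  st
}

# least-squares unmixing of an N x 3 OD matrix onto the two stain columns
he_concentrations <- function(od, stains) {
  M <- stains$M
  coef <- solve(crossprod(M), t(M))      # 2 x 3
  conc <- od %*% t(coef)
  conc[conc < 0] <- 0
  conc
}

#' Unmix an RGB image into H&E concentration channels
#'
#' Per-pixel least squares of the optical-density vector onto the two
#' stain directions; negative concentrations are clipped to zero.
#'
#' @param img a [slide_image()].
#' @param stains a [stain_matrix()] (default: package reference).
#' @return An `H x W x 2` array (hematoxylin, eosin) of class `he_image`.
#' @export
deconvolve <- function(img, stains = he_reference_stains()) {
  px <- as_pixel_array(img)
  od <- matrix(rgb_to_od(px), ncol = 3L)
  conc <- he_concentrations(od, stains)
  structure(array(conc, c(dim(px)[1:2], 2L)), class = "he_image")
}

#' Reconstruct RGB from H&E concentrations
#'
#' Inverse of [deconvolve()] under the Beer-Lambert model.
#'
#' @param he an `H x W x 2` concentration array.
#' @param stains a [stain_matrix()].
#' @return A [slide_image()].
#' @export
reconstruct_rgb <- function(he, stains = he_reference_stains()) {
  d <- dim(he)
  conc <- matrix(as.numeric(he), ncol = 2L)
  od <- conc %*% t(stains$M)
  slide_image(array(od_to_rgb(od), c(d[1:2], 3L)))
}

#' Normalize stain appearance to a reference
#'
#' Deconvolves the image with its own (or a supplied) stain matrix,
#' rescales each concentration channel so its robust maximum matches the
#' reference's, and reconstructs RGB with the reference stain vectors.
#'
#' @param img a [slide_image()].
#' @param stains source [stain_matrix()]; estimated from `img` via
#'   [estimate_stains()] when `NULL`.
#' @param reference target [stain_matrix()] (default: package reference).
#' @return A [slide_image()] with reference stain appearance.
#' @export
normalize_stains <- function(img, stains = NULL,
                             reference = he_reference_stains()) {
  if (is.null(stains)) stains <- estimate_stains(img)
  px <- as_pixel_array(img)
  od <- matrix(rgb_to_od(px), ncol = 3L)
  conc <- he_concentrations(od, stains)
  src_max <- stains$max_conc
  if (anyNA(src_max))
    src_max <- apply(conc, 2L, stats::quantile, probs = 0.99, names = FALSE)
  ref_max <- reference$max_conc
  if (anyNA(ref_max)) ref_max <- src_max
  scale <- ifelse(src_max > 0, ref_max / src_max, 1)
  conc <- sweep(conc, 2L, scale, "*")
  od_out <- conc %*% t(reference$M)
  slide_image(array(od_to_rgb(od_out), dim(px)),
              magnification = if (is_slide_image(img)) img$magnification)
}
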