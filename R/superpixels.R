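#' The eight histopathologic tissue classes
#'
#' Integer codes, names and display colors of the tissue palette used
#' throughout segmentation and diagnosis. Code 1 is deliberately absent
#' from the scheme and is rejected wherever label maps are validated.
#'
#' @return A data frame with columns `code`, `name`, `color` (hex) and
#'   `r`, `g`, `b`.
#' @export
tissue_classes <- function() {
  df <- data.frame(
    code = c(0L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    name = c("background", "benign_epithelium", "malignant_epithelium",
             "normal_stroma", "desmoplastic_stroma", "secretion",
             "blood", "necrosis"),
    color = c("#FFFFFF", "#FF00FF", "#0000FF", "#FFC0CB",
              "#EE82EE", "#00FF00", "#FFFF00", "#FF0000"),
    stringsAsFactors = FALSE)
  rgb <- t(grDevices::col2rgb(df$color))
  df$r <- rgb[, 1]; df$g <- rgb[, 2]; df$b <- rgb[, 3]
  df
}

tissue_codes <- function() tissue_classes()$code

check_label_codes <- function(map) {
  bad <- setdiff(unique(as.vector(map)), tissue_codes())
  if (length(bad) > 0L)
    stop("invalid tissue label code(s): ", paste(sort(bad), collapse = ", "))
  invisible(map)
}

label_map <- function(map, granularity = c("pixel", "superpixel")) {
  granularity <- match.arg(granularity)
  storage.mode(map) <- "integer"
  check_label_codes(map)
  structure(map, granularity = granularity)
}

#' Segment an image into SLIC superpixels
#'
#' Simple linear iterative clustering on (L, a, b, x, y): local k-means
#' with a spatial regularization weight, followed by connectivity
#' enforcement that absorbs fragments below a minimum size. Superpixel
#' ids are contiguous from 0 and each id's pixel set is 4-connected.
#'
#' @param img a [slide_image()].
#' @param n_segments requested number of superpixels; default one per
#'   3000 pixels.
#' @param compactness spatial regularization weight (default 10);
#'   larger values give squarer superpixels.
#' @param max_iter SLIC iterations (default 10).
#' @param min_size_frac minimum segment size as a fraction of the target
#'   size (default 0.25).
#' @return An integer matrix of 0-based superpixel ids with attribute
#'   `n_superpixels`.
#' @export
slic_superpixels <- function(img, n_segments = NULL, compactness = 10,
                             max_iter = 10, min_size_frac = 0.25) {
  px <- as_pixel_array(img)
  n_px <- prod(dim(px)[1:2])
  if (is.null(n_segments)) n_segments <- max(1L, n_px %/% 3000L)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > n_px)
    stop(sprintf("n_segments (%d) exceeds the pixel count (%d)",
                 n_segments, n_px))
  lab <- rgb_to_lab(px)
  sp <- slic_cpp(lab[, , 1], lab[, , 2], lab[, , 3],
                 as.integer(n_segments), compactness, as.integer(max_iter),
                 min_size_frac)
  attr(sp, "n_superpixels") <- max(sp) + 1L
  sp
}

n_superpixels <- function(sp) {
  s <- attr(sp, "n_superpixels")
  if (is.null(s)) max(sp) + 1L else s
}

# modal tissue class of each superpixel; ties break to the lowest code.
# Returns a vector indexed by superpixel id + 1.
superpixel_modal_class <- function(lab, sp) {
  S <- n_superpixels(sp)
  code_idx <- match(as.vector(lab), tissue_codes())     # 1..8, code order
  key <- as.vector(sp) * 8L + code_idx
  counts <- matrix(tabulate(key, nbins = 8L * S), nrow = 8L)
  tissue_codes()[apply(counts, 2L, which.max)]
}

#' Transfer pixel labels to superpixels by majority vote
#'
#' Every pixel of a superpixel receives the modal tissue class of that
#' superpixel; ties break to the lowest class code.
#'
#' @param pix a per-pixel tissue label map (integer matrix of codes).
#' @param sp a [slic_superpixels()] map of the same shape.
#' @return A per-superpixel label map (attribute
#'   `granularity = "superpixel"`).
#' @export
superpixel_majority_vote <- function(pix, sp) {
  if (!all(dim(pix) == dim(sp)))
    stop("label map and superpixel map dimensions differ")
  check_label_codes(pix)
  modal <- superpixel_modal_class(pix, sp)
  label_map(matrix(modal[as.vector(sp) + 1L], nrow(sp), ncol(sp)),
            granularity = "superpixel")
}

#' Render a tissue label map in its display colors
#'
#' @param lab an integer matrix of tissue class codes.
#' @return A [slide_image()] with each class painted in its palette
#'   color.
#' @export
render_labels <- function(lab) {
  check_label_codes(lab)
  cls <- tissue_classes()
  i <- match(as.vector(lab), cls$code)
  px <- array(0L, c(dim(lab), 3L))
  px[, , 1] <- cls$r[i]; px[, , 2] <- cls$g[i]; px[, , 3] <- cls$b[i]
  slide_image(px)
}

#' Recover class codes from a rendered label image
#'
#' Exact inverse of [render_labels()]; pixels whose color is not in the
#' palette raise an error.
#'
#' @param img a rendered [slide_image()].
#' @return An integer matrix of class codes.
#' @export
parse_rendered_labels <- function(img) {
  px <- as_pixel_array(img)
  cls <- tissue_classes()
  key <- px[, , 1] * 65536L + px[, , 2] * 256L + px[, , 3]
  pal <- cls$r * 65536L + cls$g * 256L + cls$b
  i <- match(as.vector(key), pal)
  if (anyNA(i)) stop("image contains colors outside the tissue palette")
  matrix(cls$code[i], nrow(key), ncol(key))
}

#' Mean intersection-over-union between two label maps
#'
#' Averaged over the classes present in either map; identical maps score
#' 1.
#'
#' @param pred,truth integer matrices of class codes, same shape.
#' @return A number in \[0, 1\].
#' @export
mean_iou <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  classes <- sort(union(unique(as.vector(pred)), unique(as.vector(truth))))
  ious <- vapply(classes, function(cl) {
    p <- pred == cl; t <- truth == cl
    u <- sum(p | t)
    if (u == 0) return(NA_real_)
    sum(p & t) / u
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}
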