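#' Construct a slide image
#'
#' The pipeline's raster container: an `H x W x 3` integer array of 8-bit
#' RGB values with an optional nominal objective power. Pixel coordinates
#' are 0-based with `x` indexing columns and `y` indexing rows; intervals
#' are half-open, so a [rect()] of width `w` at `x` covers columns
#' `x .. x+w-1`.
#'
#' @param pixels numeric or integer array `H x W x 3` with values in
#'   0..255, or an `H x W` matrix (replicated to three channels).
#' @param magnification optional nominal objective power of the scan
#'   (e.g. 40). Values other than 40 are accepted with a warning, since
#'   the feature extractors are tuned for x40 material.
#' @return An object of class `slide_image` with fields `pixels`,
#'   `width`, `height`, `magnification`.
#' @export
slide_image <- function(pixels, magnification = NULL) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("zero-area image: both dimensions must be >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  if (!is.null(magnification) && !isTRUE(all.equal(magnification, 40)))
    warning("nominal magnification is not x40; results may be inaccurate",
            call. = FALSE)
  structure(list(pixels = pixels,
                 width = dim(pixels)[2],
                 height = dim(pixels)[1],
                 magnification = magnification),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image %d x %d px%s>\n", x$width, x$height,
              if (is.null(x$magnification)) "" else
                sprintf(", x%g", x$magnification)))
  invisible(x)
}

#' @export
dim.slide_image <- function(x) dim(x$pixels)

is_slide_image <- function(x) inherits(x, "slide_image")

as_pixel_array <- function(img) {
  if (is_slide_image(img)) img$pixels else slide_image(img)$pixels
}

supported_raster_ext <- c("png", "jpg", "jpeg", "tif", "tiff", "bmp")

#' Load a raster image from disk
#'
#' Reads PNG, JPEG, BMP or TIFF into a [slide_image()]. Grayscale rasters
#' are replicated to three channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path path to the image file.
#' @param magnification optional nominal objective power recorded on the
#'   returned image.
#' @return A [slide_image()].
#' @export
load_image <- function(path, magnification = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% supported_raster_ext)
    stop(sprintf("unsupported image format '.%s' (supported: TIFF, JPEG, BMP, PNG)", ext))
  px <- tryCatch({
    if (ext == "bmp") {
      read_bmp(path)
    } else {
      im <- EBImage::readImage(path)
      a <- EBImage::imageData(im)
      if (length(dim(a)) == 2L) {
        a <- array(rep(a, 3L), c(dim(a), 3L))
      } else if (dim(a)[3] > 3L) {
        a <- a[, , 1:3, drop = FALSE]
      } else if (dim(a)[3] < 3L) {
        a <- array(rep(a[, , 1L], 3L), c(dim(a)[1:2], 3L))
      }
      aperm(round(a * 255), c(2, 1, 3)) # EBImage stores x-major
    }
  }, error = function(e) {
    stop(sprintf("unreadable '.%s' image file %s (%s)", ext, path,
                 conditionMessage(e)), call. = FALSE)
  })
  slide_image(px, magnification = magnification)
}

#' Save a raster image to disk
#'
#' Writes PNG, JPEG, BMP or TIFF. PNG and TIFF round-trip losslessly
#' through [load_image()].
#'
#' @param img a [slide_image()] or `H x W x 3` array.
#' @param path destination; the extension selects the format.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  px <- as_pixel_array(img)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% supported_raster_ext)
    stop(sprintf("unsupported image format '.%s'", ext))
  if (ext == "bmp") {
    write_bmp(px, path)
  } else {
    a <- aperm(px, c(2, 1, 3)) / 255
    EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path,
                        quality = 100L)
  }
  invisible(path)
}

# Minimal uncompressed 24-bit BMP (BITMAPINFOHEADER, bottom-up, BGR,
# rows padded to 4 bytes); no R package on hand decodes BMP.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop("not a BMP file")
  readBin(con, "integer", 2L, size = 4L)          # file size, reserved
  offset <- readBin(con, "integer", 1L, size = 4L)
  hdrsize <- readBin(con, "integer", 1L, size = 4L)
  if (hdrsize < 40L) stop("unsupported BMP header")
  w <- readBin(con, "integer", 1L, size = 4L)
  h <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 2L)          # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  comp <- readBin(con, "integer", 1L, size = 4L)
  if (bpp != 24L || comp != 0L)
    stop("only uncompressed 24-bit BMP is supported")
  seek(con, offset)
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  raw <- readBin(con, "raw", stride * abs(h))
  bottom_up <- h > 0L
  h <- abs(h)
  px <- array(0L, c(h, w, 3L))
  bytes <- matrix(as.integer(raw), nrow = stride)[seq_len(w * 3L), , drop = FALSE]
  for (ch in 1:3) {
    plane <- t(bytes[seq(4L - ch, w * 3L, by = 3L), , drop = FALSE]) # BGR
    px[, , ch] <- if (bottom_up) plane[h:1, , drop = FALSE] else plane
  }
  px
}

write_bmp <- function(px, path) {
  h <- dim(px)[1]; w <- dim(px)[2]
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  bytes <- matrix(0L, nrow = stride, ncol = h)
  flipped <- px[h:1, , , drop = FALSE]
  for (ch in 1:3)
    bytes[seq(4L - ch, w * 3L, by = 3L), ] <- t(flipped[, , ch])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(14L + 40L + stride * h), con, size = 4L)
  writeBin(0L, con, size = 4L)
  writeBin(54L, con, size = 4L)
  writeBin(40L, con, size = 4L)
  writeBin(as.integer(w), con, size = 4L)
  writeBin(as.integer(h), con, size = 4L)
  writeBin(1L, con, size = 2L)
  writeBin(24L, con, size = 2L)
  writeBin(rep(0L, 6L), con, size = 4L)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(path)
}

#' Load / save a tissue label map
#'
#' Label maps are single-channel PNG or TIFF rasters whose 8-bit gray
#' values are the integer tissue class codes.
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return `load_label_map()` returns an integer matrix of codes.
#' @export
load_label_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported label map format '.%s'", ext)))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  codes <- round(m * 255)
  storage.mode(codes) <- "integer"
  codes
}

#' @rdname load_label_map
#' @param map integer matrix of class codes (0..255).
#' @export
save_label_map <- function(map, path) {
  stopifnot(is.matrix(map), min(map) >= 0, max(map) <= 255)
  ext <- tolower(tools::file_ext(path))
  g <- map / 255
  switch(ext,
    png = png::writePNG(g, path),
    tif = ,
    tiff = tiff::writeTIFF(g, path, bits.per.sample = 8L),
    stop(sprintf("unsupported label map format '.%s'", ext)))
  invisible(path)
}

#' Axis-aligned pixel rectangle
#'
#' Rectangles are rows of a data frame with columns `x`, `y`, `w`, `h`;
#' `(x, y)` is the top-left corner, 0-based, and the covered interval is
#' half-open (`[x, x + w)` by `[y, y + h)`).
#'
#' @param x,y top-left corner (0-based).
#' @param w,h extent in pixels.
#' @return A one-row data frame of class `c("rect_df", "data.frame")`.
#' @export
rect <- function(x, y, w, h) {
  stopifnot(x >= 0, y >= 0, w >= 1, h >= 1)
  structure(data.frame(x = as.integer(x), y = as.integer(y),
                       w = as.integer(w), h = as.integer(h)),
            class = c("rect_df", "data.frame"))
}

rect_df <- function(x, y, w, h) {
  structure(data.frame(x = as.integer(x), y = as.integer(y),
                       w = as.integer(w), h = as.integer(h)),
            class = c("rect_df", "data.frame"))
}

#' Crop a rectangle out of an image
#' @param img a [slide_image()].
#' @param r a single [rect()] (one-row data frame).
#' @return A [slide_image()] of size `r$h x r$w`.
#' @export
crop_rect <- function(img, r) {
  px <- as_pixel_array(img)
  stopifnot(r$x >= 0, r$y >= 0,
            r$x + r$w <= dim(px)[2], r$y + r$h <= dim(px)[1])
  slide_image(px[(r$y + 1):(r$y + r$h), (r$x + 1):(r$x + r$w), , drop = FALSE])
}

# pairwise intersection area between two rect data frames (matrix)
rect_intersection_area <- function(a, b) {
  ix <- outer(a$x, b$x, pmax)
  iy <- outer(a$y, b$y, pmax)
  ix2 <- outer(a$x + a$w, b$x + b$w, pmin)
  iy2 <- outer(a$y + a$h, b$y + b$h, pmin)
  pmax(ix2 - ix, 0) * pmax(iy2 - iy, 0)
}

#' Tile an image into non-overlapping visual words
#'
#' Partitions the raster into a grid of `word_size` squares anchored at
#' the origin. Partial tiles at the right/bottom border are discarded, so
#' the count is `floor(W / word_size) * floor(H / word_size)`.
#'
#' @param img a [slide_image()] (or anything with `height`/`width`), used
#'   only for its dimensions.
#' @param word_size side of the square word in pixels (default 120).
#' @return A rect data frame in row-major order (x varying fastest).
#' @export
tile_words <- function(img, word_size = 120) {
  stopifnot(word_size >= 1)
  h <- if (is_slide_image(img)) img$height else dim(img)[1]
  w <- if (is_slide_image(img)) img$width else dim(img)[2]
  nx <- w %/% word_size
  ny <- h %/% word_size
  if (nx < 1 || ny < 1) return(rect_df(integer(0), integer(0), integer(0), integer(0)))
  g <- expand.grid(x = (seq_len(nx) - 1L) * word_size,
                   y = (seq_len(ny) - 1L) * word_size)
  rect_df(g$x, g$y, word_size, word_size)
}

window_starts <- function(extent, window, stride) {
  starts <- seq.int(0L, by = stride, length.out = max(1L, (extent - window) %/% stride + 1L))
  last <- extent - window
  if (starts[length(starts)] < last) starts <- c(starts, last)
  as.integer(starts)
}

#' Enumerate sliding analysis windows
#'
#' Square windows of side `window` advance by `window - overlap` in both
#' axes, starting at the origin. When the final stride position would
#' overrun the image, one last window is clamped to end exactly at the
#' border, so every pixel is covered. An image smaller than `window` in
#' either dimension yields a single whole-image window, flagged via the
#' `undersized` attribute.
#'
#' @param img image (used for its dimensions).
#' @param window window side in pixels (default 3600).
#' @param overlap overlap between successive windows in pixels (default
#'   2400); must satisfy `0 <= overlap < window`.
#' @return A rect data frame; attribute `undersized` is `TRUE` when the
#'   image could not fit one full window.
#' @export
sliding_windows <- function(img, window = 3600, overlap = 2400) {
  stopifnot(overlap >= 0, overlap < window)
  h <- if (is_slide_image(img)) img$height else dim(img)[1]
  w <- if (is_slide_image(img)) img$width else dim(img)[2]
  if (h < window || w < window) {
    out <- rect_df(0L, 0L, w, h)
    attr(out, "undersized") <- TRUE
    return(out)
  }
  stride <- window - overlap
  g <- expand.grid(x = window_starts(w, window, stride),
                   y = window_starts(h, window, stride))
  out <- rect_df(g$x, g$y, window, window)
  attr(out, "undersized") <- FALSE
  out
}
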