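#' Configuration for the tissue pixel classifier
#'
#' Two interchangeable backends share one training/prediction interface:
#' `"classical"` is a deterministic per-pixel classifier on color and
#' local-texture features (random forest); `"espnet"` is a small
#' encoder-decoder network with efficient spatial-pyramid (dilated)
#' convolution blocks, an input-aware encoder, dense encoder-to-decoder
#' skips and a multi-path decoder head (see [build_segmentation_model()]).
#'
#' @param backend `"classical"` or `"espnet"`.
#' @param patch_size side of the square training/inference patch
#'   (default 384; must be divisible by 4 for the espnet backend).
#' @param classes tissue class codes (default the 8-class palette).
#' @param num_trees,max_pixels_per_patch classical backend: forest size
#'   and per-patch training pixel sample.
#' @param width,learning_rate espnet backend: base channel width and
#'   Adam step size.
#' @param init_seed seed for espnet weight initialization.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(backend = c("classical", "espnet"),
                                patch_size = 384,
                                classes = tissue_codes(),
                                num_trees = 100,
                                max_pixels_per_patch = 2000,
                                width = 8,
                                learning_rate = 1e-2,
                                init_seed = 1) {
  backend <- match.arg(backend)
  if (length(classes) < 2L) stop("need at least two classes")
  if (backend == "espnet" && patch_size %% 4 != 0)
    stop("patch_size must be divisible by 4 for the espnet backend")
  if (width < 1) stop("invalid config: width must be >= 1")
  structure(list(backend = backend, patch_size = as.integer(patch_size),
                 classes = as.integer(classes),
                 num_trees = num_trees,
                 max_pixels_per_patch = max_pixels_per_patch,
                 width = as.integer(width), learning_rate = learning_rate,
                 init_seed = init_seed),
            class = "segmentation_config")
}

#' Build an (untrained) tissue segmentation model
#'
#' For the espnet backend this instantiates the encoder-decoder: an
#' ESP-style block (1x1 reduction feeding parallel dilated 3x3
#' convolutions) at full resolution, a downsampling stage that also
#' ingests a downsampled copy of the RGB input (input-aware encoding), a
#' decoder that concatenates upsampled deep features with every
#' shallower encoder stage and the raw input (dense connection pattern),
#' and a final score that sums class maps from three decoding paths.
#' Output has one channel per tissue class at input resolution. The
#' classical backend stores its feature and forest configuration; the
#' forest itself is fitted by [train_pixel_classifier()].
#'
#' @param config a [segmentation_config()].
#' @return An object of class `pixel_classifier_model`.
#' @export
build_segmentation_model <- function(config = segmentation_config()) {
  if (!inherits(config, "segmentation_config"))
    stop("`config` must come from segmentation_config()")
  params <- if (config$backend == "espnet")
    espnet_init(width = config$width, n_classes = length(config$classes),
                seed = config$init_seed)
  else NULL
  structure(list(config = config, backend = config$backend,
                 classes = config$classes, params = params,
                 forest = NULL, loss_trace = NULL, seed = NULL),
            class = "pixel_classifier_model")
}

#' @export
print.pixel_classifier_model <- function(x, ...) {
  cat(sprintf("<pixel_classifier_model backend=%s, %d classes, %s>\n",
              x$backend, length(x$classes),
              if (is.null(x$forest) && is.null(x$loss_trace)) "untrained"
              else "trained"))
  invisible(x)
}

check_patch_labels <- function(patches, classes) {
  for (p in patches) {
    if (is.null(p$image) || is.null(p$labels))
      stop("each patch needs `image` and `labels`")
    bad <- setdiff(unique(as.vector(p$labels)), classes)
    if (length(bad) > 0L)
      stop("label code(s) outside the class set: ",
           paste(sort(bad), collapse = ", "))
  }
  invisible(patches)
}

# per-pixel feature matrix: RGB, Lab, H&E concentrations, local mean and
# sd of L in a 5x5 box
pixel_features <- function(img, stains = he_reference_stains()) {
  px <- as_pixel_array(img)
  lab <- rgb_to_lab(px)
  he <- deconvolve(px, stains)
  L <- lab[, , 1]
  box <- matrix(1 / 25, 5, 5)
  mu <- EBImage::filter2(L, box)
  mu2 <- EBImage::filter2(L^2, box)
  sdv <- sqrt(pmax(mu2 - mu^2, 0))
  cbind(r = as.numeric(px[, , 1]) / 255,
        g = as.numeric(px[, , 2]) / 255,
        b = as.numeric(px[, , 3]) / 255,
        L = as.numeric(lab[, , 1]), a = as.numeric(lab[, , 2]),
        bb = as.numeric(lab[, , 3]),
        h = as.numeric(he[, , 1]), e = as.numeric(he[, , 2]),
        lmu = as.numeric(mu), lsd = as.numeric(sdv))
}

#' Train the tissue pixel classifier
#'
#' Minimizes per-pixel multiclass error on the supplied annotated
#' patches. Training is deterministic given `seed` (single-threaded
#' forest; fixed shuffling for the network). Label patches may only use
#' codes from the model's class set; anything else (including the
#' reserved code 1) raises an error naming the code.
#'
#' @param patches list of `list(image = , labels = )` pairs; `labels` is
#'   an integer matrix of tissue codes matching the image shape.
#' @param model a [build_segmentation_model()] model.
#' @param epochs training epochs (espnet backend; the classical forest
#'   fits in one pass and ignores it).
#' @param seed RNG seed.
#' @return The trained model, with a `loss_trace`.
#' @export
train_pixel_classifier <- function(patches, model, epochs = 30, seed = 1) {
  stopifnot(inherits(model, "pixel_classifier_model"), length(patches) >= 1L)
  check_patch_labels(patches, model$classes)
  if (model$backend == "classical") {
    set.seed(seed)
    feats <- list(); labs <- list()
    for (p in patches) {
      f <- pixel_features(p$image)
      y <- as.vector(p$labels)
      n <- length(y)
      take <- min(model$config$max_pixels_per_patch, n)
      i <- if (take < n) sample.int(n, take) else seq_len(n)
      feats[[length(feats) + 1L]] <- f[i, , drop = FALSE]
      labs[[length(labs) + 1L]] <- y[i]
    }
    x <- do.call(rbind, feats)
    y <- factor(unlist(labs), levels = model$classes)
    fit <- ranger::ranger(x = x, y = y, num.trees = model$config$num_trees,
                          seed = seed, num.threads = 1L)
    model$forest <- fit
    model$loss_trace <- fit$prediction.error
  } else {
    trained <- espnet_train(patches, model, epochs = epochs, seed = seed)
    model$params <- trained$params
    model$loss_trace <- trained$loss_trace
  }
  model$seed <- seed
  model
}

#' Predict per-pixel tissue labels
#'
#' Applies the trained classifier over the whole image. The espnet
#' backend tiles the image into model-sized patches with 50% overlap,
#' averages the class scores where tiles overlap and takes the per-pixel
#' argmax; images smaller than the patch are reflection-padded. The
#' classical backend scores every pixel directly.
#'
#' @param img a [slide_image()].
#' @param model a trained model.
#' @return A per-pixel tissue label map (integer matrix of codes).
#' @export
predict_pixel_labels <- function(img, model) {
  stopifnot(inherits(model, "pixel_classifier_model"))
  px <- as_pixel_array(img)
  if (model$backend == "classical") {
    if (is.null(model$forest)) stop("model is not trained")
    f <- pixel_features(px)
    pr <- stats::predict(model$forest, data = as.data.frame(f),
                         num.threads = 1L)
    codes <- as.integer(as.character(pr$predictions))
    return(label_map(matrix(codes, dim(px)[1], dim(px)[2]),
                     granularity = "pixel"))
  }
  if (is.null(model$loss_trace) && is.null(model$params))
    stop("model is not trained")
  label_map(espnet_predict(px, model), granularity = "pixel")
}
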