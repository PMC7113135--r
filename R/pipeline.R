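#' Pipeline configuration
#'
#' Collects the geometry, model paths and module parameters of a full
#' detect / segment / diagnose run. Defaults follow the reference
#' operating point for x40 whole-slide material: 120 px words, 3600 px
#' windows with 2400 px overlap.
#'
#' @param word_size,window,overlap ROI detection geometry (pixels).
#' @param k visual dictionary size.
#' @param n_segments_per_px SLIC target density (superpixels per pixel;
#'   default 1/3000).
#' @param compactness SLIC compactness.
#' @param n_layers structure-feature layers per side.
#' @param features diagnosis feature set: `"both"`, `"midlevel"` or
#'   `"structure"`.
#' @param min_duct_superpixels duct size threshold.
#' @param seed base RNG seed for all training stages.
#' @param models named list of model bundle paths (`roi`, `seg`, `dx`).
#' @param out_dir output directory for [run_pipeline()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(word_size = 120, window = 3600, overlap = 2400,
                            k = 64, n_segments_per_px = 1 / 3000,
                            compactness = 10, n_layers = 2,
                            features = "both", min_duct_superpixels = 3,
                            seed = 1,
                            models = list(roi = NULL, seg = NULL, dx = NULL),
                            out_dir = tempfile("wsidiag_run_")) {
  stopifnot(word_size >= 1, overlap >= 0, overlap < window)
  structure(list(word_size = word_size, window = window, overlap = overlap,
                 k = k, n_segments_per_px = n_segments_per_px,
                 compactness = compactness, n_layers = n_layers,
                 features = features,
                 min_duct_superpixels = min_duct_superpixels,
                 seed = seed, models = models, out_dir = out_dir),
            class = "pipeline_config")
}

#' Save / load a versioned model bundle
#'
#' Bundles carry the fitted model, its stage name and the configuration
#' used to train it. Serialization contains no timestamps, so identical
#' training runs produce byte-identical bundle files.
#'
#' @param model fitted model object.
#' @param stage one of `"roi"`, `"seg"`, `"dx"`.
#' @param config the [pipeline_config()] used for training.
#' @param path destination `.rds` path.
#' @return `save_model_bundle()` returns `path`; `load_model_bundle()`
#'   the bundle list.
#' @export
save_model_bundle <- function(model, stage, config, path) {
  bundle <- list(format_version = 1L, stage = stage, model = model,
                 config = config)
  saveRDS(bundle, path, compress = FALSE)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop("configuration error: model bundle not found: ",
         if (is.null(path)) "<unset>" else path)
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, 1L))
    stop("unsupported model bundle version in ", path)
  bundle
}

#' Train the ROI detector on synthetic or annotated slides
#'
#' Builds the visual dictionary from the words of all training slides
#' and fits the window classifier from windows inside (positive) and
#' near (negative) the ground-truth ROI rectangles.
#'
#' @param slides list of `list(image = , roi_rects = )`.
#' @param config a [pipeline_config()].
#' @return A list (`roi_model`) with `dict` and `clf`.
#' @export
train_roi_detector <- function(slides, config = pipeline_config()) {
  all_desc <- list(); all_bags <- list(); all_lab <- list()
  for (s in slides) {
    words <- tile_words(s$image, config$word_size)
    desc <- extract_word_descriptors(s$image, words)
    all_desc[[length(all_desc) + 1L]] <- desc
  }
  dict <- build_dictionary(do.call(rbind, all_desc), k = config$k,
                           seed = config$seed)
  for (s in slides) {
    words <- tile_words(s$image, config$word_size)
    desc <- extract_word_descriptors(s$image, words)
    assign <- assign_words(desc, dict)
    wins <- sliding_windows(s$image, config$window, config$overlap)
    pairs <- make_training_pairs(s$roi_rects, wins,
                                 near_margin = config$window)
    idx <- c(pairs$positive, pairs$negative)
    if (length(idx) == 0L) next
    bags <- t(vapply(idx, function(i)
      bag_histogram(wins[i, ], words, assign, dict$k)$hist,
      numeric(dict$k)))
    all_bags[[length(all_bags) + 1L]] <- bags
    all_lab[[length(all_lab) + 1L]] <-
      rep(c(TRUE, FALSE), c(length(pairs$positive), length(pairs$negative)))
  }
  bags <- do.call(rbind, all_bags)
  labs <- unlist(all_lab)
  clf <- train_window_classifier(bags[labs, , drop = FALSE],
                                 bags[!labs, , drop = FALSE],
                                 seed = config$seed)
  list(dict = dict, clf = clf)
}

#' Train every stage with data present in a manifest
#'
#' The manifest may hold any subset of: `slides` (`image` +
#' `roi_rects`) for the ROI detector, `patches` (`image` + `labels`)
#' for the pixel classifier, and `rois` (labeled `synthetic_roi`s or
#' `list(features, class)`) for the diagnosis cascade. Only the stages
#' with data are trained; bundles are written under `dir`.
#'
#' @param manifest list as above.
#' @param config a [pipeline_config()].
#' @param dir directory for the model bundles.
#' @param backend segmentation backend (default `"classical"`).
#' @param epochs training epochs for the espnet backend.
#' @param patch_size segmentation patch size; defaults to the patch
#'   dimensions present in the manifest.
#' @return Named list of bundle paths for the trained stages.
#' @export
train_all <- function(manifest, config = pipeline_config(), dir = config$out_dir,
                      backend = "classical", epochs = 30, patch_size = NULL) {
  has <- function(x) !is.null(manifest[[x]]) && length(manifest[[x]]) > 0L
  if (!has("slides") && !has("patches") && !has("rois"))
    stop("nothing to train: the manifest lists no slides, patches or rois")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (has("slides")) {
    roi_model <- train_roi_detector(manifest$slides, config)
    paths$roi <- file.path(dir, "roi_model.rds")
    save_model_bundle(roi_model, "roi", config, paths$roi)
  }
  if (has("patches")) {
    if (is.null(patch_size))
      patch_size <- nrow(manifest$patches[[1]]$labels)
    seg_cfg <- segmentation_config(backend = backend,
                                   patch_size = patch_size)
    model <- build_segmentation_model(seg_cfg)
    model <- train_pixel_classifier(manifest$patches, model,
                                    epochs = epochs, seed = config$seed)
    paths$seg <- file.path(dir, "seg_model.rds")
    save_model_bundle(model, "seg", config, paths$seg)
  }
  if (has("rois")) {
    feats <- list(); labs <- character(0)
    for (r in manifest$rois) {
      if (!is.null(r$features)) {
        feats[[length(feats) + 1L]] <- r$features
      } else {
        sp <- slic_superpixels(r$image,
                               n_segments = max(1L, floor(prod(dim(r$truth)) *
                                                          config$n_segments_per_px)),
                               compactness = config$compactness)
        lab <- superpixel_majority_vote(r$truth, sp)
        feats[[length(feats) + 1L]] <-
          roi_features(lab, sp, features = config$features,
                       n_layers = config$n_layers,
                       min_duct_superpixels = config$min_duct_superpixels)
      }
      labs <- c(labs, r$class)
    }
    cascade <- train_cascade(do.call(rbind, feats), labs, seed = config$seed)
    paths$dx <- file.path(dir, "dx_model.rds")
    save_model_bundle(cascade, "dx", config, paths$dx)
  }
  paths
}

write_features_csv <- function(features, path) {
  df <- data.frame(feature = names(features),
                   value = sprintf("%.10g", as.numeric(features)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Run the full pipeline on a slide
#'
#' Detects ROIs, segments each into the 8 tissue classes (SLIC
#' superpixels + pixel classifier + majority vote) and classifies each
#' with the diagnosis cascade. All outputs land under
#' `config$out_dir`: the red-box overlay, per-ROI crops, label maps
#' (raw codes and rendered colors), feature CSVs, diagnosis JSONs and a
#' run manifest with parameters, seeds and model hashes. Failures on
#' individual ROIs are logged in the manifest and skipped. The input is
#' never modified.
#'
#' @param slide a [slide_image()] or a path readable by [load_image()].
#' @param config a [pipeline_config()] whose `models` entries all point
#'   at existing bundles.
#' @param roi_index optional subset of detected ROI indices to process
#'   (default: all).
#' @return The run manifest (also written as `manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(slide, config, roi_index = NULL) {
  for (stage in c("roi", "seg", "dx"))
    if (is.null(config$models[[stage]]) || !file.exists(config$models[[stage]]))
      stop("configuration error: missing model bundle for stage '", stage, "'")
  roi_model <- load_model_bundle(config$models$roi)$model
  seg_model <- load_model_bundle(config$models$seg)$model
  dx_model <- load_model_bundle(config$models$dx)$model
  if (is.character(slide)) slide <- load_image(slide)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  det <- detect_rois(slide, roi_model$dict, roi_model$clf,
                     word_size = config$word_size, window = config$window,
                     overlap = config$overlap)
  save_image(det$overlay, file.path(config$out_dir, "overlay.png"))
  idx <- seq_len(nrow(det$boxes))
  if (!is.null(roi_index)) idx <- intersect(idx, roi_index)
  results <- list(); failures <- list()
  for (i in idx) {
    res <- tryCatch({
      roi_img <- det$rois[[i]]
      tag <- sprintf("roi_%02d", i)
      save_image(roi_img, file.path(config$out_dir, paste0(tag, ".png")))
      sp <- slic_superpixels(roi_img,
                             n_segments = max(1L, floor(roi_img$width *
                                                        roi_img$height *
                                                        config$n_segments_per_px)),
                             compactness = config$compactness)
      pix <- predict_pixel_labels(roi_img, seg_model)
      lab <- superpixel_majority_vote(pix, sp)
      save_label_map(lab, file.path(config$out_dir, paste0(tag, "_labels.png")))
      save_image(render_labels(lab),
                 file.path(config$out_dir, paste0(tag, "_rendered.png")))
      feats <- roi_features(lab, sp, features = config$features,
                            n_layers = config$n_layers,
                            min_duct_superpixels = config$min_duct_superpixels)
      write_features_csv(feats,
                         file.path(config$out_dir, paste0(tag, "_features.csv")))
      dx <- classify_diagnosis(feats, dx_model)
      jsonlite::write_json(list(roi = i, box = as.list(det$boxes[i, ]),
                                diagnosis = dx$label,
                                scores = as.list(dx$scores)),
                           file.path(config$out_dir, paste0(tag, "_diagnosis.json")),
                           auto_unbox = TRUE, digits = NA)
      list(roi = i, box = as.list(det$boxes[i, ]), diagnosis = dx$label,
           scores = as.list(dx$scores))
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        list(roi = i, error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("wsidiag")),
    parameters = config[c("word_size", "window", "overlap", "k",
                          "n_segments_per_px", "compactness", "n_layers",
                          "features", "min_duct_superpixels", "seed")],
    model_hashes = lapply(config$models,
                          function(p) unname(tools::md5sum(p))),
    n_rois_detected = nrow(det$boxes),
    rois = results, failures = failures)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
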