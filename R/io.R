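# Image and artifact IO: PNG/TIFF/JPG reading, mask and probability-map
# writing, dataset directory layout, YAML run configuration and checkpoints.

#' Read an image file as a numeric array in \[0, 1\]
#'
#' PNG, TIFF and JPEG are supported; 16-bit inputs are rescaled to \[0, 1\]
#' by their readers.  Returns an (H, W) matrix for grayscale or an
#' (H, W, channels) array.
#'
#' @param path file path.
#' @return numeric matrix or array in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = as.array(EBImage::readImage(path)),
    stop("unsupported image format: .", ext)
  )
  if (ext %in% c("jpg", "jpeg")) {
    # EBImage stores (x, y[, c]); transpose back to (row, col)
    img <- if (length(dim(img)) == 3L) aperm(img, c(2L, 1L, 3L)) else t(img)
  }
  img
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask binary (H, W) matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(pmin(pmax(mask, 0), 1), path)
  invisible(path)
}

#' Write a probability map as a 32-bit float TIFF
#'
#' @param prob (H, W) matrix in \[0, 1\].
#' @param path output path.
#' @export
write_prob_tiff <- function(prob, path) {
  tiff::writeTIFF(prob, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a phantom dataset to a directory
#'
#' Layout: `images/phantom_%04d.png`, `masks/phantom_%04d.png`, and a
#' `manifest.csv` recording the per-item seed and spec fields — the layout
#' the training CLI consumes.
#'
#' @param dataset a list from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
save_phantom_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    it <- dataset[[i]]
    nm <- sprintf("phantom_%04d.png", i)
    png::writePNG(it$image, file.path(dir, "images", nm))
    write_mask_png(it$mask, file.path(dir, "masks", nm))
    sp <- it$spec
    data.frame(file = nm, seed = sp$seed, H = sp$size[1], W = sp$size[2],
               n_vessels = sp$n_vessels, width_min = sp$width_range[1],
               width_max = sp$width_range[2], tortuosity = sp$tortuosity,
               vessel_intensity = sp$vessel_intensity,
               background_intensity = sp$background_intensity,
               noise_sigma = sp$noise_sigma, blur_sigma = sp$blur_sigma,
               preset = sp$preset)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Load an image/mask dataset from a directory
#'
#' Expects the layout written by [save_phantom_dataset()]: congruent file
#' names under `images/` and `masks/`.
#'
#' @param dir dataset directory.
#' @return a list of `list(image = , mask = )` pairs.
#' @export
load_image_dataset <- function(dir) {
  files <- sort(list.files(file.path(dir, "images")))
  if (length(files) == 0L) stop("no images found under ", dir)
  lapply(files, function(f) {
    img <- rgb_to_gray(read_image(file.path(dir, "images", f)))
    msk <- rgb_to_gray(read_image(file.path(dir, "masks", f)))
    list(image = img, mask = (msk > 0.5) * 1)
  })
}

# ---- checkpoints -------------------------------------------------------------

CKPT_VERSION <- 1L

#' Save a model checkpoint
#'
#' A single file holding the weights, batch-norm buffers, configuration
#' snapshot and seed; [load_checkpoint()] restores it bit-exactly.
#'
#' @param model a `dnlnet`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = CKPT_VERSION,
               config = model$config,
               weights = model$weights,
               bn = lapply(model$bn, function(e) list(mean = e$mean,
                                                      var = e$var)),
               seed = model$seed, trained = model$trained,
               history = model$history),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return the restored `dnlnet`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != CKPT_VERSION)
    stop("unsupported checkpoint version: ", ck$version)
  bn <- lapply(ck$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$mean <- st$mean; e$var <- st$var
    e
  })
  structure(list(config = ck$config, weights = ck$weights, bn = bn,
                 seed = ck$seed, trained = ck$trained, history = ck$history),
            class = "dnlnet")
}

# ---- run configuration -------------------------------------------------------

#' Read a YAML run configuration, merged over defaults
#'
#' @param path YAML file (optional; `NULL` gives the defaults).
#' @param defaults named list of defaults to merge under the file values.
#' @return a named list.
#' @export
read_run_config <- function(path = NULL, defaults = list()) {
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    over <- yaml::read_yaml(path)
    for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Serialise a run's configuration snapshot to JSON
#'
#' @param cfg named list.
#' @param path output JSON path.
#' @export
write_config_snapshot <- function(cfg, path) {
  drop_class <- function(x) {
    if (is.list(x)) { x <- lapply(x, drop_class); attributes(x) <- list(names = names(x)) }
    x
  }
  jsonlite::write_json(drop_class(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
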