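# Full DNL-Net assembly: a U-shaped encoder-decoder.
#
# encoder   n_stages of [3x3 conv -> BN -> ReLU] x2, 2x2 max-pool between
#           stages, channel width doubling per stage;
# bottleneck two Conv+BN+ReLU widening convs followed by the RSEP module;
# decoder   per stage, MFF fusion of the deep feature (refined by its DNL
#           block) with the matching encoder skip, then [conv -> BN -> ReLU] x2;
# head      1x1 convolution + sigmoid giving per-pixel vessel probabilities.

#' DNL-Net configuration
#'
#' @param n_stages number of encoder/decoder stages (input H, W must be
#'   divisible by `2^n_stages`).
#' @param base_width channels of the first encoder stage; doubles per stage.
#' @param in_channels input image channels.
#' @param out_classes output channels of the probability head (1: sigmoid
#'   vessel-probability map).
#' @param dnl_rate descriptor bottleneck rate of the DNL blocks (clamped per
#'   stage to the largest divisor of the stage width).
#' @param dnl_se_r SE-tail reduction of the DNL blocks (clamped likewise).
#' @param dnl_gate activation bounding the DNL channel weights.
#' @param mff an [mff_config()].
#' @param rsep an [rsep_config()].
#' @param bn_momentum momentum of the batch-norm running statistics.
#' @param bn_eps batch-norm variance stabiliser.
#' @param preset `"paper"` (4 stages from width 64, the full-size network) or
#'   `"test"` (2 stages from width 8, a small preset for CPU-scale runs);
#'   explicit arguments override the preset.
#' @return a list of class `dnlnet_config`.
#' @export
dnlnet_config <- function(n_stages = NULL, base_width = NULL, in_channels = 1L,
                          out_classes = 1L, dnl_rate = 4L, dnl_se_r = 16L,
                          dnl_gate = "sigmoid", mff = mff_config(),
                          rsep = rsep_config(), bn_momentum = 0.1,
                          bn_eps = 1e-5, preset = c("paper", "test")) {
  preset <- match.arg(preset)
  if (is.null(n_stages)) n_stages <- if (preset == "test") 2L else 4L
  if (is.null(base_width)) base_width <- if (preset == "test") 8L else 64L
  stopifnot(n_stages >= 1, base_width >= 1, in_channels >= 1, out_classes >= 1)
  structure(list(n_stages = as.integer(n_stages),
                 base_width = as.integer(base_width),
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 dnl_rate = as.integer(dnl_rate),
                 dnl_se_r = as.integer(dnl_se_r),
                 dnl_gate = dnl_gate, mff = mff, rsep = rsep,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 preset = preset),
            class = "dnlnet_config")
}

stage_widths <- function(cfg) cfg$base_width * 2L^(seq_len(cfg$n_stages) - 1L)

conv_bn_init <- function(cout, cin) {
  list(conv = conv_init(cout, cin, 3L),
       bn = list(gamma = rep(1, cout), beta = rep(0, cout)))
}

bn_state_new <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, C)
  e$var <- rep(1, C)
  e
}

#' Build a DNL-Net model
#'
#' Weight initialisation is fully deterministic given `seed` (He-style normal
#' draws per layer from derived sub-seeds).
#'
#' @param config a [dnlnet_config()].
#' @param seed integer seed controlling initialisation.
#' @return an object of class `dnlnet`: configuration, nested weight lists,
#'   batch-norm running-statistic buffers, and (after training) a history.
#' @export
dnl_net <- function(config = dnlnet_config(preset = "test"), seed = 1L) {
  cfg <- config
  cnt <- 0L
  nxt <- function() {
    cnt <<- cnt + 1L
    (as.integer(seed) %% 100000L) * 17389L + cnt * 7919L
  }
  widths <- stage_widths(cfg)
  B <- cfg$base_width * 2L^cfg$n_stages
  bn <- list()

  encoder <- vector("list", cfg$n_stages)
  cin <- cfg$in_channels
  for (s in seq_len(cfg$n_stages)) {
    st <- list()
    st$c1 <- with_seed(nxt(), conv_bn_init(widths[s], cin))
    st$c2 <- with_seed(nxt(), conv_bn_init(widths[s], widths[s]))
    encoder[[s]] <- st
    bn[[paste0("enc", s, ".bn1")]] <- bn_state_new(widths[s])
    bn[[paste0("enc", s, ".bn2")]] <- bn_state_new(widths[s])
    cin <- widths[s]
  }

  bottleneck <- list(
    c1 = with_seed(nxt(), conv_bn_init(B, widths[cfg$n_stages])),
    c2 = with_seed(nxt(), conv_bn_init(B, B)),
    rsep = rsep_weights(B, cfg$rsep, seed = nxt())
  )
  bn[["bot.bn1"]] <- bn_state_new(B)
  bn[["bot.bn2"]] <- bn_state_new(B)

  decoder <- vector("list", cfg$n_stages)
  cdeep <- B
  for (s in rev(seq_len(cfg$n_stages))) {
    cskip <- widths[s]
    dnl <- dnl_weights(cdeep, rate = pick_reduction(cdeep, cfg$dnl_rate),
                       se_r = pick_reduction(cdeep, cfg$dnl_se_r),
                       gate = cfg$dnl_gate, seed = nxt())
    st <- list(
      mff = mff_weights(cdeep, cskip, cfg$mff, dnl = dnl, seed = nxt()),
      c1 = with_seed(nxt(), conv_bn_init(cskip, cskip)),
      c2 = with_seed(nxt(), conv_bn_init(cskip, cskip))
    )
    decoder[[s]] <- st
    bn[[paste0("dec", s, ".bn1")]] <- bn_state_new(cskip)
    bn[[paste0("dec", s, ".bn2")]] <- bn_state_new(cskip)
    cdeep <- cskip
  }

  head <- with_seed(nxt(), conv_init(cfg$out_classes, cfg$base_width, 1L))

  structure(list(config = cfg,
                 weights = list(encoder = encoder, bottleneck = bottleneck,
                                decoder = decoder, head = head),
                 bn = bn, seed = as.integer(seed),
                 trained = FALSE, history = NULL),
            class = "dnlnet")
}

# ---- weight-tree utilities ---------------------------------------------------

# recurse over the weight tree applying f(leaf, path) to every double leaf;
# "cfg" subtrees hold hyper-parameters, not weights
map_wleaves <- function(x, f, path = "w") {
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (is.null(nms) || nms[i] == "") as.character(i) else nms[i]
      if (identical(nm, "cfg")) next
      x[[i]] <- map_wleaves(x[[i]], f, paste(path, nm, sep = "."))
    }
    x
  } else if (is.double(x)) f(x, path) else x
}

flatten_weights <- function(w) {
  acc <- new.env(parent = emptyenv())
  map_wleaves(w, function(leaf, path) { assign(path, leaf, envir = acc); leaf })
  as.list(acc, sorted = TRUE)
}

#' Number of trainable parameters of a model
#' @param model a `dnlnet` object.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(flatten_weights(model$weights), length, 0L))
}

# ---- forward pass ------------------------------------------------------------

conv_bn_relu <- function(h, cw, state, training, cfg) {
  h <- ad_conv2d(h, cw$conv$w, cw$conv$b, pad = 1L)
  h <- ad_batchnorm(h, cw$bn$gamma, cw$bn$beta, state, training,
                    momentum = cfg$bn_momentum, eps = cfg$bn_eps)
  ad_relu(h)
}

# wts: the weight tree with arrays or nodes at the leaves
net_forward <- function(wts, bn, x, cfg, training) {
  n <- cfg$n_stages
  skips <- vector("list", n)
  h <- x
  for (s in seq_len(n)) {
    st <- wts$encoder[[s]]
    h <- conv_bn_relu(h, st$c1, bn[[paste0("enc", s, ".bn1")]], training, cfg)
    h <- conv_bn_relu(h, st$c2, bn[[paste0("enc", s, ".bn2")]], training, cfg)
    skips[[s]] <- h
    h <- ad_maxpool2(h)
  }
  h <- conv_bn_relu(h, wts$bottleneck$c1, bn[["bot.bn1"]], training, cfg)
  h <- conv_bn_relu(h, wts$bottleneck$c2, bn[["bot.bn2"]], training, cfg)
  h <- rsep_node(h, wts$bottleneck$rsep)
  for (s in rev(seq_len(n))) {
    st <- wts$decoder[[s]]
    h <- mff_node(h, skips[[s]], st$mff)
    h <- conv_bn_relu(h, st$c1, bn[[paste0("dec", s, ".bn1")]], training, cfg)
    h <- conv_bn_relu(h, st$c2, bn[[paste0("dec", s, ".bn2")]], training, cfg)
  }
  ad_sigmoid(ad_conv2d(h, wts$head$w, wts$head$b))
}

check_input_dims <- function(cfg, d) {
  mult <- 2L^cfg$n_stages
  if (d[2] != cfg$in_channels)
    stop("input has ", d[2], " channels; the model expects ", cfg$in_channels)
  if (d[3] %% mult != 0L || d[4] %% mult != 0L)
    stop("input spatial dims (", d[3], "x", d[4],
         ") must be divisible by 2^n_stages = ", mult)
}

#' Forward pass of a DNL-Net
#'
#' Runs in evaluation mode (batch-norm running statistics).
#'
#' @param model a `dnlnet` object.
#' @param image a (C, H, W) array, or (H, W) matrix for single-channel
#'   models; H and W must be divisible by `2^n_stages`.
#' @return a (out_classes, H, W) array of probabilities in \[0, 1\].
#' @export
dnlnet_forward <- function(model, image) {
  if (is.matrix(image)) image <- array(image, c(1L, dim(image)))
  check_fmap(image, "image")
  x4 <- fmap4(image)
  check_input_dims(model$config, dim(x4))
  out <- net_forward(model$weights, model$bn, ad_const(x4), model$config,
                     training = FALSE)
  fmap3(out$value)
}

# batched forward (N,C,H,W) returning the output node; used by training
net_forward_batch <- function(model, xbatch, training, wts = model$weights) {
  check_input_dims(model$config, dim(xbatch))
  net_forward(wts, model$bn, ad_const(xbatch), model$config, training)
}

# ---- S3 methods --------------------------------------------------------------

#' @export
print.dnlnet <- function(x, ...) {
  cfg <- x$config
  cat("DNL-Net (", cfg$n_stages, " stages, base width ", cfg$base_width,
      ", ", format(n_params(x), big.mark = ","), " parameters)\n", sep = "")
  cat("  input channels: ", cfg$in_channels, "; output classes: ",
      cfg$out_classes, "\n", sep = "")
  cat("  RSEP dilations: ", paste(cfg$rsep$dilations, collapse = "/"),
      "; MFF upsampling: ", cfg$mff$upsample_mode, "\n", sep = "")
  cat(if (x$trained) "  trained" else "  untrained", "\n")
  invisible(x)
}

#' @export
summary.dnlnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat("Training: ", nrow(h), " epochs; final lr ",
        signif(h$lr[nrow(h)], 3), "\n", sep = "")
    cat("  best validation soft Dice: ", round(max(h$val_dice), 4),
        " (epoch ", which.max(h$val_dice), ")\n", sep = "")
  }
  invisible(object)
}

#' @export
coef.dnlnet <- function(object, ...) {
  fl <- flatten_weights(object$weights)
  unlist(fl, use.names = TRUE)
}

#' Predict vessel probabilities or masks from images
#'
#' Images whose spatial size is not divisible by `2^n_stages` are
#' reflect-padded for inference and cropped back.  Images larger than `tile`
#' are processed in overlapping tiles blended with a cosine window.
#'
#' @param object a trained (or untrained) `dnlnet`.
#' @param newdata a (C, H, W) array, (H, W) matrix, or list of such.
#' @param type `"prob"` for soft probability maps, `"mask"` for thresholded
#'   binary masks.
#' @param threshold binarisation threshold for `type = "mask"`.
#' @param postprocess logical; apply [remove_small_components()] to masks.
#' @param tile optional tile size for piecewise inference on large images.
#' @param overlap tile overlap fraction (cosine-window blending).
#' @param ... unused.
#' @return an (H, W) matrix (or list of matrices) of probabilities or 0/1.
#' @export
predict.dnlnet <- function(object, newdata, type = c("prob", "mask"),
                           threshold = 0.5, postprocess = FALSE,
                           tile = NULL, overlap = 0.5, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.array(newdata))
    return(lapply(newdata, predict, object = object, type = type,
                  threshold = threshold, postprocess = postprocess,
                  tile = tile, overlap = overlap))
  img <- newdata
  if (is.matrix(img)) img <- array(img, c(1L, dim(img)))
  prob <- if (!is.null(tile) && any(dim(img)[2:3] > tile))
    tile_predict(object, img, tile, overlap)
  else
    pad_predict(object, img)
  prob <- prob[1, , ]
  if (type == "prob") return(prob)
  mask <- (prob >= threshold) * 1
  if (postprocess) mask <- remove_small_components(mask)
  mask
}

# reflect-pad to the divisibility multiple, run, crop
pad_predict <- function(model, img) {
  mult <- 2L^model$config$n_stages
  d <- dim(img)
  ph <- (mult - d[2] %% mult) %% mult
  pw <- (mult - d[3] %% mult) %% mult
  if (ph > 0 || pw > 0) {
    hi <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(ph)])
    wi <- c(seq_len(d[3]), rev(seq_len(d[3]))[seq_len(pw)])
    img <- img[, hi, wi, drop = FALSE]
  }
  out <- dnlnet_forward(model, img)
  out[, seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}

tile_predict <- function(model, img, tile, overlap = 0.5) {
  d <- dim(img)
  step <- max(1L, as.integer(round(tile * (1 - overlap))))
  starts <- function(n) {
    if (n <= tile) return(1L)
    s <- seq(1L, n - tile, by = step)
    if (s[length(s)] != n - tile + 1L) s <- c(s, n - tile + 1L)
    s
  }
  win1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(tile) - 0.5) / tile)
  win <- outer(win1, win1)
  acc <- array(0, c(model$config$out_classes, d[2], d[3]))
  wacc <- matrix(0, d[2], d[3])
  for (hs in starts(d[2])) for (ws in starts(d[3])) {
    hr <- hs:(hs + tile - 1L); wr <- ws:(ws + tile - 1L)
    p <- pad_predict(model, img[, hr, wr, drop = FALSE])
    for (k in seq_len(dim(p)[1]))
      acc[k, hr, wr] <- acc[k, hr, wr] + p[k, , ] * win
    wacc[hr, wr] <- wacc[hr, wr] + win
  }
  for (k in seq_len(dim(acc)[1])) acc[k, , ] <- acc[k, , ] / pmax(wacc, 1e-12)
  acc
}

#' Display an image with its predicted vessel probability map
#'
#' @param x a `dnlnet` object.
#' @param image a (C, H, W) array or (H, W) matrix to segment.
#' @param mask optional reference mask drawn in a third panel.
#' @param ... passed to [graphics::image()].
#' @export
plot.dnlnet <- function(x, image, mask = NULL, ...) {
  if (is.matrix(image)) image <- array(image, c(1L, dim(image)))
  prob <- predict(x, image)
  np <- if (is.null(mask)) 2L else 3L
  op <- graphics::par(mfrow = c(1, np), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, main) graphics::image(
    t(m)[, nrow(m):1, drop = FALSE], col = grDevices::gray.colors(256),
    axes = FALSE, main = main, useRaster = TRUE, ...)
  show(image[1, , ], "input")
  show(prob, "predicted probability")
  if (!is.null(mask)) show(if (is.matrix(mask)) mask else mask[1, , ], "reference")
  invisible(prob)
}
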