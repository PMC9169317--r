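# Losses, learning-rate schedule, preprocessing, augmentation, patch sampling
# and the ADAM training loop.

#' Training configuration
#'
#' Defaults encode the reference training recipe: ADAM with beta1 = 0.5,
#' beta2 = 0.999, initial learning rate 1e-3 decayed per epoch by
#' `(1 - (epoch - 1)/total_epochs)^0.9`, 200 epochs, batch size 4,
#' 96 x 96 patches, and a Dice + weighted cross-entropy loss.
#'
#' @param beta1,beta2 ADAM moment decay rates.
#' @param initial_lr initial learning rate.
#' @param power exponent of the polynomial decay.
#' @param total_epochs number of training epochs.
#' @param batch_size images per gradient step.
#' @param patch_size side length of sampled training patches.
#' @param dice_w,wce_w weights of the Dice and weighted-CE loss terms.
#' @param w_pos positive-class weight of the cross-entropy term; `"auto"`
#'   uses the per-batch negative/positive pixel ratio.
#' @param val_fraction fraction of the dataset held out for validation.
#' @param eps loss clamping / denominator stabiliser.
#' @param seed seed controlling shuffling, splits and augmentation.
#' @param augment logical; apply seeded geometric augmentation to training
#'   pairs each epoch.
#' @param preset `"paper"` (the full-scale reference schedule) or `"test"`
#'   (30 epochs, for CPU-scale runs); explicit arguments override it.
#' @return a list of class `train_config`.
#' @export
train_config <- function(beta1 = 0.5, beta2 = 0.999, initial_lr = 1e-3,
                         power = 0.9, total_epochs = NULL, batch_size = 4L,
                         patch_size = 96L, dice_w = 1, wce_w = 1,
                         w_pos = "auto", val_fraction = 0.2, eps = 1e-7,
                         seed = 1L, augment = FALSE,
                         preset = c("paper", "test")) {
  preset <- match.arg(preset)
  if (is.null(total_epochs)) total_epochs <- if (preset == "test") 30L else 200L
  stopifnot(initial_lr > 0, power > 0, total_epochs >= 1, batch_size >= 1)
  structure(list(beta1 = beta1, beta2 = beta2, initial_lr = initial_lr,
                 power = power, total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 dice_w = dice_w, wce_w = wce_w, w_pos = w_pos,
                 val_fraction = val_fraction, eps = eps,
                 seed = as.integer(seed), augment = augment, preset = preset),
            class = "train_config")
}

#' Polynomial learning-rate decay factor
#'
#' `factor(epoch) = (1 - (epoch - 1)/total)^power`; the learning rate at an
#' epoch is `initial_lr * factor(epoch)`, so epoch 1 trains at the full
#' initial rate.
#'
#' @param epoch current epoch, in `1..total`.
#' @param total total number of epochs.
#' @param power decay exponent (> 0).
#' @return the multiplicative factor in (0, 1].
#' @export
poly_lr_factor <- function(epoch, total, power = 0.9) {
  if (any(epoch < 1 | epoch > total))
    stop("epoch must lie in 1..total (= ", total, ")")
  (1 - (epoch - 1) / total)^power
}

# ---- losses (plain numeric; the autodiff twins live in autodiff.R) ----------

#' Soft Dice loss
#'
#' `1 - 2*sum(p*q) / (sum(p^2) + sum(q^2))` with an epsilon-stabilised
#' numerator and denominator, so two empty masks score a perfect 0.
#'
#' @param pred predicted probabilities in \[0, 1\].
#' @param target reference labels (binary, soft allowed).
#' @param eps stabiliser.
#' @return loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target, eps = 1e-7) {
  stopifnot(length(pred) == length(target))
  1 - (2 * sum(pred * target) + eps) / (sum(pred^2) + sum(target^2) + eps)
}

#' Weighted binary cross-entropy
#'
#' Mean over pixels of `-[w_pos * t * log(p) + (1 - t) * log(1 - p)]` with
#' predictions clamped to `[eps, 1 - eps]`.  `w_pos = 1` is the standard
#' binary cross-entropy.
#'
#' @inheritParams dice_loss
#' @param w_pos weight on the positive (vessel) class.
#' @return non-negative scalar.
#' @export
weighted_cross_entropy <- function(pred, target, w_pos = 1, eps = 1e-7) {
  stopifnot(length(pred) == length(target))
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(w_pos * target * log(p) + (1 - target) * log(1 - p))
}

#' Combined segmentation loss
#'
#' `dice_w * dice_loss + wce_w * weighted_cross_entropy`, the training
#' objective.
#'
#' @inheritParams weighted_cross_entropy
#' @param dice_w,wce_w term weights.
#' @return non-negative scalar.
#' @export
combined_loss <- function(pred, target, dice_w = 1, wce_w = 1, w_pos = 1,
                          eps = 1e-7) {
  dice_w * dice_loss(pred, target, eps) +
    wce_w * weighted_cross_entropy(pred, target, w_pos, eps)
}

# ---- preprocessing -----------------------------------------------------------

rgb_to_gray <- function(img) {
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L)
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  else if (length(dim(img)) == 3L) img[, , 1]
  else img
}

#' Fundus-style preprocessing pipeline
#'
#' Applies, in order: gray-scale conversion, per-image standardisation (zero
#' mean, unit variance, epsilon-stabilised for constant images), contrast
#' limited adaptive histogram equalisation (CLAHE), and gamma adjustment.
#' CLAHE and gamma act on intensities min-max rescaled to \[0, 1\], so the
#' returned image is in \[0, 1\].
#'
#' @param image an (H, W) gray matrix or (H, W, 3) RGB array in \[0, 1\].
#' @param clahe logical; apply CLAHE.
#' @param clahe_tiles number of CLAHE tiles per axis.
#' @param clahe_clip CLAHE clip limit.
#' @param gamma gamma exponent (1 = identity).
#' @param standardize logical; apply per-image standardisation.
#' @param eps stabiliser for the standard deviation.
#' @return an (H, W) matrix in \[0, 1\].
#' @export
preprocess_drive_style <- function(image, clahe = TRUE, clahe_tiles = 8L,
                                   clahe_clip = 2, gamma = 1.2,
                                   standardize = TRUE, eps = 1e-7) {
  g <- rgb_to_gray(image)
  if (standardize) g <- (g - mean(g)) / (stats::sd(g) + eps)
  rng <- range(g)
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  if (clahe)
    g <- as.matrix(EBImage::clahe(g, nx = clahe_tiles, ny = clahe_tiles,
                                  limit = clahe_clip))
  g <- pmin(pmax(g, 0), 1)^gamma
  g
}

# ---- patch sampling ----------------------------------------------------------

reflect_index <- function(i, n) {
  # reflect out-of-range 1-based indices back into 1..n
  p <- 2L * n - 2L
  if (p <= 0L) return(rep(1L, length(i)))
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  ifelse(j < n, j + 1L, p - j + 1L)
}

#' Sample congruent random patches from an image/mask pair
#'
#' Patch centres are uniform over the image; windows crossing a border are
#' filled by reflection, so border vessels remain sampled.
#'
#' @param image (H, W) matrix or (C, H, W) array.
#' @param mask (H, W) binary matrix.
#' @param n number of patches.
#' @param size patch side length.
#' @param seed seed; the same seed reproduces the same patch set.
#' @return a list of `n` lists with elements `image`, `mask`, `center`.
#' @export
sample_patches <- function(image, mask, n, size = 96L, seed = 1L) {
  if (n <= 0) return(list())
  im3 <- if (is.matrix(image)) array(image, c(1L, dim(image))) else image
  d <- dim(im3)
  stopifnot(all(dim(mask) == d[2:3]))
  with_seed(seed, {
    ch <- sample.int(d[2], n, replace = TRUE)
    cw <- sample.int(d[3], n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      hr <- reflect_index(ch[i] - size %/% 2L + seq_len(size) - 1L, d[2])
      wr <- reflect_index(cw[i] - size %/% 2L + seq_len(size) - 1L, d[3])
      list(image = im3[, hr, wr, drop = FALSE],
           mask = mask[hr, wr, drop = FALSE],
           center = c(ch[i], cw[i]))
    })
  })
}

# ---- geometric augmentation --------------------------------------------------

# inverse-mapped affine warp about the image centre.  A maps output coords to
# source coords; bilinear for images, nearest for masks.
warp_affine <- function(img, A, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  ch <- (H + 1) / 2; cw <- (W + 1) / 2
  gh <- rep(seq_len(H), times = W) - ch
  gw <- rep(seq_len(W), each = H) - cw
  sh <- A[1, 1] * gh + A[1, 2] * gw + ch
  sw <- A[2, 1] * gh + A[2, 2] * gw + cw
  out <- rep(fill, H * W)
  if (interp == "nearest") {
    rh <- round(sh); rw <- round(sw)
    ok <- rh >= 1 & rh <= H & rw >= 1 & rw <= W
    out[ok] <- img[cbind(rh[ok], rw[ok])]
  } else {
    ok <- sh >= 1 & sh <= H & sw >= 1 & sw <= W
    h0 <- pmin(pmax(floor(sh), 1), H - 1)
    w0 <- pmin(pmax(floor(sw), 1), W - 1)
    fh <- sh - h0; fw <- sw - w0
    idx <- function(hh, ww) img[cbind(hh, ww)]
    out[ok] <- (1 - fh[ok]) * (1 - fw[ok]) * idx(h0[ok], w0[ok]) +
      (1 - fh[ok]) * fw[ok] * idx(h0[ok], w0[ok] + 1) +
      fh[ok] * (1 - fw[ok]) * idx(h0[ok] + 1, w0[ok]) +
      fh[ok] * fw[ok] * idx(h0[ok] + 1, w0[ok] + 1)
  }
  matrix(out, H, W)
}

rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' CTA-style geometric augmentation of an image/mask pair
#'
#' Randomly composes a small affine distortion (scale and shear), a rotation,
#' and a vertical flip, applied identically to both members; the mask is
#' resampled nearest-neighbour so it stays binary.  Fully reproducible given
#' `seed`.
#'
#' @param image (H, W) matrix.
#' @param mask (H, W) binary matrix, congruent with `image`.
#' @param seed seed for the random draw.
#' @param max_angle rotation range in degrees (uniform in +-`max_angle`).
#' @param max_scale_delta scale range (uniform in 1 +- delta).
#' @param max_shear shear range.
#' @param p_flip probability of the vertical flip.
#' @return a list with transformed `image` and `mask`.
#' @export
augment_ibv_style <- function(image, mask, seed = 1L, max_angle = 25,
                              max_scale_delta = 0.1, max_shear = 0.1,
                              p_flip = 0.5) {
  stopifnot(all(dim(image) == dim(mask)))
  with_seed(seed, {
    ang <- stats::runif(1, -max_angle, max_angle)
    sc <- stats::runif(1, 1 - max_scale_delta, 1 + max_scale_delta)
    sh <- stats::runif(1, -max_shear, max_shear)
    flip <- stats::runif(1) < p_flip
    # inverse map: undo rotation then the scale/shear distortion
    A <- matrix(c(1 / sc, 0, sh, 1 / sc), 2, 2) %*% rotation_matrix(-ang)
    img <- warp_affine(image, A, "bilinear")
    msk <- warp_affine(mask, A, "nearest")
    if (flip) {
      img <- img[nrow(img):1, , drop = FALSE]
      msk <- msk[nrow(msk):1, , drop = FALSE]
    }
    list(image = img, mask = (msk > 0.5) * 1)
  })
}

#' Flip an image vertically (across the horizontal mid-line)
#' @param x an (H, W) matrix.
#' @return the flipped matrix.
#' @export
vertical_flip <- function(x) x[nrow(x):1, , drop = FALSE]

# ---- ADAM training loop ------------------------------------------------------

adam_new <- function(flat) {
  list(m = lapply(flat, function(a) a * 0),
       v = lapply(flat, function(a) a * 0),
       t = 0L)
}

adam_step <- function(flat, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, st = st)
}

# rebuild the weight tree from a flat named list
unflatten_weights <- function(w, flat) {
  map_wleaves(w, function(leaf, path) flat[[path]])
}

stack_batch <- function(items) {
  d <- dim(items[[1]]$image)
  if (length(d) == 2L) d <- c(1L, d)
  n <- length(items)
  x <- array(0, c(n, d))
  y <- array(0, c(n, 1L, d[2], d[3]))
  for (i in seq_len(n)) {
    im <- items[[i]]$image
    if (is.matrix(im)) im <- array(im, c(1L, dim(im)))
    x[i, , , ] <- im
    y[i, 1L, , ] <- items[[i]]$mask
  }
  list(x = x, y = y)
}

batch_loss_node <- function(model, wts, x, y, cfg) {
  pred <- net_forward(wts, model$bn, ad_const(x), model$config, training = TRUE)
  w_pos <- if (identical(cfg$w_pos, "auto")) {
    np <- sum(y)
    if (np > 0) (length(y) - np) / np else 1
  } else cfg$w_pos
  ad_axpby(ad_dice_loss(pred, y, cfg$eps),
           ad_wbce_loss(pred, y, w_pos, cfg$eps),
           cfg$dice_w, cfg$wce_w)
}

soft_dice_of <- function(model, items) {
  vals <- vapply(items, function(it) {
    im <- it$image
    p <- dnlnet_forward(model, if (is.matrix(im)) im else im)
    1 - dice_loss(p[1, , ], it$mask)
  }, 0)
  mean(vals)
}

#' Train a DNL-Net
#'
#' ADAM optimisation of the combined Dice + weighted cross-entropy loss with
#' the polynomial learning-rate schedule.  A seeded validation split
#' (`val_fraction`) is held out; the parameters with the best validation soft
#' Dice are retained.  The per-epoch log (epoch, lr, train loss, validation
#' Dice) is attached as `model$history`.
#'
#' @param model a `dnlnet` from [dnl_net()].
#' @param dataset a list of pairs `list(image = , mask = )`; images (C, H, W)
#'   arrays or (H, W) matrices, masks (H, W) binary matrices.  All images
#'   must share one size.
#' @param cfg a [train_config()].
#' @return the trained `dnlnet` (best-validation weights, history attached).
#' @export
dnlnet_train <- function(model, dataset, cfg = train_config(preset = "test")) {
  if (length(dataset) == 0L) stop("empty dataset")
  n <- length(dataset)
  idx <- with_seed(cfg$seed, sample.int(n))
  nval <- max(if (n > 1L) 1L else 0L, round(cfg$val_fraction * n))
  val <- dataset[idx[seq_len(nval)]]
  trn <- dataset[idx[setdiff(seq_len(n), seq_len(nval))]]
  if (length(trn) == 0L) { trn <- val }

  flat <- flatten_weights(model$weights)
  opt <- adam_new(flat)
  best <- list(dice = -Inf, flat = flat, bn = NULL)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_dice = numeric())

  for (epoch in seq_len(cfg$total_epochs)) {
    lr <- cfg$initial_lr * poly_lr_factor(epoch, cfg$total_epochs, cfg$power)
    ord <- with_seed(cfg$seed + 7919L * epoch, sample.int(length(trn)))
    losses <- numeric()
    for (b0 in seq(1L, length(ord), by = cfg$batch_size)) {
      take <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
      items <- trn[take]
      if (cfg$augment)
        items <- lapply(seq_along(items), function(i) {
          it <- items[[i]]
          im <- if (is.matrix(it$image)) it$image else it$image[1, , ]
          a <- augment_ibv_style(im, it$mask,
                                 seed = cfg$seed + 1000L * epoch + b0 + i)
          list(image = a$image, mask = a$mask)
        })
      ba <- stack_batch(items)
      model$weights <- unflatten_weights(model$weights, flat)
      tape_start()
      collector <- new.env(parent = emptyenv())
      wts <- map_wleaves(model$weights, function(leaf, path) {
        nd <- ad_param(leaf)
        assign(path, nd, envir = collector)
        nd
      })
      loss <- batch_loss_node(model, wts, ba$x, ba$y, cfg)
      backward(loss)
      grads <- lapply(as.list(collector, sorted = TRUE),
                      function(nd) nd$grad)
      tape_stop()
      losses <- c(losses, loss$value)
      upd <- adam_step(flat, grads, opt, lr, cfg$beta1, cfg$beta2)
      flat <- upd$flat
      opt <- upd$st
    }
    model$weights <- unflatten_weights(model$weights, flat)
    vd <- soft_dice_of(model, val)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses), val_dice = vd))
    if (vd > best$dice)
      best <- list(dice = vd, flat = flat,
                   bn = lapply(model$bn, function(e) list(mean = e$mean,
                                                          var = e$var)))
  }

  model$weights <- unflatten_weights(model$weights, best$flat)
  if (!is.null(best$bn))
    for (nm in names(best$bn)) {
      model$bn[[nm]]$mean <- best$bn[[nm]]$mean
      model$bn[[nm]]$var <- best$bn[[nm]]$var
    }
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Build and train a DNL-Net in one call
#'
#' @param images list of (C, H, W) arrays or (H, W) matrices.
#' @param masks list of congruent (H, W) binary masks.
#' @param net_config a [dnlnet_config()].
#' @param cfg a [train_config()].
#' @param seed initialisation seed for the network weights.
#' @return a trained `dnlnet`.
#' @export
dnlnet_fit <- function(images, masks, net_config = dnlnet_config(preset = "test"),
                       cfg = train_config(preset = "test"), seed = 1L) {
  stopifnot(length(images) == length(masks), length(images) > 0L)
  model <- dnl_net(net_config, seed = seed)
  dataset <- lapply(seq_along(images),
                    function(i) list(image = images[[i]], mask = masks[[i]]))
  dnlnet_train(model, dataset, cfg)
}
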