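# Losses, schedule, preprocessing, patch sampling and augmentation.

test_that("polynomial decay reproduces its closed forms and monotonicity", {
  expect_equal(poly_lr_factor(1, 200, 0.9), 1)
  expect_equal(poly_lr_factor(101, 200, 0.9), 0.5^0.9, tolerance = 1e-12)
  expect_equal(poly_lr_factor(200, 200, 1), 1 / 200, tolerance = 1e-12)
  f <- poly_lr_factor(1:200, 200, 0.9)
  expect_true(all(diff(f) < 0))
  expect_error(poly_lr_factor(0, 200), "1..total")
  expect_error(poly_lr_factor(201, 200), "1..total")
})

test_that("Dice loss matches scalar fixtures and boundary cases", {
  t <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 2, 4)
  # perfect prediction on a nonzero mask
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  # complement prediction on a half-ones mask: disjoint support
  expect_equal(dice_loss(1 - t, t), 1, tolerance = 1e-6)
  # p = 0.5 everywhere, half-ones target, N = 8: Dice = 2/3, loss = 1/3
  expect_equal(dice_loss(matrix(0.5, 2, 4), t), 1 / 3, tolerance = 1e-6)
  # empty/empty scores a perfect 0 through the stabiliser
  expect_equal(dice_loss(t * 0, t * 0), 0)
})

test_that("weighted cross-entropy has its closed forms and a loop oracle", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  # confident correct prediction: loss bounded only by the clamp
  expect_lt(weighted_cross_entropy(t, t), 1e-5)
  # p = 0.5 everywhere: ln 2 regardless of the target
  expect_equal(weighted_cross_entropy(matrix(0.5, 2, 2), t), log(2),
               tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(matrix(0.5, 2, 2), 1 - t), log(2),
               tolerance = 1e-12)
  # w_pos = 1 equals plain BCE computed by a scalar loop
  set.seed(31)
  p <- matrix(runif(16, 0.05, 0.95), 4, 4)
  q <- matrix(rbinom(16, 1, 0.5), 4, 4)
  loop <- 0
  for (i in 1:16) loop <- loop - (q[i] * log(p[i]) + (1 - q[i]) * log(1 - p[i]))
  expect_equal(weighted_cross_entropy(p, q, w_pos = 1), loop / 16,
               tolerance = 1e-12)
  # positive weighting scales only the positive term
  expect_equal(weighted_cross_entropy(p, q, w_pos = 3),
               weighted_cross_entropy(p, q) +
                 2 * sum(q * (-log(p))) / 16, tolerance = 1e-12)
})

test_that("combined loss is compositional, non-negative, and single-pixel monotone", {
  set.seed(7)
  p <- matrix(runif(16, 0.1, 0.9), 4, 4)
  q <- matrix(rbinom(16, 1, 0.4), 4, 4)
  expect_equal(combined_loss(p, q, dice_w = 2, wce_w = 0.5, w_pos = 2),
               2 * dice_loss(p, q) +
                 0.5 * weighted_cross_entropy(p, q, w_pos = 2),
               tolerance = 1e-12)
  expect_lt(combined_loss(q, q), 1e-5)
  expect_gte(combined_loss(p, q), 0)

  # corrupting one correct confident pixel never decreases the loss
  perfect <- q * 0.98 + 0.01
  base <- combined_loss(perfect, q)
  for (i in 1:16) {
    bad <- perfect
    bad[i] <- 1 - bad[i]
    expect_gte(combined_loss(bad, q), base)
  }
})

test_that("losses are permutation-invariant over pixels", {
  set.seed(11)
  p <- runif(25); q <- rbinom(25, 1, 0.3)
  perm <- sample(25)
  expect_equal(dice_loss(p, q), dice_loss(p[perm], q[perm]))
  expect_equal(weighted_cross_entropy(p, q, 2),
               weighted_cross_entropy(p[perm], q[perm], 2))
})

test_that("fundus-style preprocessing standardises and gamma-adjusts", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  # standardisation alone: zero mean, unit sd before rescaling
  g <- preprocess_drive_style(img, clahe = FALSE, gamma = 1)
  expect_true(all(g >= 0 & g <= 1))
  # gray conversion from RGB uses luminance weights
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  gr <- dnlseg:::rgb_to_gray(rgb)
  expect_equal(gr[1, 1],
               sum(rgb[1, 1, ] * c(0.299, 0.587, 0.114)), tolerance = 1e-12)
  # gamma = 2 squares the rescaled intensity pointwise (loop check)
  g1 <- preprocess_drive_style(img, clahe = FALSE, gamma = 1,
                               standardize = FALSE)
  g2 <- preprocess_drive_style(img, clahe = FALSE, gamma = 2,
                               standardize = FALSE)
  for (i in c(1, 57, 200, 4096)) expect_equal(g2[i], g1[i]^2, tolerance = 1e-12)
  # constant image survives via the epsilon-stabilised sd
  flat <- preprocess_drive_style(matrix(0.4, 8, 8), clahe = FALSE)
  expect_true(all(is.finite(flat)))
  # CLAHE path runs and stays in range
  gc <- preprocess_drive_style(img)
  expect_true(all(gc >= 0 & gc <= 1))
})

test_that("patch sampling is seeded, congruent and border-safe", {
  set.seed(2)
  img <- matrix(runif(60 * 50), 60, 50)
  mask <- matrix(rbinom(60 * 50, 1, 0.1), 60, 50)
  a <- sample_patches(img, mask, 5, size = 24, seed = 9)
  b <- sample_patches(img, mask, 5, size = 24, seed = 9)
  expect_identical(a, b)
  expect_length(a, 5)
  for (p in a) {
    expect_equal(dim(p$image), c(1L, 24L, 24L))
    expect_equal(dim(p$mask), c(24L, 24L))
  }
  # every patch pixel traces back to a reflected source coordinate
  p1 <- a[[1]]
  ctr <- p1$center
  hsrc <- dnlseg:::reflect_index(ctr[1] - 12L + 0:23, 60L)
  wsrc <- dnlseg:::reflect_index(ctr[2] - 12L + 0:23, 50L)
  expect_equal(p1$image[1, , ], img[hsrc, wsrc])
  expect_equal(p1$mask, mask[hsrc, wsrc])
  # all-zero mask gives all-zero mask patches
  z <- sample_patches(img, mask * 0, 3, size = 96, seed = 1)
  expect_true(all(vapply(z, function(p) sum(p$mask), 0) == 0))
  expect_length(sample_patches(img, mask, 0, 24, 1), 0)
})

test_that("geometric augmentation is reproducible, involutive and mask-safe", {
  set.seed(13)
  img <- matrix(runif(32 * 32), 32, 32)
  mask <- matrix(0, 32, 32); mask[10:20, 14:18] <- 1

  a <- augment_ibv_style(img, mask, seed = 5)
  b <- augment_ibv_style(img, mask, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$mask %in% c(0, 1)))

  # vertical flip is an involution and preserves the mask pixel count
  expect_identical(vertical_flip(vertical_flip(img)), img)
  expect_equal(sum(vertical_flip(mask)), sum(mask))

  # zero rotation + identity affine + no flip leaves the pair unchanged
  idt <- augment_ibv_style(img, mask, seed = 1, max_angle = 0,
                           max_scale_delta = 0, max_shear = 0, p_flip = 0)
  expect_equal(idt$image, img, tolerance = 1e-9)
  expect_equal(idt$mask, mask)

  # pure 90-degree rotation preserves the mask pixel count exactly
  rot90 <- dnlseg:::warp_affine(mask, dnlseg:::rotation_matrix(90), "nearest")
  expect_equal(sum(rot90), sum(mask))
})

test_that("train_config encodes the published recipe", {
  tc <- train_config()
  expect_equal(tc$beta1, 0.5)
  expect_equal(tc$beta2, 0.999)
  expect_equal(tc$initial_lr, 1e-3)
  expect_equal(tc$power, 0.9)
  expect_equal(tc$total_epochs, 200L)
  expect_equal(tc$batch_size, 4L)
  expect_equal(tc$patch_size, 96L)
  expect_error(train_config(initial_lr = -1))
})

test_that("training on an empty dataset errors; lr trace follows the schedule", {
  m <- dnl_net(dnlnet_config(n_stages = 1, base_width = 2), seed = 1)
  expect_error(dnlnet_train(m, list(), train_config()), "empty")

  ds <- generate_dataset(6, phantom_spec(size = c(16, 16), n_vessels = 1,
                                         width_range = c(1, 2)), seed = 3)
  dataset <- lapply(ds, function(d) list(image = d$image, mask = d$mask))
  tc <- train_config(preset = "test", total_epochs = 3, seed = 2)
  fit <- suppressWarnings(dnlnet_train(m, dataset, tc))  # RSEP padding notes
  expect_equal(fit$history$lr,
               1e-3 * poly_lr_factor(1:3, 3, 0.9), tolerance = 1e-12)
  expect_true(fit$trained)

  # the one-call fitting interface builds and trains equivalently
  fit2 <- suppressWarnings(dnlnet_fit(
    lapply(ds, `[[`, "image"), lapply(ds, `[[`, "mask"),
    net_config = dnlnet_config(n_stages = 1, base_width = 2),
    cfg = tc, seed = 1))
  expect_s3_class(fit2, "dnlnet")
  expect_identical(fit2$history$lr, fit$history$lr)
})
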