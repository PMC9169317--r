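# Independent brute-force oracles: literal per-element evaluations of the
# block definitions and pixel-loop metric computations.  Everything here is
# written with plain scalar loops, deliberately sharing no code with the
# package internals.

sigmoid_s <- function(z) 1 / (1 + exp(-z))

# 1x1-conv weight array (Cout, Cin, 1, 1) as a Cout x Cin matrix
mat4 <- function(w) matrix(w, dim(w)[1], dim(w)[2])

# squeeze-and-excitation, per-channel loop
oracle_se <- function(x, w) {
  C <- dim(x)[1]
  g <- numeric(C)
  for (c in seq_len(C)) g[c] <- mean(x[c, , ])
  h <- pmax(as.numeric(w$w1 %*% g + w$b1), 0)
  gate <- sigmoid_s(as.numeric(w$w2 %*% h + w$b2))
  out <- x
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * gate[c]
  out
}

# standard non-local block: pairwise loop over all position pairs
oracle_nl <- function(x, w) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  hw <- H * W
  pos <- function(i) x[, (i - 1) %% H + 1, (i - 1) %/% H + 1]
  th <- function(i) as.numeric(mat4(w$theta$w) %*% pos(i) + w$theta$b)
  ph <- function(j) as.numeric(mat4(w$phi$w) %*% pos(j) + w$phi$b)
  gv <- function(j) as.numeric(mat4(w$g$w) %*% pos(j) + w$g$b)
  out <- x
  for (i in seq_len(hw)) {
    f <- numeric(hw)
    for (j in seq_len(hw)) {
      s <- sum(th(i) * ph(j))
      f[j] <- if (w$similarity == "embedded_gaussian") exp(s) else s
    }
    cx <- if (w$similarity == "embedded_gaussian") sum(f) else hw
    y <- 0
    for (j in seq_len(hw)) y <- y + f[j] * gv(j)
    y <- y / cx
    z <- as.numeric(mat4(w$z$w) %*% y + w$z$b) + pos(i)
    out[, (i - 1) %% H + 1, (i - 1) %/% H + 1] <- z
  }
  out
}

oracle_nl_attention <- function(x, w) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  hw <- H * W
  pos <- function(i) x[, (i - 1) %% H + 1, (i - 1) %/% H + 1]
  A <- matrix(0, hw, hw)
  for (i in seq_len(hw)) for (j in seq_len(hw)) {
    ti <- as.numeric(mat4(w$theta$w) %*% pos(i) + w$theta$b)
    pj <- as.numeric(mat4(w$phi$w) %*% pos(j) + w$phi$b)
    A[i, j] <- sum(ti * pj)
  }
  if (w$similarity == "embedded_gaussian") {
    for (i in seq_len(hw)) A[i, ] <- exp(A[i, ]) / sum(exp(A[i, ]))
  } else A <- A / hw
  A
}

# deformed non-local block: step-by-step loop evaluation of the channel
# attention, descriptor bottleneck, broadcast gate, SE tail and residual
oracle_dnl <- function(x, w) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  hw <- H * W
  Cb <- w$Cbar
  xm <- matrix(0, C, hw)
  for (i in seq_len(hw)) xm[, i] <- x[, (i - 1) %% H + 1, (i - 1) %/% H + 1]
  lin <- function(wc, b, m) {
    out <- matrix(0, length(b), ncol(m))
    for (i in seq_len(ncol(m))) out[, i] <- mat4(wc) %*% m[, i, drop = FALSE] + b
    out
  }
  th <- lin(w$theta$w, w$theta$b, xm)
  ph <- lin(w$phi$w, w$phi$b, xm)
  gm <- lin(w$g$w, w$g$b, xm)
  S <- matrix(0, Cb, Cb)
  for (a in seq_len(Cb)) for (b in seq_len(Cb)) S[a, b] <- sum(th[a, ] * ph[b, ])
  A <- S
  for (a in seq_len(Cb)) A[a, ] <- exp(S[a, ] - max(S[a, ])) / sum(exp(S[a, ] - max(S[a, ])))
  y1 <- matrix(0, Cb, hw)
  for (a in seq_len(Cb)) for (i in seq_len(hw)) y1[a, i] <- sum(A[a, ] * gm[, i])
  p <- numeric(hw)
  for (i in seq_len(hw)) p[i] <- sum(mat4(w$pool$w)[1, ] * xm[, i]) + w$pool$b
  y2 <- numeric(Cb)
  for (a in seq_len(Cb)) y2[a] <- sum(p * y1[a, ])
  y3 <- as.numeric(w$reduce$w %*% y2 + w$reduce$b)
  if (w$bottleneck_activation == "relu") y3 <- pmax(y3, 0)
  y4 <- as.numeric(w$expand$w %*% y3 + w$expand$b)
  if (w$gate == "sigmoid") y4 <- sigmoid_s(y4)
  xo <- lin(w$out$w, w$out$b, xm)
  ym <- xo * y4   # broadcast channel gate
  yarr <- x
  for (i in seq_len(hw)) yarr[, (i - 1) %% H + 1, (i - 1) %/% H + 1] <- ym[, i]
  oracle_se(yarr, w$se) + x
}

# channel attention vector: mean -> L2 normalise -> linear -> gate
oracle_cav <- function(x, w) {
  C <- dim(x)[1]
  g <- numeric(C)
  for (c in seq_len(C)) g[c] <- mean(x[c, , ])
  nrm <- sqrt(sum(g^2))
  gn <- if (nrm > 0) g / nrm else g * 0
  av <- as.numeric(w$w %*% gn + w$b)
  if (w$activation == "sigmoid") av <- sigmoid_s(av)
  av
}

# pixel-loop confusion counts and metrics
oracle_confusion <- function(pred, mask) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && mask[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && mask[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && mask[i] == 0) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_dice <- function(pred, mask) {
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_along(pred)) {
    num <- num + pred[i] * mask[i]
    d1 <- d1 + pred[i]^2
    d2 <- d2 + mask[i]^2
  }
  2 * num / (d1 + d2)
}

oracle_miou <- function(pred, mask, k = 2) {
  ious <- c()
  for (cl in 0:(k - 1)) {
    pii <- sum(pred == cl & mask == cl)
    den <- sum(mask == cl) + sum(pred == cl) - pii
    if (den > 0) ious <- c(ious, pii / den)
  }
  mean(ious)
}

# O(n^2) pairwise Mann-Whitney AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# deterministic small random tensors
rand_fmap <- function(C, H, W, seed) {
  set.seed(seed)
  array(stats::runif(C * H * W, -1, 1), c(C, H, W))
}

# a small valid SE reduction ratio for channel count C
pick_divisor <- function(C) {
  d <- which(C %% seq_len(C) == 0)
  max(d[d <= 4])
}
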