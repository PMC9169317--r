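# Reverse-mode automatic differentiation on dense arrays.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; a package-level tape records every gradient-tracked op in
# creation order so backward() can sweep it in reverse.  Feature maps are 4D
# (N, C, H, W) arrays; matrix-valued intermediates (attention) are 3D
# (N, A, B); vector descriptors are (N, K) matrices; losses are scalars.

.ad <- new.env(parent = emptyenv())
.ad$active <- FALSE
.ad$tape <- list()
.ad$n <- 0L

tape_start <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  .ad$active <- TRUE
  invisible(NULL)
}

tape_stop <- function() {
  .ad$active <- FALSE
  .ad$tape <- list()
  .ad$n <- 0L
  invisible(NULL)
}

tape_push <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- node
  .ad$n <- n
  invisible(NULL)
}

new_leaf <- function(value, track = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$track <- track
  class(e) <- "adnode"
  e
}

#' @keywords internal
ad_const <- function(x) new_leaf(x, track = FALSE)

#' @keywords internal
ad_param <- function(x) new_leaf(x, track = TRUE)

as_node <- function(x) if (inherits(x, "adnode")) x else ad_const(x)

new_node <- function(value, parents, backfn) {
  track <- FALSE
  for (p in parents) if (p$track) { track <- TRUE; break }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- if (track) backfn else NULL
  e$track <- track
  class(e) <- "adnode"
  if (track) {
    if (!.ad$active)
      stop("gradient-tracked computation outside an open tape; call tape_start()")
    tape_push(e)
  }
  e
}

node_value <- function(x) if (inherits(x, "adnode")) x$value else x

# Sweep the tape in reverse from `loss`, accumulating gradients into every
# tracked leaf reachable from it.
backward <- function(loss) {
  stopifnot(inherits(loss, "adnode"))
  if (!.ad$active) stop("no open tape")
  loss$grad <- array(1, dim = if (is.null(dim(loss$value))) 1L else dim(loss$value))
  if (.ad$n > 0L) for (i in .ad$n:1L) {
    nd <- .ad$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!p$track || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(NULL)
}

# ---- broadcast helpers ------------------------------------------------------

# (N, C) matrix -> (N, C, H, W) array, constant over space
bcast_nc <- function(v, dims) bcast_nc_cpp(as.matrix(v), as.integer(dims))

# per-channel vector (length C) -> (N, C, H, W)
bcast_c <- function(v, dims) array(rep(v, each = dims[1]), dims)

# sum an (N, C, H, W) array over N, H, W giving a length-C vector
csum <- function(x) chan_sum_cpp(x)

# sum over H, W giving an (N, C) matrix
ncsum <- function(x) chan_ncsum_cpp(x)

# ---- primitive ops ----------------------------------------------------------

ad_conv2d <- function(x, w, b, pad = 0L, dil = 1L) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  fw <- conv2d_forward_cpp(x$value, w$value, b$value, as.integer(pad),
                           as.integer(dil))
  xd <- dim(x$value)
  new_node(fw$out, list(x, w, b), function(g) {
    bw <- conv2d_backward_cpp(fw$col, w$value, g, xd, as.integer(pad),
                              as.integer(dil))
    list(bw$gx, bw$gw, bw$gb)
  })
}

ad_relu <- function(x) {
  x <- as_node(x)
  v <- x$value
  new_node(relu_cpp(v), list(x), function(g) list(relu_bwd_cpp(g, v)))
}

ad_sigmoid <- function(x) {
  x <- as_node(x)
  s <- 1 / (1 + exp(-x$value))
  new_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_scale_const <- function(x, s) {
  x <- as_node(x)
  new_node(x$value * s, list(x), function(g) list(g * s))
}

# scale channels of x (N,C,H,W) by v (N,C)
ad_scale_channels <- function(x, v) {
  x <- as_node(x); v <- as_node(v)
  vm <- as.matrix(v$value)
  new_node(chan_scale_nc_cpp(x$value, vm), list(x, v), function(g) {
    list(chan_scale_nc_cpp(g, vm), chan_dot_nc_cpp(g, x$value))
  })
}

# global average pooling: (N,C,H,W) -> (N,C)
ad_gap <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  m <- d[3] * d[4]
  val <- ncsum(x$value) / m
  new_node(val, list(x), function(g) list(bcast_nc(g / m, d)))
}

# fully connected: x (N,K), W (M,K), b (M) -> (N,M)
ad_linear <- function(x, w, b) {
  x <- as_node(x); w <- as_node(w); b <- as_node(b)
  val <- x$value %*% t(w$value)
  val <- sweep(val, 2L, b$value, "+")
  new_node(val, list(x, w, b), function(g) {
    list(g %*% w$value, t(g) %*% x$value, colSums(g))
  })
}

# row-wise L2 normalization of (N,K); all-zero rows map to zero rows
ad_l2norm_rows <- function(x) {
  x <- as_node(x)
  v <- x$value
  nrm <- sqrt(rowSums(v^2))
  safe <- ifelse(nrm > 0, nrm, 1)
  y <- v / safe
  zero <- nrm == 0
  y[zero, ] <- 0
  new_node(y, list(x), function(g) {
    gy <- (g - y * rowSums(g * y)) / safe
    gy[zero, ] <- 0
    list(gy)
  })
}

ad_reshape <- function(x, dims) {
  x <- as_node(x)
  od <- dim(x$value)
  v <- x$value
  dim(v) <- dims
  new_node(v, list(x), function(g) { dim(g) <- od; list(g) })
}

# batched matrix product with optional per-slice transposes:
# out[n,,] = op_a(a[n,,]) %*% op_b(b[n,,])
ad_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  out <- bmm_cpp(av, bv, ta, tb)
  new_node(out, list(a, b), function(g) {
    ga <- if (!ta) bmm_cpp(g, bv, FALSE, !tb) else bmm_cpp(bv, g, tb, TRUE)
    gb <- if (!tb) bmm_cpp(av, g, !ta, FALSE) else bmm_cpp(g, av, TRUE, ta)
    list(ga, gb)
  })
}

ad_transpose3 <- function(x) {
  x <- as_node(x)
  new_node(aperm(x$value, c(1L, 3L, 2L)), list(x),
           function(g) list(aperm(g, c(1L, 3L, 2L))))
}

# softmax over the last index of (N,A,B): each (n,a) row is a distribution
ad_softmax3 <- function(x) {
  x <- as_node(x)
  v <- x$value
  d <- dim(v)
  mx <- apply(v, c(1L, 2L), max)
  e <- exp(v - array(as.vector(mx), d))
  s <- array(as.vector(apply(e, c(1L, 2L), sum)), d)
  y <- e / s
  new_node(y, list(x), function(g) {
    dot <- array(as.vector(apply(g * y, c(1L, 2L), sum)), d)
    list(y * (g - dot))
  })
}

ad_concat_chan <- function(xs) {
  xs <- lapply(xs, as_node)
  ds <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(ds, function(d) d[2], 0)
  d1 <- ds[[1]]
  out <- array(0, c(d1[1], sum(cs), d1[3], d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, at + seq_len(cs[i]), , ] <- xs[[i]]$value
    at <- at + cs[i]
  }
  new_node(out, xs, function(g) {
    at <- 0L
    gs <- vector("list", length(xs))
    for (i in seq_along(xs)) {
      gi <- g[, at + seq_len(cs[i]), , , drop = FALSE]
      dim(gi) <- ds[[i]]
      gs[[i]] <- gi
      at <- at + cs[i]
    }
    gs
  })
}

# interpolation matrix for exact x2 upsampling along one axis
upsample2_matrix <- function(n, mode) {
  m <- matrix(0, 2L * n, n)
  if (mode == "nearest") {
    for (i in seq_len(2L * n)) m[i, ceiling(i / 2)] <- 1
  } else {
    for (i in seq_len(2L * n)) {
      cc <- (i - 0.5) / 2 - 0.5          # source coordinate, 0-based
      i0 <- floor(cc)
      w <- cc - i0
      lo <- min(max(i0, 0), n - 1)
      hi <- min(max(i0 + 1, 0), n - 1)
      m[i, lo + 1L] <- m[i, lo + 1L] + (1 - w)
      m[i, hi + 1L] <- m[i, hi + 1L] + w
    }
  }
  m
}

# exact x2 spatial upsampling, bilinear (half-pixel centres) or nearest
ad_upsample2 <- function(x, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  x <- as_node(x)
  d <- dim(x$value)
  R <- upsample2_matrix(d[3], mode)
  Cm <- upsample2_matrix(d[4], mode)
  out <- sepmm_cpp(x$value, R, Cm)
  new_node(out, list(x), function(g) list(sepmm_cpp(g, t(R), t(Cm))))
}

# 2x2 max pooling, stride 2 (ties resolved in fixed slab order)
ad_maxpool2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value)
  fw <- maxpool2_cpp(x$value)
  new_node(fw$out, list(x), function(g) list(maxpool2_bwd_cpp(g, fw$arg, d)))
}

# batch normalization over (N,H,W) per channel; `state` is an environment with
# $mean and $var running buffers, updated in place when training = TRUE
ad_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  m <- d[1] * d[3] * d[4]
  if (training) {
    mu <- as.numeric(csum(x$value)) / m
    va <- pmax(as.numeric(csum(x$value^2)) / m - mu^2, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  # fused affine: out = x * s + t with s = gamma*istd, t = beta - mu*s
  s <- gamma$value * istd
  out <- chan_affine_cpp(x$value, s, beta$value - mu * s)
  new_node(out, list(x, gamma, beta), function(g) {
    xhat <- chan_affine_cpp(x$value, istd, -mu * istd)
    dgamma <- as.numeric(chan_dot_c_cpp(g, xhat))
    dbeta <- as.numeric(csum(g))
    if (training) {
      dxhat <- chan_affine_cpp(g, gamma$value, numeric(d[2]))
      s1 <- as.numeric(csum(dxhat))
      s2 <- as.numeric(chan_dot_c_cpp(dxhat, xhat))
      gx <- chan_affine_cpp(dxhat, istd, -s1 * istd / m) -
        chan_affine_cpp(xhat, s2 * istd / m, numeric(d[2]))
    } else {
      gx <- chan_affine_cpp(g, gamma$value * istd, numeric(d[2]))
    }
    list(gx, dgamma, dbeta)
  })
}

# ---- losses -----------------------------------------------------------------

# soft Dice loss 1 - 2*sum(pq)/(sum p^2 + sum q^2), epsilon-stabilised so that
# an all-zero pair scores a perfect 0 loss
ad_dice_loss <- function(pred, target, eps = 1e-7) {
  pred <- as_node(pred); target <- as_node(target)
  p <- pred$value; q <- target$value
  num <- 2 * sum(p * q) + eps
  den <- sum(p * p) + sum(q * q) + eps
  loss <- 1 - num / den
  new_node(loss, list(pred, target), function(g) {
    gp <- -as.numeric(g) * (2 * q * den - 2 * p * num) / den^2
    list(gp, NULL)
  })
}

# mean over pixels of -[w_pos * t * log p + (1 - t) * log(1 - p)]
ad_wbce_loss <- function(pred, target, w_pos = 1, eps = 1e-7) {
  pred <- as_node(pred); target <- as_node(target)
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  q <- target$value
  n <- length(p)
  loss <- -sum(w_pos * q * log(p) + (1 - q) * log(1 - p)) / n
  new_node(loss, list(pred, target), function(g) {
    gp <- as.numeric(g) * (-w_pos * q / p + (1 - q) / (1 - p)) / n
    list(gp, NULL)
  })
}

ad_axpby <- function(a, b, ca = 1, cb = 1) {
  a <- as_node(a); b <- as_node(b)
  new_node(ca * a$value + cb * b$value, list(a, b),
           function(g) list(g * ca, g * cb))
}
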