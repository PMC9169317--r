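# Attention building blocks: squeeze-and-excitation (SE), the standard
# non-local (NL) block with positional self-attention, and the deformed
# non-local (DNL) block that replaces the (HW x HW) positional attention with
# a (Cbar x Cbar) channel-similarity attention followed by an SE gate.
#
# Public functions take plain (C, H, W) arrays and weight lists; the same code
# paths run on autodiff nodes inside the network, so the tested arithmetic is
# the trained arithmetic.

# ---- helpers ----------------------------------------------------------------

#' Evaluate an expression with a temporarily fixed RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_fmap <- function(x, what = "x") {
  if (inherits(x, "adnode")) return(invisible(x))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a (C, H, W) array")
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values")
  invisible(x)
}

# (C,H,W) -> (1,C,H,W); identical memory order, so a plain reshape
fmap4 <- function(x) { d <- dim(x); array(x, c(1L, d)) }
fmap3 <- function(x) { d <- dim(x); array(x, d[-1]) }

conv_init <- function(cout, cin, k, gain = 2) {
  w <- array(stats::rnorm(cout * cin * k * k, sd = sqrt(gain / (cin * k * k))),
             c(cout, cin, k, k))
  list(w = w, b = numeric(cout))
}

lin_init <- function(mout, kin, gain = 2) {
  list(w = matrix(stats::rnorm(mout * kin, sd = sqrt(gain / kin)), mout, kin),
       b = numeric(mout))
}

# largest divisor of C that is <= r (used to keep reduction ratios valid for
# narrow test-preset widths)
pick_reduction <- function(C, r) {
  r <- min(max(1L, as.integer(r)), as.integer(C))
  while (C %% r != 0L) r <- r - 1L
  r
}

# ---- squeeze and excitation --------------------------------------------------

#' Construct squeeze-and-excitation (SE) weights
#'
#' The SE block gates each channel by a factor in (0, 1) computed from the
#' channel's global average: squeeze (global average pool), excite (a
#' bottleneck MLP `C -> C/r -> C`), sigmoid.
#'
#' @param C number of channels the block will gate.
#' @param r reduction ratio of the bottleneck; must divide `C`.
#' @param seed integer seed for the deterministic weight draw.
#' @param zero_init logical; if `TRUE` all weights and biases are zero
#'   (useful for analytic fixtures: the gate is then exactly 0.5).
#' @return a list of class `se_weights` with fields `w1`, `b1`, `w2`, `b2`, `r`.
#' @export
se_weights <- function(C, r = 16, seed = 1, zero_init = FALSE) {
  r <- as.integer(r)
  if (r < 1L || C %% r != 0L)
    stop("SE reduction r = ", r, " must be >= 1 and divide C = ", C)
  w <- with_seed(seed, {
    a <- lin_init(C %/% r, C)
    b <- lin_init(C, C %/% r)
    list(w1 = a$w, b1 = a$b, w2 = b$w, b2 = b$b)
  })
  if (zero_init) {
    w$w1[] <- 0; w$b1[] <- 0; w$w2[] <- 0; w$b2[] <- 0
  }
  structure(c(w, list(r = r, C = as.integer(C))), class = "se_weights")
}

# node-level SE; x is a 4D node, weights entries arrays or nodes
se_forward <- function(x, w) {
  s <- ad_gap(x)
  h <- ad_relu(ad_linear(s, w$w1, w$b1))
  gate <- ad_sigmoid(ad_linear(h, w$w2, w$b2))
  ad_scale_channels(x, gate)
}

#' Apply a squeeze-and-excitation block to a feature map
#'
#' @param x a (C, H, W) numeric array of activations.
#' @param w weights from [se_weights()]; `w$C` must equal `dim(x)[1]`.
#' @return a (C, H, W) array: each channel of `x` scaled by its gate.
#' @export
se_apply <- function(x, w) {
  check_fmap(x)
  if (dim(x)[1] != w$C)
    stop("channel mismatch: x has ", dim(x)[1], " channels, weights expect ", w$C)
  fmap3(se_forward(ad_const(fmap4(x)), w)$value)
}

# ---- standard non-local block -----------------------------------------------

#' Construct standard non-local block weights
#'
#' The non-local block computes, for every pair of spatial positions (i, j), a
#' similarity f(x_i, x_j) between linear embeddings theta(x_i) and phi(x_j),
#' aggregates value embeddings g(x_j) weighted by the normalised similarity,
#' and adds the result back residually: z = W_z y + x.  All four maps are
#' 1x1 convolutions.
#'
#' @param C input channel count.
#' @param Cbar embedding width of theta/phi/g (defaults to `C`).
#' @param similarity `"embedded_gaussian"` (softmax-normalised exponential
#'   similarity) or `"dot_product"` (normalised by the position count N = H*W).
#' @param seed seed for deterministic initialisation.
#' @param bias logical; include bias terms on the 1x1 convolutions.
#' @return a list of class `nl_weights`.
#' @export
nl_weights <- function(C, Cbar = C,
                       similarity = c("embedded_gaussian", "dot_product"),
                       seed = 1, bias = TRUE) {
  similarity <- match.arg(similarity)
  stopifnot(Cbar >= 1)
  w <- with_seed(seed, list(
    theta = conv_init(Cbar, C, 1L),
    phi   = conv_init(Cbar, C, 1L),
    g     = conv_init(Cbar, C, 1L),
    z     = conv_init(C, Cbar, 1L)
  ))
  if (!bias) for (nm in names(w)) w[[nm]]$b[] <- 0
  structure(list(theta = w$theta, phi = w$phi, g = w$g, z = w$z,
                 similarity = similarity, C = as.integer(C),
                 Cbar = as.integer(Cbar)),
            class = "nl_weights")
}

# shared embedding step: returns list of 3D (N, Cbar, HW) nodes + dims
nl_embed <- function(x, w) {
  d <- dim(x$value)
  hw <- d[3] * d[4]
  th <- ad_reshape(ad_conv2d(x, w$theta$w, w$theta$b), c(d[1], w$Cbar, hw))
  ph <- ad_reshape(ad_conv2d(x, w$phi$w, w$phi$b), c(d[1], w$Cbar, hw))
  g  <- ad_reshape(ad_conv2d(x, w$g$w, w$g$b), c(d[1], w$Cbar, hw))
  list(theta = th, phi = ph, g = g, d = d, hw = hw)
}

nl_attention_node <- function(x, w) {
  e <- nl_embed(x, w)
  logits <- ad_bmm(e$theta, e$phi, ta = TRUE)        # (N, HW, HW), entry (i,j)
  if (w$similarity == "embedded_gaussian") ad_softmax3(logits)
  else ad_scale_const(logits, 1 / e$hw)
}

nl_forward <- function(x, w) {
  e <- nl_embed(x, w)
  logits <- ad_bmm(e$theta, e$phi, ta = TRUE)
  A <- if (w$similarity == "embedded_gaussian") ad_softmax3(logits)
       else ad_scale_const(logits, 1 / e$hw)
  y <- ad_bmm(e$g, A, tb = TRUE)                     # y_i = sum_j A(i,j) g_j
  y4 <- ad_reshape(y, c(e$d[1], w$Cbar, e$d[3], e$d[4]))
  ad_add(ad_conv2d(y4, w$z$w, w$z$b), x)
}

#' Apply a standard non-local block
#'
#' @inheritParams se_apply
#' @param w weights from [nl_weights()].
#' @return a (C, H, W) array, the residual output z = W_z y + x.
#' @export
nl_apply <- function(x, w) {
  check_fmap(x)
  if (dim(x)[1] != w$C) stop("channel mismatch in nl_apply")
  fmap3(nl_forward(ad_const(fmap4(x)), w)$value)
}

#' Positional attention matrix of the non-local block
#'
#' @inheritParams nl_apply
#' @return an (H*W) x (H*W) matrix; row i holds the attention of query
#'   position i over all positions (row-stochastic for embedded Gaussian).
#' @export
nl_attention <- function(x, w) {
  check_fmap(x)
  a <- nl_attention_node(ad_const(fmap4(x)), w)$value
  matrix(a[1, , ], dim(a)[2], dim(a)[3])
}

# ---- deformed non-local block -----------------------------------------------

#' Construct deformed non-local (DNL) block weights
#'
#' The DNL block flattens the map to C x HW, forms a Cbar x Cbar
#' channel-similarity attention `softmax(theta(x) phi(x)^T)`, aggregates the
#' value embedding into `y1 = A g(x)`, pools it against a 1-channel projection
#' of x into a length-Cbar descriptor `y2`, passes it through a reduce/expand
#' bottleneck (`Cbar -> Cbar/rate -> C`) into channel weights `y4`, multiplies
#' them into a 1x1-convolved copy of x, applies an SE tail and adds x
#' residually.
#'
#' @param C input channel count.
#' @param Cbar embedding width of theta/phi/g (defaults to `C`).
#' @param rate bottleneck reduction of the descriptor; must divide `Cbar`.
#' @param se_r reduction ratio of the SE tail; must divide `C`.
#' @param gate activation on the channel weights y4: `"sigmoid"` (default,
#'   bounds the gate) or `"none"`.
#' @param bottleneck_activation activation after the reduce conv: `"relu"`
#'   (default, mirroring the SE convention) or `"none"`.
#' @param seed seed for deterministic initialisation.
#' @param bias include bias terms.
#' @return a list of class `dnl_weights`.
#' @export
dnl_weights <- function(C, Cbar = C, rate = 4, se_r = 16,
                        gate = c("sigmoid", "none"),
                        bottleneck_activation = c("relu", "none"),
                        seed = 1, bias = TRUE) {
  gate <- match.arg(gate)
  bottleneck_activation <- match.arg(bottleneck_activation)
  rate <- as.integer(rate)
  if (rate < 1L || Cbar %% rate != 0L)
    stop("rate = ", rate, " must divide the descriptor width Cbar = ", Cbar)
  if (C %% se_r != 0L)
    stop("SE tail reduction se_r = ", se_r, " must divide C = ", C)
  w <- with_seed(seed, list(
    theta  = conv_init(Cbar, C, 1L),
    phi    = conv_init(Cbar, C, 1L),
    g      = conv_init(Cbar, C, 1L),
    pool   = conv_init(1L, C, 1L),
    reduce = lin_init(Cbar %/% rate, Cbar),
    expand = lin_init(C, Cbar %/% rate),
    out    = conv_init(C, C, 1L)
  ))
  if (!bias) for (nm in names(w)) w[[nm]]$b[] <- 0
  se <- with_seed(seed + 1L, se_weights(C, r = se_r, seed = seed + 1L))
  structure(c(w, list(se = se, rate = rate, gate = gate,
                      bottleneck_activation = bottleneck_activation,
                      C = as.integer(C), Cbar = as.integer(Cbar))),
            class = "dnl_weights")
}

dnl_attention_node <- function(x, w) {
  e <- nl_embed(x, w)
  ad_softmax3(ad_bmm(e$theta, e$phi, tb = TRUE))  # (N, Cbar, Cbar)
}

dnl_forward <- function(x, w) {
  e <- nl_embed(x, w)
  d <- e$d
  A <- ad_softmax3(ad_bmm(e$theta, e$phi, tb = TRUE))
  y1 <- ad_bmm(A, e$g)                                     # (N, Cbar, HW)
  p <- ad_reshape(ad_conv2d(x, w$pool$w, w$pool$b), c(d[1], 1L, e$hw))
  y2 <- ad_reshape(ad_bmm(p, y1, tb = TRUE), c(d[1], w$Cbar))
  y3 <- ad_linear(y2, w$reduce$w, w$reduce$b)
  if (w$bottleneck_activation == "relu") y3 <- ad_relu(y3)
  y4 <- ad_linear(y3, w$expand$w, w$expand$b)              # (N, C)
  if (w$gate == "sigmoid") y4 <- ad_sigmoid(y4)
  xo <- ad_conv2d(x, w$out$w, w$out$b)
  y <- ad_scale_channels(xo, y4)
  ad_add(se_forward(y, w$se), x)
}

#' Apply a deformed non-local block
#'
#' @inheritParams se_apply
#' @param w weights from [dnl_weights()].
#' @return a (C, H, W) array; the input plus the gated, SE-adjusted
#'   channel-attention response.
#' @export
dnl_apply <- function(x, w) {
  check_fmap(x)
  if (dim(x)[1] != w$C) stop("channel mismatch in dnl_apply")
  fmap3(dnl_forward(ad_const(fmap4(x)), w)$value)
}

#' Channel-similarity attention matrix of the DNL block
#'
#' @inheritParams dnl_apply
#' @return a Cbar x Cbar row-stochastic matrix (contrast with the
#'   (H*W) x (H*W) matrix of [nl_attention()]).
#' @export
dnl_attention <- function(x, w) {
  check_fmap(x)
  a <- dnl_attention_node(ad_const(fmap4(x)), w)$value
  matrix(a[1, , ], dim(a)[2], dim(a)[3])
}

# ---- analytic operation counts ----------------------------------------------

#' Multiply-accumulate counts of the attention-times-value product
#'
#' For the standard non-local block the product of the (HW x HW) similarity
#' with the value embedding costs `Cbar * (HW)^2` multiply-accumulates; for
#' the DNL block the (Cbar x Cbar) attention times the value costs
#' `HW * Cbar^2`.  Their ratio is exactly `HW / Cbar`, the analytic content of
#' the block's complexity-reduction claim.
#'
#' @param Cbar embedding channel width (>= 1).
#' @param H,W spatial dimensions (>= 1).
#' @return a list of class `op_count_report` with `nl_fg_macs`,
#'   `dnl_fg_macs`, and `ratio` (computed in reduced rational arithmetic).
#' @export
fg_product_op_counts <- function(Cbar, H, W) {
  stopifnot(Cbar >= 1, H >= 1, W >= 1)
  hw <- as.numeric(H) * as.numeric(W)
  nl <- as.numeric(Cbar) * hw^2
  dnl <- hw * as.numeric(Cbar)^2
  g <- gcd_num(nl, dnl)
  structure(list(nl_fg_macs = nl, dnl_fg_macs = dnl,
                 ratio = (nl / g) / (dnl / g)),
            class = "op_count_report")
}

gcd_num <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
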