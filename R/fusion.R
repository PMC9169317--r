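# Decoder-side fusion and bottleneck context modules.
#
# MFF (multi-scale feature fusion) gates the encoder skip feature with a
# channel-attention vector computed from the DNL-refined deep feature, and
# adds an upsampled projection of the deep feature:
#   MFF = AV(DNL(x_deep)) (.) x_skip  +  UP(x_deep)
# RSEP (residual squeeze-and-excitation pyramid pooling) runs four parallel
# atrous-convolution + SE branches (dilations 1, 6, 12, 12 by default),
# concatenates them with the input and fuses with a 1x1 convolution.

# ---- channel attention vector -----------------------------------------------

#' Construct channel-attention-vector weights
#'
#' @param C_in channels of the map the vector is computed from.
#' @param C_out length of the attention vector (channels of the map it gates).
#' @param activation `"sigmoid"` (bounded gate, default) or `"none"`.
#' @param seed seed for deterministic initialisation.
#' @return a list of class `av_weights`.
#' @export
av_weights <- function(C_in, C_out = C_in, activation = c("sigmoid", "none"),
                       seed = 1) {
  activation <- match.arg(activation)
  w <- with_seed(seed, lin_init(C_out, C_in))
  structure(list(w = w$w, b = w$b, activation = activation,
                 C_in = as.integer(C_in), C_out = as.integer(C_out)),
            class = "av_weights")
}

cav_node <- function(x, w) {
  v <- ad_l2norm_rows(ad_gap(x))
  av <- ad_linear(v, w$w, w$b)
  if (w$activation == "sigmoid") av <- ad_sigmoid(av)
  av
}

#' Channel attention vector: 1x1 conv of the L2-normalised global average
#'
#' Computes `AV = act(Conv1x1(Normalize(GAP(x))))`: the per-channel global
#' average, L2-normalised as a vector (a zero vector maps to a zero vector),
#' then a linear map `C_in -> C_out` and the configured gate activation.
#'
#' @inheritParams se_apply
#' @param w weights from [av_weights()].
#' @return a numeric vector of length `w$C_out`.
#' @export
channel_attention_vector <- function(x, w) {
  check_fmap(x)
  if (dim(x)[1] != w$C_in) stop("channel mismatch in channel_attention_vector")
  as.numeric(cav_node(ad_const(fmap4(x)), w)$value)
}

# ---- multi-scale feature fusion ---------------------------------------------

#' Configuration for the MFF decoder module
#'
#' @param upsample_mode `"bilinear"` (default) or `"nearest"`; the x2
#'   upsampling applied to the deep feature.
#' @param gate_activation activation of the channel attention vector.
#' @return a list of class `mff_config`.
#' @export
mff_config <- function(upsample_mode = c("bilinear", "nearest"),
                       gate_activation = c("sigmoid", "none")) {
  structure(list(upsample_mode = match.arg(upsample_mode),
                 gate_activation = match.arg(gate_activation)),
            class = "mff_config")
}

#' Construct the weight set of one MFF stage
#'
#' Holds the DNL block applied to the deep feature, the attention-vector map
#' (deep channels -> skip channels) and a 1x1 projection aligning deep
#' channels to skip channels before the upsampled addition.
#'
#' @param C_deep channels of the deeper (coarser) feature.
#' @param C_skip channels of the encoder skip feature.
#' @param cfg an [mff_config()].
#' @param dnl optional pre-built [dnl_weights()] for `C_deep`.
#' @param seed seed for deterministic initialisation.
#' @return a list of class `mff_weights`.
#' @export
mff_weights <- function(C_deep, C_skip, cfg = mff_config(), dnl = NULL, seed = 1) {
  if (is.null(dnl))
    dnl <- dnl_weights(C_deep, rate = pick_reduction(C_deep, 4L),
                       se_r = pick_reduction(C_deep, 16L), seed = seed)
  av <- av_weights(C_deep, C_skip, activation = cfg$gate_activation,
                   seed = seed + 1L)
  proj <- with_seed(seed + 2L, conv_init(C_skip, C_deep, 1L))
  structure(list(dnl = dnl, av = av, proj = proj, cfg = cfg,
                 C_deep = as.integer(C_deep), C_skip = as.integer(C_skip)),
            class = "mff_weights")
}

mff_node <- function(x_deep, x_skip, w) {
  refined <- dnl_forward(x_deep, w$dnl)
  av <- cav_node(refined, w$av)                      # (N, C_skip)
  mu <- ad_scale_channels(x_skip, av)
  up <- ad_upsample2(ad_conv2d(x_deep, w$proj$w, w$proj$b),
                     mode = w$cfg$upsample_mode)
  ad_add(mu, up)
}

#' Fuse a deep decoder feature with an encoder skip feature
#'
#' The deep feature is refined by its DNL block; its channel attention vector
#' gates the skip feature; the deep feature itself is projected to the skip
#' width and upsampled x2; the two terms are added.
#'
#' @param x_deep (C_deep, H, W) array, the coarser decoder feature.
#' @param x_skip (C_skip, 2H, 2W) array, the encoder skip feature.
#' @param w weights from [mff_weights()].
#' @return a (C_skip, 2H, 2W) array.
#' @export
mff_fuse <- function(x_deep, x_skip, w) {
  check_fmap(x_deep, "x_deep"); check_fmap(x_skip, "x_skip")
  dd <- dim(x_deep); ds <- dim(x_skip)
  if (!(ds[2] == 2L * dd[2] && ds[3] == 2L * dd[3]))
    stop("x_skip spatial size (", ds[2], "x", ds[3],
         ") must be exactly twice x_deep (", dd[2], "x", dd[3], ")")
  if (dd[1] != w$C_deep || ds[1] != w$C_skip)
    stop("channel mismatch in mff_fuse")
  fmap3(mff_node(ad_const(fmap4(x_deep)), ad_const(fmap4(x_skip)), w)$value)
}

# ---- residual SE pyramid pooling --------------------------------------------

#' Configuration for the RSEP bottleneck
#'
#' @param dilations dilation factors of the four parallel atrous branches.
#'   The default `c(1, 6, 12, 12)` duplicates 12; a `c(1, 6, 12, 18)` variant
#'   is available via this argument.
#' @param branch_channels channel width of each branch (default `C/4` at
#'   build time).
#' @param se_reduction SE reduction inside each branch.
#' @param pad_cap warn when a branch's padding (`dilation`, for the 3x3
#'   kernels) reaches this fraction of the smaller spatial extent.
#' @return a list of class `rsep_config`.
#' @export
rsep_config <- function(dilations = c(1L, 6L, 12L, 12L), branch_channels = NULL,
                        se_reduction = 16L, pad_cap = 1) {
  structure(list(dilations = as.integer(dilations),
                 branch_channels = branch_channels,
                 se_reduction = as.integer(se_reduction),
                 pad_cap = pad_cap),
            class = "rsep_config")
}

#' Construct RSEP weights
#'
#' @param C input (and output) channel count.
#' @param cfg an [rsep_config()].
#' @param seed seed for deterministic initialisation.
#' @return a list of class `rsep_weights` containing one
#'   atrous-conv + SE + 1x1-conv weight set per branch and the final fusion
#'   1x1 convolution mapping `C + n_branches * branch_channels` back to `C`.
#' @export
rsep_weights <- function(C, cfg = rsep_config(), seed = 1) {
  bc <- cfg$branch_channels
  if (is.null(bc)) bc <- max(1L, C %/% 4L)
  bc <- as.integer(bc)
  ser <- pick_reduction(bc, cfg$se_reduction)
  branches <- lapply(seq_along(cfg$dilations), function(i) {
    list(conv = with_seed(seed + 10L * i, conv_init(bc, C, 3L)),
         se = se_weights(bc, r = ser, seed = seed + 10L * i + 1L),
         pw = with_seed(seed + 10L * i + 2L, conv_init(bc, bc, 1L)),
         dilation = cfg$dilations[i])
  })
  fuse <- with_seed(seed + 99L, conv_init(C, C + length(branches) * bc, 1L))
  structure(list(branches = branches, fuse = fuse, cfg = cfg,
                 C = as.integer(C), branch_channels = bc,
                 warned = new.env(parent = emptyenv())),
            class = "rsep_weights")
}

rsep_node <- function(x, w, identity_gates = FALSE) {
  d <- dim(x$value)
  cap <- w$cfg$pad_cap * min(d[3], d[4])
  outs <- vector("list", length(w$branches) + 1L)
  outs[[1L]] <- x
  for (i in seq_along(w$branches)) {
    br <- w$branches[[i]]
    key <- paste(br$dilation, d[3], d[4])
    if (br$dilation > cap && !isTRUE(w$warned[[key]])) {
      w$warned[[key]] <- TRUE      # once per weight set and map size
      warning("RSEP branch dilation ", br$dilation, " pads beyond ",
              round(cap), " pixels for a ", d[3], "x", d[4], " map")
    }
    h <- ad_conv2d(x, br$conv$w, br$conv$b, pad = br$dilation, dil = br$dilation)
    if (!identity_gates) h <- se_forward(h, br$se)
    h <- ad_conv2d(h, br$pw$w, br$pw$b)
    if (!identity_gates) h <- ad_relu(h)
    outs[[i + 1L]] <- h
  }
  ad_conv2d(ad_concat_chan(outs), w$fuse$w, w$fuse$b)
}

#' Apply the residual SE pyramid pooling bottleneck
#'
#' Each branch is a 3x3 atrous convolution (zero padding equal to its
#' dilation, so the spatial size is preserved), an SE gate, a 1x1 convolution
#' and a ReLU.  The original map and the branch outputs are concatenated along
#' channels and fused back to the input width by a final 1x1 convolution.
#'
#' @inheritParams se_apply
#' @param w weights from [rsep_weights()].
#' @param identity_gates internal switch used to verify linearity: bypasses
#'   the SE gates and ReLUs.
#' @return a (C, H, W) array.
#' @export
rsep_apply <- function(x, w, identity_gates = FALSE) {
  check_fmap(x)
  if (dim(x)[1] != w$C) stop("channel mismatch in rsep_apply")
  fmap3(rsep_node(ad_const(fmap4(x)), w, identity_gates)$value)
}

#' Effective receptive field of a dilated kernel
#'
#' `k_eff = k + (k - 1) (d - 1)`: a 3x3 kernel at dilation 12 covers
#' 25 x 25 pixels.
#'
#' @param k kernel size.
#' @param d dilation factor.
#' @return the effective kernel extent in pixels.
#' @export
effective_receptive_field <- function(k, d) k + (k - 1L) * (d - 1L)
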