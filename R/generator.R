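# Holistically-nested U-Net generator: a 4-stage encoder/decoder with an
# optional inverted-residual stem, per-depth single-channel side outputs,
# softmax attention fusion across depths, and a sigmoid segmentation head.

#' Generator configuration
#'
#' @param in_channels 1 (single slice) or 3 (pseudo-colour composite).
#' @param base_widths channel counts of the four encoder stages; strictly
#'   increasing by default.
#' @param expansion_factor channel expansion inside the inverted residual
#'   stem blocks.
#' @param use_inverted_residual include the two-block inverted residual stem.
#' @param use_hed use per-depth side outputs with attention fusion; when
#'   `FALSE` the network reduces to a plain U-Net with a single 1x1 head.
#' @return a `gen_config` list.
#' @export
gen_config <- function(in_channels = 3L,
                       base_widths = c(32L, 64L, 128L, 256L),
                       expansion_factor = 4L,
                       use_inverted_residual = TRUE,
                       use_hed = TRUE) {
  stopifnot(in_channels %in% c(1L, 3L), length(base_widths) == 4)
  structure(list(in_channels = as.integer(in_channels),
                 base_widths = as.integer(base_widths),
                 expansion_factor = as.integer(expansion_factor),
                 use_inverted_residual = isTRUE(use_inverted_residual),
                 use_hed = isTRUE(use_hed),
                 levels = 4L),
            class = "gen_config")
}

# (conv3x3 + BN + ReLU) x 2
make_double_conv <- function(in_ch, out_ch) {
  list(c1 = conv_layer(in_ch, out_ch, 3L),
       n1 = batchnorm_layer(out_ch),
       c2 = conv_layer(out_ch, out_ch, 3L),
       n2 = batchnorm_layer(out_ch))
}

double_conv_fwd <- function(blk, x, train) {
  h <- t_relu(batchnorm_fwd(blk$n1, conv_fwd(blk$c1, x), train))
  t_relu(batchnorm_fwd(blk$n2, conv_fwd(blk$c2, h), train))
}

#' Build an inverted residual block
#'
#' Expand (1x1 conv), depthwise 3x3 convolution, squeeze-excitation channel
#' gating (global average descriptor -> two fully connected layers ->
#' sigmoid gates), 1x1 projection back to the input width, plus a residual
#' skip. Output channel count always equals the input channel count.
#'
#' @param channels input (= output) channel count.
#' @param expansion_factor internal channel multiplier.
#' @return an inverted-residual module list.
#' @export
make_ir_block <- function(channels, expansion_factor = 4L) {
  ex <- channels * expansion_factor
  hidden <- max(2L, as.integer(ceiling(ex / 4)))
  list(type = "ir_block", channels = as.integer(channels),
       expand = conv_layer(channels, ex, 1L, pad = 0L),
       bn1 = batchnorm_layer(ex),
       dw = conv_layer(ex, ex, 3L, groups = ex),
       bn2 = batchnorm_layer(ex),
       fc1 = linear_layer(ex, hidden),
       fc2 = linear_layer(hidden, ex),
       project = conv_layer(ex, channels, 1L, pad = 0L),
       bn3 = batchnorm_layer(channels))
}

#' Inverted residual block forward pass
#'
#' @param block a module from [make_ir_block()].
#' @param x input tensor `[H, W, C, N]` with `C == block$channels`.
#' @param train training-mode flag for the norm layers.
#' @return tensor of the same shape as `x`.
#' @export
ir_block_forward <- function(block, x, train = TRUE) {
  if (dim(x$value)[3] != block$channels)
    stop("ir_block: input channel count does not match block configuration")
  h <- t_relu(batchnorm_fwd(block$bn1, conv_fwd(block$expand, x), train))
  h <- t_relu(batchnorm_fwd(block$bn2, conv_fwd(block$dw, h), train))
  # squeeze-excitation: global descriptor -> two FC layers -> per-channel gates
  gate <- t_sigmoid(linear_fwd(block$fc2, t_relu(linear_fwd(block$fc1, t_gap(h)))))
  h <- t_channel_gate(h, gate)
  h <- batchnorm_fwd(block$bn3, conv_fwd(block$project, h), train)
  t_add(h, x)
}

#' Build the generator
#'
#' @param config a [gen_config()].
#' @return a generator module list.
#' @export
make_generator <- function(config = gen_config()) {
  w <- config$base_widths
  ic <- config$in_channels
  stem <- if (config$use_inverted_residual)
    list(make_ir_block(ic, config$expansion_factor),
         make_ir_block(ic, config$expansion_factor))
  else NULL
  enc <- list(make_double_conv(ic, w[1]),
              make_double_conv(w[1], w[2]),
              make_double_conv(w[2], w[3]),
              make_double_conv(w[3], w[4]))
  dec <- list(make_double_conv(w[3] + w[4], w[3]),
              make_double_conv(w[2] + w[3], w[2]),
              make_double_conv(w[1] + w[2], w[1]))
  if (config$use_hed) {
    dk_ch <- c(w[1], w[2], w[3], w[4])  # d_1 .. d_4 channel widths
    side_p <- lapply(dk_ch, function(ch) conv_layer(ch, 1L, 1L, pad = 0L))
    side_q <- lapply(dk_ch, function(ch) conv_layer(ch, 1L, 1L, pad = 0L))
    fusion_w <- ng_tensor(rep(1, 4), requires_grad = TRUE)
    head <- NULL
  } else {
    side_p <- side_q <- fusion_w <- NULL
    head <- conv_layer(w[1], 1L, 1L, pad = 0L)
  }
  structure(list(config = config, stem = stem, enc = enc, dec = dec,
                 side_p = side_p, side_q = side_q, fusion_w = fusion_w,
                 head = head),
            class = "nodulegan_generator")
}

#' Project a decoder feature map to a side output
#'
#' Applies a 1x1 convolution to produce the native-resolution single-channel
#' logit map `s_k`, then bilinearly upsamples it to the input resolution
#' (`F_k`). At full resolution the upsampling is the identity.
#'
#' @param p_layer the 1x1 convolution layer `p_k`.
#' @param d_k decoder feature tensor at depth k.
#' @param out_size input spatial size the upsampled map must match.
#' @return list with tensors `s` (native) and `F` (upsampled).
#' @export
side_project <- function(p_layer, d_k, out_size) {
  s <- conv_fwd(p_layer, d_k)
  list(s = s, F = t_upsample(s, out_size[1], out_size[2]))
}

#' Generator forward pass
#'
#' @param gen a generator from [make_generator()].
#' @param x input tensor or `[H, W, C, N]` array; spatial size must be
#'   divisible by 8.
#' @param train training-mode flag (batch statistics).
#' @return list with `prob` (`[H, W, 1, N]` tensor of mask probabilities),
#'   `logit` (pre-sigmoid fusion), `side` (native logits `s`, upsampled maps
#'   `F`, attention weights tensor `A` of dim `[H, W, 4, N]`), and
#'   `fusion_w` (the trainable per-depth fusion weights).
#' @export
generator_forward <- function(gen, x, train = TRUE) {
  if (!is_tensor(x)) x <- ng_tensor(x)
  d <- dim(x$value)
  if (d[3] != gen$config$in_channels)
    stop("generator input channel count does not match config$in_channels")
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("generator input spatial size must be divisible by 8")
  h <- x
  if (!is.null(gen$stem))
    for (blk in gen$stem) h <- ir_block_forward(blk, h, train)
  e1 <- double_conv_fwd(gen$enc[[1]], h, train)
  e2 <- double_conv_fwd(gen$enc[[2]], t_maxpool2(e1), train)
  e3 <- double_conv_fwd(gen$enc[[3]], t_maxpool2(e2), train)
  d4 <- double_conv_fwd(gen$enc[[4]], t_maxpool2(e3), train)
  up <- function(t, ref) t_upsample(t, dim(ref$value)[1], dim(ref$value)[2])
  d3 <- double_conv_fwd(gen$dec[[1]], t_cat_any(list(up(d4, e3), e3)), train)
  d2 <- double_conv_fwd(gen$dec[[2]], t_cat_any(list(up(d3, e2), e2)), train)
  d1 <- double_conv_fwd(gen$dec[[3]], t_cat_any(list(up(d2, e1), e1)), train)
  dk <- list(d1, d2, d3, d4)
  out_size <- d[1:2]
  if (gen$config$use_hed) {
    side <- lapply(1:4, function(k) side_project(gen$side_p[[k]], dk[[k]], out_size))
    s_list <- lapply(side, `[[`, "s")
    F_list <- lapply(side, `[[`, "F")
    q_list <- lapply(1:4, function(k)
      t_upsample(conv_fwd(gen$side_q[[k]], dk[[k]]), out_size[1], out_size[2]))
    A <- t_softmax_channels(t_cat_channels(q_list))
    fused <- t_sum_channels(
      t_channel_scale(t_mul(A, t_cat_channels(F_list)), gen$fusion_w))
    list(prob = t_sigmoid(fused), logit = fused,
         side = list(native = s_list, upsampled = F_list, attention = A),
         fusion_w = gen$fusion_w)
  } else {
    logit <- conv_fwd(gen$head, d1)
    list(prob = t_sigmoid(logit), logit = logit,
         side = NULL, fusion_w = NULL)
  }
}

# concatenate feature tensors with arbitrary channel counts along dim 3
t_cat_any <- function(maps) {
  dims <- lapply(maps, function(m) dim(m$value))
  ch <- vapply(dims, `[`, integer(1), 3L)
  d1 <- dims[[1]]
  y <- array(0, c(d1[1], d1[2], sum(ch), d1[4]))
  ends <- cumsum(ch)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (i in seq_along(maps)) y[, , starts[i]:ends[i], ] <- maps[[i]]$value
  ng_node(y, maps, function(g) {
    lapply(seq_along(maps), function(i) {
      gk <- g[, , starts[i]:ends[i], , drop = FALSE]
      dim(gk) <- dims[[i]]
      gk
    })
  }, "cat_any")
}
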