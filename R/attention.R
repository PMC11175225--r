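# Convolutional block attention (CBAM): sequential channel attention then
# spatial attention, applied to the locally fused features of each RDAB.

#' Channel attention weights
#'
#' Global average-pooled and global max-pooled channel descriptors are each
#' passed through a shared two-layer bottleneck (`C -> C/r -> C`, ReLU in
#' between, no biases); the two outputs are summed and sigmoid-squashed into
#' per-channel weights in (0, 1).
#'
#' @param f feature tensor `(H, W, C, N)`.
#' @param cbam the CBAM parameter list of a block (`mlp_w1`, `mlp_w2`,
#'   `spatial`).
#' @param reduction bottleneck reduction ratio; must be smaller than the
#'   channel count.
#' @return an autodiff tensor of channel weights, shape `(C, N)`.
#' @export
channel_attention <- function(f, cbam, reduction = 16L) {
  f <- as_tensor(f)
  ch <- dim(f$value)[3]
  if (reduction >= ch)
    stop("configuration error: reduction ratio must be smaller than the channel count")
  mlp <- function(v) op_matmul(op_relu(op_matmul(v, cbam$mlp_w1)), cbam$mlp_w2)
  logits <- op_add(mlp(op_gap(f)), mlp(op_gmp(f)))
  op_sigmoid(logits)
}

#' Spatial attention weights
#'
#' Per-pixel mean and max across channels are stacked into a two-channel map
#' and convolved with a single `k x k` kernel (default 7), then
#' sigmoid-squashed into per-pixel weights in (0, 1).
#'
#' @inheritParams channel_attention
#' @return an autodiff tensor of spatial weights, shape `(H, W, 1, N)`.
#' @export
spatial_attention <- function(f, cbam) {
  f <- as_tensor(f)
  k <- dim(cbam$spatial$w$value)[1]
  if (k %% 2L != 1L)
    stop("configuration error: spatial attention kernel must be odd")
  pooled <- op_concat_c(list(op_cmean(f), op_cmax(f)))
  op_sigmoid(op_conv2d(pooled, cbam$spatial$w, cbam$spatial$b))
}

#' CBAM refinement
#'
#' Sequential attention: the features are first scaled per channel, then the
#' channel-refined features are scaled per pixel. The order
#' (channel-then-spatial) is fixed.
#'
#' @inheritParams channel_attention
#' @param spec a [generator_spec()] (supplies the reduction ratio).
#' @return the refined feature tensor, same shape as `f`.
#' @export
cbam_refine <- function(f, cbam, spec = generator_spec()) {
  f <- as_tensor(f)
  cw <- channel_attention(f, cbam, spec$cbam_reduction)
  fc <- op_scale_channels(f, cw)
  sw <- spatial_attention(fc, cbam)
  op_scale_spatial(fc, sw)
}
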