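# The residual dense attention generator: shallow feature extraction, a stack
# of residual dense attention blocks (RDABs), dense feature fusion with global
# residual learning, and sub-pixel upsampling reconstruction.

#' Generator architecture specification
#'
#' Describes every architectural hyperparameter of the super-resolution
#' generator. The defaults are the calibrated configuration of the package:
#' 16 RDABs with 7 densely connected convolutions per block, growth rate 48,
#' base width 64 and a global-fusion hidden width of 380, which together give
#' a trainable-parameter budget of 11.25 M at scale 2.
#'
#' @param num_blocks number of RDABs (`D`); default 16.
#' @param convs_per_block densely connected conv+ReLU layers per block (`C`).
#' @param growth channels added by each dense layer (`G`).
#' @param base_channels width of the shallow features and of all fused
#'   features (`G0`).
#' @param fusion_width hidden width of the global feature fusion stage (the
#'   1x1 fusion conv maps `D * G0` channels to this width before the 3x3 conv
#'   maps back to `G0`).
#' @param scale integer upscaling factor; must be a power of 2.
#' @param kernel_size odd spatial kernel size of the 3x3-class convolutions.
#' @param cbam_enabled apply CBAM inside each block?
#' @param cbam_reduction channel-attention bottleneck reduction ratio `r`.
#' @param cbam_spatial_kernel spatial-attention kernel size (odd).
#' @param cbam_position `"pre_residual"` applies CBAM to the locally fused
#'   features before the residual addition; `"post_residual"` after it.
#' @param use_rdb `TRUE` for residual dense blocks; `FALSE` swaps in a plain
#'   two-convolution residual block (ablation configuration).
#' @param in_channels,out_channels image channel counts (RGB: 3).
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(num_blocks = 16L, convs_per_block = 7L, growth = 48L,
                           base_channels = 64L, fusion_width = 380L,
                           scale = 2L, kernel_size = 3L,
                           cbam_enabled = TRUE, cbam_reduction = 16L,
                           cbam_spatial_kernel = 7L,
                           cbam_position = c("pre_residual", "post_residual"),
                           use_rdb = TRUE, in_channels = 3L, out_channels = 3L) {
  cbam_position <- match.arg(cbam_position)
  spec <- list(
    num_blocks = as.integer(num_blocks),
    convs_per_block = as.integer(convs_per_block),
    growth = as.integer(growth),
    base_channels = as.integer(base_channels),
    fusion_width = as.integer(fusion_width),
    scale = as.integer(scale),
    kernel_size = as.integer(kernel_size),
    cbam_enabled = isTRUE(cbam_enabled),
    cbam_reduction = as.integer(cbam_reduction),
    cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
    cbam_position = cbam_position,
    use_rdb = isTRUE(use_rdb),
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels)
  )
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  with(spec, {
    if (num_blocks < 1 || convs_per_block < 1 || growth < 1 || base_channels < 1)
      stop("generator_spec: block counts and widths must be positive integers")
    if (kernel_size %% 2L != 1L || kernel_size < 1L)
      stop("generator_spec: kernel_size must be an odd positive integer")
    if (cbam_spatial_kernel %% 2L != 1L)
      stop("generator_spec: cbam_spatial_kernel must be odd")
    if (scale < 1L || bitwAnd(scale, scale - 1L) != 0L)
      stop("unsupported configuration: scale must be a power of 2")
    if (cbam_enabled && cbam_reduction >= base_channels)
      stop("generator_spec: cbam_reduction must be smaller than base_channels")
  })
  invisible(spec)
}

#' Serialize / deserialize a generator specification
#'
#' Round-trips a [generator_spec()] through structured JSON text; the
#' round-trip is the identity.
#'
#' @param spec a `generator_spec`.
#' @param json a JSON string from `generator_spec_to_json()`.
#' @return a JSON string, or the reconstructed `generator_spec`.
#' @export
generator_spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
}

#' @rdname generator_spec_to_json
#' @export
generator_spec_from_json <- function(json) {
  do.call(generator_spec, jsonlite::fromJSON(json))
}

#' Build a generator with freshly initialized parameters
#'
#' Convolution weights use Kaiming fan-in initialization, biases start at
#' zero. Initialization draws from the current R RNG stream, so a prior
#' `set.seed()` makes construction reproducible.
#'
#' @param spec a [generator_spec()].
#' @return an object of class `rdagan_generator` holding the spec and all
#'   parameter tensors.
#' @export
build_generator <- function(spec = generator_spec()) {
  k <- spec$kernel_size
  g0 <- spec$base_channels
  g <- spec$growth
  cc <- spec$convs_per_block

  make_cbam <- function() {
    hidden <- max(1L, g0 %/% spec$cbam_reduction)
    list(
      mlp_w1 = ag_param(matrix(rnorm(g0 * hidden, sd = sqrt(2 / g0)), g0, hidden)),
      mlp_w2 = ag_param(matrix(rnorm(hidden * g0, sd = sqrt(2 / hidden)), hidden, g0)),
      spatial = layer_conv(spec$cbam_spatial_kernel, 2L, 1L)
    )
  }

  # residual-branch convolutions start at a tenth of the Kaiming magnitude
  # (the ESRGAN initialization), so every block is near-identity at step 0;
  # extraction and reconstruction layers use the full magnitude
  res_scale <- 0.1
  make_block <- function() {
    blk <- if (spec$use_rdb) {
      dense <- lapply(seq_len(cc), function(c)
        layer_conv(k, g0 + (c - 1L) * g, g, init_scale = res_scale))
      list(dense = dense,
           lff = layer_conv(1L, g0 + cc * g, g0, init_scale = res_scale))
    } else {
      list(conv1 = layer_conv(k, g0, g0, init_scale = res_scale),
           conv2 = layer_conv(k, g0, g0, init_scale = res_scale))
    }
    if (spec$cbam_enabled) blk$cbam <- make_cbam()
    blk
  }

  n_stages <- as.integer(round(log2(spec$scale)))
  params <- list(
    sfe = layer_conv(k, spec$in_channels, g0),
    blocks = lapply(seq_len(spec$num_blocks), function(i) make_block()),
    gff1 = layer_conv(1L, spec$num_blocks * g0, spec$fusion_width,
                      init_scale = res_scale),
    gff3 = layer_conv(k, spec$fusion_width, g0, init_scale = res_scale),
    upsample = lapply(seq_len(n_stages), function(i)
      list(conv = layer_conv(k, g0, 4L * g0), prelu = layer_prelu(g0))),
    out_conv = layer_conv(k, g0, spec$out_channels)
  )
  structure(list(spec = spec, params = params), class = "rdagan_generator")
}

# ---- forward passes ---------------------------------------------------------

#' Shallow feature extraction
#'
#' First convolution of the generator: lifts the RGB low-resolution input to
#' `base_channels` feature channels at unchanged spatial size. The result is
#' both the input of the first RDAB and the global residual term.
#'
#' @param generator an `rdagan_generator`.
#' @param lr a `raster_image`, an `(H, W, 3)` array, an `(H, W, 3, N)` batch
#'   array, or an autodiff tensor thereof.
#' @return an autodiff tensor of shape `(H, W, base_channels, N)`.
#' @export
shallow_extract <- function(generator, lr) {
  x <- as_feature_batch(lr)
  if (dim(x$value)[3] != generator$spec$in_channels)
    stop("invalid input: expected ", generator$spec$in_channels, "-channel image")
  op_conv2d(x, generator$params$sfe$w, generator$params$sfe$b)
}

#' Densely connected convolutions with local feature fusion
#'
#' Runs the `C` conv+ReLU layers of one residual dense block, each consuming
#' the channel-concatenation of the block input and every previous layer
#' output, then fuses block input plus all layer outputs with a 1x1
#' convolution back to `base_channels` (local feature fusion).
#'
#' @param f_in block input tensor with `base_channels` channels.
#' @param block one element of `generator$params$blocks`.
#' @param spec the `generator_spec`.
#' @return list with `f_lf` (the fused features) and `layer_outputs`.
#' @export
rdb_dense_forward <- function(f_in, block, spec) {
  f_in <- as_tensor(f_in)
  if (dim(f_in$value)[3] != spec$base_channels)
    stop("invalid state: block input must have base_channels channels")
  feats <- list(f_in)
  outs <- vector("list", spec$convs_per_block)
  for (c in seq_len(spec$convs_per_block)) {
    x <- if (length(feats) == 1L) f_in else op_concat_c(feats)
    conv <- block$dense[[c]]
    if (dim(x$value)[3] != dim(conv$w$value)[3])
      stop("invalid state: dense-layer channel mismatch")
    y <- op_relu(op_conv2d(x, conv$w, conv$b))
    outs[[c]] <- y
    feats[[c + 1L]] <- y
  }
  cat_all <- op_concat_c(feats)
  f_lf <- op_conv2d(cat_all, block$lff$w, block$lff$b, pad = 0L)
  list(f_lf = f_lf, layer_outputs = outs)
}

#' One residual dense attention block
#'
#' Local residual learning around the densely fused features: the block
#' output is `f_prev + CBAM(f_lf)` (with `cbam_position = "pre_residual"`),
#' or `f_prev + f_lf` when CBAM is disabled. With `use_rdb = FALSE` the dense
#' wiring is replaced by a plain conv-ReLU-conv residual body.
#'
#' @inheritParams rdb_dense_forward
#' @param f_prev output of the previous block (or the shallow features).
#' @return the block output tensor, same shape as `f_prev`.
#' @export
rdab_forward <- function(f_prev, block, spec) {
  f_prev <- as_tensor(f_prev)
  body <- if (spec$use_rdb) {
    rdb_dense_forward(f_prev, block, spec)$f_lf
  } else {
    op_conv2d(op_relu(op_conv2d(f_prev, block$conv1$w, block$conv1$b)),
              block$conv2$w, block$conv2$b)
  }
  if (spec$cbam_enabled && spec$cbam_position == "pre_residual")
    body <- cbam_refine(body, block$cbam, spec)
  out <- op_add(f_prev, body)
  if (spec$cbam_enabled && spec$cbam_position == "post_residual")
    out <- cbam_refine(out, block$cbam, spec)
  out
}

#' Dense feature fusion with global residual learning
#'
#' Concatenates the outputs of all `D` blocks, fuses them with a 1x1 then a
#' 3x3 convolution (global feature fusion) and adds the shallow features
#' (global residual learning).
#'
#' @param f0 the shallow features.
#' @param block_outputs list of the `D` block outputs.
#' @param generator an `rdagan_generator`.
#' @return the fused feature tensor with `base_channels` channels.
#' @export
dense_feature_fusion <- function(f0, block_outputs, generator) {
  spec <- generator$spec
  if (length(block_outputs) != spec$num_blocks)
    stop("invalid state: expected ", spec$num_blocks, " block outputs")
  f0 <- as_tensor(f0)
  d0 <- dim(f0$value)
  for (b in block_outputs) {
    db <- dim(as_tensor(b)$value)
    if (!identical(db, d0))
      stop("invalid state: block outputs must match the shallow feature dims")
  }
  cat_all <- op_concat_c(block_outputs)
  fgf <- op_conv2d(cat_all, generator$params$gff1$w, generator$params$gff1$b, pad = 0L)
  fgf <- op_conv2d(fgf, generator$params$gff3$w, generator$params$gff3$b)
  op_add(f0, fgf)
}

#' Sub-pixel upsampling reconstruction
#'
#' One conv + pixel-shuffle + PReLU stage per factor of 2 in `scale`, then a
#' final convolution to RGB. The raw (unclipped) output is returned as a
#' tensor; use `clip = TRUE` for inference-time clipping to `[0, 1]`.
#'
#' @param fdf fused feature tensor with `base_channels` channels.
#' @param generator an `rdagan_generator`.
#' @param clip clip the output into `[0, 1]`?
#' @return an autodiff tensor of shape `(scale*H, scale*W, 3, N)`.
#' @export
upsample_reconstruct <- function(fdf, generator, clip = FALSE) {
  spec <- generator$spec
  validate_generator_spec(spec)
  x <- as_tensor(fdf)
  for (stage in generator$params$upsample) {
    x <- op_conv2d(x, stage$conv$w, stage$conv$b)
    x <- op_pixel_shuffle(x, 2L)
    x <- op_prelu(x, stage$prelu$alpha)
  }
  x <- op_conv2d(x, generator$params$out_conv$w, generator$params$out_conv$b)
  if (clip) x <- op_clamp(x, 0, 1)
  x
}

#' Full generator forward pass
#'
#' Composition of shallow extraction, the RDAB stack, dense feature fusion
#' and upsampling reconstruction. Deterministic given parameters and input.
#'
#' @param generator an `rdagan_generator`.
#' @param lr low-resolution input (see [shallow_extract()]).
#' @param train keep the output unclipped (loss sees raw values)? With
#'   `train = FALSE` the output is clipped to `[0, 1]`.
#' @return an autodiff tensor of shape `(scale*H, scale*W, 3, N)`.
#' @export
generator_forward <- function(generator, lr, train = FALSE) {
  spec <- generator$spec
  f0 <- shallow_extract(generator, lr)
  f <- f0
  outs <- vector("list", spec$num_blocks)
  for (d in seq_len(spec$num_blocks)) {
    f <- rdab_forward(f, generator$params$blocks[[d]], spec)
    outs[[d]] <- f
  }
  fdf <- dense_feature_fusion(f0, outs, generator)
  upsample_reconstruct(fdf, generator, clip = !train)
}

#' Super-resolve an image
#'
#' Convenience wrapper returning a clipped RGB [raster_image()] (or a list of
#' them for a batch input).
#'
#' @param generator an `rdagan_generator` or a fitted [rdagan()] model.
#' @param lr low-resolution input image(s).
#' @return a `raster_image` (single input) or list of them (batch input).
#' @export
sr_upscale <- function(generator, lr) {
  if (inherits(generator, "rdagan")) generator <- generator$generator
  out <- generator_forward(generator, lr, train = FALSE)$value
  n <- dim(out)[4]
  imgs <- lapply(seq_len(n), function(i)
    raster_image(array(out[, , , i], dim = dim(out)[1:3])))
  if (n == 1L) imgs[[1]] else imgs
}

#' Count trainable generator parameters
#'
#' Total number of trainable scalars (weights and biases) of a generator, a
#' discriminator, or any parameter module.
#'
#' @param x an `rdagan_generator`, fitted `rdagan` model, or parameter module.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "rdagan")) x <- x$generator
  module <- if (inherits(x, "rdagan_generator")) x$params else x
  as.integer(n_params(module))
}

#' @rdname count_parameters
#' @return `param_budget_m()`: the count in millions, rounded to two decimals.
#' @export
param_budget_m <- function(x) round(count_parameters(x) / 1e6, 2)

# ---- input plumbing ---------------------------------------------------------

# Accept raster_image / (H,W,C) / (H,W,C,N) / tensor and return a 4D tensor.
#' @noRd
as_feature_batch <- function(x) {
  if (inherits(x, "ag_tensor")) {
    if (length(dim(x$value)) == 3L) x$value <- array(x$value, dim = c(dim(x$value), 1L))
    return(x)
  }
  if (is.list(x) && !inherits(x, "raster_image")) {   # list of images -> batch
    arrs <- lapply(x, function(im) unclass_image(im))
    d <- dim(arrs[[1]])
    batch <- array(0, dim = c(d, length(arrs)))
    for (i in seq_along(arrs)) batch[, , , i] <- arrs[[i]]
    return(ag_tensor(batch))
  }
  a <- unclass_image(x)
  if (length(dim(a)) == 3L) a <- array(a, dim = c(dim(a), 1L))
  if (length(dim(a)) != 4L) stop("invalid input: expected an (H, W, C[, N]) array")
  ag_tensor(a)
}

#' @noRd
unclass_image <- function(im) {
  v <- if (inherits(im, "raster_image")) im$values else im
  if (is.null(dim(v)) || length(dim(v)) < 3L)
    stop("invalid input: expected an array with a channel dimension")
  v
}
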