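# The two adversaries and the frozen feature extractor: an SRGAN-style image
# discriminator working on pixels, a VGG-19 convolutional stack tapped at a
# configurable activation (default conv5_4, post-ReLU, before the fifth
# pool), and a small strided-conv feature discriminator working on the tapped
# feature maps.

# VGG-19 convolutional schedule: widths per stage, four convs in stages 3-5.
vgg19_layout <- function() {
  stages <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  layers <- list()
  cin <- 3L
  for (s in seq_along(stages)) {
    for (i in seq_along(stages[[s]])) {
      layers[[length(layers) + 1L]] <- list(
        name = sprintf("conv%d_%d", s, i), cin = cin, cout = stages[[s]][i],
        pool_before = (i == 1L && s > 1L))
      cin <- stages[[s]][i]
    }
  }
  layers
}

#' Frozen VGG-19 feature extractor
#'
#' Builds the VGG-19 convolutional stack up to a tap point. Weights are
#' either drawn from a seeded RNG (`weights = "random"`, the offline default;
#' deterministic given the seed) or supplied as a list of pretrained arrays.
#' Extractor parameters are frozen: no optimizer ever updates them, while
#' gradients still flow through to the input image.
#'
#' @param tap activation to return, e.g. `"conv5_4"` (the default; `"conv5"`
#'   is accepted as an alias) down to `"conv1_1"`. The tap is taken after the
#'   ReLU of that convolution and before any subsequent pooling.
#' @param weights `"random"` or a named list of `w`/`b` arrays per layer.
#' @param seed RNG seed used when `weights = "random"`.
#' @param means per-channel input shift (images in `[0, 1]` minus these).
#' @return an object of class `vgg_extractor`.
#' @export
vgg_extractor <- function(tap = "conv5_4", weights = "random", seed = 1L,
                          means = c(0.485, 0.456, 0.406)) {
  if (identical(tap, "conv5")) tap <- "conv5_4"
  layout <- vgg19_layout()
  names(layout) <- vapply(layout, `[[`, character(1), "name")
  if (!tap %in% names(layout))
    stop("configuration error: unknown VGG tap point '", tap, "'")
  keep <- seq_len(match(tap, names(layout)))
  layout <- layout[keep]
  params <- if (identical(weights, "random")) {
    had_seed <- exists(".Random.seed", envir = globalenv())
    if (had_seed) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    p <- lapply(layout, function(l) layer_conv(3L, l$cin, l$cout))
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    p
  } else {
    p <- lapply(names(layout), function(nm) {
      l <- weights[[nm]]
      list(w = ag_param(l$w), b = ag_param(l$b))
    })
    names(p) <- names(layout)
    p
  }
  ext <- structure(list(tap = tap, layout = layout, params = params,
                        means = means, seed = seed,
                        source = if (identical(weights, "random")) "seeded-random" else "pretrained"),
                   class = "vgg_extractor")
  freeze_params(ext$params)
  ext
}

#' Extract frozen VGG features
#'
#' Runs the extractor on a batch of RGB images in `[0, 1]` and returns the
#' activation at the tap point. Gradients may flow to the image, never to the
#' extractor weights.
#'
#' @param extractor a [vgg_extractor()].
#' @param img image batch (see [shallow_extract()] for accepted forms).
#' @return an autodiff feature tensor.
#' @export
vgg_features <- function(extractor, img) {
  x <- as_feature_batch(img)
  shift <- array(rep(rep(extractor$means, each = prod(dim(x$value)[1:2])),
                     times = dim(x$value)[4]), dim = dim(x$value))
  x <- op_sub(x, ag_tensor(shift))
  for (nm in names(extractor$layout)) {
    if (extractor$layout[[nm]]$pool_before) x <- op_maxpool2(x)
    p <- extractor$params[[nm]]
    x <- op_relu(op_conv2d(x, p$w, p$b))
  }
  x
}

# ---- image discriminator ----------------------------------------------------

#' Build the image discriminator
#'
#' SRGAN-style pixel-domain classifier: eight 3x3 convolutions alternating
#' stride 1/2 with widths `b, b, 2b, 2b, 4b, 4b, 8b, 8b`, LeakyReLU(0.2)
#' activations, batch normalization from the second convolution on, then a
#' flattened dense layer, LeakyReLU, and a sigmoid head.
#'
#' @param input_size side of the (square) HR training patches; must be a
#'   multiple of 16 (four stride-2 convolutions).
#' @param base_width width `b` of the first convolution (64 in the reference
#'   layout; smaller for desk-scale configurations).
#' @param dense_width width of the penultimate dense layer.
#' @return an object of class `image_discriminator`.
#' @export
build_image_discriminator <- function(input_size = 192L, base_width = 64L,
                                      dense_width = 1024L) {
  if (input_size %% 16L != 0L || input_size < 16L)
    stop("configuration error: input_size must be a positive multiple of 16")
  b <- as.integer(base_width)
  widths <- c(b, b, 2L * b, 2L * b, 4L * b, 4L * b, 8L * b, 8L * b)
  strides <- c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L)
  convs <- list()
  bns <- list()
  cin <- 3L
  for (i in seq_along(widths)) {
    convs[[i]] <- layer_conv(3L, cin, widths[i])
    if (i > 1L) bns[[i]] <- layer_bn(widths[i])
    cin <- widths[i]
  }
  feat_side <- input_size %/% 16L
  structure(list(
    input_size = as.integer(input_size), widths = widths, strides = strides,
    convs = convs, bns = bns,
    fc1 = layer_dense(8L * b * feat_side^2, dense_width),
    fc2 = layer_dense(dense_width, 1L)
  ), class = "image_discriminator")
}

#' Image discriminator forward pass
#'
#' @param disc an [build_image_discriminator()] object.
#' @param img HR-patch-sized RGB image batch.
#' @return an autodiff tensor of probabilities in (0, 1), shape `(1, N)`.
#' @export
image_discriminator_forward <- function(disc, img) {
  x <- as_feature_batch(img)
  d <- dim(x$value)
  if (d[3] != 3L) stop("invalid input: image discriminator expects RGB input")
  if (d[1] != disc$input_size || d[2] != disc$input_size)
    stop("configuration error: discriminator built for ", disc$input_size,
         "x", disc$input_size, " input")
  for (i in seq_along(disc$convs)) {
    cl <- disc$convs[[i]]
    x <- op_conv2d(x, cl$w, cl$b, stride = disc$strides[i], pad = 1L)
    if (i > 1L) x <- op_batchnorm(x, disc$bns[[i]]$gamma, disc$bns[[i]]$beta)
    x <- op_leaky_relu(x, 0.2)
  }
  x <- op_flatten(x)
  x <- op_leaky_relu(op_dense(x, disc$fc1$w, disc$fc1$b), 0.2)
  op_sigmoid(op_dense(x, disc$fc2$w, disc$fc2$b))
}

# ---- feature discriminator --------------------------------------------------

#' Build the feature discriminator
#'
#' Small strided classifier over frozen VGG feature maps: four 3x3
#' convolutions with stride 2 and LeakyReLU(0.2) (default widths
#' 256, 256, 512, 512 from a 512-channel tap), global average pooling, and a
#' dense sigmoid head. Working on feature maps lets it judge structural
#' content, not just pixels.
#'
#' @param in_channels channel width of the VGG tap it consumes.
#' @param widths convolution widths.
#' @return an object of class `feature_discriminator`.
#' @export
build_feature_discriminator <- function(in_channels = 512L,
                                        widths = c(256L, 256L, 512L, 512L)) {
  convs <- list()
  cin <- as.integer(in_channels)
  for (i in seq_along(widths)) {
    convs[[i]] <- layer_conv(3L, cin, widths[i])
    cin <- widths[i]
  }
  structure(list(in_channels = as.integer(in_channels), widths = widths,
                 convs = convs, fc = layer_dense(cin, 1L)),
            class = "feature_discriminator")
}

#' Feature discriminator forward pass
#'
#' @param disc a [build_feature_discriminator()] object.
#' @param feat VGG feature tensor batch (from [vgg_features()]).
#' @return an autodiff tensor of probabilities in (0, 1), shape `(1, N)`.
#' @export
feature_discriminator_forward <- function(disc, feat) {
  x <- as_tensor(feat)
  if (dim(x$value)[3] != disc$in_channels)
    stop("invalid state: feature discriminator expects ", disc$in_channels,
         " input channels")
  for (cl in disc$convs) {
    x <- op_conv2d(x, cl$w, cl$b, stride = 2L, pad = 1L)
    x <- op_leaky_relu(x, 0.2)
  }
  x <- op_gap(x)
  op_sigmoid(op_dense(x, disc$fc$w, disc$fc$b))
}
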