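# The five loss terms and the composite generator objective:
#   Cg  = Cp + lambda * (Cai + Caf)
#   Cai = mean(-log Di(Ig))            Cdi = mean(-log Di(Ih) - log(1 - Di(Ig)))
#   Caf = mean(-log Df(w(Ig)))         Cdf = mean(-log Df(w(Ih)) - log(1 - Df(w(Ig))))
# All reductions are batch means; probabilities are clamped to
# [eps, 1 - eps] before any logarithm.

.loss_eps <- 1e-12

#' @noRd
is_plain_numeric <- function(x) !inherits(x, "ag_tensor")

#' @noRd
loss_value <- function(x) if (inherits(x, "ag_tensor")) as.numeric(x$value) else as.numeric(x)

# Shared negative-log GAN loss pair on probability tensors.
#' @noRd
gan_loss_pair <- function(d_real, d_fake, eps = .loss_eps) {
  plain <- is_plain_numeric(d_real) && is_plain_numeric(d_fake)
  r <- as_tensor(d_real)
  f <- as_tensor(d_fake)
  if (any(r$value <= 0 | r$value >= 1) || any(f$value <= 0 | f$value >= 1))
    warning("discriminator probabilities at the boundary were clamped to [eps, 1-eps]")
  neg_log_mean <- function(p) op_mean_all(op_neg(op_log(op_clamp(p, eps, 1 - eps))))
  adv <- neg_log_mean(f)
  ones <- ag_tensor(array(1, dim = dim_or_len(f$value)))
  disc <- op_add(neg_log_mean(r), neg_log_mean(op_sub(ones, f)))
  if (plain) list(adv = loss_value(adv), disc = loss_value(disc))
  else list(adv = adv, disc = disc)
}

# generator-side adversarial term alone (used inside the training step)
#' @noRd
gan_adv_loss <- function(d_fake, eps = .loss_eps) {
  op_mean_all(op_neg(op_log(op_clamp(as_tensor(d_fake), eps, 1 - eps))))
}

#' Image-domain GAN losses
#'
#' Generator term `Cai = mean(-log Di(Ig))` and discriminator term
#' `Cdi = mean(-log Di(Ih) - log(1 - Di(Ig)))` from image-discriminator
#' probabilities. Numeric inputs give numeric outputs; autodiff tensors stay
#' differentiable.
#'
#' @param di_real discriminator probabilities on real HR images.
#' @param di_fake discriminator probabilities on generated images.
#' @param eps clamping guard applied before logarithms.
#' @return list with elements `adv` (Cai) and `disc` (Cdi).
#' @export
image_gan_losses <- function(di_real, di_fake, eps = .loss_eps) {
  gan_loss_pair(di_real, di_fake, eps)
}

#' Feature-domain GAN losses
#'
#' Identical functional form to [image_gan_losses()], applied to
#' feature-discriminator probabilities: `Caf` and `Cdf`.
#'
#' @param df_real feature-discriminator probabilities on real HR features.
#' @param df_fake feature-discriminator probabilities on generated features.
#' @inheritParams image_gan_losses
#' @return list with elements `adv` (Caf) and `disc` (Cdf).
#' @export
feature_gan_losses <- function(df_real, df_fake, eps = .loss_eps) {
  gan_loss_pair(df_real, df_fake, eps)
}

#' Perceptual loss
#'
#' Mean squared error between frozen VGG feature maps of the generated and
#' real images at the tap point, plus pixel-domain mean squared error, with
#' configurable weights (`pixel_weight`, `feature_weight`). With
#' `feature_weight = 0` (or no extractor) only the pixel term is used.
#'
#' @param sr generated image batch (tensor or array).
#' @param hr real HR image batch, same shape.
#' @param extractor a [vgg_extractor()], or `NULL` for pixel-only loss.
#' @param pixel_weight,feature_weight term weights (both default 1).
#' @param hr_features optional precomputed `vgg_features(extractor, hr)`
#'   (the HR side carries no gradient, so it can be cached across steps).
#' @return scalar loss (tensor in, tensor out; numeric in, numeric out).
#' @export
perceptual_loss <- function(sr, hr, extractor = NULL, pixel_weight = 1,
                            feature_weight = 1, hr_features = NULL) {
  plain <- is_plain_numeric(sr) && is_plain_numeric(hr)
  sr <- as_feature_batch(sr)
  hr <- as_feature_batch(hr)
  if (!identical(dim(sr$value), dim(hr$value)))
    stop("invalid input: sr and hr must have identical shapes")
  total <- op_smul(op_mse(sr, hr), pixel_weight)
  if (!is.null(extractor) && feature_weight > 0) {
    fs <- vgg_features(extractor, sr)
    fh <- if (is.null(hr_features)) vgg_features(extractor, hr) else hr_features
    total <- op_add(total, op_smul(op_mse(fs, ag_detach(as_tensor(fh))), feature_weight))
  }
  if (plain) loss_value(total) else total
}

#' Composite generator objective
#'
#' `Cg = Cp + lambda * (Cai + Caf)` with `lambda_scope = "both"` (the
#' default reading: the weight scales both adversarial terms), or
#' `Cg = Cp + lambda * Cai + Caf` with `lambda_scope = "image_only"`.
#'
#' @param cp perceptual loss.
#' @param cai,caf image and feature adversarial generator losses.
#' @param lambda nonnegative adversarial weight (1e-3 in the reference
#'   training configuration).
#' @param lambda_scope `"both"` or `"image_only"`.
#' @return scalar composite loss (tensor in, tensor out).
#' @export
generator_total_loss <- function(cp, cai, caf, lambda = 1e-3,
                                 lambda_scope = c("both", "image_only")) {
  lambda_scope <- match.arg(lambda_scope)
  if (lambda < 0) stop("lambda must be nonnegative")
  plain <- is_plain_numeric(cp) && is_plain_numeric(cai) && is_plain_numeric(caf)
  cp <- as_tensor(cp); cai <- as_tensor(cai); caf <- as_tensor(caf)
  total <- if (lambda_scope == "both") {
    op_add(cp, op_smul(op_add(cai, caf), lambda))
  } else {
    op_add(op_add(cp, op_smul(cai, lambda)), caf)
  }
  if (plain) loss_value(total) else total
}

#' Bundle the loss terms of one training step
#'
#' @param cp,cai,caf,cdi,cdf the five scalar loss terms.
#' @param lambda adversarial weight.
#' @param lambda_scope see [generator_total_loss()].
#' @return a `loss_bundle` list with the five terms, `lambda`, and the
#'   composite `cg`.
#' @export
loss_bundle <- function(cp, cai, caf, cdi, cdf, lambda = 1e-3,
                        lambda_scope = "both") {
  vals <- lapply(list(cp = cp, cai = cai, caf = caf, cdi = cdi, cdf = cdf),
                 loss_value)
  vals$lambda <- lambda
  vals$cg <- generator_total_loss(vals$cp, vals$cai, vals$caf, lambda,
                                  lambda_scope)
  structure(vals, class = "loss_bundle")
}
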