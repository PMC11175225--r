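# Evaluation protocol: BT.601 YCbCr conversion, Y-channel PSNR and SSIM,
# and model-level reports against paired datasets.

#' RGB to YCbCr conversion (BT.601)
#'
#' Studio-swing ITU-R BT.601 by default (Y in `[16/255, 235/255]`, neutral
#' chroma at 128/255), the convention of the SR evaluation literature;
#' `swing = "full"` gives the full-range transform.
#'
#' @param img an RGB [raster_image()] or `(H, W, 3)` array in `[0, 1]`.
#' @param swing `"studio"` or `"full"`.
#' @return a `raster_image` tagged `"YCbCr"`.
#' @export
rgb_to_ycbcr <- function(img, swing = c("studio", "full")) {
  swing <- match.arg(swing)
  if (inherits(img, "raster_image") && img$colorspace != "RGB")
    stop("invalid input: expected an RGB image")
  v <- unclass_image(img)
  r <- v[, , 1]; g <- v[, , 2]; b <- v[, , 3]
  out <- array(0, dim = dim(v))
  if (swing == "studio") {
    out[, , 1] <- (16 + 65.481 * r + 128.553 * g + 24.966 * b) / 255
    out[, , 2] <- (128 - 37.797 * r - 74.203 * g + 112.000 * b) / 255
    out[, , 3] <- (128 + 112.000 * r - 93.786 * g - 18.214 * b) / 255
  } else {
    out[, , 1] <- 0.299 * r + 0.587 * g + 0.114 * b
    out[, , 2] <- 0.5 - 0.168736 * r - 0.331264 * g + 0.5 * b
    out[, , 3] <- 0.5 + 0.5 * r - 0.418688 * g - 0.081312 * b
  }
  raster_image(out, colorspace = "YCbCr")
}

#' @noRd
y_channel <- function(img, swing = "studio") {
  im <- if (inherits(img, "raster_image") && img$colorspace == "YCbCr") img
        else rgb_to_ycbcr(img, swing)
  im$values[, , 1]
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB. Identical inputs return the documented
#' cap (default 100 dB) with attribute `identical = TRUE` instead of
#' infinity.
#'
#' @param a,b numeric image planes (matrices) of the same shape.
#' @param peak signal peak (1 for normalized images).
#' @param cap value reported for identical inputs.
#' @return PSNR in dB (with an `identical` attribute flag).
#' @export
psnr <- function(a, b, peak = 1, cap = 100) {
  if (!identical(dim(a), dim(b)))
    stop("invalid input: psnr needs identically shaped planes")
  if (peak <= 0) stop("invalid input: peak must be positive")
  mse <- mean((a - b)^2)
  if (mse == 0) return(structure(cap, identical = TRUE))
  structure(min(cap, 10 * log10(peak^2 / mse)), identical = FALSE)
}

#' Structural similarity index
#'
#' Standard windowed SSIM: 11x11 Gaussian window (sigma 1.5), k1 = 0.01,
#' k2 = 0.03, dynamic range 1, population (weighted-mean) statistics, mean
#' over all valid windows.
#'
#' @param a,b numeric image planes (matrices), side at least 11.
#' @param k1,k2 stability constants.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(a, b, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b)))
    stop("invalid input: ssim needs identically shaped planes")
  if (any(dim(a) < 11L))
    stop("invalid input: ssim needs images of side >= 11")
  k <- exp(-(seq(-5, 5))^2 / (2 * 1.5^2))
  k <- k / sum(k)
  valid_op <- function(n) {
    V <- matrix(0, n - 10L, n)
    for (i in seq_len(n - 10L)) V[i, i:(i + 10L)] <- k
    V
  }
  Vr <- valid_op(nrow(a)); Vc <- valid_op(ncol(a))
  w <- function(x) Vr %*% x %*% t(Vc)
  mu_a <- w(a); mu_b <- w(b)
  var_a <- w(a * a) - mu_a^2
  var_b <- w(b * b) - mu_b^2
  cov_ab <- w(a * b) - mu_a * mu_b
  c1 <- k1^2; c2 <- k2^2
  s <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(s)
}

#' Evaluate a super-resolution model on a paired dataset
#'
#' Runs the model on every LR image and scores the reconstruction against
#' the HR reference with Y-channel PSNR and SSIM (BT.601 studio swing), with
#' an optional border shave (default: `scale` pixels). LPIPS is reported
#' only when a plug-in scorer is supplied; otherwise the column is `NA`.
#'
#' @param model a fitted [rdagan()] object, an `rdagan_generator`, or a
#'   function mapping an LR `raster_image` to an SR `raster_image` (e.g. the
#'   bicubic baseline `function(lr) bicubic_upsample(lr, 2)`).
#' @param dataset a `paired_dataset`.
#' @param shave border pixels removed before scoring (`NULL`: the scale).
#' @param lpips_fn optional `function(sr, hr) -> numeric` perceptual scorer.
#' @param dataset_tag label stored in the report.
#' @return a `metric_report`: list with the per-image data frame and the
#'   means.
#' @export
evaluate_model <- function(model, dataset, shave = NULL, lpips_fn = NULL,
                           dataset_tag = "dataset") {
  if (length(dataset) == 0L) stop("invalid input: empty dataset")
  runner <- if (is.function(model)) model else function(lr) sr_upscale(model, lr)
  rows <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    t0 <- proc.time()[["elapsed"]]
    sr <- runner(s$lr)
    dt <- proc.time()[["elapsed"]] - t0
    sh <- if (is.null(shave)) s$scale else shave
    ys <- y_channel(sr); yh <- y_channel(s$hr)
    if (sh > 0) {
      keep_r <- (sh + 1):(nrow(ys) - sh)
      keep_c <- (sh + 1):(ncol(ys) - sh)
      ys <- ys[keep_r, keep_c]; yh <- yh[keep_r, keep_c]
    }
    p <- psnr(ys, yh)
    data.frame(
      image = i, provenance = as.character(s$provenance),
      psnr = as.numeric(p), psnr_capped = attr(p, "identical"),
      ssim = ssim(ys, yh),
      lpips = if (is.null(lpips_fn)) NA_real_ else lpips_fn(sr, s$hr),
      time_s = dt
    )
  })
  per_image <- do.call(rbind, rows)
  structure(list(
    per_image = per_image,
    mean_psnr = mean(per_image$psnr),
    mean_ssim = mean(per_image$ssim),
    mean_lpips = if (is.null(lpips_fn)) NA_real_ else mean(per_image$lpips),
    mean_time_s = mean(per_image$time_s),
    n_parameters = if (is.function(model)) NA_integer_ else count_parameters(model),
    dataset_tag = dataset_tag
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report [%s], %d image(s)\n", x$dataset_tag,
              nrow(x$per_image)))
  cat(sprintf("  mean Y-PSNR: %.2f dB\n  mean Y-SSIM: %.4f\n",
              x$mean_psnr, x$mean_ssim))
  if (!is.na(x$mean_lpips)) cat(sprintf("  mean LPIPS: %.4f\n", x$mean_lpips))
  if (!is.na(x$n_parameters))
    cat(sprintf("  parameters: %.2f M\n", x$n_parameters / 1e6))
  invisible(x)
}
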