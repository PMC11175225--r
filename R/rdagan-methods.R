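# S3 methods for the fitted model and the specification objects.

#' @export
print.generator_spec <- function(x, ...) {
  cat("Generator specification\n")
  cat(sprintf("  RDABs (D): %d   convs/block (C): %d   growth (G): %d\n",
              x$num_blocks, x$convs_per_block, x$growth))
  cat(sprintf("  base width (G0): %d   fusion width: %d   scale: x%d\n",
              x$base_channels, x$fusion_width, x$scale))
  cat(sprintf("  CBAM: %s (r = %d, spatial k = %d, %s)   dense blocks: %s\n",
              if (x$cbam_enabled) "on" else "off", x$cbam_reduction,
              x$cbam_spatial_kernel, x$cbam_position,
              if (x$use_rdb) "RDB" else "plain residual"))
  invisible(x)
}

#' @export
print.rdagan_generator <- function(x, ...) {
  cat(sprintf("<rdagan generator: %d RDABs, %.2f M parameters>\n",
              x$spec$num_blocks, count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
print.rdagan <- function(x, ...) {
  cat("Residual dense attention GAN (fitted)\n")
  cat(sprintf("  generator: %d RDABs, %.2f M parameters, scale x%d\n",
              x$spec$num_blocks, count_parameters(x) / 1e6, x$spec$scale))
  cat(sprintf("  trained: %d epoch(s), %d step(s)\n", x$epochs_run,
              nrow(x$log)))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  final losses: Cg = %.4f, Cp = %.4f\n", last$cg, last$cp))
  }
  invisible(x)
}

#' @export
summary.rdagan <- function(object, ...) {
  out <- list(
    spec = object$spec,
    n_parameters = count_parameters(object),
    parameters_m = param_budget_m(object),
    epochs_run = object$epochs_run,
    steps_run = nrow(object$log),
    feature_discriminator = !is.null(object$disc_feature),
    config_hash = object$config$config_hash,
    final_losses = if (nrow(object$log) > 0) object$log[nrow(object$log), ]
  )
  class(out) <- "summary.rdagan"
  out
}

#' @export
print.summary.rdagan <- function(x, ...) {
  print(x$spec)
  cat(sprintf("Parameters: %d (%.2f M)\n", x$n_parameters, x$parameters_m))
  cat(sprintf("Training: %d epochs / %d steps; feature discriminator: %s\n",
              x$epochs_run, x$steps_run,
              if (x$feature_discriminator) "on" else "off"))
  cat(sprintf("Config hash: %s\n", x$config_hash))
  if (!is.null(x$final_losses)) {
    cat("Final step losses:\n")
    print(x$final_losses, row.names = FALSE)
  }
  invisible(x)
}

#' Super-resolve new images with a fitted model
#'
#' @param object a fitted [rdagan()] model.
#' @param newdata a `raster_image`, an `(H, W, 3)` array, a list of images,
#'   or a `paired_dataset` (its LR members are upscaled).
#' @param ... unused.
#' @return a `raster_image` or list of them.
#' @export
predict.rdagan <- function(object, newdata, ...) {
  if (inherits(newdata, "paired_dataset"))
    return(lapply(newdata$samples, function(s) sr_upscale(object, s$lr)))
  sr_upscale(object, newdata)
}

#' @export
coef.rdagan <- function(object, ...) {
  param_values(object$generator$params)
}

#' Plot training loss traces
#'
#' @param x a fitted [rdagan()] model.
#' @param which loss columns to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rdagan <- function(x, which = c("cg", "cp", "cdi", "cdf"), ...) {
  log <- x$log
  if (nrow(log) == 0) stop("no training steps logged")
  cols <- intersect(which, names(log))
  y <- as.matrix(log[, cols, drop = FALSE])
  keep <- colSums(is.finite(y)) > 0
  y <- y[, keep, drop = FALSE]
  graphics::matplot(log$step, y, type = "l", lty = 1, xlab = "step",
                    ylab = "loss", ...)
  graphics::legend("topright", legend = colnames(y), lty = 1,
                   col = seq_len(ncol(y)), bty = "n")
  invisible(x)
}

#' Write the training log as CSV
#'
#' Columns: step, epoch, cp, cai, caf, cg, cdi, cdf, lr.
#'
#' @param model a fitted [rdagan()] model.
#' @param path output CSV path.
#' @export
write_train_log <- function(model, path) {
  utils::write.csv(model$log, path, row.names = FALSE)
  invisible(path)
}
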