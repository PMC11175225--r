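# Alternating adversarial training: per step the image discriminator is
# updated on Cdi (generated images detached), the feature discriminator on
# Cdf, then the generator on Cg with both discriminators frozen. One ADAM
# optimizer per model, all with the same schedule.

#' Training configuration
#'
#' All knobs of the adversarial training run. Defaults follow the reference
#' protocol: 192-pixel HR crops with dihedral augmentation, ADAM
#' (beta1 = 0.9, beta2 = 0.999), learning rate 2e-4 halved once after epoch
#' 200, adversarial weight lambda = 1e-3.
#'
#' @param epochs training epochs.
#' @param steps_per_epoch optimizer steps per epoch (`NULL`: one pass,
#'   `ceiling(n_samples / batch_size)`).
#' @param batch_size samples per step.
#' @param hr_crop HR crop side (divisible by `scale`).
#' @param scale super-resolution factor.
#' @param lambda adversarial weight in the composite generator loss.
#' @param lambda_scope see [generator_total_loss()].
#' @param pixel_weight,feature_weight perceptual-loss term weights.
#' @param lr initial learning rate.
#' @param lr_decay_epoch epoch after which the rate is multiplied by
#'   `lr_decay_factor`.
#' @param lr_decay_factor multiplicative decay.
#' @param lr_decay_every `FALSE` (default): a single decay step;
#'   `TRUE`: decay repeats every `lr_decay_epoch` epochs.
#' @param adam_beta1,adam_beta2 ADAM moment coefficients.
#' @param seed RNG seed governing initialization, batching, cropping and
#'   augmentation.
#' @param cbam,use_rdb,feature_discriminator ablation toggles.
#' @param augment apply random dihedral augmentation to each crop?
#' @param vgg_tap VGG tap point for the perceptual loss and the feature
#'   discriminator.
#' @param vgg_weights `"random"` (offline default) or pretrained arrays.
#' @param vgg_seed seed of the seeded-random extractor.
#' @param disc_base_width,disc_dense_width image-discriminator widths.
#' @param fdisc_widths feature-discriminator convolution widths.
#' @param pretrain_epochs optional pixel-only warm-up epochs before
#'   adversarial training starts (0 = none; an extension, off by default).
#' @param checkpoint_every save a checkpoint every this many epochs
#'   (0 = only on completion).
#' @param checkpoint_dir directory for checkpoints (`NULL`: none written).
#' @return an object of class `train_config` (with a `config_hash` field).
#' @export
train_config <- function(epochs = 400L, steps_per_epoch = NULL, batch_size = 16L,
                         hr_crop = 192L, scale = 2L,
                         lambda = 1e-3, lambda_scope = "both",
                         pixel_weight = 1, feature_weight = 1,
                         lr = 2e-4, lr_decay_epoch = 200L,
                         lr_decay_factor = 0.5, lr_decay_every = FALSE,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         seed = 1L, cbam = TRUE, use_rdb = TRUE,
                         feature_discriminator = TRUE, augment = TRUE,
                         vgg_tap = "conv5_4", vgg_weights = "random",
                         vgg_seed = 42L,
                         disc_base_width = 64L, disc_dense_width = 1024L,
                         fdisc_widths = c(256L, 256L, 512L, 512L),
                         pretrain_epochs = 0L,
                         checkpoint_every = 0L, checkpoint_dir = NULL) {
  cfg <- list(epochs = as.integer(epochs), steps_per_epoch = steps_per_epoch,
              batch_size = as.integer(batch_size), hr_crop = as.integer(hr_crop),
              scale = as.integer(scale), lambda = lambda,
              lambda_scope = lambda_scope, pixel_weight = pixel_weight,
              feature_weight = feature_weight, lr = lr,
              lr_decay_epoch = as.integer(lr_decay_epoch),
              lr_decay_factor = lr_decay_factor,
              lr_decay_every = isTRUE(lr_decay_every),
              adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
              seed = as.integer(seed), cbam = isTRUE(cbam),
              use_rdb = isTRUE(use_rdb),
              feature_discriminator = isTRUE(feature_discriminator),
              augment = isTRUE(augment), vgg_tap = vgg_tap,
              vgg_weights = vgg_weights, vgg_seed = as.integer(vgg_seed),
              disc_base_width = as.integer(disc_base_width),
              disc_dense_width = as.integer(disc_dense_width),
              fdisc_widths = as.integer(fdisc_widths),
              pretrain_epochs = as.integer(pretrain_epochs),
              checkpoint_every = as.integer(checkpoint_every),
              checkpoint_dir = checkpoint_dir)
  if (cfg$lr <= 0 || cfg$lambda < 0 || cfg$lr_decay_factor <= 0)
    stop("train_config: rates must be positive and lambda nonnegative")
  if (cfg$hr_crop %% cfg$scale != 0L)
    stop("train_config: hr_crop must be divisible by scale")
  if (cfg$epochs < 0L || cfg$batch_size < 1L)
    stop("train_config: epochs must be >= 0 and batch_size >= 1")
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = "train_config")
}

# Rolling polynomial hash over the JSON form; provenance tag stored in every
# checkpoint.
#' @noRd
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Learning-rate schedule
#'
#' 2e-4 up to and including the decay epoch, halved thereafter (a single
#' halving under the default one-shot reading; set `lr_decay_every = TRUE`
#' in the config for repeated decay).
#'
#' @param epoch epoch number (1-based).
#' @param config a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  if (epoch < 1) stop("epoch must be >= 1")
  if (config$lr_decay_every) {
    config$lr * config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_epoch)
  } else {
    if (epoch <= config$lr_decay_epoch) config$lr
    else config$lr * config$lr_decay_factor
  }
}

# ---- training state ---------------------------------------------------------

#' @noRd
new_train_state <- function(spec, config) {
  gen <- build_generator(spec)
  disc_i <- build_image_discriminator(config$hr_crop, config$disc_base_width,
                                      config$disc_dense_width)
  need_vgg <- config$feature_discriminator || config$feature_weight > 0
  ext <- if (need_vgg) vgg_extractor(config$vgg_tap, config$vgg_weights,
                                     seed = config$vgg_seed)
  disc_f <- if (config$feature_discriminator) {
    tapw <- ext$layout[[ext$tap]]$cout
    build_feature_discriminator(tapw, config$fdisc_widths)
  }
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$config <- config
  st$generator <- gen
  st$disc_image <- disc_i
  st$disc_feature <- disc_f
  st$extractor <- ext
  st$opt_g <- adam_new(collect_params(gen$params), config$lr,
                       config$adam_beta1, config$adam_beta2)
  st$opt_di <- adam_new(collect_params(unclass(disc_i)), config$lr,
                        config$adam_beta1, config$adam_beta2)
  st$opt_df <- if (!is.null(disc_f))
    adam_new(collect_params(unclass(disc_f)), config$lr,
             config$adam_beta1, config$adam_beta2)
  st$epoch <- 0L
  st$step <- 0L
  st$lr <- config$lr
  st$log <- list()
  class(st) <- "rdagan_train_state"
  st
}

#' @noRd
batch_arrays <- function(batch) {
  stack <- function(field) {
    arrs <- lapply(batch, function(s) s[[field]]$values)
    d <- dim(arrs[[1]])
    out <- array(0, dim = c(d, length(arrs)))
    for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
    out
  }
  list(hr = stack("hr"), lr = stack("lr"))
}

#' One alternating training step
#'
#' Phase 1 updates the image discriminator on `Cdi` with the generated batch
#' detached; phase 2 updates the feature discriminator on `Cdf` (skipped
#' when the toggle is off); phase 3 updates the generator on `Cg` with both
#' discriminators frozen. During warm-up (`pretrain` phase) only the pixel
#' loss trains the generator.
#'
#' @param batch list of crop-sized [paired_sample()]s.
#' @param state an `rdagan_train_state` (modified in place).
#' @param pretrain run the pixel-only warm-up variant of the step?
#' @return the loss bundle of the step (invisibly via the state log too).
#' @export
train_step <- function(batch, state, pretrain = FALSE) {
  config <- state$config
  ab <- batch_arrays(batch)
  hr <- ag_tensor(ab$hr)
  lr_in <- ag_tensor(ab$lr)
  lrate <- state$lr

  tape_start()
  on.exit(tape_end())

  sr <- generator_forward(state$generator, lr_in, train = TRUE)
  sr_det <- ag_detach(sr)

  cdi_v <- cdf_v <- cai_v <- caf_v <- NA_real_

  if (!pretrain) {
    # (1) image discriminator
    di_params <- state$opt_di$params
    zero_grad(di_params)
    p_real <- image_discriminator_forward(state$disc_image, hr)
    p_fake <- image_discriminator_forward(state$disc_image, sr_det)
    cdi <- suppressWarnings(image_gan_losses(p_real, p_fake)$disc)
    backward(cdi)
    state$opt_di <- adam_step(state$opt_di, lrate)
    cdi_v <- loss_value(cdi)

    # (2) feature discriminator
    if (!is.null(state$disc_feature)) {
      df_params <- state$opt_df$params
      zero_grad(df_params)
      f_real <- vgg_features(state$extractor, hr)
      f_fake_det <- vgg_features(state$extractor, sr_det)
      q_real <- feature_discriminator_forward(state$disc_feature, f_real)
      q_fake <- feature_discriminator_forward(state$disc_feature, f_fake_det)
      cdf <- suppressWarnings(feature_gan_losses(q_real, q_fake)$disc)
      backward(cdf)
      state$opt_df <- adam_step(state$opt_df, lrate)
      cdf_v <- loss_value(cdf)
    }
  }

  # (3) generator
  g_params <- state$opt_g$params
  zero_grad(g_params)
  if (!pretrain) {
    zero_grad(state$opt_di$params)
    if (!is.null(state$opt_df)) zero_grad(state$opt_df$params)
  }
  cp <- perceptual_loss(sr, hr, extractor = state$extractor,
                        pixel_weight = config$pixel_weight,
                        feature_weight = if (pretrain) 0 else config$feature_weight)
  if (pretrain) {
    cg <- cp
  } else {
    cai <- gan_adv_loss(image_discriminator_forward(state$disc_image, sr))
    caf <- if (!is.null(state$disc_feature)) {
      gan_adv_loss(feature_discriminator_forward(
        state$disc_feature, vgg_features(state$extractor, sr)))
    } else ag_tensor(0)
    cg <- generator_total_loss(cp, cai, caf, config$lambda, config$lambda_scope)
    cai_v <- loss_value(cai)
    caf_v <- if (is.null(state$disc_feature)) NA_real_ else loss_value(caf)
  }
  cg_v <- loss_value(cg)
  if (!all(is.finite(c(cg_v, cdi_v, cdf_v)[!is.na(c(cg_v, cdi_v, cdf_v))])))
    stop("non-finite loss at step ", state$step + 1L, "; batch provenance: ",
         paste(vapply(batch, function(s) as.character(s$provenance),
                      character(1)), collapse = ", "))
  backward(cg)
  state$opt_g <- adam_step(state$opt_g, lrate)

  state$step <- state$step + 1L
  row <- data.frame(step = state$step, epoch = state$epoch,
                    cp = loss_value(cp), cai = cai_v, caf = caf_v, cg = cg_v,
                    cdi = cdi_v, cdf = cdf_v, lr = lrate)
  state$log[[length(state$log) + 1L]] <- row
  invisible(row)
}

# ---- the fitting entry point ------------------------------------------------

#' Fit the super-resolution GAN
#'
#' Trains the residual dense attention generator adversarially on a paired
#' dataset: each step draws a batch of scale-aligned random crops (with
#' dihedral augmentation), updates the image discriminator, the feature
#' discriminator, and then the generator, following the configured schedule.
#'
#' @param data a `paired_dataset` (from [load_image_pairs()],
#'   [synthesize_cell_dataset()] or [paired_dataset()]).
#' @param config a [train_config()].
#' @param spec optional [generator_spec()]; by default derived from the
#'   config's ablation toggles with the calibrated default architecture.
#' @param resume path to a checkpoint to resume from.
#' @param verbose print a line per epoch?
#' @return an object of class `rdagan`: the fitted generator, both
#'   discriminators, the extractor, the config, and the per-step loss log.
#' @export
rdagan <- function(data, config = train_config(), spec = NULL, resume = NULL,
                   verbose = FALSE) {
  if (inherits(data, "paired_sample")) data <- paired_dataset(list(data))
  if (!inherits(data, "paired_dataset"))
    stop("invalid input: data must be a paired_dataset")
  n <- length(data)
  if (n == 0L) stop("invalid input: empty dataset")

  state <- if (!is.null(resume)) {
    load_checkpoint(resume)
  } else {
    set.seed(config$seed)
    if (is.null(spec))
      spec <- generator_spec(scale = config$scale, cbam_enabled = config$cbam,
                             use_rdb = config$use_rdb)
    new_train_state(spec, config)
  }
  config <- state$config

  spe <- config$steps_per_epoch
  if (is.null(spe)) spe <- max(1L, as.integer(ceiling(n / config$batch_size)))

  total_epochs <- config$pretrain_epochs + config$epochs
  while (state$epoch < total_epochs) {
    state$epoch <- state$epoch + 1L
    pretrain <- state$epoch <= config$pretrain_epochs
    state$lr <- lr_schedule(state$epoch, config)
    for (s in seq_len(spe)) {
      idx <- sample.int(n, config$batch_size, replace = config$batch_size > n)
      batch <- lapply(idx, function(i) {
        smp <- data$samples[[i]]
        if (dim(smp$hr$values)[1] > config$hr_crop ||
            dim(smp$hr$values)[2] > config$hr_crop)
          smp <- paired_random_crop(smp, config$hr_crop)
        if (config$augment) smp <- dihedral_augment(smp, sample.int(8L, 1L) - 1L)
        smp
      })
      train_step(batch, state, pretrain = pretrain)
    }
    if (verbose) {
      last <- state$log[[length(state$log)]]
      cat(sprintf("epoch %d/%d  cg=%.4f  cdi=%s  lr=%.2e\n", state$epoch,
                  total_epochs, last$cg,
                  ifelse(is.na(last$cdi), "-", sprintf("%.4f", last$cdi)),
                  state$lr))
    }
    if (!is.null(config$checkpoint_dir) && config$checkpoint_every > 0L &&
        state$epoch %% config$checkpoint_every == 0L)
      save_checkpoint(state, file.path(config$checkpoint_dir,
                                       sprintf("epoch_%04d.rds", state$epoch)))
  }

  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(state, file.path(config$checkpoint_dir, "final.rds"))
  }

  structure(list(
    generator = state$generator,
    disc_image = state$disc_image,
    disc_feature = state$disc_feature,
    extractor = state$extractor,
    spec = state$spec,
    config = config,
    log = if (length(state$log)) do.call(rbind, state$log) else
      data.frame(step = integer(), epoch = integer(), cp = numeric(),
                 cai = numeric(), caf = numeric(), cg = numeric(),
                 cdi = numeric(), cdf = numeric(), lr = numeric()),
    epochs_run = state$epoch,
    state = state
  ), class = "rdagan")
}

#' Tiny-overfit benchmark
#'
#' The package's CPU-scale training smoke experiment: 8 synthetic 64x64
#' bright-field HR patches are paired by bicubic x2 degradation; a reduced
#' generator is trained for 300 steps (batch 4) with the distortion (pixel)
#' objective, and its train-set Y-channel PSNR is compared against the
#' bicubic upsampling baseline and against the untrained (randomly
#' initialized) generator. A sound training loop places the untrained model
#' far below the baseline and the trained model above it.
#'
#' The fixture scenes sit at the sharp, texture-rich end of the synthetic
#' generator's range (`blur_sigma = 0.2`, `texture_amplitude = 0.5`,
#' `noise_sigma = 0.02`): that is the regime where interpolation leaves
#' reconstruction headroom, so the check measures training capability
#' rather than fixture smoothness.
#'
#' @param seed RNG seed for synthesis and training.
#' @param steps optimizer steps (300 in the reference protocol).
#' @param config optional [train_config()] override.
#' @param spec optional [generator_spec()] override for the reduced model.
#' @return list with `baseline_psnr`, `untrained_psnr`, `trained_psnr`
#'   (train-set means, dB), the fitted model and the fixture dataset.
#' @export
overfit_benchmark <- function(seed = 101L, steps = 300L, config = NULL,
                              spec = NULL) {
  ds <- synthesize_cell_dataset(
    8, synthetic_scene_spec(side = 64L, cell_count = 4L,
                            radius_range = c(6, 14), blur_sigma = 0.2,
                            texture_amplitude = 0.5, noise_sigma = 0.02,
                            seed = seed))
  if (is.null(spec))
    spec <- generator_spec(num_blocks = 1L, convs_per_block = 3L,
                           growth = 24L, base_channels = 32L,
                           fusion_width = 48L, cbam_reduction = 4L)
  if (is.null(config))
    config <- train_config(
      epochs = 0L, pretrain_epochs = as.integer(steps / 2),
      steps_per_epoch = 2L, batch_size = 4L,
      hr_crop = 64L, lr = 5e-3, adam_beta2 = 0.99, augment = FALSE,
      disc_base_width = 16L, disc_dense_width = 64L,
      feature_discriminator = FALSE, feature_weight = 0,
      seed = seed)
  baseline <- evaluate_model(function(lr) bicubic_upsample(lr, config$scale),
                             ds, dataset_tag = "bicubic")
  set.seed(config$seed)
  untrained <- build_generator(spec)
  before <- evaluate_model(untrained, ds, dataset_tag = "untrained")
  fit <- rdagan(ds, config, spec = spec)
  after <- evaluate_model(fit, ds, dataset_tag = "trained")
  list(baseline_psnr = baseline$mean_psnr,
       untrained_psnr = before$mean_psnr,
       trained_psnr = after$mean_psnr,
       model = fit, dataset = ds)
}

# ---- checkpointing ----------------------------------------------------------

.checkpoint_schema <- "rdagan-checkpoint-1"

#' Save / load a training checkpoint
#'
#' A checkpoint is a single versioned archive holding the generator spec (as
#' structured data), all parameter arrays of the three models, the optimizer
#' moments, the configuration (with its hash) and the RNG state, so a resumed
#' run continues the exact RNG stream.
#'
#' @param state an `rdagan_train_state` or a fitted `rdagan` model.
#' @param path file path.
#' @return `load_checkpoint()` returns a reconstructed `rdagan_train_state`.
#' @export
save_checkpoint <- function(state, path) {
  if (inherits(state, "rdagan")) state <- state$state
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- list(
    schema = .checkpoint_schema,
    spec = unclass(state$spec),
    config = unclass(state$config),
    generator = param_values(state$generator$params),
    disc_image = param_values(unclass(state$disc_image)),
    disc_feature = if (!is.null(state$disc_feature))
      param_values(unclass(state$disc_feature)),
    opt = list(
      g = state$opt_g[c("t", "m", "v")],
      di = state$opt_di[c("t", "m", "v")],
      df = if (!is.null(state$opt_df)) state$opt_df[c("t", "m", "v")]
    ),
    epoch = state$epoch, step = state$step, lr = state$lr,
    log = state$log,
    rng = if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$schema, .checkpoint_schema))
    stop("incompatible checkpoint schema '", payload$schema,
         "'; this build reads '", .checkpoint_schema, "'")
  spec <- do.call(generator_spec, payload$spec)
  config <- structure(payload$config, class = "train_config")
  state <- new_train_state(spec, config)
  set_param_values(state$generator$params, payload$generator)
  set_param_values(unclass(state$disc_image), payload$disc_image)
  if (!is.null(state$disc_feature))
    set_param_values(unclass(state$disc_feature), payload$disc_feature)
  restore_opt <- function(opt, saved) {
    opt$t <- saved$t; opt$m <- saved$m; opt$v <- saved$v
    opt
  }
  state$opt_g <- restore_opt(state$opt_g, payload$opt$g)
  state$opt_di <- restore_opt(state$opt_di, payload$opt$di)
  if (!is.null(state$opt_df)) state$opt_df <- restore_opt(state$opt_df, payload$opt$df)
  state$epoch <- payload$epoch
  state$step <- payload$step
  state$lr <- payload$lr
  state$log <- payload$log
  if (!is.null(payload$rng))
    assign(".Random.seed", payload$rng, envir = globalenv())
  state
}

# ---- inference over directories ---------------------------------------------

#' Batch inference over a directory
#'
#' Upscales every PNG/TIFF in `input_dir` by the model's scale factor and
#' writes `<name>_sr.png` files plus a manifest CSV logging the checkpoint
#' hash per output.
#'
#' @param model a fitted [rdagan()] model, an `rdagan_generator`, or a
#'   checkpoint path.
#' @param input_dir directory of LR images.
#' @param output_dir output directory (created if needed).
#' @return the manifest data frame, invisibly.
#' @export
infer_dir <- function(model, input_dir, output_dir) {
  if (is.character(model)) {
    state <- load_checkpoint(model)
    hash <- state$config$config_hash
    gen <- state$generator
  } else {
    gen <- if (inherits(model, "rdagan")) model$generator else model
    hash <- if (inherits(model, "rdagan")) model$config$config_hash else NA_character_
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- sort(list.files(input_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) warning("empty input directory")
  rows <- lapply(files, function(f) {
    img <- read_image(file.path(input_dir, f))
    sr <- sr_upscale(gen, img)
    out <- paste0(tools::file_path_sans_ext(f), "_sr.png")
    write_image(sr, file.path(output_dir, out))
    data.frame(input = f, output = out, checkpoint_hash = hash)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(input = character(), output = character(),
               checkpoint_hash = character())
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
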