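# Training orchestration: schedule, alternation contracts, determinism,
# checkpointing, and inference plumbing.

ns <- asNamespace("rdagan")

tiny_cfg <- function(...) {
  defaults <- list(epochs = 1L, steps_per_epoch = 1L, batch_size = 2L,
                   hr_crop = 32L, disc_base_width = 8L, disc_dense_width = 16L,
                   feature_discriminator = TRUE, feature_weight = 1,
                   vgg_tap = "conv1_2", seed = 5L)
  over <- list(...)
  do.call(train_config, utils::modifyList(defaults, over))
}

tiny_train_spec <- function(...) {
  generator_spec(num_blocks = 2L, convs_per_block = 2L, growth = 8L,
                 base_channels = 16L, fusion_width = 16L,
                 cbam_reduction = 4L, ...)
}

tiny_data <- function(n = 2, side = 32L) {
  synthesize_cell_dataset(n, synthetic_scene_spec(
    side = side, cell_count = 2L, radius_range = c(4, 8), seed = 31L))
}

test_that("the learning-rate schedule halves once after the decay epoch", {
  cfg <- train_config()
  expect_identical(lr_schedule(1, cfg), 2e-4)
  expect_identical(lr_schedule(200, cfg), 2e-4)
  expect_identical(lr_schedule(201, cfg), 1e-4)
  expect_identical(lr_schedule(1000, cfg), 1e-4)
  cfg2 <- train_config(lr_decay_every = TRUE)
  expect_identical(lr_schedule(401, cfg2), 5e-5)
  expect_error(lr_schedule(0, cfg), ">= 1")
})

test_that("configuration validation and hashing behave", {
  expect_error(train_config(hr_crop = 33L), "divisible")
  expect_error(train_config(lr = 0), "positive")
  expect_error(train_config(lambda = -1), "nonnegative")
  a <- train_config(seed = 1L)
  b <- train_config(seed = 1L)
  c <- train_config(seed = 2L)
  expect_identical(a$config_hash, b$config_hash)
  expect_false(identical(a$config_hash, c$config_hash))
})

test_that("each training phase only updates its own model", {
  set.seed(5)
  cfg <- tiny_cfg()
  st <- ns$new_train_state(tiny_train_spec(), cfg)
  ds <- tiny_data()
  batch <- ds$samples

  snap <- function(m) lapply(ns$collect_params(m), function(p) p$value)

  # phase 3 in isolation: generator update leaves both discriminators and
  # the extractor bitwise unchanged
  di0 <- snap(unclass(st$disc_image))
  df0 <- snap(unclass(st$disc_feature))
  ex0 <- snap(st$extractor$params)
  ab <- ns$batch_arrays(batch)
  ns$tape_start()
  sr <- generator_forward(st$generator, ns$ag_tensor(ab$lr), train = TRUE)
  cp <- perceptual_loss(sr, ns$ag_tensor(ab$hr), st$extractor)
  cai <- ns$gan_adv_loss(image_discriminator_forward(st$disc_image, sr))
  caf <- ns$gan_adv_loss(feature_discriminator_forward(
    st$disc_feature, vgg_features(st$extractor, sr)))
  cg <- generator_total_loss(cp, cai, caf, cfg$lambda)
  ns$zero_grad(st$opt_g$params)
  ns$backward(cg)
  ns$tape_end()
  g0 <- snap(st$generator$params)
  st$opt_g <- ns$adam_step(st$opt_g, st$lr)
  expect_identical(snap(unclass(st$disc_image)), di0)
  expect_identical(snap(unclass(st$disc_feature)), df0)
  expect_identical(snap(st$extractor$params), ex0)
  expect_false(identical(snap(st$generator$params), g0))

  # phases 1-2 in isolation: discriminator updates leave the generator
  # bitwise unchanged
  g1 <- snap(st$generator$params)
  ns$tape_start()
  sr_det <- ns$ag_detach(generator_forward(st$generator, ns$ag_tensor(ab$lr),
                                           train = TRUE))
  p_r <- image_discriminator_forward(st$disc_image, ns$ag_tensor(ab$hr))
  p_f <- image_discriminator_forward(st$disc_image, sr_det)
  cdi <- image_gan_losses(p_r, p_f)$disc
  ns$zero_grad(st$opt_di$params)
  ns$backward(cdi)
  ns$tape_end()
  st$opt_di <- ns$adam_step(st$opt_di, st$lr)
  expect_identical(snap(st$generator$params), g1)
  expect_false(identical(snap(unclass(st$disc_image)), di0))
  expect_identical(snap(st$extractor$params), ex0)
})

test_that("a full training step exercises all phases and logs all terms", {
  set.seed(6)
  cfg <- tiny_cfg()
  st <- ns$new_train_state(tiny_train_spec(), cfg)
  ex0 <- lapply(ns$collect_params(st$extractor$params), function(p) p$value)
  row <- train_step(tiny_data()$samples, st)
  expect_true(all(is.finite(unlist(row[c("cp", "cai", "caf", "cg", "cdi", "cdf")]))))
  expect_identical(row$step, 1L)
  # extractor stays bitwise frozen through a full alternation
  expect_identical(lapply(ns$collect_params(st$extractor$params),
                          function(p) p$value), ex0)
})

test_that("disabling the feature discriminator skips its phase and loss", {
  set.seed(7)
  cfg <- tiny_cfg(feature_discriminator = FALSE, feature_weight = 0)
  st <- ns$new_train_state(tiny_train_spec(), cfg)
  expect_null(st$disc_feature)
  row <- train_step(tiny_data()$samples, st)
  expect_true(is.na(row$caf))
  expect_true(is.na(row$cdf))
  expect_true(is.finite(row$cdi))
})

test_that("seeded training is reproducible step for step", {
  ds <- tiny_data()
  cfg <- tiny_cfg(epochs = 5L, steps_per_epoch = 2L,
                  feature_discriminator = FALSE, feature_weight = 0)
  f1 <- rdagan(ds, cfg, spec = tiny_train_spec())
  f2 <- rdagan(ds, cfg, spec = tiny_train_spec())
  expect_identical(f1$log, f2$log)
  expect_gte(nrow(f1$log), 10L)
  img <- ds$samples[[1]]$lr
  expect_identical(sr_upscale(f1, img)$values, sr_upscale(f2, img)$values)
})

test_that("checkpoints round-trip and resumed steps match unbroken runs", {
  ds <- tiny_data()
  cfg <- tiny_cfg(epochs = 3L, steps_per_epoch = 1L,
                  feature_discriminator = FALSE, feature_weight = 0)

  # unbroken run of 3 epochs, checkpointing every epoch
  ckdir <- tempfile("ck")
  cfg$checkpoint_dir <- ckdir
  cfg$checkpoint_every <- 1L
  full <- rdagan(ds, cfg, spec = tiny_train_spec())

  # resume from the epoch-2 checkpoint: the third epoch must reproduce the
  # unbroken run bitwise (same RNG stream, same moments)
  resumed <- rdagan(ds, resume = file.path(ckdir, "epoch_0002.rds"))
  expect_identical(resumed$log, full$log)
  img <- ds$samples[[1]]$lr
  expect_identical(sr_upscale(resumed, img)$values,
                   sr_upscale(full, img)$values)

  # schema guard
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(schema = "other-0"), bad)
  expect_error(load_checkpoint(bad), "schema")
})

test_that("zero-epoch fits emit a checkpoint and an empty log", {
  ds <- tiny_data()
  ckdir <- tempfile("ck")
  cfg <- tiny_cfg(epochs = 0L, feature_discriminator = FALSE,
                  feature_weight = 0, checkpoint_dir = ckdir)
  fit <- rdagan(ds, cfg, spec = tiny_train_spec())
  expect_identical(nrow(fit$log), 0L)
  expect_true(file.exists(file.path(ckdir, "final.rds")))
  st <- load_checkpoint(file.path(ckdir, "final.rds"))
  expect_identical(st$step, 0L)
})

test_that("directory inference writes suffixed outputs and a manifest", {
  set.seed(8)
  gen <- build_generator(tiny_train_spec())
  ind <- tempfile("in"); outd <- tempfile("out")
  dir.create(ind)
  for (i in 1:2)
    write_image(random_image(12, 12, seed = i), file.path(ind, sprintf("cell%d.png", i)))
  man <- infer_dir(gen, ind, outd)
  expect_identical(man$output, c("cell1_sr.png", "cell2_sr.png"))
  sr <- read_image(file.path(outd, "cell1_sr.png"))
  expect_identical(dim(sr$values), c(24L, 24L, 3L))
  # rerun is bitwise identical on disk
  h1 <- tools::md5sum(file.path(outd, "cell1_sr.png"))
  infer_dir(gen, ind, outd)
  expect_identical(tools::md5sum(file.path(outd, "cell1_sr.png")), h1)

  emptyd <- tempfile("empty"); dir.create(emptyd)
  expect_warning(m2 <- infer_dir(gen, emptyd, outd), "empty")
  expect_identical(nrow(m2), 0L)
})

test_that("the fitted model exposes the usual S3 surface", {
  ds <- tiny_data()
  cfg <- tiny_cfg(feature_discriminator = FALSE, feature_weight = 0)
  fit <- rdagan(ds, cfg, spec = tiny_train_spec())
  expect_s3_class(fit, "rdagan")
  expect_output(print(fit), "RDABs")
  s <- summary(fit)
  expect_identical(s$n_parameters, count_parameters(fit))
  expect_output(print(s), "Parameters")
  sr <- predict(fit, ds$samples[[1]]$lr)
  expect_identical(dim(sr$values), dim(ds$samples[[1]]$hr$values))
  co <- coef(fit)
  expect_true(length(co) > 10)
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(pf))
  lg <- tempfile(fileext = ".csv")
  write_train_log(fit, lg)
  expect_identical(nrow(utils::read.csv(lg)), nrow(fit$log))
})
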