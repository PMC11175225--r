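# Generator architecture: spec handling, dense wiring, residual identities,
# fusion, upsampling, shapes and the parameter budget.

ns <- asNamespace("rdagan")

test_that("spec validation rejects unsupported configurations", {
  expect_error(generator_spec(scale = 3L), "unsupported configuration")
  expect_error(generator_spec(kernel_size = 4L), "odd")
  expect_error(generator_spec(cbam_reduction = 64L, base_channels = 64L),
               "cbam_reduction")
  expect_error(generator_spec(num_blocks = 0L), "positive")
})

test_that("spec JSON serialization round-trips to the identity", {
  sp <- tiny_spec(cbam_position = "post_residual", use_rdb = FALSE)
  expect_identical(generator_spec_from_json(generator_spec_to_json(sp)), sp)
  sp2 <- generator_spec()
  expect_identical(generator_spec_from_json(generator_spec_to_json(sp2)), sp2)
})

test_that("shallow extraction produces G0 channels at the input size", {
  set.seed(1)
  sp <- generator_spec(num_blocks = 1L, convs_per_block = 1L, growth = 8L,
                       base_channels = 64L, fusion_width = 16L)
  gen <- build_generator(sp)
  f0 <- shallow_extract(gen, random_image(96, 96))
  expect_identical(dim(f0$value), c(96L, 96L, 64L, 1L))

  # zero weights map anything to zero; 1x1 input keeps its spatial size
  zero_all_params <- get("zero_all_params", envir = ns)
  zero_all_params(gen$params)
  f0z <- shallow_extract(gen, random_image(8, 8))
  expect_true(all(f0z$value == 0))
  one <- raster_image(array(0.5, dim = c(1, 1, 3)))
  expect_identical(dim(shallow_extract(gen, one)$value)[1:2], c(1L, 1L))

  expect_error(shallow_extract(gen, array(0.1, dim = c(4, 4, 2, 1))),
               "invalid input")
})

test_that("dense wiring widths follow G0 + (c-1)G and the LFF contracts", {
  sp <- generator_spec(num_blocks = 1L, convs_per_block = 6L, growth = 32L,
                       base_channels = 64L, fusion_width = 64L)
  set.seed(2)
  gen <- build_generator(sp)
  blk <- gen$params$blocks[[1]]
  for (c in 1:6)
    expect_identical(dim(blk$dense[[c]]$w$value)[3:4],
                     c(64L + (c - 1L) * 32L, 32L))
  expect_identical(dim(blk$lff$w$value), c(1L, 1L, 64L + 6L * 32L, 64L))

  # zero input + zero weights -> zero fused output
  zp <- get("zero_all_params", envir = ns)
  zp(gen$params)
  z <- ns$ag_tensor(array(0, c(5, 5, 64, 1)))
  expect_true(all(rdb_dense_forward(z, blk, sp)$f_lf$value == 0))
})

test_that("rdb_dense_forward matches a naive explicit-concatenation oracle", {
  sp <- tiny_spec()
  set.seed(3)
  for (rep in 1:3) {
    gen <- build_generator(sp)
    blk <- gen$params$blocks[[1]]
    x <- array(rnorm(8 * 8 * 16 * 1), c(8, 8, 16, 1))
    got <- rdb_dense_forward(ns$ag_tensor(x), blk, sp)

    feats <- list(x)
    for (c in 1:sp$convs_per_block) {
      cat_in <- array(0, c(8, 8, 16 + (c - 1) * 8, 1))
      off <- 0
      for (f in feats) {
        cat_in[, , off + seq_len(dim(f)[3]), ] <- f
        off <- off + dim(f)[3]
      }
      y <- naive_conv2d(cat_in, blk$dense[[c]]$w$value, blk$dense[[c]]$b$value)
      y[y < 0] <- 0
      expect_equal(got$layer_outputs[[c]]$value, y, tolerance = 1e-10)
      feats[[c + 1]] <- y
    }
    cat_all <- array(0, c(8, 8, 16 + 3 * 8, 1))
    off <- 0
    for (f in feats) {
      cat_all[, , off + seq_len(dim(f)[3]), ] <- f
      off <- off + dim(f)[3]
    }
    lff <- naive_conv2d(cat_all, blk$lff$w$value, blk$lff$b$value, pad = 0)
    expect_equal(got$f_lf$value, lff, tolerance = 1e-10)
  }
})

test_that("zero-weight blocks are residual pass-throughs", {
  sp <- tiny_spec(cbam_enabled = FALSE)
  set.seed(4)
  gen <- build_generator(sp)
  get("zero_all_params", envir = ns)(gen$params)
  f0 <- ns$ag_tensor(array(rnorm(6 * 6 * 16 * 2), c(6, 6, 16, 2)))
  f1 <- rdab_forward(f0, gen$params$blocks[[1]], sp)
  expect_identical(f1$value, f0$value)
  fdf <- dense_feature_fusion(f0, list(f1, rdab_forward(f1, gen$params$blocks[[2]], sp)), gen)
  expect_identical(fdf$value, f0$value)
})

test_that("the plain residual ablation block still satisfies the contracts", {
  sp <- tiny_spec(use_rdb = FALSE)
  set.seed(5)
  gen <- build_generator(sp)
  expect_null(gen$params$blocks[[1]]$dense)
  f <- ns$ag_tensor(array(rnorm(6 * 6 * 16), c(6, 6, 16, 1)))
  out <- rdab_forward(f, gen$params$blocks[[1]], sp)
  expect_identical(dim(out$value), dim(f$value))
  img <- random_image(10, 10)
  expect_identical(dim(generator_forward(gen, img)$value), c(20L, 20L, 3L, 1L))
})

test_that("dense feature fusion is order-sensitive and deterministic", {
  sp <- tiny_spec()
  set.seed(6)
  gen <- build_generator(sp)
  b1 <- ns$ag_tensor(array(rnorm(5 * 5 * 16), c(5, 5, 16, 1)))
  b2 <- ns$ag_tensor(array(rnorm(5 * 5 * 16), c(5, 5, 16, 1)))
  f0 <- ns$ag_tensor(array(rnorm(5 * 5 * 16), c(5, 5, 16, 1)))
  r12 <- dense_feature_fusion(f0, list(b1, b2), gen)
  r12b <- dense_feature_fusion(f0, list(b1, b2), gen)
  r21 <- dense_feature_fusion(f0, list(b2, b1), gen)
  expect_identical(r12$value, r12b$value)
  expect_false(isTRUE(all.equal(r12$value, r21$value)))
  expect_error(dense_feature_fusion(f0, list(b1), gen), "invalid state")
})

test_that("pixel-shuffle upsampling preserves values and doubles dims", {
  sp <- tiny_spec()
  set.seed(7)
  gen <- build_generator(sp)
  fdf <- ns$ag_tensor(array(rnorm(7 * 9 * 16), c(7, 9, 16, 1)))
  out <- upsample_reconstruct(fdf, gen)
  expect_identical(dim(out$value), c(14L, 18L, 3L, 1L))

  # pixel shuffle alone: constant stays constant, multiset preserved
  const <- ns$ag_tensor(array(0.3, c(4, 4, 8, 1)))
  expect_true(all(ns$op_pixel_shuffle(const, 2L)$value == 0.3))
  x <- ns$ag_tensor(array(rnorm(4 * 4 * 8), c(4, 4, 8, 1)))
  y <- ns$op_pixel_shuffle(x, 2L)
  expect_identical(dim(y$value), c(8L, 8L, 2L, 1L))
  expect_equal(sort(as.numeric(y$value)), sort(as.numeric(x$value)))
})

test_that("the fused forward equals the explicit stage-by-stage pipeline", {
  sp <- tiny_spec()
  set.seed(8)
  gen <- build_generator(sp)
  img <- random_image(9, 11)
  fused <- generator_forward(gen, img, train = TRUE)
  f0 <- shallow_extract(gen, img)
  f <- f0
  outs <- list()
  for (d in 1:sp$num_blocks) {
    f <- rdab_forward(f, gen$params$blocks[[d]], sp)
    outs[[d]] <- f
  }
  manual <- upsample_reconstruct(dense_feature_fusion(f0, outs, gen), gen)
  expect_identical(fused$value, manual$value)

  # determinism across calls
  expect_identical(generator_forward(gen, img, train = TRUE)$value, fused$value)
})

test_that("parameter counting follows the closed form and the default budget", {
  set.seed(9)
  expect_identical(count_parameters(ns$layer_conv(3L, 3L, 64L)), 1792L)
  expect_identical(count_parameters(list()), 0L)

  # hand-computed total for the tiny spec (biases included)
  sp <- tiny_spec()
  gen <- build_generator(sp)
  dense <- sum(sapply(1:3, function(c) 9 * (16 + (c - 1) * 8) * 8 + 8))
  lff <- (16 + 3 * 8) * 16 + 16
  cbam <- 16 * 4 * 2 + (7 * 7 * 2 + 1)
  block <- dense + lff + cbam
  tail_p <- (9 * 3 * 16 + 16) + (2 * 16 * 16 + 16) + (9 * 16 * 16 + 16) +
    (9 * 16 * 64 + 64) + 16 + (9 * 16 * 3 + 3)
  expect_identical(count_parameters(gen), as.integer(2 * block + tail_p))
})

test_that("every generator parameter receives a finite nonzero gradient", {
  sp <- tiny_spec()
  set.seed(10)
  gen <- build_generator(sp)
  lr <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  hr <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  params <- ns$collect_params(gen$params)
  ns$zero_grad(params)
  ns$tape_start()
  sr <- generator_forward(gen, ns$ag_tensor(lr), train = TRUE)
  loss <- perceptual_loss(sr, ns$ag_tensor(hr))
  ns$backward(loss)
  ns$tape_end()
  for (nm in names(params)) {
    g <- params[[nm]]$grad
    expect_false(is.null(g), info = nm)
    expect_true(all(is.finite(g)), info = nm)
    expect_gt(max(abs(g)), 0)
  }
})
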