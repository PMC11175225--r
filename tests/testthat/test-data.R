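# Data pipeline: bicubic degradation, aligned crops, dihedral augmentation,
# directory loading, and the synthetic scene generator.

ns <- asNamespace("rdagan")

test_that("raster images validate and clip on creation", {
  v <- array(seq(-0.5, 1.5, length.out = 4 * 4 * 3), c(4, 4, 3))
  im <- raster_image(v)
  expect_true(all(im$values >= 0 & im$values <= 1))
  expect_error(raster_image(array(0, c(4, 4, 2))), "invalid input")
  expect_error(raster_image(matrix(0, 4, 4)), "invalid input")
})

test_that("bicubic resampling reproduces constants and linear ramps", {
  const <- raster_image(array(0.42, c(16, 16, 3)))
  down <- bicubic_downsample(const, 2L)
  expect_identical(dim(down$values), c(8L, 8L, 3L))
  expect_equal(as.numeric(down$values), rep(0.42, 8 * 8 * 3), tolerance = 1e-12)

  # linear ramp: decimation equals the analytic mid-point subsampling away
  # from borders (bicubic reproduces degree-1 polynomials)
  n <- 32
  ramp <- array(rep((seq_len(n) - 0.5) / n, times = n * 3), c(n, n, 3))
  dn <- bicubic_downsample(ramp, 2L)$values
  analytic <- (2 * (seq_len(n / 2)) - 1) / n
  expect_equal(as.numeric(dn[3:14, 8, 1]), analytic[3:14], tolerance = 1e-3)

  expect_error(bicubic_downsample(raster_image(array(0, c(15, 16, 3))), 2L),
               "divisible")
})

test_that("paired samples enforce the scale relation", {
  hr <- random_image(16, 16, seed = 1)
  lr <- bicubic_downsample(hr, 2L)
  s <- paired_sample(hr, lr, provenance = "fixture")
  expect_identical(s$scale, 2L)
  expect_error(paired_sample(hr, random_image(7, 7)), "invalid input")
})

test_that("random crops stay aligned between the HR and LR members", {
  set.seed(2)
  # build an HR image that is an exact 2x nearest-neighbour blow-up of LR,
  # so alignment is directly observable after any aligned crop
  lr_v <- array(runif(8 * 8 * 3), c(8, 8, 3))
  hr_v <- array(0, c(16, 16, 3))
  for (i in 1:8) for (j in 1:8)
    hr_v[2 * i - 1:0, 2 * j - 1:0, ] <- rep(lr_v[i, j, ], each = 4)
  s <- paired_sample(hr_v, lr_v)
  for (rep in 1:10) {
    cr <- paired_random_crop(s, 8L)
    expect_identical(dim(cr$lr$values), c(4L, 4L, 3L))
    expect_identical(dim(cr$hr$values), c(8L, 8L, 3L))
    expect_equal(cr$hr$values[seq(1, 8, 2), seq(1, 8, 2), ], cr$lr$values,
                 tolerance = 1e-12)
  }
  # full-side crop is the identity
  full <- paired_random_crop(s, 16L)
  expect_identical(full$hr$values, s$hr$values)
  expect_error(paired_random_crop(s, 32L), "invalid input")
  expect_error(paired_random_crop(s, 7L), "invalid input")
})

test_that("dihedral augmentation forms the 8-element group", {
  s0 <- asym_patch(8)
  lr0 <- bicubic_downsample(s0, 2L)
  s <- paired_sample(s0, lr0)

  expect_identical(dihedral_augment(s, 0L)$hr$values, s$hr$values)
  # 180-degree rotation is an involution
  r180 <- dihedral_augment(dihedral_augment(s, 2L), 2L)
  expect_equal(r180$hr$values, s$hr$values, tolerance = 1e-12)

  # the 8 codes give pairwise distinct images on an asymmetric patch
  variants <- lapply(0:7, function(cd) dihedral_augment(s, cd)$hr$values)
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(isTRUE(all.equal(variants[[i]], variants[[j]])))

  # closure: composing any two codes lands on some single code
  apply_code <- function(v, cd) ns$apply_dihedral(v, cd)
  for (c1 in 0:7) for (c2 in 0:7) {
    comp <- apply_code(apply_code(s$hr$values, c1), c2)
    hits <- vapply(variants, function(v) isTRUE(all.equal(v, comp)), logical(1))
    expect_identical(sum(hits), 1L)
  }

  expect_error(dihedral_augment(s, 8L), "invalid input")
  ns_sq <- paired_sample(random_image(8, 12), bicubic_downsample(random_image(8, 12), 2L))
  expect_error(dihedral_augment(ns_sq, 1L), "invalid input")
})

test_that("directory loading pairs, degrades and reports rejections", {
  hr_dir <- tempfile("hr")
  dir.create(hr_dir)
  for (i in 1:3)
    write_image(random_image(16, 16, seed = i), file.path(hr_dir, sprintf("img%d.png", i)))
  ds <- load_image_pairs(hr_dir, scale = 2L)
  expect_identical(length(ds), 3L)
  expect_identical(nrow(ds$rejected), 0L)
  for (s in ds$samples)
    expect_identical(dim(s$hr$values)[1:2], dim(s$lr$values)[1:2] * 2L)

  # explicit LR dir with one mismatched pair and one unpaired file
  lr_dir <- tempfile("lr")
  dir.create(lr_dir)
  write_image(bicubic_downsample(read_image(file.path(hr_dir, "img1.png")), 2L),
              file.path(lr_dir, "img1.png"))
  write_image(random_image(5, 5, seed = 9), file.path(lr_dir, "img2.png"))
  ds2 <- load_image_pairs(hr_dir, lr_dir, scale = 2L)
  expect_identical(length(ds2), 1L)
  expect_setequal(ds2$rejected$reason,
                  c("dimension mismatch", "no LR counterpart"))

  empty <- tempfile("none")
  dir.create(empty)
  expect_warning(e <- load_image_pairs(empty), "empty")
  expect_identical(length(e), 0L)
})

test_that("image files round-trip through PNG and TIFF", {
  im <- random_image(9, 7, seed = 3)
  quant <- raster_image(round(im$values * 255) / 255)   # 8-bit grid
  for (ext in c("png", "tiff")) {
    p <- tempfile(fileext = paste0(".", ext))
    write_image(quant, p)
    back <- read_image(p)
    expect_equal(back$values, quant$values, tolerance = 1 / 255)
  }
})

test_that("scene synthesis is seed-deterministic with full provenance", {
  sp <- synthetic_scene_spec(side = 64L, cell_count = 5L,
                             radius_range = c(5, 10), seed = 7L)
  a <- synthesize_cell_scene(sp)
  b <- synthesize_cell_scene(sp)
  expect_identical(a$values, b$values)
  prov <- attr(a, "provenance")
  expect_identical(nrow(prov$centers), 5L)
  expect_identical(prov$seed, 7L)

  # synthesis must not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(synthesize_cell_scene(sp)); after <- runif(1)
  expect_identical(before, after)

  # cell-free noise-free spec gives a smooth background field
  flat <- synthesize_cell_scene(synthetic_scene_spec(
    side = 32L, cell_count = 0L, noise_sigma = 0, seed = 1L))
  expect_lt(max(abs(diff(flat$values[, 16, 1]))), 0.01)

  expect_error(synthesize_cell_scene(synthetic_scene_spec(
    side = 32L, radius_range = c(10, 20), seed = 1L)), "cannot fit")
})

test_that("synthetic scenes carry genuine high-frequency content", {
  sp <- synthetic_scene_spec(side = 64L, cell_count = 4L,
                             radius_range = c(6, 14), seed = 11L)
  hr <- synthesize_cell_scene(sp)
  roundtrip <- bicubic_upsample(bicubic_downsample(hr, 2L), 2L)
  edge_energy <- function(img) {
    y <- img$values[, , 2]
    mean(abs(diff(y))) + mean(abs(t(diff(t(y)))))
  }
  expect_gt(edge_energy(hr), edge_energy(roundtrip))
})
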