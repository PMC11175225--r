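# Paired HR/LR data handling: raster images, the bicubic degradation model,
# aligned random cropping, dihedral augmentation, directory loading, and the
# synthetic bright-field cell-scene generator used for offline fixtures.

#' Raster image container
#'
#' A real-valued `(H, W, 3)` array with values in `[0, 1]` and a colorspace
#' tag. Values are clipped into `[0, 1]` on creation.
#'
#' @param values numeric `(H, W, 3)` array.
#' @param colorspace `"RGB"` or `"YCbCr"`.
#' @param clip clip values into `[0, 1]`? (default `TRUE`).
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(values, colorspace = c("RGB", "YCbCr"), clip = TRUE) {
  colorspace <- match.arg(colorspace)
  d <- dim(values)
  if (length(d) != 3L || d[3] != 3L)
    stop("invalid input: raster images are (H, W, 3) arrays")
  if (d[1] < 1L || d[2] < 1L) stop("invalid input: empty image")
  if (clip) {
    values[values < 0] <- 0
    values[values > 1] <- 1
  }
  structure(list(values = values, colorspace = colorspace),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_image %dx%d %s, range [%.3f, %.3f]>\n",
              d[1], d[2], x$colorspace, min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write raster images
#'
#' PNG and TIFF are supported; 8- and 16-bit files are normalized to
#' `[0, 1]`. Grayscale files are replicated to three channels, alpha
#' channels are dropped.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @param img a [raster_image()] (written as 8-bit PNG/TIFF).
#' @return `read_image()`: a `raster_image`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("invalid input: unsupported image format '", ext, "'")
  )
  if (is.null(dim(a)) || length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  if (dim(a)[3] == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  raster_image(a)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  v <- unclass_image(img)
  v[v < 0] <- 0; v[v > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop("invalid input: unsupported image format '", ext, "'")
  )
  invisible(path)
}

# ---- bicubic resampling -----------------------------------------------------

# Keys-cubic kernel, a = -0.5 (the SR-literature standard dialect).
#' @noRd
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  out <- numeric(length(x))
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  out[i1] <- (a + 2) * ax[i1]^3 - (a + 3) * ax[i1]^2 + 1
  out[i2] <- a * (ax[i2]^3 - 5 * ax[i2]^2 + 8 * ax[i2] - 4)
  out
}

# Dense (n_out x n_in) resampling matrix for one axis: bicubic kernel,
# antialias prefilter when decimating, reflect border handling.
#' @noRd
resample_matrix <- function(n_in, n_out) {
  s <- n_in / n_out
  ks <- max(1, s)           # kernel stretch = antialias prefilter
  support <- 2 * ks
  A <- matrix(0, n_out, n_in)
  reflect <- function(j, n) {       # 0-based symmetric reflection
    while (any(j < 0 | j >= n)) {
      j[j < 0] <- -j[j < 0] - 1
      j[j >= n] <- 2 * n - 1 - j[j >= n]
    }
    j
  }
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) * s - 0.5
    j <- ceiling(center - support):floor(center + support)
    w <- cubic_kernel((j - center) / ks)
    keep <- w != 0
    j <- reflect(j[keep], n_in)
    w <- w[keep] / sum(w[keep])
    for (t in seq_along(j)) A[i, j[t] + 1L] <- A[i, j[t] + 1L] + w[t]
  }
  A
}

#' Bicubic resize
#'
#' Separable bicubic resampling (kernel parameter a = -0.5) with an
#' antialias prefilter whenever an axis is decimated and reflected borders.
#' This is the degradation dialect used throughout the package.
#'
#' @param img a [raster_image()] or `(H, W, 3)` array.
#' @param out_h,out_w output dimensions.
#' @return a `raster_image` (clipped to `[0, 1]`).
#' @export
bicubic_resize <- function(img, out_h, out_w) {
  v <- unclass_image(img)
  A <- resample_matrix(dim(v)[1], out_h)
  B <- resample_matrix(dim(v)[2], out_w)
  out <- array(0, dim = c(out_h, out_w, dim(v)[3]))
  for (c in seq_len(dim(v)[3])) out[, , c] <- A %*% v[, , c] %*% t(B)
  raster_image(out)
}

#' Bicubic downsampling (the degradation model)
#'
#' Produces the LR counterpart of an HR image by bicubic decimation.
#'
#' @param hr HR image; both dimensions must be divisible by `scale`.
#' @param scale integer decimation factor.
#' @return a `raster_image` of size `H/scale x W/scale`.
#' @export
bicubic_downsample <- function(hr, scale = 2L) {
  v <- unclass_image(hr)
  if (any(dim(v)[1:2] %% scale != 0L))
    stop("invalid input: image dimensions must be divisible by scale")
  bicubic_resize(v, dim(v)[1] %/% scale, dim(v)[2] %/% scale)
}

#' @rdname bicubic_downsample
#' @param lr LR image to upsample by `scale` (the interpolation baseline).
#' @export
bicubic_upsample <- function(lr, scale = 2L) {
  v <- unclass_image(lr)
  bicubic_resize(v, dim(v)[1] * scale, dim(v)[2] * scale)
}

# ---- paired samples ---------------------------------------------------------

#' Paired HR/LR sample
#'
#' @param hr,lr HR and LR [raster_image()]s; HR dimensions must be an exact
#'   integer multiple of the LR dimensions.
#' @param provenance free-form tag (file path or synthesis seed).
#' @return an object of class `paired_sample` with the inferred `scale`.
#' @export
paired_sample <- function(hr, lr, provenance = NA_character_) {
  hv <- unclass_image(hr); lv <- unclass_image(lr)
  sc <- dim(hv)[1] / dim(lv)[1]
  if (sc != round(sc) || !identical(dim(hv)[1:2], dim(lv)[1:2] * as.integer(sc)))
    stop("invalid input: hr dims must be an integer multiple of lr dims")
  structure(list(hr = raster_image(hv), lr = raster_image(lv),
                 scale = as.integer(sc), provenance = provenance),
            class = "paired_sample")
}

#' Aligned random crop of a paired sample
#'
#' Crops an `hr_size` square from the HR image at a random scale-aligned
#' origin and the corresponding `hr_size/scale` square from the LR image;
#' alignment is exact by construction. Uses the current R RNG stream.
#'
#' @param sample a [paired_sample()].
#' @param hr_size HR crop side; must be divisible by the sample's scale and
#'   no larger than the HR side.
#' @return a cropped `paired_sample`.
#' @export
paired_random_crop <- function(sample, hr_size) {
  sc <- sample$scale
  hv <- sample$hr$values; lv <- sample$lr$values
  if (hr_size %% sc != 0L) stop("invalid input: hr_size must be divisible by scale")
  if (hr_size > dim(hv)[1] || hr_size > dim(hv)[2])
    stop("invalid input: hr_size exceeds the image side")
  lr_size <- hr_size %/% sc
  y_lr <- sample.int(dim(lv)[1] - lr_size + 1L, 1L) - 1L
  x_lr <- sample.int(dim(lv)[2] - lr_size + 1L, 1L) - 1L
  y_hr <- y_lr * sc; x_hr <- x_lr * sc
  paired_sample(
    hr = hv[y_hr + seq_len(hr_size), x_hr + seq_len(hr_size), , drop = FALSE],
    lr = lv[y_lr + seq_len(lr_size), x_lr + seq_len(lr_size), , drop = FALSE],
    provenance = sample$provenance
  )
}

# one 90-degree rotation of an (H, W, C) array
#' @noRd
rot90_arr <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[rev(seq_len(dim(b)[1])), , , drop = FALSE]
}

#' @noRd
apply_dihedral <- function(a, code) {
  if (code %/% 4L == 1L) a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  k <- code %% 4L
  if (k > 0) for (i in seq_len(k)) a <- rot90_arr(a)
  a
}

#' Dihedral augmentation
#'
#' Applies one of the 8 symmetries of the square (4 rotations x optional
#' horizontal flip) identically to the HR and LR members of a pair. Codes
#' 0-3 are rotations by 0/90/180/270 degrees, codes 4-7 add the flip.
#'
#' @param sample a square-cropped [paired_sample()].
#' @param code integer 0-7.
#' @return the transformed `paired_sample`.
#' @export
dihedral_augment <- function(sample, code) {
  code <- as.integer(code)
  if (code < 0L || code > 7L) stop("invalid input: dihedral code must be 0-7")
  hv <- sample$hr$values
  if (dim(hv)[1] != dim(hv)[2])
    stop("invalid input: dihedral augmentation needs square crops")
  paired_sample(apply_dihedral(hv, code),
                apply_dihedral(sample$lr$values, code),
                provenance = sample$provenance)
}

# ---- directory loading ------------------------------------------------------

#' Load a directory of paired images
#'
#' Builds an order-stable dataset of [paired_sample()]s from an HR directory
#' and either a matching LR directory (paired by filename) or on-the-fly
#' bicubic degradation. Problem files are listed in the `rejected` report of
#' the returned object, never silently dropped.
#'
#' @param hr_dir directory of HR PNG/TIFF files.
#' @param lr_dir optional directory of LR files with matching names.
#' @param scale degradation factor used when `lr_dir` is `NULL`, and the
#'   expected HR/LR ratio otherwise.
#' @return an object of class `paired_dataset`: list with `samples` and a
#'   `rejected` data frame.
#' @export
load_image_pairs <- function(hr_dir, lr_dir = NULL, scale = 2L) {
  if (!dir.exists(hr_dir)) stop("invalid input: hr_dir does not exist")
  pat <- "\\.(png|tif|tiff)$"
  hr_files <- sort(list.files(hr_dir, pattern = pat, ignore.case = TRUE))
  rejected <- data.frame(file = character(), reason = character(),
                         stringsAsFactors = FALSE)
  samples <- list()
  if (length(hr_files) == 0L) warning("empty HR directory: empty dataset")
  lr_files <- if (!is.null(lr_dir)) {
    if (!dir.exists(lr_dir)) stop("invalid input: lr_dir does not exist")
    sort(list.files(lr_dir, pattern = pat, ignore.case = TRUE))
  }
  for (f in hr_files) {
    hr <- try(read_image(file.path(hr_dir, f)), silent = TRUE)
    if (inherits(hr, "try-error")) {
      rejected <- rbind(rejected, data.frame(file = f, reason = "unreadable HR file"))
      next
    }
    if (is.null(lr_dir)) {
      if (any(dim(hr$values)[1:2] %% scale != 0L)) {
        rejected <- rbind(rejected, data.frame(file = f, reason = "HR dims not divisible by scale"))
        next
      }
      samples[[length(samples) + 1L]] <-
        paired_sample(hr, bicubic_downsample(hr, scale), provenance = f)
    } else {
      if (!f %in% lr_files) {
        rejected <- rbind(rejected, data.frame(file = f, reason = "no LR counterpart"))
        next
      }
      lr <- read_image(file.path(lr_dir, f))
      ok <- try(paired_sample(hr, lr, provenance = f), silent = TRUE)
      if (inherits(ok, "try-error") ||
          !identical(dim(hr$values)[1:2], dim(lr$values)[1:2] * as.integer(scale))) {
        rejected <- rbind(rejected, data.frame(file = f, reason = "dimension mismatch"))
        next
      }
      samples[[length(samples) + 1L]] <- ok
    }
  }
  if (!is.null(lr_dir)) for (f in setdiff(lr_files, hr_files))
    rejected <- rbind(rejected, data.frame(file = f, reason = "no HR counterpart"))
  structure(list(samples = samples, rejected = rejected),
            class = "paired_dataset")
}

#' @export
length.paired_dataset <- function(x) length(x$samples)

#' Wrap a list of paired samples as a dataset
#' @param samples list of [paired_sample()]s.
#' @return a `paired_dataset`.
#' @export
paired_dataset <- function(samples) {
  structure(list(samples = samples,
                 rejected = data.frame(file = character(), reason = character())),
            class = "paired_dataset")
}

# ---- synthetic bright-field scenes ------------------------------------------

#' Synthetic scene specification
#'
#' Parameters of the bright-field cell-field emulator: rounded cell bodies
#' with darker nuclei and intra-cell texture on a smoothly illuminated bright
#' background, followed by mild optical blur and sensor noise. The seed fully
#' determines the output.
#'
#' @param side canvas side in pixels.
#' @param cell_count number of cells.
#' @param radius_range min/max cell semi-axis in pixels.
#' @param nucleus_contrast extra darkening of the nucleus (fraction).
#' @param texture_amplitude amplitude of the multiplicative intra-cell texture.
#' @param illumination_gradient peak-to-center amplitude of the smooth
#'   background illumination ramp (fraction of the base level).
#' @param blur_sigma Gaussian blur sigma in pixels (optical softness).
#' @param noise_sigma additive Gaussian sensor-noise sigma.
#' @param seed integer RNG seed.
#' @return an object of class `scene_spec`.
#' @export
synthetic_scene_spec <- function(side = 256L, cell_count = 12L,
                                 radius_range = c(10, 24),
                                 nucleus_contrast = 0.25,
                                 texture_amplitude = 0.2,
                                 illumination_gradient = 0.08,
                                 blur_sigma = 0.5, noise_sigma = 0.015,
                                 seed = 1L) {
  if (any(radius_range <= 0) || blur_sigma < 0 || noise_sigma < 0 ||
      cell_count < 0 || side < 8)
    stop("invalid scene specification")
  structure(list(side = as.integer(side), cell_count = as.integer(cell_count),
                 radius_range = radius_range, nucleus_contrast = nucleus_contrast,
                 texture_amplitude = texture_amplitude,
                 illumination_gradient = illumination_gradient,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# separable Gaussian blur with reflected borders (matrix-operator form)
#' @noRd
gaussian_blur_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n1 <- nrow(m); n2 <- ncol(m)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      j <- seq_len(n) + d
      j[j < 1] <- 1 - (j[j < 1])       # 0-based reflection: -j-1 -> 1-based
      j[j > n] <- 2 * n + 1 - j[j > n]
      for (i in seq_len(n)) B[i, j[i]] <- B[i, j[i]] + k[d + r + 1]
    }
    B
  }
  band(n1) %*% m %*% t(band(n2))
}

#' Synthesize a bright-field cell scene
#'
#' Fully seed-deterministic fixture generator (see
#' [synthetic_scene_spec()]). The caller's RNG stream is left untouched.
#' Provenance metadata — the seed and the matrix of cell centers — is
#' attached as the `"provenance"` attribute.
#'
#' @param spec a [synthetic_scene_spec()].
#' @return a `raster_image` with provenance attribute.
#' @export
synthesize_cell_scene <- function(spec = synthetic_scene_spec()) {
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$side
  rmax <- max(spec$radius_range)
  if (spec$cell_count > 0 && 2 * rmax >= n)
    stop("invalid scene specification: cells cannot fit the canvas")

  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)

  # smooth bright background with an illumination ramp
  theta <- runif(1, 0, 2 * pi)
  ramp <- ((xx / n - 0.5) * cos(theta) + (yy / n - 0.5) * sin(theta))
  lum <- 0.86 * (1 + spec$illumination_gradient * 2 * ramp)

  cell_mask <- matrix(0, n, n)
  nuc_mask <- matrix(0, n, n)
  centers <- matrix(numeric(0), ncol = 2)
  if (spec$cell_count > 0) {
    centers <- cbind(runif(spec$cell_count, rmax + 1, n - rmax),
                     runif(spec$cell_count, rmax + 1, n - rmax))
    for (i in seq_len(spec$cell_count)) {
      a <- runif(1, spec$radius_range[1], spec$radius_range[2])
      b <- runif(1, spec$radius_range[1], spec$radius_range[2])
      phi <- runif(1, 0, pi)
      dy <- yy - centers[i, 1]; dx <- xx - centers[i, 2]
      u <- (dx * cos(phi) + dy * sin(phi)) / a
      v <- (-dx * sin(phi) + dy * cos(phi)) / b
      inside <- u^2 + v^2 <= 1
      cell_mask[inside] <- 1
      nuc <- u^2 + v^2 <= runif(1, 0.12, 0.25)
      nuc_mask[nuc] <- 1
    }
  }

  # darker cytoplasm, darker still nucleus, multiplicative intra-cell texture
  tex <- gaussian_blur_mat(matrix(rnorm(n * n), n, n), 1.2)
  tex <- tex / max(1e-9, sd(tex))
  lum <- lum * (1 - 0.18 * cell_mask) * (1 - spec$nucleus_contrast * nuc_mask) *
    (1 + spec$texture_amplitude * tex * cell_mask)

  # eosin-like tint inside cells, then optics blur and sensor noise
  img <- array(0, dim = c(n, n, 3))
  tint <- c(0.03, 0.12, 0.05)
  for (c in 1:3) {
    ch <- lum * (1 - tint[c] * cell_mask)
    ch <- gaussian_blur_mat(ch, spec$blur_sigma)
    if (spec$noise_sigma > 0) ch <- ch + rnorm(n * n, sd = spec$noise_sigma)
    img[, , c] <- ch
  }
  out <- raster_image(img)
  attr(out, "provenance") <- list(seed = spec$seed, centers = centers,
                                  spec = unclass(spec))
  out
}

#' Synthesize a paired dataset of cell scenes
#'
#' Generates `n` scenes with consecutive seeds and pairs each with its
#' bicubic-downsampled LR counterpart.
#'
#' @param n number of scenes.
#' @param spec template [synthetic_scene_spec()]; its seed is the base seed.
#' @param scale degradation factor.
#' @return a `paired_dataset`.
#' @export
synthesize_cell_dataset <- function(n, spec = synthetic_scene_spec(),
                                    scale = 2L) {
  samples <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    hr <- synthesize_cell_scene(sp)
    paired_sample(hr, bicubic_downsample(hr, scale),
                  provenance = paste0("seed:", sp$seed))
  })
  paired_dataset(samples)
}
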