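# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Tensors are environments holding a value, an (accumulated) gradient, and —
# while a tape is active — the parent tensors plus a vector-Jacobian-product
# closure. The tape is a flat list in creation order; backward() walks it in
# reverse, so topological order is free. Layout conventions:
#   feature maps  (H, W, C, N)   channel descriptors (C, N)
#   dense acts    (F, N)         scalars             length-1
# Gradients always match the shape of the value they belong to.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

ag_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires_grad <- requires_grad
  t$needs_grad <- requires_grad
  class(t) <- "ag_tensor"
  t
}

ag_param <- function(value) ag_tensor(value, requires_grad = TRUE)

as_tensor <- function(x) if (inherits(x, "ag_tensor")) x else ag_tensor(x)

ag_detach <- function(t) ag_tensor(t$value)

tape_start <- function() {
  .ag$recording <- TRUE
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

tape_end <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

# Build a result node; goes on the tape only if some parent needs gradients.
ag_node <- function(value, parents, vjp) {
  t <- ag_tensor(value)
  if (.ag$recording &&
      any(vapply(parents, function(p) isTRUE(p$needs_grad), logical(1)))) {
    t$needs_grad <- TRUE
    t$parents <- parents
    t$vjp <- vjp
    n <- .ag$n + 1L
    if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
    .ag$tape[[n]] <- t
    .ag$n <- n
  }
  t
}

# Reverse pass from a scalar loss. Gradients accumulate into every tensor on
# the tape and into leaf parameters (requires_grad = TRUE).
backward <- function(loss) {
  if (!.ag$recording) stop("backward() called with no active tape")
  if (length(loss$value) != 1L) stop("backward() expects a scalar loss")
  if (!isTRUE(loss$needs_grad)) stop("loss does not depend on any parameter")
  loss$grad <- array(1, dim = dim_or_len(loss$value))
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (is.null(node$grad) || is.null(node$vjp)) next
    gs <- node$vjp(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      g <- gs[[j]]
      if (is.null(g) || !isTRUE(p$needs_grad)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise ops --------------------------------------------------------

op_add <- function(x, y) {
  x <- as_tensor(x); y <- as_tensor(y)
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

op_sub <- function(x, y) {
  x <- as_tensor(x); y <- as_tensor(y)
  ag_node(x$value - y$value, list(x, y), function(g) list(g, -g))
}

op_mul <- function(x, y) {
  x <- as_tensor(x); y <- as_tensor(y)
  xv <- x$value; yv <- y$value
  ag_node(xv * yv, list(x, y), function(g) list(g * yv, g * xv))
}

# multiply by a plain numeric constant
op_smul <- function(x, k) {
  x <- as_tensor(x)
  ag_node(x$value * k, list(x), function(g) list(g * k))
}

op_neg <- function(x) op_smul(x, -1)

op_relu <- function(x) {
  x <- as_tensor(x)
  v <- x$value
  mask <- v > 0
  v[!mask] <- 0
  ag_node(v, list(x), function(g) list(g * mask))
}

op_leaky_relu <- function(x, slope = 0.2) {
  x <- as_tensor(x)
  v <- x$value
  neg <- v < 0
  v[neg] <- slope * v[neg]
  ag_node(v, list(x), function(g) {
    gx <- g
    gx[neg] <- slope * gx[neg]
    list(gx)
  })
}

# PReLU with one learnable slope per channel (alpha: length-C tensor),
# input (H, W, C, N).
op_prelu <- function(x, alpha) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  slope <- rep(rep(alpha$value, each = hw), times = d[4])
  v <- x$value
  neg <- v < 0
  v[neg] <- (slope * x$value)[neg]
  ag_node(v, list(x, alpha), function(g) {
    gx <- g
    gx[neg] <- (slope * g)[neg]
    gn <- g * x$value
    gn[!neg] <- 0
    cs <- colSums(matrix(gn, nrow = hw))        # length C * N
    list(gx, rowSums(matrix(cs, nrow = d[3])))
  })
}

op_sigmoid <- function(x) {
  x <- as_tensor(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_log <- function(x) {
  x <- as_tensor(x)
  xv <- x$value
  ag_node(log(xv), list(x), function(g) list(g / xv))
}

# Clamp with straight-through gradient inside the interval.
op_clamp <- function(x, lo, hi) {
  x <- as_tensor(x)
  v <- x$value
  inside <- v > lo & v < hi
  v[v < lo] <- lo
  v[v > hi] <- hi
  ag_node(v, list(x), function(g) list(g * inside))
}

# ---- reductions and losses --------------------------------------------------

op_mean_all <- function(x) {
  x <- as_tensor(x)
  n <- length(x$value)
  d <- dim_or_len(x$value)
  ag_node(mean(x$value), list(x), function(g) list(array(as.numeric(g) / n, dim = d)))
}

op_mse <- function(x, y) {
  x <- as_tensor(x); y <- as_tensor(y)
  diff <- x$value - y$value
  n <- length(diff)
  ag_node(mean(diff^2), list(x, y), function(g) {
    gx <- (2 * as.numeric(g) / n) * diff
    list(gx, -gx)
  })
}

# ---- structural ops ---------------------------------------------------------

op_concat_c <- function(xs) {
  xs <- lapply(xs, as_tensor)
  dims <- lapply(xs, function(t) dim(t$value))
  cc <- vapply(dims, `[`, numeric(1), 3)
  d0 <- dims[[1]]
  out <- array(0, dim = c(d0[1], d0[2], sum(cc), d0[4]))
  hi <- cumsum(cc)
  lo <- hi - cc + 1
  for (i in seq_along(xs)) out[, , lo[i]:hi[i], ] <- xs[[i]]$value
  ag_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, , lo[i]:hi[i], , drop = FALSE])
  })
}

op_flatten <- function(x) {
  d <- dim(x$value)
  ag_node(matrix(x$value, nrow = prod(d[1:3]), ncol = d[4]), list(x),
          function(g) list(array(g, dim = d)))
}

# ---- convolution / pooling / shuffle ----------------------------------------

op_conv2d <- function(x, w, b, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- dim(w$value)[1] %/% 2L
  v <- cpp_conv2d_forward(x$value, w$value, b$value, stride, pad)
  xn <- isTRUE(x$needs_grad)
  ag_node(v, list(x, w, b), function(g) {
    r <- cpp_conv2d_backward(x$value, w$value, g, stride, pad, xn)
    list(if (xn) r$gx else NULL, r$gw, r$gb)
  })
}

op_maxpool2 <- function(x) {
  d <- dim(x$value)
  r <- cpp_maxpool2_forward(x$value)
  ag_node(r$out, list(x), function(g) {
    list(cpp_maxpool2_backward(g, r$argmax, d[1], d[2]))
  })
}

# Sub-pixel rearrangement: (H, W, C, N) -> (rH, rW, C/r^2, N), channel group
# c*r^2 + dh*r + dw lands on spatial offset (dh, dw).
op_pixel_shuffle <- function(x, r = 2L) {
  d <- dim(x$value)
  if (d[3] %% (r * r) != 0L) stop("pixel shuffle needs channels divisible by r^2")
  co <- d[3] %/% (r * r)
  out <- array(0, dim = c(d[1] * r, d[2] * r, co, d[4]))
  idx <- vector("list", r * r)
  for (dh in 0:(r - 1)) for (dw in 0:(r - 1)) {
    src <- (0:(co - 1)) * r * r + dh * r + dw + 1
    rows <- seq(dh + 1, d[1] * r, by = r)
    cols <- seq(dw + 1, d[2] * r, by = r)
    out[rows, cols, , ] <- x$value[, , src, ]
    idx[[dh * r + dw + 1]] <- list(src = src, rows = rows, cols = cols)
  }
  ag_node(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (it in idx) gx[, , it$src, ] <- g[it$rows, it$cols, , , drop = FALSE]
    list(gx)
  })
}

# ---- pooling over axes ------------------------------------------------------

# global average pool: (H, W, C, N) -> (C, N)
op_gap <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- matrix(colSums(matrix(x$value, nrow = hw)) / hw, nrow = d[3])
  ag_node(v, list(x), function(g) {
    list(array(rep(as.numeric(g) / hw, each = hw), dim = d))
  })
}

# global max pool: (H, W, C, N) -> (C, N)
op_gmp <- function(x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, nrow = hw)
  arg <- max.col(t(m), ties.method = "first")
  v <- matrix(m[cbind(arg, seq_along(arg))], nrow = d[3])
  ag_node(v, list(x), function(g) {
    gx <- numeric(length(x$value))
    gx[arg + (seq_along(arg) - 1L) * hw] <- as.numeric(g)
    list(array(gx, dim = d))
  })
}

# mean across channels: (H, W, C, N) -> (H, W, 1, N)
op_cmean <- function(x) {
  d <- dim(x$value)
  s <- array(0, dim = c(d[1], d[2], 1, d[4]))
  for (c in seq_len(d[3])) s[, , 1, ] <- s[, , 1, ] + x$value[, , c, ]
  s <- s / d[3]
  ag_node(s, list(x), function(g) {
    gx <- array(0, dim = d)
    g3 <- array(g, dim = c(d[1], d[2], d[4])) / d[3]
    for (c in seq_len(d[3])) gx[, , c, ] <- g3
    list(gx)
  })
}

# max across channels: (H, W, C, N) -> (H, W, 1, N)
op_cmax <- function(x) {
  d <- dim(x$value)
  best <- x$value[, , 1, , drop = FALSE]
  arg <- array(1L, dim = dim(best))
  if (d[3] > 1) for (c in 2:d[3]) {
    v <- x$value[, , c, , drop = FALSE]
    upd <- v > best
    best[upd] <- v[upd]
    arg[upd] <- c
  }
  ag_node(best, list(x), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[3])) {
      mask <- arg == c
      sl <- gx[, , c, , drop = FALSE]
      sl[mask] <- g[mask]
      gx[, , c, ] <- sl
    }
    list(gx)
  })
}

# ---- broadcast multiplies for attention -------------------------------------

# scale each channel: x (H, W, C, N) * s (C, N)
op_scale_channels <- function(x, s) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  e <- array(rep(as.numeric(s$value), each = hw), dim = d)
  xv <- x$value
  ag_node(xv * e, list(x, s), function(g) {
    gs <- matrix(colSums(matrix(g * xv, nrow = hw)), nrow = d[3])
    list(g * e, gs)
  })
}

# scale each pixel: x (H, W, C, N) * m (H, W, 1, N)
op_scale_spatial <- function(x, m) {
  d <- dim(x$value)
  m3 <- array(m$value, dim = c(d[1], d[2], d[4]))
  e <- array(0, dim = d)
  for (c in seq_len(d[3])) e[, , c, ] <- m3
  xv <- x$value
  ag_node(xv * e, list(x, m), function(g) {
    gm <- array(0, dim = c(d[1], d[2], d[4]))
    gxv <- g * xv
    for (c in seq_len(d[3])) gm <- gm + gxv[, , c, ]
    list(g * e, array(gm, dim = c(d[1], d[2], 1, d[4])))
  })
}

# ---- dense / batchnorm ------------------------------------------------------

# bias-free linear map: x (F, N), w (F, Fo) -> (Fo, N)
op_matmul <- function(x, w) {
  v <- crossprod(w$value, x$value)
  ag_node(v, list(x, w), function(g) {
    list(w$value %*% g, x$value %*% t(g))
  })
}

# x (F, N), w (F, Fo), b length Fo -> (Fo, N)
op_dense <- function(x, w, b) {
  v <- crossprod(w$value, x$value) + b$value
  ag_node(v, list(x, w, b), function(g) {
    list(w$value %*% g, x$value %*% t(g), rowSums(g))
  })
}

# Batch normalization over (H, W, N) per channel, batch statistics
# (training-mode; the discriminators are only ever run in training).
op_batchnorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- hw * d[4]
  per_cn <- matrix(colSums(matrix(x$value, nrow = hw)), nrow = d[3])
  mu <- rowSums(per_cn) / m
  per_cn2 <- matrix(colSums(matrix(x$value^2, nrow = hw)), nrow = d[3])
  varc <- rowSums(per_cn2) / m - mu^2
  inv_sd <- 1 / sqrt(varc + eps)

  expand <- function(v) array(rep(rep(v, each = hw), times = d[4]), dim = d)
  xhat <- (x$value - expand(mu)) * expand(inv_sd)
  ge <- expand(gamma$value)
  v <- ge * xhat + expand(beta$value)

  csum <- function(a) rowSums(matrix(colSums(matrix(a, nrow = hw)), nrow = d[3]))
  ag_node(v, list(x, gamma, beta), function(g) {
    gbeta <- csum(g)
    ggamma <- csum(g * xhat)
    ghat <- g * ge
    s1 <- csum(ghat)
    s2 <- csum(ghat * xhat)
    gx <- expand(inv_sd / m) * (m * ghat - expand(s1) - xhat * expand(s2))
    list(gx, ggamma, gbeta)
  })
}
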