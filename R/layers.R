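# Parameterized layers: construction, Kaiming initialization, and parameter
# bookkeeping. A "module" is a named list whose leaves are ag_tensor
# parameters; nesting mirrors the architecture.

#' @noRd
layer_conv <- function(k, cin, cout, bias = TRUE, init = c("kaiming", "zero"),
                       init_scale = 1) {
  init <- match.arg(init)
  w <- if (init == "zero") array(0, dim = c(k, k, cin, cout)) else {
    sd <- init_scale * sqrt(2 / (k * k * cin))   # fan-in
    array(rnorm(k * k * cin * cout, sd = sd), dim = c(k, k, cin, cout))
  }
  list(w = ag_param(w), b = ag_param(numeric(cout)), bias = bias)
}

#' @noRd
layer_dense <- function(fin, fout, init = c("kaiming", "zero")) {
  init <- match.arg(init)
  w <- if (init == "zero") matrix(0, fin, fout) else
    matrix(rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout)
  list(w = ag_param(w), b = ag_param(numeric(fout)))
}

#' @noRd
layer_prelu <- function(channels, init = 0.25) {
  list(alpha = ag_param(rep(init, channels)))
}

#' @noRd
layer_bn <- function(channels) {
  list(gamma = ag_param(rep(1, channels)), beta = ag_param(numeric(channels)))
}

# Flatten a module tree into a named list of parameter tensors.
#' @noRd
collect_params <- function(module, prefix = "") {
  out <- list()
  if (inherits(module, "ag_tensor")) {
    out[[prefix]] <- module
    return(out)
  }
  if (!is.list(module)) return(out)
  nms <- names(module)
  for (i in seq_along(module)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    child <- module[[i]]
    if (inherits(child, "ag_tensor") || is.list(child)) {
      p <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      out <- c(out, collect_params(child, p))
    }
  }
  out
}

#' @noRd
n_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$value), numeric(1)))
}

# Copy all parameter values (for freeze checks and checkpoints).
#' @noRd
param_values <- function(module) lapply(collect_params(module), function(p) p$value)

#' @noRd
set_param_values <- function(module, values) {
  ps <- collect_params(module)
  stopifnot(identical(names(ps), names(values)))
  for (nm in names(ps)) ps[[nm]]$value <- values[[nm]]
  invisible(module)
}

#' @noRd
zero_all_params <- function(module) {
  for (p in collect_params(module)) p$value[] <- 0
  invisible(module)
}

#' @noRd
freeze_params <- function(module) {
  for (p in collect_params(module)) {
    p$requires_grad <- FALSE
    p$needs_grad <- FALSE
  }
  invisible(module)
}

# ---- ADAM -------------------------------------------------------------------

# One optimizer instance per model; params is a named list of ag_tensors.
#' @noRd
adam_new <- function(params, lr = 2e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(
    params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p$value * 0),
    v = lapply(params, function(p) p$value * 0)
  )
  class(st) <- "rdagan_adam"
  st
}

# Applies one update in place on the tensors; returns the updated moments.
#' @noRd
adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}
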