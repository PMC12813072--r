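#' @useDynLib leafcga, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames predict
#' @importFrom utils head tail
NULL

# ---- module infrastructure ---------------------------------------------------
#
# A module is an environment carrying trainable parameters, their gradients,
# non-trainable buffers, child modules and a forward cache. Reference semantics
# let the optimiser update weights in place and let backward passes consume
# caches written by the matching forward pass.

new_module <- function(.cls, ..., .children = list()) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$grads <- list()
  m$buffers <- list()
  m$children <- .children
  m$training <- FALSE
  m$cache <- NULL
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- c(.cls, "lcga_module")
  m
}

#' Run a module's forward pass
#'
#' @param m a module created by one of the block constructors.
#' @param x input array of shape `(batch, channels, height, width)` (or a
#'   matrix for fully-connected layers).
#' @return the module output; shape depends on the module.
#' @export
nn_forward <- function(m, x) UseMethod("nn_forward")

# Backward pass: takes the gradient w.r.t. the module output, accumulates
# parameter gradients into m$grads, and returns the gradient w.r.t. the input.
nn_backward <- function(m, gy) UseMethod("nn_backward")

# Static profile: given the per-sample input shape c(C, H, W), returns
# list(shape = output shape, rows = data.frame(name, kind, params, macs)).
nn_profile <- function(m, in_shape, name = class(m)[1]) UseMethod("nn_profile")

#' @export
print.lcga_module <- function(x, ...) {
  cat(sprintf("<%s> parameters: %s\n", class(x)[1],
              format(param_count(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a module or model
#'
#' Walks the module tree and sums the lengths of every trainable array
#' (convolution and linear weights, biases, batch-norm scale and shift).
#'
#' @param m a module or assembled model.
#' @return integer-valued count of trainable parameters.
#' @export
param_count <- function(m) {
  sum(vapply(module_params(m), length, numeric(1)))
}

# Named flat list of all parameter arrays (references into module envs).
module_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params))
    out <- setNames(m$params, paste0(prefix, names(m$params)))
  for (nm in names(m$children)) {
    ch <- m$children[[nm]]
    if (is.list(ch) && !inherits(ch, "lcga_module")) {
      for (i in seq_along(ch))
        out <- c(out, module_params(ch[[i]], sprintf("%s%s%d.", prefix, nm, i)))
    } else {
      out <- c(out, module_params(ch, paste0(prefix, nm, ".")))
    }
  }
  out
}

# Apply fn(module) to every module in the tree (parents first).
module_walk <- function(m, fn) {
  fn(m)
  for (ch in m$children) {
    if (is.list(ch) && !inherits(ch, "lcga_module")) lapply(ch, module_walk, fn = fn)
    else module_walk(ch, fn)
  }
  invisible(m)
}

set_training <- function(m, flag) {
  module_walk(m, function(mm) mm$training <- flag)
}

zero_grads <- function(m) {
  module_walk(m, function(mm) {
    mm$grads <- lapply(mm$params, function(p) array(0, dim = dim(p) %||% length(p)))
    if (length(mm$params)) names(mm$grads) <- names(mm$params)
  })
}

# Deep copy of all parameter and buffer values (for checkpointing best weights).
module_state <- function(m) {
  state <- list()
  i <- 0L
  module_walk(m, function(mm) {
    i <<- i + 1L
    state[[i]] <<- list(params = mm$params, buffers = mm$buffers)
  })
  state
}

module_restore <- function(m, state) {
  i <- 0L
  module_walk(m, function(mm) {
    i <<- i + 1L
    mm$params <- state[[i]]$params
    mm$buffers <- state[[i]]$buffers
  })
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- small numeric helpers ---------------------------------------------------

tdim <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array input")
  d
}

# broadcast a per-channel vector over an (N, C, H, W) array
bcast_chan <- function(v, dm) {
  array(rep(rep(v, each = dm[1]), times = prod(dm[3:4])), dim = dm)
}

# broadcast an (N, C) matrix over an (N, C, H, W) array
bcast_nc <- function(g, dm) array(as.vector(g), dim = dm)

# per-channel sum of an (N, C, H, W) array -> length C
chan_sum <- function(x) {
  dm <- tdim(x)
  colSums(matrix(aperm(x, c(1, 3, 4, 2)), ncol = dm[2]))
}

# per-(n, c) spatial sum -> (N, C) matrix
nc_sum <- function(x) {
  dm <- tdim(x)
  y <- rowSums(matrix(x, nrow = dm[1] * dm[2]))
  matrix(y, dm[1], dm[2])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

cat_channels <- function(parts) {
  dms <- lapply(parts, tdim)
  dm <- dms[[1]]
  dm[2] <- sum(vapply(dms, `[`, numeric(1), 2))
  out <- array(0, dim = dm)
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[2]
    out[, at + seq_len(cp), , ] <- p
    at <- at + cp
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    part <- x[, at + seq_len(s), , , drop = FALSE]
    at <<- at + s
    part
  })
}

conv_out_hw <- function(hw, k, stride, pad) (hw + 2 * pad - k) %/% stride + 1

profile_row <- function(name, kind, params, macs = 0) {
  data.frame(name = name, kind = kind, params = params, macs = macs,
             stringsAsFactors = FALSE)
}

# seeded evaluation helper (restores the caller's RNG state afterwards)
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max),
             kind = "Mersenne-Twister", normal.kind = "Inversion")
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}
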