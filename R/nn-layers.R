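# ---- primitive layers --------------------------------------------------------

# Kaiming-normal initialisation keyed off fan-in; deterministic under the
# RNG state active when the module is built.
init_weight <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / ncol)), nrow, ncol)
}

nn_conv2d <- function(c_in, c_out, k, stride = 1, pad = NULL, groups = 1,
                      bias = FALSE) {
  if (c_in < 1 || c_out < 1) stop("channel counts must be positive")
  if (c_in %% groups != 0 || c_out %% groups != 0)
    stop("groups must divide both channel counts")
  pad <- pad %||% (k %/% 2)
  m <- new_module("nn_conv2d", c_in = c_in, c_out = c_out, k = k,
                  stride = stride, pad = pad, groups = groups, has_bias = bias)
  m$params$w <- init_weight(c_out, (c_in %/% groups) * k * k)
  if (bias) m$params$b <- numeric(c_out)
  m
}

#' @export
nn_forward.nn_conv2d <- function(m, x) {
  y <- .conv2d_fw(x, dim(x), m$params$w, m$k, m$stride, m$pad, m$groups)
  if (m$has_bias) y <- y + bcast_chan(m$params$b, dim(y))
  if (m$training) m$cache <- list(x = x)
  y
}

#' @export
nn_backward.nn_conv2d <- function(m, gy) {
  x <- m$cache$x
  r <- .conv2d_bw(x, dim(x), gy, m$params$w, m$k, m$stride, m$pad, m$groups)
  m$grads$w <- m$grads$w + r$gw
  if (m$has_bias) m$grads$b <- m$grads$b + chan_sum(gy)
  r$gx
}

#' @export
nn_profile.nn_conv2d <- function(m, in_shape, name = "conv") {
  ho <- conv_out_hw(in_shape[2], m$k, m$stride, m$pad)
  wo <- conv_out_hw(in_shape[3], m$k, m$stride, m$pad)
  macs <- m$k^2 * (m$c_in / m$groups) * m$c_out * ho * wo
  params <- length(m$params$w) + if (m$has_bias) m$c_out else 0
  list(shape = c(m$c_out, ho, wo),
       rows = profile_row(name, sprintf("conv%dx%d", m$k, m$k), params, macs))
}

nn_batchnorm2d <- function(c, eps = 1e-5, momentum = 0.1) {
  m <- new_module("nn_batchnorm2d", c = c, eps = eps, momentum = momentum)
  m$params$gamma <- rep(1, c)
  m$params$beta <- rep(0, c)
  m$buffers$running_mean <- rep(0, c)
  m$buffers$running_var <- rep(1, c)
  m
}

#' @export
nn_forward.nn_batchnorm2d <- function(m, x) {
  dm <- tdim(x)
  if (m$training) {
    mat <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = dm[2])
    mu <- colMeans(mat)
    v <- colMeans(mat^2) - mu^2
    m$buffers$running_mean <- (1 - m$momentum) * m$buffers$running_mean + m$momentum * mu
    m$buffers$running_var <- (1 - m$momentum) * m$buffers$running_var + m$momentum * v
  } else {
    mu <- m$buffers$running_mean
    v <- m$buffers$running_var
  }
  invstd <- 1 / sqrt(v + m$eps)
  xhat <- (x - bcast_chan(mu, dm)) * bcast_chan(invstd, dm)
  y <- xhat * bcast_chan(m$params$gamma, dm) + bcast_chan(m$params$beta, dm)
  if (m$training) m$cache <- list(xhat = xhat, invstd = invstd, dm = dm)
  y
}

#' @export
nn_backward.nn_batchnorm2d <- function(m, gy) {
  cc <- m$cache
  dm <- cc$dm
  nper <- dm[1] * dm[3] * dm[4]
  gxhat <- gy * bcast_chan(m$params$gamma, dm)
  m$grads$gamma <- m$grads$gamma + chan_sum(gy * cc$xhat)
  m$grads$beta <- m$grads$beta + chan_sum(gy)
  mean_g <- chan_sum(gxhat) / nper
  mean_gx <- chan_sum(gxhat * cc$xhat) / nper
  (gxhat - bcast_chan(mean_g, dm) - cc$xhat * bcast_chan(mean_gx, dm)) *
    bcast_chan(cc$invstd, dm)
}

#' @export
nn_profile.nn_batchnorm2d <- function(m, in_shape, name = "bn") {
  list(shape = in_shape, rows = profile_row(name, "batchnorm", 2 * m$c, 0))
}

nn_silu <- function() new_module("nn_silu")

#' @export
nn_forward.nn_silu <- function(m, x) {
  s <- sigmoid(x)
  if (m$training) m$cache <- list(x = x, s = s)
  x * s
}

#' @export
nn_backward.nn_silu <- function(m, gy) {
  s <- m$cache$s
  gy * (s * (1 + m$cache$x * (1 - s)))
}

#' @export
nn_profile.nn_silu <- function(m, in_shape, name = "silu") {
  list(shape = in_shape, rows = profile_row(name, "silu", 0, 0))
}

nn_relu <- function() new_module("nn_relu")

#' @export
nn_forward.nn_relu <- function(m, x) {
  y <- pmax(x, 0)
  if (is.null(dim(y)) && !is.null(dim(x))) dim(y) <- dim(x)
  if (m$training) m$cache <- list(pos = x > 0)
  y
}

#' @export
nn_backward.nn_relu <- function(m, gy) gy * m$cache$pos

#' @export
nn_profile.nn_relu <- function(m, in_shape, name = "relu") {
  list(shape = in_shape, rows = profile_row(name, "relu", 0, 0))
}

nn_linear <- function(c_in, c_out, bias = TRUE) {
  m <- new_module("nn_linear", c_in = c_in, c_out = c_out, has_bias = bias)
  m$params$w <- init_weight(c_out, c_in)
  if (bias) m$params$b <- numeric(c_out)
  m
}

#' @export
nn_forward.nn_linear <- function(m, x) {
  y <- x %*% t(m$params$w)
  if (m$has_bias) y <- sweep(y, 2, m$params$b, "+")
  if (m$training) m$cache <- list(x = x)
  y
}

#' @export
nn_backward.nn_linear <- function(m, gy) {
  m$grads$w <- m$grads$w + t(gy) %*% m$cache$x
  if (m$has_bias) m$grads$b <- m$grads$b + colSums(gy)
  gy %*% m$params$w
}

#' @export
nn_profile.nn_linear <- function(m, in_shape, name = "linear") {
  params <- length(m$params$w) + if (m$has_bias) m$c_out else 0
  list(shape = c(m$c_out), rows = profile_row(name, "linear", params, m$c_in * m$c_out))
}

nn_dropout <- function(p = 0) new_module("nn_dropout", p = p)

#' @export
nn_forward.nn_dropout <- function(m, x) {
  if (!m$training || m$p <= 0) {
    m$cache <- list(mask = NULL)
    return(x)
  }
  mask <- array(stats::runif(length(x)) >= m$p, dim = dim(x) %||% length(x)) / (1 - m$p)
  m$cache <- list(mask = mask)
  x * mask
}

#' @export
nn_backward.nn_dropout <- function(m, gy) {
  if (is.null(m$cache$mask)) gy else gy * m$cache$mask
}

#' @export
nn_profile.nn_dropout <- function(m, in_shape, name = "dropout") {
  list(shape = in_shape, rows = profile_row(name, "dropout", 0, 0))
}

# global average pool (N, C, H, W) -> (N, C)
nn_gap <- function() new_module("nn_gap")

#' @export
nn_forward.nn_gap <- function(m, x) {
  dm <- tdim(x)
  if (m$training) m$cache <- list(dm = dm)
  nc_sum(x) / (dm[3] * dm[4])
}

#' @export
nn_backward.nn_gap <- function(m, gy) {
  dm <- m$cache$dm
  bcast_nc(gy, dm) / (dm[3] * dm[4])
}

#' @export
nn_profile.nn_gap <- function(m, in_shape, name = "gap") {
  list(shape = c(in_shape[1]), rows = profile_row(name, "global_avgpool", 0, 0))
}

nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "lcga_module"))
    mods <- mods[[1]]
  if (is.null(names(mods)) || any(names(mods) == ""))
    names(mods) <- sprintf("m%d", seq_along(mods))
  new_module("nn_sequential", .children = mods)
}

#' @export
nn_forward.nn_sequential <- function(m, x) {
  for (ch in m$children) x <- nn_forward(ch, x)
  x
}

#' @export
nn_backward.nn_sequential <- function(m, gy) {
  for (ch in rev(m$children)) gy <- nn_backward(ch, gy)
  gy
}

#' @export
nn_profile.nn_sequential <- function(m, in_shape, name = "seq") {
  rows <- list()
  for (nm in names(m$children)) {
    pr <- nn_profile(m$children[[nm]], in_shape, name = paste0(name, ".", nm))
    in_shape <- pr$shape
    rows[[nm]] <- pr$rows
  }
  list(shape = in_shape, rows = do.call(rbind, rows))
}

# ---- functional pooling with explicit caches (used inside composite blocks) --

pool_max <- function(x, k, stride, pad) {
  r <- .maxpool_fw(x, dim(x), k, stride, pad)
  attr(r$y, "pool_cache") <- list(idx = r$idx, xdim = dim(x), k = k,
                                  stride = stride, pad = pad)
  r$y
}

pool_max_bw <- function(gy, y) {
  cc <- attr(y, "pool_cache")
  .maxpool_bw(gy, cc$idx, cc$xdim)
}

pool_avg <- function(x, k, stride, pad) {
  y <- .avgpool_fw(x, dim(x), k, stride, pad)
  attr(y, "pool_cache") <- list(xdim = dim(x), k = k, stride = stride, pad = pad)
  y
}

pool_avg_bw <- function(gy, y) {
  cc <- attr(y, "pool_cache")
  .avgpool_bw(gy, cc$xdim, cc$k, cc$stride, cc$pad)
}
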