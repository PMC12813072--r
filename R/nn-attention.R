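# ---- attention mechanisms ----------------------------------------------------
#
# All five mechanisms gate the input multiplicatively with sigmoid weights, so
# every gate value lies in (0, 1) and output shape always equals input shape.
# Each module records the range of its gates from the most recent forward pass
# in $gate_range for diagnostics.

# spread an (N, 1, H, W) map over all channels of an (N, C, H, W) array
bcast_spatial <- function(g, dm) {
  gv <- array(g, c(dm[1], dm[3], dm[4]))
  aperm(array(rep(as.vector(gv), times = dm[2]),
              c(dm[1], dm[3], dm[4], dm[2])), c(1, 4, 2, 3))
}

# reduce an (N, C, H, W) gradient to the (N, 1, H, W) map it was spread from
reduce_spatial <- function(g) {
  dm <- tdim(g)
  array(rowSums(matrix(aperm(g, c(1, 3, 4, 2)), ncol = dm[2])),
        c(dm[1], 1, dm[3], dm[4]))
}

# global max pool with argmax bookkeeping: x (N,C,H,W) -> list(val (N,C), idx)
gmax_pool <- function(x) {
  dm <- tdim(x)
  mat <- matrix(x, nrow = dm[1] * dm[2])
  j <- max.col(mat, ties.method = "first")
  list(val = matrix(mat[cbind(seq_len(nrow(mat)), j)], dm[1], dm[2]),
       lin = seq_len(nrow(mat)) + (j - 1) * nrow(mat))  # linear index into x
}

# channel-wise max map: x (N,C,H,W) -> list(val (N,1,H,W), channel idx)
cmax_map <- function(x) {
  dm <- tdim(x)
  mat <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = dm[2])  # (N*H*W) x C
  j <- max.col(mat, ties.method = "first")
  val <- array(mat[cbind(seq_len(nrow(mat)), j)], c(dm[1], 1, dm[3], dm[4]))
  list(val = val, j = j)
}

#' Convolutional block attention (CBAM)
#'
#' Sequential channel and spatial attention. Channel attention passes the
#' global-average and global-max pooled descriptors through a shared two-layer
#' bias-free MLP (`c -> floor(c/r) -> c`, ReLU between), sums them and gates
#' the input with the sigmoid. Spatial attention convolves the concatenated
#' channel-mean and channel-max maps with a 7x7 bias-free kernel and gates
#' with the sigmoid. Parameter count: `2 c floor(c/r) + 2 k^2`.
#'
#' @param c attended channel count.
#' @param r reduction ratio of the shared MLP (hidden width `floor(c/r)`,
#'   clamped to at least 1).
#' @param k_spatial spatial attention kernel size.
#' @return a module.
#' @export
cbam <- function(c, r = 16, k_spatial = 7) {
  if (c < 1) stop("c must be >= 1")
  h <- max(1L, c %/% r)
  m <- new_module("lcga_cbam", c = c, h = h,
                  children = list(conv = nn_conv2d(2, 1, k_spatial)))
  m$params$w1 <- init_weight(h, c)
  m$params$w2 <- init_weight(c, h)
  m
}

#' @export
nn_forward.lcga_cbam <- function(m, x) {
  dm <- tdim(x)
  s_avg <- nc_sum(x) / (dm[3] * dm[4])
  mx <- gmax_pool(x)
  mlp <- function(s) {
    h1 <- pmax(s %*% t(m$params$w1), 0)
    list(h = h1, a = h1 %*% t(m$params$w2))
  }
  pa <- mlp(s_avg); pm <- mlp(mx$val)
  g1 <- sigmoid(pa$a + pm$a)
  x1 <- x * bcast_nc(g1, dm)
  mm <- array(rowSums(matrix(aperm(x1, c(1, 3, 4, 2)), ncol = dm[2])) / dm[2],
              c(dm[1], 1, dm[3], dm[4]))
  cm <- cmax_map(x1)
  z <- nn_forward(m$children$conv, cat_channels(list(mm, cm$val)))
  g2 <- sigmoid(z)
  y <- x1 * bcast_spatial(g2, dm)
  m$gate_range <- range(c(g1, g2))
  if (m$training)
    m$cache <- list(x = x, dm = dm, s_avg = s_avg, mx = mx, pa = pa, pm = pm,
                    g1 = g1, x1 = x1, cm = cm, g2 = g2)
  y
}

#' @export
nn_backward.lcga_cbam <- function(m, gy) {
  cc <- m$cache; dm <- cc$dm
  # spatial gate
  gx1 <- gy * bcast_spatial(cc$g2, dm)
  gg2 <- reduce_spatial(gy * cc$x1)
  gz <- gg2 * cc$g2 * (1 - cc$g2)
  gsmap <- nn_backward(m$children$conv, gz)
  gmm <- gsmap[, 1, , , drop = FALSE]
  gmx <- gsmap[, 2, , , drop = FALSE]
  gx1 <- gx1 + bcast_spatial(gmm, dm) / dm[2]
  # scatter channel-max gradient
  gmaxv <- as.vector(array(gmx, c(dm[1], dm[3], dm[4])))
  sc <- array(0, dim = dm)
  scm <- matrix(aperm(sc, c(1, 3, 4, 2)), ncol = dm[2])
  scm[cbind(seq_along(cc$cm$j), cc$cm$j)] <- gmaxv
  gx1 <- gx1 + aperm(array(scm, c(dm[1], dm[3], dm[4], dm[2])), c(1, 4, 2, 3))
  # channel gate
  gx <- gx1 * bcast_nc(cc$g1, dm)
  gg1 <- nc_sum(gx1 * cc$x)
  ga <- gg1 * cc$g1 * (1 - cc$g1)
  mlp_bw <- function(p, s, ga) {
    m$grads$w2 <<- m$grads$w2 + t(ga) %*% p$h
    gh <- (ga %*% m$params$w2) * (p$h > 0)
    m$grads$w1 <<- m$grads$w1 + t(gh) %*% s
    gh %*% m$params$w1
  }
  gs_avg <- mlp_bw(cc$pa, cc$s_avg, ga)
  gs_max <- mlp_bw(cc$pm, cc$mx$val, ga)
  gx <- gx + bcast_nc(gs_avg, dm) / (dm[3] * dm[4])
  sc2 <- numeric(prod(dm))
  sc2[cc$mx$lin] <- as.vector(gs_max)
  gx + array(sc2, dm)
}

#' @export
nn_profile.lcga_cbam <- function(m, in_shape, name = "cbam") {
  pc <- nn_profile(m$children$conv, c(2, in_shape[2], in_shape[3]),
                   paste0(name, ".spatial"))
  rows <- rbind(profile_row(paste0(name, ".mlp"), "attention_mlp",
                            2 * m$c * m$h, 2 * 2 * m$c * m$h),
                pc$rows)
  list(shape = in_shape, rows = rows)
}

#' Squeeze-and-excitation channel attention (SE)
#'
#' Global-average pooled descriptor through a bias-free `c -> floor(c/r) -> c`
#' MLP with ReLU, sigmoid channel gate. Parameter count: `2 c floor(c/r)`.
#'
#' @inheritParams cbam
#' @return a module.
#' @export
se_block <- function(c, r = 16) {
  if (c < 1) stop("c must be >= 1")
  h <- max(1L, c %/% r)
  m <- new_module("lcga_se", c = c, h = h)
  m$params$w1 <- init_weight(h, c)
  m$params$w2 <- init_weight(c, h)
  m
}

#' @export
nn_forward.lcga_se <- function(m, x) {
  dm <- tdim(x)
  s <- nc_sum(x) / (dm[3] * dm[4])
  h1 <- pmax(s %*% t(m$params$w1), 0)
  g <- sigmoid(h1 %*% t(m$params$w2))
  m$gate_range <- range(g)
  if (m$training) m$cache <- list(x = x, dm = dm, s = s, h1 = h1, g = g)
  x * bcast_nc(g, dm)
}

#' @export
nn_backward.lcga_se <- function(m, gy) {
  cc <- m$cache; dm <- cc$dm
  gx <- gy * bcast_nc(cc$g, dm)
  gg <- nc_sum(gy * cc$x)
  ga <- gg * cc$g * (1 - cc$g)
  m$grads$w2 <- m$grads$w2 + t(ga) %*% cc$h1
  gh <- (ga %*% m$params$w2) * (cc$h1 > 0)
  m$grads$w1 <- m$grads$w1 + t(gh) %*% cc$s
  gs <- gh %*% m$params$w1
  gx + bcast_nc(gs, dm) / (dm[3] * dm[4])
}

#' @export
nn_profile.lcga_se <- function(m, in_shape, name = "se") {
  list(shape = in_shape,
       rows = profile_row(name, "attention_mlp", 2 * m$c * m$h, 2 * m$c * m$h))
}

#' Adaptive 1-D kernel size of efficient channel attention
#'
#' `t = floor((log2(c) + 1) / 2)`; the kernel is `t` if odd, else `t + 1`.
#'
#' @param c channel count (>= 2).
#' @return odd kernel size.
#' @export
eca_kernel <- function(c) {
  t <- floor((log2(c) + 1) / 2)
  as.integer(if (t %% 2 == 1) t else t + 1)
}

#' Efficient channel attention (ECA)
#'
#' A 1-D convolution with an adaptive odd kernel over the global-average
#' pooled channel descriptor, sigmoid channel gate. Parameter count equals
#' the kernel size.
#'
#' @param c channel count (>= 2).
#' @return a module.
#' @export
eca <- function(c) {
  if (c < 2) stop("c must be >= 2")
  k <- eca_kernel(c)
  m <- new_module("lcga_eca", c = c, k = k)
  m$params$w <- stats::rnorm(k, sd = sqrt(2 / k))
  m
}

# shift columns of an (N, C) matrix by d with zero fill
shift_cols <- function(s, d) {
  C <- ncol(s)
  out <- matrix(0, nrow(s), C)
  src <- seq_len(C) + d
  ok <- src >= 1 & src <= C
  out[, ok] <- s[, src[ok]]
  out
}

#' @export
nn_forward.lcga_eca <- function(m, x) {
  dm <- tdim(x)
  s <- nc_sum(x) / (dm[3] * dm[4])
  off <- (m$k - 1) %/% 2
  a <- matrix(0, dm[1], dm[2])
  for (j in seq_len(m$k)) a <- a + m$params$w[j] * shift_cols(s, j - 1 - off)
  g <- sigmoid(a)
  m$gate_range <- range(g)
  if (m$training) m$cache <- list(x = x, dm = dm, s = s, g = g)
  x * bcast_nc(g, dm)
}

#' @export
nn_backward.lcga_eca <- function(m, gy) {
  cc <- m$cache; dm <- cc$dm
  off <- (m$k - 1) %/% 2
  gx <- gy * bcast_nc(cc$g, dm)
  gg <- nc_sum(gy * cc$x)
  ga <- gg * cc$g * (1 - cc$g)
  gs <- matrix(0, dm[1], dm[2])
  for (j in seq_len(m$k)) {
    m$grads$w[j] <- m$grads$w[j] + sum(ga * shift_cols(cc$s, j - 1 - off))
    gs <- gs + m$params$w[j] * shift_cols(ga, -(j - 1 - off))
  }
  gx + bcast_nc(gs, dm) / (dm[3] * dm[4])
}

#' @export
nn_profile.lcga_eca <- function(m, in_shape, name = "eca") {
  list(shape = in_shape, rows = profile_row(name, "attention_1dconv", m$k, m$k * m$c))
}

#' Parameter-free energy-based spatial attention (SimAM-style)
#'
#' Gates each activation by the sigmoid of its normalised energy
#' `(x - mu)^2 / (4 (v + lambda)) + 0.5`, where `mu` and `v` are the
#' per-channel spatial mean and variance. No trainable parameters.
#'
#' @param c channel count (shape bookkeeping only).
#' @param lambda variance regulariser.
#' @return a module.
#' @export
siam <- function(c, lambda = 1e-4) {
  new_module("lcga_siam", c = c, lambda = lambda)
}

#' @export
nn_forward.lcga_siam <- function(m, x) {
  dm <- tdim(x)
  M <- dm[3] * dm[4]
  mu <- nc_sum(x) / M
  u <- x - bcast_nc(mu, dm)
  d <- u^2
  v <- nc_sum(d) / max(M - 1, 1)
  tt <- d / bcast_nc(4 * (v + m$lambda), dm) + 0.5
  g <- sigmoid(tt)
  m$gate_range <- range(g)
  if (m$training) m$cache <- list(x = x, dm = dm, u = u, d = d, v = v, g = g, M = M)
  x * g
}

#' @export
nn_backward.lcga_siam <- function(m, gy) {
  cc <- m$cache; dm <- cc$dm
  denom <- 4 * (cc$v + m$lambda)
  gx <- gy * cc$g
  gt <- gy * cc$x * cc$g * (1 - cc$g)
  gd <- gt / bcast_nc(denom, dm)
  gv <- -4 * nc_sum(gt * cc$d) / denom^2
  gd <- gd + bcast_nc(gv / max(cc$M - 1, 1), dm)
  gu <- 2 * cc$u * gd
  gx + gu - bcast_nc(nc_sum(gu) / cc$M, dm)
}

#' @export
nn_profile.lcga_siam <- function(m, in_shape, name = "siam") {
  list(shape = in_shape, rows = profile_row(name, "attention_free", 0, 0))
}

#' Global attention mechanism (GAM)
#'
#' Channel sub-module: a per-position two-layer MLP across channels
#' (`c -> c/r -> c`, biased, ReLU between), sigmoid gate. Spatial sub-module:
#' 7x7 convolution `c -> c/r` (biased) + batch norm + ReLU, 7x7 convolution
#' `c/r -> c` (biased) + batch norm, sigmoid gate.
#'
#' @param c channel count (>= r).
#' @param r reduction ratio (hidden width `floor(c/r)`).
#' @return a module.
#' @export
gam <- function(c, r = 4) {
  if (c < r) stop("c must be >= r")
  cr <- max(1L, c %/% r)
  new_module("lcga_gam", c = c, cr = cr,
             children = list(
               fc1 = nn_linear(c, cr, bias = TRUE),
               relu1 = nn_relu(),
               fc2 = nn_linear(cr, c, bias = TRUE),
               conv1 = nn_conv2d(c, cr, 7, bias = TRUE),
               bn1 = nn_batchnorm2d(cr),
               relu2 = nn_relu(),
               conv2 = nn_conv2d(cr, c, 7, bias = TRUE),
               bn2 = nn_batchnorm2d(c)))
}

#' @export
nn_forward.lcga_gam <- function(m, x) {
  dm <- tdim(x)
  mat <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = dm[2])
  a <- nn_forward(m$children$fc2,
                  nn_forward(m$children$relu1, nn_forward(m$children$fc1, mat)))
  g1 <- sigmoid(aperm(array(a, c(dm[1], dm[3], dm[4], dm[2])), c(1, 4, 2, 3)))
  y1 <- x * g1
  z <- nn_forward(m$children$relu2,
                  nn_forward(m$children$bn1, nn_forward(m$children$conv1, y1)))
  z2 <- nn_forward(m$children$bn2, nn_forward(m$children$conv2, z))
  g2 <- sigmoid(z2)
  m$gate_range <- range(c(g1, g2))
  if (m$training) m$cache <- list(x = x, dm = dm, g1 = g1, y1 = y1, g2 = g2)
  y1 * g2
}

#' @export
nn_backward.lcga_gam <- function(m, gy) {
  cc <- m$cache; dm <- cc$dm
  gy1 <- gy * cc$g2
  gz2 <- gy * cc$y1 * cc$g2 * (1 - cc$g2)
  gz <- nn_backward(m$children$conv2, nn_backward(m$children$bn2, gz2))
  gy1 <- gy1 + nn_backward(m$children$conv1,
                           nn_backward(m$children$bn1,
                                       nn_backward(m$children$relu2, gz)))
  gx <- gy1 * cc$g1
  ga_arr <- gy1 * cc$x * cc$g1 * (1 - cc$g1)
  amat <- matrix(aperm(ga_arr, c(1, 3, 4, 2)), ncol = dm[2])
  gmat <- nn_backward(m$children$fc1,
                      nn_backward(m$children$relu1,
                                  nn_backward(m$children$fc2, amat)))
  gx + aperm(array(gmat, c(dm[1], dm[3], dm[4], dm[2])), c(1, 4, 2, 3))
}

#' @export
nn_profile.lcga_gam <- function(m, in_shape, name = "gam") {
  hw <- in_shape[2] * in_shape[3]
  mlp_p <- (m$c * m$cr + m$cr) + (m$cr * m$c + m$c)
  rows <- profile_row(paste0(name, ".mlp"), "attention_mlp", mlp_p,
                      (m$c * m$cr + m$cr * m$c) * hw)
  p1 <- nn_profile(m$children$conv1, in_shape, paste0(name, ".conv1"))
  b1 <- nn_profile(m$children$bn1, p1$shape, paste0(name, ".bn1"))
  p2 <- nn_profile(m$children$conv2, p1$shape, paste0(name, ".conv2"))
  b2 <- nn_profile(m$children$bn2, p2$shape, paste0(name, ".bn2"))
  list(shape = in_shape, rows = rbind(rows, p1$rows, b1$rows, p2$rows, b2$rows))
}

#' Construct an attention module by kind
#'
#' @param kind one of `"none"`, `"cbam"`, `"se"`, `"eca"`, `"siam"`, `"gam"`.
#' @param c attended channel count.
#' @param r reduction ratio override (defaults: CBAM/SE 16, GAM 4).
#' @return a module, or `NULL` for kind `"none"`.
#' @export
attention_block <- function(kind = c("none", "cbam", "se", "eca", "siam", "gam"),
                            c, r = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         none = NULL,
         cbam = cbam(c, r %||% 16),
         se = se_block(c, r %||% 16),
         eca = eca(c),
         siam = siam(c),
         gam = gam(c, r %||% 4))
}

#' Closed-form attention parameter counts
#'
#' @inheritParams attention_block
#' @return the parameter count of one attention instance at width `c`.
#' @export
attention_param_formula <- function(kind, c, r = NULL) {
  switch(kind,
         none = 0,
         cbam = 2 * c * max(1, c %/% (r %||% 16)) + 7^2 * 2,
         se = 2 * c * max(1, c %/% (r %||% 16)),
         eca = as.numeric(eca_kernel(c)),
         siam = 0,
         gam = {
           cr <- max(1, c %/% (r %||% 4))
           (c * cr + cr) + (cr * c + c) +
             (49 * c * cr + cr + 2 * cr) + (49 * cr * c + c + 2 * c)
         },
         stop("unknown attention kind: ", kind))
}

#' Attention-augmented asymmetric downsampler
#'
#' An [adown()] downsampler with one attention block applied to each branch
#' output (at `c_out / 2` channels) before concatenation. With
#' `kind = "none"` this is exactly the plain downsampler.
#'
#' @param c_in,c_out even channel counts.
#' @inheritParams attention_block
#' @return a module.
#' @export
attention_adown <- function(c_in, c_out, kind = "none", r = NULL) {
  a1 <- attention_block(kind, c_out %/% 2, r)
  a2 <- attention_block(kind, c_out %/% 2, r)
  if (is.null(a1)) adown(c_in, c_out) else adown(c_in, c_out, list(a1, a2))
}
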