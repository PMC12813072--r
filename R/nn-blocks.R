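# ---- building blocks ---------------------------------------------------------
#
# Every convolution in these blocks is bias-free and followed by batch
# normalisation; every activation is SiLU. This is the convention under which
# the block parameter counts below close against their printed totals.

#' Convolution + batch norm + SiLU block
#'
#' The basic stem/downsampling unit: a bias-free `k x k` convolution with
#' stride `s` and same-padding `k %/% 2`, batch normalisation and SiLU.
#' Parameter count: `k^2 * c_in * c_out + 2 * c_out`.
#'
#' @param c_in,c_out input and output channel counts (>= 1).
#' @param k kernel size.
#' @param s stride.
#' @param groups convolution groups (used internally for depthwise variants).
#' @param act apply the SiLU activation (`TRUE` for all standard blocks).
#' @return a module; use [nn_forward()] to apply it and [param_count()] to
#'   count its trainable parameters.
#' @export
conv_bn_act <- function(c_in, c_out, k, s = 1, groups = 1, act = TRUE) {
  if (c_in < 1 || c_out < 1) stop("channel counts must be positive")
  ch <- list(conv = nn_conv2d(c_in, c_out, k, stride = s, groups = groups),
             bn = nn_batchnorm2d(c_out))
  if (act) ch$act <- nn_silu()
  m <- nn_sequential(ch)
  class(m) <- c("lcga_cba", class(m))
  m
}

#' Cross-stage feature-fusion block (C2f)
#'
#' The standard cross-stage block of the baseline backbone: a 1x1 projection
#' to `c_out` channels, a channel split into two halves, `n` shortcut
#' bottlenecks (two 3x3 convolutions at half width plus identity) applied to
#' the second half, and a 1x1 fusion convolution over the concatenation of all
#' `(2 + n)` half-width parts.
#'
#' @param c_in,c_out channel counts; `c_out` must be even.
#' @param n number of bottlenecks (>= 1).
#' @return a module.
#' @export
c2f <- function(c_in, c_out, n = 1) {
  if (c_out %% 2 != 0) stop("c_out must be even")
  if (n < 1) stop("repeat count n must be >= 1")
  h <- c_out %/% 2
  bots <- lapply(seq_len(n), function(i) {
    new_module("lcga_bottleneck",
               children = list(cv1 = conv_bn_act(h, h, 3),
                               cv2 = conv_bn_act(h, h, 3)))
  })
  new_module("lcga_c2f", h = h, n = n,
             children = list(cv1 = conv_bn_act(c_in, c_out, 1),
                             bots = bots,
                             cv2 = conv_bn_act((2 + n) * h, c_out, 1)))
}

#' @export
nn_forward.lcga_bottleneck <- function(m, x) {
  y <- nn_forward(m$children$cv2, nn_forward(m$children$cv1, x)) + x
  y
}

#' @export
nn_backward.lcga_bottleneck <- function(m, gy) {
  nn_backward(m$children$cv1, nn_backward(m$children$cv2, gy)) + gy
}

#' @export
nn_profile.lcga_bottleneck <- function(m, in_shape, name = "bottleneck") {
  p1 <- nn_profile(m$children$cv1, in_shape, paste0(name, ".cv1"))
  p2 <- nn_profile(m$children$cv2, p1$shape, paste0(name, ".cv2"))
  list(shape = in_shape, rows = rbind(p1$rows, p2$rows))
}

#' @export
nn_forward.lcga_c2f <- function(m, x) {
  h <- m$h
  y <- nn_forward(m$children$cv1, x)
  parts <- split_channels(y, c(h, h))
  cur <- parts[[2]]
  for (b in m$children$bots) {
    cur <- nn_forward(b, cur)
    parts <- c(parts, list(cur))
  }
  nn_forward(m$children$cv2, cat_channels(parts))
}

#' @export
nn_backward.lcga_c2f <- function(m, gy) {
  h <- m$h
  g <- nn_backward(m$children$cv2, gy)
  chunks <- split_channels(g, rep(h, 2 + m$n))
  gcur <- chunks[[2 + m$n]]
  for (j in rev(seq_len(m$n))) {
    gcur <- nn_backward(m$children$bots[[j]], gcur) + chunks[[j + 1]]
  }
  nn_backward(m$children$cv1, cat_channels(list(chunks[[1]], gcur)))
}

#' @export
nn_profile.lcga_c2f <- function(m, in_shape, name = "c2f") {
  p1 <- nn_profile(m$children$cv1, in_shape, paste0(name, ".cv1"))
  rows <- list(p1$rows)
  hshape <- c(m$h, p1$shape[2], p1$shape[3])
  for (i in seq_len(m$n))
    rows[[i + 1]] <- nn_profile(m$children$bots[[i]], hshape,
                                sprintf("%s.b%d", name, i))$rows
  p2 <- nn_profile(m$children$cv2, c((2 + m$n) * m$h, p1$shape[2], p1$shape[3]),
                   paste0(name, ".cv2"))
  list(shape = p2$shape, rows = do.call(rbind, c(rows, list(p2$rows))))
}

#' Asymmetric dual-branch downsampler (ADown)
#'
#' Halves the spatial resolution with two complementary half-width branches:
#' the input is smoothed by a 2x2 stride-1 average pool and split into channel
#' halves; the first half goes through a 3x3 stride-2 convolution, the second
#' through a 3x3 stride-2 max pool followed by a 1x1 convolution. The branch
#' outputs (convolution branch first, pooling branch second) are concatenated.
#'
#' @param c_in,c_out channel counts, both even (each branch carries half).
#' @param attention optional pair of attention modules applied to the branch
#'   outputs before concatenation (used by [attention_adown()]).
#' @return a module.
#' @export
adown <- function(c_in, c_out, attention = NULL) {
  if (c_in %% 2 != 0 || c_out %% 2 != 0) stop("c_in and c_out must be even")
  ch <- list(cv1 = conv_bn_act(c_in %/% 2, c_out %/% 2, 3, s = 2),
             cv2 = conv_bn_act(c_in %/% 2, c_out %/% 2, 1))
  if (!is.null(attention)) {
    ch$att1 <- attention[[1]]
    ch$att2 <- attention[[2]]
  }
  new_module("lcga_adown", c_in = c_in, c_out = c_out,
             has_att = !is.null(attention), children = ch)
}

#' @export
nn_forward.lcga_adown <- function(m, x) {
  xp <- pool_avg(x, 2, 1, 0)
  halves <- split_channels(xp, rep(m$c_in %/% 2, 2))
  b1 <- nn_forward(m$children$cv1, halves[[1]])
  p2 <- pool_max(halves[[2]], 3, 2, 1)
  b2 <- nn_forward(m$children$cv2, p2)
  if (m$has_att) {
    b1 <- nn_forward(m$children$att1, b1)
    b2 <- nn_forward(m$children$att2, b2)
  }
  if (m$training) m$cache <- list(xp = xp, p2 = p2)
  cat_channels(list(b1, b2))
}

#' @export
nn_backward.lcga_adown <- function(m, gy) {
  half <- m$c_out %/% 2
  gs <- split_channels(gy, c(half, half))
  g1 <- gs[[1]]; g2 <- gs[[2]]
  if (m$has_att) {
    g1 <- nn_backward(m$children$att1, g1)
    g2 <- nn_backward(m$children$att2, g2)
  }
  g1 <- nn_backward(m$children$cv1, g1)
  g2 <- pool_max_bw(nn_backward(m$children$cv2, g2), m$cache$p2)
  pool_avg_bw(cat_channels(list(g1, g2)), m$cache$xp)
}

#' @export
nn_profile.lcga_adown <- function(m, in_shape, name = "adown") {
  hp <- in_shape[2] - 1; wp <- in_shape[3] - 1           # after 2x2 s1 avg pool
  half_in <- c(m$c_in %/% 2, hp, wp)
  p1 <- nn_profile(m$children$cv1, half_in, paste0(name, ".cv1"))
  pool_shape <- c(m$c_in %/% 2, conv_out_hw(hp, 3, 2, 1), conv_out_hw(wp, 3, 2, 1))
  p2 <- nn_profile(m$children$cv2, pool_shape, paste0(name, ".cv2"))
  rows <- rbind(p1$rows, p2$rows)
  out <- c(m$c_out, p1$shape[2], p1$shape[3])
  if (m$has_att) {
    half_out <- c(m$c_out %/% 2, out[2], out[3])
    rows <- rbind(rows,
                  nn_profile(m$children$att1, half_out, paste0(name, ".att1"))$rows,
                  nn_profile(m$children$att2, half_out, paste0(name, ".att2"))$rows)
  }
  list(shape = out, rows = rows)
}

#' Ghost convolution
#'
#' Generates `c_out / 2` channels with a standard `k x k` convolution and the
#' remaining half with a cheap 5x5 depthwise convolution applied to the
#' primary output, then concatenates both halves.
#'
#' @param c_in input channels.
#' @param c_out output channels (even).
#' @param k primary kernel size.
#' @param act apply SiLU after both halves (disabled for the second ghost
#'   convolution inside a ghost bottleneck).
#' @return a module.
#' @export
ghost_conv <- function(c_in, c_out, k = 1, act = TRUE) {
  if (c_out %% 2 != 0) stop("c_out must be even")
  h <- c_out %/% 2
  new_module("lcga_ghost", c_in = c_in, c_out = c_out,
             children = list(primary = conv_bn_act(c_in, h, k, act = act),
                             cheap = conv_bn_act(h, h, 5, groups = h, act = act)))
}

#' @export
nn_forward.lcga_ghost <- function(m, x) {
  y1 <- nn_forward(m$children$primary, x)
  y2 <- nn_forward(m$children$cheap, y1)
  cat_channels(list(y1, y2))
}

#' @export
nn_backward.lcga_ghost <- function(m, gy) {
  h <- m$c_out %/% 2
  gs <- split_channels(gy, c(h, h))
  g1 <- gs[[1]] + nn_backward(m$children$cheap, gs[[2]])
  nn_backward(m$children$primary, g1)
}

#' @export
nn_profile.lcga_ghost <- function(m, in_shape, name = "ghost") {
  p1 <- nn_profile(m$children$primary, in_shape, paste0(name, ".primary"))
  p2 <- nn_profile(m$children$cheap, p1$shape, paste0(name, ".cheap"))
  list(shape = c(m$c_out, p1$shape[2], p1$shape[3]), rows = rbind(p1$rows, p2$rows))
}

#' Cross-stage ghost block (C3Ghost)
#'
#' Cross-stage-partial block whose processed path is built from ghost
#' bottlenecks: two 1x1 half-width projections (main and bypass), `n` ghost
#' bottlenecks (ghost convolution down to quarter width, ghost convolution
#' back up without activation, identity shortcut) on the main path, and a 1x1
#' fusion convolution over the concatenated paths.
#'
#' @inheritParams c2f
#' @return a module.
#' @export
c3ghost <- function(c_in, c_out, n = 1) {
  if (c_out %% 2 != 0) stop("c_out must be even")
  if (n < 1) stop("repeat count n must be >= 1")
  h <- c_out %/% 2
  bots <- lapply(seq_len(n), function(i) {
    new_module("lcga_ghost_bottleneck",
               children = list(g1 = ghost_conv(h, h %/% 2, 1),
                               g2 = ghost_conv(h %/% 2, h, 1, act = FALSE)))
  })
  new_module("lcga_c3ghost", h = h, n = n,
             children = list(cv1 = conv_bn_act(c_in, h, 1),
                             cv2 = conv_bn_act(c_in, h, 1),
                             bots = bots,
                             cv3 = conv_bn_act(2 * h, c_out, 1)))
}

#' @export
nn_forward.lcga_ghost_bottleneck <- function(m, x) {
  nn_forward(m$children$g2, nn_forward(m$children$g1, x)) + x
}

#' @export
nn_backward.lcga_ghost_bottleneck <- function(m, gy) {
  nn_backward(m$children$g1, nn_backward(m$children$g2, gy)) + gy
}

#' @export
nn_profile.lcga_ghost_bottleneck <- function(m, in_shape, name = "gbot") {
  p1 <- nn_profile(m$children$g1, in_shape, paste0(name, ".g1"))
  p2 <- nn_profile(m$children$g2, p1$shape, paste0(name, ".g2"))
  list(shape = in_shape, rows = rbind(p1$rows, p2$rows))
}

#' @export
nn_forward.lcga_c3ghost <- function(m, x) {
  main <- nn_forward(m$children$cv1, x)
  for (b in m$children$bots) main <- nn_forward(b, main)
  side <- nn_forward(m$children$cv2, x)
  nn_forward(m$children$cv3, cat_channels(list(main, side)))
}

#' @export
nn_backward.lcga_c3ghost <- function(m, gy) {
  g <- nn_backward(m$children$cv3, gy)
  gs <- split_channels(g, rep(m$h, 2))
  gmain <- gs[[1]]
  for (b in rev(m$children$bots)) gmain <- nn_backward(b, gmain)
  nn_backward(m$children$cv1, gmain) + nn_backward(m$children$cv2, gs[[2]])
}

#' @export
nn_profile.lcga_c3ghost <- function(m, in_shape, name = "c3ghost") {
  p1 <- nn_profile(m$children$cv1, in_shape, paste0(name, ".cv1"))
  p2 <- nn_profile(m$children$cv2, in_shape, paste0(name, ".cv2"))
  rows <- list(p1$rows, p2$rows)
  for (i in seq_len(m$n))
    rows[[length(rows) + 1]] <-
      nn_profile(m$children$bots[[i]], p1$shape, sprintf("%s.b%d", name, i))$rows
  p3 <- nn_profile(m$children$cv3, c(2 * m$h, p1$shape[2], p1$shape[3]),
                   paste0(name, ".cv3"))
  list(shape = p3$shape, rows = do.call(rbind, c(rows, list(p3$rows))))
}

#' Fast spatial pyramid pooling (SPPF)
#'
#' A 1x1 convolution to half width, three cascaded `k x k` stride-1 max pools,
#' concatenation of the four tensors, and a 1x1 convolution back to `c`.
#'
#' @param c channel count (even).
#' @param k pooling kernel (odd; stride-1 same-size pooling).
#' @return a module.
#' @export
sppf <- function(c, k = 5) {
  if (c %% 2 != 0) stop("c must be even")
  if (k %% 2 == 0) stop("pooling kernel must be odd for same-size pooling")
  h <- c %/% 2
  new_module("lcga_sppf", c = c, k = k,
             children = list(cv1 = conv_bn_act(c, h, 1),
                             cv2 = conv_bn_act(4 * h, c, 1)))
}

#' @export
nn_forward.lcga_sppf <- function(m, x) {
  k <- m$k; p <- k %/% 2
  y0 <- nn_forward(m$children$cv1, x)
  p1 <- pool_max(y0, k, 1, p)
  p2 <- pool_max(p1, k, 1, p)
  p3 <- pool_max(p2, k, 1, p)
  if (m$training) m$cache <- list(p1 = p1, p2 = p2, p3 = p3)
  nn_forward(m$children$cv2, cat_channels(list(y0, p1, p2, p3)))
}

#' @export
nn_backward.lcga_sppf <- function(m, gy) {
  h <- m$c %/% 2
  g <- nn_backward(m$children$cv2, gy)
  gs <- split_channels(g, rep(h, 4))
  g3 <- pool_max_bw(gs[[4]], m$cache$p3)
  g2 <- pool_max_bw(gs[[3]] + g3, m$cache$p2)
  g1 <- pool_max_bw(gs[[2]] + g2, m$cache$p1)
  nn_backward(m$children$cv1, gs[[1]] + g1)
}

#' @export
nn_profile.lcga_sppf <- function(m, in_shape, name = "sppf") {
  p1 <- nn_profile(m$children$cv1, in_shape, paste0(name, ".cv1"))
  p2 <- nn_profile(m$children$cv2, c(4 * (m$c %/% 2), p1$shape[2], p1$shape[3]),
                   paste0(name, ".cv2"))
  list(shape = p2$shape, rows = rbind(p1$rows, p2$rows))
}

#' Four-branch adaptive-fusion pooling block (AFC-SPPF)
#'
#' Four parameter-free branches at the input resolution — identity, the final
#' output of three cascaded `k_main x k_main` stride-1 max pools, a 3x3
#' stride-1 max pool and a 5x5 stride-1 max pool — are concatenated to `4c`
#' channels and fused by a 1x1 bias-free compression convolution + batch norm
#' and a 3x3 depthwise convolution + batch norm (SiLU after each). An adaptive
#' max-pool guard forces any branch whose spatial size drifted from the input
#' back to `H x W` (a no-op for odd kernels with same-padding).
#' Parameter count: `4 c^2 + 13 c`.
#'
#' @param c channel count (>= 1).
#' @param k_main main-branch pooling kernel, one of 3, 5, 7, 9.
#' @return a module.
#' @export
afc_sppf <- function(c, k_main = 5) {
  if (c < 1) stop("c must be >= 1")
  if (!k_main %in% c(3, 5, 7, 9)) stop("k_main must be one of 3, 5, 7, 9")
  new_module("lcga_afc_sppf", c = c, k_main = k_main,
             children = list(
               compress = conv_bn_act(4 * c, c, 1),
               dw = conv_bn_act(c, c, 3, groups = c)))
}

# adaptive max pool to a fixed output size (guard; windows cover the input)
adaptive_pool_to <- function(x, ho, wo) {
  dm <- tdim(x)
  if (dm[3] == ho && dm[4] == wo) return(x)
  hs <- floor(seq(0, dm[3], length.out = ho + 1))
  ws <- floor(seq(0, dm[4], length.out = wo + 1))
  y <- array(0, dim = c(dm[1], dm[2], ho, wo))
  for (i in seq_len(ho))
    for (j in seq_len(wo)) {
      block <- x[, , (hs[i] + 1):max(hs[i + 1], hs[i] + 1),
                 (ws[j] + 1):max(ws[j + 1], ws[j] + 1), drop = FALSE]
      y[, , i, j] <- apply(block, c(1, 2), max)
    }
  y
}

#' @export
nn_forward.lcga_afc_sppf <- function(m, x) {
  k <- m$k_main; p <- k %/% 2
  dm <- tdim(x)
  b2a <- pool_max(x, k, 1, p)
  b2b <- pool_max(b2a, k, 1, p)
  b2 <- pool_max(b2b, k, 1, p)
  b3 <- pool_max(x, 3, 1, 1)
  b4 <- pool_max(x, 5, 1, 2)
  guard <- function(b) adaptive_pool_to(b, dm[3], dm[4])
  y <- cat_channels(list(x, guard(b2), guard(b3), guard(b4)))
  if (m$training) m$cache <- list(b2a = b2a, b2b = b2b, b2 = b2, b3 = b3, b4 = b4)
  nn_forward(m$children$dw, nn_forward(m$children$compress, y))
}

#' @export
nn_backward.lcga_afc_sppf <- function(m, gy) {
  g <- nn_backward(m$children$compress, nn_backward(m$children$dw, gy))
  gs <- split_channels(g, rep(m$c, 4))
  cc <- m$cache
  g2 <- pool_max_bw(pool_max_bw(pool_max_bw(gs[[2]], cc$b2), cc$b2b), cc$b2a)
  gs[[1]] + g2 + pool_max_bw(gs[[3]], cc$b3) + pool_max_bw(gs[[4]], cc$b4)
}

#' @export
nn_profile.lcga_afc_sppf <- function(m, in_shape, name = "afc_sppf") {
  p1 <- nn_profile(m$children$compress, c(4 * m$c, in_shape[2], in_shape[3]),
                   paste0(name, ".compress"))
  p2 <- nn_profile(m$children$dw, p1$shape, paste0(name, ".dw"))
  list(shape = p2$shape, rows = rbind(p1$rows, p2$rows))
}

#' Closed-form parameter counts for the building blocks
#'
#' Arithmetic formulas for the trainable-parameter count of each block kind,
#' independent of block construction; [param_count()] on the built block must
#' agree with these.
#'
#' @param kind one of `"conv_bn_act"`, `"c2f"`, `"adown"`, `"ghost_conv"`,
#'   `"c3ghost"`, `"sppf"`, `"afc_sppf"`.
#' @param c_in,c_out channel counts (`c_out` ignored where a single width `c`
#'   is used; pass the width as `c_in`).
#' @param k kernel size where applicable.
#' @param n repeat count for the cross-stage blocks.
#' @return the parameter count as a number.
#' @export
param_formula <- function(kind, c_in, c_out = c_in, k = 1, n = 1) {
  cba_p <- function(ci, co, kk) kk^2 * ci * co + 2 * co
  switch(kind,
    conv_bn_act = cba_p(c_in, c_out, k),
    c2f = {
      h <- c_out / 2
      cba_p(c_in, c_out, 1) + n * 2 * cba_p(h, h, 3) + cba_p((2 + n) * h, c_out, 1)
    },
    adown = 9 * (c_in / 2) * (c_out / 2) + 2 * (c_out / 2) +
      (c_in / 2) * (c_out / 2) + 2 * (c_out / 2),
    ghost_conv = {
      h <- c_out / 2
      cba_p(c_in, h, k) + 25 * h + 2 * h
    },
    c3ghost = {
      h <- c_out / 2
      bot <- param_formula("ghost_conv", h, h / 2, 1) +
        param_formula("ghost_conv", h / 2, h, 1)
      2 * cba_p(c_in, h, 1) + n * bot + cba_p(2 * h, c_out, 1)
    },
    sppf = {
      h <- c_in / 2
      cba_p(c_in, h, 1) + cba_p(4 * h, c_in, 1)
    },
    afc_sppf = 4 * c_in^2 + 13 * c_in,
    stop("unknown block kind: ", kind)
  )
}
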