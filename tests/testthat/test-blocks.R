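# Building blocks: parameter-exact construction and forward contracts.

test_that("block parameter counts match independent closed-form arithmetic", {
  # expected values computed by hand from the block structure (conv k^2*ci*co,
  # BN 2c), independent of both package routes
  expect_identical(param_count(conv_bn_act(3, 16, 3, s = 2)), 9 * 3 * 16 + 32)
  expect_identical(param_count(conv_bn_act(128, 256, 3, s = 2)), 295424)
  expect_identical(param_count(conv_bn_act(1, 2, 1)), 1 * 2 + 4)
  expect_identical(param_count(c2f(32, 32, 1)), 1088 + 4672 + 1600)
  expect_identical(param_count(c2f(64, 64, 2)), 4224 + 2 * 18560 + 8320)
  expect_identical(param_count(c2f(256, 256, 1)), 66048 + 295424 + 98816)
  expect_identical(param_count(adown(64, 128)), 20736)
  expect_identical(param_count(adown(128, 256)), 82432)
  expect_identical(param_count(adown(16, 32)), 9 * 8 * 16 + 32 + 8 * 16 + 32)
  expect_identical(param_count(ghost_conv(16, 8, 1)), (16 * 4 + 8) + (25 * 4 + 8))
  expect_identical(param_count(ghost_conv(128, 64, 1)), (128 * 32 + 64) + (25 * 32 + 64))
  expect_identical(param_count(ghost_conv(2, 2, 1)), 31)
  expect_identical(param_count(c3ghost(256, 256, 1)), 33024 + 33024 + 66048 + 10976)
  expect_identical(param_count(c3ghost(32, 32, 1)), 544 + 544 + 1088 + 476)
  expect_identical(param_count(c3ghost(64, 64, 2)), 2112 + 2112 + 4224 + 2 * 1208)
  expect_identical(param_count(sppf(256, 5)), (256 * 128 + 256) + (512 * 256 + 512))
  expect_identical(param_count(sppf(2, 5)), (2 * 1 + 2) + (4 * 2 + 4))
  expect_identical(param_count(afc_sppf(256, 5)), 4 * 256^2 + 13 * 256)
  expect_identical(param_count(afc_sppf(32, 5)), 4 * 32^2 + 13 * 32)
})

test_that("generic parameter counter equals the closed-form formula on random configs", {
  set.seed(3)
  for (i in 1:12) {
    ci <- 2 * sample(1:16, 1)
    co <- 2 * sample(2:16, 1)
    n <- sample(1:3, 1)
    expect_identical(param_count(conv_bn_act(ci, co, 3)),
                     param_formula("conv_bn_act", ci, co, 3))
    expect_identical(param_count(c2f(ci, co, n)), param_formula("c2f", ci, co, n = n))
    expect_identical(param_count(adown(ci, co)), param_formula("adown", ci, co))
    expect_identical(param_count(ghost_conv(ci, co, 1)),
                     param_formula("ghost_conv", ci, co, 1))
    c4 <- 8 * sample(1:4, 1)   # ghost bottlenecks need width divisible by 8
    expect_identical(param_count(c3ghost(ci, c4, n)),
                     param_formula("c3ghost", ci, c4, n = n))
    expect_identical(param_count(sppf(co, 5)), param_formula("sppf", co))
    expect_identical(param_count(afc_sppf(co, 5)), param_formula("afc_sppf", co))
  }
})

test_that("forward passes give finite values and the contracted shapes", {
  x <- rand_tensor(c(2, 8, 16, 16))
  cases <- list(
    list(m = conv_bn_act(8, 12, 3, s = 2), shape = c(2, 12, 8, 8)),
    list(m = c2f(8, 8, 2), shape = c(2, 8, 16, 16)),
    list(m = adown(8, 16), shape = c(2, 16, 8, 8)),
    list(m = ghost_conv(8, 8, 1), shape = c(2, 8, 16, 16)),
    list(m = c3ghost(8, 8, 1), shape = c(2, 8, 16, 16)),
    list(m = sppf(8, 5), shape = c(2, 8, 16, 16)),
    list(m = afc_sppf(8, 5), shape = c(2, 8, 16, 16)))
  for (cs in cases) {
    y <- nn_forward(cs$m, x)
    expect_identical(dim(y), as.integer(cs$shape))
    expect_true(all(is.finite(y)))
  }
  # resolution contract at a second size, odd input floor-divides
  y <- nn_forward(adown(8, 16), rand_tensor(c(1, 8, 18, 18)))
  expect_identical(dim(y), c(1L, 16L, 9L, 9L))
  y <- nn_forward(sppf(256, 5), rand_tensor(c(1, 256, 16, 16), seed = 2))
  expect_identical(dim(y), c(1L, 256L, 16L, 16L))
})

test_that("static profile shapes agree with actual forward shapes", {
  x <- rand_tensor(c(1, 8, 20, 20))
  for (m in list(conv_bn_act(8, 12, 3, s = 2), c2f(8, 8, 1), adown(8, 16),
                 c3ghost(8, 8, 1), sppf(8, 5), afc_sppf(8, 3),
                 attention_adown(8, 16, "cbam"))) {
    pr <- leafcga:::nn_profile(m, c(8, 20, 20))
    y <- nn_forward(m, x)
    expect_identical(as.integer(dim(y)[-1]), as.integer(pr$shape))
    expect_identical(sum(pr$rows$params), param_count(m))
  }
})

test_that("four-branch pooling fusion is invariant to the main kernel on constant input", {
  x <- array(0.37, c(1, 6, 12, 12))
  outs <- lapply(c(3, 5, 7, 9), function(k) {
    m <- with(list(), { set.seed(11); afc_sppf(6, k) })  # identical weights per k
    nn_forward(m, x)
  })
  # max pooling of a constant is the constant, so all branch stacks coincide
  for (i in 2:4) expect_equal(outs[[i]], outs[[1]], tolerance = 1e-12)
})

test_that("dual-branch downsampler concatenates conv branch first, pool branch second", {
  m <- adown(4, 8)
  # make the two branch convolutions produce distinguishable constants
  m$children$cv1$children$conv$params$w[] <- 0
  m$children$cv1$children$bn$params$beta[] <- 7
  m$children$cv2$children$conv$params$w[] <- 0
  m$children$cv2$children$bn$params$beta[] <- -3
  y <- nn_forward(m, rand_tensor(c(1, 4, 8, 8)))
  silu <- function(z) z / (1 + exp(-z))     # each branch ends conv-BN-SiLU
  expect_true(all(abs(y[, 1:4, , ] - silu(7)) < 1e-12))
  expect_true(all(abs(y[, 5:8, , ] - silu(-3)) < 1e-12))
})

test_that("configuration errors are raised for invalid block arguments", {
  expect_error(conv_bn_act(0, 4, 3), "positive")
  expect_error(c2f(4, 7, 1), "even")
  expect_error(c2f(4, 4, 0), ">= 1")
  expect_error(adown(3, 8), "even")
  expect_error(ghost_conv(4, 5, 1), "even")
  expect_error(sppf(8, 4), "odd")
  expect_error(afc_sppf(8, 4), "k_main")
  expect_error(afc_sppf(0, 5), ">= 1")
})

test_that("block backward passes match numerical gradients", {
  # spot-check the hand-written backward of the two bespoke blocks
  for (spec in list(list(build = function() adown(4, 8), c_in = 4),
                    list(build = function() afc_sppf(3, 3), c_in = 3))) {
    set.seed(5)
    m <- spec$build()
    x <- rand_tensor(c(2, spec$c_in, 8, 8), seed = 9)
    leafcga:::set_training(m, TRUE)
    y0 <- nn_forward(m, x)
    w <- rand_tensor(dim(y0), seed = 10)
    leafcga:::zero_grads(m)
    nn_forward(m, x)
    gx <- leafcga:::nn_backward(m, w)
    for (t in 1:4) {
      i <- sample(length(x), 1)
      eps <- 1e-5
      x[i] <- x[i] + eps; lp <- sum(nn_forward(m, x) * w)
      x[i] <- x[i] - 2 * eps; lm <- sum(nn_forward(m, x) * w)
      x[i] <- x[i] + eps
      expect_equal(gx[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})
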