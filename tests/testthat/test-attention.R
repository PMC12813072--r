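# Attention mechanisms and their attachment to the dual-branch downsampler.

test_that("attention-downsampler parameter counts reproduce all printed channel rows", {
  printed <- rbind(
    none = c(20736, 82432, 328704),
    se   = c(21760, 86528, 345088),
    eca  = c(20742, 82442, 328714),
    siam = c(20736, 82432, 328704),
    cbam = c(21956, 86724, 345284),
    gam  = c(226176, 902912, 3608064))
  pairs <- list(c(64, 128), c(128, 256), c(256, 512))
  for (kind in rownames(printed))
    for (j in seq_along(pairs)) {
      m <- attention_adown(pairs[[j]][1], pairs[[j]][2], kind)
      expect_identical(param_count(m), unname(printed[kind, j]),
                       info = sprintf("%s %d->%d", kind, pairs[[j]][1], pairs[[j]][2]))
    }
})

test_that("single attention instances have the stated parameter counts", {
  expect_identical(param_count(cbam(64)), 2 * 64 * 4 + 49 * 2)
  expect_identical(param_count(cbam(128)), 2 * 128 * 8 + 98)
  expect_identical(param_count(se_block(64)), 512)
  expect_identical(param_count(se_block(128)), 2048)
  expect_identical(param_count(eca(64)), 3)
  expect_identical(param_count(eca(128)), 5)
  expect_identical(param_count(eca(256)), 5)
  expect_identical(param_count(siam(64)), 0)
  expect_identical(param_count(siam(256)), 0)
  expect_identical(param_count(gam(64)), 102720)
  expect_identical(param_count(gam(256)), 1639680)
  # generic counter vs closed form across widths
  for (c in c(16, 32, 48, 64, 96))
    for (kind in c("cbam", "se", "eca", "siam", "gam"))
      expect_identical(param_count(attention_block(kind, c)),
                       attention_param_formula(kind, c))
})

test_that("attention gates lie in (0,1) and output shape equals input shape", {
  x <- rand_tensor(c(2, 16, 10, 10), seed = 4)
  for (kind in c("cbam", "se", "eca", "siam", "gam")) {
    m <- attention_block(kind, 16)
    y <- nn_forward(m, x)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
    expect_true(all(m$gate_range > 0 & m$gate_range < 1),
                info = paste("gates", kind))
  }
  # sigmoid-of-pooled-constant contracts
  m <- se_block(8)
  m$params$w1[] <- 0; m$params$w2[] <- 0
  y <- nn_forward(m, array(1, c(1, 8, 4, 4)))
  expect_equal(y, array(0.5, c(1, 8, 4, 4)))   # zero descriptor -> gate 0.5
  # CBAM on constant input scales by a constant per-channel gate in (0,1)
  m <- cbam(8)
  xc <- array(0.3, c(1, 8, 6, 6))
  y <- nn_forward(m, xc)
  inner <- y[1, , 4, 4] / xc[1, , 4, 4]
  expect_true(all(inner > 0 & inner < 1))
})

test_that("attention kind none reduces to the plain downsampler exactly", {
  set.seed(21); plain <- adown(8, 16)
  set.seed(21); none <- attention_adown(8, 16, "none")
  expect_identical(param_count(plain), param_count(none))
  x <- rand_tensor(c(2, 8, 12, 12), seed = 6)
  expect_identical(nn_forward(plain, x), nn_forward(none, x))
})

test_that("the adaptive 1-D kernel rule is odd and monotone non-decreasing", {
  cs <- 2^(1:10)
  ks <- vapply(cs, eca_kernel, integer(1))
  expect_true(all(ks %% 2 == 1))
  expect_true(all(diff(ks) >= 0))
  expect_identical(eca_kernel(64), 3L)
  expect_identical(eca_kernel(128), 5L)
})

test_that("attention backward passes match numerical gradients", {
  for (kind in c("cbam", "se", "eca", "siam", "gam")) {
    set.seed(13)
    m <- attention_block(kind, 8)
    x <- rand_tensor(c(2, 8, 6, 6), seed = 14)
    leafcga:::set_training(m, TRUE)
    y0 <- nn_forward(m, x)
    w <- rand_tensor(dim(y0), seed = 15)
    leafcga:::zero_grads(m)
    nn_forward(m, x)
    gx <- leafcga:::nn_backward(m, w)
    for (t in 1:3) {
      i <- sample(length(x), 1)
      eps <- 1e-5
      x[i] <- x[i] + eps; lp <- sum(nn_forward(m, x) * w)
      x[i] <- x[i] - 2 * eps; lm <- sum(nn_forward(m, x) * w)
      x[i] <- x[i] + eps
      expect_equal(gx[i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   info = paste("input grad", kind))
    }
  }
})
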