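# Model assembly, the experiment grid, and the profiler.

test_that("built model totals reproduce every arithmetically consistent printed value", {
  grid <- ablation_grid()
  for (nm in names(grid)) {
    e <- grid[[nm]]
    built <- param_count(build_model(e$plan, seed = 1))
    expect_identical(built, e$params_derived, info = nm)
    if (isTRUE(e$consistent))
      expect_identical(built, e$params_printed, info = nm)
  }
  # the two reference models, straight from their plan constructors
  expect_identical(param_count(build_model(plan_baseline(), seed = 2)), 1445974)
  expect_identical(param_count(build_model(plan_cga(), seed = 2)), 916594)
})

test_that("the experiment grid contains all reported variants", {
  grid <- ablation_grid()
  tabs <- vapply(grid, `[[`, character(1), "table")
  expect_identical(sum(tabs == "ablation"), 8L)
  expect_identical(sum(tabs == "attention"), 6L)
  expect_identical(sum(tabs == "kernel"), 4L)
  expect_identical(sum(tabs == "placement"), 4L)
  # specific printed rows
  expect_identical(grid$ablation_exp2$params_derived, 927778)
  expect_identical(grid$ablation_exp5$params_derived, 1434790)
  expect_identical(grid$placement_2$params_derived, 668338)
  # main-branch kernel size does not change the parameter count
  expect_identical(unique(vapply(grid[tabs == "kernel"], `[[`, numeric(1),
                                 "params_derived")), 916594)
})

test_that("classify head scales with the class count by exactly 1280 + 1 per class", {
  p6 <- param_count(build_model(plan_baseline(6), seed = 1))
  p1 <- param_count(build_model(plan_baseline(1), seed = 1))
  expect_identical(p6 - p1, 5 * 1280 + 5)
})

test_that("pooling-fusion placement moves parameters as 4c^2 + 13c of the stage width", {
  base <- param_count(build_model(plan_cga(afc_placement = 0), seed = 1))
  widths <- c(32, 64, 128, 256)
  for (i in 1:4) {
    p <- param_count(build_model(plan_cga(afc_placement = i), seed = 1))
    expect_identical(p - base, 4 * widths[i]^2 + 13 * widths[i])
  }
})

test_that("profiler MACs follow the definition on a single convolution", {
  m <- nn_sequential(list(conv = leafcga:::nn_conv2d(8, 8, 1)))
  pr <- leafcga:::nn_profile(m, c(8, 10, 12))
  expect_identical(pr$rows$macs, 8^2 * 10 * 12)   # c^2 * H * W for a 1x1 conv
  m2 <- nn_sequential(list(conv = leafcga:::nn_conv2d(4, 6, 3, stride = 2)))
  pr2 <- leafcga:::nn_profile(m2, c(4, 16, 16))
  expect_identical(pr2$rows$macs, 9 * 4 * 6 * 8 * 8)
})

test_that("profiler totals and reduction identities from built models", {
  pb <- profile_model(plan_baseline())
  pg <- profile_model(plan_cga())
  expect_identical(pb$total_params, 1445974)
  expect_identical(pg$total_params, 916594)
  # printed reduction percentages recomputed from the models
  expect_equal(round(100 * (pb$total_params - pg$total_params) / pb$total_params, 1),
               36.6)
  p_ghost <- profile_model(stage_plan(stage_block = "c3ghost"))
  expect_equal(round(100 * (pb$total_params - p_ghost$total_params) /
                       pb$total_params, 2), 35.84)
  p_afc <- profile_model(stage_plan(afc_placement = 4))
  expect_equal(round(100 * (p_afc$total_params - pb$total_params) /
                       pb$total_params, 2), 18.36)
})

test_that("GFLOPs ratio is resolution-independent for the fully convolutional trunk", {
  r1 <- 100 * (1 - profile_model(plan_cga(), c(640, 640))$gflops /
                 profile_model(plan_baseline(), c(640, 640))$gflops)
  r2 <- 100 * (1 - profile_model(plan_cga(), c(320, 320))$gflops /
                 profile_model(plan_baseline(), c(320, 320))$gflops)
  expect_equal(r1, r2, tolerance = 1e-3)   # head linear term is negligible
})

test_that("model forward has the logit contract at multiple resolutions", {
  plan <- tiny_plan(num_classes = 6)
  model <- build_model(plan, seed = 3)
  y <- model_forward(model, rand_tensor(c(1, 3, 64, 64)))
  expect_identical(dim(y), c(1L, 6L))
  y2 <- model_forward(model, rand_tensor(c(4, 3, 48, 48)))
  expect_identical(dim(y2), c(4L, 6L))
  p <- leafcga:::softmax(y2)
  expect_equal(rowSums(p), rep(1, 4))
  expect_true(all(is.finite(y2)))
  # deterministic in eval mode
  x <- rand_tensor(c(2, 3, 32, 32), seed = 8)
  expect_identical(model_forward(model, x), model_forward(model, x))
  expect_error(model_forward(model, rand_tensor(c(1, 4, 32, 32))), "3, H, W")
})

test_that("plan validation rejects malformed configurations", {
  expect_error(stage_plan(widths = c(32, 64), repeats = c(1, 2, 2)), "same length")
  expect_error(stage_plan(afc_placement = 9), "afc_placement")
  expect_error(stage_plan(num_classes = 0), "num_classes")
  expect_error(stage_plan(attention = "nope"), "attention")
})

test_that("plan round-trips through the YAML config format", {
  plan <- plan_cga()
  f <- tempfile(fileext = ".yaml")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_identical(unclass(back), unclass(plan))
  m1 <- build_model(plan, seed = 5)
  m2 <- build_model(back, seed = 5)
  expect_identical(param_count(m1), param_count(m2))
  # malformed config errors
  writeLines("bogus_field: 3", f)
  expect_error(read_plan(f), "unknown config fields")
})
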