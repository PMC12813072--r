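# Command-line interface and result-object presentation.

test_that("the profile subcommand prints the reference model totals", {
  out <- capture.output(status <- cli_main(c("profile", "--model", "cga")))
  expect_identical(status, 0L)
  expect_true(any(grepl("916,594", out)))
  out2 <- capture.output(status2 <- cli_main(c("profile", "--model", "baseline")))
  expect_identical(status2, 0L)
  expect_true(any(grepl("1,445,974", out2)))
})

test_that("the CLI script runs out of process and profiles the reference model", {
  script <- system.file("cli", "leafcga.R", package = "leafcga")
  skip_if(script == "", "CLI script not installed")
  res <- suppressWarnings(
    system2("Rscript", c(script, "build", "--model", "cga", "--seed", "1"),
            stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  expect_true(any(grepl("916,594", res)))
})

test_that("unknown commands and malformed configs exit non-zero with a message", {
  out <- capture.output(status <- cli_main(c("frobnicate")))
  expect_identical(status, 1L)
  expect_true(any(grepl("unknown command", out)))
  bad <- tempfile(fileext = ".yaml")
  writeLines("widths: [3, 5]", bad)
  out2 <- capture.output(status2 <- cli_main(c("build", "--config", bad)))
  expect_identical(status2, 1L)
  expect_true(any(grepl("error", out2)))
})

test_that("result objects print and plot without error", {
  rep <- profile_model(plan_cga())
  expect_output(print(rep), "916,594")
  m <- eval_metrics(c(1, 2, 2), c(1, 2, 1), n_classes = 2)
  expect_output(print(m), "accuracy")
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  model <- build_model(tiny_plan(), seed = 1)
  hm <- activation_heatmap(model, fixture_image(64))
  expect_s3_class(ggplot2::autoplot(hm), "ggplot")
})
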