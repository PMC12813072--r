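# ONNX serialisation: wire format round-trip and graph-interpreter parity.

test_that("the protobuf varint codec round-trips", {
  for (v in c(0, 1, 127, 128, 300, 65535, 2^31, 2^45)) {
    enc <- leafcga:::pb_varint(v)
    expect_identical(leafcga:::pb_read_varint(enc, 1)$val, v)
  }
})

test_that("tensor and node messages survive an encode/decode round-trip", {
  data <- c(-1.5, 0, 2.25, pi)
  enc <- leafcga:::onnx_tensor("t0", c(2, 2), data)
  dec <- leafcga:::decode_tensor(enc)
  expect_identical(dec$name, "t0")
  expect_identical(dec$dims, c(2, 2))
  expect_identical(dec$data, data)             # DOUBLE payload is lossless
  node <- leafcga:::onnx_node("Conv", list("x", "w"), list("y"), "n1",
                              list(leafcga:::onnx_attr_ints("pads", c(1, 1, 1, 1)),
                                   leafcga:::onnx_attr_int("group", 2)))
  nd <- leafcga:::decode_node(node)
  expect_identical(nd$op_type, "Conv")
  expect_identical(nd$inputs, c("x", "w"))
  expect_identical(nd$attrs$pads, rep(1, 4))
  expect_identical(nd$attrs$group, 2)
})

test_that("exported graphs declare the fixed input shape and class count", {
  model <- build_model(tiny_plan(num_classes = 6), seed = 4)
  f <- tempfile(fileext = ".onnx")
  export_onnx(model, f, input_shape = c(1, 3, 64, 64))
  g <- onnx_load(f)
  expect_identical(g$graph$input$dims, c(1, 3, 64, 64))
  expect_identical(g$graph$output$dims, c(1, 6))
  expect_identical(g$opset, 13)
  x <- array(0, c(1, 3, 64, 64))
  y <- onnx_forward(g, x)
  expect_identical(dim(y), c(1L, 6L))
})

test_that("graph-interpreter logits match the native forward pass within 1e-4", {
  # covers every exportable module kind: attention downsamplers (cbam),
  # ghost cross-stage blocks, the pooling-fusion block and the classify head
  model <- build_model(tiny_plan(num_classes = 3), seed = 7)
  f <- tempfile(fileext = ".onnx")
  export_onnx(model, f, input_shape = c(2, 3, 48, 48))
  g <- onnx_load(f)
  x <- rand_tensor(c(2, 3, 48, 48), seed = 20) * 0.25 + 0.5
  expect_lt(max(abs(onnx_forward(g, x) - model_forward(model, x))), 1e-4)
  # baseline plan (plain conv + c2f) at a second resolution
  base <- build_model(stage_plan(stem_width = 8, widths = c(8, 16, 16, 32),
                                 repeats = c(1, 1, 1, 1), num_classes = 2),
                      seed = 8)
  f2 <- tempfile(fileext = ".onnx")
  export_onnx(base, f2, input_shape = c(1, 3, 64, 64))
  x2 <- rand_tensor(c(1, 3, 64, 64), seed = 21) * 0.25 + 0.5
  expect_lt(max(abs(onnx_forward(onnx_load(f2), x2) - model_forward(base, x2))),
            1e-4)
})

test_that("unsupported attention kinds raise an export error naming the module", {
  model <- build_model(tiny_plan(attention = "gam"), seed = 1)
  expect_error(export_onnx(model, tempfile(fileext = ".onnx")), "lcga_gam")
  model2 <- build_model(tiny_plan(attention = "eca"), seed = 1)
  expect_error(export_onnx(model2, tempfile(fileext = ".onnx")), "lcga_eca")
})
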