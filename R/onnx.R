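# ---- ONNX export and graph interpreter ---------------------------------------

onnx_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$nodes <- list()
  ctx$inits <- list()
  ctx$n <- 0L
  ctx
}

ctx_name <- function(ctx, base) {
  ctx$n <- ctx$n + 1L
  sprintf("%s_%d", base, ctx$n)
}

ctx_node <- function(ctx, op, inputs, outputs = ctx_name(ctx, tolower(op)),
                     attrs = list()) {
  ctx$nodes[[length(ctx$nodes) + 1]] <-
    onnx_node(op, as.list(inputs), as.list(outputs),
              ctx_name(ctx, paste0("n_", tolower(op))), attrs)
  outputs
}

ctx_init <- function(ctx, base, dims, data) {
  name <- ctx_name(ctx, base)
  ctx$inits[[length(ctx$inits) + 1]] <- onnx_tensor(name, dims, data)
  name
}

# conv weight matrix (Cout x Cing*k*k, columns ci-major then ki then kj) to
# ONNX row-major (Cout, Cing, kh, kw) payload
conv_weight_payload <- function(w, c_out, c_ing, k) {
  arr <- array(w, c(c_out, c_ing, k, k))
  as.vector(aperm(arr, c(4, 3, 2, 1)))
}

onnx_emit <- function(m, ctx, input) UseMethod("onnx_emit")

#' @export
onnx_emit.default <- function(m, ctx, input) {
  stop("ONNX export does not support module kind: ", class(m)[1])
}

#' @export
onnx_emit.nn_conv2d <- function(m, ctx, input) {
  cing <- m$c_in %/% m$groups
  wname <- ctx_init(ctx, "W", c(m$c_out, cing, m$k, m$k),
                    conv_weight_payload(m$params$w, m$c_out, cing, m$k))
  ins <- c(input, wname)
  if (m$has_bias) ins <- c(ins, ctx_init(ctx, "Wb", m$c_out, m$params$b))
  ctx_node(ctx, "Conv", ins,
           attrs = list(onnx_attr_ints("kernel_shape", c(m$k, m$k)),
                        onnx_attr_ints("strides", c(m$stride, m$stride)),
                        onnx_attr_ints("pads", rep(m$pad, 4)),
                        onnx_attr_int("group", m$groups)))
}

#' @export
onnx_emit.nn_batchnorm2d <- function(m, ctx, input) {
  ctx_node(ctx, "BatchNormalization",
           c(input,
             ctx_init(ctx, "bn_scale", m$c, m$params$gamma),
             ctx_init(ctx, "bn_bias", m$c, m$params$beta),
             ctx_init(ctx, "bn_mean", m$c, m$buffers$running_mean),
             ctx_init(ctx, "bn_var", m$c, m$buffers$running_var)),
           attrs = list(onnx_attr_float("epsilon", m$eps)))
}

#' @export
onnx_emit.nn_silu <- function(m, ctx, input) {
  s <- ctx_node(ctx, "Sigmoid", input)
  ctx_node(ctx, "Mul", c(input, s))
}

#' @export
onnx_emit.nn_relu <- function(m, ctx, input) ctx_node(ctx, "Relu", input)

#' @export
onnx_emit.nn_dropout <- function(m, ctx, input) input   # eval-mode export

#' @export
onnx_emit.nn_gap <- function(m, ctx, input) {
  g <- ctx_node(ctx, "GlobalAveragePool", input)
  ctx_node(ctx, "Flatten", g, attrs = list(onnx_attr_int("axis", 1)))
}

#' @export
onnx_emit.nn_linear <- function(m, ctx, input) {
  wname <- ctx_init(ctx, "G", dim(m$params$w), as.vector(t(m$params$w)))
  ins <- c(input, wname)
  if (m$has_bias) ins <- c(ins, ctx_init(ctx, "Gb", m$c_out, m$params$b))
  ctx_node(ctx, "Gemm", ins, attrs = list(onnx_attr_int("transB", 1)))
}

#' @export
onnx_emit.nn_sequential <- function(m, ctx, input) {
  for (ch in m$children) input <- onnx_emit(ch, ctx, input)
  input
}

#' @export
onnx_emit.lcga_bottleneck <- function(m, ctx, input) {
  y <- onnx_emit(m$children$cv2, ctx, onnx_emit(m$children$cv1, ctx, input))
  ctx_node(ctx, "Add", c(y, input))
}

#' @export
onnx_emit.lcga_c2f <- function(m, ctx, input) {
  y <- onnx_emit(m$children$cv1, ctx, input)
  outs <- c(ctx_name(ctx, "split_a"), ctx_name(ctx, "split_b"))
  ctx_node(ctx, "Split", y, outputs = outs,
           attrs = list(onnx_attr_int("axis", 1),
                        onnx_attr_ints("split", c(m$h, m$h))))
  parts <- outs
  cur <- outs[2]
  for (b in m$children$bots) {
    cur <- onnx_emit(b, ctx, cur)
    parts <- c(parts, cur)
  }
  cc <- ctx_node(ctx, "Concat", parts, attrs = list(onnx_attr_int("axis", 1)))
  onnx_emit(m$children$cv2, ctx, cc)
}

#' @export
onnx_emit.lcga_adown <- function(m, ctx, input) {
  xp <- ctx_node(ctx, "AveragePool", input,
                 attrs = list(onnx_attr_ints("kernel_shape", c(2, 2)),
                              onnx_attr_ints("strides", c(1, 1)),
                              onnx_attr_ints("pads", rep(0, 4))))
  half <- m$c_in %/% 2
  outs <- c(ctx_name(ctx, "ad_a"), ctx_name(ctx, "ad_b"))
  ctx_node(ctx, "Split", xp, outputs = outs,
           attrs = list(onnx_attr_int("axis", 1),
                        onnx_attr_ints("split", c(half, half))))
  b1 <- onnx_emit(m$children$cv1, ctx, outs[1])
  p2 <- ctx_node(ctx, "MaxPool", outs[2],
                 attrs = list(onnx_attr_ints("kernel_shape", c(3, 3)),
                              onnx_attr_ints("strides", c(2, 2)),
                              onnx_attr_ints("pads", rep(1, 4))))
  b2 <- onnx_emit(m$children$cv2, ctx, p2)
  if (m$has_att) {
    b1 <- onnx_emit(m$children$att1, ctx, b1)
    b2 <- onnx_emit(m$children$att2, ctx, b2)
  }
  ctx_node(ctx, "Concat", c(b1, b2), attrs = list(onnx_attr_int("axis", 1)))
}

#' @export
onnx_emit.lcga_ghost <- function(m, ctx, input) {
  y1 <- onnx_emit(m$children$primary, ctx, input)
  y2 <- onnx_emit(m$children$cheap, ctx, y1)
  ctx_node(ctx, "Concat", c(y1, y2), attrs = list(onnx_attr_int("axis", 1)))
}

#' @export
onnx_emit.lcga_ghost_bottleneck <- function(m, ctx, input) {
  y <- onnx_emit(m$children$g2, ctx, onnx_emit(m$children$g1, ctx, input))
  ctx_node(ctx, "Add", c(y, input))
}

#' @export
onnx_emit.lcga_c3ghost <- function(m, ctx, input) {
  main <- onnx_emit(m$children$cv1, ctx, input)
  for (b in m$children$bots) main <- onnx_emit(b, ctx, main)
  side <- onnx_emit(m$children$cv2, ctx, input)
  cc <- ctx_node(ctx, "Concat", c(main, side),
                 attrs = list(onnx_attr_int("axis", 1)))
  onnx_emit(m$children$cv3, ctx, cc)
}

onnx_maxpool_same <- function(ctx, input, k) {
  ctx_node(ctx, "MaxPool", input,
           attrs = list(onnx_attr_ints("kernel_shape", c(k, k)),
                        onnx_attr_ints("strides", c(1, 1)),
                        onnx_attr_ints("pads", rep(k %/% 2, 4))))
}

#' @export
onnx_emit.lcga_sppf <- function(m, ctx, input) {
  y0 <- onnx_emit(m$children$cv1, ctx, input)
  p1 <- onnx_maxpool_same(ctx, y0, m$k)
  p2 <- onnx_maxpool_same(ctx, p1, m$k)
  p3 <- onnx_maxpool_same(ctx, p2, m$k)
  cc <- ctx_node(ctx, "Concat", c(y0, p1, p2, p3),
                 attrs = list(onnx_attr_int("axis", 1)))
  onnx_emit(m$children$cv2, ctx, cc)
}

#' @export
onnx_emit.lcga_afc_sppf <- function(m, ctx, input) {
  b2 <- onnx_maxpool_same(ctx,
          onnx_maxpool_same(ctx,
            onnx_maxpool_same(ctx, input, m$k_main), m$k_main), m$k_main)
  b3 <- onnx_maxpool_same(ctx, input, 3)
  b4 <- onnx_maxpool_same(ctx, input, 5)
  cc <- ctx_node(ctx, "Concat", c(input, b2, b3, b4),
                 attrs = list(onnx_attr_int("axis", 1)))
  onnx_emit(m$children$dw, ctx, onnx_emit(m$children$compress, ctx, cc))
}

# shared-MLP branch as 1x1 convolutions on the pooled (N, C, 1, 1) descriptor
cbam_mlp_branch <- function(ctx, pooled, w1name, w2name) {
  h1 <- ctx_node(ctx, "Conv", c(pooled, w1name),
                 attrs = list(onnx_attr_ints("kernel_shape", c(1, 1)),
                              onnx_attr_ints("strides", c(1, 1)),
                              onnx_attr_ints("pads", rep(0, 4)),
                              onnx_attr_int("group", 1)))
  r <- ctx_node(ctx, "Relu", h1)
  ctx_node(ctx, "Conv", c(r, w2name),
           attrs = list(onnx_attr_ints("kernel_shape", c(1, 1)),
                        onnx_attr_ints("strides", c(1, 1)),
                        onnx_attr_ints("pads", rep(0, 4)),
                        onnx_attr_int("group", 1)))
}

#' @export
onnx_emit.lcga_cbam <- function(m, ctx, input) {
  w1 <- ctx_init(ctx, "cbam_w1", c(m$h, m$c, 1, 1), as.vector(t(m$params$w1)))
  w2 <- ctx_init(ctx, "cbam_w2", c(m$c, m$h, 1, 1), as.vector(t(m$params$w2)))
  pa <- ctx_node(ctx, "GlobalAveragePool", input)
  pm <- ctx_node(ctx, "GlobalMaxPool", input)
  s <- ctx_node(ctx, "Add", c(cbam_mlp_branch(ctx, pa, w1, w2),
                              cbam_mlp_branch(ctx, pm, w1, w2)))
  g1 <- ctx_node(ctx, "Sigmoid", s)
  x1 <- ctx_node(ctx, "Mul", c(input, g1))
  mm <- ctx_node(ctx, "ReduceMean", x1,
                 attrs = list(onnx_attr_ints("axes", 1),
                              onnx_attr_int("keepdims", 1)))
  mx <- ctx_node(ctx, "ReduceMax", x1,
                 attrs = list(onnx_attr_ints("axes", 1),
                              onnx_attr_int("keepdims", 1)))
  cc <- ctx_node(ctx, "Concat", c(mm, mx), attrs = list(onnx_attr_int("axis", 1)))
  z <- onnx_emit(m$children$conv, ctx, cc)
  g2 <- ctx_node(ctx, "Sigmoid", z)
  ctx_node(ctx, "Mul", c(x1, g2))
}

#' @export
onnx_emit.lcga_se <- function(m, ctx, input) {
  w1 <- ctx_init(ctx, "se_w1", c(m$h, m$c, 1, 1), as.vector(t(m$params$w1)))
  w2 <- ctx_init(ctx, "se_w2", c(m$c, m$h, 1, 1), as.vector(t(m$params$w2)))
  g <- ctx_node(ctx, "Sigmoid",
                cbam_mlp_branch(ctx, ctx_node(ctx, "GlobalAveragePool", input),
                                w1, w2))
  ctx_node(ctx, "Mul", c(input, g))
}

#' @export
onnx_emit.lcga_head <- function(m, ctx, input) {
  f <- onnx_emit(m$children$conv, ctx, input)
  g <- ctx_node(ctx, "GlobalAveragePool", f)
  fl <- ctx_node(ctx, "Flatten", g, attrs = list(onnx_attr_int("axis", 1)))
  onnx_emit(m$children$fc, ctx, fl)
}

#' Export a model to an ONNX file
#'
#' Serialises the eval-mode graph (batch-norm running statistics folded in as
#' initializers, dropout removed) as a genuine ONNX protobuf with DOUBLE
#' weight tensors, fixed input shape and opset 13. Graphs containing module
#' kinds without an ONNX mapping (the ECA / SimAM-style / GAM attention
#' variants) raise an error naming the offending module.
#'
#' @param model a built model.
#' @param path output `.onnx` file.
#' @param input_shape fixed input tensor shape (default `c(1, 3, 512, 512)`).
#' @param opset ONNX opset version to declare.
#' @return `path`, invisibly.
#' @export
export_onnx <- function(model, path, input_shape = c(1, 3, 512, 512),
                        opset = 13) {
  stopifnot(inherits(model, "lcga_model"))
  set_training(model, FALSE)
  ctx <- onnx_ctx()
  out <- "input"
  for (ch in model$children) out <- onnx_emit(ch, ctx, out)
  # rename the final node output to "logits"
  graph <- onnx_graph(ctx$nodes, ctx$inits,
                      onnx_value_info("input", input_shape),
                      onnx_value_info(out, c(input_shape[1],
                                             model$plan$num_classes)))
  bytes <- onnx_model_bytes(graph, opset)
  writeBin(bytes, path)
  invisible(path)
}

#' Load an ONNX file exported by this package
#'
#' @param path `.onnx` file.
#' @return an `lcga_onnx_graph`: nodes, initializers, input/output value
#'   infos and the declared opset.
#' @export
onnx_load <- function(path) {
  if (!file.exists(path)) stop("ONNX file not found: ", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  mdl <- decode_model(bytes)
  structure(mdl, class = "lcga_onnx_graph")
}

#' @export
print.lcga_onnx_graph <- function(x, ...) {
  cat(sprintf("<ONNX graph> %d nodes, %d initializers, opset %s, input (%s)\n",
              length(x$graph$nodes), length(x$graph$initializers),
              format(x$opset), paste(x$graph$input$dims, collapse = ", ")))
  invisible(x)
}

# broadcastable elementwise op over the shapes our graphs produce
bc_binop <- function(a, b, op) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (identical(da, db)) return(op(a, b))
  if (length(da) == 4 && length(db) == 4) {
    if (all(db[3:4] == 1) && db[2] == da[2])       # (N,C,1,1) over (N,C,H,W)
      return(op(a, bcast_nc(array(b, db[1:2]), da)))
    if (db[2] == 1 && all(db[3:4] == da[3:4]))     # (N,1,H,W) over (N,C,H,W)
      return(op(a, bcast_spatial(b, da)))
  }
  stop("unsupported broadcast: ", paste(da, collapse = "x"), " vs ",
       paste(db, collapse = "x"))
}

#' Evaluate an ONNX graph on an input tensor
#'
#' A self-contained interpreter for the operator subset the exporter emits
#' (Conv, BatchNormalization, Relu, Sigmoid, Mul, Add, Concat, Split,
#' MaxPool, AveragePool, GlobalAveragePool, GlobalMaxPool, ReduceMean,
#' ReduceMax, Flatten, Gemm). Execution is driven entirely by the
#' deserialised graph — nodes, attributes and initializer payloads — not by
#' the in-memory module tree, so it provides an independent check that the
#' serialised file reproduces the native forward pass.
#'
#' @param graph an [onnx_load()] result.
#' @param x input array matching the exported input shape.
#' @return the output tensor (logit matrix for classifier graphs).
#' @export
onnx_forward <- function(graph, x) {
  stopifnot(inherits(graph, "lcga_onnx_graph"))
  g <- graph$graph
  vals <- new.env(parent = emptyenv())
  assign(g$input$name, x, envir = vals)
  inits <- new.env(parent = emptyenv())
  for (t in g$initializers) assign(t$name, t, envir = inits)
  getv <- function(nm) {
    if (exists(nm, vals, inherits = FALSE)) return(get(nm, vals))
    t <- get(nm, inits)
    array(t$data, rev(t$dims))                 # placeholder; tensors fetched raw
  }
  get_tensor <- function(nm) get(nm, inits)
  for (node in g$nodes) {
    a <- node$attrs
    ins <- node$inputs
    out <- switch(node$op_type,
      Conv = {
        xx <- get(ins[1], vals)
        wt <- get_tensor(ins[2])
        dims <- wt$dims                         # (Cout, Cing, kh, kw)
        k <- dims[3]
        arr <- array(wt$data, rev(dims))        # (kw, kh, Cing, Cout)
        wmat <- matrix(aperm(arr, c(4, 3, 2, 1)), nrow = dims[1])
        y <- .conv2d_fw(xx, dim(xx), wmat, k, a$strides[1], a$pads[1],
                        a$group %||% 1)
        if (length(ins) >= 3) y <- y + bcast_chan(get_tensor(ins[3])$data, dim(y))
        y
      },
      BatchNormalization = {
        xx <- get(ins[1], vals)
        sc <- get_tensor(ins[2])$data; bs <- get_tensor(ins[3])$data
        mu <- get_tensor(ins[4])$data; vv <- get_tensor(ins[5])$data
        dm <- dim(xx)
        (xx - bcast_chan(mu, dm)) *
          bcast_chan(sc / sqrt(vv + (a$epsilon %||% 1e-5)), dm) +
          bcast_chan(bs, dm)
      },
      Relu = pmax(get(ins[1], vals), 0),
      Sigmoid = sigmoid(get(ins[1], vals)),
      Mul = bc_binop(get(ins[1], vals), get(ins[2], vals), `*`),
      Add = bc_binop(get(ins[1], vals), get(ins[2], vals), `+`),
      Concat = cat_channels(lapply(ins, function(nm) get(nm, vals))),
      Split = {
        xx <- get(ins[1], vals)
        parts <- split_channels(xx, a$split)
        for (i in seq_along(parts)) assign(node$outputs[i], parts[[i]], vals)
        NULL
      },
      MaxPool = {
        xx <- get(ins[1], vals)
        .maxpool_fw(xx, dim(xx), a$kernel_shape[1], a$strides[1], a$pads[1])$y
      },
      AveragePool = {
        xx <- get(ins[1], vals)
        .avgpool_fw(xx, dim(xx), a$kernel_shape[1], a$strides[1], a$pads[1])
      },
      GlobalAveragePool = {
        xx <- get(ins[1], vals)
        dm <- dim(xx)
        array(nc_sum(xx) / (dm[3] * dm[4]), c(dm[1], dm[2], 1, 1))
      },
      GlobalMaxPool = {
        xx <- get(ins[1], vals)
        dm <- dim(xx)
        array(gmax_pool(xx)$val, c(dm[1], dm[2], 1, 1))
      },
      ReduceMean = {
        xx <- get(ins[1], vals)
        dm <- dim(xx)
        array(rowSums(matrix(aperm(xx, c(1, 3, 4, 2)), ncol = dm[2])) / dm[2],
              c(dm[1], 1, dm[3], dm[4]))
      },
      ReduceMax = cmax_map(get(ins[1], vals))$val,
      Flatten = {
        xx <- get(ins[1], vals)
        dm <- dim(xx)
        matrix(xx, dm[1], prod(dm[-1]))
      },
      Gemm = {
        xx <- get(ins[1], vals)
        wt <- get_tensor(ins[2])
        W <- matrix(wt$data, wt$dims[1], wt$dims[2], byrow = TRUE)
        y <- xx %*% t(W)
        if (length(ins) >= 3) y <- sweep(y, 2, get_tensor(ins[3])$data, "+")
        y
      },
      stop("ONNX interpreter does not implement op: ", node$op_type))
    if (!is.null(out)) assign(node$outputs[1], out, envir = vals)
  }
  get(g$output$name, vals)
}
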