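# ---- minimal protobuf wire-format codec for ONNX graphs ----------------------
#
# Implements exactly the subset of the proto3 wire format that ONNX model
# files use: varint (wire type 0) and length-delimited (wire type 2) fields,
# with packed or expanded repeated integers. Field numbers follow the ONNX
# schema (ModelProto, GraphProto, NodeProto, AttributeProto, TensorProto,
# ValueInfoProto). Tensor payloads are written as DOUBLE (data_type 11)
# raw_data so the exported weights are bit-identical to the in-memory model.

pb_varint <- function(x) {
  x <- as.numeric(x)
  if (x < 0) stop("negative varints are not supported")
  out <- raw(0)
  repeat {
    b <- x %% 128
    x <- floor(x / 128)
    if (x > 0) out <- c(out, as.raw(b + 128)) else return(c(out, as.raw(b)))
  }
}

pb_tag <- function(field, wire) pb_varint(field * 8 + wire)

pb_int <- function(field, x) c(pb_tag(field, 0), pb_varint(x))

pb_bytes <- function(field, payload) {
  c(pb_tag(field, 2), pb_varint(length(payload)), payload)
}

pb_string <- function(field, s) pb_bytes(field, charToRaw(s))

pb_cat <- function(...) do.call(c, Filter(length, list(...)))

# ---- message writers ----------------------------------------------------------

onnx_attr_int <- function(name, val) {
  pb_cat(pb_string(1, name), pb_int(3, val), pb_int(20, 2))      # type INT
}

onnx_attr_ints <- function(name, vals) {
  pb_cat(pb_string(1, name),
         do.call(c, lapply(vals, function(v) pb_int(8, v))),
         pb_int(20, 7))                                          # type INTS
}

onnx_attr_float <- function(name, val) {
  pb_cat(pb_string(1, name),
         c(pb_tag(2, 5), writeBin(as.numeric(val), raw(), size = 4,
                                  endian = "little")),
         pb_int(20, 1))                                          # type FLOAT
}

onnx_tensor <- function(name, dims, data) {
  pb_cat(do.call(c, lapply(dims, function(d) pb_int(1, d))),
         pb_int(2, 11),                                          # DOUBLE
         pb_string(8, name),
         pb_bytes(9, writeBin(as.numeric(data), raw(), size = 8,
                              endian = "little")))
}

onnx_value_info <- function(name, dims) {
  shape <- do.call(c, lapply(dims, function(d) pb_bytes(1, pb_int(1, d))))
  ttype <- pb_cat(pb_int(1, 11), pb_bytes(2, shape))
  pb_cat(pb_string(1, name), pb_bytes(2, pb_bytes(1, ttype)))
}

onnx_node <- function(op_type, inputs, outputs, name, attrs = list()) {
  pb_cat(do.call(c, lapply(inputs, function(s) pb_string(1, s))),
         do.call(c, lapply(outputs, function(s) pb_string(2, s))),
         pb_string(3, name),
         pb_string(4, op_type),
         if (length(attrs)) do.call(c, lapply(attrs, function(a) pb_bytes(5, a)))
         else raw(0))
}

onnx_graph <- function(nodes, inits, input_vi, output_vi, name = "leafcga") {
  pb_cat(do.call(c, lapply(nodes, function(n) pb_bytes(1, n))),
         pb_string(2, name),
         do.call(c, lapply(inits, function(t) pb_bytes(5, t))),
         pb_bytes(11, input_vi),
         pb_bytes(12, output_vi))
}

onnx_model_bytes <- function(graph, opset = 13) {
  opset_msg <- pb_cat(pb_string(1, ""), pb_int(2, opset))
  pb_cat(pb_int(1, 8),                                           # ir_version
         pb_string(2, "leafcga"),
         pb_bytes(7, graph),
         pb_bytes(8, opset_msg))
}

# ---- wire-format reader --------------------------------------------------------

pb_read_varint <- function(bytes, i) {
  val <- 0; mult <- 1
  repeat {
    b <- as.integer(bytes[i]); i <- i + 1
    val <- val + (b %% 128) * mult
    if (b < 128) return(list(val = val, i = i))
    mult <- mult * 128
  }
}

# parse one message into a list of fields (field, wire, val)
pb_parse <- function(bytes) {
  i <- 1; n <- length(bytes)
  out <- list()
  while (i <= n) {
    r <- pb_read_varint(bytes, i)
    field <- r$val %/% 8; wire <- r$val %% 8
    i <- r$i
    if (wire == 0) {
      r <- pb_read_varint(bytes, i); val <- r$val; i <- r$i
    } else if (wire == 2) {
      r <- pb_read_varint(bytes, i); len <- r$val; i <- r$i
      val <- if (len > 0) bytes[i:(i + len - 1)] else raw(0)
      i <- i + len
    } else if (wire == 5) {
      val <- bytes[i:(i + 3)]; i <- i + 4
    } else if (wire == 1) {
      val <- bytes[i:(i + 7)]; i <- i + 8
    } else stop("unsupported wire type: ", wire)
    out[[length(out) + 1]] <- list(field = field, wire = wire, val = val)
  }
  out
}

pb_fields <- function(parsed, field) Filter(function(f) f$field == field, parsed)

pb_field1 <- function(parsed, field) {
  f <- pb_fields(parsed, field)
  if (!length(f)) NULL else f[[1]]$val
}

# repeated int64 field that may be packed (wire 2) or expanded (wire 0)
pb_repeated_ints <- function(parsed, field) {
  vals <- numeric(0)
  for (f in pb_fields(parsed, field)) {
    if (f$wire == 0) vals <- c(vals, f$val)
    else {
      i <- 1
      while (i <= length(f$val)) {
        r <- pb_read_varint(f$val, i)
        vals <- c(vals, r$val); i <- r$i
      }
    }
  }
  vals
}

decode_tensor <- function(bytes) {
  p <- pb_parse(bytes)
  dims <- pb_repeated_ints(p, 1)
  dtype <- pb_field1(p, 2)
  raw_data <- pb_field1(p, 9)
  data <- if (dtype == 11) {
    readBin(raw_data, numeric(), n = length(raw_data) / 8, size = 8,
            endian = "little")
  } else if (dtype == 1) {
    readBin(raw_data, numeric(), n = length(raw_data) / 4, size = 4,
            endian = "little")
  } else stop("unsupported tensor data type: ", dtype)
  list(name = rawToChar(pb_field1(p, 8)), dims = dims, data = data)
}

decode_attr <- function(bytes) {
  p <- pb_parse(bytes)
  name <- rawToChar(pb_field1(p, 1))
  type <- pb_field1(p, 20) %||% 0
  val <- if (type == 2) pb_field1(p, 3)
         else if (type == 7) pb_repeated_ints(p, 8)
         else if (type == 1) readBin(pb_field1(p, 2), numeric(), 1, size = 4,
                                     endian = "little")
         else NULL
  list(name = name, val = val)
}

decode_node <- function(bytes) {
  p <- pb_parse(bytes)
  attrs <- lapply(pb_fields(p, 5), function(f) decode_attr(f$val))
  attr_list <- setNames(lapply(attrs, `[[`, "val"),
                        vapply(attrs, `[[`, character(1), "name"))
  list(op_type = rawToChar(pb_field1(p, 4)),
       inputs = vapply(pb_fields(p, 1), function(f) rawToChar(f$val), character(1)),
       outputs = vapply(pb_fields(p, 2), function(f) rawToChar(f$val), character(1)),
       name = if (is.null(pb_field1(p, 3))) "" else rawToChar(pb_field1(p, 3)),
       attrs = attr_list)
}

decode_value_info <- function(bytes) {
  p <- pb_parse(bytes)
  name <- rawToChar(pb_field1(p, 1))
  dims <- numeric(0)
  tp <- pb_field1(p, 2)
  if (!is.null(tp)) {
    tt <- pb_field1(pb_parse(tp), 1)
    if (!is.null(tt)) {
      sh <- pb_field1(pb_parse(tt), 2)
      if (!is.null(sh)) {
        dims <- vapply(pb_fields(pb_parse(sh), 1), function(d) {
          dv <- pb_field1(pb_parse(d$val), 1)
          if (is.null(dv)) NA_real_ else dv
        }, numeric(1))
      }
    }
  }
  list(name = name, dims = dims)
}

decode_graph <- function(bytes) {
  p <- pb_parse(bytes)
  list(nodes = lapply(pb_fields(p, 1), function(f) decode_node(f$val)),
       initializers = lapply(pb_fields(p, 5), function(f) decode_tensor(f$val)),
       input = decode_value_info(pb_field1(p, 11)),
       output = decode_value_info(pb_field1(p, 12)))
}

decode_model <- function(bytes) {
  p <- pb_parse(bytes)
  opset <- NA_real_
  op <- pb_field1(p, 8)
  if (!is.null(op)) opset <- pb_field1(pb_parse(op), 2) %||% NA_real_
  list(ir_version = pb_field1(p, 1),
       opset = opset,
       graph = decode_graph(pb_field1(p, 7)))
}
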