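# ---- parameter / MAC profiler ------------------------------------------------

#' Profile a model's parameters and multiply-accumulate operations
#'
#' Produces a per-layer report of trainable parameters and MACs by static
#' shape propagation (no forward pass is run). The counting convention is:
#' parameters over every trainable array (weights, biases, batch-norm scale
#' and shift); MACs over convolution and linear layers only — batch norm,
#' activations and pooling are free; GFLOPs = 2 x MACs / 1e9 at the stated
#' input size (default 640 x 640).
#'
#' @param x a built model ([build_model()]) or a plan ([stage_plan()]).
#' @param input_size spatial input size `c(H, W)` used for MAC counting.
#' @return an object of class `lcga_param_report`: a list with `layers`
#'   (data frame of name, kind, params, macs), `total_params`, `total_macs`,
#'   `gflops` (full precision) and `input_size`.
#' @export
profile_model <- function(x, input_size = c(640, 640)) {
  model <- if (inherits(x, "lcga_plan")) build_model(x, seed = 0) else x
  stopifnot(inherits(model, "lcga_model"))
  pr <- nn_profile(model, c(3, input_size[1], input_size[2]), name = "model")
  layers <- pr$rows
  rownames(layers) <- NULL
  total_macs <- sum(layers$macs)
  structure(list(layers = layers,
                 total_params = sum(layers$params),
                 total_macs = total_macs,
                 gflops = 2 * total_macs / 1e9,
                 input_size = input_size,
                 plan_name = model$plan$name),
            class = "lcga_param_report")
}

#' @export
print.lcga_param_report <- function(x, ...) {
  cat(sprintf("Per-layer profile at %dx%d input\n",
              x$input_size[1], x$input_size[2]))
  df <- x$layers
  df$params <- format(df$params, big.mark = ",")
  df$macs <- format(df$macs, big.mark = ",")
  print(df, right = FALSE)
  cat(sprintf("\nTotal parameters: %s\nTotal MACs:       %s\nGFLOPs (2*MACs):  %.1f\n",
              format(x$total_params, big.mark = ","),
              format(x$total_macs, big.mark = ","), x$gflops))
  invisible(x)
}

#' @export
format.lcga_param_report <- function(x, ...) {
  sprintf("%s params, %.1f GFLOPs", format(x$total_params, big.mark = ","),
          x$gflops)
}

# tab-separated per-layer dump (used by the command-line profiler)
write_profile_tsv <- function(report, path) {
  utils::write.table(report$layers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
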