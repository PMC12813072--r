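# ---- ggplot2 visualisations ---------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_col
#'   geom_text scale_fill_gradient labs theme_minimal facet_wrap annotation_raster
#'   theme element_blank coord_fixed .data
NULL

#' Confusion-matrix heatmap for a metrics object
#'
#' @param object an [eval_metrics()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lcga_metrics <- function(object, ...) {
  cm <- as.data.frame(as.table(object$confusion))
  names(cm) <- c("truth", "pred", "count")
  ggplot(cm, aes(x = .data$pred, y = .data$truth, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "#2c7fb8") +
    labs(x = "predicted", y = "true", fill = "n",
         title = sprintf("Confusion matrix (accuracy %.3f)", object$accuracy)) +
    theme_minimal()
}

#' Cross-validation summary plot: per-fold test metrics
#'
#' @param object a [cross_validate()] report.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lcga_cv_report <- function(object, ...) {
  mm <- object$fold_metrics
  df <- data.frame(fold = rep(seq_len(nrow(mm)), ncol(mm)),
                   metric = rep(colnames(mm), each = nrow(mm)),
                   value = as.vector(mm))
  ggplot(df, aes(x = factor(.data$fold), y = .data$value)) +
    geom_col(fill = "#41ab5d") +
    facet_wrap(~metric) +
    labs(x = "fold", y = "test-set value",
         title = "Nested cross-validation: per-fold test metrics") +
    theme_minimal()
}

#' Training-history curves for one fold
#'
#' @param history the `history` data frame returned by [train_fold()].
#' @return a ggplot object.
#' @export
plot_history <- function(history) {
  df <- rbind(
    data.frame(epoch = history$epoch, value = history$train_loss, series = "train loss"),
    data.frame(epoch = history$epoch, value = history$val_loss, series = "val loss"),
    data.frame(epoch = history$epoch, value = history$train_acc, series = "train acc"),
    data.frame(epoch = history$epoch, value = history$val_acc, series = "val acc"))
  ggplot(df, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    labs(x = "epoch", y = NULL, title = "Training history") +
    theme_minimal()
}

#' Class-activation heatmap overlay plot
#'
#' @param object an [activation_heatmap()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lcga_heatmap <- function(object, ...) {
  ov <- object$overlay
  rast <- grDevices::rgb(ov[, , 1], ov[, , 2], ov[, , 3])
  dim(rast) <- dim(ov)[1:2]
  ggplot() +
    annotation_raster(rast, xmin = 0, xmax = 1, ymin = 0, ymax = 1) +
    coord_fixed(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    labs(title = sprintf("Class activation map (class %d)", object$class_index)) +
    theme_minimal() +
    theme(axis.text = element_blank(), axis.title = element_blank())
}

#' Per-layer parameter profile plot
#'
#' @param object a [profile_model()] report.
#' @param top show only the `top` largest layers.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lcga_param_report <- function(object, top = 25, ...) {
  df <- object$layers[object$layers$params > 0, ]
  df <- df[order(-df$params), ][seq_len(min(top, nrow(df))), ]
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot(df, aes(x = .data$params, y = .data$name)) +
    geom_col(fill = "#756bb1") +
    labs(x = "trainable parameters", y = NULL,
         title = sprintf("Largest layers (total %s)",
                         format(object$total_params, big.mark = ","))) +
    theme_minimal()
}
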