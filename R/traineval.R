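# ---- training & evaluation protocol ------------------------------------------

#' Training configuration
#'
#' Defaults follow the reference protocol: 512x512 inputs, batch 32, 100
#' epochs with no early stopping (patience 0), Adam with initial learning
#' rate `lr0 = 0.001` decaying linearly to `lr0 * lrf`, first-moment decay
#' (momentum) 0.937, weight decay 5e-4 and seed 42. Everything is
#' overridable; tests and examples use much smaller sizes.
#'
#' @param image_size square input side in pixels.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param patience epochs without validation improvement before stopping;
#'   0 disables early stopping (all epochs run).
#' @param workers reserved for API compatibility (loading is in-process).
#' @param optimizer `"adam"` (the only implemented optimiser).
#' @param lr0 initial learning rate.
#' @param lrf final learning-rate fraction (`lr` decays linearly to
#'   `lr0 * lrf` over the epoch budget).
#' @param momentum Adam first-moment decay (beta1); beta2 is 0.999.
#' @param weight_decay L2 penalty applied to convolution/linear weights.
#' @param seed base RNG seed.
#' @return a `lcga_train_config` list.
#' @export
train_config <- function(image_size = 512, batch_size = 32, epochs = 100,
                         patience = 0, workers = 8, optimizer = "adam",
                         lr0 = 0.001, lrf = 0.01, momentum = 0.937,
                         weight_decay = 5e-4, seed = 42) {
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(image_size = image_size, batch_size = batch_size,
                 epochs = epochs, patience = patience, workers = workers,
                 optimizer = optimizer, lr0 = lr0, lrf = lrf,
                 momentum = momentum, weight_decay = weight_decay,
                 seed = seed),
            class = "lcga_train_config")
}

#' Nested stratified split: held-out test set plus K cross-validation folds
#'
#' Splits the sample 80:20 into a training pool and an independent test set
#' (stratified by class), then partitions the pool into `k` folds; each fold
#' uses one part as validation (20% of the pool for `k = 5`) and the rest as
#' its sub-training set. Deterministic under `seed`.
#'
#' @param labels integer or factor class labels for all samples.
#' @param k number of folds.
#' @param test_frac held-out test fraction.
#' @param seed RNG seed.
#' @return a `lcga_fold_split`: `list(test, folds, k, seed)` where `folds`
#'   is a list of `list(train, val)` index vectors.
#' @export
cv_split <- function(labels, k = 5, test_frac = 0.2, seed = 42) {
  y <- as.integer(as.factor(labels))
  classes <- sort(unique(y))
  lev <- if (is.factor(labels)) levels(labels) else as.character(sort(unique(labels)))
  test <- integer(0)
  pool_chunks <- replicate(k, integer(0), simplify = FALSE)
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(y == cl))
      n_test <- max(1L, round(length(idx) * test_frac))
      if (length(idx) - n_test < k)
        stop(sprintf("class '%s' has too few samples for %d folds (%d after the test split)",
                     lev[cl], k, length(idx) - n_test))
      test <- c(test, idx[seq_len(n_test)])
      pool <- idx[-seq_len(n_test)]
      grp <- rep(seq_len(k), length.out = length(pool))
      for (f in seq_len(k))
        pool_chunks[[f]] <- c(pool_chunks[[f]], pool[grp == f])
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(train = sort(unlist(pool_chunks[-f], use.names = FALSE)),
         val = sort(pool_chunks[[f]]))
  })
  structure(list(test = sort(test), folds = folds, k = k, seed = seed),
            class = "lcga_fold_split")
}

#' @export
print.lcga_fold_split <- function(x, ...) {
  cat(sprintf("<fold split> test %d | %d folds: sub-train %s / validation %s\n",
              length(x$test),
              x$k,
              paste(unique(vapply(x$folds, function(f) length(f$train), numeric(1))),
                    collapse = "/"),
              paste(unique(vapply(x$folds, function(f) length(f$val), numeric(1))),
                    collapse = "/")))
  invisible(x)
}

# ---- loss & optimiser --------------------------------------------------------

softmax <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

cross_entropy <- function(logits, y) {
  p <- softmax(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = g / n)
}

# Adam step over all modules; weight decay on matrix weights only (not BN
# scale/shift, not biases), mirroring standard practice.
adam_step <- function(model, lr, beta1, beta2, wd, eps = 1e-8) {
  model$adam_t <- (model$adam_t %||% 0) + 1
  t <- model$adam_t
  module_walk(model, function(mm) {
    if (!length(mm$params)) return()
    if (is.null(mm$opt)) {
      mm$opt <- lapply(mm$params, function(p) {
        list(m = array(0, dim = dim(p) %||% length(p)),
             v = array(0, dim = dim(p) %||% length(p)))
      })
    }
    for (nm in names(mm$params)) {
      g <- mm$grads[[nm]]
      if (nm == "w" && !is.null(dim(mm$params[[nm]])))
        g <- g + wd * mm$params[[nm]]
      st <- mm$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mm$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      mm$params[[nm]] <- mm$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  })
}

# batched eval-mode prediction
predict_logits <- function(model, x, batch_size = 64) {
  n <- dim(x)[1]
  out <- NULL
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    lg <- model_forward(model, x[idx, , , , drop = FALSE], training = FALSE)
    out <- rbind(out, lg)
  }
  out
}

#' Predicted class labels
#'
#' @param object a built model.
#' @param x input batch `(N, 3, H, W)`.
#' @param ... unused.
#' @return integer class indices.
#' @export
predict.lcga_model <- function(object, x, ...) {
  max.col(predict_logits(object, x), ties.method = "first")
}

#' Train one cross-validation fold
#'
#' Minibatch Adam training with linear learning-rate decay and cross-entropy
#' loss; after every epoch the model is evaluated on the fold's validation
#' indices and the weights with the highest validation accuracy are retained
#' (ties resolved to the earliest epoch). With `patience = 0` exactly
#' `epochs` epochs run.
#'
#' @param plan a [stage_plan()] (a fresh model is built per fold).
#' @param ds a dataset from [read_image_folder()].
#' @param fold `list(train, val)` index vectors.
#' @param config a [train_config()].
#' @param seed seed for weight init and batch shuffling.
#' @return list with the trained `model` (best weights restored),
#'   `best_epoch`, `best_val_acc` and a per-epoch `history` data frame.
#' @export
train_fold <- function(plan, ds, fold, config = train_config(), seed = config$seed) {
  model <- build_model(plan, seed = seed)
  n_tr <- length(fold$train)
  best <- list(acc = -Inf, epoch = NA_integer_, state = NULL)
  hist <- vector("list", config$epochs)
  since_improve <- 0
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr0 * (1 - (epoch - 1) / max(1, config$epochs) * (1 - config$lrf))
    ord <- with_seed(seed + 1000 * epoch, sample(fold$train))
    tr_loss <- 0; tr_hits <- 0
    for (s in seq(1, n_tr, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1, n_tr)]
      xb <- ds$x[idx, , , , drop = FALSE]
      yb <- ds$y[idx]
      logits <- model_forward(model, xb, training = TRUE)
      ce <- cross_entropy(logits, yb)
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      tr_loss <- tr_loss + ce$loss * length(idx)
      tr_hits <- tr_hits + sum(max.col(logits, ties.method = "first") == yb)
      zero_grads(model)
      nn_backward(model, ce$grad)
      adam_step(model, lr, config$momentum, 0.999, config$weight_decay)
    }
    vl <- predict_logits(model, ds$x[fold$val, , , , drop = FALSE])
    vce <- cross_entropy(vl, ds$y[fold$val])
    val_acc <- mean(max.col(vl, ties.method = "first") == ds$y[fold$val])
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = tr_loss / n_tr,
                                train_acc = tr_hits / n_tr,
                                val_loss = vce$loss, val_acc = val_acc)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, state = module_state(model))
      since_improve <- 0
    } else {
      since_improve <- since_improve + 1
      if (config$patience > 0 && since_improve >= config$patience) break
    }
  }
  module_restore(model, best$state)
  list(model = model, best_epoch = best$epoch, best_val_acc = best$acc,
       history = do.call(rbind, hist))
}

# ---- metrics -----------------------------------------------------------------

#' Classification metrics from predictions and labels
#'
#' One-vs-rest confusion counts per class with the four standard indicators:
#' accuracy `(TP + TN) / (TP + TN + FP + FN)`, precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)` and `F1 = 2 P R / (P + R)` (0 whenever the
#' denominator is 0), plus their macro averages, the overall accuracy and
#' the full confusion matrix (rows = truth, columns = prediction).
#'
#' @param pred predicted class indices (or factor).
#' @param truth true class indices (or factor), same length.
#' @param n_classes number of classes (inferred when missing).
#' @param classes optional class names.
#' @return an object of class `lcga_metrics`.
#' @export
eval_metrics <- function(pred, truth, n_classes = NULL, classes = NULL) {
  if (!length(pred) || length(pred) != length(truth))
    stop("pred and truth must be non-empty vectors of equal length")
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  K <- n_classes %||% max(pred, truth)
  classes <- classes %||% as.character(seq_len(K))
  n <- length(truth)
  conf <- matrix(0L, K, K, dimnames = list(truth = classes, pred = classes))
  for (i in seq_len(n)) conf[truth[i], pred[i]] <- conf[truth[i], pred[i]] + 1L
  tp <- as.integer(diag(conf))
  fp <- as.integer(colSums(conf) - tp)
  fn <- as.integer(rowSums(conf) - tp)
  tn <- as.integer(n - tp - fp - fn)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(class = classes, tp = tp, tn = tn, fp = fp, fn = fn,
                          accuracy = (tp + tn) / n, precision = prec,
                          recall = rec, f1 = f1, stringsAsFactors = FALSE,
                          row.names = NULL)
  structure(list(confusion = conf, per_class = per_class,
                 accuracy = sum(tp) / n,
                 macro = list(accuracy = mean(per_class$accuracy),
                              precision = mean(prec), recall = mean(rec),
                              f1 = mean(f1)),
                 n = n),
            class = "lcga_metrics")
}

#' @export
print.lcga_metrics <- function(x, ...) {
  cat(sprintf("<metrics> n = %d | accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$n, x$accuracy, x$macro$precision, x$macro$recall, x$macro$f1))
  print(x$per_class[, c("class", "precision", "recall", "f1")], digits = 4)
  invisible(x)
}

# ---- nested cross-validation -------------------------------------------------

#' Nested K-fold cross-validation of a model plan
#'
#' Splits the dataset into a held-out test set and `k` folds
#' ([cv_split()]), trains one model per fold ([train_fold()]), evaluates
#' every fold's best-on-validation weights on the *same* held-out test set,
#' and reports per-fold metrics, their mean and population standard
#' deviation, and the representative fold (test accuracy closest to the
#' mean, earliest on ties).
#'
#' @param plan a [stage_plan()].
#' @param ds a dataset.
#' @param config a [train_config()].
#' @param k number of folds.
#' @param seed split / initialisation seed (defaults to the config seed).
#' @return an object of class `lcga_cv_report`.
#' @export
cross_validate <- function(plan, ds, config = train_config(), k = 5,
                           seed = config$seed) {
  split <- cv_split(ds$y, k = k, seed = seed)
  fold_results <- vector("list", k)
  test_x <- ds$x[split$test, , , , drop = FALSE]
  test_y <- ds$y[split$test]
  for (f in seq_len(k)) {
    tr <- train_fold(plan, ds, split$folds[[f]], config, seed = seed + f)
    lg <- predict_logits(tr$model, test_x)
    m <- eval_metrics(max.col(lg, ties.method = "first"), test_y,
                      n_classes = length(ds$classes), classes = ds$classes)
    fold_results[[f]] <- list(metrics = m, best_epoch = tr$best_epoch,
                              best_val_acc = tr$best_val_acc,
                              history = tr$history, model = tr$model)
  }
  metric_of <- function(fr) c(accuracy = fr$metrics$accuracy,
                              precision = fr$metrics$macro$precision,
                              recall = fr$metrics$macro$recall,
                              f1 = fr$metrics$macro$f1)
  mm <- t(vapply(fold_results, metric_of, numeric(4)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  summary <- data.frame(metric = colnames(mm), mean = colMeans(mm),
                        sd = apply(mm, 2, pop_sd), row.names = NULL)
  rep_fold <- which.min(abs(mm[, "accuracy"] - mean(mm[, "accuracy"])))
  structure(list(folds = fold_results, fold_metrics = mm, summary = summary,
                 representative_fold = rep_fold, split = split,
                 config = config, plan = plan, classes = ds$classes),
            class = "lcga_cv_report")
}

#' @export
print.lcga_cv_report <- function(x, ...) {
  cat(sprintf("<cross-validation report> %d folds | test n = %d\n",
              length(x$folds), length(x$split$test)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  representative fold: %d (accuracy %.4f)\n",
              x$representative_fold,
              x$fold_metrics[x$representative_fold, "accuracy"]))
  invisible(x)
}

# representative-fold rule on a bare accuracy vector (exposed for reuse)
representative_fold <- function(acc) {
  which.min(abs(acc - mean(acc)))
}

# ---- class activation heatmap ------------------------------------------------

#' Class-activation heatmap from the final convolutional stage
#'
#' Projects the classifier's final-stage feature maps (pre-pooling head
#' activations) onto the weight vector of the requested class, normalises
#' the map to `[0, 1]`, bilinearly upsamples it to the input size and
#' blends it over the image.
#'
#' @param model a trained model.
#' @param img an `(H, W, 3)` image in `[0, 1]` (or a path).
#' @param class target class index; defaults to the predicted class.
#' @return an `lcga_heatmap`: `list(map, overlay, class_index, logits)` with
#'   `map` an `(H, W)` matrix in `[0, 1]`.
#' @export
activation_heatmap <- function(model, img, class = NULL) {
  img <- as_image(img)
  d <- dim(img)
  x <- array(aperm(img, c(3, 1, 2)), c(1, 3, d[1], d[2]))
  logits <- model_forward(model, x, training = FALSE, keep_features = TRUE)
  feat <- model$children$head$feat
  if (is.null(feat)) stop("no convolutional features captured")
  k <- class %||% which.max(logits[1, ])
  wfc <- model$children$head$children$fc$params$w   # (classes x 1280)
  fd <- dim(feat)
  fm <- matrix(aperm(feat[1, , , , drop = FALSE], c(2, 3, 4, 1)), nrow = fd[2])
  cam <- matrix(as.vector(wfc[k, ] %*% fm), fd[3], fd[4])
  rng <- range(cam)
  map_small <- if (rng[2] - rng[1] < 1e-8) {
    matrix(0.5, fd[3], fd[4])        # degenerate (constant) activation map
  } else (cam - rng[1]) / (rng[2] - rng[1])
  map <- t(EBImage::imageData(EBImage::resize(EBImage::Image(t(map_small)),
                                              w = d[2], h = d[1])))
  map <- clamp01(map)
  heat <- array(0, d)
  heat[, , 1] <- map
  heat[, , 2] <- pmax(0, 1 - 2 * abs(map - 0.5))
  heat[, , 3] <- 1 - map
  overlay <- clamp01(0.5 * img + 0.5 * heat)
  structure(list(map = map, overlay = overlay, class_index = k,
                 logits = logits[1, ]),
            class = "lcga_heatmap")
}
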