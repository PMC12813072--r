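# Nested split, metrics, the training loop and class-activation maps.

test_that("nested stratified split has the contracted sizes and is seed-stable", {
  y <- rep(1:6, each = 50)                  # 300 samples
  sp <- cv_split(y, k = 5, seed = 42)
  expect_identical(length(sp$test), 60L)
  for (f in sp$folds) {
    expect_identical(length(f$train), 192L)
    expect_identical(length(f$val), 48L)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(sp$test, c(f$train, f$val)), 0)
    expect_identical(sort(union(f$train, f$val)), sort(setdiff(seq_along(y), sp$test)))
    # stratification: every class appears in every part
    expect_identical(sort(unique(y[f$val])), 1:6)
  }
  # validation chunks partition the pool across folds
  vals <- unlist(lapply(sp$folds, `[[`, "val"))
  expect_identical(sort(vals), sort(setdiff(seq_along(y), sp$test)))
  expect_identical(cv_split(y, k = 5, seed = 42), sp)
  expect_false(identical(cv_split(y, k = 5, seed = 43)$test, sp$test))
  expect_error(cv_split(rep(1:2, c(50, 5)), k = 5), "too few samples")
})

test_that("metrics reproduce direct confusion-count substitutions", {
  m <- eval_metrics(c(1, 1, 1, 2, 2, 1, 2, 2, 2, 2),
                    c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2), n_classes = 2)
  # class 1: TP=3, FP=1 (pred 1, true 2), FN=2 -> precision .75, recall .6
  expect_equal(m$per_class$precision[1], 0.75)
  expect_equal(m$per_class$recall[1], 0.6)
  expect_equal(m$per_class$f1[1], 2 * 0.75 * 0.6 / 1.35)
  # perfect predictions
  mp <- eval_metrics(1:4, 1:4, n_classes = 4)
  expect_equal(mp$accuracy, 1)
  expect_true(all(mp$per_class$precision == 1 & mp$per_class$recall == 1 &
                    mp$per_class$f1 == 1))
  # all-one-class predictions on a balanced two-class set
  mo <- eval_metrics(rep(1, 10), rep(1:2, 5), n_classes = 2)
  expect_equal(mo$accuracy, 0.5)
  expect_equal(mo$per_class$f1[2], 0)       # P + R = 0 convention
  expect_error(eval_metrics(integer(0), integer(0)), "non-empty")
})

test_that("metrics agree with a brute-force confusion-matrix oracle on 1000 random trials", {
  set.seed(123)
  for (trial in 1:1000) {
    K <- sample(2:5, 1)
    n <- sample(5:40, 1)
    truth <- sample(K, n, replace = TRUE)
    pred <- sample(K, n, replace = TRUE)
    m <- eval_metrics(pred, truth, n_classes = K)
    # oracle: literal double loop over the confusion definition
    for (k in seq_len(K)) {
      tp <- sum(pred == k & truth == k); fp <- sum(pred == k & truth != k)
      fn <- sum(pred != k & truth == k); tn <- sum(pred != k & truth != k)
      expect_identical(m$per_class$tp[k], tp)
      expect_identical(m$per_class$tn[k], tn)
      expect_equal(m$per_class$accuracy[k], (tp + tn) / n)
      expect_equal(m$per_class$precision[k], if (tp + fp > 0) tp / (tp + fp) else 0)
      expect_equal(m$per_class$recall[k], if (tp + fn > 0) tp / (tp + fn) else 0)
      expect_identical(tp + tn + fp + fn, n)
    }
    expect_equal(m$accuracy, mean(pred == truth))
  }
})

test_that("training runs the full epoch budget under patience 0 and is deterministic", {
  ds <- read_image_folder(fixture_2class_dir())
  plan <- tiny_plan()
  cfg <- train_config(image_size = 32, batch_size = 8, epochs = 3, seed = 42)
  fold <- list(train = 1:16, val = 17:20)
  tr1 <- train_fold(plan, ds, fold, cfg)
  expect_identical(nrow(tr1$history), 3L)            # patience 0: all epochs
  expect_true(all(is.finite(tr1$history$train_loss)))
  expect_true(all(diff(cummax(tr1$history$val_acc)) >= 0))
  tr2 <- train_fold(plan, ds, fold, cfg)
  expect_identical(tr1$history$train_loss[1], tr2$history$train_loss[1])
  expect_identical(tr1$history, tr2$history)
  # linear learning-rate decay from lr0 toward lr0 * lrf
  expect_equal(tr1$history$lr[1], cfg$lr0)
  expect_true(all(diff(tr1$history$lr) < 0))
})

test_that("a width-reduced model overfits a small two-class set to train accuracy 1", {
  ds <- read_image_folder(fixture_2class_dir())
  cfg <- train_config(image_size = 32, batch_size = 8, epochs = 40, seed = 42)
  tr <- train_fold(tiny_plan(), ds, list(train = 1:20, val = 1:20), cfg)
  expect_identical(max(tr$history$train_acc), 1)
})

test_that("the representative-fold rule picks the accuracy closest to the mean", {
  expect_identical(leafcga:::representative_fold(c(0.95, 0.96, 0.97, 0.98, 0.99)), 3L)
  expect_identical(leafcga:::representative_fold(c(0.9, 0.9, 1.0, 1.0, 1.0)), 3L)
  expect_equal(mean(c(0.9, 0.9, 1.0, 1.0, 1.0)), 0.96)
  # earliest fold wins ties
  expect_identical(leafcga:::representative_fold(c(0.95, 1.0, 0.9, 1.0)), 1L)
})

test_that("activation heatmaps are normalised, input-sized and symmetry-respecting", {
  model <- build_model(tiny_plan(), seed = 2)
  img <- fixture_image(64)
  hm <- activation_heatmap(model, img)
  expect_identical(dim(hm$map), c(64L, 64L))
  expect_true(all(hm$map >= 0 & hm$map <= 1))
  expect_identical(dim(hm$overlay), dim(img))
  expect_true(hm$class_index %in% 1:2)
  # constant input at the stride-32 resolution: the final feature map is a
  # single spatial cell, so the activation map is exactly constant (the
  # normaliser's degenerate value 0.5); at larger inputs zero-padding reaches
  # every cell of the tiny final grid, so only determinism is contracted
  hc <- activation_heatmap(model, array(0.5, c(32, 32, 3)))
  expect_true(all(hc$map == 0.5))
  hc64a <- activation_heatmap(model, array(0.25, c(64, 64, 3)))
  hc64b <- activation_heatmap(model, array(0.25, c(64, 64, 3)))
  expect_identical(hc64a$map, hc64b$map)
})
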