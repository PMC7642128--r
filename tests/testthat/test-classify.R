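test_that("training is deterministic under a fixed seed", {
  prep <- fixture_separable_prep()
  cfg <- fast_cnn(max_epochs = 5L, seed = 11L)
  m1 <- train(prep, cfg)
  m2 <- train(prep, cfg)
  expect_identical(m1$history$train_loss, m2$history$train_loss)
  expect_identical(m1$history$val_loss, m2$history$val_loss)
  expect_identical(m1$weights, m2$weights)
  m3 <- train(prep, fast_cnn(max_epochs = 5L, seed = 12L))
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("a separable synthetic session is classified accurately", {
  prep <- fixture_separable_prep()
  hold <- holdout_idx(prep)
  tr <- setdiff(seq_len(n_trials(prep)), hold)
  m <- train(subset_epochs(prep, tr), fast_cnn(seed = 2L))
  ev <- evaluate(m, subset_epochs(prep, hold))
  expect_gte(ev$accuracy, 0.9)
  # training-set accuracy is at least as high as held-out (sanity ordering)
  ev_tr <- evaluate(m, subset_epochs(prep, tr))
  expect_gte(ev_tr$accuracy + 0.05, ev$accuracy)
  # confusion matrix rows are the true classes
  expect_equal(rowSums(ev$confusion), c(left = 15, right = 15),
               ignore_attr = TRUE)
})

test_that("the LSTM also learns the separable session", {
  prep <- fixture_separable_prep()
  hold <- holdout_idx(prep)
  cfg <- classifier_config("lstm", max_epochs = 20L,
                           early_stop_patience = 6L, batch_size = 16L,
                           seed = 2L)
  m <- train(subset_epochs(prep, setdiff(seq_len(n_trials(prep)), hold)),
             cfg)
  expect_gte(evaluate(m, subset_epochs(prep, hold))$accuracy, 0.8)
})

test_that("permuting labels destroys the signal: accuracy falls to chance", {
  prep <- fixture_separable_prep()
  set.seed(77)
  prep$labels <- sample(prep$labels)
  hold <- holdout_idx(prep)
  m <- train(subset_epochs(prep, setdiff(seq_len(n_trials(prep)), hold)),
             fast_cnn(max_epochs = 15L, seed = 3L))
  acc <- evaluate(m, subset_epochs(prep, hold))$accuracy
  # binomial 95% interval around 0.5 at n = 30
  expect_gte(acc, 0.5 - 1.96 * sqrt(0.25 / 30))
  expect_lte(acc, 0.5 + 1.96 * sqrt(0.25 / 30))
})

test_that("no information leaks from the evaluation set into training", {
  prep <- fixture_separable_prep()
  hold <- holdout_idx(prep)
  m <- train(subset_epochs(prep, setdiff(seq_len(n_trials(prep)), hold)),
             fast_cnn(max_epochs = 5L, seed = 4L))
  test_set <- subset_epochs(prep, hold)
  p1 <- predict_epochs(m, test_set)
  shuffled <- test_set
  set.seed(1)
  shuffled$labels <- sample(shuffled$labels)
  p2 <- predict_epochs(m, shuffled)
  expect_identical(attr(p1, "prob"), attr(p2, "prob"))
})

test_that("stratified folds are balanced and seeded", {
  labels <- factor(rep(c("left", "right"), each = 140),
                   levels = c("left", "right"))
  f <- mierd:::make_folds(labels, 5L, seed = 9L)
  expect_equal(as.vector(table(f)), rep(56L, 5))           # 280 / 5
  for (k in 1:5)
    expect_equal(as.vector(table(labels[f == k])), c(28L, 28L))
  expect_identical(f, mierd:::make_folds(labels, 5L, seed = 9L))
  expect_error(mierd:::make_folds(labels, 141L, seed = 1L), "smallest class")
})

test_that("cross-validation reports per-fold accuracies reproducibly", {
  prep <- fixture_separable_prep()
  cfg <- fast_cnn(max_epochs = 8L, seed = 5L)
  r1 <- cross_validate(prep, k = 2L, config = cfg)
  r2 <- cross_validate(prep, k = 2L, config = cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_equal(length(r1$fold_accuracies), 2L)
  expect_true(all(r1$fold_accuracies >= 0 & r1$fold_accuracies <= 1))
  expect_equal(r1$mean_accuracy, mean(r1$fold_accuracies))
})

test_that("architecture comparison shares folds across configurations", {
  prep <- fixture_separable_prep()
  configs <- list(cnn = fast_cnn(max_epochs = 8L, seed = 6L),
                  lstm = classifier_config("lstm", max_epochs = 8L,
                                           early_stop_patience = 4L,
                                           batch_size = 16L, seed = 6L))
  cmp <- compare_archs(prep, configs, k = 2L)
  expect_identical(cmp$reports[[1]]$folds, cmp$reports[[2]]$folds)
  expect_equal(cmp$paired_diff[, 1], c(0, 0), ignore_attr = TRUE)
  expect_true(!is.unsorted(rev(cmp$mean_accuracies)))
  cmp2 <- compare_archs(prep, configs, k = 2L)
  expect_identical(cmp$fold_accuracies, cmp2$fold_accuracies)
})

test_that("evaluation on a single-class set reports that class's recall", {
  prep <- fixture_separable_prep()
  hold <- holdout_idx(prep)
  m <- train(subset_epochs(prep, setdiff(seq_len(n_trials(prep)), hold)),
             fast_cnn(max_epochs = 8L, seed = 7L))
  lefts <- subset_epochs(prep, which(prep$labels == "left")[1:15])
  ev <- evaluate(m, lefts)
  expect_equal(ev$accuracy, ev$confusion["left", "left"] / 15)
})

test_that("training preconditions are enforced", {
  prep <- fixture_separable_prep()
  one_class <- subset_epochs(prep, which(prep$labels == "left"))
  expect_error(train(one_class, fast_cnn()), "single class")
  tiny <- subset_epochs(prep, c(which(prep$labels == "left")[1:8],
                                which(prep$labels == "right")[1:8]))
  expect_error(train(tiny, fast_cnn()), "at least 20")
  m <- train(subset_epochs(prep, setdiff(seq_len(n_trials(prep)),
                                         holdout_idx(prep))),
             fast_cnn(max_epochs = 2L, seed = 8L))
  short <- epoch_set(prep$data[1:5, , 1:300], prep$labels[1:5], 100,
                     prep$channel_names, 99L)
  expect_error(predict_epochs(m, short), "length")
  wrong_ch <- epoch_set(prep$data[1:5, 1:4, ], prep$labels[1:5], 100,
                        prep$channel_names[1:4], 100L)
  expect_error(predict_epochs(m, wrong_ch), "channel")
  expect_error(classifier_config(validation_fraction = 0.6),
               "validation_fraction")
  expect_error(classifier_config(n_layers = 2L), "single")
})
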