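#' Classifier configuration
#'
#' Two compact architectures for left/right motor-imagery epochs:
#'
#' * `cnn` — a shallow spectral-spatial convolutional net: temporal
#'   convolution (kernel `temporal_kernel` samples, `n_temporal_filters`
#'   filters, linear), spatial convolution across all channels and temporal
#'   filters (`n_spatial_filters` filters, linear), squaring,
#'   non-overlapping average pooling by `pool_factor`, a log, and a dense
#'   softmax layer. The square-pool-log pipeline makes the features
#'   approximate log band power, the quantity ERD/ERS modulates.
#' * `lstm` — a single recurrent layer of `hidden_units` LSTM cells reading
#'   channels as per-timestep features, mean of the hidden states over time,
#'   dense softmax.
#'
#' Training uses Adam, minibatches, and early stopping on a stratified
#' validation split. Epochs are decimated by `decim` after wavelet band
#' limiting (the retained band ends at 25 Hz, so a factor of 2 at 100 Hz
#' keeps the feature band intact while halving compute).
#'
#' @param arch `"cnn"` or `"lstm"`.
#' @param temporal_kernel,n_temporal_filters,n_spatial_filters,pool_factor
#'   CNN shape parameters (defaults 11, 8, 16, 10). The pooling window sets
#'   the power-integration time: at 50 Hz (after decimation) the default of
#'   10 samples integrates squared conv outputs over 200 ms, long enough for
#'   stable log band-power estimates.
#' @param hidden_units,n_layers LSTM shape parameters (defaults 64, 1; only
#'   single-layer is implemented).
#' @param batch_size,max_epochs,early_stop_patience,learning_rate,
#'   validation_fraction training parameters (defaults 32, 100, 10, 1e-3,
#'   0.2).
#' @param early_stop_min_epochs epochs to run before early stopping may
#'   trigger (default 20; the small validation split is noisy early in
#'   training, and stopping before the loss surface settles strands the run
#'   at an undertrained snapshot).
#' @param decim integer decimation factor applied to the time axis
#'   (default 2).
#' @param seed integer seed controlling initialisation, validation split and
#'   minibatch order.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(arch = c("cnn", "lstm"),
                              temporal_kernel = 11L,
                              n_temporal_filters = 8L,
                              n_spatial_filters = 16L,
                              pool_factor = 10L,
                              hidden_units = 64L,
                              n_layers = 1L,
                              batch_size = 32L,
                              max_epochs = 100L,
                              early_stop_patience = 10L,
                              early_stop_min_epochs = 20L,
                              learning_rate = 1e-3,
                              validation_fraction = 0.2,
                              decim = 2L,
                              seed = 1L) {
  arch <- match.arg(arch)
  counts <- c(temporal_kernel, n_temporal_filters, n_spatial_filters,
              pool_factor, hidden_units, n_layers, batch_size, max_epochs,
              early_stop_patience, early_stop_min_epochs, decim)
  if (any(counts < 1L)) stop("all count parameters must be >= 1",
                             call. = FALSE)
  if (n_layers != 1L) stop("only a single LSTM layer is implemented",
                           call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop("validation_fraction must lie in (0, 0.5)", call. = FALSE)
  structure(list(arch = arch,
                 temporal_kernel = as.integer(temporal_kernel),
                 n_temporal_filters = as.integer(n_temporal_filters),
                 n_spatial_filters = as.integer(n_spatial_filters),
                 pool_factor = as.integer(pool_factor),
                 hidden_units = as.integer(hidden_units),
                 n_layers = as.integer(n_layers),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_min_epochs = as.integer(early_stop_min_epochs),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 decim = as.integer(decim),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# epoch_set -> (channels x time x trials) cube, normalized and decimated.
prepare_input <- function(es, norm, decim) {
  X <- aperm(es$data, c(2L, 3L, 1L))            # channel x sample x trial
  X <- sweep(X, 1L, norm$mean, "-")
  X <- sweep(X, 1L, norm$sd, "/")
  X[, seq(1L, dim(X)[2L], by = decim), , drop = FALSE]
}

# Glorot-uniform initial weights drawn from R's RNG.
glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

stratified_split <- function(labels, fraction) {
  val <- integer(0)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    n_val <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train a motor-imagery classifier
#'
#' Splits off a stratified validation set, z-scores every channel with
#' statistics from the training partition only, and fits the configured
#' architecture with Adam and early stopping on validation loss. All
#' randomness derives from `config$seed`, so training is deterministic
#' (single-threaded numeric kernels; repeated runs give identical losses).
#'
#' @param es_train an [epoch_set()] containing both classes and >= 20 trials.
#' @param config a [classifier_config()].
#' @return A `trained_model` with weights, normalization statistics, and the
#'   training history.
#' @export
train <- function(es_train, config = classifier_config()) {
  stopifnot(inherits(es_train, "epoch_set"),
            inherits(config, "classifier_config"))
  if (nlevels(droplevels(es_train$labels)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  if (n_trials(es_train) < 20L)
    stop("need at least 20 training trials", call. = FALSE)
  set.seed(config$seed)
  y_all <- as.integer(es_train$labels) - 1L      # left = 0, right = 1
  val_idx <- stratified_split(es_train$labels, config$validation_fraction)
  tr_idx <- setdiff(seq_len(n_trials(es_train)), val_idx)

  tr_dat <- es_train$data[tr_idx, , , drop = FALSE]
  norm <- list(mean = apply(tr_dat, 2L, mean),
               sd = pmax(apply(tr_dat, 2L, stats::sd), 1e-12))
  X <- prepare_input(es_train, norm, config$decim)
  Xtr <- X[, , tr_idx, drop = FALSE]
  Xval <- X[, , val_idx, drop = FALSE]
  ytr <- y_all[tr_idx]
  yval <- y_all[val_idx]
  n_tr <- length(tr_idx)
  batch_order <- t(vapply(seq_len(config$max_epochs),
                          function(i) sample.int(n_tr) - 1L,
                          integer(n_tr)))

  C <- dim(X)[1L]
  Tn <- dim(X)[2L]
  if (config$arch == "cnn") {
    k <- config$temporal_kernel
    F1 <- config$n_temporal_filters
    F2 <- config$n_spatial_filters
    T1 <- Tn - k + 1L
    T2 <- T1 %/% config$pool_factor
    if (T1 < config$pool_factor)
      stop("epochs too short for the configured kernel/pool sizes",
           call. = FALSE)
    fit <- cnn_train_cpp(Xtr, ytr, Xval, yval,
                         W1 = glorot(k, F1), b1 = numeric(F1),
                         W2 = glorot(F2, F1 * C), b2 = numeric(F2),
                         W3 = glorot(2L, F2 * T2), b3 = numeric(2L),
                         pool = config$pool_factor,
                         batch_order = batch_order,
                         batch_size = config$batch_size,
                         lr = config$learning_rate,
                         patience = config$early_stop_patience,
                         min_epochs = config$early_stop_min_epochs)
    weights <- fit[c("W1", "b1", "W2", "b2", "W3", "b3")]
  } else {
    H <- config$hidden_units
    fit <- lstm_train_cpp(Xtr, ytr, Xval, yval,
                          Wx = glorot(4L * H, C), Wh = glorot(4L * H, H),
                          b = rep(c(0, 1, 0, 0), each = H),  # forget bias 1
                          Wo = glorot(2L, H), bo = numeric(2L),
                          batch_order = batch_order,
                          batch_size = config$batch_size,
                          lr = config$learning_rate,
                          patience = config$early_stop_patience,
                          min_epochs = config$early_stop_min_epochs)
    weights <- fit[c("Wx", "Wh", "b", "Wo", "bo")]
  }
  structure(list(arch = config$arch, config = config, weights = weights,
                 norm = norm, channel_names = es_train$channel_names,
                 n_samples = n_samples(es_train), fs = es_train$fs,
                 classes = levels(es_train$labels),
                 history = fit[c("train_loss", "val_loss", "best_epoch",
                                 "epochs_run")],
                 config_hash = config_hash(unclass(config))),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s, %d channels x %d samples @ %g Hz\n",
              toupper(x$arch), length(x$channel_names), x$n_samples, x$fs))
  cat(sprintf("  best epoch %d of %d (val loss %.4f)\n",
              x$history$best_epoch, x$history$epochs_run,
              min(x$history$val_loss)))
  invisible(x)
}

#' Class probabilities / predictions for an epoch_set
#'
#' @param model a `trained_model` from [train()].
#' @param es an [epoch_set()] with the same channels and trial length as the
#'   training data.
#' @return `predict_epochs()`: factor of predicted labels with a
#'   `"prob"` attribute (matrix trials x 2).
#' @export
predict_epochs <- function(model, es) {
  stopifnot(inherits(model, "trained_model"), inherits(es, "epoch_set"))
  if (!identical(es$channel_names, model$channel_names))
    stop("channel set does not match the training data", call. = FALSE)
  if (n_samples(es) != model$n_samples)
    stop(sprintf("trial length %d does not match training length %d",
                 n_samples(es), model$n_samples), call. = FALSE)
  X <- prepare_input(es, model$norm, model$config$decim)
  w <- model$weights
  prob <- if (model$arch == "cnn")
    cnn_predict_cpp(X, w$W1, w$b1, w$W2, w$b2, w$W3, w$b3,
                    model$config$pool_factor)
  else
    lstm_predict_cpp(X, w$Wx, w$Wh, w$b, w$Wo, w$bo)
  colnames(prob) <- model$classes
  pred <- factor(model$classes[max.col(prob, ties.method = "first")],
                 levels = model$classes)
  attr(pred, "prob") <- prob
  pred
}

#' Evaluate a trained model on labelled epochs
#'
#' @param model a `trained_model`.
#' @param es_test labelled [epoch_set()].
#' @return List with `accuracy` and `confusion` (rows = true class,
#'   columns = predicted).
#' @export
evaluate <- function(model, es_test) {
  pred <- predict_epochs(model, es_test)
  conf <- table(true = es_test$labels, predicted = pred)
  list(accuracy = mean(pred == es_test$labels), confusion = conf)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds. Returns an integer vector of fold ids.
make_folds <- function(labels, k, seed) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > min(table(labels)))
    stop("k exceeds the size of the smallest class", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Shuffles trials into `k` class-stratified folds (seeded), trains on k-1
#' folds and evaluates on the held-out fold. Fold assignment, weight
#' initialisation and batch order all derive from `config$seed`, so the
#' report is reproducible.
#'
#' @param es a labelled [epoch_set()].
#' @param k number of folds (default 5).
#' @param config a [classifier_config()].
#' @param folds optional precomputed fold assignment (integer vector in
#'   `1..k`), e.g. to share folds across architectures.
#' @return A `cv_report`: `fold_accuracies`, `mean_accuracy`, `std`,
#'   `confusions`, `folds`, `config_hash`, `seed`.
#' @export
cross_validate <- function(es, k = 5L, config = classifier_config(),
                           folds = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  if (is.null(folds)) folds <- make_folds(es$labels, k, config$seed)
  stopifnot(length(folds) == n_trials(es), max(folds) == k)
  acc <- numeric(k)
  confs <- vector("list", k)
  for (f in seq_len(k)) {
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    model <- train(subset_epochs(es, which(folds != f)), cfg_f)
    ev <- evaluate(model, subset_epochs(es, which(folds == f)))
    acc[f] <- ev$accuracy
    confs[[f]] <- ev$confusion
  }
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 std = stats::sd(acc), confusions = confs, folds = folds,
                 k = k, arch = config$arch,
                 config_hash = config_hash(unclass(config)),
                 seed = config$seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold: mean accuracy %.3f (sd %.3f)\n",
              toupper(x$arch), x$k, x$mean_accuracy, x$std))
  cat("  folds:", paste(sprintf("%.3f", x$fold_accuracies), collapse = " "),
      "\n")
  invisible(x)
}

#' Compare classifier architectures on identical folds
#'
#' Runs [cross_validate()] for every configuration on one shared stratified
#' fold assignment and reports per-architecture mean accuracies plus the
#' paired per-fold differences against the first configuration.
#'
#' @param es a labelled [epoch_set()].
#' @param configs named list of [classifier_config()]s (>= 2).
#' @param k number of folds (default 5).
#' @param seed seed for the shared fold assignment (default: seed of the
#'   first config).
#' @return An `arch_comparison`: per-arch `cv_report`s (in decreasing mean
#'   accuracy), `mean_accuracies`, and `paired_diff` matrix of per-fold
#'   differences vs the first config.
#' @export
compare_archs <- function(es, configs, k = 5L, seed = NULL) {
  if (length(configs) < 2L) stop("need at least two configurations",
                                 call. = FALSE)
  if (is.null(names(configs)) || any(names(configs) == ""))
    names(configs) <- vapply(configs, function(cf) cf$arch, "")
  if (is.null(seed)) seed <- configs[[1L]]$seed
  folds <- make_folds(es$labels, k, seed)
  reports <- lapply(configs, function(cf)
    cross_validate(es, k = k, config = cf, folds = folds))
  means <- vapply(reports, function(r) r$mean_accuracy, 0)
  fold_mat <- vapply(reports, function(r) r$fold_accuracies, numeric(k))
  paired <- fold_mat - fold_mat[, 1L]
  structure(list(reports = reports[order(-means)],
                 mean_accuracies = sort(means, decreasing = TRUE),
                 fold_accuracies = fold_mat,
                 paired_diff = paired, folds = folds, seed = seed),
            class = "arch_comparison")
}

#' @export
print.arch_comparison <- function(x, ...) {
  cat("<arch_comparison>\n")
  for (nm in names(x$mean_accuracies))
    cat(sprintf("  %-6s mean accuracy %.3f\n", nm, x$mean_accuracies[[nm]]))
  invisible(x)
}
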