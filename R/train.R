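#' Training configuration
#'
#' Optimization and evaluation protocol: Adam with coupled L2 weight decay,
#' mini-batches of 8, at most 20 epochs, early stopping once test accuracy
#' has not improved for `patience` consecutive epochs, class-balanced loss,
#' and an 80/20 holdout. The split can group by speaker (no speaker appears
#' on both sides; the default) or stratify by clip within class.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay Coupled L2 weight decay coefficient.
#' @param batch_size Mini-batch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Epochs without test-accuracy improvement before stopping.
#' @param use_dropout,use_weight_decay,use_early_stopping Regularization
#'   switches (the ablation study toggles these).
#' @param class_balanced Weight the loss by inverse class frequency?
#' @param train_fraction Fraction of clips assigned to training.
#' @param split_mode `"speaker_grouped"` or `"clip_stratified"`.
#' @param seed Seed for the split, batch shuffling, and dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         batch_size = 8L, max_epochs = 20L, patience = 3L,
                         use_dropout = TRUE, use_weight_decay = TRUE,
                         use_early_stopping = TRUE, class_balanced = TRUE,
                         train_fraction = 0.8,
                         split_mode = c("speaker_grouped", "clip_stratified"),
                         seed = 0L) {
  split_mode <- match.arg(split_mode)
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(
    learning_rate = learning_rate, weight_decay = weight_decay,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    use_dropout = isTRUE(use_dropout),
    use_weight_decay = isTRUE(use_weight_decay),
    use_early_stopping = isTRUE(use_early_stopping),
    class_balanced = isTRUE(class_balanced),
    train_fraction = train_fraction, split_mode = split_mode,
    seed = as.integer(seed)
  ), class = "train_config")
}

#' Speaker-independent (or stratified) train/test split
#'
#' In `speaker_grouped` mode, speakers are shuffled with the config seed and
#' assigned whole to the training side until the training clip count is as
#' close to `train_fraction` of the corpus as speaker granularity allows; no
#' speaker contributes clips to both sides. In `clip_stratified` mode, clips
#' are split at `train_fraction` within each class of `label_col`.
#'
#' @param corpus A corpus table (data frame with `clip_id` and `speaker_id`).
#' @param config A [train_config()].
#' @param label_col Column used for stratification in `clip_stratified` mode.
#' @return List with integer row indices `train` and `test`.
#' @export
split_corpus <- function(corpus, config = train_config(),
                         label_col = "pain") {
  stopifnot(is.data.frame(corpus), nrow(corpus) > 0,
            all(c("clip_id", "speaker_id") %in% names(corpus)))
  n <- nrow(corpus)
  if (config$split_mode == "speaker_grouped") {
    speakers <- unique(corpus$speaker_id)
    if (length(speakers) < 2) {
      stop("speaker_grouped split needs at least 2 speakers", call. = FALSE)
    }
    with_seed(config$seed, {
      ord <- sample(speakers)
      counts <- table(corpus$speaker_id)[ord]
      target <- config$train_fraction * n
      cum <- cumsum(as.numeric(counts))
      # take speakers while the running clip count stays closest to target
      k <- which.min(abs(cum - target))
      k <- max(1L, min(k, length(ord) - 1L))   # both sides non-empty
      train_speakers <- ord[seq_len(k)]
      train_idx <- which(corpus$speaker_id %in% train_speakers)
      list(train = train_idx, test = setdiff(seq_len(n), train_idx))
    })
  } else {
    stopifnot(label_col %in% names(corpus))
    with_seed(config$seed, {
      train_idx <- integer(0)
      for (cls in unique(corpus[[label_col]])) {
        rows <- which(corpus[[label_col]] == cls)
        n_tr <- round(config$train_fraction * length(rows))
        train_idx <- c(train_idx, sample(rows, n_tr))
      }
      train_idx <- sort(train_idx)
      list(train = train_idx, test = setdiff(seq_len(n), train_idx))
    })
  }
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (n_classes * N_c)`: weights average to 1 on balanced
#' data, and the weighted class counts always sum to `N_total`.
#'
#' @param labels Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return Numeric weight vector of length `n_classes`.
#' @export
class_weights <- function(labels, n_classes) {
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0)) {
    stop("every class must be present to compute class weights; empty: ",
         paste(which(counts == 0), collapse = ", "), call. = FALSE)
  }
  length(labels) / (n_classes * counts)
}

#' Class-weighted cross-entropy
#'
#' For one item, `-w_y * log(p_y)` where `y` is the true class; for a batch
#' (matrix of probability rows), the mean over items. Probabilities are
#' floored at 1e-12 before the log.
#'
#' @param probabilities Simplex vector, or matrix with one simplex per row.
#' @param y_onehot One-hot vector, or matrix matching `probabilities`.
#' @param weights Per-class weight vector (default all 1).
#' @return Non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, y_onehot, weights = NULL) {
  if (!is.matrix(probabilities)) probabilities <- matrix(probabilities, 1)
  if (!is.matrix(y_onehot)) y_onehot <- matrix(y_onehot, 1)
  stopifnot(all(dim(probabilities) == dim(y_onehot)))
  if (is.null(weights)) weights <- rep(1, ncol(probabilities))
  y <- max.col(y_onehot, ties.method = "first")
  p <- probabilities[cbind(seq_len(nrow(probabilities)), y)]
  if (any(p < 1e-12)) {
    warning("probability at true class below 1e-12; clamped", call. = FALSE)
    p <- pmax(p, 1e-12)
  }
  mean(-weights[y] * log(p))
}

# Pure early-stopping rule: given the test accuracies seen so far, stop when
# the latest `patience` epochs all failed to exceed the running best from
# before them.
.should_stop <- function(test_accs, patience) {
  n <- length(test_accs)
  if (n <= patience) return(FALSE)
  # an improvement strictly exceeds the best of all earlier epochs
  improved <- test_accs > cummax(c(-Inf, test_accs[-n]))
  (n - max(which(improved))) >= patience
}

#' Predict labels for a list of feature matrices
#'
#' Batched evaluation-mode forward pass.
#'
#' @param params A [model_init()] parameter set.
#' @param feats List of `T x input_size` matrices.
#' @param batch_size Mini-batch size for the forward passes.
#' @return List with `labels` (integer) and `probabilities` (matrix, one row
#'   per clip).
#' @export
predict_labels <- function(params, feats, batch_size = 8L) {
  n <- length(feats)
  probs <- matrix(NA_real_, n, params$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- .model_forward_batch(feats[idx], params, training = FALSE)
    p <- exp(out$logits - apply(out$logits, 1, max))
    probs[idx, ] <- p / rowSums(p)
  }
  list(labels = max.col(probs, ties.method = "first"), probabilities = probs)
}

#' Train the sequence classifier
#'
#' Runs the full optimization protocol: seeded mini-batch shuffling, Adam
#' with coupled L2 weight decay (when enabled), class-balanced softmax
#' cross-entropy, per-epoch test evaluation, early stopping on test accuracy,
#' and best-epoch checkpoint selection (the returned parameters are those of
#' the epoch with the highest test accuracy). Monitoring test accuracy for
#' stopping and selection follows the protocol being modeled; pass a held-out
#' validation set as `test` if unbiased test estimates are needed.
#'
#' @param params Initial [model_init()] parameters.
#' @param train,test Datasets: lists with `x` (list of `T x F` feature
#'   matrices) and `y` (integer labels in `1..n_classes`).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return List with `params` (best epoch), `history` (data frame of
#'   per-epoch train/test loss and accuracy), `best_epoch`,
#'   `best_test_accuracy`.
#' @export
train_model <- function(params, train, test, config = train_config(),
                        verbose = FALSE) {
  stopifnot(length(train$x) > 0, length(test$x) > 0,
            length(train$x) == length(train$y),
            length(test$x) == length(test$y))
  n_classes <- params$config$n_classes
  weights <- if (config$class_balanced) {
    class_weights(train$y, n_classes)
  } else {
    rep(1, n_classes)
  }
  wd <- if (config$use_weight_decay) config$weight_decay else 0
  if (!config$use_dropout) params$config$dropout_p <- 0

  theta <- .trainable(params)
  opt <- .adam_init(theta)
  n_train <- length(train$x)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_accuracy = numeric(), test_loss = numeric(),
                        test_accuracy = numeric())
  best <- list(acc = -Inf, epoch = 0L, theta = theta)

  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n_train)
    ep_loss <- 0
    n_correct <- 0
    for (start in seq(1, n_train, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n_train)]
      params_cur <- .set_trainable(params, theta)
      fwd <- .model_forward_batch(train$x[idx], params_cur, training = TRUE,
                                  keep_cache = TRUE)
      ld <- .loss_and_dlogits(fwd$logits, train$y[idx], weights)
      if (!is.finite(ld$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; aborting", call. = FALSE)
      }
      grads <- .model_backward_batch(params_cur, fwd$cache, ld$dlogits)
      step <- .adam_step(theta, grads, opt, lr = config$learning_rate,
                         weight_decay = wd)
      theta <- step$theta
      opt <- step$state
      ep_loss <- ep_loss + ld$loss * length(idx)
      n_correct <- n_correct +
        sum(max.col(fwd$logits, ties.method = "first") == train$y[idx])
    }
    params_cur <- .set_trainable(params, theta)
    ev <- .evaluate_split(params_cur, test, weights, config$batch_size)
    history <- rbind(history, data.frame(
      epoch = epoch,
      train_loss = ep_loss / n_train,
      train_accuracy = n_correct / n_train,
      test_loss = ev$loss,
      test_accuracy = ev$accuracy
    ))
    if (ev$accuracy > best$acc) {
      best <- list(acc = ev$accuracy, epoch = epoch, theta = theta)
    }
    if (verbose) {
      message(sprintf(
        "epoch %2d  train loss %.4f acc %.4f | test loss %.4f acc %.4f%s",
        epoch, ep_loss / n_train, n_correct / n_train, ev$loss, ev$accuracy,
        if (epoch == best$epoch) "  *" else ""))
    }
    if (config$use_early_stopping &&
        .should_stop(history$test_accuracy, config$patience)) {
      break
    }
  }
  list(
    params = .set_trainable(params, best$theta),
    history = history,
    best_epoch = best$epoch,
    best_test_accuracy = best$acc
  )
}

.evaluate_split <- function(params, dataset, weights, batch_size) {
  n <- length(dataset$x)
  loss <- 0
  correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- .model_forward_batch(dataset$x[idx], params, training = FALSE)
    ld <- .loss_and_dlogits(out$logits, dataset$y[idx], weights)
    loss <- loss + ld$loss * length(idx)
    correct <- correct +
      sum(max.col(out$logits, ties.method = "first") == dataset$y[idx])
  }
  list(loss = loss / n, accuracy = correct / n)
}

#' Regularization ablation runner
#'
#' Trains six variants of the binary pain classifier that differ only in
#' which regularization mechanisms are active: the full model; without
#' dropout; without weight decay; without early stopping; without dropout and
#' weight decay; and a plain GRU with none of the three. All runs share the
#' same seed, learning rate, batch size, split, and initial weights. Clip
#' stratification (rather than speaker grouping) is used so class balance is
#' preserved across the split.
#'
#' @param corpus A corpus table (see [synth_corpus()] / [read_corpus()]).
#' @param config Base [train_config()].
#' @param model_cfg A [model_config()] (binary head).
#' @param preproc,spec Feature-extraction configs.
#' @param feats Optional precomputed feature list (bypasses audio loading).
#' @return Data frame with one row per configuration: the three flags,
#'   accuracy, and macro plus pain-class precision/recall/F1.
#' @export
run_ablation <- function(corpus, config = train_config(split_mode = "clip_stratified"),
                         model_cfg = model_config(),
                         preproc = preproc_config(),
                         spec = spectrogram_config(), feats = NULL) {
  variants <- list(
    list(name = "Full Model",                   d = TRUE,  w = TRUE,  e = TRUE),
    list(name = "No Dropout",                   d = FALSE, w = TRUE,  e = TRUE),
    list(name = "No Weight Decay",              d = TRUE,  w = FALSE, e = TRUE),
    list(name = "No Early Stopping",            d = TRUE,  w = TRUE,  e = FALSE),
    list(name = "No Dropout + No Weight Decay", d = FALSE, w = FALSE, e = TRUE),
    list(name = "GRU Only",                     d = FALSE, w = FALSE, e = FALSE)
  )
  task <- task_spec("pain_binary")
  ds <- select_task(corpus, task)
  if (is.null(feats)) feats <- corpus_features(ds$corpus, preproc, spec)
  split <- split_corpus(ds$corpus, config, label_col = "pain")

  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$use_dropout <- v$d
    cfg$use_weight_decay <- v$w
    cfg$use_early_stopping <- v$e
    params <- model_init(model_cfg, seed = config$seed)
    fit <- train_model(params,
                       train = list(x = feats[split$train],
                                    y = ds$labels[split$train]),
                       test = list(x = feats[split$test],
                                   y = ds$labels[split$test]),
                       config = cfg)
    pred <- predict_labels(fit$params, feats[split$test], cfg$batch_size)
    cm <- confusion_matrix(task$class_names[ds$labels[split$test]],
                           task$class_names[pred$labels],
                           task$class_names)
    rep <- metrics_report(cm)
    data.frame(
      model = v$name,
      use_dropout = v$d, use_weight_decay = v$w, use_early_stopping = v$e,
      accuracy = rep$accuracy,
      precision_macro = rep$macro$precision,
      recall_macro = rep$macro$recall,
      f1_macro = rep$macro$f1,
      precision_pain = rep$per_class$precision["pain"],
      recall_pain = rep$per_class$recall["pain"],
      f1_pain = rep$per_class$f1["pain"],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
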