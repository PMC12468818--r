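#' Train and evaluate one task end-to-end
#'
#' Convenience wrapper over the whole pipeline: select the task's clips,
#' extract Log-Mel features, split (speaker-grouped by default), compute
#' class weights, initialize the model, train with the full protocol, and
#' evaluate the best checkpoint on the test side.
#'
#' @param corpus A corpus data frame ([read_corpus()] / [synth_corpus()]).
#' @param task A [task_spec()] or task name string.
#' @param train_cfg A [train_config()].
#' @param model_cfg A [model_config()]; its `n_classes` is set from the task.
#' @param preproc,spec Feature-extraction configs.
#' @param feats Optional precomputed features for `corpus` rows (after task
#'   filtering they are subset accordingly), bypassing audio loading.
#' @param verbose Print epoch progress?
#' @return List with `fit` (see [train_model()]), `split`, `dataset`,
#'   `report` ([metrics_report()]), `cm`, `task`.
#' @export
train_task <- function(corpus, task = "pain_binary",
                       train_cfg = train_config(),
                       model_cfg = model_config(),
                       preproc = preproc_config(),
                       spec = spectrogram_config(),
                       feats = NULL, verbose = FALSE) {
  if (is.character(task)) task <- task_spec(task)
  ds <- select_task(corpus, task)
  if (is.null(feats)) {
    feats <- corpus_features(ds$corpus, preproc, spec)
  } else if (length(feats) == nrow(corpus) && nrow(ds$corpus) < nrow(corpus)) {
    feats <- feats[match(ds$corpus$clip_id, corpus$clip_id)]
  }
  model_cfg$n_classes <- task$n_classes
  if (model_cfg$input_size != spec$n_mels) {
    stop("model input_size must equal the number of Mel bands", call. = FALSE)
  }
  split <- split_corpus(ds$corpus, train_cfg, label_col = task$label_col)
  params <- model_init(model_cfg, seed = train_cfg$seed)
  fit <- train_model(params,
                     train = list(x = feats[split$train],
                                  y = ds$labels[split$train]),
                     test = list(x = feats[split$test],
                                 y = ds$labels[split$test]),
                     config = train_cfg, verbose = verbose)
  pred <- predict_labels(fit$params, feats[split$test], train_cfg$batch_size)
  cm <- confusion_matrix(task$class_names[ds$labels[split$test]],
                         task$class_names[pred$labels], task$class_names)
  list(fit = fit, split = split, dataset = ds,
       report = metrics_report(cm), cm = cm, task = task)
}
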