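#' Read and validate a corpus metadata table
#'
#' Expects a CSV with columns `clip_id, speaker_id, pain, intensity, thermal,
#' duration, path` (the format written by [synth_corpus()]). Validates the
#' label invariants: `intensity == "none"` exactly for non-pain clips, known
#' thermal levels, unique clip ids, and (optionally) that every referenced
#' audio file exists.
#'
#' @param metadata_path Path to the metadata CSV.
#' @param check_files Verify that each `path` exists?
#' @return The validated corpus data frame.
#' @export
read_corpus <- function(metadata_path, check_files = TRUE) {
  if (!file.exists(metadata_path)) {
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  }
  corpus <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (nrow(corpus) == 0) stop("empty corpus: ", metadata_path, call. = FALSE)
  required <- c("clip_id", "speaker_id", "pain", "intensity", "thermal",
                "duration", "path")
  missing <- setdiff(required, names(corpus))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # audio paths are stored relative to the metadata file's directory or
  # absolute; resolve relative ones
  rel <- !file.exists(corpus$path)
  corpus$path[rel] <- file.path(dirname(metadata_path),
                                basename(corpus$path[rel]))
  .validate_corpus(corpus, check_files = check_files)
  corpus
}

.validate_corpus <- function(corpus, check_files = TRUE) {
  if (anyDuplicated(corpus$clip_id)) {
    stop("duplicate clip_id(s): ",
         paste(unique(corpus$clip_id[duplicated(corpus$clip_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_pain <- !corpus$pain %in% c("non-pain", "pain")
  if (any(bad_pain)) {
    stop("unknown pain label(s): ",
         paste(unique(corpus$pain[bad_pain]), collapse = ", "), call. = FALSE)
  }
  bad_int <- !corpus$intensity %in% .intensity_levels
  if (any(bad_int)) {
    stop("unknown intensity label(s): ",
         paste(unique(corpus$intensity[bad_int]), collapse = ", "),
         call. = FALSE)
  }
  mism <- xor(corpus$pain == "non-pain", corpus$intensity == "none")
  if (any(mism)) {
    stop("label invariant violated (intensity must be 'none' exactly for ",
         "non-pain clips) for clip(s): ",
         paste(utils::head(corpus$clip_id[mism], 5), collapse = ", "),
         call. = FALSE)
  }
  bad_th <- !corpus$thermal %in% .thermal_levels
  if (any(bad_th)) {
    stop("unknown thermal label(s): ",
         paste(unique(corpus$thermal[bad_th]), collapse = ", "),
         call. = FALSE)
  }
  if (check_files) {
    gone <- !file.exists(corpus$path)
    if (any(gone)) {
      stop("missing audio file(s): ",
           paste(utils::head(corpus$path[gone], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(corpus)
}

#' Classification task specification
#'
#' The three supervised tasks over a corpus: `pain_binary`
#' (non-pain/pain, all clips), `thermal_binary` (cold/warm, all clips),
#' and `intensity_3class` (mild/moderate/severe, pain clips only). Integer
#' labels follow the order of `class_names`.
#'
#' @param task One of `"pain_binary"`, `"thermal_binary"`,
#'   `"intensity_3class"`.
#' @return A `task_spec` list with `task`, `class_names`, `label_col`,
#'   `n_classes`.
#' @export
task_spec <- function(task = c("pain_binary", "thermal_binary",
                               "intensity_3class")) {
  task <- match.arg(task)
  spec <- switch(task,
    pain_binary = list(class_names = c("non-pain", "pain"),
                       label_col = "pain"),
    thermal_binary = list(class_names = c("cold", "warm"),
                          label_col = "thermal"),
    intensity_3class = list(class_names = c("mild", "moderate", "severe"),
                            label_col = "intensity")
  )
  structure(c(list(task = task), spec,
              list(n_classes = length(spec$class_names))),
            class = "task_spec")
}

#' Select and encode a task's dataset from a corpus
#'
#' Applies the task's clip filter (the intensity task keeps only pain clips)
#' and maps labels to integers `1..n_classes` following the task's class
#' order.
#'
#' @param corpus A corpus data frame.
#' @param spec A [task_spec()].
#' @return List with `corpus` (filtered rows), `labels` (integer vector),
#'   and `spec`.
#' @export
select_task <- function(corpus, spec = task_spec()) {
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  if (spec$task == "intensity_3class") {
    corpus <- corpus[corpus$pain == "pain", , drop = FALSE]
  }
  labels <- match(corpus[[spec$label_col]], spec$class_names)
  present <- sort(unique(labels))
  if (length(present) < spec$n_classes) {
    stop("class(es) absent after filtering: ",
         paste(spec$class_names[setdiff(seq_len(spec$n_classes), present)],
               collapse = ", "), call. = FALSE)
  }
  list(corpus = corpus, labels = labels, spec = spec)
}

#' Extract Log-Mel features for every clip of a corpus
#'
#' Reads, standardizes, and featurizes each clip.
#'
#' @param corpus A corpus data frame with a `path` column.
#' @param preproc A [preproc_config()].
#' @param spec A [spectrogram_config()].
#' @return List of `T x n_mels` matrices, one per corpus row.
#' @export
corpus_features <- function(corpus, preproc = preproc_config(),
                            spec = spectrogram_config()) {
  lapply(corpus$path, function(p) {
    logmel(preprocess(read_wav(p), preproc), spec)$values
  })
}

#' Cache corpus features on disk
#'
#' Stores the feature matrices in one container file with a JSON sidecar
#' recording the spectrogram configuration, so stale caches can be detected.
#'
#' @param feats Output of [corpus_features()].
#' @param corpus The corpus the features belong to.
#' @param spec The [spectrogram_config()] used.
#' @param path Output path (an `.rds` container; `<path>.json` sidecar).
#' @return `path`, invisibly.
#' @export
write_feature_cache <- function(feats, corpus, spec, path) {
  names(feats) <- corpus$clip_id
  saveRDS(feats, path)
  jsonlite::write_json(list(
    n_clips = length(feats),
    config = unclass(spec)
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Adapter for a local copy of a clinical pain-speech corpus
#'
#' Maps an externally collected cold-pressor pain-speech dataset onto the
#' package's corpus schema. The expected layout is a root directory holding
#' `metadata.csv` with columns `file` (audio path relative to root),
#' `subject_id`, `pain_binary` (`yes`/`no` or `pain`/`non-pain`),
#' `pain_level` (`mild`/`moderate`/`severe`, empty for non-pain), and
#' `temperature` (`cold`/`warm`), plus an optional `quality` column
#' (0 = clean .. 4 = highly corrupted). Rows without a pain label are
#' dropped. No quality filter is applied by default; pass `max_quality` to
#' exclude corrupted clips.
#'
#' @param root Directory holding the corpus.
#' @param max_quality Optional maximum quality rating to keep.
#' @return A validated corpus data frame in the package schema.
#' @export
tame_adapter <- function(root, max_quality = NULL) {
  if (!dir.exists(root)) stop("corpus root not found: ", root, call. = FALSE)
  meta_path <- file.path(root, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("schema mismatch: expected ", meta_path, call. = FALSE)
  }
  raw <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  expected <- c("file", "subject_id", "pain_binary", "pain_level",
                "temperature")
  missing <- setdiff(expected, names(raw))
  if (length(missing) > 0) {
    stop("schema mismatch: metadata lacks column(s) ",
         paste(missing, collapse = ", "),
         "; expected columns: ", paste(expected, collapse = ", "),
         call. = FALSE)
  }
  has_pain <- !is.na(raw$pain_binary) & nzchar(trimws(raw$pain_binary))
  raw <- raw[has_pain, , drop = FALSE]
  if (!is.null(max_quality) && "quality" %in% names(raw)) {
    raw <- raw[raw$quality <= max_quality, , drop = FALSE]
  }
  pain <- ifelse(tolower(raw$pain_binary) %in% c("yes", "pain", "1", "true"),
                 "pain", "non-pain")
  intensity <- tolower(trimws(raw$pain_level))
  intensity[pain == "non-pain"] <- "none"
  corpus <- data.frame(
    clip_id = tools::file_path_sans_ext(basename(raw$file)),
    speaker_id = as.character(raw$subject_id),
    pain = pain,
    intensity = intensity,
    thermal = tolower(trimws(raw$temperature)),
    duration = NA_real_,
    path = file.path(root, raw$file),
    stringsAsFactors = FALSE
  )
  .validate_corpus(corpus, check_files = TRUE)
  corpus
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the full parameter set together with the model,
#' preprocessing, and spectrogram configurations and a format version;
#' loading restores everything bit-exactly.
#'
#' @param params A [model_init()] (or trained) parameter set.
#' @param path Checkpoint file path.
#' @param preproc,spec The feature configs the model was trained with.
#' @param extra Optional named list of additional metadata.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, path, preproc = preproc_config(),
                            spec = spectrogram_config(), extra = list()) {
  saveRDS(list(format_version = 1L, params = params, preproc = preproc,
               spec = spec, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L) {
    stop("unsupported checkpoint format: ", path, call. = FALSE)
  }
  ck
}
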