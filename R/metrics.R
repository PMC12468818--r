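#' Confusion matrix
#'
#' Counts with rows indexed by true class and columns by predicted class, in
#' the order given by `class_names`.
#'
#' @param truth,predicted Label vectors (character or factor) over
#'   `class_names`.
#' @param class_names Ordered class labels.
#' @return An object of class `confusion` wrapping the `K x K` integer count
#'   matrix (accessible as `$counts`) and `class_names`.
#' @export
confusion_matrix <- function(truth, predicted, class_names) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), class_names)
  if (length(bad) > 0) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(truth, levels = class_names),
                  factor(predicted, levels = class_names))
  counts <- matrix(as.integer(counts), nrow = length(class_names),
                   dimnames = list(true = class_names,
                                   predicted = class_names))
  as_confusion(counts, class_names)
}

#' @rdname confusion_matrix
#' @param counts A `K x K` non-negative integer matrix (rows = truth).
#' @export
as_confusion <- function(counts, class_names = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0)) {
    stop("counts must be a square non-negative matrix", call. = FALSE)
  }
  dimnames(counts) <- list(true = class_names, predicted = class_names)
  structure(list(counts = counts, class_names = class_names),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' Precision / recall / F1 / accuracy report
#'
#' Per-class precision (`TP / (TP + FP)`), recall (`TP / (TP + FN)`) and F1
#' (their harmonic mean), plus macro (unweighted class mean) and
#' support-weighted averages, and overall accuracy (`trace / total`). A class
#' that is never predicted gets precision 0 and is flagged in
#' `$zero_division`. All values are kept at double precision; rounding to 4
#' decimals happens only in [render_report()].
#'
#' @param cm A [confusion_matrix()] (or square count matrix).
#' @return An object of class `metrics_report`: list with `per_class`
#'   (`precision`, `recall`, `f1`, named by class), `macro`, `weighted`,
#'   `accuracy`, `supports`, `zero_division`.
#' @export
metrics_report <- function(cm) {
  if (!inherits(cm, "confusion")) cm <- as_confusion(cm)
  m <- cm$counts
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  col_tot <- colSums(m)
  row_tot <- rowSums(m)
  zero_div <- col_tot == 0
  precision <- ifelse(zero_div, 0, tp / pmax(col_tot, 1))
  recall <- ifelse(row_tot == 0, 0, tp / pmax(row_tot, 1))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  names(precision) <- names(recall) <- names(f1) <- cm$class_names
  supports <- row_tot
  wavg <- function(v) sum(v * supports) / total
  structure(list(
    per_class = list(precision = precision, recall = recall, f1 = f1),
    macro = list(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
    weighted = list(precision = wavg(precision), recall = wavg(recall),
                    f1 = wavg(f1)),
    accuracy = sum(tp) / total,
    supports = supports,
    zero_division = cm$class_names[zero_div]
  ), class = "metrics_report")
}

#' Render a metrics report as a fixed-layout text table
#'
#' Rows in fixed order: one per class, then `Macro Avg.`, `Weighted Avg.`,
#' and `Accuracy`; all values formatted to 4 decimals (half-even).
#'
#' @param report A [metrics_report()].
#' @return A single character string (lines separated by newlines).
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  fmt <- function(x) formatC(round(x, 4), format = "f", digits = 4)
  classes <- names(report$per_class$precision)
  width <- max(nchar(c(classes, "Weighted Avg.", "Accuracy"))) + 2
  line <- function(name, p, r, f) {
    sprintf("%-*s%s  %s  %s", width, name, fmt(p), fmt(r), fmt(f))
  }
  rows <- c(
    sprintf("%-*s%s", width, "Class", "Precision  Recall  F1-Score"),
    vapply(classes, function(cl) {
      line(cl, report$per_class$precision[cl], report$per_class$recall[cl],
           report$per_class$f1[cl])
    }, character(1)),
    line("Macro Avg.", report$macro$precision, report$macro$recall,
         report$macro$f1),
    line("Weighted Avg.", report$weighted$precision, report$weighted$recall,
         report$weighted$f1),
    sprintf("%-*s%s", width, "Accuracy", fmt(report$accuracy))
  )
  paste(rows, collapse = "\n")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(render_report(x), "\n")
  invisible(x)
}

# Parse the output of render_report() back to its numbers; used to check
# that rendering is a fixed point under round-tripping.
.parse_report <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  body <- lines[-1]
  parse_row <- function(ln) {
    parts <- strsplit(trimws(ln), "\\s{2,}")[[1]]
    list(name = parts[1], values = as.numeric(parts[-1]))
  }
  lapply(body, parse_row)
}

#' Write a metrics report and confusion matrix to disk
#'
#' The report goes to JSON (per-class and aggregate fields), the confusion
#' matrix to CSV, and the rendered table to plain text.
#'
#' @param report A [metrics_report()].
#' @param cm The matching [confusion_matrix()].
#' @param path_prefix Output path prefix; writes `<prefix>.json`,
#'   `<prefix>_confusion.csv`, `<prefix>.txt`.
#' @return Invisibly, the JSON path.
#' @export
write_metrics <- function(report, cm, path_prefix) {
  json_path <- paste0(path_prefix, ".json")
  jsonlite::write_json(list(
    per_class = lapply(report$per_class, as.list),
    macro = report$macro,
    weighted = report$weighted,
    accuracy = report$accuracy,
    supports = as.list(report$supports)
  ), json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(cm$counts), paste0(path_prefix, "_confusion.csv"))
  writeLines(render_report(report), paste0(path_prefix, ".txt"))
  invisible(json_path)
}
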