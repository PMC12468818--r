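test_that("confusion matrix counts by true row and predicted column", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                         c("a", "b"))
  expect_equal(unname(cm$counts), rbind(c(1, 1), c(0, 2)))
  expect_equal(sum(cm$counts), 4)

  perfect <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"),
                              c("a", "b", "c"))
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  expect_true(all(perfect$counts[lower.tri(perfect$counts)] == 0))

  expect_error(confusion_matrix("a", "z", c("a", "b")), "unknown label")
  expect_error(confusion_matrix(c("a", "a"), "a", c("a", "b")), "length")
})

test_that("binary pain worked example reproduces the published table", {
  cm <- as_confusion(rbind(c(740, 94), c(130, 424)), c("non-pain", "pain"))
  rep <- metrics_report(cm)
  expect_equal(round(rep$per_class$precision[["pain"]], 4), 0.8185)
  expect_equal(round(rep$per_class$recall[["pain"]], 4), 0.7653)
  expect_equal(round(rep$per_class$f1[["pain"]], 4), 0.7910)
  expect_equal(round(rep$per_class$precision[["non-pain"]], 4), 0.8506)
  expect_equal(round(rep$per_class$recall[["non-pain"]], 4), 0.8873)
  expect_equal(round(rep$per_class$f1[["non-pain"]], 4), 0.8685)
  expect_equal(round(rep$macro$f1, 4), 0.8298)
  expect_equal(round(rep$weighted$f1, 4), 0.8376)
  expect_equal(round(rep$accuracy, 4), 0.8386)
})

test_that("thermal worked example reproduces the published table", {
  cm <- as_confusion(rbind(c(534, 124), c(62, 689)), c("cold", "warm"))
  rep <- metrics_report(cm)
  expect_equal(round(rep$per_class$precision[["cold"]], 4), 0.8960)
  expect_equal(round(rep$per_class$recall[["cold"]], 4), 0.8116)
  expect_equal(round(rep$per_class$f1[["cold"]], 4), 0.8517)
  expect_equal(round(rep$per_class$recall[["warm"]], 4), 0.9174)
  expect_equal(round(rep$accuracy, 4), 0.8680)
})

test_that("three-class intensity worked example reproduces the published table", {
  # diagonals and row totals as published; remaining cells fixed by the
  # printed off-diagonals (112, 64) and row sums
  cm <- as_confusion(rbind(c(757, 61, 16),
                           c(112, 189, 33),
                           c(56, 64, 100)),
                     c("mild", "moderate", "severe"))
  rep <- metrics_report(cm)
  expect_equal(round(rep$per_class$recall[["mild"]], 4), 0.9077)
  expect_equal(round(rep$per_class$precision[["mild"]], 4), 0.8184)
  expect_equal(round(rep$per_class$f1[["mild"]], 4), 0.8607)
  expect_equal(round(rep$per_class$f1[["moderate"]], 4), 0.5833)
  expect_equal(round(rep$per_class$f1[["severe"]], 4), 0.5420)
  expect_equal(round(rep$macro$f1, 4), 0.6620)
  expect_equal(round(rep$accuracy, 4), 0.7536)
})

test_that("identity matrix gives all-ones metrics and zero-division is flagged", {
  rep <- metrics_report(as_confusion(diag(c(5, 5)), c("a", "b")))
  expect_equal(rep$accuracy, 1)
  expect_equal(unname(rep$per_class$f1), c(1, 1))
  expect_length(rep$zero_division, 0)

  # class never predicted: precision 0, flagged
  cm <- as_confusion(rbind(c(5, 0), c(3, 0)), c("a", "b"))
  rep2 <- metrics_report(cm)
  expect_equal(unname(rep2$per_class$precision[["b"]]), 0)
  expect_equal(rep2$zero_division, "b")

  expect_error(metrics_report(as_confusion(matrix(0, 2, 2), c("a", "b"))),
               "empty")
})

test_that("weighted recall equals accuracy and macro F1 is bracketed", {
  set.seed(50)
  for (rep_i in 1:25) {
    K <- sample(2:4, 1)
    n <- 60
    truth <- sample(letters[1:K], n, replace = TRUE)
    pred <- sample(letters[1:K], n, replace = TRUE)
    # ensure every class occurs as truth
    truth[1:K] <- letters[1:K]
    r <- metrics_report(confusion_matrix(truth, pred, letters[1:K]))
    expect_equal(r$weighted$recall, r$accuracy, tolerance = 1e-12)
    expect_gte(max(r$per_class$f1) + 1e-12, r$macro$f1)
    expect_lte(min(r$per_class$f1) - 1e-12, r$macro$f1)
  }
})

test_that("metrics are permutation-consistent", {
  set.seed(51)
  truth <- sample(c("a", "b", "c"), 90, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 90, replace = TRUE)
  r1 <- metrics_report(confusion_matrix(truth, pred, c("a", "b", "c")))
  r2 <- metrics_report(confusion_matrix(truth, pred, c("c", "a", "b")))
  for (f in c("precision", "recall", "f1")) {
    expect_equal(r1$per_class[[f]][c("c", "a", "b")], r2$per_class[[f]])
  }
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$macro$f1, r2$macro$f1)
})

test_that("metrics agree with an independent reference implementation", {
  set.seed(52)
  for (rep_i in 1:100) {
    n <- 40
    truth <- factor(sample(c("a", "b"), n, replace = TRUE),
                    levels = c("a", "b"))
    pred <- factor(sample(c("a", "b"), n, replace = TRUE),
                   levels = c("a", "b"))
    truth[1:2] <- c("a", "b")
    r <- metrics_report(confusion_matrix(as.character(truth),
                                         as.character(pred), c("a", "b")))
    ref <- caret::confusionMatrix(pred, truth, positive = "a",
                                  mode = "prec_recall")
    if (!is.na(ref$byClass[["Precision"]])) {
      expect_equal(unname(r$per_class$precision[["a"]]),
                   unname(ref$byClass[["Precision"]]), tolerance = 1e-12)
    }
    expect_equal(unname(r$per_class$recall[["a"]]),
                 unname(ref$byClass[["Recall"]]), tolerance = 1e-12)
    expect_equal(unname(r$accuracy), unname(ref$overall[["Accuracy"]]),
                 tolerance = 1e-12)
  }
})

test_that("rendered report is stable under render-parse-render", {
  cm <- as_confusion(rbind(c(740, 94), c(130, 424)), c("non-pain", "pain"))
  rep <- metrics_report(cm)
  text <- render_report(rep)
  expect_match(text, "0.8386")
  expect_match(text, "Weighted Avg.", fixed = TRUE)

  parsed <- asNamespace("painvoice")$.parse_report(text)
  # rebuild a report-like rounding from parsed values and re-render rows
  vals <- parsed[[which(vapply(parsed, function(p) p$name == "pain",
                               logical(1)))]]$values
  expect_equal(vals, round(c(rep$per_class$precision[["pain"]],
                             rep$per_class$recall[["pain"]],
                             rep$per_class$f1[["pain"]]), 4))
  # symmetric matrix renders identical class rows
  sym <- metrics_report(as_confusion(rbind(c(10, 5), c(5, 10)),
                                     c("x", "y")))
  lines <- strsplit(render_report(sym), "\n")[[1]]
  strip <- function(s) sub("^\\S+\\s+", "", s)
  expect_identical(strip(lines[2]), strip(lines[3]))
})

test_that("write_metrics produces JSON, CSV, and text artifacts", {
  cm <- as_confusion(rbind(c(3, 1), c(0, 4)), c("a", "b"))
  rep <- metrics_report(cm)
  prefix <- tempfile()
  write_metrics(rep, cm, prefix)
  j <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(j$accuracy, rep$accuracy)
  expect_true(file.exists(paste0(prefix, "_confusion.csv")))
  expect_true(file.exists(paste0(prefix, ".txt")))
})
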