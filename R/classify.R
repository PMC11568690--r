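# Cell classification from per-marker counts: stratified training split
# (2/5/1/1/1 quotas at n = 1000), random-forest training, one-vs-rest
# evaluation metrics with multiclass Matthews correlation, and cohort
# summary tables (positivity, median, IQR).

#' Stratified training/test split with per-class quotas
#'
#' Draws `quotas[class]` cells uniformly at random per class among
#' eligible cells (all quality flags FALSE); everything else is the test
#' set. Cells with over-/under-segmented nuclei or with mixed true and
#' false signals are never eligible for training but stay in the test set.
#'
#' @param profiles data.frame of per-cell features; may carry logical
#'   columns `oversegmented`, `undersegmented`, `mixed_true_false_signals`.
#' @param labels factor/character class per row.
#' @param quotas named integer vector, class -> training count (default
#'   the 2/5/1/1/1 ratio at n = 1000).
#' @param seed RNG seed.
#' @return list with `train_idx`, `test_idx` (row indices).
#' @export
split_training <- function(profiles, labels,
                           quotas = c(CTC = 200L, PBMC = 500L,
                                      artefact = 100L,
                                      false_positive = 100L,
                                      negative = 100L),
                           seed = 1L) {
  stopifnot(nrow(profiles) == length(labels))
  labels <- as.character(labels)
  flags <- rep(FALSE, nrow(profiles))
  for (fl in c("oversegmented", "undersegmented", "mixed_true_false_signals"))
    if (fl %in% names(profiles)) flags <- flags | as.logical(profiles[[fl]])
  set.seed(seed)
  train <- integer(0)
  for (cl in names(quotas)) {
    eligible <- which(labels == cl & !flags)
    if (length(eligible) < quotas[[cl]])
      stop("split_training: class ", cl, " has ", length(eligible),
           " eligible cells, quota is ", quotas[[cl]],
           " (short by ", quotas[[cl]] - length(eligible), ")")
    train <- c(train, sort(sample(eligible, quotas[[cl]])))
  }
  train <- sort(train)
  list(train_idx = train, test_idx = setdiff(seq_len(nrow(profiles)), train))
}

#' Training quotas from a class ratio
#'
#' E.g. ratio 2/5/1/1/1 at n = 1000 gives 200/500/100/100/100.
#'
#' @param ratio named numeric vector of class ratio parts.
#' @param n total training size.
#' @return named integer vector of quotas.
#' @export
quota_from_ratio <- function(ratio, n) {
  q <- n * ratio / sum(ratio)
  if (any(q != round(q)))
    stop("quota_from_ratio: n not divisible by the ratio")
  stats::setNames(as.integer(round(q)), names(ratio))
}

#' Train the cell classifier
#'
#' Random forest over the marker-count features (the 11 markers plus the
#' `total` column when present).
#'
#' @param profiles data.frame of per-cell counts.
#' @param labels class labels.
#' @param features feature columns (default: every numeric column except
#'   `cell_id`; includes `total`).
#' @param n_trees,mtry,seed forest hyperparameters, see [rf_train()].
#' @return a `coduco_forest`.
#' @export
train_classifier <- function(profiles, labels, features = NULL,
                             n_trees = 100L, mtry = NULL, seed = 1L) {
  if (is.null(features)) {
    num <- vapply(profiles, is.numeric, logical(1))
    features <- setdiff(names(profiles)[num], "cell_id")
  }
  X <- as.matrix(profiles[, features, drop = FALSE])
  rf_train(X, labels, n_trees = n_trees, mtry = mtry, seed = seed)
}

#' Evaluate predictions against truth
#'
#' One-vs-rest precision, recall (sensitivity), specificity, F1 and
#' support per class; multiclass Matthews correlation (generalized
#' Gorodkin form); confusion matrix with truth on rows.
#'
#' @param predicted,truth equal-length label vectors.
#' @param positive_class class highlighted in the `positive` summary
#'   (default "CTC").
#' @return object of class `coduco_eval`: list with `confusion`,
#'   `per_class` (data.frame), `mcc`, `accuracy`, `positive`.
#' @export
evaluate <- function(predicted, truth, positive_class = "CTC") {
  if (length(predicted) != length(truth))
    stop("evaluate: predicted and truth differ in length")
  lev <- union(unique(as.character(truth)), unique(as.character(predicted)))
  lev <- c(intersect(CLASS_LEVELS, lev), setdiff(lev, CLASS_LEVELS))
  p <- factor(as.character(predicted), levels = lev)
  t <- factor(as.character(truth), levels = lev)
  cm <- table(truth = t, predicted = p)
  n <- length(t)
  per <- lapply(lev, function(cl) {
    tp <- sum(t == cl & p == cl)
    fp <- sum(t != cl & p == cl)
    fn <- sum(t == cl & p != cl)
    tn <- n - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    data.frame(class = cl, precision = precision, recall = recall,
               specificity = specificity, f1 = f1, support = tp + fn)
  })
  per <- do.call(rbind, per)
  # multiclass MCC (Gorodkin): cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))
  C <- unclass(cm)
  s <- sum(C); c_trace <- sum(diag(C))
  pk <- colSums(C); tk <- rowSums(C)
  num <- c_trace * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  mcc <- if (den > 0) num / den else NA_real_
  pos <- per[per$class == positive_class, , drop = FALSE]
  structure(list(confusion = cm, per_class = per, mcc = mcc,
                 accuracy = c_trace / s,
                 positive = if (nrow(pos)) as.list(pos) else NULL),
            class = "coduco_eval")
}

#' @export
print.coduco_eval <- function(x, ...) {
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  cat("\nper-class metrics:\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("\naccuracy %.4f, multiclass MCC %.4f\n", x$accuracy, x$mcc))
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report a `coduco_eval`.
#' @param path file path.
#' @export
write_eval <- function(report, path) {
  jsonlite::write_json(list(confusion = unclass(report$confusion),
                            confusion_levels = rownames(report$confusion),
                            per_class = report$per_class,
                            mcc = report$mcc, accuracy = report$accuracy),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cohort summary table (positivity, median, IQR)
#'
#' Per group and marker: positivity (% of cells with >= 1 count), median,
#' Q1 and Q3 (linear-interpolation quantiles), plus a `total` row.
#'
#' @param profiles data.frame with marker count columns (and optionally
#'   `total`).
#' @param groups group label per row.
#' @param markers marker columns to summarize (default: numeric columns
#'   except `cell_id`/`total`).
#' @return data.frame with `group`, `marker`, `positivity`, `median`,
#'   `q1`, `q3`, `n`. Empty groups yield NA rows (flagged, not zero).
#' @export
cohort_summary <- function(profiles, groups, markers = NULL) {
  if (is.null(markers)) {
    num <- vapply(profiles, is.numeric, logical(1))
    markers <- setdiff(names(profiles)[num], c("cell_id", "total"))
  }
  cols <- c(markers, intersect("total", names(profiles)))
  glev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  groups <- as.character(groups)
  out <- list()
  for (g in glev) {
    rows <- which(groups == g)
    for (m in cols) {
      v <- profiles[[m]][rows]
      if (length(v) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, marker = m, positivity = NA_real_, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, n = 0L)
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, marker = m, positivity = 100 * mean(v >= 1),
        median = q[2], q1 = q[1], q3 = q[3], n = length(v))
    }
  }
  if (length(out) == 0L)
    return(data.frame(group = character(), marker = character(),
                      positivity = numeric(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), n = integer()))
  do.call(rbind, out)
}
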