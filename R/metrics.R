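#' Confusion matrix
#'
#' Entry `(i, j)` counts samples with true class `i` predicted as class `j`
#' (0-based labels; row/column names carry the 0-based indices or supplied
#' class names).
#'
#' @param y_true,y_pred Integer labels in `[0, C-1]`.
#' @param C Number of classes; defaults to `max(labels) + 1`.
#' @param class_names Optional dimnames.
#' @return C x C integer matrix.
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), C = 2)
#' @export
confusion_matrix <- function(y_true, y_pred, C = NULL, class_names = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop_config("length mismatch")
  if (length(y_true) == 0) stop_config("empty label vectors")
  if (is.null(C)) C <- max(y_true, y_pred) + 1L
  bad <- which(y_true < 0 | y_true >= C | y_pred < 0 | y_pred >= C)
  if (length(bad) > 0) {
    stop_config("label out of range [0, %d] at index %d", C - 1L, bad[1])
  }
  cm <- matrix(0L, C, C)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  if (is.null(class_names)) class_names <- as.character(seq_len(C) - 1L)
  dimnames(cm) <- list(true = class_names, predicted = class_names)
  cm
}

#' Per-class one-vs-rest metrics
#'
#' For each class `k` the confusion matrix is binarized k-vs-rest into
#' TP/FP/FN/TN, from which accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, F-score `2PR/(P+R)`, and the Matthews correlation
#' coefficient are computed, all expressed in percent (MCC in
#' `[-100, 100]`). Ratios with a zero denominator are reported as 0 and
#' flagged in the `undefined` column.
#'
#' @param confusion C x C confusion matrix (rows = true).
#' @return Data frame with one row per class: `class`, `accuracy`,
#'   `precision`, `recall`, `f_score`, `mcc`, `undefined` (logical).
#' @examples
#' per_class_metrics(confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1)))
#' @export
per_class_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  C <- nrow(confusion)
  if (C == 0 || ncol(confusion) != C) stop_config("confusion must be a non-empty square matrix")
  N <- sum(confusion)
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(C) - 1L)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  rows <- lapply(seq_len(C), function(k) {
    TP <- confusion[k, k]
    FP <- sum(confusion[-k, k])
    FN <- sum(confusion[k, -k])
    TN <- N - TP - FP - FN
    acc <- (TP + TN) / N
    prec <- safe_div(TP, TP + FP)
    rec <- safe_div(TP, TP + FN)
    f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
    mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
    mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
    undef <- any(is.na(c(prec, rec, f1, mcc)))
    vals <- c(accuracy = acc, precision = prec, recall = rec,
              f_score = f1, mcc = mcc)
    vals[is.na(vals)] <- 0
    data.frame(class = cls[k], t(vals * 100), undefined = undef,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Macro averages of a per-class metric table
#'
#' Unweighted arithmetic mean of each metric column; the raw means are
#' returned, with a `display` attribute rounded half-up to 2 decimals (the
#' tabulation convention, e.g. 98.125 displays as 98.13).
#'
#' @param per_class A [per_class_metrics()] data frame (or any data frame
#'   with numeric metric columns `accuracy..mcc`).
#' @return Named numeric vector of macro means (percent).
#' @examples
#' macro_average(per_class_metrics(diag(c(5, 5))))
#' @export
macro_average <- function(per_class) {
  cols <- c("accuracy", "precision", "recall", "f_score", "mcc")
  cols <- intersect(cols, names(per_class))
  if (nrow(per_class) < 1) stop_config("need at least one class")
  avg <- vapply(per_class[cols], mean, numeric(1))
  attr(avg, "display") <- round_half_up(avg, 2)
  avg
}

#' Classifier error-rate fitness
#'
#' The objective both tuning stages minimize: the percentage of
#' misclassified instances, `100 * misclassified / total`. Always equals
#' `100 - micro-accuracy`.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Error rate in percent.
#' @examples
#' error_rate_fitness(c(0, 1, 1, 0), c(0, 1, 0, 0))
#' @export
error_rate_fitness <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop_config("empty input")
  if (length(y_true) != length(y_pred)) stop_config("length mismatch")
  100 * sum(y_true != y_pred) / length(y_true)
}

#' Full evaluation report
#'
#' Confusion matrix, per-class one-vs-rest metrics and macro averages for a
#' prediction, in the layout of a per-class results table with an Average
#' row.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_names Optional class names (defaults to 0-based indices).
#' @param split_tag Text tag identifying the evaluated split (e.g. `"TR80"`).
#' @return An object of class `evaluation_report`: list with `confusion`,
#'   `per_class`, `averages`, `error_rate`, `split_tag`.
#' @export
evaluation_report <- function(y_true, y_pred, class_names = NULL,
                              split_tag = "") {
  C <- if (is.null(class_names)) NULL else length(class_names)
  cm <- confusion_matrix(y_true, y_pred, C = C, class_names = class_names)
  pc <- per_class_metrics(cm)
  structure(list(confusion = cm, per_class = pc,
                 averages = macro_average(pc),
                 error_rate = error_rate_fitness(y_true, y_pred),
                 split_tag = split_tag),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  tag <- if (nzchar(x$split_tag)) sprintf(" [%s]", x$split_tag) else ""
  cat(sprintf("Evaluation report%s: %d samples, %d classes\n",
              tag, sum(x$confusion), nrow(x$confusion)))
  tab <- x$per_class
  num <- vapply(tab[-1][seq_len(5)], round_half_up, numeric(nrow(tab)), digits = 2)
  if (is.null(dim(num))) num <- matrix(num, nrow = 1,
                                       dimnames = list(NULL, names(tab)[2:6]))
  out <- data.frame(class = tab$class, num, check.names = FALSE)
  avg <- attr(x$averages, "display")
  out <- rbind(out, data.frame(class = "Average", t(avg), check.names = FALSE))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' One row per class plus an `Average` row (metric columns in percent,
#' rounded half-up to 2 decimals); the confusion matrix goes to a sibling
#' file when `confusion_path` is given. `as_json = TRUE` writes the full
#' report (raw precision) as JSON instead.
#'
#' @param report An [evaluation_report()].
#' @param path Output path.
#' @param confusion_path Optional CSV path for the confusion matrix.
#' @param as_json Write JSON instead of CSV.
#' @export
write_report <- function(report, path, confusion_path = NULL, as_json = FALSE) {
  if (as_json) {
    obj <- list(split_tag = report$split_tag,
                confusion = unclass(report$confusion),
                per_class = report$per_class,
                averages = as.list(report$averages),
                error_rate = report$error_rate)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
    return(invisible(path))
  }
  tab <- report$per_class
  cols <- c("accuracy", "precision", "recall", "f_score", "mcc")
  disp <- as.data.frame(lapply(tab[cols], round_half_up, digits = 2))
  out <- cbind(class = tab$class, disp)
  out <- rbind(out, cbind(class = "Average",
                          as.data.frame(t(attr(report$averages, "display")))))
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(confusion_path)) {
    utils::write.csv(as.data.frame(unclass(report$confusion)), confusion_path)
  }
  invisible(path)
}
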