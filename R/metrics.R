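# Classification and sequence metrics: accuracy, macro precision / recall /
# F1 (percent), macro one-vs-rest AUC, confusion matrix, sequence MSE, and
# repeated-run aggregation.

# Rank-based (Mann-Whitney) AUC of scores for a binary indicator.
binary_auc <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics report
#'
#' Computes accuracy and macro-averaged precision, recall and F1 (all in
#' percent), macro one-vs-rest AUC from the class-probability columns, a
#' per-class breakdown and the confusion matrix. Micro averaging is
#' available via `average = "micro"` (with balanced classes micro and macro
#' nearly coincide).
#'
#' @param y_true Integer vector of true labels in `0:(n_classes - 1)`.
#' @param y_prob Matrix `n x n_classes` of predicted class probabilities
#'   (rows sum to 1); or an integer vector of hard predictions, in which
#'   case AUC is computed from the implied one-hot scores.
#' @param n_classes Number of classes (default 3).
#' @param average `"macro"` (default) or `"micro"` for precision / recall /
#'   F1.
#' @return Object of class `metrics_report`.
#' @export
classification_metrics <- function(y_true, y_prob, n_classes = 3L,
                                   average = c("macro", "micro")) {
  average <- match.arg(average)
  if (any(!y_true %in% 0:(n_classes - 1L)))
    stop("labels outside 0:(n_classes-1)")
  if (!is.matrix(y_prob)) {
    pred <- as.integer(y_prob)
    if (any(!pred %in% 0:(n_classes - 1L)))
      stop("predicted labels outside 0:(n_classes-1)")
    y_prob <- matrix(0, length(pred), n_classes)
    y_prob[cbind(seq_along(pred), pred + 1L)] <- 1
  }
  if (nrow(y_prob) != length(y_true)) stop("length mismatch")
  pred <- max.col(y_prob, ties.method = "first") - 1L
  cm <- table(factor(y_true, levels = 0:(n_classes - 1L)),
              factor(pred, levels = 0:(n_classes - 1L)))
  cm <- unclass(cm)
  dimnames(cm) <- list(truth = 0:(n_classes - 1L),
                       prediction = 0:(n_classes - 1L))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec_c <- ifelse(predicted > 0, tp / predicted, 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  present <- support > 0
  if (average == "macro") {
    precision <- mean(prec_c[present])
    recall <- mean(rec_c[present])
    f1 <- mean(f1_c[present])
  } else {
    precision <- sum(tp) / max(sum(predicted), 1)
    recall <- sum(tp) / max(sum(support), 1)
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  auc_c <- vapply(0:(n_classes - 1L), function(k)
    binary_auc(y_prob[, k + 1L], y_true == k), numeric(1))
  auc <- mean(auc_c, na.rm = TRUE)
  structure(list(
    accuracy = 100 * sum(tp) / length(y_true),
    precision = 100 * precision,
    recall = 100 * recall,
    f1 = 100 * f1,
    auc = auc,
    per_class = data.frame(class = 0:(n_classes - 1L),
                           precision = 100 * prec_c, recall = 100 * rec_c,
                           f1 = 100 * f1_c, auc = auc_c, support = support),
    confusion = cm,
    average = average,
    n = length(y_true)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d (%s-averaged)\n", x$n, x$average))
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%%  AUC %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc))
  if (!is.null(x$sd)) {
    cat(sprintf("  across %d repetitions (sd: acc %.2f, AUC %.3f)\n",
                x$n_repetitions, x$sd["accuracy"], x$sd["auc"]))
  }
  invisible(x)
}

#' Mean squared error of a sequence of predictions
#'
#' `E = (1/K) * sum_k || pred_k - true_k ||^2` over a length-K sequence of
#' vectors (rows of a matrix, or elements of a list).
#'
#' @param pred_sequence,true_sequence Matrices with K rows, or lists of K
#'   equal-length numeric vectors, or plain numeric vectors.
#' @return Scalar E.
#' @export
sequence_mse <- function(pred_sequence, true_sequence) {
  as_rows <- function(x) {
    if (is.list(x)) do.call(rbind, lapply(x, as.numeric))
    else if (is.matrix(x)) x
    else matrix(as.numeric(x), ncol = 1)
  }
  p <- as_rows(pred_sequence)
  y <- as_rows(true_sequence)
  if (!all(dim(p) == dim(y))) stop("sequence length/shape mismatch")
  mean(rowSums((p - y)^2))
}

#' Repeat an experiment over seeds and aggregate its metrics
#'
#' @param experiment Function `seed -> metrics_report` (or a named numeric
#'   vector of metrics).
#' @param n Number of repetitions (default 3).
#' @param seeds Optional explicit seeds (length `n`); defaults to `1:n`.
#' @return A `metrics_report` carrying the mean metrics plus `sd`,
#'   `n_repetitions` and the individual `runs`.
#' @export
repeat_and_average <- function(experiment, n = 3L, seeds = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (is.null(seeds)) seeds <- seq_len(n)
  if (length(seeds) != n) stop("need exactly n seeds")
  runs <- lapply(seeds, experiment)
  take <- function(r) {
    if (inherits(r, "metrics_report"))
      c(accuracy = r$accuracy, precision = r$precision, recall = r$recall,
        f1 = r$f1, auc = r$auc)
    else unlist(r)
  }
  vals <- do.call(rbind, lapply(runs, take))
  m <- colMeans(vals)
  s <- apply(vals, 2, sd)
  if (n == 1L) s[] <- 0
  out <- list(accuracy = m["accuracy"], precision = m["precision"],
              recall = m["recall"], f1 = m["f1"], auc = m["auc"],
              sd = s, n_repetitions = n, runs = runs,
              average = "macro", n = NA_integer_)
  out <- lapply(out, function(v) if (is.numeric(v) && !is.null(names(v)) &&
                                       length(v) == 1) unname(v) else v)
  structure(out, class = "metrics_report")
}
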