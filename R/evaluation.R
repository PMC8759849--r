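#' Confusion matrix from truth and predictions
#'
#' Rows are the true class, columns the predicted class — the convention
#' under which precision is a column ratio and recall a row ratio.
#'
#' @param truth,estimate Factors (or vectors) of equal length.
#' @param class_names Optional explicit class ordering.
#' @return A `confusion_mat`: `counts` (C x C integer), `proportions`
#'   (counts / total), `class_names`.
#' @export
confusion_matrix <- function(truth, estimate, class_names = NULL) {
  class_names <- class_names %||%
    union(levels(factor(truth)), levels(factor(estimate)))
  t_ <- factor(truth, levels = class_names)
  e_ <- factor(estimate, levels = class_names)
  counts <- unclass(table(t_, e_))
  dimnames(counts) <- list(true = class_names, predicted = class_names)
  new_confusion(counts, class_names)
}

new_confusion <- function(counts, class_names) {
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 proportions = counts / sum(counts),
                 class_names = class_names),
            class = "confusion_mat")
}

#' Reconstruct integer confusion counts from printed proportions
#'
#' Published confusion matrices are often printed as proportions of the
#' evaluation-set size. Given the proportion matrix and the total, counts
#' are recovered as `round(P * total)`; if rounding breaks the total, a
#' largest-remainder correction restores it.
#'
#' @param P C x C matrix of non-negative proportions (rows = true class);
#'   must sum to 1 within 0.02.
#' @param total Total number of samples (`>= C`).
#' @param class_names Optional class names (defaults to `0, 1, ...`).
#' @return A `confusion_mat`.
#' @examples
#' counts_from_proportions(rbind(c(0.12, 0.06), c(0.03, 0.79)), 33)$counts
#' @export
counts_from_proportions <- function(P, total, class_names = NULL) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) abort("proportion matrix must be square")
  if (any(P < 0)) abort("proportions must be non-negative")
  stopifnot(total >= nrow(P))
  dev <- abs(sum(P) - 1)
  if (dev > 0.02) {
    abort(sprintf("proportions sum to %.4f (deviation %.4f > 0.02)",
                  sum(P), dev))
  }
  counts <- round(P * total)
  if (sum(counts) != total) {
    base <- floor(P * total)
    rem <- P * total - base
    extra <- total - sum(base)
    ord <- order(-rem, seq_along(rem))
    counts <- base
    if (extra > 0) counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1
  }
  class_names <- class_names %||% as.character(seq_len(nrow(P)) - 1L)
  dimnames(counts) <- list(true = class_names, predicted = class_names)
  new_confusion(counts, class_names)
}

#' @export
print.confusion_mat <- function(x, ...) {
  cat("confusion matrix (rows = true class):\n")
  print(x$counts)
  invisible(x)
}

#' @method tidy confusion_mat
#' @export
tidy.confusion_mat <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)) |>
    stats::setNames(c("true", "predicted", "count"))
}

#' @method autoplot confusion_mat
#' @export
autoplot.confusion_mat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(object$class_names)) +
    ggplot2::labs(title = "confusion matrix")
}

#' Per-class classification report
#'
#' Precision (`TP / column sum`, 0 when the column is empty), recall
#' (`TP / row sum`), F1 (`2PR/(P+R)`, 0 when `P + R = 0`) and support per
#' class, plus accuracy (`trace / total`), macro averages (unweighted) and
#' weighted averages (by support). Metrics are kept at full precision; the
#' print method renders the conventional 2-decimal table (half-even
#' rounding).
#'
#' @param cm A `confusion_mat`.
#' @return A `class_report`: `by_class` tibble, `accuracy`, `macro_avg`,
#'   `weighted_avg`, `total`.
#' @export
classification_report <- function(cm) {
  counts <- cm$counts
  total <- sum(counts)
  if (total <= 0) abort("empty confusion matrix")
  tp <- diag(counts)
  col_sum <- colSums(counts)
  row_sum <- rowSums(counts)
  precision <- ifelse(col_sum > 0, tp / col_sum, 0)
  recall <- ifelse(row_sum > 0, tp / row_sum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  by_class <- tibble(class = cm$class_names,
                     precision = unname(precision),
                     recall = unname(recall), f1 = unname(f1),
                     support = unname(as.integer(row_sum)))
  wavg <- function(v) sum(v * row_sum) / total
  structure(list(
    by_class = by_class,
    accuracy = sum(tp) / total,
    macro_avg = c(precision = mean(precision), recall = mean(recall),
                  f1 = mean(f1)),
    weighted_avg = c(precision = wavg(precision), recall = wavg(recall),
                     f1 = wavg(f1)),
    total = total), class = "class_report")
}

#' @method tidy class_report
#' @export
tidy.class_report <- function(x, ...) x$by_class

#' @method glance class_report
#' @export
glance.class_report <- function(x, ...) {
  tibble(accuracy = x$accuracy,
         macro_precision = x$macro_avg[["precision"]],
         macro_recall = x$macro_avg[["recall"]],
         macro_f1 = x$macro_avg[["f1"]],
         weighted_precision = x$weighted_avg[["precision"]],
         weighted_recall = x$weighted_avg[["recall"]],
         weighted_f1 = x$weighted_avg[["f1"]],
         total = x$total)
}

#' Render a classification report as a fixed-width 2-decimal table
#'
#' @param x A `class_report`.
#' @param digits Decimal places (default 2, half-even rounding as in
#'   standard machine-learning report printers).
#' @return Character vector of table lines.
#' @export
format_report <- function(x, digits = 2) {
  r2 <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  b <- x$by_class
  lines <- sprintf("%-14s %9s %9s %9s %9s", "", "precision", "recall",
                   "f1-score", "support")
  for (i in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%-14s %9s %9s %9s %9d", b$class[i],
                              r2(b$precision[i]), r2(b$recall[i]),
                              r2(b$f1[i]), b$support[i]))
  }
  lines <- c(lines,
             sprintf("%-14s %9s %9s %9s %9d", "accuracy", "", "",
                     r2(x$accuracy), x$total),
             sprintf("%-14s %9s %9s %9s %9d", "macro avg",
                     r2(x$macro_avg[["precision"]]),
                     r2(x$macro_avg[["recall"]]),
                     r2(x$macro_avg[["f1"]]), x$total),
             sprintf("%-14s %9s %9s %9s %9d", "weighted avg",
                     r2(x$weighted_avg[["precision"]]),
                     r2(x$weighted_avg[["recall"]]),
                     r2(x$weighted_avg[["f1"]]), x$total))
  lines
}

#' @export
print.class_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

# JSON-friendly structure for a report
report_as_list <- function(x) {
  list(by_class = x$by_class, accuracy = x$accuracy,
       macro_avg = as.list(x$macro_avg),
       weighted_avg = as.list(x$weighted_avg), total = x$total)
}
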