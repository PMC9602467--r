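#' Per-class F1 score
#'
#' Harmonic mean of precision and recall for one class, with the usual
#' convention that an undefined score (no predicted and no true
#' positives) is 0.
#'
#' @param predictions,labels Aligned character vectors of predicted and
#'   true labels.
#' @param class The class scored as positive.
#' @return F1 in `[0, 1]`.
#' @export
f1_per_class <- function(predictions, labels, class) {
  check_aligned(predictions, labels)
  tp <- sum(predictions == class & labels == class)
  fp <- sum(predictions == class & labels != class)
  fn <- sum(predictions != class & labels == class)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Support-weighted F1 score
#'
#' Mean of the per-class F1 scores weighted by each class's share of the
#' true labels. With equal supports this equals macro F1.
#'
#' @inheritParams f1_per_class
#' @return Weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(predictions, labels) {
  check_aligned(predictions, labels)
  classes <- sort(unique(labels))
  f1 <- vapply(classes, function(cl) f1_per_class(predictions, labels, cl),
               numeric(1))
  support <- vapply(classes, function(cl) mean(labels == cl), numeric(1))
  sum(support * f1)
}

check_aligned <- function(predictions, labels) {
  if (length(predictions) == 0 || length(labels) == 0) {
    stop("empty prediction or label vector", call. = FALSE)
  }
  if (length(predictions) != length(labels)) {
    stop("`predictions` and `labels` must have equal length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-task evaluation report
#'
#' Breaks test-set performance down by elicitation task. For every task
#' the report carries the correct-prediction rate (`correct / n_test`
#' within the task), the number of test samples, and the within-task
#' weighted F1 — the two quantities are reported side by side rather than
#' conflated. The average row is the unweighted mean over the tasks that
#' have test samples; a task with none is reported with `n_test = 0` and
#' `NA` rates.
#'
#' @param predictions,labels Aligned character vectors over the test set.
#' @param tasks Character vector of task identifiers, aligned with
#'   `predictions`.
#' @return An object of class `evaluation_report`: a list with
#'   `weighted_f1`, `per_class_f1` (named numeric), `per_task` (tibble
#'   `task`, `correct_rate`, `n_test`, `f1`), and `average_row`.
#' @export
per_task_report <- function(predictions, labels, tasks) {
  check_aligned(predictions, labels)
  stopifnot(length(tasks) == length(predictions))
  if (!all(tasks %in% task_ids())) {
    stop("unknown task identifier(s) in `tasks`", call. = FALSE)
  }
  classes <- sort(unique(labels))
  per_class <- vapply(classes, function(cl) f1_per_class(predictions, labels, cl),
                      numeric(1))
  per_task <- dplyr::bind_rows(lapply(task_ids(), function(tk) {
    ix <- tasks == tk
    if (!any(ix)) {
      return(tibble::tibble(task = tk, correct_rate = NA_real_,
                            n_test = 0L, f1 = NA_real_))
    }
    tibble::tibble(
      task = tk,
      correct_rate = mean(predictions[ix] == labels[ix]),
      n_test = sum(ix),
      f1 = weighted_f1(predictions[ix], labels[ix])
    )
  }))
  populated <- per_task[per_task$n_test > 0, ]
  structure(
    list(
      weighted_f1 = weighted_f1(predictions, labels),
      per_class_f1 = per_class,
      per_task = per_task,
      average_row = list(
        correct_rate = mean(populated$correct_rate),
        n_test = mean(populated$n_test),
        f1 = mean(populated$f1)
      )
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Evaluation report\n")
  cat("  weighted F1:", round(x$weighted_f1, digits), "\n")
  cat("  per-class F1:",
      paste(names(x$per_class_f1), round(x$per_class_f1, digits),
            sep = "=", collapse = "  "), "\n\n")
  tab <- x$per_task
  tab$correct_rate <- round(tab$correct_rate, digits)
  tab$f1 <- round(tab$f1, digits)
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("  Average  %.3f  %.1f  (F1 %.3f)\n",
              x$average_row$correct_rate, x$average_row$n_test,
              x$average_row$f1))
  invisible(x)
}

#' Write an evaluation report
#'
#' `write_report_tsv()` writes the per-task table (task, correct rate,
#' test count, within-task F1) with the average row appended;
#' `write_report_json()` writes the full report structure.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  tab <- report$per_task
  tab <- rbind(
    tab,
    tibble::tibble(task = "Average",
                   correct_rate = report$average_row$correct_rate,
                   n_test = report$average_row$n_test,
                   f1 = report$average_row$f1)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(weighted_f1 = report$weighted_f1,
         per_class_f1 = as.list(report$per_class_f1),
         per_task = report$per_task,
         average_row = report$average_row),
    path, auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  invisible(path)
}
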