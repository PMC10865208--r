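#' Confusion matrix of triage predictions
#'
#' Rows are the annotated (true) classes, columns the predicted classes, in
#' class order.
#'
#' @param true Vector of annotated classes.
#' @param pred Vector of predicted classes, same length.
#' @param classes Class set defining the matrix dimensions (default 0:3).
#' @return Integer matrix of class `triage_confusion`; `counts[i, j]` is the
#'   number of rows annotated `i` and predicted `j`.
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2))
#' @export
confusion <- function(true, pred, classes = 0:3) {
  if (length(true) != length(pred)) {
    stop("true (", length(true), ") and pred (", length(pred),
         ") differ in length", call. = FALSE)
  }
  true <- as.integer(as.character(true))
  pred <- as.integer(as.character(pred))
  bad <- setdiff(unique(c(true, pred)), classes)
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cm <- table(factor(true, levels = classes), factor(pred, levels = classes))
  out <- matrix(as.integer(cm), nrow = length(classes),
                dimnames = list(true = as.character(classes),
                                pred = as.character(classes)))
  structure(out, class = c("triage_confusion", class(out)))
}

#' Precision, recall and F1 from a confusion matrix
#'
#' Per class (one-versus-rest): `TP` is the diagonal cell, `FP` the rest of
#' the class's column, `FN` the rest of its row; then
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)` and
#' `F1 = 2 P R / (P + R)`. A zero denominator yields 0 by convention (with
#' a warning). The macro F1 is the unweighted class mean; micro and
#' support-weighted means are reported alongside.
#'
#' @param cm A confusion matrix from [confusion()] (or any square count
#'   matrix with classes on both dimensions in the same order).
#' @return List of class `f1_report`: `per_class` data frame (class,
#'   support, precision, recall, f1), `macro_f1`, `micro_f1`, `weighted_f1`
#'   and `accuracy`.
#' @examples
#' f1_from_confusion(confusion(c(0, 0, 1, 1), c(0, 1, 1, 1)))
#' @export
f1_from_confusion <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)) - 1L)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_ratio <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning("zero denominator for ", what, " of class(es) ",
              paste(classes[bad], collapse = ", "), "; using 0", call. = FALSE)
    }
    ifelse(den > 0, num / den, 0)
  }
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  support <- rowSums(cm)
  total <- sum(cm)
  micro <- if (total > 0) sum(tp) / total else 0
  weighted <- if (total > 0) sum(f1 * support) / total else 0
  structure(
    list(per_class = data.frame(class = classes, support = support,
                                precision = precision, recall = recall,
                                f1 = f1, row.names = NULL),
         macro_f1 = mean(f1), micro_f1 = micro, weighted_f1 = weighted,
         accuracy = micro),
    class = "f1_report")
}

#' @export
print.f1_report <- function(x, ...) {
  cat(sprintf("<f1_report> macro F1 = %.4f (micro %.4f, weighted %.4f)\n",
              x$macro_f1, x$micro_f1, x$weighted_f1))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bundle the per-run scores of one model under one condition
#'
#' @param model Model family name.
#' @param condition `"ED"` or `"BD"`.
#' @param run_f1s Numeric vector of per-run macro-F1 values.
#' @param confusions List of per-run confusion matrices.
#' @param reports Optional list of per-run `f1_report`s.
#' @return List of class `score_report` with `mean_f1 = mean(run_f1s)`.
#' @export
score_report <- function(model, condition, run_f1s, confusions = NULL,
                         reports = NULL) {
  structure(
    list(model = model, condition = condition,
         run_f1s = as.numeric(run_f1s), mean_f1 = mean(as.numeric(run_f1s)),
         confusions = confusions, reports = reports),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report %s [%s]> mean macro F1 = %.4f over %d run(s)\n",
              x$model, x$condition, x$mean_f1, length(x$run_f1s)))
  invisible(x)
}

#' Compare model scores between the extended and basic data sets
#'
#' Tabulates, per model family, the run-averaged macro F1 under the ED and
#' the BD and their difference in percentage points (F1 x 100); the headline
#' quantity of the enrichment analysis is the maximum difference over
#' models.
#'
#' @param ed_reports List of [score_report()]s for the ED condition.
#' @param bd_reports List of [score_report()]s for the BD condition, same
#'   model families.
#' @return Data frame of class `condition_comparison` with columns `model`,
#'   `f1_ed`, `f1_bd`, `diff_pp`, and attribute `max_diff_pp`.
#' @export
compare_conditions <- function(ed_reports, bd_reports) {
  ed_models <- vapply(ed_reports, function(r) r$model, character(1))
  bd_models <- vapply(bd_reports, function(r) r$model, character(1))
  if (!identical(sort(ed_models), sort(bd_models))) {
    stop("model lists differ between conditions: ED = {",
         paste(ed_models, collapse = ", "), "}, BD = {",
         paste(bd_models, collapse = ", "), "}", call. = FALSE)
  }
  bd_by <- setNames(bd_reports, bd_models)
  out <- do.call(rbind, lapply(ed_reports, function(r) {
    b <- bd_by[[r$model]]
    data.frame(model = r$model, f1_ed = r$mean_f1, f1_bd = b$mean_f1,
               diff_pp = 100 * (r$mean_f1 - b$mean_f1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("condition_comparison", "data.frame"),
            max_diff_pp = max(out$diff_pp))
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> ED vs BD mean macro F1\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("max difference: %.1f percentage points\n",
              attr(x, "max_diff_pp")))
  invisible(x)
}

#' Heatmap of a confusion matrix
#'
#' @param cm A `triage_confusion` matrix.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_confusion needs the ggplot2 package", call. = FALSE)
  }
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = pred, y = true, fill = n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = n)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "predicted class", y = "annotated class",
                  title = title) +
    ggplot2::theme_minimal()
}
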