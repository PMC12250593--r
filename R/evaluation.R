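#' Multiclass confusion matrix
#'
#' Entry (i, j) counts records of true class i predicted as class j;
#' rows are truths, columns predictions, in the order of `levels`.
#'
#' @param y_true,y_pred Vectors of labels (factors or characters) over
#'   the four rhythm classes.
#' @param levels Class order (defaults to [ecg_classes]).
#' @return A K x K integer count matrix.
#' @export
ecg_confusion <- function(y_true, y_pred, levels = ecg_classes) {
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  tt <- factor(as.character(y_true), levels = levels)
  pp <- factor(as.character(y_pred), levels = levels)
  if (anyNA(tt) || anyNA(pp)) {
    abort(sprintf(
      "labels outside the class set; valid labels are %s",
      paste(levels, collapse = ", ")
    ))
  }
  m <- table(truth = tt, prediction = pp)
  matrix(as.integer(m), nrow = length(levels),
         dimnames = list(truth = levels, prediction = levels))
}

#' Per-class precision, sensitivity, specificity, F1 and accuracy
#'
#' One-vs-rest decomposition of a confusion matrix: precision =
#' TP/(TP+FP), sensitivity (recall) = TP/(TP+FN), specificity =
#' TN/(TN+FP), F1 = 2PS/(P+S). Zero denominators yield 0 and raise a
#' warning of class `fedecg_degenerate_metric`.
#'
#' @param confusion K x K count matrix (rows = truth).
#' @return A tibble with one row per class and an `accuracy` attribute.
#' @export
per_class_metrics <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) abort("empty confusion matrix")
  k <- nrow(confusion)
  classes <- rownames(confusion) %||% paste0("class", seq_len(k))
  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      warn(sprintf("%s undefined for class %s (0/0); returning 0", what, cls),
           class = "fedecg_degenerate_metric")
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_len(k), function(i) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    tn <- total - tp - fp - fn
    p <- safe_div(tp, tp + fp, "precision", classes[i])
    s <- safe_div(tp, tp + fn, "sensitivity", classes[i])
    sp <- safe_div(tn, tn + fp, "specificity", classes[i])
    f1 <- if (p + s == 0) {
      warn(sprintf("F1 undefined for class %s (0/0); returning 0", classes[i]),
           class = "fedecg_degenerate_metric")
      0
    } else {
      2 * p * s / (p + s)
    }
    tibble::tibble(
      class = classes[i], precision = p, sensitivity = s,
      specificity = sp, f1 = f1
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "accuracy") <- sum(diag(confusion)) / total
  out
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace/total` and expected agreement
#' `p_e = sum(row_k * col_k) / total^2`. Returns 0 when `p_e = 1` (0/0).
#'
#' @inheritParams per_class_metrics
#' @return Scalar in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) abort("empty confusion matrix")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (abs(1 - pe) < .Machine$double.eps) {
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Multiclass Matthews correlation coefficient
#'
#' Covariance (Gorodkin) form on the confusion matrix:
#' `(c*s - sum(t_k p_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, `t_k` the row (truth) sums and
#' `p_k` the column (prediction) sums. A zero denominator returns 0.
#'
#' @inheritParams per_class_metrics
#' @return Scalar in `[-1, 1]`.
#' @export
mcc_multiclass <- function(confusion) {
  s <- sum(confusion)
  if (s == 0) abort("empty confusion matrix")
  cc <- sum(diag(confusion))
  tk <- rowSums(confusion)
  pk <- colSums(confusion)
  num <- cc * s - sum(tk * pk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) {
    return(0)
  }
  num / den
}

#' Full diagnostic report from a confusion matrix
#'
#' @inheritParams per_class_metrics
#' @return An object of class `metrics_report`: confusion matrix,
#'   per-class table, accuracy, kappa, and MCC.
#' @export
metrics_report <- function(confusion) {
  pc <- per_class_metrics(confusion)
  structure(
    list(
      confusion = confusion,
      per_class = pc,
      accuracy = attr(pc, "accuracy"),
      kappa = cohen_kappa(confusion),
      mcc = mcc_multiclass(confusion)
    ),
    class = "metrics_report"
  )
}

#' Evaluate a model on a test record table
#'
#' Predicts each record's class as the argmax of the forward
#' probabilities (ties broken toward the lowest class index) and
#' tabulates all diagnostic metrics.
#'
#' @param model A `gru_fit`, a `gru_params` object, or a function that
#'   maps a record table to an n x 4 probability matrix.
#' @param records Nonempty test record table.
#' @param stride Temporal decimation used for the forward pass (for
#'   `gru_fit` inputs the fit's own configuration is used).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, records, stride = 1) {
  check_ecg_tbl(records)
  if (nrow(records) == 0) abort("test set is empty")
  probs <- if (inherits(model, "gru_fit")) {
    gru_predict_probs(model$params, records, stride = model$config$stride)
  } else if (inherits(model, "gru_params")) {
    gru_predict_probs(model, records, stride = stride)
  } else if (is.function(model)) {
    model(records)
  } else {
    abort("model must be a gru_fit, gru_params, or a probability function")
  }
  pred <- ecg_classes[max.col(probs, ties.method = "first")]
  metrics_report(ecg_confusion(records$label, pred))
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "accuracy %.4f | kappa %.4f | MCC %.4f\n", x$accuracy, x$kappa, x$mcc
  ))
  print(as.data.frame(x$per_class), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Per-class metric table of a report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with class, precision, sensitivity, specificity, f1.
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' One-row aggregate summary of a report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with accuracy, kappa, mcc, n.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, kappa = x$kappa, mcc = x$mcc,
    n = sum(x$confusion)
  )
}

#' Confusion-matrix heatmap
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot heatmap of the row-normalized confusion matrix.
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::as_tibble(as.data.frame.table(cm / pmax(rowSums(cm), 1)))
  names(df) <- c("truth", "prediction", "fraction")
  df$count <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(x = "predicted", y = "true", fill = "row fraction")
}

#' Write a report's per-class table to CSV
#'
#' Mirrors the class x (P, S, Sp, F1) layout used for diagnostic
#' reporting, with aggregate rows appended.
#'
#' @param report A `metrics_report`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  pc <- report$per_class
  agg <- tibble::tibble(
    class = c("accuracy", "kappa", "mcc"),
    precision = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
    f1 = c(report$accuracy, report$kappa, report$mcc)
  )
  readr::write_csv(dplyr::bind_rows(pc, agg), path)
  invisible(path)
}
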