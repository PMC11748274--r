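#' Evaluate trajectory classification
#'
#' One-vs-rest ROC curves per class by threshold sweep over the predicted
#' class probability, AUC by the trapezoid rule, overall accuracy, and
#' per-class sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`.
#'
#' @param predictions Prediction tibble from [predict.gru_classifier()]
#'   (columns `p_retracing`, `p_congressing`, `p_quasistatic`, `label`).
#' @param truth True labels: character vector aligned with `predictions`,
#'   or NULL to use its `true_label` column.
#' @return A `classifier_evaluation`: list with `metrics` (per-class AUC,
#'   sensitivity, specificity; AUC is NA-flagged for a class with no
#'   positives), `accuracy`, `macro_auc`, `min_auc`, `confusion` (rows =
#'   truth), `roc` (tibble of ROC points per class).
#' @export
evaluate_classifier <- function(predictions, truth = NULL) {
  truth <- truth %||% predictions$true_label
  if (is.null(truth)) abort("no true labels available")
  if (length(truth) != nrow(predictions)) {
    abort("predictions and truth have different lengths")
  }
  truth <- factor(truth, levels = TRAJECTORY_CLASSES)
  pred_lab <- factor(predictions$label, levels = TRAJECTORY_CLASSES)
  prob_cols <- c("p_retracing", "p_congressing", "p_quasistatic")
  roc_all <- list(); metrics <- list()
  for (i in seq_along(TRAJECTORY_CLASSES)) {
    cl <- TRAJECTORY_CLASSES[[i]]
    scores <- predictions[[prob_cols[[i]]]]
    pos <- truth == cl
    auc <- if (!any(pos) || all(pos)) NA_real_ else
      auc_threshold_sweep(scores, pos)
    rc <- if (!any(pos) || all(pos)) NULL else
      mutate(roc_points(scores, pos), class = cl)
    if (!is.null(rc)) roc_all[[cl]] <- rc
    tp <- sum(pred_lab == cl & pos)
    fn <- sum(pred_lab != cl & pos)
    tn <- sum(pred_lab != cl & !pos)
    fp <- sum(pred_lab == cl & !pos)
    metrics[[cl]] <- tibble(class = cl, auc = auc,
                            sensitivity = if (tp + fn > 0) tp / (tp + fn)
                                          else NA_real_,
                            specificity = if (tn + fp > 0) tn / (tn + fp)
                                          else NA_real_,
                            n_positive = sum(pos))
  }
  metrics <- bind_rows(metrics)
  structure(list(metrics = metrics,
                 accuracy = mean(pred_lab == truth),
                 macro_auc = mean(metrics$auc, na.rm = TRUE),
                 min_auc = suppressWarnings(min(metrics$auc, na.rm = TRUE)),
                 confusion = table(truth = truth, predicted = pred_lab),
                 roc = bind_rows(roc_all)),
            class = "classifier_evaluation")
}

# ROC points from a threshold sweep: predict positive when score >= tau,
# tau descending over the observed scores (plus an all-negative start)
roc_points <- function(scores, positives) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positives[ord]
  n_pos <- sum(p); n_neg <- sum(!p)
  tps <- cumsum(p); fps <- cumsum(!p)
  keep <- c(diff(s) != 0, TRUE)   # one point per distinct threshold
  tibble(threshold = c(Inf, s[keep]),
         tpr = c(0, tps[keep]) / n_pos,
         fpr = c(0, fps[keep]) / n_neg)
}

auc_threshold_sweep <- function(scores, positives) {
  rc <- roc_points(scores, positives)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("<classifier_evaluation> accuracy %.3f, macro AUC %.3f\n",
              x$accuracy, x$macro_auc))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-class metrics of a classifier evaluation
#' @param x A `classifier_evaluation`.
#' @param ... Unused.
#' @return Tibble with one row per class: AUC, sensitivity, specificity.
#' @method tidy classifier_evaluation
#' @export
tidy.classifier_evaluation <- function(x, ...) x$metrics

#' One-row summary of a classifier evaluation
#' @param x A `classifier_evaluation`.
#' @param ... Unused.
#' @method glance classifier_evaluation
#' @export
glance.classifier_evaluation <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_auc = x$macro_auc,
         min_auc = x$min_auc, n = sum(x$confusion))
}

#' Tidy the training trace of a fitted GRU classifier
#' @param x A `gru_classifier`.
#' @param ... Unused.
#' @method tidy gru_classifier
#' @export
tidy.gru_classifier <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a fitted GRU classifier
#' @param x A `gru_classifier`.
#' @param ... Unused.
#' @method glance gru_classifier
#' @export
glance.gru_classifier <- function(x, ...) {
  n_par <- sum(unlist(map_params(length, x$params)))
  tibble(hidden_size = x$spec$hidden_size, n_parameters = n_par,
         epochs_run = length(x$loss_trace),
         final_loss = tail(x$loss_trace, 1), n_train = x$n_train)
}
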