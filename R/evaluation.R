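#' Labeled calls for accuracy evaluation
#'
#' @param bioset_id Character vector of unique bioset identifiers.
#' @param truth Character vector, `"positive"` or `"negative"`.
#' @param call Character vector, `"activated"`, `"suppressed"` or
#'   `"neutral"`.
#' @return data.frame of class `labeled_calls`.
#' @export
labeled_calls <- function(bioset_id, truth, call) {
  stopifnot(length(bioset_id) == length(truth),
            length(truth) == length(call),
            all(truth %in% c("positive", "negative")),
            all(call %in% c("activated", "suppressed", "neutral")))
  if (anyDuplicated(bioset_id))
    stop("bioset ids must be unique", call. = FALSE)
  structure(data.frame(bioset_id = as.character(bioset_id),
                       truth = truth, call = call, stringsAsFactors = FALSE),
            class = c("labeled_calls", "data.frame"))
}

# round half up to whole percents (matching printed presentation)
percent_half_up <- function(x) floor(100 * x + 0.5)

#' Confusion-matrix accuracy of screen calls
#'
#' Counts true/false positives and negatives of the calls against the truth
#' labels and reports sensitivity, specificity and balanced accuracy. With
#' `positive_means = "activated"` (default) only an `activated` call counts
#' as a positive prediction - a truth-positive called `suppressed` is a
#' false negative. With `"activated_or_suppressed"` either significant call
#' counts.
#'
#' @param calls A [labeled_calls()] data.frame (or any data.frame with
#'   columns `truth` and `call`).
#' @param positive_means Which calls count as positive predictions.
#' @return An `accuracy_report`: list with counts `tp`, `fp`, `tn`, `fn`;
#'   proportions `sensitivity`, `specificity`, `balanced_accuracy` (`NaN`
#'   when a denominator is empty); and `percent`, the three proportions
#'   rounded half-up to whole percents.
#' @export
evaluate_calls <- function(calls,
                           positive_means = c("activated",
                                              "activated_or_suppressed")) {
  positive_means <- match.arg(positive_means)
  stopifnot(all(c("truth", "call") %in% names(calls)))
  pos_calls <- if (positive_means == "activated") "activated"
               else c("activated", "suppressed")
  predicted_pos <- calls$call %in% pos_calls
  truth_pos <- calls$truth == "positive"
  tp <- sum(truth_pos & predicted_pos)
  fn <- sum(truth_pos & !predicted_pos)
  fp <- sum(!truth_pos & predicted_pos)
  tn <- sum(!truth_pos & !predicted_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0) tn / (tn + fp) else NaN
  bacc <- (sens + spec) / 2
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = bacc,
                 percent = c(sensitivity = percent_half_up(sens),
                             specificity = percent_half_up(spec),
                             balanced_accuracy = percent_half_up(bacc))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp,
              x$tn, x$fn))
  cat(sprintf("  sensitivity %.4f (%d%%)  specificity %.4f (%d%%)  balanced accuracy %.4f (%d%%)\n",
              x$sensitivity, x$percent["sensitivity"],
              x$specificity, x$percent["specificity"],
              x$balanced_accuracy, x$percent["balanced_accuracy"]))
  invisible(x)
}
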