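#' Pooled confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the supplied level
#' order.
#'
#' @param truth,predicted Label vectors of equal length.
#' @param levels Class label order; default = unique truth labels in
#'   first-seen order.
#' @return Integer matrix of class `icp_confusion`.
#' @export
confusion_matrix <- function(truth, predicted, levels = unique(truth)) {
  stopifnot(length(truth) == length(predicted))
  tab <- table(factor(truth, levels = levels),
               factor(predicted, levels = levels))
  out <- matrix(as.integer(tab), nrow = length(levels),
                dimnames = list(truth = levels, predicted = levels))
  class(out) <- c("icp_confusion", class(out))
  out
}

#' Per-class sensitivity, Sn
#'
#' `Sn(i) = TP_i / (TP_i + FN_i) * 100`, where `TP_i` is the diagonal entry
#' for class i and `FN_i` the off-diagonal sum of row i. A class with no
#' evaluated instances (empty row) yields `NA` with a warning; such classes
#' are excluded from the average accuracy.
#'
#' @param conf Confusion matrix (true rows, predicted columns).
#' @return Named numeric vector of percentages.
#' @export
sensitivity <- function(conf) {
  rs <- rowSums(conf)
  sn <- ifelse(rs > 0, diag(conf) / rs * 100, NA_real_)
  if (anyNA(sn)) {
    warning("class(es) with no evaluated instances: ",
            paste(rownames(conf)[is.na(sn)], collapse = ", "),
            "; excluded from AA", call. = FALSE)
  }
  names(sn) <- rownames(conf)
  sn
}

#' Overall accuracy, OA
#'
#' `OA = sum_i TP_i / N * 100`: the percentage of all evaluated instances
#' that were predicted correctly.
#'
#' @inheritParams sensitivity
#' @return A percentage.
#' @export
overall_accuracy <- function(conf) {
  n <- sum(conf)
  stopifnot(n > 0)
  sum(diag(conf)) / n * 100
}

#' Average accuracy, AA
#'
#' The unweighted mean of the per-class sensitivities (classes with no
#' evaluated instances excluded).
#'
#' @inheritParams sensitivity
#' @return A percentage.
#' @export
average_accuracy <- function(conf) {
  mean(suppressWarnings(sensitivity(conf)), na.rm = TRUE)
}
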