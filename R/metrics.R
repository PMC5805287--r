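# Confusion-matrix statistics and per-patient aggregation.
#
# Convention: the POSITIVE class is the CONTROL class (label 0), so TP counts
# correctly classified control samples and TN correctly classified diseased
# samples.  The explicit `positive` argument makes the conventional
# diseased-as-positive usage available too.

#' Confusion counts for binary predictions
#'
#' Tallies TP/TN/FP/FN with an explicit positive class.  The default
#' positive class is control (label 0): TP is a control sample predicted
#' control, TN a diseased sample predicted diseased, FP a diseased sample
#' predicted control, and FN a control sample predicted diseased.
#'
#' @param truth Integer vector of true labels (0 = control, 1 = diseased).
#' @param pred Integer vector of predicted labels, same length.
#' @param positive The label treated as positive (default `0`, control).
#' @return An object of class `confusion_counts`: a list with `TP`, `TN`,
#'   `FP`, `FN` and the `positive` label.
#' @examples
#' cc <- confusion_counts(c(0, 0, 1, 1), c(0, 1, 1, 0))
#' accuracy(cc)
#' @export
confusion_counts <- function(truth, pred, positive = 0L) {
  if (length(truth) != length(pred) || length(truth) < 1L) {
    stop("truth and pred must be nonempty vectors of equal length",
         call. = FALSE)
  }
  pos_t <- truth == positive
  pos_p <- pred == positive
  structure(
    list(TP = sum(pos_t & pos_p), TN = sum(!pos_t & !pos_p),
         FP = sum(!pos_t & pos_p), FN = sum(pos_t & !pos_p),
         positive = positive),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (positive =", x$positive, "): TP", x$TP,
      " TN", x$TN, " FP", x$FP, " FN", x$FN, "\n")
  invisible(x)
}

#' Confusion-matrix statistics
#'
#' * `accuracy()`: `(TP + TN) / (TP + TN + FP + FN)`.
#' * `sensitivity()`: `TP / (TP + FN)`; `NA` when no positive samples were
#'   scored (reported as `"-"` by [metrics_row()]).
#' * `specificity()`: `TN / (TN + FP)`; `NA` when no negative samples were
#'   scored.
#' * `mcc()`: the Matthews correlation coefficient
#'   `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#'   `[-1, 1]`; defined as 0 when any factor of the denominator is zero.
#'
#' All four are invariant under scaling the confusion matrix, and `mcc()` is
#' symmetric under swapping the positive and negative classes.
#'
#' @param cc A [confusion_counts()] object.
#' @return A scalar.
#' @name confusion_stats
NULL

#' @rdname confusion_stats
#' @export
accuracy <- function(cc) {
  (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN)
}

#' @rdname confusion_stats
#' @export
sensitivity <- function(cc) {
  if (cc$TP + cc$FN == 0) return(NA_real_)
  cc$TP / (cc$TP + cc$FN)
}

#' @rdname confusion_stats
#' @export
specificity <- function(cc) {
  if (cc$TN + cc$FP == 0) return(NA_real_)
  cc$TN / (cc$TN + cc$FP)
}

#' @rdname confusion_stats
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Aggregate record-level predictions to individual-level diagnoses
#'
#' Clinical speech datasets carry several records per individual; the
#' diagnosis attaches to the individual.  An individual is classified
#' diseased only when strictly more than half of their records are
#' classified diseased; an exact tie is classified control.
#'
#' @param pred Integer vector of record-level 0/1 predictions.
#' @param patient_ids Vector of individual identifiers, same length.
#' @return Named integer vector of per-individual labels, in order of first
#'   appearance.
#' @examples
#' aggregate_patients(c(1, 1, 0, 1, 0, 0), c("a", "a", "a", "b", "b", "b"))
#' @export
aggregate_patients <- function(pred, patient_ids) {
  if (length(pred) != length(patient_ids)) {
    stop("pred and patient_ids must have equal length", call. = FALSE)
  }
  ids <- factor(patient_ids, levels = unique(patient_ids))
  vapply(split(as.integer(pred), ids),
         function(p) as.integer(sum(p == 1L) > length(p) / 2),
         integer(1))
}

#' Format a row of performance measures as percentages
#'
#' Renders measures as percentages with one decimal place, printing `"-"`
#' for measures that are not computable (e.g. specificity when no diseased
#' individuals were scored).
#'
#' @param ... Named fractions in `[0, 1]` (or `NA`).
#' @return A single tab-separated character string.
#' @export
metrics_row <- function(...) {
  vals <- c(...)
  paste(vapply(vals, function(v) {
    if (is.na(v)) "-" else sprintf("%.1f", 100 * v)
  }, character(1)), collapse = "\t")
}
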