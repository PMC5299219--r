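#' Two-class confusion matrix
#'
#' Counts with the usual clinical convention: TP = positives predicted
#' positive, FP = negatives predicted positive, FN = positives predicted
#' negative, TN = negatives predicted negative.
#'
#' @param y_true,y_pred Equal-length label vectors; values must come from
#'   the same two-value set.
#' @param positive The value designating the positive class; default
#'   `"positive"` (the package's internal label). With +1/-1 vectors pass
#'   `positive = 1`.
#' @return An object of class `igk_confusion` with integer fields `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
confusion <- function(y_true, y_pred, positive = "positive") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  vals <- unique(c(as.character(y_true), as.character(y_pred)))
  if (length(vals) > 2) stop("more than two distinct labels")
  if (!as.character(positive) %in% vals)
    stop("positive label '", positive, "' absent from the data")
  tp <- as.character(y_true) == as.character(positive)
  pp <- as.character(y_pred) == as.character(positive)
  structure(list(TP = sum(tp & pp), FP = sum(!tp & pp),
                 FN = sum(tp & !pp), TN = sum(!tp & !pp)),
            class = "igk_confusion")
}

#' @export
print.igk_confusion <- function(x, ...) {
  cat(sprintf("<igk_confusion> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

# ratio with the degenerate-cell convention: 0 when the denominator is 0
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity (recall on positives), specificity, precision,
#' G-mean (`sqrt(sensitivity * specificity)`, robust to imbalance) and the
#' F-measure `(b^2+1) * precision * sensitivity /
#' (b^2 * precision + sensitivity)` with `b = f_beta` (1 gives the harmonic
#' mean, F1). All returned as fractions in [0, 1]; reporting layers
#' multiply by 100. Ratios with a zero denominator are reported as 0 and
#' recorded in the `degenerate` field — this generalizes the usual
#' convention that a classifier missing every positive scores an F of 0.
#'
#' @param cm An [confusion()] object.
#' @param f_beta Weight of sensitivity relative to precision in the
#'   F-measure; default 1.
#' @return An object of class `igk_metrics`: the six metrics plus
#'   `degenerate`, the names of any zero-denominator metrics.
#' @export
classification_metrics <- function(cm, f_beta = 1) {
  stopifnot(inherits(cm, "igk_confusion"), f_beta >= 0)
  total <- cm$TP + cm$FP + cm$FN + cm$TN
  if (total < 1) stop("empty confusion matrix")
  sens <- safe_ratio(cm$TP, cm$TP + cm$FN)
  spec <- safe_ratio(cm$TN, cm$TN + cm$FP)
  prec <- safe_ratio(cm$TP, cm$TP + cm$FP)
  fden <- f_beta^2 * prec + sens
  m <- list(
    accuracy = (cm$TP + cm$TN) / total,
    sensitivity = sens,
    specificity = spec,
    precision = prec,
    g_mean = sqrt(sens * spec),
    f_measure = if (fden == 0) 0 else (f_beta^2 + 1) * prec * sens / fden
  )
  deg <- character(0)
  if (cm$TP + cm$FN == 0) deg <- c(deg, "sensitivity")
  if (cm$TN + cm$FP == 0) deg <- c(deg, "specificity")
  if (cm$TP + cm$FP == 0) deg <- c(deg, "precision")
  if (fden == 0) deg <- c(deg, "f_measure")
  m$degenerate <- deg
  structure(m, class = "igk_metrics")
}

metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                  "g_mean", "f_measure")

#' @export
print.igk_metrics <- function(x, ...) {
  for (nm in metric_names)
    cat(sprintf("%-12s %6.2f%%\n", nm, 100 * x[[nm]]))
  if (length(x$degenerate))
    cat("zero-denominator:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}
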