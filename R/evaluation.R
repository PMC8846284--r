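#' @include AllClasses.R AllGenerics.R
NULL

#' Diagnostic metrics from a confusion matrix
#'
#' Collapses each class one-vs-rest: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`; overall accuracy is
#' the trace over the total. Metrics with a zero denominator are reported
#' as `NA` and named in the `undefined` field rather than raising, so
#' degenerate classifiers still produce a report.
#'
#' @param cm a [ConfusionMatrix-class] (rows = predicted, columns = true).
#' @return list with `accuracy`, per-class data.frame `perClass`
#'   (sensitivity, specificity, ppv, npv), and `undefined` (character
#'   vector of flagged metrics).
#' @export
metricsFromMatrix <- function(cm) {
  m <- counts(cm)
  total <- sum(m)
  stopIfNot(total > 0, "confusion matrix is empty")
  classes <- rownames(m)
  undef <- character()
  safe <- function(num, den, what) {
    if (den == 0) { undef <<- c(undef, what); return(NA_real_) }
    num / den
  }
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- m[cl, cl]
    fp <- sum(m[cl, ]) - tp
    fn <- sum(m[, cl]) - tp
    tn <- total - tp - fp - fn
    data.frame(class = cl,
               sensitivity = safe(tp, tp + fn, paste0(cl, ":sensitivity")),
               specificity = safe(tn, tn + fp, paste0(cl, ":specificity")),
               ppv = safe(tp, tp + fp, paste0(cl, ":ppv")),
               npv = safe(tn, tn + fn, paste0(cl, ":npv")),
               stringsAsFactors = FALSE)
  }))
  list(accuracy = sum(diag(m)) / total, perClass = per, undefined = undef)
}

#' Reconstruct a binary accuracy from printed sensitivity and specificity
#'
#' Given a task's sensitivity, specificity and class sizes, recover the
#' integer true-positive/true-negative counts by rounding and return the
#' implied accuracy `(TP + TN) / (nPos + nNeg)`. Used to check published
#' binary accuracies for internal consistency.
#'
#' @param sens,spec proportions in \[0, 1\].
#' @param nPos,nNeg positive/negative class sizes.
#' @return the reconstructed accuracy (proportion).
#' @export
binaryAccuracyFromSensSpec <- function(sens, spec, nPos, nNeg) {
  stopIfNot(sens >= 0 && sens <= 1 && spec >= 0 && spec <= 1,
            "sens/spec must lie in [0, 1]")
  stopIfNot(nPos > 0 && nNeg > 0, "class sizes must be positive")
  tp <- roundHalfUp(sens * nPos)
  tn <- roundHalfUp(spec * nNeg)
  stopIfNot(tp >= 0 && tp <= nPos && tn >= 0 && tn <= nNeg,
            "rounded counts outside [0, n]")
  (tp + tn) / (nPos + nNeg)
}

#' Accuracy from an error count
#'
#' `1 - errors/total`, reported as a percentage at one decimal (half away
#' from zero), the precision of published strategy tables.
#'
#' @param errors,total integer counts with `0 <= errors <= total`.
#' @return percentage accuracy (e.g. 77.8).
#' @export
accuracyFromErrorCount <- function(errors, total) {
  stopIfNot(errors >= 0 && errors <= total && total > 0,
            "need 0 <= errors <= total, total > 0")
  asPercent(1 - errors / total)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank tie handling: the probability that a random positive scores
#' above a random negative, counting ties as one half.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or a factor whose second
#'   level is positive).
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  pos <- as.logical(labels)
  nPos <- sum(pos); nNeg <- sum(!pos)
  stopIfNot(nPos > 0 && nNeg > 0, "both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
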