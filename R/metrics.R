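#' Confusion table with uHC as the positive class
#'
#' Cross-tabulates true vs predicted labels. The converter (uHC) group is
#' the "condition existing" / positive class.
#'
#' @param labels_true,labels_pred Vectors of labels in {HC, uHC}.
#' @param positive_class Positive label; default `"uHC"`.
#' @return Object of class `confusion_table`: list with counts `tp`, `fn`,
#'   `fp`, `tn` and margins `ce`, `ca`, `ep`, `en`, `total`.
#' @export
confusion <- function(labels_true, labels_pred, positive_class = "uHC") {
  if (!length(labels_true)) stop("empty input")
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length")
  }
  pos_t <- labels_true == positive_class
  pos_p <- labels_pred == positive_class
  ct <- list(
    tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
    fp = sum(!pos_t & pos_p), tn = sum(!pos_t & !pos_p)
  )
  confusion_from_counts(ct$tp, ct$fn, ct$fp, ct$tn)
}

#' @rdname confusion
#' @param tp,fn,fp,tn Non-negative counts.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  ct <- list(tp = tp, fn = fn, fp = fp, tn = tn,
             ce = tp + fn, ca = fp + tn, ep = tp + fp, en = fn + tn)
  ct$total <- ct$ce + ct$ca
  if (ct$total < 1) stop("confusion table must contain at least one case")
  structure(ct, class = "confusion_table")
}

#' Derived classification metrics
#'
#' Computes accuracy, F1, the Matthews correlation coefficient (MCC), its
#' normalized form MCC' = 0.5 * (1 + MCC), and the four rates TPR, TNR,
#' PPV, NPV. Degenerate denominators follow the independence convention:
#' MCC with any zero margin is 0, PPV/NPV with a zero denominator are 0;
#' such results carry `degenerate = TRUE`.
#'
#' @param ct A `confusion_table`.
#' @return List of metrics (all in `[0,1]` except `mcc` in `[-1,1]`) plus a
#'   `degenerate` flag.
#' @export
compute_metrics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  degenerate <- FALSE
  sdiv <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  tpr <- sdiv(ct$tp, ct$ce)
  tnr <- sdiv(ct$tn, ct$ca)
  ppv <- sdiv(ct$tp, ct$ep)
  npv <- sdiv(ct$tn, ct$en)
  acc <- (ct$tp + ct$tn) / ct$total
  f1 <- if (ppv + tpr == 0) { degenerate <- TRUE; 0 } else {
    2 * ppv * tpr / (ppv + tpr)
  }
  denom <- as.numeric(ct$ce) * ct$ca * ct$ep * ct$en
  mcc <- if (denom == 0) { degenerate <- TRUE; 0 } else {
    (as.numeric(ct$tp) * ct$tn - as.numeric(ct$fp) * ct$fn) / sqrt(denom)
  }
  list(acc = acc, f1 = f1, mcc = mcc, mcc_prime = 0.5 * (1 + mcc),
       tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
       degenerate = degenerate)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AROC: the probability that a random positive
#' scores above a random negative, ties counted one half.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param labels_true Labels in {HC, uHC}.
#' @param positive_class Positive label; default `"uHC"`.
#' @return Area in `[0, 1]`.
#' @export
aroc <- function(scores, labels_true, positive_class = "uHC") {
  pos <- labels_true == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("aroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
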