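# Pixel-wise segmentation metrics against a ground-truth vessel mask.

#' Confusion counts between a predicted and a ground-truth mask
#'
#' Counts, optionally restricted to a region mask:
#' * `TN`  — true vessel count: pixels vessel in both prediction and truth;
#' * `BN`  — true background count: background in both;
#' * `FN`  — background pixels called vessel by the prediction (the
#'   false-positive count used as the numerator of the false positive rate);
#' * `Nvp` / `Nuvp` — ground-truth vessel / background pixel counts.
#'
#' Note on naming: the symbols follow the source method's notation, in which
#' `TN` counts *true vessels* (not "true negatives") and `FN` — despite its
#' prose definition — is only consistent with the reported tables when read
#' as the false-vessel-call count; that reading is implemented here.
#'
#' @param pred,truth 0/1 matrices of equal shape (1 = vessel).
#' @param region optional 0/1 matrix; only pixels with `region != 0` count.
#' @return named list `TN`, `BN`, `FN`, `Nvp`, `Nuvp`.
#' @export
confusion_counts <- function(pred, truth, region = NULL) {
  if (!all(dim(pred) == dim(truth))) {
    stop("confusion_counts: shape mismatch: pred is ",
         paste(dim(pred), collapse = "x"), ", truth is ",
         paste(dim(truth), collapse = "x"))
  }
  p <- pred != 0
  t <- truth != 0
  if (!is.null(region)) {
    if (!all(dim(region) == dim(pred))) {
      stop("confusion_counts: region shape mismatch")
    }
    keep <- region != 0
    p <- p[keep]
    t <- t[keep]
  }
  list(
    TN = sum(p & t),
    BN = sum(!p & !t),
    FN = sum(p & !t),
    Nvp = sum(t),
    Nuvp = sum(!t)
  )
}

#' Evaluate a segmentation against ground truth
#'
#' Computes the average accuracy, true positive rate, and false positive
#' rate:
#' `Ac = (TN + BN) / (Nvp + Nuvp)`, `TPR = TN / Nvp`, `FPR = FN / Nuvp`,
#' where `TN` is the true-vessel count, `BN` the true-background count, and
#' `FN` the count of background pixels falsely called vessel (see
#' [confusion_counts()]).
#'
#' @inheritParams confusion_counts
#' @return object of class `vessel_metrics`: the confusion counts plus
#'   `Ac`, `TPR`, `FPR`.
#' @export
evaluate_segmentation <- function(pred, truth, region = NULL) {
  cc <- confusion_counts(pred, truth, region)
  if (cc$Nvp == 0L) stop("evaluate_segmentation: no vessel pixels in truth; ",
                         "TPR undefined")
  if (cc$Nuvp == 0L) stop("evaluate_segmentation: no background pixels in ",
                          "truth; FPR undefined")
  structure(
    c(cc, list(
      Ac = (cc$TN + cc$BN) / (cc$Nvp + cc$Nuvp),
      TPR = cc$TN / cc$Nvp,
      FPR = cc$FN / cc$Nuvp
    )),
    class = "vessel_metrics"
  )
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat("Segmentation metrics\n")
  cat(sprintf("  accuracy Ac = %.6f\n", x$Ac))
  cat(sprintf("  true positive rate  TPR = %.6f  (%d / %d vessel px)\n",
              x$TPR, x$TN, x$Nvp))
  cat(sprintf("  false positive rate FPR = %.6f  (%d / %d background px)\n",
              x$FPR, x$FN, x$Nuvp))
  invisible(x)
}

#' @export
as.data.frame.vessel_metrics <- function(x, ...) {
  data.frame(TN = x$TN, BN = x$BN, FN = x$FN, Nvp = x$Nvp, Nuvp = x$Nuvp,
             Ac = x$Ac, TPR = x$TPR, FPR = x$FPR)
}

#' Dice overlap between two masks
#'
#' `2|A and B| / (|A| + |B|)`; 1 for identical non-empty masks. Used for
#' phantom-recovery checks.
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return numeric in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dice: shape mismatch")
  a <- a != 0
  b <- b != 0
  2 * sum(a & b) / (sum(a) + sum(b))
}
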