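#' Confusion counts for binary predictions
#'
#' @param truth,pred binary vectors (0/1) of equal length.
#' @return one-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and pred have different lengths", call. = FALSE)
  }
  stopifnot(all(truth %in% c(0, 1)), all(pred %in% c(0, 1)))
  tibble::tibble(
    tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fn = sum(truth == 1 & pred == 0)
  )
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' Standard binary-classification metrics:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP),}
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}}.}
#' Precision \eqn{TP/(TP+FP)} is reported as well. When any factor of the
#' MCC radical is zero the coefficient is reported as 0 and
#' `mcc_degenerate` is set, never `NaN`.
#'
#' @param truth,pred binary vectors (0/1); alternatively pass a confusion
#'   tibble from [confusion()] via `counts`.
#' @param counts optional one-row tibble `tp`, `fp`, `tn`, `fn`; overrides
#'   `truth`/`pred`.
#' @return one-row tibble: `sn`, `sp`, `acc`, `precision` in `[0, 1]`,
#'   `mcc` in `[-1, 1]`, `mcc_degenerate`, and the four counts.
#' @export
classification_metrics <- function(truth = NULL, pred = NULL, counts = NULL) {
  if (is.null(counts)) counts <- confusion(truth, pred)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  n <- tp + fp + tn + fn
  if (n == 0) stop("no samples to evaluate", call. = FALSE)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / n
  denom2 <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  degenerate <- denom2 == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  tibble::tibble(sn = sn, sp = sp, acc = acc, precision = prec,
                 mcc = mcc, mcc_degenerate = degenerate,
                 tp = counts$tp, fp = counts$fp,
                 tn = counts$tn, fn = counts$fn)
}

#' Render a metrics row the way results tables print it
#'
#' Percentages with two decimals for Sn/Sp/Acc, MCC to four decimals.
#'
#' @param metrics one-row tibble from [classification_metrics()].
#' @return one-row tibble of formatted strings plus numeric `mcc`.
#' @export
format_metrics <- function(metrics) {
  tibble::tibble(
    sn_pct = sprintf("%.2f", 100 * metrics$sn),
    sp_pct = sprintf("%.2f", 100 * metrics$sp),
    acc_pct = sprintf("%.2f", 100 * metrics$acc),
    mcc = round(metrics$mcc, 4)
  )
}
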