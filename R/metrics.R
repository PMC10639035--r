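#' Binary classification metric suite
#'
#' Computes MCC, accuracy, sensitivity, specificity, AUC, F1 and precision
#' from labels and predicted scores. Class calls use
#' \code{score >= threshold}. MCC returns 0 when any confusion-table
#' marginal is zero; precision and F1 return 0 when undefined. AUC is the
#' Mann-Whitney rank statistic with midrank tie handling; with single-class
#' labels AUC is reported as \code{NA} with a warning, other metrics are
#' still computed.
#'
#' @param labels Integer/logical vector of 0/1 labels.
#' @param scores Numeric scores in \code{[0, 1]}.
#' @param threshold Decision threshold (default 0.5).
#' @return A \code{metrics_report}: named list with \code{MCC}, \code{Ac},
#'   \code{Sn}, \code{Sp}, \code{AUC}, \code{F1}, \code{Precision} and the
#'   confusion counts.
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)),
            all(scores >= 0 & scores <= 1))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  sn <- if (tp + fn == 0) 0 else tp / (tp + fn)
  sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sn == 0) 0 else 2 * prec * sn / (prec + sn)
  structure(list(MCC = mcc, Ac = (tp + tn) / length(labels), Sn = sn,
                 Sp = sp, AUC = auc_score(labels, scores), F1 = f1,
                 Precision = prec,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "metrics_report")
}

#' Area under the ROC curve (rank statistic, midrank ties)
#'
#' @inheritParams compute_metrics
#' @return AUC in \code{[0, 1]}, or \code{NA} (with a warning) when only one
#'   class is present.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    warning("AUC undefined: labels contain a single class")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' @export
print.metrics_report <- function(x, ...) {
  v <- unlist(x[c("MCC", "Ac", "Sn", "Sp", "AUC", "F1", "Precision")])
  print(round(v, 4))
  invisible(x)
}

metrics_as_row <- function(m) {
  as.data.frame(m[c("MCC", "Ac", "Sn", "Sp", "AUC", "F1", "Precision")])
}
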