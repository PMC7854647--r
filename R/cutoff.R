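# ROC construction over patient ADTA scores against the died-of-melanoma
# label, and operating-cutoff selection. Orientation: a LOW score (little
# lymphocytic infiltrate) predicts death, i.e. score < threshold calls
# "died". Candidate thresholds are midpoints between consecutive sorted
# unique scores plus -Inf/+Inf sentinels, so a selected cutoff never
# coincides with an observed score.

#' ROC curve for ADTA scores against death from melanoma
#'
#' @param scores Per-patient ADTA scores.
#' @param died Binary labels (1 = died of melanoma).
#' @return Object of class `roc_result`: list with `curve` (data.frame:
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`), `auc`
#'   (trapezoid over (1-specificity, sensitivity), equal to the two-sample
#'   concordance probability with half credit for ties), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, died) {
  if (length(scores) != length(died))
    abort_validation("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(died)
  scores <- scores[keep]; died <- died[keep]
  if (!all(died %in% c(0, 1))) abort_validation("labels must be 0/1")
  n_pos <- sum(died == 1); n_neg <- sum(died == 0)
  if (n_pos == 0 || n_neg == 0)
    abort_validation("degenerate ROC: both label classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(scores[died == 1] < t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[died == 0] >= t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec,
                                    youden_j = sens + spec - 1),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Select the operating cutoff from an ROC
#'
#' Default criterion is Youden's J (sensitivity + specificity - 1); ties are
#' broken toward the smaller threshold, which calls more patients low risk.
#' Alternative criteria are raw accuracy and closest-to-(0,1) distance, for
#' reporting how sensitive the chosen cutoff is to the criterion.
#'
#' @param roc A [roc_curve()] result.
#' @param criterion `"youden"` (default), `"accuracy"`, or
#'   `"closest_topleft"`.
#' @return The selected cutoff (numeric scalar). Patients with
#'   `score >= cutoff` are low risk.
#' @export
select_cutoff <- function(roc, criterion = c("youden", "accuracy", "closest_topleft")) {
  stopifnot(inherits(roc, "roc_result"))
  criterion <- match.arg(criterion)
  cv <- roc$curve
  obj <- switch(criterion,
    # J rescaled by n_pos*n_neg is an integer count (TP*n_neg + TN*n_pos -
    # n_pos*n_neg); rounding removes float noise so that mathematically tied
    # thresholds compare as exactly tied
    youden = round((cv$sensitivity + cv$specificity - 1) * roc$n_pos * roc$n_neg),
    accuracy = round(cv$sensitivity * roc$n_pos + cv$specificity * roc$n_neg),
    closest_topleft = -((1 - cv$sensitivity)^2 + (1 - cv$specificity)^2))
  cv$threshold[which.max(obj)]   # which.max takes the first, i.e. smallest
}

#' @export
print.roc_result <- function(x, ...) {
  j <- which.max(x$curve$youden_j)
  cat(sprintf("<roc_result> %d died / %d survived; AUC = %.4f; max J = %.3f at %.4g\n",
              x$n_pos, x$n_neg, x$auc, x$curve$youden_j[j], x$curve$threshold[j]))
  invisible(x)
}
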