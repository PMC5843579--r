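#' Root mean square error
#'
#' `rmse()` is the fitting-set error, `rmsep()` the identical quantity
#' computed on external (test) predictions — reported separately because the
#' two play different roles in model evaluation.
#'
#' @param obs,pred Observed and predicted numeric vectors of equal length.
#' @return A single non-negative number, on the response scale.
#' @export
rmse <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("length mismatch", call. = FALSE)
  if (length(obs) < 1) stop("need at least one observation", call. = FALSE)
  sqrt(mean((obs - pred)^2))
}

#' @rdname rmse
#' @export
rmsep <- function(obs, pred) rmse(obs, pred)

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - RSS/TSS}: the fraction of response variance explained by
#' the predictions. Independent of the response scale, unlike RMSE.
#'
#' @param obs,pred Observed and predicted numeric vectors.
#' @return A number at most 1 (negative when predictions do worse than the
#'   mean).
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("length mismatch", call. = FALSE)
  tss <- sum((obs - mean(obs))^2)
  if (tss == 0) stop("constant observed response: R2 undefined", call. = FALSE)
  1 - sum((obs - pred)^2) / tss
}

#' External predictive squared correlation coefficient
#'
#' \deqn{Q^2 = 1 - \frac{\sum_{test}(y_i - \hat y_i)^2 / n_{EXT}}
#'                      {\sum_{train}(y_i - \bar y_{TR})^2 / n_{TR}}}
#'
#' The test-set mean squared error is referenced against the *training* set
#' variance around the training mean, which makes the statistic independent
#' of the response scale, invariant for a fixed RMSEP, and invariant to how
#' the external set is split into subsets.
#'
#' @param obs_test,pred_test Observed and predicted responses of the external
#'   set.
#' @param obs_train Observed responses of the training set.
#' @return A number at most 1.
#' @export
q_squared <- function(obs_test, pred_test, obs_train) {
  if (length(obs_test) != length(pred_test)) stop("length mismatch", call. = FALSE)
  if (length(obs_test) < 1) stop("need at least one external observation",
                                 call. = FALSE)
  denom <- sum((obs_train - mean(obs_train))^2) / length(obs_train)
  if (denom == 0) stop("constant training response: Q2 undefined", call. = FALSE)
  1 - mean((obs_test - pred_test)^2) / denom
}

#' Sensitivity, specificity and balanced accuracy from confusion counts
#'
#' \eqn{Sn = TP/(TP+FN)}, \eqn{Sp = TN/(TN+FP)},
#' \eqn{BA = (Sn+Sp)/2}, expressed as ratios (not percentages). In a binary
#' problem the Sn of one class is the Sp of the other.
#'
#' @param tp,tn,fp,fn Confusion-matrix counts.
#' @return A one-row tibble with columns `Sn`, `Sp`, `BA`.
#' @export
#' @examples
#' classification_metrics(tp = 8, tn = 6, fp = 4, fn = 2)
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn == 0 || tn + fp == 0) {
    stop("empty class: sensitivity/specificity undefined", call. = FALSE)
  }
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  tibble::tibble(Sn = sn, Sp = sp, BA = (sn + sp) / 2)
}

#' Confusion counts of a binary prediction
#'
#' @param obs,pred Observed and predicted class labels (factors or character).
#' @param positive The class counted as positive; defaults to the first
#'   factor level of `obs`.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(obs, pred, positive = NULL) {
  obs <- as_class_factor(obs)
  positive <- positive %||% levels(obs)[1]
  o <- as.character(obs) == positive
  p <- as.character(pred) == positive
  tibble::tibble(tp = sum(o & p), tn = sum(!o & !p),
                 fp = sum(!o & p), fn = sum(o & !p))
}

#' Balanced accuracy of predicted labels
#'
#' Binary problems use \eqn{(Sn + Sp)/2}; with more than two classes the
#' macro-average of per-class recalls is returned.
#'
#' @inheritParams confusion_counts
#' @return A single number in `[0, 1]`.
#' @export
balanced_accuracy <- function(obs, pred) {
  obs <- as_class_factor(obs)
  pred <- as.character(pred)
  recalls <- vapply(levels(obs), function(cl) {
    in_cl <- as.character(obs) == cl
    if (!any(in_cl)) stop("empty class: ", cl, call. = FALSE)
    mean(pred[in_cl] == cl)
  }, numeric(1))
  mean(recalls)
}
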