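#' Interval classification of a pooled activation
#'
#' A region of interest is called amyloid-positive when its pooled activation
#' lies inside the transfer window: `alpha <= q <= alpha + beta` (endpoints
#' inclusive). Activation above the upper bound counts as overdetection and
#' classifies as 0.
#'
#' @param q Pooled activation(s).
#' @param p A [transfer_params()].
#' @return Integer vector of 0/1 labels.
#' @export
classify_roi <- function(q, p = transfer_params()) {
  as.integer(q >= p$alpha & q <= p$alpha + p$beta)
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Traces the ROC over all score thresholds (ties grouped) and integrates by
#' the trapezoid rule; equivalent to the Mann-Whitney statistic with
#' half-credit for ties.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores Numeric scores, larger = more positive.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_trapezoid <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  P <- sum(y_true == 1); N <- sum(y_true == 0)
  if (P == 0 || N == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  grp_last <- c(s[-1] != s[-length(s)], TRUE) # last index of each tie group
  tp <- cumsum(y == 1)[grp_last] / P
  fp <- cumsum(y == 0)[grp_last] / N
  tp <- c(0, tp); fp <- c(0, fp)
  sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
}

#' Classification metrics report
#'
#' Confusion-derived accuracy, sensitivity, specificity, precision and F1
#' (harmonic mean of precision and sensitivity), plus AUC-ROC when scores are
#' provided.
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @param scores Optional numeric scores for the AUC.
#' @return A list of class `metrics_report`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- if (!is.null(scores)) auc_trapezoid(y_true, scores) else NA_real_
  structure(list(accuracy = (tp + tn) / length(y_true),
                 sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1, auc_roc = auc,
                 tp = tp, fp = fp, tn = tn, fn = fn),
            class = "metrics_report")
}

#' Select the final model epoch
#'
#' The epoch with the highest validation specificity is chosen, taking the
#' other metrics into account: degenerate single-class epochs (sensitivity 0
#' or specificity 0) are not eligible when any non-degenerate epoch exists,
#' since an all-negative epoch scores specificity 1 while detecting nothing.
#' Ties are broken by the higher F1, then by the earlier epoch.
#'
#' @param per_epoch Data frame with columns `specificity`, `f1` and
#'   optionally `sensitivity` (one row per epoch), or a list of
#'   `metrics_report`s.
#' @return 1-based epoch index.
#' @export
select_model <- function(per_epoch) {
  if (is.list(per_epoch) && !is.data.frame(per_epoch)) {
    per_epoch <- data.frame(
      specificity = vapply(per_epoch, function(m) m$specificity, numeric(1)),
      f1 = vapply(per_epoch, function(m) m$f1, numeric(1)),
      sensitivity = vapply(per_epoch, function(m) m$sensitivity, numeric(1)))
  }
  stopifnot(nrow(per_epoch) >= 1)
  spec <- ifelse(is.na(per_epoch$specificity), -Inf, per_epoch$specificity)
  f1 <- ifelse(is.na(per_epoch$f1), -Inf, per_epoch$f1)
  idx <- seq_along(spec)
  if (!is.null(per_epoch$sensitivity)) {
    ok <- !is.na(per_epoch$sensitivity) & per_epoch$sensitivity > 0 &
      !is.na(per_epoch$specificity) & per_epoch$specificity > 0
    if (any(ok)) { spec <- spec[ok]; f1 <- f1[ok]; idx <- idx[ok] }
  }
  idx[order(-spec, -f1, seq_along(spec))[1]]
}
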