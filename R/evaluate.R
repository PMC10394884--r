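# Classifier evaluation: confusion metrics, ROC/AUC, Bayes posterior
# probabilities of true status given the prediction, and PCA separation
# diagnostics on the signature probes.

#' Confusion-matrix metrics
#'
#' Case is the positive class. Returns counts and the derived rates:
#' sensitivity tp/(tp+fn), specificity tn/(tn+fp), false-negative rate
#' 1 - sensitivity, accuracy, and balanced accuracy
#' (sensitivity + specificity)/2.
#'
#' @param truth,predicted equal-length \code{"case"}/\code{"control"}
#'   vectors; truth must contain both classes.
#' @return list of class \code{eval_report}.
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_cpg("truth and predicted must have equal length")
  truth <- check_labels(truth, length(truth))
  tp <- sum(truth == "case" & predicted == "case")
  fn <- sum(truth == "case" & predicted == "control")
  tn <- sum(truth == "control" & predicted == "control")
  fp <- sum(truth == "control" & predicted == "case")
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 fnr = 1 - sens,
                 accuracy = (tp + tn) / length(truth),
                 balanced_accuracy = (sens + spec) / 2,
                 auc = NA_real_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Confusion: TP", x$tp, " FP", x$fp, " TN", x$tn, " FN", x$fn, "\n")
  cat(sprintf("sensitivity %.3f  specificity %.3f  FNR %.3f\n",
              x$sensitivity, x$specificity, x$fnr))
  cat(sprintf("accuracy %.3f  balanced accuracy %.3f", x$accuracy,
              x$balanced_accuracy))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random case scores above
#' a random control, with half credit for ties; the ROC is the step curve
#' over all score thresholds.
#'
#' @param truth \code{"case"}/\code{"control"} vector with both classes.
#' @param prob numeric case scores (higher = more case-like).
#' @return list with \code{roc} (data.frame threshold, fpr, tpr) and
#'   \code{auc}.
#' @export
roc_auc <- function(truth, prob) {
  truth <- check_labels(truth, length(prob))
  pos <- prob[truth == "case"]; neg <- prob[truth == "control"]
  if (length(unique(prob)) == 1L) {
    warning("constant scores; AUC is 0.5 by convention")
    auc <- 0.5
  } else {
    # rank-based Mann-Whitney with midranks for ties
    r <- rank(prob)
    auc <- (sum(r[truth == "case"]) - length(pos) * (length(pos) + 1) / 2) /
      (length(pos) * length(neg))
  }
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)))
  list(roc = roc, auc = auc)
}

#' Bayes posterior probabilities of true status given the prediction
#'
#' Given a classifier's sensitivity P(PM|M), specificity P(notPM|notM) and a
#' prior mutation prevalence P(M), evaluates by Bayes' theorem the
#' posterior probability of true mutation given a positive prediction,
#' P(M|PM) = P(PM|M) P(M) / P(PM), and given a negative prediction,
#' P(M|notPM) = P(notPM|M) P(M) / P(notPM), with the marginals from the law
#' of total probability.
#'
#' @param sensitivity,specificity classifier rates in (0,1).
#' @param prior prior probability of mutation in (0,1), e.g. the case
#'   prevalence of the training cohort.
#' @return list: \code{prior}, \code{p_pm} (marginal positive-prediction
#'   probability), \code{p_m_given_pm}, \code{p_m_given_not_pm}.
#' @export
bayes_posteriors <- function(sensitivity, specificity, prior) {
  for (v in c(sensitivity, specificity))
    if (!is.finite(v) || v < 0 || v > 1)
      stop_cpg("sensitivity and specificity must lie in [0,1]")
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop_cpg("prior must lie strictly inside (0,1)")
  fnr <- 1 - sensitivity; fpr <- 1 - specificity
  p_pm <- sensitivity * prior + fpr * (1 - prior)
  p_not_pm <- fnr * prior + specificity * (1 - prior)
  list(prior = prior, p_pm = p_pm,
       p_m_given_pm = if (p_pm > 0) sensitivity * prior / p_pm else NA_real_,
       p_m_given_not_pm = if (p_not_pm > 0) fnr * prior / p_not_pm else NA_real_)
}

#' PCA projection of samples on a probe subset
#'
#' Principal components of the samples over (typically) the signature
#' probes, probe-centred but not scaled; missing betas are imputed to the
#' probe mean with a warning. Used to visualize case/control separation
#' along PC1.
#'
#' @param betas probes x samples beta matrix (>= 2 probes, >= 3 samples).
#' @return list: \code{scores} (samples x components),
#'   \code{variance_fraction} (per component, sums to 1),
#'   \code{rotation}.
#' @export
pca_projection <- function(betas) {
  if (nrow(betas) < 2 || ncol(betas) < 3)
    stop_cpg("PCA needs >= 2 probes and >= 3 samples")
  if (anyNA(betas)) {
    warning("missing betas imputed to probe means for PCA")
    for (i in seq_len(nrow(betas)))
      betas[i, is.na(betas[i, ])] <- mean(betas[i, ], na.rm = TRUE)
  }
  pc <- prcomp(t(betas), center = TRUE, scale. = FALSE)
  list(scores = pc$x,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
       rotation = pc$rotation)
}
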