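#' Fit a CpG methylation signature of mutation status
#'
#' The central model-fitting routine: runs the full repeated
#' random-sampling engine ([run_resampling()]) across a ladder of
#' training-set sizes, summarizes test errors per size with 95 percent
#' confidence intervals, picks the winning size by the lowest CI upper
#' bound and the best model within it ([select_best_model()]), tabulates
#' per-CpG inclusion probabilities at the winning size, and (optionally)
#' tunes the classification threshold to maximize balanced accuracy on the
#' full data set.
#'
#' @param betas probes x samples beta matrix in \[0,1\] (missing allowed).
#' @param labels per-sample status, \code{"case"}/\code{"control"}; case is
#'   the positive class throughout.
#' @param sizes training-set sizes; default five sizes spanning 20 to 80
#'   percent of the sample count.
#' @param replicates random splits per size (default 50).
#' @param grid a [signature_grid()] of hyperparameters searched by the
#'   inner 10-fold cross-validation.
#' @param k inner cross-validation folds.
#' @param seed master seed; the entire fit is a deterministic function of
#'   it and the data.
#' @param tune if TRUE, tune the threshold on the full data set after
#'   selection (default), otherwise keep 0.5.
#' @return object of class \code{cpg_signature} with components
#'   \code{signature} (probes, coefficients, intercept, threshold,
#'   training means), \code{models}, \code{size_summary},
#'   \code{inclusion}, \code{winning_size} and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{plot}.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cases = 30, n_controls = 50,
#'                                      n_probes = 300, seed = 7))
#' fit <- fit_cpg_signature(cohort$betas, cohort$samples$status,
#'                          sizes = c(30, 50), replicates = 3,
#'                          grid = signature_grid(n_keep = 10, alpha = 1,
#'                                                lambda = c(0.1, 0.02)),
#'                          k = 5, seed = 1)
#' coef(fit)
#' @export
fit_cpg_signature <- function(betas, labels, sizes = NULL, replicates = 50,
                              grid = signature_grid(), k = 10, seed = 1L,
                              tune = TRUE) {
  check_beta_matrix(betas)
  labels <- check_labels(labels, ncol(betas))
  n <- length(labels)
  if (is.null(sizes))
    sizes <- unique(pmax(2L * k, as.integer(round(seq(0.2, 0.8, length.out = 5) * n))))
  models <- run_resampling(betas, labels, sizes, replicates, grid = grid,
                           seed = seed, k = k)
  size_summary <- summarize_sizes(models, error = "misclass")
  sel <- select_best_model(models, size_summary)
  inclusion <- inclusion_probability(models, size = sel$winning_size)
  signature <- sel$signature
  if (tune) signature <- tune_threshold(signature, betas, labels)
  structure(list(signature = signature, models = models,
                 size_summary = size_summary, inclusion = inclusion,
                 winning_size = sel$winning_size, best_model = sel$model,
                 n_samples = n, seed = seed, call = match.call()),
            class = "cpg_signature")
}

#' @export
print.cpg_signature <- function(x, ...) {
  cat("CpG methylation signature (", length(x$signature$probes),
      " probes)\n", sep = "")
  cat("  winning training size:", x$winning_size, "of", x$n_samples,
      "samples;", length(x$models), "candidate models\n")
  cat("  test misclassification of best model:",
      format(x$best_model$err_misclass, digits = 3), "\n")
  cat("  classification threshold:", format(x$signature$threshold, digits = 3), "\n")
  cat("  probes:", paste(x$signature$probes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cpg_signature <- function(object, ...) {
  cat("Per-size test error (misclassification, 95% CI):\n")
  print(object$size_summary, row.names = FALSE)
  cat("\nSignature coefficients (log-odds per unit beta):\n")
  print(coef(object))
  cat("\nInclusion probabilities at winning size",
      object$winning_size, "(top 10):\n")
  print(head(object$inclusion, 10), row.names = FALSE)
  invisible(object)
}

#' @export
coef.cpg_signature <- function(object, ...) {
  c("(Intercept)" = unname(object$signature$intercept),
    object$signature$coefficients)
}

#' Predict from a fitted CpG signature
#'
#' @param object a \code{cpg_signature} fit.
#' @param newdata probes x samples beta matrix containing the signature
#'   probes.
#' @param type \code{"response"} for case probabilities, \code{"class"}
#'   for labels at the fitted threshold, \code{"both"} for the full
#'   data.frame.
#' @param ... unused.
#' @export
predict.cpg_signature <- function(object, newdata,
                                  type = c("response", "class", "both"), ...) {
  type <- match.arg(type)
  out <- predict_signature(object$signature, newdata)
  switch(type,
         response = setNames(out$probability, out$sample_id),
         class = setNames(out$label, out$sample_id),
         both = out)
}

#' Plot test error against training-set size
#'
#' Mean misclassification error with its 95 percent confidence band across
#' training sizes; the winning size is highlighted.
#'
#' @param x a \code{cpg_signature} fit.
#' @param ... passed to \code{plot.default}.
#' @importFrom graphics arrows points
#' @export
plot.cpg_signature <- function(x, ...) {
  s <- x$size_summary
  plot(s$train_size, s$mean_err, type = "b", pch = 19,
       ylim = range(c(s$ci_low, s$ci_high)),
       xlab = "training-set size", ylab = "misclassification error", ...)
  nz <- s$ci_high - s$ci_low > 1e-12  # zero-width bars draw as points only
  if (any(nz))
    arrows(s$train_size[nz], s$ci_low[nz], s$train_size[nz], s$ci_high[nz],
           angle = 90, code = 3, length = 0.04)
  win <- s[s$train_size == x$winning_size, ]
  points(win$train_size, win$mean_err, col = 2, cex = 1.6, lwd = 2)
  invisible(x)
}
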