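# Signature selection: moderated-t feature screening and elastic-net
# logistic regression nested inside repeated stratified random sampling
# across training-set sizes, with CI-based size selection, per-CpG
# inclusion probabilities and threshold tuning.

#' Screen features by moderated t-statistic
#'
#' Ranks probes by the absolute empirical-Bayes moderated t-statistic
#' computed on the training samples only and returns the strongest
#' \code{n_keep}; ties broken by probe id. Deterministic given its input.
#'
#' @param betas probes x samples beta matrix (training samples only).
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @param n_keep number of probes to keep (> 0).
#' @return character vector of probe ids, strongest first.
#' @export
screen_features <- function(betas, labels, n_keep) {
  if (n_keep <= 0) stop_cpg("n_keep must be > 0")
  if (n_keep > nrow(betas)) stop_cpg("n_keep exceeds the number of probes")
  ranking <- screening_ranking(betas, labels)
  ranking[seq_len(n_keep)]
}

# full screening order (used so one ranking serves every n_keep in a grid)
screening_ranking <- function(betas, labels) {
  rec <- suppressWarnings(moderated_t_test(betas, labels))
  rec$probe_id[order(-abs(rec$t_mod), rec$probe_id)]
}

#' Fit an elastic-net penalized logistic regression at fixed hyperparameters
#'
#' Minimizes the mean binomial deviance plus
#' \eqn{\lambda[\alpha \|w\|_1 + (1-\alpha)\|w\|_2^2/2]} via glmnet, with
#' internal standardization of features and coefficients reported on the
#' original beta scale. Features with a coefficient of exactly zero are
#' dropped from the returned feature list.
#'
#' @param x samples x features numeric matrix (no missing values).
#' @param y per-sample labels (\code{"case"}/\code{"control"}); case is the
#'   positive class.
#' @param alpha elastic-net mixing in \[0,1\] (1 = lasso).
#' @param lambda penalty strength (> 0).
#' @return list with \code{features}, \code{coefficients} (nonzero only),
#'   \code{intercept}, and \code{all_coefficients} on the full feature set.
#' @export
fit_penalized_logistic <- function(x, y, alpha, lambda) {
  if (any(!is.finite(x))) stop_cpg("non-finite values in feature matrix")
  if (ncol(x) < 2) stop_cpg("need >= 2 features for a penalized fit")
  y01 <- as.integer(check_labels(y, nrow(x)) == "case")
  if (lambda <= 0) stop_cpg("lambda must be > 0")
  if (alpha < 0 || alpha > 1) stop_cpg("alpha must be in [0,1]")
  path <- lambda_path(x, y01, alpha, lambda)
  fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = alpha,
                        lambda = path, standardize = TRUE)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- rownames(fit$beta)
  beta[abs(beta) < 1e-10] <- 0  # coordinate-descent dust is a zero
  nz <- beta != 0
  list(features = names(beta)[nz], coefficients = beta[nz],
       intercept = fit$a0[[ncol(fit$beta)]], all_coefficients = beta)
}

# decreasing warm-start path ending exactly at the requested lambda
lambda_path <- function(x, y01, alpha, lambda) {
  n <- nrow(x)
  xs <- scale(x)
  xs[is.nan(xs)] <- 0  # constant columns
  r <- y01 - mean(y01)
  lmax <- max(abs(crossprod(xs, r))) / (n * max(alpha, 1e-3))
  if (lambda >= lmax) return(lambda)
  rev(sort(unique(c(lambda, exp(seq(log(lmax), log(lambda), length.out = 25))))))
}

#' Hyperparameter grid for signature selection
#'
#' Cartesian grid over screening size, elastic-net mixing and penalty
#' strength. The default covers moderate screening sizes, mostly-sparse
#' mixing values, and a 30-point log-spaced lambda ladder.
#'
#' @param n_keep vector of screening sizes.
#' @param alpha vector of elastic-net mixing values in \[0,1\].
#' @param lambda vector of penalty strengths (> 0).
#' @return object of class \code{signature_grid} (a list of the three
#'   vectors, validated).
#' @export
signature_grid <- function(n_keep = c(10, 50, 100),
                           alpha = c(0.1, 0.5, 0.9, 1.0),
                           lambda = exp(seq(log(0.25), log(0.0025),
                                            length.out = 30))) {
  if (!length(n_keep) || !length(alpha) || !length(lambda))
    stop_cpg("empty hyperparameter grid")
  if (any(n_keep <= 0) || any(lambda <= 0) || any(alpha < 0 | alpha > 1))
    stop_cpg("invalid grid values")
  structure(list(n_keep = sort(unique(n_keep)),
                 alpha = sort(unique(alpha)),
                 lambda = sort(unique(lambda), decreasing = TRUE)),
            class = "signature_grid")
}

# stratified k-fold assignment; refolds (new derived seed) when a fold
# loses a class, at most 10 attempts
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  seeds <- derive_seeds(seed, 10)
  for (attempt in 1:10) {
    set.seed(seeds[attempt])
    fold <- integer(n)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold != f])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stop_cpg("could not build stratified folds with both classes in every training part")
}

# column-mean imputation fitted on training rows only
impute_train_test <- function(xtr, xte) {
  mu <- colMeans(xtr, na.rm = TRUE)
  mu[is.nan(mu)] <- 0.5
  for (j in seq_along(mu)) {
    xtr[is.na(xtr[, j]), j] <- mu[j]
    if (!is.null(xte)) xte[is.na(xte[, j]), j] <- mu[j]
  }
  list(train = xtr, test = xte, means = mu)
}

binomial_deviance <- function(y01, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * (y01 * log(p) + (1 - y01) * log(1 - p))
}

#' Select hyperparameters by stratified k-fold cross-validation
#'
#' Grid search minimizing the mean out-of-fold binomial deviance. The
#' moderated-t screening is re-run inside every fold on the fold-training
#' samples only, so no information from held-out samples leaks into
#' feature selection. Ties are broken toward the smaller screening size,
#' then the larger penalty, then the smaller mixing value. Deterministic
#' given \code{seed}.
#'
#' @param betas probes x samples beta matrix (the training set).
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @param grid a [signature_grid()].
#' @param k number of folds.
#' @param seed integer seed controlling fold assignment.
#' @return list with \code{n_keep}, \code{alpha}, \code{lambda} (the
#'   winning point) and \code{cv_deviance}, the full grid with mean
#'   deviances.
#' @export
cross_validate_hyperparams <- function(betas, labels, grid = signature_grid(),
                                       k = 10, seed = 1L) {
  stopifnot(inherits(grid, "signature_grid"))
  labels <- check_labels(labels, ncol(betas))
  if (ncol(betas) < k) stop_cpg("training set smaller than the number of folds")
  fold <- stratified_folds(labels, k, seed)
  lambdas <- grid$lambda
  dims <- c(length(grid$n_keep), length(grid$alpha), length(lambdas))
  dev_sum <- array(0, dims)
  y01 <- as.integer(labels == "case")
  for (f in seq_len(k)) {
    tr <- fold != f
    if (!any(!tr)) next
    ranking <- screening_ranking(betas[, tr, drop = FALSE], labels[tr])
    for (i in seq_along(grid$n_keep)) {
      feats <- ranking[seq_len(min(grid$n_keep[i], length(ranking)))]
      imp <- impute_train_test(t(betas[feats, tr, drop = FALSE]),
                               t(betas[feats, !tr, drop = FALSE]))
      for (j in seq_along(grid$alpha)) {
        fit <- glmnet::glmnet(imp$train, y01[tr], family = "binomial",
                              alpha = grid$alpha[j], lambda = lambdas,
                              standardize = TRUE)
        p <- predict(fit, newx = imp$test, s = lambdas, type = "response")
        for (l in seq_along(lambdas))
          dev_sum[i, j, l] <- dev_sum[i, j, l] +
            sum(binomial_deviance(y01[!tr], p[, l]))
      }
    }
  }
  mean_dev <- dev_sum / length(labels)
  cv <- expand.grid(n_keep = grid$n_keep, alpha = grid$alpha,
                    lambda = lambdas, KEEP.OUT.ATTRS = FALSE)
  cv$deviance <- as.vector(mean_dev)
  # min deviance; ties -> smaller n_keep, then larger lambda, then smaller alpha
  ord <- order(cv$deviance, cv$n_keep, -cv$lambda, cv$alpha)
  best <- cv[ord[1], ]
  list(n_keep = best$n_keep, alpha = best$alpha, lambda = best$lambda,
       cv_deviance = cv)
}

# stratified train/test split of a given training size
stratified_split <- function(labels, size, seed) {
  n <- length(labels)
  if (size >= n) stop_cpg("training size ", size, " must be smaller than n = ", n)
  idx_case <- which(labels == "case"); idx_ctrl <- which(labels == "control")
  n_case_tr <- round(size * length(idx_case) / n)
  n_case_tr <- min(max(n_case_tr, 1L), length(idx_case) - 1L)
  n_ctrl_tr <- size - n_case_tr
  if (n_ctrl_tr < 1L || n_ctrl_tr > length(idx_ctrl) - 1L)
    stop_cpg("training size ", size, " leaves a test set without both classes")
  set.seed(seed)
  train <- c(sample(idx_case, n_case_tr), sample(idx_ctrl, n_ctrl_tr))
  sort(train)
}

#' Repeated random-sampling model fitting across training-set sizes
#'
#' For each training-set size and replicate: draw a stratified random
#' train/test split, select hyperparameters by in-training 10-fold
#' cross-validation ([cross_validate_hyperparams()]), refit on the entire
#' training set at the selected hyperparameters, and score the left-out
#' test set with three error measures (misclassification at threshold 0.5,
#' mean squared error of the predicted probability / Brier score, and mean
#' absolute error). Per-replicate seeds are derived deterministically from
#' the master seed, so the full run is bit-reproducible.
#'
#' @param betas probes x samples beta matrix.
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @param sizes integer vector of training-set sizes (< number of samples).
#' @param replicates number of random splits per size.
#' @param grid a [signature_grid()].
#' @param seed master integer seed.
#' @param k folds for the inner cross-validation.
#' @return object of class \code{candidate_models}: a list of candidate
#'   models, each carrying its split, hyperparameters, nonzero features and
#'   coefficients, intercept, training means and the three test errors.
#' @export
run_resampling <- function(betas, labels, sizes, replicates, grid = signature_grid(),
                           seed = 1L, k = 10) {
  check_beta_matrix(betas)
  labels <- check_labels(labels, ncol(betas))
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) >= length(labels))
    stop_cpg("largest training size must be below the sample count")
  combos <- expand.grid(rep = seq_len(replicates), size = sizes,
                        KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(derive_seeds(seed, 2L * nrow(combos)), ncol = 2)
  models <- vector("list", nrow(combos))
  y01 <- as.integer(labels == "case")
  for (m in seq_len(nrow(combos))) {
    size <- combos$size[m]; rep_i <- combos$rep[m]
    split_seed <- seeds[m, 1]; cv_seed <- seeds[m, 2]
    tr <- stratified_split(labels, size, split_seed)
    te <- setdiff(seq_along(labels), tr)
    if (length(unique(labels[te])) < 2L)
      stop_cpg("size ", size, " leaves a single-class test set")
    hp <- cross_validate_hyperparams(betas[, tr, drop = FALSE], labels[tr],
                                     grid = grid, k = k, seed = cv_seed)
    ranking <- screening_ranking(betas[, tr, drop = FALSE], labels[tr])
    feats <- ranking[seq_len(hp$n_keep)]
    imp <- impute_train_test(t(betas[feats, tr, drop = FALSE]),
                             t(betas[feats, te, drop = FALSE]))
    fit <- fit_penalized_logistic(imp$train, labels[tr], hp$alpha, hp$lambda)
    p_te <- plogis(fit$intercept +
                     as.numeric(imp$test %*% fit$all_coefficients))
    pred <- as.integer(p_te >= 0.5)
    models[[m]] <- list(
      train_size = size, replicate = rep_i, seed = split_seed,
      hyperparams = hp[c("n_keep", "alpha", "lambda")],
      features = fit$features, coefficients = fit$coefficients,
      intercept = fit$intercept,
      train_means = imp$means[fit$features],
      train_idx = tr,
      err_misclass = mean(pred != y01[te]),
      err_mse = mean((p_te - y01[te])^2),
      err_mae = mean(abs(p_te - y01[te])))
  }
  structure(models, class = "candidate_models")
}

#' Tabulate candidate models
#'
#' One row per candidate model, features and coefficients collapsed into
#' semicolon-separated strings — the layout written to \code{models.tsv}.
#'
#' @param models a \code{candidate_models} object.
#' @return data.frame.
#' @export
models_df <- function(models) {
  stopifnot(inherits(models, "candidate_models"))
  do.call(rbind, lapply(models, function(m) data.frame(
    train_size = m$train_size, replicate = m$replicate, seed = m$seed,
    n_keep = m$hyperparams$n_keep, alpha = m$hyperparams$alpha,
    lambda = m$hyperparams$lambda,
    n_features = length(m$features),
    features = paste(m$features, collapse = ";"),
    coefficients = paste(formatC(m$coefficients, digits = 10, format = "g"),
                         collapse = ";"),
    intercept = m$intercept,
    err_misclass = m$err_misclass, err_mse = m$err_mse, err_mae = m$err_mae,
    stringsAsFactors = FALSE)))
}

#' Per-size error summaries with 95 percent confidence intervals
#'
#' Mean of the chosen test error over replicates at each training size with
#' a t-based 95 percent confidence interval
#' (mean +/- t(0.975, R-1) * sd / sqrt(R)).
#'
#' @param models a \code{candidate_models} object.
#' @param error which test error to summarize: \code{"misclass"},
#'   \code{"mse"} or \code{"mae"}.
#' @return data.frame ordered by size: \code{train_size},
#'   \code{n_replicates}, \code{mean_err}, \code{ci_low}, \code{ci_high}.
#' @export
summarize_sizes <- function(models, error = c("misclass", "mse", "mae")) {
  stopifnot(inherits(models, "candidate_models"))
  error <- match.arg(error)
  field <- paste0("err_", error)
  sizes <- sort(unique(vapply(models, `[[`, numeric(1), "train_size")))
  out <- lapply(sizes, function(s) {
    errs <- vapply(Filter(function(m) m$train_size == s, models),
                   `[[`, numeric(1), field)
    r <- length(errs)
    if (r < 2) stop_cpg("need >= 2 replicates per size (size ", s, " has ", r, ")")
    m <- mean(errs); half <- qt(0.975, r - 1) * sd(errs) / sqrt(r)
    data.frame(train_size = s, n_replicates = r, mean_err = m,
               ci_low = m - half, ci_high = m + half)
  })
  do.call(rbind, out)
}

#' Two-stage best-model selection
#'
#' Stage 1 picks the training-set size with the lowest upper bound of the
#' 95 percent confidence interval of the mean error (ties go to the larger
#' size). Stage 2 picks, among that size's candidate models, the one with
#' the minimum test misclassification error (ties: fewer features, then
#' larger penalty, then lower replicate index). A model at another size
#' with a smaller individual error is deliberately never chosen: the size
#' is fixed first.
#'
#' @param models a \code{candidate_models} object.
#' @param summaries output of [summarize_sizes()] covering all sizes.
#' @return list: \code{signature} (probes, coefficients, intercept,
#'   threshold 0.5, training means), \code{winning_size}, \code{model}
#'   (the winning candidate).
#' @export
select_best_model <- function(models, summaries) {
  stopifnot(inherits(models, "candidate_models"))
  sizes <- vapply(models, `[[`, numeric(1), "train_size")
  if (!all(sizes %in% summaries$train_size))
    stop_cpg("summaries do not cover every size present in models")
  ord <- order(summaries$ci_high, -summaries$train_size)
  win_size <- summaries$train_size[ord[1]]
  at_size <- models[sizes == win_size]
  key <- order(vapply(at_size, `[[`, numeric(1), "err_misclass"),
               vapply(at_size, function(m) length(m$features), numeric(1)),
               -vapply(at_size, function(m) m$hyperparams$lambda, numeric(1)),
               vapply(at_size, `[[`, numeric(1), "replicate"))
  best <- at_size[[key[1]]]
  sig <- new_signature(best$features, best$coefficients, best$intercept,
                       threshold = 0.5, train_means = best$train_means)
  list(signature = sig, winning_size = win_size, model = best)
}

new_signature <- function(probes, coefficients, intercept, threshold = 0.5,
                          train_means = NULL) {
  structure(list(probes = probes, coefficients = coefficients,
                 intercept = intercept, threshold = threshold,
                 train_means = train_means),
            class = "cpg_signature_model")
}

#' Per-CpG inclusion probability at one training size
#'
#' The probability measure of how likely each CpG is to be included in the
#' candidate models developed at a training-set size: the fraction of that
#' size's models in which the probe carries a nonzero coefficient.
#'
#' @param models a \code{candidate_models} object.
#' @param size the training-set size to tabulate (default: all models).
#' @return data.frame \code{probe_id}, \code{p}, sorted by decreasing p.
#' @export
inclusion_probability <- function(models, size = NULL) {
  stopifnot(inherits(models, "candidate_models"))
  if (!is.null(size))
    models <- Filter(function(m) m$train_size == size, models)
  if (!length(models)) stop_cpg("no candidate models at the requested size")
  feats <- unlist(lapply(models, `[[`, "features"))
  tab <- table(feats) / length(models)
  out <- data.frame(probe_id = names(tab), p = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$p, out$probe_id), , drop = FALSE]
}

#' Tune the classification threshold by balanced accuracy
#'
#' Scans candidate cut-offs (midpoints between consecutive sorted unique
#' predicted probabilities, plus 0.5) on the full training set and returns
#' the signature with the threshold that maximizes balanced accuracy; ties
#' resolve toward the threshold closest to 0.5. Constant predictions keep
#' 0.5 with a warning.
#'
#' @param signature a \code{cpg_signature_model}.
#' @param betas probes x samples beta matrix (the full training set).
#' @param labels per-sample \code{"case"}/\code{"control"}.
#' @return the signature with \code{threshold} updated; attributes
#'   \code{balanced_accuracy} carries the achieved value.
#' @export
tune_threshold <- function(signature, betas, labels) {
  stopifnot(inherits(signature, "cpg_signature_model"))
  labels <- check_labels(labels, ncol(betas))
  p <- predict_signature(signature, betas)$probability
  u <- sort(unique(p))
  if (length(u) < 2) {
    warning("constant predicted probabilities; keeping threshold 0.5")
    attr(signature, "balanced_accuracy") <-
      balanced_accuracy_at(p, labels, 0.5)
    return(signature)
  }
  cand <- unique(c((u[-1] + u[-length(u)]) / 2, 0.5))
  ba <- vapply(cand, balanced_accuracy_at, numeric(1), p = p, labels = labels)
  best_ba <- max(ba)
  winners <- cand[ba == best_ba]
  thr <- winners[order(abs(winners - 0.5), winners)][1]
  signature$threshold <- thr
  attr(signature, "balanced_accuracy") <- best_ba
  signature
}

balanced_accuracy_at <- function(p, labels, thr) {
  pred <- ifelse(p >= thr, "case", "control")
  sens <- mean(pred[labels == "case"] == "case")
  spec <- mean(pred[labels == "control"] == "control")
  (sens + spec) / 2
}

#' Predict case probabilities and labels from a signature
#'
#' probability = logistic(intercept + sum(coef * beta)); a sample is
#' labelled \code{case} when its probability is at or above the signature's
#' threshold. Missing betas at signature probes are imputed with the
#' training means stored in the signature.
#'
#' @param signature a \code{cpg_signature_model}.
#' @param betas probes x samples beta matrix containing all signature probes.
#' @return data.frame \code{sample_id}, \code{probability}, \code{label}.
#' @export
predict_signature <- function(signature, betas) {
  stopifnot(inherits(signature, "cpg_signature_model"))
  miss <- setdiff(signature$probes, rownames(betas))
  if (length(miss))
    stop_cpg("signature probes absent from beta matrix: ",
             paste(miss, collapse = ", "))
  if (length(signature$probes)) {
    x <- betas[signature$probes, , drop = FALSE]
    mu <- signature$train_means %||% rowMeans(x, na.rm = TRUE)
    for (i in seq_len(nrow(x))) x[i, is.na(x[i, ])] <- mu[[i]]
    eta <- signature$intercept + as.numeric(signature$coefficients %*% x)
  } else {
    eta <- rep(signature$intercept, ncol(betas))
  }
  prob <- plogis(eta)
  data.frame(sample_id = colnames(betas), probability = prob,
             label = ifelse(prob >= signature$threshold, "case", "control"),
             stringsAsFactors = FALSE)
}
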