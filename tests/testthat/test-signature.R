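test_that("screening keeps the most discriminative probes deterministically", {
  set.seed(10)
  m <- matrix(rbeta(100 * 40, 2, 2), nrow = 100,
              dimnames = list(sprintf("cg%03d", 1:100), sprintf("s%02d", 1:40)))
  labels <- rep(c("case", "control"), each = 20)
  m["cg050", ] <- c(rep(0.9, 20), rep(0.1, 20))  # perfect separator
  expect_equal(screen_features(m, labels, 1), "cg050")
  expect_setequal(screen_features(m, labels, 100), rownames(m))
  expect_identical(screen_features(m, labels, 10), screen_features(m, labels, 10))
  expect_error(screen_features(m, labels, 0), "n_keep")
})

test_that("screening recovers planted probes within the top 50", {
  hits <- 0L
  for (s in 1:20) {
    co <- simulate_cohort(sim_config(n_cases = 50, n_controls = 50,
                                     n_probes = 1000, n_signal_hypo = 5,
                                     delta_hypo = 0.3, missing_rate = 0,
                                     seed = 1000 + s))
    top <- screen_features(co$betas, co$samples$status, 50)
    if (all(co$truth$probe_id %in% top)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("penalized logistic fits honor the elastic-net limits", {
  set.seed(3)
  n <- 60
  x <- cbind(f1 = c(rnorm(n / 2, 2), rnorm(n / 2, -2)), f2 = rnorm(n))
  y <- rep(c("case", "control"), each = n / 2)
  # full-shrinkage limit: zero coefficients, intercept = log-odds prevalence
  big <- fit_penalized_logistic(x, y, alpha = 1, lambda = 50)
  expect_length(big$features, 0)
  expect_equal(unname(big$intercept), qlogis(0.5), tolerance = 1e-6)
  yub <- rep(c("case", "control"), c(20, 40))
  big2 <- fit_penalized_logistic(x[1:60, ], yub, alpha = 1, lambda = 50)
  expect_equal(unname(big2$intercept), qlogis(1 / 3), tolerance = 1e-6)

  # ridge at tiny lambda reproduces the unpenalized fit's labels
  ridge <- fit_penalized_logistic(x, y, alpha = 0, lambda = 1e-5)
  glm_fit <- glm((y == "case") ~ x, family = binomial)
  p_ridge <- plogis(as.numeric(ridge$intercept + x %*% ridge$all_coefficients))
  expect_equal(p_ridge >= 0.5, unname(fitted(glm_fit) >= 0.5))

  # lasso keeps at most one of two duplicated features
  xd <- cbind(a = x[, 1], b = x[, 1], c = rnorm(n))
  las <- fit_penalized_logistic(xd, y, alpha = 1, lambda = 0.05)
  expect_lte(sum(c("a", "b") %in% las$features), 1L)
  expect_error(fit_penalized_logistic(x, rep("case", n), 1, 0.1), "both classes")
})

test_that("cross-validation selects sensible hyperparameters deterministically", {
  co <- std_cohort()
  betas <- co$betas; labels <- co$samples$status
  g1 <- signature_grid(n_keep = 5, alpha = 1, lambda = 0.05)
  hp <- cross_validate_hyperparams(betas, labels, g1, k = 5, seed = 2)
  expect_equal(hp[c("n_keep", "alpha", "lambda")],
               list(n_keep = 5, alpha = 1, lambda = 0.05))
  # huge vs moderate penalty on separable data: moderate wins on deviance
  g2 <- signature_grid(n_keep = 5, alpha = 1, lambda = c(50, 0.05))
  hp2 <- cross_validate_hyperparams(betas, labels, g2, k = 5, seed = 2)
  expect_equal(hp2$lambda, 0.05)
  hp3 <- cross_validate_hyperparams(betas, labels, g2, k = 5, seed = 2)
  expect_identical(hp2$cv_deviance, hp3$cv_deviance)
})

test_that("resampling produces one scored candidate model per size and replicate", {
  co <- std_cohort()
  models <- cached("std_models", run_resampling(
    co$betas, co$samples$status, sizes = c(30, 60), replicates = 3,
    grid = tiny_grid(), seed = 5, k = 5))
  expect_length(models, 6L)
  expect_equal(vapply(models, `[[`, numeric(1), "train_size"),
               rep(c(30, 60), each = 3))
  df <- models_df(models)
  expect_true(all(df$err_misclass >= 0 & df$err_misclass <= 1))
  expect_true(all(df$n_features == lengths(lapply(models, `[[`, "features"))))
})

test_that("a candidate model is a function of its training data alone", {
  co <- std_cohort()
  models <- cached("std_models", run_resampling(
    co$betas, co$samples$status, sizes = c(30, 60), replicates = 3,
    grid = tiny_grid(), seed = 5, k = 5))
  m <- models[[1]]
  tr <- m$train_idx
  # reproduce the derived per-replicate cv seed (combo 1 of 6, second column)
  all_seeds <- cpgmark:::derive_seeds(5, 12)
  cv_seed <- matrix(all_seeds, ncol = 2)[1, 2]
  # refit from the training slice only; coefficients must be bit-identical
  hp <- cross_validate_hyperparams(co$betas[, tr], co$samples$status[tr],
                                   grid = tiny_grid(), k = 5, seed = cv_seed)
  feats <- screen_features(co$betas[, tr], co$samples$status[tr], hp$n_keep)
  xtr <- t(co$betas[feats, tr])
  mu <- colMeans(xtr, na.rm = TRUE)
  for (j in seq_along(mu)) xtr[is.na(xtr[, j]), j] <- mu[j]
  refit <- fit_penalized_logistic(xtr, co$samples$status[tr],
                                  hp$alpha, hp$lambda)
  expect_identical(refit$coefficients, m$coefficients)
  expect_identical(refit$intercept, m$intercept)
})

test_that("null-label resampling errors hover at the minority prevalence", {
  co <- std_cohort()
  set.seed(123)
  null_labels <- sample(co$samples$status)  # breaks the probe-label link
  # then shuffle betas columns relative to labels to destroy all signal
  models <- run_resampling(co$betas[, sample(ncol(co$betas))], null_labels,
                           sizes = 50, replicates = 5,
                           grid = signature_grid(n_keep = 5, alpha = 1,
                                                 lambda = c(0.2, 0.05)),
                           seed = 9, k = 5)
  s <- summarize_sizes(models)
  expect_gt(s$mean_err, 0.15)   # minority prevalence is 0.4
  expect_lt(s$mean_err, 0.65)
})

test_that("per-size summaries use the t-based confidence interval", {
  fake <- structure(lapply(1:4, function(i) list(
    train_size = c(20, 20, 40, 40)[i], replicate = c(1, 2, 1, 2)[i],
    seed = i, hyperparams = list(n_keep = 5, alpha = 1, lambda = 0.1),
    features = "cg1", coefficients = c(cg1 = 1), intercept = 0,
    train_means = c(cg1 = 0.5), train_idx = 1:20,
    err_misclass = c(0, 0.2, 0.1, 0.1)[i],
    err_mse = 0.1, err_mae = 0.1)), class = "candidate_models")
  s <- summarize_sizes(fake)
  expect_equal(s$train_size, c(20, 40))
  expect_equal(s$mean_err[1], 0.1)
  half <- qt(0.975, 1) * sd(c(0, 0.2)) / sqrt(2)
  expect_equal(s$ci_high[1], 0.1 + half, tolerance = 1e-12)
  expect_equal(s$ci_low[2], 0.1)
  expect_equal(s$ci_high[2], 0.1)
  expect_error(summarize_sizes(structure(fake[1], class = "candidate_models")),
               ">= 2 replicates")
})

test_that("best-model selection fixes the size before the model", {
  mk <- function(size, rep, err, feats = c("cg1", "cg2"), lambda = 0.1) {
    list(train_size = size, replicate = rep, seed = rep,
         hyperparams = list(n_keep = 5, alpha = 1, lambda = lambda),
         features = feats, coefficients = setNames(rep(1, length(feats)), feats),
         intercept = 0, train_means = setNames(rep(0.5, length(feats)), feats),
         train_idx = 1:size, err_misclass = err, err_mse = err, err_mae = err)
  }
  models <- structure(list(mk(20, 1, 0.05), mk(20, 2, 0.40),
                           mk(40, 1, 0.15), mk(40, 2, 0.20)),
                      class = "candidate_models")
  summ <- data.frame(train_size = c(20, 40), n_replicates = 2,
                     mean_err = c(0.225, 0.175),
                     ci_low = c(0, 0.1), ci_high = c(0.3, 0.2))
  sel <- select_best_model(models, summ)
  # size 40 wins on ci_high although the global best error (0.05) sits at 20
  expect_equal(sel$winning_size, 40)
  expect_equal(sel$model$err_misclass, 0.15)

  # brute-force re-selection oracle on a randomized model list
  set.seed(4)
  rnd <- structure(lapply(1:30, function(i)
    mk(sample(c(20, 40, 60), 1), i, round(runif(1), 2),
       feats = sprintf("cg%d", seq_len(sample(1:3, 1))),
       lambda = sample(c(0.1, 0.2), 1))), class = "candidate_models")
  summ_r <- summarize_sizes(rnd)
  sel_r <- select_best_model(rnd, summ_r)
  win <- summ_r$train_size[order(summ_r$ci_high, -summ_r$train_size)][1]
  cand <- Filter(function(m) m$train_size == win, rnd)
  errs <- vapply(cand, `[[`, numeric(1), "err_misclass")
  expect_equal(sel_r$winning_size, win)
  expect_equal(sel_r$model$err_misclass, min(errs))
})

test_that("inclusion probabilities are nonzero-coefficient frequencies", {
  mk <- function(feats) list(train_size = 20, replicate = 1, seed = 1,
                             hyperparams = list(n_keep = 5, alpha = 1, lambda = 0.1),
                             features = feats,
                             coefficients = setNames(rep(1, length(feats)), feats),
                             intercept = 0, train_means = NULL, train_idx = 1:20,
                             err_misclass = 0, err_mse = 0, err_mae = 0)
  models <- structure(c(replicate(98, mk(c("cgA", "cgB")), simplify = FALSE),
                        replicate(2, mk("cgB"), simplify = FALSE)),
                      class = "candidate_models")
  inc <- inclusion_probability(models, 20)
  expect_equal(inc$p[inc$probe_id == "cgA"], 0.98)
  expect_equal(inc$p[inc$probe_id == "cgB"], 1)
  expect_false("cgZ" %in% inc$probe_id)  # never selected -> absent (p = 0)
})

test_that("threshold tuning maximizes balanced accuracy over midpoints", {
  sig <- structure(list(probes = "cg1", coefficients = c(cg1 = 20),
                        intercept = -10, threshold = 0.5, train_means = NULL),
                   class = "cpg_signature_model")
  # perfectly separated: gap midpoint closest to 0.5, BA = 1
  b <- matrix(c(0.9, 0.95, 0.1, 0.05), nrow = 1,
              dimnames = list("cg1", paste0("s", 1:4)))
  labels <- c("case", "case", "control", "control")
  tuned <- tune_threshold(sig, b, labels)
  expect_equal(attr(tuned, "balanced_accuracy"), 1)
  p <- predict_signature(sig, b)$probability
  gaps <- sort(unique(p))
  mids <- (gaps[-1] + gaps[-length(gaps)]) / 2
  ok <- vapply(mids, function(t) all((p >= t) == (labels == "case")), logical(1))
  expect_true(tuned$threshold %in% c(mids[ok], 0.5))
  expect_equal(tuned$threshold,
               c(mids[ok], 0.5)[which.min(abs(c(mids[ok], 0.5) - 0.5))])

  # 6-sample toy vs exhaustive grid-search oracle
  b6 <- matrix(qlogis(c(0.1, 0.3, 0.45, 0.55, 0.6, 0.9)) / 20 + 0.5, nrow = 1,
               dimnames = list("cg1", paste0("t", 1:6)))
  l6 <- c("control", "case", "control", "case", "control", "case")
  tuned6 <- tune_threshold(sig, b6, l6)
  p6 <- predict_signature(sig, b6)$probability
  u <- sort(unique(p6)); cand <- unique(c((u[-1] + u[-length(u)]) / 2, 0.5))
  ba <- vapply(cand, function(t) {
    pred <- ifelse(p6 >= t, "case", "control")
    (mean(pred[l6 == "case"] == "case") +
       mean(pred[l6 == "control"] == "control")) / 2
  }, numeric(1))
  expect_equal(attr(tuned6, "balanced_accuracy"), max(ba))
  ba_05 <- ba[cand == 0.5]
  expect_gte(attr(tuned6, "balanced_accuracy"), ba_05)

  # degenerate constant predictions keep 0.5
  sig0 <- sig; sig0$coefficients <- c(cg1 = 0)
  expect_warning(t0 <- tune_threshold(sig0, b, labels), "constant")
  expect_equal(t0$threshold, 0.5)
})

test_that("signature prediction applies the >= threshold rule and imputation", {
  sig <- structure(list(probes = c("cg1", "cg2"),
                        coefficients = c(cg1 = 2, cg2 = -1),
                        intercept = 0.5, threshold = 0.7,
                        train_means = c(cg1 = 0.4, cg2 = 0.6)),
                   class = "cpg_signature_model")
  b <- matrix(c(0.5, 0.2, NA, 0.8), nrow = 2,
              dimnames = list(c("cg1", "cg2"), c("sA", "sB")))
  out <- predict_signature(sig, b)
  expect_equal(out$probability[1], plogis(0.5 + 2 * 0.5 - 1 * 0.2))
  expect_equal(out$probability[2], plogis(0.5 + 2 * 0.4 - 1 * 0.8))
  # probability exactly at threshold classifies as case
  sigt <- sig; sigt$threshold <- out$probability[1]
  expect_equal(predict_signature(sigt, b)$label[1], "case")
  # zero coefficients: all probabilities collapse to logistic(intercept)
  sigz <- sig; sigz$coefficients[] <- 0
  expect_equal(unique(predict_signature(sigz, b)$probability), plogis(0.5))
  expect_error(predict_signature(sig, b[1, , drop = FALSE]), "cg2")
})

test_that("a signature built from the planted truth separates the cohort", {
  co <- simulate_cohort(sim_config(n_cases = 100, n_controls = 100,
                                   n_probes = 200, n_signal_hypo = 3,
                                   delta_hypo = 0.3, missing_rate = 0,
                                   seed = 55))
  pr <- co$truth$probe_id
  sig <- structure(list(probes = pr,
                        coefficients = setNames(rep(-15, 3), pr),
                        intercept = 15 * 3 * 0.65, threshold = 0.5,
                        train_means = NULL),
                   class = "cpg_signature_model")
  p <- predict_signature(sig, co$betas)$probability
  expect_gte(roc_auc(co$samples$status, p)$auc, 0.95)
})

test_that("the umbrella fit returns a signature with working methods", {
  co <- std_cohort()
  fit <- cached("std_fit", fit_cpg_signature(
    co$betas, co$samples$status, sizes = c(40, 70), replicates = 3,
    grid = tiny_grid(), k = 5, seed = 17))
  expect_s3_class(fit, "cpg_signature")
  expect_true(fit$winning_size %in% c(40, 70))
  cf <- coef(fit)
  expect_equal(names(cf)[1], "(Intercept)")
  pr <- predict(fit, co$betas)
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(fit, co$betas, type = "class")
  expect_true(all(cl %in% c("case", "control")))
  expect_output(print(fit), "CpG methylation signature")
  expect_output(summary(fit), "Inclusion probabilities")
  # plot method draws without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
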