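# shared fixtures, generated in code; cached per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# mid-sized cohort with 3 planted hypo + 2 planted hyper probes
std_cohort <- function() cached("std", {
  simulate_cohort(sim_config(n_cases = 40, n_controls = 60, n_probes = 500,
                             n_signal_hypo = 3, n_signal_hyper = 2,
                             delta_hypo = 0.3, delta_hyper = 0.3,
                             missing_rate = 0.02, seed = 11))
})

# tiny hyperparameter grid used wherever the full grid would be overkill
tiny_grid <- function() signature_grid(
  n_keep = c(5, 10), alpha = c(0.5, 1),
  lambda = exp(seq(log(0.2), log(0.01), length.out = 8)))

# pooled two-sample t-statistics, coded independently of moderated_t_test
pooled_t_oracle <- function(betas, labels) {
  case <- betas[, labels == "case", drop = FALSE]
  ctrl <- betas[, labels == "control", drop = FALSE]
  vapply(seq_len(nrow(betas)), function(i) {
    x <- case[i, ][!is.na(case[i, ])]; y <- ctrl[i, ][!is.na(ctrl[i, ])]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }, numeric(1))
}

# step-up BH oracle written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# two-sided hypergeometric p by exhaustive enumeration of the support
hyper_oracle <- function(k_fore, n_fore, k_back, n_back) {
  support <- max(0, n_fore - (n_back - k_back)):min(n_fore, k_back)
  probs <- dhyper(support, k_back, n_back - k_back, n_fore)
  p_obs <- dhyper(k_fore, k_back, n_back - k_back, n_fore)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all-pairs Mann-Whitney AUC with half credit for ties
auc_oracle <- function(truth, prob) {
  pos <- prob[truth == "case"]; neg <- prob[truth == "control"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# per-cut standardized log-rank statistic computed from scratch:
# O - E via the hypergeometric summation at event times, standardized by
# the permutation variance of the linear log-rank statistic
maxstat_oracle <- function(beta, time, event, minprop = 0.1) {
  n <- length(beta)
  ut <- sort(unique(time[event == 1]))
  scores <- vapply(seq_len(n), function(i) {
    lam <- sum(vapply(ut[ut <= time[i]], function(u)
      sum(event[time == u]) / sum(time >= u), numeric(1)))
    event[i] - lam
  }, numeric(1))
  vtot <- sum((scores - mean(scores))^2)
  ub <- sort(unique(beta))
  cuts <- (ub[-1] + ub[-length(ub)]) / 2
  lo <- ceiling(minprop * n)
  keep <- vapply(cuts, function(ct) {
    n1 <- sum(beta <= ct); n1 >= lo && (n - n1) >= lo
  }, logical(1))
  cuts <- cuts[keep]
  z <- vapply(cuts, function(ct) {
    g <- beta <= ct; n1 <- sum(g)
    v <- n1 * (n - n1) / (n * (n - 1)) * vtot
    abs(sum(scores[g])) / sqrt(v)
  }, numeric(1))
  list(cuts = cuts, z = z, best = cuts[which.max(z)])
}
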