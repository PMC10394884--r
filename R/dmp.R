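# Differential methylation: empirical-Bayes moderated t-tests on beta
# values, BH correction, direction calls, genomic-region enrichment and the
# pan-negative confounder-removal comparison.

#' Filter probes by missingness and variance
#'
#' Drops probes missing in more than \code{max_missing_frac} of samples,
#' then keeps the top \code{variance_top_frac} fraction (by ceiling) of the
#' most variable surviving probes, variance computed over non-missing
#' entries. Standard pre-processing before differential methylation on
#' array data.
#'
#' @param betas probes x samples beta matrix.
#' @param max_missing_frac maximal tolerated missing fraction per probe.
#' @param variance_top_frac fraction of most-variable probes to retain.
#' @return the filtered beta matrix (same samples).
#' @export
preprocess_betas <- function(betas, max_missing_frac = 0.5,
                             variance_top_frac = 0.25) {
  check_beta_matrix(betas)
  miss <- rowMeans(is.na(betas))
  kept <- betas[miss <= max_missing_frac, , drop = FALSE]
  if (!nrow(kept)) stop_cpg("all probes removed by the missingness filter")
  v <- apply(kept, 1, var, na.rm = TRUE)
  v[is.na(v)] <- -Inf  # probes with < 2 observations rank last
  n_keep <- ceiling(variance_top_frac * nrow(kept))
  ord <- order(v, decreasing = TRUE)
  kept[sort(ord[seq_len(n_keep)]), , drop = FALSE]
}

# Newton inversion of the trigamma function (for the moment estimator of
# the prior degrees of freedom); monotone decreasing on (0, Inf)
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < 1e-10) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderated two-group t-test per probe
#'
#' For each probe, the two-group effect is the difference of group means of
#' beta values, with pooled residual variance s^2 on d = n1 + n2 - 2
#' degrees of freedom (missing entries dropped per probe). A scaled
#' inverse-chi-square prior (d0, s0^2) is estimated across probes by the
#' method of moments on log s^2; the posterior variance
#' (d0 s0^2 + d s^2) / (d0 + d) shrinks probe variances toward the prior,
#' and the moderated t-statistic is referred to a t distribution on d + d0
#' degrees of freedom. Probes with fewer than two observed values in either
#' group are excluded (a single warning reports the count).
#'
#' @param betas probes x samples beta matrix.
#' @param labels per-sample status, \code{"case"}/\code{"control"};
#'   effects are case minus control.
#' @param prior_df \code{"moment"} (default) to estimate d0 across probes,
#'   or a fixed numeric value: \code{0} disables moderation (ordinary
#'   pooled t), \code{Inf} uses the common prior variance for every probe.
#' @return data.frame with one row per tested probe: \code{probe_id},
#'   group means, \code{delta_beta}, \code{s2}, \code{df}, \code{t_mod},
#'   \code{df_total}, \code{p}, \code{p_adj} (BH across tested probes).
#'   Attributes \code{d0} and \code{s0_2} carry the fitted prior.
#' @export
moderated_t_test <- function(betas, labels, prior_df = "moment") {
  check_beta_matrix(betas)
  labels <- check_labels(labels, ncol(betas))
  case <- betas[, labels == "case", drop = FALSE]
  ctrl <- betas[, labels == "control", drop = FALSE]
  n1 <- rowSums(!is.na(case)); n2 <- rowSums(!is.na(ctrl))
  ok <- n1 >= 2 & n2 >= 2
  if (!all(ok))
    warning(sum(!ok), " probe(s) excluded: fewer than 2 observed values per group")
  if (!any(ok)) stop_cpg("no testable probes")
  case <- case[ok, , drop = FALSE]; ctrl <- ctrl[ok, , drop = FALSE]
  n1 <- n1[ok]; n2 <- n2[ok]
  m1 <- rowMeans(case, na.rm = TRUE); m2 <- rowMeans(ctrl, na.rm = TRUE)
  ss1 <- rowSums((case - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((ctrl - m2)^2, na.rm = TRUE)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  prior <- fit_variance_prior(s2, d, prior_df)
  d0 <- prior$d0; s0_2 <- prior$s0_2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- (m1 - m2) / se
  df_total <- d + d0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  out <- data.frame(probe_id = rownames(case), n_case = n1, n_control = n2,
                    mean_beta_case = m1, mean_beta_control = m2,
                    delta_beta = m1 - m2, s2 = s2, df = d,
                    t_mod = t_mod, df_total = df_total, p = p,
                    p_adj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior on
# the log-variance scale: with s^2 ~ s0^2 F(d, d0),
#   E[log s^2]  = log s0^2 + digamma(d/2) - log(d/2)
#                          - digamma(d0/2) + log(d0/2)
#   Var[log s^2] = trigamma(d/2) + trigamma(d0/2)
fit_variance_prior <- function(s2, d, prior_df) {
  z <- log(pmax(s2, 1e-12))
  # the digamma(d0/2) - log(d0/2) bias term vanishes as d0 -> Inf
  s0_scale <- function(d0) {
    bias <- if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0
    exp(mean(z) - mean(digamma(d / 2) - log(d / 2)) + bias)
  }
  if (is.numeric(prior_df)) {
    d0 <- prior_df
    if (d0 < 0) stop_cpg("prior_df must be >= 0")
    return(list(d0 = d0, s0_2 = if (d0 == 0) 0 else s0_scale(d0)))
  }
  if (!identical(prior_df, "moment")) stop_cpg("prior_df must be 'moment' or numeric")
  if (length(z) < 2) return(list(d0 = Inf, s0_2 = s0_scale(Inf)))
  evar <- var(z) - mean(trigamma(d / 2))
  if (!is.finite(evar) || evar <= 0) {
    warning("non-positive moment estimate of prior variance; using d0 = Inf (full shrinkage)")
    d0 <- Inf
  } else {
    d0 <- 2 * trigamma_inverse(evar)
  }
  list(d0 = d0, s0_2 = s0_scale(d0))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop_cpg("p-values must be finite and in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significant hypo-/hypermethylated probes
#'
#' Significance is a strict \code{p_adj < alpha}; direction follows the
#' sign of delta beta (case minus control). A significant probe with delta
#' beta exactly zero is inconsistent and rejected.
#'
#' @param records data.frame from [moderated_t_test()].
#' @param alpha adjusted-p significance cut-off.
#' @return list with data.frames \code{hypo} and \code{hyper}.
#' @export
call_dmps <- function(records, alpha = 0.05) {
  stopifnot(all(c("p_adj", "delta_beta") %in% names(records)))
  sig <- records[records$p_adj < alpha, , drop = FALSE]
  if (any(sig$delta_beta == 0))
    stop_cpg("significant probe with delta_beta exactly 0: direction undefined")
  hypo <- sig[sig$delta_beta < 0, , drop = FALSE]
  hyper <- sig[sig$delta_beta > 0, , drop = FALSE]
  hypo$direction <- if (nrow(hypo)) "hypo" else character()
  hyper$direction <- if (nrow(hyper)) "hyper" else character()
  list(hypo = hypo, hyper = hyper)
}

#' Select the top fraction of records by absolute delta beta
#'
#' Returns the \code{ceiling(fraction * n)} records with the largest
#' absolute methylation difference; ties broken by smaller adjusted p, then
#' probe id.
#'
#' @param records data.frame with \code{delta_beta}, \code{p_adj},
#'   \code{probe_id}.
#' @param fraction fraction to keep (default 0.10, i.e. the top 10 percent).
#' @return subset of \code{records}.
#' @export
top_fraction_by_delta <- function(records, fraction = 0.10) {
  if (!nrow(records)) stop_cpg("no records to rank")
  k <- ceiling(fraction * nrow(records))
  ord <- order(-abs(records$delta_beta), records$p_adj, records$probe_id)
  records[ord[seq_len(k)], , drop = FALSE]
}

#' Genomic-region enrichment of a probe set
#'
#' Tests, per region category, whether the foreground probe set is enriched
#' or depleted relative to a background set (typically the whole array),
#' with a two-sided hypergeometric (Fisher exact) test. Direction follows
#' the sign of the foreground-minus-background proportion difference at
#' p < 0.05.
#'
#' @param foreground character vector of probe ids (subset of background).
#' @param manifest probe manifest annotating both sets.
#' @param background character vector of probe ids.
#' @return data.frame with one row per region: counts, proportions, odds
#'   ratio, p-value, direction.
#' @export
region_enrichment <- function(foreground, manifest, background) {
  if (!length(foreground)) stop_cpg("empty foreground set")
  manifest <- validate_manifest(manifest)
  if (!all(foreground %in% background))
    stop_cpg("foreground must be a subset of background")
  miss <- setdiff(background, manifest$probe_id)
  if (length(miss)) stop_cpg(length(miss), " probes not annotated in manifest")
  reg <- setNames(manifest$region, manifest$probe_id)
  fore_reg <- reg[foreground]; back_reg <- reg[background]
  n_fore <- length(foreground); n_back <- length(background)
  out <- lapply(REGION_LEVELS, function(r) {
    k_fore <- sum(fore_reg == r); k_back <- sum(back_reg == r)
    tab <- matrix(c(k_fore, n_fore - k_fore,
                    k_back - k_fore, (n_back - n_fore) - (k_back - k_fore)),
                  nrow = 2)
    ft <- fisher.test(tab)
    prop_f <- k_fore / n_fore; prop_b <- k_back / n_back
    dir <- if (ft$p.value >= 0.05 || prop_f == prop_b) "none"
           else if (prop_f > prop_b) "enriched" else "depleted"
    data.frame(region = r, k_fore = k_fore, n_fore = n_fore,
               k_back = k_back, n_back = n_back,
               proportion_fore = prop_f, proportion_back = prop_b,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               enrichment_direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Differential methylation against pan-negative samples
#'
#' Removes every sample (case or control) flagged mutant for any of the
#' named confounder genes, then reruns the moderated t-test with BH
#' correction on the remainder. This disentangles the focal mutation's
#' methylation signal from co-occurring drivers: controls become
#' "pan-negative" wild types and cases are purged of carriers.
#'
#' @param betas probes x samples beta matrix.
#' @param samples sample sheet with \code{status} and one flag column per
#'   confounder gene (\code{mutant}/\code{wild-type}/\code{unknown};
#'   unknown is treated as wild-type).
#' @param confounders character vector of confounder gene column names.
#' @return list: \code{records} (moderated test results),
#'   \code{excluded} (named counts of dropped cases and controls),
#'   \code{kept_samples}.
#' @export
pan_negative_compare <- function(betas, samples, confounders) {
  check_beta_matrix(betas)
  samples <- validate_sample_sheet(samples)
  miss <- setdiff(confounders, names(samples))
  if (length(miss))
    stop_cpg("confounder flag column(s) missing from sample sheet: ",
             paste(miss, collapse = ", "))
  samples <- samples[match(colnames(betas), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop_cpg("sample sheet does not cover all beta-matrix samples")
  flags <- samples[, confounders, drop = FALSE] == "mutant"
  carrier <- rowSums(flags, na.rm = TRUE) > 0
  excluded <- c(case = sum(carrier & samples$status == "case"),
                control = sum(carrier & samples$status == "control"))
  keep <- !carrier
  kept_labels <- samples$status[keep]
  if (sum(kept_labels == "case") < 2 || sum(kept_labels == "control") < 2)
    stop_cpg("fewer than 2 samples remain in a group after pan-negative filtering")
  records <- moderated_t_test(betas[, keep, drop = FALSE], kept_labels)
  list(records = records, excluded = excluded,
       kept_samples = samples$sample_id[keep])
}
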