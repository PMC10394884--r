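# Synthetic 450K-style cohorts with planted case/control methylation
# structure, a correlated confounder mutation, linked expression and
# survival. Everything is deterministic given the config seed.

# baseline group means for planted probe classes: gene bodies start highly
# methylated (hypomethylation is a loss from a high baseline), promoters
# start lowly methylated
BASE_MEAN_HYPO  <- 0.80   # control mean of planted gene-body probes
BASE_MEAN_HYPER <- 0.15   # control mean of planted promoter probes
BASE_MEAN_CONF  <- 0.70   # baseline of confounder-only probes
CONF_DELTA      <- -0.30  # shift applied in confounder-positive samples
CONTROL_CONF_RATE <- 0.10 # background confounder prevalence in controls

#' Configuration for a simulated methylation cohort
#'
#' Bundles and validates the knobs of [simulate_cohort()]. Defaults emulate
#' a mid-sized renal-cancer 450K cohort: a case:control imbalance of about
#' 30:70, bimodal background methylation, a handful of planted gene-body
#' probes hypomethylated in cases and promoter probes hypermethylated in
#' cases, a confounder mutation co-occurring with case status, and sparse
#' missingness.
#'
#' @param n_cases,n_controls sample counts per group.
#' @param n_probes total number of probes on the simulated array.
#' @param region_mix named proportions over the region vocabulary
#'   (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, IGR); must sum to 1.
#'   The default follows the rough composition of the 450K array (gene
#'   bodies about a third of probes).
#' @param n_signal_hypo planted gene-body probes hypomethylated in cases.
#' @param n_signal_hyper planted promoter (TSS200/TSS1500) probes
#'   hypermethylated in cases.
#' @param delta_hypo,delta_hyper mean beta shift magnitudes in (0,1).
#' @param concentration beta-distribution precision (> 0); per-entry values
#'   are Beta(mean * concentration, (1 - mean) * concentration).
#' @param missing_rate fraction of entries masked missing completely at
#'   random, in \[0,1).
#' @param confounder_cooccurrence probability that a case also carries the
#'   confounder mutation (controls carry it at rate 0.1).
#' @param confounder_signal number of probes shifted only in
#'   confounder-positive samples (by -0.3 from a 0.7 baseline).
#' @param n_genes number of genes for the expression component.
#' @param survival_link_probes probe ids whose beta will drive hazard in
#'   [simulate_survival()] (bookkeeping only at cohort level).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_cases = 60, n_controls = 140, n_probes = 2000,
                       region_mix = c("TSS1500" = 0.14, "TSS200" = 0.11,
                                      "5'UTR" = 0.12, "1stExon" = 0.07,
                                      "Body" = 0.32, "3'UTR" = 0.04,
                                      "IGR" = 0.20),
                       n_signal_hypo = 3, n_signal_hyper = 0,
                       delta_hypo = 0.3, delta_hyper = 0.3,
                       concentration = 12, missing_rate = 0.02,
                       confounder_cooccurrence = 0.6,
                       confounder_signal = 0, n_genes = 100,
                       survival_link_probes = character(), seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls, n_probes = n_probes,
              n_signal_hypo = n_signal_hypo, n_signal_hyper = n_signal_hyper,
              confounder_signal = confounder_signal, n_genes = n_genes)
  if (any(counts < 0)) stop_cpg("all counts must be >= 0")
  if (n_signal_hypo + n_signal_hyper + confounder_signal > n_probes)
    stop_cpg("planted probe counts exceed n_probes")
  if (!setequal(names(region_mix), REGION_LEVELS))
    stop_cpg("region_mix must be named over: ", paste(REGION_LEVELS, collapse = ", "))
  region_mix <- region_mix[REGION_LEVELS]
  if (any(region_mix < 0) || abs(sum(region_mix) - 1) > 1e-9)
    stop_cpg("region_mix entries must be >= 0 and sum to 1")
  for (d in c(delta_hypo = delta_hypo, delta_hyper = delta_hyper))
    if (d < 0 || d >= 1) stop_cpg("delta shifts must lie in [0,1)")
  if (BASE_MEAN_HYPO - delta_hypo <= 0)
    stop_cpg("infeasible shift for hypomethylated gene-body probes: case mean ",
             BASE_MEAN_HYPO - delta_hypo, " outside (0,1)")
  if (BASE_MEAN_HYPER + delta_hyper >= 1)
    stop_cpg("infeasible shift for hypermethylated promoter probes: case mean ",
             BASE_MEAN_HYPER + delta_hyper, " outside (0,1)")
  if (concentration <= 0) stop_cpg("concentration must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop_cpg("missing_rate must be in [0,1)")
  if (confounder_cooccurrence < 0 || confounder_cooccurrence > 1)
    stop_cpg("confounder_cooccurrence must be in [0,1]")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_probes = n_probes, region_mix = region_mix,
                 n_signal_hypo = n_signal_hypo, n_signal_hyper = n_signal_hyper,
                 delta_hypo = delta_hypo, delta_hyper = delta_hyper,
                 concentration = concentration, missing_rate = missing_rate,
                 confounder_cooccurrence = confounder_cooccurrence,
                 confounder_signal = confounder_signal, n_genes = n_genes,
                 survival_link_probes = survival_link_probes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rbeta_mean <- function(n, mean, conc) {
  rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Simulate a 450K-style methylation cohort
#'
#' Background probes draw per-probe baseline means from a bimodal mixture
#' (half low-methylated around 0.15, half high-methylated around 0.85, the
#' familiar two-hump beta-value landscape); per-entry values are Beta
#' distributed around the probe mean with precision
#' \code{config$concentration}. Planted hypomethylated probes are gene-body
#' probes whose case mean is the control mean minus \code{delta_hypo};
#' planted hypermethylated probes are promoter (TSS200/TSS1500) probes
#' shifted up by \code{delta_hyper}. Confounder probes shift only in
#' samples carrying the confounder mutation, which co-occurs with case
#' status at rate \code{confounder_cooccurrence} (0.1 in controls).
#' Entries are masked missing completely at random. Betas are sampled
#' directly on the beta scale (recorded in \code{meta$beta_model}).
#'
#' @param config a [sim_config()].
#' @return list of class \code{sim_cohort} with elements \code{betas}
#'   (probes x samples matrix), \code{manifest}, \code{samples},
#'   \code{expression} (baseline, see [simulate_expression()] for linked
#'   expression), \code{gene_tss}, \code{truth} (planted probe ids with
#'   direction and source) and \code{meta}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  p <- config$n_probes
  sample_ids <- sprintf("S%03d", seq_len(n))
  status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  probe_ids <- sprintf("cg%08d", seq_len(p))

  # manifest: multinomial region draw, then force planted probes' regions
  region <- sample(REGION_LEVELS, p, replace = TRUE, prob = config$region_mix)
  idx_hypo <- idx_hyper <- idx_conf <- integer()
  planted_total <- config$n_signal_hypo + config$n_signal_hyper + config$confounder_signal
  if (planted_total > 0) {
    planted <- sample.int(p, planted_total)
    idx_hypo  <- planted[seq_len(config$n_signal_hypo)]
    idx_hyper <- planted[config$n_signal_hypo + seq_len(config$n_signal_hyper)]
    idx_conf  <- planted[config$n_signal_hypo + config$n_signal_hyper +
                           seq_len(config$confounder_signal)]
    region[idx_hypo] <- "Body"
    if (length(idx_hyper))
      region[idx_hyper] <- sample(c("TSS200", "TSS1500"), length(idx_hyper),
                                  replace = TRUE)
  }
  manifest <- data.frame(
    probe_id = probe_ids,
    chrom = paste0("chr", sample(1:22, p, replace = TRUE)),
    pos = sample.int(5e7, p, replace = TRUE),
    gene = "",
    region = region,
    stringsAsFactors = FALSE)

  # confounder mutation flag, correlated with case status
  conf_prob <- ifelse(status == "case", config$confounder_cooccurrence,
                      CONTROL_CONF_RATE)
  confounder <- rbinom(n, 1, conf_prob)
  samples <- data.frame(sample_id = sample_ids, status = status,
                        CONF = ifelse(confounder == 1, "mutant", "wild-type"),
                        stringsAsFactors = FALSE)

  # per-probe baseline means from a bimodal mixture, truncated away from 0/1
  low <- runif(p) < 0.5
  base_mean <- ifelse(low, rbeta_mean(p, 0.15, 30), rbeta_mean(p, 0.85, 30))
  base_mean <- pmin(pmax(base_mean, 0.02), 0.98)
  base_mean[idx_hypo]  <- BASE_MEAN_HYPO
  base_mean[idx_hyper] <- BASE_MEAN_HYPER
  base_mean[idx_conf]  <- BASE_MEAN_CONF

  mean_mat <- matrix(base_mean, nrow = p, ncol = n)
  is_case <- status == "case"
  mean_mat[idx_hypo,  is_case] <- BASE_MEAN_HYPO - config$delta_hypo
  mean_mat[idx_hyper, is_case] <- BASE_MEAN_HYPER + config$delta_hyper
  mean_mat[idx_conf, confounder == 1] <- BASE_MEAN_CONF + CONF_DELTA

  conc <- config$concentration
  betas <- matrix(rbeta(p * n, c(mean_mat) * conc, (1 - c(mean_mat)) * conc),
                  nrow = p, ncol = n, dimnames = list(probe_ids, sample_ids))
  if (config$missing_rate > 0)
    betas[runif(p * n) < config$missing_rate] <- NA_real_

  truth <- data.frame(
    probe_id = probe_ids[c(idx_hypo, idx_hyper, idx_conf)],
    direction = rep(c("hypo", "hyper", "hypo"),
                    c(length(idx_hypo), length(idx_hyper), length(idx_conf))),
    source = rep(c("status", "status", "confounder"),
                 c(length(idx_hypo), length(idx_hyper), length(idx_conf))),
    stringsAsFactors = FALSE)

  # genes: TSS placed near randomly chosen probes so cis pairs exist
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  anchor <- sample.int(p, config$n_genes, replace = TRUE)
  gene_tss <- data.frame(
    gene_id = gene_ids,
    chrom = manifest$chrom[anchor],
    tss = pmax(1L, manifest$pos[anchor] +
                 as.integer(round(runif(config$n_genes, -2e5, 2e5)))),
    stringsAsFactors = FALSE)
  manifest$gene[anchor] <- gene_ids

  # constant per-gene baseline; sample-level variation enters only through
  # the methylation links and noise of simulate_expression()
  baseline_expr <- matrix(
    exp(rep(rnorm(config$n_genes, 5, 1), n)),
    nrow = config$n_genes, ncol = n, dimnames = list(gene_ids, sample_ids))

  structure(list(betas = betas, manifest = manifest, samples = samples,
                 expression = baseline_expr, gene_tss = gene_tss,
                 truth = truth,
                 meta = list(beta_model = "direct", config = config)),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated methylation cohort:",
      nrow(x$betas), "probes x", ncol(x$betas), "samples\n")
  cat("  cases:", sum(x$samples$status == "case"),
      " controls:", sum(x$samples$status == "control"), "\n")
  cat("  planted probes:", nrow(x$truth),
      " missing entries:", sum(is.na(x$betas)), "\n")
  invisible(x)
}

#' Simulate survival outcomes driven by CpG methylation
#'
#' Event times are exponential with per-sample rate
#' \code{baseline * exp(sum(coef * beta))}; censoring is an independent
#' exponential at \code{censor_rate} (no censoring when 0). Missing betas
#' at hazard probes are imputed to the probe's cohort mean.
#'
#' @param cohort a \code{sim_cohort}.
#' @param hazard_coefs named numeric vector, probe id -> log-hazard slope;
#'   may be empty for pure baseline hazard.
#' @param baseline baseline event rate (> 0, per day).
#' @param censor_rate censoring rate (>= 0).
#' @param seed integer RNG seed.
#' @return the cohort's sample sheet with \code{time} and \code{event} filled.
#' @export
simulate_survival <- function(cohort, hazard_coefs = numeric(), baseline,
                              censor_rate = 0, seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (baseline <= 0) stop_cpg("baseline hazard must be > 0")
  if (censor_rate < 0) stop_cpg("censor_rate must be >= 0")
  missing_probes <- setdiff(names(hazard_coefs), rownames(cohort$betas))
  if (length(missing_probes))
    stop_cpg("hazard probes absent from cohort: ",
             paste(missing_probes, collapse = ", "))
  set.seed(as.integer(seed))
  n <- ncol(cohort$betas)
  lp <- rep(0, n)
  for (pr in names(hazard_coefs)) {
    b <- cohort$betas[pr, ]
    b[is.na(b)] <- mean(b, na.rm = TRUE)
    lp <- lp + hazard_coefs[[pr]] * b
  }
  rate <- baseline * exp(lp)
  t_event <- rexp(n, rate)
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  out <- cohort$samples
  out$time <- pmin(t_event, t_cens)
  out$event <- as.integer(t_event <= t_cens)
  out
}

#' Simulate expression linked to nearby CpG methylation
#'
#' For each linked (probe, gene, slope) triple, log-expression is the
#' gene's baseline plus \code{slope * beta} plus Gaussian noise; values are
#' returned exponentiated on a non-negative RSEM-like scale. A linked pair
#' whose probe sits farther than 250 kb from the gene TSS is rejected,
#' since no downstream cis analysis could recover it.
#'
#' @param cohort a \code{sim_cohort}.
#' @param linked_pairs data.frame with columns \code{probe}, \code{gene},
#'   \code{slope}.
#' @param noise_sd Gaussian noise standard deviation on the log scale (>= 0).
#' @param seed integer RNG seed.
#' @return genes x samples expression matrix.
#' @export
simulate_expression <- function(cohort, linked_pairs, noise_sd = 0.3, seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (noise_sd < 0) stop_cpg("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  expr <- log(cohort$expression)
  tss <- setNames(cohort$gene_tss$tss, cohort$gene_tss$gene_id)
  tss_chrom <- setNames(cohort$gene_tss$chrom, cohort$gene_tss$gene_id)
  pos <- setNames(cohort$manifest$pos, cohort$manifest$probe_id)
  chrom <- setNames(cohort$manifest$chrom, cohort$manifest$probe_id)
  if (nrow(linked_pairs)) {
    for (i in seq_len(nrow(linked_pairs))) {
      pr <- linked_pairs$probe[i]; g <- linked_pairs$gene[i]
      if (!pr %in% names(pos)) stop_cpg("unknown probe '", pr, "'")
      if (!g %in% names(tss)) stop_cpg("unknown gene '", g, "'")
      if (chrom[[pr]] != tss_chrom[[g]] || abs(pos[[pr]] - tss[[g]]) > 250000)
        stop_cpg("linked pair (", pr, ", ", g, ") lies beyond the 250 kb cis window")
      b <- cohort$betas[pr, ]
      b[is.na(b)] <- mean(b, na.rm = TRUE)
      expr[g, ] <- expr[g, ] + linked_pairs$slope[i] * b
    }
  }
  if (noise_sd > 0)
    expr <- expr + matrix(rnorm(length(expr), sd = noise_sd), nrow = nrow(expr))
  exp(expr)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits \code{betas.tsv}, \code{samples.tsv}, \code{manifest.tsv},
#' \code{expression.tsv} and \code{truth.tsv}.
#'
#' @param cohort a \code{sim_cohort}.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$betas, file.path(dir, "betas.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  expr <- data.frame(gene_id = rownames(cohort$expression), cohort$expression,
                     check.names = FALSE)
  write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
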