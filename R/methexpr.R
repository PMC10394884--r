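# Cis methylation-expression correlation: probe-gene pairing within a
# flanking window around the gene TSS, then per-pair correlation with BH
# adjustment across all tested pairs.

#' Enumerate probe-gene pairs within a cis flanking window
#'
#' A (probe, gene) pair is formed when both lie on the same chromosome and
#' the distance between the probe position and the gene transcription
#' start site is at most \code{window} base pairs (inclusive). Probes with
#' no gene in range simply produce no pairs.
#'
#' @param manifest probe manifest (or subset) with \code{probe_id},
#'   \code{chrom}, \code{pos}.
#' @param gene_tss data.frame with \code{gene_id}, \code{chrom},
#'   \code{tss} (1-based).
#' @param window flanking distance in bp (default 250000).
#' @return data.frame \code{probe_id}, \code{gene_id}, \code{distance},
#'   each pair once.
#' @export
flanking_pairs <- function(manifest, gene_tss, window = 250000) {
  manifest <- validate_manifest(manifest)
  for (col in c("gene_id", "chrom", "tss"))
    if (!col %in% names(gene_tss)) stop_cpg("gene_tss lacks column '", col, "'")
  out <- list()
  for (ch in intersect(unique(manifest$chrom), unique(gene_tss$chrom))) {
    pr <- manifest[manifest$chrom == ch, ]
    gn <- gene_tss[gene_tss$chrom == ch, ]
    d <- abs(outer(pr$pos, gn$tss, "-"))
    hit <- which(d <= window, arr.ind = TRUE)
    if (nrow(hit))
      out[[ch]] <- data.frame(probe_id = pr$probe_id[hit[, 1]],
                              gene_id = gn$gene_id[hit[, 2]],
                              distance = d[hit],
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(probe_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$probe_id, res$gene_id), , drop = FALSE]
}

#' Correlate methylation with expression over cis pairs
#'
#' For each pair, correlates beta values against \code{log1p}-transformed
#' expression over the samples where both are observed (Pearson by
#' default, Spearman as an option), with a two-sided test and BH
#' adjustment across all tested pairs. Pairs with fewer than
#' \code{min_samples} complete observations, or a zero-variance vector,
#' are skipped with a warning count.
#'
#' @param pairs data.frame from [flanking_pairs()].
#' @param betas probes x samples beta matrix.
#' @param expression genes x samples non-negative expression matrix
#'   (shared sample ids with \code{betas}).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param min_samples minimum complete observations per pair (default 10).
#' @param alpha BH significance cut-off for the \code{significant} flag.
#' @return data.frame: pair columns plus \code{n}, \code{r}, \code{p},
#'   \code{p_adj}, \code{direction}, \code{significant}.
#' @export
correlate_pairs <- function(pairs, betas, expression,
                            method = c("pearson", "spearman"),
                            min_samples = 10, alpha = 0.05) {
  method <- match.arg(method)
  shared <- intersect(colnames(betas), colnames(expression))
  if (length(shared) < min_samples)
    stop_cpg("fewer than ", min_samples, " shared samples between betas and expression")
  skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs$probe_id[i]; g <- pairs$gene_id[i]
    if (!pr %in% rownames(betas) || !g %in% rownames(expression)) {
      skipped <- skipped + 1L; next
    }
    b <- betas[pr, shared]
    e <- log1p(expression[g, shared])
    ok <- !is.na(b) & !is.na(e)
    if (sum(ok) < min_samples || sd(b[ok]) == 0 || sd(e[ok]) == 0) {
      skipped <- skipped + 1L; next
    }
    ct <- suppressWarnings(cor.test(b[ok], e[ok], method = method))
    rows[[i]] <- data.frame(probe_id = pr, gene_id = g,
                            distance = pairs$distance[i], n = sum(ok),
                            r = unname(ct$estimate), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " pair(s) skipped (missing ids, too few samples, or zero variance)")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop_cpg("no testable pairs")
  out <- do.call(rbind, rows)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$p_adj <- bh_adjust(out$p)
  out$direction <- ifelse(out$r >= 0, "positive", "negative")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
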