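#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef predict cor cor.test fisher.test pchisq plogis
#'   prcomp psigamma pt quantile rbeta rbinom rexp rnorm runif sd var
#'   p.adjust qt setNames
#' @importFrom utils read.delim write.table head
NULL

# fixed Illumina-style region vocabulary used throughout
REGION_LEVELS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                   "3'UTR", "IGR")

STATUS_LEVELS <- c("case", "control")

stop_cpg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# validate a case/control label vector against sample count
check_labels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n)
    stop_cpg("labels length (", length(labels), ") does not match sample count (", n, ")")
  bad <- setdiff(unique(labels), STATUS_LEVELS)
  if (length(bad))
    stop_cpg("labels must be 'case'/'control'; found: ", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop_cpg("both classes ('case' and 'control') must be present")
  labels
}

check_beta_matrix <- function(betas) {
  if (!is.matrix(betas) || !is.numeric(betas))
    stop_cpg("beta matrix must be a numeric matrix (probes x samples)")
  if (is.null(rownames(betas)) || is.null(colnames(betas)))
    stop_cpg("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(betas)))
    stop_cpg("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(betas)))
    stop_cpg("duplicate sample ids in beta matrix")
  rng <- range(betas, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    idx <- which(betas < 0 | betas > 1, arr.ind = TRUE)[1, ]
    stop_cpg("beta value out of [0,1] at probe '", rownames(betas)[idx[1]],
             "', sample '", colnames(betas)[idx[2]], "'")
  }
  invisible(betas)
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seeds <- function(master, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}
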