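#' Read a beta-value matrix from TSV
#'
#' Expects a header row of sample ids and a first column of probe ids;
#' empty cells, \code{"NA"} and \code{"NaN"} are treated as missing. Values
#' must lie in \[0,1\]; violations are rejected with the offending
#' probe/sample coordinates.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, probes in rows, samples in columns.
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA", "NaN"),
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_cpg("beta matrix file needs a probe column plus >= 1 sample")
  probes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop_cpg("non-numeric entries in sample column '", names(df)[-1][bad], "'")
  }
  rownames(m) <- probes
  check_beta_matrix(m)
  m
}

#' Write a beta-value matrix as TSV
#'
#' Missing values are written as \code{NA}; \code{read_beta_matrix} inverts
#' the operation exactly.
#'
#' @param betas numeric probes x samples matrix.
#' @param path output path.
#' @export
write_beta_matrix <- function(betas, path) {
  check_beta_matrix(betas)
  df <- data.frame(probe_id = rownames(betas), betas, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires columns \code{sample_id} and \code{status} (case/control);
#' co-mutation flag columns hold \code{mutant}/\code{wild-type}/\code{unknown};
#' optional \code{time} (days > 0) and \code{event} (0/1) survival columns
#' must be present together.
#'
#' @param path path to a tab-separated file.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  for (col in c("sample_id", "status"))
    if (!col %in% names(df)) stop_cpg("sample sheet lacks required column '", col, "'")
  if (anyDuplicated(df$sample_id))
    stop_cpg("duplicate sample ids: ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$status), STATUS_LEVELS)
  if (length(bad)) stop_cpg("invalid status values: ", paste(bad, collapse = ", "))
  if (xor("time" %in% names(df), "event" %in% names(df)))
    stop_cpg("'time' and 'event' must be present together")
  if ("time" %in% names(df)) {
    if (any(!is.na(df$time) & df$time <= 0)) stop_cpg("survival times must be > 0")
    if (any(!is.na(df$event) & !df$event %in% c(0, 1))) stop_cpg("event must be 0/1")
  }
  df
}

#' Write a sample sheet as TSV
#' @param samples data.frame with at least sample_id and status.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_sample_sheet(samples)
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a probe manifest
#'
#' Columns: \code{probe_id}, \code{chrom}, \code{pos} (1-based),
#' \code{gene} (may be empty), \code{region} (one of TSS1500, TSS200,
#' 5'UTR, 1stExon, Body, 3'UTR, IGR).
#'
#' @param path path to a tab-separated file.
#' @return data.frame manifest.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"),
                   stringsAsFactors = FALSE)
  validate_manifest(df)
}

validate_manifest <- function(df) {
  for (col in c("probe_id", "chrom", "pos", "region"))
    if (!col %in% names(df)) stop_cpg("manifest lacks required column '", col, "'")
  if (anyDuplicated(df$probe_id)) stop_cpg("duplicate probe ids in manifest")
  if (any(df$pos < 1)) {
    bad <- df$probe_id[which(df$pos < 1)[1]]
    stop_cpg("manifest positions must be 1-based >= 1 (probe '", bad, "')")
  }
  bad <- setdiff(unique(df$region), REGION_LEVELS)
  if (length(bad))
    stop_cpg("unknown region categories: ", paste(bad, collapse = ", "))
  if (is.null(df$gene)) df$gene <- ""
  df
}

#' Write a probe manifest as TSV
#' @param manifest data.frame manifest.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Export a manifest as 6-column BED
#'
#' Converts the 1-based probe position to a half-open 0-based interval of
#' width 1 (chrom, pos-1, pos, probe_id, 0, .).
#'
#' @param manifest data.frame manifest.
#' @param path output path.
#' @export
manifest_to_bed <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  bed <- data.frame(manifest$chrom, manifest$pos - 1L, manifest$pos,
                    manifest$probe_id, 0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Header row of sample ids, first column gene ids; values must be
#' non-negative (RSEM-like scale).
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA", "NaN"),
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(rownames(m))) stop_cpg("duplicate gene ids in expression matrix")
  if (any(m < 0, na.rm = TRUE)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_cpg("negative expression at gene '", rownames(m)[idx[1]],
             "', sample '", colnames(m)[idx[2]], "'")
  }
  m
}

#' Split samples by the top and bottom quartile of one gene's expression
#'
#' Groups samples at or below the first quartile (low) and at or above the
#' third quartile (high) of a per-sample expression vector, the grouping
#' used to contrast low against high expressors of a gene of interest.
#' Quartiles use the linear-interpolation (type-7) convention; ties on a
#' boundary are kept, which can enlarge a group.
#'
#' @param expr named numeric vector of one gene's expression per sample.
#' @return list with character vectors \code{low} and \code{high} of sample
#'   names (indices if unnamed).
#' @export
split_by_expression_quartiles <- function(expr) {
  if (length(expr) < 8L) stop_cpg("need >= 8 samples to form quartile groups")
  if (anyNA(expr)) stop_cpg("expression vector contains missing values")
  q <- quantile(expr, c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) stop_cpg("degenerate quartiles: expression values are (nearly) all equal")
  ids <- names(expr) %||% seq_along(expr)
  low <- ids[expr <= q[1]]
  high <- ids[expr >= q[2]]
  if (!length(low) || !length(high)) stop_cpg("empty quartile group")
  list(low = low, high = high)
}
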