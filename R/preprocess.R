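#' Expression matrix container
#'
#' Tags a real-valued genes x samples matrix with its processing stage so the
#' fixed preprocessing contract — `log2(CPM + 1)` then per-gene z-score — is
#' enforced by construction rather than by convention.
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param stage one of `"raw_counts"`, `"cpm_log"`, `"zscored"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, stage = c("raw_counts", "cpm_log", "zscored")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene row names and sample column names")
  }
  if (any(!is.finite(values))) {
    stop("expression matrix contains non-finite values")
  }
  if (stage == "cpm_log" && any(values < 0)) {
    stop("cpm_log values must be non-negative")
  }
  structure(list(values = values, gene_ids = rownames(values),
                 sample_ids = colnames(values), stage = stage),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Library-size normalise counts to log2(CPM + 1)
#'
#' Per sample, counts are scaled to counts-per-million and transformed
#' `x -> log2(x + 1)`. This is the first half of the fixed preprocessing
#' contract under which SID models are trained and applied, so scores stay
#' comparable across datasets.
#'
#' @param counts a [count_matrix()].
#' @return an [expr_matrix()] at stage `cpm_log`.
#' @export
cpm_log <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- colSums(counts$counts)
  bad <- totals <= 0
  if (any(bad)) {
    stop(sprintf("sample(s) with zero total count: %s",
                 paste(counts$sample_ids[bad], collapse = ", ")))
  }
  cpm <- sweep(counts$counts, 2L, totals, "/") * 1e6
  expr_matrix(log2(cpm + 1), stage = "cpm_log")
}

#' Z-score each gene across samples
#'
#' Second half of the preprocessing contract: each gene row is centred and
#' scaled by its sample standard deviation (denominator n - 1). Constant rows
#' are set to all zeros with a warning rather than dropped, so feature-gene
#' indices of a trained model stay resolvable in any query matrix.
#'
#' @param expr an [expr_matrix()] at stage `cpm_log`.
#' @return an [expr_matrix()] at stage `zscored`.
#' @export
zscore_genes <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$stage != "cpm_log") {
    stop("zscore_genes expects a cpm_log expression matrix")
  }
  x <- expr$values
  if (ncol(x) < 2L) {
    stop("z-scoring needs at least 2 samples")
  }
  mu <- rowMeans(x)
  centered <- x - mu
  sd <- sqrt(rowSums(centered^2) / (ncol(x) - 1L))
  constant <- sd < .Machine$double.eps^0.5
  if (any(constant)) {
    warning(sprintf("%d constant gene row(s) set to zero", sum(constant)))
    sd[constant] <- 1
    centered[constant, ] <- 0
  }
  expr_matrix(centered / sd, stage = "zscored")
}

#' Preprocess counts for SID scoring
#'
#' Convenience composition `zscore_genes(cpm_log(counts))`.
#'
#' @param counts a [count_matrix()].
#' @return an [expr_matrix()] at stage `zscored`.
#' @export
preprocess_counts <- function(counts) {
  zscore_genes(cpm_log(counts))
}

#' Aggregate cells into pseudobulk samples
#'
#' Sums raw counts across all cells sharing a group label (typically donor),
#' producing a bulk-like counts matrix whose sample identifiers are the group
#' labels. Aggregation happens on raw counts — not normalised values — so the
#' count sampling model is preserved and the grand total is conserved exactly.
#'
#' @param counts a [count_matrix()].
#' @param grouping character/factor vector, one group label per sample of
#'   `counts`, or the name of a column in `metadata`.
#' @param metadata optional data.frame with `sample_id` and the grouping
#'   column, used when `grouping` is a column name.
#' @return a [count_matrix()] with one column per group.
#' @export
pseudobulk <- function(counts, grouping, metadata = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (length(grouping) == 1L && !is.null(metadata)) {
    col <- grouping
    if (!col %in% names(metadata)) {
      stop(sprintf("metadata has no column '%s'", col))
    }
    idx <- match(counts$sample_ids, metadata$sample_id)
    if (any(is.na(idx))) {
      stop("metadata does not cover all samples in the count matrix")
    }
    grouping <- metadata[[col]][idx]
  }
  if (length(grouping) != ncol(counts$counts)) {
    stop("grouping must assign exactly one group per sample")
  }
  if (any(is.na(grouping) | !nzchar(as.character(grouping)))) {
    stop("every sample must be assigned to a group")
  }
  grouping <- as.character(grouping)
  agg <- t(rowsum(t(counts$counts), group = grouping, reorder = FALSE))
  count_matrix(agg, layout = "dense")
}

#' Filter genes by total count and detection
#'
#' Retains genes with total count >= `min_total` that are detected (count > 0)
#' in at least `min_samples` samples. Gene order is preserved.
#'
#' @param counts a [count_matrix()].
#' @param min_total minimum summed count across samples (default 1).
#' @param min_samples minimum number of samples with a non-zero count
#'   (default 1).
#' @return a filtered [count_matrix()].
#' @export
filter_genes <- function(counts, min_total = 1L, min_samples = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  if (min_total < 0 || min_samples < 0) {
    stop("filter thresholds must be non-negative")
  }
  keep <- rowSums(counts$counts) >= min_total &
    rowSums(counts$counts > 0) >= min_samples
  if (!any(keep)) {
    stop("gene filter removed all genes")
  }
  out <- counts
  out$counts <- counts$counts[keep, , drop = FALSE]
  out$gene_ids <- rownames(out$counts)
  out
}
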