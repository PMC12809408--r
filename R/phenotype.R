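#' Kernel-CDF rank statistic per gene and sample
#'
#' First stage of the gene-set variation score. For each gene, the empirical
#' cumulative distribution of its `log2(CPM+1)` values across samples is
#' smoothed with a Gaussian kernel (bandwidth = per-gene sample SD / 4) and
#' evaluated at each sample's value. Within each sample the resulting CDF
#' values are then ranked across genes and mapped to a symmetric statistic
#' centred at zero: magnitude `|N/2 - rank|`, positive for genes ranked above
#' the median, negative below. Ties in ranking are broken by input gene order.
#'
#' @param expr an [expr_matrix()] at stage `cpm_log` with >= 3 samples.
#' @return numeric matrix, genes x samples, of symmetric rank statistics.
#' @export
gene_stat <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$stage != "cpm_log") {
    stop("gene_stat expects cpm_log expression")
  }
  x <- expr$values
  n <- ncol(x)
  if (n < 3L) {
    stop("gene_stat needs at least 3 samples")
  }
  p <- nrow(x)
  z <- matrix(0, p, n, dimnames = dimnames(x))
  for (i in seq_len(p)) {
    xi <- x[i, ]
    h <- stats::sd(xi) / 4
    if (h < .Machine$double.eps^0.5) {
      z[i, ] <- 0.5  # constant gene: identical statistic in every sample
    } else {
      z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h))
    }
  }
  out <- matrix(0, p, n, dimnames = dimnames(x))
  for (j in seq_len(n)) {
    # rank 1 = largest CDF value; ties broken by input gene order
    r <- rank(-z[, j], ties.method = "first")
    out[, j] <- p / 2 - r  # symmetric about zero; positive above median rank
  }
  out
}

#' Gene-set variation enrichment scores
#'
#' Second stage: per sample, genes are ordered by decreasing symmetric rank
#' statistic and a weighted Kolmogorov-Smirnov random walk is run for each
#' gene set — in-set steps proportional to `|stat|^tau`, out-of-set steps a
#' uniform `1/(p - m)` decrement. The enrichment score is the sum of the
#' maximum positive and maximum negative deviation (`max_diff`, the default)
#' or the single larger-magnitude deviation (`two_sided_max`).
#'
#' @param stat genes x samples matrix from [gene_stat()].
#' @param sets a `gene_set_collection` from [read_gmt()], or a named list of
#'   gene-id vectors.
#' @param tau weight exponent on the rank statistic (default 1).
#' @param statistic `"max_diff"` or `"two_sided_max"`.
#' @return a `phenotype_scores` object: list with `scores` (sets x samples
#'   matrix), `set_names`, `sample_ids`, `params`.
#' @export
gsva_es <- function(stat, sets, tau = 1, statistic = c("max_diff", "two_sided_max")) {
  statistic <- match.arg(statistic)
  if (inherits(sets, "gene_set_collection")) {
    sets <- sets$sets
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("gene sets must have unique names")
  }
  genes <- rownames(stat)
  p <- nrow(stat)
  matched <- lapply(sets, function(g) intersect(normalize_gene_ids(g), genes))
  empty <- vapply(matched, length, integer(1)) == 0L
  if (all(empty)) {
    stop("no gene set shares any gene with the expression matrix")
  }
  if (any(empty)) {
    warning(sprintf("dropping %d gene set(s) with no matched genes: %s",
                    sum(empty), paste(names(sets)[empty], collapse = ", ")))
    matched <- matched[!empty]
  }
  scores <- matrix(0, length(matched), ncol(stat),
                   dimnames = list(names(matched), colnames(stat)))
  for (j in seq_len(ncol(stat))) {
    sj <- stat[, j]
    ord <- order(-sj, seq_len(p))  # decreasing statistic, ties by gene order
    ranked_genes <- genes[ord]
    wj <- abs(sj[ord])^tau
    for (k in seq_along(matched)) {
      scores[k, j] <- ks_walk_score(ranked_genes, wj, matched[[k]], statistic)
    }
  }
  structure(
    list(scores = scores, set_names = rownames(scores),
         sample_ids = colnames(scores),
         params = list(kernel = "gaussian", tau = tau, statistic = statistic)),
    class = "phenotype_scores"
  )
}

# Weighted KS random walk over one ranked gene list.
ks_walk_score <- function(ranked_genes, weights, set_genes, statistic) {
  p <- length(ranked_genes)
  in_set <- ranked_genes %in% set_genes
  m <- sum(in_set)
  steps <- numeric(p)
  wsum <- sum(weights[in_set])
  if (wsum > 0) {
    steps[in_set] <- weights[in_set] / wsum
  } else {
    steps[in_set] <- 1 / m  # all-zero statistics: uniform in-set increments
  }
  if (m < p) {
    steps[!in_set] <- -1 / (p - m)
  }
  walk <- cumsum(steps)
  dev_pos <- max(0, max(walk))
  dev_neg <- min(0, min(walk))
  if (statistic == "max_diff") {
    dev_pos + dev_neg
  } else {
    # equal-magnitude deviations tie toward the positive one (with a small
    # tolerance so the choice is not decided by rounding noise)
    if (dev_pos >= -dev_neg - 1e-12) dev_pos else dev_neg
  }
}

#' @export
print.phenotype_scores <- function(x, ...) {
  cat(sprintf("phenotype_scores: %d sets x %d samples (tau=%g, %s)\n",
              nrow(x$scores), ncol(x$scores), x$params$tau,
              x$params$statistic))
  invisible(x)
}

#' Compare phenotype scores between two groups
#'
#' Welch t-test per gene set, with Benjamini-Hochberg FDR adjustment across
#' sets; results are sorted by adjusted p-value. Sets that are constant and
#' identical in both groups are reported with `t = 0`, `p = 1`.
#'
#' @param scores a `phenotype_scores` object.
#' @param groups two-level factor (or character) vector, one entry per sample.
#' @return data.frame with columns `set`, `mean_a`, `mean_b`, `t`, `p`, `q`,
#'   sorted by `q`. Group "a" is the first factor level.
#' @export
compare_phenotypes <- function(scores, groups) {
  stopifnot(inherits(scores, "phenotype_scores"))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("groups must have exactly two levels")
  }
  if (length(groups) != ncol(scores$scores)) {
    stop("groups must have one entry per sample")
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 samples")
  }
  a <- groups == levels(groups)[1L]
  res <- lapply(rownames(scores$scores), function(set) {
    xa <- scores$scores[set, a]
    xb <- scores$scores[set, !a]
    if (stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12) {
      tt <- list(statistic = c(t = if (mean(xa) == mean(xb)) 0 else Inf),
                 p.value = if (mean(xa) == mean(xb)) 1 else 0)
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
    }
    data.frame(set = set, mean_a = mean(xa), mean_b = mean(xb),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[order(out$q, out$p, out$set), , drop = FALSE]
}
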