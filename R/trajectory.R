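new_trajectory <- function(cell_ids, pseudotime, root_cell, method,
                           excluded_genes = character()) {
  ord <- order(pseudotime, cell_ids)
  structure(
    list(
      cell_ids = cell_ids,
      pseudotime = stats::setNames(pseudotime, cell_ids),
      ordering = ord,
      root_cell = root_cell,
      method = method,
      excluded_genes = excluded_genes
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory [%s]: %d cells, root %s, %d excluded gene(s)\n",
              x$method, length(x$cell_ids), x$root_cell,
              length(x$excluded_genes)))
  invisible(x)
}

minmax_scale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps^0.5) {
    stop("cannot scale a constant vector to [0, 1]")
  }
  (x - r[1]) / (r[2] - r[1])
}

#' SID-anchored pseudotime
#'
#' Orders cells by their SID score: pseudotime is the min-max-scaled rank of
#' the score (ties get tied average ranks; equal-score cells keep a stable
#' order by cell id), and the root is the lowest-SID cell.
#'
#' @param result a `sid_result` from [sid_score()] with >= 3 cells.
#' @return a `trajectory` with `method = "sid_rank"`.
#' @export
sid_pseudotime <- function(result) {
  stopifnot(inherits(result, "sid_result"))
  if (nrow(result) < 3L) {
    stop("pseudotime needs at least 3 cells")
  }
  sid <- result$sid
  if (max(sid) - min(sid) < .Machine$double.eps^0.5) {
    stop("all SID scores are equal; no ordering exists")
  }
  r <- rank(sid, ties.method = "average")
  pt <- minmax_scale(r)
  root <- result$sample_id[order(sid, result$sample_id)][1L]
  new_trajectory(result$sample_id, pt, root, "sid_rank")
}

#' Graph-based pseudotime on a held-out gene space
#'
#' Independent expression-driven ordering used to validate the SID-anchored
#' trajectory: PCA on the genes remaining after `exclude_genes` are removed,
#' a k-nearest-neighbour graph in PC space with Euclidean edge weights, its
#' minimum spanning tree, and pseudotime as the min-max-scaled geodesic
#' distance from the root cell along that tree. The excluded genes (typically
#' the SID model's feature genes) are recorded and provably unused.
#'
#' @param expr an [expr_matrix()] at stage `zscored`, genes x cells.
#' @param exclude_genes gene ids to remove before embedding (default none).
#' @param root_hint cell id to use as the trajectory root.
#' Of the first `n_components` principal components, only those whose
#' eigenvalue exceeds the Marchenko-Pastur noise edge
#' `sigma^2 (1 + sqrt(p/n))^2` are kept (minimum 2): Euclidean geodesics
#' over pure-noise directions otherwise swamp the biological axis.
#'
#' @param k_neighbors neighbours per cell in the kNN graph (default 15).
#' @param n_components maximum number of principal components (default 10);
#'   components below the random-matrix noise edge are discarded.
#' @param seed recorded for provenance; the procedure itself is deterministic.
#' @return a `trajectory` with `method = "graph_mst"`.
#' @export
graph_pseudotime <- function(expr, exclude_genes = character(), root_hint,
                             k_neighbors = 15L, n_components = 10L,
                             seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$stage != "zscored") {
    stop("graph_pseudotime expects z-scored expression")
  }
  exclude_genes <- normalize_gene_ids(exclude_genes)
  keep <- setdiff(expr$gene_ids, exclude_genes)
  if (length(keep) < 10L) {
    stop(sprintf("only %d gene(s) remain after exclusion; need at least 10",
                 length(keep)))
  }
  x <- t(expr$values[keep, , drop = FALSE])  # cells x genes
  n <- nrow(x)
  if (!root_hint %in% rownames(x)) {
    stop(sprintf("root cell '%s' not found", root_hint))
  }
  if (k_neighbors >= n) {
    stop("k_neighbors must be smaller than the number of cells")
  }
  n_components <- min(n_components, ncol(x), n - 1L)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                       rank. = n_components)
  # Marchenko-Pastur upper edge under i.i.d. noise of variance sigma^2
  sigma2 <- stats::median(colSums(scale(x, scale = FALSE)^2) / (n - 1L))
  mp_edge <- sigma2 * (1 + sqrt(ncol(x) / n))^2
  n_signal <- sum(pca$sdev^2 > mp_edge)
  n_keep <- min(n_components, max(n_signal, min(2L, n_components)))
  pcs <- pca$x[, seq_len(n_keep), drop = FALSE]
  d <- as.matrix(stats::dist(pcs))
  edges <- NULL
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k_neighbors + 1L)]
    edges <- rbind(edges, cbind(i, nb, d[i, nb]))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = edges[, 3]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  g <- igraph::simplify(g, edge.attr.comb = "min")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    stop(sprintf(
      "kNN graph is disconnected (%d components of sizes %s); increase k_neighbors",
      comp$no, paste(comp$csize, collapse = ", ")))
  }
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  root_idx <- match(root_hint, rownames(x))
  geo <- igraph::distances(tree, v = as.character(root_idx),
                           weights = igraph::E(tree)$weight)[1L, ]
  geo <- geo[order(as.integer(names(geo)))]
  pt <- minmax_scale(unname(geo))
  new_trajectory(rownames(x), pt, root_hint, "graph_mst",
                 excluded_genes = intersect(exclude_genes, expr$gene_ids))
}

#' Concordance between two trajectories
#'
#' Spearman rank correlation (tie-corrected) between the pseudotimes of two
#' trajectories over the same cells, with a two-sided p-value.
#'
#' @param a,b `trajectory` objects over identical cell sets.
#' @return list with `rho` and `p`.
#' @export
trajectory_concordance <- function(a, b) {
  stopifnot(inherits(a, "trajectory"), inherits(b, "trajectory"))
  if (!setequal(a$cell_ids, b$cell_ids)) {
    stop("trajectories cover different cell sets")
  }
  pa <- a$pseudotime[a$cell_ids]
  pb <- b$pseudotime[a$cell_ids]
  ct <- suppressWarnings(
    stats::cor.test(pa, pb, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Gene expression kinetics along a trajectory
#'
#' Smooths each gene's `log2(CPM+1)` expression over pseudotime with a
#' tri-cube-weighted local average evaluated on a uniform pseudotime grid,
#' reports the Spearman correlation of expression with pseudotime
#' (`trend_correlation`; constant genes are flagged and reported as 0), and
#' clusters the standardised smoothed profiles by k-means with a fixed seed.
#'
#' @param expr an [expr_matrix()] at stage `cpm_log`, genes x cells.
#' @param traj a `trajectory` over the same cells.
#' @param grid_size number of grid points (default 100, minimum 3).
#' @param window_fraction smoothing window as a fraction of the pseudotime
#'   range (default 0.3).
#' @param n_clusters k for k-means on smoothed profiles (default 2).
#' @param seed k-means seed (default 1).
#' @return a `gene_kinetics` object: list with `smoothed` (genes x grid),
#'   `grid`, `trend_correlation`, `flat_gene`, `cluster`.
#' @export
gene_kinetics <- function(expr, traj, grid_size = 100L, window_fraction = 0.3,
                          n_clusters = 2L, seed = 1L) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(traj, "trajectory"))
  if (expr$stage != "cpm_log") {
    stop("gene_kinetics expects cpm_log expression")
  }
  if (grid_size < 3L) {
    stop("grid_size must be at least 3")
  }
  if (window_fraction <= 0 || window_fraction > 1) {
    stop("window_fraction must be in (0, 1]")
  }
  if (!setequal(expr$sample_ids, traj$cell_ids)) {
    stop("expression matrix and trajectory cover different cells")
  }
  pt <- unname(traj$pseudotime[expr$sample_ids])
  grid <- seq(min(pt), max(pt), length.out = grid_size)
  half <- window_fraction * (max(pt) - min(pt)) / 2
  W <- sapply(grid, function(g) {
    u <- abs(pt - g) / half
    ifelse(u < 1, (1 - u^3)^3, 0)
  })
  if (any(colSums(W) <= 0)) {
    stop("smoothing window contains no cells at some grid points; increase window_fraction")
  }
  W <- sweep(W, 2L, colSums(W), "/")
  smoothed <- expr$values %*% W
  colnames(smoothed) <- sprintf("t%03d", seq_len(grid_size))
  rho <- suppressWarnings(
    apply(expr$values, 1L, function(g) stats::cor(g, pt, method = "spearman")))
  flat <- !is.finite(rho)
  rho[flat] <- 0
  std <- smoothed - rowMeans(smoothed)
  sds <- sqrt(rowSums(std^2) / (ncol(std) - 1L))
  sds[sds < .Machine$double.eps^0.5] <- 1
  std <- std / sds
  n_clusters <- min(n_clusters, nrow(std))
  cl <- withr::with_seed(as.integer(seed),
                         stats::kmeans(std, centers = n_clusters,
                                       nstart = 10L)$cluster)
  structure(
    list(
      gene_ids = expr$gene_ids,
      smoothed = smoothed,
      grid = grid,
      trend_correlation = stats::setNames(rho, expr$gene_ids),
      flat_gene = stats::setNames(flat, expr$gene_ids),
      cluster = stats::setNames(cl, expr$gene_ids)
    ),
    class = "gene_kinetics"
  )
}

#' @export
print.gene_kinetics <- function(x, ...) {
  cat(sprintf("gene_kinetics: %d genes on a %d-point pseudotime grid, %d cluster(s)\n",
              length(x$gene_ids), length(x$grid), length(unique(x$cluster))))
  invisible(x)
}

#' Heatmap of smoothed gene kinetics
#'
#' Draws the standardised smoothed profiles (genes x pseudotime grid) ordered
#' by cluster and trend correlation. Uses pheatmap when available, otherwise
#' base `image()`.
#'
#' @param kinetics a `gene_kinetics` object.
#' @param filename optional PNG path; default plots to the active device.
#' @return invisibly, the matrix that was drawn.
#' @export
plot_kinetics <- function(kinetics, filename = NA) {
  stopifnot(inherits(kinetics, "gene_kinetics"))
  m <- kinetics$smoothed
  m <- (m - rowMeans(m)) / pmax(apply(m, 1L, stats::sd), 1e-12)
  ord <- order(kinetics$cluster, -kinetics$trend_correlation)
  m <- m[ord, , drop = FALSE]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       show_colnames = FALSE,
                       filename = if (is.na(filename)) NA else filename)
  } else {
    if (!is.na(filename)) {
      grDevices::png(filename, width = 800, height = 600)
      on.exit(grDevices::dev.off())
    }
    graphics::image(t(m), axes = FALSE,
                    xlab = "pseudotime", ylab = "genes")
  }
  invisible(m)
}
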