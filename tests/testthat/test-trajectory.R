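make_sid_result <- function(sids, ids = NULL) {
  ids <- ids %||% sprintf("C%02d", seq_along(sids))
  structure(data.frame(sample_id = ids, decision = qlogis(pmin(pmax(sids,
    1e-6), 1 - 1e-6)), sid = sids, call = as.integer(sids > 0.5),
    mode_id = 1L, stringsAsFactors = FALSE),
    class = c("sid_result", "data.frame"))
}

test_that("SID pseudotime is the min-max-scaled score rank", {
  res <- make_sid_result(c(0.1, 0.5, 0.9))
  tj <- sid_pseudotime(res)
  expect_equal(unname(tj$pseudotime), c(0, 0.5, 1))
  expect_identical(tj$root_cell, "C01")
  expect_equal(oracle_spearman(tj$pseudotime, res$sid), 1)

  # ties receive tied average ranks
  tied <- sid_pseudotime(make_sid_result(c(0.2, 0.4, 0.4, 0.8)))
  expect_equal(unname(tied$pseudotime), c(0, 0.5, 0.5, 1))
  expect_error(sid_pseudotime(make_sid_result(c(0.3, 0.3, 0.3))), "equal")
  expect_error(sid_pseudotime(make_sid_result(c(0.3, 0.6))), "3 cells")
})

test_that("graph pseudotime recovers a noiseless 1-D gradient exactly", {
  n <- 24
  pos <- seq_len(n)
  slopes <- seq(0.5, 2, length.out = 12)
  vals <- outer(slopes, pos)  # 12 genes, all linear in position
  expr <- make_zscored(vals, samples = sprintf("C%02d", pos))
  tj <- graph_pseudotime(expr, root_hint = "C01", k_neighbors = 5)
  expect_equal(abs(oracle_spearman(tj$pseudotime, pos)), 1, tolerance = 1e-12)
  expect_equal(unname(tj$pseudotime["C01"]), 0)

  # rooting at the far end reverses the ordering
  tj2 <- graph_pseudotime(expr, root_hint = sprintf("C%02d", n),
                          k_neighbors = 5)
  expect_equal(oracle_spearman(tj$pseudotime, tj2$pseudotime), -1,
               tolerance = 1e-12)
})

test_that("three collinear cells give the exhaustive-MST path geodesics", {
  vals <- outer(rep(1, 12), c(0, 1, 5))  # positions 0, 1, 5
  vals <- vals + matrix(rep(seq(0.1, 1.2, by = 0.1), 3), 12)
  expr <- make_zscored(vals, samples = c("A", "B", "C"))
  tj <- graph_pseudotime(expr, root_hint = "A", k_neighbors = 2)
  # exhaustive MST on 3 nodes drops the A-C edge; geodesics follow positions
  expect_equal(unname(tj$pseudotime[c("A", "B", "C")]), c(0, 0.2, 1),
               tolerance = 1e-9)
})

test_that("disconnected graphs and over-excluded gene sets are rejected", {
  withr::with_seed(51, {
    half <- cbind(matrix(rnorm(12 * 5), 12), matrix(rnorm(12 * 5) + 100, 12))
    expr <- make_zscored(half)
    expect_error(graph_pseudotime(expr, root_hint = "S01", k_neighbors = 2),
                 "disconnected.*components", ignore.case = TRUE)
    expect_error(graph_pseudotime(expr, exclude_genes = expr$gene_ids[1:9],
                                  root_hint = "S01"), "at least 10")
    expect_error(graph_pseudotime(expr, root_hint = "nope", k_neighbors = 3),
                 "root")
  })
})

test_that("excluded genes cannot influence the held-out pseudotime", {
  withr::with_seed(52, {
    n <- 30
    grad <- outer(seq(0.5, 1.5, length.out = 15), seq_len(n))
    noise <- matrix(rnorm(5 * n), 5)
    expr <- make_zscored(rbind(grad, noise))
    excl <- expr$gene_ids[16:20]
    tj <- graph_pseudotime(expr, exclude_genes = excl, root_hint = "S01",
                           k_neighbors = 6)
    # wildly perturb the excluded rows: result must be identical
    vals <- expr$values
    vals[excl, ] <- matrix(rnorm(5 * n, 0, 100), 5)
    tj2 <- graph_pseudotime(expr_matrix(vals, stage = "zscored"),
                            exclude_genes = excl, root_hint = "S01",
                            k_neighbors = 6)
    expect_identical(tj$pseudotime, tj2$pseudotime)
    expect_setequal(tj$excluded_genes, excl)
  })
})

test_that("concordance is a symmetric tie-corrected Spearman correlation", {
  a <- make_sid_result(c(0.1, 0.3, 0.5, 0.7, 0.9))
  ta <- sid_pseudotime(a)
  expect_equal(trajectory_concordance(ta, ta)$rho, 1)
  rev_res <- make_sid_result(rev(c(0.1, 0.3, 0.5, 0.7, 0.9)))
  tb <- sid_pseudotime(rev_res)
  expect_equal(trajectory_concordance(ta, tb)$rho, -1)

  c1 <- sid_pseudotime(make_sid_result(c(0.1, 0.4, 0.2, 0.8, 0.6)))
  expect_equal(trajectory_concordance(ta, c1)$rho,
               oracle_spearman(ta$pseudotime, c1$pseudotime[ta$cell_ids]),
               tolerance = 1e-12)
  expect_equal(trajectory_concordance(ta, c1)$rho,
               trajectory_concordance(c1, ta)$rho)
  other <- sid_pseudotime(make_sid_result(c(0.1, 0.5, 0.9), ids = c("X", "Y", "Z")))
  expect_error(trajectory_concordance(ta, other), "different cell sets")
})

test_that("gene kinetics smooths, correlates and clusters planted trends", {
  n <- 40
  pt <- seq(0, 1, length.out = n)
  ids <- sprintf("C%02d", seq_len(n))
  x <- rbind(UP = 2 + 3 * pt, DOWN = 5 - 4 * pt, FLAT = rep(1, n))
  colnames(x) <- ids
  expr <- expr_matrix(x, stage = "cpm_log")
  traj <- sid_pseudotime(make_sid_result(seq(0.05, 0.95, length.out = n),
                                         ids = ids))
  kin <- gene_kinetics(expr, traj, grid_size = 20, n_clusters = 2)
  expect_equal(unname(kin$trend_correlation["UP"]), 1)
  expect_equal(unname(kin$trend_correlation["DOWN"]), -1)
  expect_true(!is.unsorted(kin$smoothed["UP", ]))
  expect_true(kin$flat_gene["FLAT"])
  expect_equal(unname(kin$trend_correlation["FLAT"]), 0)
  # planted up and down genes land in different clusters at k = 2
  expect_false(kin$cluster["UP"] == kin$cluster["DOWN"])
  expect_true(!is.unsorted(kin$grid))

  expect_error(gene_kinetics(expr, traj, grid_size = 2), "grid_size")
  # cells piled at the ends leave mid-grid windows empty
  traj2 <- sid_pseudotime(make_sid_result(c(rep(0.01, 19), 0.011, 0.99),
                                          ids = sprintf("D%02d", 1:21)))
  x2 <- matrix(rpois(21, 10), 1, dimnames = list("G1", sprintf("D%02d", 1:21)))
  expect_error(gene_kinetics(expr_matrix(x2, stage = "cpm_log"), traj2,
                             window_fraction = 0.05), "window")
})
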