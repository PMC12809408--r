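test_that("logistic calibration matches a grid-search maximum likelihood", {
  withr::with_seed(31, {
    d <- c(rnorm(40, -1), rnorm(40, 1))
    y <- rep(c(0, 1), each = 40)
    cal <- calibrate_decisions(d, y)
    ref <- oracle_logistic_mle(d, y)
    expect_equal(cal$alpha, ref[1], tolerance = 0.05)
    expect_equal(cal$beta, ref[2], tolerance = 0.05)
    expect_gt(cal$alpha, 0)
    expect_lt(abs(cal$beta), 0.5)  # symmetric construction

    # labels independent of decisions: slope near zero, SID near prevalence
    y_rand <- sample(rep(c(0, 1), 40))
    cal2 <- calibrate_decisions(d, y_rand)
    ref2 <- oracle_logistic_mle(d, y_rand)
    expect_equal(cal2$alpha, ref2[1], tolerance = 0.05)
    expect_lt(abs(cal2$alpha), 0.5)
    expect_equal(mean(plogis(cal2$alpha * d + cal2$beta)), mean(y_rand),
                 tolerance = 0.05)

    # inverted labels flip the slope sign
    cal3 <- calibrate_decisions(d, 1 - y)
    expect_lt(cal3$alpha, 0)
  })
})

test_that("perfect separation falls back to a bounded-slope fit", {
  d <- c(-3, -2, -1, 1, 2, 3)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_warning(cal <- calibrate_decisions(d, y), "separat")
  expect_true(cal$separation_fallback)
  expect_lte(abs(cal$alpha), 50 / sd(d) + 1e-9)
  expect_gt(cal$alpha, 0)
  expect_error(calibrate_decisions(d, rep(1, 6)), "both classes")
})

test_that("scoring evaluates the logistic formula and imputes missing genes", {
  expr <- make_zscored(matrix(rnorm(30), 3), genes = c("A", "B", "C"))
  model <- make_model(c("A", "C"), weights = c(2, -1), bias = 0.5,
                      alpha = 2, beta = 1)
  res <- sid_score(model, expr)
  f <- drop(c(2, -1) %*% expr$values[c("A", "C"), ]) + 0.5
  expect_equal(res$decision, unname(f), tolerance = 1e-12)
  expect_equal(res$sid, unname(1 / (1 + exp(-(2 * f + 1)))), tolerance = 1e-12)
  # alpha=2, beta=1, f=1 -> 1/(1+e^-3)
  m1 <- make_model("A", weights = 1, alpha = 2, beta = 1)
  one <- make_zscored(matrix(1, 1, 3), genes = "A")
  one$values[] <- 1
  expect_equal(sid_score(m1, one)$sid, rep(1 / (1 + exp(-3)), 3),
               tolerance = 1e-12)

  # gene B missing from query: imputed at z = 0
  expr2 <- make_zscored(matrix(rnorm(20), 2), genes = c("A", "X"))
  model2 <- make_model(c("A", "B"), weights = c(1, 5), bias = 0)
  expect_message(res2 <- sid_score(model2, expr2), "coverage")
  expect_equal(attr(res2, "feature_coverage"), 0.5)
  expect_equal(res2$decision, unname(expr2$values["A", ]), tolerance = 1e-12)
  model3 <- make_model(c("Q", "R"), weights = c(1, 1))
  expect_error(sid_score(model3, expr2), "none of the model")
})

test_that("SID is a strictly monotone transform of the decision value", {
  withr::with_seed(32, {
    expr <- make_zscored(matrix(rnorm(200), 5))
    model <- make_model(expr$gene_ids, weights = rnorm(5), alpha = 1.7,
                        beta = -0.4)
    res <- sid_score(model, expr)
    expect_identical(order(res$sid), order(res$decision))
    expect_true(all(res$sid >= 0 & res$sid <= 1))
  })
})

test_that("classification at the fixed threshold uses a strict inequality", {
  expect_identical(sid_classify(c(0.5, 0.50001, 0.9, 0.1)), c(0L, 1L, 1L, 0L))
  expect_error(sid_classify(0.5, threshold = 1.5), "threshold")
  expect_error(sid_classify(1.2), "\\[0, 1\\]")
})

test_that("RFE retains planted separators and honours the no-op bound", {
  withr::with_seed(33, {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    planted <- rbind(SEP1 = y + rnorm(n, 0, 0.01),
                     SEP2 = -y + rnorm(n, 0, 0.01))
    noise <- matrix(rnorm(20 * n), 20,
                    dimnames = list(sprintf("N%02d", 1:20), NULL))
    expr <- make_zscored(rbind(planted, noise))
    model <- suppressWarnings(
      train_sid(expr, y, n_features_target = 2L, seed = 1))
    expect_setequal(model$feature_genes, c("SEP1", "SEP2"))
    # eliminated genes recorded, disjoint from survivors
    expect_setequal(c(model$feature_genes, model$elimination_order),
                    expr$gene_ids)

    # no-op bound: target = all genes leaves the single SVM fit untouched
    full <- suppressWarnings(
      train_sid(expr, y, n_features_target = nrow(expr$values), seed = 1))
    expect_identical(length(full$elimination_order), 0L)
    expect_setequal(full$feature_genes, expr$gene_ids)
  })
  expr2 <- make_zscored(matrix(rnorm(40), 4))
  expect_error(train_sid(expr2, rep(1, 10)), "both classes")
  expect_error(suppressWarnings(
    train_sid(expr2, rep(c(0, 1), 5), n_features_target = 99L)),
    "n_features_target")
})

test_that("training is seed-reproducible and permutation-equivariant", {
  withr::with_seed(34, {
    y <- rep(c(0, 1), each = 15)
    x <- matrix(rnorm(40 * 30), 40)
    x[1:4, y == 1] <- x[1:4, y == 1] + 2
    expr <- make_zscored(x)
    m1 <- suppressWarnings(train_sid(expr, y, n_features_target = 10L, seed = 9))
    m2 <- suppressWarnings(train_sid(expr, y, n_features_target = 10L, seed = 9))
    expect_identical(m1$weights, m2$weights)
    expect_identical(m1$alpha, m2$alpha)

    perm <- sample(ncol(expr$values))
    expr_p <- expr_matrix(expr$values[, perm], stage = "zscored")
    r <- sid_score(m1, expr)
    r_p <- sid_score(m1, expr_p)
    expect_equal(r_p$sid, r$sid[perm], tolerance = 1e-12)
    expect_identical(r_p$sample_id, r$sample_id[perm])
  })
})

test_that("mode selection maximises AUROC when labelled, bimodality otherwise", {
  withr::with_seed(35, {
    expr <- make_zscored(matrix(rnorm(300), 3), genes = c("A", "B", "C"))
    y <- as.integer(expr$values["A", ] > 0)
    good <- make_model("A", weights = 1, alpha = 5, mode_id = 1L)
    bad <- make_model("B", weights = 1, alpha = 5, mode_id = 2L)
    sel <- select_mode(list(bad, good), expr, labels = y)
    expect_identical(sel$mode_id, 1L)
    au <- sel$diagnostics$value[sel$diagnostics$mode_id == 1L]
    expect_equal(au, oracle_auroc(sid_score(good, expr)$sid, y),
                 tolerance = 1e-12)

    # unlabelled: clearly bimodal scores beat unimodal noise
    xb <- matrix(0, 2, 60, dimnames = list(c("BI", "UNI"), sprintf("S%02d", 1:60)))
    xb["BI", ] <- c(rnorm(30, -3, 0.2), rnorm(30, 3, 0.2))
    xb["UNI", ] <- rnorm(60, 0, 1)
    exprb <- expr_matrix(t(scale(t(xb))), stage = "zscored")
    bi <- make_model("BI", weights = 1, mode_id = 1L)
    uni <- make_model("UNI", weights = 1, mode_id = 2L)
    expect_identical(select_mode(list(uni, bi), exprb)$mode_id, 1L)
    expect_identical(select_mode(list(uni), exprb)$mode_id, 2L)  # singleton
    expect_error(select_mode(list(), exprb), "empty")
  })
})

test_that("bimodality silhouette equals the exhaustive split-point oracle", {
  withr::with_seed(36, {
    for (rep in 1:8) {
      s <- rnorm(12 + rep)
      expect_equal(bimodality_silhouette(s), oracle_bimodality(s),
                   tolerance = 1e-9)
    }
    expect_equal(bimodality_silhouette(rep(0.3, 10)), 0)
  })
})
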