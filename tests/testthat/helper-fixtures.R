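# Small in-memory fixtures and a cache for the expensive simulated datasets
# so they are built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_counts <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  count_matrix(m)
}

# Z-scored expression wrapper for hand-built feature matrices.
make_zscored <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  m <- t(scale(t(m)))
  m[!is.finite(m)] <- 0
  expr_matrix(m, stage = "zscored")
}

# A model with hand-set parameters, bypassing training.
make_model <- function(feature_genes, weights, bias = 0, alpha = 1, beta = 0,
                       mode_id = 1L) {
  senoscope:::new_sid_model(mode_id = mode_id, feature_genes = feature_genes,
                            weights = weights, bias = bias, alpha = alpha,
                            beta = beta)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# sc_medium simulation plus the canonical 70/30 stratified fit.
sc_medium_fit <- function() {
  cached("sc_medium_fit", {
    spec <- fixture_spec("sc_medium")
    sim <- simulate_counts(spec)
    expr <- preprocess_counts(sim$counts)
    split <- stratified_split(sim$truth$label, 0.7, seed = spec$seed)
    train_expr <- expr_matrix(expr$values[, split$train, drop = FALSE],
                              stage = "zscored")
    test_expr <- expr_matrix(expr$values[, split$test, drop = FALSE],
                             stage = "zscored")
    model <- suppressWarnings(
      train_sid(train_expr, sim$truth$label[split$train],
                n_features_target = 100L, seed = spec$seed))
    list(sim = sim, split = split, model = model,
         result = sid_score(model, test_expr),
         test_labels = sim$truth$label[split$test])
  })
}

# gradient simulation plus SID model and both pseudotimes.
gradient_fit <- function() {
  cached("gradient_fit", {
    spec <- fixture_spec("gradient")
    sim <- simulate_counts(spec)
    expr <- preprocess_counts(sim$counts)
    model <- suppressWarnings(
      train_sid(expr, sim$truth$label, n_features_target = 30L,
                seed = spec$seed))
    result <- sid_score(model, expr)
    traj_sid <- sid_pseudotime(result)
    traj_graph <- graph_pseudotime(expr,
                                   exclude_genes = sim$signature_genes,
                                   root_hint = traj_sid$root_cell)
    list(sim = sim, expr = expr, model = model, result = result,
         traj_sid = traj_sid, traj_graph = traj_graph)
  })
}
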