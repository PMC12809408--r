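#' @keywords internal
new_sid_model <- function(mode_id, feature_genes, weights, bias, alpha, beta,
                          threshold = 0.5, train_meta = list(),
                          elimination_order = character()) {
  stopifnot(length(weights) == length(feature_genes))
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(bias)) {
    stop("model parameters must be finite")
  }
  structure(
    list(
      mode_id = as.integer(mode_id),
      feature_genes = as.character(feature_genes),
      weights = stats::setNames(as.numeric(weights),
                                as.character(feature_genes)),
      bias = as.numeric(bias),
      alpha = as.numeric(alpha),
      beta = as.numeric(beta),
      threshold = as.numeric(threshold),
      train_meta = train_meta,
      elimination_order = elimination_order
    ),
    class = "sid_model"
  )
}

#' @export
print.sid_model <- function(x, ...) {
  cat(sprintf(
    "sid_model (mode %d): %d feature genes, alpha=%.4g, beta=%.4g, threshold=%g\n",
    x$mode_id, length(x$feature_genes), x$alpha, x$beta, x$threshold))
  invisible(x)
}

fit_linear_svm <- function(X, y, cost) {
  yf <- factor(y, levels = c(0, 1))
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  # inverse-prevalence weights: senescent cells are typically a minority
  cw <- c("0" = length(y) / (2 * n0), "1" = length(y) / (2 * n1))
  fit <- e1071::svm(x = X, y = yf, kernel = "linear", cost = cost,
                    scale = FALSE, class.weights = cw)
  w <- drop(t(fit$coefs) %*% fit$SV)
  names(w) <- colnames(X)
  list(w = w, b = -fit$rho)
}

#' Fit logistic calibration of decision values
#'
#' One-dimensional logistic regression of binary labels on raw SVM decision
#' values, by maximum likelihood: `SID = 1 / (1 + exp(-(alpha * f + beta)))`.
#' Under perfect separation the unbounded MLE diverges; the fit then falls
#' back to Platt-style regularised targets `(n1+1)/(n1+2)` and `1/(n0+2)`
#' with the slope magnitude capped at `50 / sd(decision)`, and warns.
#'
#' @param decision numeric vector of raw decision values f(x).
#' @param labels binary 0/1 vector, both classes present.
#' @return list with `alpha`, `beta` and logical `separation_fallback`.
#' @export
calibrate_decisions <- function(decision, labels) {
  decision <- as.numeric(decision)
  labels <- as.integer(labels)
  if (length(decision) != length(labels)) {
    stop("decision and labels must have equal length")
  }
  if (any(!is.finite(decision))) {
    stop("decision values must be finite")
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must contain both classes (0 and 1)")
  }
  sdd <- stats::sd(decision)
  if (sdd < .Machine$double.eps^0.5) {
    # constant decisions carry no information: flat calibration at prevalence
    return(list(alpha = 0, beta = stats::qlogis(mean(labels)),
                separation_fallback = FALSE))
  }
  max_slope <- 50 / sdd
  separated <- max(decision[labels == 0]) < min(decision[labels == 1]) ||
    max(decision[labels == 1]) < min(decision[labels == 0])
  if (!separated) {
    fit <- suppressWarnings(
      stats::glm(labels ~ decision, family = stats::binomial()))
    a <- unname(stats::coef(fit)[2L])
    b <- unname(stats::coef(fit)[1L])
    if (fit$converged && is.finite(a) && is.finite(b) &&
        abs(a) <= max_slope) {
      return(list(alpha = a, beta = b, separation_fallback = FALSE))
    }
  }
  warning("decision values separate the classes; using bounded-slope (Platt) calibration")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  soft <- ifelse(labels == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  fit <- suppressWarnings(
    stats::glm(soft ~ decision, family = stats::quasibinomial()))
  a <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  if (!is.finite(a) || abs(a) > max_slope) {
    a <- sign(if (is.finite(a) && a != 0) a else
      stats::cor(decision, labels)) * max_slope
    # refit intercept alone at the capped slope (1-D MLE on soft targets)
    nll <- function(b0) {
      p <- stats::plogis(a * decision + b0)
      -sum(soft * log(p) + (1 - soft) * log1p(-p))
    }
    b <- stats::optimize(nll, interval = c(-100, 100))$minimum
  }
  list(alpha = a, beta = b, separation_fallback = TRUE)
}

#' Train a senescence-mode SID model (linear SVM + RFE)
#'
#' Iteratively fits a linear soft-margin SVM to z-scored expression, ranks
#' genes by the magnitude of their weight in the separating hyperplane, and
#' eliminates the lowest-ranked fraction until at most `n_features_target`
#' genes remain. The final refit gives the weight vector and bias of the raw
#' decision value `f(x) = w . x + b`, which is then mapped to a SID score in
#' [0, 1] by logistic calibration on the training decision values
#' ([calibrate_decisions()]).
#'
#' Class imbalance is handled by inverse-prevalence sample weights. The weight
#' orientation is fixed so that higher decision values correspond to the
#' senescent class (label 1).
#'
#' @param expr an [expr_matrix()] at stage `zscored`.
#' @param labels binary 0/1 vector, one per sample; 1 = senescent.
#' @param n_features_target number of feature genes to retain (default 100).
#' @param rfe_fraction fraction of remaining genes removed per RFE iteration
#'   (default 0.1).
#' @param svm_cost soft-margin cost parameter C (default 1).
#' @param seed integer seed recorded in the model and used for any stochastic
#'   step (cross-fit folds).
#' @param mode_id integer identity of the senescence mode this model scores.
#' @param cross_fit if `TRUE`, calibration decision values come from 5-fold
#'   cross-fitting at the final feature set instead of the training fit.
#' @return a `sid_model`.
#' @export
train_sid <- function(expr, labels, n_features_target = 100L,
                      rfe_fraction = 0.1, svm_cost = 1, seed = 1L,
                      mode_id = 1L, cross_fit = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$stage != "zscored") {
    stop("train_sid expects z-scored expression (see preprocess_counts)")
  }
  labels <- as.integer(labels)
  if (length(labels) != ncol(expr$values)) {
    stop("labels must have one entry per sample")
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must contain both classes (0 and 1)")
  }
  n_genes <- nrow(expr$values)
  if (n_features_target < 1L || n_features_target > n_genes) {
    stop("n_features_target must be between 1 and the number of genes")
  }
  if (rfe_fraction <= 0 || rfe_fraction >= 1) {
    stop("rfe_fraction must be in (0, 1)")
  }
  X <- t(expr$values)
  withr::with_seed(as.integer(seed), {
    current <- colnames(X)
    eliminated <- character()
    while (length(current) > n_features_target) {
      fit <- fit_linear_svm(X[, current, drop = FALSE], labels, svm_cost)
      n_drop <- min(ceiling(rfe_fraction * length(current)),
                    length(current) - n_features_target)
      ord <- order(abs(fit$w), seq_along(fit$w))  # ties: earlier index survives
      drop_idx <- ord[seq_len(n_drop)]
      eliminated <- c(eliminated, current[drop_idx])
      current <- current[-drop_idx]
    }
    fit <- fit_linear_svm(X[, current, drop = FALSE], labels, svm_cost)
    w <- fit$w
    b <- fit$b
    d <- drop(X[, current, drop = FALSE] %*% w) + b
    if (auroc(d, labels) < 0.5) {  # orient: senescent class scores higher
      w <- -w
      b <- -b
      d <- -d
    }
    surv <- order(-abs(w), seq_along(w))
    w <- w[surv]
    feature_genes <- names(w)
    if (cross_fit) {
      folds <- sample(rep_len(1:5, length(labels)))
      d_cal <- numeric(length(labels))
      for (k in 1:5) {
        hold <- folds == k
        fk <- fit_linear_svm(X[!hold, feature_genes, drop = FALSE],
                             labels[!hold], svm_cost)
        dk <- drop(X[hold, feature_genes, drop = FALSE] %*% fk$w) + fk$b
        if (auroc(drop(X[!hold, feature_genes, drop = FALSE] %*% fk$w) + fk$b,
                  labels[!hold]) < 0.5) {
          dk <- -dk
        }
        d_cal[hold] <- dk
      }
    } else {
      d_cal <- d
    }
    cal <- calibrate_decisions(d_cal, labels)
    new_sid_model(
      mode_id = mode_id,
      feature_genes = feature_genes,
      weights = w,
      bias = b,
      alpha = cal$alpha,
      beta = cal$beta,
      threshold = 0.5,
      train_meta = list(
        n_samples = length(labels),
        n_senescent = sum(labels == 1L),
        seed = as.integer(seed),
        rfe_schedule = list(fraction = rfe_fraction,
                            n_features_target = as.integer(n_features_target)),
        svm_cost = svm_cost,
        cross_fit = cross_fit,
        separation_fallback = cal$separation_fallback
      ),
      elimination_order = eliminated
    )
  })
}

#' Score samples with a trained SID model
#'
#' Computes the raw decision value `f(x) = w . x + b` on z-scored expression
#' and the SID score `1 / (1 + exp(-(alpha * f + beta)))`. Model genes absent
#' from the query matrix are imputed at z = 0 (the gene mean), and the
#' fraction of model genes found is reported as `feature_coverage`.
#'
#' @param model a `sid_model`.
#' @param expr an [expr_matrix()] at stage `zscored`.
#' @return a `sid_result` data.frame with columns `sample_id`, `decision`,
#'   `sid`, `call`, `mode_id`; attribute `feature_coverage`.
#' @export
sid_score <- function(model, expr) {
  stopifnot(inherits(model, "sid_model"), inherits(expr, "expr_matrix"))
  if (expr$stage != "zscored") {
    stop("sid_score expects z-scored expression (see preprocess_counts)")
  }
  idx <- match(model$feature_genes, expr$gene_ids)
  coverage <- mean(!is.na(idx))
  if (coverage == 0) {
    stop("none of the model's feature genes are present in the query matrix")
  }
  if (coverage < 1) {
    message(sprintf("feature coverage: %.1f%% of %d model genes found; missing genes imputed at z = 0",
                    100 * coverage, length(model$feature_genes)))
  }
  xf <- matrix(0, nrow = length(model$feature_genes), ncol = ncol(expr$values),
               dimnames = list(model$feature_genes, expr$sample_ids))
  present <- !is.na(idx)
  xf[present, ] <- expr$values[idx[present], , drop = FALSE]
  decision <- drop(model$weights %*% xf) + model$bias
  sid <- stats::plogis(model$alpha * decision + model$beta)
  out <- data.frame(
    sample_id = expr$sample_ids,
    decision = unname(decision),
    sid = unname(sid),
    call = sid_classify(unname(sid), model$threshold),
    mode_id = model$mode_id,
    stringsAsFactors = FALSE
  )
  attr(out, "feature_coverage") <- coverage
  class(out) <- c("sid_result", "data.frame")
  out
}

#' Classify SID scores at a fixed threshold
#'
#' `call = 1` (senescent) iff `sid > threshold`, with strict inequality:
#' a score exactly at the threshold is non-senescent.
#'
#' @param sid numeric SID scores in [0, 1], or a `sid_result`.
#' @param threshold classification threshold in [0, 1] (default 0.5).
#' @return integer 0/1 vector of calls.
#' @export
sid_classify <- function(sid, threshold = 0.5) {
  if (inherits(sid, "sid_result")) {
    sid <- sid$sid
  }
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  if (any(sid < 0 | sid > 1)) {
    stop("SID scores must lie in [0, 1]")
  }
  as.integer(sid > threshold)
}

#' Select the best-fitting senescence mode for a dataset
#'
#' With labels, returns the mode whose SID scores maximise AUROC on the
#' labelled samples. Without labels, returns the mode whose SID score
#' distribution is most bimodal, measured by the best two-cluster silhouette
#' over all one-dimensional split points — a senescent subpopulation shows up
#' as a second score mode. Ties break toward the lowest `mode_id`.
#'
#' @param ensemble list of `sid_model` objects with distinct `mode_id`s.
#' @param expr an [expr_matrix()] at stage `zscored`.
#' @param labels optional binary 0/1 vector per sample.
#' @return list with `mode_id` and a `diagnostics` data.frame
#'   (`mode_id`, `criterion`, `value`).
#' @export
select_mode <- function(ensemble, expr, labels = NULL) {
  if (length(ensemble) == 0L) {
    stop("ensemble is empty")
  }
  mode_ids <- vapply(ensemble, function(m) m$mode_id, integer(1))
  if (anyDuplicated(mode_ids)) {
    stop("ensemble mode_ids must be distinct")
  }
  criterion <- if (is.null(labels)) "silhouette" else "auroc"
  value <- vapply(ensemble, function(m) {
    s <- sid_score(m, expr)$sid
    if (is.null(labels)) bimodality_silhouette(s) else auroc(s, labels)
  }, numeric(1))
  ord <- order(-value, mode_ids)
  list(
    mode_id = mode_ids[ord[1L]],
    diagnostics = data.frame(mode_id = mode_ids, criterion = criterion,
                             value = value)[order(mode_ids), ]
  )
}

#' Two-cluster silhouette bimodality diagnostic for 1-D scores
#'
#' Maximises the mean silhouette width over all contiguous two-cluster splits
#' of the sorted scores (the optimal 1-D 2-partition is always contiguous).
#' Returns 0 for constant score vectors. Score vectors longer than
#' `max_points` are deterministically thinned to keep the diagnostic cheap.
#'
#' @param scores numeric vector.
#' @param max_points subsample cap (default 1000).
#' @return best mean silhouette width in [-1, 1].
#' @export
bimodality_silhouette <- function(scores, max_points = 1000L) {
  s <- sort(as.numeric(scores))
  n <- length(s)
  if (n < 3L || max(s) - min(s) < .Machine$double.eps^0.5) {
    return(0)
  }
  if (n > max_points) {
    s <- s[unique(round(seq(1L, n, length.out = max_points)))]
    n <- length(s)
  }
  P <- cumsum(s)
  # sum_{j=l..r} |s_i - s_j| for sorted s, i inside [l, r]
  sumdist <- function(i, l, r) {
    left <- s[i] * (i - l + 1) - (P[i] - if (l > 1) P[l - 1] else 0)
    right <- (P[r] - P[i]) - s[i] * (r - i)
    left + right
  }
  best <- -Inf
  idx <- seq_len(n)
  for (k in seq_len(n - 1L)) {
    a <- numeric(n)
    b <- numeric(n)
    inA <- idx <= k
    nA <- k
    nB <- n - k
    for (i in idx) {
      if (inA[i]) {
        a[i] <- if (nA > 1) sumdist(i, 1L, k) / (nA - 1) else 0
        b[i] <- (sum(s[(k + 1):n]) - s[i] * nB) / nB  # all B are >= s[i]
      } else {
        a[i] <- if (nB > 1) sumdist(i, k + 1L, n) / (nB - 1) else 0
        b[i] <- (s[i] * nA - P[k]) / nA  # all A are <= s[i]
      }
    }
    sil <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
    sil[(inA & nA == 1) | (!inA & nB == 1)] <- 0  # singleton convention
    best <- max(best, mean(sil))
  }
  best
}
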