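# Independent brute-force oracles. These deliberately use naive loops and
# closed forms, never the package's own code paths.

# AUROC as explicit enumeration of positive-negative pairs (ties = 1/2).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# Gaussian-kernel CDF statistic: direct summation per gene and sample,
# then the symmetric rank statistic, all with explicit loops.
oracle_gene_stat <- function(x) {
  p <- nrow(x)
  n <- ncol(x)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    h <- sd(x[i, ]) / 4
    for (j in seq_len(n)) {
      if (h < 1e-12) {
        z[i, j] <- 0.5
      } else {
        acc <- 0
        for (k in seq_len(n)) {
          acc <- acc + pnorm((x[i, j] - x[i, k]) / h)
        }
        z[i, j] <- acc / n
      }
    }
  }
  out <- matrix(0, p, n, dimnames = dimnames(x))
  for (j in seq_len(n)) {
    r <- rank(-z[, j], ties.method = "first")
    for (i in seq_len(p)) {
      out[i, j] <- p / 2 - r[i]
    }
  }
  out
}

# Step-by-step weighted KS walk for one sample and one gene set.
oracle_walk <- function(stat_col, gene_ids, set_genes, tau, statistic) {
  p <- length(stat_col)
  ord <- order(-stat_col, seq_len(p))
  walk <- numeric(p)
  level <- 0
  in_set <- gene_ids[ord] %in% set_genes
  m <- sum(in_set)
  wsum <- sum(abs(stat_col[ord][in_set])^tau)
  for (t in seq_len(p)) {
    if (in_set[t]) {
      level <- level + if (wsum > 0) abs(stat_col[ord][t])^tau / wsum else 1 / m
    } else {
      level <- level - 1 / (p - m)
    }
    walk[t] <- level
  }
  dev_pos <- max(0, max(walk))
  dev_neg <- min(0, min(walk))
  if (statistic == "max_diff") {
    dev_pos + dev_neg
  } else if (dev_pos >= -dev_neg - 1e-12) {  # tie -> positive deviation
    dev_pos
  } else {
    dev_neg
  }
}

# 1-D logistic maximum likelihood by grid search (coarse-to-fine).
oracle_logistic_mle <- function(d, y, a_range = c(-30, 30),
                                b_range = c(-10, 10)) {
  nll <- function(a, b) {
    eta <- a * d + b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  best <- c(0, 0)
  for (pass in 1:3) {
    a_grid <- seq(a_range[1], a_range[2], length.out = 61)
    b_grid <- seq(b_range[1], b_range[2], length.out = 61)
    vals <- outer(a_grid, b_grid, Vectorize(nll))
    idx <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(a_grid[idx[1]], b_grid[idx[2]])
    a_step <- diff(a_range) / 60
    b_step <- diff(b_range) / 60
    a_range <- best[1] + c(-2, 2) * a_step
    b_range <- best[2] + c(-2, 2) * b_step
  }
  best
}

# Mean silhouette of a given contiguous split of sorted 1-D points,
# maximised over all split points, with naive O(n^2) distances.
oracle_bimodality <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  if (diff(range(s)) < 1e-12) {
    return(0)
  }
  best <- -Inf
  for (k in 1:(n - 1)) {
    sil <- numeric(n)
    for (i in 1:n) {
      own <- if (i <= k) 1:k else (k + 1):n
      other <- if (i <= k) (k + 1):n else 1:k
      a <- if (length(own) > 1) mean(abs(s[i] - s[setdiff(own, i)])) else NA
      b <- mean(abs(s[i] - s[other]))
      sil[i] <- if (is.na(a)) 0 else if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    best <- max(best, mean(sil))
  }
  best
}

# Spearman rank correlation from the rank formula (tie-corrected via
# Pearson on average ranks).
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
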