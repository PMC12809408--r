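#' Specification for a synthetic senescence dataset
#'
#' Defines the generative model of [simulate_counts()]: a negative-binomial
#' count matrix with a planted senescent subpopulation. Each cell carries a
#' latent senescence depth in [0, 1] (senescent cells uniform on (0.5, 1],
#' others uniform on [0, 0.5]); signature-gene and gradient-gene means scale
#' continuously with depth as `2^(log2fc * (2 * depth - 1))`, so a cell at
#' depth 1 is up-shifted by the full fold change and a cell at depth 0
#' down-shifted symmetrically. Donor effects are multiplicative log-normal
#' per gene and donor; library sizes are log-normal per cell.
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param frac_senescent fraction of cells with depth > 0.5.
#' @param signature_size number of senescence-signature genes (the genes a
#'   SID model should discover).
#' @param signature_log2fc log2 fold change of signature and gradient genes
#'   between depth 0 and depth 1 extremes (per unit of `2*depth - 1`).
#' @param gradient_module_size number of non-signature genes tracking depth
#'   continuously (held-out trajectory signal).
#' @param nb_dispersion shared negative-binomial dispersion (> 0).
#' @param libsize_log_mean,libsize_log_sd log-normal library-size parameters.
#' @param n_donors number of donors (assigned uniformly at random).
#' @param donor_effect_sd SD of per-gene, per-donor log-normal effects.
#' @param seed integer seed; all randomness flows from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 1000L, n_cells = 2000L,
                           frac_senescent = 0.3, signature_size = 60L,
                           signature_log2fc = 2, gradient_module_size = 40L,
                           nb_dispersion = 0.3,
                           libsize_log_mean = log(3000),
                           libsize_log_sd = 0.3, n_donors = 2L,
                           donor_effect_sd = 0.1, seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
               frac_senescent = frac_senescent,
               signature_size = as.integer(signature_size),
               signature_log2fc = signature_log2fc,
               gradient_module_size = as.integer(gradient_module_size),
               nb_dispersion = nb_dispersion,
               libsize_log_mean = libsize_log_mean,
               libsize_log_sd = libsize_log_sd,
               n_donors = as.integer(n_donors),
               donor_effect_sd = donor_effect_sd, seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_genes < 1L || n_cells < 2L) {
      stop("n_genes and n_cells must be positive (>= 2 cells)")
    }
    if (frac_senescent <= 0 || frac_senescent >= 1) {
      stop("frac_senescent must lie in (0, 1)")
    }
    if (signature_size < 1L || gradient_module_size < 0L) {
      stop("module sizes must be positive")
    }
    if (signature_size + gradient_module_size > n_genes) {
      stop("signature and gradient modules exceed the gene count")
    }
    if (nb_dispersion <= 0) {
      stop("nb_dispersion must be > 0")
    }
    if (n_donors < 1L) {
      stop("n_donors must be >= 1")
    }
  })
  invisible(spec)
}

#' Simulate a count matrix with planted senescence structure
#'
#' Draws a genes x cells negative-binomial count matrix under the generative
#' model described in [synthetic_spec()], fully reproducible from the spec's
#' seed, together with the ground truth needed to test every downstream
#' module: binary labels (`label = 1` iff depth > 0.5 by construction),
#' continuous depth, the identities of signature and gradient genes, and
#' donor assignments.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `counts` (a [count_matrix()]), `truth` (data.frame:
#'   `cell_id`, `depth`, `label`, `donor`), `signature_genes`,
#'   `gradient_genes`, `spec`.
#' @export
simulate_counts <- function(spec) {
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, {
    n <- spec$n_cells
    p <- spec$n_genes
    n_sen <- round(spec$frac_senescent * n)
    status <- sample(c(rep(1L, n_sen), rep(0L, n - n_sen)))
    depth <- ifelse(status == 1L, stats::runif(n, 0.5, 1),
                    stats::runif(n, 0, 0.5))
    label <- as.integer(depth > 0.5)
    donor <- sprintf("D%d", sample.int(spec$n_donors, n, replace = TRUE))

    gene_ids <- sprintf("G%04d", seq_len(p))
    sig <- gene_ids[seq_len(spec$signature_size)]
    grad <- if (spec$gradient_module_size > 0L) {
      gene_ids[spec$signature_size + seq_len(spec$gradient_module_size)]
    } else {
      character()
    }
    rel <- stats::rlnorm(p, meanlog = 0, sdlog = 1)
    rel <- rel / sum(rel)
    libsize <- stats::rlnorm(n, spec$libsize_log_mean, spec$libsize_log_sd)
    donor_fac <- matrix(stats::rlnorm(p * spec$n_donors, 0,
                                      spec$donor_effect_sd),
                        nrow = p,
                        dimnames = list(gene_ids,
                                        sprintf("D%d", seq_len(spec$n_donors))))

    mu <- outer(rel, libsize)
    dimnames(mu) <- list(gene_ids, sprintf("C%05d", seq_len(n)))
    mod <- c(sig, grad)
    fold <- 2^(spec$signature_log2fc * (2 * depth - 1))
    mu[mod, ] <- mu[mod, , drop = FALSE] *
      matrix(fold, nrow = length(mod), ncol = n, byrow = TRUE)
    mu <- mu * donor_fac[, donor]

    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu),
                     size = 1 / spec$nb_dispersion),
      nrow = p, dimnames = dimnames(mu))
    list(
      counts = count_matrix(counts,
                            layout = if (n > 100L) "sparse" else "dense"),
      truth = data.frame(cell_id = colnames(mu), depth = depth,
                         label = label, donor = donor,
                         stringsAsFactors = FALSE),
      signature_genes = sig,
      gradient_genes = grad,
      spec = spec
    )
  })
}

#' Built-in fixture specifications
#'
#' Three canonical synthetic datasets used throughout the test suite and the
#' worked examples, with frozen seeds:
#' \describe{
#'   \item{bulk_small}{12 samples x 500 genes, 6 young vs 6 senescent, a
#'     bulk passaging-style design (seed 101).}
#'   \item{sc_medium}{2000 cells x 1000 genes, 2 donors, 30% senescent,
#'     60-gene signature at log2FC 2 (seed 202).}
#'   \item{gradient}{500 cells x 200 genes, continuous depth spanning [0, 1]
#'     with a 40-gene non-signature gradient module, for trajectory tests
#'     (seed 303).}
#' }
#'
#' @param name one of `"bulk_small"`, `"sc_medium"`, `"gradient"`.
#' @return a [synthetic_spec()].
#' @export
fixture_spec <- function(name = c("bulk_small", "sc_medium", "gradient")) {
  name <- match.arg(name)
  switch(name,
    bulk_small = synthetic_spec(
      n_genes = 500L, n_cells = 12L, frac_senescent = 0.5,
      signature_size = 50L, signature_log2fc = 2,
      gradient_module_size = 20L, nb_dispersion = 0.2,
      libsize_log_mean = log(2e5), libsize_log_sd = 0.2,
      n_donors = 1L, donor_effect_sd = 0, seed = 101L),
    sc_medium = synthetic_spec(
      n_genes = 1000L, n_cells = 2000L, frac_senescent = 0.3,
      signature_size = 60L, signature_log2fc = 2,
      gradient_module_size = 0L, nb_dispersion = 0.3,
      libsize_log_mean = log(800), libsize_log_sd = 0.3,
      n_donors = 2L, donor_effect_sd = 0.1, seed = 202L),
    gradient = synthetic_spec(
      n_genes = 200L, n_cells = 500L, frac_senescent = 0.5,
      signature_size = 30L, signature_log2fc = 2,
      gradient_module_size = 40L, nb_dispersion = 0.3,
      libsize_log_mean = log(3000), libsize_log_sd = 0.3,
      n_donors = 1L, donor_effect_sd = 0, seed = 303L)
  )
}

#' Stratified train/hold-out split
#'
#' Splits sample indices into a training and a hold-out set, sampling within
#' each label stratum so class prevalence is preserved — the standard
#' convention for imbalanced classification data.
#'
#' @param labels binary 0/1 vector.
#' @param train_fraction fraction of each stratum assigned to training
#'   (default 0.7).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  labels <- as.integer(labels)
  withr::with_seed(as.integer(seed), {
    train <- integer()
    for (lv in sort(unique(labels))) {
      idx <- which(labels == lv)
      train <- c(train, sample(idx, round(train_fraction * length(idx))))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Write a named fixture to disk
#'
#' Simulates the requested [fixture_spec()] dataset and writes counts
#' (dense TSV for `bulk_small`, MatrixMarket directory otherwise), a sample
#' metadata table, the ground truth, the gene roles, and a YAML echo of the
#' generating spec. Output is byte-identical across runs.
#'
#' @param name fixture name, see [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the simulation list from [simulate_counts()].
#' @export
make_fixture <- function(name = c("bulk_small", "sc_medium", "gradient"),
                         dir) {
  name <- match.arg(name)
  spec <- fixture_spec(name)
  sim <- simulate_counts(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "bulk_small") {
    write_counts(sim$counts, file.path(dir, "counts.tsv"), format = "tsv")
  } else {
    write_counts(sim$counts, file.path(dir, "counts"), format = "mtx_dir")
  }
  meta <- data.frame(
    sample_id = sim$truth$cell_id,
    group = ifelse(sim$truth$label == 1L, "senescent", "young"),
    donor = sim$truth$donor,
    label = sim$truth$label,
    stringsAsFactors = FALSE
  )
  utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  roles <- data.frame(
    gene_id = c(sim$signature_genes, sim$gradient_genes),
    role = c(rep("signature", length(sim$signature_genes)),
             rep("gradient", length(sim$gradient_genes))),
    stringsAsFactors = FALSE
  )
  utils::write.table(roles, file.path(dir, "gene_roles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(unclass(spec)), file.path(dir, "spec.yaml"))
  invisible(sim)
}
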