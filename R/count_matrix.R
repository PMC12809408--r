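#' Construct a count matrix container
#'
#' A `count_matrix` holds non-negative integer counts with genes in rows and
#' samples (or cells) in columns. Gene identifiers are upper-cased on
#' construction so that human and mouse symbols (e.g. `SLPI` / `Slpi`) match;
#' duplicate gene rows arising from the normalisation are collapsed by
#' summation.
#'
#' @param counts numeric matrix, genes x samples, non-negative integers.
#'   Row names are gene identifiers, column names sample identifiers.
#' @param layout `"dense"` or `"sparse"`, recording how the data arrived.
#' @return An object of class `count_matrix` with elements `counts`
#'   (base matrix), `gene_ids`, `sample_ids` and `layout`.
#' @export
count_matrix <- function(counts, layout = c("dense", "sparse")) {
  layout <- match.arg(layout)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (any(!is.finite(counts))) {
    stop("counts contain non-finite entries")
  }
  if (any(counts < 0)) {
    stop("counts contain negative entries")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts contain non-integer entries")
  }
  counts <- round(counts)
  rownames(counts) <- normalize_gene_ids(rownames(counts))
  counts <- collapse_duplicate_genes(counts)
  if (anyDuplicated(colnames(counts))) {
    stop("sample identifiers are not unique")
  }
  structure(
    list(
      counts = counts,
      gene_ids = rownames(counts),
      sample_ids = colnames(counts),
      layout = layout
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (%s), total count %s\n",
    nrow(x$counts), ncol(x$counts), x$layout,
    format(sum(x$counts), big.mark = ",")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Upper-case gene identifiers
#'
#' Idempotent normalisation used throughout the package so that gene symbols
#' from different species/annotations compare equal.
#'
#' @param ids character vector of gene identifiers.
#' @return normalised character vector.
#' @export
normalize_gene_ids <- function(ids) {
  toupper(trimws(as.character(ids)))
}

collapse_duplicate_genes <- function(counts) {
  ids <- rownames(counts)
  if (!anyDuplicated(ids)) {
    return(counts)
  }
  if (length(unique(ids)) == 1L && nrow(counts) > 1L) {
    # still legal; everything collapses onto one row
    warning(sprintf("all %d gene rows share one identifier '%s'; summed",
                    nrow(counts), ids[[1L]]))
  } else {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("%d duplicated gene identifier(s) collapsed by summation: %s",
                    length(dup), paste(utils::head(dup, 5L), collapse = ", ")))
  }
  out <- rowsum(counts, group = ids, reorder = FALSE)
  out[unique(ids), , drop = FALSE]
}

#' Read a counts matrix from disk
#'
#' Supports dense TSV/CSV tables (genes in rows, first column gene IDs, header
#' row of sample IDs) and 10x-style MatrixMarket directories containing
#' `matrix.mtx`, a gene/feature sidecar and a barcode sidecar. MatrixMarket
#' triplet indices are 1-based per that standard.
#'
#' @param path file (tsv/csv) or directory (mtx_dir).
#' @param format one of `"tsv"`, `"csv"`, `"mtx_dir"`; default guessed from
#'   the path (directory -> mtx_dir, extension otherwise).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) {
      "mtx_dir"
    } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      "csv"
    } else {
      "tsv"
    }
  }
  format <- match.arg(format, c("tsv", "csv", "mtx_dir"))
  if (format == "mtx_dir") {
    return(read_counts_mtx_dir(path))
  }
  if (!file.exists(path)) {
    stop(sprintf("counts file not found: %s", path))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    stop("counts table contains non-numeric entries")
  }
  count_matrix(m, layout = "dense")
}

read_counts_mtx_dir <- function(path) {
  if (!dir.exists(path)) {
    stop(sprintf("mtx directory not found: %s", path))
  }
  find_one <- function(cands, what) {
    hits <- cands[file.exists(file.path(path, cands))]
    if (length(hits) == 0L) {
      stop(sprintf("missing %s sidecar in %s (looked for %s)",
                   what, path, paste(cands, collapse = ", ")))
    }
    file.path(path, hits[[1L]])
  }
  mtx <- find_one(c("matrix.mtx", "counts.mtx"), "matrix")
  genes <- find_one(c("features.tsv", "genes.tsv"), "gene")
  barcodes <- find_one("barcodes.tsv", "barcode")
  m <- as.matrix(Matrix::readMM(mtx))
  gene_tab <- utils::read.table(genes, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)
  bc_tab <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
  if (nrow(gene_tab) != nrow(m)) {
    stop(sprintf("gene sidecar has %d rows but matrix has %d",
                 nrow(gene_tab), nrow(m)))
  }
  if (nrow(bc_tab) != ncol(m)) {
    stop(sprintf("barcode sidecar has %d rows but matrix has %d columns",
                 nrow(bc_tab), ncol(m)))
  }
  rownames(m) <- gene_tab[[1L]]
  colnames(m) <- bc_tab[[1L]]
  count_matrix(m, layout = "sparse")
}

#' Write a counts matrix to disk
#'
#' Inverse of [read_counts()]: dense layouts go to a TSV/CSV table, sparse
#' layouts to a MatrixMarket directory with gene/barcode sidecars.
#'
#' @param x a [count_matrix()].
#' @param path output file (dense) or directory (sparse).
#' @param format `"tsv"`, `"csv"` or `"mtx_dir"`; default follows `x$layout`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(format)) {
    format <- if (x$layout == "sparse") "mtx_dir" else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "mtx_dir"))
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(x$gene_ids, file.path(path, "features.tsv"))
    writeLines(x$sample_ids, file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- data.frame(gene_id = x$gene_ids, x$counts, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`. Blank gene
#' tokens (including trailing empty fields) are dropped; gene symbols are
#' normalised with [normalize_gene_ids()] to match count matrices.
#'
#' @param path GMT file.
#' @return an object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors), `descriptions`, and `provenance`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file is empty")
  }
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", i))
    }
    name <- fields[[1L]]
    genes <- normalize_gene_ids(fields[-(1:2)])
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0L) {
      stop(sprintf("gene set '%s' (line %d) has no genes", name, i))
    }
    if (name %in% names(sets)) {
      stop(sprintf("duplicate gene-set name '%s'", name))
    }
    sets[[name]] <- genes
    descriptions[[name]] <- fields[[2L]]
  }
  structure(
    list(sets = sets, descriptions = descriptions, provenance = path),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (%s)\n", length(x$sets),
              paste(utils::head(names(x$sets), 4L), collapse = ", ")))
  invisible(x)
}

#' Read a sample metadata table
#'
#' TSV with a `sample_id` column plus arbitrary annotation columns (e.g.
#' `group`, `donor`, `label`). When a `label` column is present it must be
#' binary 0/1.
#'
#' @param path TSV file.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("metadata file not found: %s", path))
  }
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata must contain a 'sample_id' column")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("metadata sample_id values are not unique")
  }
  if ("label" %in% names(meta) && !all(meta$label %in% c(0L, 1L, NA))) {
    stop("metadata 'label' column must be binary 0/1")
  }
  meta
}
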