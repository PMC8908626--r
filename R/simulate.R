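# Synthetic UMI count generator. Every downstream stage of the package is
# validated on data from this module because it carries ground truth: known
# cluster memberships, known signature-positive cells, and known gene roles.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulate_counts()]. Defaults
#' describe a mid-sized droplet-style experiment: 2,000 cells, 3,000 genes,
#' five clusters of equal size, log-normal library sizes around 15,000 UMIs,
#' negative-binomial overdispersion, 50 marker genes per cluster at 4-fold
#' (log2 FC 2) enrichment, a 50-gene planted signature up-shifted ~2.8-fold
#' (log2 FC 1.5) in 40% of cells, and a mitochondrial gene block averaging
#' 5% of each cell's library.
#'
#' @param n_cells,n_genes Matrix dimensions (cells, genes).
#' @param n_clusters Number of latent clusters K.
#' @param cluster_props Length-K simplex of cluster proportions
#'   (default uniform). Must sum to 1 within 1e-9.
#' @param libsize_mu,libsize_sigma Mean and sd of log library size
#'   (natural log scale).
#' @param dispersion Negative-binomial size parameter (inverse dispersion);
#'   smaller means more overdispersed.
#' @param n_marker_genes_per_cluster,marker_log2fc Per-cluster marker gene
#'   count and their log2 fold-change over baseline.
#' @param signature_genes Number of planted signature genes.
#' @param pos_fraction Fraction of cells that are signature-positive.
#' @param pos_log2fc Log2 up-shift of signature genes in positive cells.
#' @param pos_placement `"spread"` (positivity independent of cluster) or
#'   `"concentrated"` (positive cells drawn from one cluster,
#'   see `pos_cluster`).
#' @param pos_cluster 0-based cluster id hosting the positive cells when
#'   `pos_placement = "concentrated"`.
#' @param mito_genes,mito_fraction_mu Mitochondrial gene count and the mean
#'   fraction of each cell's library they absorb.
#' @param seed Integer seed; the same config (seed included) reproduces the
#'   simulated matrix bit-for-bit.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 3000L, n_clusters = 5L,
                       cluster_props = NULL,
                       libsize_mu = log(15000), libsize_sigma = 0.25,
                       dispersion = 2,
                       n_marker_genes_per_cluster = 50L, marker_log2fc = 2,
                       signature_genes = 50L, pos_fraction = 0.4,
                       pos_log2fc = 1.5,
                       pos_placement = c("spread", "concentrated"),
                       pos_cluster = 0L,
                       mito_genes = 50L, mito_fraction_mu = 0.05,
                       seed = 1L) {
  pos_placement <- match.arg(pos_placement)
  if (is.null(cluster_props)) cluster_props <- rep(1 / n_clusters, n_clusters)
  stopifnot(
    n_cells >= 1, n_genes >= 1, n_clusters >= 1,
    length(cluster_props) == n_clusters, all(cluster_props > 0),
    dispersion > 0, n_marker_genes_per_cluster >= 0, marker_log2fc > 0,
    signature_genes >= 1, pos_fraction >= 0, pos_fraction <= 1,
    pos_log2fc > 0, mito_genes >= 0,
    mito_fraction_mu > 0, mito_fraction_mu < 1,
    libsize_sigma > 0
  )
  if (abs(sum(cluster_props) - 1) > 1e-9) {
    stop("cluster_props must sum to 1 (got ", sum(cluster_props), ")")
  }
  if (pos_placement == "concentrated" &&
      (pos_cluster < 0 || pos_cluster >= n_clusters)) {
    stop("pos_cluster must be in 0..", n_clusters - 1,
         " (got ", pos_cluster, ")")
  }
  n_special <- signature_genes + n_clusters * n_marker_genes_per_cluster +
    mito_genes
  if (signature_genes > n_genes) {
    stop("signature_genes (", signature_genes, ") exceeds n_genes (",
         n_genes, ")")
  }
  if (n_special > n_genes) {
    stop("signature + marker + mitochondrial genes (", n_special,
         ") exceed n_genes (", n_genes, ")")
  }
  structure(
    list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
         n_clusters = as.integer(n_clusters), cluster_props = cluster_props,
         libsize_mu = libsize_mu, libsize_sigma = libsize_sigma,
         dispersion = dispersion,
         n_marker_genes_per_cluster = as.integer(n_marker_genes_per_cluster),
         marker_log2fc = marker_log2fc,
         signature_genes = as.integer(signature_genes),
         pos_fraction = pos_fraction, pos_log2fc = pos_log2fc,
         pos_placement = pos_placement, pos_cluster = as.integer(pos_cluster),
         mito_genes = as.integer(mito_genes),
         mito_fraction_mu = mito_fraction_mu, seed = as.integer(seed)),
    class = "sim_config")
}

#' Count matrix container
#'
#' Lightweight container pairing a sparse genes x cells UMI count matrix
#' with a per-gene mitochondrial flag. Gene and cell identifiers live in the
#' matrix dimnames. If `mito` is omitted it is inferred from the
#' conventional "MT-" gene-name prefix.
#'
#' @param counts Non-negative integer matrix (genes x cells), dense or
#'   sparse, with row and column names.
#' @param mito Optional logical vector, one entry per gene.
#' @return Object of class `count_matrix` with elements `counts`
#'   (`dgCMatrix`) and `mito`.
#' @export
count_matrix <- function(counts, mito = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_matrix: counts must have gene (row) and cell (column) names")
  }
  if (any(counts@x < 0)) stop("count_matrix: negative counts")
  if (is.null(mito)) mito <- startsWith(rownames(counts), "MT-")
  stopifnot(length(mito) == nrow(counts))
  structure(list(counts = counts, mito = mito), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      sum(x$mito), "mitochondrial genes;",
      format(100 * Matrix::nnzero(x$counts) / length(x$counts), digits = 3),
      "% nonzero\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Gene role layout: signature genes first, then K marker blocks, then
# background, with the mitochondrial block last (MT- names).
sim_gene_roles <- function(config) {
  roles <- rep("background", config$n_genes)
  idx <- 0L
  sig <- seq_len(config$signature_genes)
  roles[sig] <- "signature"
  idx <- config$signature_genes
  for (k in seq_len(config$n_clusters) - 1L) {
    if (config$n_marker_genes_per_cluster > 0) {
      roles[idx + seq_len(config$n_marker_genes_per_cluster)] <-
        paste0("marker_", k)
      idx <- idx + config$n_marker_genes_per_cluster
    }
  }
  if (config$mito_genes > 0) {
    roles[config$n_genes - config$mito_genes + seq_len(config$mito_genes)] <-
      "mito"
  }
  roles
}

#' Simulate a UMI count matrix with a planted signature-positive population
#'
#' Draws gene-by-cell counts from a negative binomial (gamma-Poisson) whose
#' mean is `library_size(cell) * program(gene, cluster(cell), positive(cell))`
#' with the per-cell program normalized to a simplex. Cluster identity sets
#' a marker-gene block; signature-positivity up-shifts the signature gene
#' block by `2^pos_log2fc`; mitochondrial genes absorb a Dirichlet-perturbed
#' fraction of each library centered on `mito_fraction_mu`. Output is
#' bit-reproducible for a fixed config.
#'
#' @param config A [sim_config()].
#' @return List with `matrix` (a [count_matrix()]) and `truth`, a list of
#'   `cells` (data.frame: cell_id, cluster, positive) and `genes`
#'   (data.frame: gene_id, role).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  nc <- config$n_cells
  K <- config$n_clusters

  gene_ids <- sprintf("G%06d", seq_len(ng))
  roles <- sim_gene_roles(config)
  mito_idx <- which(roles == "mito")
  sig_idx <- which(roles == "signature")
  if (length(mito_idx)) {
    gene_ids[mito_idx] <- sprintf("MT-G%06d", seq_along(mito_idx))
  }
  cell_ids <- sprintf("CELL%06d", seq_len(nc))

  cluster <- sample.int(K, nc, replace = TRUE,
                        prob = config$cluster_props) - 1L
  n_pos <- round(config$pos_fraction * nc)
  positive <- rep(FALSE, nc)
  if (n_pos > 0) {
    if (config$pos_placement == "spread") {
      positive[sample.int(nc, n_pos)] <- TRUE
    } else {
      host <- which(cluster == config$pos_cluster)
      if (length(host) < n_pos) {
        stop("concentrated placement: cluster ", config$pos_cluster,
             " has ", length(host), " cells but ", n_pos,
             " positives requested")
      }
      positive[sample(host, n_pos)] <- TRUE
    }
  }

  # baseline gene weights and per-cluster programs
  w <- rlnorm(ng, meanlog = 0, sdlog = 1)
  prog <- matrix(w, nrow = ng, ncol = K)
  for (k in seq_len(K) - 1L) {
    mk <- which(roles == paste0("marker_", k))
    if (length(mk)) prog[mk, k + 1L] <- prog[mk, k + 1L] * 2^config$marker_log2fc
  }

  expr <- prog[, cluster + 1L, drop = FALSE] # genes x cells
  if (any(positive) && length(sig_idx)) {
    expr[sig_idx, positive] <- expr[sig_idx, positive] * 2^config$pos_log2fc
  }

  # mitochondrial block: per-cell Beta fraction, Dirichlet-perturbed weights
  if (length(mito_idx)) {
    conc <- 50
    f <- rbeta(nc, conc * config$mito_fraction_mu,
               conc * (1 - config$mito_fraction_mu))
    w_m <- w[mito_idx] / sum(w[mito_idx])
    dir <- matrix(rgamma(length(mito_idx) * nc, shape = conc * w_m),
                  nrow = length(mito_idx))
    dir <- sweep(dir, 2, colSums(dir), "/")
    non_mito <- setdiff(seq_len(ng), mito_idx)
    expr[non_mito, ] <- sweep(expr[non_mito, , drop = FALSE], 2,
                              (1 - f) / colSums(expr[non_mito, , drop = FALSE]),
                              "*")
    expr[mito_idx, ] <- sweep(dir, 2, f, "*")
  } else {
    expr <- sweep(expr, 2, colSums(expr), "/")
  }

  libsize <- rlnorm(nc, config$libsize_mu, config$libsize_sigma)
  mu <- sweep(expr, 2, libsize, "*")
  counts <- matrix(rnbinom(ng * nc, size = config$dispersion, mu = as.vector(mu)),
                   nrow = ng, dimnames = list(gene_ids, cell_ids))

  list(
    matrix = count_matrix(counts, mito = roles == "mito"),
    truth = list(
      cells = data.frame(cell_id = cell_ids, cluster = cluster,
                         positive = positive, stringsAsFactors = FALSE),
      genes = data.frame(gene_id = gene_ids, role = roles,
                         stringsAsFactors = FALSE)
    )
  )
}

#' Write a count matrix as a MatrixMarket bundle
#'
#' Writes `matrix.mtx` (coordinate integer), `features.tsv` and
#' `barcodes.tsv` under `dir`, mirroring cellRanger-style output.
#'
#' @param x A [count_matrix()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (nrow(x$counts) == 0 || ncol(x$counts) == 0) {
    stop("write_mtx: empty matrix")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(
    data.frame(id = rownames(x$counts), name = rownames(x$counts),
               type = ifelse(x$mito, "Mito", "Gene Expression")),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket count bundle
#'
#' Reads `matrix.mtx` + `features.tsv` + `barcodes.tsv` written by
#' [write_mtx()] (or cellRanger-style equivalents). Validates dimensions
#' against the feature/barcode files and rejects negative entries.
#'
#' @param dir Directory containing the three files.
#' @return A [count_matrix()].
#' @export
read_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("read_mtx: missing file(s): ",
                            paste(basename(missing), collapse = ", "))
  m <- tryCatch(Matrix::readMM(paths[1]),
                error = function(e) stop("read_mtx: malformed MTX (",
                                         conditionMessage(e), ")"))
  feats <- read.delim(paths[2], header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(paths[3])
  if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m)) {
    stop("read_mtx: dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but features/barcodes give ", nrow(feats), " x ", length(barcodes))
  }
  if (methods::is(m, "nMatrix")) m <- methods::as(m, "dMatrix") # all-zero files
  if (length(m@x) && any(m@x < 0)) stop("read_mtx: negative entries")
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(feats[[1]], barcodes)
  mito <- if (ncol(feats) >= 3) feats[[3]] == "Mito" else NULL
  count_matrix(m, mito = mito)
}

#' Write simulation ground truth as TSV
#'
#' @param truth The `truth` element returned by [simulate_counts()].
#' @param path Output file for the per-cell table (cell_id, cluster,
#'   positive).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth$cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
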