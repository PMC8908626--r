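# QC, normalization, scaling, dimensionality reduction and clustering.
# The recipe follows the common Seurat-style conventions: barcode-count and
# detected-gene floors, a mitochondrial-fraction ceiling, LogNormalize with
# scale factor 10,000, gene-wise standardization with clipping, PCA with a
# permutation-based component selection, and community detection on a
# shared-nearest-neighbor graph.

#' QC thresholds
#'
#' @param min_barcode_counts Keep cells with total counts strictly greater
#'   than this (default 500).
#' @param min_genes_per_cell Keep cells detecting at least this many genes
#'   (default 2000).
#' @param max_mito_fraction Keep cells whose mitochondrial count fraction is
#'   at most this (default 0.10).
#' @param doublet_quantile Proxy doublet filter: cells whose total counts
#'   exceed this quantile of the input totals are removed. `1` disables it.
#'   The quantile is resolved to an absolute cutoff on first application
#'   (reported as `max_counts` in the QC report), so re-filtering with the
#'   resolved thresholds is a no-op.
#' @param max_counts Absolute upper total-count cutoff (overrides
#'   `doublet_quantile` when finite).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_barcode_counts = 500L, min_genes_per_cell = 2000L,
                          max_mito_fraction = 0.10, doublet_quantile = 0.99,
                          max_counts = Inf) {
  stopifnot(min_barcode_counts >= 0, min_genes_per_cell >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            doublet_quantile > 0, doublet_quantile <= 1, max_counts > 0)
  structure(list(min_barcode_counts = min_barcode_counts,
                 min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 doublet_quantile = doublet_quantile,
                 max_counts = max_counts),
            class = "qc_thresholds")
}

#' Filter cells on QC criteria
#'
#' Retains cells with total counts above `min_barcode_counts`, at least
#' `min_genes_per_cell` detected genes, mitochondrial fraction at most
#' `max_mito_fraction`, and total counts at most the resolved doublet
#' cutoff. Genes are never removed.
#'
#' @param x A [count_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `matrix` (filtered [count_matrix()]) and `report`: per
#'   filter removal counts, the resolved absolute thresholds, and per-cell
#'   QC metrics for the input.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "count_matrix"), inherits(thresholds, "qc_thresholds"))
  counts <- x$counts
  totals <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_frac <- if (any(x$mito)) {
    Matrix::colSums(counts[x$mito, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, ncol(counts))
  }

  max_counts <- thresholds$max_counts
  if (!is.finite(max_counts) && thresholds$doublet_quantile < 1) {
    max_counts <- as.numeric(quantile(totals, thresholds$doublet_quantile))
  }

  pass_counts <- totals > thresholds$min_barcode_counts
  pass_genes <- detected >= thresholds$min_genes_per_cell
  pass_mito <- mito_frac <= thresholds$max_mito_fraction
  pass_doublet <- totals <= max_counts
  keep <- pass_counts & pass_genes & pass_mito & pass_doublet

  if (!any(keep)) {
    fails <- c(counts = sum(!pass_counts), genes = sum(!pass_genes),
               mito = sum(!pass_mito), doublet = sum(!pass_doublet))
    stop("empty after QC: no cell passes all filters (binding filter: ",
         names(which.max(fails)), ", removing ", max(fails), "/",
         ncol(counts), " cells)")
  }

  resolved <- qc_thresholds(thresholds$min_barcode_counts,
                            thresholds$min_genes_per_cell,
                            thresholds$max_mito_fraction,
                            doublet_quantile = 1,
                            max_counts = max_counts)
  report <- list(
    n_input = ncol(counts), n_retained = sum(keep),
    removed_low_counts = sum(!pass_counts),
    removed_low_genes = sum(!pass_genes),
    removed_high_mito = sum(!pass_mito),
    removed_doublet_proxy = sum(pass_counts & pass_genes & pass_mito &
                                  !pass_doublet),
    thresholds = resolved,
    metrics = data.frame(cell_id = colnames(counts), total_counts = totals,
                         detected_genes = detected, mito_fraction = mito_frac,
                         retained = keep, row.names = NULL)
  )
  list(matrix = count_matrix(counts[, keep, drop = FALSE], mito = x$mito),
       report = report)
}

#' Log-normalize counts
#'
#' Seurat-style LogNormalize: `log(1 + count * scale_factor / cell_total)`,
#' natural log. Zeros stay zero (the sparse pattern is preserved).
#'
#' @param x A [count_matrix()].
#' @param scale_factor Pseudo library size each cell is rescaled to
#'   (default 10,000).
#' @return Object of class `normalized_matrix`: list with `values`
#'   (sparse genes x cells), `scale_factor`, and `counts` (the raw counts,
#'   kept for expression-fraction statistics downstream).
#' @export
log_normalize <- function(x, scale_factor = 10000) {
  stopifnot(inherits(x, "count_matrix"), scale_factor > 0)
  counts <- x$counts
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop("log_normalize: ", sum(totals == 0),
         " cell(s) with zero total counts; run qc_filter first")
  }
  values <- counts
  # column-wise scale on the nonzero entries of the CSC representation
  per_entry_total <- rep.int(totals, diff(values@p))
  values@x <- log1p(values@x * scale_factor / per_entry_total)
  structure(list(values = values, scale_factor = scale_factor, counts = counts),
            class = "normalized_matrix")
}

#' Gene-wise standardization
#'
#' Centers and scales each gene across cells (sample standard deviation,
#' n - 1), clips extreme values to about `±clip`, and drops zero-variance
#' genes. Clipping is followed by one exact re-standardization pass (no
#' second clip), so every retained row has mean 0 and unit sd to machine
#' precision; values that were capped may therefore sit marginally beyond
#' `clip` after re-standardization.
#'
#' @param norm A [log_normalize()] result (or a plain genes x cells numeric
#'   matrix).
#' @param clip Absolute value at which standardized values are capped
#'   (default 10, the Seurat convention). `Inf` disables clipping.
#' @return Object of class `scaled_matrix`: list with `values` (dense genes
#'   x cells), `dropped_genes` (zero-variance gene ids), and `clip`.
#' @export
scale_genes <- function(norm, clip = 10) {
  values <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("scale_genes: need at least 2 cells")
  standardize <- function(m) {
    mu <- rowMeans(m)
    sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
    list(values = (m - mu) / sdv, sd = sdv)
  }
  s <- standardize(values)
  keep <- s$sd > 0
  dropped <- rownames(values)[!keep]
  if (!any(keep)) stop("scale_genes: all genes have zero variance")
  scaled <- s$values[keep, , drop = FALSE]
  if (is.finite(clip) && any(abs(scaled) > clip)) {
    scaled[scaled > clip] <- clip
    scaled[scaled < -clip] <- -clip
    scaled <- standardize(scaled)$values
  }
  structure(list(values = scaled, dropped_genes = dropped, clip = clip),
            class = "scaled_matrix")
}

#' Residualize scaled values on a per-cell covariate
#'
#' Optional mitochondrial-load correction: per gene, ordinary-least-squares
#' residuals of the scaled values on a per-cell covariate (typically the
#' mitochondrial fraction), followed by re-standardization. This is a
#' simplified stand-in for model-based covariate regression; it is off by
#' default in [preprocess()].
#'
#' @param scaled A [scale_genes()] result.
#' @param covariate Numeric per-cell vector (same cell order).
#' @return A `scaled_matrix` of residualized, re-standardized values.
#' @export
regress_out <- function(scaled, covariate) {
  stopifnot(inherits(scaled, "scaled_matrix"),
            length(covariate) == ncol(scaled$values))
  x <- covariate - mean(covariate)
  ssx <- sum(x^2)
  if (ssx == 0) return(scaled)
  v <- scaled$values
  beta <- (v %*% x) / ssx      # rows are centered already
  resid <- v - tcrossprod(beta, x)
  scale_genes(resid, clip = scaled$clip)
}

#' PCA with permutation-based component selection
#'
#' Computes principal components of the cells (observations = cells,
#' variables = standardized genes) and selects components whose explained
#' variance exceeds what independent permutation of each gene's values
#' across cells produces. This replaces resampling-based component selection
#' (JackStraw-like) with a fully specified permutation null: for each of
#' `n_permutations` replicates every gene row is permuted independently, the
#' top component variances of the permuted matrix are computed, and the
#' empirical p-value of component j compares its observed variance with the
#' null distribution of the j-th permuted variance. Retention is sequential
#' (parallel-analysis style): the longest leading run of components with
#' p < `alpha` is kept, stopping at the first non-significant component, so
#' that on structureless data no component survives by multiplicity alone.
#' At least the first two components are always kept.
#'
#' Singular values are computed by a randomized subspace iteration (Halko-
#' style, two power iterations, 10-dimensional oversampling), accurate to
#' well below the permutation resolution and deterministic given `seed`.
#'
#' @param scaled A [scale_genes()] result.
#' @param n_components Number of leading components to compute (must be
#'   less than `min(genes, cells)`).
#' @param n_permutations Number of null replicates (minimum 20).
#' @param alpha Retention threshold on the empirical p-value.
#' @param seed Integer seed.
#' @return Object of class `embedding`: list with `scores` (cells x
#'   retained-components), `selected_components`, `var_explained` and
#'   `p_values` for all computed components, and `umap` (`NULL` until
#'   [umap_embed()] is called).
#' @export
pca_select <- function(scaled, n_components = 20L, n_permutations = 100L,
                       alpha = 0.05, seed = 1L) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  if (n_permutations < 20) {
    stop("pca_select: n_permutations must be >= 20 (null too coarse)")
  }
  x <- t(scaled$values) # cells x genes
  if (n_components >= min(dim(x))) {
    stop("pca_select: n_components must be < min(genes, cells)")
  }
  set.seed(seed)
  total_var <- sum(apply(scaled$values, 1, var)) # invariant under row permutation
  sv <- rsvd_values(x, n_components)
  obs_var <- sv^2 / (nrow(x) - 1)

  null_var <- matrix(NA_real_, n_permutations, n_components)
  g <- ncol(x)
  for (b in seq_len(n_permutations)) {
    xp <- x
    for (j in seq_len(g)) xp[, j] <- xp[sample.int(nrow(x)), j]
    null_var[b, ] <- rsvd_values(xp, n_components)^2 / (nrow(x) - 1)
  }
  p <- vapply(seq_len(n_components), function(j) {
    (1 + sum(null_var[, j] >= obs_var[j])) / (n_permutations + 1)
  }, numeric(1))
  n_sig <- which(c(p >= alpha, TRUE))[1] - 1L # first failure stops retention
  selected <- seq_len(max(n_sig, 2L))

  # scores for the retained components via projection
  pr <- rsvd_scores(x, max(selected))
  scores <- pr$scores[, selected, drop = FALSE]
  rownames(scores) <- colnames(scaled$values)
  colnames(scores) <- paste0("PC", selected)
  structure(list(scores = scores, selected_components = selected,
                 var_explained = obs_var / total_var, p_values = p,
                 umap = NULL),
            class = "embedding")
}

#' Plain PCA embedding with a fixed number of components
#'
#' Deterministic alternative to [pca_select()] when the component count is
#' chosen a priori.
#'
#' @inheritParams pca_select
#' @return An `embedding` (see [pca_select()]); `p_values` is `NULL`.
#' @export
pca_embed <- function(scaled, n_components = 15L, seed = 1L) {
  stopifnot(inherits(scaled, "scaled_matrix"))
  x <- t(scaled$values)
  if (n_components >= min(dim(x))) {
    stop("pca_embed: n_components must be < min(genes, cells)")
  }
  set.seed(seed)
  pr <- rsvd_scores(x, n_components)
  scores <- pr$scores
  rownames(scores) <- colnames(scaled$values)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  total_var <- sum(apply(scaled$values, 1, var))
  structure(list(scores = scores,
                 selected_components = seq_len(n_components),
                 var_explained = pr$d^2 / (nrow(x) - 1) / total_var,
                 p_values = NULL, umap = NULL),
            class = "embedding")
}

# Randomized subspace iteration for the top-k singular values/vectors of a
# (possibly tall) dense matrix. Two power iterations with oversampling 10
# give singular values accurate far beyond what the permutation p-values
# resolve. Consumes the RNG stream (callers seed).
rsvd_basis <- function(x, k, q = 2L, oversample = 10L) {
  l <- min(k + oversample, min(dim(x)))
  omega <- matrix(rnorm(ncol(x) * l), ncol(x), l)
  y <- x %*% omega
  for (i in seq_len(q)) {
    y <- qr.Q(qr(y))
    y <- x %*% crossprod(x, y)
  }
  qr.Q(qr(y))
}

rsvd_values <- function(x, k, ...) {
  q <- rsvd_basis(x, k, ...)
  b <- crossprod(q, x)
  svd(b, nu = 0, nv = 0)$d[seq_len(k)]
}

rsvd_scores <- function(x, k, ...) {
  q <- rsvd_basis(x, k, ...)
  b <- crossprod(q, x) # l x genes
  sv <- svd(b)
  u <- q %*% sv$u[, seq_len(k), drop = FALSE]
  # fix sign convention: largest-|loading| coordinate positive
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  list(scores = u %*% diag(sv$d[seq_len(k)], k), d = sv$d[seq_len(k)])
}

#' Cluster cells on a PCA embedding
#'
#' Default method builds a k-nearest-neighbor graph in component space,
#' reweights edges by the Jaccard similarity of neighbor sets (shared
#' nearest neighbors), prunes weak edges, and runs Louvain community
#' detection. A k-means fallback is provided for a fixed cluster count.
#' Labels are contiguous integers from 0, ordered by decreasing cluster
#' size; results are deterministic given `seed`.
#'
#' @param embedding An `embedding` from [pca_select()]/[pca_embed()].
#' @param method `"louvain"` (default) or `"kmeans"`.
#' @param k_neighbors Neighborhood size for the graph (default 20).
#' @param resolution Louvain resolution parameter (default 0.8).
#' @param snn_prune Minimum Jaccard weight for an edge to survive
#'   (default 1/15).
#' @param centers Cluster count for `method = "kmeans"`.
#' @param seed Integer seed.
#' @return Object of class `clustering`: list with `labels` (named integer
#'   vector, 0-based) and `parameters`.
#' @export
cluster_cells <- function(embedding, method = c("louvain", "kmeans"),
                          k_neighbors = 20L, resolution = 0.8,
                          snn_prune = 1 / 15, centers = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(embedding, "embedding"))
  x <- embedding$scores
  n <- nrow(x)
  if (n == 0) stop("cluster_cells: empty embedding")
  if (method == "louvain") {
    if (k_neighbors >= n) {
      stop("cluster_cells: k_neighbors (", k_neighbors,
           ") must be less than the number of cells (", n, ")")
    }
    set.seed(seed)
    nn <- knn_indices(x, k_neighbors)
    adj <- snn_graph(nn, n, snn_prune)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- igraph::membership(comm)
  } else {
    if (is.null(centers)) stop("cluster_cells: kmeans requires `centers`")
    set.seed(seed)
    labels <- kmeans(x, centers = centers, nstart = 10, iter.max = 50)$cluster
  }
  # contiguous 0-based labels ordered by decreasing size (ties: first seen)
  sizes <- sort(table(labels), decreasing = TRUE)
  remap <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- unname(remap[as.character(labels)])
  names(out) <- rownames(x)
  structure(list(labels = out,
                 parameters = list(method = method, k_neighbors = k_neighbors,
                                   resolution = resolution, centers = centers,
                                   seed = seed)),
            class = "clustering")
}

# k nearest neighbors (excluding self) by exact Euclidean distance
knn_indices <- function(x, k) {
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

# shared-nearest-neighbor adjacency: Jaccard overlap of kNN sets, pruned
snn_graph <- function(nn, n, prune) {
  k <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)             # |N_i intersect N_j|
  jac <- shared / (2 * k - shared)              # Jaccard (|N_i| = |N_j| = k)
  jac <- methods::as(jac, "CsparseMatrix")
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  Matrix::drop0(jac)
}

#' Attach 2-D visualization coordinates
#'
#' Produces a UMAP-style 2-D layout for plotting: a force-directed
#' (Fruchterman-Reingold) layout of the k-nearest-neighbor graph of the
#' embedding. No UMAP implementation is available to this package, and the
#' coordinates are consumed by nothing downstream — they exist purely for
#' visualization, so any faithful neighbor-graph layout serves.
#' Deterministic given `seed`.
#'
#' @param embedding An `embedding`.
#' @param k_neighbors Neighborhood size for the layout graph.
#' @param seed Integer seed.
#' @return The embedding with `umap` set to a cells x 2 coordinate matrix.
#' @export
umap_embed <- function(embedding, k_neighbors = 15L, seed = 1L) {
  stopifnot(inherits(embedding, "embedding"))
  x <- embedding$scores
  if (nrow(x) < 10) stop("umap_embed: need at least 10 cells")
  set.seed(seed)
  nn <- knn_indices(x, min(k_neighbors, nrow(x) - 1L))
  adj <- snn_graph(nn, nrow(x), prune = 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  coords <- igraph::layout_with_fr(g, niter = 200)
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("DIM1", "DIM2")
  embedding$umap <- coords
  embedding
}

#' Run the full preprocessing pipeline
#'
#' Convenience wrapper: QC filter, log-normalization, gene-wise scaling,
#' optional mitochondrial-fraction regression, PCA (permutation-selected or
#' fixed component count), and graph clustering.
#'
#' @param x A [count_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @param scale_factor,clip See [log_normalize()], [scale_genes()].
#' @param regress_mito Residualize scaled values on mitochondrial fraction.
#' @param pca `"fixed"` (default; `n_components` PCs) or `"permutation"`
#'   ([pca_select()]).
#' @param n_components,n_permutations,alpha PCA parameters.
#' @param cluster_params List passed on to [cluster_cells()].
#' @param seed Integer seed for PCA and clustering.
#' @return List with `qc`, `norm`, `scaled`, `embedding`, `clustering`.
#' @export
preprocess <- function(x, thresholds = qc_thresholds(), scale_factor = 10000,
                       clip = 10, regress_mito = FALSE,
                       pca = c("fixed", "permutation"), n_components = 15L,
                       n_permutations = 100L, alpha = 0.05,
                       cluster_params = list(), seed = 1L) {
  pca <- match.arg(pca)
  qc <- qc_filter(x, thresholds)
  norm <- log_normalize(qc$matrix, scale_factor)
  scaled <- scale_genes(norm, clip = clip)
  if (regress_mito) {
    mf <- qc$report$metrics
    mf <- mf$mito_fraction[mf$retained]
    scaled <- regress_out(scaled, mf)
  }
  embedding <- if (pca == "permutation") {
    pca_select(scaled, n_components, n_permutations, alpha, seed)
  } else {
    pca_embed(scaled, n_components, seed)
  }
  clustering <- do.call(cluster_cells,
                        c(list(embedding = embedding, seed = seed),
                          cluster_params))
  list(qc = qc, norm = norm, scaled = scaled, embedding = embedding,
       clustering = clustering)
}
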