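# Cluster differential expression and derivation of custom population
# signatures from a cluster's DEGs. Conventions follow the de-facto
# FindMarkers defaults: expression-fraction pre-filter (min_pct 0.1),
# two-sided Wilcoxon rank-sum on log-normalized values, natural-log fold
# change of expm1-means, Bonferroni correction over tested genes.

#' Differentially expressed genes of a cluster versus the rest
#'
#' Genes are pre-filtered to those detected (raw count > 0) in at least
#' `min_pct` of cells on either side and with `|log_fc| >= min_logfc`; each
#' surviving gene is tested with a two-sided Wilcoxon rank-sum on its
#' log-normalized values, cluster vs rest. The fold change is
#' `ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))` (natural log).
#' P-values are Bonferroni-adjusted over all genes in the matrix (not just
#' the tested ones) — correcting only over genes that survive the
#' fold-change pre-filter would be anti-conservative, since the filter
#' selects on the same contrast the test measures. Records are sorted by
#' adjusted p, then `|log_fc|` descending, then gene id.
#'
#' @param norm A [log_normalize()] result.
#' @param clustering A [cluster_cells()] result.
#' @param cluster_k 0-based cluster label (cluster and complement each need
#'   at least 3 cells).
#' @param min_pct Minimum detection fraction on at least one side.
#' @param min_logfc Minimum absolute natural-log fold change.
#' @return data.frame with gene, cluster, log_fc, p_value, p_adjusted,
#'   pct_in, pct_out.
#' @export
find_degs <- function(norm, clustering, cluster_k, min_pct = 0.1,
                      min_logfc = 0.25) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(clustering, "clustering"))
  cells <- names(clustering$labels)
  if (!all(cells %in% colnames(norm$values))) {
    stop("find_degs: clustering covers cells absent from the matrix")
  }
  v <- norm$values[, cells, drop = FALSE]
  counts <- norm$counts[, cells, drop = FALSE]
  in_k <- clustering$labels == cluster_k
  if (sum(in_k) < 3 || sum(!in_k) < 3) {
    stop("find_degs: cluster ", cluster_k, " and its complement each need ",
         ">= 3 cells (got ", sum(in_k), " vs ", sum(!in_k), ")")
  }
  pct_in <- Matrix::rowSums(counts[, in_k, drop = FALSE] > 0) / sum(in_k)
  pct_out <- Matrix::rowSums(counts[, !in_k, drop = FALSE] > 0) / sum(!in_k)
  mean_in <- Matrix::rowMeans(v[, in_k, drop = FALSE])
  mean_out <- Matrix::rowMeans(v[, !in_k, drop = FALSE])
  # expm1-mean fold change on the log-normalized scale
  em_in <- Matrix::rowMeans(expm1_sparse(v[, in_k, drop = FALSE]))
  em_out <- Matrix::rowMeans(expm1_sparse(v[, !in_k, drop = FALSE]))
  log_fc <- log((em_in + 1) / (em_out + 1))

  keep <- pmax(pct_in, pct_out) >= min_pct & abs(log_fc) >= min_logfc
  if (!any(keep)) stop("find_degs: no gene passes the pct/logfc pre-filters")
  genes <- rownames(v)[keep]

  vd <- as.matrix(v[keep, , drop = FALSE])
  p <- apply(vd, 1, function(row) {
    r <- rank(row)
    wilcox_normal_p(r, sum(in_k), sum(!in_k),
                    sum(r[in_k]) - sum(in_k) * (sum(in_k) + 1) / 2)
  })
  # exact p for small groups (matches the package-wide Wilcoxon conventions)
  if (sum(in_k) <= 10 && sum(!in_k) <= 10) {
    p <- apply(vd, 1, function(row) {
      wilcox_rank_sum(row[in_k], row[!in_k])$p_value
    })
  }
  out <- data.frame(gene = genes, cluster = cluster_k, log_fc = log_fc[keep],
                    p_value = p, p_adjusted = pmin(1, p * nrow(v)),
                    pct_in = pct_in[keep], pct_out = pct_out[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_adjusted, -abs(out$log_fc), out$gene), , drop = FALSE]
}

expm1_sparse <- function(m) {
  if (methods::is(m, "sparseMatrix")) {
    m@x <- expm1(m@x)
    m
  } else {
    expm1(m)
  }
}

#' Derive a population signature from a DEG table
#'
#' Takes the top up-regulated DEGs (positive log fold change, adjusted p
#' below `p_cutoff`, log fold change at least `logfc_cutoff`) in the
#' [find_degs()] sort order and packages them as a [gene_signature()] with
#' the derivation parameters stored for provenance. Deterministic for a
#' given DEG table (ties broken lexicographically by gene id upstream).
#'
#' @param degs A [find_degs()] data.frame.
#' @param max_genes Maximum signature size.
#' @param p_cutoff Adjusted p-value ceiling.
#' @param logfc_cutoff Minimum natural-log fold change.
#' @param name Signature name.
#' @return A `gene_signature` with an extra `derivation` element.
#' @export
derive_signature <- function(degs, max_genes = 50L, p_cutoff = 0.05,
                             logfc_cutoff = 0.25,
                             name = paste0("cluster", degs$cluster[1],
                                           "_population_signature")) {
  stopifnot(is.data.frame(degs), max_genes >= 1)
  up <- degs[degs$log_fc > 0 & degs$p_adjusted < p_cutoff &
               degs$log_fc >= logfc_cutoff, , drop = FALSE]
  if (nrow(up) == 0) {
    stop("derive_signature: no up-regulated DEG passes p < ", p_cutoff,
         " and log_fc >= ", logfc_cutoff)
  }
  sel <- head(up, max_genes)
  sig <- gene_signature(name, sel$gene, source = "custom_degs")
  sig$derivation <- list(cluster = degs$cluster[1], max_genes = max_genes,
                         p_cutoff = p_cutoff, logfc_cutoff = logfc_cutoff,
                         n_candidates = nrow(up))
  sig
}

#' Dot-plot statistics per gene and cluster
#'
#' Mean log-normalized expression and fraction of expressing cells
#' (raw count > 0), per gene x cluster — the two quantities a marker
#' dot plot encodes as color and size.
#'
#' @param norm A [log_normalize()] result.
#' @param clustering A [cluster_cells()] result.
#' @param genes Gene identifiers (all must exist in the matrix).
#' @return data.frame with gene, cluster, mean_expression, pct_expressing.
#' @export
dotplot_stats <- function(norm, clustering, genes) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(clustering, "clustering"))
  unknown <- setdiff(genes, rownames(norm$values))
  if (length(unknown)) {
    stop("dotplot_stats: unknown gene id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  cells <- names(clustering$labels)
  v <- norm$values[genes, cells, drop = FALSE]
  counts <- norm$counts[genes, cells, drop = FALSE]
  ks <- sort(unique(clustering$labels))
  res <- lapply(ks, function(k) {
    in_k <- clustering$labels == k
    data.frame(gene = genes, cluster = k,
               mean_expression = Matrix::rowMeans(v[, in_k, drop = FALSE]),
               pct_expressing = Matrix::rowSums(counts[, in_k, drop = FALSE] > 0) /
                 sum(in_k),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare expression between signature-positive and -negative cells
#'
#' The [find_degs()] statistics (fold change, Wilcoxon p, detection
#' fractions) computed with the positivity call as the grouping, restricted
#' to the listed genes. No multiplicity correction is applied (the gene list
#' is taken as given).
#'
#' @param norm A [log_normalize()] result.
#' @param call A [classify_cells()] result (both classes non-empty).
#' @param genes Gene identifiers present in the matrix.
#' @return data.frame with gene, mean_pos, mean_neg, log_fc, p_value,
#'   pct_pos, pct_neg.
#' @export
compare_pos_neg <- function(norm, call, genes) {
  stopifnot(inherits(norm, "normalized_matrix"), inherits(call, "positivity_call"))
  unknown <- setdiff(genes, rownames(norm$values))
  if (length(unknown)) {
    stop("compare_pos_neg: unknown gene id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  cells <- names(call$positive)
  if (!all(cells %in% colnames(norm$values))) {
    stop("compare_pos_neg: positivity call covers cells absent from the matrix")
  }
  pos <- call$positive
  if (!any(pos) || all(pos)) {
    stop("compare_pos_neg: both classes must be non-empty")
  }
  v <- norm$values[genes, cells, drop = FALSE]
  counts <- norm$counts[genes, cells, drop = FALSE]
  em_pos <- Matrix::rowMeans(expm1_sparse(v[, pos, drop = FALSE]))
  em_neg <- Matrix::rowMeans(expm1_sparse(v[, !pos, drop = FALSE]))
  vd <- as.matrix(v)
  p <- apply(vd, 1, function(row) {
    wilcox_rank_sum(row[pos], row[!pos])$p_value
  })
  data.frame(gene = genes,
             mean_pos = Matrix::rowMeans(v[, pos, drop = FALSE]),
             mean_neg = Matrix::rowMeans(v[, !pos, drop = FALSE]),
             log_fc = log((em_pos + 1) / (em_neg + 1)),
             p_value = p,
             pct_pos = Matrix::rowSums(counts[, pos, drop = FALSE] > 0) / sum(pos),
             pct_neg = Matrix::rowSums(counts[, !pos, drop = FALSE] > 0) / sum(!pos),
             row.names = NULL, stringsAsFactors = FALSE)
}
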