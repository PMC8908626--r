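# Shared fixtures. Everything is built in code; unit tests use scaled-down
# simulations (the full-size stated world is exercised in test-acceptance.R).

# small, fast simulation world for unit tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 300L, n_genes = 400L, n_clusters = 3L,
         libsize_mu = log(2000), n_marker_genes_per_cluster = 30L,
         signature_genes = 30L, mito_genes = 20L),
    list(...))
  do.call(sim_config, args)
}

# QC thresholds matched to the small world (the paper-scale defaults assume
# thousands of genes)
small_thresholds <- function(...) {
  args <- utils::modifyList(
    list(min_barcode_counts = 200L, min_genes_per_cell = 100L,
         max_mito_fraction = 0.15, doublet_quantile = 1),
    list(...))
  do.call(qc_thresholds, args)
}

small_pipeline <- function(seed = 1L, config = small_config(seed = seed), ...) {
  sim <- simulate_counts(config)
  pp <- preprocess(sim$matrix, thresholds = small_thresholds(),
                   n_components = 10L, seed = seed, ...)
  truth <- sim$truth$cells[match(names(pp$clustering$labels),
                                 sim$truth$cells$cell_id), ]
  list(sim = sim, pp = pp, truth = truth)
}

planted_signature <- function(sim) {
  gene_signature("planted",
                 sim$truth$genes$gene_id[sim$truth$genes$role == "signature"])
}

# hand-made count_matrix from a dense integer matrix (genes get G ids, an
# optional leading block of MT- genes)
toy_counts <- function(m, n_mito = 0L) {
  rownames(m) <- c(sprintf("MT-G%06d", seq_len(n_mito)),
                   sprintf("G%06d", seq_len(nrow(m) - n_mito)))
  colnames(m) <- sprintf("CELL%06d", seq_len(ncol(m)))
  count_matrix(m)
}

# scaled_matrix wrapper for hand-built value matrices (bypasses scaling so
# arithmetic oracles stay exact)
as_scaled <- function(values) {
  structure(list(values = values, dropped_genes = character(0), clip = Inf),
            class = "scaled_matrix")
}

# clustering object from a plain 0-based label vector
as_clustering <- function(labels, cells = names(labels)) {
  if (is.null(cells)) cells <- sprintf("CELL%06d", seq_along(labels))
  structure(list(labels = setNames(as.integer(labels), cells),
                 parameters = list(method = "fixture")),
            class = "clustering")
}

# score_vector from a plain named numeric vector
as_scores <- function(scores, name = "toy") {
  if (is.null(names(scores))) names(scores) <- sprintf("CELL%06d", seq_along(scores))
  structure(list(signature = name, scores = scores,
                 matched_genes = character(0), missing_genes = character(0),
                 method = "mean"),
            class = "score_vector")
}

# brute-force all-pairs AUC (independent oracle for rank_auc)
brute_auc <- function(x, in_group) {
  xi <- x[in_group]
  xo <- x[!in_group]
  total <- 0
  for (a in xi) for (b in xo) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(xi) * length(xo))
}

# independent exact Wilcoxon oracle: enumerate all group assignments of the
# pooled values and compute the two-sided p as twice the smaller tail of U
# (point mass included in both tails)
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  m <- length(x)
  offset <- m * (m + 1) / 2
  combos <- combn(n, m)
  u <- apply(combos, 2, function(idx) sum(r[idx])) - offset
  u_obs <- sum(r[seq_len(m)]) - offset
  lo <- mean(u <= u_obs + 1e-9)
  hi <- mean(u >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
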