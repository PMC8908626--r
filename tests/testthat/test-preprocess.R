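# QC, normalization, scaling, component selection, clustering.

# 4-cell QC toy, one cell per filter outcome: cell 1 fails the barcode-count
# (and gene) floor, cell 3 fails the mito ceiling, cells 2 and 4 pass all
# three rules. Totals are chosen so each cell's detected-gene count is
# realizable (a cell cannot detect more genes than it has counts).
qc_toy <- function() {
  n_genes <- 2600L
  n_mito <- 50L
  m <- matrix(0L, n_genes, 4)
  fill <- function(total, detected, mito_frac) {
    col <- integer(n_genes)
    mito_counts <- round(total * mito_frac)
    body <- total - mito_counts
    regular <- n_mito + seq_len(detected) # first `detected` non-mito genes
    col[regular] <- c(rep(body %/% detected + 1L, body %% detected),
                      rep(body %/% detected, detected - body %% detected))
    if (mito_counts > 0) col[1:n_mito] <- c(mito_counts, rep(0L, n_mito - 1L))
    col
  }
  m[, 1] <- fill(400L, 50L, 0)
  m[, 2] <- fill(2800L, 2500L, 0.05)
  m[, 3] <- fill(3200L, 2500L, 0.20)
  m[, 4] <- fill(3000L, 2500L, 0.05)
  toy_counts(m, n_mito = n_mito)
}

test_that("qc_filter applies the three rules as specified", {
  x <- qc_toy()
  # sanity on the constructed metrics
  totals <- Matrix::colSums(x$counts)
  expect_equal(unname(totals), c(400, 2800, 3200, 3000))
  expect_equal(unname(Matrix::colSums(x$counts > 0)), c(50, 2501, 2501, 2501))

  out <- qc_filter(x, qc_thresholds(doublet_quantile = 1))
  # cell 1 fails counts+genes; cell 3 fails mito; cells 2 and 4 retained
  expect_equal(colnames(out$matrix$counts),
               sprintf("CELL%06d", c(2L, 4L)))
  expect_equal(out$report$removed_low_counts, 1)
  expect_equal(out$report$removed_high_mito, 1)
  expect_equal(nrow(out$matrix$counts), nrow(x$counts)) # genes untouched

  # vacuous thresholds keep everything
  all_kept <- qc_filter(x, qc_thresholds(0, 0, 1, doublet_quantile = 1))
  expect_equal(ncol(all_kept$matrix$counts), 4)

  # all-zero matrix: every cell fails, explicit error naming a filter
  expect_error(qc_filter(toy_counts(matrix(0L, 10, 3))),
               "empty after QC.*binding filter")
})

test_that("qc_filter is idempotent under its resolved thresholds", {
  sim <- simulate_counts(small_config(seed = 5))
  first <- qc_filter(sim$matrix, small_thresholds(doublet_quantile = 0.95))
  second <- qc_filter(first$matrix, first$report$thresholds)
  expect_equal(second$report$n_retained, first$report$n_retained)
  expect_identical(colnames(second$matrix$counts),
                   colnames(first$matrix$counts))
  # the quantile was resolved to an absolute cutoff
  expect_true(is.finite(first$report$thresholds$max_counts))
})

test_that("log_normalize matches its closed form and is scale-equivariant", {
  m <- matrix(c(1L, 0L, 9999L, 5L, 0L, 1995L), ncol = 2)
  x <- toy_counts(m)
  norm <- log_normalize(x) # totals 10000 and 2000, scale factor 10000
  v <- as.matrix(norm$values)
  expect_equal(v[1, 1], log(2))
  expect_equal(v[2, 1], 0)
  expect_equal(v[1, 2], log(26))
  # zeros stay zeros exactly
  expect_identical(v == 0, as.matrix(x$counts) == 0)

  # doubling every count of a cell leaves its normalized vector unchanged
  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  norm2 <- log_normalize(toy_counts(m2))
  expect_equal(as.matrix(norm2$values)[, 2], v[, 2])

  expect_error(log_normalize(toy_counts(matrix(c(1L, 2L, 0L, 0L), 2))),
               "zero total")
})

test_that("scale_genes centers, standardizes, drops and clips", {
  m <- matrix(c(1, 2, 3,
                5, 5, 5,
                0, 4, 8), nrow = 3, byrow = TRUE)
  rownames(m) <- c("a", "const", "b")
  colnames(m) <- paste0("c", 1:3)
  sc <- scale_genes(m, clip = 10)
  expect_equal(unname(sc$values["a", ]), c(-1, 0, 1)) # sample sd convention
  expect_equal(sc$dropped_genes, "const")
  expect_false("const" %in% rownames(sc$values))
  # exact moments
  expect_lt(max(abs(rowMeans(sc$values))), 1e-10)
  expect_equal(unname(apply(sc$values, 1, sd)), c(1, 1))

  expect_error(scale_genes(m[, 1, drop = FALSE]), "at least 2 cells")

  # idempotence (clip not binding)
  sc2 <- scale_genes(sc$values, clip = 10)
  expect_equal(sc2$values, sc$values)

  # clipping caps extremes, then moments are restored exactly
  spiky <- matrix(c(rep(0, 49), 50), nrow = 1,
                  dimnames = list("g", paste0("c", 1:50)))
  scs <- scale_genes(spiky, clip = 3)
  expect_lt(max(abs(rowMeans(scs$values))), 1e-10)
  expect_equal(unname(sd(scs$values[1, ])), 1)
  expect_lt(max(scs$values), 50 / sqrt(49)) # far below the unclipped extreme
})

test_that("regress_out removes linear dependence on a covariate", {
  set.seed(11)
  covar <- runif(80)
  base <- matrix(rnorm(40 * 80), 40, 80,
                 dimnames = list(sprintf("G%03d", 1:40), sprintf("C%03d", 1:80)))
  confounded <- base + outer(seq(0.5, 2, length.out = 40), covar)
  sc <- scale_genes(confounded, clip = Inf)
  before <- mean(abs(apply(sc$values, 1, function(r) cor(r, covar))))
  reg <- regress_out(sc, covar)
  after <- mean(abs(apply(reg$values, 1, function(r) cor(r, covar))))
  expect_gt(before, 0.3)
  expect_lt(after, 1e-8)
  expect_lt(max(abs(rowMeans(reg$values))), 1e-10)
})

test_that("pca_select keeps planted structure and floors on noise", {
  set.seed(21)
  # one strong planted axis: two blobs along a 30-gene program
  g <- 60; n <- 50
  shift <- rep(c(0, 3), each = n / 2)
  m <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("G%03d", 1:g), sprintf("C%03d", 1:n)))
  m[1:30, ] <- m[1:30, ] + rep(shift, each = 30)
  emb <- pca_select(scale_genes(m, clip = Inf), n_components = 10,
                    n_permutations = 50, seed = 1)
  expect_true(1 %in% emb$selected_components)
  expect_lt(emb$p_values[1], 0.05)
  expect_equal(dim(emb$scores), c(n, length(emb$selected_components)))

  # pure iid noise: retention hits the floor of 2 in >= 90% of seeds
  floors <- vapply(1:20, function(s) {
    set.seed(s + 100)
    noise <- matrix(rnorm(40 * 30), 40, 30,
                    dimnames = list(sprintf("G%03d", 1:40),
                                    sprintf("C%03d", 1:30)))
    emb <- pca_select(scale_genes(noise, clip = Inf), n_components = 8,
                      n_permutations = 40, seed = s)
    length(emb$selected_components)
  }, numeric(1))
  expect_gte(mean(floors == 2), 0.9)

  expect_error(pca_select(scale_genes(m, clip = Inf), n_permutations = 10),
               "n_permutations")
  expect_error(pca_select(scale_genes(m, clip = Inf), n_components = 200,
                          n_permutations = 30), "n_components")
})

test_that("pca_select is invariant to cell order", {
  set.seed(22)
  m <- matrix(rnorm(50 * 40), 50, 40,
              dimnames = list(sprintf("G%03d", 1:50), sprintf("C%03d", 1:40)))
  m[1:20, 1:20] <- m[1:20, 1:20] + 2
  sc <- scale_genes(m, clip = Inf)
  emb1 <- pca_select(sc, n_components = 8, n_permutations = 30, seed = 5)
  perm <- sample(ncol(m))
  sc2 <- as_scaled(sc$values[, perm])
  emb2 <- pca_select(sc2, n_components = 8, n_permutations = 30, seed = 5)
  expect_equal(length(emb1$selected_components),
               length(emb2$selected_components))
})

test_that("cluster_cells separates point clouds and is deterministic", {
  set.seed(31)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2), n, 2), 2, center, "+")
  pts <- rbind(blob(c(0, 0), 60), blob(c(20, 0), 60), blob(c(0, 20), 60))
  rownames(pts) <- sprintf("CELL%06d", seq_len(nrow(pts)))
  emb <- structure(list(scores = pts, selected_components = 1:2,
                        var_explained = NULL, p_values = NULL, umap = NULL),
                   class = "embedding")
  truth <- rep(0:2, each = 60)
  cl <- cluster_cells(emb, k_neighbors = 15, seed = 1)
  expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  expect_equal(sort(unique(cl$labels)), 0:2) # contiguous from 0

  cl2 <- cluster_cells(emb, k_neighbors = 15, seed = 1)
  expect_identical(cl$labels, cl2$labels)

  km <- cluster_cells(emb, method = "kmeans", centers = 3, seed = 1)
  expect_equal(adjusted_rand_index(km$labels, truth), 1)
  expect_error(cluster_cells(emb, k_neighbors = 500), "k_neighbors")
  expect_error(cluster_cells(emb, method = "kmeans"), "centers")
})

test_that("clustering recovers simulated clusters when markers drive structure", {
  # pos_fraction = 0: marker blocks are the only latent structure
  run <- small_pipeline(seed = 41,
                        config = small_config(pos_fraction = 0, seed = 41))
  expect_gte(adjusted_rand_index(run$pp$clustering$labels, run$truth$cluster),
             0.9)
  # concentrated placement: positives coincide with their host cluster
  run2 <- small_pipeline(
    seed = 42,
    config = small_config(pos_fraction = 0.15,
                          pos_placement = "concentrated", pos_cluster = 0L,
                          seed = 42))
  expect_gte(adjusted_rand_index(run2$pp$clustering$labels, run2$truth$cluster),
             0.9)
})

test_that("default spread config recovers marker clusters at small scale", {
  # at this scale the spread positivity program is too weak to split the
  # marker clusters (at full scale it is genuine substructure and Louvain
  # resolves cluster x positivity states; see the methods vignette)
  run <- small_pipeline(seed = 43)
  expect_gte(adjusted_rand_index(run$pp$clustering$labels, run$truth$cluster),
             0.9)
})

test_that("umap_embed yields deterministic 2-D coordinates and is isolated", {
  run <- small_pipeline(seed = 51)
  emb <- umap_embed(run$pp$embedding, seed = 9)
  expect_equal(dim(emb$umap), c(nrow(run$pp$embedding$scores), 2L))
  emb2 <- umap_embed(run$pp$embedding, seed = 9)
  expect_identical(emb$umap, emb2$umap)

  # downstream results are identical with and without the 2-D layout
  sig <- planted_signature(run$sim)
  sv <- score_cells(run$pp$scaled, sig)
  e1 <- cluster_enrichment(sv, run$pp$clustering)
  cl_after <- cluster_cells(emb, seed = run$pp$clustering$parameters$seed)
  e2 <- cluster_enrichment(sv, cl_after)
  expect_equal(e1, e2)

  small <- structure(list(scores = matrix(rnorm(10), 5, 2,
                                          dimnames = list(paste0("C", 1:5), NULL)),
                          umap = NULL), class = "embedding")
  expect_error(umap_embed(small), "at least 10 cells")
})

test_that("full preprocess retains > 80% of cells at the default world", {
  sim <- simulate_counts(sim_config(seed = 61))
  qc <- qc_filter(sim$matrix) # paper-scale default thresholds
  expect_gt(qc$report$n_retained / qc$report$n_input, 0.8)
})
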