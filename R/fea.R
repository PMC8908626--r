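# Functional enrichment analysis: per-cell z-scored signature scores,
# one-vs-rest ROC-AUC cluster enrichment under the AUC > 0.7 & Wilcoxon
# p < 0.01 rule, per-cell positive/negative classification at score > 0,
# and cross-condition abundance shifts.

#' Gene signature
#'
#' A named, order-irrelevant set of gene identifiers representing a pathway
#' program (e.g., an MSigDB hallmark set or a custom derived signature).
#'
#' @param name Signature name.
#' @param genes Character vector of gene identifiers (deduplicated).
#' @param source Free-text provenance (e.g., collection name or "custom").
#' @return Object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, source = "custom") {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("gene_signature: empty gene set for '", name, "'")
  structure(list(name = name, genes = genes, source = source),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "' (", length(x$genes), " genes, source: ",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' GMT: one tab-separated line per set — name, description, then genes.
#'
#' @param path GMT file path.
#' @param source Source label attached to each signature (default the file
#'   name).
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("read_gmt: empty file ", path)
  sigs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("read_gmt: malformed line (need name, description, >=1 gene): ",
           substr(ln, 1, 60))
    }
    gene_signature(parts[1], parts[-(1:2)], source = source)
  })
  setNames(sigs, vapply(sigs, `[[`, character(1), "name"))
}

#' Write gene signatures to a GMT file
#'
#' @param signatures A [gene_signature()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, s$source, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Score cells against a gene signature
#'
#' The per-cell z-scored signature score: the mean (or sum) over the
#' signature genes of the gene-wise standardized expression values. Because
#' each retained gene row has mean zero across cells, mean-based scores are
#' centered at zero over all cells by construction. Signature genes absent
#' from the matrix are dropped with a warning; an error is raised only when
#' no gene matches.
#'
#' @param scaled A [scale_genes()] result.
#' @param signature A [gene_signature()].
#' @param method `"mean"` (default) or `"sum"` over matched gene rows.
#' @return Object of class `score_vector`: list with `signature` (name),
#'   `scores` (named per-cell numeric), `matched_genes`, `missing_genes`,
#'   `method`.
#' @export
score_cells <- function(scaled, signature, method = c("mean", "sum")) {
  method <- match.arg(method)
  stopifnot(inherits(scaled, "scaled_matrix"),
            inherits(signature, "gene_signature"))
  matched <- intersect(signature$genes, rownames(scaled$values))
  missing <- setdiff(signature$genes, matched)
  if (length(matched) == 0) {
    stop("score_cells: no gene of signature '", signature$name,
         "' is present in the matrix")
  }
  if (length(missing) > 0) {
    warning("score_cells: ", length(missing), "/", length(signature$genes),
            " genes of '", signature$name, "' absent from the matrix")
  }
  sub <- scaled$values[matched, , drop = FALSE]
  scores <- if (method == "mean") colMeans(sub) else colSums(sub)
  structure(list(signature = signature$name, scores = scores,
                 matched_genes = matched, missing_genes = missing,
                 method = method),
            class = "score_vector")
}

# align a score vector with a clustering; errors on cell mismatch
align_scores <- function(scores, clustering) {
  stopifnot(inherits(scores, "score_vector"), inherits(clustering, "clustering"))
  cells <- names(clustering$labels)
  if (!all(cells %in% names(scores$scores))) {
    stop("scores and clustering cover different cells")
  }
  list(scores = scores$scores[cells], labels = clustering$labels)
}

#' One-vs-rest AUC of a signature score for one cluster
#'
#' Probability that a random in-cluster cell outscores a random out-cluster
#' cell (ties counted 1/2), computed exactly via the Mann-Whitney U
#' statistic. See [rank_auc()].
#'
#' @param scores A [score_cells()] result.
#' @param clustering A [cluster_cells()] result.
#' @param cluster_k 0-based cluster label.
#' @return AUC in `[0, 1]`.
#' @export
cluster_auc <- function(scores, clustering, cluster_k) {
  a <- align_scores(scores, clustering)
  in_group <- a$labels == cluster_k
  if (!any(in_group) || all(in_group)) {
    stop("cluster_auc: cluster ", cluster_k, " has ", sum(in_group), "/",
         length(in_group), " cells; one-vs-rest AUC undefined")
  }
  rank_auc(a$scores, in_group)
}

#' Cluster-level enrichment calls for a signature
#'
#' For every cluster, one-vs-rest AUC and a two-sided Wilcoxon rank-sum
#' p-value (exact enumeration when both groups have at most 10 cells,
#' tie- and continuity-corrected normal approximation otherwise). A cluster
#' is called enriched when AUC > `auc_threshold` and p < `p_threshold`
#' (defaults 0.7 and 0.01). Raw p-values drive the call; a
#' Benjamini-Hochberg column is reported for information only.
#'
#' @param scores A [score_cells()] result.
#' @param clustering A [cluster_cells()] result (at least 2 clusters).
#' @param auc_threshold,p_threshold Enrichment rule thresholds.
#' @return data.frame with columns signature, cluster, n_cells, auc,
#'   p_value, p_bh, enriched.
#' @export
cluster_enrichment <- function(scores, clustering, auc_threshold = 0.7,
                               p_threshold = 0.01) {
  a <- align_scores(scores, clustering)
  ks <- sort(unique(a$labels))
  if (length(ks) < 2) stop("cluster_enrichment: need at least 2 clusters")
  res <- lapply(ks, function(k) {
    in_group <- a$labels == k
    w <- wilcox_rank_sum(a$scores[in_group], a$scores[!in_group])
    data.frame(signature = scores$signature, cluster = k,
               n_cells = sum(in_group), auc = w$auc, p_value = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$auc > auc_threshold & out$p_value < p_threshold
  out
}

#' Classify cells as signature-positive
#'
#' A cell is positive when its signature score strictly exceeds `threshold`
#' (default 0, i.e., a per-cell z-score above zero).
#'
#' @param scores A [score_cells()] result.
#' @param threshold Positivity threshold (strict inequality).
#' @return Object of class `positivity_call`: list with `signature`,
#'   `positive` (named logical), `positive_fraction`, `threshold`.
#' @export
classify_cells <- function(scores, threshold = 0) {
  stopifnot(inherits(scores, "score_vector"), is.finite(threshold) ||
              threshold == Inf || threshold == -Inf)
  if (any(!is.finite(scores$scores))) stop("classify_cells: non-finite scores")
  positive <- scores$scores > threshold
  structure(list(signature = scores$signature, positive = positive,
                 positive_fraction = mean(positive), threshold = threshold),
            class = "positivity_call")
}

#' Cross-tabulate positivity against clusters
#'
#' @param call A [classify_cells()] result.
#' @param clustering A [cluster_cells()] result.
#' @return data.frame with per-cluster cell counts and positive fraction.
#' @export
positivity_by_cluster <- function(call, clustering) {
  stopifnot(inherits(call, "positivity_call"), inherits(clustering, "clustering"))
  cells <- names(clustering$labels)
  if (!all(cells %in% names(call$positive))) {
    stop("positivity call and clustering cover different cells")
  }
  pos <- call$positive[cells]
  lab <- clustering$labels
  agg <- tapply(pos, lab, function(v) c(n = length(v), n_positive = sum(v)))
  out <- data.frame(cluster = as.integer(names(agg)),
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    n_positive = vapply(agg, `[[`, numeric(1), "n_positive"),
                    row.names = NULL)
  out$positive_fraction <- out$n_positive / out$n
  out
}

#' Cluster abundance shift between two conditions
#'
#' For each cluster, the per-condition composition proportions, the percent
#' change of condition B relative to condition A, and a two-proportion
#' chi-squared p-value (2x2 table of cluster membership vs condition, Yates
#' continuity correction).
#'
#' @param clustering A [cluster_cells()] result.
#' @param condition Per-cell factor/character with exactly two levels; the
#'   first level (alphabetical for character input) is the reference "A".
#' @return data.frame with cluster, n_A, n_B, prop_A, prop_B,
#'   percent_change, chi2, p_value. `percent_change` is `NA` when the
#'   cluster is absent from condition A.
#' @export
abundance_shift <- function(clustering, condition) {
  stopifnot(inherits(clustering, "clustering"))
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) {
    stop("abundance_shift: condition must have exactly 2 levels (got ",
         nlevels(condition), ")")
  }
  if (length(condition) != length(clustering$labels)) {
    stop("abundance_shift: condition length does not match cell count")
  }
  lab <- clustering$labels
  n_a <- sum(condition == levels(condition)[1])
  n_b <- sum(condition == levels(condition)[2])
  if (n_a == 0 || n_b == 0) stop("abundance_shift: a condition is empty")
  ks <- sort(unique(lab))
  res <- lapply(ks, function(k) {
    in_k <- lab == k
    ka <- sum(in_k & condition == levels(condition)[1])
    kb <- sum(in_k & condition == levels(condition)[2])
    prop_a <- ka / n_a
    prop_b <- kb / n_b
    tab <- rbind(c(ka, n_a - ka), c(kb, n_b - kb))
    cs <- chisq_stat(tab, correct = TRUE)
    data.frame(cluster = k, n_A = ka, n_B = kb, prop_A = prop_a,
               prop_B = prop_b,
               percent_change = if (prop_a > 0) 100 * (prop_b - prop_a) / prop_a
                                else NA_real_,
               chi2 = cs$chi2, p_value = cs$p_value)
  })
  do.call(rbind, res)
}
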