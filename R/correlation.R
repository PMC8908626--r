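# Signature-signature association: Pearson correlation per cluster (and
# overall), two-sided p from the t transform, and the conventional
# correlation-strength banding (0.3-0.5 moderate, 0.5-0.9 strong).

#' Correlate two signature score vectors
#'
#' Pearson correlation between two per-cell signature scores, overall and
#' (when a clustering is supplied) within each cluster with at least 3
#' cells. The two-sided p-value uses the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#' Positive correlations are banded: `[0.3, 0.5]` moderate, `(0.5, 0.9]`
#' strong, `[0, 0.3)` negligible, `> 0.9` or negative `out_of_band` (the
#' raw r is always reported). Clusters where either vector has zero
#' variance get `r = NA` with band `"undefined"`.
#'
#' @param scores_a,scores_b [score_cells()] results over the same cells.
#' @param clustering Optional [cluster_cells()] result for per-cluster runs.
#' @return data.frame with sig_a, sig_b, cluster ("all" or the 0-based
#'   label), n, r, p_value, band.
#' @export
correlate_signatures <- function(scores_a, scores_b, clustering = NULL) {
  stopifnot(inherits(scores_a, "score_vector"), inherits(scores_b, "score_vector"))
  cells <- names(scores_a$scores)
  if (!setequal(cells, names(scores_b$scores))) {
    stop("correlate_signatures: score vectors cover different cells")
  }
  b <- scores_b$scores[cells]
  a <- scores_a$scores
  rows <- list(cor_row(scores_a$signature, scores_b$signature, "all", a, b))
  if (!is.null(clustering)) {
    stopifnot(inherits(clustering, "clustering"))
    if (!all(names(clustering$labels) %in% cells)) {
      stop("correlate_signatures: clustering covers cells absent from scores")
    }
    for (k in sort(unique(clustering$labels))) {
      kc <- names(clustering$labels)[clustering$labels == k]
      if (length(kc) < 3) next
      rows[[length(rows) + 1]] <-
        cor_row(scores_a$signature, scores_b$signature, as.character(k),
                a[kc], b[kc])
    }
  }
  do.call(rbind, rows)
}

cor_row <- function(name_a, name_b, cluster, a, b) {
  n <- length(a)
  if (sd(a) == 0 || sd(b) == 0) {
    return(data.frame(sig_a = name_a, sig_b = name_b, cluster = cluster,
                      n = n, r = NA_real_, p_value = NA_real_,
                      band = "undefined", stringsAsFactors = FALSE))
  }
  r <- stats::cor(a, b)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  data.frame(sig_a = name_a, sig_b = name_b, cluster = cluster, n = n,
             r = r, p_value = p, band = correlation_band(r),
             stringsAsFactors = FALSE)
}

#' Correlation strength band
#'
#' @param r Pearson coefficient.
#' @return `"negligible"` for r in `[0, 0.3)`, `"moderate"` for
#'   `[0.3, 0.5]`, `"strong"` for `(0.5, 0.9]`, `"out_of_band"` otherwise
#'   (negative or > 0.9).
#' @export
correlation_band <- function(r) {
  if (is.na(r)) return("undefined")
  if (r < 0 || r > 0.9) return("out_of_band")
  if (r >= 0.3 && r <= 0.5) return("moderate")
  if (r > 0.5) return("strong")
  "negligible"
}
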