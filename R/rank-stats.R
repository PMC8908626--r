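# Rank statistics underlying enrichment calls: one-vs-rest ROC AUC via the
# Mann-Whitney U statistic, and a Wilcoxon rank-sum test with exact
# enumeration for small groups and a tie/continuity-corrected normal
# approximation otherwise. These are implemented from first principles
# because the enrichment rule (AUC > 0.7 with p < 0.01) is the core
# statistic of the package; tests check them against brute-force oracles.

#' One-vs-rest ROC AUC from rank statistics
#'
#' Computes the probability that a randomly chosen "in-group" value exceeds a
#' randomly chosen "out-group" value, counting ties as 1/2 — identical to the
#' area under the ROC curve for separating the two groups, and to the
#' Mann-Whitney U statistic divided by `n_in * n_out`.
#'
#' @param x Numeric vector of values (e.g., per-cell signature scores).
#' @param in_group Logical vector, same length as `x`; `TRUE` marks the
#'   in-group (e.g., membership in one cluster).
#' @return AUC in `[0, 1]`.
#' @examples
#' rank_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)) # 0.75
#' @export
rank_auc <- function(x, in_group) {
  stopifnot(is.numeric(x), is.logical(in_group), length(x) == length(in_group))
  if (anyNA(x) || anyNA(in_group)) stop("rank_auc: NA values not allowed")
  n_in <- sum(in_group)
  n_out <- sum(!in_group)
  if (n_in == 0L || n_out == 0L) {
    stop("rank_auc: both groups must be non-empty (in = ", n_in,
         ", out = ", n_out, ")")
  }
  r <- rank(x) # midranks handle ties
  u <- sum(r[in_group]) - n_in * (n_in + 1) / 2
  u / (n_in * n_out)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank-sum test. When both group sizes are at most `exact_max`
#' the two-sided p-value is computed by exact enumeration of all
#' `choose(n_x + n_y, n_x)` group assignments of the observed (tied) ranks;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Always two-sided.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_max Largest group size for which exact enumeration is used
#'   (both groups must be at or below it). Default 10.
#' @return List with `statistic` (U for `x` vs `y`), `auc`
#'   (`U / (n_x * n_y)`), `p_value`, and `method` ("exact" or "normal").
#' @export
wilcox_rank_sum <- function(x, y, exact_max = 10L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  if (anyNA(x) || anyNA(y)) stop("wilcox_rank_sum: NA values not allowed")
  n_x <- length(x)
  n_y <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2

  if (n_x <= exact_max && n_y <= exact_max) {
    p <- wilcox_exact_p(r, n_x)
    method <- "exact"
  } else {
    p <- wilcox_normal_p(r, n_x, n_y, u)
    method <- "normal"
  }
  list(statistic = u, auc = u / (n_x * n_y), p_value = p, method = method)
}

# Exact two-sided p by full enumeration over group assignments of the
# observed rank multiset. Two-sided p doubles the smaller tail probability
# of U (capped at 1), with the point mass counted in both tails.
wilcox_exact_p <- function(r, n_x) {
  n <- length(r)
  offset <- n_x * (n_x + 1) / 2
  idx <- combn(n, n_x)
  u_all <- colSums(matrix(r[idx], nrow = n_x)) - offset
  u_obs <- sum(r[seq_len(n_x)]) - offset
  eps <- 1e-9
  lower <- mean(u_all <= u_obs + eps)
  upper <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(lower, upper))
}

# Normal approximation with tie correction and continuity correction,
# matching the classical large-sample Mann-Whitney z test.
wilcox_normal_p <- function(r, n_x, n_y, u) {
  n <- n_x + n_y
  mu <- n_x * n_y / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_x * n_y / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1) # all values tied
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Pearson chi-squared test on a contingency table
#'
#' Classical Pearson chi-squared statistic with optional Yates continuity
#' correction (only ever applied to 2x2 tables).
#'
#' @param tab Integer matrix of observed counts (R x C, all margins > 0).
#' @param correct Apply the Yates continuity correction when `tab` is 2x2.
#' @return List with `chi2`, `df`, `p_value`, `expected`, and
#'   `min_expected`.
#' @export
chisq_stat <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2, ncol(tab) >= 2)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chisq_stat: degenerate table (zero row or column margin)")
  }
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  dev <- abs(tab - expected)
  if (correct && all(dim(tab) == c(2L, 2L))) {
    dev <- pmax(0, dev - 0.5)
  }
  chi2 <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE),
       expected = expected, min_expected = min(expected))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions (up to label renaming), approximately 0 for
#' independent ones. Used to validate clustering against simulation ground
#' truth.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(v) sum(choose(v, 2))
  s_nij <- sum_comb(as.vector(tab))
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (s_nij - expected) / (max_index - expected)
}
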