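# Bulk-cohort interrogation of a derived signature: tumor-level scoring and
# dichotomization, grade association by Pearson chi-squared, and
# relapse-free survival by Kaplan-Meier curves with a two-group log-rank
# test. The survival machinery is implemented from the product-limit /
# hypergeometric-variance definitions and validated against hand-computed
# risk tables in the tests.

#' Bulk cohort container
#'
#' @param expression Tumors x genes numeric matrix (assumed already
#'   normalized), with tumor row names and gene column names.
#' @param grade Per-tumor ordinal grade (factor or coercible).
#' @param rfs_time Per-tumor relapse-free survival time (>= 0).
#' @param rfs_event Per-tumor event indicator (1/TRUE = relapse observed,
#'   0/FALSE = censored).
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(expression, grade, rfs_time, rfs_event) {
  expression <- as.matrix(expression)
  stopifnot(!is.null(rownames(expression)), !is.null(colnames(expression)))
  n <- nrow(expression)
  grade <- as.factor(grade)
  rfs_event <- as.logical(rfs_event)
  stopifnot(length(grade) == n, length(rfs_time) == n, length(rfs_event) == n,
            all(rfs_time >= 0), !anyNA(rfs_time), !anyNA(rfs_event))
  structure(list(expression = expression, grade = grade,
                 rfs_time = as.numeric(rfs_time), rfs_event = rfs_event),
            class = "cohort_table")
}

#' Read a cohort from an expression + clinical TSV pair
#'
#' The clinical table must have columns `tumor_id`, `grade`, `rfs_time`,
#' `rfs_event`; the expression table has tumors as rows (first column
#' `tumor_id`) and genes as columns.
#'
#' @param expr_path,clinical_path File paths.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(expr_path, clinical_path) {
  expr <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
  clin <- read.delim(clinical_path, stringsAsFactors = FALSE)
  need <- c("tumor_id", "grade", "rfs_time", "rfs_event")
  if (!all(need %in% names(clin))) {
    stop("read_cohort: clinical table lacks column(s): ",
         paste(setdiff(need, names(clin)), collapse = ", "))
  }
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr[[1]]
  if (!setequal(rownames(m), clin$tumor_id)) {
    stop("read_cohort: tumor ids differ between expression and clinical tables")
  }
  clin <- clin[match(rownames(m), clin$tumor_id), ]
  cohort_table(m, clin$grade, clin$rfs_time, clin$rfs_event)
}

#' Score and dichotomize tumors for a signature
#'
#' Genes are z-scored across tumors (sample sd); a tumor's score is the mean
#' z over the matched signature genes; status is positive when the score
#' strictly exceeds `threshold` (or the cohort median score when
#' `threshold = "median"`).
#'
#' @param cohort A [cohort_table()].
#' @param signature A [gene_signature()].
#' @param threshold Numeric dichotomization threshold (default 0), or
#'   `"median"` for a median split.
#' @return Object of class `cohort_call`: list with `signature`, `score`
#'   (named per-tumor), `status` (logical, TRUE = positive), `threshold`,
#'   `matched_genes`, `missing_genes`.
#' @export
score_cohort <- function(cohort, signature, threshold = 0) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(signature, "gene_signature"))
  if (nrow(cohort$expression) < 2) stop("score_cohort: need >= 2 tumors")
  matched <- intersect(signature$genes, colnames(cohort$expression))
  missing <- setdiff(signature$genes, matched)
  if (length(matched) == 0) {
    stop("score_cohort: no gene of signature '", signature$name,
         "' is present in the cohort")
  }
  sub <- cohort$expression[, matched, drop = FALSE]
  z <- scale(sub) # columns: center, sample sd
  z[, attr(z, "scaled:scale") == 0] <- 0
  score <- rowMeans(z)
  thr <- if (identical(threshold, "median")) median(score) else threshold
  structure(list(signature = signature$name, score = score,
                 status = score > thr, threshold = thr,
                 matched_genes = matched, missing_genes = missing),
            class = "cohort_call")
}

#' Grade association of a dichotomized cohort
#'
#' R x 2 contingency of grade level against signature status, tested with
#' the Pearson chi-squared statistic. The Yates continuity correction is
#' applied only to 2x2 tables and only when `correct = TRUE`. A warning is
#' issued when any expected count falls below 5.
#'
#' @param call A [score_cohort()] result.
#' @param grade Per-tumor grade (same order as the call's tumors).
#' @param correct Apply Yates correction on 2x2 tables (default `FALSE`).
#' @return List with `table` (grade x status), `expected`, `chi2`, `df`,
#'   `p_value`.
#' @export
grade_association <- function(call, grade, correct = FALSE) {
  stopifnot(inherits(call, "cohort_call"))
  grade <- droplevels(as.factor(grade))
  stopifnot(length(grade) == length(call$status))
  if (nlevels(grade) < 2) stop("grade_association: need >= 2 grade levels")
  tab <- table(grade = grade,
               status = factor(ifelse(call$status, "positive", "negative"),
                               levels = c("negative", "positive")))
  cs <- chisq_stat(tab, correct = correct)
  if (cs$min_expected < 5) {
    warning("grade_association: expected count below 5 (",
            format(cs$min_expected, digits = 3),
            "); chi-squared approximation may be poor")
  }
  list(table = tab, expected = cs$expected, chi2 = cs$chi2, df = cs$df,
       p_value = cs$p_value)
}

#' Kaplan-Meier estimator for one group
#'
#' Product-limit estimate with ties grouped at identical times.
#'
#' @param time Follow-up times (>= 0).
#' @param event Logical event indicator (FALSE = censored).
#' @return data.frame with time, n_risk, n_event, n_censor, survival (the
#'   estimate just after each distinct observed time).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0))
  event <- as.logical(event)
  ts <- sort(unique(time))
  n_risk <- vapply(ts, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ts, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(ts, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ts, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Standard two-group log-rank: at each distinct event time, the observed
#' group-1 events are compared with the expectation under the null
#' (hypergeometric), the statistic is `(sum(O - E))^2 / sum(V)` and the
#' p-value is chi-squared on 1 df.
#'
#' @param group A [score_cohort()] result (its `status` defines the groups)
#'   or any two-level per-subject vector.
#' @param time,event Per-subject follow-up time and event indicator.
#' @return List with `curves` (named list of [km_curve()] frames),
#'   `observed`, `expected` (group-1 totals), `variance`, `chi2`,
#'   `p_value`, and `group_levels`.
#' @export
km_logrank <- function(group, time, event) {
  if (inherits(group, "cohort_call")) {
    group <- ifelse(group$status, "positive", "negative")
  }
  group <- as.factor(group)
  event <- as.logical(event)
  stopifnot(length(group) == length(time), length(time) == length(event))
  if (nlevels(droplevels(group)) != 2) {
    stop("km_logrank: need exactly 2 non-empty groups")
  }
  group <- droplevels(group)
  if (!any(event)) stop("km_logrank: no events (all observations censored)")

  g1 <- group == levels(group)[1]
  event_times <- sort(unique(time[event]))
  o <- e <- v <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) (o - e)^2 / v else 0
  curves <- lapply(split(seq_along(time), group), function(idx) {
    km_curve(time[idx], event[idx])
  })
  list(curves = curves, observed = o, expected = e, variance = v,
       chi2 = chi2, p_value = pchisq(chi2, 1, lower.tail = FALSE),
       group_levels = levels(group))
}

#' Simulate a bulk tumor cohort with a planted signature-positive subset
#'
#' Expression is standard Gaussian per gene with the signature genes shifted
#' by `+effect_sd` in positive tumors. Grade (levels 1-3) is drawn with the
#' odds of grade 3 multiplied by `grade_or` in positive tumors. Relapse
#' times are exponential with the hazard multiplied by `hazard_ratio` for
#' positives; censoring is independent exponential calibrated so that about
#' `censor_rate` of tumors are censored. Deterministic per seed.
#'
#' @param n_tumors,n_genes Cohort dimensions.
#' @param signature A [gene_signature()] over a subset of the simulated
#'   genes, or an integer gene count (the first genes are used).
#' @param pos_fraction Fraction of signature-positive tumors.
#' @param effect_sd Expression up-shift (in sd units) in positive tumors.
#' @param grade_or Odds ratio of high grade (level 3) for positive tumors.
#' @param hazard_ratio Relapse hazard multiplier for positive tumors.
#' @param censor_rate Target censoring fraction, in `[0, 1)`.
#' @param base_median Median relapse time of negative tumors (time units).
#' @param seed Integer seed.
#' @return List with `cohort` (a [cohort_table()]), `signature`
#'   (the [gene_signature()] used) and `truth` (data.frame: tumor_id,
#'   positive).
#' @export
simulate_cohort <- function(n_tumors = 500L, n_genes = 1000L, signature = 50L,
                            pos_fraction = 0.3, effect_sd = 1, grade_or = 2,
                            hazard_ratio = 2, censor_rate = 0.3,
                            base_median = 10, seed = 1L) {
  stopifnot(n_tumors >= 2, n_genes >= 1, pos_fraction >= 0, pos_fraction <= 1,
            hazard_ratio > 0, grade_or > 0, base_median > 0)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("simulate_cohort: censor_rate must be in [0, 1)")
  }
  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  if (is.numeric(signature) && length(signature) == 1) {
    stopifnot(signature >= 1, signature <= n_genes)
    signature <- gene_signature("planted_signature",
                                gene_ids[seq_len(signature)],
                                source = "simulated")
  }
  stopifnot(inherits(signature, "gene_signature"),
            all(signature$genes %in% gene_ids))
  set.seed(seed)
  tumor_ids <- sprintf("TUMOR%05d", seq_len(n_tumors))
  positive <- rep(FALSE, n_tumors)
  n_pos <- round(pos_fraction * n_tumors)
  if (n_pos > 0) positive[sample.int(n_tumors, n_pos)] <- TRUE

  expr <- matrix(rnorm(n_tumors * n_genes), n_tumors, n_genes,
                 dimnames = list(tumor_ids, gene_ids))
  expr[positive, signature$genes] <- expr[positive, signature$genes] + effect_sd

  # grade: base P(grade 3) = 0.3, odds scaled by grade_or in positives;
  # remaining mass split 2:5 between grades 1 and 2
  p3_base <- 0.3
  odds <- p3_base / (1 - p3_base) * ifelse(positive, grade_or, 1)
  p3 <- odds / (1 + odds)
  u <- runif(n_tumors)
  grade <- ifelse(u < p3, 3L, ifelse(u < p3 + (1 - p3) * 5 / 7, 2L, 1L))

  base_rate <- log(2) / base_median
  rate <- base_rate * ifelse(positive, hazard_ratio, 1)
  t_event <- rexp(n_tumors, rate)
  if (censor_rate > 0) {
    mean_rate <- base_rate * (1 - pos_fraction + pos_fraction * hazard_ratio)
    c_rate <- censor_rate / (1 - censor_rate) * mean_rate
    t_censor <- rexp(n_tumors, c_rate)
  } else {
    t_censor <- rep(Inf, n_tumors)
  }
  rfs_time <- pmin(t_event, t_censor)
  rfs_event <- t_event <= t_censor

  list(cohort = cohort_table(expr, grade, rfs_time, rfs_event),
       signature = signature,
       truth = data.frame(tumor_id = tumor_ids, positive = positive,
                          stringsAsFactors = FALSE))
}
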