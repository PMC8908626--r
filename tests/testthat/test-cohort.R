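# Bulk cohort: scoring/dichotomization, grade association, KM/log-rank,
# cohort simulator.

toy_cohort <- function(n = 40, g = 30, seed = 1) {
  set.seed(seed)
  expr <- matrix(rnorm(n * g), n, g,
                 dimnames = list(sprintf("TUMOR%05d", 1:n),
                                 sprintf("G%06d", 1:g)))
  cohort_table(expr, grade = sample(1:3, n, TRUE),
               rfs_time = rexp(n, 0.1), rfs_event = rbinom(n, 1, 0.7))
}

test_that("score_cohort z-scores genes and dichotomizes strictly", {
  cohort <- toy_cohort()
  sig <- gene_signature("s", colnames(cohort$expression)[1:5])
  call <- score_cohort(cohort, sig)
  expect_lt(abs(mean(call$score)), 1e-8) # centering identity
  expect_identical(unname(call$status), unname(call$score > 0))
  # single-gene signature equals that gene's z-scored column
  one <- score_cohort(cohort, gene_signature("one", "G000003"))
  z <- as.vector(scale(cohort$expression[, "G000003"]))
  expect_equal(unname(one$score), z)
  # median split
  med <- score_cohort(cohort, sig, threshold = "median")
  expect_equal(sum(med$status), sum(call$score > median(call$score)))
  expect_error(score_cohort(cohort, gene_signature("x", "NOPE")), "no gene")
})

test_that("planted positive tumors are recovered near the planted fraction", {
  for (s in 1:3) {
    sim <- simulate_cohort(n_tumors = 300, n_genes = 200, signature = 30,
                           pos_fraction = 0.3, effect_sd = 1, seed = s)
    call <- score_cohort(sim$cohort, sim$signature)
    expect_gte(mean(call$status), 0.2)
    expect_lte(mean(call$status), 0.4)
    # recovered positives substantially overlap the planted truth
    expect_gte(mean(call$status[sim$truth$positive]), 0.75)
  }
})

test_that("grade_association matches the closed-form chi-squared", {
  status <- c(rep(TRUE, 10), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 10))
  grade <- rep(c(1, 2), each = 30)
  call <- structure(list(signature = "s", score = numeric(60), status = status,
                         threshold = 0), class = "cohort_call")
  out <- grade_association(call, grade)
  # 2x2 [[20,10],[10,20]] in (negative, positive) orientation:
  # chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) = 60*(400-100)^2/30^4 = 6.6667
  expect_equal(out$chi2, 20 / 3, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_equal(out$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  # proportional rows: independence exactly
  status2 <- rep(c(TRUE, FALSE), 30)
  call2 <- structure(list(signature = "s", score = numeric(60),
                          status = status2, threshold = 0),
                     class = "cohort_call")
  expect_equal(grade_association(call2, grade)$chi2, 0)
  # swapping status columns leaves chi2 unchanged
  call3 <- call
  call3$status <- !status
  expect_equal(grade_association(call3, grade)$chi2, out$chi2)
  # 3-level grade: df = 2, matches the reference Pearson statistic
  grade3 <- rep(1:3, each = 20)
  out3 <- grade_association(call, grade3)
  tab <- table(grade3, factor(status, levels = c(FALSE, TRUE)))
  expect_equal(out3$chi2,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(out3$df, 2)
  # sparse expected counts produce a warning
  expect_warning(
    grade_association(call, c(rep(1, 57), rep(2, 3))), "below 5")
})

test_that("km_curve satisfies the product-limit invariants", {
  set.seed(41)
  t <- rexp(30); e <- rbinom(30, 1, 0.6) == 1
  if (!any(e)) e[1] <- TRUE
  kc <- km_curve(t, e)
  expect_true(all(diff(kc$survival) <= 1e-12)) # non-increasing
  expect_lte(kc$survival[1], 1)
  # survival only drops at event times
  drops <- which(diff(c(1, kc$survival)) < -1e-12)
  expect_true(all(kc$n_event[drops] > 0))
  # no censoring, all events: matches the empirical survival function
  kc2 <- km_curve(1:5, rep(TRUE, 5))
  expect_equal(kc2$survival, (4:0) / 5)
})

test_that("km_logrank matches the hand-computed risk table and survdiff", {
  # A = (1,2,3) events, B = (4,5,6) events; per event time (O1, E1, V):
  # t=1 (6 at risk, 3 in A): E=1/2,  V=1/4
  # t=2 (5 at risk, 2 in A): E=2/5,  V=6/25
  # t=3 (4 at risk, 1 in A): E=1/4,  V=3/16
  # t=4..6: no A subjects at risk, E=V=0
  # O=3, E=1.15, V=0.6775 -> chi2 = (3-1.15)^2/0.6775 = 5.0516605...
  lr <- km_logrank(rep(c("A", "B"), each = 3), c(1, 2, 3, 4, 5, 6),
                   rep(TRUE, 6))
  expect_equal(lr$observed, 3)
  expect_equal(lr$expected, 1.15)
  expect_equal(lr$variance, 0.6775)
  expect_equal(lr$chi2, (3 - 1.15)^2 / 0.6775)
  expect_equal(lr$p_value, pchisq(lr$chi2, 1, lower.tail = FALSE))

  # identical survival data in both groups: statistic exactly 0
  lr0 <- km_logrank(rep(c("A", "B"), 4), rep(c(1, 2, 5, 7), each = 2),
                    rep(c(TRUE, TRUE, FALSE, TRUE), each = 2))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p_value, 1)

  # random small instances against the reference implementation
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    t <- sample(1:6, n, replace = TRUE)
    e <- rbinom(n, 1, 0.7) == 1
    g <- rep(c("A", "B"), length.out = n)
    if (!any(e)) next
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(km_logrank(g, t, e)$chi2, ref$chisq, tolerance = 1e-10)
  }

  expect_error(km_logrank(rep(c("A", "B"), 3), 1:6, rep(FALSE, 6)),
               "no events")
  expect_error(km_logrank(rep("A", 6), 1:6, rep(TRUE, 6)), "2 non-empty")
})

test_that("simulate_cohort is deterministic and plants the stated effects", {
  a <- simulate_cohort(n_tumors = 100, n_genes = 50, signature = 10, seed = 5)
  b <- simulate_cohort(n_tumors = 100, n_genes = 50, signature = 10, seed = 5)
  expect_identical(a$cohort$expression, b$cohort$expression)
  expect_identical(a$cohort$rfs_time, b$cohort$rfs_time)
  expect_error(simulate_cohort(censor_rate = 1), "censor_rate")

  # hazard direction: positive group has shorter median RFS at n = 500
  sim <- simulate_cohort(n_tumors = 500, n_genes = 100, signature = 20,
                         hazard_ratio = 2, seed = 6)
  med <- tapply(sim$cohort$rfs_time, sim$truth$positive, median)
  expect_lt(med[["TRUE"]], med[["FALSE"]])
  # censoring is close to its target rate
  expect_lt(abs(mean(!sim$cohort$rfs_event) - 0.3), 0.1)
  # grade odds ratio shows up as more grade-3 among positives
  g3 <- tapply(sim$cohort$grade == 3, sim$truth$positive, mean)
  expect_gt(g3[["TRUE"]], g3[["FALSE"]])
})

test_that("cohort TSV pair round-trips through read_cohort", {
  sim <- simulate_cohort(n_tumors = 30, n_genes = 10, signature = 5, seed = 7)
  ed <- withr::local_tempfile(fileext = ".tsv")
  cd <- withr::local_tempfile(fileext = ".tsv")
  expr <- data.frame(tumor_id = rownames(sim$cohort$expression),
                     sim$cohort$expression, check.names = FALSE)
  write.table(expr, ed, sep = "\t", quote = FALSE, row.names = FALSE)
  clin <- data.frame(tumor_id = rownames(sim$cohort$expression),
                     grade = sim$cohort$grade,
                     rfs_time = sim$cohort$rfs_time,
                     rfs_event = as.integer(sim$cohort$rfs_event))
  write.table(clin, cd, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cohort(ed, cd)
  expect_equal(back$expression, sim$cohort$expression)
  expect_equal(back$rfs_time, sim$cohort$rfs_time)
  expect_equal(back$rfs_event, sim$cohort$rfs_event)
  expect_error(read_cohort(ed, ed), "lacks column")
})
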