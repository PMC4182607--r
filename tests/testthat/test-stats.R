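# Paired inference: signed-rank tests, ratio tests, BH adjustment, QC
# filtering, summaries, and the comparison family.

test_that("exact signed-rank p-values match hand-computed tail cases", {
  # n = 5, all positive: one-sided tail 1/32, doubled
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p.value, 0.0625)
  # antisymmetric pairs: W at the center of the distribution
  expect_equal(wilcoxon_signed_rank(c(3, -3, 1.5, -1.5))$p.value, 1)
  # all differences zero: p = 1 with a warning
  expect_warning(res <- wilcoxon_signed_rank(rep(2, 4), rep(2, 4)), "zero")
  expect_equal(res$p.value, 1)
})

test_that("exact p equals full sign-pattern enumeration, ties included", {
  withr::local_seed(31)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n), sample(0:1, 1)) # rounding induces ties and zeros
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p.value, enum_wilcoxon_p(d))
  }
})

test_that("exact p agrees with stats::wilcox.test when no ties are present", {
  withr::local_seed(32)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("the normal approximation tracks the exact test at moderate n", {
  withr::local_seed(33)
  for (i in 1:10) {
    d <- rnorm(24, 0.3)
    pe <- wilcoxon_signed_rank(d, mode = "exact")$p.value
    pn <- wilcoxon_signed_rank(d, mode = "normal")$p.value
    expect_equal(pn, pe, tolerance = 0.08)
  }
})

test_that("ratio tests match enumeration and are scale- and log-invariant", {
  # n = 6, all ratios above 1: tail 1/64, doubled
  r6 <- c(1.2, 1.5, 1.1, 2.0, 1.3, 1.7)
  expect_equal(ratio_test(r6)$p.value, 2 / 64)
  expect_warning(p_ones <- ratio_test(rep(1, 5))$p.value, "zero")
  expect_equal(p_ones, 1)
  expect_error(ratio_test(c(1.2, -0.5)), "ratios")
  withr::local_seed(34)
  inner <- rlnorm(12); outer <- rlnorm(12)
  p1 <- ratio_test(inner = inner, outer = outer)$p.value
  # common positive rescaling of both sites leaves the ratios unchanged
  p2 <- ratio_test(inner = 7.3 * inner, outer = 7.3 * outer)$p.value
  expect_equal(p1, p2)
  # cross-check the log-scale formulation against stats::wilcox.test
  ratios <- inner / outer
  ref <- wilcox.test(log(ratios), mu = 0, exact = TRUE)$p.value
  expect_equal(p1, ref)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.03, 1), 0.03)
  expect_equal(bh_adjust(c(0.001, 0.5), m = 53), c(0.053, 1.0))
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "family size")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
  withr::local_seed(35)
  for (i in 1:200) {
    k <- sample(1:40, 1)
    p <- runif(k)
    m <- k + sample(0:20, 1)
    expect_equal(bh_adjust(p, m), brute_bh(p, m))
  }
})

test_that("BH adjusted p-values are monotone in the raw p-values", {
  withr::local_seed(36)
  p <- runif(30)
  adj <- bh_adjust(p, 53)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
})

test_that("the hemoglobin filter excludes at LOD + 1 CI inclusively", {
  rec <- data.frame(subject_id = c("A", "B", "C", "D"),
                    compartment = "explant_epidermis",
                    hemoglobin = c(0.05, 0.1499, 0.15, 0.30),
                    lod = 0.1, lod_ci = 0.05)
  f <- filter_explants(rec)
  expect_equal(f$kept$subject_id, c("A", "B"))
  expect_equal(f$excluded$subject_id, c("C", "D")) # boundary case C excluded
  expect_match(f$excluded$reason[1], "hemoglobin")
  # dermal records are never excluded by this rule
  rec$compartment <- "explant_dermis"
  expect_equal(nrow(filter_explants(rec)$excluded), 0)
  expect_error(filter_explants(rec[, -4]), "QC fields")
})

test_that("the filter reproduces generator contamination flags exactly", {
  for (s in 1:10) {
    co <- generate_cohort(cohort_spec(n_subjects = 20,
                                      hemoglobin_contamination_rate = 0.15,
                                      seed = s))
    f <- filter_explants(co$explants)
    flagged <- names(which(co$truth$contaminated))
    expect_setequal(unique(f$excluded$subject_id), flagged)
  }
})

test_that("median/IQR use linear interpolation and agree with an independent oracle", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  s1 <- median_iqr(42)
  expect_equal(s1$median, 42); expect_equal(s1$q1, 42); expect_equal(s1$q3, 42)
  expect_error(median_iqr(numeric(0)), "empty")
  # type-7 interpolation oracle: q = x[(n-1)p + 1] with linear interpolation
  oracle_q <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  withr::local_seed(37)
  for (i in 1:200) {
    x <- rnorm(sample(2:50, 1))
    s <- median_iqr(x)
    expect_equal(s$q1, oracle_q(x, 0.25))
    expect_equal(s$median, oracle_q(x, 0.5))
    expect_equal(s$q3, oracle_q(x, 0.75))
  }
})

test_that("a family of one comparison leaves the p-value unadjusted", {
  eff <- study_effect_map()[1, ]
  co <- generate_cohort(cohort_spec(n_subjects = 8, effects = eff,
                                    analytes = study_analyte_map()[0, ], seed = 2))
  co$analytes <- NULL
  res <- run_comparison_family(co, comparison_family(m = 1))
  expect_equal(nrow(res), 1)
  expect_equal(res$p_adj, res$p)
})

test_that("the family run applies one BH adjustment, QC exclusion and verdicts", {
  co <- generate_cohort(cohort_spec(seed = 41))
  res <- run_comparison_family(co, comparison_family(m = 53))
  expect_equal(nrow(res), nrow(study_effect_map()) + nrow(study_analyte_map()))
  expect_true(all(res$m == 53))
  expect_equal(res$p_adj, bh_adjust(res$p, 53))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  lab <- ifelse(res$p_adj < 0.05, "significant", ifelse(res$p_adj < 0.1, "trend", "ns"))
  expect_equal(res$verdict, lab)
  # epidermal explant comparisons drop contaminated subjects
  flagged <- names(which(co$truth$contaminated))
  n_epi <- res$n[grepl("explant_epidermis", res$comparison)][1]
  expect_equal(n_epi, co$spec$n_subjects - length(flagged))
  # whereas dermal and lysate comparisons keep everyone
  expect_true(all(res$n[grepl("lysate", res$comparison)] == co$spec$n_subjects))
})

test_that("a declared family smaller than the comparisons run is an error", {
  co <- generate_cohort(cohort_spec(n_subjects = 6, seed = 5))
  expect_error(run_comparison_family(co, comparison_family(m = 10)),
               "smaller than")
})

test_that("unresolvable metric names in the family are an error naming them", {
  co <- generate_cohort(cohort_spec(n_subjects = 6, seed = 6))
  expect_error(run_comparison_family(co, comparison_family(metrics = "no_such_metric")),
               "no_such_metric")
})
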