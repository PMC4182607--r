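# Paired inner-vs-outer inference: Wilcoxon signed-rank tests (exact by
# signed-rank distribution, or normal approximation with tie correction),
# analyte ratio-vs-1 tests on the log scale, Benjamini-Hochberg adjustment
# over a declared comparison family, explant hemoglobin QC filtering, and
# median/IQR summaries.

# exact two-sided signed-rank p-value by dynamic programming over the
# distribution of the positive-rank sum. Mid-ranks are doubled so tied ranks
# stay integral; the result is identical to enumerating all 2^n sign
# assignments (the enumeration oracle lives in the test suite).
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided matched-pairs signed-rank test. Zero differences are dropped
#' before ranking (standard convention); ties among absolute differences get
#' mid-ranks. The exact p-value (default for n <= 25 after dropping zeros)
#' is computed from the exact signed-rank distribution including ties; the
#' normal approximation applies a tie-corrected variance and continuity
#' correction.
#'
#' @param inner,outer paired measurement vectors; alternatively pass the
#'   differences as `inner` and leave `outer` NULL.
#' @param mode `"auto"` (exact for n <= 25), `"exact"`, or `"normal"`.
#' @return list of class `wilcoxon_signed_rank`: `statistic` (W = sum of
#'   positive ranks), `p.value`, `n` (pairs used), `n_zero` (dropped),
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(inner, outer = NULL,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  d <- if (is.null(outer)) inner else {
    if (length(inner) != length(outer)) stop("paired vectors differ in length",
                                             call. = FALSE)
    inner - outer
  }
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = 0, p.value = 1, n = 0L,
                          n_zero = n_zero, method = "degenerate"),
                     class = "wilcoxon_signed_rank"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  exact <- mode == "exact" || (mode == "auto" && n <= 25L)
  if (exact) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(statistic = W, p.value = p, n = n, n_zero = n_zero,
                 method = method),
            class = "wilcoxon_signed_rank")
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n, x$p.value))
  invisible(x)
}

#' Test whether paired analyte ratios differ from 1
#'
#' Signed-rank test of log(inner/outer) against 0, i.e. of the concentration
#' ratio against 1 on the scale where up- and down-regulation are symmetric.
#' The test is invariant to rescaling both sites by a common positive
#' constant.
#'
#' @param ratios per-subject inner/outer concentration ratios (> 0);
#'   alternatively give `inner` and `outer` concentration vectors.
#' @param inner,outer optional paired concentration vectors.
#' @param mode see [wilcoxon_signed_rank()].
#' @return a `wilcoxon_signed_rank` result.
#' @export
ratio_test <- function(ratios = NULL, inner = NULL, outer = NULL,
                       mode = c("auto", "exact", "normal")) {
  if (is.null(ratios)) {
    if (is.null(inner) || is.null(outer)) {
      stop("give either `ratios` or both `inner` and `outer`", call. = FALSE)
    }
    if (any(inner <= 0) || any(outer <= 0)) {
      fail_field("inner", "concentrations must be > 0 to form ratios")
    }
    ratios <- inner / outer
  }
  if (any(ratios <= 0)) fail_field("ratios", "must be > 0")
  wilcoxon_signed_rank(log(ratios), mode = mode)
}

#' Benjamini-Hochberg adjustment over a declared family
#'
#' Step-up BH adjustment of raw p-values for a comparison family of size `m`,
#' which may exceed the number of supplied p-values (the remaining family
#' members are treated as unobserved, making the adjustment conservative) --
#' e.g. a declared family of 53 comparisons.
#'
#' @param p raw p-values in \[0, 1\].
#' @param m family size, `m >= length(p)` (default `length(p)`).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) fail_field("p", "p-values must lie in [0, 1]")
  if (m < length(p)) {
    fail_field("m", sprintf("family size (%d) smaller than number of p-values (%d)",
                            m, length(p)))
  }
  p.adjust(p, method = "BH", n = m)
}

#' Filter explant records for dermal (hemoglobin) contamination
#'
#' Only the dermis is vascularized, so hemoglobin in an epidermal explant
#' culture indicates dermal contamination. Epidermal records with hemoglobin
#' concentration >= LOD + 1 CI (inclusive) are excluded.
#'
#' @param records data.frame with columns `subject_id`, `compartment`,
#'   `hemoglobin`, `lod`, `lod_ci` (see [generate_cohort()]'s `explants`).
#' @return list with `kept` and `excluded` data.frames; `excluded` carries a
#'   `reason` column, and the exclusion applies to epidermal records only.
#' @export
filter_explants <- function(records) {
  need <- c("subject_id", "compartment", "hemoglobin", "lod", "lod_ci")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("explant records missing QC fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(records$hemoglobin) | is.na(records$lod) | is.na(records$lod_ci))) {
    stop("explant records contain missing QC values", call. = FALSE)
  }
  epi <- grepl("epidermis", records$compartment)
  thr <- records$lod + records$lod_ci
  # ">= LOD + 1 CI" inclusive, robust to floating-point in the sum
  out <- epi & (records$hemoglobin > thr | abs(records$hemoglobin - thr) < 1e-9)
  excluded <- records[out, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf("hemoglobin %.3g >= LOD %.3g + CI %.3g",
                               excluded$hemoglobin, excluded$lod, excluded$lod_ci)
  } else excluded$reason <- character(0)
  list(kept = records[!out, , drop = FALSE], excluded = excluded)
}

#' Median and interquartile range
#'
#' Median with 25th/75th percentiles by linear interpolation between order
#' statistics (type-7 quantiles), matching the reporting convention
#' "median (IQR q1--q3)".
#'
#' @param values nonempty numeric vector.
#' @return list with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2L], q1 = q[1L], q3 = q[3L])
}

#' Declare a comparison family
#'
#' @param metrics metric names to compare inner vs outer (NULL = all in the
#'   cohort).
#' @param analytes data.frame with columns `compartment`, `analyte` (NULL =
#'   all in the cohort).
#' @param m declared family size for BH adjustment (NULL = number of
#'   comparisons run; the declared size may exceed it, e.g. 53).
#' @param significant,trend adjusted-p thresholds for the verdicts.
#' @return list of class `comparison_family`.
#' @export
comparison_family <- function(metrics = NULL, analytes = NULL, m = NULL,
                              significant = 0.05, trend = 0.10) {
  if (significant <= 0 || trend < significant) {
    fail_field("significant", "need 0 < significant <= trend")
  }
  structure(list(metrics = metrics, analytes = analytes, m = m,
                 significant = significant, trend = trend),
            class = "comparison_family")
}

#' Run the full paired comparison family on a cohort
#'
#' Section measurements are summarized per subject (median over sections),
#' epidermal-explant analytes from hemoglobin-contaminated subjects are
#' excluded, each metric gets a paired inner-vs-outer signed-rank test and
#' each analyte a ratio-vs-1 test, and one BH adjustment is applied over the
#' declared family. Verdicts: `significant` (adjusted p < 0.05), `trend`
#' (adjusted p < 0.10), `ns`.
#'
#' @param cohort an `EpiCohort` (or a list with compatible `measurements`,
#'   `analytes`, `explants` data.frames).
#' @param family a [comparison_family()].
#' @param measurements optional subject-level summaries to use instead of
#'   summarizing `cohort$measurements` (columns subject_id, site, metric,
#'   value).
#' @return data.frame of class `comparison_results`: `comparison`, `type`,
#'   `n`, `statistic`, `p`, `p_adj`, `m`, `verdict`.
#' @export
run_comparison_family <- function(cohort, family = comparison_family(),
                                  measurements = NULL) {
  if (is.null(measurements)) {
    measurements <- suppressWarnings(summarize_subject(cohort$measurements))
  }
  metrics <- family$metrics
  if (is.null(metrics)) metrics <- unique(measurements$metric)
  missing_m <- setdiff(metrics, unique(measurements$metric))
  if (length(missing_m)) {
    stop("comparison family names unresolvable metric(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  ana <- cohort$analytes
  pairs_of <- function(df, valcol) {
    inner <- df[df$site == "inner", c("subject_id", valcol)]
    outer <- df[df$site == "outer", c("subject_id", valcol)]
    common <- intersect(inner$subject_id, outer$subject_id)
    dropped <- setdiff(union(inner$subject_id, outer$subject_id), common)
    if (length(dropped)) {
      message("dropping incomplete pairs: ", paste(dropped, collapse = ", "))
    }
    list(inner = inner[[valcol]][match(common, inner$subject_id)],
         outer = outer[[valcol]][match(common, outer$subject_id)])
  }

  rows <- list()
  for (mt in metrics) {
    pr <- pairs_of(measurements[measurements$metric == mt, ], "value")
    ts <- wilcoxon_signed_rank(pr$inner, pr$outer)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = mt, type = "paired_metric", n = ts$n,
      statistic = ts$statistic, p = ts$p.value, stringsAsFactors = FALSE)
  }

  if (!is.null(ana) && nrow(ana)) {
    excluded_subjects <- character(0)
    if (!is.null(cohort$explants)) {
      qc <- filter_explants(cohort$explants)
      excluded_subjects <- unique(qc$excluded$subject_id)
    }
    fam_an <- family$analytes
    if (is.null(fam_an)) fam_an <- unique(ana[, c("compartment", "analyte")])
    keys_have <- paste(ana$compartment, ana$analyte)
    miss <- setdiff(paste(fam_an$compartment, fam_an$analyte), unique(keys_have))
    if (length(miss)) {
      stop("comparison family names unresolvable analyte(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(fam_an))) {
      cp <- fam_an$compartment[i]; an <- fam_an$analyte[i]
      df <- ana[ana$compartment == cp & ana$analyte == an, ]
      if (grepl("epidermis", cp)) df <- df[!df$subject_id %in% excluded_subjects, ]
      pr <- pairs_of(df, "concentration")
      ts <- ratio_test(inner = pr$inner, outer = pr$outer)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(cp, an, sep = ":"), type = "analyte_ratio", n = ts$n,
        statistic = ts$statistic, p = ts$p.value, stringsAsFactors = FALSE)
    }
  }

  res <- do.call(rbind, rows)
  m <- if (is.null(family$m)) nrow(res) else family$m
  if (m < nrow(res)) {
    stop(sprintf("declared family size m = %d is smaller than the %d comparisons run",
                 m, nrow(res)), call. = FALSE)
  }
  res$p_adj <- bh_adjust(res$p, m)
  res$m <- m
  res$verdict <- ifelse(res$p_adj < family$significant, "significant",
                        ifelse(res$p_adj < family$trend, "trend", "ns"))
  class(res) <- c("comparison_results", "data.frame")
  res
}
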