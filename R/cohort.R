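# Paired inner/outer cohort generator.
#
# Values are drawn from a multiplicative (log-normal) random-effects model:
#   log v[i, s, k] = log(outer_median) + [s == inner] * log(ratio)
#                    + b_i + c_{i,s} + e_{i,s,k}
# with independent Gaussian subject (b), subject-by-site (c) and section (e)
# effects, drawn independently per metric. A ratio of 1 for every metric and
# analyte gives an exchangeable (null) inner/outer cohort.

#' Study-condition effect map for morphometry/stain/cell metrics
#'
#' Outer-site medians and inner/outer multiplicative effects mirroring the
#' reported paired foreskin comparisons (SC thinning ratio ~0.79, claudin-1
#' coverage/intensity increases, loss of claudin-4 polarization, occludin
#' intensity increase, CCR5 and CD4+CCR5+ enrichment); metrics the study found
#' comparable between sites carry a ratio of 1. Dispersion defaults are chosen
#' to reproduce the printed interquartile spreads (see the methods vignette).
#'
#' @return data.frame with columns `metric`, `outer_median`, `ratio`,
#'   `sigma_subject`, `sigma_site`, `sigma_section`.
#' @export
study_effect_map <- function() {
  m <- data.frame(
    metric = c("epidermal_thickness_um", "sc_thickness_um", "parakeratosis_per_mm",
               "ki67_pct",
               "claudin1_coverage_pct", "claudin1_intensity_au",
               "claudin4_coverage_pct", "claudin4_intensity_au",
               "claudin4_polarization_au",
               "occludin_coverage_pct", "occludin_intensity_au",
               "cd4_whole_per_mm2", "cd4_epidermis_per_mm2",
               "ccr5_whole_per_mm2", "ccr5_epidermis_per_mm2",
               "cd4ccr5_whole_per_mm2", "cd4ccr5_epidermis_per_mm2"),
    outer_median = c(60, 19.90, 0.5,
                     3,
                     53.27, 0.039,
                     58.86, 0.047,
                     0.838,
                     52.77, 0.027,
                     50, 14.5,
                     6.46, 3.21,
                     2, 0.25),
    ratio = c(1, 15.69 / 19.90, 1,
              1,
              58.85 / 53.27, 0.060 / 0.039,
              58.45 / 58.86, 0.038 / 0.047,
              0.267 / 0.838,
              56.42 / 52.77, 0.042 / 0.027,
              1, 29.94 / 14.5,
              21.34 / 6.46, 13.30 / 3.21,
              1, 2.01 / 0.25),
    stringsAsFactors = FALSE
  )
  # Between-subject spread sqrt(s_subj^2 + s_site^2 + s_sec^2/4) ~ 0.37 on
  # the log scale matches the printed interquartile ranges (e.g. outer SC
  # 14.19-23.83 um); the within-pair component is set so the reported
  # significant paired differences are reproduced as the typical outcome.
  m$sigma_subject <- 0.33
  m$sigma_site <- 0.16
  m$sigma_section <- 0.15
  m
}

#' Null effect map (all inner/outer ratios 1)
#' @return data.frame as [study_effect_map()] with every `ratio` set to 1.
#' @export
null_effect_map <- function() {
  m <- study_effect_map()
  m$ratio <- 1
  m
}

#' Study-condition analyte map for explant supernatants and lysates
#'
#' Geometric-mean inner/outer concentration ratios mirroring the reported
#' explant cytokine panel (epidermal GM-CSF ~2.9x, IP-10 ~4.5x, RANTES ~2.5x,
#' IFN-gamma ~1.25x; dermal RANTES ~1.5x, MIP-1a ~1.3x) and the lysate skin
#' panel (fibronectin, keratin 6, involucrin, keratin 1,10: no effect).
#'
#' @return data.frame with columns `analyte`, `compartment`, `outer_median`
#'   (ng/ml), `ratio_gm`, `sigma_subject`, `sigma_ratio`.
#' @export
study_analyte_map <- function() {
  cyt <- c("GM-CSF", "IFN-a", "IFN-g", "IL-10", "IL-1a", "IL-1b", "IL-2",
           "IL-6", "IL-8", "IP-10", "MCP-1", "MIP-1a", "MIP-1b", "RANTES", "TNF-a")
  epi <- data.frame(analyte = cyt, compartment = "explant_epidermis",
                    outer_median = 1, ratio_gm = 1, stringsAsFactors = FALSE)
  epi$outer_median[epi$analyte == "GM-CSF"] <- 0.94
  epi$outer_median[epi$analyte == "IP-10"] <- 2.2
  epi$outer_median[epi$analyte == "RANTES"] <- 5.7
  epi$outer_median[epi$analyte == "IFN-g"] <- 0.88
  epi$ratio_gm[epi$analyte == "GM-CSF"] <- 2.7 / 0.94
  epi$ratio_gm[epi$analyte == "IP-10"] <- 9.9 / 2.2
  epi$ratio_gm[epi$analyte == "RANTES"] <- 14.0 / 5.7
  epi$ratio_gm[epi$analyte == "IFN-g"] <- 1.25
  der <- data.frame(analyte = cyt, compartment = "explant_dermis",
                    outer_median = 5, ratio_gm = 1, stringsAsFactors = FALSE)
  der$outer_median[der$analyte == "RANTES"] <- 19.8
  der$ratio_gm[der$analyte == "RANTES"] <- 30.0 / 19.8
  der$ratio_gm[der$analyte == "MIP-1a"] <- 1.3
  lys <- data.frame(analyte = c("fibronectin", "keratin6", "involucrin", "keratin1_10"),
                    compartment = "lysate", outer_median = c(100, 50, 80, 120),
                    ratio_gm = 1, stringsAsFactors = FALSE)
  out <- rbind(epi, der, lys)
  out$sigma_subject <- 1.0
  out$sigma_ratio <- 0.6
  out
}

#' Null analyte map (all geometric-mean ratios 1)
#' @return data.frame as [study_analyte_map()] with every `ratio_gm` set to 1.
#' @export
null_analyte_map <- function() {
  m <- study_analyte_map()
  m$ratio_gm <- 1
  m
}

#' Specify a paired inner/outer cohort
#'
#' @param n_subjects number of subjects (default 17, the sexually-active
#'   analysis subset size).
#' @param sections_per_site sections measured per subject and site; values
#'   outside 3--5 draw a warning (the thickness summary convention assumes
#'   3--5 sections).
#' @param effects per-metric effect map, see [study_effect_map()] /
#'   [null_effect_map()].
#' @param analytes per-analyte map, see [study_analyte_map()] /
#'   [null_analyte_map()].
#' @param hemoglobin_contamination_rate probability that a subject's epidermal
#'   explants are contaminated with dermal blood (default 0.15 ~ 3 of 20).
#' @param hemoglobin_lod,hemoglobin_lod_ci synthetic hemoglobin assay limit of
#'   detection and its confidence interval (arbitrary mg/l-scale units; the
#'   exclusion rule is hemoglobin >= LOD + 1 CI).
#' @param seed integer seed.
#' @return validated object of class `CohortSpec`.
#' @export
cohort_spec <- function(n_subjects = 17L, sections_per_site = 4L,
                        effects = study_effect_map(),
                        analytes = study_analyte_map(),
                        hemoglobin_contamination_rate = 0.15,
                        hemoglobin_lod = 0.1, hemoglobin_lod_ci = 0.05,
                        seed = 1L) {
  if (n_subjects < 1) fail_field("n_subjects", "must be >= 1")
  if (sections_per_site < 1) fail_field("sections_per_site", "must be >= 1")
  if (sections_per_site < 3 || sections_per_site > 5) {
    warning("sections_per_site outside the conventional 3-5 range")
  }
  if (hemoglobin_contamination_rate < 0 || hemoglobin_contamination_rate > 1) {
    fail_field("hemoglobin_contamination_rate", "must lie in [0, 1]")
  }
  need <- c("metric", "outer_median", "ratio", "sigma_subject", "sigma_site", "sigma_section")
  if (!all(need %in% names(effects))) fail_field("effects", "missing columns")
  if (any(effects$sigma_subject <= 0 | effects$sigma_site <= 0 | effects$sigma_section <= 0)) {
    fail_field("effects", "dispersion parameters must be positive")
  }
  needa <- c("analyte", "compartment", "outer_median", "ratio_gm", "sigma_subject", "sigma_ratio")
  if (!all(needa %in% names(analytes))) fail_field("analytes", "missing columns")
  if (any(analytes$sigma_subject <= 0 | analytes$sigma_ratio <= 0)) {
    fail_field("analytes", "dispersion parameters must be positive")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 sections_per_site = as.integer(sections_per_site),
                 effects = effects, analytes = analytes,
                 hemoglobin_contamination_rate = hemoglobin_contamination_rate,
                 hemoglobin_lod = hemoglobin_lod,
                 hemoglobin_lod_ci = hemoglobin_lod_ci,
                 seed = seed),
            class = "CohortSpec")
}

#' Generate a paired inner/outer cohort
#'
#' Draws section-level metric values, analyte concentration panels, and
#' epidermal-explant hemoglobin QC records for every subject, with ground
#' truth (effects and contamination flags) attached. With `render = TRUE` a
#' subset of metrics is additionally realized as synthetic image sections so
#' the imaging modules can be exercised end-to-end (intended for small
#' cohorts; images are ~0.2 MB per section).
#'
#' @param spec a [cohort_spec()].
#' @param render also generate image sections per subject/site/section.
#' @return object of class `EpiCohort`: list with `measurements` (long
#'   data.frame: subject_id, site, section_index, metric, value), `analytes`
#'   (subject_id, compartment, analyte, site, concentration), `explants`
#'   (epidermal explant QC records), `truth`, `spec`, and (if rendered)
#'   `images`.
#' @export
generate_cohort <- function(spec, render = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"))
  with_private_seed(spec$seed, {
    ns <- spec$n_subjects
    subjects <- sprintf("S%02d", seq_len(ns))
    sites <- c("inner", "outer")
    nk <- spec$sections_per_site

    # layout: subject-major, then site (inner, outer), then section
    sub_col <- rep(subjects, each = 2L * nk)
    site_col <- rep(rep(sites, each = nk), ns)
    sec_col <- rep(seq_len(nk), 2L * ns)
    inner_sel <- site_col == "inner"
    meas <- vector("list", nrow(spec$effects))
    for (i in seq_len(nrow(spec$effects))) {
      e <- spec$effects[i, ]
      b <- rnorm(ns, 0, e$sigma_subject)
      c_is <- rnorm(ns * 2L, 0, e$sigma_site)
      eps <- rnorm(ns * 2L * nk, 0, e$sigma_section)
      lv <- log(e$outer_median) + ifelse(inner_sel, log(e$ratio), 0) +
        rep(b, each = 2L * nk) + rep(c_is, each = nk) + eps
      meas[[i]] <- data.frame(
        subject_id = sub_col, site = site_col, section_index = sec_col,
        metric = e$metric, value = exp(lv), stringsAsFactors = FALSE)
    }
    measurements <- do.call(rbind, meas)

    ana <- vector("list", nrow(spec$analytes))
    for (i in seq_len(nrow(spec$analytes))) {
      a <- spec$analytes[i, ]
      outer_v <- a$outer_median * exp(rnorm(ns, 0, a$sigma_subject))
      ratio_v <- a$ratio_gm * exp(rnorm(ns, 0, a$sigma_ratio))
      ana[[i]] <- data.frame(
        subject_id = rep(subjects, 2L),
        compartment = a$compartment, analyte = a$analyte,
        site = rep(sites, each = ns),
        concentration = c(outer_v * ratio_v, outer_v),
        stringsAsFactors = FALSE)
    }
    analytes <- do.call(rbind, ana)

    contaminated <- runif(ns) < spec$hemoglobin_contamination_rate
    expl <- data.frame(
      subject_id = rep(subjects, each = 2L),
      site = rep(sites, ns),
      compartment = "explant_epidermis",
      hemoglobin = NA_real_,
      lod = spec$hemoglobin_lod, lod_ci = spec$hemoglobin_lod_ci,
      stringsAsFactors = FALSE)
    for (si in seq_len(ns)) {
      rows <- which(expl$subject_id == subjects[si])
      expl$hemoglobin[rows] <- if (contaminated[si]) {
        spec$hemoglobin_lod + spec$hemoglobin_lod_ci * (1 + rexp(2))
      } else {
        runif(2, 0, 0.8 * spec$hemoglobin_lod)
      }
    }

    cohort <- structure(list(
      measurements = measurements, analytes = analytes, explants = expl,
      truth = list(effects = spec$effects, analytes = spec$analytes,
                   contaminated = setNames(contaminated, subjects)),
      spec = spec), class = "EpiCohort")

    if (render) cohort$images <- render_cohort_images(cohort)
    cohort
  })
}

# metrics run through the imaging path when a cohort is rendered
RENDERED_METRICS <- c("epidermal_thickness_um", "sc_thickness_um",
                      "parakeratosis_per_mm", "tj_coverage_pct",
                      "tj_intensity_au", "cd4_epidermis_per_mm2",
                      "ccr5_epidermis_per_mm2", "cd4ccr5_epidermis_per_mm2")

# realize drawn section-level values as synthetic image sections
render_cohort_images <- function(cohort, width_px = 220L, height_px = 120L,
                                 pixel_size_um = 2) {
  m <- cohort$measurements
  key <- interaction(m$subject_id, m$site, m$section_index, drop = FALSE)
  images <- list()
  px <- pixel_size_um
  for (sid in unique(m$subject_id)) {
    images[[sid]] <- list()
    for (st in c("inner", "outer")) {
      images[[sid]][[st]] <- list()
      for (k in seq_len(cohort$spec$sections_per_site)) {
        sel <- m$subject_id == sid & m$site == st & m$section_index == k
        val <- function(metric, default) {
          v <- m$value[sel & m$metric == metric]
          if (length(v)) v[1] else default
        }
        thick_um <- val("epidermal_thickness_um", 60)
        sc_um <- val("sc_thickness_um", 12)
        epi_px <- max(16L, min(70L, round(thick_um / px)))
        sc_frac <- min(0.5, max(0.06, sc_um / (epi_px * px)))
        rest <- 1 - sc_frac
        fr <- c(sb = 0.45 * rest, ss = 0.35 * rest, sg = 0.20 * rest, sc = sc_frac)
        cov <- val("tj_coverage_pct", 50)
        inten <- val("tj_intensity_au", 0.04)
        band_fr <- min(1, max(0.05, cov / 100 / 0.8)) # cellular band ~80% of epidermis
        stain_i <- min(1, inten / (band_fr * 0.8))
        cell_area_mm2 <- width_px * epi_px * (1 - sc_frac) * px^2 / 1e6
        n_dp <- round(val("cd4ccr5_epidermis_per_mm2", 0) * cell_area_mm2)
        n_cd4 <- max(0L, round(val("cd4_epidermis_per_mm2", 0) * cell_area_mm2) - n_dp)
        n_ccr5 <- max(0L, round(val("ccr5_epidermis_per_mm2", 0) * cell_area_mm2) - n_dp)
        mk_cells <- function(n, markers) {
          lapply(seq_len(n), function(i) list(area_um2 = 20, intensity = 0.5,
                                              markers = markers, compartment = "epidermis"))
        }
        sp <- section_spec(
          width_px = width_px, height_px = height_px, pixel_size_um = px,
          epithelium_px = epi_px, strata_fractions = fr,
          undulation_amplitude_px = 4, undulation_period_px = 110,
          nuclei_density_per_mm2 = 2500,
          sc_nuclei_per_mm = val("parakeratosis_per_mm", 0),
          stains = list(farred = list(band_fraction = band_fr, intensity = stain_i)),
          cells = c(mk_cells(n_dp, c("CD4", "CCR5")), mk_cells(n_cd4, "CD4"),
                    mk_cells(n_ccr5, "CCR5")),
          noise_sd = 0.02,
          seed = sample.int(.Machine$integer.max, 1L),
          subject_id = sid, site = st, section_index = k)
        images[[sid]][[st]][[k]] <- generate_section(sp)
      }
    }
  }
  images
}

#' @export
print.EpiCohort <- function(x, ...) {
  cat(sprintf("EpiCohort: %d subjects x 2 sites x %d sections; %d metrics, %d analytes\n",
              x$spec$n_subjects, x$spec$sections_per_site,
              length(unique(x$measurements$metric)),
              nrow(unique(x$analytes[, c("compartment", "analyte")]))))
  cat(sprintf("  contaminated epidermal explants: %d subject(s)\n",
              sum(x$truth$contaminated)))
  invisible(x)
}
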