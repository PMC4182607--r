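# Synthetic section and cohort generator.

test_that("flat noise-free strip reproduces its specified geometry exactly", {
  sp <- section_spec(undulation_amplitude_px = 0, noise_sd = 0, seed = 1)
  g <- generate_section(sp)
  expect_equal(g$truth$true_mean_thickness_um,
               sp$epithelium_px * sp$pixel_size_um)
  expect_equal(g$truth$true_sc_thickness_um,
               round(sp$strata_fractions[["sc"]] * sp$epithelium_px) * sp$pixel_size_um)
  # channel intensities all in [0, 1]
  rng <- range(vapply(g$section$channels, range, numeric(2)))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  # masks are consistent: sc and cellular partition the epithelium
  expect_equal(g$truth$true_sc_mask | g$truth$true_epidermis_mask,
               g$truth$true_epithelium_mask)
  expect_false(any(g$truth$true_sc_mask & g$truth$true_epidermis_mask))
})

test_that("generation is bit-identical for equal spec and leaves global RNG untouched", {
  sp <- section_spec(seed = 99, noise_sd = 0.03, sc_nuclei_per_mm = 2)
  set.seed(555)
  before <- .Random.seed
  g1 <- generate_section(sp)
  expect_identical(.Random.seed, before)
  g2 <- generate_section(sp)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
})

test_that("different seeds move the nuclei but not the deterministic geometry", {
  g1 <- generate_section(section_spec(seed = 1))
  g2 <- generate_section(section_spec(seed = 2))
  expect_identical(g1$truth$true_epidermis_mask, g2$truth$true_epidermis_mask)
  expect_identical(g1$truth$true_sc_mask, g2$truth$true_sc_mask)
  expect_false(identical(g1$truth$nuclei_centroids, g2$truth$nuclei_centroids))
})

test_that("ground-truth gate counts apply the 10-33 um^2 area gate", {
  cells <- lapply(c(5, 20, 50), function(a) {
    list(area_um2 = a, intensity = 0.5, markers = "CD4", compartment = "epidermis")
  })
  g <- generate_section(section_spec(cells = cells, noise_sd = 0, seed = 3))
  cbg <- g$truth$true_counts_by_gate
  expect_equal(cbg$count[cbg$marker == "CD4" & cbg$compartment == "epidermis"], 1)
  expect_equal(cbg$count[cbg$marker == "CCR5" & cbg$compartment == "epidermis"], 0)
})

test_that("double-marker cells are counted in both single gates and the double gate", {
  cells <- list(
    list(area_um2 = 20, intensity = 0.5, markers = c("CD4", "CCR5"), compartment = "epidermis"),
    list(area_um2 = 20, intensity = 0.5, markers = "CCR5", compartment = "dermis"))
  g <- generate_section(section_spec(cells = cells, noise_sd = 0, seed = 4))
  cbg <- g$truth$true_counts_by_gate
  pick <- function(mk, cp) cbg$count[cbg$marker == mk & cbg$compartment == cp]
  expect_equal(pick("CD4+CCR5+", "epidermis"), 1)
  expect_equal(pick("CD4", "epidermis"), 1)
  expect_equal(pick("CCR5", "epidermis"), 1)
  expect_equal(pick("CCR5", "dermis"), 1)
  expect_equal(pick("CD4+CCR5+", "dermis"), 0)
})

test_that("invalid section specs fail naming the offending field", {
  expect_error(section_spec(strata_fractions = c(0.5, 0.5, 0.2, 0.2)),
               "strata_fractions")
  expect_error(section_spec(pixel_size_um = -1), "pixel_size_um")
  expect_error(section_spec(noise_sd = -0.1), "noise_sd")
  expect_error(section_spec(cells = list(list(area_um2 = 20, intensity = 2,
                                              markers = "CD4", compartment = "epidermis"))),
               "cells")
  expect_error(section_spec(epithelium_px = 500), "epithelium_px")
})

test_that("membrane stains render sparse borders, cytosolic stains fill the stratum", {
  memb <- generate_section(section_spec(
    seed = 5, noise_sd = 0,
    stains = list(farred = list(pattern = c(sb = "none", ss = "none", sg = "membrane", sc = "none"),
                                intensity = 0.5))))
  cyto <- generate_section(section_spec(
    seed = 5, noise_sd = 0,
    stains = list(farred = list(pattern = c(sb = "none", ss = "none", sg = "cytosolic", sc = "none"),
                                intensity = 0.5))))
  cov_m <- memb$truth$true_coverage_pct[["farred"]]
  cov_c <- cyto$truth$true_coverage_pct[["farred"]]
  expect_gt(cov_m, 0)
  expect_lt(cov_m, cov_c) # borders cover less area than a fill
  expect_gt(cov_c, 10)
})

test_that("null cohorts are exchangeable between sites and contaminated subjects follow the rate", {
  n_flag <- 0; diffs <- numeric(0)
  for (s in 1:60) {
    co <- generate_cohort(cohort_spec(n_subjects = 10, effects = null_effect_map(),
                                      analytes = null_analyte_map(),
                                      hemoglobin_contamination_rate = 0.15,
                                      seed = s))
    n_flag <- n_flag + sum(co$truth$contaminated)
    sm <- suppressWarnings(summarize_subject(
      co$measurements[co$measurements$metric == "sc_thickness_um", ]))
    inner <- sm$value[sm$site == "inner"][order(sm$subject_id[sm$site == "inner"])]
    outer <- sm$value[sm$site == "outer"][order(sm$subject_id[sm$site == "outer"])]
    diffs <- c(diffs, log(inner) - log(outer))
  }
  # binomial expectation: 60 cohorts x 10 subjects x 0.15 = 90 flags
  expect_gt(n_flag, 60)
  expect_lt(n_flag, 125)
  # paired log-differences centered at zero under the null
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("a specified SC-thinning ratio is realized in the generated medians", {
  eff <- null_effect_map()
  eff$ratio[eff$metric == "sc_thickness_um"] <- 0.8
  eff <- eff[eff$metric == "sc_thickness_um", ]
  ana <- null_analyte_map()[1, ]
  lr <- numeric(200)
  for (s in 1:200) {
    co <- generate_cohort(cohort_spec(n_subjects = 17, effects = eff, analytes = ana,
                                      seed = 1000 + s))
    sm <- suppressWarnings(summarize_subject(co$measurements))
    lr[s] <- log(median(sm$value[sm$site == "inner"]) /
                   median(sm$value[sm$site == "outer"]))
  }
  # Monte-Carlo mean of the inner/outer median ratio recovers the effect
  expect_equal(exp(mean(lr)), 0.8, tolerance = 0.03)
})

test_that("explant hemoglobin values respect the contamination flags", {
  co <- generate_cohort(cohort_spec(n_subjects = 20, hemoglobin_contamination_rate = 0.3,
                                    seed = 11))
  ex <- co$explants
  thr <- ex$lod + ex$lod_ci
  for (sid in names(co$truth$contaminated)) {
    hb <- ex$hemoglobin[ex$subject_id == sid]
    if (co$truth$contaminated[[sid]]) expect_true(all(hb >= thr[1]))
    else expect_true(all(hb < thr[1]))
  }
})
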