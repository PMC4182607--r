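# epiquant

Quantitative morphometry and immunofluorescence analysis of stratified
squamous epithelium, built for paired site comparisons — the motivating case
is inner vs outer foreskin from the same donor, where subtle differences in
barrier structure (stratum corneum thickness, tight-junction localization)
and in HIV target-cell content (CD4+/CCR5+ densities) are the biology of
interest.

The package implements the full measurement-to-inference chain:

* **Segmentation** — epidermis outlined from red-channel autofluorescence
  (Otsu or manual threshold, small-object removal, hole filling), external
  outline masks (the stand-in for manual H&E outlining), nucleus detection,
  all with 8-connectivity.
* **Morphometry** — Feret's diameter by convex hull over pixel corners;
  mean thickness = outline area / Feret (for a `w x h` strip this is
  `w*h/sqrt(w^2+h^2)`, converging to the true height `h` as the strip gets
  long); parakeratosis as retained SC nuclei per mm of SC Feret; px-to-um
  conversion through objective magnification and mosaic compression;
  per-subject medians over 3–5 sections.
* **Stain quantification** — Ki-67 positive fraction, % epidermal area
  covered, mean intensity per epidermal area (AU 0–1), and a polarization
  score `sum(I^2 * r) / n_pixels` (r = distance from the epidermal
  midpoint) that separates membrane stain concentrated toward the SC from
  uniform cytosolic stain — each with scalar isotype-control subtraction,
  floored at zero.
* **Cell detection** — 10–33 um^2 objects with aggregate intensity above
  0.03 AU (CD4) / 0.025 AU (CCR5), densities per mm^2 of epidermis or whole
  tissue, per-subject isotype-density subtraction, and CD4+CCR5+ double
  positives by maximum bipartite centroid matching.
* **Inference** — exact paired Wilcoxon signed-rank tests (full signed-rank
  distribution, ties included), analyte ratio-vs-1 tests on the log scale,
  one Benjamini–Hochberg adjustment over a declared family (53 comparisons
  by default; adjusted p < 0.05 significant, < 0.10 trend), and a hemoglobin
  QC rule excluding dermally contaminated epidermal explants
  (hemoglobin >= LOD + 1 CI).
* **Synthetic data** — a ground-truthed generator for sections (stratified
  SB/SS/SG/SC geometry, membrane vs cytosolic stains, size-controlled
  infiltrating cells, isotype channels, seeded noise) and for paired
  cohorts (multiplicative random-effects model with per-metric inner/outer
  effects and log-normal analyte ratios), so every stage is testable
  without any tissue scans.

## Worked example

Measure one synthetic section and run the paired family on a cohort:

```r
library(epiquant)

g <- generate_section(section_spec(seed = 11, noise_sd = 0.02, sc_nuclei_per_mm = 2,
  cells = rep(list(list(area_um2 = 20, intensity = 0.5,
                        markers = c("CD4", "CCR5"), compartment = "epidermis")), 6)))
px <- g$section$pixel_size_um

epi        <- segment_epidermis(g$section)                     # autofluorescence outline
epithelium <- region_mask(g$truth$true_epithelium_mask, "epidermis", px)
sc         <- region_mask(g$truth$true_sc_mask, "stratum_corneum", px)

feret_diameter(epithelium)   # 451.2 um  -- caliper length of the strip
mean_thickness(epithelium)   # 97.5 um   -- area/Feret (truth: 100 um; the
                             #              Feret slightly exceeds the length)
n_sc <- detect_nuclei(g$section, sc)$count                     # 1 retained nucleus
parakeratosis_density(n_sc, sc)                                # 2.27 nuclei/mm

cd4  <- detect_cells(get_channel(g$section, "blue"),   epi, cell_gate("CD4"))
ccr5 <- detect_cells(get_channel(g$section, "farred"), epi, cell_gate("CCR5"))
double_positive(cd4$centroids, ccr5$centroids, 3)              # 6 CD4+CCR5+ cells
raw <- density_result("S1", "inner", "CD4+CCR5+", "epidermis",
                      cell_density(6, epi))                    # 170.5 cells/mm^2
subtract_isotype_density(raw, 2.1)$corrected_density           # 168.4 cells/mm^2
```

Cohort-level inference under the study conditions (17 subjects, 4 sections
per site, family of 53):

```r
co  <- generate_cohort(cohort_spec(seed = 2026))
res <- run_comparison_family(co, comparison_family(m = 53))
res[res$comparison %in% c("sc_thickness_um", "claudin1_intensity_au",
                          "claudin4_polarization_au", "ccr5_whole_per_mm2",
                          "epidermal_thickness_um", "explant_epidermis:IP-10"),
    c("comparison", "n", "statistic", "p", "p_adj", "verdict")]
#>                comparison  n statistic        p    p_adj     verdict
#>        ccr5_whole_per_mm2 17       153 1.53e-05 0.000116 significant
#>     claudin1_intensity_au 17       153 1.53e-05 0.000116 significant
#>  claudin4_polarization_au 17         0 1.53e-05 0.000116 significant
#>    epidermal_thickness_um 17       119 4.48e-02 0.158185          ns
#>           sc_thickness_um 17         4 1.07e-04 0.000515 significant
#>   explant_epidermis:IP-10 15       120 6.10e-05 0.000323 significant
```

W = 153 is every one of the 17 paired differences positive (W = 0, all
negative); the epidermal-thickness comparison — generated with no
inner/outer effect — stays non-significant after the family-wide
adjustment, while IP-10 is tested on n = 15 because two subjects'
contaminated epidermal explants were excluded by the hemoglobin rule. The
generated SC medians land where the effect map puts them, e.g. inner
13.95 um (IQR 12.59–17.94) vs outer 20.64 um (IQR 17.84–24.87) in this
cohort.

`run_pipeline(pipeline_config(out_dir, seed, ...))` chains everything —
simulate, render sections, segment, measure, summarize, QC-filter, test —
into CSV + JSON outputs with a config hash on every row; identical configs
give byte-identical files.

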