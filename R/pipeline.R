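# Pipeline orchestration: simulate -> segment -> measure -> summarize ->
# QC filter -> family statistics -> report.

#' Build and validate a pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param n_subjects,sections_per_site cohort size (images are rendered per
#'   section; keep the cohort small when `render_images = TRUE`).
#' @param effects,analytes generator maps, see [study_effect_map()] and
#'   [study_analyte_map()].
#' @param hemoglobin_contamination_rate see [cohort_spec()].
#' @param render_images run the imaging path (simulated sections measured by
#'   the segmentation/morphometry/stain/cell modules) for the rendered metric
#'   subset; otherwise the generator's value-level measurements are used
#'   directly.
#' @param family_m declared BH family size (NULL = number of comparisons).
#' @param cd4_gate,ccr5_gate [cell_gate()]s used on the blue/far-red
#'   channels.
#' @param pairing_radius_um double-positive pairing radius.
#' @param write_images also write each rendered section as TIFF + sidecar.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 6L,
                            sections_per_site = 3L,
                            effects = study_effect_map(),
                            analytes = study_analyte_map(),
                            hemoglobin_contamination_rate = 0.15,
                            render_images = TRUE, family_m = NULL,
                            cd4_gate = cell_gate("CD4"),
                            ccr5_gate = cell_gate("CCR5"),
                            pairing_radius_um = 3,
                            write_images = FALSE) {
  cfg <- list(out_dir = out_dir, seed = seed, n_subjects = n_subjects,
              sections_per_site = sections_per_site, effects = effects,
              analytes = analytes,
              hemoglobin_contamination_rate = hemoglobin_contamination_rate,
              render_images = isTRUE(render_images), family_m = family_m,
              cd4_gate = cd4_gate, ccr5_gate = ccr5_gate,
              pairing_radius_um = pairing_radius_um,
              write_images = isTRUE(write_images))
  class(cfg) <- "PipelineConfig"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1L) {
    fail_field("out_dir", "must be a single path")
  }
  stopifnot(inherits(cfg$cd4_gate, "CellGate"), inherits(cfg$ccr5_gate, "CellGate"))
  if (cfg$pairing_radius_um <= 0) fail_field("pairing_radius_um", "must be > 0")
  # the family size must cover every comparison the run will produce;
  # checked here, before any computation
  metrics <- cfg$effects$metric
  if (cfg$render_images) metrics <- union(metrics, RENDERED_METRICS)
  n_cmp <- length(metrics) + nrow(cfg$analytes)
  if (!is.null(cfg$family_m) && cfg$family_m < n_cmp) {
    fail_field("family_m",
               sprintf("declared family size %d is smaller than the %d comparisons the run produces",
                       cfg$family_m, n_cmp))
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be given in a YAML file; unknown
#' keys are an error.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "n_subjects", "sections_per_site",
             "hemoglobin_contamination_rate", "render_images", "family_m",
             "pairing_radius_um", "write_images")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, y)
}

# measure one rendered (section, truth) pair through the imaging modules
measure_rendered_section <- function(rendered, cfg) {
  sec <- rendered$section
  truth <- rendered$truth
  px <- sec$pixel_size_um
  epi <- segment_epidermis(sec)
  sc <- region_mask(truth$true_sc_mask, "stratum_corneum", px)
  epithelium <- region_mask(truth$true_epithelium_mask, "epidermis", px)
  sc_nuc <- detect_nuclei(sec, sc)
  cd4 <- detect_cells(get_channel(sec, "blue"), epi, cfg$cd4_gate)
  ccr5 <- detect_cells(get_channel(sec, "farred"), epi, cfg$ccr5_gate)
  ndp <- double_positive(cd4$centroids, ccr5$centroids, cfg$pairing_radius_um)
  cov <- coverage_percent(get_channel(sec, "farred"), epi,
                          threshold = cfg$ccr5_gate$intensity_threshold)
  inten <- mean_intensity(get_channel(sec, "farred"), epi)
  a_mm2 <- region_area_mm2(epi)
  data.frame(
    subject_id = sec$subject_id, site = sec$site, section_index = sec$section_index,
    metric = c("epidermal_thickness_um", "sc_thickness_um", "parakeratosis_per_mm",
               "tj_coverage_pct", "tj_intensity_au",
               "cd4_epidermis_per_mm2", "ccr5_epidermis_per_mm2",
               "cd4ccr5_epidermis_per_mm2"),
    value = c(mean_thickness(epithelium), mean_thickness(sc),
              parakeratosis_density(sc_nuc$count, sc),
              cov$corrected, inten$corrected,
              cd4$count / a_mm2, ccr5$count / a_mm2, ndp / a_mm2),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates a paired cohort, optionally renders and measures image sections
#' (segmentation, thickness, parakeratosis, stain coverage/intensity, cell
#' densities), summarizes subjects, filters contaminated explants, runs the
#' comparison family with BH adjustment, and writes CSV outputs plus a JSON
#' report. Fully deterministic given the config (the config hash and seed
#' are recorded in the report; every output row carries subject/site/section
#' provenance). All file writes are atomic.
#'
#' @param config a [pipeline_config()].
#' @return the report list, invisibly; files are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cspec <- suppressWarnings(cohort_spec(
    n_subjects = config$n_subjects, sections_per_site = config$sections_per_site,
    effects = config$effects, analytes = config$analytes,
    hemoglobin_contamination_rate = config$hemoglobin_contamination_rate,
    seed = config$seed))
  cohort <- generate_cohort(cspec, render = config$render_images)

  measurements <- cohort$measurements
  if (config$render_images) {
    measured <- list()
    for (sid in names(cohort$images)) {
      for (st in names(cohort$images[[sid]])) {
        for (rendered in cohort$images[[sid]][[st]]) {
          measured[[length(measured) + 1L]] <- measure_rendered_section(rendered, config)
          if (config$write_images) {
            sec <- rendered$section
            write_section(sec, file.path(config$out_dir,
                                         sprintf("%s_%s_%02d.tiff", sec$subject_id,
                                                 sec$site, sec$section_index)))
          }
        }
      }
    }
    measured <- do.call(rbind, measured)
    # imaging-path values replace the generator's value-level draws for the
    # rendered metrics; unrendered metrics keep their value-level draws
    keep <- !measurements$metric %in% RENDERED_METRICS
    measurements <- rbind(measurements[keep, ], measured)
  }

  summaries <- suppressWarnings(summarize_subject(measurements))
  qc <- filter_explants(cohort$explants)
  fam <- comparison_family(m = config$family_m)
  results <- run_comparison_family(
    list(analytes = cohort$analytes, explants = cohort$explants),
    fam, measurements = summaries)

  prov <- function(df) { df$config_hash <- cfg_hash; df }
  write_csv_atomic(prov(measurements), file.path(config$out_dir, "measurements.csv"))
  write_csv_atomic(prov(summaries), file.path(config$out_dir, "subject_summaries.csv"))
  write_csv_atomic(prov(cohort$analytes), file.path(config$out_dir, "analytes.csv"))
  write_csv_atomic(prov(as.data.frame(results)), file.path(config$out_dir, "comparisons.csv"))

  report <- list(
    config_hash = cfg_hash, seed = config$seed,
    n_subjects = config$n_subjects,
    n_sections = config$n_subjects * 2L * config$sections_per_site,
    rendered = config$render_images,
    excluded_subjects = unique(qc$excluded$subject_id),
    n_comparisons = nrow(results), family_m = results$m[1L],
    n_significant = sum(results$verdict == "significant"),
    n_trend = sum(results$verdict == "trend"),
    outputs = c("measurements.csv", "subject_summaries.csv", "analytes.csv",
                "comparisons.csv"))
  atomic_write(function(p) jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA),
               file.path(config$out_dir, "report.json"))
  invisible(report)
}
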