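# Feret diameter, thickness, parakeratosis density, unit conversion, and
# per-subject median summaries.
#
# Feret's diameter is the maximum caliper distance across the region. It is
# computed over pixel-corner points (each mask pixel treated as a unit
# square), so an axis-aligned w x h pixel rectangle has Feret exactly
# sqrt(w^2 + h^2) * pixel_size and the closed-form thickness identity
# w*h/sqrt(w^2+h^2) holds exactly. The implementation takes the convex hull
# of boundary-pixel corners and scans hull-vertex pairs; a brute-force
# pairwise oracle is kept in the test suite.

# corner points (x, y) in pixel units of the pixels flagged in `mask`
pixel_corner_points <- function(mask, boundary_only = TRUE) {
  sel <- if (boundary_only) boundary_pixels(mask) else mask
  idx <- which(sel)
  if (length(idx) == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  nr <- nrow(mask)
  cc <- ((idx - 1L) %/% nr) + 1L
  rr <- ((idx - 1L) %% nr) + 1L
  x <- c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
  y <- c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5)
  pts <- unique(cbind(x = x, y = y))
  pts
}

#' Feret's diameter of a region
#'
#' Maximum caliper distance between any two boundary points of the region,
#' in micrometers. Closely approximates the length of a strip-shaped
#' epithelium outline. Disconnected masks are allowed (the hull spans the
#' union); a single-pixel mask has Feret `sqrt(2) * pixel_size_um` (its
#' diagonal extent).
#'
#' @param region a [region_mask()], or a logical matrix (then
#'   `pixel_size_um` applies).
#' @param pixel_size_um pixel edge when `region` is a bare matrix.
#' @return length in micrometers.
#' @export
feret_diameter <- function(region, pixel_size_um = NULL) {
  m <- as_mask(region, pixel_size_um)
  if (!any(m$mask)) stop("empty mask: Feret diameter undefined", call. = FALSE)
  pts <- pixel_corner_points(m$mask)
  h <- chull(pts[, 1L], pts[, 2L])
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) == 1L) return(0)
  d <- max(stats::dist(hp))
  d * m$px
}

#' Mean thickness of a strip-shaped region
#'
#' Outline area divided by Feret's diameter of the outline: for an epithelium
#' strip whose length greatly exceeds its height, this estimates the average
#' height. For a w x h pixel rectangle the value is
#' `w*h/sqrt(w^2+h^2) * pixel_size_um`, which converges to the true height h
#' as w/h grows (relative error <= h^2 / (2 w^2)).
#'
#' @inheritParams feret_diameter
#' @return thickness in micrometers.
#' @export
mean_thickness <- function(region, pixel_size_um = NULL) {
  m <- as_mask(region, pixel_size_um)
  if (!any(m$mask)) stop("empty mask: thickness undefined", call. = FALSE)
  f <- feret_diameter(region, pixel_size_um)
  if (f == 0) stop("degenerate mask: zero Feret diameter", call. = FALSE)
  area_um2 <- sum(m$mask) * m$px^2
  area_um2 / f
}

#' Parakeratosis density: retained SC nuclei per millimeter
#'
#' The SC nucleus count divided by the SC outline's Feret diameter (in mm),
#' i.e. nuclei per mm of stratum corneum length.
#'
#' @param nuclei_count number of nuclei counted within the SC.
#' @param sc_mask the SC [region_mask()].
#' @return nuclei per millimeter.
#' @export
parakeratosis_density <- function(nuclei_count, sc_mask) {
  if (nuclei_count < 0) fail_field("nuclei_count", "must be >= 0")
  f_mm <- feret_diameter(sc_mask) / 1e3
  if (f_mm == 0) stop("degenerate SC mask: zero Feret diameter", call. = FALSE)
  nuclei_count / f_mm
}

#' Convert pixel lengths to micrometers
#'
#' `value_um = value_px * camera_scale_um_per_px / objective_magnification /
#' compression_factor`. A composite image compressed to 50% of its original
#' size (`compression_factor = 0.5`) doubles the effective um/px.
#'
#' @param value_px length in pixels (or um when `inverse = TRUE`).
#' @param objective_magnification e.g. 20 for a 20x objective.
#' @param compression_factor stored-image scale relative to acquisition
#'   (1 = uncompressed, 0.5 = half size).
#' @param camera_scale_um_per_px camera pixel pitch at the specimen for 1x,
#'   um per pixel.
#' @param inverse convert micrometers back to pixels.
#' @return converted length.
#' @export
convert_length <- function(value_px, objective_magnification = 20,
                           compression_factor = 1, camera_scale_um_per_px = 6.45,
                           inverse = FALSE) {
  for (f in c("objective_magnification", "compression_factor", "camera_scale_um_per_px")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0) fail_field(f, "must be > 0")
  }
  k <- camera_scale_um_per_px / objective_magnification / compression_factor
  if (inverse) value_px / k else value_px * k
}

#' Summarize section measurements per subject, site and metric
#'
#' The subject-level summary of a metric is the median over that subject's
#' sections (3--5 sections by convention; a warning is issued outside that
#' range). Even section counts use the mean-of-middle-two median.
#'
#' @param measurements data.frame with columns `subject_id`, `site`,
#'   `metric`, `value` (and optionally `section_index`).
#' @return data.frame with one row per (subject_id, site, metric):
#'   `value` = median, `n_sections`.
#' @export
summarize_subject <- function(measurements) {
  need <- c("subject_id", "site", "metric", "value")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns subject_id, site, metric, value",
         call. = FALSE)
  }
  if (nrow(measurements) == 0L) stop("no measurements to summarize", call. = FALSE)
  key <- interaction(measurements$subject_id, measurements$site,
                     measurements$metric, drop = TRUE)
  med <- tapply(measurements$value, key, median)
  n <- tabulate(key, nbins = nlevels(key))
  first <- match(levels(key), as.character(key))
  out <- data.frame(subject_id = measurements$subject_id[first],
                    site = measurements$site[first],
                    metric = measurements$metric[first],
                    value = as.numeric(med[levels(key)]),
                    n_sections = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  bad <- out$n_sections < 3L | out$n_sections > 5L
  if (any(bad)) {
    warning(sprintf("%d subject/site/metric group(s) summarized from outside 3-5 sections",
                    sum(bad)))
  }
  out
}
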