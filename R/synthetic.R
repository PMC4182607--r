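# Synthetic histology: ground-truthed sections and paired cohorts.
#
# The generator emulates a strip of stratified squamous epithelium imaged in
# four fluorescence channels (nuclear counterstain, red autofluorescence,
# far-red stain, blue stain) plus isotype-control channels, together with the
# paired inner/outer cohort structure the downstream inference assumes.

STRATA <- c("sb", "ss", "sg", "sc") # basale, spinosum, granulosum, corneum

#' Specify a synthetic epithelium section
#'
#' Geometry is a horizontal epithelial strip: from the image top, a background
#' margin, then the stratum corneum (SC), granulosum (SG), spinosum (SS) and
#' basale (SB) bands, then dermis down to the bottom edge. The basal boundary
#' can undulate sinusoidally; the SC surface is flat, so the "length >>
#' thickness" geometry of the area/Feret thickness estimator holds.
#'
#' @param width_px,height_px raster dimensions in pixels.
#' @param pixel_size_um physical pixel edge, micrometers.
#' @param epithelium_px total epithelium (SB..SC) height in pixels; the four
#'   `strata_fractions` partition it.
#' @param strata_fractions nonnegative fractions for the SB/SS/SG/SC band
#'   heights, in that order, summing to 1 (within 1e-9).
#' @param undulation_amplitude_px,undulation_period_px sinusoidal undulation
#'   of the basal boundary (amplitude 0 = flat strip).
#' @param nuclei_density_per_mm2 keratinocyte nuclei per mm^2 in each cellular
#'   stratum (SB, SS, SG).
#' @param sc_nuclei_per_mm retained (parakeratotic) nuclei per mm of SC
#'   length; this is the parakeratosis ground truth.
#' @param stains named list describing stain rendering per channel, e.g.
#'   `list(farred = list(pattern = c(sb="none", ss="none", sg="membrane",
#'   sc="none"), intensity = 0.5))`. `pattern` entries are `"membrane"`
#'   (thin high-intensity Voronoi cell borders seeded at nuclei),
#'   `"cytosolic"` (uniform fill) or `"none"`; `intensity` is a scalar or a
#'   per-stratum vector in \[0, 1\]. An entry may instead give
#'   `band_fraction` and `intensity` to paint a uniform band occupying the
#'   top (SC-adjacent) fraction of the cellular epidermis.
#' @param isotype_background_level uniform background of the isotype-control
#'   channels, \[0, 1\].
#' @param cells list of infiltrating cells, each
#'   `list(area_um2 =, intensity =, markers = c("CD4","CCR5"), compartment =
#'   "epidermis"|"dermis")`. CD4 renders on the blue channel, CCR5 on the
#'   far-red channel.
#' @param autofluorescence_intensity red-channel autofluorescence of the
#'   cellular epidermis.
#' @param dermis_autofluorescence faint red-channel level of the dermis.
#' @param sc_autofluorescence should the SC autofluoresce on the red channel?
#'   Default FALSE: the autofluorescent "epidermis" region used for stain
#'   denominators excludes the SC (see the methods vignette).
#' @param nucleus_area_um2,nucleus_intensity rendered nucleus size and
#'   nuclear-channel intensity.
#' @param noise_sd additive Gaussian noise (clipped to \[0, 1\]) applied to
#'   every channel.
#' @param seed integer seed; all randomness flows from it, and the caller's
#'   RNG state is untouched.
#' @param subject_id,site,section_index metadata carried into the section.
#' @return validated object of class `SectionSpec`.
#' @export
section_spec <- function(width_px = 220L, height_px = 120L, pixel_size_um = 2,
                         epithelium_px = 50L,
                         strata_fractions = c(sb = 0.35, ss = 0.30, sg = 0.15, sc = 0.20),
                         undulation_amplitude_px = 6, undulation_period_px = 110,
                         nuclei_density_per_mm2 = 3000, sc_nuclei_per_mm = 0,
                         stains = list(), isotype_background_level = 0.01,
                         cells = list(),
                         autofluorescence_intensity = 0.6,
                         dermis_autofluorescence = 0.05,
                         sc_autofluorescence = FALSE,
                         nucleus_area_um2 = 20, nucleus_intensity = 0.85,
                         noise_sd = 0, seed = 1L,
                         subject_id = "S1", site = "inner", section_index = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um, epithelium_px = as.integer(epithelium_px),
               strata_fractions = strata_fractions,
               undulation_amplitude_px = undulation_amplitude_px,
               undulation_period_px = undulation_period_px,
               nuclei_density_per_mm2 = nuclei_density_per_mm2,
               sc_nuclei_per_mm = sc_nuclei_per_mm,
               stains = stains, isotype_background_level = isotype_background_level,
               cells = cells,
               autofluorescence_intensity = autofluorescence_intensity,
               dermis_autofluorescence = dermis_autofluorescence,
               sc_autofluorescence = isTRUE(sc_autofluorescence),
               nucleus_area_um2 = nucleus_area_um2,
               nucleus_intensity = nucleus_intensity,
               noise_sd = noise_sd, seed = seed,
               subject_id = subject_id, site = site,
               section_index = as.integer(section_index))
  class(spec) <- "SectionSpec"
  validate_section_spec(spec)
  spec
}

validate_section_spec <- function(spec) {
  pos_int <- function(v, f) if (length(v) != 1L || is.na(v) || v <= 0)
    fail_field(f, "must be a positive integer")
  pos_int(spec$width_px, "width_px"); pos_int(spec$height_px, "height_px")
  pos_int(spec$epithelium_px, "epithelium_px")
  if (!is.numeric(spec$pixel_size_um) || spec$pixel_size_um <= 0) {
    fail_field("pixel_size_um", "must be > 0")
  }
  fr <- spec$strata_fractions
  if (length(fr) != 4L || any(fr < 0)) {
    fail_field("strata_fractions", "must be four nonnegative reals")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    fail_field("strata_fractions", sprintf("must sum to 1 (got %.12f)", sum(fr)))
  }
  if (is.null(names(fr))) names(spec$strata_fractions) <- STRATA
  if (spec$undulation_amplitude_px < 0) fail_field("undulation_amplitude_px", "must be >= 0")
  if (spec$undulation_amplitude_px > 0 && spec$undulation_period_px <= 0) {
    fail_field("undulation_period_px", "must be > 0 when amplitude > 0")
  }
  if (spec$nuclei_density_per_mm2 < 0) fail_field("nuclei_density_per_mm2", "must be >= 0")
  if (spec$sc_nuclei_per_mm < 0) fail_field("sc_nuclei_per_mm", "must be >= 0")
  for (f in c("isotype_background_level", "autofluorescence_intensity",
              "dermis_autofluorescence", "nucleus_intensity")) {
    v <- spec[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail_field(f, "must lie in [0, 1]")
  }
  if (spec$noise_sd < 0) fail_field("noise_sd", "must be >= 0")
  margin_top <- section_margin_top(spec)
  if (margin_top + spec$epithelium_px + ceiling(spec$undulation_amplitude_px) >
      spec$height_px - 3L) {
    fail_field("epithelium_px",
               "epithelium plus undulation does not fit above the dermis margin")
  }
  for (i in seq_along(spec$stains)) {
    st <- spec$stains[[i]]
    f <- sprintf("stains[['%s']]", names(spec$stains)[i])
    if (!is.null(st$band_fraction)) {
      if (st$band_fraction < 0 || st$band_fraction > 1) {
        fail_field(f, "band_fraction must lie in [0, 1]")
      }
      if (any(st$intensity < 0 | st$intensity > 1)) fail_field(f, "intensity must lie in [0, 1]")
      next
    }
    if (is.null(st$pattern) || !all(st$pattern %in% c("membrane", "cytosolic", "none"))) {
      fail_field(f, "pattern entries must be membrane/cytosolic/none")
    }
    if (any(st$intensity < 0 | st$intensity > 1)) fail_field(f, "intensity must lie in [0, 1]")
  }
  for (i in seq_along(spec$cells)) {
    cl <- spec$cells[[i]]
    f <- sprintf("cells[[%d]]", i)
    if (is.null(cl$area_um2) || cl$area_um2 <= 0) fail_field(f, "area_um2 must be > 0")
    if (is.null(cl$intensity) || cl$intensity < 0 || cl$intensity > 1) {
      fail_field(f, "intensity must lie in [0, 1]")
    }
    if (!all(cl$markers %in% c("CD4", "CCR5")) || length(cl$markers) == 0L) {
      fail_field(f, "markers must be a non-empty subset of {CD4, CCR5}")
    }
    if (is.null(cl$compartment) || !cl$compartment %in% c("epidermis", "dermis")) {
      fail_field(f, "compartment must be 'epidermis' or 'dermis'")
    }
  }
  invisible(spec)
}

section_margin_top <- function(spec) max(2L, round(0.08 * spec$height_px))

# deterministic near-round disk: the npx pixels nearest to a center
disk_pixels <- function(cx, cy, npx, nr, nc) {
  R <- ceiling(sqrt(npx / pi)) + 2L
  dx <- rep(-R:R, times = 2L * R + 1L)
  dy <- rep(-R:R, each = 2L * R + 1L)
  d2 <- dx^2 + dy^2
  o <- order(d2, dy, dx)
  xs <- round(cx) + dx[o]; ys <- round(cy) + dy[o]
  keep <- xs >= 1L & xs <= nc & ys >= 1L & ys <= nr
  xs <- xs[keep][seq_len(min(npx, sum(keep)))]
  ys <- ys[keep][seq_len(min(npx, sum(keep)))]
  cbind(x = xs, y = ys)
}

# sample up to n points among candidate pixel indices with a minimum
# center-to-center separation, also kept from `existing` points (greedy
# rejection; deterministic under seed)
place_points <- function(candidates_idx, n, min_sep_px, nr, existing = NULL) {
  if (n <= 0L || length(candidates_idx) == 0L) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  xs <- ((candidates_idx - 1L) %/% nr) + 1L
  ys <- ((candidates_idx - 1L) %% nr) + 1L
  ord <- sample.int(length(candidates_idx))
  ex <- numeric(0); ey <- numeric(0)
  if (!is.null(existing) && nrow(existing)) {
    ex <- existing[, 1L]; ey <- existing[, 2L]
  }
  px <- numeric(0); py <- numeric(0)
  min2 <- min_sep_px^2
  for (i in ord) {
    if (length(px) >= n) break
    if (all((c(px, ex) - xs[i])^2 + (c(py, ey) - ys[i])^2 >= min2)) {
      px <- c(px, xs[i]); py <- c(py, ys[i])
    }
  }
  cbind(x = px, y = py)
}

# nearest-seed (Voronoi) labels for a set of pixels, chunked for memory
voronoi_labels <- function(pix_xy, seeds_xy, chunk = 4000L) {
  n <- nrow(pix_xy)
  lab <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(pix_xy[s:e, 1L], seeds_xy[, 1L], "-")^2 +
      outer(pix_xy[s:e, 2L], seeds_xy[, 2L], "-")^2
    lab[s:e] <- max.col(-d2, ties.method = "first")
  }
  lab
}

#' Generate a synthetic section with ground truth
#'
#' Renders the section described by a [section_spec()] and returns both the
#' multi-channel image and the ground truth every measuring module is tested
#' against. Identical spec (including seed) gives bit-identical output;
#' geometry (masks) is deterministic given the spec, while nucleus and cell
#' placement is stochastic under the seed.
#'
#' @param spec a [section_spec()].
#' @return list with elements `section` (an [image_section()]) and `truth`,
#'   a `GroundTruth` list holding: the true epidermis (cellular strata),
#'   SC, epithelium, dermis and whole-tissue masks; true mean epithelium and
#'   SC thickness (area / length, um); nucleus counts and centroids; noise-free
#'   per-channel coverage percentages and mean intensities over the epidermis;
#'   cell centroid table and in-gate counts by marker and compartment.
#' @export
generate_section <- function(spec) {
  validate_section_spec(spec)
  with_private_seed(spec$seed, {
    nr <- spec$height_px; nc <- spec$width_px; px <- spec$pixel_size_um
    margin_top <- section_margin_top(spec)
    fr <- spec$strata_fractions
    if (is.null(names(fr))) names(fr) <- STRATA
    # band heights from the top: sc, sg, ss, sb (rounded, total preserved)
    hh <- diff(round(cumsum(c(0, fr[c("sc", "sg", "ss", "sb")])) * spec$epithelium_px))
    names(hh) <- c("sc", "sg", "ss", "sb")

    xcols <- seq_len(nc)
    y_base <- margin_top + spec$epithelium_px +
      if (spec$undulation_amplitude_px > 0) {
        round(spec$undulation_amplitude_px *
                sin(2 * pi * (xcols - 1) / spec$undulation_period_px))
      } else 0
    RI <- matrix(seq_len(nr), nr, nc)
    YB <- matrix(y_base, nr, nc, byrow = TRUE)

    epithelium <- RI > margin_top & RI <= YB
    band_top <- margin_top + cumsum(c(0, hh[c("sc", "sg", "ss")]))
    names(band_top) <- c("sc", "sg", "ss", "sb")
    band <- list(
      sc = RI > band_top["sc"] & RI <= band_top["sc"] + hh["sc"],
      sg = RI > band_top["sg"] & RI <= band_top["sg"] + hh["sg"],
      ss = RI > band_top["ss"] & RI <= band_top["ss"] + hh["ss"],
      sb = RI > band_top["sb"] & RI <= YB
    )
    sc_mask <- band$sc
    cellular <- epithelium & !sc_mask
    dermis <- RI > YB
    whole_tissue <- epithelium | dermis

    blank <- matrix(0, nr, nc)
    ch <- list(nuclear = blank, red = blank, farred = blank, blue = blank)

    ch$red[cellular] <- spec$autofluorescence_intensity
    if (spec$sc_autofluorescence) ch$red[sc_mask] <- spec$autofluorescence_intensity
    ch$red[dermis] <- spec$dermis_autofluorescence

    # --- nuclei -----------------------------------------------------------
    r_nuc <- sqrt(spec$nucleus_area_um2 / pi) / px
    npx_nuc <- max(1L, round(spec$nucleus_area_um2 / px^2))
    min_sep <- 2 * r_nuc + 2.5
    nuc_xy <- list()
    placed_all <- cbind(x = numeric(0), y = numeric(0))
    for (s in c("sb", "ss", "sg")) {
      area_mm2 <- sum(band[[s]]) * px^2 / 1e6
      n <- round(spec$nuclei_density_per_mm2 * area_mm2)
      nuc_xy[[s]] <- place_points(which(band[[s]]), n, min_sep, nr,
                                  existing = placed_all)
      placed_all <- rbind(placed_all, nuc_xy[[s]])
    }
    sc_len_mm <- nc * px / 1e3
    n_sc <- round(spec$sc_nuclei_per_mm * sc_len_mm)
    nuc_xy$sc <- place_points(which(sc_mask), n_sc, min_sep, nr,
                              existing = placed_all)
    for (s in names(nuc_xy)) {
      xy <- nuc_xy[[s]]
      for (i in seq_len(nrow(xy))) {
        d <- disk_pixels(xy[i, 1L], xy[i, 2L], npx_nuc, nr, nc)
        ch$nuclear[cbind(d[, "y"], d[, "x"])] <- spec$nucleus_intensity
      }
    }
    cellular_nuclei <- do.call(rbind, nuc_xy[c("sb", "ss", "sg")])

    # --- stains -----------------------------------------------------------
    for (chan in names(spec$stains)) {
      st <- spec$stains[[chan]]
      if (is.null(ch[[chan]])) ch[[chan]] <- blank
      if (!is.null(st$band_fraction)) {
        # uniform band occupying the top (SC-adjacent) fraction of the
        # cellular epidermis
        depth <- band_top["sg"] + st$band_fraction * (YB - band_top["sg"])
        sel <- cellular & RI <= depth
        ch[[chan]][sel] <- pmax(ch[[chan]][sel], st$intensity[1L])
        next
      }
      inten <- st$intensity
      if (length(inten) == 1L) inten <- setNames(rep(inten, 4L), STRATA)
      for (s in STRATA) {
        pat <- st$pattern[[s]]
        if (is.null(pat) || pat == "none" || inten[[s]] <= 0) next
        bm <- band[[s]]
        if (!any(bm)) next
        if (pat == "cytosolic") {
          ch[[chan]][bm] <- pmax(ch[[chan]][bm], inten[[s]])
        } else { # membrane: Voronoi cell borders seeded at stratum nuclei
          seeds <- nuc_xy[[s]]
          if (is.null(seeds) || nrow(seeds) < 3L) {
            gx <- seq(3, nc - 2, by = 6); gy <- which(apply(bm, 1, any))
            gy <- gy[seq(1, length(gy), by = max(1L, length(gy) %/% 3L))]
            seeds <- as.matrix(expand.grid(x = gx, y = gy))
          }
          idx <- which(bm)
          pxy <- cbind(((idx - 1L) %/% nr) + 1L, ((idx - 1L) %% nr) + 1L)
          lab <- voronoi_labels(pxy, seeds)
          LM <- matrix(0L, nr, nc)
          LM[idx] <- lab
          pad <- function(m, dr, dc) {
            out <- matrix(0L, nr, nc)
            rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
            out[rs, cs] <- m[rs - dr, cs - dc]
            out
          }
          border <- matrix(FALSE, nr, nc)
          for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
            nbr <- pad(LM, sh[1], sh[2])
            border <- border | (bm & nbr > 0L & nbr != LM)
          }
          ch[[chan]][border] <- pmax(ch[[chan]][border], inten[[s]])
        }
      }
    }

    # --- infiltrating cells ----------------------------------------------
    occupied <- matrix(FALSE, nr, nc)
    comp_mask <- list(epidermis = cellular, dermis = dermis)
    cell_rows <- list()
    for (i in seq_along(spec$cells)) {
      cl <- spec$cells[[i]]
      npx_cell <- max(1L, round(cl$area_um2 / px^2))
      cm <- comp_mask[[cl$compartment]]
      cand <- which(cm)
      if (length(cand) == 0L) stop("no room for cell in compartment ", cl$compartment)
      placed <- FALSE
      ord <- sample(cand, min(length(cand), 400L))
      for (j in ord) {
        cx <- ((j - 1L) %/% nr) + 1L; cy <- ((j - 1L) %% nr) + 1L
        d <- disk_pixels(cx, cy, npx_cell, nr, nc)
        if (nrow(d) < npx_cell) next
        if (!all(cm[cbind(d[, "y"], d[, "x"])])) next
        # require a 1-px clear halo so separate cells never 8-touch
        halo_ok <- TRUE
        for (dd in -1:1) for (ee in -1:1) {
          yy <- pmin(pmax(d[, "y"] + dd, 1L), nr); xx <- pmin(pmax(d[, "x"] + ee, 1L), nc)
          if (any(occupied[cbind(yy, xx)])) { halo_ok <- FALSE; break }
        }
        if (!halo_ok) next
        occupied[cbind(d[, "y"], d[, "x"])] <- TRUE
        if ("CD4" %in% cl$markers) {
          ch$blue[cbind(d[, "y"], d[, "x"])] <- pmax(ch$blue[cbind(d[, "y"], d[, "x"])], cl$intensity)
        }
        if ("CCR5" %in% cl$markers) {
          ch$farred[cbind(d[, "y"], d[, "x"])] <- pmax(ch$farred[cbind(d[, "y"], d[, "x"])], cl$intensity)
        }
        cell_rows[[length(cell_rows) + 1L]] <- data.frame(
          x = mean(d[, "x"]), y = mean(d[, "y"]),
          area_um2 = nrow(d) * px^2,
          markers = paste(intersect(c("CD4", "CCR5"), cl$markers), collapse = "+"),
          compartment = cl$compartment, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place cell ", i, " without overlap; skipped")
    }
    cell_df <- if (length(cell_rows)) do.call(rbind, cell_rows) else
      data.frame(x = numeric(0), y = numeric(0), area_um2 = numeric(0),
                 markers = character(0), compartment = character(0),
                 stringsAsFactors = FALSE)

    # --- isotype channels -------------------------------------------------
    ch$blue_isotype <- matrix(spec$isotype_background_level, nr, nc)
    ch$farred_isotype <- matrix(spec$isotype_background_level, nr, nc)

    # --- noise-free truth summaries --------------------------------------
    stain_channels <- unique(c(names(spec$stains), "farred", "blue"))
    cov_pct <- vapply(stain_channels, function(cn) 100 * mean(ch[[cn]][cellular] > 0), numeric(1))
    mean_int <- vapply(stain_channels, function(cn) mean(ch[[cn]][cellular]), numeric(1))

    gate_counts <- counts_by_gate(cell_df)

    truth <- structure(list(
      true_epidermis_mask = cellular,
      true_sc_mask = sc_mask,
      true_epithelium_mask = epithelium,
      true_dermis_mask = dermis,
      true_whole_tissue_mask = whole_tissue,
      true_mean_thickness_um = sum(epithelium) / nc * px,
      true_sc_thickness_um = sum(sc_mask) / nc * px,
      true_nuclei_count = nrow(cellular_nuclei),
      true_sc_nuclei_count = nrow(nuc_xy$sc),
      nuclei_centroids = cellular_nuclei,
      sc_nuclei_centroids = nuc_xy$sc,
      true_coverage_pct = cov_pct,
      true_mean_intensity = mean_int,
      true_cell_centroids = cell_df,
      true_counts_by_gate = gate_counts,
      band_heights_px = hh,
      pixel_size_um = px
    ), class = "GroundTruth")

    if (spec$noise_sd > 0) {
      ch <- lapply(ch, function(m) clip01(m + rnorm(length(m), 0, spec$noise_sd)))
    }

    section <- image_section(ch, pixel_size_um = px, subject_id = spec$subject_id,
                             site = spec$site, section_index = spec$section_index)
    list(section = section, truth = truth)
  })
}

#' In-gate cell counts by marker and compartment
#'
#' @param cell_df ground-truth cell table (`x`, `y`, `area_um2`, `markers`,
#'   `compartment`).
#' @param area_min_um2,area_max_um2 inclusive area gate, um^2.
#' @return data.frame with columns `marker`, `compartment`, `count`; markers
#'   are `CD4`, `CCR5` (single positives included in both) and `CD4+CCR5+`.
#' @export
counts_by_gate <- function(cell_df, area_min_um2 = 10, area_max_um2 = 33) {
  in_gate <- cell_df$area_um2 >= area_min_um2 & cell_df$area_um2 <= area_max_um2
  out <- expand.grid(marker = c("CD4", "CCR5", "CD4+CCR5+"),
                     compartment = c("epidermis", "dermis"),
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(mk, cp) {
    sel <- in_gate & cell_df$compartment == cp
    if (mk == "CD4+CCR5+") sum(sel & cell_df$markers == "CD4+CCR5")
    else sum(sel & grepl(mk, cell_df$markers, fixed = TRUE))
  }, out$marker, out$compartment)
  out
}
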