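# Size-gated cell detection, densities, isotype subtraction, double
# positives.

make_blob_image <- function(areas_px, intensity = 0.5, nr = 60, nc = 120) {
  ch <- matrix(0, nr, nc)
  x0 <- 10
  for (a in areas_px) {
    w <- ceiling(sqrt(a))
    pix <- 0
    for (col in seq_len(w + 2)) {
      for (row in seq_len(w + 2)) {
        if (pix < a) { ch[20 + row, x0 + col] <- intensity; pix <- pix + 1 }
      }
    }
    x0 <- x0 + w + 8
  }
  ch
}

test_that("the 10-33 um^2 area gate passes only mid-sized blobs", {
  px <- 1 # 1 um/px so areas in px == areas in um^2
  ch <- make_blob_image(c(5, 20, 50))
  region <- region_mask(matrix(TRUE, 60, 120), "whole_tissue", px)
  det <- detect_cells(ch, region, cell_gate("CD4"))
  expect_equal(det$count, 1)
  expect_equal(det$centroids$area_um2, 20)
})

test_that("blobs below the aggregate intensity threshold are rejected", {
  region <- region_mask(matrix(TRUE, 60, 120), "whole_tissue", 1)
  dim_blob <- make_blob_image(20, intensity = 0.02)
  expect_equal(detect_cells(dim_blob, region, cell_gate("CD4"))$count, 0)
  # 0.025 < intensity < 0.03 separates the two marker gates
  mid_blob <- make_blob_image(20, intensity = 0.028)
  expect_equal(detect_cells(mid_blob, region, cell_gate("CD4"))$count, 0)
  expect_equal(detect_cells(mid_blob, region, cell_gate("CCR5"))$count, 1)
})

test_that("noise-free synthetic cells are recovered with centroids within 1 px", {
  cells <- rep(list(list(area_um2 = 20, intensity = 0.5, markers = "CCR5",
                         compartment = "epidermis")), 30)
  g <- generate_section(section_spec(cells = cells, noise_sd = 0, seed = 17,
                                     width_px = 300))
  px <- g$section$pixel_size_um
  epi <- region_mask(g$truth$true_epidermis_mask, "epidermis", px)
  det <- detect_cells(get_channel(g$section, "farred"), epi, cell_gate("CCR5"))
  truth <- g$truth$true_cell_centroids
  expect_equal(det$count, nrow(truth))
  d <- sqrt(outer(det$centroids$x, truth$x, "-")^2 +
              outer(det$centroids$y, truth$y, "-")^2)
  expect_true(all(apply(d, 1, min) <= 1))
})

test_that("cell density divides count by region area in mm^2", {
  m <- matrix(FALSE, 100, 100); m[1:50, 1:100] <- TRUE # 5000 px
  r <- region_mask(m, "whole_tissue", 10) # 100 um^2/px -> 0.5 mm^2
  expect_equal(cell_density(10, r), 20)
  expect_equal(cell_density(0, r), 0)
  expect_error(cell_density(-1, r), "count")
})

test_that("density over a disjoint union of equal-area regions is the mean of the parts", {
  a <- matrix(FALSE, 40, 40); a[1:20, ] <- TRUE
  b <- matrix(FALSE, 40, 40); b[21:40, ] <- TRUE
  ra <- region_mask(a, "whole_tissue", 5)
  rb <- region_mask(b, "whole_tissue", 5)
  ru <- region_mask(a | b, "whole_tissue", 5)
  da <- cell_density(6, ra); db <- cell_density(10, rb)
  expect_equal(cell_density(16, ru), (da + db) / 2)
})

test_that("compartment densities recover generator truth", {
  cells <- c(rep(list(list(area_um2 = 20, intensity = 0.5, markers = "CCR5",
                           compartment = "epidermis")), 8),
             rep(list(list(area_um2 = 20, intensity = 0.5, markers = "CCR5",
                           compartment = "dermis")), 12))
  g <- generate_section(section_spec(cells = cells, noise_sd = 0, seed = 23))
  px <- g$section$pixel_size_um
  epi <- region_mask(g$truth$true_epidermis_mask, "epidermis", px)
  whole <- region_mask(g$truth$true_whole_tissue_mask, "whole_tissue", px)
  ch <- get_channel(g$section, "farred")
  det_epi <- detect_cells(ch, epi, cell_gate("CCR5"))
  det_whole <- detect_cells(ch, whole, cell_gate("CCR5"))
  cbg <- g$truth$true_counts_by_gate
  n_epi_truth <- cbg$count[cbg$marker == "CCR5" & cbg$compartment == "epidermis"]
  expect_equal(det_epi$count, n_epi_truth)
  expect_equal(det_whole$count, sum(cbg$count[cbg$marker == "CCR5"]))
  expect_equal(cell_density(det_epi$count, epi),
               n_epi_truth / region_area_mm2(epi))
})

test_that("isotype density subtraction floors at zero and checks provenance", {
  raw <- density_result("S1", "inner", "CCR5", "epidermis", 21.34)
  expect_equal(subtract_isotype_density(raw, 4.2)$corrected_density, 17.14)
  expect_equal(subtract_isotype_density(raw, 30)$corrected_density, 0)
  expect_equal(subtract_isotype_density(raw, 0)$corrected_density, 21.34)
  iso_other <- density_result("S2", "inner", "IgG", "epidermis", 4.2)
  expect_error(subtract_isotype_density(raw, iso_other), "different subject")
  iso_comp <- density_result("S1", "inner", "IgG", "whole_tissue", 4.2)
  expect_error(subtract_isotype_density(raw, iso_comp), "compartment")
})

test_that("widening the area gate or lowering the threshold never loses cells", {
  g <- generate_section(section_spec(
    cells = lapply(c(8, 12, 20, 28, 40), function(a)
      list(area_um2 = a, intensity = 0.5, markers = "CD4", compartment = "epidermis")),
    noise_sd = 0, seed = 29))
  px <- g$section$pixel_size_um
  epi <- region_mask(g$truth$true_epidermis_mask, "epidermis", px)
  ch <- get_channel(g$section, "blue")
  n_narrow <- detect_cells(ch, epi, cell_gate(NULL, 12, 26, 0.03))$count
  n_wide <- detect_cells(ch, epi, cell_gate(NULL, 6, 45, 0.03))$count
  expect_gte(n_wide, n_narrow)
  n_low <- detect_cells(ch, epi, cell_gate(NULL, 10, 33, 0.01))$count
  n_high <- detect_cells(ch, epi, cell_gate(NULL, 10, 33, 0.45))$count
  n_higher <- detect_cells(ch, epi, cell_gate(NULL, 10, 33, 0.6))$count
  expect_gte(n_low, n_high)
  expect_gte(n_high, n_higher)
})

test_that("double positives: identical lists pair fully, distant lists not at all", {
  pts <- cbind(x_um = c(10, 20, 30), y_um = c(5, 5, 5))
  expect_equal(double_positive(pts, pts, 3), 3)
  far <- cbind(x_um = c(100, 200), y_um = c(50, 50))
  expect_equal(double_positive(pts, far, 3), 0)
  expect_equal(double_positive(pts[0, , drop = FALSE], pts, 3), 0)
})

test_that("double positive count never exceeds the smaller detection list", {
  withr::local_seed(5)
  for (i in 1:25) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    a <- cbind(runif(na, 0, 30), runif(na, 0, 30))
    b <- cbind(runif(nb, 0, 30), runif(nb, 0, 30))
    expect_lte(double_positive(a, b, 5), min(na, nb))
  }
})

test_that("bipartite pairing equals the brute-force optimum on small inputs", {
  withr::local_seed(6)
  for (i in 1:40) {
    na <- sample(1:7, 1); nb <- sample(1:7, 1)
    a <- cbind(runif(na, 0, 12), runif(na, 0, 12))
    b <- cbind(runif(nb, 0, 12), runif(nb, 0, 12))
    r <- runif(1, 1, 6)
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    expect_equal(double_positive(a, b, r), brute_matching(d2, r))
  }
})

test_that("double-positive truth is recovered from synthetic sections", {
  cells <- c(rep(list(list(area_um2 = 20, intensity = 0.5,
                           markers = c("CD4", "CCR5"), compartment = "epidermis")), 5),
             rep(list(list(area_um2 = 20, intensity = 0.5, markers = "CD4",
                           compartment = "epidermis")), 4),
             rep(list(list(area_um2 = 20, intensity = 0.5, markers = "CCR5",
                           compartment = "epidermis")), 3))
  g <- generate_section(section_spec(cells = cells, noise_sd = 0, seed = 37,
                                     width_px = 300))
  px <- g$section$pixel_size_um
  epi <- region_mask(g$truth$true_epidermis_mask, "epidermis", px)
  cd4 <- detect_cells(get_channel(g$section, "blue"), epi, cell_gate("CD4"))
  ccr5 <- detect_cells(get_channel(g$section, "farred"), epi, cell_gate("CCR5"))
  expect_equal(cd4$count, 9)
  expect_equal(ccr5$count, 8)
  expect_equal(double_positive(cd4$centroids, ccr5$centroids, 3), 5)
})
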