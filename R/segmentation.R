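# Epidermis segmentation, outline-mask ingestion, and nucleus detection.

#' Segment the epidermis from red-channel autofluorescence
#'
#' The autofluorescence of the cellular epidermis on the red channel outlines
#' the epidermis area: pixels are split into foreground/background by a
#' threshold (Otsu by default), objects smaller than `min_object_area_um2`
#' are discarded, and holes are filled. 8-neighbor connectivity throughout.
#'
#' @param section an [image_section()] with a red channel.
#' @param method `"otsu"` (default) or `"manual"` (requires `threshold`).
#' @param threshold manual threshold in AU \[0, 1\]; overrides `method`.
#' @param channel channel name carrying the autofluorescence (default
#'   `"red"`).
#' @param min_object_area_um2 objects below this area are removed before hole
#'   filling (default 500; the epidermis is a single large structure).
#' @param fill_holes fill enclosed background regions (default TRUE).
#' @return a [region_mask()] with role `"epidermis"`.
#' @export
segment_epidermis <- function(section, method = c("otsu", "manual"),
                              threshold = NULL, channel = "red",
                              min_object_area_um2 = 500, fill_holes = TRUE) {
  method <- match.arg(method)
  ch <- get_channel(section, channel)
  px <- section$pixel_size_um
  t <- if (!is.null(threshold)) {
    if (threshold < 0 || threshold > 1) fail_field("threshold", "must lie in [0, 1]")
    threshold
  } else if (method == "otsu") {
    EBImage::otsu(ch, range = c(0, 1))
  } else {
    stop("method 'manual' requires `threshold`", call. = FALSE)
  }
  fg <- ch > t
  if (!any(fg)) stop("no epidermis detected: empty foreground after thresholding",
                     call. = FALSE)
  lab <- label_components(fg)
  st <- component_stats(lab)
  keep <- st$label[st$area_px * px^2 >= min_object_area_um2]
  if (length(keep) == 0L) {
    stop("no epidermis detected: all foreground objects below minimum area",
         call. = FALSE)
  }
  mask <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  if (fill_holes) {
    mask <- as.matrix(EBImage::fillHull(mask * 1)) > 0.5
  }
  region_mask(mask, "epidermis", px)
}

#' Load an externally provided outline mask
#'
#' Stands in for manual outlining of the epithelium or SC on H&E images.
#' The mask is trusted input and preserved verbatim (no cleanup).
#'
#' @param path single-channel TIFF; pixels > 0.5 are inside the region.
#' @param region_role `"epidermis"`, `"stratum_corneum"` or `"whole_tissue"`.
#' @param pixel_size_um pixel edge, micrometers.
#' @param expected_dim optional `c(rows, cols)`; a mismatch is an error.
#' @return a [region_mask()].
#' @export
load_outline_mask <- function(path, region_role = "epidermis", pixel_size_um = 1,
                              expected_dim = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file '%s' does not exist", path),
                               call. = FALSE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  if (!is.null(expected_dim) && !identical(dim(m), as.integer(expected_dim))) {
    stop(sprintf("mask dimensions %dx%d do not match expected %dx%d",
                 nrow(m), ncol(m), expected_dim[1], expected_dim[2]), call. = FALSE)
  }
  mask <- m > 0.5
  if (!any(mask)) stop("empty region: mask file contains no foreground pixels",
                       call. = FALSE)
  region_mask(mask, region_role, pixel_size_um)
}

#' Write a RegionMask as a single-channel TIFF (0/1)
#'
#' @param region a [region_mask()].
#' @param path output TIFF path (written atomically).
#' @return the path, invisibly.
#' @export
write_mask <- function(region, path) {
  stopifnot(inherits(region, "RegionMask"))
  atomic_write(function(p) tiff::writeTIFF(region$mask * 1, p, bits.per.sample = 8L),
               path)
}

#' Detect and count nuclei within a region
#'
#' Connected nuclear-channel objects (8-connectivity) above a threshold are
#' counted when their area reaches `min_area_um2` and their centroid lies
#' inside `within`. Touching nuclei that merge into one blob count once: no
#' declumping is attempted (documented limitation).
#'
#' @param section an [image_section()] with a nuclear channel.
#' @param within a [region_mask()] restricting the count.
#' @param channel nuclear channel name (default `"nuclear"`).
#' @param threshold manual threshold in AU; default Otsu on the channel.
#' @param min_area_um2 minimum object area (default 5, rejects single-pixel
#'   noise).
#' @return list with `count` (integer) and `centroids` (data.frame `x`, `y`
#'   in pixel coordinates, `area_um2`). Zero nuclei is a valid result.
#' @export
detect_nuclei <- function(section, within, channel = "nuclear", threshold = NULL,
                          min_area_um2 = 5) {
  ch <- get_channel(section, channel)
  stopifnot(inherits(within, "RegionMask"))
  if (!identical(dim(ch), dim(within$mask))) {
    stop("region mask dimensions do not match the section", call. = FALSE)
  }
  px <- section$pixel_size_um
  t <- if (is.null(threshold)) {
    if (max(ch) == min(ch)) 1 else EBImage::otsu(ch, range = c(0, 1))
  } else threshold
  fg <- ch > t
  if (!any(fg)) {
    return(list(count = 0L,
                centroids = data.frame(x = numeric(0), y = numeric(0),
                                       area_um2 = numeric(0))))
  }
  st <- component_stats(label_components(fg))
  st <- st[st$area_px * px^2 >= min_area_um2, , drop = FALSE]
  inside <- vapply(seq_len(nrow(st)), function(i) {
    within$mask[round(st$y[i]), round(st$x[i])]
  }, logical(1))
  st <- st[inside, , drop = FALSE]
  list(count = nrow(st),
       centroids = data.frame(x = st$x, y = st$y, area_um2 = st$area_px * px^2))
}
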