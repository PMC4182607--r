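# Core S3 containers: ImageSection and RegionMask.

#' Construct an ImageSection
#'
#' A multi-channel fluorescence (or transmitted-light) raster with pixel-size
#' metadata. All channel intensities are arbitrary units scaled to \[0, 1\]
#' (0 = lowest, 1 = highest); all channels share dimensions.
#'
#' @param channels named list of numeric matrices, one per channel (e.g.
#'   `nuclear`, `red`, `farred`, `blue`, plus isotype-control channels).
#' @param pixel_size_um physical size of one pixel edge, micrometers.
#' @param subject_id subject identifier.
#' @param site anatomical site, `"inner"` or `"outer"`.
#' @param section_index integer index of the section within the subject/site.
#' @return object of class `ImageSection`.
#' @export
image_section <- function(channels, pixel_size_um, subject_id = "S1",
                          site = c("inner", "outer"), section_index = 1L) {
  site <- match.arg(site)
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    fail_field("channels", "must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1)))) {
    fail_field("channels", "every channel must be a numeric matrix")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    fail_field("channels", "all channel rasters must share dimensions")
  }
  rng <- range(vapply(channels, range, numeric(2)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    fail_field("channels", "intensities must lie within [0, 1]")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0) {
    fail_field("pixel_size_um", "must be a positive scalar")
  }
  structure(
    list(channels = lapply(channels, clip01), pixel_size_um = pixel_size_um,
         subject_id = as.character(subject_id), site = site,
         section_index = as.integer(section_index)),
    class = "ImageSection"
  )
}

#' @export
print.ImageSection <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("ImageSection %s/%s section %d: %d x %d px (%.3g um/px)\n",
              x$subject_id, x$site, x$section_index, d[1], d[2], x$pixel_size_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Fetch a channel from an ImageSection
#'
#' @param section an [image_section()].
#' @param channel channel name.
#' @return numeric matrix.
#' @export
get_channel <- function(section, channel) {
  stopifnot(inherits(section, "ImageSection"))
  if (!channel %in% names(section$channels)) {
    stop(sprintf("channel '%s' not present in section (has: %s)", channel,
                 paste(names(section$channels), collapse = ", ")), call. = FALSE)
  }
  section$channels[[channel]]
}

#' Construct a RegionMask
#'
#' A binary region of interest (epidermis, stratum corneum, or whole tissue)
#' with its pixel scale. Region area in um^2 is pixel count times
#' `pixel_size_um^2`.
#'
#' @param mask logical matrix (TRUE = inside region).
#' @param region_role one of `"epidermis"`, `"stratum_corneum"`,
#'   `"whole_tissue"`.
#' @param pixel_size_um pixel edge length, micrometers.
#' @param allow_empty allow an all-FALSE mask (default FALSE: empty regions
#'   are an error, matching the segmentation contract).
#' @return object of class `RegionMask`.
#' @export
region_mask <- function(mask, region_role = c("epidermis", "stratum_corneum",
                                              "whole_tissue"),
                        pixel_size_um = 1, allow_empty = FALSE) {
  region_role <- match.arg(region_role)
  if (!is.matrix(mask)) fail_field("mask", "must be a matrix")
  if (!is.logical(mask)) mask <- mask > 0.5
  if (!allow_empty && !any(mask)) fail_field("mask", "empty region")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0) {
    fail_field("pixel_size_um", "must be a positive scalar")
  }
  structure(list(mask = mask, region_role = region_role,
                 pixel_size_um = pixel_size_um),
            class = "RegionMask")
}

#' @export
print.RegionMask <- function(x, ...) {
  cat(sprintf("RegionMask [%s]: %d x %d px, %d px in region (%.4g mm^2)\n",
              x$region_role, nrow(x$mask), ncol(x$mask), sum(x$mask),
              region_area_mm2(x)))
  invisible(x)
}

#' Region area in mm^2
#'
#' @param region a [region_mask()].
#' @return area in square millimeters.
#' @export
region_area_mm2 <- function(region) {
  stopifnot(inherits(region, "RegionMask"))
  sum(region$mask) * region$pixel_size_um^2 / 1e6
}

# coerce a RegionMask or logical matrix to (mask, pixel_size) internally
as_mask <- function(x, pixel_size_um = NULL) {
  if (inherits(x, "RegionMask")) return(list(mask = x$mask, px = x$pixel_size_um))
  if (is.matrix(x)) {
    if (is.null(pixel_size_um)) pixel_size_um <- 1
    return(list(mask = if (is.logical(x)) x else x > 0.5, px = pixel_size_um))
  }
  stop("expected a RegionMask or a logical matrix", call. = FALSE)
}
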