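# Section TIFF I/O with JSON sidecars.
#
# The JSON sidecar (not TIFF tags) is the source of truth for pixel size and
# metadata, avoiding dialect ambiguity across TIFF writers. Channels are
# stored as TIFF pages in the sidecar's declared order.

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path, ignore.case = TRUE)

#' Write an ImageSection to a multi-page TIFF + JSON sidecar
#'
#' One 32-bit float page per channel, in the order listed in the sidecar's
#' `channels` field. Both files are written atomically.
#'
#' @param section an [image_section()].
#' @param path output TIFF path; the sidecar gets the same path with a
#'   `.json` extension.
#' @return the TIFF path, invisibly.
#' @export
write_section <- function(section, path) {
  stopifnot(inherits(section, "ImageSection"))
  atomic_write(function(p) {
    tiff::writeTIFF(unname(section$channels), p, bits.per.sample = 32L)
  }, path)
  meta <- list(channels = names(section$channels),
               pixel_size_um = section$pixel_size_um,
               subject_id = section$subject_id, site = section$site,
               section_index = section$section_index)
  atomic_write(function(p) {
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
  }, sidecar_path(path))
  invisible(path)
}

#' Read an ImageSection from a TIFF + JSON sidecar
#'
#' Integer TIFFs are rescaled to \[0, 1\] by their sample maximum (the tiff
#' reader's native convention); float pages are taken as-is and validated to
#' lie in \[0, 1\].
#'
#' @param path TIFF path with an accompanying `.json` sidecar.
#' @return an [image_section()].
#' @export
read_section <- function(path) {
  if (!file.exists(path)) stop(sprintf("section file '%s' does not exist", path),
                               call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("missing JSON sidecar '%s' (pixel size and channel names required)", sc),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("channels", "pixel_size_um", "subject_id", "site", "section_index")) {
    if (is.null(meta[[f]])) stop(sprintf("sidecar missing field '%s'", f), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$channels)) {
    stop(sprintf("TIFF has %d page(s) but sidecar declares %d channel(s)",
                 length(pages), length(meta$channels)), call. = FALSE)
  }
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    if (min(m) < -1e-6 || max(m) > 1 + 1e-6) {
      stop("channel intensities outside [0, 1] after scaling", call. = FALSE)
    }
    clip01(m)
  })
  names(pages) <- meta$channels
  image_section(pages, pixel_size_um = meta$pixel_size_um,
                subject_id = meta$subject_id, site = meta$site,
                section_index = meta$section_index)
}

#' Write a data.frame as CSV, atomically
#'
#' @param df data.frame.
#' @param path output path; the write is write-then-rename so interrupted
#'   runs never leave truncated files.
#' @return the path, invisibly.
#' @export
write_csv_atomic <- function(df, path) {
  atomic_write(function(p) write.csv(df, p, row.names = FALSE), path)
}
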