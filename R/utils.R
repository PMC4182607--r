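# Internal helpers shared across modules.

#' Evaluate code with a private, restored RNG state
#'
#' All generator randomness flows from an explicit seed; the caller's global
#' RNG state is untouched.
#' @noRd
with_private_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' 8-connected component labeling
#'
#' Thin wrapper around the compiled two-pass union-find labeler. 8-neighbor
#' connectivity is the single convention used throughout the package.
#'
#' @param x logical matrix (TRUE = foreground).
#' @return integer matrix of component labels, 0 = background.
#' @export
label_components <- function(x) {
  stopifnot(is.matrix(x))
  if (!is.logical(x)) x <- x > 0
  cc_label8(x)
}

#' Component areas and centroids from a label matrix
#'
#' Centroids are pixel-center coordinates: x = column index, y = row index.
#' @noRd
component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      x = numeric(), y = numeric()))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l, nbins = n)
  data.frame(
    label = seq_len(n),
    area_px = area,
    x = as.numeric(rowsum(as.numeric(cc), l, reorder = TRUE)) / area,
    y = as.numeric(rowsum(as.numeric(rr), l, reorder = TRUE)) / area
  )
}

#' Otsu threshold of a numeric vector on [0, 1]
#'
#' Histogram-based Otsu used where only the pixels inside a mask are
#' thresholded (EBImage's otsu operates on whole images).
#' @noRd
otsu_vector <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite pixels to threshold", call. = FALSE)
  h <- tabulate(pmin(pmax(floor(x * levels) + 1L, 1L), levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  bcv <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' Mean-filter-free binary erosion test: boundary pixels of a mask
#' @noRd
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !interior
}

#' Clip a numeric array into [0, 1]
#' @noRd
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Stop with a validation error naming the offending field
#' @noRd
fail_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Atomic file write: write to a sibling temp file, then rename
#' @noRd
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp", basename(path)))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop(sprintf("atomic rename to '%s' failed", path), call. = FALSE)
  }
  invisible(path)
}
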