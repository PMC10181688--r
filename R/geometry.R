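#' Probe geometry for a continuous-wave fNIRS montage
#'
#' Describes an optode montage: source and detector positions in a common 3D
#' frame, and the measurement channels formed by source-detector pairs at a
#' given wavelength. The position of a channel is defined as the midpoint of
#' its source and detector, so the two wavelength channels of one
#' source-detector pair share a single coordinate.
#'
#' @param sources numeric matrix (n_sources x 3) of source positions.
#' @param detectors numeric matrix (n_detectors x 3) of detector positions.
#' @param channels data frame with integer columns `source`, `detector` and a
#'   numeric `wavelength` (nm), one row per measurement channel.
#'
#' @return An object of class `probe_geometry` with fields `sources`,
#'   `detectors`, `channels` and `coords` (L x 3 channel midpoints).
#' @examples
#' g <- probe_geometry(
#'   sources   = rbind(c(0, 0, 0)),
#'   detectors = rbind(c(3, 0, 0)),
#'   channels  = data.frame(source = c(1, 1), detector = c(1, 1),
#'                          wavelength = c(760, 850))
#' )
#' channel_midpoints(g)
#' @export
probe_geometry <- function(sources, detectors, channels) {
  sources <- as_coord_matrix(sources, "sources")
  detectors <- as_coord_matrix(detectors, "detectors")
  channels <- as.data.frame(channels)
  need <- c("source", "detector", "wavelength")
  if (!all(need %in% names(channels))) {
    abort_validation("`channels` needs columns source, detector, wavelength")
  }
  if (nrow(channels) == 0L) {
    abort_validation("`channels` must contain at least one channel")
  }
  channels$source <- as.integer(channels$source)
  channels$detector <- as.integer(channels$detector)
  channels$wavelength <- as.numeric(channels$wavelength)
  bad_s <- channels$source < 1L | channels$source > nrow(sources)
  bad_d <- channels$detector < 1L | channels$detector > nrow(detectors)
  if (any(bad_s | bad_d, na.rm = TRUE) || anyNA(channels$source) ||
      anyNA(channels$detector)) {
    abort_data(sprintf(
      "channel rows %s reference a nonexistent source or detector",
      paste(which(bad_s | bad_d), collapse = ", ")
    ))
  }
  out <- structure(
    list(sources = sources, detectors = detectors, channels = channels),
    class = "probe_geometry"
  )
  out$coords <- channel_midpoints(out)
  out
}

as_coord_matrix <- function(x, name) {
  x <- as.matrix(x)
  if (!is.numeric(x) || ncol(x) != 3L || anyNA(x)) {
    abort_validation(sprintf("`%s` must be a numeric n x 3 matrix", name))
  }
  storage.mode(x) <- "double"
  dimnames(x) <- list(NULL, c("x", "y", "z"))
  x
}

#' Channel coordinates as source-detector midpoints
#'
#' @param geometry a [probe_geometry()].
#' @return L x 3 matrix; row k is (source_k + detector_k) / 2.
#' @export
channel_midpoints <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  (geometry$sources[geometry$channels$source, , drop = FALSE] +
     geometry$detectors[geometry$channels$detector, , drop = FALSE]) / 2
}

#' Source-detector separation per channel
#'
#' Euclidean distance between the source and detector of each channel, in the
#' montage's length units (cm by convention; the modified Beer-Lambert step
#' assumes cm).
#'
#' @inheritParams channel_midpoints
#' @return numeric vector of length L.
#' @export
channel_distances <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  d <- geometry$sources[geometry$channels$source, , drop = FALSE] -
    geometry$detectors[geometry$channels$detector, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf(
    "<probe_geometry> %d sources, %d detectors, %d channels (%s nm)\n",
    nrow(x$sources), nrow(x$detectors), nrow(x$channels),
    paste(sort(unique(x$channels$wavelength)), collapse = "/")
  ))
  invisible(x)
}
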