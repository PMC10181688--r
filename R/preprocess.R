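#' Hemoglobin concentration-change series
#'
#' Per-channel oxy- and deoxy-hemoglobin concentration changes in micromolar,
#' after the modified Beer-Lambert conversion. One row per source-detector
#' pair (the two wavelength channels collapse into one hemoglobin channel).
#'
#' @param hbo,hbr numeric matrices (pairs x time), micromolar.
#' @param fs sampling frequency in Hz.
#' @param coords pairs x 3 channel coordinates.
#' @param condition run condition label.
#' @param events event marker data frame (onset, duration, label).
#' @param pairs data frame with `source`, `detector` per row.
#' @return An object of class `hb_series`.
#' @export
hb_series <- function(hbo, hbr, fs, coords, condition = "unknown",
                      events = empty_events(), pairs = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr))) {
    abort_validation("`hbo` and `hbr` must share shape and channel ordering")
  }
  if (anyNA(hbo) || anyNA(hbr) || any(!is.finite(hbo)) || any(!is.finite(hbr))) {
    abort_data("hemoglobin series must be finite everywhere")
  }
  stopifnot_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  coords <- as_coord_matrix(coords, "coords")
  if (nrow(coords) != nrow(hbo)) {
    abort_validation("`coords` must have one row per hemoglobin channel")
  }
  structure(
    list(hbo = hbo, hbr = hbr, fs = fs, coords = coords,
         condition = as.character(condition), events = as_events(events),
         pairs = pairs),
    class = "hb_series"
  )
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf(
    "<hb_series> %d channels x %d samples @ %g Hz (uM), condition '%s'\n",
    nrow(x$hbo), ncol(x$hbo), x$fs, x$condition
  ))
  invisible(x)
}

#' Optical density change from raw intensities
#'
#' \eqn{\Delta OD_k(t) = -\log(I_k(t) / \bar I_k)} with the natural logarithm
#' and \eqn{\bar I_k} the within-run temporal mean of channel k. Invariant to
#' global intensity scaling.
#'
#' @param recording an [fnirs_recording()].
#' @return channels x time matrix of optical density changes.
#' @export
optical_density <- function(recording) {
  stopifnot(inherits(recording, "fnirs_recording"))
  I <- recording$intensity
  if (any(I <= 0)) {
    abort_data(sprintf("nonpositive intensity in channel(s) %s",
                       paste(which(rowSums(I <= 0) > 0), collapse = ", ")))
  }
  -log(I / rowMeans(I))
}

#' Default extinction coefficients for 760/850 nm
#'
#' Molar extinction coefficients of oxy- and deoxy-hemoglobin at the two
#' operating wavelengths, in 1/(mM cm) (compiled Prahl values as used across
#' continuous-wave fNIRS toolchains). Rows are wavelengths, columns HbO, HbR.
#'
#' @param wavelengths the two wavelengths in nm; only 760 and 850 are tabled.
#' @return 2 x 2 matrix with dimnames.
#' @export
default_extinction <- function(wavelengths = c(760, 850)) {
  table <- rbind(`760` = c(hbo = 0.5860, hbr = 1.5485),
                 `850` = c(hbo = 1.0580, hbr = 0.6913))
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(table))) {
    abort_validation("extinction defaults are tabled for 760 and 850 nm only")
  }
  table[key, , drop = FALSE]
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' For every source-detector pair with optical-density traces at two
#' wavelengths, solves the 2x2 linear system
#' \deqn{\Delta OD_\lambda(t) = (\epsilon_{HbO,\lambda} \Delta HbO(t) +
#'   \epsilon_{HbR,\lambda} \Delta HbR(t)) \, d \, DPF_\lambda}
#' for \eqn{(\Delta HbO, \Delta HbR)} at every time point, where d is the
#' source-detector distance (cm) and DPF the differential pathlength factor.
#' Concentrations are returned in micromolar (extinction in 1/(mM cm)).
#'
#' @param od channels x time optical-density matrix (rows aligned with
#'   `geometry$channels`).
#' @param geometry a [probe_geometry()]; each source-detector pair must
#'   appear at exactly two wavelengths.
#' @param dpf differential pathlength factor, one value per wavelength
#'   (recycled if scalar). Default 6.
#' @param extinction 2 x 2 matrix, rows = the pair's two wavelengths
#'   (ascending), columns = (HbO, HbR), in 1/(mM cm).
#' @param fs,condition,events passed through to the returned [hb_series()].
#' @return An [hb_series()] with one row per source-detector pair.
#' @export
mbll <- function(od, geometry, dpf = 6, extinction = NULL,
                 fs = 1, condition = "unknown", events = empty_events()) {
  stopifnot(inherits(geometry, "probe_geometry"))
  od <- as.matrix(od)
  ch <- geometry$channels
  if (nrow(od) != nrow(ch)) {
    abort_validation("`od` must have one row per geometry channel")
  }
  pair_key <- paste(ch$source, ch$detector, sep = "-")
  pairs <- split(seq_len(nrow(ch)), pair_key)
  bad <- names(pairs)[lengths(pairs) != 2L]
  if (length(bad)) {
    abort_data(sprintf(
      "source-detector pair(s) %s need exactly two wavelength channels",
      paste(bad, collapse = ", ")
    ))
  }
  pairs <- pairs[unique(pair_key)]  # preserve first-appearance order
  dist <- channel_distances(geometry)
  if (any(dist <= 0)) abort_data("source-detector distance must be > 0")

  n_pair <- length(pairs)
  hbo <- matrix(0, n_pair, ncol(od))
  hbr <- matrix(0, n_pair, ncol(od))
  coords <- matrix(0, n_pair, 3)
  pair_df <- data.frame(source = integer(n_pair), detector = integer(n_pair))

  for (i in seq_len(n_pair)) {
    idx <- pairs[[i]]
    wl <- ch$wavelength[idx]
    idx <- idx[order(wl)]
    wl <- sort(wl)
    eps <- extinction %||% default_extinction(wl)
    eps <- as.matrix(eps)
    if (abs(det(eps)) < 1e-12) {
      abort_numerical("extinction matrix is singular; chromophores not separable")
    }
    dpf2 <- rep_len(dpf, 2L)
    # A %*% c(hbo_mM, hbr_mM) = od for each time point
    A <- eps * (dist[idx] * dpf2)
    sol <- solve(A, od[idx, , drop = FALSE]) * 1000  # mM -> uM
    hbo[i, ] <- sol[1L, ]
    hbr[i, ] <- sol[2L, ]
    coords[i, ] <- geometry$coords[idx[1L], ]
    pair_df$source[i] <- ch$source[idx[1L]]
    pair_df$detector[i] <- ch$detector[idx[1L]]
  }
  hb_series(hbo, hbr, fs = fs, coords = coords, condition = condition,
            events = events, pairs = pair_df)
}

#' Linear-phase FIR band-pass design
#'
#' Windowed-sinc (Hamming) design of an order-`order` (i.e. `order + 1` tap)
#' linear-phase band-pass filter. The defaults reproduce the hemodynamic
#' band used throughout the package: 10-400 mHz at 10.2 Hz sampling.
#'
#' @param order filter order (taps - 1). Default 71.
#' @param band numeric length-2 passband edges in Hz, `c(low, high)`.
#' @param fs sampling frequency in Hz.
#' @return numeric tap vector of length `order + 1`, symmetric.
#' @export
design_fir_bandpass <- function(order = 71, band = c(0.010, 0.400), fs = 10.2) {
  stopifnot_scalar_number(order, "order", lower = 1)
  stopifnot_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  if (length(band) != 2L || !(0 < band[1] && band[1] < band[2])) {
    abort_validation("`band` must satisfy 0 < low < high")
  }
  if (band[2] >= fs / 2) {
    abort_validation(sprintf("upper band edge %g Hz must be below Nyquist %g Hz",
                             band[2], fs / 2))
  }
  as.numeric(signal::fir1(order, band / (fs / 2), type = "pass"))
}

#' Zero-phase filtering of a hemoglobin series
#'
#' Forward-backward application of an FIR filter with reflection padding at
#' both ends, preserving length and cancelling the filter's group delay.
#' Zero phase matters here because downstream connectivity estimates rely on
#' lead-lag structure that a one-pass filter would shift.
#'
#' @param hb an [hb_series()] (or a plain channels x time matrix).
#' @param taps FIR coefficient vector, e.g. from [design_fir_bandpass()].
#' @return Same type as `hb`, filtered along time.
#' @export
apply_filter <- function(hb, taps) {
  if (inherits(hb, "hb_series")) {
    hb$hbo <- apply_filter(hb$hbo, taps)
    hb$hbr <- apply_filter(hb$hbr, taps)
    return(hb)
  }
  x <- as.matrix(hb)
  n <- ncol(x)
  ntaps <- length(taps)
  if (n <= 3L * ntaps) {
    abort_data(sprintf(
      "series length %d too short for zero-phase filtering with %d taps (need > %d)",
      n, ntaps, 3L * ntaps
    ))
  }
  t(apply(x, 1L, filtfilt_reflect, taps = taps))
}

# forward-backward FIR with reflection padding (odd reflection about end values)
filtfilt_reflect <- function(x, taps) {
  n <- length(x)
  pad <- length(taps) * 3L
  pre <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- c(pre, x, post)
  y <- stats::filter(y, taps, method = "convolution", sides = 1L)
  y <- rev(as.numeric(y))
  y <- stats::filter(y, taps, method = "convolution", sides = 1L)
  y <- rev(as.numeric(y))
  # startup NAs of both causal passes land inside the padding
  y[seq(pad + 1L, pad + n)]
}
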