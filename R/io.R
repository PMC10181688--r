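#' Raw continuous-wave fNIRS intensity recording
#'
#' Container for one run: strictly positive light intensities (channels x
#' time), the sampling frequency, the condition label of the run, and event
#' markers for the block design.
#'
#' @param intensity numeric matrix, channels x time, all values > 0.
#' @param fs sampling frequency in Hz.
#' @param condition condition label for the run (character scalar).
#' @param events data frame with columns `onset`, `duration` (seconds) and
#'   `label`; may have zero rows.
#' @return An object of class `fnirs_recording`.
#' @export
fnirs_recording <- function(intensity, fs, condition = "unknown",
                            events = empty_events()) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(intensity) == 0L || ncol(intensity) == 0L) {
    abort_validation("`intensity` must have at least one channel and sample")
  }
  if (anyNA(intensity) || any(intensity <= 0)) {
    bad <- which(apply(intensity, 1L, function(r) anyNA(r) || any(r <= 0)))
    abort_data(sprintf(
      "intensities must be strictly positive and finite; offending channel(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  stopifnot_scalar_number(fs, "fs", lower = 0, strict = TRUE)
  events <- as_events(events)
  dur <- ncol(intensity) / fs
  if (nrow(events) && any(events$onset < 0 | events$onset > dur)) {
    abort_data("event onsets fall outside the run duration")
  }
  structure(
    list(intensity = intensity, fs = fs, condition = as.character(condition),
         events = events),
    class = "fnirs_recording"
  )
}

empty_events <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

as_events <- function(events) {
  events <- as.data.frame(events)
  if (!all(c("onset", "duration", "label") %in% names(events))) {
    abort_validation("`events` needs columns onset, duration, label")
  }
  events$onset <- as.numeric(events$onset)
  events$duration <- as.numeric(events$duration)
  events$label <- as.character(events$label)
  events[c("onset", "duration", "label")]
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf(
    "<fnirs_recording> %d channels x %d samples @ %g Hz, condition '%s', %d events\n",
    nrow(x$intensity), ncol(x$intensity), x$fs, x$condition, nrow(x$events)
  ))
  invisible(x)
}

#' Write / read an fNIRS run as a directory of CSV files
#'
#' Plain-text on-disk format for one run: `probe.csv` (optode positions),
#' `channels.csv` (source/detector indices and wavelength per channel),
#' `intensities.csv` (one column per channel, named `S<i>_D<j>_<nm>`),
#' `events.csv` (onset, duration, label) and `meta.csv` (fs, condition).
#' All files are UTF-8, comma-separated with a header row; the round trip
#' `read_fnirs(write_fnirs(...))` is lossless to double precision.
#'
#' @param geometry a [probe_geometry()].
#' @param recording an [fnirs_recording()] whose channel count matches
#'   `geometry`.
#' @param path directory to create/populate.
#' @return `write_fnirs` returns `path` invisibly; `read_fnirs` returns a
#'   list with elements `geometry` and `recording`.
#' @export
write_fnirs <- function(geometry, recording, path) {
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(recording, "fnirs_recording"))
  if (nrow(geometry$channels) != nrow(recording$intensity)) {
    abort_validation(sprintf(
      "geometry has %d channels but recording has %d rows",
      nrow(geometry$channels), nrow(recording$intensity)
    ))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(sprintf("cannot create '%s'", path), "cdvar_io_error")

  optodes <- rbind(
    data.frame(role = "source", index = seq_len(nrow(geometry$sources)),
               geometry$sources),
    data.frame(role = "detector", index = seq_len(nrow(geometry$detectors)),
               geometry$detectors)
  )
  write_csv15(optodes, file.path(path, "probe.csv"))
  write_csv15(geometry$channels, file.path(path, "channels.csv"))

  inten <- as.data.frame(t(recording$intensity))
  names(inten) <- channel_names(geometry)
  write_csv15(inten, file.path(path, "intensities.csv"))
  write_csv15(recording$events, file.path(path, "events.csv"))
  write_csv15(
    data.frame(key = c("fs", "condition"),
               value = c(format(recording$fs, digits = 17), recording$condition)),
    file.path(path, "meta.csv")
  )
  invisible(path)
}

channel_names <- function(geometry) {
  sprintf("S%d_D%d_%g", geometry$channels$source, geometry$channels$detector,
          geometry$channels$wavelength)
}

write_csv15 <- function(df, file) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

#' @rdname write_fnirs
#' @export
read_fnirs <- function(path) {
  need <- c("probe.csv", "channels.csv", "intensities.csv", "events.csv",
            "meta.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    abort(sprintf("'%s' is not a valid fNIRS directory (missing %s)",
                  path, paste(missing, collapse = ", ")), "cdvar_format_error")
  }
  rd <- function(f) utils::read.csv(file.path(path, f), stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  optodes <- rd("probe.csv")
  geometry <- probe_geometry(
    sources = as.matrix(optodes[optodes$role == "source", c("x", "y", "z")]),
    detectors = as.matrix(optodes[optodes$role == "detector", c("x", "y", "z")]),
    channels = rd("channels.csv")
  )
  meta <- rd("meta.csv")
  metav <- stats::setNames(meta$value, meta$key)
  inten <- rd("intensities.csv")
  recording <- fnirs_recording(
    intensity = t(as.matrix(inten)),
    fs = as.numeric(metav[["fs"]]),
    condition = metav[["condition"]],
    events = rd("events.csv")
  )
  list(geometry = geometry, recording = recording)
}
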