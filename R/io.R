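# On-disk containers. A recording or epochs object is stored as one binary
# array file (little-endian doubles) next to a JSON header carrying the
# schema version, dimensions, units and metadata; channels and events as
# TSV; spectra as two-column TSV. Coordinates are millimetres on disk and
# metres in memory.

SCHEMA_VERSION <- "opmgamma-container-1"

write_array_container <- function(path, x, header) {
  header$schema <- SCHEMA_VERSION
  header$dim <- dim(x) %||% length(x)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8, endian = "little")
}

read_array_container <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(hdr$schema) || !identical(hdr$schema, SCHEMA_VERSION)) {
    stop("container schema mismatch: file has '",
         hdr$schema %||% "<none>", "', reader expects '", SCHEMA_VERSION, "'")
  }
  n <- prod(hdr$dim)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n + 1, size = 8, endian = "little")
  if (length(x) != n) {
    stop("container truncated or padded: expected ", n, " values, found ",
         length(x))
  }
  if (length(hdr$dim) > 1) dim(x) <- hdr$dim
  list(data = x, header = hdr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_channels_tsv <- function(path, array) {
  df <- data.frame(label = array$channel_labels,
                   x = array$positions[, 1] * 1e3,
                   y = array$positions[, 2] * 1e3,
                   z = array$positions[, 3] * 1e3,
                   ox = array$orientations[, 1],
                   oy = array$orientations[, 2],
                   oz = array$orientations[, 3])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

read_channels_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  list(channel_labels = df$label,
       positions = unname(as.matrix(df[, c("x", "y", "z")])) / 1e3,
       orientations = unname(as.matrix(df[, c("ox", "oy", "oz")])))
}

#' Write and read recordings and epochs
#'
#' `write_recording()` stores a recording as `<base>.bin` (channels x
#' samples doubles) + `<base>.json` (header) + `<base>_channels.tsv` +
#' `<base>_events.tsv`; `read_recording()` restores it. `write_epochs()` /
#' `read_epochs()` do the same for trial-segmented data. Floats round-trip
#' bit-exactly.
#'
#' @param rec,ep the object to store.
#' @param base path prefix (no extension).
#' @return The restored object (readers) or `base` invisibly (writers).
#' @export
write_recording <- function(rec, base) {
  write_array_container(base, rec$data, list(
    kind = "recording", fs = rec$fs, units = "T",
    bad_channels = rec$bad_channels,
    n_axes_per_sensor = rec$array$n_axes_per_sensor,
    line_freq = rec$array$line_freq, head_radius = rec$array$head_radius,
    sensor_ids = rec$array$sensor_ids))
  write_channels_tsv(paste0(base, "_channels.tsv"), rec$array)
  utils::write.table(rec$events, paste0(base, "_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(base)
}

#' @rdname write_recording
#' @export
read_recording <- function(base) {
  rc <- read_array_container(base)
  if (!identical(rc$header$kind, "recording")) {
    stop("container holds '", rc$header$kind, "', not a recording")
  }
  ch <- read_channels_tsv(paste0(base, "_channels.tsv"))
  events <- utils::read.table(paste0(base, "_events.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  array <- structure(c(ch, list(
    sensor_ids = rc$header$sensor_ids,
    n_axes_per_sensor = rc$header$n_axes_per_sensor,
    line_freq = rc$header$line_freq,
    head_radius = rc$header$head_radius)), class = "sensor_array")
  structure(list(data = rc$data, fs = as.numeric(rc$header$fs),
                 events = events,
                 bad_channels = as.character(rc$header$bad_channels %||%
                                               character(0)),
                 array = array),
            class = "recording")
}

#' @rdname write_recording
#' @export
write_epochs <- function(ep, base) {
  write_array_container(base, ep$data, list(
    kind = "epochs", fs = ep$fs, units = "T", tmin = ep$tmin,
    tmax = ep$tmax, retained_trial_ids = ep$retained_trial_ids,
    n_axes_per_sensor = ep$array$n_axes_per_sensor,
    line_freq = ep$array$line_freq, head_radius = ep$array$head_radius,
    sensor_ids = ep$array$sensor_ids))
  write_channels_tsv(paste0(base, "_channels.tsv"), ep$array)
  invisible(base)
}

#' @rdname write_recording
#' @export
read_epochs <- function(base) {
  rc <- read_array_container(base)
  if (!identical(rc$header$kind, "epochs")) {
    stop("container holds '", rc$header$kind, "', not epochs")
  }
  ch <- read_channels_tsv(paste0(base, "_channels.tsv"))
  array <- structure(c(ch, list(
    sensor_ids = rc$header$sensor_ids,
    n_axes_per_sensor = rc$header$n_axes_per_sensor,
    line_freq = rc$header$line_freq,
    head_radius = rc$header$head_radius)), class = "sensor_array")
  structure(list(data = rc$data, tmin = as.numeric(rc$header$tmin),
                 tmax = as.numeric(rc$header$tmax),
                 fs = as.numeric(rc$header$fs),
                 retained_trial_ids = rc$header$retained_trial_ids,
                 array = array),
            class = "epochs")
}

#' Write and read a relative spectrum as TSV
#'
#' Two columns (`freq_hz`, `value`) plus a JSON sidecar with subject
#' metadata and stage flags.
#'
#' @param spec a `rel_spectrum`; `base` path prefix.
#' @export
write_spectrum <- function(spec, base) {
  utils::write.table(
    data.frame(freq_hz = spec$freqs, value = spec$values),
    paste0(base, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(schema = SCHEMA_VERSION,
                            subject_id = spec$subject_id,
                            age_years = spec$age_years,
                            normalized = spec$normalized,
                            alpha_removed = spec$alpha_removed),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(base) {
  df <- utils::read.table(paste0(base, ".tsv"), sep = "\t", header = TRUE)
  hdr <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  if (!identical(hdr$schema, SCHEMA_VERSION)) {
    stop("spectrum schema mismatch: '", hdr$schema %||% "<none>",
         "' vs '", SCHEMA_VERSION, "'")
  }
  rel_spectrum(df$freq_hz, df$value, subject_id = hdr$subject_id,
               age_years = hdr$age_years, normalized = hdr$normalized,
               alpha_removed = hdr$alpha_removed)
}

#' Write a pseudo-T image as TSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`, `value`, with band/window metadata in a
#' JSON sidecar.
#'
#' @param img a `pseudo_t_image`; `base` path prefix.
#' @export
write_pseudo_t <- function(img, base) {
  utils::write.table(
    data.frame(x_mm = img$grid[, 1] * 1e3, y_mm = img$grid[, 2] * 1e3,
               z_mm = img$grid[, 3] * 1e3, value = img$values),
    paste0(base, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(schema = SCHEMA_VERSION, band = img$band,
                            windows = img$windows,
                            spacing_mm = (img$spacing %||% NA) * 1e3),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}
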