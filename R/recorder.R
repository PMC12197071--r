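#' Assemble a recording from a serial-frame stream
#'
#' Host-side consumption of the hub's frame stream: per-channel payloads
#' are concatenated in frame order and per-frame QoS snapshots are summed
#' into the session lost-packet count per channel. The metadata sidecar
#' carries the five descriptive fields a recording needs -- signal
#' description, channel names, QoS factor, sampling frequency and ADC
#' resolution -- plus the format version and any extra configuration.
#'
#' @param frames List of [serial_frame()] objects (a [hub_session()]'s
#'   `frames`), or raw bytes to be run through [decode_frame_stream()].
#' @param description Free-text signal description.
#' @param fs Sampling frequency in Hz recorded in the metadata.
#' @param bits ADC resolution recorded in the metadata.
#' @param channel_names Optional named character vector `c("1" = ...)`;
#'   defaults to `"ch<k>"`.
#' @param extra Optional list merged into the metadata (seeds, config).
#' @return A list of class `recording` with `streams` (named list of
#'   integer code vectors) and `meta`.
#' @export
assemble <- function(frames, description = "", fs = 1000, bits = 12,
                     channel_names = NULL, extra = list()) {
  if (is.raw(frames)) frames <- decode_frame_stream(frames)
  streams <- list()
  qos <- list()
  for (f in frames) {
    for (e in f$entries) {
      key <- as.character(e$channel_id)
      streams[[key]] <- c(streams[[key]], e$payload)
      qos[[key]] <- (qos[[key]] %||% 0) + e$qos
    }
  }
  ids <- sort(as.integer(names(streams)))
  keys <- as.character(ids)
  names_out <- if (is.null(channel_names)) {
    stats::setNames(paste0("ch", ids), keys)
  } else {
    channel_names[keys]
  }
  recording(
    streams = stats::setNames(streams[keys], keys),
    meta = c(
      list(
        format_version = 1L,
        description = description,
        channel_names = as.list(names_out),
        qos = qos[keys],
        sampling_frequency_hz = fs,
        adc_bits = bits
      ),
      extra
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

REQUIRED_META <- c("description", "channel_names", "qos",
                   "sampling_frequency_hz", "adc_bits")

#' Construct a recording
#'
#' @param streams Named list (by channel id) of integer ADC code vectors.
#' @param meta Metadata list; must contain `description`, `channel_names`,
#'   `qos`, `sampling_frequency_hz` and `adc_bits`.
#' @return A list of class `recording`.
#' @export
recording <- function(streams, meta) {
  missing <- setdiff(REQUIRED_META, names(meta))
  if (length(missing)) {
    rlang::abort(paste("recording metadata missing:",
                       paste(missing, collapse = ", ")),
                 class = "semgsim_schema_error")
  }
  bits <- meta$adc_bits
  for (s in streams) {
    if (any(s < 0 | s > 2^bits - 1)) {
      rlang::abort("stream codes outside ADC range",
                   class = "semgsim_schema_error")
    }
  }
  structure(list(streams = streams, meta = meta), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  lens <- vapply(x$streams, length, integer(1))
  cat(sprintf(
    "<recording> %d channel(s) @ %g Hz, %d-bit; samples: %s; QoS: %s\n",
    length(x$streams), x$meta$sampling_frequency_hz, x$meta$adc_bits,
    paste(lens, collapse = " "),
    paste(unlist(x$meta$qos), collapse = " ")
  ))
  invisible(x)
}

#' Write / read a recording on disk
#'
#' One binary file per channel (`channel_<id>.bin`, 2-byte little-endian
#' codes) plus a single JSON sidecar (`recording.json`) holding the
#' metadata and the channel-to-file mapping; one file per channel keeps
#' partial sessions readable. `read_recording()` inverts
#' `write_recording()` exactly.
#'
#' @param rec A [recording()].
#' @param path Directory to write into (created if needed).
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: a
#'   [recording()].
#' @section Errors: a sidecar missing a required field raises
#'   `semgsim_schema_error`; a binary file whose length is not a multiple
#'   of 2 raises `semgsim_corrupt_file`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(
    paste0("channel_", names(rec$streams), ".bin"), names(rec$streams)
  )
  for (key in names(rec$streams)) {
    con <- file(file.path(path, files[[key]]), "wb")
    writeBin(as.integer(rec$streams[[key]]), con, size = 2L,
             endian = "little")
    close(con)
  }
  meta <- rec$meta
  meta$channel_files <- as.list(files)
  jsonlite::write_json(meta, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- file.path(path, "recording.json")
  if (!file.exists(sidecar)) {
    rlang::abort("recording.json sidecar not found",
                 class = "semgsim_schema_error")
  }
  meta <- jsonlite::read_json(sidecar)
  missing <- setdiff(REQUIRED_META, names(meta))
  if (length(missing)) {
    rlang::abort(paste("sidecar missing required field(s):",
                       paste(missing, collapse = ", ")),
                 class = "semgsim_schema_error")
  }
  files <- meta$channel_files
  meta$channel_files <- NULL
  streams <- purrr::imap(files, function(fname, key) {
    fpath <- file.path(path, fname)
    sz <- file.size(fpath)
    if (is.na(sz) || sz %% 2 != 0) {
      rlang::abort(paste("corrupt channel file:", fname),
                   class = "semgsim_corrupt_file")
    }
    con <- file(fpath, "rb")
    on.exit(close(con))
    readBin(con, "integer", n = sz / 2, size = 2L, endian = "little",
            signed = FALSE)
  })
  # JSON deserializes scalars/lists; normalize to the in-memory shape
  meta$format_version <- as.integer(meta$format_version)
  meta$adc_bits <- as.integer(meta$adc_bits)
  meta$sampling_frequency_hz <- as.numeric(meta$sampling_frequency_hz)
  meta$qos <- purrr::map(meta$qos, as.numeric)
  meta$channel_names <- purrr::map(meta$channel_names, as.character)
  recording(streams = streams, meta = meta)
}

#' Tidy a recording into a long tibble
#'
#' @param x A [recording()].
#' @param ... Unused.
#' @return A tibble with columns `channel_id`, `channel_name`, `time`,
#'   `code`.
#' @method tidy recording
#' @export
tidy.recording <- function(x, ...) {
  fs <- x$meta$sampling_frequency_hz
  purrr::imap(x$streams, function(codes, key) {
    tibble::tibble(
      channel_id = as.integer(key),
      channel_name = x$meta$channel_names[[key]] %||% paste0("ch", key),
      time = (seq_along(codes) - 1) / fs,
      code = as.integer(codes)
    )
  }) |>
    dplyr::bind_rows()
}

#' Summarize a recording
#'
#' @param x A [recording()].
#' @param ... Unused.
#' @return One row per channel: sample count, duration, session QoS.
#' @method glance recording
#' @export
glance.recording <- function(x, ...) {
  fs <- x$meta$sampling_frequency_hz
  purrr::imap(x$streams, function(codes, key) {
    tibble::tibble(
      channel_id = as.integer(key),
      n_samples = length(codes),
      duration_s = length(codes) / fs,
      qos = as.numeric(x$meta$qos[[key]] %||% NA_real_)
    )
  }) |>
    dplyr::bind_rows()
}
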