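#' Averaged-periodogram (Welch) power spectrum
#'
#' One-sided averaged periodogram with a Hann window (default) over
#' overlapping segments. `scale = "density"` gives power spectral density
#' in V^2/Hz normalized so that `sum(power) * df` equals the signal's mean
#' square power (Parseval); `scale = "spectrum"` gives power per bin so a
#' full-scale sinusoid of amplitude A on an exact bin reads `A^2/2`.
#'
#' @param x Numeric samples, an [emg_trace()], or a `digital_trace`
#'   (codes are converted to volts via [codes_to_volts()]).
#' @param fs Sampling rate in Hz; taken from the trace when `x` is one.
#' @param segment Segment length in samples, default 1024.
#' @param overlap Fractional segment overlap in `[0, 1)`, default 0.5.
#' @param window `"hann"` or `"rect"`.
#' @param scale `"density"` (V^2/Hz) or `"spectrum"` (V^2 per bin).
#' @return A tibble of class `spectrum_result` with columns `freq`,
#'   `power`, `power_db` (10 log10 power); attributes record `fs`,
#'   `segment`, `overlap`, `window`, `scale`, `n_segments`.
#' @export
power_spectrum <- function(x, fs = NULL, segment = 1024, overlap = 0.5,
                           window = c("hann", "rect"),
                           scale = c("density", "spectrum")) {
  window <- match.arg(window)
  scale <- match.arg(scale)
  if (inherits(x, "digital_trace")) {
    fs <- attr(x, "fs")
    x <- codes_to_volts(x)
  } else if (inherits(x, "emg_trace")) {
    fs <- trace_fs(x)
    x <- x$voltage
  }
  if (is.null(fs)) rlang::abort("fs must be given for plain numeric input")
  n <- length(x)
  if (n < segment) {
    rlang::abort("signal shorter than one segment",
                 class = "semgsim_short_signal")
  }
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, segment - 1) / (segment - 1))
  } else {
    rep(1, segment)
  }
  step <- max(1L, round(segment * (1 - overlap)))
  starts <- seq(1L, n - segment + 1L, by = step)
  nf <- segment %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)] * w
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[seq_len(nf)]
  }
  acc <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even lengths)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (segment %% 2 == 0) dbl[nf] <- 1
  acc <- acc * dbl
  power <- switch(scale,
    density = acc / (fs * sum(w^2)),
    spectrum = acc / sum(w)^2
  )
  out <- tibble::tibble(
    freq = seq(0, nf - 1) * fs / segment,
    power = power,
    power_db = 10 * log10(power)
  )
  structure(out, fs = fs, segment = segment, overlap = overlap,
            window = window, scale = scale, n_segments = length(starts),
            class = c("spectrum_result", class(out)))
}

#' Mains-interference delta between rest and contraction spectra
#'
#' The difference in spectral power (dB) at the mains frequency between a
#' contraction ("active") recording and a rest recording:
#' `power_db(active)[f0 bin] - power_db(rest)[f0 bin]`, with the bin taken
#' as the grid frequency nearest `f0`. During contraction the EMG band
#' covers the mains frequency, so this delta measures how far interference
#' pickup sits below the physiological signal.
#'
#' @param rest,active `spectrum_result` objects on identical grids.
#' @param f0 Mains frequency in Hz, default 60.
#' @return The delta in dB (scalar).
#' @export
mains_delta <- function(rest, active, f0 = 60) {
  if (nrow(rest) != nrow(active) ||
      max(abs(rest$freq - active$freq)) > 1e-9) {
    rlang::abort("rest and active spectra must share the frequency grid")
  }
  i <- which.min(abs(rest$freq - f0))
  active$power_db[i] - rest$power_db[i]
}

#' Battery autonomy estimate
#'
#' Plain capacity-over-draw arithmetic: a 180 mAh cell at 100 mA average
#' draw runs 1.8 h (1 h 48 min).
#'
#' @param capacity_mah Battery capacity in mAh.
#' @param draw_ma Average current draw in mA (> 0).
#' @return Autonomy in hours.
#' @export
autonomy_estimate <- function(capacity_mah = 180, draw_ma = 100) {
  if (draw_ma <= 0) rlang::abort("current draw must be positive")
  if (capacity_mah < 0) rlang::abort("capacity must be non-negative")
  capacity_mah / draw_ma
}

#' Per-channel arrival raster from a transmission log
#'
#' Shifts each channel's receive timestamps so its first message sits at
#' time 0 (as on a synchronization raster plot) and computes inter-arrival
#' intervals. A lossless 1 kS/s / 120-sample stream has a modal interval of
#' 0.120 s; each dropped packet widens one interval by a packet period.
#'
#' @param log A [transmit()] log.
#' @return A tibble of class `timing_raster` with columns `channel_id`,
#'   `counter`, `rel_time`, `dt` (NA for each channel's first arrival).
#' @export
timing_raster <- function(log) {
  del <- delivered(log)
  if (nrow(del) == 0) rlang::abort("no delivered packets to raster")
  out <- del |>
    dplyr::select("channel_id", "counter", "recv_time") |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::arrange(.data$recv_time, .by_group = TRUE) |>
    dplyr::mutate(
      rel_time = .data$recv_time - dplyr::first(.data$recv_time),
      dt = .data$rel_time - dplyr::lag(.data$rel_time)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"recv_time")
  structure(out, class = c("timing_raster", class(out)))
}

#' Packet-loss sweep over distance and channel count
#'
#' Runs one full acquisition simulation per (distance, active-channel
#' count) cell: synthetic EMG through the analog chain, digitization,
#' packetization, lossy transmission with the distance-mapped loss
#' probability, and hub QoS accounting. Per-channel lost-packet counts come
#' from the hub's counter-gap bookkeeping and are returned next to the
#' link's ground-truth drop counts.
#'
#' @param distances Meters, default `seq(0, 100, by = 10)`.
#' @param n_channels Active channel counts to sweep, default `1:6`.
#' @param duration Seconds of signal per cell, default 2.
#' @param seed Base RNG seed; each cell derives its own.
#' @param loss_curve Distance-to-loss mapping, default
#'   [loss_from_distance()].
#' @param spec A [synth_spec()] for the per-channel signals.
#' @param params A [chain_params()].
#' @param fs_sim,fs Simulation and acquisition rates in Hz.
#' @return A tibble of class `qos_table`: one row per
#'   (distance, n_channels, channel_id) with `sent`, `lost` (hub QoS) and
#'   `dropped` (link ground truth).
#' @export
qos_vs_distance <- function(distances = seq(0, 100, by = 10),
                            n_channels = 1:6, duration = 2, seed = 1L,
                            loss_curve = loss_from_distance,
                            spec = synth_spec(), params = chain_params(),
                            fs_sim = 10000, fs = 1000) {
  cells <- tidyr::expand_grid(distance = distances, n_ch = n_channels)
  rows <- purrr::pmap(cells, function(distance, n_ch) {
    cell_seed <- (seed + 7919 * round(distance) + 104729 * n_ch) %% 2^31
    sess <- run_end_to_end(e2e_config(
      n_channels = n_ch, duration = duration, spec = spec, params = params,
      fs_sim = fs_sim, fs = fs,
      link = link_params(loss_prob = loss_curve(distance),
                         seed = cell_seed),
      seed = cell_seed
    ))
    per_ch <- tidy(sess)
    tibble::tibble(
      distance = distance, n_channels = n_ch,
      channel_id = per_ch$channel_id, sent = per_ch$sent,
      lost = per_ch$qos, dropped = per_ch$dropped
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("qos_table", class(out)))
}

#' End-to-end session configuration
#'
#' @param n_channels Number of active channels, 1-6.
#' @param duration Seconds of signal per channel.
#' @param spec A [synth_spec()]; each channel uses `spec$seed + channel`.
#' @param params A [chain_params()].
#' @param link A [link_params()].
#' @param mains_amplitude Peak 60 Hz interference added at the electrode,
#'   volts (0 disables).
#' @param fs_sim,fs Simulation and acquisition rates (Hz); `fs_sim` must be
#'   a multiple of `fs`.
#' @param bits,vref Digitizer resolution and reference.
#' @param timeout Hub channel-deactivation threshold in seconds.
#' @param description Recording description text.
#' @param seed Session seed (drives the link unless `link` carries its
#'   own).
#' @return A list of class `e2e_config`.
#' @export
e2e_config <- function(n_channels = 2, duration = 2, spec = synth_spec(),
                       params = chain_params(), link = NULL,
                       mains_amplitude = 0, fs_sim = 10000, fs = 1000,
                       bits = 12, vref = 3.3, timeout = 1.0,
                       description = "simulated multichannel sEMG session",
                       seed = 1L) {
  stopifnot(n_channels >= 1, n_channels <= 6, duration > 0)
  if (is.null(link)) link <- link_params(loss_prob = 0, seed = seed)
  structure(
    list(n_channels = as.integer(n_channels), duration = duration,
         spec = spec, params = params, link = link,
         mains_amplitude = mains_amplitude, fs_sim = fs_sim, fs = fs,
         bits = bits, vref = vref, timeout = timeout,
         description = description, seed = as.integer(seed)),
    class = "e2e_config"
  )
}

#' Run a full acquisition session end to end
#'
#' The complete pipeline for each active channel: synthetic EMG (plus
#' optional mains pickup) -> analog chain -> 12-bit digitization ->
#' packetization -> lossy transmission -> hub ingestion with QoS
#' accounting -> synchronized serial frames -> assembled recording. On a
#' lossless link the recorded codes are bit-identical to the quantizer
#' output (up to the trailing partial packet the sensor withholds).
#'
#' @param config An [e2e_config()].
#' @return A list of class `semg_session`: `recording`, `frames`,
#'   `hub` ([hub_session()] result), `log` (transmission log), `digital`
#'   (per-channel `digital_trace` list), `config`.
#' @export
run_end_to_end <- function(config = e2e_config()) {
  stopifnot(inherits(config, "e2e_config"))
  chans <- seq_len(config$n_channels)
  digital <- purrr::map(chans, function(ch) {
    spec_ch <- config$spec
    spec_ch$seed <- (spec_ch$seed + ch) %% 2^31
    tr <- generate_semg(spec_ch, config$duration, config$fs_sim)
    if (config$mains_amplitude > 0) {
      tr <- add_mains(tr, config$mains_amplitude)
    }
    tr |>
      apply_chain(config$params) |>
      quantize(fs = config$fs, bits = config$bits, vref = config$vref)
  })
  packets <- purrr::map2(digital, chans, ~ packetize(.x, .y)) |>
    dplyr::bind_rows()
  log <- transmit(packets, config$link)
  hub <- hub_session(log, timeout = config$timeout)
  rec <- assemble(
    hub$frames,
    description = config$description, fs = config$fs, bits = config$bits,
    extra = list(
      vref = config$vref,
      seeds = list(session = config$seed, synth = config$spec$seed,
                   link = config$link$seed)
    )
  )
  structure(
    list(recording = rec, frames = hub$frames, hub = hub, log = log,
         digital = digital, config = config),
    class = "semg_session"
  )
}

#' Per-channel summary of an end-to-end session
#'
#' @param x A `semg_session`.
#' @param ... Unused.
#' @return A tibble with one row per channel: packets `sent`, `delivered`,
#'   `dropped` (link ground truth), hub `qos`, and `recorded` sample
#'   count.
#' @method tidy semg_session
#' @export
tidy.semg_session <- function(x, ...) {
  per_link <- x$log |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(
      sent = dplyr::n(),
      delivered = sum(!.data$dropped),
      dropped = sum(.data$dropped),
      .groups = "drop"
    )
  states <- x$hub$states
  rec_len <- vapply(
    as.character(per_link$channel_id),
    function(k) length(x$recording$streams[[k]] %||% integer()),
    integer(1)
  )
  per_link |>
    dplyr::mutate(
      qos = states$qos_cum[match(.data$channel_id, states$channel_id)],
      recorded = rec_len
    )
}

#' One-row summary of an end-to-end session
#'
#' @param x A `semg_session`.
#' @param ... Unused.
#' @return One-row tibble: channels, frames, totals of sent / delivered /
#'   dropped packets and hub QoS.
#' @method glance semg_session
#' @export
glance.semg_session <- function(x, ...) {
  t <- tidy(x)
  tibble::tibble(
    n_channels = nrow(t),
    n_frames = length(x$frames),
    sent = sum(t$sent),
    delivered = sum(t$delivered),
    dropped = sum(t$dropped),
    qos_total = sum(t$qos)
  )
}

#' Plot a power spectrum
#' @param object A `spectrum_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_result
#' @export
autoplot.spectrum_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$power_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (dB)")
}

#' Plot a loss-sweep table
#' @param object A `qos_table`.
#' @param ... Unused.
#' @return A ggplot of total lost packets vs distance, one line per
#'   channel count.
#' @method autoplot qos_table
#' @export
autoplot.qos_table <- function(object, ...) {
  totals <- object |>
    dplyr::group_by(.data$distance, .data$n_channels) |>
    dplyr::summarise(total_lost = sum(.data$lost), .groups = "drop")
  ggplot2::ggplot(totals, ggplot2::aes(.data$distance, .data$total_lost,
                                       colour = factor(.data$n_channels))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance (m)", y = "lost packets",
                  colour = "active channels")
  }

#' Plot an arrival raster
#' @param object A `timing_raster`.
#' @param ... Unused.
#' @return A ggplot with time on x and channel id on y.
#' @method autoplot timing_raster
#' @export
autoplot.timing_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$rel_time,
                                       factor(.data$channel_id))) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "time since channel start (s)", y = "channel")
}
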