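#' Trace container for electrode-referred voltage signals
#'
#' An `emg_trace` is a tibble with columns `time` (seconds) and `voltage`
#' (volts, electrode-referred), carrying the simulation sampling rate and a
#' set of component tags (`"emg"`, `"mains"`, `"drift"`, `"impact"`,
#' `"chain"`) as attributes. Surface EMG amplitudes live in the
#' microvolt-to-millivolt range, so `voltage` values are typically
#' 1e-6 to 1e-2 V.
#'
#' @param voltage Numeric vector of sample values (volts).
#' @param fs_sim Simulation sampling rate in Hz.
#' @param components Character vector of tags describing injected parts.
#' @return A tibble of class `emg_trace` with columns `time`, `voltage`.
#' @export
emg_trace <- function(voltage, fs_sim, components = character()) {
  stopifnot(is.numeric(voltage), all(is.finite(voltage)), fs_sim > 0)
  out <- tibble::tibble(
    time = (seq_along(voltage) - 1) / fs_sim,
    voltage = as.numeric(voltage)
  )
  structure(out,
    fs_sim = fs_sim,
    components = unique(components),
    class = c("emg_trace", class(out))
  )
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf(
    "<emg_trace> %d samples @ %g Hz (%.3g s), components: %s\n",
    nrow(x), trace_fs(x), nrow(x) / trace_fs(x),
    paste(attr(x, "components"), collapse = ", ")
  ))
  NextMethod()
}

#' Sampling rate and duration of a trace
#' @param trace An [emg_trace()].
#' @return `trace_fs()`: the simulation rate in Hz; `trace_duration()`:
#'   seconds.
#' @export
trace_fs <- function(trace) attr(trace, "fs_sim")

#' @rdname trace_fs
#' @export
trace_duration <- function(trace) nrow(trace) / trace_fs(trace)

# rebuild a trace with new samples, preserving/extending tags
trace_with <- function(trace, voltage, add_components = character()) {
  emg_trace(voltage, trace_fs(trace),
    components = c(attr(trace, "components"), add_components)
  )
}

#' Specification of a synthetic sEMG process
#'
#' Describes the stochastic process used by [generate_semg()]: a white
#' Gaussian process shaped in the frequency domain by a band-pass window on
#' `band` with a first-order spectral tilt (power halved at `tilt_hz`),
#' concentrating mass below ~250 Hz as real sEMG does, then amplitude-
#' modulated by a contraction envelope between `rms_rest` and `rms_max`.
#'
#' @param envelope Contraction intensity on `[0, 1]` versus time. Either a
#'   single number (constant envelope) or a data frame with columns `time`
#'   (seconds) and `level`, interpolated piecewise-linearly and held constant
#'   beyond its endpoints. Default: sustained full contraction (1).
#' @param band Two-element passband in Hz, default `c(20, 500)`.
#' @param tilt_hz Corner of the power tilt `1/(1 + (f/tilt_hz)^2)`, default
#'   200 Hz so most spectral mass sits below 250 Hz.
#' @param rms_rest Baseline (rest) RMS in volts, default 2e-6 V.
#' @param rms_max Full-contraction RMS in volts, default 1e-3 V.
#' @param seed RNG seed; identical spec + seed give bit-identical traces.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(envelope = 1, band = c(20, 500), tilt_hz = 200,
                       rms_rest = 2e-6, rms_max = 1e-3, seed = 1L) {
  stopifnot(
    length(band) == 2, band[1] >= 0, band[1] < band[2],
    tilt_hz > 0, rms_rest >= 0, rms_max >= rms_rest
  )
  if (is.data.frame(envelope)) {
    stopifnot(all(c("time", "level") %in% names(envelope)))
    if (any(envelope$level < 0 | envelope$level > 1)) {
      rlang::abort("envelope levels must lie in [0, 1]")
    }
  } else {
    stopifnot(is.numeric(envelope), length(envelope) == 1,
              envelope >= 0, envelope <= 1)
  }
  structure(
    list(envelope = envelope, band = band, tilt_hz = tilt_hz,
         rms_rest = rms_rest, rms_max = rms_max, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# evaluate the contraction envelope at times t
envelope_at <- function(envelope, t) {
  if (is.data.frame(envelope)) {
    stats::approx(envelope$time, envelope$level, xout = t, rule = 2)$y
  } else {
    rep(envelope, length(t))
  }
}

# frequency-domain shaping window (amplitude); brick-wall band edges with a
# first-order power tilt inside the band
shape_window <- function(f, band, tilt_hz) {
  inband <- f >= band[1] & f <= band[2]
  sqrt(inband / (1 + (f / tilt_hz)^2))
}

# zero-mean unit-RMS shaped Gaussian noise of length n at rate fs
shaped_noise <- function(n, fs, band, tilt_hz) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f) # two-sided -> absolute frequency
  w <- shape_window(f, band, tilt_hz)
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) rlang::abort("shaping window removed all spectral content")
  y / r
}

#' Generate a synthetic surface-EMG trace
#'
#' Draws a band-limited Gaussian process (see [synth_spec()]) whose
#' instantaneous RMS follows the contraction envelope between `rms_rest` and
#' `rms_max`. The trace is zero-mean and reproducible for a fixed seed.
#'
#' @param spec A [synth_spec()].
#' @param duration Trace length in seconds (> 0).
#' @param fs_sim Simulation sampling rate in Hz; must exceed twice the upper
#'   band edge (Nyquist).
#' @return An [emg_trace()] of `round(duration * fs_sim)` samples.
#' @examples
#' tr <- generate_semg(synth_spec(seed = 7), duration = 1, fs_sim = 10000)
#' sqrt(mean(tr$voltage^2)) # ~ rms_max for the default sustained envelope
#' @export
generate_semg <- function(spec, duration, fs_sim = 10000) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.numeric(duration) || duration <= 0) {
    rlang::abort("duration must be positive")
  }
  if (fs_sim <= 2 * spec$band[2]) {
    rlang::abort(sprintf(
      "fs_sim = %g Hz violates Nyquist for band upper edge %g Hz",
      fs_sim, spec$band[2]
    ))
  }
  n <- round(duration * fs_sim)
  voltage <- withr::with_seed(spec$seed, {
    x <- shaped_noise(n, fs_sim, spec$band, spec$tilt_hz)
    t <- (seq_len(n) - 1) / fs_sim
    e <- envelope_at(spec$envelope, t)
    x * (spec$rms_rest + (spec$rms_max - spec$rms_rest) * e)
  })
  emg_trace(voltage, fs_sim, components = "emg")
}

#' Inject mains (power-line) interference
#'
#' Adds a sinusoid at the mains fundamental plus optional harmonics to a
#' trace; the input is left unmodified. Cabled acquisition systems commonly
#' show the fundamental together with its second harmonic (120 Hz for a
#' 60 Hz supply).
#'
#' @param trace An [emg_trace()].
#' @param amplitude Fundamental peak amplitude in volts.
#' @param f0 Mains frequency in Hz, default 60.
#' @param harmonics Optional list of `c(order, relative_amplitude)` pairs;
#'   each adds `amplitude * relative_amplitude * sin(2 pi * order * f0 * t)`.
#' @param phase Phase of the fundamental in radians (harmonic phases scale
#'   with order), default 0.
#' @return A new [emg_trace()] tagged with `"mains"` when `amplitude != 0`.
#' @export
add_mains <- function(trace, amplitude, f0 = 60, harmonics = NULL,
                      phase = 0) {
  fs <- trace_fs(trace)
  if (f0 >= fs / 2) rlang::abort("mains frequency above Nyquist")
  orders <- c(1, vapply(harmonics, `[`, numeric(1), 1))
  rel <- c(1, vapply(harmonics, `[`, numeric(1), 2))
  if (any(orders * f0 >= fs / 2)) {
    rlang::abort("harmonic frequency above Nyquist")
  }
  t <- trace$time
  extra <- rep(0, nrow(trace))
  for (i in seq_along(orders)) {
    extra <- extra +
      amplitude * rel[i] * sin(2 * pi * orders[i] * f0 * t + orders[i] * phase)
  }
  tag <- if (amplitude != 0) "mains" else character()
  trace_with(trace, trace$voltage + extra, tag)
}

#' Inject motion artifacts: baseline drift and impact bursts
#'
#' Adds (a) low-frequency electrode-shift drift -- shaped noise confined
#' below `drift_band` Hz, scaled to RMS `drift_amp` -- and (b) short
#' broadband bursts (Hann-windowed white noise of `impact_dur` seconds,
#' amplitude scale `impact_amp`) at `impact_times`, emulating impacts that
#' shift electrodes and inject brief high-frequency noise.
#'
#' @param trace An [emg_trace()].
#' @param drift_amp Drift RMS in volts (0 disables drift).
#' @param drift_band Upper edge of the drift band in Hz, default 5 (below a
#'   20 Hz front-end high-pass corner).
#' @param impact_times Numeric vector of burst centers in seconds, within
#'   `[0, duration]`.
#' @param impact_amp Burst amplitude scale in volts.
#' @param impact_dur Burst duration in seconds, default 0.02.
#' @param seed RNG seed for the stochastic parts.
#' @return A new [emg_trace()] tagged `"drift"` / `"impact"` as applicable.
#' @export
add_motion_artifact <- function(trace, drift_amp = 0, drift_band = 5,
                                impact_times = numeric(), impact_amp = 0,
                                impact_dur = 0.02, seed = 1L) {
  fs <- trace_fs(trace)
  dur <- trace_duration(trace)
  if (length(impact_times) && any(impact_times < 0 | impact_times > dur)) {
    rlang::abort("impact time outside trace span")
  }
  n <- nrow(trace)
  do_drift <- drift_amp > 0
  do_impact <- length(impact_times) > 0 && impact_amp > 0
  tags <- c(if (do_drift) "drift", if (do_impact) "impact")
  extra <- withr::with_seed(as.integer(seed), {
    add <- rep(0, n)
    if (do_drift) {
      add <- add + drift_amp * shaped_noise(n, fs, c(fs / n, drift_band), Inf)
    }
    if (do_impact) {
      m <- max(3L, round(impact_dur * fs))
      win <- 0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1))
      for (tc in impact_times) {
        i0 <- round(tc * fs) + 1L
        idx <- seq(i0 - m %/% 2L, length.out = m)
        keep <- idx >= 1L & idx <= n
        add[idx[keep]] <- add[idx[keep]] +
          impact_amp * (stats::rnorm(m) * win)[keep]
      }
    }
    add
  })
  trace_with(trace, trace$voltage + extra, tags)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trace
#'
#' @param object An [emg_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emg_trace
#' @export
autoplot.emg_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (V)")
}
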