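#' Analog front-end parameters
#'
#' Parametric description of the acquisition chain: an instrumentation
#' amplifier of fixed gain `ia_gain`, a unity-gain high-pass realized as two
#' cascaded identical first-order sections at `hp_fc` (the DC-blocking
#' architecture of integrated biopotential front-ends), a second-order
#' low-pass at `lp_fc` with gain `lp_gain` and quality factor `lp_q`, and a
#' mid-rail DC offset ahead of the digitizer. Defaults follow a 3.3 V
#' single-supply design: gain 100 V/V, 20 Hz high-pass, 500 Hz low-pass with
#' gain 9.27, offset at half supply (1.65 V).
#'
#' @param ia_gain Instrumentation-amplifier gain in V/V (> 0).
#' @param hp_fc High-pass design corner in Hz (each of the two cascaded
#'   first-order sections).
#' @param lp_fc Low-pass corner in Hz (> `hp_fc`).
#' @param lp_gain Low-pass stage gain in V/V (> 0).
#' @param lp_q Low-pass quality factor; default Butterworth `1/sqrt(2)`.
#'   Exposed because assembled hardware can peak above the design value.
#' @param v_offset DC offset in volts, strictly between the rails.
#' @param v_rail_lo,v_rail_hi Supply rails in volts.
#' @return A list of class `chain_params`.
#' @export
chain_params <- function(ia_gain = 100, hp_fc = 20, lp_fc = 500,
                         lp_gain = 9.27, lp_q = 1 / sqrt(2),
                         v_offset = 1.65, v_rail_lo = 0, v_rail_hi = 3.3) {
  stopifnot(
    ia_gain > 0, lp_gain > 0, lp_q > 0,
    hp_fc > 0, hp_fc < lp_fc,
    v_rail_lo < v_offset, v_offset < v_rail_hi
  )
  structure(
    list(ia_gain = ia_gain, hp_fc = hp_fc, lp_fc = lp_fc, lp_gain = lp_gain,
         lp_q = lp_q, v_offset = v_offset, v_rail_lo = v_rail_lo,
         v_rail_hi = v_rail_hi),
    class = "chain_params"
  )
}

# small-signal magnitude (linear) of the full chain at frequencies f,
# allowing per-section corner scale factors for the tolerance Monte Carlo
chain_mag <- function(params, f, hp_scale = c(1, 1), lp_scale = 1) {
  hp1 <- (f / (params$hp_fc * hp_scale[1]))
  hp2 <- (f / (params$hp_fc * hp_scale[2]))
  mag_hp <- hp1 / sqrt(1 + hp1^2) * hp2 / sqrt(1 + hp2^2)
  r <- f / (params$lp_fc * lp_scale)
  mag_lp <- 1 / sqrt((1 - r^2)^2 + (r / params$lp_q)^2)
  params$ia_gain * params$lp_gain * mag_hp * mag_lp
}

#' Logarithmic frequency grid
#'
#' @param f_lo,f_hi Grid limits in Hz.
#' @param points_per_decade Grid density; 200/decade keeps adjacent points
#'   within ~1.2% in frequency, dense enough for -3 dB interpolation.
#' @return Numeric vector of frequencies.
#' @export
bode_grid <- function(f_lo = 1, f_hi = 5000, points_per_decade = 200) {
  stopifnot(f_lo > 0, f_hi > f_lo)
  n <- ceiling(log10(f_hi / f_lo) * points_per_decade) + 1
  10^seq(log10(f_lo), log10(f_hi), length.out = n)
}

#' Small-signal frequency response of the chain
#'
#' Magnitude (in dB) of instrumentation amplifier x two cascaded first-order
#' high-pass sections x second-order low-pass, evaluated analytically;
#' offset and rails are ignored (small-signal). The default chain has a
#' mid-band gain of `20*log10(ia_gain * lp_gain)` ~ 59.3 dB.
#'
#' @param params A [chain_params()].
#' @param freqs Positive frequency grid in Hz; default [bode_grid()].
#' @return A tibble of class `freq_response` with columns `freq`,
#'   `magnitude_db`.
#' @examples
#' fr <- frequency_response(chain_params())
#' extract_cutoffs(fr)
#' @export
frequency_response <- function(params, freqs = bode_grid()) {
  stopifnot(inherits(params, "chain_params"))
  if (any(freqs <= 0)) rlang::abort("frequencies must be positive")
  if (is.unsorted(freqs, strictly = TRUE)) {
    rlang::abort("frequency grid must be strictly increasing")
  }
  out <- tibble::tibble(
    freq = freqs,
    magnitude_db = 20 * log10(chain_mag(params, freqs))
  )
  structure(out, params = params, class = c("freq_response", class(out)))
}

# interpolate the crossing of `target` dB between grid points i and i+1,
# linear in log-frequency
interp_crossing <- function(freq, db, i, target) {
  lf <- log10(freq[i]) + (target - db[i]) / (db[i + 1] - db[i]) *
    (log10(freq[i + 1]) - log10(freq[i]))
  10^lf
}

#' Extract the half-power (-3 dB) cutoff frequencies from a response curve
#'
#' Locates the two frequencies at which the magnitude falls
#' `10*log10(2)` ~ 3.01 dB below the curve's maximum (half power), by
#' log-frequency interpolation between bracketing grid points. Invariant to
#' adding a constant dB offset to the whole curve. A side on which the curve
#' never reaches the half-power level yields `NA` for that side.
#'
#' @param fr A `freq_response` (or any data frame with `freq`,
#'   `magnitude_db`).
#' @return Named numeric `c(f_low = , f_high = )` in Hz.
#' @export
extract_cutoffs <- function(fr) {
  db <- fr$magnitude_db
  find_crossings(fr$freq, db, max(db) - 10 * log10(2))
}

# locate the outermost crossings of `target` dB around the curve peak
find_crossings <- function(freq, db, target) {
  imax <- which.max(db)
  f_low <- NA_real_
  below <- which(db[seq_len(imax)] < target)
  if (length(below)) {
    i <- max(below) # last point below target left of the peak
    f_low <- interp_crossing(freq, db, i, target)
  }
  f_high <- NA_real_
  right <- seq(imax, length(db))
  below <- right[db[right] < target]
  if (length(below)) {
    i <- min(below) - 1L # first point below target right of the peak
    f_high <- interp_crossing(freq, db, i, target)
  }
  c(f_low = f_low, f_high = f_high)
}

#' Mid-band gain of the chain
#'
#' The design reference gain: the product of the stage gains,
#' `20*log10(ia_gain * lp_gain)` dB. For the default 100 V/V x 9.27 V/V
#' chain this is `20*log10(927)` ~ 59.3 dB.
#'
#' @param params A [chain_params()].
#' @return Gain in dB.
#' @export
midband_gain_db <- function(params) {
  20 * log10(params$ia_gain * params$lp_gain)
}

#' Half-power cutoffs of a chain relative to its mid-band gain
#'
#' Amplifier bandwidth is conventionally quoted as the half-power points
#' relative to the mid-band (design reference) gain rather than the curve's
#' absolute maximum; with the high-pass and low-pass corners only a factor
#' ~25 apart, the realized curve maximum sags a fraction of a dB below the
#' stage-gain product, which would otherwise bias the extracted corners.
#' For the default chain this gives `f_low` ~ 31.1 Hz -- the analytic
#' half-power point of two cascaded 20 Hz first-order sections,
#' `20 * sqrt(1 / (sqrt(2) - 1))`.
#'
#' @param params A [chain_params()].
#' @param freqs Evaluation grid, default [bode_grid()].
#' @return Named numeric `c(f_low = , f_high = )` in Hz.
#' @export
chain_cutoffs <- function(params, freqs = bode_grid()) {
  fr <- frequency_response(params, freqs)
  find_crossings(fr$freq, fr$magnitude_db,
                 midband_gain_db(params) - 10 * log10(2))
}

# biquad/one-pole coefficients, bilinear transform with corner prewarping
hp1_coefs <- function(fc, fs) {
  k <- tan(pi * fc / fs)
  list(b = c(1, -1) / (1 + k), a = c(1, (k - 1) / (k + 1)))
}

lp2_coefs <- function(fc, fs, q) {
  k <- tan(pi * fc / fs)
  norm <- 1 / (1 + k / q + k^2)
  list(
    b = c(k^2, 2 * k^2, k^2) * norm,
    a = c(1, 2 * (k^2 - 1) * norm, (1 - k / q + k^2) * norm)
  )
}

#' Apply the front-end chain to a trace in the time domain
#'
#' Runs the discretized filters (bilinear transform, corners prewarped),
#' applies the stage gains, shifts by the DC offset and hard-clips to the
#' supply rails. A zero input therefore yields a constant `v_offset` output.
#' Steady-state sinusoidal gain matches [frequency_response()]; allow ~5
#' high-pass time constants of transient before asserting amplitudes.
#'
#' @param trace An [emg_trace()]; `trace_fs(trace)` must be at least
#'   `10 * lp_fc` so the bilinear discretization stays accurate.
#' @param params A [chain_params()].
#' @return An [emg_trace()] of the conditioned signal (volts at the ADC pin),
#'   tagged `"chain"`.
#' @export
apply_chain <- function(trace, params) {
  fs <- trace_fs(trace)
  if (fs < 10 * params$lp_fc) {
    rlang::abort(sprintf(
      "fs_sim = %g Hz too low to emulate a %g Hz low-pass (need >= 10x)",
      fs, params$lp_fc
    ))
  }
  hp <- hp1_coefs(params$hp_fc, fs)
  lp <- lp2_coefs(params$lp_fc, fs, params$lp_q)
  x <- trace$voltage
  x <- signal::filter(hp$b, hp$a, x)
  x <- signal::filter(hp$b, hp$a, x)
  x <- signal::filter(lp$b, lp$a, x)
  v <- params$ia_gain * params$lp_gain * as.numeric(x) + params$v_offset
  v <- pmin(pmax(v, params$v_rail_lo), params$v_rail_hi)
  trace_with(trace, v, "chain")
}

#' Component-tolerance specification
#'
#' @param r_tol Relative resistor tolerance (default 0.01, i.e. 1%).
#' @param c_tol Relative capacitor tolerance (default 0.10, i.e. 10%).
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed RNG seed.
#' @return A list of class `tolerance_spec`.
#' @export
tolerance_spec <- function(r_tol = 0.01, c_tol = 0.10, n_draws = 500,
                           seed = 1L) {
  stopifnot(
    r_tol >= 0, r_tol < 0.5, c_tol >= 0, c_tol < 0.5, n_draws >= 1
  )
  structure(
    list(r_tol = r_tol, c_tol = c_tol, n_draws = as.integer(n_draws),
         seed = as.integer(seed)),
    class = "tolerance_spec"
  )
}

#' Corner-frequency scale factor for component deviations
#'
#' An RC corner `1/(2*pi*R*C)` with relative deviations `delta_r`, `delta_c`
#' moves by the factor `1/((1 + delta_r) * (1 + delta_c))`: capacitors at
#' -10% with nominal resistors scale every corner by `1/0.9` ~ 1.11.
#'
#' @param delta_r,delta_c Relative component deviations.
#' @return The multiplicative corner-frequency factor.
#' @export
corner_scale_factor <- function(delta_r, delta_c) {
  1 / ((1 + delta_r) * (1 + delta_c))
}

#' Monte Carlo of cutoff-frequency spread under component tolerances
#'
#' For each draw, every first-order section corner is scaled by
#' [corner_scale_factor()] with independent uniform deviations within
#' tolerance (one RC pair per first-order high-pass section); the
#' second-order low-pass corner `1/(2*pi*sqrt(R1*C1*R2*C2))` is scaled by
#' the geometric mean of its two pairs' factors. Cutoffs are then extracted
#' from the perturbed response. Reproducible for a fixed seed.
#'
#' @param params A [chain_params()].
#' @param tol A [tolerance_spec()].
#' @param freqs Evaluation grid, default [bode_grid()].
#' @return A tibble of class `tol_mc` with columns `draw`, `f_low`, `f_high`
#'   and the nominal cutoffs as attribute `nominal`.
#' @export
tolerance_monte_carlo <- function(params, tol = tolerance_spec(),
                                  freqs = bode_grid()) {
  stopifnot(inherits(params, "chain_params"), inherits(tol, "tolerance_spec"))
  nominal <- extract_cutoffs(frequency_response(params, freqs))
  draws <- withr::with_seed(tol$seed, {
    purrr::map(seq_len(tol$n_draws), function(i) {
      dr <- stats::runif(4, -tol$r_tol, tol$r_tol)
      dc <- stats::runif(4, -tol$c_tol, tol$c_tol)
      fac <- corner_scale_factor(dr, dc)
      hp_scale <- fac[1:2]
      lp_scale <- sqrt(fac[3] * fac[4])
      db <- 20 * log10(chain_mag(params, freqs, hp_scale, lp_scale))
      cut <- extract_cutoffs(tibble::tibble(freq = freqs, magnitude_db = db))
      tibble::tibble(draw = i, f_low = cut[["f_low"]],
                     f_high = cut[["f_high"]])
    })
  })
  out <- dplyr::bind_rows(draws)
  structure(out, nominal = nominal, tol = tol, params = params,
            class = c("tol_mc", class(out)))
}

#' Digitize a conditioned trace (sample-and-hold ADC model)
#'
#' Decimates the chain output to the acquisition rate (every k-th sample;
#' the low-pass stage is the anti-alias filter) and quantizes with a
#' mid-tread uniform SAR-ADC model: `code = clamp(floor(v / vref * 2^bits),
#' 0, 2^bits - 1)`. Mid-rail 1.65 V on a 3.3 V / 12-bit converter maps to
#' code 2048; reconstructing `(code + 0.5) * vref / 2^bits` is within half
#' an LSB for in-range inputs.
#'
#' @param trace An [emg_trace()] (typically [apply_chain()] output);
#'   `trace_fs(trace)` must be an integer multiple of `fs`.
#' @param fs Acquisition sampling rate in Hz, default 1000 (1 kS/s).
#' @param bits ADC resolution, default 12.
#' @param vref Full-scale reference in volts, default 3.3.
#' @return A tibble of class `digital_trace` with columns `time`, `code`
#'   and attributes `fs`, `bits`, `vref`.
#' @export
quantize <- function(trace, fs = 1000, bits = 12, vref = 3.3) {
  fs_sim <- trace_fs(trace)
  k <- fs_sim / fs
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort(sprintf(
      "fs_sim (%g Hz) must be an integer multiple of fs (%g Hz)", fs_sim, fs
    ))
  }
  k <- as.integer(round(k))
  v <- trace$voltage[seq(1L, nrow(trace), by = k)]
  code <- pmin(pmax(floor(v / vref * 2^bits), 0), 2^bits - 1)
  out <- tibble::tibble(
    time = (seq_along(code) - 1) / fs,
    code = as.integer(code)
  )
  structure(out, fs = fs, bits = bits, vref = vref,
            class = c("digital_trace", class(out)))
}

#' Reconstruct voltages from ADC codes
#'
#' Mid-step reconstruction `(code + 0.5) * vref / 2^bits`.
#'
#' @param codes Integer codes or a `digital_trace`.
#' @param bits,vref Converter parameters (taken from the trace when given
#'   one).
#' @return Numeric voltages.
#' @export
codes_to_volts <- function(codes, bits = 12, vref = 3.3) {
  if (inherits(codes, "digital_trace")) {
    bits <- attr(codes, "bits")
    vref <- attr(codes, "vref")
    codes <- codes$code
  }
  (codes + 0.5) * vref / 2^bits
}

#' Plot a frequency response (Bode magnitude)
#'
#' @param object A `freq_response`.
#' @param ... Unused.
#' @return A ggplot with log-frequency axis and the half-power cutoffs
#'   marked.
#' @method autoplot freq_response
#' @export
autoplot.freq_response <- function(object, ...) {
  cuts <- extract_cutoffs(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$freq, .data$magnitude_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude (dB)")
  for (f in cuts[!is.na(cuts)]) {
    p <- p + ggplot2::geom_vline(xintercept = f, linetype = "dashed",
                                 colour = "grey50")
  }
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the tolerance Monte Carlo draws
#' @param x A `tol_mc`.
#' @param ... Unused.
#' @return A tibble with one row per draw (`draw`, `f_low`, `f_high`).
#' @method tidy tol_mc
#' @export
tidy.tol_mc <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize a tolerance Monte Carlo run
#'
#' @param x A `tol_mc`.
#' @param band Relative corner band to report coverage for; default
#'   `c(0.9, 1.11)`, the worst-case capacitor-tolerance factors of a 10%
#'   part.
#' @param ... Unused.
#' @return One-row tibble with nominal cutoffs, spread quantiles and the
#'   fraction of draws whose cutoffs lie within `band` times nominal.
#' @method glance tol_mc
#' @export
glance.tol_mc <- function(x, band = c(0.9, 1.11), ...) {
  nominal <- attr(x, "nominal")
  in_band <- function(f, f0) f >= band[1] * f0 & f <= band[2] * f0
  tibble::tibble(
    n_draws = nrow(x),
    f_low_nominal = nominal[["f_low"]],
    f_high_nominal = nominal[["f_high"]],
    f_low_q05 = stats::quantile(x$f_low, 0.05, names = FALSE),
    f_low_q95 = stats::quantile(x$f_low, 0.95, names = FALSE),
    f_high_q05 = stats::quantile(x$f_high, 0.05, names = FALSE),
    f_high_q95 = stats::quantile(x$f_high, 0.95, names = FALSE),
    coverage_low = mean(in_band(x$f_low, nominal[["f_low"]])),
    coverage_high = mean(in_band(x$f_high, nominal[["f_high"]]))
  )
}
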