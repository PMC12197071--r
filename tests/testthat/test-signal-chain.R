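test_that("frequency response has the designed mid-band gain and asymptotes", {
  params <- chain_params()
  expect_equal(midband_gain_db(params), 20 * log10(100 * 9.27))

  fr <- frequency_response(params, bode_grid(0.01, 1e5))
  # DC is blocked: magnitude plunges at low frequency
  expect_lt(fr$magnitude_db[1], -60)
  # above the low-pass corner the rolloff approaches -40 dB/decade
  hi <- fr$freq >= 2e4
  slope <- stats::coef(stats::lm(fr$magnitude_db[hi] ~
                                   log10(fr$freq[hi])))[2]
  expect_equal(unname(slope), -40, tolerance = 0.02)

  expect_error(frequency_response(params, c(-1, 10)), "positive")
})

test_that("the high-pass cascade contributes -6.02 dB at its corner", {
  # isolate the HP: unit gains, low-pass corner pushed far away
  p <- chain_params(ia_gain = 1, hp_fc = 20, lp_fc = 1e5, lp_gain = 1)
  fr <- frequency_response(p, bode_grid(1, 5e4))
  at <- function(f) {
    stats::approx(log10(fr$freq), fr$magnitude_db, xout = log10(f))$y
  }
  # two first-order sections at their common corner: 2 x -3.01 dB
  expect_equal(at(20) - at(2000), -2 * 10 * log10(2), tolerance = 1e-3)
})

test_that("cutoff extraction matches analytic corners and ignores dB offsets", {
  # two cascaded 20 Hz sections: half-power from mid-band at
  # 20 * sqrt(1 / (sqrt(2) - 1)) ~ 31.08 Hz
  f_analytic <- 20 * sqrt(1 / (sqrt(2) - 1))
  cuts <- chain_cutoffs(chain_params())
  expect_equal(cuts[["f_low"]], f_analytic, tolerance = 2e-3)

  # HP-only curve: the plateau is the maximum, so the plain extractor
  # lands on the same analytic corner
  p <- chain_params(ia_gain = 1, hp_fc = 20, lp_fc = 1e6, lp_gain = 1)
  cuts_hp <- extract_cutoffs(frequency_response(p, bode_grid(1, 1e4)))
  expect_equal(cuts_hp[["f_low"]], f_analytic, tolerance = 2e-3)

  # a single first-order section cuts off at its corner by definition
  f <- bode_grid(1, 1000)
  x <- f / 20
  one_pole <- tibble::tibble(
    freq = f, magnitude_db = 20 * log10(x / sqrt(1 + x^2))
  )
  expect_equal(extract_cutoffs(one_pole)[["f_low"]], 20, tolerance = 2e-3)
  expect_true(is.na(extract_cutoffs(one_pole)[["f_high"]]))

  # ideal rectangular band-pass
  rect <- tibble::tibble(
    freq = f,
    magnitude_db = ifelse(f >= 50 & f <= 100, 0, -80)
  )
  cr <- extract_cutoffs(rect)
  expect_equal(cr[["f_low"]], 50, tolerance = 0.012)
  expect_equal(cr[["f_high"]], 100, tolerance = 0.012)

  # invariance to a constant dB offset
  shifted <- dplyr::mutate(one_pole, magnitude_db = magnitude_db + 17)
  expect_equal(extract_cutoffs(shifted), extract_cutoffs(one_pole),
               tolerance = 1e-12)
})

test_that("time-domain chain: offset, clipping and steady-state gain", {
  params <- chain_params()
  z <- zero_trace(0.5, 10000)
  out <- apply_chain(z, params)
  expect_true(all(out$voltage == params$v_offset))

  # overdrive clips exactly to the rails
  big <- add_mains(zero_trace(1, 10000), amplitude = 0.1, f0 = 100)
  clipped <- apply_chain(big, params)
  expect_equal(min(clipped$voltage), 0)
  expect_equal(max(clipped$voltage), 3.3)

  # mid-band sinusoid: output amplitude ~ a x (analytic gain at f)
  a <- 1e-4
  f0 <- 100
  tr <- add_mains(zero_trace(1.5, 10000), a, f0 = f0)
  v <- apply_chain(tr, params)$voltage
  tail <- v[5001:15000] - params$v_offset # discard transient
  amp <- sqrt(2 * mean(tail^2))
  hp <- (f0 / 20) / sqrt(1 + (f0 / 20)^2)
  r <- f0 / 500
  lp <- 1 / sqrt((1 - r^2)^2 + (r * sqrt(2))^2)
  expect_equal(amp, a * 927 * hp^2 * lp, tolerance = 0.02)

  expect_error(apply_chain(zero_trace(0.1, 2000), params), "low")
})

test_that("quantizer codes, clamps and reconstructs within half an LSB", {
  mk <- function(v) emg_trace(rep(v, 10), 1000)
  expect_true(all(quantize(mk(1.65))$code == 2048))
  expect_true(all(quantize(mk(-0.5))$code == 0))
  expect_true(all(quantize(mk(5))$code == 4095))

  # decimation picks every k-th sample
  tr <- emg_trace(seq(0, 3.3, length.out = 10000), 10000)
  dt <- quantize(tr, fs = 1000)
  expect_equal(nrow(dt), 1000)

  # reconstruction error bounded by half an LSB for in-range inputs
  set.seed(42)
  v <- stats::runif(5000, 0.01, 3.29)
  q <- quantize(emg_trace(v, 1000), fs = 1000)
  expect_lt(max(abs(v - codes_to_volts(q))), 0.5 * 3.3 / 4096 + 1e-12)

  expect_error(quantize(emg_trace(rep(0, 100), 1500), fs = 1000),
               "multiple")
})

test_that("tolerance Monte Carlo: degenerate and worst-case behavior", {
  # zero tolerances: every draw equals nominal
  mc0 <- tolerance_monte_carlo(chain_params(),
                               tolerance_spec(r_tol = 0, c_tol = 0,
                                              n_draws = 5))
  nominal <- attr(mc0, "nominal")
  expect_true(all(abs(mc0$f_low - nominal[["f_low"]]) < 1e-9))
  expect_true(all(abs(mc0$f_high - nominal[["f_high"]]) < 1e-9))

  # capacitors all at -10%, resistors nominal: corners scale by 1/0.9
  expect_equal(corner_scale_factor(0, -0.1), 1 / 0.9)
  expect_equal(round(corner_scale_factor(0, -0.1), 2), 1.11)

  # reproducibility
  mc1 <- tolerance_monte_carlo(chain_params(),
                               tolerance_spec(n_draws = 50, seed = 7))
  mc2 <- tolerance_monte_carlo(chain_params(),
                               tolerance_spec(n_draws = 50, seed = 7))
  expect_identical(mc1$f_low, mc2$f_low)

  # glance reports nominal corners and band coverage
  g <- glance(mc1)
  expect_equal(g$f_low_nominal, nominal[["f_low"]])
  expect_true(g$coverage_low >= 0 && g$coverage_low <= 1)
})
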