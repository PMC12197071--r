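test_that("generated traces have the right length, mean and envelope-scaled RMS", {
  spec <- synth_spec(seed = 3)
  tr <- generate_semg(spec, duration = 5, fs_sim = 10000)
  expect_equal(nrow(tr), 50000)
  expect_equal(trace_fs(tr), 10000)
  expect_lt(abs(mean(tr$voltage)), 1e-8) # zero-mean (band excludes DC)

  # sustained contraction: RMS tracks rms_max
  expect_equal(sqrt(mean(tr$voltage^2)), spec$rms_max, tolerance = 0.1)

  # degenerate envelope: rest-level RMS
  rest <- generate_semg(synth_spec(envelope = 0, seed = 3), 5, 10000)
  expect_equal(sqrt(mean(rest$voltage^2)), spec$rms_rest, tolerance = 0.1)

  # piecewise envelope: quiet half vs active half differ by design ratio
  env <- data.frame(time = c(0, 2.49, 2.51, 5), level = c(0, 0, 1, 1))
  tr2 <- generate_semg(synth_spec(envelope = env, seed = 5,
                                  rms_rest = 1e-5), 5, 10000)
  r1 <- sqrt(mean(tr2$voltage[tr2$time < 2.4]^2))
  r2 <- sqrt(mean(tr2$voltage[tr2$time > 2.6]^2))
  expect_equal(r1, 1e-5, tolerance = 0.15)
  expect_equal(r2, 1e-3, tolerance = 0.15)
})

test_that("identical spec and seed give bit-identical traces", {
  spec <- synth_spec(seed = 11)
  a <- generate_semg(spec, 1, 10000)
  b <- generate_semg(spec, 1, 10000)
  expect_identical(a$voltage, b$voltage)
  c <- generate_semg(synth_spec(seed = 12), 1, 10000)
  expect_false(identical(a$voltage, c$voltage))
})

test_that("generation rejects bad durations and Nyquist violations", {
  expect_error(generate_semg(synth_spec(), 0, 10000), "duration")
  expect_error(generate_semg(synth_spec(), -1, 10000), "duration")
  expect_error(generate_semg(synth_spec(), 1, fs_sim = 900), "Nyquist")
})

test_that("spectral mass concentrates in the sEMG band (periodogram oracle)", {
  tr <- generate_semg(synth_spec(seed = 1), duration = 5, fs_sim = 10000)
  sp <- stats::spec.pgram(stats::ts(tr$voltage, frequency = 10000),
                          plot = FALSE, taper = 0)
  frac_main <- sum(sp$spec[sp$freq >= 20 & sp$freq <= 250]) / sum(sp$spec)
  # value pinned from the independent periodogram oracle at this seed
  expect_equal(frac_main, 0.720019, tolerance = 1e-4)
  expect_gte(frac_main, 0.60)

  # spectral confinement: mass outside [band_lo/2, 2*band_hi] is < 5%
  frac_out <- sum(sp$spec[sp$freq < 10 | sp$freq > 1000]) / sum(sp$spec)
  expect_lt(frac_out, 0.05)
})

test_that("mains injection is additive, band-exact and linear", {
  tr <- generate_semg(synth_spec(seed = 2), 1, 10000)

  # zero amplitude is the identity
  expect_identical(add_mains(tr, 0)$voltage, tr$voltage)

  # pure sinusoid on an exact bin carries A^2/2 of one-sided power
  a <- 2e-3
  z <- add_mains(zero_trace(1, 10000), a, f0 = 60)
  sp <- power_spectrum(z, segment = 1000, window = "rect",
                       scale = "spectrum")
  i <- which.min(abs(sp$freq - 60))
  expect_equal(sp$freq[i], 60)
  expect_equal(sp$power[i], a^2 / 2, tolerance = 1e-9)
  expect_lt(max(sp$power[-i]), a^2 / 2 * 1e-20)

  # a second harmonic puts a secondary peak at 120 Hz
  z2 <- add_mains(zero_trace(1, 10000), a, f0 = 60,
                  harmonics = list(c(2, 0.5)))
  sp2 <- power_spectrum(z2, segment = 1000, window = "rect",
                        scale = "spectrum")
  i120 <- which.min(abs(sp2$freq - 120))
  expect_equal(sp2$power[i120], (0.5 * a)^2 / 2, tolerance = 1e-9)

  # linearity: two injections equal one injection of the summed sinusoid
  s1 <- add_mains(add_mains(tr, 1e-3), 2e-3)
  s2 <- add_mains(tr, 3e-3)
  expect_equal(s1$voltage, s2$voltage, tolerance = 1e-12)

  # harmonic expressed as a fundamental at the harmonic frequency
  h1 <- add_mains(tr, a, f0 = 60, harmonics = list(c(2, 0.5)))
  h2 <- add_mains(add_mains(tr, a, f0 = 60), 0.5 * a, f0 = 120)
  expect_equal(h1$voltage, h2$voltage, tolerance = 1e-12)

  expect_error(add_mains(tr, 1e-3, f0 = 6000), "Nyquist")
  expect_error(add_mains(tr, 1e-3, harmonics = list(c(90, 1))), "Nyquist")
})

test_that("motion artifacts: identity when disabled, drift crushed by the high-pass", {
  tr <- zero_trace(2, 10000)
  expect_identical(add_motion_artifact(tr, drift_amp = 0)$voltage,
                   tr$voltage)
  expect_error(
    add_motion_artifact(tr, impact_times = 3.5, impact_amp = 1e-3),
    "outside"
  )

  # drift confined below 5 Hz: after the chain, attenuation is at least the
  # two-pole high-pass rolloff evaluated at the drift band's upper edge
  params <- chain_params()
  drifted <- add_motion_artifact(tr, drift_amp = 1e-3, drift_band = 5,
                                 seed = 4)
  out <- apply_chain(drifted, params)
  # analytic two-pole attenuation at the band top (5 Hz), LP ~ unity there
  x <- 5 / params$hp_fc
  gain_bound <- params$ia_gain * params$lp_gain * (x / sqrt(1 + x^2))^2
  out_rms <- sqrt(mean((out$voltage - params$v_offset)^2))
  expect_lt(out_rms, 1e-3 * gain_bound * 1.2)
})

test_that("an impact burst stays temporally confined after the chain", {
  tr <- zero_trace(3, 10000)
  burst <- 0.02
  hit <- add_motion_artifact(tr, impact_times = 1.5, impact_amp = 5e-4,
                             impact_dur = burst, seed = 9)
  out <- apply_chain(hit, chain_params())
  dev <- abs(out$voltage - chain_params()$v_offset)
  peak <- max(dev)
  inside <- out$time >= 1.5 - 3 * burst & out$time <= 1.5 + 3 * burst
  expect_gt(peak, 0) # the burst is visible at all
  expect_lt(max(dev[!inside]), 0.01 * peak) # ring-down confined
})
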