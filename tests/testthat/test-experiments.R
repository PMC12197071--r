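test_that("welch spectrum: peak location, flatness, Parseval", {
  # a pure tone dominates its own bin
  tone <- add_mains(zero_trace(4, 1000), 1e-3, f0 = 60)
  sp <- power_spectrum(tone, segment = 1024)
  expect_lt(abs(sp$freq[which.max(sp$power)] - 60), 1000 / 1024)

  # white noise is flat within +-3 dB at sufficient averaging (fixed seed)
  set.seed(2024)
  wn <- stats::rnorm(2^16)
  spw <- power_spectrum(wn, fs = 1000, segment = 1024)
  db <- spw$power_db[spw$freq > 5 & spw$freq < 495]
  expect_lt(max(abs(db - stats::median(db))), 3)

  # energy conservation: integrated density ~ mean square power
  df <- spw$freq[2] - spw$freq[1]
  expect_equal(sum(spw$power) * df, mean(wn^2), tolerance = 0.01)

  expect_error(power_spectrum(stats::rnorm(100), fs = 1000, segment = 1024),
               class = "semgsim_short_signal")
  expect_error(power_spectrum(stats::rnorm(3000), segment = 1024),
               "fs")
})

test_that("mains delta: zero for identical spectra, invariant to common pickup", {
  tr <- generate_semg(synth_spec(seed = 5), 10, 2000)
  sp <- power_spectrum(tr, segment = 1024)
  expect_equal(mains_delta(sp, sp), 0)

  # designed 40 dB rest-vs-contraction ratio is recovered at the 60 Hz bin
  rest <- generate_semg(synth_spec(envelope = 0, rms_rest = 1e-5,
                                   rms_max = 1e-3, seed = 21), 30, 2000)
  act <- generate_semg(synth_spec(envelope = 1, rms_rest = 1e-5,
                                  rms_max = 1e-3, seed = 22), 30, 2000)
  d <- mains_delta(power_spectrum(rest, segment = 1024),
                   power_spectrum(act, segment = 1024))
  expect_equal(d, 40, tolerance = 0.075) # dB, i.e. +-3 dB

  # identical weak mains added to both conditions barely moves the delta
  rest_m <- add_mains(rest, 1e-9)
  act_m <- add_mains(act, 1e-9)
  d_m <- mains_delta(power_spectrum(rest_m, segment = 1024),
                     power_spectrum(act_m, segment = 1024))
  expect_lt(abs(d_m - d), 0.1)

  sp_other <- power_spectrum(tr, segment = 512)
  expect_error(mains_delta(sp, sp_other), "grid")
})

test_that("autonomy arithmetic", {
  expect_identical(autonomy_estimate(180, 100), 1.8)
  expect_identical(autonomy_estimate(180, 180), 1)
  expect_identical(autonomy_estimate(0, 100), 0)
  expect_error(autonomy_estimate(180, 0), "positive")
})

test_that("timing raster: zero-referenced channels and packet-period intervals", {
  pk <- dplyr::bind_rows(make_packets(20, 1), make_packets(20, 2))
  log <- transmit(pk, link_params(loss_prob = 0, latency_jitter = 0,
                                  seed = 1))
  ras <- timing_raster(log)
  firsts <- ras |>
    dplyr::group_by(channel_id) |>
    dplyr::summarise(first = min(rel_time), .groups = "drop")
  expect_true(all(firsts$first == 0))
  dts <- ras$dt[!is.na(ras$dt)]
  expect_true(all(abs(dts - 0.120) < 1e-9))

  # one dropped packet doubles exactly one interval
  log2 <- log
  drop_row <- which(log2$channel_id == 1)[10]
  log2$dropped[drop_row] <- TRUE
  log2$recv_time[drop_row] <- NA
  ras2 <- timing_raster(log2)
  d1 <- ras2$dt[ras2$channel_id == 1 & !is.na(ras2$dt)]
  expect_equal(sum(abs(d1 - 0.240) < 1e-9), 1)
  expect_equal(sum(abs(d1 - 0.120) < 1e-9), length(d1) - 1)

  expect_error(timing_raster(transmit(pk, link_params(loss_prob = 1))),
               "delivered")
})

test_that("loss sweep: zero curve gives a zero table, QoS matches ground truth", {
  zero_curve <- function(d) 0 * d
  tab0 <- qos_vs_distance(distances = c(0, 100), n_channels = c(1, 2),
                          duration = 2, seed = 3, loss_curve = zero_curve)
  expect_true(all(tab0$lost == 0))
  expect_true(all(tab0$dropped == 0))
  expect_equal(nrow(tab0), 2 * 1 + 2 * 2)

  # a harsh monotone curve produces losses the hub accounts for exactly
  harsh <- function(d) loss_from_distance(d, p_max = 0.3, d50 = 40,
                                          scale = 15)
  tab <- qos_vs_distance(distances = c(0, 60, 100), n_channels = 2,
                         duration = 3, seed = 3, loss_curve = harsh)
  expect_gt(sum(tab$lost[tab$distance == 100]), 0)
  # hub QoS never exceeds the link's ground-truth drop count and equals it
  # up to drops after a channel's final delivered packet
  expect_true(all(tab$lost <= tab$dropped))
  totals <- tab |>
    dplyr::group_by(distance) |>
    dplyr::summarise(total = sum(lost), .groups = "drop")
  expect_equal(nrow(totals), 3)
})

test_that("end-to-end: lossless identity and frame accounting", {
  sess <- small_session(n_channels = 3, loss = 0, seed = 10, duration = 2)
  for (ch in 1:3) {
    q <- sess$digital[[ch]]$code
    n_full <- (length(q) %/% packet_samples()) * packet_samples()
    expect_identical(sess$recording$streams[[as.character(ch)]],
                     as.integer(q[seq_len(n_full)]))
  }
  g <- glance(sess)
  expect_equal(g$dropped, 0)
  expect_equal(g$qos_total, 0)

  # per-channel frame membership is bounded by the packetization floor
  sess5 <- run_end_to_end(e2e_config(n_channels = 6, duration = 5,
                                     seed = 2))
  floor_packets <- (5 * 1000) %/% packet_samples()
  expect_equal(floor_packets, 41)
  membership <- purrr::map(sess5$frames, ~ purrr::map_int(.x$entries,
                                                          "channel_id"))
  per_ch <- table(unlist(membership))
  expect_true(all(per_ch <= 41))
  expect_equal(unname(vapply(
    as.character(1:6),
    function(k) length(sess5$recording$streams[[k]]), integer(1)
  )), rep(41 * 120L, 6))
})

test_that("session summaries line up with the transport oracle", {
  sess <- small_session(n_channels = 4, loss = 0.15, seed = 77,
                        duration = 3)
  t <- tidy(sess)
  o <- qos_oracle(sess$log)
  expect_equal(t$qos, o$dropped_detectable)
  expect_equal(t$sent, o$sent)
  expect_equal(t$delivered, o$delivered_n)
  full_eq <- o$head_delivered & o$tail_delivered
  expect_equal(t$qos[full_eq], t$dropped[full_eq])
})
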