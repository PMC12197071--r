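# number of ADC codes per radio packet; the sensor fills a fixed-length
# vector before broadcasting, giving a 0.120 s cadence at 1 kS/s
PACKET_SAMPLES <- 120L
# wire layout: 1 byte channel id + 4 byte counter + 120 x 2-byte samples
PACKET_BYTES <- 1L + 4L + 2L * PACKET_SAMPLES
COUNTER_MOD <- 2^32

#' Packet and frame wire-format constants
#'
#' Each radio packet carries a 1-byte channel identifier (1-6), a 4-byte
#' little-endian incrementing counter (unsigned 32-bit, wraparound), and 120
#' ADC codes as 2-byte little-endian words (12-bit value in the low bits):
#' 245 bytes, under the radio's 250-byte message bound. 16-bit containers
#' are used instead of 12-bit packing for inspectability.
#'
#' @return `packet_samples()`: codes per packet (120); `packet_bytes()`:
#'   encoded packet length in bytes (245).
#' @export
packet_samples <- function() PACKET_SAMPLES

#' @rdname packet_samples
#' @export
packet_bytes <- function() PACKET_BYTES

#' Construct a sample packet
#'
#' @param channel_id Integer 1-6.
#' @param counter Unsigned 32-bit packet counter (stored as a double;
#'   wraparound at `2^32`).
#' @param samples Exactly 120 ADC codes in `[0, 4095]`.
#' @return A list of class `sample_packet`.
#' @export
sample_packet <- function(channel_id, counter, samples) {
  channel_id <- as.integer(channel_id)
  if (is.na(channel_id) || channel_id < 1L || channel_id > 6L) {
    rlang::abort("channel_id must be in 1..6", class = "semgsim_bad_packet")
  }
  counter <- as.numeric(counter) %% COUNTER_MOD
  samples <- as.integer(samples)
  if (length(samples) != PACKET_SAMPLES) {
    rlang::abort(sprintf("samples must have length %d", PACKET_SAMPLES),
                 class = "semgsim_bad_packet")
  }
  if (any(samples < 0L | samples > 4095L)) {
    rlang::abort("samples must be 12-bit codes in [0, 4095]",
                 class = "semgsim_bad_packet")
  }
  structure(list(channel_id = channel_id, counter = counter,
                 samples = samples),
            class = "sample_packet")
}

#' Split an ADC code stream into fixed-size packets
#'
#' Consecutive non-overlapping blocks of 120 codes with counters running
#' from `start_counter`; a trailing partial block is withheld (the sensor
#' only transmits full vectors), so 5000 codes yield `floor(5000/120) = 41`
#' packets.
#'
#' @param codes Integer ADC codes, or a `digital_trace`.
#' @param channel_id Integer 1-6.
#' @param start_counter First packet counter, default 0.
#' @return A tibble with columns `channel_id`, `counter`, `samples`
#'   (list-column of length-120 integer vectors).
#' @export
packetize <- function(codes, channel_id, start_counter = 0) {
  if (inherits(codes, "digital_trace")) codes <- codes$code
  channel_id <- as.integer(channel_id)
  if (is.na(channel_id) || channel_id < 1L || channel_id > 6L) {
    rlang::abort("channel_id must be in 1..6")
  }
  n_pkt <- length(codes) %/% PACKET_SAMPLES
  if (n_pkt == 0L) {
    return(tibble::tibble(channel_id = integer(), counter = numeric(),
                          samples = list()))
  }
  idx <- seq_len(n_pkt * PACKET_SAMPLES)
  blocks <- split(as.integer(codes[idx]),
                  rep(seq_len(n_pkt), each = PACKET_SAMPLES))
  tibble::tibble(
    channel_id = channel_id,
    counter = (start_counter + seq_len(n_pkt) - 1) %% COUNTER_MOD,
    samples = unname(blocks)
  )
}

# unsigned little-endian integer <-> raw helpers (counters exceed R's
# signed 32-bit range, so values travel as doubles)
uint_to_raw_le <- function(x, n_bytes) {
  as.raw(floor(x / 256^(seq_len(n_bytes) - 1)) %% 256)
}

raw_le_to_uint <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

#' Encode / decode a sample packet
#'
#' Fixed 245-byte layout (see [packet_bytes()]); `decode_packet()` is the
#' exact inverse of `encode_packet()`. Malformed input (wrong length,
#' channel id outside 1-6, sample word above 4095) raises a classed
#' `semgsim_malformed_packet` error.
#'
#' @param p A [sample_packet()], or anything with `channel_id`, `counter`,
#'   `samples` fields (a one-row [packetize()] tibble slice works).
#' @return `encode_packet()`: a raw vector of 245 bytes.
#' @export
encode_packet <- function(p) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1)
    p <- sample_packet(p$channel_id, p$counter, p$samples[[1]])
  } else if (!inherits(p, "sample_packet")) {
    p <- sample_packet(p$channel_id, p$counter, p$samples)
  }
  c(
    as.raw(p$channel_id),
    uint_to_raw_le(p$counter, 4L),
    as.raw(as.vector(rbind(p$samples %% 256L, p$samples %/% 256L)))
  )
}

#' @rdname encode_packet
#' @param bytes A raw vector as produced by `encode_packet()`.
#' @export
decode_packet <- function(bytes) {
  if (!is.raw(bytes) || length(bytes) != PACKET_BYTES) {
    rlang::abort(sprintf("malformed packet: expected %d bytes, got %d",
                         PACKET_BYTES, length(bytes)),
                 class = "semgsim_malformed_packet")
  }
  channel_id <- as.integer(bytes[1])
  if (channel_id < 1L || channel_id > 6L) {
    rlang::abort("malformed packet: channel id outside 1..6",
                 class = "semgsim_malformed_packet")
  }
  counter <- raw_le_to_uint(bytes[2:5])
  words <- as.integer(bytes[-(1:5)])
  samples <- words[c(TRUE, FALSE)] + 256L * words[c(FALSE, TRUE)]
  if (any(samples > 4095L)) {
    rlang::abort("malformed packet: sample word above 12-bit range",
                 class = "semgsim_malformed_packet")
  }
  sample_packet(channel_id, counter, samples)
}

#' Lossy-link parameters
#'
#' A seeded stand-in for the 2.45 GHz radio between sensor nodes and the
#' hub. Packets are dropped i.i.d. with probability `loss_prob`, or -- when
#' `burst` is given -- according to a two-state Gilbert-Elliott chain
#' (good/bad; drops happen in the bad state), which reproduces the loss
#' concentration bursts that i.i.d. loss cannot. `distance` maps through
#' [loss_from_distance()] when `loss_prob` is not given.
#'
#' @param loss_prob Per-packet drop probability in `[0, 1]`.
#' @param distance Link distance in meters (used when `loss_prob` is NULL).
#' @param burst Optional `c(p_good_to_bad, p_bad_to_good)` transition
#'   probabilities of the Gilbert-Elliott chain; NULL means i.i.d. loss.
#' @param latency_mean Mean one-way latency in seconds, default 0.002.
#' @param latency_jitter Uniform jitter added to the latency, seconds.
#' @param packet_period Packet send cadence in seconds, default 0.120
#'   (120 samples at 1 kS/s).
#' @param seed RNG seed.
#' @param loss_curve Distance-to-loss mapping, default [loss_from_distance()].
#' @return A list of class `link_params`.
#' @export
link_params <- function(loss_prob = NULL, distance = NULL, burst = NULL,
                        latency_mean = 0.002, latency_jitter = 0.001,
                        packet_period = PACKET_SAMPLES / 1000, seed = 1L,
                        loss_curve = loss_from_distance) {
  if (is.null(loss_prob)) {
    loss_prob <- if (is.null(distance)) 0 else loss_curve(distance)
  }
  stopifnot(
    loss_prob >= 0, loss_prob <= 1,
    latency_mean >= 0, latency_jitter >= 0, packet_period > 0
  )
  if (!is.null(burst)) {
    stopifnot(length(burst) == 2, all(burst >= 0), all(burst <= 1))
  }
  structure(
    list(loss_prob = loss_prob, burst = burst, latency_mean = latency_mean,
         latency_jitter = latency_jitter, packet_period = packet_period,
         seed = as.integer(seed)),
    class = "link_params"
  )
}

#' Monotone distance-to-loss curve
#'
#' A logistic curve `p_max * plogis((d - d50) / scale)`: a pure simulation
#' knob giving near-zero loss at short range rising smoothly toward `p_max`.
#'
#' @param distance Meters.
#' @param p_max Asymptotic loss probability, default 0.02.
#' @param d50 Distance of half-maximum loss, default 80 m.
#' @param scale Logistic width in meters, default 15.
#' @return Per-packet loss probability, monotone in `distance`.
#' @export
loss_from_distance <- function(distance, p_max = 0.02, d50 = 80,
                               scale = 15) {
  p_max * stats::plogis((distance - d50) / scale)
}

# per-channel drop indicator vector (i.i.d. or Gilbert-Elliott)
draw_drops <- function(n, link) {
  if (is.null(link$burst)) {
    stats::runif(n) < link$loss_prob
  } else {
    p_gb <- link$burst[1]
    p_bg <- link$burst[2]
    state_bad <- logical(n)
    bad <- FALSE
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      bad <- if (bad) u[i] >= p_bg else u[i] < p_gb
      state_bad[i] <- bad
    }
    state_bad
  }
}

#' Simulate transmission of packets over the lossy link
#'
#' Every packet gets a send time on the channel's cadence and is either
#' dropped or delivered with sampled latency; the link is FIFO per channel
#' (delivered packets keep send order). The complete log -- including
#' dropped packets -- is returned so loss accounting downstream can be
#' checked against ground truth. Deterministic for a fixed seed.
#'
#' @param packets A [packetize()] tibble (may mix channels).
#' @param link A [link_params()].
#' @param t0 Session start time in seconds, default 0.
#' @return A tibble of class `delivered_log` with columns `channel_id`,
#'   `counter`, `samples`, `send_time`, `recv_time` (NA when dropped),
#'   `dropped`.
#' @export
transmit <- function(packets, link, t0 = 0) {
  stopifnot(inherits(link, "link_params"))
  out <- withr::with_seed(link$seed, {
    packets |>
      dplyr::group_by(.data$channel_id) |>
      dplyr::group_modify(function(df, key) {
        n <- nrow(df)
        df$send_time <- t0 + (seq_len(n) - 1) * link$packet_period
        df$dropped <- draw_drops(n, link)
        lat <- link$latency_mean + stats::runif(n, 0, link$latency_jitter)
        recv <- df$send_time + lat
        # FIFO link: arrival order matches send order per channel
        recv <- cummax(recv)
        df$recv_time <- ifelse(df$dropped, NA_real_, recv)
        df
      }) |>
      dplyr::ungroup()
  })
  structure(out, link = link, class = c("delivered_log", class(out)))
}

#' Delivered / dropped views of a transmission log
#'
#' @param log A [transmit()] log.
#' @return A tibble of the delivered (resp. dropped) packets.
#' @export
delivered <- function(log) dplyr::filter(log, !.data$dropped)

#' @rdname delivered
#' @export
drop_log <- function(log) dplyr::filter(log, .data$dropped)

#' Ground-truth loss counts a counter-gap accountant can be checked against
#'
#' Counter-gap loss accounting detects a drop only when packets of the same
#' channel arrive on both sides of it: the first delivered packet merely
#' initializes the counter (drops before it leave no reference), and drops
#' after the last delivered packet leave no later counter to reveal the
#' gap. The exact oracle for the hub's per-channel QoS is therefore the
#' number of dropped packets whose counter lies strictly between the
#' channel's first and last delivered counters (`dropped_detectable`);
#' when a channel's first and final packets are both delivered this equals
#' the total drop count.
#'
#' @param log A [transmit()] log.
#' @return A tibble with one row per channel: `sent`, `delivered_n`,
#'   `dropped_total`, `dropped_detectable`, `head_delivered` /
#'   `tail_delivered` (were the channel's first / last packets
#'   delivered?).
#' @export
qos_oracle <- function(log) {
  log |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(
      sent = dplyr::n(),
      delivered_n = sum(!.data$dropped),
      dropped_total = sum(.data$dropped),
      dropped_detectable = sum(
        .data$dropped &
          .data$counter > suppressWarnings(
            min(.data$counter[!.data$dropped])) &
          .data$counter < suppressWarnings(
            max(.data$counter[!.data$dropped]))
      ),
      head_delivered = !.data$dropped[which.min(.data$counter)],
      tail_delivered = !.data$dropped[which.max(.data$counter)],
      .groups = "drop"
    )
}
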