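# serial-frame end marker; chosen as a two-byte constant the decoder can
# resynchronize on after corruption
FRAME_END <- as.raw(c(0x55, 0xAA))

#' Initialize hub channel bookkeeping
#'
#' One row per possible channel (1-6): activity flag, last-seen time, last
#' packet counter, cumulative lost-packet count (`qos_cum`, the running
#' counter-gap sum over the session), the gap count accumulated since the
#' last emitted frame (`qos_frame`, the per-frame QoS snapshot), and the
#' channel's payload queue (list-column).
#'
#' @return A tibble of class `hub_state`.
#' @export
hub_init <- function() {
  out <- tibble::tibble(
    channel_id = 1:6,
    active = FALSE,
    last_seen = NA_real_,
    last_counter = NA_real_,
    qos_cum = 0,
    qos_frame = 0,
    queue = purrr::map(1:6, ~ list())
  )
  structure(out, class = c("hub_state", class(out)))
}

#' Update a channel's lost-packet count from a packet counter
#'
#' The hub counts losses as gaps in the per-packet counter: each arriving
#' counter adds `(counter - last_counter - 1) mod 2^32` to the channel's
#' cumulative QoS (consecutive counters add 0; a jump from 5 to 9 adds 3).
#' The first packet on a channel initializes the counter and adds 0.
#'
#' @param states A [hub_init()] tibble.
#' @param channel_id Channel 1-6.
#' @param counter Arriving packet counter (unsigned 32-bit semantics).
#' @return Updated states.
#' @section Errors: a repeated counter raises `semgsim_duplicate_packet`;
#'   a modular gap above `2^31` (counter moving backwards) raises
#'   `semgsim_reorder_error`.
#' @export
qos_update <- function(states, channel_id, counter) {
  i <- match(channel_id, states$channel_id)
  last <- states$last_counter[i]
  if (is.na(last)) {
    states$last_counter[i] <- counter
    return(states)
  }
  if (counter == last) {
    rlang::abort(sprintf("duplicate counter %.0f on channel %d",
                         counter, channel_id),
                 class = "semgsim_duplicate_packet")
  }
  gap <- (counter - last - 1) %% COUNTER_MOD
  if (gap > 2^31) {
    rlang::abort(sprintf(
      "counter moved backwards on channel %d (last %.0f, got %.0f)",
      channel_id, last, counter
    ), class = "semgsim_reorder_error")
  }
  states$qos_cum[i] <- states$qos_cum[i] + gap
  states$qos_frame[i] <- states$qos_frame[i] + gap
  states$last_counter[i] <- counter
  states
}

#' Ingest one delivered packet into the hub
#'
#' Marks the channel active (a channel announces itself simply by sending
#' its ID), records the arrival time, updates QoS from the counter, and
#' enqueues the payload. A malformed packet (bad channel id or payload) is
#' rejected with a `semgsim_rejected_packet` warning and the state returned
#' unchanged -- reception on other channels is never interrupted.
#'
#' @param states A [hub_init()] tibble.
#' @param packet A [sample_packet()] or list with `channel_id`, `counter`,
#'   `samples`.
#' @param now Current simulation time in seconds (injected clock).
#' @return Updated states.
#' @export
ingest <- function(states, packet, now) {
  ok <- tryCatch(
    {
      if (!inherits(packet, "sample_packet")) {
        packet <- sample_packet(packet$channel_id, packet$counter,
                                packet$samples)
      }
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    rlang::warn(paste("packet rejected:", conditionMessage(ok)),
                class = "semgsim_rejected_packet")
    return(states)
  }
  states <- qos_update(states, packet$channel_id, packet$counter)
  i <- match(packet$channel_id, states$channel_id)
  states$active[i] <- TRUE
  states$last_seen[i] <- now
  states$queue[[i]] <- c(states$queue[[i]], list(packet$samples))
  states
}

#' Deactivate silent channels
#'
#' A channel that has not sent for more than `timeout` seconds is considered
#' deactivated (default 1 s); its queue is retained. This also releases the
#' synchronization barrier when one channel stalls while others accumulate
#' messages.
#'
#' @param states A [hub_init()] tibble.
#' @param now Current simulation time (seconds).
#' @param timeout Silence threshold in seconds; `Inf` disables expiry.
#' @return Updated states.
#' @export
expire <- function(states, now, timeout = 1.0) {
  stale <- states$active & (now - states$last_seen > timeout)
  states$active[stale] <- FALSE
  states
}

#' Construct a hub-to-host serial frame
#'
#' @param entries List of `list(channel_id, qos, payload)` per active
#'   channel; payloads are equal-length integer code vectors.
#' @return A list of class `serial_frame` with fields `bpc` (bytes per
#'   active channel), `n_c` (active channel count) and `entries`.
#' @export
serial_frame <- function(entries) {
  stopifnot(length(entries) >= 1)
  lens <- vapply(entries, function(e) length(e$payload), integer(1))
  if (length(unique(lens)) != 1) {
    rlang::abort("all frame payloads must have equal length")
  }
  structure(
    list(bpc = 2L * lens[1], n_c = length(entries), entries = entries),
    class = "serial_frame"
  )
}

#' Pop one synchronized frame from the hub queues
#'
#' Messages are synchronized across channels with a queue barrier: a frame
#' is emitted only when every active channel has at least one queued
#' payload, popping exactly one payload per active channel. Each entry
#' carries the channel id, the QoS snapshot (gaps accumulated since that
#' channel's previous frame, then reset) and the payload. Inactive channels
#' contribute nothing. With no active channels, or any active queue empty,
#' no frame is emitted.
#'
#' @param states A [hub_init()] tibble.
#' @return `list(states = updated states, frame = serial_frame or NULL)`.
#' @export
build_frame <- function(states) {
  act <- which(states$active)
  if (length(act) == 0 ||
      any(vapply(states$queue[act], length, integer(1)) == 0)) {
    return(list(states = states, frame = NULL))
  }
  entries <- purrr::map(act, function(i) {
    list(channel_id = states$channel_id[i],
         qos = states$qos_frame[i],
         payload = states$queue[[i]][[1]])
  })
  for (i in act) {
    states$queue[[i]] <- states$queue[[i]][-1]
    states$qos_frame[i] <- 0
  }
  list(states = states, frame = serial_frame(entries))
}

#' Encode / decode a hub-to-host serial frame
#'
#' Layout (all little-endian): 2-byte `bpc` (bytes per active channel),
#' 1-byte `n_c`, then per active channel 1-byte channel id, 2-byte QoS
#' snapshot (clamped to 65535), `bpc` payload bytes (2-byte sample words);
#' finally the 2-byte end marker `0x55 0xAA`. `decode_frame()` inverts
#' `encode_frame()`; inconsistent header/length or a missing end marker
#' raises a classed `semgsim_malformed_frame` error.
#'
#' @param f A [serial_frame()].
#' @return `encode_frame()`: a raw vector.
#' @export
encode_frame <- function(f) {
  stopifnot(inherits(f, "serial_frame"))
  body <- purrr::map(f$entries, function(e) {
    c(as.raw(e$channel_id),
      uint_to_raw_le(min(e$qos, 65535), 2L),
      as.raw(as.vector(rbind(e$payload %% 256L, e$payload %/% 256L))))
  })
  c(uint_to_raw_le(f$bpc, 2L), as.raw(f$n_c), unlist(body), FRAME_END)
}

#' @rdname encode_frame
#' @param bytes A raw vector holding exactly one encoded frame.
#' @export
decode_frame <- function(bytes) {
  fail <- function(msg) {
    rlang::abort(paste("malformed frame:", msg),
                 class = "semgsim_malformed_frame")
  }
  if (!is.raw(bytes) || length(bytes) < 7) fail("too short")
  n <- length(bytes)
  if (!identical(bytes[(n - 1):n], FRAME_END)) fail("missing end marker")
  bpc <- raw_le_to_uint(bytes[1:2])
  n_c <- as.integer(bytes[3])
  if (n_c < 1) fail("no channel entries")
  if (bpc < 2 || bpc %% 2 != 0) fail("bad bytes-per-channel")
  expected <- 3 + n_c * (3 + bpc) + 2
  if (n != expected) {
    fail(sprintf("length %d inconsistent with n_c=%d, bpc=%d", n, n_c, bpc))
  }
  entries <- purrr::map(seq_len(n_c), function(k) {
    off <- 3 + (k - 1) * (3 + bpc)
    id <- as.integer(bytes[off + 1])
    if (id < 1 || id > 6) fail("channel id outside 1..6")
    qos <- raw_le_to_uint(bytes[off + 2:3])
    words <- as.integer(bytes[off + 3 + seq_len(bpc)])
    payload <- words[c(TRUE, FALSE)] + 256L * words[c(FALSE, TRUE)]
    if (any(payload > 4095L)) fail("sample word above 12-bit range")
    list(channel_id = id, qos = qos, payload = payload)
  })
  serial_frame(entries)
}

#' Decode a byte stream of frames, resynchronizing after corruption
#'
#' Splits a concatenated frame stream on end markers and decodes each
#' frame. When a span fails to decode (corruption), the decoder first tries
#' extending to the next marker (the failed marker may be spurious payload
#' bytes), then skips the unparseable span and resumes at the following
#' marker, so one corrupted frame costs at most itself.
#'
#' @param bytes Raw vector of concatenated encoded frames.
#' @return List of decoded [serial_frame()] objects, in stream order.
#' @export
decode_frame_stream <- function(bytes) {
  n <- length(bytes)
  # positions where a marker ends
  is55 <- bytes == FRAME_END[1]
  isAA <- bytes == FRAME_END[2]
  marker_end <- which(c(FALSE, is55[-n] & isAA[-1]))
  frames <- list()
  starts <- 1L # candidate frame starts: stream head, then byte after each
  mi <- 1L     # marker consumed so far
  while (mi <= length(marker_end)) {
    span_end <- marker_end[mi]
    decoded <- NULL
    used_start <- NA_integer_
    for (s in starts) {
      if (s > span_end - 6L) break
      res <- tryCatch(decode_frame(bytes[s:span_end]), error = function(e) NULL)
      if (!is.null(res)) {
        decoded <- res
        used_start <- s
        break
      }
    }
    if (!is.null(decoded)) {
      frames[[length(frames) + 1L]] <- decoded
      starts <- span_end + 1L
    } else {
      starts <- sort(unique(c(starts, span_end + 1L)))
    }
    mi <- mi + 1L
  }
  frames
}

#' Run a hub session over a transmission log
#'
#' Drives the hub with the delivered packets of a [transmit()] log in
#' arrival order, using the receive timestamps as the injected clock:
#' before each ingest, silent channels are expired; after each ingest, as
#' many synchronized frames as the barrier allows are emitted.
#'
#' At end of stream, every channel eventually falls silent for `timeout`
#' seconds and deactivates; `flush = TRUE` (default) simulates that tail:
#' the clock is advanced past the timeout, drained channels deactivate and
#' the remaining queued payloads are emitted, so a finished session leaves
#' no data stuck behind the barrier.
#'
#' @param log A [transmit()] log (dropped rows are ignored).
#' @param timeout Channel-deactivation silence threshold in seconds.
#' @param flush Drain remaining queues at end of stream (see above).
#' @return A list of class `hub_session`: `frames` (list of
#'   [serial_frame()]), `frame_times` (emission clock per frame), `states`
#'   (final [hub_init()] tibble).
#' @export
hub_session <- function(log, timeout = 1.0, flush = TRUE) {
  del <- delivered(log) |> dplyr::arrange(.data$recv_time, .data$channel_id)
  states <- hub_init()
  frames <- list()
  frame_times <- numeric()
  for (i in seq_len(nrow(del))) {
    now <- del$recv_time[i]
    states <- expire(states, now, timeout)
    pkt <- list(channel_id = del$channel_id[i], counter = del$counter[i],
                samples = del$samples[[i]])
    states <- ingest(states, pkt, now)
    repeat {
      res <- build_frame(states)
      states <- res$states
      if (is.null(res$frame)) break
      frames[[length(frames) + 1L]] <- res$frame
      frame_times <- c(frame_times, now)
    }
  }
  if (flush && nrow(del) > 0) {
    now <- max(del$recv_time) + timeout + 1e-9
    repeat {
      res <- build_frame(states)
      states <- res$states
      if (!is.null(res$frame)) {
        frames[[length(frames) + 1L]] <- res$frame
        frame_times <- c(frame_times, now)
        next
      }
      # barrier blocked: channels whose queues ran dry have gone silent
      drained <- states$active &
        vapply(states$queue, length, integer(1)) == 0
      if (!any(drained)) break
      states$active[drained] <- FALSE
      if (!any(states$active)) break
    }
  }
  structure(list(frames = frames, frame_times = frame_times,
                 states = states),
            class = "hub_session")
}

#' @export
print.hub_session <- function(x, ...) {
  cat(sprintf("<hub_session> %d frames, per-channel QoS: %s\n",
              length(x$frames),
              paste(x$states$qos_cum, collapse = " ")))
  invisible(x)
}
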