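# shared fixtures: small sessions and hand-built packets

zero_trace <- function(duration = 1, fs_sim = 10000) {
  emg_trace(rep(0, round(duration * fs_sim)), fs_sim)
}

# packets tibble without going through the analog chain (payload content
# is irrelevant to transport/hub bookkeeping tests)
make_packets <- function(n, channel_id = 1L, start_counter = 0) {
  tibble::tibble(
    channel_id = as.integer(channel_id),
    counter = (start_counter + seq_len(n) - 1) %% 2^32,
    samples = rep(list(rep(0L, packet_samples())), n)
  )
}

small_session <- function(n_channels = 2, loss = 0, seed = 1,
                          duration = 2) {
  run_end_to_end(e2e_config(
    n_channels = n_channels, duration = duration,
    link = link_params(loss_prob = loss, seed = seed),
    seed = seed
  ))
}

# a frame with random payloads for codec tests
random_frame <- function(n_ch, payload_len = 120) {
  ids <- sample(1:6, n_ch)
  serial_frame(purrr::map(ids, function(id) {
    list(channel_id = id,
         qos = sample(0:500, 1),
         payload = sample(0:4095, payload_len, replace = TRUE))
  }))
}
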