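---
title: "A desk-scale twin of a wireless multichannel sEMG acquisition chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale twin of a wireless multichannel sEMG acquisition chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgsim)
```

semgsim models a complete wireless surface-electromyography (sEMG)
acquisition system in software: synthetic electrode-referred signals, the
analog front-end of a sensor node, its 12-bit 1 kS/s digitizer, the radio
packet format, a lossy multi-node link, the central hub's channel
bookkeeping and lost-packet (QoS) accounting, the hub-to-host serial frame
protocol, and a host-side recording format. This vignette explains the
models, the defaults and why they were chosen, the numerical choices, and
what the simulation can and cannot say about real hardware.

## The synthetic sEMG process

Surface EMG is a small (microvolts to ~10 mV), noise-like signal occupying
roughly 10-500 Hz, with most energy below ~200-250 Hz. No published
amplitude or spectral shape is available for any specific recording, so
the generator uses the standard shaped-noise convention: white Gaussian
noise shaped in the frequency domain by a brick-wall band-pass on the EMG
band (default 20-500 Hz) with a first-order power tilt
$1/(1+(f/f_t)^2)$, $f_t = 200$ Hz, so spectral mass concentrates below
250 Hz. The shaped process is normalized to unit RMS and multiplied by a
contraction envelope: the instantaneous RMS moves between `rms_rest`
(default 2 uV, electrode/amplifier baseline noise) and `rms_max` (default
1 mV, a strong voluntary contraction -- both inside the physiological
range above). Envelopes are piecewise-linear in time; the default is a
sustained full contraction.

Injectors add deterministic mains interference (a 60 Hz sinusoid plus
optional harmonics -- cabled systems typically also show the 120 Hz
second harmonic) and motion artifacts: band-limited drift below the
front-end's high-pass corner, and short Hann-windowed broadband bursts
emulating impacts. All stochastic parts derive from one per-trace seed,
recorded in session metadata, so every trace is bit-reproducible.

What the generator does *not* emulate: motor-unit action potentials and
their firing statistics, electrode-skin impedance and its drift,
amplitude non-stationarity beyond the envelope, or inter-subject
variability. Tests passing on this process therefore validate the signal
*chain* -- filtering, digitization, transport, bookkeeping -- not any
physiological claim.

## The analog front-end model

The front-end is an integrated biopotential chain (instrumentation
amplifier with DC-blocking, then filtering) parameterized by
`chain_params()`:

| parameter | default | meaning |
|---|---|---|
| `ia_gain` | 100 V/V | instrumentation-amplifier gain |
| `hp_fc` | 20 Hz | high-pass design corner (two cascaded identical first-order sections) |
| `lp_fc` | 500 Hz | second-order low-pass corner |
| `lp_gain` | 9.27 V/V | low-pass stage gain |
| `lp_q` | $1/\sqrt2$ | low-pass quality factor (Butterworth) |
| `v_offset` | 1.65 V | mid-rail DC offset for a single 3.3 V supply |

The high-pass is fixed as two cascaded identical real-pole sections: that
is how the DC-blocking architecture of this class of front-end IC is
built, and it is the only topology whose half-power corner lands at
$20\sqrt{1/(\sqrt2-1)} \approx 31.1$ Hz for a 20 Hz design value, which
is what such a design simulates. The low-pass Q is exposed rather than
hard-coded because assembled units can peak above the Butterworth
response; without the actual component values such peaking is not
reproducible, so the default stays maximally flat.

`frequency_response()` evaluates the small-signal magnitude analytically.
`apply_chain()` runs the same sections in the time domain as discretized
filters (bilinear transform with the corner prewarped per section), adds
the offset and hard-clips at the rails. Numerical choices:

* **Discretization accuracy.** Bilinear warping is exact at each
  prewarped corner but grows toward $f_s/10$; the chain therefore
  requires `fs_sim >= 10 * lp_fc`, and consistency checks between
  time-domain gain and the analytic response are run at 50 kHz, where
  warping is negligible across 10-1000 Hz.
* **Transients.** Steady-state amplitude assertions discard at least five
  high-pass time constants.
* **Cutoff search.** Responses are evaluated on a log grid of >= 200
  points/decade; the half-power crossing is interpolated linearly in
  (log f, dB) between bracketing grid points, accurate to well under 1%
  at that density. A side that never reaches the half-power level
  returns `NA`.
* **Cutoff reference.** `extract_cutoffs()` measures 3 dB below the
  *curve maximum* (and is hence invariant to constant dB offsets);
  `chain_cutoffs()` measures 3 dB below the *mid-band gain*
  $20\log_{10}(\text{ia\_gain}\cdot\text{lp\_gain}) \approx 59.3$ dB.
  The distinction matters because with the high- and low-pass corners
  only a factor 25 apart the realized maximum sags ~0.2 dB below the
  stage-gain product, which would bias a max-referenced corner by about
  1 Hz. Amplifier bandwidth is conventionally quoted from mid-band, so
  `chain_cutoffs()` is the quantity reported for the design.

The digitizer is a mid-tread uniform quantizer,
`code = clamp(floor(v/vref * 2^bits), 0, 2^bits - 1)` at 12 bits over
3.3 V, fed by picking every k-th chain-output sample (the low-pass is the
anti-alias filter). Effective-resolution loss of real converters is not
modelled.

### Component tolerances

Every first-order RC corner moves by $1/((1+\delta_R)(1+\delta_C))$ under
relative component deviations; the second-order corner
$1/(2\pi\sqrt{R_1C_1R_2C_2})$ moves by the geometric mean of its two
pairs' factors. With 10% capacitors and nominal resistors the worst-case
factor is $1/0.9 \approx 1.11$. `tolerance_monte_carlo()` draws
independent uniform deviations per pair (1% resistors, 10% capacitors by
default), rescales each section's corner and re-extracts cutoffs; the
draws stay inside the interval-arithmetic bounds
$[1/(1.1\cdot1.01),\,1/(0.9\cdot0.99)]$ relative to nominal. Q is held
nominal: tolerances are modelled as corner scaling, since no actual R/C
values are published to perturb individually.

## Wire formats and the lossy link

A sensor fills a 120-sample vector before broadcasting, so each packet is
1 byte channel id (1-6) + 4 byte little-endian counter + 120 two-byte
little-endian sample words = 245 bytes, under the radio's 250-byte
message bound. Twelve-bit codes travel in 16-bit containers: bit-packing
would save 60 bytes but makes dumps unreadable and still fits either
way. The counter is 32-bit unsigned with wraparound; gap arithmetic is
modulo $2^{32}$ and a modular gap above $2^{31}$ is treated as
reordering, not loss. Counter width and endianness are conventions of
this implementation -- the hardware protocol does not publish them.

The link simulator stands in for the 2.45 GHz radio. Per-packet loss is
i.i.d. Bernoulli by default, or a two-state Gilbert-Elliott chain
(drops occur in the bad state) when burstiness matters -- field
measurements of such systems show loss concentrating heavily on single
channels, which i.i.d. loss cannot produce. Distance maps to loss through
a monotone logistic curve with configurable ceiling; this is purely a
simulation knob, not a propagation model. Latency is a constant plus
uniform jitter, and the link is FIFO per channel (arrival times are made
non-decreasing), so delivered packets keep send order. Everything is
seeded and bit-reproducible.

## Hub bookkeeping and the serial frame

A channel announces itself by sending; one second of silence deactivates
it (queues are retained). Arriving counters update the per-channel
lost-packet count by `counter - last_counter - 1` (mod $2^{32}$); the
first packet only initializes the counter. Frames to the host are
synchronized with a queue barrier: one payload per active channel,
emitted only when every active queue is non-empty. The frame layout is
2-byte bytes-per-channel, 1-byte active-channel count, then per channel
id/QoS-snapshot/payload, terminated by the end marker `0x55 0xAA` (the
marker value is this implementation's choice). The QoS field carries the
gaps accumulated since that channel's previous frame; the host sums
snapshots into session totals. Because sample words keep their high
nibble below 0x10, the marker cannot occur inside payload bytes, and the
stream decoder can resynchronize on it after corruption, losing at most
the corrupted frame.

Two deliberate behaviors are worth flagging:

* **End-of-stream flush.** When the input ends, `hub_session()` advances
  its injected clock past the deactivation timeout and drains the
  queues, exactly as the silence rule would on hardware. Without this, a
  channel that activated late would permanently hold one payload per
  peer behind the barrier -- the unbounded queue accumulation failure
  mode the barrier design invites.
* **What counter-gap accounting can and cannot see.** A drop is
  detectable only if packets arrive on both sides of it. Drops before a
  channel's first delivered packet and after its last leave no gap any
  counter can reveal -- on real hardware just as here. The package
  exposes the exact ground truth via `qos_oracle()`: the hub's QoS
  equals the *detectable* drop count exactly, for every seed, and equals
  the total drop count whenever the channel's first and last packets
  were delivered. Tests assert precisely that.

## Recording format

The host assembles frames into per-channel code streams and writes one
2-byte little-endian binary file per channel plus a JSON sidecar carrying
a format version, the signal description, channel names, per-channel
session QoS, sampling frequency, ADC resolution, and the seeds/config
used. One file per channel keeps partially transferred sessions readable.
Reading is the exact inverse of writing; a missing required field is a
schema error, an odd-length binary a corruption error.

## The evaluation methodology

* **Spectra** use an averaged (Welch) periodogram: Hann window, 1024-sample
  segments, 50% overlap by default, one-sided, with density scaling
  normalized so integrated density equals mean-square power. The choice
  of 1024 at 1 kS/s gives ~1 Hz resolution; parameters are recorded in
  the result's attributes.
* **The mains delta** is the dB difference between contraction and rest
  spectra at the grid bin nearest 60 Hz (no interpolation). A designed
  contrast of 40 dB (rest RMS 10 uV vs contraction RMS 1 mV) is
  recovered by construction; with ~115 averaged segments the per-seed
  estimate scatters a fraction of a dB, so the recovery test asserts the
  mean over 20 seeds within +-1 dB rather than each seed individually.
* **Loss sweeps** run one full pipeline simulation per
  (distance, channel-count) cell and tabulate hub QoS next to
  ground-truth drops.
* **Timing rasters** shift each channel's arrivals so its first message
  is at 0 s; a lossless 1 kS/s / 120-sample stream has 0.120 s modal
  inter-arrival, and each drop widens one interval by a packet period.
* **The power budget** is capacity/draw: 180 mAh at 100 mA gives 1.8 h.

## Problem sizes

Simulations are sized for a desk run: sessions of 1-6 channels and 2-5 s
at 10 kHz simulation rate, 100-session oracle sweeps, 1000-draw tolerance
Monte Carlo, 10,000-packet codec and binomial checks, and 30 s
spectral-recovery traces at 2 kHz. The full test suite finishes in well
under a minute; all quantities scale with the parameters if larger runs
are wanted.

## Known limitations

The front-end ignores slew rate, finite CMRR, input impedance and
effective-resolution loss; the link is not a propagation model and its
distance-loss curve is arbitrary; hardware-measured corner frequencies of
assembled units (which spread with component tolerances) are emulated
only distributionally; and human-subject comparisons are outside what a
synthetic process can reproduce. The simulation's value is that every
bookkeeping claim -- codec bijectivity, barrier conservation, QoS-versus-
ground-truth equality, recording round-trips -- is checked exactly, which
is infeasible on the bench.

## A worked session

```{r, eval = FALSE}
library(semgsim)

sess <- run_end_to_end(e2e_config(
  n_channels = 3, duration = 2,
  link = link_params(loss_prob = 0.1, seed = 42),
  seed = 42
))
glance(sess)        # packets sent / delivered / dropped, hub QoS
tidy(sess)          # the same per channel
qos_oracle(sess$log) # link ground truth to compare against

write_recording(sess$recording, "session01")
rec <- read_recording("session01")
autoplot(power_spectrum(codes_to_volts(rec$streams[["1"]]), fs = 1000))
```
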