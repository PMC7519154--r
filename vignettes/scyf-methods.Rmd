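---
title: "Single-cycle fractal ECG compression: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cycle fractal ECG compression: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scyf)
```

## The model and its assumptions

Fractal block coding represents a signal through its self-similarity: every
*range block* (RB) of the input is approximated as an affine image of some
*domain block* (DB) drawn from a reference region. The single-cycle variant
implemented here makes one strong, ECG-specific assumption: **one heart
cycle is representative of the whole record**. The codec stores exactly one
cycle — from a P-wave onset to just before the next one — verbatim, and
codes every range block of the DC-removed signal as

$$\widehat{RB} = s \cdot T(DB) + o,$$

with $s$ and $o$ the least-squares scale and shift, and $T$ either the
identity or the pairwise swap of adjacent samples (a one-bit transform
choice). The matching criterion, and the split trigger, is the
root-mean-square residual of that approximation (FRMS). A range block whose
best match exceeds the FRMS limit is halved and each half is encoded
independently, recursively, up to a maximum depth; a leaf forced at maximum
depth keeps the minimum-FRMS match available at that size.

Because the reference region is stored in the stream rather than defined on
the reconstructed signal, decoding needs **one pass** and no fixed-point
iteration: dequantize each leaf's coefficients, apply them to the indexed
domain block, concatenate, add the DC value back.

The assumption buys efficiency exactly where ECG is favourable — strongly
quasiperiodic, slowly varying morphology — and costs fidelity where it is
not: beats that drift away from the stored cycle (rate changes, ectopy,
noise bursts) can only be approximated by affine patches of it, so
distortion concentrates there. The stored cycle is also a fixed overhead
that dominates short records; the codec pays off on longer signals.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `block_size` (BS) | samples | 256 | Power of two so halving always yields integer block lengths; 256 suits cycle lengths of a few hundred samples (250–1000 Hz recordings). |
| `jump_step` (JS) | samples | 1 | Densest possible domain pool; the dominant cost of a leaf is its index width, which grows only logarithmically in pool size. |
| `frms_limit` | sample units | 12 | Split threshold in the units of the stored samples (ADC counts for integer records). The 256/1/12/2 default matches the standard-database preset (`scyf_preset("cse")`); the ambulatory preset (`"mitadb"`) is 128/1/5/3. |
| `max_divisions` | count | 2 | Caps tree depth; `BS/2^max_divisions` must stay ≥ 2 so a leaf can still carry the pairwise swap. |
| `scale_bits`, `scale_range` | bits, – | 8 over [−2, 2] | Scale coefficients of well-matched blocks sit near 1; [−2, 2] at 8 bits gives a bin of 1/64, whose induced amplitude error is far below useful FRMS limits. |
| `shift_bits` | bits | 11 | The shift is coded over the recorded amplitude range of the DC-removed signal, kept in the header; 11 bits keeps the bin near 0.05 % of full scale. |
| `domain_halved` | flag | off | Stores the cycle as pairwise means (half the payload, smoother reference, attenuated R peak). |
| `extension` (E) | samples/side | 0 | Mirror extension for short records, so edge blocks see full-length context. |
| `smooth`, `smooth_span` | flag, samples | off, 7 | Post-reconstruction local-regression smoothing (see below). It helps some signals and harms others, so it is strictly opt-in. |
| `lossless_coeffs` | flag | off | Debug mode: coefficients stored as doubles, bypassing quantization. Used by tests to isolate the matching error from the coding error. |

## Numerical choices

* **Affine fit.** Closed-form least squares; for a constant domain block the
  normal equations are rank-deficient and the minimum-norm solution
  ($s = 0$, $o = \bar r$) is used.
* **Candidate ranking.** Candidates are scored by the FRMS achieved with the
  *dequantized* coefficients, not the raw fit: the stored code should be the
  one that is best after coding, since ranking on unquantized fits can pick
  a leaf whose coded version is worse.
* **Tie-breaking.** Lowest FRMS, then lowest DB index, then "none" before
  "swap" — a total order, so encoding is deterministic across platforms.
* **Quantizer.** Uniform mid-rise; out-of-range values clamp to the extreme
  bins, codes decode to bin centres, so the round-trip error is at most half
  a bin.
* **Tail handling.** The DC-removed signal is zero-padded to a BS multiple,
  the true sample count travels in the header, and reconstruction crops.
* **Domain payload.** Stored verbatim: integer-valued sources (ADC counts)
  at `source_bits` per sample as offsets from the payload minimum — exact —
  and all other inputs as IEEE float64, flagged in the header. The encoder
  canonicalises its in-memory domain through this payload codec *before*
  building the matching pool, so encoder and decoder always operate on
  bit-identical domains and serialization is exactly invertible.
* **Halved domains** are re-expanded to the full cycle length by linear
  interpolation at the pairwise-average centres (the first-order inverse of
  pairwise averaging) before pool building, keeping DB and RB lengths
  commensurate.
* **Automatic cycle selection.** With onset annotations but no explicit
  bounds, the codec takes, among the first five cycles, the one whose length
  is closest to the median cycle length (earliest on ties). Explicit bounds
  always override. No beat detector is built in: onsets come from the
  caller (the synthetic generator provides exact ones).
* **Smoothing.** Tricube-weighted local quadratic regression over a centred
  window (span 7 by default), window shrunk at the edges. It reproduces
  quadratic and constant sequences exactly, so it perturbs only curvature
  above the window scale — the block-joint discontinuities it targets.
* **Coordinates.** All sample indices are 0-based with half-open intervals,
  matching the stream format exactly; the R documentation flags this
  prominently since R itself is 1-based.

## The bitstream

The `.scyf` container is a 4-byte magic, a version byte, a fixed-width
byte-aligned header (sampling rate, sample count, source resolution, DC
value as a 64-bit float, the full configuration echo, quantizer ranges,
domain coordinates), then a bit section: domain payload followed by the
per-tree codes, zero-padded to a byte boundary. Bits are packed
MSB-first; header integers are little-endian. Each tree node spends one
split bit while above the maximum division depth (at maximum depth a leaf
is implied); a leaf is `[db_index][transform][scale_code][shift_code]` with
the index width `ceil(log2(pool size))` re-derived from the header, so the
stream is fully self-describing. Division is encoded as per-node split bits
rather than one division count per range block, because the two halves of a
split block are compressed separately and may split asymmetrically — a
single integer cannot express such trees. avL and CF are computed on the
whole serialized stream, header, payload and padding included.

## The synthetic generator

`generate_ecg()` emulates what the codec exploits and what stresses it:
quasiperiodic multi-wave beats (five Gaussian bumps for P, Q, R, S, T),
beat-to-beat RR jitter realised by linearly resampling the template,
per-beat amplitude scaling, sinusoidal baseline wander, white noise, and a
DC offset. Defaults describe a clean resting recording: 500 Hz, 60 bpm, 4 %
RR jitter, 5 % amplitude jitter, noise at 2 % of the R amplitude, 0.1-unit
baseline wander at 0.25 Hz. With all stochastic terms at zero the output is
an exactly periodic tiling — the regime where the codec is exact, which the
tests use as the zero-error limit.

What it does **not** emulate: true ECG morphology variation (ectopic beats,
ST changes), muscle-artifact noise spectra, electrode motion, pacemaker
spikes, or multi-lead correlation. Passing tests therefore demonstrate the
codec's contracts and its behaviour under controlled quasiperiodicity, not
clinical performance on real recordings.

## Problem sizes used by the tests and the acceptance script

The test suite runs on short records chosen to exercise every code path
while keeping the suite quick: 6-second synthetic records (≈ 12 range
trees each) for the codec-level properties, batches of 20 records for the
FRMS-contract and division-monotonicity checks, 50 seeded instances with
pools of ≈ 250–290 domain blocks for matcher/brute-force equivalence, and
100 randomized compressed objects for bitstream round-trips. The
acceptance script uses a single 20-second record at 500 Hz — long enough
that the domain payload no longer dominates avL, short enough to re-run
casually.

## Known limitations

* One domain cycle per stream: signals whose morphology changes mid-record
  are systematically disadvantaged; re-chunking long records into segments,
  each with its own domain, is the natural extension.
* The stored-cycle overhead makes avL on very short (≈ 10 s) records
  unflattering.
* No entropy coding of the body; leaf codes are fixed-width. A Huffman or
  arithmetic stage would lower avL at the cost of bit-exact simplicity.
* Automatic domain selection needs onset annotations; no delineation
  algorithm ships with the package.
* `frms_limit` is expressed in sample units, so the same numeric limit means
  different physical fidelity at different ADC gains — intentional, since
  published settings are given in those terms, but worth knowing when
  comparing across sources.
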