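# Fixture builders (everything is generated in code; no stored data).

# Smooth random cycle: a few random harmonics, so domain blocks are
# non-constant and matching is well conditioned.
random_cycle <- function(len, seed) {
  set.seed(seed)
  t <- (seq_len(len) - 1) / len
  out <- numeric(len)
  for (k in 1:5) out <- out + stats::rnorm(1) * sin(2 * pi * k * t + stats::runif(1, 0, 2 * pi))
  out
}

tiled_signal <- function(n_tiles, cycle_len, seed) {
  rep(random_cycle(cycle_len, seed), n_tiles)
}

# Integer ADC representation at a MIT-BIH-like gain of 200 counts per unit.
adc <- function(x, gain = 200) round(gain * x)

# Zero-jitter generator spec whose cycle is exactly `cycle_len` samples.
exact_tiling_spec <- function(n_tiles = 8, cycle_len = 256, fs = 500, seed = 1) {
  generator_spec(fs = fs, duration = n_tiles * cycle_len / fs,
                 heart_rate = fs * 60 / cycle_len,
                 rr_jitter = 0, amp_jitter = 0, noise_sd = 0,
                 baseline_amp = 0, seed = seed)
}

# A compressed object with randomized configuration and content, for
# bitstream round-trip property tests.
random_compressed <- function(seed) {
  set.seed(seed)
  bs <- sample(c(32L, 64L, 128L), 1)
  maxd <- sample(0:2, 1)
  cfg <- scyf_config(
    block_size = bs,
    jump_step = sample(1:4, 1),
    frms_limit = stats::runif(1, 0.01, 20),
    max_divisions = maxd,
    domain_halved = stats::runif(1) < 0.3,
    extension = sample(c(0L, 5L, 10L), 1),
    scale_bits = sample(4:10, 1),
    shift_bits = sample(6:12, 1),
    lossless_coeffs = stats::runif(1) < 0.3,
    smooth = stats::runif(1) < 0.2
  )
  n <- sample((2 * bs):(6 * bs), 1)
  cyc <- sample(bs:min(3 * bs, n), 1)
  x <- stats::filter(stats::rnorm(n + cyc), rep(1 / 5, 5), sides = 1)
  x <- as.numeric(x[!is.na(x)])[seq_len(n)]
  if (stats::runif(1) < 0.5) x <- round(100 * x)  # exercise the integer payload
  scyf_compress(x, fs = sample(c(250, 360, 500), 1), source_bits = sample(c(12L, 16L, 24L), 1),
                config = cfg, cycle_bounds = c(0, cyc))
}
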