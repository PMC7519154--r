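#' Default wave parameters of the beat template
#'
#' Five Gaussian bumps stand in for the P, Q, R, S and T waves of one heart
#' cycle. The cycle runs from P-wave onset to the next P-wave onset, so the
#' P centre sits early in the cycle. Amplitudes are in signal units
#' (roughly millivolt-like, R = 1), centres and widths are fractions of the
#' cycle length.
#'
#' @param amplitude,center,width Optional length-5 overrides (order P, Q, R,
#'   S, T).
#' @return A data frame with columns `wave`, `amplitude`, `center`, `width`.
#' @export
ecg_waves <- function(amplitude = c(0.15, -0.12, 1.00, -0.25, 0.35),
                      center = c(0.0625, 0.21875, 0.25, 0.28125, 0.50),
                      width = c(0.035, 0.012, 0.018, 0.014, 0.060)) {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amplitude = amplitude, center = center, width = width)
}

#' Evaluate a beat template
#'
#' Sums the five Gaussian wave bumps on `cycle_length` evenly spaced points
#' `t = (0:(L-1)) / L` of the cycle. Deterministic: equal parameters give
#' identical output.
#'
#' @param waves Wave table as from [ecg_waves()].
#' @param cycle_length Cycle length in samples.
#' @return Numeric vector of `cycle_length` samples.
#' @examples
#' plot(beat_template(ecg_waves(), 500), type = "l")
#' @export
beat_template <- function(waves, cycle_length) {
  if (!is.data.frame(waves) || nrow(waves) < 1L ||
      !all(c("amplitude", "center", "width") %in% names(waves)))
    scyf_stop("`waves` must be a data frame with amplitude/center/width columns",
              "scyf_invalid_input")
  if (any(diff(waves$center) <= 0) || any(waves$center <= 0) || any(waves$center >= 1))
    scyf_stop("wave centers must be strictly increasing within (0, 1)",
              "scyf_invalid_input")
  if (any(waves$width <= 0))
    scyf_stop("wave widths must be > 0", "scyf_invalid_input")
  r_amp <- if ("wave" %in% names(waves) && "R" %in% waves$wave)
    abs(waves$amplitude[waves$wave == "R"]) else max(abs(waves$amplitude))
  if (any(abs(waves$amplitude) > r_amp))
    scyf_stop("the R wave must have the largest amplitude magnitude",
              "scyf_invalid_input")
  cycle_length <- as.integer(cycle_length)
  if (cycle_length < 2L)
    scyf_stop("`cycle_length` must be >= 2", "scyf_invalid_input")
  t <- (seq_len(cycle_length) - 1) / cycle_length
  out <- numeric(cycle_length)
  for (k in seq_len(nrow(waves))) {
    out <- out + waves$amplitude[k] *
      exp(-(t - waves$center[k])^2 / (2 * waves$width[k]^2))
  }
  out
}

#' Synthetic-ECG generator specification
#'
#' Defaults describe a clean resting recording: 500 Hz sampling, 60 bpm,
#' 4 % RR-interval jitter and 5 % beat-amplitude jitter (ordinary short-term
#' heart-rate/amplitude variability), additive white noise with a standard
#' deviation of 2 % of the R amplitude, 0.1-unit respiratory baseline wander
#' at 0.25 Hz, and no DC offset.
#'
#' @param fs Sampling frequency in Hz.
#' @param duration Record length in seconds (>= 2 cycles).
#' @param heart_rate Mean heart rate in beats per minute.
#' @param rr_jitter Fractional standard deviation of the beat-to-beat cycle
#'   length.
#' @param amp_jitter Fractional standard deviation of the per-beat amplitude
#'   scaling.
#' @param noise_sd Additive white-noise standard deviation, signal units.
#' @param baseline_amp,baseline_freq Sinusoidal baseline-wander amplitude
#'   (signal units) and frequency (Hz).
#' @param dc_offset Constant offset added to the whole signal.
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @param waves Wave table, see [ecg_waves()].
#' @return An object of class `scyf_genspec`.
#' @export
generator_spec <- function(fs = 500, duration = 10, heart_rate = 60,
                           rr_jitter = 0.04, amp_jitter = 0.05,
                           noise_sd = 0.02, baseline_amp = 0.1,
                           baseline_freq = 0.25, dc_offset = 0,
                           seed = 1L, waves = ecg_waves()) {
  spec <- list(fs = fs, duration = duration, heart_rate = heart_rate,
               rr_jitter = rr_jitter, amp_jitter = amp_jitter,
               noise_sd = noise_sd, baseline_amp = baseline_amp,
               baseline_freq = baseline_freq, dc_offset = dc_offset,
               seed = as.integer(seed), waves = waves)
  class(spec) <- "scyf_genspec"
  validate_genspec(spec)
}

validate_genspec <- function(spec) {
  if (spec$fs <= 0 || spec$heart_rate <= 0)
    scyf_stop("`fs` and `heart_rate` must be positive", "scyf_config_error")
  base_len <- spec$fs * 60 / spec$heart_rate
  if (base_len < 4)
    scyf_stop("cycle length fs*60/heart_rate must be at least 4 samples",
              "scyf_config_error")
  if (spec$duration * spec$fs < 2 * base_len)
    scyf_stop("`duration` must cover at least 2 cycles", "scyf_config_error")
  if (spec$rr_jitter < 0 || spec$amp_jitter < 0 || spec$noise_sd < 0 ||
      spec$baseline_amp < 0)
    scyf_stop("jitter/noise amplitudes must be >= 0", "scyf_config_error")
  spec
}

#' Generate a synthetic quasiperiodic ECG
#'
#' Concatenates per-beat copies of the Gaussian-bump template: each beat's
#' length is `round(fs * 60 / heart_rate * (1 + N(0, rr_jitter)))` samples
#' (the template is resampled to that length by linear interpolation, which
#' approximately preserves morphology the way real RR variability does) and
#' its amplitude is scaled by `1 + N(0, amp_jitter)`. Sinusoidal baseline
#' wander, white Gaussian noise and the DC offset are then added. Beat
#' starts are reported as 0-based `p_onsets`, directly usable as the
#' domain-cycle annotation of [scyf_compress()].
#'
#' With all jitters, noise and baseline at zero the output is an exactly
#' periodic tiling of the template — the regime in which the codec is
#' exact.
#'
#' @param spec A [generator_spec()].
#' @return A list with `signal` (length `round(fs * duration)`) and
#'   `p_onsets` (0-based beat-start indices).
#' @examples
#' sim <- generate_ecg(generator_spec(duration = 5, seed = 42))
#' str(sim)
#' @export
generate_ecg <- function(spec) {
  if (!inherits(spec, "scyf_genspec")) spec <- do.call(generator_spec, spec)
  validate_genspec(spec)
  set.seed(spec$seed)
  n <- as.integer(round(spec$fs * spec$duration))
  base_len <- as.integer(round(spec$fs * 60 / spec$heart_rate))
  template <- beat_template(spec$waves, base_len)
  sig <- numeric(0)
  onsets <- integer(0)
  while (length(sig) < n) {
    len_i <- as.integer(round(base_len * (1 + stats::rnorm(1, 0, spec$rr_jitter))))
    len_i <- max(len_i, 2L)
    amp_i <- 1 + stats::rnorm(1, 0, spec$amp_jitter)
    beat <- if (len_i == base_len) template else
      stats::approx(seq(0, 1, length.out = base_len), template,
                    xout = seq(0, 1, length.out = len_i))$y
    onsets <- c(onsets, length(sig))
    sig <- c(sig, amp_i * beat)
  }
  sig <- sig[seq_len(n)]
  onsets <- onsets[onsets < n]
  t <- (seq_len(n) - 1) / spec$fs
  sig <- sig + spec$baseline_amp * sin(2 * pi * spec$baseline_freq * t) +
    stats::rnorm(n, 0, spec$noise_sd) + spec$dc_offset
  list(signal = sig, p_onsets = onsets)
}
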