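#' Least-squares affine fit of a domain block onto a range block
#'
#' Finds the scale `s` and shift `o` minimising `sum((s*d + o - r)^2)` and
#' reports the FRMS residual `sqrt(mean((s*d + o - r)^2))`, the similarity
#' criterion of the matcher. A constant domain block makes the system
#' rank-deficient; the minimum-norm solution `s = 0`, `o = mean(r)` is
#' returned.
#'
#' @param d Domain-block samples.
#' @param r Range-block samples (same length as `d`, length >= 2).
#' @return A list with `s` (dimensionless), `o` (amplitude) and `frms`.
#' @examples
#' fit_affine(c(0, 1, 2, 3), 2 * c(0, 1, 2, 3) + 3)
#' @export
fit_affine <- function(d, r) {
  if (length(d) != length(r))
    scyf_stop("`d` and `r` must have the same length", "scyf_invalid_input")
  n <- length(d)
  if (n < 2L)
    scyf_stop("blocks must have length >= 2", "scyf_invalid_input")
  sd_ <- sum(d); sr <- sum(r)
  sdd <- sum(d * d); sdr <- sum(d * r)
  den <- n * sdd - sd_ * sd_
  if (den > 0) {
    s <- (n * sdr - sd_ * sr) / den
    o <- (sr - s * sd_) / n
  } else {
    s <- 0
    o <- mean(r)
  }
  frms <- sqrt(mean((s * d + o - r)^2))
  list(s = s, o = o, frms = frms)
}

# Uniform mid-rise quantizer over [lo, hi) with 2^bits bins. Values outside
# the range clamp to the extreme bins; codes decode to bin centres.
q_encode <- function(v, lo, hi, bits) {
  nbin <- 2^bits
  if (hi <= lo) return(rep(0, length(v)))
  w <- (hi - lo) / nbin
  k <- floor((v - lo) / w)
  pmin(pmax(k, 0), nbin - 1)
}

q_decode <- function(k, lo, hi, bits) {
  if (hi <= lo) return(rep(lo, length(k)))
  w <- (hi - lo) / 2^bits
  lo + (k + 0.5) * w
}

#' Quantize / dequantize affine coefficients
#'
#' The scale coefficient is coded over the fixed `config$scale_range` with
#' `config$scale_bits` bits; the shift coefficient over `shift_range` (the
#' amplitude range of the DC-removed signal, recorded in the stream header)
#' with `config$shift_bits` bits. Both use a uniform mid-rise quantizer:
#' out-of-range values clamp to the extreme bins and codes decode to bin
#' centres, so the round-trip error is at most half a bin width. With
#' `config$lossless_coeffs` the codes carry the full-precision values
#' unchanged (testing only).
#'
#' @param s,o Scale and shift coefficients (vectorised).
#' @param shift_range Length-2 numeric, the shift quantizer range.
#' @param config A [scyf_config()].
#' @return `quantize_affine`: list with `scale_code`, `shift_code`.
#' @export
quantize_affine <- function(s, o, shift_range, config) {
  if (config$lossless_coeffs)
    return(list(scale_code = s, shift_code = o))
  list(
    scale_code = q_encode(s, config$scale_range[1], config$scale_range[2],
                          config$scale_bits),
    shift_code = q_encode(o, shift_range[1], shift_range[2], config$shift_bits)
  )
}

#' @param scale_code,shift_code Quantizer codes as produced by
#'   `quantize_affine`.
#' @return `dequantize_affine`: list with `s` and `o` (bin-centre values).
#' @rdname quantize_affine
#' @export
dequantize_affine <- function(scale_code, shift_code, shift_range, config) {
  if (config$lossless_coeffs)
    return(list(s = scale_code, o = shift_code))
  list(
    s = q_decode(scale_code, config$scale_range[1], config$scale_range[2],
                 config$scale_bits),
    o = q_decode(shift_code, shift_range[1], shift_range[2], config$shift_bits)
  )
}
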