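#' Compression-efficiency metrics
#'
#' `avl()` (average value length) is the ratio between the bit size of the
#' output stream and the length of the original signal in samples, in bits
#' per sample (bps). `cf()` (compression factor, elsewhere called
#' compression ratio CR) is the ratio of original to compressed bit sizes;
#' for a fixed-width source it equals `source_bits / avl`.
#'
#' @param total_bits Bit size of the compressed output stream.
#' @param n Length of the original signal in samples.
#' @return `avl`: bits per sample.
#' @examples
#' avl(512, 1024)
#' cf(24 * 5000, 0.4460 * 5000)  # ~ 53.8
#' @export
avl <- function(total_bits, n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    scyf_stop("`n` must be a positive sample count", "scyf_invalid_input")
  total_bits / n
}

#' @param original_bits,compressed_bits Bit sizes of the original and
#'   compressed representations.
#' @return `cf`: dimensionless compression factor.
#' @rdname avl
#' @export
cf <- function(original_bits, compressed_bits) {
  if (length(compressed_bits) != 1L || is.na(compressed_bits) || compressed_bits < 1)
    scyf_stop("`compressed_bits` must be >= 1", "scyf_invalid_input")
  original_bits / compressed_bits
}

check_pair <- function(x, xr) {
  check_numeric_vector(x, "x", min_len = 2L)
  check_numeric_vector(xr, "xr", min_len = 2L)
  if (length(x) != length(xr))
    scyf_stop("`x` and `xr` must have the same length", "scyf_invalid_input")
}

#' Distortion metrics for original/reconstructed signal pairs
#'
#' `prdn()` is the normalized percentage root-mean-square difference,
#' `100 * sqrt(sum((x - xr)^2) / sum((x - mean(x))^2))`: the mean (DC) of
#' the original is removed from the denominator, so the value is invariant
#' to offset and the honest variant to report. `prd()` keeps the raw
#' denominator `sum(x^2)` and is artificially flattered by any DC offset;
#' the two agree exactly when `mean(x) = 0`.
#'
#' `snr()` is `10*log10(sum((x - mean(x))^2) / sum(e^2))` in dB (so
#' `snr = -20*log10(prdn/100)` exactly), `mse()` the mean squared error,
#' `max_err()` the maximum absolute error and `std_err()` the population
#' (1/n) standard deviation of the error.
#'
#' @param x Original samples.
#' @param xr Reconstructed samples (same length).
#' @return A scalar; `snr` returns `Inf` for a zero error vector.
#' @examples
#' prdn(c(1, 2, 3), c(1, 2, 4))
#' @export
prdn <- function(x, xr) {
  check_pair(x, xr)
  den <- sum((x - mean(x))^2)
  if (den == 0)
    scyf_stop("`x` is constant: PRDN denominator is zero", "scyf_invalid_input")
  100 * sqrt(sum((x - xr)^2) / den)
}

#' @rdname prdn
#' @export
prd <- function(x, xr) {
  check_pair(x, xr)
  den <- sum(x^2)
  if (den == 0)
    scyf_stop("`x` is identically zero: PRD denominator is zero", "scyf_invalid_input")
  100 * sqrt(sum((x - xr)^2) / den)
}

#' @rdname prdn
#' @export
mse <- function(x, xr) {
  check_pair(x, xr)
  mean((x - xr)^2)
}

#' @rdname prdn
#' @export
snr <- function(x, xr) {
  check_pair(x, xr)
  e2 <- sum((x - xr)^2)
  if (e2 == 0) return(Inf)
  10 * log10(sum((x - mean(x))^2) / e2)
}

#' @rdname prdn
#' @export
max_err <- function(x, xr) {
  check_pair(x, xr)
  max(abs(x - xr))
}

#' @rdname prdn
#' @export
std_err <- function(x, xr) {
  check_pair(x, xr)
  e <- x - xr
  sqrt(mean((e - mean(e))^2))
}

#' Quality score
#'
#' `QS = CF / PRDN`: compression factor per percent of normalized
#' distortion. Higher is better; a perfect reconstruction has no finite
#' score (reported as `Inf`).
#'
#' @param cf Compression factor.
#' @param prdn Normalized PRD in percent.
#' @return Dimensionless score.
#' @export
qs <- function(cf, prdn) {
  if (prdn < 0) scyf_stop("`prdn` must be >= 0", "scyf_invalid_input")
  if (prdn == 0) return(Inf)
  cf / prdn
}

#' Full efficiency + distortion report
#'
#' Bundles every metric for an (original, reconstructed, stream-size)
#' triple.
#'
#' @param x Original samples.
#' @param xr Reconstructed samples.
#' @param total_bits Bit size of the compressed stream (e.g. [bit_cost()]),
#'   or `NA` if only distortion is of interest.
#' @param source_bits Source resolution in bits per sample.
#' @return An object of class `scyf_quality` (also convertible with
#'   `as.data.frame()`): fields `n`, `source_bits`, `total_bits`, `avl`,
#'   `cf`, `prd`, `prdn`, `mse`, `snr`, `max_err`, `stderr`, `qs`.
#' @export
quality_report <- function(x, xr, total_bits = NA_real_, source_bits = 16L) {
  check_pair(x, xr)
  n <- length(x)
  avl_v <- if (is.na(total_bits)) NA_real_ else avl(total_bits, n)
  cf_v <- if (is.na(total_bits)) NA_real_ else cf(n * source_bits, total_bits)
  prdn_v <- prdn(x, xr)
  out <- list(
    n = n,
    source_bits = as.integer(source_bits),
    total_bits = as.numeric(total_bits),
    avl = avl_v,
    cf = cf_v,
    prd = prd(x, xr),
    prdn = prdn_v,
    mse = mse(x, xr),
    snr = snr(x, xr),
    max_err = max_err(x, xr),
    stderr = std_err(x, xr),
    qs = if (is.na(cf_v)) NA_real_ else qs(cf_v, prdn_v)
  )
  class(out) <- "scyf_quality"
  out
}

#' @export
as.data.frame.scyf_quality <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' @export
print.scyf_quality <- function(x, ...) {
  cat("<scyf_quality>\n")
  cat(sprintf("  n = %d samples, %d-bit source\n", x$n, x$source_bits))
  if (!is.na(x$total_bits))
    cat(sprintf("  avL = %.4f bps   CF = %.2f   QS = %.2f\n", x$avl, x$cf, x$qs))
  cat(sprintf("  PRDN = %.4f %%   PRD = %.4f %%   SNR = %.2f dB\n",
              x$prdn, x$prd, x$snr))
  cat(sprintf("  MSE = %.4g   MAX = %.4g   STDERR = %.4g\n",
              x$mse, x$max_err, x$stderr))
  invisible(x)
}
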