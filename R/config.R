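#' Codec configuration
#'
#' Bundles every user-tunable knob of the codec. `block_size` (BS) is the
#' range-block length in samples and must be a power of two; `jump_step` (JS)
#' is the offset between adjacent overlapping domain blocks; `frms_limit` is
#' the FRMS threshold (in the units of the stored samples — ADC counts for
#' integer records) below which a match is accepted; `max_divisions` caps the
#' recursive halving depth of a range block.
#'
#' The affine coefficients are stored through a uniform mid-rise quantizer:
#' the scale coefficient over the fixed `scale_range` with `scale_bits` bits,
#' the shift coefficient over the amplitude range of the DC-removed signal
#' (recorded in the stream header) with `shift_bits` bits.
#' `lossless_coeffs = TRUE` bypasses quantization and stores full-precision
#' doubles — a debugging/testing mode, not a compression mode.
#'
#' @param block_size Range/domain block size BS in samples (power of two).
#' @param jump_step Distance JS in samples between adjacent domain blocks.
#' @param frms_limit FRMS acceptance threshold, same units as the samples.
#' @param max_divisions Maximum number of recursive range-block halvings
#'   (`block_size / 2^max_divisions` must stay >= 2).
#' @param smooth Apply local-regression smoothing after reconstruction?
#' @param smooth_span Smoothing window length in samples (odd, >= 3).
#' @param domain_halved Store the domain downsampled by pairwise averaging?
#' @param extension Mirror-extension length E in samples per side.
#' @param scale_bits,scale_range Quantizer spec for the scale coefficient.
#' @param shift_bits Quantizer bits for the shift coefficient (its range is
#'   the recorded signal amplitude range).
#' @param lossless_coeffs Store coefficients unquantized (testing only)?
#' @return An object of class `scyf_config`.
#' @examples
#' scyf_config(block_size = 128, frms_limit = 5, max_divisions = 3)
#' @seealso [scyf_preset()] for the published per-database settings.
#' @export
scyf_config <- function(block_size = 256L,
                        jump_step = 1L,
                        frms_limit = 12,
                        max_divisions = 2L,
                        smooth = FALSE,
                        smooth_span = 7L,
                        domain_halved = FALSE,
                        extension = 0L,
                        scale_bits = 8L,
                        scale_range = c(-2, 2),
                        shift_bits = 11L,
                        lossless_coeffs = FALSE) {
  cfg <- list(
    block_size = as.integer(block_size),
    jump_step = as.integer(jump_step),
    frms_limit = as.numeric(frms_limit),
    max_divisions = as.integer(max_divisions),
    smooth = isTRUE(smooth),
    smooth_span = as.integer(smooth_span),
    domain_halved = isTRUE(domain_halved),
    extension = as.integer(extension),
    scale_bits = as.integer(scale_bits),
    scale_range = as.numeric(scale_range),
    shift_bits = as.integer(shift_bits),
    lossless_coeffs = isTRUE(lossless_coeffs)
  )
  class(cfg) <- "scyf_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!is_power_of_two(cfg$block_size))
    scyf_stop("`block_size` must be a power of two", "scyf_config_error")
  if (cfg$max_divisions < 0L)
    scyf_stop("`max_divisions` must be >= 0", "scyf_config_error")
  if (cfg$block_size / 2^cfg$max_divisions < 2)
    scyf_stop("`block_size` / 2^`max_divisions` must be >= 2", "scyf_config_error")
  if (cfg$jump_step < 1L)
    scyf_stop("`jump_step` must be >= 1", "scyf_config_error")
  if (is.na(cfg$frms_limit) || cfg$frms_limit <= 0)  # Inf is allowed (never split)
    scyf_stop("`frms_limit` must be > 0", "scyf_config_error")
  if (cfg$extension < 0L)
    scyf_stop("`extension` must be >= 0", "scyf_config_error")
  if (cfg$scale_bits < 1L || cfg$scale_bits > 32L ||
      cfg$shift_bits < 1L || cfg$shift_bits > 32L)
    scyf_stop("quantizer bit widths must be in 1..32", "scyf_config_error")
  if (length(cfg$scale_range) != 2L || diff(cfg$scale_range) <= 0)
    scyf_stop("`scale_range` must be an increasing [min, max] pair", "scyf_config_error")
  if (cfg$smooth_span < 3L || cfg$smooth_span %% 2L == 0L)
    scyf_stop("`smooth_span` must be odd and >= 3", "scyf_config_error")
  cfg
}

#' Published per-database codec presets
#'
#' Named settings used for the four evaluation databases: `"cse"`, `"upt"`
#' and `"butqdb"` share BS = 256, JS = 1, FRMS limit 12, max 2 divisions;
#' `"mitadb"` uses BS = 128, JS = 1, FRMS limit 5, max 3 divisions.
#'
#' @param name One of `"cse"`, `"mitadb"`, `"upt"`, `"butqdb"`.
#' @param ... Further arguments passed to [scyf_config()] to override
#'   non-preset knobs (e.g. `smooth = TRUE`, `extension = 10`).
#' @return A `scyf_config` object.
#' @examples
#' scyf_preset("mitadb")
#' @export
scyf_preset <- function(name = c("cse", "mitadb", "upt", "butqdb"), ...) {
  name <- match.arg(name)
  p <- switch(name,
    cse    = list(block_size = 256L, jump_step = 1L, frms_limit = 12, max_divisions = 2L),
    upt    = list(block_size = 256L, jump_step = 1L, frms_limit = 12, max_divisions = 2L),
    butqdb = list(block_size = 256L, jump_step = 1L, frms_limit = 12, max_divisions = 2L),
    mitadb = list(block_size = 128L, jump_step = 1L, frms_limit = 5,  max_divisions = 3L)
  )
  do.call(scyf_config, c(p, list(...)))
}

#' @export
print.scyf_config <- function(x, ...) {
  cat("<scyf_config>\n")
  cat(sprintf("  block_size (BS): %d   jump_step (JS): %d\n", x$block_size, x$jump_step))
  cat(sprintf("  frms_limit: %g   max_divisions: %d\n", x$frms_limit, x$max_divisions))
  cat(sprintf("  smooth: %s (span %d)   domain_halved: %s   extension: %d\n",
              x$smooth, x$smooth_span, x$domain_halved, x$extension))
  cat(sprintf("  scale: %d bits over [%g, %g]   shift: %d bits   lossless_coeffs: %s\n",
              x$scale_bits, x$scale_range[1], x$scale_range[2], x$shift_bits,
              x$lossless_coeffs))
  invisible(x)
}
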