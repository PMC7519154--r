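#' Find the most similar domain block for a range block
#'
#' Evaluates every domain block of the matching size under both transforms
#' (none and pairwise swap). Each candidate gets the least-squares affine
#' fit, the coefficients are quantized, and the candidate is scored by the
#' FRMS achieved with the *dequantized* coefficients — the residual the
#' decoder will actually realise. The minimum-FRMS candidate wins; ties
#' break to the lower domain-block index, then to "none" before "swap".
#'
#' @param r Range-block samples; the length must be one of the pool's leaf
#'   sizes.
#' @param pool A [build_domain_pool()] result.
#' @param header List with `shift_range` (from the stream header).
#' @param config A [scyf_config()].
#' @return A match leaf: list with `size`, `db_index` (0-based), `scale_code`,
#'   `shift_code`, `transform` (0 = none, 1 = swap) and `frms` (achieved,
#'   post-quantization; bookkeeping only, not serialized).
#' @export
match_block <- function(r, pool, header, config) {
  L <- length(r)
  m <- pool$mats[[as.character(L)]]
  if (is.null(m) || m$count == 0L)
    scyf_stop(sprintf("empty domain pool at size %d", L), "scyf_internal_error")
  n <- L
  sr <- sum(r); srr <- sum(r * r)
  nm <- m$count
  frms_all <- numeric(2L * nm)
  s_code <- numeric(2L * nm)
  o_code <- numeric(2L * nm)
  sq_all <- numeric(2L * nm)
  oq_all <- numeric(2L * nm)
  for (tr in 0:1) {
    # sum(T(d) * r) = sum(d * T(r)) because the swap is an involution that
    # also leaves sum(d) and sum(d^2) unchanged.
    rt <- if (tr == 1L) pairwise_swap(r) else r
    sdr <- as.vector(crossprod(m$D, rt))
    den <- n * m$sdd - m$sd^2
    s <- ifelse(den > 0, (n * sdr - m$sd * sr) / den, 0)
    o <- (sr - s * m$sd) / n
    qc <- quantize_affine(s, o, header$shift_range, config)
    dq <- dequantize_affine(qc$scale_code, qc$shift_code, header$shift_range, config)
    fr2 <- (dq$s^2 * m$sdd + n * dq$o^2 + srr +
              2 * dq$s * dq$o * m$sd - 2 * dq$s * sdr - 2 * dq$o * sr) / n
    fr2[fr2 < 0] <- 0
    sl <- tr * nm + seq_len(nm)
    frms_all[sl] <- sqrt(fr2)
    s_code[sl] <- qc$scale_code
    o_code[sl] <- qc$shift_code
    sq_all[sl] <- dq$s
    oq_all[sl] <- dq$o
  }
  db_all <- rep(seq_len(nm) - 1L, 2L)
  tr_all <- rep(0:1, each = nm)
  win <- order(frms_all, db_all, tr_all)[1L]
  # Recompute the winner's FRMS from the explicit residual so the recorded
  # value matches what decode_leaf realises to machine precision.
  d <- m$D[, db_all[win] + 1L]
  td <- if (tr_all[win] == 1L) pairwise_swap(d) else d
  frms <- sqrt(mean((sq_all[win] * td + oq_all[win] - r)^2))
  list(size = L, db_index = db_all[win], scale_code = s_code[win],
       shift_code = o_code[win], transform = tr_all[win], frms = frms)
}

#' Encode one range block as a binary division tree
#'
#' The block is accepted as a leaf when its best match meets the FRMS limit
#' or the maximum division depth is reached; otherwise it is halved and each
#' half is encoded independently at depth + 1. Leaves forced at the maximum
#' depth carry the minimum achievable FRMS at that size.
#'
#' @param r Range-block samples of length `block_size / 2^depth`.
#' @param pool,header,config As in [match_block()].
#' @param depth Current division depth (0 at the top level).
#' @return A range node: either `list(type = "leaf", depth, leaf)` or
#'   `list(type = "split", depth, left, right)`.
#' @export
encode_range <- function(r, pool, header, config, depth = 0L) {
  leaf <- match_block(r, pool, header, config)
  if (leaf$frms <= config$frms_limit || depth >= config$max_divisions)
    return(list(type = "leaf", depth = depth, leaf = leaf))
  h <- length(r) %/% 2L
  list(type = "split", depth = depth,
       left = encode_range(r[seq_len(h)], pool, header, config, depth + 1L),
       right = encode_range(r[h + seq_len(h)], pool, header, config, depth + 1L))
}

#' Compress an ECG segment
#'
#' Runs the full pipeline: optional mirror extension by `config$extension`
#' samples per side, DC removal, domain-cycle selection, domain-pool
#' construction, then partition of the DC-removed (extended) signal into
#' consecutive non-overlapping range blocks of `block_size` samples (the
#' tail zero-padded to a block multiple) and recursive encoding of each
#' block. The result is fully self-contained: the header records the
#' sampling rate, sample count, source resolution, DC value, configuration,
#' shift-quantizer range and the domain payload.
#'
#' `cycle_bounds` / `p_onsets` are 0-based indices into the *original*
#' signal; the extension shift is applied internally.
#'
#' @param x Numeric sample vector, or an [ecg_record()] (in which case `fs`
#'   and `source_bits` default to the record's metadata).
#' @param fs Sampling frequency in Hz.
#' @param source_bits Bit resolution of the source samples (8..32).
#' @param config A [scyf_config()].
#' @param cycle_bounds,p_onsets Domain-cycle annotation, see
#'   [select_domain()].
#' @return An object of class `scyf_compressed`.
#' @examples
#' sim <- generate_ecg(generator_spec(duration = 4, seed = 1))
#' cfg <- scyf_preset("cse", lossless_coeffs = TRUE)
#' cz <- scyf_compress(sim$signal, fs = 500, source_bits = 16,
#'                     config = cfg, p_onsets = sim$p_onsets)
#' cz
#' @export
scyf_compress <- function(x, fs = NULL, source_bits = NULL,
                          config = scyf_config(),
                          cycle_bounds = NULL, p_onsets = NULL) {
  if (inherits(x, "scyf_record")) {
    if (is.null(fs)) fs <- x$fs
    if (is.null(source_bits)) source_bits <- x$source_bits
    x <- x$samples
  }
  if (is.null(fs) || !is.numeric(fs) || fs <= 0)
    scyf_stop("`fs` must be a positive sampling frequency", "scyf_invalid_input")
  if (is.null(source_bits)) source_bits <- 16L
  source_bits <- as.integer(source_bits)
  if (source_bits < 8L || source_bits > 32L)
    scyf_stop("`source_bits` must be in 8..32", "scyf_invalid_input")
  check_numeric_vector(x, "x", min_len = 2L)
  validate_config(config)
  e <- config$extension
  if (length(x) + 2L * e < config$block_size)
    scyf_stop("signal (after extension) shorter than block_size", "scyf_config_error")
  xe <- mirror_extend(x, e)
  dcr <- subtract_dc(xe)
  x0 <- dcr$x0
  dc <- dcr$dc
  cb <- if (!is.null(cycle_bounds)) cycle_bounds + e
  po <- if (!is.null(p_onsets)) p_onsets + e
  domain <- select_domain(x0, config, cycle_bounds = cb, p_onsets = po)
  # Canonicalise the stored domain through the payload codec so the encoder
  # matches against exactly the samples every decoder will rebuild.
  pay <- encode_payload(domain$samples, dc, source_bits)
  domain$samples <- decode_payload(pay, dc)
  pool <- build_domain_pool(domain, config)
  shift_range <- range(x0)
  header <- list(shift_range = shift_range)
  bs <- config$block_size
  n_e <- length(x0)
  n_pad <- as.integer(ceiling(n_e / bs) * bs)
  xp <- c(x0, numeric(n_pad - n_e))
  trees <- lapply(seq_len(n_pad %/% bs), function(i) {
    encode_range(xp[(i - 1L) * bs + seq_len(bs)], pool, header, config, 0L)
  })
  structure(list(
    fs = as.numeric(fs),
    n_samples = length(x),
    source_bits = source_bits,
    dc = dc,
    shift_range = shift_range,
    config = config,
    domain = domain,
    payload_mode = pay$mode,
    payload_offset = pay$offset,
    trees = trees
  ), class = "scyf_compressed")
}

# Domain payload codec. Integer-valued sources (ADC counts) are stored at
# source_bits per sample as offsets from the minimum; everything else falls
# back to verbatim IEEE float64 samples.
encode_payload <- function(samples, dc, source_bits) {
  v <- samples + dc
  vr <- round(v)
  if (max(abs(v - vr)) < 1e-9 && (max(vr) - min(vr)) <= 2^source_bits - 1) {
    list(mode = "int", offset = min(vr), values = vr - min(vr))
  } else {
    list(mode = "float", offset = 0, values = samples)
  }
}

decode_payload <- function(pay, dc) {
  if (pay$mode == "int") (pay$values + pay$offset) - dc else pay$values
}

tree_leaves <- function(node) {
  if (node$type == "leaf") return(list(node$leaf))
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' @export
print.scyf_compressed <- function(x, ...) {
  leaves <- unlist(lapply(x$trees, function(t) length(tree_leaves(t))))
  cat("<scyf_compressed>\n")
  cat(sprintf("  %d samples @ %g Hz, %d-bit source, dc = %.6g\n",
              x$n_samples, x$fs, x$source_bits, x$dc))
  cat(sprintf("  domain cycle [%d, %d), payload mode '%s'\n",
              x$domain$start, x$domain$end, x$payload_mode))
  cat(sprintf("  %d range trees, %d leaves total\n", length(x$trees), sum(leaves)))
  cat(sprintf("  stream size: %d bits (avL %.4f bps)\n",
              bit_cost(x), bit_cost(x) / x$n_samples))
  invisible(x)
}
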