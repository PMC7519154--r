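#' Decode a single match leaf
#'
#' Applies the stored transform and dequantized affine coefficients to the
#' indexed domain block: `s_q * T(d) + o_q`, with `T` the identity or the
#' pairwise swap.
#'
#' @param leaf A match leaf (see [match_block()]).
#' @param pool A [build_domain_pool()] result.
#' @param header List with `shift_range`.
#' @param config A [scyf_config()].
#' @return The reconstructed range-block samples.
#' @export
decode_leaf <- function(leaf, pool, header, config) {
  m <- pool$mats[[as.character(leaf$size)]]
  if (is.null(m) || leaf$db_index < 0 || leaf$db_index >= m$count)
    scyf_stop("leaf domain-block index outside the pool", "scyf_corrupt_stream")
  d <- m$D[, leaf$db_index + 1L]
  td <- if (leaf$transform == 1L) pairwise_swap(d) else d
  dq <- dequantize_affine(leaf$scale_code, leaf$shift_code, header$shift_range, config)
  dq$s * td + dq$o
}

#' Reconstruct the signal from a compressed representation
#'
#' One-pass decoding: the domain is rebuilt from the header (re-expanded by
#' linear interpolation if it was stored halved), the domain pool is rebuilt
#' deterministically, every range tree is decoded depth-first with leaves
#' concatenated in temporal order, the tail padding and mirror extension are
#' cropped, the DC value is added back, and (optionally) the result is
#' smoothed with [loess_smooth()]. There is no fixed-point iteration.
#'
#' @param c A `scyf_compressed` object (from [scyf_compress()] or
#'   [scyf_deserialize()]).
#' @param smooth `NULL` to follow `c$config$smooth`, otherwise a logical
#'   override.
#' @return An object of class `scyf_reconstruction`: list with `signal`
#'   (length `c$n_samples`) and `leaf_map`, a per-sample data frame of leaf
#'   provenance (`size`, `db_index`, `depth`).
#' @examples
#' sim <- generate_ecg(generator_spec(duration = 4, seed = 1))
#' cz <- scyf_compress(sim$signal, fs = 500, source_bits = 16,
#'                     config = scyf_preset("cse"), p_onsets = sim$p_onsets)
#' rec <- scyf_reconstruct(cz)
#' prdn(sim$signal, rec$signal)
#' @export
scyf_reconstruct <- function(c, smooth = NULL) {
  if (!inherits(c, "scyf_compressed"))
    scyf_stop("`c` must be a scyf_compressed object", "scyf_invalid_input")
  config <- c$config
  pool <- build_domain_pool(c$domain, config)
  header <- list(shift_range = c$shift_range)
  bs <- config$block_size
  n_pad <- length(c$trees) * bs
  n_ext <- c$n_samples + 2L * config$extension
  if (n_pad < n_ext)
    scyf_stop("tree count inconsistent with the recorded sample count",
              "scyf_corrupt_stream")
  signal <- numeric(n_pad)
  size_map <- integer(n_pad)
  db_map <- integer(n_pad)
  depth_map <- integer(n_pad)
  pos <- 0L
  emit <- function(node) {
    if (node$type == "leaf") {
      lf <- node$leaf
      seg <- decode_leaf(lf, pool, header, config)
      idx <- pos + seq_len(lf$size)
      signal[idx] <<- seg
      size_map[idx] <<- lf$size
      db_map[idx] <<- lf$db_index
      depth_map[idx] <<- node$depth
      pos <<- pos + lf$size
    } else {
      emit(node$left)
      emit(node$right)
    }
  }
  for (tree in c$trees) emit(tree)
  if (pos != n_pad)
    scyf_stop("decoded sample count does not match the tree layout",
              "scyf_corrupt_stream")
  keep <- config$extension + seq_len(c$n_samples)
  out <- signal[keep] + c$dc
  do_smooth <- if (is.null(smooth)) config$smooth else isTRUE(smooth)
  if (do_smooth) out <- loess_smooth(out, config$smooth_span)
  structure(list(
    signal = out,
    leaf_map = data.frame(size = size_map[keep], db_index = db_map[keep],
                          depth = depth_map[keep])
  ), class = "scyf_reconstruction")
}

#' @export
print.scyf_reconstruction <- function(x, ...) {
  cat(sprintf("<scyf_reconstruction> %d samples, leaf sizes: %s\n",
              length(x$signal),
              paste(sort(unique(x$leaf_map$size), decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Local-regression smoothing
#'
#' Replaces each sample by the value at the window centre of a
#' tricube-weighted quadratic local-regression fit over a centred window of
#' `span` samples (shrunk at the signal edges; the polynomial degree drops
#' only when a shrunk window has fewer points than coefficients). Quadratic
#' and constant sequences are reproduced exactly. Intended to soften the
#' joints between reconstructed range blocks; strictly optional and off by
#' default.
#'
#' @param x Numeric sample vector.
#' @param span Odd window length in samples, `3 <= span <= length(x)`.
#' @return Smoothed vector of the same length.
#' @export
loess_smooth <- function(x, span = 7L) {
  check_numeric_vector(x, "x")
  span <- as.integer(span)
  if (span %% 2L == 0L || span < 3L || span > length(x))
    scyf_stop("`span` must be odd and within 3..length(x)", "scyf_config_error")
  n <- length(x)
  h <- (span - 1L) %/% 2L
  tric <- function(d) (1 - (d / (h + 1))^3)^3
  # Interior windows share one weight/design pattern, so the fitted value is
  # a fixed linear combination of the window: a single convolution.
  t_int <- -h:h
  w_int <- tric(abs(t_int))
  X <- cbind(1, t_int, t_int^2)
  kernel <- solve(t(X) %*% (w_int * X), t(w_int * X))[1L, ]
  out <- x
  interior <- (h + 1L):(n - h)
  sm <- stats::filter(x, rev(kernel), method = "convolution", sides = 2)
  out[interior] <- as.numeric(sm[interior])
  edge_fit <- function(i) {
    j <- max(1L, i - h):min(n, i + h)
    tt <- j - i
    ww <- tric(abs(tt))
    deg <- min(2L, length(j) - 1L)
    Xe <- outer(tt, 0:deg, `^`)
    b <- solve(t(Xe) %*% (ww * Xe), t(Xe) %*% (ww * x[j]))
    b[1L]
  }
  for (i in seq_len(h)) out[i] <- edge_fit(i)
  for (i in (n - h + 1L):n) out[i] <- edge_fit(i)
  out
}
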