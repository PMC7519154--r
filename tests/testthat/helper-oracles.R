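# Independent oracles: deliberately naive re-implementations of the
# documented contracts, used only to cross-check the package's optimised
# code paths. They share no code with the package internals.

# Least-squares affine fit via QR (stats::lsfit), with the documented
# degenerate rule for constant domain blocks.
oracle_fit <- function(d, r) {
  if (stats::var(d) == 0) {
    s <- 0; o <- mean(r)
  } else {
    co <- stats::lsfit(d, r)$coefficients
    s <- unname(co[2]); o <- unname(co[1])
  }
  list(s = s, o = o, frms = sqrt(mean((s * d + o - r)^2)))
}

# Mid-rise quantizer per the documented contract.
oracle_q_enc <- function(v, lo, hi, bits) {
  nbin <- 2^bits
  if (hi <= lo) return(0)
  w <- (hi - lo) / nbin
  min(max(floor((v - lo) / w), 0), nbin - 1)
}
oracle_q_dec <- function(k, lo, hi, bits) {
  if (hi <= lo) return(lo)
  lo + (k + 0.5) * (hi - lo) / 2^bits
}

oracle_swap <- function(b) {
  i <- seq(1, length(b), by = 2)
  out <- b
  out[i] <- b[i + 1]
  out[i + 1] <- b[i]
  out
}

# Exhaustive double-loop matcher: every domain block of the right size under
# both transforms, scored by the post-quantization residual RMS; first
# encountered wins ties (loop order = ascending index, none before swap).
oracle_match <- function(r, domain_eff, offsets, shift_range, config) {
  L <- length(r)
  best <- NULL
  for (j in seq_along(offsets)) {
    d <- domain_eff[offsets[j] + seq_len(L)]
    for (tr in 0:1) {
      td <- if (tr == 1) oracle_swap(d) else d
      fit <- oracle_fit(td, r)
      if (config$lossless_coeffs) {
        cs <- fit$s; co <- fit$o; sq <- fit$s; oq <- fit$o
      } else {
        cs <- oracle_q_enc(fit$s, config$scale_range[1], config$scale_range[2],
                           config$scale_bits)
        co <- oracle_q_enc(fit$o, shift_range[1], shift_range[2], config$shift_bits)
        sq <- oracle_q_dec(cs, config$scale_range[1], config$scale_range[2],
                           config$scale_bits)
        oq <- oracle_q_dec(co, shift_range[1], shift_range[2], config$shift_bits)
      }
      frms <- sqrt(mean((sq * td + oq - r)^2))
      if (is.null(best) || frms < best$frms) {
        best <- list(size = L, db_index = j - 1L, scale_code = cs,
                     shift_code = co, transform = tr, frms = frms)
      }
    }
  }
  best
}

# Recursive range encoding per the documented rule, on top of oracle_match.
oracle_encode <- function(r, domain_eff, offsets_by_size, shift_range, config,
                          depth = 0) {
  L <- length(r)
  leaf <- oracle_match(r, domain_eff, offsets_by_size[[as.character(L)]],
                       shift_range, config)
  if (leaf$frms <= config$frms_limit || depth >= config$max_divisions)
    return(list(type = "leaf", depth = depth, leaf = leaf))
  h <- L %/% 2
  list(type = "split", depth = depth,
       left = oracle_encode(r[seq_len(h)], domain_eff, offsets_by_size,
                            shift_range, config, depth + 1),
       right = oracle_encode(r[h + seq_len(h)], domain_eff, offsets_by_size,
                             shift_range, config, depth + 1))
}

# Strip non-serialized bookkeeping so tree comparisons are field-exact.
strip_frms <- function(node) {
  if (node$type == "leaf") {
    node$leaf$frms <- NULL
    node
  } else {
    node$left <- strip_frms(node$left)
    node$right <- strip_frms(node$right)
    node
  }
}

collect_leaves <- function(node) {
  if (node$type == "leaf") return(list(list(depth = node$depth, leaf = node$leaf)))
  c(collect_leaves(node$left), collect_leaves(node$right))
}
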