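#' Remove the DC component of a signal
#'
#' Subtracts the arithmetic mean (which absorbs any constant offset) so that
#' compression always operates on a zero-mean signal; the mean is recorded in
#' the stream header and restored after reconstruction.
#'
#' @param x Numeric sample vector.
#' @return A list with `x0` (the DC-removed samples) and `dc` (the mean).
#' @examples
#' subtract_dc(c(1, 2, 3))
#' @export
subtract_dc <- function(x) {
  check_numeric_vector(x, "x")
  dc <- mean(x)
  list(x0 = x - dc, dc = dc)
}

#' Select the single-cycle domain
#'
#' The domain is one ECG cycle, running from a P-wave onset to just before
#' the next P-wave onset. With explicit `cycle_bounds` the cycle is taken
#' verbatim. Otherwise the cycle whose length is closest to the median cycle
#' length among the first five cycles delimited by `p_onsets` is chosen
#' (ties resolved to the earliest cycle). If `config$domain_halved` the
#' stored samples are pairwise means of adjacent samples.
#'
#' Indices are 0-based; `cycle_bounds = c(start, end)` is half-open.
#'
#' @param x0 DC-removed sample vector.
#' @param config A [scyf_config()].
#' @param cycle_bounds Optional integer pair `c(start, end)`, 0-based
#'   half-open, overriding automatic selection.
#' @param p_onsets Optional 0-based P-wave onset indices (>= 2 required for
#'   automatic selection).
#' @return An object of class `scyf_domain` with fields `samples` (the
#'   stored, possibly halved cycle), `start`, `end`, `halved`.
#' @export
select_domain <- function(x0, config, cycle_bounds = NULL, p_onsets = NULL) {
  check_numeric_vector(x0, "x0")
  if (!is.null(cycle_bounds)) {
    if (length(cycle_bounds) != 2L)
      scyf_stop("`cycle_bounds` must be c(start, end)", "scyf_invalid_input")
    start <- as.integer(cycle_bounds[1]); end <- as.integer(cycle_bounds[2])
    if (start < 0L || start >= end || end > length(x0))
      scyf_stop("`cycle_bounds` out of range", "scyf_invalid_input")
  } else if (!is.null(p_onsets) && length(p_onsets) >= 2L) {
    on <- as.integer(sort(p_onsets))
    starts <- on[-length(on)]
    ends <- on[-1]
    keep <- seq_len(min(5L, length(starts)))  # first five cycles
    lens <- (ends - starts)[keep]
    med <- stats::median(lens)
    pick <- which.min(abs(lens - med))        # which.min takes the earliest tie
    start <- starts[pick]; end <- ends[pick]
    if (start < 0L || end > length(x0))
      scyf_stop("`p_onsets` out of range", "scyf_invalid_input")
  } else {
    scyf_stop("no `cycle_bounds` and fewer than two `p_onsets`: cannot demarcate a domain cycle",
              "scyf_missing_annotation")
  }
  if (end - start < config$block_size)
    scyf_stop(sprintf("domain cycle (%d samples) is shorter than block_size (%d)",
                      end - start, config$block_size), "scyf_config_error")
  cycle <- x0[(start + 1L):end]
  samples <- if (config$domain_halved) halve_samples(cycle) else cycle
  structure(list(samples = samples, start = start, end = end,
                 halved = config$domain_halved),
            class = "scyf_domain")
}

# Pairwise means; an odd trailing sample stands alone.
halve_samples <- function(x) {
  n <- length(x)
  h <- ceiling(n / 2)
  out <- numeric(h)
  full <- seq_len(floor(n / 2))
  out[full] <- (x[2 * full - 1] + x[2 * full]) / 2
  if (n %% 2L == 1L) out[h] <- x[n]
  out
}

# Full-length view of the domain used for matching: halved domains are
# re-expanded by linear interpolation at the pairwise-average centres.
domain_effective <- function(domain) {
  n <- domain$end - domain$start
  if (!domain$halved) return(domain$samples)
  h <- length(domain$samples)
  centers <- 2 * seq_len(h) - 1.5       # 0-based centre of samples (2k, 2k+1)
  if (n %% 2L == 1L) centers[h] <- n - 1
  stats::approx(centers, domain$samples, xout = seq_len(n) - 1, rule = 2)$y
}

#' @export
print.scyf_domain <- function(x, ...) {
  cat(sprintf("<scyf_domain> cycle [%d, %d) (%d samples%s)\n", x$start, x$end,
              length(x$samples), if (x$halved) ", halved" else ""))
  invisible(x)
}

#' Build the pool of overlapping domain blocks
#'
#' For every permitted leaf size `L = BS / 2^k`, `k = 0..max_divisions`, the
#' domain is sliced into overlapping blocks starting at offsets
#' `0, JS, 2 JS, ...` with the last block fully inside the domain, giving
#' `floor((Ld - L) / JS) + 1` blocks of size `L` for a domain of length `Ld`.
#'
#' @param domain A `scyf_domain` (halved domains are re-expanded to the full
#'   cycle length by linear interpolation before slicing).
#' @param config A [scyf_config()].
#' @return An object of class `scyf_pool`: offsets per size plus the
#'   per-size block matrices and their cached column sums used by the
#'   matcher.
#' @export
build_domain_pool <- function(domain, config) {
  eff <- domain_effective(domain)
  ld <- length(eff)
  bs <- config$block_size
  js <- config$jump_step
  if (ld < bs)
    scyf_stop("domain shorter than block_size", "scyf_config_error")
  sizes <- bs / 2^(0:config$max_divisions)
  offsets <- list()
  mats <- list()
  for (L in sizes) {
    m <- floor((ld - L) / js) + 1
    off <- (seq_len(m) - 1L) * js
    idx <- outer(seq_len(L), off, `+`)     # 1-based sample indices per block
    D <- matrix(eff[idx], nrow = L)
    key <- as.character(L)
    offsets[[key]] <- off
    mats[[key]] <- list(D = D, sd = colSums(D), sdd = colSums(D * D), count = m)
  }
  structure(list(sizes = sizes, offsets = offsets, mats = mats,
                 domain_length = ld),
            class = "scyf_pool")
}

pool_count <- function(pool, size) {
  m <- pool$mats[[as.character(size)]]
  if (is.null(m)) scyf_stop(sprintf("no domain blocks of size %d in pool", size),
                            "scyf_internal_error")
  m$count
}

#' Pairwise sample swap (the affine block transform)
#'
#' Exchanges each two adjacent samples: `y[2i] = x[2i+1]`, `y[2i+1] = x[2i]`.
#' It is an involution — applying it twice restores the input — and is the
#' single non-trivial block transform the codec uses (the other option being
#' "none"), so one bit encodes the choice.
#'
#' @param block Numeric vector of even length.
#' @return The swapped vector.
#' @examples
#' pairwise_swap(c(1, 2, 3, 4))
#' @export
pairwise_swap <- function(block) {
  n <- length(block)
  if (n %% 2L != 0L)
    scyf_stop("`block` must have even length", "scyf_invalid_input")
  i <- seq(1L, n, by = 2L)
  out <- block
  out[i] <- block[i + 1L]
  out[i + 1L] <- block[i]
  out
}

# Mirror extension: reflect E samples (excluding the endpoint) on each side.
mirror_extend <- function(x, e) {
  n <- length(x)
  if (e == 0L) return(x)
  if (e >= n)
    scyf_stop("`extension` must be smaller than the signal length", "scyf_config_error")
  c(x[(e + 1L):2L], x, x[(n - 1L):(n - e)])
}
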