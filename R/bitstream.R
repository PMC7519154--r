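# ---- bit-level plumbing ----------------------------------------------------
# The stream is packed most-significant-bit first; multi-byte header integers
# are little-endian; doubles are IEEE 754 binary64, little-endian bytes.

bits_to_raw <- function(bits) {
  pad <- (-length(bits)) %% 8L
  if (pad) bits <- c(bits, integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(colSums(m * 2^(7:0)))
}

raw_to_bits <- function(r) {
  b <- as.integer(rawToBits(r))          # LSB-first within each byte
  if (length(b) == 0L) return(integer(0))
  m <- matrix(b, nrow = 8L)
  as.integer(m[8:1, , drop = FALSE])     # reorder to MSB-first
}

int_to_bits <- function(v, n) {
  if (n == 0L) return(integer(0))
  as.integer(floor(v / 2^((n - 1):0)) %% 2)
}

bits_to_num <- function(bits) {
  if (length(bits) == 0L) return(0)
  sum(bits * 2^((length(bits) - 1):0))
}

doubles_to_bits <- function(v) {
  raw_to_bits(writeBin(as.numeric(v), raw(), size = 8L, endian = "little"))
}

bit_writer <- function() {
  env <- new.env(parent = emptyenv())
  env$chunks <- vector("list", 64L)
  env$k <- 0L
  env
}

bw_push <- function(bw, bits) {
  bw$k <- bw$k + 1L
  if (bw$k > length(bw$chunks)) bw$chunks <- c(bw$chunks, vector("list", length(bw$chunks)))
  bw$chunks[[bw$k]] <- bits
  invisible(bw)
}

bw_bits <- function(bw) {
  as.integer(unlist(bw$chunks[seq_len(bw$k)], use.names = FALSE))
}

bit_reader <- function(bits) {
  env <- new.env(parent = emptyenv())
  env$bits <- bits
  env$pos <- 0L
  env
}

br_read <- function(br, n) {
  if (br$pos + n > length(br$bits))
    scyf_stop("stream truncated mid-body", "scyf_corrupt_stream")
  out <- br$bits[br$pos + seq_len(n)]
  br$pos <- br$pos + n
  out
}

br_read_num <- function(br, n) bits_to_num(br_read(br, n))

br_read_double <- function(br) {
  readBin(bits_to_raw(br_read(br, 64L)), "double", size = 8L, endian = "little")
}

index_bits <- function(count) max(ceiling(log2(count)), 0)

# ---- header ----------------------------------------------------------------

SCYF_MAGIC <- charToRaw("SCYF")
SCYF_VERSION <- 1L

write_header <- function(c) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  wint <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wdbl <- function(v) writeBin(as.numeric(v), con, size = 8L, endian = "little")
  cfg <- c$config
  writeBin(SCYF_MAGIC, con)
  wint(SCYF_VERSION, 1L)
  flags <- bitwOr(bitwOr(as.integer(cfg$domain_halved),
                         bitwShiftL(as.integer(cfg$smooth), 1L)),
                  bitwOr(bitwShiftL(as.integer(cfg$lossless_coeffs), 2L),
                         bitwShiftL(as.integer(c$payload_mode == "float"), 3L)))
  wint(flags, 1L)
  wdbl(c$fs)
  wint(c$n_samples, 4L)
  wint(c$source_bits, 1L)
  wdbl(c$dc)
  wint(cfg$block_size, 2L)
  wint(cfg$jump_step, 2L)
  wint(cfg$max_divisions, 1L)
  wint(cfg$extension, 2L)
  wint(cfg$smooth_span, 2L)
  wdbl(cfg$frms_limit)
  wint(cfg$scale_bits, 1L)
  wdbl(cfg$scale_range[1]); wdbl(cfg$scale_range[2])
  wint(cfg$shift_bits, 1L)
  wdbl(c$shift_range[1]); wdbl(c$shift_range[2])
  wint(c$domain$start, 4L)
  wint(c$domain$end, 4L)
  wint(length(c$domain$samples), 4L)
  wdbl(c$payload_offset)
  rawConnectionValue(con)
}

HEADER_BYTES <- 4L + 1L + 1L + 8L + 4L + 1L + 8L + 2L + 2L + 1L + 2L + 2L +
  8L + 1L + 16L + 1L + 16L + 4L + 4L + 4L + 8L

read_header <- function(b) {
  if (length(b) < HEADER_BYTES)
    scyf_stop("stream shorter than a SCYF header", "scyf_corrupt_stream")
  if (!identical(b[1:4], SCYF_MAGIC))
    scyf_stop("not a SCYF stream (bad magic)", "scyf_format_error")
  con <- rawConnection(b[-(1:4)], "rb")
  on.exit(close(con))
  rint <- function(size, signed = size >= 4L)
    readBin(con, "integer", size = size, endian = "little", signed = signed)
  rdbl <- function() readBin(con, "double", size = 8L, endian = "little")
  version <- rint(1L)
  if (version != SCYF_VERSION)
    scyf_stop(sprintf("unsupported SCYF stream version %d", version),
              "scyf_version_error")
  flags <- rint(1L)
  h <- list(
    fs = rdbl(),
    n_samples = rint(4L),
    source_bits = rint(1L),
    dc = rdbl(),
    block_size = rint(2L),
    jump_step = rint(2L),
    max_divisions = rint(1L),
    extension = rint(2L),
    smooth_span = rint(2L),
    frms_limit = rdbl(),
    scale_bits = rint(1L),
    scale_min = rdbl(), scale_max = rdbl(),
    shift_bits = rint(1L),
    shift_min = rdbl(), shift_max = rdbl(),
    domain_start = rint(4L),
    domain_end = rint(4L),
    domain_len = rint(4L),
    payload_offset = rdbl()
  )
  h$domain_halved <- bitwAnd(flags, 1L) > 0L
  h$smooth <- bitwAnd(flags, 2L) > 0L
  h$lossless_coeffs <- bitwAnd(flags, 4L) > 0L
  h$payload_float <- bitwAnd(flags, 8L) > 0L
  h
}

# ---- tree body -------------------------------------------------------------

write_node <- function(bw, node, depth, config, pool_counts) {
  at_max <- depth >= config$max_divisions
  if (node$type == "split") {
    if (at_max)
      scyf_stop("split node below the maximum division depth", "scyf_internal_error")
    bw_push(bw, 1L)
    write_node(bw, node$left, depth + 1L, config, pool_counts)
    write_node(bw, node$right, depth + 1L, config, pool_counts)
  } else {
    if (!at_max) bw_push(bw, 0L)
    lf <- node$leaf
    size <- config$block_size / 2^depth
    if (lf$size != size)
      scyf_stop("leaf size inconsistent with its depth", "scyf_internal_error")
    count <- pool_counts[[as.character(size)]]
    if (lf$db_index < 0 || lf$db_index >= count)
      scyf_stop("leaf db_index exceeds its fixed width", "scyf_encoding_error")
    bw_push(bw, int_to_bits(lf$db_index, index_bits(count)))
    bw_push(bw, as.integer(lf$transform))
    if (config$lossless_coeffs) {
      bw_push(bw, doubles_to_bits(lf$scale_code))
      bw_push(bw, doubles_to_bits(lf$shift_code))
    } else {
      bw_push(bw, int_to_bits(lf$scale_code, config$scale_bits))
      bw_push(bw, int_to_bits(lf$shift_code, config$shift_bits))
    }
  }
}

read_node <- function(br, depth, config, pool_counts) {
  at_max <- depth >= config$max_divisions
  split <- if (at_max) 0L else br_read(br, 1L)
  if (split == 1L) {
    list(type = "split", depth = depth,
         left = read_node(br, depth + 1L, config, pool_counts),
         right = read_node(br, depth + 1L, config, pool_counts))
  } else {
    size <- as.integer(config$block_size / 2^depth)
    count <- pool_counts[[as.character(size)]]
    db <- as.integer(br_read_num(br, index_bits(count)))
    tr <- as.integer(br_read_num(br, 1L))
    if (config$lossless_coeffs) {
      sc <- br_read_double(br)
      sh <- br_read_double(br)
    } else {
      sc <- br_read_num(br, config$scale_bits)
      sh <- br_read_num(br, config$shift_bits)
    }
    list(type = "leaf", depth = depth,
         leaf = list(size = size, db_index = db, scale_code = sc,
                     shift_code = sh, transform = tr, frms = NA_real_))
  }
}

# Domain-block counts per leaf size, derived purely from header quantities so
# the body is self-describing.
derive_pool_counts <- function(domain_length, config) {
  sizes <- config$block_size / 2^(0:config$max_divisions)
  counts <- lapply(sizes, function(L) floor((domain_length - L) / config$jump_step) + 1)
  names(counts) <- as.character(sizes)
  counts
}

# ---- public API ------------------------------------------------------------

#' Serialize a compressed ECG to the `.scyf` byte stream
#'
#' Layout: 4-byte magic `"SCYF"`, a version byte, a fixed-width header
#' (flags, sampling rate, sample count, source resolution, DC value, codec
#' configuration, quantizer ranges, domain coordinates), then a bit section
#' holding the domain payload followed by the per-tree node codes, zero
#' padded to a byte boundary. Bits are packed most-significant-bit first;
#' multi-byte header integers are little-endian. Each tree node spends one
#' split bit while above the maximum division depth (a leaf is implied at
#' the maximum); a leaf is `[db_index][transform][scale_code][shift_code]`
#' with the index width `ceiling(log2(pool count))` derived from the header.
#'
#' @param c A `scyf_compressed` object.
#' @return A raw vector; identical input yields identical bytes.
#' @seealso [scyf_deserialize()], [bit_cost()], [scyf_write()]
#' @export
scyf_serialize <- function(c) {
  if (!inherits(c, "scyf_compressed"))
    scyf_stop("`c` must be a scyf_compressed object", "scyf_invalid_input")
  header <- write_header(c)
  bw <- bit_writer()
  if (c$payload_mode == "float") {
    bw_push(bw, doubles_to_bits(c$domain$samples))
  } else {
    vals <- round(c$domain$samples + c$dc) - c$payload_offset
    if (any(vals < 0) || any(vals > 2^c$source_bits - 1))
      scyf_stop("domain payload exceeds its fixed width", "scyf_encoding_error")
    for (v in vals) bw_push(bw, int_to_bits(v, c$source_bits))
  }
  counts <- derive_pool_counts(c$domain$end - c$domain$start, c$config)
  for (tree in c$trees) write_node(bw, tree, 0L, c$config, counts)
  c(header, bits_to_raw(bw_bits(bw)))
}

#' Deserialize a `.scyf` byte stream
#'
#' Exact inverse of [scyf_serialize()]; everything needed to rebuild the
#' compressed object (pool counts, index widths, tree count) is re-derived
#' from the header, so the stream is fully self-contained. Leaf `frms`
#' bookkeeping is not serialized and comes back as `NA`.
#'
#' @param b Raw vector beginning with the magic bytes `"SCYF"`.
#' @return A `scyf_compressed` object.
#' @export
scyf_deserialize <- function(b) {
  if (!is.raw(b)) scyf_stop("`b` must be a raw vector", "scyf_invalid_input")
  h <- read_header(b)
  config <- scyf_config(
    block_size = h$block_size, jump_step = h$jump_step,
    frms_limit = h$frms_limit, max_divisions = h$max_divisions,
    smooth = h$smooth, smooth_span = h$smooth_span,
    domain_halved = h$domain_halved, extension = h$extension,
    scale_bits = h$scale_bits, scale_range = c(h$scale_min, h$scale_max),
    shift_bits = h$shift_bits, lossless_coeffs = h$lossless_coeffs
  )
  br <- bit_reader(raw_to_bits(b[-seq_len(HEADER_BYTES)]))
  if (h$payload_float) {
    samples <- vapply(seq_len(h$domain_len), function(i) br_read_double(br), numeric(1))
    payload_mode <- "float"
    payload_offset <- 0
  } else {
    vals <- vapply(seq_len(h$domain_len), function(i) br_read_num(br, h$source_bits),
                   numeric(1))
    samples <- (vals + h$payload_offset) - h$dc
    payload_mode <- "int"
    payload_offset <- h$payload_offset
  }
  domain <- structure(list(samples = samples, start = h$domain_start,
                           end = h$domain_end, halved = h$domain_halved),
                      class = "scyf_domain")
  counts <- derive_pool_counts(h$domain_end - h$domain_start, config)
  n_trees <- ceiling((h$n_samples + 2L * config$extension) / config$block_size)
  trees <- lapply(seq_len(n_trees), function(i) read_node(br, 0L, config, counts))
  structure(list(
    fs = h$fs, n_samples = h$n_samples, source_bits = h$source_bits,
    dc = h$dc, shift_range = c(h$shift_min, h$shift_max),
    config = config, domain = domain,
    payload_mode = payload_mode, payload_offset = payload_offset,
    trees = trees
  ), class = "scyf_compressed")
}

#' Exact bit size of the compressed stream
#'
#' The total counts everything the output stream contains — header, domain
#' payload, tree body and the final byte padding — because the efficiency
#' metrics (avL, CF) are defined on the whole output stream.
#'
#' @param c A `scyf_compressed` object.
#' @return Total size in bits (`8 *` the serialized byte length).
#' @export
bit_cost <- function(c) 8L * length(scyf_serialize(c))

#' Read/write `.scyf` container files
#'
#' @param c A `scyf_compressed` object.
#' @param path File path.
#' @return `scyf_write` returns `path` invisibly; `scyf_read` returns a
#'   `scyf_compressed` object.
#' @export
scyf_write <- function(c, path) {
  writeBin(scyf_serialize(c), path)
  invisible(path)
}

#' @rdname scyf_write
#' @export
scyf_read <- function(path) {
  scyf_deserialize(readBin(path, "raw", n = file.size(path)))
}

#' Inspect a compressed stream
#'
#' Debugging aid: returns (JSON-serialisable) header fields plus per-tree
#' leaf counts and maximum depths.
#'
#' @param c A `scyf_compressed` object or a path to a `.scyf` file.
#' @return A list with `header` and `trees` components.
#' @export
scyf_inspect <- function(c) {
  if (is.character(c)) c <- scyf_read(c)
  if (!inherits(c, "scyf_compressed"))
    scyf_stop("`c` must be a scyf_compressed object or a path", "scyf_invalid_input")
  depths <- function(node) if (node$type == "leaf") node$depth else
    c(depths(node$left), depths(node$right))
  list(
    header = list(
      fs = c$fs, n_samples = c$n_samples, source_bits = c$source_bits,
      dc = c$dc, shift_range = c$shift_range,
      block_size = c$config$block_size, jump_step = c$config$jump_step,
      frms_limit = c$config$frms_limit, max_divisions = c$config$max_divisions,
      domain_halved = c$config$domain_halved, extension = c$config$extension,
      smooth = c$config$smooth, lossless_coeffs = c$config$lossless_coeffs,
      domain = list(start = c$domain$start, end = c$domain$end,
                    stored_samples = length(c$domain$samples)),
      payload_mode = c$payload_mode,
      total_bits = bit_cost(c)
    ),
    trees = lapply(c$trees, function(t) {
      d <- depths(t)
      list(leaves = length(d), max_depth = max(d))
    })
  )
}
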