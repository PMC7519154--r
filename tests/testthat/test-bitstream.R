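test_that("serialization is deterministic and bit_cost is 8x the byte length", {
  cz <- random_compressed(101)
  b1 <- scyf_serialize(cz)
  b2 <- scyf_serialize(cz)
  expect_identical(b1, b2)
  expect_identical(rawToChar(b1[1:4]), "SCYF")
  expect_equal(bit_cost(cz), 8 * length(b1))
})

test_that("stream length follows the documented fixed-width layout exactly", {
  # all-leaf encoding with a known pool: 512-sample domain, BS 256, JS 1
  # -> 257 blocks at size 256, so a depth-0 leaf costs
  # 1 (split) + 9 (index) + 1 (transform) + 8 (scale) + 11 (shift) bits.
  x <- round(100 * tiled_signal(8, 512, seed = 12))
  cfg <- scyf_config(block_size = 256, jump_step = 1, max_divisions = 2,
                     frms_limit = Inf, scale_bits = 8, shift_bits = 11)
  cz <- scyf_compress(x, fs = 500, source_bits = 16, config = cfg,
                      cycle_bounds = c(0, 512))
  header_bytes <- 98                      # fixed-width header incl. magic+version
  payload_bits <- 512 * 16                # integer payload at source resolution
  body_bits <- length(cz$trees) * (1 + 9 + 1 + 8 + 11)
  expected <- header_bytes + ceiling((payload_bits + body_bits) / 8)
  expect_equal(length(scyf_serialize(cz)), expected)
  # one more all-leaf tree adds exactly its layout width (modulo byte padding)
  cz2 <- cz
  cz2$trees <- c(cz$trees, cz$trees[1])
  cz2$n_samples <- cz$n_samples + 256L
  expected2 <- header_bytes + ceiling((payload_bits + body_bits + 30) / 8)
  expect_equal(length(scyf_serialize(cz2)), expected2)
})

test_that("round-trip reproduces every field and the reconstruction bit-exactly", {
  for (seed in 1:20) {
    cz <- random_compressed(seed)
    cz2 <- scyf_deserialize(scyf_serialize(cz))
    expect_identical(cz2$fs, cz$fs)
    expect_identical(cz2$n_samples, cz$n_samples)
    expect_identical(cz2$source_bits, cz$source_bits)
    expect_identical(cz2$dc, cz$dc)
    expect_identical(cz2$shift_range, cz$shift_range)
    expect_identical(unclass(cz2$config), unclass(cz$config))
    expect_identical(cz2$domain$samples, cz$domain$samples)
    expect_identical(cz2$domain$start, cz$domain$start)
    expect_identical(cz2$domain$end, cz$domain$end)
    expect_identical(lapply(cz2$trees, strip_frms), lapply(cz$trees, strip_frms))
    expect_identical(scyf_reconstruct(cz2)$signal, scyf_reconstruct(cz)$signal)
  }
})

test_that("malformed streams fail with the documented error classes", {
  cz <- random_compressed(55)
  b <- scyf_serialize(cz)
  bad <- b; bad[1:4] <- charToRaw("NOPE")
  expect_error(scyf_deserialize(bad), class = "scyf_format_error")
  badv <- b; badv[5] <- as.raw(99)
  expect_error(scyf_deserialize(badv), class = "scyf_version_error")
  expect_error(scyf_deserialize(b[1:60]), class = "scyf_corrupt_stream")
  expect_error(scyf_deserialize(b[1:(length(b) - 2)]), class = "scyf_corrupt_stream")
  expect_error(scyf_deserialize("not raw"), class = "scyf_invalid_input")
})

test_that("stream size grows with the number of leaves for a fixed header", {
  x <- adc(generate_ecg(generator_spec(duration = 6, seed = 3))$signal)
  sizes <- vapply(c(Inf, 20, 5, 1), function(lim) {
    cfg <- scyf_config(block_size = 256, frms_limit = lim, max_divisions = 2)
    bit_cost(scyf_compress(x, fs = 500, source_bits = 16, config = cfg,
                           cycle_bounds = c(0, 500)))
  }, numeric(1))
  expect_false(is.unsorted(sizes))   # tighter limits -> more leaves -> more bits
})

test_that("file IO and inspect round-trip through the .scyf container", {
  cz <- random_compressed(77)
  path <- withr::local_tempfile(fileext = ".scyf")
  scyf_write(cz, path)
  expect_identical(scyf_serialize(scyf_read(path)), scyf_serialize(cz))
  info <- scyf_inspect(path)
  expect_equal(info$header$n_samples, cz$n_samples)
  expect_length(info$trees, length(cz$trees))
  expect_equal(info$header$total_bits, bit_cost(cz))
})
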