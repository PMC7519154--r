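# Small manual pool over a known cycle, shared by several blocks below.
make_pool <- function(cycle, cfg) {
  d <- structure(list(samples = cycle, start = 0L, end = length(cycle),
                      halved = FALSE), class = "scyf_domain")
  build_domain_pool(d, cfg)
}

test_that("match_block finds exact members and constructed swap matches", {
  cyc <- random_cycle(128, seed = 2)
  cfg <- scyf_config(block_size = 32, jump_step = 1, max_divisions = 0,
                     lossless_coeffs = TRUE)
  pool <- make_pool(cyc, cfg)
  header <- list(shift_range = range(cyc))
  # r identical to some domain block -> that block, no transform, frms 0
  r <- cyc[41:72]
  leaf <- match_block(r, pool, header, cfg)
  expect_equal(leaf$db_index, 40)
  expect_equal(leaf$transform, 0)
  expect_lt(leaf$frms, 1e-12)
  # r equal to the swap of DB_k -> index k, swap transform, frms 0
  k <- 17
  r2 <- pairwise_swap(cyc[k + (1:32)])
  leaf2 <- match_block(r2, pool, header, cfg)
  expect_equal(leaf2$db_index, k)
  expect_equal(leaf2$transform, 1)
  expect_lt(leaf2$frms, 1e-12)
  expect_error(match_block(stats::rnorm(16), pool, header, cfg),
               class = "scyf_internal_error")
})

test_that("match_block equals the brute-force enumeration on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    cfg <- scyf_config(block_size = 32, jump_step = sample(1:3, 1),
                       max_divisions = 1,
                       scale_bits = sample(5:8, 1), shift_bits = sample(7:10, 1),
                       lossless_coeffs = seed %% 3 == 0)
    cyc <- random_cycle(sample(64:128, 1), seed = seed + 100)
    pool <- make_pool(cyc, cfg)
    header <- list(shift_range = range(cyc) * 1.5)
    for (L in c(32, 16)) {
      r <- stats::rnorm(L, sd = stats::sd(cyc))
      got <- match_block(r, pool, header, cfg)
      want <- oracle_match(r, cyc, pool$offsets[[as.character(L)]],
                           header$shift_range, cfg)
      expect_equal(got$db_index, want$db_index)
      expect_equal(got$transform, want$transform)
      expect_equal(got$scale_code, want$scale_code)
      expect_equal(got$shift_code, want$shift_code)
      expect_equal(got$frms, want$frms, tolerance = 1e-9)
    }
  }
})

test_that("encode_range splits per the FRMS rule and matches the oracle recursion", {
  cyc <- random_cycle(200, seed = 9)
  header <- list(shift_range = range(cyc) * 2)
  # infinite limit: always a single depth-0 leaf
  cfg_inf <- scyf_config(block_size = 64, frms_limit = Inf, max_divisions = 2)
  pool <- make_pool(cyc, cfg_inf)
  set.seed(1)
  r <- stats::rnorm(64)
  node <- encode_range(r, pool, header, cfg_inf)
  expect_equal(node$type, "leaf")
  expect_equal(node$depth, 0)
  # unreachably small limit on noise: full tree of depth-2 leaves
  cfg_zero <- scyf_config(block_size = 64, frms_limit = 1e-12, max_divisions = 2)
  node2 <- encode_range(r, pool, header, cfg_zero)
  leaves <- collect_leaves(node2)
  expect_length(leaves, 4)
  expect_true(all(vapply(leaves, function(l) l$depth, numeric(1)) == 2))
  # seeded instance vs the naive recursive oracle
  for (seed in 1:5) {
    set.seed(seed + 40)
    cfg <- scyf_config(block_size = 64, frms_limit = stats::runif(1, 0.1, 0.6),
                       max_divisions = 2)
    r3 <- stats::rnorm(64, sd = 1)
    got <- encode_range(r3, pool, header, cfg)
    want <- oracle_encode(r3, cyc, pool$offsets, header$shift_range, cfg)
    expect_equal(strip_frms(got), strip_frms(want), tolerance = 1e-12)
  }
})

test_that("compress of an exact tiling yields identity leaves everywhere", {
  x <- tiled_signal(8, 256, seed = 3)
  cfg <- scyf_config(block_size = 256, jump_step = 1, max_divisions = 2,
                     lossless_coeffs = TRUE)
  cz <- scyf_compress(x, fs = 500, source_bits = 16, config = cfg,
                      cycle_bounds = c(0, 256))
  expect_length(cz$trees, 8)
  for (tree in cz$trees) {
    expect_equal(tree$type, "leaf")
    expect_equal(tree$leaf$db_index, 0)
    expect_equal(tree$leaf$transform, 0)
    expect_lt(tree$leaf$frms, 1e-10)
    expect_equal(tree$leaf$scale_code, 1, tolerance = 1e-9)
    expect_lt(abs(tree$leaf$shift_code), 1e-9)
  }
})

test_that("presets carry the published per-database settings", {
  for (nm in c("cse", "upt", "butqdb")) {
    p <- scyf_preset(nm)
    expect_equal(p$block_size, 256L)
    expect_equal(p$jump_step, 1L)
    expect_equal(p$frms_limit, 12)
    expect_equal(p$max_divisions, 2L)
  }
  m <- scyf_preset("mitadb")
  expect_equal(m$block_size, 128L)
  expect_equal(m$jump_step, 1L)
  expect_equal(m$frms_limit, 5)
  expect_equal(m$max_divisions, 3L)
  # the configuration echo survives into the compressed header
  x <- tiled_signal(3, 300, seed = 8)
  cz <- scyf_compress(x, fs = 500, source_bits = 16,
                      config = scyf_preset("cse"), cycle_bounds = c(0, 300))
  expect_equal(cz$config$block_size, 256L)
  expect_equal(cz$config$jump_step, 1L)
  expect_equal(cz$config$frms_limit, 12)
  expect_equal(cz$config$max_divisions, 2L)
})

test_that("tail padding: tree count and crop follow ceil(n_padded/BS)", {
  set.seed(14)
  x <- as.numeric(stats::filter(stats::rnorm(1000), rep(0.2, 5), sides = 1))
  x[is.na(x)] <- 0
  cfg <- scyf_config(block_size = 256, max_divisions = 1)
  cz <- scyf_compress(x, fs = 500, source_bits = 16, config = cfg,
                      cycle_bounds = c(0, 400))
  expect_length(cz$trees, 4)     # ceil(1000/256)
  rec <- scyf_reconstruct(cz)
  expect_length(rec$signal, 1000)
  # with extension, trees cover n + 2E
  cfg_e <- scyf_config(block_size = 256, max_divisions = 1, extension = 20L)
  cz_e <- scyf_compress(x, fs = 500, source_bits = 16, config = cfg_e,
                        cycle_bounds = c(0, 400))
  expect_length(cz_e$trees, ceiling((1000 + 40) / 256))
  expect_length(scyf_reconstruct(cz_e)$signal, 1000)
})

test_that("compress validates its inputs", {
  cfg <- scyf_config(block_size = 256)
  expect_error(scyf_compress(stats::rnorm(100), fs = 500, config = cfg,
                             cycle_bounds = c(0, 64)),
               class = "scyf_config_error")     # shorter than BS
  x <- stats::rnorm(600)
  x[5] <- NaN
  expect_error(scyf_compress(x, fs = 500, config = cfg, cycle_bounds = c(0, 300)),
               class = "scyf_invalid_input")
  expect_error(scyf_compress(stats::rnorm(600), fs = -1, config = cfg,
                             cycle_bounds = c(0, 300)),
               class = "scyf_invalid_input")
})
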