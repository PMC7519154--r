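test_that("subtract_dc removes the mean and records it", {
  expect_equal(subtract_dc(c(5, 5, 5)), list(x0 = c(0, 0, 0), dc = 5))
  expect_equal(subtract_dc(c(1, 2, 3)), list(x0 = c(-1, 0, 1), dc = 2))
  expect_error(subtract_dc(numeric(0)), class = "scyf_invalid_input")
  expect_error(subtract_dc(c(1, NA)), class = "scyf_invalid_input")
  # residual-mean property against direct summation, over random signals
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(sample(2:2000, 1), mean = stats::runif(1, -50, 50))
    r <- subtract_dc(x)
    expect_lt(abs(sum(r$x0) / length(x)), 1e-12 * max(abs(x)))
    expect_equal(r$x0 + r$dc, x)
  }
})

test_that("manual cycle bounds pass through verbatim", {
  x0 <- stats::rnorm(1000)
  cfg <- scyf_config(block_size = 256)
  d <- select_domain(x0, cfg, cycle_bounds = c(100, 612))
  expect_equal(d$start, 100)
  expect_equal(d$end, 612)
  expect_equal(d$samples, x0[101:612])
  expect_false(d$halved)
})

test_that("automatic selection picks the cycle closest to the median length", {
  x0 <- stats::rnorm(2600)
  cfg <- scyf_config(block_size = 256)
  on <- c(0, 500, 1010, 1500, 2005, 2500)
  # oracle: cycle lengths 500, 510, 490, 505, 495; median 500 -> cycle [0, 500)
  lens <- diff(on)
  pick <- which.min(abs(lens - stats::median(lens)))
  expect_equal(pick, 1L)
  d <- select_domain(x0, cfg, p_onsets = on)
  expect_equal(c(d$start, d$end), c(0, 500))
  # only the first five cycles are candidates
  on2 <- c(0, 400, 800, 1200, 1600, 2000, 2300)  # sixth cycle (300) ignored
  d2 <- select_domain(x0, cfg, p_onsets = on2)
  expect_equal(c(d2$start, d2$end), c(0, 400))
})

test_that("domain selection error contract", {
  x0 <- stats::rnorm(600)
  cfg <- scyf_config(block_size = 256)
  expect_error(select_domain(x0, cfg), class = "scyf_missing_annotation")
  expect_error(select_domain(x0, cfg, p_onsets = 10), class = "scyf_missing_annotation")
  expect_error(select_domain(x0, cfg, cycle_bounds = c(0, 100)),
               class = "scyf_config_error")  # cycle shorter than BS
  expect_error(select_domain(x0, cfg, cycle_bounds = c(500, 400)),
               class = "scyf_invalid_input")
})

test_that("halved domains store pairwise means and re-expand to full length", {
  x0 <- stats::rnorm(600)
  cfg <- scyf_config(block_size = 256, domain_halved = TRUE)
  d <- select_domain(x0, cfg, cycle_bounds = c(0, 512))
  expect_length(d$samples, 256)
  cyc <- x0[1:512]
  expect_equal(d$samples, (cyc[seq(1, 511, 2)] + cyc[seq(2, 512, 2)]) / 2)
  eff <- scyf:::domain_effective(d)
  expect_length(eff, 512)
  # linear re-expansion reproduces a linear ramp exactly away from the edges
  lin <- structure(list(samples = scyf:::halve_samples(as.numeric(1:512)),
                        start = 0L, end = 512L, halved = TRUE),
                   class = "scyf_domain")
  expect_equal(scyf:::domain_effective(lin)[3:510], as.numeric(3:510))
  # odd cycle length: ceiling(n/2) stored samples
  cfg2 <- scyf_config(block_size = 256, domain_halved = TRUE)
  d2 <- select_domain(x0, cfg2, cycle_bounds = c(0, 513))
  expect_length(d2$samples, 257)
  expect_length(scyf:::domain_effective(d2), 513)
})

test_that("domain pool has floor((Ld - L)/JS) + 1 ascending offsets per size", {
  x0 <- stats::rnorm(600)
  cfg <- scyf_config(block_size = 256, jump_step = 1, max_divisions = 2)
  d <- select_domain(x0, cfg, cycle_bounds = c(0, 512))
  pool <- build_domain_pool(d, cfg)
  expect_equal(length(pool$offsets[["256"]]), 257)
  expect_equal(length(pool$offsets[["128"]]), 385)
  expect_equal(length(pool$offsets[["64"]]), 449)
  expect_equal(pool$offsets[["256"]], 0:256)
  # every block lies fully inside the domain
  for (L in c(256, 128, 64)) {
    off <- pool$offsets[[as.character(L)]]
    expect_true(all(off + L <= 512))
    expect_false(is.unsorted(off, strictly = TRUE))
  }
  # boundary: domain exactly one block long
  d2 <- select_domain(x0, cfg, cycle_bounds = c(0, 256))
  pool2 <- build_domain_pool(d2, cfg)
  expect_equal(length(pool2$offsets[["256"]]), 1)
  # jump step thins the pool per the same formula
  cfg3 <- scyf_config(block_size = 256, jump_step = 7, max_divisions = 0)
  pool3 <- build_domain_pool(d, cfg3)
  expect_equal(length(pool3$offsets[["256"]]), floor((512 - 256) / 7) + 1)
})

test_that("pairwise swap is the documented involution", {
  expect_equal(pairwise_swap(c(1, 2, 3, 4)), c(2, 1, 4, 3))
  expect_equal(pairwise_swap(c(5, 5)), c(5, 5))
  expect_error(pairwise_swap(c(1, 2, 3)), class = "scyf_invalid_input")
  set.seed(4)
  for (i in 1:10) {
    b <- stats::rnorm(2 * sample(1:64, 1))
    expect_identical(pairwise_swap(pairwise_swap(b)), b)
  }
})

test_that("mirror extension reflects without repeating the edge sample", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(scyf:::mirror_extend(x, 2L), c(3, 2, 1, 2, 3, 4, 5, 4, 3))
  expect_equal(scyf:::mirror_extend(x, 0L), x)
  expect_error(scyf:::mirror_extend(x, 5L), class = "scyf_config_error")
})
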