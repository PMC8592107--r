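test_that("the CI back-derivation reproduces the hand-computed sampling SD", {
  se_c <- (2389 - 1126) / 3.92
  se_e <- (0.11 + 0.13) / 3.92
  by_hand <- sqrt((20000 * se_e)^2 + se_c^2) * sqrt(125)
  expect_equal(derive_pair_sd(), by_hand)
  expect_equal(round(by_hand, -1), 14160)   # the shipped default, to the tens
  # degenerate CIs carry no sampling noise
  expect_equal(derive_pair_sd(c(5, 5), c(0, 0)), 0)
  # perfect positive correlation with matched scales cancels exactly
  expect_equal(derive_pair_sd(ci_cost = c(0, 1000), ci_eff = c(0, 0.05),
                              wtp_lambda = 20000, correlation = 1), 0)
})

test_that("noise-free specifications reproduce the configured means exactly", {
  blocks <- generate_blocks(n_pairs = 30, block_size = 10, mean_inc_eff = -0.0101,
                            mean_inc_cost = 1758, sd_inc_eff = 0, sd_inc_cost = 0,
                            seed = 1)
  expect_equal(blocks$mean_inc_eff, rep(-0.0101, 3))
  expect_equal(blocks$mean_inc_cost, rep(1758, 3))
  expect_equal(block_inb(blocks, 20000)$mean_inb, rep(-1960, 3))
})

test_that("generation is seed-reproducible and block/pair tables stay consistent", {
  g1 <- generate_blocks(n_pairs = 45, block_size = 10, seed = 8, return_pairs = TRUE)
  g2 <- generate_blocks(n_pairs = 45, block_size = 10, seed = 8, return_pairs = TRUE)
  expect_identical(g1, g2)
  # final partial block of 5 pairs
  expect_equal(g1$blocks$n_pairs, c(10L, 10L, 10L, 10L, 5L))
  # per-pair net benefit equals the transform of the generated outcomes
  expect_equal(g1$pairs$inb,
               incremental_net_benefit(g1$pairs$eff_new, g1$pairs$eff_std,
                                       g1$pairs$cost_new, g1$pairs$cost_std,
                                       20000))
  # block means aggregate the pair stream
  agg <- as.numeric(tapply(g1$pairs$inb, g1$pairs$block_index, mean))
  expect_equal(agg, block_inb(g1$blocks, 20000)$mean_inb)
})

test_that("large samples recover the specified moments", {
  n <- 1e5
  pairs <- generate_pairs(n_pairs = n, mean_inc_eff = 0.02, mean_inc_cost = 1500,
                          sd_inc_eff = 0.5, sd_inc_cost = 3000,
                          eff_cost_correlation = 0.4, seed = 3)
  expect_lt(abs(mean(pairs$inc_eff) - 0.02), 3 * 0.5 / sqrt(n))
  expect_lt(abs(mean(pairs$inc_cost) - 1500), 3 * 3000 / sqrt(n))
  expect_lt(abs(sd(pairs$inc_eff) - 0.5), 3 * 0.5 / sqrt(2 * n))
  expect_lt(abs(sd(pairs$inc_cost) - 3000), 3 * 3000 / sqrt(2 * n))
  expect_lt(abs(cor(pairs$inc_eff, pairs$inc_cost) - 0.4), 3 / sqrt(n))
  # net benefit inherits the combined moments
  sd_inb <- sqrt((20000 * 0.5)^2 + 3000^2 - 2 * 0.4 * 20000 * 0.5 * 3000)
  expect_lt(abs(sd(pairs$inb) - sd_inb) / sd_inb, 0.02)
})

test_that("conditioning pins the realised table moments without breaking consistency", {
  got <- generate_blocks(n_pairs = 125, block_size = 10, seed = 4,
                         exact_mean_inb = -1808, exact_block_sd = 4477,
                         return_pairs = TRUE)
  expect_equal(mean(got$pairs$inb), -1808)
  binb <- block_inb(got$blocks, 20000)$mean_inb
  expect_equal(sd(binb[got$blocks$n_pairs == 10]), 4477)
  # pair and block tables still agree after the shifts
  agg <- as.numeric(tapply(got$pairs$inb, got$pairs$block_index, mean))
  expect_equal(agg, binb)
  # the shipped stand-in table uses the same conditioning
  std <- synthetic_profher_blocks(seed = 4)
  winb <- block_inb(std, 20000)
  expect_equal(weighted.mean(winb$mean_inb, winb$n_pairs), -1808)
})
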