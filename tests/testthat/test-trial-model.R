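test_that("incremental net monetary benefit follows the lambda*dE - dC transform", {
  # the worked example's trial estimates
  expect_equal(incremental_net_benefit(-0.0101, 0, 1758, 0, wtp_lambda = 20000),
               -1960)
  # identical arms
  expect_equal(incremental_net_benefit(0.3, 0.3, 500, 500, wtp_lambda = 20000), 0)
  # lambda = 0 reduces to negative incremental cost
  expect_equal(incremental_net_benefit(0.5, 0.1, 1758, 0, wtp_lambda = 0), -1758)
  # vectorised
  expect_equal(incremental_net_benefit(c(0, 0.1), 0, c(1758, 0), 0, 20000),
               c(-1758, 2000))
  expect_error(incremental_net_benefit(NA, 0, 1, 0, 1), class = "valseq_invalid_input")
  expect_error(incremental_net_benefit(Inf, 0, 1, 0, 1), class = "valseq_invalid_input")
})

test_that("block-level transform matches the pairwise one and accepts both schemas", {
  blocks <- tibble::tibble(block_index = 1:3, n_pairs = 10,
                           mean_inc_eff = c(0, 0.1, -0.0101),
                           mean_inc_cost = c(1758, 0, 1758))
  out <- block_inb(blocks, wtp_lambda = 20000)
  expect_equal(out$mean_inb, c(-1758, 2000, -1960))
  ready <- tibble::tibble(block_index = 1:2, n_pairs = 5, mean_inb = c(-1, 2))
  expect_equal(block_inb(ready, 20000)$mean_inb, c(-1, 2))

  expect_error(block_inb(tibble::tibble(block_index = 1, n_pairs = 1), 1),
               class = "valseq_invalid_input")
  disordered <- blocks[c(2, 1, 3), ]
  expect_error(block_inb(disordered, 20000), class = "valseq_invalid_input")
  bad <- blocks; bad$n_pairs[2] <- 0
  expect_error(block_inb(bad, 20000), class = "valseq_invalid_input")
})

test_that("posterior updating is the precision-weighted average", {
  b <- beliefs(mu = 0, m = 2, sigma_x = 7)
  expect_identical(update_posterior(b, numeric(0)), b)
  up <- update_posterior(b, c(3, 3))
  expect_equal(up$mu, 1.5)
  expect_equal(up$m, 4)
  expect_equal(up$sigma_x, 7)
  blockwise <- update_posterior(b, -1000, weights = 10)
  expect_equal(blockwise$mu, -10000 / 12)
  expect_equal(blockwise$m, 12)
  expect_error(update_posterior(b, c(1, 2), weights = 1), class = "valseq_invalid_input")
  expect_error(update_posterior(b, NA_real_), class = "valseq_invalid_input")
})

test_that("updating conserves mu*m, is order-invariant and aggregation-invariant", {
  set.seed(41)
  for (rep in 1:20) {
    mu0 <- rnorm(1, 0, 100); n0 <- runif(1, 0.5, 10)
    b0 <- beliefs(mu0, n0, sigma_x = 50)
    x <- rnorm(7, 0, 200); w <- sample(1:10, 7, replace = TRUE)
    b1 <- update_posterior(b0, x, w)
    # conservation
    expect_equal(b1$mu * b1$m, mu0 * n0 + sum(x * w))
    # order invariance
    ord <- sample(7)
    b2 <- b0
    for (i in ord) b2 <- update_posterior(b2, x[i], w[i])
    expect_equal(b2$mu, b1$mu)
    expect_equal(b2$m, b1$m)
    # aggregation invariance: pooled mean with total multiplicity
    b3 <- update_posterior(b0, weighted.mean(x, w), sum(w))
    expect_equal(b3$mu, b1$mu)
    expect_equal(b3$m, b1$m)
  }
})

test_that("prior effective sample size is the variance ratio", {
  expect_equal(effective_sample_size(10, 5), 4)
  expect_equal(effective_sample_size(3, 3), 1)
  expect_lt(effective_sample_size(10, 1e8), 1e-10)
  expect_error(effective_sample_size(10, 0), class = "valseq_invalid_input")
})

test_that("block tables round-trip through CSV in both schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  blocks <- tibble::tibble(block_index = 1:3, n_pairs = c(10L, 10L, 5L),
                           mean_inc_eff = c(-0.01, 0.02, 0),
                           mean_inc_cost = c(1500, -200, 300.25))
  write_block_table(blocks, path, header = c("seed: 7"))
  back <- read_block_table(path)
  expect_equal(as.data.frame(back), as.data.frame(blocks))
  expect_match(readLines(path)[1], "^# seed: 7")

  inb_only <- tibble::tibble(block_index = 1:2, n_pairs = 10L,
                             mean_inb = c(-1808.5, 12.25))
  write_block_table(inb_only, path)
  expect_equal(as.data.frame(read_block_table(path)), as.data.frame(inb_only))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(economic_params(-1, 10, 1, q_max = 10, delay_tau = 2),
               class = "valseq_invalid_params")
  expect_error(economic_params(1, 0, 1, q_max = 10, delay_tau = 2),
               class = "valseq_invalid_params")
  expect_error(economic_params(1, 10, 1, q_max = 5, delay_tau = 5),
               class = "valseq_invalid_params")
  expect_error(economic_params(1, 10, 1, q_max = 5, delay_tau = 2, block_size = 0),
               class = "valseq_invalid_params")
  expect_error(beliefs(0, 0, 1), class = "valseq_invalid_beliefs")
  expect_error(beliefs(0, 1, -1), class = "valseq_invalid_beliefs")
})
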