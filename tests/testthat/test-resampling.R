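b_res <- solve_small()
w_res <- small_world()

test_that("a one-block table makes every bootstrap path the deterministic replay", {
  one <- tibble::tibble(block_index = 1L, n_pairs = 5L, mean_inb = -40)
  oc <- bootstrap_paths(one, 50, b_res, seed = 11)
  g <- glance(oc)
  expect_equal(g$sd_allocations, 0)
  ref <- glance(run_path(const_blocks(-40, 60), b_res))
  expect_true(all(oc$per_path$allocations_T == ref$allocations_T))
  expect_true(all(oc$per_path$mu_final == ref$mu_final))
  expect_true(all(oc$per_path$crossing == ref$crossing))
})

test_that("identical seeds reproduce resampling analyses bit for bit", {
  blocks <- generate_blocks(n_pairs = 60, block_size = 5, mean_inc_eff = 0,
                            mean_inc_cost = 40, sd_inc_eff = 0,
                            sd_inc_cost = 100, seed = 5, wtp_lambda = 1)
  oc1 <- bootstrap_paths(blocks, 200, b_res, seed = 3)
  oc2 <- bootstrap_paths(blocks, 200, b_res, seed = 3)
  expect_identical(oc1$per_path, oc2$per_path)
  oc3 <- bootstrap_paths(blocks, 200, b_res, seed = 4)
  expect_false(identical(oc1$per_path, oc3$per_path))
  mc1 <- monte_carlo_paths(-40, 200, b_res, seed = 9)
  mc2 <- monte_carlo_paths(-40, 200, b_res, seed = 9)
  expect_identical(mc1$per_path, mc2$per_path)
})

test_that("overwhelming signals stop at the first look and recover the truth", {
  # strongly negative mean: every path exits low immediately, recommends standard
  dn <- monte_carlo_paths(-20 * 100 / sqrt(5), 300, b_res, seed = 21)
  g <- glance(dn)
  expect_equal(g$prob_standard, 1)
  expect_equal(g$frac_stop_look1, 1)
  expect_equal(g$mean_allocations, 5 + 10)
  expect_equal(g$min_allocations, 15)
  # strongly positive: the mirror image
  up <- monte_carlo_paths(20 * 100 / sqrt(5), 300, b_res, seed = 22)
  expect_equal(glance(up)$prob_new, 1)
})

test_that("a zero mean splits decisions evenly under the symmetric boundary", {
  oc <- monte_carlo_paths(0, 1000, b_res, seed = 13)
  g <- glance(oc)
  # 3 binomial SEs at p = 0.5, n = 1000 is about 0.047
  expect_lt(abs(g$prob_standard - 0.5), 3 * 0.5 / sqrt(1000) + 0.02)
})

test_that("operating characteristics respect structural invariants", {
  oc <- monte_carlo_paths(-40, 500, b_res, seed = 17)
  expect_equal(sum(oc$decision_matrix$prob), 1)
  expect_gte(glance(oc)$min_allocations, 5 + 10)
  expect_lte(glance(oc)$max_allocations, 60)
  expect_equal(sum(oc$look_fractions$fraction), 1)
  # budget identity: mean change equals the transform of mean allocations
  g <- glance(oc)
  expect_equal(g$mean_budget_change_gbp,
               (g$mean_allocations - oc$meta$reference_pairs) * 30)
})

test_that("aggregates use the textbook sample formulas", {
  paths <- tibble::tibble(
    stop_look = c(1L, 10L), n_observed_at_stop = c(10, 50),
    allocations_T = c(57, 250), mu_at_stop = c(-5, 1), mu_final = c(-4, 2),
    decision = c("standard", "new"), crossing = c("lower", "reached_max"),
    variable_cost = c(57, 250) * 4080
  )
  pf <- profher_params()
  oc <- summarize_paths(paths, pf$params)
  agg <- oc$aggregates[oc$aggregates$statistic == "allocations", ]
  expect_equal(agg$mean, 153.5)
  expect_equal(agg$sd, sd(c(57, 250)))   # n-1 denominator
  expect_equal(agg$min, 57)
  expect_equal(agg$max, 250)
  single <- summarize_paths(paths[1, ], pf$params)
  agg1 <- single$aggregates[single$aggregates$statistic == "allocations", ]
  expect_equal(agg1$mean, agg1$min)
  expect_equal(agg1$mean, agg1$max)
  expect_equal(agg1$sd, 0)
})

test_that("Monte Carlo error shrinks roughly as one over root n-paths", {
  est <- function(n_paths, seeds) {
    vapply(seeds, function(s)
      glance(monte_carlo_paths(-40, n_paths, b_res, seed = s))$mean_allocations,
      numeric(1))
  }
  sd_small <- sd(est(100, 1:8))
  sd_large <- sd(est(900, 11:18))
  expect_lt(sd_large, sd_small)     # more paths, tighter estimate
  expect_lt(sd_large, sd_small / 1.5)
})

test_that("the fixed design never stops early and flags degenerate sources", {
  neg <- tibble::tibble(block_index = 1L, n_pairs = 5L, mean_inb = -40)
  fx <- fixed_design_paths(100, w_res$params, w_res$prior, seed = 31, blocks = neg)
  g <- glance(fx)
  expect_equal(g$prob_standard, 1)
  expect_equal(g$mean_allocations, 60)
  expect_equal(g$sd_allocations, 0)
  expect_error(fixed_design_paths(10, w_res$params, w_res$prior, seed = 1),
               class = "valseq_invalid_input")
  expect_error(fixed_design_paths(10, w_res$params, w_res$prior, seed = 1,
                                  blocks = neg, true_mean = 0),
               class = "valseq_invalid_input")
})
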