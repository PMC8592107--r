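test_that("the normal partial expectation matches closed forms and Monte Carlo", {
  expect_equal(expected_positive_part(5, 0), 5)
  expect_equal(expected_positive_part(-3, 0), 0)
  expect_equal(expected_positive_part(0, 1), 1 / sqrt(2 * pi))
  # Monte Carlo oracle at mu = -1, s = 2
  set.seed(7)
  z <- pmax(rnorm(1e6, -1, 2), 0)
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(expected_positive_part(-1, 2) - mean(z)), 3 * se)
  # recycling
  expect_equal(expected_positive_part(0, c(1, 2)), c(1, 2) / sqrt(2 * pi))
  expect_error(expected_positive_part(0, -1), class = "valseq_invalid_input")
})

test_that("preposterior SD follows the conjugate information identity", {
  expect_equal(preposterior_sd(2, 0, 5), 0)
  expect_equal(preposterior_sd(2, 2, 2), 1)
  expect_equal(preposterior_sd(4, Inf, 10), 5)
  k <- c(0, 1, 5, 50, 1e6)
  expect_true(all(diff(preposterior_sd(3, k, 10)) > 0))
})

test_that("stopping value prices the terminal adoption decision over the pipeline", {
  # no delay: immediate decision by the sign of the posterior mean
  p0 <- economic_params(wtp_lambda = 1, pop_to_benefit_P = 1000, var_cost_c = 1,
                        q_max = 10, delay_tau = 0)
  pr <- beliefs(0, 2, 10)
  expect_equal(stop_value(3, -100, p0, pr), 0)
  expect_equal(stop_value(3, 100, p0, pr), 100 * 1000)
  # with a pipeline, mu = 0 gives P * s / sqrt(2*pi)
  p1 <- economic_params(wtp_lambda = 1, pop_to_benefit_P = 1000, var_cost_c = 1,
                        q_max = 10, delay_tau = 4)
  s <- preposterior_sd(2, 4, 10)
  expect_equal(stop_value(0, 0, p1, pr), 1000 * s / sqrt(2 * pi))
  expect_error(stop_value(11, 0, p1, pr), class = "valseq_invalid_input")
})

test_that("Gauss-Hermite rule reproduces normal moments", {
  gh <- valseq:::gauss_hermite(21)
  expect_equal(sum(gh$w), 1)
  # known 3-node rule: nodes 0, +/- sqrt(3/2) with weights 2/3, 1/6, 1/6
  gh3 <- valseq:::gauss_hermite(3)
  expect_equal(sort(gh3$x), c(-sqrt(1.5), 0, sqrt(1.5)))
  expect_equal(gh3$w[order(gh3$x)], c(1, 4, 1) / 6)
  # E[Z^2] = 1, E[Z^4] = 3 for Z ~ N(0,1) under the scaled rule
  z <- sqrt(2) * gh$x
  expect_equal(sum(gh$w * z^2), 1)
  expect_equal(sum(gh$w * z^4), 3)
})

b_small <- solve_small()

test_that("the value function dominates stopping, with equality off the continuation set", {
  w <- small_world()
  for (n in c(0, 7, 25, 49, 50)) {
    sv <- stop_value(n, b_small$grid, w$params, w$prior)
    v <- b_small$value[n + 1, ]
    expect_true(all(v >= sv - 1e-9))
    lo <- b_small$lower[n + 1]; hi <- b_small$upper[n + 1]
    outside <- if (is.na(lo)) rep(TRUE, length(b_small$grid))
               else b_small$grid < lo | b_small$grid > hi
    expect_equal(v[outside], sv[outside])
  }
})

test_that("the value function is convex in the posterior mean", {
  for (n in c(0, 10, 30, 50)) {
    d2 <- diff(b_small$value[n + 1, ], differences = 2)
    expect_gt(min(d2), -1e-6 * max(abs(b_small$value[n + 1, ])))
  }
})

test_that("with I = 0 the problem is symmetric: V(n, mu) - P*mu = V(n, -mu)", {
  P <- small_world()$params$pop_to_benefit_P
  for (n in c(0, 10, 30, 50)) {
    v <- b_small$value[n + 1, ]
    # the grid is symmetric about mu0 = 0, so reversal negates mu
    expect_equal(v - P * b_small$grid, rev(v), tolerance = 1e-6)
  }
  ok <- !is.na(b_small$lower)
  expect_equal(b_small$upper[ok], -b_small$lower[ok], tolerance = 1e-3)
})

test_that("the continuation region closes exactly at the last observable pair", {
  N <- 60 - 10
  expect_true(is.na(b_small$lower[N + 1]))
  expect_true(is.na(b_small$upper[N + 1]))
  expect_false(is.na(b_small$lower[1]))
  # interval widths shrink towards the closing cone
  width <- b_small$upper - b_small$lower
  expect_true(all(diff(width[!is.na(width)]) < 0))
})

test_that("prohibitive sampling cost empties the continuation region everywhere", {
  w <- small_world()
  pricey <- economic_params(wtp_lambda = 1, pop_to_benefit_P = 2000,
                            var_cost_c = 1e7, q_max = 60, delay_tau = 10,
                            block_size = 5)
  b <- solve_boundary(pricey, w$prior, grid_points = 301)
  expect_true(all(is.na(b$lower)))
  expect_true(all(is.na(b$upper)))
})

test_that("a grid that the boundary approaches is rejected with advice", {
  w <- small_world()
  expect_error(solve_boundary(w$params, w$prior, grid_points = 301,
                              grid_halfwidth_sds = 1.5),
               class = "valseq_grid_too_narrow")
})

test_that("doubling the recruitment ceiling barely moves the early boundary", {
  b2 <- solve_small(q_max = 120)
  ok <- !is.na(b_small$lower)
  height <- max(b_small$upper[ok])
  shared <- which(ok)   # n values observable under the smaller ceiling
  dif <- abs(b2$lower[shared] - b_small$lower[shared])
  expect_lt(max(dif, na.rm = TRUE), 0.05 * height)
})

test_that("backward induction reproduces the exhaustively enumerated optimal policy", {
  cases <- list(
    list(mu0 = 0.05, c = 0.02),
    list(mu0 = -0.3, c = 0.02),
    list(mu0 = 0.0, c = 0.005)
  )
  for (cs in cases) {
    params <- economic_params(wtp_lambda = 1, pop_to_benefit_P = 1,
                              var_cost_c = cs$c, q_max = 4, delay_tau = 1,
                              block_size = 1)
    prior <- beliefs(mu = cs$mu0, m = 1, sigma_x = 1)
    oracle <- oracle_best_policy(params, prior)
    b <- solve_boundary(params, prior, grid_points = 2001,
                        grid_halfwidth_sds = 8, quadrature = "two_point")
    # same optimal value at the root
    expect_equal(boundary_value(b, 0, prior$mu), oracle$value, tolerance = 1e-4)
    # the DP-induced stopping set achieves the enumerated optimum exactly
    dp_val <- oracle_policy_value(dp_tree_policy(b, oracle$lev, params),
                                  oracle$lev, params, prior)
    expect_equal(dp_val, oracle$value, tolerance = 1e-6)
  }
})

test_that("one-stage design: free information takes the delay, worthless populations abstain", {
  w <- small_world()
  free <- economic_params(wtp_lambda = 1, pop_to_benefit_P = 2000,
                          var_cost_c = 0, q_max = 60, delay_tau = 10,
                          block_size = 5)
  expect_equal(one_stage_design(free, w$prior)$n_star, 9)
  tinyP <- economic_params(wtp_lambda = 1, pop_to_benefit_P = 1e-9,
                           var_cost_c = 30, q_max = 60, delay_tau = 10,
                           block_size = 5)
  os <- one_stage_design(tinyP, w$prior)
  expect_equal(os$n_star, 0)
  expect_lt(abs(os$value), 1e-6)
  # EVSI is non-decreasing in the sample size
  tab <- one_stage_design(w$params, w$prior)$table
  expect_true(all(diff(tab$evsi_gbp) >= -1e-9))
})

test_that("prior-mean classification finds ordered thresholds around a sequential centre", {
  d <- classify_prior(b_small)
  expect_equal(d$label, "sequential")
  th <- d$thresholds$mu0_gbp
  expect_true(all(diff(th) >= -1e-6))            # B <= D <= C <= A
  expect_lt(th[2], 0); expect_gt(th[3], 0)       # D < 0 < C around mu0 = 0
  expect_equal(th[3], -th[2], tolerance = 2)     # symmetric design
  expect_equal(th[4], -th[1], tolerance = 2)
  # far beyond A the prior alone decides
  w <- small_world()
  up <- classify_prior(b_small, beliefs(th[4] + 50, w$prior$m, w$prior$sigma_x))
  expect_equal(up$label, "adopt_new_no_trial")
  dn <- classify_prior(b_small, beliefs(th[1] - 50, w$prior$m, w$prior$sigma_x))
  expect_equal(dn$label, "adopt_std_no_trial")
  expect_error(classify_prior(b_small, beliefs(0, 99, 100)),
               class = "valseq_invalid_input")
})

test_that("boundary tables expose both plotting coordinates", {
  tb <- tidy(b_small)
  expect_equal(tb$allocations, tb$n_observed + pmin(10, 60 - tb$n_observed))
  expect_equal(tb$plot_coordinate, tb$allocations + 2)
  lim <- boundary_limits(b_small, c(0, 5))
  expect_equal(lim$lower_gbp, b_small$lower[c(1, 6)])
  expect_error(boundary_limits(b_small, 51), class = "valseq_invalid_input")
})
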