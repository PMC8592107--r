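# Shared fixtures and independent oracles. Everything here is built in
# code at test time; no stored data.

# A fast, well-behaved sequential design: continuation region nonempty
# at n = 0 and empty at N = q_max - tau, sequential optimal at mu0 = 0.
small_world <- function(q_max = 60) {
  list(
    params = economic_params(wtp_lambda = 1, pop_to_benefit_P = 2000,
                             var_cost_c = 30, q_max = q_max, delay_tau = 10,
                             block_size = 5),
    prior = beliefs(mu = 0, m = 2, sigma_x = 100)
  )
}

solve_small <- function(q_max = 60, ...) {
  w <- small_world(q_max)
  solve_boundary(w$params, w$prior, grid_points = 601, ...)
}

# constant-outcome block table for the small world
const_blocks <- function(value, n_pairs_total, block_size = 5) {
  n_blocks <- ceiling(n_pairs_total / block_size)
  sizes <- rep(block_size, n_blocks)
  sizes[n_blocks] <- n_pairs_total - block_size * (n_blocks - 1)
  tibble::tibble(block_index = seq_len(n_blocks), n_pairs = sizes,
                 mean_inb = value)
}

# --- exhaustive-policy oracle for tiny instances -----------------------
# Exact optimal stopping on the binary outcome tree mu' = mu +/- v(n)
# with probability 1/2 each, evaluated by enumerating every stopping set
# over the decision nodes (levels 0 .. N-1). Independent of the DP code
# path: no grids, no interpolation, no quadrature.

oracle_tree <- function(params, prior) {
  N <- params$q_max - params$delay_tau
  lev <- list(prior$mu)
  if (N >= 1) {
    for (n in 1:N) {
      v <- preposterior_sd(prior$m + n - 1, 1, prior$sigma_x)
      # children of node i sit at positions 2i-1 (down) and 2i (up)
      lev[[n + 1]] <- as.vector(rbind(lev[[n]] - v, lev[[n]] + v))
    }
  }
  lev
}

oracle_policy_value <- function(stop_ids, lev, params, prior) {
  N <- params$q_max - params$delay_tau
  val <- function(n, i, mu) {
    if (n == N || paste(n, i) %in% stop_ids)
      return(stop_value(n, mu, params, prior))
    v <- preposterior_sd(prior$m + n, 1, prior$sigma_x)
    -params$var_cost_c +
      0.5 * (val(n + 1, 2 * i - 1, mu - v) + val(n + 1, 2 * i, mu + v))
  }
  val(0, 1, lev[[1]][1])
}

oracle_best_policy <- function(params, prior) {
  N <- params$q_max - params$delay_tau
  lev <- oracle_tree(params, prior)
  ids <- unlist(lapply(0:(N - 1), function(n) paste(n, seq_len(2^n))))
  best <- -Inf; best_set <- NULL
  for (mask in 0:(2^length(ids) - 1)) {
    ss <- ids[bitwAnd(bitwShiftL(1, seq_along(ids) - 1), mask) != 0]
    v <- oracle_policy_value(ss, lev, params, prior)
    if (v > best) { best <- v; best_set <- ss }
  }
  list(value = best, stop_set = best_set, lev = lev)
}

# stopping set induced by a solved boundary on the tree's decision nodes
dp_tree_policy <- function(boundary, lev, params) {
  N <- params$q_max - params$delay_tau
  unlist(lapply(0:(N - 1), function(n) {
    lo <- boundary$lower[n + 1]; hi <- boundary$upper[n + 1]
    mus <- lev[[n + 1]]
    stopped <- if (is.na(lo)) rep(TRUE, length(mus)) else !(mus > lo & mus < hi)
    paste(n, seq_along(mus))[stopped]
  }))
}
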