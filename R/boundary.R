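#' Partial expectation of a normal variable above zero
#'
#' E\[max(Z, 0)\] for Z ~ Normal(mu, s^2):
#' mu * Phi(mu/s) + s * phi(mu/s), with the degenerate limit
#' max(mu, 0) at s = 0. This values the terminal adoption decision:
#' with zero switching cost the new technology is adopted exactly when
#' the terminal posterior mean is positive, so the expected per-patient
#' payoff of deciding after the remaining uncertainty s resolves is
#' E[max(W, 0)].
#'
#' @param mu Mean (GBP); vectorised.
#' @param s Standard deviation (GBP, >= 0); vectorised.
#' @return E\[max(Z, 0)\] (GBP).
#' @examples
#' expected_positive_part(0, 1) # 1/sqrt(2*pi)
#' @export
expected_positive_part <- function(mu, s) {
  if (any(s < 0)) abort("`s` must be non-negative", class = "valseq_invalid_input")
  len <- max(length(mu), length(s))
  mu <- rep_len(mu, len)
  s <- rep_len(s, len)
  out <- pmax(mu, 0)
  pos <- s > 0
  if (any(pos)) {
    z <- mu[pos] / s[pos]
    out[pos] <- mu[pos] * pnorm(z) + s[pos] * dnorm(z)
  }
  out
}

#' Preposterior standard deviation of the posterior mean
#'
#' The SD, under current beliefs, of the movement of the posterior mean
#' after k further observations in the conjugate-normal known-variance
#' model: sigma_x * sqrt(1/m - 1/(m + k)). It is 0 at k = 0 and rises to
#' the full posterior SD sigma_x / sqrt(m) as k grows without bound
#' (`k = Inf` is accepted).
#'
#' @param m Current effective pair count (> 0).
#' @param k Number of future observations (>= 0); vectorised.
#' @param sigma_x Per-pair sampling SD (GBP).
#' @return SD of the posterior-mean increment (GBP).
#' @examples
#' preposterior_sd(2, 2, 2) # 1
#' @export
preposterior_sd <- function(m, k, sigma_x) {
  stopifnot(all(m > 0), all(k >= 0), all(sigma_x > 0))
  sigma_x * sqrt(1 / m - ifelse(is.infinite(k), 0, 1 / (m + k)))
}

#' Expected value of stopping recruitment now
#'
#' When recruitment halts after `n_observed` observed pairs, the
#' p = min(tau, q_max - n_observed) pipeline pairs already allocated are
#' still followed up, moving the posterior mean by a Normal(0, s^2)
#' increment with s = [preposterior_sd()]. Adoption then goes by the
#' sign of the terminal posterior mean (switching cost 0), so the
#' expected payoff over the P patients to benefit is
#' P * E\[max(terminal mean, 0)\]. Sampling costs already incurred are
#' sunk and excluded.
#'
#' @param n_observed Observed pairs, 0 .. q_max - tau.
#' @param mu Current posterior mean (GBP); vectorised.
#' @param params [economic_params()].
#' @param prior [beliefs()] prior (supplies n0 and sigma_x).
#' @return Expected stopping value (GBP); vectorised over `mu`.
#' @export
stop_value <- function(n_observed, mu, params, prior) {
  validate_params(params); validate_beliefs(prior)
  if (n_observed < 0 || n_observed > params$q_max - params$delay_tau)
    abort("`n_observed` must lie in [0, q_max - delay_tau]", class = "valseq_invalid_input")
  p <- min(params$delay_tau, params$q_max - n_observed)
  s <- preposterior_sd(prior$m + n_observed, p, prior$sigma_x)
  params$pop_to_benefit_P * expected_positive_part(mu, s)
}

# Gauss-Hermite nodes/weights by Golub-Welsch on the Jacobi matrix of the
# (physicists') Hermite polynomials. Returns nodes x and weights w with
# sum(w) = 1 such that E f(Z) ~ sum w_i f(mu + sqrt(2) s x_i) for
# Z ~ N(mu, s^2).
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(x = 0, w = 1))
  b <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- b
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = (e$vectors[1, ]^2)[ord])
}

# Evaluate V(n_next, q) for off-grid query points: linear interpolation
# inside the grid, the analytic stopping value outside (far from the
# continuation region the value function equals the stopping value).
interp_value <- function(grid, v, q, n_next, params, prior) {
  out <- numeric(length(q))
  inside <- q >= grid[1] & q <= grid[length(grid)]
  if (any(inside))
    out[inside] <- approx(grid, v, xout = q[inside], rule = 2)$y
  if (any(!inside))
    out[!inside] <- stop_value(n_next, q[!inside], params, prior)
  out
}

#' Solve the optimal stopping boundary by backward induction
#'
#' Computes the value of the sequential monitoring stage on a uniform
#' grid of posterior means and the induced continuation region. With
#' N = q_max - tau observable pairs, the terminal condition is
#' V(N, mu) = [stop_value()]; stepping backwards,
#' \deqn{C(n, \mu) = -c + E[V(n+1, \mu')], \quad
#'       \mu' \sim N(\mu, v^2),\ v = \mathrm{preposterior\_sd}(n_0+n, 1, \sigma_X)}
#' and V(n, mu) = max(stop_value, C). Recruitment continues only on
#' strict improvement (C > stop value); the continuation region at each
#' n is the mu-interval where that holds, and its endpoints form the
#' lower and upper stopping boundary.
#'
#' The expectation is evaluated by Gauss-Hermite quadrature with linear
#' interpolation of V(n+1, .) on the grid; quadrature points falling
#' outside the grid use the analytic stopping value, exact far from the
#' continuation region. A two-point (+/- v, equal weight) outcome
#' discretisation is available for cross-checks against exhaustive
#' policy enumeration on tiny instances.
#'
#' @param params [economic_params()]; `switch_cost_I` must be 0 (the
#'   nonzero case is a documented extension point, not implemented).
#' @param prior [beliefs()] prior state.
#' @param grid_points Number of grid points (default 1001).
#' @param grid_halfwidth_sds Half-width of the grid in units of the
#'   prior SD sigma_x/sqrt(n0) (default 6, covering the prior-predictive
#'   spread of the terminal posterior mean).
#' @param quadrature_nodes Gauss-Hermite nodes (default 21).
#' @param quadrature `"hermite"` (default) or `"two_point"`.
#' @return An object of class `valseq_boundary`: the grid, per-n lower
#'   and upper continuation limits (NA where the continuation region is
#'   empty), the value table, and the inputs. Use [tidy()] for the
#'   boundary table and [autoplot()] to draw it.
#' @examples
#' pf <- profher_params(q_max = 125)
#' b <- solve_boundary(pf$params, pf$prior, grid_points = 401)
#' tidy(b)
#' @export
solve_boundary <- function(params, prior,
                           grid_points = 1001,
                           grid_halfwidth_sds = 6,
                           quadrature_nodes = 21,
                           quadrature = c("hermite", "two_point")) {
  validate_params(params); validate_beliefs(prior)
  quadrature <- match.arg(quadrature)
  if (params$switch_cost_I != 0)
    abort("nonzero switch_cost_I is not implemented; the terminal rule assumes I = 0",
          class = "valseq_not_implemented")
  stopifnot(grid_points >= 5, grid_halfwidth_sds > 0, quadrature_nodes >= 1)

  halfwidth <- grid_halfwidth_sds * prior$sigma_x / sqrt(prior$m)
  grid <- seq(prior$mu - halfwidth, prior$mu + halfwidth, length.out = grid_points)
  N <- params$q_max - params$delay_tau
  n_seq <- 0:N

  gh <- if (quadrature == "hermite") gauss_hermite(quadrature_nodes)
        else list(x = c(-1, 1) / sqrt(2), w = c(0.5, 0.5))

  V <- matrix(NA_real_, nrow = N + 1L, ncol = grid_points,
              dimnames = list(n_observed = n_seq, NULL))
  lower <- upper <- rep(NA_real_, N + 1L)

  V[N + 1L, ] <- stop_value(N, grid, params, prior)

  for (n in rev(seq_len(N)) - 1L) {       # N-1 down to 0
    v1 <- preposterior_sd(prior$m + n, 1, prior$sigma_x)
    shifts <- sqrt(2) * v1 * gh$x
    q <- rep(grid, times = length(shifts)) + rep(shifts, each = grid_points)
    vnext <- interp_value(grid, V[n + 2L, ], q, n + 1L, params, prior)
    EV <- matrix(vnext, nrow = grid_points) %*% gh$w
    cont_val <- -params$var_cost_c + as.numeric(EV)
    stopv <- stop_value(n, grid, params, prior)
    V[n + 1L, ] <- pmax(stopv, cont_val)
    idx <- which(cont_val > stopv)
    if (length(idx)) {
      gap <- cont_val - stopv
      i_lo <- idx[1]; i_hi <- idx[length(idx)]
      lower[n + 1L] <- if (i_lo == 1L) grid[1L] else
        root_between(grid[i_lo - 1L], grid[i_lo], gap[i_lo - 1L], gap[i_lo])
      upper[n + 1L] <- if (i_hi == grid_points) grid[grid_points] else
        root_between(grid[i_hi], grid[i_hi + 1L], gap[i_hi], gap[i_hi + 1L])
    }
  }

  if (any(!is.na(lower))) {
    margin <- 0.05 * halfwidth
    if (min(lower, na.rm = TRUE) < grid[1] + margin ||
        max(upper, na.rm = TRUE) > grid[grid_points] - margin)
      abort(paste("the stopping boundary approaches the edge of the mu grid;",
                  "re-solve with a larger `grid_halfwidth_sds`"),
            class = "valseq_grid_too_narrow")
  }

  structure(
    list(params = params, prior = prior, grid = grid,
         n_observed = n_seq, lower = lower, upper = upper, value = V,
         quadrature = quadrature, quadrature_nodes = quadrature_nodes,
         grid_halfwidth_sds = grid_halfwidth_sds),
    class = "valseq_boundary"
  )
}

# linear root of a sign change between (x1, y1) and (x2, y2)
root_between <- function(x1, x2, y1, y2) {
  if (y1 == y2) return((x1 + x2) / 2)
  x1 - y1 * (x2 - x1) / (y2 - y1)
}

#' @export
print.valseq_boundary <- function(x, ...) {
  n_cont <- sum(!is.na(x$lower))
  cat("<valseq_boundary>\n")
  cat(sprintf("  Qmax = %d, tau = %d: %d observable looks, continuation region at %d of them\n",
              x$params$q_max, x$params$delay_tau, length(x$n_observed), n_cont))
  if (n_cont)
    cat(sprintf("  widest continuation interval: [%.0f, %.0f] GBP at n = %d\n",
                min(x$lower, na.rm = TRUE), max(x$upper, na.rm = TRUE),
                x$n_observed[which.max(x$upper - x$lower)]))
  invisible(x)
}

#' @describeIn solve_boundary Boundary table: one row per observed-pair
#'   count with `allocations` (observed + pipeline), `plot_coordinate`
#'   (n0 + allocations) and the continuation limits in GBP (NA where
#'   the continuation region is empty).
#' @param x A `valseq_boundary` object.
#' @param ... Unused.
#' @method tidy valseq_boundary
#' @export
tidy.valseq_boundary <- function(x, ...) {
  n <- x$n_observed
  alloc <- n + pmin(x$params$delay_tau, x$params$q_max - n)
  tibble(
    n_observed = n,
    allocations = alloc,
    plot_coordinate = x$prior$m + alloc,
    lower_gbp = x$lower,
    upper_gbp = x$upper
  )
}

#' Continuation limits at a given number of observed pairs
#'
#' @param boundary A `valseq_boundary`.
#' @param n_observed Observed-pair count(s).
#' @return A tibble with `n_observed`, `lower_gbp`, `upper_gbp` (NA when
#'   the continuation region is empty at that n).
#' @export
boundary_limits <- function(boundary, n_observed) {
  stopifnot(inherits(boundary, "valseq_boundary"))
  i <- match(n_observed, boundary$n_observed)
  if (any(is.na(i)))
    abort("`n_observed` outside the solved range", class = "valseq_invalid_input")
  tibble(n_observed = n_observed,
         lower_gbp = boundary$lower[i], upper_gbp = boundary$upper[i])
}

#' Value function lookup with interpolation
#'
#' @param boundary A `valseq_boundary`.
#' @param n_observed A single observed-pair count in the solved range.
#' @param mu Posterior mean(s) (GBP).
#' @return V(n_observed, mu) in GBP; the analytic stopping value is used
#'   outside the grid.
#' @export
boundary_value <- function(boundary, n_observed, mu) {
  stopifnot(inherits(boundary, "valseq_boundary"), length(n_observed) == 1L)
  i <- match(n_observed, boundary$n_observed)
  if (is.na(i)) abort("`n_observed` outside the solved range", class = "valseq_invalid_input")
  interp_value(boundary$grid, boundary$value[i, ], mu, n_observed,
               boundary$params, boundary$prior)
}

#' Export a boundary table to CSV
#'
#' Writes the [tidy()] boundary table with columns `n_observed`,
#' `allocations`, `plot_coordinate`, `lower_gbp`, `upper_gbp`; "NA"
#' marks an empty continuation region.
#'
#' @param boundary A `valseq_boundary`.
#' @param path Output path.
#' @param header Optional `#` comment lines (provenance).
#' @return `path`, invisibly.
#' @export
write_boundary <- function(boundary, path, header = NULL) {
  tb <- tidy(boundary)
  if (!is.null(header)) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    writeLines(paste0("# ", header), con)
    close(con)
    readr::write_csv(tb, path, append = TRUE, col_names = TRUE)
  } else readr::write_csv(tb, path)
  invisible(path)
}
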