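#' Optimal Bayes one-stage design
#'
#' The best fixed sample size smaller than the delay: because outcomes
#' arrive tau pairs late, a trial of n < tau pairs observes nothing
#' until recruitment has finished, so no sequential monitoring is
#' possible and the design question is purely how many pairs to fund.
#' The design maximises expected value of sample information minus
#' sampling cost,
#' \deqn{n^* = \arg\max_{n \in 1..\tau-1}
#'   P\,\mathrm{E}[\max(\mu_n, 0)] - c\,n}
#' where the preposterior distribution of mu_n is
#' Normal(mu0, preposterior_sd(n0, n, sigma_x)^2). The no-trial value
#' P * max(mu0, 0) is included as n = 0.
#'
#' @param params [economic_params()] (requires `delay_tau >= 1`).
#' @param prior [beliefs()].
#' @return A list: `n_star` (pairs), `value` (GBP, net of sampling
#'   cost), and `table`, a tibble of n, EVSI, cost and net value.
#' @examples
#' pf <- profher_params()
#' one_stage_design(pf$params, pf$prior)$n_star
#' @export
one_stage_design <- function(params, prior) {
  validate_params(params); validate_beliefs(prior)
  if (params$delay_tau < 1)
    abort("one-stage design requires `delay_tau` >= 1", class = "valseq_invalid_input")
  n <- 0:(params$delay_tau - 1L)
  s <- preposterior_sd(prior$m, n, prior$sigma_x)
  evsi <- params$pop_to_benefit_P *
    (expected_positive_part(prior$mu, s) - max(prior$mu, 0))
  net <- params$pop_to_benefit_P * expected_positive_part(prior$mu, s) -
    params$var_cost_c * n
  best <- which.max(net)   # first maximum: smallest optimal n
  list(
    n_star = n[best],
    value = net[best],
    table = tibble(n_pairs = n, evsi_gbp = evsi,
                   sampling_cost_gbp = params$var_cost_c * n, net_value_gbp = net)
  )
}

# Value of each candidate design as a function of the prior mean.
# no_trial: adopt on the sign of mu0 alone.
# one_stage: best fixed n in 1..tau-1.
# sequential: commit the tau Stage I pairs (cost c*tau) and enter the
#   monitoring stage, whose value V(0, mu0) comes from the solved DP.
design_values <- function(mu0, boundary) {
  params <- boundary$params; prior <- boundary$prior
  P <- params$pop_to_benefit_P
  no_trial <- P * pmax(mu0, 0)
  one <- vapply(mu0, function(m) {
    tb <- one_stage_design(params, beliefs(m, prior$m, prior$sigma_x))$table
    if (nrow(tb) < 2L) -Inf else max(tb$net_value_gbp[tb$n_pairs >= 1L])
  }, numeric(1L))
  seq_val <- -params$var_cost_c * params$delay_tau +
    boundary_value(boundary, 0L, mu0)
  tibble(mu0 = mu0, no_trial = no_trial, one_stage = one, sequential = seq_val)
}

#' Classify the optimal design from the prior mean
#'
#' Compares, at the prior mean, the value of (i) no trial (adopt by the
#' sign of mu0), (ii) the best one-stage design, and (iii) the
#' sequential design (Stage I cost c*tau plus the monitoring-stage
#' value V(0, mu0) from the solved boundary), and reports which is
#' optimal together with the four prior-mean thresholds that partition
#' the mu0 axis: reading downward, above A adopt the new technology
#' without a trial, (C, A] one-stage, [D, C] sequential, [B, D)
#' one-stage, below B adopt the standard technology without a trial.
#' Thresholds are located by bisection on the pairwise value
#' differences.
#'
#' @param boundary A solved [solve_boundary()] object.
#' @param prior Optional [beliefs()]; defaults to the prior the boundary
#'   was solved with. Only `mu` may differ from the solve-time prior.
#' @param tol Bisection tolerance on mu0 (GBP).
#' @return An object of class `valseq_design`: `label` (one of
#'   `adopt_new_no_trial`, `adopt_std_no_trial`, `one_stage`,
#'   `sequential`), `one_stage_n`, `values` (the three candidate values
#'   at mu0) and `thresholds`, a tibble of the four cutpoints.
#' @examples
#' pf <- profher_params(q_max = 125)
#' b <- solve_boundary(pf$params, pf$prior, grid_points = 401)
#' classify_prior(b)
#' @export
classify_prior <- function(boundary, prior = boundary$prior, tol = 1) {
  stopifnot(inherits(boundary, "valseq_boundary"))
  validate_beliefs(prior)
  if (prior$m != boundary$prior$m || prior$sigma_x != boundary$prior$sigma_x)
    abort("`prior` must share n0 and sigma_x with the boundary's prior",
          class = "valseq_invalid_input")
  vals <- design_values(prior$mu, boundary)
  labels <- c("no_trial", "one_stage", "sequential")
  best <- labels[max.col(as.matrix(vals[, labels]), ties.method = "first")]
  label <- switch(best,
    sequential = "sequential",
    one_stage = "one_stage",
    no_trial = if (prior$mu > 0) "adopt_new_no_trial" else "adopt_std_no_trial")

  os <- one_stage_design(boundary$params, prior)

  trial_minus_no <- function(m) {
    v <- design_values(m, boundary)
    max(v$one_stage, v$sequential) - v$no_trial
  }
  seq_minus_rest <- function(m) {
    v <- design_values(m, boundary)
    v$sequential - max(v$one_stage, v$no_trial)
  }
  lo <- boundary$grid[1]; hi <- boundary$grid[length(boundary$grid)]
  ctr <- boundary$prior$mu
  A <- bisect_threshold(trial_minus_no, ctr, hi, tol)
  B <- bisect_threshold(trial_minus_no, ctr, lo, tol)
  C <- bisect_threshold(seq_minus_rest, ctr, hi, tol)
  D <- bisect_threshold(seq_minus_rest, ctr, lo, tol)

  structure(
    list(label = label, one_stage_n = os$n_star, values = vals,
         thresholds = tibble(letter = c("B", "D", "C", "A"),
                             mu0_gbp = c(B, D, C, A),
                             meaning = c("below: adopt standard, no trial",
                                         "lower sequential limit",
                                         "upper sequential limit",
                                         "above: adopt new, no trial")),
         prior = prior, params = boundary$params),
    class = "valseq_design"
  )
}

# Root of f between a centre where f > 0 and an endpoint where f <= 0.
# Returns NA if f is not positive at the centre (region empty) and the
# endpoint value if f never changes sign (region unbounded in the grid).
bisect_threshold <- function(f, centre, edge, tol) {
  fc <- f(centre)
  if (!is.finite(fc) || fc <= 0) return(NA_real_)
  fe <- f(edge)
  if (fe > 0) return(edge)
  a <- centre; b <- edge
  while (abs(b - a) > tol) {
    mid <- (a + b) / 2
    if (f(mid) > 0) a <- mid else b <- mid
  }
  (a + b) / 2
}

#' @export
print.valseq_design <- function(x, ...) {
  cat("<valseq_design>\n")
  cat(sprintf("  optimal design at mu0 = %.0f GBP: %s\n", x$prior$mu, x$label))
  if (x$label == "one_stage")
    cat(sprintf("  one-stage sample size: %d pairs\n", x$one_stage_n))
  tt <- x$thresholds
  cat("  prior-mean thresholds (GBP):\n")
  for (i in rev(seq_len(nrow(tt))))
    cat(sprintf("    %s = %s  (%s)\n", tt$letter[i],
                ifelse(is.na(tt$mu0_gbp[i]), "NA", sprintf("%.0f", tt$mu0_gbp[i])),
                tt$meaning[i]))
  invisible(x)
}

#' @describeIn classify_prior Threshold table (letters B, D, C, A in
#'   increasing mu0 order).
#' @param x A `valseq_design`.
#' @param ... Unused.
#' @method tidy valseq_design
#' @export
tidy.valseq_design <- function(x, ...) x$thresholds

#' @describeIn classify_prior One-row summary: label, one-stage n, and
#'   the three candidate values at mu0.
#' @method glance valseq_design
#' @export
glance.valseq_design <- function(x, ...) {
  tibble(
    label = x$label,
    one_stage_n = x$one_stage_n,
    value_no_trial_gbp = x$values$no_trial,
    value_one_stage_gbp = x$values$one_stage,
    value_sequential_gbp = x$values$sequential
  )
}
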