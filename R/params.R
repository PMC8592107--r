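#' Economic and design parameters of a value-based sequential trial
#'
#' Bundles the health-economic and logistical constants that define one
#' sequential trial design: the willingness to pay per unit of
#' effectiveness, the size of the population that stands to benefit from
#' the adoption decision, the research cost structure, the recruitment
#' ceiling and the outcome-observation delay.
#'
#' All monetary values are GBP. The sampling unit throughout is the
#' *pairwise allocation*: one patient randomised to each arm.
#'
#' @param wtp_lambda Willingness to pay for one unit of effectiveness
#'   (GBP per QALY). Must be non-negative.
#' @param pop_to_benefit_P Number of future patients to whom the adoption
#'   decision applies. Must be positive.
#' @param var_cost_c Variable research cost per pairwise allocation (GBP).
#' @param fixed_cost Fixed research cost (GBP); sunk at design time and
#'   carried for reporting only.
#' @param switch_cost_I Cost of switching technologies (GBP). All shipped
#'   analyses use 0, under which adoption reduces to the sign of the
#'   terminal posterior mean; nonzero values are carried as an extension
#'   point and rejected by the boundary solver.
#' @param q_max Maximum number of pairwise allocations.
#' @param delay_tau Outcome-observation delay, in pairwise allocations:
#'   the number of pairs recruited during one follow-up period.
#' @param delay_delta Delay in years (informational only).
#' @param block_size Pairwise allocations per interim analysis.
#' @return An object of class `valseq_params` (a named list).
#' @seealso [profher_params()] for the shipped worked-example values.
#' @examples
#' economic_params(wtp_lambda = 20000, pop_to_benefit_P = 5000,
#'                 var_cost_c = 4080, q_max = 250, delay_tau = 47)
#' @export
economic_params <- function(wtp_lambda,
                            pop_to_benefit_P,
                            var_cost_c,
                            fixed_cost = 0,
                            switch_cost_I = 0,
                            q_max,
                            delay_tau,
                            delay_delta = NA_real_,
                            block_size = 10) {
  p <- list(
    wtp_lambda = as.numeric(wtp_lambda),
    pop_to_benefit_P = as.numeric(pop_to_benefit_P),
    var_cost_c = as.numeric(var_cost_c),
    fixed_cost = as.numeric(fixed_cost),
    switch_cost_I = as.numeric(switch_cost_I),
    q_max = as.integer(q_max),
    delay_tau = as.integer(delay_tau),
    delay_delta = as.numeric(delay_delta),
    block_size = as.integer(block_size)
  )
  class(p) <- "valseq_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "valseq_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) abort(msg, class = "valseq_invalid_params")
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$wtp_lambda) && p$wtp_lambda >= 0, "`wtp_lambda` must be a single non-negative number")
  chk(num1(p$pop_to_benefit_P) && p$pop_to_benefit_P > 0, "`pop_to_benefit_P` must be positive")
  chk(num1(p$var_cost_c) && p$var_cost_c >= 0, "`var_cost_c` must be non-negative")
  chk(num1(p$fixed_cost) && p$fixed_cost >= 0, "`fixed_cost` must be non-negative")
  chk(num1(p$switch_cost_I), "`switch_cost_I` must be a single finite number")
  chk(length(p$q_max) == 1L && !is.na(p$q_max) && p$q_max >= 1L, "`q_max` must be a positive integer")
  chk(length(p$delay_tau) == 1L && !is.na(p$delay_tau) && p$delay_tau >= 0L,
      "`delay_tau` must be a non-negative integer")
  chk(p$q_max > p$delay_tau, "`q_max` must exceed `delay_tau`")
  chk(length(p$block_size) == 1L && !is.na(p$block_size) && p$block_size >= 1L,
      "`block_size` must be a positive integer")
  invisible(p)
}

#' @export
print.valseq_params <- function(x, ...) {
  cat("<valseq_params>\n")
  cat(sprintf("  lambda = %s GBP/QALY, P = %s patients\n",
              format(x$wtp_lambda, big.mark = ","),
              format(x$pop_to_benefit_P, big.mark = ",")))
  cat(sprintf("  c = %s GBP/pair, fixed = %s GBP, I = %s GBP\n",
              format(x$var_cost_c, big.mark = ","),
              format(x$fixed_cost, big.mark = ","),
              format(x$switch_cost_I, big.mark = ",")))
  cat(sprintf("  Qmax = %d pairs, tau = %d pairs, looks every %d pairs\n",
              x$q_max, x$delay_tau, x$block_size))
  invisible(x)
}

#' Conjugate-normal belief state for expected incremental net benefit
#'
#' The model treats per-pair incremental net monetary benefit X as
#' normal with unknown mean W and known sampling standard deviation
#' `sigma_x`. Beliefs about W are normal with mean `mu` and variance
#' `sigma_x^2 / m`, where `m` is the effective number of pairs behind
#' the belief (prior effective sample size plus pairs observed).
#'
#' @param mu Mean of the belief about W (GBP).
#' @param m Effective pair count (> 0); for a prior this is the prior
#'   effective sample size n0 = sigma_x^2 / sigma_0^2.
#' @param sigma_x Known per-pair sampling standard deviation (GBP, > 0).
#' @return An object of class `valseq_beliefs`.
#' @examples
#' beliefs(mu = 0, m = 2, sigma_x = 14157)
#' @export
beliefs <- function(mu, m, sigma_x) {
  b <- list(mu = as.numeric(mu), m = as.numeric(m), sigma_x = as.numeric(sigma_x))
  class(b) <- "valseq_beliefs"
  validate_beliefs(b)
  b
}

validate_beliefs <- function(b) {
  stopifnot(inherits(b, "valseq_beliefs"))
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok(b$mu)) abort("`mu` must be a single finite number", class = "valseq_invalid_beliefs")
  if (!ok(b$m) || b$m <= 0) abort("`m` must be positive", class = "valseq_invalid_beliefs")
  if (!ok(b$sigma_x) || b$sigma_x <= 0) abort("`sigma_x` must be positive", class = "valseq_invalid_beliefs")
  invisible(b)
}

#' @export
print.valseq_beliefs <- function(x, ...) {
  cat(sprintf("<valseq_beliefs> mu = %.2f GBP, m = %.3g pairs, sigma_x = %.1f GBP (posterior SD %.1f)\n",
              x$mu, x$m, x$sigma_x, x$sigma_x / sqrt(x$m)))
  invisible(x)
}

#' Average variable cost per pairwise allocation from a budget split
#'
#' Derives the per-pair variable research cost from the spend incurred
#' during the recruitment and follow-up phases, a fixed:variable split,
#' and the number of pairs recruited. The worked example uses the
#' ProFHER budget: a recruitment/follow-up spend of about 1,020,000 GBP,
#' an assumed 50:50 fixed-to-variable split and 125 pairs, giving
#' 4,080 GBP per pairwise allocation.
#'
#' @param recruit_phase_spend Spend during recruitment and follow-up (GBP).
#' @param variable_share Fraction of that spend treated as variable.
#' @param n_pairs Pairwise allocations recruited.
#' @return Variable cost per pairwise allocation (GBP).
#' @examples
#' derive_variable_cost(1020000, 0.5, 125) # 4080
#' @export
derive_variable_cost <- function(recruit_phase_spend = 1020000,
                                 variable_share = 0.5,
                                 n_pairs = 125) {
  stopifnot(recruit_phase_spend >= 0, variable_share >= 0, variable_share <= 1, n_pairs > 0)
  recruit_phase_spend * variable_share / n_pairs
}

#' Worked-example trial parameters (surgery vs sling, ProFHER-like)
#'
#' Returns the design constants used throughout the package's worked
#' example, patterned on a UK pragmatic trial comparing surgery with
#' sling immobilisation for displaced proximal humeral fracture:
#' willingness to pay 20,000 GBP/QALY, variable cost 4,080 GBP per pair
#' (from a 50:50 split of the 1,020,000 GBP recruitment/follow-up spend
#' over 125 pairs), a one-year observation delay equal to 47 pairs at
#' the observed recruitment rate, interim analyses every 10 pairs, and a
#' near non-informative prior (mu0 = 0, n0 = 2 pairs).
#'
#' Two inputs are estimates rather than published constants, and both
#' can be overridden:
#' * `sigma_x` defaults to [derive_pair_sd()] applied to the published
#'   95% confidence intervals for incremental cost and incremental
#'   QALYs (about 14,157 GBP per pair).
#' * `pop_to_benefit_P` defaults to 2,000 patients, an
#'   incidence-times-horizon figure consistent with the published
#'   operating characteristics; see the methods vignette.
#'
#' @param q_max Maximum pairwise allocations (125 or 250 in the example).
#' @param pop_to_benefit_P Population to benefit from the adoption decision.
#' @param sigma_x Per-pair sampling SD of incremental net monetary
#'   benefit (GBP).
#' @return A list with elements `params` (a [economic_params()] object)
#'   and `prior` (a [beliefs()] object).
#' @examples
#' pf <- profher_params(q_max = 250)
#' pf$params
#' pf$prior
#' @export
profher_params <- function(q_max = 250,
                           pop_to_benefit_P = 2000,
                           sigma_x = derive_pair_sd()) {
  params <- economic_params(
    wtp_lambda = 20000,
    pop_to_benefit_P = pop_to_benefit_P,
    var_cost_c = derive_variable_cost(1020000, 0.5, 125),
    fixed_cost = 161000 + 1020000 * 0.5,
    switch_cost_I = 0,
    q_max = q_max,
    delay_tau = 47,
    delay_delta = 1,
    block_size = 10
  )
  prior <- beliefs(mu = 0, m = 2, sigma_x = sigma_x)
  list(params = params, prior = prior)
}
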