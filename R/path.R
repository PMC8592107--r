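# Interim-analysis schedule: looks every block_size observed pairs plus
# a forced final look at N = q_max - tau (recruitment cannot exceed
# q_max, so the last look happens even when N is not a multiple of the
# block size).
look_schedule <- function(params) {
  N <- params$q_max - params$delay_tau
  unique(c(seq(params$block_size, N, by = params$block_size), N))
}

# Vectorised replay of many paths of per-pair incremental net monetary
# benefit against a solved boundary. `values` is a matrix with one
# column per path and at least (first exit + tau) rows of per-pair
# outcomes. Returns a list: per-path results tibble and the posterior
# mean at every scheduled look (matrix looks x paths).
replay_engine <- function(values, boundary) {
  params <- boundary$params; prior <- boundary$prior
  N <- params$q_max - params$delay_tau
  looks <- look_schedule(params)
  L <- nrow(values); K <- ncol(values)

  cum <- apply(values, 2L, cumsum)
  if (K == 1L) cum <- matrix(cum, ncol = 1L)

  max_look_avail <- max(c(0L, looks[looks <= L]))
  usable_looks <- looks[looks <= L]
  if (length(usable_looks) == 0L)
    abort("outcome stream shorter than the first interim look", class = "valseq_stream_exhausted")

  mu_looks <- (prior$mu * prior$m + cum[usable_looks, , drop = FALSE]) /
    (prior$m + usable_looks)
  lim <- boundary_limits(boundary, usable_looks)
  lo <- lim$lower_gbp; hi <- lim$upper_gbp
  # empty continuation (NA limits) means any posterior mean is outside
  outside <- (is.na(lo) | mu_looks < lo) | (is.na(hi) | mu_looks > hi)

  if (!all(apply(outside, 2L, any)))
    abort(paste("outcome stream exhausted before any boundary exit:",
                "supply at least q_max pairs per path"),
          class = "valseq_stream_exhausted")
  stop_idx <- apply(outside, 2L, which.max)
  n_stop <- usable_looks[stop_idx]
  mu_stop <- mu_looks[cbind(stop_idx, seq_len(K))]

  pipeline <- pmin(params$delay_tau, params$q_max - n_stop)
  need <- n_stop + pipeline
  if (any(need > L))
    abort("outcome stream exhausted before the pipeline pairs were observed",
          class = "valseq_stream_exhausted")
  mu_final <- (prior$mu * prior$m + cum[cbind(need, seq_len(K))]) / (prior$m + need)

  # classification: boundary exit side where a boundary existed at the
  # stopping look; reaching the final look (empty continuation at N) is
  # its own category
  lo_stop <- lo[stop_idx]; hi_stop <- hi[stop_idx]
  crossing <- dplyr::case_when(
    n_stop == N & (is.na(lo_stop) | (mu_stop >= lo_stop & mu_stop <= hi_stop)) ~ "reached_max",
    !is.na(lo_stop) & mu_stop < lo_stop ~ "lower",
    !is.na(hi_stop) & mu_stop > hi_stop ~ "upper",
    is.na(lo_stop) & mu_stop <= boundary$prior$mu ~ "lower",
    is.na(lo_stop) ~ "upper",
    .default = "reached_max"
  )

  res <- tibble(
    path = seq_len(K),
    stop_look = stop_idx,
    n_observed_at_stop = n_stop,
    allocations_T = n_stop + pipeline,
    mu_at_stop = mu_stop,
    mu_final = mu_final,
    decision = ifelse(mu_final > 0, "new", "standard"),
    crossing = crossing,
    variable_cost = params$var_cost_c * (n_stop + pipeline)
  )
  list(results = res, looks = usable_looks, mu_looks = mu_looks)
}

# expand a block table to the per-pair stream of incremental net
# monetary benefit values it summarises
blocks_to_pairs <- function(blocks, wtp_lambda) {
  blocks <- block_inb(blocks, wtp_lambda)
  rep(blocks$mean_inb, times = blocks$n_pairs)
}

#' Replay a block-level outcome stream against a stopping boundary
#'
#' Runs the three-stage monitoring logic on one ordered stream of block
#' summaries. During Stage II the posterior mean is recomputed at every
#' scheduled interim analysis (each `block_size` observed pairs, plus a
#' forced final look at q_max - tau) and recruitment stops the first
#' time it falls outside the continuation interval — the boundary
#' itself counts as continuation. Stage III then consumes the tau
#' pipeline pairs already allocated, and the technology decision goes
#' by the sign of the final posterior mean (ties favour the standard
#' technology).
#'
#' @param blocks Block-summary table (see [read_block_table()]),
#'   supplying at least `allocations_T` pairs; streams as long as
#'   `q_max` can never be exhausted.
#' @param boundary A [solve_boundary()] result.
#' @param params,prior Optional; must equal the boundary's own. Present
#'   so a mismatched boundary is an error rather than a silent misuse.
#' @param reference_pairs,total_budget Budget-reporting conventions
#'   passed to [budget_change()].
#' @return An object of class `valseq_path`. [glance()] gives the
#'   one-row result (stop look, allocations, posterior means, decision,
#'   crossing side, costs); [tidy()] gives the look-by-look posterior
#'   mean with the continuation limits.
#' @examples
#' pf <- profher_params(q_max = 125)
#' b <- solve_boundary(pf$params, pf$prior, grid_points = 401)
#' blocks <- synthetic_profher_blocks(seed = 1)
#' glance(run_path(blocks, b))
#' @export
run_path <- function(blocks, boundary, params = boundary$params,
                     prior = boundary$prior,
                     reference_pairs = 125, total_budget = 1470000) {
  stopifnot(inherits(boundary, "valseq_boundary"))
  check_same_design(params, boundary$params)
  check_same_prior(prior, boundary$prior)
  values <- matrix(blocks_to_pairs(blocks, params$wtp_lambda), ncol = 1L)
  eng <- replay_engine(values, boundary)
  res <- eng$results
  res$path <- NULL
  bc <- budget_change(res$allocations_T, params, reference_pairs, total_budget)
  res <- dplyr::bind_cols(res, bc)
  N <- params$q_max - params$delay_tau
  res$stopped_at <- ifelse(res$crossing == "reached_max", "reached_max",
                           as.character(res$stop_look))
  lim <- boundary_limits(boundary, eng$looks)
  looks_tb <- tibble(
    look = seq_along(eng$looks),
    n_observed = eng$looks,
    allocations = eng$looks + pmin(params$delay_tau, params$q_max - eng$looks),
    mu = as.numeric(eng$mu_looks[, 1L]),
    lower_gbp = lim$lower_gbp,
    upper_gbp = lim$upper_gbp
  )
  looks_tb <- looks_tb[looks_tb$look <= res$stop_look, ]
  structure(list(result = res, looks = looks_tb, boundary = boundary),
            class = "valseq_path")
}

check_same_design <- function(a, b) {
  validate_params(a)
  same <- a$q_max == b$q_max && a$delay_tau == b$delay_tau &&
    a$block_size == b$block_size && a$var_cost_c == b$var_cost_c &&
    a$wtp_lambda == b$wtp_lambda && a$pop_to_benefit_P == b$pop_to_benefit_P
  if (!same)
    abort("`params` does not match the design the boundary was solved for",
          class = "valseq_design_mismatch")
  invisible(a)
}

check_same_prior <- function(a, b) {
  validate_beliefs(a)
  if (a$mu != b$mu || a$m != b$m || a$sigma_x != b$sigma_x)
    abort("`prior` does not match the prior the boundary was solved with",
          class = "valseq_design_mismatch")
  invisible(a)
}

#' Budget impact of a realised sample size
#'
#' Converts a trial's realised number of pairwise allocations into the
#' change in spend relative to a reference design: GBP change =
#' (allocations - reference) * c, also expressed as a percentage of the
#' total research budget, plus the percentage change in sample size
#' relative to the reference.
#'
#' @param allocations_T Realised pairwise allocations; vectorised.
#' @param params [economic_params()] (supplies c).
#' @param reference_pairs Reference sample size (default 125 pairs).
#' @param total_budget Total research budget (default 1,470,000 GBP).
#' @return A tibble with `budget_change_gbp`, `budget_change_pct` and
#'   `sample_size_change_pct`.
#' @examples
#' pf <- profher_params()
#' budget_change(77, pf$params)  # about -196,000 GBP, -13% of budget
#' @export
budget_change <- function(allocations_T, params, reference_pairs = 125,
                          total_budget = 1470000) {
  validate_params(params)
  stopifnot(reference_pairs > 0, total_budget > 0)
  gbp <- (allocations_T - reference_pairs) * params$var_cost_c
  tibble(
    budget_change_gbp = gbp,
    budget_change_pct = gbp / total_budget * 100,
    sample_size_change_pct = (allocations_T - reference_pairs) / reference_pairs * 100
  )
}

#' @export
print.valseq_path <- function(x, ...) {
  r <- x$result
  cat("<valseq_path>\n")
  cat(sprintf("  stopped at interim %s (%d observed pairs, %d allocations)\n",
              r$stopped_at, r$n_observed_at_stop, r$allocations_T))
  cat(sprintf("  posterior mean %.0f GBP at stop, %.0f GBP after pipeline follow-up\n",
              r$mu_at_stop, r$mu_final))
  cat(sprintf("  decision: %s technology (crossing: %s)\n", r$decision, r$crossing))
  cat(sprintf("  variable cost %.0f GBP; budget change %.0f GBP (%.1f%%)\n",
              r$variable_cost, r$budget_change_gbp, r$budget_change_pct))
  invisible(x)
}

#' @describeIn run_path Look-by-look posterior mean and continuation
#'   limits up to the stopping look.
#' @param x A `valseq_path`.
#' @param ... Unused.
#' @method tidy valseq_path
#' @export
tidy.valseq_path <- function(x, ...) x$looks

#' @describeIn run_path One-row path result.
#' @method glance valseq_path
#' @export
glance.valseq_path <- function(x, ...) as_tibble(x$result)
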