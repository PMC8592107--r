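# Draw one bootstrap stream of exactly q_max per-pair values by
# resampling blocks with replacement (the resampling unit is the block,
# matching the granularity of the published summaries).
draw_bootstrap_stream <- function(mean_inb, n_pairs, q_max) {
  need <- q_max
  out <- numeric(0)
  while (need > 0) {
    idx <- sample.int(length(mean_inb), size = ceiling(need / min(n_pairs)),
                      replace = TRUE)
    add <- rep(mean_inb[idx], times = n_pairs[idx])
    out <- c(out, add)
    need <- q_max - length(out)
  }
  out[seq_len(q_max)]
}

#' Bootstrap operating characteristics of the sequential design
#'
#' Resamples blocks at random and with replacement from a block-summary
#' table to form `n_paths` outcome streams of `q_max` pairs each,
#' replays every stream against the stopping boundary with the standard
#' interim schedule, and aggregates the per-path results into operating
#' characteristics (sample size, budget impact, terminal posterior
#' mean, decision-by-crossing probabilities, look-by-look stopping
#' fractions).
#'
#' @param blocks Block-summary table to resample from.
#' @param n_paths Number of bootstrap paths (>= 1).
#' @param boundary A [solve_boundary()] result.
#' @param params,prior Optional; must match the boundary's (guards
#'   against replaying a stale boundary).
#' @param seed Integer seed; required, so shipped analyses are
#'   reproducible bit-for-bit.
#' @param reference_pairs,total_budget Budget conventions, see
#'   [budget_change()].
#' @return A `valseq_oc` object; see [summarize_paths()].
#' @examples
#' pf <- profher_params(q_max = 125)
#' b <- solve_boundary(pf$params, pf$prior, grid_points = 401)
#' oc <- bootstrap_paths(synthetic_profher_blocks(seed = 1), 200, b, seed = 2)
#' glance(oc)
#' @export
bootstrap_paths <- function(blocks, n_paths, boundary,
                            params = boundary$params, prior = boundary$prior,
                            seed, reference_pairs = 125, total_budget = 1470000) {
  stopifnot(inherits(boundary, "valseq_boundary"), n_paths >= 1)
  check_same_design(params, boundary$params)
  check_same_prior(prior, boundary$prior)
  blocks <- block_inb(blocks, params$wtp_lambda)
  if (nrow(blocks) == 0L) abort("`blocks` is empty", class = "valseq_invalid_input")
  values <- withr::with_seed(seed, {
    vapply(seq_len(n_paths),
           function(i) draw_bootstrap_stream(blocks$mean_inb, blocks$n_pairs,
                                             params$q_max),
           numeric(params$q_max))
  })
  eng <- replay_engine(matrix(values, nrow = params$q_max), boundary)
  summarize_paths(eng$results, params, reference_pairs, total_budget,
                  design = "sequential", source = "bootstrap", seed = seed)
}

#' Monte Carlo operating characteristics under a known true mean
#'
#' Draws per-pair incremental net monetary benefit i.i.d. from
#' Normal(`true_mean`, `sigma_x`^2), assembles blocks on the standard
#' schedule (so look times match the bootstrap exactly) and replays
#' each simulated stream against the boundary.
#'
#' @param true_mean True expected incremental net monetary benefit
#'   (GBP per pair).
#' @param sigma_x Per-pair sampling SD; defaults to the boundary
#'   prior's.
#' @inheritParams bootstrap_paths
#' @return A `valseq_oc` object.
#' @export
monte_carlo_paths <- function(true_mean, n_paths, boundary,
                              sigma_x = boundary$prior$sigma_x,
                              params = boundary$params, prior = boundary$prior,
                              seed, reference_pairs = 125, total_budget = 1470000) {
  stopifnot(inherits(boundary, "valseq_boundary"), n_paths >= 1, sigma_x > 0)
  check_same_design(params, boundary$params)
  check_same_prior(prior, boundary$prior)
  values <- withr::with_seed(seed, {
    matrix(rnorm(params$q_max * n_paths, mean = true_mean, sd = sigma_x),
           nrow = params$q_max)
  })
  eng <- replay_engine(values, boundary)
  summarize_paths(eng$results, params, reference_pairs, total_budget,
                  design = "sequential", source = "monte_carlo", seed = seed)
}

#' Operating characteristics of the fixed (non-stopping) design
#'
#' Every path runs to `q_max` pairwise allocations with no interim
#' stopping; the technology decision goes by the sign of the posterior
#' mean after all outcomes are observed. Streams come either from
#' bootstrap resampling of `blocks` or from Normal(`true_mean`,
#' `sigma_x`^2) draws — supply exactly one source.
#'
#' @inheritParams bootstrap_paths
#' @inheritParams monte_carlo_paths
#' @param blocks Block table to resample (bootstrap source), or NULL.
#' @param true_mean True mean for Monte Carlo draws, or NULL.
#' @return A `valseq_oc` object (crossing category `"none"`).
#' @export
fixed_design_paths <- function(n_paths, params, prior, seed,
                               blocks = NULL, true_mean = NULL,
                               sigma_x = prior$sigma_x,
                               reference_pairs = 125, total_budget = 1470000) {
  validate_params(params); validate_beliefs(prior)
  stopifnot(n_paths >= 1)
  if (is.null(blocks) == is.null(true_mean))
    abort("supply exactly one of `blocks` (bootstrap) or `true_mean` (Monte Carlo)",
          class = "valseq_invalid_input")
  totals <- withr::with_seed(seed, {
    if (!is.null(blocks)) {
      blocks <- block_inb(blocks, params$wtp_lambda)
      vapply(seq_len(n_paths),
             function(i) sum(draw_bootstrap_stream(blocks$mean_inb, blocks$n_pairs,
                                                   params$q_max)),
             numeric(1L))
    } else {
      colSums(matrix(rnorm(params$q_max * n_paths, true_mean, sigma_x),
                     nrow = params$q_max))
    }
  })
  mu_final <- (prior$mu * prior$m + totals) / (prior$m + params$q_max)
  res <- tibble(
    path = seq_len(n_paths),
    stop_look = NA_integer_,
    n_observed_at_stop = params$q_max,
    allocations_T = params$q_max,
    mu_at_stop = mu_final,
    mu_final = mu_final,
    decision = ifelse(mu_final > 0, "new", "standard"),
    crossing = "none",
    variable_cost = params$var_cost_c * params$q_max
  )
  summarize_paths(res, params, reference_pairs, total_budget,
                  design = "fixed", source = if (is.null(blocks)) "monte_carlo" else "bootstrap",
                  seed = seed)
}

#' Aggregate per-path results into operating characteristics
#'
#' Builds the summary object behind every resampling analysis: sample
#' moments (mean, SD with the n-1 denominator, min, max) of the number
#' of allocations, the budget change and the terminal posterior mean;
#' the decision-by-crossing probability matrix; the fraction of paths
#' stopping at each interim look; and the empirical CDF of the sample
#' size.
#'
#' @param paths Per-path results tibble (as produced by the replay
#'   engine): columns `allocations_T`, `mu_final`, `decision`,
#'   `crossing`, `stop_look`, `n_observed_at_stop`.
#' @param params [economic_params()].
#' @param reference_pairs,total_budget Budget conventions; percentage
#'   changes follow (mean - reference)/reference * 100 for sample size
#'   and (mean - reference) * c / total_budget * 100 for budget.
#' @param design,source,seed Metadata recorded on the object.
#' @return An object of class `valseq_oc` with elements `per_path`,
#'   `aggregates`, `decision_matrix`, `look_fractions`, `ecdf` and
#'   `meta`. [tidy()] returns the per-path table, [glance()] a one-row
#'   summary.
#' @export
summarize_paths <- function(paths, params, reference_pairs = 125,
                            total_budget = 1470000,
                            design = "sequential", source = "data", seed = NA) {
  validate_params(params)
  paths <- as_tibble(paths)
  if (nrow(paths) == 0L) abort("`paths` is empty", class = "valseq_invalid_input")
  if (!"path" %in% names(paths)) paths$path <- seq_len(nrow(paths))
  paths <- dplyr::bind_cols(
    paths[setdiff(names(paths), c("budget_change_gbp", "budget_change_pct",
                                  "sample_size_change_pct"))],
    budget_change(paths$allocations_T, params, reference_pairs, total_budget)
  )

  one_stat <- function(x, name) {
    tibble(statistic = name, mean = mean(x),
           sd = if (length(x) > 1L) sd(x) else 0,
           min = min(x), max = max(x))
  }
  aggregates <- dplyr::bind_rows(
    one_stat(paths$allocations_T, "allocations"),
    one_stat(paths$budget_change_gbp, "budget_change_gbp"),
    one_stat(paths$mu_final, "mu_final_gbp")
  )
  mean_alloc <- mean(paths$allocations_T)
  pct <- tibble(
    sample_size_change_pct = (mean_alloc - reference_pairs) / reference_pairs * 100,
    budget_change_pct = (mean_alloc - reference_pairs) * params$var_cost_c /
      total_budget * 100
  )

  decision_matrix <- paths |>
    dplyr::count(.data$crossing, .data$decision) |>
    dplyr::mutate(prob = .data$n / nrow(paths))

  look_fractions <- paths |>
    dplyr::filter(!is.na(.data$stop_look)) |>
    dplyr::count(.data$stop_look, .data$n_observed_at_stop) |>
    dplyr::mutate(fraction = .data$n / nrow(paths),
                  allocations = .data$n_observed_at_stop +
                    pmin(params$delay_tau, params$q_max - .data$n_observed_at_stop))

  structure(
    list(per_path = paths, aggregates = aggregates, pct = pct,
         decision_matrix = decision_matrix, look_fractions = look_fractions,
         ecdf = stats::ecdf(paths$allocations_T), params = params,
         meta = list(design = design, source = source, seed = seed,
                     n_paths = nrow(paths), reference_pairs = reference_pairs,
                     total_budget = total_budget)),
    class = "valseq_oc"
  )
}

oc_prob <- function(x, what, value) {
  m <- x$decision_matrix
  sum(m$prob[m[[what]] == value])
}

#' @export
print.valseq_oc <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<valseq_oc> %s design, %s source, %d paths (seed %s)\n",
              x$meta$design, x$meta$source, x$meta$n_paths, format(x$meta$seed)))
  cat(sprintf("  allocations: mean %.1f (sd %.1f, min %d, max %d); change %.0f%% vs %d\n",
              g$mean_allocations, g$sd_allocations, g$min_allocations,
              g$max_allocations, g$sample_size_change_pct, x$meta$reference_pairs))
  cat(sprintf("  budget change: mean %.0f GBP (%.1f%% of %s)\n",
              g$mean_budget_change_gbp, g$budget_change_pct,
              format(x$meta$total_budget, big.mark = ",")))
  cat(sprintf("  terminal posterior mean: %.0f GBP (sd %.0f)\n",
              g$mean_mu_final_gbp, g$sd_mu_final_gbp))
  cat(sprintf("  P(standard) = %.3f, P(new) = %.3f; crossings: lower %.3f, upper %.3f, reached max %.3f\n",
              g$prob_standard, g$prob_new, g$prob_lower, g$prob_upper,
              g$prob_reached_max))
  invisible(x)
}

#' @describeIn summarize_paths Per-path results.
#' @param x A `valseq_oc`.
#' @param ... Unused.
#' @method tidy valseq_oc
#' @export
tidy.valseq_oc <- function(x, ...) x$per_path

#' @describeIn summarize_paths One-row summary of the headline
#'   operating characteristics.
#' @method glance valseq_oc
#' @export
glance.valseq_oc <- function(x, ...) {
  a <- function(stat, col) x$aggregates[[col]][x$aggregates$statistic == stat]
  lf <- x$look_fractions
  tibble(
    design = x$meta$design, source = x$meta$source, n_paths = x$meta$n_paths,
    mean_allocations = a("allocations", "mean"),
    sd_allocations = a("allocations", "sd"),
    min_allocations = a("allocations", "min"),
    max_allocations = a("allocations", "max"),
    sample_size_change_pct = x$pct$sample_size_change_pct,
    mean_budget_change_gbp = a("budget_change_gbp", "mean"),
    budget_change_pct = x$pct$budget_change_pct,
    mean_mu_final_gbp = a("mu_final_gbp", "mean"),
    sd_mu_final_gbp = a("mu_final_gbp", "sd"),
    prob_standard = oc_prob(x, "decision", "standard"),
    prob_new = oc_prob(x, "decision", "new"),
    prob_lower = oc_prob(x, "crossing", "lower"),
    prob_upper = oc_prob(x, "crossing", "upper"),
    prob_reached_max = oc_prob(x, "crossing", "reached_max"),
    frac_stop_look1 = if (nrow(lf) && any(lf$stop_look == 1L))
      lf$fraction[lf$stop_look == 1L] else 0
  )
}

#' Operating-characteristics table in the published layout
#'
#' A long table in the published-summary layout: one row per
#' statistic (sample size, budget change, terminal posterior mean, each
#' with mean/%-change/SD/min/max) followed by the decision-by-crossing
#' probabilities.
#'
#' @param x A `valseq_oc`.
#' @return A tibble with columns `statistic` and `value`.
#' @export
oc_table <- function(x) {
  stopifnot(inherits(x, "valseq_oc"))
  g <- glance(x)
  base <- tibble(
    statistic = c(
      "sample_size_mean", "sample_size_pct_change", "sample_size_sd",
      "sample_size_min", "sample_size_max",
      "budget_change_mean_gbp", "budget_change_pct", "budget_change_sd_gbp",
      "posterior_mean_mean_gbp", "posterior_mean_sd_gbp",
      "prob_standard", "prob_new"),
    value = c(g$mean_allocations, g$sample_size_change_pct, g$sd_allocations,
              g$min_allocations, g$max_allocations,
              g$mean_budget_change_gbp, g$budget_change_pct,
              x$aggregates$sd[x$aggregates$statistic == "budget_change_gbp"],
              g$mean_mu_final_gbp, g$sd_mu_final_gbp,
              g$prob_standard, g$prob_new)
  )
  cross <- x$decision_matrix |>
    dplyr::transmute(statistic = paste0("prob_", .data$crossing, "_", .data$decision),
                     value = .data$prob)
  dplyr::bind_rows(base, cross)
}

#' Write per-path and summary CSVs for an operating-characteristics run
#'
#' @param x A `valseq_oc`.
#' @param summary_path,per_path_path Output CSV paths; either may be
#'   NULL to skip.
#' @param header Optional `#` comment lines (seed, configuration hash).
#' @return Invisibly, the paths written.
#' @export
write_oc <- function(x, summary_path = NULL, per_path_path = NULL, header = NULL) {
  stopifnot(inherits(x, "valseq_oc"))
  emit <- function(tb, path) {
    if (!is.null(header)) {
      con <- file(path, open = "wt", encoding = "UTF-8")
      writeLines(paste0("# ", header), con)
      close(con)
      readr::write_csv(tb, path, append = TRUE, col_names = TRUE)
    } else readr::write_csv(tb, path)
  }
  if (!is.null(summary_path)) emit(oc_table(x), summary_path)
  if (!is.null(per_path_path)) emit(x$per_path, per_path_path)
  invisible(c(summary_path, per_path_path))
}
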