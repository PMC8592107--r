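#' Read, validate and write run configurations
#'
#' A run configuration is a single YAML document that fully specifies a
#' shipped analysis. Keys:
#'
#' * model: `lambda`, `P`, `c`, `c_fixed`, `I`, `Qmax`, `tau`,
#'   `sigma_x`, `mu0`, `n0`, `block_size`
#' * numerics: `grid_points`, `grid_halfwidth_sds`, `quadrature_nodes`
#' * analysis: `reps`, `seed`, `mc_mean`, `analyses` (subset of
#'   `"replay"`, `"bootstrap"`, `"montecarlo"`, `"fixed"`),
#'   `blocks` (path to a block CSV; NULL to use the synthetic
#'   emulator), `reference_pairs`, `total_budget`, `out_dir`
#'
#' Configurations round-trip losslessly: `read_run_config(write_run_config(x))`
#' equals `x`.
#'
#' @param path YAML file path.
#' @return `read_run_config()` / `default_config()` return a named list
#'   of class `valseq_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(modifyList(default_config(), cfg))
}

#' @rdname read_run_config
#' @param config A `valseq_config` list.
#' @export
write_run_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_config <- function() {
  structure(list(
    lambda = 20000, P = 2000, c = 4080, c_fixed = 671000, I = 0,
    Qmax = 250L, tau = 47L, sigma_x = derive_pair_sd(), mu0 = 0, n0 = 2,
    block_size = 10L,
    grid_points = 1001L, grid_halfwidth_sds = 6, quadrature_nodes = 21L,
    reps = 5000L, seed = 1L, mc_mean = -1808,
    analyses = c("replay", "bootstrap", "montecarlo", "fixed"),
    blocks = NULL, reference_pairs = 125L, total_budget = 1470000,
    out_dir = "valseq-report"
  ), class = "valseq_config")
}

validate_config <- function(cfg) {
  cfg <- unclass(cfg)
  # YAML drops NULL entries; an absent `blocks` means the synthetic emulator
  if (!"blocks" %in% names(cfg)) cfg["blocks"] <- list(NULL)
  known <- names(default_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")),
          class = "valseq_invalid_config")
  missing <- setdiff(setdiff(known, "blocks"), names(cfg))
  if (length(missing))
    abort(paste0("missing configuration key(s): ", paste(missing, collapse = ", ")),
          class = "valseq_invalid_config")
  bad <- setdiff(cfg$analyses, c("replay", "bootstrap", "montecarlo", "fixed"))
  if (length(bad))
    abort(paste0("unknown analyses: ", paste(bad, collapse = ", ")),
          class = "valseq_invalid_config")
  if (!is.null(cfg$blocks) && !is.character(cfg$blocks))
    abort("`blocks` must be NULL or a file path", class = "valseq_invalid_config")
  config_params(cfg)   # constructors run the numeric invariants
  cfg <- cfg[known]    # canonical key order
  structure(cfg, class = "valseq_config")
}

#' Trial parameters and prior from a configuration
#'
#' @param config A `valseq_config`.
#' @return A list with `params` ([economic_params()]) and `prior`
#'   ([beliefs()]).
#' @export
config_params <- function(config) {
  list(
    params = economic_params(
      wtp_lambda = config$lambda, pop_to_benefit_P = config$P,
      var_cost_c = config$c, fixed_cost = config$c_fixed,
      switch_cost_I = config$I, q_max = config$Qmax, delay_tau = config$tau,
      block_size = config$block_size),
    prior = beliefs(mu = config$mu0, m = config$n0, sigma_x = config$sigma_x)
  )
}
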