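#' Run a full solve / replay / resample analysis from one configuration
#'
#' Orchestrates the package end to end: solves the stopping boundary,
#' classifies the optimal design at the prior mean, replays the
#' provided (or synthetic) block table, and runs the bootstrap, Monte
#' Carlo and fixed-design resampling analyses as requested. All
#' outputs are plain CSV/JSON files in `out_dir`, each headed by a
#' comment naming the seed and the configuration hash, plus a run log.
#' Identical configurations produce byte-identical outputs.
#'
#' Files written (per requested analysis): `boundary.csv`,
#' `design.csv`, `replay.json`, `bootstrap_summary.csv` +
#' `bootstrap_paths.csv`, `montecarlo_summary.csv` +
#' `montecarlo_paths.csv`, `fixed_summary.csv`, `blocks.csv` (the table
#' replayed), and `run_log.txt`.
#'
#' @param config A `valseq_config` (see [read_run_config()]) or a path
#'   to a YAML configuration.
#' @param out_dir Output directory; defaults to the configuration's.
#' @return Invisibly, a list with the in-memory results: `boundary`,
#'   `design`, `replay`, `bootstrap`, `montecarlo`, `fixed` (NULL where
#'   not requested).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (!is.null(config$blocks) && !file.exists(config$blocks))
    abort(sprintf("block table `%s` not found", config$blocks),
          class = "valseq_invalid_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  hash <- rlang::hash(unclass(config))
  hdr <- c(sprintf("seed: %s", config$seed), sprintf("config_hash: %s", hash))
  mp <- config_params(config)

  boundary <- solve_boundary(mp$params, mp$prior,
                             grid_points = config$grid_points,
                             grid_halfwidth_sds = config$grid_halfwidth_sds,
                             quadrature_nodes = config$quadrature_nodes)
  write_boundary(boundary, file.path(out_dir, "boundary.csv"), header = hdr)

  design <- classify_prior(boundary)
  dtab <- dplyr::bind_cols(glance(design)[, c("label", "one_stage_n")],
                           tidyr::pivot_wider(tidy(design)[, c("letter", "mu0_gbp")],
                                              names_from = "letter",
                                              values_from = "mu0_gbp"))
  write_csv_header(dtab, file.path(out_dir, "design.csv"), hdr)

  blocks <- if (is.null(config$blocks)) {
    # synthetic stand-in stream long enough to replay to q_max
    synthetic_profher_blocks(seed = config$seed, n_pairs = config$Qmax,
                             mean_inc_cost = -config$mc_mean,
                             exact_mean_inb = config$mc_mean,
                             wtp_lambda = config$lambda)
  } else read_block_table(config$blocks)
  write_block_table(blocks, file.path(out_dir, "blocks.csv"), header = hdr)

  res <- list(boundary = boundary, design = design, config = config,
              replay = NULL, bootstrap = NULL, montecarlo = NULL, fixed = NULL)

  if ("replay" %in% config$analyses) {
    res$replay <- run_path(blocks, boundary,
                           reference_pairs = config$reference_pairs,
                           total_budget = config$total_budget)
    jsonlite::write_json(as.list(glance(res$replay)),
                         file.path(out_dir, "replay.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (config$reps >= 1 && "bootstrap" %in% config$analyses) {
    res$bootstrap <- bootstrap_paths(blocks, config$reps, boundary,
                                     seed = config$seed,
                                     reference_pairs = config$reference_pairs,
                                     total_budget = config$total_budget)
    write_oc(res$bootstrap, file.path(out_dir, "bootstrap_summary.csv"),
             file.path(out_dir, "bootstrap_paths.csv"), header = hdr)
  }
  if (config$reps >= 1 && "montecarlo" %in% config$analyses) {
    res$montecarlo <- monte_carlo_paths(config$mc_mean, config$reps, boundary,
                                        seed = config$seed + 1L,
                                        reference_pairs = config$reference_pairs,
                                        total_budget = config$total_budget)
    write_oc(res$montecarlo, file.path(out_dir, "montecarlo_summary.csv"),
             file.path(out_dir, "montecarlo_paths.csv"), header = hdr)
  }
  if (config$reps >= 1 && "fixed" %in% config$analyses) {
    res$fixed <- fixed_design_paths(config$reps, mp$params, mp$prior,
                                    seed = config$seed + 2L, blocks = blocks,
                                    reference_pairs = config$reference_pairs,
                                    total_budget = config$total_budget)
    write_oc(res$fixed, file.path(out_dir, "fixed_summary.csv"), header = hdr)
  }

  writeLines(c(
    "valseq run log",
    sprintf("package version: %s", as.character(utils::packageVersion("valseq"))),
    sprintf("seed: %s", config$seed),
    sprintf("config hash: %s", hash),
    sprintf("analyses: %s", paste(config$analyses, collapse = ", ")),
    sprintf("reps: %s", config$reps),
    sprintf("block table: %s", config$blocks %||% "synthetic emulator")
  ), file.path(out_dir, "run_log.txt"))
  write_run_config(config, file.path(out_dir, "config.yaml"))

  invisible(res)
}

write_csv_header <- function(tb, path, header) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  writeLines(paste0("# ", header), con)
  close(con)
  readr::write_csv(tb, path, append = TRUE, col_names = TRUE)
}
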