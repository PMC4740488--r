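# run manifest: everything needed to reproduce an output file bit-for-bit
build_manifest <- function(command, params, n, seed, extra = list()) {
  c(list(
    command = command,
    package = "wakeupcea",
    version = as.character(utils::packageVersion("wakeupcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    n = n, seed = seed,
    fixture_provenance = list(
      mrs_dist = provenance(params$mrs_dist),
      life_table = if (is.list(params$life_table) &&
                       !is.data.frame(params$life_table) &&
                       identical(params$life_table$source, "makeham"))
        "synthetic" else provenance(resolve_life_table(params))
    ),
    parameters = unclass_params_for_json(params)
  ), extra)
}

unclass_params_for_json <- function(params) {
  x <- unclass(params)
  x$mrs_dist <- as.list(tibble::as_tibble(x$mrs_dist))
  if (is.data.frame(x$life_table))
    x$life_table <- as.list(tibble::as_tibble(x$life_table))
  x
}

write_manifest <- function(manifest, out_dir, name) {
  path <- file.path(out_dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

round_cols <- function(df) {
  # printed precision: percentages to 1 decimal, currency to whole dollars,
  # (QA)LYs to 3 decimals
  for (nm in names(df)) {
    if (startsWith(nm, "pct_")) df[[nm]] <- round(df[[nm]], 1)
    if (nm %in% c("cost", "delta_cost", "icer")) df[[nm]] <- round(df[[nm]], 0)
    if (nm %in% c("life_years", "qalys", "delta_qalys"))
      df[[nm]] <- round(df[[nm]], 3)
  }
  df
}

#' Run a scenario and write strategy and comparison tables
#'
#' Runs the requested strategies for a named scenario (or an explicit
#' configuration file), writes a per-strategy CSV, the comparison summary
#' (when both strategies run) and a JSON run manifest, and returns the
#' tables invisibly.
#'
#' @param scenario a name from [scenario_library()], ignored when `config`
#'   is given.
#' @param config optional YAML configuration path (see
#'   [load_parameters()]).
#' @param n patients per strategy.
#' @param seed master seed.
#' @param strategies character vector of strategies to run.
#' @param out output directory (created if needed); `NULL` writes nothing.
#' @param wtp willingness to pay.
#' @return Invisibly, a list with `strategies` (tibble) and `cea`
#'   (a `wus_cea` or `NULL`).
#' @export
cmd_run <- function(scenario = "base8h", config = NULL, n = 100000, seed = 1,
                    strategies = c("no_treatment", "mri_based"), out = NULL,
                    wtp = 100000) {
  params <- if (!is.null(config)) load_parameters(config)
            else scenario_parameters(scenario)
  strategies <- match.arg(strategies, c("no_treatment", "mri_based"),
                          several.ok = TRUE)
  cea <- NULL
  if (length(strategies) == 2) {
    cea <- compare_strategies(params, n = n, seed = seed, crn = TRUE, wtp = wtp)
    tab <- cea$strategies
  } else {
    tab <- tibble::as_tibble(run_strategy(strategies, params, n, seed))
  }
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(round_cols(tab), file.path(out, "strategies.csv"),
                     row.names = FALSE)
    if (!is.null(cea))
      utils::write.csv(round_cols(glance(cea)), file.path(out, "cea.csv"),
                       row.names = FALSE)
    write_manifest(build_manifest("run", params, n, seed,
                                  list(scenario = scenario, wtp = wtp)),
                   out, "run")
  }
  invisible(list(strategies = tab, cea = cea))
}

#' Run the tornado (one-way) analysis and write its table
#'
#' @inheritParams cmd_run
#' @param spec optional `path`/`low`/`high` tibble; defaults to every
#'   ranged row of [psa_default_spec()].
#' @return Invisibly, the `wus_tornado` tibble.
#' @export
cmd_tornado <- function(scenario = "base8h", config = NULL, spec = NULL,
                        n = 2000, seed = 1, out = NULL, wtp = 100000) {
  params <- if (!is.null(config)) load_parameters(config)
            else scenario_parameters(scenario)
  if (is.null(spec)) {
    spec <- psa_default_spec(params)
    spec <- spec[!spec$family %in% c("dirichlet", "fixed"), ]
  }
  res <- one_way_analysis(params, spec, n = n, seed = seed, wtp = wtp)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(round_cols(tibble::as_tibble(res)),
                     file.path(out, "tornado.csv"), row.names = FALSE)
    write_manifest(build_manifest("tornado", params, n, seed,
                                  list(scenario = scenario, wtp = wtp)),
                   out, "tornado")
  }
  invisible(res)
}

#' Run the two-way MRI sensitivity x specificity analysis
#'
#' @inheritParams cmd_run
#' @param se_grid,sp_grid probability grids.
#' @return Invisibly, the `wus_twoway` tibble.
#' @export
cmd_twoway <- function(scenario = "base8h", config = NULL,
                       se_grid = seq(0.4, 0.9, by = 0.1),
                       sp_grid = seq(0.5, 1.0, by = 0.05),
                       n = 2000, seed = 1, out = NULL, wtp = 100000) {
  params <- if (!is.null(config)) load_parameters(config)
            else scenario_parameters(scenario)
  res <- two_way_sensitivity_specificity(params, se_grid, sp_grid,
                                         wtp = wtp, n = n, seed = seed)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tibble::as_tibble(res), file.path(out, "twoway.csv"),
                     row.names = FALSE)
    write_manifest(build_manifest("twoway", params, n, seed,
                                  list(scenario = scenario, wtp = wtp)),
                   out, "twoway")
  }
  invisible(res)
}

#' Run a threshold search on one parameter
#'
#' @inheritParams cmd_run
#' @param path parameter path, e.g. `"timing.wake_to_hospital_minutes"`.
#' @param bounds length-2 search interval.
#' @param tol bisection tolerance in the parameter's units.
#' @return Invisibly, the threshold-search result list.
#' @export
cmd_threshold <- function(path, bounds, scenario = "base8h", config = NULL,
                          n = 2000, seed = 1, out = NULL, wtp = 100000,
                          tol = 0.5) {
  params <- if (!is.null(config)) load_parameters(config)
            else scenario_parameters(scenario)
  res <- threshold_search(params, path, bounds, wtp = wtp, n = n,
                          seed = seed, tol = tol)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res, file.path(out, "threshold.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_manifest(build_manifest("threshold", params, n, seed,
                                  list(scenario = scenario, wtp = wtp,
                                       path = path, bounds = bounds)),
                   out, "threshold")
  }
  invisible(res)
}

#' Run the probabilistic sensitivity analysis and write draws and CEAC
#'
#' @inheritParams cmd_run
#' @param draws number of joint parameter draws.
#' @param n_per_draw patients per strategy within each draw.
#' @param fixed_all if `TRUE`, replace every family with `fixed` (degenerate
#'   draws at base values; diagnostic use).
#' @return Invisibly, the `wus_psa` object.
#' @export
cmd_psa <- function(scenario = "base8h", config = NULL, draws = 10000,
                    n_per_draw = 10000, seed = 1, out = NULL,
                    wtp_grid = seq(0, 200000, by = 10000), fixed_all = FALSE) {
  params <- if (!is.null(config)) load_parameters(config)
            else scenario_parameters(scenario)
  spec <- psa_default_spec(params)
  if (fixed_all) spec$family <- "fixed"
  res <- run_psa(params, spec, draws = draws, n_per_draw = n_per_draw,
                 seed = seed, wtp_grid = wtp_grid)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$draws, file.path(out, "psa_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ceac, file.path(out, "ceac.csv"), row.names = FALSE)
    write_manifest(build_manifest("psa", params, n_per_draw, seed,
                                  list(scenario = scenario, draws = draws)),
                   out, "psa")
  }
  invisible(res)
}

#' @param wtp_grid willingness-to-pay grid for the CEAC.
#' @name cmd_psa
NULL

#' Export the packaged fixtures as editable text files
#'
#' Writes the synthetic life table, the placeholder mRS outcome
#' distribution and the base-case configuration into a directory so users
#' can edit and pass them back via `config`.
#'
#' @param out output directory.
#' @return Invisibly, the written paths.
#' @export
export_fixtures <- function(out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  params <- default_parameters()
  lt_path <- file.path(out, "life_table_synthetic.tsv")
  utils::write.table(resolve_life_table(params), lt_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  mrs_path <- file.path(out, "mrs_distribution_synthetic.tsv")
  utils::write.table(tibble::as_tibble(params$mrs_dist), mrs_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg_path <- file.path(out, "base_case.yaml")
  save_parameters(params, cfg_path)
  invisible(c(lt_path, mrs_path, cfg_path))
}
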