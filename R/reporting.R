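#' Published base-case strategy results
#'
#' The five (cost, QALY) pairs of the original study's base-case table,
#' shipped as a plain-text fixture. They serve as inputs to the frontier
#' algebra (dominance classification, incremental values, ICERs), which
#' reproduces the published frontier structure from them.
#'
#' @return A data.frame: \code{strategy}, \code{cost} (KRW), \code{qaly}.
#' @export
published_strategy_results <- function() {
  path <- system.file("extdata", "published_base_case.csv",
                      package = "amdscreen")
  if (!nzchar(path)) {
    path <- file.path("inst", "extdata", "published_base_case.csv")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write a results table as CSV
#'
#' Writes the frontier/incremental table in the standard column order
#' (strategy, cost, incremental cost, effect, incremental effect, ICER,
#' dominance status), rounded to 2 decimals in the printed view, with a
#' full-precision companion file (suffix \code{_full}) whose round-trip read
#' reproduces the entries.
#'
#' @param entries data.frame from [dominance_frontier()] or
#'   [incremental_table()]; must be non-empty.
#' @param path output CSV path.
#' @return Invisibly, the paths written (printed view and full-precision
#'   companion).
#' @export
write_results <- function(entries, path) {
  if (is.null(entries) || nrow(entries) == 0) {
    stop("no entries to write", call. = FALSE)
  }
  cols <- c("strategy", "cost", "inc_cost", "qaly", "inc_qaly", "icer", "status")
  out <- entries[, intersect(cols, names(entries)), drop = FALSE]
  full_path <- sub("(\\.csv)?$", "_full.csv", path)
  utils::write.csv(format(.round_df(out), scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(out, full_path, row.names = FALSE, na = "")
  invisible(c(path, full_path))
}

.write_manifest <- function(out_dir, params, seed = NULL, lt_source, outputs) {
  cfg_path <- file.path(out_dir, "config.yaml")
  save_parameters(params, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    life_table_source = lt_source,
    strategies = strategy_catalog()$id,
    outputs = c(basename(cfg_path), basename(outputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Run the base case and write the result tables
#'
#' Runs all five strategies at the given parameters, writes the
#' all-strategies incremental table, the frontier table (dominated rows
#' excluded), a per-strategy cohort trace CSV, cost-effectiveness plane data,
#' and a JSON run manifest. The pipeline is deterministic: rerunning with the
#' same inputs reproduces identical files.
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}; defaults to the packaged synthetic
#'   table.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with \code{results} (per-strategy cost/QALY),
#'   \code{frontier} (classified table) and the output directory.
#' @export
run_base_case <- function(params = amd_parameters(), lt = default_life_table(),
                          out_dir = "results/base_case") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohorts <- lapply(strategy_catalog()$id,
                    function(s) run_cohort(params, lt, s))
  results <- do.call(rbind, lapply(cohorts, `[[`, "result"))
  all_view <- incremental_table(results)
  frontier <- dominance_frontier(results)
  frontier_view <- frontier[frontier$status == "frontier", ]

  outputs <- character()
  outputs <- c(outputs,
               write_results(all_view, file.path(out_dir, "table_all_strategies.csv")),
               write_results(frontier_view, file.path(out_dir, "table_frontier.csv")))
  for (co in cohorts) {
    f <- file.path(out_dir, sprintf("trace_%s.csv", co$result$strategy))
    utils::write.csv(co$trace, f, row.names = FALSE)
    outputs <- c(outputs, f)
  }
  plane <- file.path(out_dir, "ce_plane.csv")
  utils::write.csv(results, plane, row.names = FALSE)
  outputs <- c(outputs, plane)
  .write_manifest(out_dir, params, seed = NULL, lt_source = "packaged", outputs)

  invisible(list(results = results, frontier = frontier, out_dir = out_dir))
}

#' Run a sensitivity analysis and write its tables
#'
#' Dispatches to [one_way_sa()], [two_way_sa()] or [psa_run()] + [ceac()] and
#' writes the corresponding CSVs plus a run manifest.
#'
#' @param params an \code{amd_parameters} object.
#' @param lt an \code{amd_life_table}.
#' @param mode one of \code{"owsa"}, \code{"twsa"}, \code{"psa"}.
#' @param out_dir output directory.
#' @param param_x,param_y,range_x,range_y,grid_n two-way options (required for
#'   \code{twsa}).
#' @param n_draws,seed PSA options.
#' @param wtp threshold; defaults to \code{params$wtp}.
#' @return Invisibly, the analysis result data.frame (for \code{psa}, a list
#'   with \code{draws} and \code{ceac}).
#' @export
run_sensitivity <- function(params = amd_parameters(),
                            lt = default_life_table(),
                            mode = c("owsa", "twsa", "psa"),
                            out_dir = file.path("results", mode[1]),
                            param_x = NULL, range_x = NULL,
                            param_y = NULL, range_y = NULL, grid_n = 11,
                            n_draws = 1000, seed = 1, wtp = params$wtp) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  res <- switch(mode,
    owsa = {
      tor <- one_way_sa(params, default_ranges(params), lt, wtp)
      f <- file.path(out_dir, "tornado.csv")
      utils::write.csv(tor, f, row.names = FALSE)
      outputs <- f
      tor
    },
    twsa = {
      if (is.null(param_x) || is.null(param_y)) {
        stop("twsa requires param_x and param_y", call. = FALSE)
      }
      grid <- two_way_sa(params, lt, wtp, param_x, range_x, param_y, range_y,
                         grid_n)
      f <- file.path(out_dir, sprintf("two_way_%s_x_%s.csv", param_x, param_y))
      utils::write.csv(grid, f, row.names = FALSE)
      outputs <- f
      grid
    },
    psa = {
      draws <- psa_run(params, default_ranges(params), lt, n_draws, seed)
      cc <- ceac(draws)
      f1 <- file.path(out_dir, "psa_draws.csv")
      f2 <- file.path(out_dir, "ceac.csv")
      utils::write.csv(draws, f1, row.names = FALSE)
      utils::write.csv(cc, f2, row.names = FALSE)
      outputs <- c(f1, f2)
      list(draws = draws, ceac = cc)
    }
  )
  .write_manifest(out_dir, params, seed = if (mode == "psa") seed else NULL,
                  lt_source = "packaged", outputs)
  invisible(res)
}
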