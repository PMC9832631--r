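# Result serialisation: CSV tables with pinned numeric formatting plus a
# run.json provenance record (config echo, seed, version, timestamp).
# Commands never mutate their inputs; everything goes to the declared
# output directory.

.fmt_num <- function(x) {
  if (!is.numeric(x)) return(x)
  out <- formatC(x, digits = 10, format = "g")
  trimws(out)
}

.write_table <- function(df, path) {
  df[] <- lapply(df, .fmt_num)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.write_run_json <- function(out_dir, seed, extra = list(), config = NULL) {
  rec <- c(list(package = "pops",
                version = as.character(packageVersion("pops")),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed),
           extra,
           list(config = config))
  jsonlite::write_json(rec, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Write results to an output directory
#'
#' Serialises a PoPS curve, a scenario analysis, a target-attainment
#' comparison, or a [run_case()] result.  CSV numeric columns are printed
#' with 10 significant digits (pinned, so identical runs give byte-identical
#' tables); `run.json` records the package version, timestamp, master seed
#' and (when available) the configuration echo.
#'
#' Files per result type:
#' * `pops_curve` — `pops_curve.csv` (dose, pops, per-criterion pass rates
#'   and proportion bands), `replicates.csv` (per-replicate diagnostics:
#'   replicate, dose, criterion, realised K and n, fraction, pass),
#'   `run.json`.
#' * `pops_scenarios` — `scenario_curves.csv` (one row per cell x dose),
#'   `run.json`.
#' * `pops_pta` — `index_distributions.csv` (population, value),
#'   `pta_summary.json` (overlap, attainment, target value, n, seed),
#'   `run.json`.
#'
#' @param x the result object.
#' @param out_dir output directory (created if necessary).
#' @param config optional configuration list echoed into `run.json`.
#' @param ... unused.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(x, out_dir, config = NULL, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  UseMethod("write_results")
}

#' @export
write_results.pops_curve <- function(x, out_dir, config = NULL, ...) {
  plan <- attr(x, "plan")
  .write_table(as.data.frame(x), file.path(out_dir, "pops_curve.csv"))
  .write_table(attr(x, "replicates"), file.path(out_dir, "replicates.csv"))
  .write_run_json(out_dir, plan$seed,
                  list(M = plan$M, N = plan$N, model = attr(x, "model_name")),
                  config)
  invisible(file.path(out_dir,
                      c("pops_curve.csv", "replicates.csv", "run.json")))
}

#' @export
write_results.pops_scenarios <- function(x, out_dir, config = NULL, ...) {
  .write_table(as.data.frame(x), file.path(out_dir, "scenario_curves.csv"))
  .write_run_json(out_dir, x$seed, list(cells = length(x$curves)), config)
  invisible(file.path(out_dir, c("scenario_curves.csv", "run.json")))
}

#' @export
write_results.pops_pta <- function(x, out_dir, config = NULL, ...) {
  df <- data.frame(
    population = rep(c("candidate", "benchmark"),
                     c(length(x$candidate$values), length(x$benchmark$values))),
    index = c(rep(x$candidate$kind, length(x$candidate$values)),
              rep(x$benchmark$kind, length(x$benchmark$values))),
    value = c(x$candidate$values, x$benchmark$values),
    stringsAsFactors = FALSE)
  .write_table(df, file.path(out_dir, "index_distributions.csv"))
  jsonlite::write_json(
    list(overlap = x$overlap, attainment = x$attainment,
         target_quantile = x$target_quantile, target_value = x$target_value,
         n = x$n, seed = x$seed),
    file.path(out_dir, "pta_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_run_json(out_dir, x$seed, list(n = x$n), config)
  invisible(file.path(out_dir, c("index_distributions.csv",
                                 "pta_summary.json", "run.json")))
}

#' @export
write_results.list <- function(x, out_dir, config = NULL, ...) {
  # run_case() results: write each component into a subdirectory
  files <- character(0)
  if (!is.null(x$curves))
    for (nm in names(x$curves))
      files <- c(files, write_results(x$curves[[nm]],
                                      file.path(out_dir, nm), config))
  if (!is.null(x$curve))
    files <- c(files, write_results(x$curve, out_dir, config))
  if (!is.null(x$scenarios))
    files <- c(files, write_results(x$scenarios,
                                    file.path(out_dir, "scenarios"), config))
  if (!is.null(x$pta))
    files <- c(files, write_results(x$pta, out_dir, config))
  invisible(files)
}
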