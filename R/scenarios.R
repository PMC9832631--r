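# Scenario analysis: a full factorial sweep of named assumptions, each cell
# an independent PoPS run sharing the master seed (common draws across
# cells wherever the draw shapes permit).

.axis_labels <- function(levels) {
  if (!is.null(names(levels)) && all(names(levels) != ""))
    return(names(levels))
  if (is.atomic(levels)) return(as.character(levels))
  vapply(seq_along(levels), function(j) {
    lv <- levels[[j]]
    if (is.numeric(lv) && length(lv) == 1L) format(lv)
    else if (is.list(lv) && !is.null(lv$family))
      paste0(lv$family, "(", paste(format(unlist(lv$params), digits = 4),
                                   collapse = ","), ")")
    else paste0("level", j)
  }, "")
}

#' Full factorial scenario analysis
#'
#' Sweeps a named set of assumptions — criterion thresholds, BSV levels,
#' translation factors, any configuration entry addressable by
#' [set_config_path()] — over a full factorial grid.  Each cell re-runs
#' [run_config()] with the shared master seed, so cells differ only through
#' the assumption levels (common random numbers wherever the changed
#' assumption does not alter draw shapes).
#'
#' Axes and fixed overrides may also live in the configuration itself under
#' `scenarios: {axes: ..., overrides: ...}`; overrides are applied to every
#' cell before the axis levels.
#'
#' @param config a run configuration.
#' @param axes named list: axis path -> vector/list of levels.  Defaults to
#'   `config$scenarios$axes`.
#' @param verbose passed through to [run_config()].
#' @return A `pops_scenarios` object: `grid` (one row per cell, axis level
#'   labels), `curves` (list of `pops_curve`s, aligned with `grid` rows) and
#'   `axes`.  `as.data.frame()` flattens it to one row per cell x dose.
#' @export
scenario_analysis <- function(config, axes = NULL, verbose = FALSE) {
  axes <- axes %||% config$scenarios$axes
  if (is.null(axes) || length(axes) == 0L || is.null(names(axes)))
    .stopf("scenario axes must be a named list (assumption path -> levels)")
  overrides <- config$scenarios$overrides
  base <- config
  base$scenarios <- NULL
  for (p in names(overrides))
    base <- set_config_path(base, p, overrides[[p]])
  for (p in names(axes)) get_config_path(base, p)  # validate axis paths
  labels <- lapply(axes, .axis_labels)
  grid <- expand.grid(lapply(axes, seq_along), KEEP.OUT.ATTRS = FALSE)
  label_df <- as.data.frame(
    lapply(names(axes), function(a) labels[[a]][grid[[a]]]),
    col.names = names(axes), stringsAsFactors = FALSE, optional = TRUE)
  names(label_df) <- names(axes)
  curves <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- base
    for (a in names(axes)) {
      lv <- axes[[a]]
      lv <- if (is.atomic(lv)) lv[[grid[r, a]]] else lv[[grid[r, a]]]
      cfg <- set_config_path(cfg, a, lv)
    }
    curves[[r]] <- run_config(cfg, verbose = verbose)
  }
  structure(list(grid = label_df, curves = curves, axes = axes,
                 seed = config$plan$seed),
            class = "pops_scenarios")
}

#' @export
as.data.frame.pops_scenarios <- function(x, ...) {
  out <- lapply(seq_along(x$curves), function(r) {
    cbind(x$grid[rep(r, nrow(x$curves[[r]])), , drop = FALSE],
          as.data.frame(x$curves[[r]]), row.names = NULL)
  })
  do.call(rbind, out)
}

#' @export
print.pops_scenarios <- function(x, ...) {
  cat(sprintf("PoPS scenario analysis: %d cells over %d axis/axes\n",
              length(x$curves), length(x$axes)))
  peak <- vapply(x$curves, function(cv) max(cv$pops), numeric(1))
  df <- cbind(x$grid, peak_pops = peak)
  print.data.frame(df, digits = 3, row.names = FALSE)
  invisible(x)
}
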