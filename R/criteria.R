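# Success criteria: thresholded proportions over a simulated population,
# with optional uncertainty on the threshold K and required proportion n.

.comparators <- c(">", ">=", "<", "<=")

.compare <- function(values, comparator, K) {
  switch(comparator,
    ">" = values > K,
    ">=" = values >= K,
    "<" = values < K,
    "<=" = values <= K,
    .stopf("unknown comparator '%s' (use one of %s)",
           comparator, paste(.comparators, collapse = " ")))
}

#' Success criterion
#'
#' A criterion compares a per-subject endpoint against a threshold `K` and
#' requires the resulting proportion of subjects to clear a required
#' proportion `n`:
#'
#' * **benefit**: the fraction *meeting* the comparison must reach `n`
#'   (boundary inclusive by default: `fraction >= n` passes);
#' * **risk**: the fraction is the proportion *violating* a safety limit and
#'   must stay below `n` (boundary strict by default: `fraction < n`
#'   passes).
#'
#' Both `K` and `n` may be uncertainty distributions, realised once per
#' outer replicate ([realize_criteria()]).  `n` is a fraction in `[0, 1]`.
#' Ties between the endpoint value and `K` are resolved exactly by the
#' configured comparator; there is no epsilon fuzzing.
#'
#' @param endpoint name of a simulated endpoint (a column of the endpoint
#'   matrix produced by the model).
#' @param comparator one of `">"`, `">="`, `"<"`, `"<="`.
#' @param threshold threshold `K`: a number or a [dist_spec()].
#' @param required_proportion required proportion `n` in `[0, 1]`: a number
#'   or a distribution with support in `[0, 1]`.
#' @param kind `"benefit"` or `"risk"`.
#' @param label unique label (defaults to the endpoint name).
#' @param boundary `"inclusive"` or `"strict"` comparison of the achieved
#'   fraction against `n`; defaults to inclusive for benefit and strict for
#'   risk, mirroring the usual ">= n%" / "< n%" phrasing of such criteria.
#' @return An object of class `pops_criterion`.
#' @examples
#' criterion("balanced", ">=", 0.5, 0.80, kind = "benefit")
#' @export
criterion <- function(endpoint, comparator, threshold, required_proportion,
                      kind = c("benefit", "risk"), label = endpoint,
                      boundary = NULL) {
  kind <- match.arg(kind)
  if (!comparator %in% .comparators)
    .stopf("unknown comparator '%s'", comparator)
  boundary <- boundary %||% if (kind == "benefit") "inclusive" else "strict"
  if (!boundary %in% c("inclusive", "strict"))
    .stopf("'boundary' must be 'inclusive' or 'strict'")
  threshold <- as_dist(threshold)
  required_proportion <- as_dist(required_proportion)
  rp <- required_proportion$params
  bounds <- switch(required_proportion$family,
    point = c(rp$value, rp$value),
    uniform = c(rp$lower, rp$upper),
    scaled_beta = c(rp$lower, rp$upper),
    weighted_categorical = range(rp$values),
    NULL)
  if (!is.null(bounds) && (bounds[1] < 0 || bounds[2] > 1))
    .stopf("required_proportion support must lie within [0, 1]")
  structure(list(endpoint = endpoint, comparator = comparator,
                 threshold = threshold,
                 required_proportion = required_proportion,
                 kind = kind, label = label, boundary = boundary),
            class = "pops_criterion")
}

#' Conjunction of success criteria
#'
#' A criteria set passes only if every member criterion passes (benefit and
#' risk criteria are considered together).  Labels must be unique.
#'
#' @param ... `pops_criterion` objects, or a single list of them.
#' @return An object of class `pops_criteria` (a list of criteria).
#' @export
criteria_set <- function(...) {
  crits <- list(...)
  if (length(crits) == 1L && !inherits(crits[[1L]], "pops_criterion"))
    crits <- crits[[1L]]
  if (length(crits) == 0L)
    .stopf("a criteria set needs at least one criterion")
  ok <- vapply(crits, inherits, TRUE, what = "pops_criterion")
  if (!all(ok)) .stopf("all elements must be pops_criterion objects")
  labs <- vapply(crits, `[[`, "", "label")
  if (anyDuplicated(labs))
    .stopf("criterion labels must be unique (duplicated: %s)",
           paste(unique(labs[duplicated(labs)]), collapse = ", "))
  structure(crits, class = "pops_criteria")
}

#' Realise the uncertain elements of a criteria set
#'
#' Draws one `(K, n)` pair per criterion, in set order, `K` before `n`.
#' Point-mass distributions return their value without consuming random
#' numbers.
#'
#' @param set a [criteria_set()].
#' @param seed optional isolated seed.
#' @return List with one `list(label, K, n)` per criterion.
#' @export
realize_criteria <- function(set, seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(seed, realize_criteria(set)))
  lapply(set, function(cr) {
    list(label = cr$label,
         K = dist_sample(cr$threshold, 1L),
         n = dist_sample(cr$required_proportion, 1L))
  })
}

#' Proportion of subjects meeting a threshold
#'
#' @param values endpoint values over the simulated subjects (no missing
#'   values; at least one subject).
#' @param comparator one of `">"`, `">="`, `"<"`, `"<="`; strict versus
#'   non-strict comparison is honoured exactly at the boundary.
#' @param K threshold value.
#' @return Fraction of subjects satisfying the comparison.
#' @examples
#' proportion_meeting(c(1, 2, 3, 4), ">=", 3)  # 0.5
#' @export
proportion_meeting <- function(values, comparator, K) {
  if (length(values) == 0L) .stopf("empty population")
  if (anyNA(values)) .stopf("endpoint values contain missing values")
  mean(.compare(values, comparator, K))
}

#' Does a single criterion pass?
#'
#' @param fraction achieved proportion (for risk criteria: the proportion
#'   violating the limit), in `[0, 1]`.
#' @param n required proportion in `[0, 1]`.
#' @param kind `"benefit"` or `"risk"`.
#' @param boundary `"inclusive"` or `"strict"`; defaults as in
#'   [criterion()].
#' @return Logical.
#' @examples
#' criterion_pass(0.80, 0.80, "benefit")  # TRUE  (inclusive)
#' criterion_pass(0.05, 0.05, "risk")     # FALSE (strict)
#' @export
criterion_pass <- function(fraction, n, kind = c("benefit", "risk"),
                           boundary = NULL) {
  kind <- match.arg(kind)
  boundary <- boundary %||% if (kind == "benefit") "inclusive" else "strict"
  if (fraction < 0 || fraction > 1 || n < 0 || n > 1)
    .stopf("'fraction' and 'n' must be in [0, 1]")
  if (kind == "benefit") {
    if (boundary == "inclusive") fraction >= n else fraction > n
  } else {
    if (boundary == "strict") fraction < n else fraction <= n
  }
}

#' Evaluate a criteria set on a simulated population
#'
#' Applies each realised criterion to its endpoint column and combines the
#' results conjunctively.  The per-criterion record keeps the achieved
#' fraction and the realised `(K, n)` for diagnostics.
#'
#' @param realized output of [realize_criteria()] for this replicate.
#' @param endpoints numeric matrix, one row per subject, columns named by
#'   endpoint.
#' @param set the [criteria_set()] the realisations came from.
#' @return List with `pass` (logical, the conjunction) and `records`
#'   (data frame: criterion, kind, K, n, fraction, pass).
#' @export
criteria_pass <- function(realized, endpoints, set) {
  if (length(realized) != length(set))
    .stopf("'realized' and 'set' must have the same length")
  cols <- colnames(endpoints)
  recs <- vector("list", length(set))
  for (j in seq_along(set)) {
    cr <- set[[j]]; rz <- realized[[j]]
    if (!cr$endpoint %in% cols)
      .stopf("configuration error: endpoint '%s' (criterion '%s') not in model output (%s)",
             cr$endpoint, cr$label, paste(cols, collapse = ", "))
    frac <- proportion_meeting(endpoints[, cr$endpoint], cr$comparator, rz$K)
    recs[[j]] <- data.frame(
      criterion = cr$label, kind = cr$kind, K = rz$K, n = rz$n,
      fraction = frac,
      pass = criterion_pass(frac, rz$n, cr$kind, cr$boundary),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  list(pass = all(records$pass), records = records)
}
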