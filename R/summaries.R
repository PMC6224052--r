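#' Qualitative utilization labels for the states of a fitted mixture
#'
#' Each state is labeled from its expected emission value
#' \eqn{e_s = \sum_k k B_{sk}} using fixed thresholds. Defaults: below 0.5
#' "zero", below 2 "low", below 5 "medium", below 10 "high", otherwise
#' "very high". The thresholds are a reporting convention, not part of the
#' model, and are configurable.
#'
#' @param model an [mhmm()] object (or single [hmm()]).
#' @param thresholds increasing numeric vector of bin edges, one fewer than
#'   `labels`.
#' @param labels label set, lowest bin first.
#' @return Data frame with columns `cluster`, `state`, `expected_count`,
#'   `label`.
#' @export
label_states <- function(model, thresholds = c(0.5, 2, 5, 10),
                         labels = c("zero", "low", "medium", "high",
                                    "very high")) {
  stopifnot(length(labels) == length(thresholds) + 1L,
            !is.unsorted(thresholds, strictly = TRUE))
  comps <- if (inherits(model, "hmm")) list(model) else model$components
  rows <- list()
  for (m in seq_along(comps)) {
    e <- expected_emissions(comps[[m]])
    lab <- labels[findInterval(e, thresholds) + 1L]
    rows[[m]] <- data.frame(cluster = m, state = seq_along(e),
                            expected_count = e, label = lab,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

stacked_tally <- function(values_list, axis) {
  lens <- lengths(values_list)
  L <- max(lens)
  rows <- list()
  totals <- integer(L)
  for (m in seq_len(L)) {
    at <- vapply(values_list[lens >= m], `[[`, numeric(1), m)
    totals[m] <- length(at)
    tab <- table(at)
    rows[[m]] <- data.frame(month = m, value = as.integer(names(tab)),
                            count = as.integer(tab))
  }
  out <- do.call(rbind, rows)
  structure(out, axis = axis, month_totals = totals, class =
              c("stacked_matrix", "data.frame"))
}

#' Stacked per-month tallies of counts or decoded states
#'
#' The tidy analogue of the stacked trajectory plots: for each month since
#' first utilization, how many series carry each count value (or each
#' decoded state). For every month the tallies sum to the number of series
#' at least that long.
#'
#' @param series list of count vectors or [utilization_series()] objects.
#' @return Data frame (class `stacked_matrix`) with columns `month`,
#'   `value`, `count` and attributes `axis` and `month_totals`.
#' @export
stacked_counts <- function(series) {
  stopifnot(length(series) > 0L)
  vals <- lapply(series, function(s)
    if (inherits(s, "utilization_series")) as.numeric(s$counts) else as.numeric(s))
  stacked_tally(vals, axis = "counts")
}

#' @rdname stacked_counts
#' @param paths list of integer state vectors (e.g. Viterbi paths) or
#'   `state_path` objects.
#' @export
stacked_states <- function(paths) {
  stopifnot(length(paths) > 0L)
  vals <- lapply(paths, function(p)
    if (inherits(p, "state_path")) as.numeric(p$states) else as.numeric(p))
  stacked_tally(vals, axis = "states")
}

#' State diagram of one mixture component
#'
#' Summarizes an HMM as the pie-and-arrow diagram used to display fitted
#' utilization regimes: per state, the emission distribution with slices
#' below `collapse_threshold` merged into an `"other"` slice, the expected
#' dwell time `1 / (1 - A[s, s])` months (infinite and flagged for
#' absorbing states), and the off-diagonal transition probabilities at or
#' above the threshold as edges.
#'
#' @param hmm an [hmm()] object (a fitted mixture component).
#' @param labels optional character vector of state labels (e.g. from
#'   [label_states()]).
#' @param collapse_threshold emission probabilities below this are merged
#'   into a single `"other"` slice; default 0.01.
#' @return Object of class `state_diagram`: list with `states` (per-state
#'   list: `label`, `expected_dwell_months`, `absorbing`, `slices`) and
#'   `edges` (data frame `from`, `to`, `probability`).
#' @export
state_diagram <- function(hmm, labels = NULL, collapse_threshold = 0.01) {
  validate_hmm(hmm)
  N <- hmm$n_states
  if (is.null(labels)) labels <- label_states(hmm)$label
  stopifnot(length(labels) == N)
  states <- vector("list", N)
  for (s in seq_len(N)) {
    b <- hmm$emission[s, ]
    keep <- b >= collapse_threshold
    slices <- b[keep]
    names(slices) <- as.character(which(keep) - 1L)
    other <- sum(b[!keep])
    if (other > 0) slices <- c(slices, other = other)
    stay <- hmm$transition[s, s]
    states[[s]] <- list(
      state = s, label = labels[s],
      expected_dwell_months = if (stay >= 1) Inf else 1 / (1 - stay),
      absorbing = stay >= 1,
      slices = slices)
  }
  ed <- which(hmm$transition >= collapse_threshold &
                row(hmm$transition) != col(hmm$transition), arr.ind = TRUE)
  edges <- data.frame(from = as.integer(ed[, 1L]), to = as.integer(ed[, 2L]),
                      probability = hmm$transition[ed])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  structure(list(states = states, edges = edges), class = "state_diagram")
}

#' Export a state diagram (or one per cluster) as JSON
#'
#' @param x a `state_diagram`, [hmm()] or [mhmm()] object.
#' @param path optional output path.
#' @param ... passed to [state_diagram()] when `x` is a model.
#' @return JSON string, invisibly when written to file.
#' @export
state_diagram_json <- function(x, path = NULL, ...) {
  diags <- if (inherits(x, "state_diagram")) list(x)
  else if (inherits(x, "hmm")) list(state_diagram(x, ...))
  else lapply(x$components, state_diagram, ...)
  payload <- lapply(diags, function(d) list(
    nodes = lapply(d$states, function(s) list(
      state = s$state, label = s$label,
      expected_dwell_months = if (is.finite(s$expected_dwell_months))
        s$expected_dwell_months else "absorbing",
      slices = as.list(s$slices))),
    edges = d$edges))
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Per-cluster descriptive report
#'
#' Sizes, shares, mean series length, mean yearly utilization (12 times the
#' mean monthly count), and the fraction of active series at count zero by
#' month — the table behind statements like "by month 4 more than half of
#' the brief cluster has reached zero utilization".
#'
#' @param fit an `mhmm_fit` object (or [mhmm()] model).
#' @param series the series the model was fitted to.
#' @param months months at which to report the zero fraction (default
#'   `c(4, 12, 20, 50)`).
#' @return List with `clusters` (data frame: cluster, size, share,
#'   mean_length_months, mean_yearly_utilization) and `zero_fraction`
#'   (data frame: cluster, month, active_series, fraction_zero).
#' @export
cluster_report <- function(fit, series, months = c(4L, 12L, 20L, 50L)) {
  model <- if (inherits(fit, "mhmm_fit")) fit$model else fit
  asg <- assign_clusters(series, model)
  obs <- series_obs_list(series, model$n_symbols)
  M <- model$n_clusters
  sizes <- tabulate(asg$hard_label, M)
  rows <- lapply(seq_len(M), function(m) {
    sel <- obs[asg$hard_label == m]
    mean_len <- if (length(sel)) mean(lengths(sel)) else NA_real_
    mean_yearly <- if (length(sel))
      mean(vapply(sel, mean, numeric(1))) * 12 else NA_real_
    data.frame(cluster = m, size = sizes[m], share = sizes[m] / length(obs),
               mean_length_months = mean_len,
               mean_yearly_utilization = mean_yearly)
  })
  zf <- list()
  for (m in seq_len(M)) {
    sel <- obs[asg$hard_label == m]
    for (mo in months) {
      act <- sel[lengths(sel) >= mo]
      zf[[length(zf) + 1L]] <- data.frame(
        cluster = m, month = mo, active_series = length(act),
        fraction_zero = if (length(act))
          mean(vapply(act, function(x) x[mo] == 0L, logical(1))) else NA_real_)
    }
  }
  list(clusters = do.call(rbind, rows), zero_fraction = do.call(rbind, zf),
       assignments = asg)
}
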