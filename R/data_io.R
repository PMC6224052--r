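#' A single claimant's monthly utilization series
#'
#' Counts are aligned at the month of first utilization: element 1 is the
#' first month with at least one service event, the last element the last
#' such month, and intervening months with no events carry count 0.
#'
#' @param claim_id claim identifier (coerced to character).
#' @param start_month calendar month of first utilization (`Date`, first day
#'   of month).
#' @param counts integer vector of monthly counts; first and last elements
#'   must be at least 1.
#' @return Object of class `utilization_series`.
#' @export
utilization_series <- function(claim_id, start_month, counts) {
  counts <- as.integer(counts)
  if (length(counts) < 1L) stop("counts must be non-empty")
  if (counts[1L] < 1L || counts[length(counts)] < 1L)
    stop("series must start and end in a month with at least one utilization")
  if (any(counts < 0L)) stop("counts must be non-negative")
  structure(list(claim_id = as.character(claim_id),
                 start_month = as.Date(start_month), counts = counts),
            class = "utilization_series")
}

#' @export
print.utilization_series <- function(x, ...) {
  cat(sprintf("claim %s, from %s (%d months): %s\n", x$claim_id,
              format(x$start_month, "%Y-%m"), length(x$counts),
              paste(x$counts, collapse = " ")))
  invisible(x)
}

#' @export
length.utilization_series <- function(x) length(x$counts)

first_of_month <- function(d) as.Date(format(as.Date(d), "%Y-%m-01"))

# months elapsed between two first-of-month dates
month_index <- function(d, origin) {
  d <- as.POSIXlt(d); o <- as.POSIXlt(origin)
  (d$year - o$year) * 12L + (d$mon - o$mon)
}

#' Build monthly utilization series from a long event table
#'
#' Events of the requested (most detailed) service category are aggregated
#' by claim and calendar month; months between a claim's first and last
#' utilization with no events receive count 0. Series shorter than
#' `min_length` months are dropped (with a message). Counts at or above the
#' emission support size `K` are clipped to `K - 1` with a warning.
#'
#' @param events data frame with columns `claim_id`, `service_date` (ISO
#'   dates), `category_l1`, `category_l2`, `category_l3`.
#' @param category service category to select, matched against
#'   `category_l3` (default `"psychology"`).
#' @param min_length minimum series length in months (default 2).
#' @param K count support size; monthly counts are clipped to `0:(K-1)`
#'   (default 25).
#' @return List of [utilization_series()], named by claim id.
#' @export
build_series <- function(events, category = "psychology", min_length = 2L,
                         K = 25L) {
  stopifnot(is.data.frame(events), nrow(events) > 0L, min_length >= 1L)
  needed <- c("claim_id", "service_date", "category_l3")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols))
    stop("events table lacks columns: ", paste(missing_cols, collapse = ", "))
  dates <- suppressWarnings(as.Date(as.character(events$service_date)))
  bad <- is.na(dates)
  if (any(bad)) {
    warning(sum(bad), " event(s) with unparseable service_date rejected")
    events <- events[!bad, , drop = FALSE]
    dates <- dates[!bad]
  }
  keep <- events$category_l3 == category & nzchar(events$category_l3)
  if (!any(keep)) {
    warning("no events with category_l3 == ", shQuote(category))
    return(structure(list(), names = character(0)))
  }
  events <- events[keep, , drop = FALSE]
  dates <- first_of_month(dates[keep])
  out <- list()
  dropped <- 0L
  clipped <- 0L
  for (id in unique(as.character(events$claim_id))) {
    d <- dates[as.character(events$claim_id) == id]
    start <- min(d)
    idx <- month_index(d, start) + 1L
    T_len <- max(idx)
    counts <- tabulate(idx, T_len)
    if (T_len < min_length) { dropped <- dropped + 1L; next }
    over <- counts >= K
    if (any(over)) { clipped <- clipped + sum(over); counts[over] <- K - 1L }
    out[[id]] <- utilization_series(id, start, counts)
  }
  if (dropped)
    message(dropped, " series shorter than ", min_length, " months dropped")
  if (clipped)
    warning(clipped, " monthly count(s) clipped to the support maximum ", K - 1L)
  out
}

#' Years between accident and first service utilization
#'
#' Day difference divided by 365.25.
#'
#' @param accident_date,first_utilization_date `Date` vectors (recycled).
#' @return Non-negative numeric vector of years.
#' @export
compute_elapsed_time <- function(accident_date, first_utilization_date) {
  a <- as.Date(accident_date); f <- as.Date(first_utilization_date)
  days <- as.numeric(f - a)
  if (any(days < 0, na.rm = TRUE))
    stop("first utilization precedes the accident date for some claims")
  days / 365.25
}

#' Coverage filter for binary/categorical covariates
#'
#' Retains a binary covariate only when its minority level covers at least
#' `threshold` of the claims (a flag set for under 10 percent of the sample
#' carries too little information to model). Multi-level categorical
#' covariates are retained with their level shares reported; dropped names
#' are messaged.
#'
#' @param covariates data frame of claim covariates (factors, characters or
#'   0/1 columns); a `claim_id` column is ignored.
#' @param threshold minimum minority-level share, in `(0, 1]` (default
#'   0.10).
#' @return Character vector of retained covariate names, with a
#'   `"level_shares"` attribute listing per-level shares for every
#'   candidate.
#' @export
filter_covariates <- function(covariates, threshold = 0.10) {
  stopifnot(is.data.frame(covariates))
  if (nrow(covariates) == 0L) stop("empty covariate table")
  stopifnot(threshold > 0, threshold <= 1)
  cols <- setdiff(names(covariates), "claim_id")
  shares <- list()
  keep <- character(0)
  for (nm in cols) {
    v <- covariates[[nm]]
    if (is.numeric(v) && length(unique(stats::na.omit(v))) > 2L) {
      keep <- c(keep, nm)  # numeric covariates are not coverage-filtered
      next
    }
    tab <- table(factor(v), useNA = "no")
    share <- as.numeric(tab) / sum(tab)
    names(share) <- names(tab)
    shares[[nm]] <- share
    if (length(share) <= 1L) next  # constant column: uninformative, dropped
    if (length(share) == 2L) {
      if (min(share) >= threshold) keep <- c(keep, nm)
    } else {
      keep <- c(keep, nm)
    }
  }
  dropped <- setdiff(cols, keep)
  if (length(dropped))
    message("covariates dropped by the ", format(threshold),
            " coverage filter: ", paste(dropped, collapse = ", "))
  structure(keep, level_shares = shares)
}

#' Write series to a wide CSV with a JSON metadata sidecar
#'
#' Layout: `claim_id`, `start_month`, `t1..tL` with trailing `NA` beyond
#' each series' length. The sidecar records the support size and build
#' parameters so a round-trip is lossless.
#'
#' @param series list of [utilization_series()].
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @param meta optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, meta = list()) {
  L <- max(vapply(series, function(s) length(s$counts), integer(1)))
  rows <- lapply(series, function(s)
    c(list(claim_id = s$claim_id,
           start_month = format(s$start_month, "%Y-%m-%d")),
      as.list(c(s$counts, rep(NA_integer_, L - length(s$counts))))))
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, col.names =
                    c("claim_id", "start_month", paste0("t", seq_len(L))))))
  utils::write.csv(df, path, row.names = FALSE)
  side <- c(list(n_series = length(series), max_length = L,
                 written = "utilization series, wide layout"), meta)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read series written by [write_series_csv()]
#'
#' @param path CSV path.
#' @return Named list of [utilization_series()].
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcols <- grep("^t[0-9]+$", names(df), value = TRUE)
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  out <- lapply(seq_len(nrow(df)), function(i) {
    counts <- as.integer(df[i, tcols])
    counts <- counts[!is.na(counts)]
    utilization_series(df$claim_id[i], df$start_month[i], counts)
  })
  names(out) <- as.character(df$claim_id)
  out
}
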