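#' Number of free parameters of an M-cluster, N-state mixture
#'
#' Each mixture contributes `M - 1` free weights; each component contributes
#' `N - 1` initial probabilities, `N (N - 1)` transition probabilities and
#' `N (K - 1)` emission probabilities.
#'
#' @param M number of clusters.
#' @param N number of states per cluster.
#' @param K count support size.
#' @return Integer parameter count.
#' @examples
#' count_params(3, 3, 25)  # 242
#' @export
count_params <- function(M, N, K) {
  stopifnot(M >= 1, N >= 1, K >= 2)
  as.integer((M - 1) + M * ((N - 1) + N * (N - 1) + N * (K - 1)))
}

#' Bayesian and Akaike information criteria
#'
#' `BIC = p log(n) - 2 loglik` and `AIC = 2 p - 2 loglik`; lower is better.
#' For the mixture fits the sample size `n` is taken as the total number of
#' monthly observations across series (each month is one datum under the
#' likelihood), not the number of series; this convention is configurable in
#' [select_mhmm()].
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_obs sample size.
#' @return Criterion value.
#' @export
bic <- function(loglik, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  n_params * log(n_obs) - 2 * loglik
}

#' @rdname bic
#' @export
aic <- function(loglik, n_params) {
  2 * n_params - 2 * loglik
}

#' Grid search over numbers of clusters and states
#'
#' Fits [fit_mhmm()] for every pair in `M_values` x `N_values` and selects
#' the pair minimizing the chosen criterion (ties broken toward smaller `M`,
#' then smaller `N`). Cells whose every restart fails are excluded from
#' selection and flagged in the grid.
#'
#' @param series list of count vectors or [utilization_series()] objects.
#' @param M_values,N_values integer vectors of candidate cluster/state
#'   counts.
#' @param K count support size.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param n_obs sample-size convention for the BIC penalty: `"months"`
#'   (default, total monthly observations) or `"series"`.
#' @param restarts,tol,max_iter,seed passed to [fit_mhmm()].
#' @param verbose print per-cell progress.
#' @return An object of class `mhmm_selection`: list with `grid` (data frame
#'   of M, N, loglik, n_params, bic, aic, converged, failed), `selected`
#'   (`c(M, N)`), `criterion`, and `fits` (named list of `mhmm_fit`
#'   objects).
#' @export
select_mhmm <- function(series, M_values, N_values, K = 25L,
                        criterion = c("bic", "aic"), n_obs = c("months", "series"),
                        restarts = 5L, tol = 1e-6, max_iter = 500L, seed = 1L,
                        verbose = FALSE) {
  criterion <- match.arg(criterion)
  n_obs <- match.arg(n_obs)
  stopifnot(length(M_values) >= 1L, length(N_values) >= 1L)
  obs <- series_obs_list(series, K)
  n <- if (n_obs == "months") sum(lengths(obs)) else length(obs)
  cells <- expand.grid(M = as.integer(M_values), N = as.integer(N_values))
  cells <- cells[order(cells$M, cells$N), , drop = FALSE]
  fits <- list()
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    M <- cells$M[i]; N <- cells$N[i]
    key <- sprintf("M%d_N%d", M, N)
    fit <- tryCatch(
      fit_mhmm(obs, M, N, K, restarts = restarts, tol = tol,
               max_iter = max_iter, seed = seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("grid cell (M=%d, N=%d) failed: %s", M, N,
                      conditionMessage(fit)))
      rows[[i]] <- data.frame(M = M, N = N, loglik = NA_real_,
                              n_params = count_params(M, N, K),
                              bic = NA_real_, aic = NA_real_,
                              converged = NA, failed = TRUE)
      next
    }
    fits[[key]] <- fit
    p <- count_params(M, N, K)
    rows[[i]] <- data.frame(M = M, N = N, loglik = fit$loglik, n_params = p,
                            bic = bic(fit$loglik, p, n),
                            aic = aic(fit$loglik, p),
                            converged = fit$converged, failed = FALSE)
    if (verbose)
      message(sprintf("(M=%d, N=%d): loglik %.2f, BIC %.2f", M, N,
                      fit$loglik, rows[[i]]$bic))
  }
  grid <- do.call(rbind, rows)
  ok <- !grid$failed
  if (!any(ok)) stop("every grid cell failed to fit")
  crit <- grid[[criterion]]
  # ties toward smaller M then smaller N: grid is sorted that way already
  best <- which(ok)[which.min(crit[ok])]
  structure(list(grid = grid, selected = c(M = grid$M[best], N = grid$N[best]),
                 criterion = criterion, n_obs_convention = n_obs,
                 n_obs = n, fits = fits),
            class = "mhmm_selection")
}

#' @export
print.mhmm_selection <- function(x, ...) {
  cat(sprintf("MHMM model selection by %s (n = %d %s)\n",
              toupper(x$criterion), x$n_obs, x$n_obs_convention))
  print(x$grid, row.names = FALSE)
  cat(sprintf("selected: M = %d, N = %d\n", x$selected["M"], x$selected["N"]))
  invisible(x)
}

#' The winning fit of a model-selection run
#'
#' @param selection an `mhmm_selection` object.
#' @return The `mhmm_fit` of the selected `(M, N)` pair.
#' @export
selected_fit <- function(selection) {
  selection$fits[[sprintf("M%d_N%d", selection$selected["M"],
                          selection$selected["N"])]]
}
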