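#' Construct a hidden Markov model with categorical count emissions
#'
#' An HMM over monthly utilization counts is defined by the initial state
#' distribution \eqn{\pi}, the row-stochastic transition matrix \eqn{A}
#' (\eqn{A_{rs} = p(y_t = s \mid y_{t-1} = r)}), and the row-stochastic
#' emission matrix \eqn{B} over the count support \eqn{\{0, \dots, K-1\}}
#' (\eqn{B_{sk} = p(x_t = k - 1 \mid y_t = s)}).
#'
#' @param initial numeric vector of length `N`, the initial state
#'   probabilities.
#' @param transition `N x N` row-stochastic matrix of state transition
#'   probabilities.
#' @param emission `N x K` row-stochastic matrix of emission probabilities
#'   over counts `0:(K-1)`.
#' @return An object of class `hmm` with elements `initial`, `transition`,
#'   `emission`, `n_states` and `n_symbols`.
#' @examples
#' h <- hmm(c(0.5, 0.5),
#'          rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'          rbind(c(0.7, 0.3), c(0.1, 0.9)))
#' hmm_loglik(c(0, 1, 1), h)
#' @export
hmm <- function(initial, transition, emission) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition)
  emission <- as.matrix(emission)
  obj <- structure(
    list(initial = initial, transition = transition, emission = emission,
         n_states = length(initial), n_symbols = ncol(emission)),
    class = "hmm")
  validate_hmm(obj)
  obj
}

#' @export
print.hmm <- function(x, ...) {
  cat(sprintf("Hidden Markov model: %d states, count support 0..%d\n",
              x$n_states, x$n_symbols - 1L))
  cat("Expected emission per state:",
      paste(sprintf("%.2f", expected_emissions(x)), collapse = ", "), "\n")
  invisible(x)
}

validate_hmm <- function(h, tol = 1e-12) {
  stopifnot(is.numeric(h$initial), is.matrix(h$transition), is.matrix(h$emission))
  N <- length(h$initial)
  if (nrow(h$transition) != N || ncol(h$transition) != N)
    stop("transition matrix must be ", N, "x", N)
  if (nrow(h$emission) != N)
    stop("emission matrix must have one row per state")
  if (any(h$initial < 0) || any(h$transition < 0) || any(h$emission < 0))
    stop("all probabilities must be non-negative")
  sums <- c(sum(h$initial), rowSums(h$transition), rowSums(h$emission))
  if (any(abs(sums - 1) > sqrt(tol)))
    stop("initial vector and all rows of transition/emission must sum to 1")
  invisible(h)
}

# Extract a plain integer count vector from any accepted series representation
# and check it against the emission support.
series_obs <- function(x, K) {
  if (inherits(x, "utilization_series")) x <- x$counts
  x <- as.integer(x)
  if (length(x) < 1L) stop("series must have at least one observation")
  if (any(x < 0L)) stop("counts must be non-negative")
  bad <- which(x >= K)
  if (length(bad))
    stop(sprintf("count %d at position %d is outside the emission support 0..%d",
                 x[bad[1L]], bad[1L], K - 1L))
  x
}

log_clip <- function(p) {
  # log of probabilities, mapping exact zeros to -Inf without warnings
  out <- rep(-Inf, length(p))
  pos <- p > 0
  out[pos] <- log(p[pos])
  if (is.matrix(p)) { dim(out) <- dim(p) }
  out
}

hmm_log_params <- function(h) {
  list(log_pi = log_clip(h$initial),
       log_A = matrix(log_clip(h$transition), h$n_states, h$n_states),
       log_B = matrix(log_clip(h$emission), h$n_states, h$n_symbols))
}

#' Marginal log-likelihood of a count series under an HMM
#'
#' Computes \eqn{\log p(x_{1:T})} by the forward recursion carried out in log
#' space, marginalizing over all state paths. Returns `-Inf` when some
#' observation has zero probability under every reachable state.
#'
#' @param series integer vector of monthly counts (or a
#'   [utilization_series()] object).
#' @param hmm an [hmm()] object.
#' @return The log-likelihood, a single numeric value.
#' @export
hmm_loglik <- function(series, hmm) {
  validate_hmm(hmm)
  x <- series_obs(series, hmm$n_symbols)
  lp <- hmm_log_params(hmm)
  hmm_loglik_cpp(x, lp$log_pi, lp$log_A, lp$log_B)
}

#' Forward-backward state posteriors
#'
#' Runs the scaled (log-space) forward and backward recursions and returns
#' the smoothed state posteriors \eqn{\gamma_t(s) = p(y_t = s \mid x_{1:T})},
#' the pairwise posteriors
#' \eqn{\xi_t(r, s) = p(y_t = r, y_{t+1} = s \mid x_{1:T})} and the
#' log-likelihood computed by both recursions.
#'
#' @inheritParams hmm_loglik
#' @return A list with `gamma` (`T x N`), `xi` (`(T-1) x N x N` array),
#'   `loglik` and `loglik_backward`.
#' @export
hmm_forward_backward <- function(series, hmm) {
  validate_hmm(hmm)
  x <- series_obs(series, hmm$n_symbols)
  lp <- hmm_log_params(hmm)
  out <- hmm_forward_backward_cpp(x, lp$log_pi, lp$log_A, lp$log_B)
  if (!is.finite(out$loglik))
    stop("series has zero probability under the model; posteriors undefined")
  out
}

#' Viterbi decoding of the most likely state path
#'
#' Returns the jointly most probable state sequence
#' \eqn{y^*_{1:T} = \arg\max_{y_{1:T}} p(x_{1:T}, y_{1:T})} and its log joint
#' probability. Ties at any backtracking step are broken toward the lower
#' state index, so the decoded path is deterministic.
#'
#' @inheritParams hmm_loglik
#' @return An object of class `state_path`: list with `states` (integer
#'   vector in `1:N`) and `log_joint`.
#' @export
hmm_viterbi <- function(series, hmm) {
  validate_hmm(hmm)
  x <- series_obs(series, hmm$n_symbols)
  lp <- hmm_log_params(hmm)
  out <- hmm_viterbi_cpp(x, lp$log_pi, lp$log_A, lp$log_B)
  if (!is.finite(out$log_joint))
    stop("all state paths have probability zero for this series")
  structure(list(states = out$states + 1L, log_joint = out$log_joint),
            class = "state_path")
}

#' Expected emission value of each state
#'
#' The mean count \eqn{e_s = \sum_k k \, B_{sk}} emitted by each state; used
#' to order states and to attach qualitative utilization labels.
#'
#' @param hmm an [hmm()] object.
#' @return Numeric vector of length `N`.
#' @export
expected_emissions <- function(hmm) {
  as.numeric(hmm$emission %*% (seq_len(hmm$n_symbols) - 1))
}

#' Serialize an HMM to JSON
#'
#' @param hmm an [hmm()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
hmm_to_json <- function(hmm, path = NULL) {
  js <- jsonlite::toJSON(list(
    n_states = hmm$n_states, n_symbols = hmm$n_symbols,
    initial = hmm$initial, transition = hmm$transition,
    emission = hmm$emission), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read an HMM back from JSON
#'
#' @param path file path or JSON string produced by [hmm_to_json()].
#' @return An [hmm()] object.
#' @export
hmm_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  hmm(obj$initial, obj$transition, obj$emission)
}
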