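#' Construct a mixture of hidden Markov models
#'
#' The mixture assigns each whole series to a latent cluster \eqn{z} with
#' prior weights \eqn{w = p(z)}; conditional on \eqn{z} the series follows
#' the cluster-specific HMM. All components share the number of states `N`
#' and the count support size `K`.
#'
#' @param weights numeric vector of mixture weights, summing to 1.
#' @param components list of [hmm()] objects, one per cluster, all with the
#'   same `N` and `K`.
#' @return An object of class `mhmm`.
#' @export
mhmm <- function(weights, components) {
  weights <- as.numeric(weights)
  if (length(weights) != length(components))
    stop("one component per mixture weight required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6)
    stop("mixture weights must be non-negative and sum to 1")
  lapply(components, validate_hmm)
  Ns <- vapply(components, function(h) h$n_states, integer(1))
  Ks <- vapply(components, function(h) h$n_symbols, integer(1))
  if (length(unique(Ns)) != 1L || length(unique(Ks)) != 1L)
    stop("all components must share n_states and n_symbols")
  structure(list(weights = weights, components = components,
                 n_clusters = length(weights),
                 n_states = Ns[1L], n_symbols = Ks[1L]),
            class = "mhmm")
}

#' @export
print.mhmm <- function(x, ...) {
  cat(sprintf("Mixture of %d HMMs (%d states each, count support 0..%d)\n",
              x$n_clusters, x$n_states, x$n_symbols - 1L))
  cat("Weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

mhmm_log_params <- function(model) {
  list(log_w = log_clip(model$weights),
       log_pi = lapply(model$components, function(h) log_clip(h$initial)),
       log_A = lapply(model$components, function(h)
         matrix(log_clip(h$transition), h$n_states, h$n_states)),
       log_B = lapply(model$components, function(h)
         matrix(log_clip(h$emission), h$n_states, h$n_symbols)))
}

# Coerce a series collection to a list of checked integer vectors.
series_obs_list <- function(series, K) {
  if (inherits(series, "utilization_series")) series <- list(series)
  lapply(series, series_obs, K = K)
}

series_ids <- function(series) {
  ids <- vapply(seq_along(series), function(i) {
    s <- series[[i]]
    if (inherits(s, "utilization_series") && !is.null(s$claim_id))
      as.character(s$claim_id) else ""
  }, character(1))
  nm <- names(series)
  if (!is.null(nm)) ids[ids == ""] <- nm[ids == ""]
  ids[ids == ""] <- as.character(seq_along(series))[ids == ""]
  ids
}

#' E-step of the mixture EM
#'
#' Computes per-series cluster posteriors
#' \eqn{p(z = m \mid x_{1:T}) \propto w_m \, p(x_{1:T} \mid m)} and the
#' cluster-posterior-weighted expected counts (initial-state, transition and
#' emission occupancies) needed by the M-step.
#'
#' @param series list of count vectors or [utilization_series()] objects.
#' @param model an [mhmm()] object.
#' @param boundary use the boundary-truncated likelihood: the first and
#'   last months of a series are utilization months by construction, so
#'   their emissions are treated as zero-truncated draws (see
#'   [fit_mhmm()]).
#' @return List with `resp` (`n x M` responsibility matrix), `comp_loglik`
#'   (`n x M` per-component log-likelihoods), `loglik` (total mixture
#'   log-likelihood), and expected counts `init` (`M x N`), `trans` and
#'   `emit` (lists of `M` matrices).
#' @export
mhmm_e_step <- function(series, model, boundary = FALSE) {
  obs <- series_obs_list(series, model$n_symbols)
  out <- mhmm_estep_cpp(obs, model$weights,
                        lapply(model$components, `[[`, "initial"),
                        lapply(model$components, `[[`, "transition"),
                        lapply(model$components, `[[`, "emission"),
                        isTRUE(boundary))
  if (anyNA(out$resp)) {
    bad <- which(apply(is.na(out$resp), 1L, any))
    stop("series with zero probability under every component: ",
         paste(series_ids(series)[bad], collapse = ", "))
  }
  out
}

#' M-step of the mixture EM
#'
#' Maximum-likelihood updates from the expected counts: mixture weights,
#' initial vectors, transition rows and emission rows are each set to the
#' normalized expected counts. Emission rows receive a floor of `1e-10`
#' before renormalization so no observed count can acquire exactly zero
#' probability during fitting; empty transition/initial rows fall back to
#' uniform.
#'
#' @param stats expected counts as returned by [mhmm_e_step()].
#' @return An [mhmm()] object.
#' @export
mhmm_m_step <- function(stats) {
  if (is.null(stats$resp) || nrow(stats$resp) == 0L)
    stop("empty sufficient statistics")
  M <- ncol(stats$resp)
  w <- colSums(stats$resp)
  w <- w / sum(w)
  comps <- vector("list", M)
  for (m in seq_len(M)) {
    pi_m <- normalize_row(stats$init[m, ])
    A_m <- t(apply(stats$trans[[m]], 1L, normalize_row))
    B_m <- t(apply(stats$emit[[m]], 1L, normalize_row, floor = 1e-10))
    comps[[m]] <- hmm(pi_m, A_m, B_m)
  }
  mhmm(w, comps)
}

normalize_row <- function(v, floor = 0) {
  s <- sum(v)
  if (s <= 0) return(rep(1 / length(v), length(v)))
  v <- v / s
  if (floor > 0) {
    v <- v + floor
    v <- v / sum(v)
  }
  v
}

#' Total mixture log-likelihood
#'
#' \eqn{\sum_i \log \sum_m w_m \, p(x^{(i)}_{1:T_i} \mid m)}, the criterion
#' EM maximizes.
#'
#' @inheritParams mhmm_e_step
#' @return A single numeric value.
#' @export
mhmm_loglik <- function(series, model, boundary = FALSE) {
  obs <- series_obs_list(series, model$n_symbols)
  cl <- mhmm_comp_logliks(obs, model, boundary)
  lw <- sweep(cl, 2L, log_clip(model$weights), "+")
  sum(apply(lw, 1L, logsumexp_r))
}

mhmm_comp_logliks <- function(obs, model, boundary) {
  mhmm_comp_loglik_cpp(obs,
                       lapply(model$components, `[[`, "initial"),
                       lapply(model$components, `[[`, "transition"),
                       lapply(model$components, `[[`, "emission"),
                       isTRUE(boundary))
}

logsumexp_r <- function(v) {
  m <- max(v)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(v - m)))
}

#' Soft and hard cluster assignment of series
#'
#' @inheritParams mhmm_e_step
#' @return A data frame with one row per series: `claim_id`, posterior
#'   membership columns `p_1 ... p_M`, and `hard_label` (argmax, ties to the
#'   lower cluster index).
#' @export
assign_clusters <- function(series, model, boundary = FALSE) {
  obs <- series_obs_list(series, model$n_symbols)
  cl <- mhmm_comp_logliks(obs, model, boundary)
  lw <- sweep(cl, 2L, log_clip(model$weights), "+")
  lse <- apply(lw, 1L, logsumexp_r)
  if (any(!is.finite(lse)))
    stop("series with zero probability under every component: ",
         paste(series_ids(series)[!is.finite(lse)], collapse = ", "))
  post <- exp(sweep(lw, 1L, lse, "-"))
  out <- data.frame(claim_id = series_ids(series), stringsAsFactors = FALSE)
  for (m in seq_len(ncol(post))) out[[paste0("p_", m)]] <- post[, m]
  out$hard_label <- max.col(post, ties.method = "first")
  out
}

# Initialization: series are grouped by a per-series summary (k-means, one
# dimension) to seed the cluster split, and within each group the states
# are seeded on complementary bands of the group's count distribution
# (highest band first) so the utilization ladder is represented from the
# first iteration. Successive restarts alternate the grouping summary
# between the mean monthly count and an upper-quantile count (which
# isolates short bursts of very high utilization that the mean dilutes);
# randomness enters through jitter on all rows. Purely random
# initialization finds poor optima too often at M*N around 9.
mhmm_init <- function(obs, M, N, K, flavor = c("mean", "upper")) {
  flavor <- match.arg(flavor)
  n <- length(obs)
  means <- if (flavor == "mean") {
    vapply(obs, mean, numeric(1))
  } else {
    vapply(obs, stats::quantile, numeric(1), probs = 0.9, names = FALSE)
  }
  grp <- if (M == 1L) {
    rep(1L, n)
  } else if (length(unique(means)) >= M) {
    km <- suppressWarnings(stats::kmeans(means, centers = M, nstart = 5L))
    # order groups by center so cluster seeds are reproducible
    ord <- order(km$centers[, 1L], decreasing = TRUE)
    match(km$cluster, ord)
  } else {
    sample.int(M, n, replace = TRUE)
  }
  w <- tabulate(grp, M) + 1
  w <- w / sum(w)
  comps <- vector("list", M)
  support <- seq_len(K) - 1L
  for (m in seq_len(M)) {
    cnts <- unlist(obs[grp == m], use.names = FALSE)
    freq <- tabulate(cnts + 1L, K) + 0.25
    freq <- freq / sum(freq)
    # state s concentrates on the s-th band (top quantile band first) of
    # the group's counts, so states start on distinct utilization levels
    qs <- stats::quantile(cnts, probs = seq(1, 0, length.out = N + 1L),
                          names = FALSE, type = 1L)
    B <- matrix(0, N, K)
    for (s in seq_len(N)) {
      hi <- qs[s]; lo <- qs[s + 1L]
      band <- as.numeric(support >= lo & support <= max(hi, lo))
      band <- band * freq
      if (sum(band) <= 0) band <- freq
      tilt <- stats::rgamma(K, shape = 2)
      B[s, ] <- normalize_row(0.75 * band / sum(band) +
                                0.15 * freq + 0.10 * tilt / sum(tilt))
    }
    A <- matrix(stats::rgamma(N * N, shape = 2), N, N) + diag(N) * 4 * N
    A <- t(apply(A, 1L, normalize_row))
    # series open at a utilization month: favor the higher states first
    pi0 <- normalize_row(rev(seq_len(N))^2 + stats::rgamma(N, shape = 1))
    comps[[m]] <- hmm(pi0, A, B)
  }
  mhmm(w, comps)
}

# Reorder clusters by descending hard-assignment count (cluster 1 becomes
# the largest, matching the reference-cluster convention) and states within
# each cluster by descending expected emission value.
canonicalize_mhmm <- function(model, obs, boundary = FALSE) {
  asg <- assign_clusters(obs, model, boundary)
  sizes <- tabulate(asg$hard_label, model$n_clusters)
  ord <- order(-sizes, seq_len(model$n_clusters))
  comps <- model$components[ord]
  w <- model$weights[ord]
  comps <- lapply(comps, function(h) {
    sord <- order(-expected_emissions(h), seq_len(h$n_states))
    hmm(h$initial[sord], h$transition[sord, sord, drop = FALSE],
        h$emission[sord, , drop = FALSE])
  })
  mhmm(w / sum(w), comps)
}

#' Fit a mixture of HMMs by EM with restarts
#'
#' Runs the EM (Baum-Welch) algorithm jointly over all series: the E-step
#' computes soft cluster responsibilities and state occupancies, the M-step
#' re-estimates the mixture weights and every component's initial,
#' transition and emission distributions. The best of `restarts` random
#' initializations (by final log-likelihood) is returned. Clusters of the
#' returned model are relabeled in decreasing size order and states within
#' each cluster in decreasing expected-emission order, which resolves
#' label-switching deterministically.
#'
#' @param series list of count vectors or [utilization_series()] objects.
#' @param M number of mixture components (clusters).
#' @param N number of hidden states per component.
#' @param K count support size; counts take values in `0:(K-1)`. Default 25.
#' @param restarts number of random EM restarts (default 5).
#' @param tol relative log-likelihood improvement below which EM is declared
#'   converged (default `1e-6`).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param seed integer seed controlling initialization; the fit is a pure
#'   function of (`series`, arguments, `seed`).
#' @param boundary fit with the boundary-truncated likelihood (default
#'   `TRUE`). Aligned series start and end at a month with at least one
#'   utilization, so the first and last emissions are zero-truncated draws
#'   by construction; ignoring this biases the emission rows of
#'   low-utilization states. The truncated months contribute an augmented
#'   expected count of unobserved zeros (`B[s,0] / (1 - B[s,0])` per
#'   month), which keeps the M-step closed-form and the EM exactly
#'   monotone in the truncated likelihood.
#' @param verbose print per-restart progress.
#' @return An object of class `mhmm_fit`: list with `model` (the fitted,
#'   canonically ordered [mhmm()]), `loglik` (final total log-likelihood),
#'   `loglik_trace` of the winning restart, `n_iter`, `converged`,
#'   `restart_logliks`, `seed`, and `n_series`/`n_obs` bookkeeping.
#' @export
fit_mhmm <- function(series, M, N, K = 25L, restarts = 5L, tol = 1e-6,
                     max_iter = 500L, seed = 1L, boundary = TRUE,
                     verbose = FALSE) {
  stopifnot(M >= 1L, N >= 1L, K >= 2L, restarts >= 1L, max_iter >= 1L)
  obs <- series_obs_list(series, K)
  if (length(obs) < M)
    stop("need at least M series to fit M clusters")
  best <- NULL
  restart_ll <- rep(NA_real_, restarts)
  for (r in seq_len(restarts)) {
    set.seed(seed + 1000003L * (r - 1L))
    flavor <- if (r %% 2L == 1L) "mean" else "upper"
    fit <- tryCatch(
      em_single_run(obs, M, N, K, tol, max_iter, flavor, boundary),
      error = function(e) NULL)
    if (is.null(fit)) next
    restart_ll[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (verbose)
      message(sprintf("restart %d: loglik %.3f (%d iter%s)", r, fit$loglik,
                      fit$n_iter, if (fit$converged) ", converged" else ""))
  }
  if (is.null(best))
    stop("all EM restarts failed with non-finite log-likelihood")
  model <- canonicalize_mhmm(best$model, obs, boundary)
  structure(list(model = model, loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter,
                 converged = best$converged, restart_logliks = restart_ll,
                 seed = seed, boundary = boundary, n_series = length(obs),
                 n_obs = sum(lengths(obs))),
            class = "mhmm_fit")
}

em_single_run <- function(obs, M, N, K, tol, max_iter, flavor = "mean",
                          boundary = TRUE) {
  model <- mhmm_init(obs, M, N, K, flavor)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    st <- mhmm_e_step(obs, model, boundary)
    if (!is.finite(st$loglik)) stop("non-finite log-likelihood during EM")
    trace <- c(trace, st$loglik)
    if (is.finite(prev)) {
      rel <- (st$loglik - prev) / max(1, abs(prev))
      if (rel < tol) { converged <- TRUE; break }
    }
    prev <- st$loglik
    model <- mhmm_m_step(st)
  }
  list(model = model, loglik = trace[length(trace)], trace = trace,
       n_iter = it, converged = converged)
}

#' @export
print.mhmm_fit <- function(x, ...) {
  cat(sprintf(
    "MHMM fit: M=%d clusters, N=%d states, %d series (%d monthly obs)\n",
    x$model$n_clusters, x$model$n_states, x$n_series, x$n_obs))
  cat(sprintf("log-likelihood %.2f after %d EM iterations (%sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "not "))
  invisible(x)
}

#' Serialize a fitted mixture to JSON
#'
#' @param fit an `mhmm_fit` or [mhmm()] object.
#' @param path optional output path.
#' @return JSON string, invisibly when written to file.
#' @export
mhmm_to_json <- function(fit, path = NULL) {
  model <- if (inherits(fit, "mhmm_fit")) fit$model else fit
  js <- jsonlite::toJSON(list(
    n_clusters = model$n_clusters, n_states = model$n_states,
    n_symbols = model$n_symbols, weights = model$weights,
    components = lapply(model$components, function(h)
      list(initial = h$initial, transition = h$transition,
           emission = h$emission))), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a mixture back from JSON
#'
#' @param path file path or JSON string from [mhmm_to_json()].
#' @return An [mhmm()] object.
#' @export
mhmm_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_mat <- function(rows) do.call(rbind, lapply(rows, function(r) unlist(r)))
  comps <- lapply(obj$components, function(c)
    hmm(unlist(c$initial), as_mat(c$transition), as_mat(c$emission)))
  mhmm(unlist(obj$weights), comps)
}
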