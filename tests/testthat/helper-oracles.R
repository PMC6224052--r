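# Brute-force oracles for the HMM recursions: every quantity is computed by
# explicit enumeration over all N^T state paths, independently of the
# package's forward-backward / Viterbi code paths.

lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

all_paths <- function(T_len, N) {
  as.matrix(expand.grid(rep(list(seq_len(N)), T_len)))
}

path_log_joint <- function(x, h, path) {
  lp <- log(h$initial[path[1L]]) + log(h$emission[path[1L], x[1L] + 1L])
  for (t in seq_along(x)[-1L])
    lp <- lp + log(h$transition[path[t - 1L], path[t]]) +
      log(h$emission[path[t], x[t] + 1L])
  lp
}

enum_loglik <- function(x, h) {
  paths <- all_paths(length(x), h$n_states)
  lse(apply(paths, 1L, function(p) path_log_joint(x, h, p)))
}

enum_posteriors <- function(x, h) {
  T_len <- length(x); N <- h$n_states
  paths <- all_paths(T_len, N)
  lj <- apply(paths, 1L, function(p) path_log_joint(x, h, p))
  w <- exp(lj - lse(lj))
  gamma <- matrix(0, T_len, N)
  for (t in seq_len(T_len))
    for (s in seq_len(N))
      gamma[t, s] <- sum(w[paths[, t] == s])
  xi <- if (T_len > 1L) array(0, c(T_len - 1L, N, N)) else
    array(0, c(0L, N, N))
  for (t in seq_len(T_len - 1L))
    for (r in seq_len(N))
      for (s in seq_len(N))
        xi[t, r, s] <- sum(w[paths[, t] == r & paths[, t + 1L] == s])
  list(gamma = gamma, xi = xi, loglik = lse(lj))
}

enum_viterbi_logjoint <- function(x, h) {
  paths <- all_paths(length(x), h$n_states)
  max(apply(paths, 1L, function(p) path_log_joint(x, h, p)))
}

random_hmm <- function(N, K) {
  rrow <- function(n) { v <- stats::runif(n, 0.05, 1); v / sum(v) }
  hmm(rrow(N),
      t(vapply(seq_len(N), function(i) rrow(N), numeric(N))),
      t(vapply(seq_len(N), function(i) rrow(K), numeric(K))))
}

random_instance <- function(max_T = 6L, max_N = 3L, max_K = 5L) {
  N <- sample(1:max_N, 1L); K <- sample(2:max_K, 1L)
  T_len <- sample(1:max_T, 1L)
  h <- random_hmm(N, K)
  x <- sample(0:(K - 1L), T_len, replace = TRUE)
  list(x = x, h = h)
}

# independent per-point silhouette via the textbook double loop
brute_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(dm[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

brute_dunn <- function(dm, labels) {
  inter <- Inf; intra <- 0
  n <- nrow(dm)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      if (labels[i] == labels[j]) intra <- max(intra, dm[i, j])
      else inter <- min(inter, dm[i, j])
    }
  inter / intra
}
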