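make_series <- function(n, h, T_len, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    N <- h$n_states
    y <- integer(T_len); y[1] <- sample.int(N, 1, prob = h$initial)
    for (t in seq_len(T_len - 1))
      y[t + 1] <- sample.int(N, 1, prob = h$transition[y[t], ])
    vapply(y, function(s)
      sample(0:(h$n_symbols - 1L), 1, prob = h$emission[s, ]), integer(1))
  })
}

test_that("E-step posteriors behave in the degenerate mixtures", {
  set.seed(11)
  h <- random_hmm(2, 5)
  series <- make_series(20, h, 6, seed = 12)

  # single component: every posterior is 1
  st1 <- mhmm_e_step(series, mhmm(1, list(h)))
  expect_equal(as.numeric(st1$resp), rep(1, 20))

  # identical components: posteriors equal the mixture weights
  st2 <- mhmm_e_step(series, mhmm(c(0.7, 0.3), list(h, h)))
  expect_equal(st2$resp[, 1], rep(0.7, 20), tolerance = 1e-12)

  # disjoint emission supports: posteriors are exactly 0/1
  lo <- hmm(1, matrix(1), matrix(c(0.5, 0.5, 0, 0), 1))
  hi <- hmm(1, matrix(1), matrix(c(0, 0, 0.5, 0.5), 1))
  mix <- mhmm(c(0.5, 0.5), list(lo, hi))
  st3 <- mhmm_e_step(list(c(0L, 1L, 0L), c(2L, 3L)), mix)
  expect_equal(st3$resp, rbind(c(1, 0), c(0, 1)), ignore_attr = TRUE)

  # a series impossible under every component is reported by id
  expect_error(mhmm_e_step(list(c(0L, 2L)), mix), "zero probability")
})

test_that("M-step recovers supervised frequencies in the 1-state case", {
  x <- c(0L, 1L, 1L, 2L, 1L)
  h <- hmm(1, matrix(1), matrix(rep(1 / 3, 3), 1))
  st <- mhmm_e_step(list(x), mhmm(1, list(h)))
  up <- mhmm_m_step(st)
  expect_equal(as.numeric(up$components[[1]]$emission),
               c(1, 3, 1) / 5, tolerance = 1e-6)
  expect_error(mhmm_m_step(list(resp = matrix(numeric(0), 0, 1))),
               "empty")
})

test_that("one EM step never decreases the total log-likelihood", {
  set.seed(21)
  gen <- random_hmm(2, 6)
  series <- make_series(40, gen, 8, seed = 22)
  model <- mhmm(c(0.5, 0.5), list(random_hmm(2, 6), random_hmm(2, 6)))
  for (i in 1:10) {
    st <- mhmm_e_step(series, model)
    model2 <- mhmm_m_step(st)
    st2 <- mhmm_e_step(series, model2)
    expect_gte(st2$loglik, st$loglik - 1e-6)
    model <- model2
  }
})

test_that("total log-likelihood reduces and respects null weights", {
  set.seed(31)
  h <- random_hmm(2, 5)
  series <- make_series(10, h, 5, seed = 32)

  # M = 1 reduction to the sum of component log-likelihoods
  expect_equal(mhmm_loglik(series, mhmm(1, list(h))),
               sum(vapply(series, hmm_loglik, numeric(1), hmm = h)),
               tolerance = 1e-9)

  # hand log-sum-exp on a two-series, two-component toy
  h2 <- random_hmm(2, 5)
  mix <- mhmm(c(0.6, 0.4), list(h, h2))
  hand <- sum(vapply(series[1:2], function(x)
    lse(c(log(0.6) + hmm_loglik(x, h), log(0.4) + hmm_loglik(x, h2))),
    numeric(1)))
  expect_equal(mhmm_loglik(series[1:2], mix), hand, tolerance = 1e-9)

  # adding an impossible component with weight 0 changes nothing
  imp <- hmm(c(1, 0), rbind(c(1, 0), c(0, 1)),
             rbind(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)))
  mix0 <- mhmm(c(0.6, 0.4, 0), list(h, h2, imp))
  expect_equal(mhmm_loglik(series[1:2], mix0),
               mhmm_loglik(series[1:2], mix), tolerance = 1e-12)

  # permutation invariance
  expect_equal(mhmm_loglik(series, mhmm(c(0.4, 0.6), list(h2, h))),
               mhmm_loglik(series, mix), tolerance = 1e-9)
})

test_that("fit_mhmm converges, is deterministic, and orders clusters by size", {
  set.seed(41)
  lo <- hmm(c(0.9, 0.1), rbind(c(0.9, 0.1), c(0.1, 0.9)),
            rbind(c(0.7, 0.2, 0.1, 0, 0), c(0.3, 0.4, 0.3, 0, 0)))
  hi <- hmm(c(0.1, 0.9), rbind(c(0.8, 0.2), c(0.2, 0.8)),
            rbind(c(0, 0, 0.2, 0.4, 0.4), c(0, 0.1, 0.3, 0.3, 0.3)))
  series <- c(make_series(60, lo, 10, seed = 42),
              make_series(20, hi, 10, seed = 43))
  fit <- fit_mhmm(series, M = 2, N = 2, K = 5, restarts = 3, seed = 4)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_true(fit$converged)

  asg <- assign_clusters(series, fit$model, boundary = fit$boundary)
  sizes <- tabulate(asg$hard_label, 2)
  expect_true(sizes[1] >= sizes[2])  # cluster 1 is the largest

  fit2 <- fit_mhmm(series, M = 2, N = 2, K = 5, restarts = 3, seed = 4)
  expect_identical(fit$model, fit2$model)
  expect_identical(fit$loglik_trace, fit2$loglik_trace)

  # degenerate 1-cluster fit on 1-cluster data converges monotonically
  fit1 <- fit_mhmm(series[1:60], M = 1, N = 2, K = 5, restarts = 2, seed = 5)
  expect_true(all(diff(fit1$loglik_trace) >= -1e-6))
  expect_true(fit1$converged)
})

test_that("boundary-truncated likelihood only affects first and last months", {
  set.seed(51)
  h <- random_hmm(2, 5)
  mix <- mhmm(1, list(h))
  x <- c(1L, 0L, 2L, 0L, 3L)
  plain <- mhmm_loglik(list(x), mix, boundary = FALSE)
  trunc <- mhmm_loglik(list(x), mix, boundary = TRUE)
  # conditioning on positive boundary emissions raises the likelihood
  expect_gt(trunc, plain)
  # interior zeros are untouched: a series with boundary-only months
  x2 <- c(2L, 3L)
  hand <- {
    Bc <- h$emission[, -1] / (1 - h$emission[, 1])
    lse(log(h$initial) + log(Bc[, 2]) +
          apply(log(h$transition) + rep(log(Bc[, 3]), each = 2), 1, lse))
  }
  expect_equal(mhmm_loglik(list(x2), mix, boundary = TRUE), hand,
               tolerance = 1e-9)
})

test_that("mixture JSON serialization round-trips", {
  set.seed(61)
  mix <- mhmm(c(0.3, 0.7), list(random_hmm(2, 4), random_hmm(2, 4)))
  mix2 <- mhmm_from_json(mhmm_to_json(mix))
  expect_equal(mix2$weights, mix$weights, tolerance = 1e-12)
  expect_equal(mix2$components[[2]]$emission, mix$components[[2]]$emission,
               tolerance = 1e-12)
})
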