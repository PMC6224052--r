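test_that("default scenario is internally consistent", {
  scen <- default_scenario()
  expect_equal(sum(scen$true_model$weights), 1, tolerance = 1e-12)
  expect_equal(scen$true_model$weights, c(0.67, 0.27, 0.06))
  expect_identical(scen$length_dist$min, 2L)
  expect_identical(scen$length_dist$max, 106L)
  # mean series length close to the 29-month descriptive target
  expect_lt(abs(scenario_mean_length(scen) - 29), 1)
  # the nine states cover all five utilization labels
  expect_setequal(label_states(scen$true_model)$label,
                  c("zero", "low", "medium", "high", "very high"))
})

test_that("sampling is reproducible and respects the series invariants", {
  scen <- default_scenario()
  sim1 <- sample_mhmm(scen, 60, seed = 7)
  sim2 <- sample_mhmm(scen, 60, seed = 7)
  expect_identical(sim1, sim2)

  lens <- lengths(sim1$paths)
  expect_true(all(lens >= 2 & lens <= 106))
  for (s in sim1$series) {
    expect_gte(s$counts[1], 1)
    expect_gte(s$counts[length(s$counts)], 1)
    expect_true(all(s$counts < 25))
  }
  expect_identical(unname(lengths(lapply(sim1$series, `[[`, "counts"))), lens)
})

test_that("point-mass emissions make series readable from the state paths", {
  scen <- default_scenario()
  pm <- function(k, K = 25) { v <- numeric(K); v[k + 1] <- 1; v }
  comps <- lapply(list(c(3, 1, 2), c(5, 4, 6), c(9, 8, 7)), function(ks)
    hmm(c(1, 0, 0), matrix(1 / 3, 3, 3), do.call(rbind, lapply(ks, pm))))
  scen$true_model <- mhmm(c(0.67, 0.27, 0.06), comps)
  sim <- sample_mhmm(scen, 30, seed = 3)
  emitted <- list(c(3, 1, 2), c(5, 4, 6), c(9, 8, 7))
  for (i in seq_len(30)) {
    want <- emitted[[sim$labels[i]]][sim$paths[[i]]]
    expect_identical(sim$series[[i]]$counts, as.integer(want))
  }
})

test_that("cluster shares and empirical dynamics match the generative truth", {
  scen <- default_scenario()
  n <- 3000
  sim <- sample_mhmm(scen, n, seed = 17)
  shares <- tabulate(sim$labels, 3) / n
  for (m in 1:3) {
    w <- scen$true_model$weights[m]
    expect_lt(abs(shares[m] - w), 3 * sqrt(w * (1 - w) / n))
  }
  # mean length within 3 months of the analytic truncated mean
  expect_lt(abs(mean(lengths(sim$paths)) - scenario_mean_length(scen)), 3)

  # empirical transition frequencies from true paths converge to A (the
  # largest cluster gives the most transitions, so check it)
  A <- scen$true_model$components[[1]]$transition
  paths <- sim$paths[sim$labels == 1]
  counts <- matrix(0, 3, 3)
  for (p in paths)
    for (t in seq_len(length(p) - 1))
      counts[p[t], p[t + 1]] <- counts[p[t], p[t + 1]] + 1
  Ahat <- counts / rowSums(counts)
  expect_lt(max(rowSums(abs(Ahat - A))), 0.05)

  # empirical emission frequencies per true state converge to B away from
  # the truncated boundary months
  B <- scen$true_model$components[[1]]$emission
  emit <- matrix(0, 3, 25)
  series <- sim$series[sim$labels == 1]
  for (i in seq_along(paths)) {
    p <- paths[[i]]; x <- series[[i]]$counts
    Tl <- length(p)
    if (Tl <= 2) next
    for (t in 2:(Tl - 1)) emit[p[t], x[t] + 1] <- emit[p[t], x[t] + 1] + 1
  }
  Bhat <- emit / rowSums(emit)
  expect_lt(max(rowSums(abs(Bhat - B))), 0.05)
})

test_that("null covariate effects leave covariates independent of labels", {
  scen <- default_scenario()
  scen$covariate_effects[] <- 0
  labels <- sample.int(3, 2500, replace = TRUE,
                       prob = scen$true_model$weights)
  cov <- sample_covariates(labels, scen, seed = 23)
  for (v in c("gender", "age_group", "role", "brain_head")) {
    p <- suppressWarnings(stats::chisq.test(table(cov[[v]], labels))$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("a single strong binary effect is recovered from the sampled table", {
  scen <- default_scenario()
  scen$covariate_effects[] <- 0
  scen$covariate_effects["cluster2", "brain_head"] <- 2.0
  set.seed(29)
  labels <- sample.int(2, 4000, replace = TRUE, prob = c(0.6, 0.4))
  cov <- sample_covariates(labels, scen, seed = 31)
  tab <- table(cov$brain_head, labels)
  lor <- log(tab["1", "2"] * tab["0", "1"] / (tab["0", "2"] * tab["1", "1"]))
  expect_lt(abs(lor - 2.0), 0.2)

  cov2 <- sample_covariates(labels, scen, seed = 31)
  expect_identical(cov, cov2)
})

test_that("degenerate scenarios are rejected", {
  scen <- default_scenario()
  expect_error(mhmm(c(0.7, 0.4, -0.1), scen$true_model$components),
               "non-negative")
})
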