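test_that("padding and distances follow the zero-fill convention", {
  m <- pad_series(list(a = c(1, 2), b = c(1, 2, 3)))
  expect_equal(unname(m), rbind(c(1, 2, 0), c(1, 2, 3)))
  expect_equal(as.numeric(series_dist(m)), 3)
  expect_equal(as.numeric(series_dist(pad_series(list(c(1, 2), c(1, 2))))), 0)

  set.seed(41)
  series <- lapply(1:15, function(i) sample(0:6, sample(2:8, 1), TRUE))
  m2 <- pad_series(series)
  dm <- as.matrix(series_dist(m2))
  for (i in 1:14) for (j in (i + 1):15)
    expect_equal(dm[i, j], sqrt(sum((m2[i, ] - m2[j, ])^2)),
                 tolerance = 1e-12)
  expect_true(isSymmetric(dm))
  expect_true(all(diag(dm) == 0))
})

test_that("PAM recovers the two obvious pairs and saturates at M = n", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- stats::dist(x)
  fit <- pam_series(d, 2)
  expect_equal(fit$labels[1], fit$labels[2])
  expect_equal(fit$labels[3], fit$labels[4])
  expect_true(fit$labels[1] != fit$labels[3])
  # brute force over all medoid pairs confirms the optimum
  dm <- as.matrix(d)
  costs <- combn(4, 2, function(md) sum(apply(dm[, md], 1, min)))
  expect_equal(sum(apply(dm[, fit$medoids], 1, min)), min(costs))

  fit4 <- pam_series(d, 4)
  expect_equal(sort(fit4$medoids), 1:4)  # every point its own medoid
})

test_that("CLARA with a full-data sample reduces to PAM", {
  set.seed(51)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 8), ncol = 2))
  pam_fit <- pam_series(stats::dist(x), 2)
  clara_fit <- clara_series(x, 2, sample_size = nrow(x), n_samples = 1,
                            seed = 1)
  expect_equal(clara_fit$labels, pam_fit$labels)
  # determinism under a fixed seed
  expect_identical(clara_series(x, 2, 10, 3, seed = 9),
                   clara_series(x, 2, 10, 3, seed = 9))
})

test_that("FCM memberships are normalized, symmetric and monotone", {
  # symmetric 1-D configuration: the midpoint has membership 1/2
  x <- matrix(c(-10, -10, -9, 9, 10, 10, 0), ncol = 1)
  fit <- fcm_series(x, 2, seed = 3)
  expect_equal(rowSums(fit$membership), rep(1, 7), tolerance = 1e-9)
  expect_equal(unname(fit$membership[7, 1]), 0.5, tolerance = 0.05)
  # a point at a center has membership ~1 for that cluster
  expect_gt(max(fit$membership[1, ]), 0.95)
  # alternating optimization never increases the objective
  set.seed(4)
  y <- matrix(rnorm(60), ncol = 2)
  fit2 <- fcm_series(y, 3, seed = 5)
  expect_true(all(diff(fit2$objective) <= 1e-8))
})

test_that("silhouette summary and Dunn match hand values and brute force", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- stats::dist(x)
  lab <- c(1, 1, 2, 2)
  s <- silhouette_summary(d, lab)
  w <- attr(s, "widths")
  expect_equal(sort(unique(round(w, 4))), c(0.8947, 0.9048))
  expect_equal(unname(s["mean"]), 0.89974, tolerance = 1e-4)
  expect_equal(dunn_index(d, lab), 9)

  # perfect-separation limit: all widths near 1
  x2 <- matrix(c(0, 0, 100, 100.5), ncol = 1)
  w2 <- attr(silhouette_summary(stats::dist(x2), c(1, 1, 2, 2)), "widths")
  expect_true(all(w2 > 0.99))

  set.seed(61)
  for (rep in 1:5) {
    y <- matrix(rnorm(36), ncol = 2)
    labs <- sample(1:3, 18, replace = TRUE)
    if (length(unique(labs)) < 2) next
    dm <- as.matrix(stats::dist(y))
    ss <- silhouette_summary(stats::dist(y), labs)
    expect_equal(sort(attr(ss, "widths")), sort(brute_silhouette(dm, labs)),
                 tolerance = 1e-10)
    expect_equal(dunn_index(stats::dist(y), labs), brute_dunn(dm, labs),
                 tolerance = 1e-10)
  }

  # degenerate: zero-diameter clusters flag an infinite Dunn index
  x3 <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_warning(dz <- dunn_index(stats::dist(x3), c(1, 1, 2, 2)),
                 "infinite")
  expect_identical(dz, Inf)
})

test_that("classical MDS reproduces Euclidean configurations", {
  set.seed(71)
  pts <- matrix(rnorm(24), ncol = 2)
  xy <- mds_2d(stats::dist(pts))
  expect_equal(as.numeric(stats::dist(xy)), as.numeric(stats::dist(pts)),
               tolerance = 1e-6)
  # collinear points embed on one axis with distances 5, 5, 10
  xy2 <- mds_2d(stats::dist(matrix(c(0, 5, 10), ncol = 1)))
  expect_equal(sort(as.numeric(stats::dist(xy2))), c(5, 5, 10),
               tolerance = 1e-9)
  expect_lt(max(abs(xy2[, 2])), 1e-6)
  # identical points collapse to the origin
  xy3 <- mds_2d(stats::dist(matrix(0, 4, 2)))
  expect_lt(max(abs(xy3)), 1e-9)
  # sign canonicalization makes the embedding deterministic
  expect_identical(mds_2d(stats::dist(pts)), xy)
})

test_that("the method comparison reports a coherent validation table", {
  scen <- default_scenario()
  sim <- sample_mhmm(scen, 120, seed = 81)
  v <- compare_clusterings(sim$series, sim$labels, M = 3, seed = 81)
  expect_setequal(rownames(v$sizes), c("MHMM", "PAM", "CLARA", "FCM"))
  expect_true(all(rowSums(v$sizes) == 120))
  expect_true(all(v$silhouette >= -1 & v$silhouette <= 1))
  expect_true(all(v$dunn >= 0))
  expect_equal(dim(v$mds), c(120L, 2L))
  # every baseline partition is relabeled largest-first
  for (m in rownames(v$sizes))
    expect_true(all(diff(v$sizes[m, ]) <= 0))
})
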