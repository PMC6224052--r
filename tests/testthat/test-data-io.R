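events_df <- function(ids, dates, cat = "psychology") {
  data.frame(claim_id = ids, service_date = dates,
             category_l1 = "health", category_l2 = "allied",
             category_l3 = cat, stringsAsFactors = FALSE)
}

test_that("events aggregate by calendar month with zero-filled gaps", {
  ev <- events_df("A", c("2009-03-05", "2009-03-20", "2009-05-02"))
  out <- build_series(ev)
  expect_length(out, 1)
  expect_identical(out$A$counts, c(2L, 0L, 1L))
  expect_equal(out$A$start_month, as.Date("2009-03-01"))

  # a single-event claim yields a length-1 series, dropped at min_length 2
  ev2 <- rbind(ev, events_df("B", "2009-07-10"))
  expect_message(out2 <- build_series(ev2, min_length = 2),
                 "shorter than 2 months")
  expect_named(out2, "A")
  out3 <- build_series(ev2, min_length = 1)
  expect_identical(out3$B$counts, 1L)
})

test_that("aggregation matches an independent group-by recount", {
  set.seed(101)
  n_ev <- 400
  ids <- sample(sprintf("C%02d", 1:12), n_ev, replace = TRUE)
  dates <- as.Date("2009-01-01") + sample(0:700, n_ev, replace = TRUE)
  ev <- events_df(ids, as.character(dates))
  out <- build_series(ev, min_length = 1)

  for (id in unique(ids)) {
    d <- dates[ids == id]
    mo <- format(d, "%Y-%m")
    oracle <- table(mo)
    s <- out[[id]]
    # conservation: total counts equal the number of events for the claim
    expect_equal(sum(s$counts), length(d))
    # month-by-month equality against the group-by oracle
    months <- format(seq(s$start_month, by = "month",
                         length.out = length(s$counts)), "%Y-%m")
    got <- stats::setNames(s$counts, months)
    expect_equal(unname(got[names(oracle)]), as.integer(oracle))
    expect_true(all(got[setdiff(months, names(oracle))] == 0))
  }
})

test_that("bad dates and unknown categories degrade with warnings", {
  ev <- rbind(events_df("A", c("2009-03-05", "not-a-date", "2009-04-02")))
  expect_warning(out <- build_series(ev, min_length = 1), "unparseable")
  expect_equal(sum(out$A$counts), 2)
  expect_warning(out2 <- build_series(events_df("A", "2009-01-01"),
                                      category = "nope"),
                 "no events")
  expect_length(out2, 0)
})

test_that("counts at or above the support are clipped with a warning", {
  ev <- events_df(rep("A", 30),
                  c(rep("2009-01-10", 28), "2009-01-11", "2009-02-01"))
  expect_warning(out <- build_series(ev, K = 25), "clipped")
  expect_identical(out$A$counts, c(24L, 1L))
})

test_that("series CSV round-trips bit-identically", {
  set.seed(7)
  scen <- default_scenario()
  sim <- sample_mhmm(scen, 12, seed = 7)
  path <- file.path(tempdir(), "series-roundtrip.csv")
  write_series_csv(sim$series, path)
  back <- read_series_csv(path)
  expect_identical(lapply(back, `[[`, "counts"),
                   lapply(sim$series, `[[`, "counts"))
  expect_true(file.exists(paste0(path, ".json")))
  # second write from the re-read series is byte-identical
  path2 <- file.path(tempdir(), "series-roundtrip2.csv")
  write_series_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("elapsed time is the day difference in Julian years", {
  expect_equal(compute_elapsed_time("2009-05-01", "2009-05-01"), 0)
  expect_equal(compute_elapsed_time("2008-01-01", "2009-01-01"),
               366 / 365.25)  # 2008 is a leap year
  set.seed(13)
  a <- as.Date("2009-01-01") + sample(0:1000, 50, replace = TRUE)
  f <- a + sample(0:2000, 50, replace = TRUE)
  expect_equal(compute_elapsed_time(a, f), as.numeric(f - a) / 365.25)
  expect_error(compute_elapsed_time("2009-05-01", "2009-04-30"), "precedes")
})

test_that("the coverage filter keeps covariates by minority-level share", {
  set.seed(17)
  n <- 200
  cov <- data.frame(
    claim_id = seq_len(n),
    rare_flag = rep(c(1, 0), c(10, n - 10)),          # 5%: dropped
    brain_head = rep(c(1, 0), c(48, n - 48)),         # 24%: retained
    gender = rep(c("male", "female"), c(96, n - 96)), # balanced: retained
    constant = 1)
  expect_message(kept <- filter_covariates(cov, threshold = 0.10), "dropped")
  expect_setequal(kept, c("brain_head", "gender"))
  shares <- attr(kept, "level_shares")
  expect_equal(unname(shares$brain_head["1"]), 0.24)
  expect_error(filter_covariates(cov[0, ]), "empty")

  # hand-counted synthetic shares drive retention exactly
  cov2 <- data.frame(claim_id = 1:100, f1 = rep(c(1, 0), c(9, 91)),
                     f2 = rep(c(1, 0), c(10, 90)))
  kept2 <- suppressMessages(filter_covariates(cov2, threshold = 0.10))
  expect_setequal(kept2, "f2")
})
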