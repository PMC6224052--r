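toy_covariates <- function() {
  data.frame(
    claim_id = 1:5,
    gender = c("male", "female", "male", "female", "male"),
    age_group = c("<30", "30-40", ">60", "<30", "50-60"),
    role = c("pedestrian", "driver", "witness", "cyclist", "pedestrian"),
    brain_head = c(1, 0, 0, 1, 0),
    soft_tissue = c(0, 1, 1, 0, 0),
    non_limb_fractures = c(0, 0, 1, 0, 1),
    elapsed_time_years = c(0.5, 1.2, 0, 2.5, 0.1),
    stringsAsFactors = FALSE)
}

test_that("covariate encoding uses the stated reference levels", {
  cov <- toy_covariates()
  spec <- regression_spec()
  enc <- encode_covariates(cov, spec$models$model4, spec)
  X <- enc$design
  # pedestrian and <30 rows have all role/age dummies zero
  role_cols <- grep("^role", colnames(X))
  age_cols <- grep("^age_group", colnames(X))
  expect_true(all(X[1, role_cols] == 0))
  expect_true(all(X[1, age_cols] == 0))
  expect_true(all(X[5, role_cols] == 0))
  # hand encoding of row 3: male, >60, witness, soft tissue + nlf
  expect_equal(unname(X[3, "gendermale"]), 1)
  expect_equal(unname(X[3, "age_group>60"]), 1)
  expect_equal(unname(X[3, "rolewitness"]), 1)
  expect_equal(unname(X[3, "brain_head"]), 0)
  expect_equal(unname(X[3, "elapsed_time_years"]), 0)
  expect_equal(sum(X[, "(Intercept)"]), 5)

  # unknown / missing values drop the row (complete-case)
  cov$gender[2] <- "unknown"
  enc2 <- encode_covariates(cov, spec$models$model1, spec)
  expect_equal(enc2$n_dropped, 1L)
  expect_equal(nrow(enc2$design), 4)
})

test_that("intercept-only fits reproduce log share ratios", {
  labels <- rep(1:3, c(600, 300, 100))
  cov <- data.frame(claim_id = seq_along(labels))
  fit <- fit_multinomial(labels, cov, character(0))
  co <- fit$coefficients
  expect_equal(co$estimate[co$cluster == 2], log(300 / 600),
               tolerance = 1e-6)
  expect_equal(co$estimate[co$cluster == 3], log(100 / 600),
               tolerance = 1e-6)
  expect_equal(fit$reference_cluster, 1L)
})

test_that("significance stars follow the p-value thresholds", {
  expect_identical(significance_stars(c(0.005, 0.03, 0.07, 0.5)),
                   c("***", "**", "*", ""))
  expect_error(significance_stars(1.5))
})

test_that("separation and collinearity are reported as errors", {
  set.seed(91)
  n <- 120
  cov <- data.frame(claim_id = 1:n,
                    brain_head = rep(c(1, 0), each = n / 2),
                    soft_tissue = rep(c(1, 0), each = n / 2))
  labels <- rep(c(2, 1), each = n / 2)  # perfectly separated by the flag
  expect_error(fit_multinomial(labels, cov, "brain_head"), "separation")
  expect_error(fit_multinomial(sample(labels), cov,
                               c("brain_head", "soft_tissue")),
               "collinear")
})

test_that("the nested model suite is ordered and Table-3 shaped", {
  scen <- default_scenario()
  set.seed(95)
  labels <- sample.int(3, 900, replace = TRUE,
                       prob = scen$true_model$weights)
  cov <- sample_covariates(labels, scen, seed = 96)
  suite <- model_suite(labels, cov)
  expect_named(suite, paste0("model", 1:4))
  lls <- vapply(suite, `[[`, numeric(1), "loglik")
  expect_true(all(diff(lls) >= -1e-6))  # nested models on identical cases
  expect_true(all(vapply(suite, `[[`, integer(1), "n") == suite$model1$n))

  tab <- format_regression_table(suite)
  expect_true(all(grepl("^[23]:", rownames(tab))))
  expect_true(any(grepl("rolewitness", rownames(tab))))
  expect_false(any(grepl("pedestrian", rownames(tab))))  # reference level
  expect_false(any(grepl("<30", rownames(tab))))
  # models 1-3 leave the role rows blank; model 4 fills them
  expect_equal(unname(tab["2:rolewitness", "model1"]), "")
  expect_match(tab["2:rolewitness", "model4"], "\\(")
  long <- regression_suite_table(suite)
  expect_setequal(unique(long$model), paste0("model", 1:4))
  expect_true(all(c("estimate", "std_error", "p_value", "stars")
                  %in% names(long)))
})

test_that("fitted class probabilities sum to one with zero reference coefficients", {
  labels <- rep(1:2, c(70, 50))
  set.seed(99)
  cov <- data.frame(claim_id = 1:120,
                    elapsed_time_years = stats::rgamma(120, 1.2, 1.2))
  fit <- fit_multinomial(labels, cov, "elapsed_time_years")
  pr <- stats::predict(fit$fit, type = "probs")
  expect_equal(unname(pr + (1 - pr)), rep(1, 120))  # binary case sanity
  expect_true(all(fit$coefficients$cluster == 2))   # reference has no rows
  expect_true(all(fit$coefficients$std_error > 0))
})
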