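#' Specification of the cluster-membership regression suite
#'
#' Encodes the analysis conventions: the reference cluster is the largest
#' one; reference covariate levels are female (gender), under-30 (age
#' group) and pedestrian (role); and four nested covariate sets are fitted:
#' Model 1 demographics (gender, age group), Model 2 adds the injury flags
#' (brain head, soft tissue, non-limb fractures), Model 3 adds elapsed time
#' from accident to first utilization, Model 4 adds the road-user role.
#'
#' @param gender_levels,age_levels,role_levels factor level orders, the
#'   reference level first.
#' @param injury_vars names of the binary injury columns used from Model 2
#'   on.
#' @return Object of class `regression_spec`.
#' @export
regression_spec <- function(
    gender_levels = c("female", "male"),
    age_levels = c("<30", "30-40", "40-50", "50-60", ">60"),
    role_levels = c("pedestrian", "driver", "passenger", "cyclist", "witness"),
    injury_vars = c("brain_head", "soft_tissue", "non_limb_fractures")) {
  models <- list(
    model1 = c("gender", "age_group"),
    model2 = c("gender", "age_group", injury_vars),
    model3 = c("gender", "age_group", injury_vars, "elapsed_time_years"),
    model4 = c("gender", "age_group", injury_vars, "elapsed_time_years",
               "role"))
  structure(list(gender_levels = gender_levels, age_levels = age_levels,
                 role_levels = role_levels, injury_vars = injury_vars,
                 models = models),
            class = "regression_spec")
}

#' Encode claimant covariates as a model frame and design matrix
#'
#' Binary covariates become 0/1 indicators against their alternative;
#' categorical covariates are dummy-coded against the spec's reference
#' level; elapsed time stays numeric. Rows with a missing (or `"unknown"`)
#' value in any requested covariate are dropped (complete-case analysis)
#' and counted in the `n_dropped` attribute.
#'
#' @param covariates data frame as produced by [sample_covariates()] (or
#'   real claims covariates with the same column names).
#' @param vars covariate names to include (e.g. one of
#'   `regression_spec()$models`).
#' @param spec a [regression_spec()].
#' @return List with `frame` (model frame of releveled factors/numerics),
#'   `design` (the dummy-coded matrix including intercept) and `kept`
#'   (logical row filter applied to `covariates`).
#' @export
encode_covariates <- function(covariates, vars, spec = regression_spec()) {
  stopifnot(is.data.frame(covariates), all(vars %in% names(covariates)))
  if (length(vars) == 0L) {  # intercept-only model
    return(list(frame = data.frame(row.names = seq_len(nrow(covariates))),
                design = matrix(1, nrow(covariates), 1L,
                                dimnames = list(NULL, "(Intercept)")),
                kept = rep(TRUE, nrow(covariates)), n_dropped = 0L))
  }
  df <- covariates[, vars, drop = FALSE]
  if ("gender" %in% vars)
    df$gender <- factor(df$gender, levels = spec$gender_levels)
  if ("age_group" %in% vars)
    df$age_group <- factor(df$age_group, levels = spec$age_levels)
  if ("role" %in% vars)
    df$role <- factor(df$role, levels = spec$role_levels)
  for (v in intersect(spec$injury_vars, vars))
    df[[v]] <- as.numeric(df[[v]])
  is_missing <- function(col) is.na(col) | (is.character(col) & col == "unknown")
  kept <- !Reduce(`|`, lapply(df, is_missing))
  df <- df[kept, , drop = FALSE]
  design <- stats::model.matrix(~ ., data = df)
  list(frame = df, design = design,
       kept = kept, n_dropped = sum(!kept))
}

#' Multinomial logistic regression of cluster membership
#'
#' Fits one logit model per non-reference cluster against the reference
#' (the largest cluster unless overridden) by maximum likelihood via
#' [nnet::multinom()]. Standard errors come from the observed information;
#' p-values are two-sided Wald tests.
#'
#' @param labels integer (or factor) hard cluster labels, one per row of
#'   `covariates`.
#' @param covariates claimant covariate data frame.
#' @param vars covariate names to model.
#' @param spec a [regression_spec()].
#' @param reference_cluster reference label; default the most frequent.
#' @return Object of class `cluster_regression`: list with `coefficients`
#'   (long data frame: cluster, term, estimate, std_error, z, p_value,
#'   stars), `loglik`, `n`, `reference_cluster`, `fit` (the underlying
#'   `multinom` object) and `vars`.
#' @export
fit_multinomial <- function(labels, covariates, vars, spec = regression_spec(),
                            reference_cluster = NULL) {
  labels <- as.integer(as.character(factor(labels)))
  stopifnot(length(labels) == nrow(covariates))
  if (length(unique(labels)) < 2L)
    stop("at least two clusters are required")
  if (is.null(reference_cluster)) {
    tab <- table(labels)
    reference_cluster <- as.integer(names(tab)[which.max(tab)])
  }
  enc <- encode_covariates(covariates, vars, spec)
  y <- labels[enc$kept]
  lev <- c(reference_cluster, sort(setdiff(unique(y), reference_cluster)))
  resp <- factor(y, levels = lev)
  # rank check on the dummy-coded design
  qr_d <- qr(enc$design)
  if (qr_d$rank < ncol(enc$design)) {
    drop_cols <- colnames(enc$design)[qr_d$pivot[(qr_d$rank + 1L):ncol(enc$design)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  dat <- cbind(data.frame(.cluster = resp), enc$frame)
  form <- if (ncol(enc$frame)) .cluster ~ . else .cluster ~ 1
  fit <- nnet::multinom(form, data = dat, trace = FALSE,
                        maxit = 1000, reltol = 1e-14)
  sm <- summary(fit)
  co <- sm$coefficients; se <- sm$standard.errors
  if (is.null(dim(co))) {  # two-cluster case: multinom returns vectors
    co <- matrix(co, nrow = 1, dimnames = list(lev[2L], names(co)))
    se <- matrix(se, nrow = 1, dimnames = list(lev[2L], colnames(co)))
  }
  div_cols <- colnames(co)[apply(abs(co) > 15, 2L, any)]
  div_cols <- setdiff(div_cols, "(Intercept)")
  if (length(div_cols)) {
    # true perfect separation: the response is constant within a level of
    # the predictor; sparse cells (some cluster unobserved at a level)
    # only inflate that coefficient's standard error and are kept
    X <- enc$design
    separating <- vapply(div_cols, function(j) {
      v <- X[, j]
      lv <- unique(v)
      length(lv) <= 2L &&
        all(vapply(lv, function(l) length(unique(y[v == l])) == 1L,
                   logical(1)))
    }, logical(1))
    if (any(separating))
      stop("perfect separation by covariate(s): ",
           paste(div_cols[separating], collapse = ", "))
    warning("sparse cells give quasi-separated coefficient(s) with ",
            "inflated standard errors: ",
            paste(div_cols, collapse = ", "))
  }
  z <- co / se
  p <- 2 * stats::pnorm(-abs(z))
  long <- do.call(rbind, lapply(rownames(co), function(cl)
    data.frame(cluster = as.integer(cl), term = colnames(co),
               estimate = co[cl, ], std_error = se[cl, ], z = z[cl, ],
               p_value = p[cl, ], stars = significance_stars(p[cl, ]),
               row.names = NULL, stringsAsFactors = FALSE)))
  structure(list(coefficients = long, loglik = as.numeric(stats::logLik(fit)),
                 n = length(y), n_dropped = enc$n_dropped,
                 reference_cluster = reference_cluster, vars = vars,
                 fit = fit),
            class = "cluster_regression")
}

#' Significance stars for Wald p-values
#'
#' `"***"` below 0.01, `"**"` below 0.05, `"*"` below 0.1, otherwise empty.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- character(length(p))
  out[p < 0.1] <- "*"
  out[p < 0.05] <- "**"
  out[p < 0.01] <- "***"
  out
}

#' Fit the four nested membership models
#'
#' One [fit_multinomial()] per covariate set of the [regression_spec()],
#' all on the complete cases of the largest (Model 4) covariate set so the
#' four log-likelihoods are comparable.
#'
#' @inheritParams fit_multinomial
#' @return Object of class `regression_suite`: named list of
#'   `cluster_regression` fits plus attributes `spec` and
#'   `reference_cluster`.
#' @export
model_suite <- function(labels, covariates, spec = regression_spec(),
                        reference_cluster = NULL) {
  all_vars <- spec$models[[length(spec$models)]]
  enc <- encode_covariates(covariates, all_vars, spec)
  labels <- labels[enc$kept]
  covariates <- covariates[enc$kept, , drop = FALSE]
  fits <- lapply(spec$models, function(vars)
    fit_multinomial(labels, covariates, vars, spec, reference_cluster))
  structure(fits, class = "regression_suite", spec = spec,
            reference_cluster = fits[[1L]]$reference_cluster)
}

#' Render a regression suite as an aligned coefficient table
#'
#' One row per (non-reference cluster, covariate) pair, prefixed
#' `"2:"`/`"3:"` by cluster, with `estimate(std error)` and significance
#' stars, one column per model; covariates absent from a model are blank.
#'
#' @param suite a `regression_suite` from [model_suite()].
#' @return Character matrix (rows: cluster-prefixed terms; columns:
#'   models), printed with [print.regression_suite()].
#' @export
format_regression_table <- function(suite) {
  stopifnot(inherits(suite, "regression_suite"))
  terms <- unique(unlist(lapply(suite, function(f) f$coefficients$term)))
  clusters <- sort(unique(suite[[length(suite)]]$coefficients$cluster))
  rows <- as.vector(t(outer(terms, clusters, function(tm, cl)
    paste0(cl, ":", tm))))
  out <- matrix("", nrow = length(rows), ncol = length(suite),
                dimnames = list(rows, names(suite)))
  for (j in seq_along(suite)) {
    cf <- suite[[j]]$coefficients
    key <- paste0(cf$cluster, ":", cf$term)
    out[key[key %in% rows], j] <- sprintf("%.2f%s(%.2f)", cf$estimate,
                                          cf$stars, cf$std_error)[key %in% rows]
  }
  out
}

#' @export
print.regression_suite <- function(x, ...) {
  cat(sprintf("Multinomial logistic regression (reference cluster %d)\n",
              attr(x, "reference_cluster")))
  print(format_regression_table(x), quote = FALSE)
  cat("Note: *p<0.1; **p<0.05; ***p<0.01\n")
  invisible(x)
}

#' Long-format export of a regression suite
#'
#' @param suite a `regression_suite`.
#' @param path optional CSV path.
#' @return Data frame with columns `model`, `cluster`, `term`, `estimate`,
#'   `std_error`, `p_value`, `stars`.
#' @export
regression_suite_table <- function(suite, path = NULL) {
  out <- do.call(rbind, lapply(names(suite), function(nm) {
    cf <- suite[[nm]]$coefficients
    cbind(model = nm, cf[, c("cluster", "term", "estimate", "std_error",
                             "p_value", "stars")])
  }))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
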