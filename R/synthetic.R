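#' Default synthetic scenario emulating transport-accident claims data
#'
#' Defines the generative truth used throughout testing: a 3-cluster,
#' 3-state mixture over monthly psychology-service counts with mixture
#' weights (0.67, 0.27, 0.06); series lengths from cluster-specific shifted,
#' truncated negative binomials with support 2..106 months and overall mean
#' about 29; and claimant covariates whose link to cluster membership
#' follows a known multinomial-logit coefficient matrix, so regression
#' recovery is well-posed.
#'
#' Cluster 1 ("brief") moves quickly from a medium-utilization state through
#' low to an absorbing-like zero state; cluster 2 ("intermediate") starts
#' high and decays more slowly; cluster 3 ("sustained") holds very-high and
#' high states for most of the observation window. Emission rows over
#' counts 0..24 mix three shapes chosen for the regime they describe:
#' active-treatment states of the brief cluster are zero-truncated Poisson
#' (a month in care has at least one visit, hurdle-style), moderate states
#' are Poisson, and the sustained cluster's high regimes are binomial
#' (visits capped by monthly appointment capacity, hence narrower than
#' Poisson). The nine states span the five qualitative utilization levels
#' (zero, low, medium, high, very high).
#'
#' @return Object of class `mhmm_scenario`: list with `true_model`
#'   ([mhmm()]), `length_dist` (per-cluster shifted negative binomial
#'   specification, truncated to 2..106), `covariate_margins`,
#'   `covariate_effects` (2 x 14 coefficient matrix for clusters 2 and 3
#'   against cluster 1), and `elapsed_dist`.
#' @export
default_scenario <- function() {
  K <- 25L
  pois_row <- function(mu) {
    p <- stats::dpois(0:(K - 1L), mu)
    p / sum(p)
  }
  tpois_row <- function(mu) {
    p <- stats::dpois(0:(K - 1L), mu)
    p[1L] <- 0
    p / sum(p)
  }
  bin_row <- function(mu) stats::dbinom(0:(K - 1L), K - 1L, mu / (K - 1L))
  comp <- function(rows, pi0, A) hmm(pi0, A, do.call(rbind, rows))
  components <- list(
    # brief: medium -> low -> zero, fast decay; in-care states hurdle-style
    comp(list(tpois_row(4.0), tpois_row(1.2), pois_row(0.3)), c(1, 0, 0),
         rbind(c(0.500, 0.480, 0.020),
               c(0.030, 0.620, 0.350),
               c(0.004, 0.036, 0.960))),
    # intermediate: starts high, decays through medium/low more slowly
    comp(list(pois_row(7.8), pois_row(4.9), pois_row(0.9)), c(1, 0, 0),
         rbind(c(0.900, 0.080, 0.020),
               c(0.030, 0.900, 0.070),
               c(0.005, 0.025, 0.970))),
    # sustained: very high and high (capacity-capped) for long periods
    comp(list(bin_row(19), bin_row(9.8), pois_row(0.6)), c(0.72, 0.28, 0.00),
         rbind(c(0.945, 0.045, 0.010),
               c(0.020, 0.950, 0.030),
               c(0.010, 0.040, 0.950))))
  true_model <- mhmm(c(0.67, 0.27, 0.06), components)

  # lengths: T = 2 + NegBin(size, mu - 2), truncated at 106 months, with
  # cluster-specific mean and dispersion; the weighted mean across clusters
  # sits near 29 months
  length_dist <- list(type = "nbinom_shifted", min = 2L, max = 106L,
                      size = c(2, 4, 6), mu = c(22, 40, 70))

  covariate_margins <- list(
    gender = c(female = 0.52, male = 0.48),
    age_group = c("<30" = 0.35, "30-40" = 0.22, "40-50" = 0.21,
                  "50-60" = 0.13, ">60" = 0.09),
    role = c(driver = 0.48, passenger = 0.23, cyclist = 0.16,
             pedestrian = 0.12, witness = 0.03),
    injuries = c(brain_head = 0.24, concussion = 0.19, internal = 0.29,
                 soft_tissue = 0.53, dislocation = 0.19,
                 sprain_strains = 0.24, limb_fractures = 0.37,
                 non_limb_fractures = 0.38, contusion_abrasion = 0.67,
                 degloving = 0.01))

  eff_names <- c("(intercept)", "gender_male", "age30_40", "age40_50",
                 "age50_60", "age_gt60", "brain_head", "soft_tissue",
                 "non_limb_fractures", "elapsed_time", "role_driver",
                 "role_passenger", "role_cyclist", "role_witness")
  covariate_effects <- rbind(
    cluster2 = c(-2.5, -0.30, 0.65, 0.80, 0.60, 0.20, 0.60, 0.60, 0.10,
                 0.00, 0.40, 0.40, 0.40, 1.30),
    cluster3 = c(-4.4, -0.55, -0.10, -0.40, -1.20, -0.75, 2.90, 0.00, 1.30,
                 0.23, -0.55, 0.00, -0.35, 1.20))
  colnames(covariate_effects) <- eff_names

  structure(list(true_model = true_model, length_dist = length_dist,
                 covariate_margins = covariate_margins,
                 covariate_effects = covariate_effects,
                 # years from accident to first utilization: right-skewed
                 elapsed_dist = list(type = "gamma", shape = 1.2, rate = 1.2),
                 seed = 1L),
            class = "mhmm_scenario")
}

#' Analytic mean series length of a scenario
#'
#' Mixture-weighted mean of the truncated, shifted negative binomial length
#' distributions, computed from the probability mass function.
#'
#' @param scenario an `mhmm_scenario`.
#' @return Mean length in months.
#' @export
scenario_mean_length <- function(scenario) {
  ld <- scenario$length_dist
  support <- 0:(ld$max - ld$min)
  size <- rep_len(ld$size, length(ld$mu))
  means <- vapply(seq_along(ld$mu), function(m) {
    p <- stats::dnbinom(support, size = size[m], mu = ld$mu[m] - ld$min)
    ld$min + sum(support * p) / sum(p)
  }, numeric(1))
  sum(scenario$true_model$weights * means)
}

sample_length <- function(n, cluster, ld) {
  size <- rep_len(ld$size, length(ld$mu))
  out <- integer(n)
  todo <- seq_len(n)
  for (attempt in 1:1000) {
    draw <- ld$min + stats::rnbinom(length(todo), size = size[cluster[todo]],
                                    mu = ld$mu[cluster[todo]] - ld$min)
    out[todo] <- draw
    todo <- todo[draw > ld$max]
    if (!length(todo)) return(out)
  }
  stop("length truncation failed after bounded resampling attempts")
}

#' Sample series, true labels and true state paths from a scenario
#'
#' For each series the generative process of the mixture is followed
#' literally: draw cluster `z` from the mixture weights, series length `T`
#' from the cluster's truncated length distribution, a state path from the
#' cluster's initial/transition distributions, and counts from the state
#' emissions. The first and last counts are forced positive by sampling the
#' emission at `t = 1` and `t = T` from the emission distribution
#' conditioned on a count of at least 1 (series are defined to start and
#' end at a utilization month); the number of affected draws is recorded in
#' the `truncated_draws` attribute.
#'
#' @param scenario an `mhmm_scenario` (see [default_scenario()]).
#' @param n number of series.
#' @param seed integer seed; the whole draw is a pure function of
#'   (`scenario`, `n`, `seed`).
#' @return List with `series` (named list of [utilization_series()], claim
#'   ids `"C0001"` ...), `labels` (true cluster per series) and `paths`
#'   (list of true state vectors).
#' @export
sample_mhmm <- function(scenario, n, seed = scenario$seed) {
  stopifnot(n >= 1L)
  model <- scenario$true_model
  if (any(model$weights < 0)) stop("degenerate mixture weights")
  set.seed(seed)
  M <- model$n_clusters; N <- model$n_states; K <- model$n_symbols
  z <- sample.int(M, n, replace = TRUE, prob = model$weights)
  T_len <- sample_length(n, z, scenario$length_dist)
  series <- vector("list", n)
  paths <- vector("list", n)
  truncated <- 0L
  start_pool <- seq(as.Date("2009-01-01"), as.Date("2009-12-01"), by = "month")
  starts <- sample(start_pool, n, replace = TRUE)
  support <- seq_len(K) - 1L
  for (i in seq_len(n)) {
    h <- model$components[[z[i]]]
    Ti <- T_len[i]
    y <- integer(Ti)
    y[1L] <- sample.int(N, 1L, prob = h$initial)
    for (t in seq_len(Ti - 1L))
      y[t + 1L] <- sample.int(N, 1L, prob = h$transition[y[t], ])
    x <- integer(Ti)
    for (t in seq_len(Ti))
      x[t] <- sample(support, 1L, prob = h$emission[y[t], ])
    for (t in unique(c(1L, Ti))) {
      if (x[t] == 0L) {
        pos <- h$emission[y[t], -1L]
        if (sum(pos) <= 0) stop("state emits no positive count; cannot anchor series")
        x[t] <- sample(support[-1L], 1L, prob = pos)
        truncated <- truncated + 1L
      }
    }
    id <- sprintf("C%04d", i)
    series[[i]] <- utilization_series(id, starts[i], x)
    paths[[i]] <- y
  }
  names(series) <- vapply(series, function(s) s$claim_id, character(1))
  structure(list(series = series, labels = z, paths = paths),
            truncated_draws = truncated)
}

draw_margin <- function(n, margin) {
  sample(names(margin), n, replace = TRUE, prob = margin)
}

# design row in the scenario's effect encoding for one claimant
scenario_design_row <- function(gender, age_group, role, brain, soft, nlf,
                                elapsed) {
  c(1,
    as.numeric(gender == "male"),
    as.numeric(age_group == "30-40"), as.numeric(age_group == "40-50"),
    as.numeric(age_group == "50-60"), as.numeric(age_group == ">60"),
    brain, soft, nlf, elapsed,
    as.numeric(role == "driver"), as.numeric(role == "passenger"),
    as.numeric(role == "cyclist"), as.numeric(role == "witness"))
}

#' Sample claimant covariates consistent with given cluster labels
#'
#' Covariates are proposed independently from the scenario's marginal
#' distributions and accepted for a claimant with probability
#' \eqn{p(z_i \mid x)} under the scenario's multinomial-logit model
#' (reference cluster 1). Among accepted draws the conditional law of the
#' covariates given the label is exactly Bayes-consistent with that logit:
#' all slope coefficients of the generating model are recoverable by
#' multinomial logistic regression, while intercepts are shifted by the
#' known offset \eqn{\log(P(z) c_1 / (P(1) c_z))} with
#' \eqn{c_z = E[p(z \mid x)]} (label frequencies enter through the
#' conditioning on fixed labels).
#'
#' @param labels integer cluster labels from [sample_mhmm()].
#' @param scenario an `mhmm_scenario`.
#' @param seed integer seed.
#' @param max_attempts bound on rejection rounds before declaring the
#'   margins/effects combination infeasible.
#' @return Data frame with one row per claimant: `claim_id`, `gender`,
#'   `age_group`, `role`, one 0/1 column per injury flag, `accident_date`,
#'   `first_utilization_date`, `elapsed_time_years`.
#' @export
sample_covariates <- function(labels, scenario, seed = scenario$seed + 1L,
                              max_attempts = 10000L) {
  set.seed(seed)
  n <- length(labels)
  mg <- scenario$covariate_margins
  beta <- scenario$covariate_effects
  out <- vector("list", n)
  for (i in seq_len(n)) {
    accepted <- FALSE
    for (a in seq_len(max_attempts)) {
      gender <- draw_margin(1L, mg$gender)
      age <- draw_margin(1L, mg$age_group)
      role <- draw_margin(1L, mg$role)
      inj <- stats::rbinom(length(mg$injuries), 1L, mg$injuries)
      names(inj) <- names(mg$injuries)
      elapsed <- stats::rgamma(1L, shape = scenario$elapsed_dist$shape,
                               rate = scenario$elapsed_dist$rate)
      xrow <- scenario_design_row(gender, age, role, inj[["brain_head"]],
                                  inj[["soft_tissue"]],
                                  inj[["non_limb_fractures"]], elapsed)
      eta <- c(0, as.numeric(beta %*% xrow))
      p <- exp(eta - logsumexp_r(eta))
      if (stats::runif(1L) < p[labels[i]]) { accepted <- TRUE; break }
    }
    if (!accepted)
      stop("covariate rejection sampler exhausted attempts; ",
           "margins and effects are incompatible with label ", labels[i])
    out[[i]] <- c(list(gender = gender, age_group = age, role = role),
                  as.list(inj), list(elapsed_time_years = elapsed))
  }
  df <- do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df <- cbind(claim_id = sprintf("C%04d", seq_len(n)), df,
              stringsAsFactors = FALSE)
  df$accident_date <- as.Date("2009-01-01") +
    sample.int(365L, n, replace = TRUE) - 1L
  df$first_utilization_date <- df$accident_date +
    round(df$elapsed_time_years * 365.25)
  df$elapsed_time_years <- compute_elapsed_time(df$accident_date,
                                                df$first_utilization_date)
  df
}

#' Serialize a scenario to JSON
#'
#' @param scenario an `mhmm_scenario`.
#' @param path optional output path.
#' @return JSON string, invisibly when written to file.
#' @export
scenario_to_json <- function(scenario, path = NULL) {
  js <- jsonlite::toJSON(list(
    true_model = jsonlite::fromJSON(mhmm_to_json(scenario$true_model),
                                    simplifyVector = FALSE),
    length_dist = scenario$length_dist,
    covariate_margins = scenario$covariate_margins,
    covariate_effects = list(values = scenario$covariate_effects,
                             colnames = colnames(scenario$covariate_effects)),
    elapsed_dist = scenario$elapsed_dist, seed = scenario$seed),
    digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
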