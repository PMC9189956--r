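#' Standardized absolute risks and maternal-effect contrasts
#'
#' Regression standardization turns a fitted logistic model into marginal
#' absolute risks: the mean predicted outcome probability over every row of
#' the analysis data with the exposure forced to 1 and to 0, and their
#' difference. The ratio-of-odds-ratios (ROR) contrast compares the
#' exposure-outcome odds ratio between two relative cohorts (mothers vs
#' fathers, aunts vs uncles, maternal vs paternal side) through an
#' exposure-by-group interaction on the merged data -- the design used to
#' probe maternal (including gestational) effects.
#'
#' @name marginal-effects
NULL

# design builder: intercept, exposure, covariates and (optionally) the
# exposure-by-covariate interaction columns, evaluated at the observed or a
# forced exposure level
.std_design <- function(exposure, covariates, interaction, force = NULL) {
  x <- if (is.null(force)) exposure else rep(force, length(exposure))
  X <- cbind(`(Intercept)` = 1, .x = x)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    colnames(cv) <- paste0("cv", seq_len(ncol(cv)))
    X <- cbind(X, cv)
    if (interaction) {
      Xi <- cv * x
      colnames(Xi) <- paste0("x_cv", seq_len(ncol(cv)))
      X <- cbind(X, Xi)
    }
  }
  X
}

.standardize_once <- function(coefs, exposure, covariates, interaction) {
  X1 <- .std_design(exposure, covariates, interaction, force = 1)
  X0 <- .std_design(exposure, covariates, interaction, force = 0)
  c(ar1 = mean(plogis(as.vector(X1 %*% coefs))),
    ar0 = mean(plogis(as.vector(X0 %*% coefs))))
}

#' Regression-standardized absolute risks and risk difference
#'
#' Fits (or reuses) a logistic outcome model and averages predicted
#' probabilities over all rows with the exposure forced to each level; the
#' risk difference is their difference. Confidence intervals are percentile
#' intervals from a nonparametric bootstrap resampled at cluster level,
#' reproducible under the seed.
#'
#' @param outcome,exposure Binary vectors.
#' @param covariates Optional covariate matrix; must not itself depend on
#'   the exposure (exposure-covariate product terms are handled through
#'   `interaction`).
#' @param interaction Also include exposure-by-covariate product terms in
#'   the outcome model (a saturated model when the covariate is a full
#'   stratum coding).
#' @param cluster_ids Cluster labels for the bootstrap resampling (each
#'   observation its own cluster when `NULL`).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return An object of class `standardized_risk` with `ar_exposed`,
#'   `ar_unexposed`, `rd`, percentile CI bounds for each, `n_boot`, `seed`.
#' @export
standardized_risks <- function(outcome, exposure, covariates = NULL,
                               interaction = FALSE, cluster_ids = NULL,
                               n_boot = 500L, seed = 1L,
                               conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  n <- length(outcome)
  if (is.null(cluster_ids)) cluster_ids <- seq_len(n)
  fit_coefs <- function(y, x, cv) {
    M <- .std_design(x, cv, interaction)
    f <- suppressWarnings(
      glm.fit(M, y, family = binomial(),
              control = glm.control(epsilon = 1e-8, maxit = 100L)))
    f$coefficients
  }
  std <- function(idx) {
    cv <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[idx, , drop = FALSE]
    e <- .standardize_once(fit_coefs(outcome[idx], exposure[idx], cv),
                           exposure[idx], cv, interaction)
    c(e["ar1"], e["ar0"], e["ar1"] - e["ar0"])
  }
  est <- std(seq_len(n))
  rd <- unname(est[3])

  cl <- split(seq_len(n), cluster_ids)
  boot <- matrix(NA_real_, n_boot, 3L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    take <- unlist(cl[sample.int(length(cl), length(cl), replace = TRUE)],
                   use.names = FALSE)
    boot[b, ] <- tryCatch(std(take), error = function(err) rep(NA_real_, 3L))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  alpha <- (1 - conf_level) / 2
  qs <- apply(boot, 2, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  structure(
    list(ar_exposed = unname(est[1]), ar_unexposed = unname(est[2]),
         rd = rd,
         ar_exposed_ci = qs[, 1], ar_unexposed_ci = qs[, 2], rd_ci = qs[, 3],
         n_boot = n_boot, n_boot_failed = sum(is.na(boot[, 1])),
         seed = seed, conf_level = conf_level),
    class = "standardized_risk")
}

#' @export
print.standardized_risk <- function(x, ...) {
  cat(sprintf("standardized AR exposed   %.5f (%.5f-%.5f)\n",
              x$ar_exposed, x$ar_exposed_ci[1], x$ar_exposed_ci[2]))
  cat(sprintf("standardized AR unexposed %.5f (%.5f-%.5f)\n",
              x$ar_unexposed, x$ar_unexposed_ci[1], x$ar_unexposed_ci[2]))
  cat(sprintf("risk difference           %.5f (%.5f-%.5f)  [%d bootstrap]\n",
              x$rd, x$rd_ci[1], x$rd_ci[2], x$n_boot))
  invisible(x)
}

#' Ratio-of-odds-ratios contrast between two relative cohorts
#'
#' Merges two pair cohorts, fits the outcome on exposure, a group indicator
#' (1 = first cohort), their interaction and the birth-year splines of both
#' members, and exponentiates the interaction coefficient: the ratio of the
#' group-A odds ratio to the group-B odds ratio, with family-clustered
#' robust Wald inference. Component odds ratios come from per-group fits.
#'
#' @param pairs_a,pairs_b Two `relative_pair_cohort` objects, disjoint in
#'   (index, relative) pairs.
#' @param phenotypes A `phenotype_table` covering both cohorts.
#' @param persons Person table.
#' @param exposure_phenotype,outcome_phenotype Phenotype names.
#' @param contrast Label, e.g. `"mother_vs_father"`.
#' @param n_knots Spline knots per birth-year term.
#' @param conf_level Confidence level.
#' @return An object of class `ror_result`: `ror`, `ci_low`, `ci_high`,
#'   `p_value`, `contrast` and `component_ors` (group A and B `or_result`).
#' @export
ror_contrast <- function(pairs_a, pairs_b, phenotypes, persons,
                         exposure_phenotype, outcome_phenotype,
                         contrast = "group_a_vs_group_b", n_knots = 5L,
                         conf_level = 0.95) {
  key_a <- paste(pairs_a$index_id, pairs_a$relative_id)
  key_b <- paste(pairs_b$index_id, pairs_b$relative_id)
  if (length(intersect(key_a, key_b))) {
    stop("the two cohorts share (index, relative) pairs; the contrast ",
         "requires disjoint groups", call. = FALSE)
  }
  if (!nrow(pairs_a) || !nrow(pairs_b)) {
    stop("empty contrast group", call. = FALSE)
  }
  merged <- rbind(as.data.frame(pairs_a), as.data.frame(pairs_b))
  group <- rep(c(1, 0), c(nrow(pairs_a), nrow(pairs_b)))
  fr <- .pair_analysis_frame(merged, phenotypes, persons, exposure_phenotype,
                             outcome_phenotype, n_knots)
  inter <- fit_or_with_interaction(fr$outcome, fr$exposure, group,
                                   fr$covariates, fr$cluster_ids,
                                   conf_level = conf_level)
  structure(
    list(ror = inter$ratio, log_se = inter$log_se,
         ci_low = inter$ci_low, ci_high = inter$ci_high,
         p_value = inter$p_value, contrast = contrast,
         component_ors = list(group_a = inter$strata$modifier1,
                              group_b = inter$strata$modifier0),
         conf_level = conf_level),
    class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR [%s] %.4f (%.0f%% CI %.4f-%.4f), p = %.3g\n",
              x$contrast, x$ror, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$p_value))
  cat(sprintf("  OR group A %.4f, OR group B %.4f\n",
              x$component_ors$group_a$estimate,
              x$component_ors$group_b$estimate))
  invisible(x)
}
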