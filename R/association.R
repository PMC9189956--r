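#' Odds-ratio estimation with cluster-robust inference
#'
#' Logistic-regression machinery for the within-individual and familial
#' co-aggregation analyses: natural cubic spline adjustment for birth year,
#' maximum-likelihood fits via iteratively reweighted least squares,
#' cluster-robust (sandwich) standard errors aggregated on family clusters,
#' Wald 95% confidence intervals and two-sided p-values, and
#' exposure-by-modifier interaction models with stratum-specific estimates.
#' No multiple-testing adjustment is applied anywhere.
#'
#' @name association
NULL

#' Natural cubic spline basis
#'
#' Basis of dimension (number of knots - 1) that is cubic between knots and
#' linear beyond the boundary knots. The default knot policy places 5 knots
#' at the 5th, 27.5th, 50th, 72.5th and 95th percentiles of the data (the
#' outer two acting as boundary knots).
#'
#' @param x Numeric vector with at least two distinct values.
#' @param n_knots Number of knots under the percentile policy.
#' @param knots Optional explicit knot locations (ordered; first and last
#'   are treated as boundary knots).
#' @return An n x (knots-1) basis matrix of class `spline_basis` with
#'   attributes `knots` and `boundary`; use [predict_spline_basis()] to
#'   evaluate the same basis at new values.
#' @export
natural_cubic_spline_basis <- function(x, n_knots = 5L, knots = NULL) {
  if (length(unique(x[is.finite(x)])) < 2L) {
    stop("spline basis needs at least two distinct values", call. = FALSE)
  }
  if (is.null(knots)) {
    knots <- unname(quantile(x, c(0.05, 0.275, 0.50, 0.725, 0.95),
                             names = FALSE, type = 7))
    if (n_knots != 5L) {
      knots <- unname(quantile(x, seq(0.05, 0.95, length.out = n_knots),
                               names = FALSE, type = 7))
    }
    knots <- unique(knots)
    if (length(knots) < 2L) {
      stop("knot percentiles collapse onto fewer than two distinct values",
           call. = FALSE)
    }
  } else {
    knots <- sort(knots)
    if (anyDuplicated(knots)) {
      stop("coincident knots are not allowed", call. = FALSE)
    }
  }
  boundary <- knots[c(1L, length(knots))]
  interior <- knots[-c(1L, length(knots))]
  b <- splines::ns(x, knots = interior, Boundary.knots = boundary)
  out <- unclass(b)[, , drop = FALSE]
  attr(out, "knots") <- knots
  attr(out, "boundary") <- boundary
  class(out) <- c("spline_basis", "matrix")
  out
}

#' @rdname natural_cubic_spline_basis
#' @param basis A `spline_basis`.
#' @param newx Values at which to evaluate the basis.
#' @export
predict_spline_basis <- function(basis, newx) {
  knots <- attr(basis, "knots")
  boundary <- attr(basis, "boundary")
  interior <- knots[-c(1L, length(knots))]
  m <- splines::ns(newx, knots = interior, Boundary.knots = boundary)
  unclass(m)[, , drop = FALSE]
}

.robust_vcov <- function(fit, cluster_ids) {
  if (is.null(cluster_ids) || length(unique(cluster_ids)) < 2L) {
    if (!is.null(cluster_ids)) {
      warning("fewer than two clusters; falling back to ",
              "heteroscedasticity-robust variance", call. = FALSE)
    }
    sandwich::vcovHC(fit, type = "HC0")
  } else {
    sandwich::vcovCL(fit, cluster = cluster_ids, type = "HC0")
  }
}

.glm_binomial <- function(formula, data, weights) {
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(formula, family = binomial(), data = data, weights = weights,
        control = glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) separation <- TRUE
  list(fit = fit, separation = separation)
}

.or_from_fit <- function(fit, vc, term, n_obs, n_clusters, model_spec,
                         separation, conf_level = 0.95) {
  b <- coef(fit)[[term]]
  se <- sqrt(vc[term, term])
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(estimate = exp(b), log_or = b, log_se = se,
         ci_low = exp(b - z * se), ci_high = exp(b + z * se),
         p_value = 2 * pnorm(-abs(b / se)),
         n_pairs = n_obs, n_clusters = n_clusters,
         model_spec = model_spec, separation = separation,
         conf_level = conf_level, fit = fit, vcov = vc),
    class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.4f (%.0f%% CI %.4f-%.4f), p = %.3g  [n = %s, clusters = %s]%s\n",
              x$estimate, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value,
              format(x$n_pairs, big.mark = ","),
              ifelse(is.na(x$n_clusters), "-",
                     format(x$n_clusters, big.mark = ",")),
              if (isTRUE(x$separation)) "  [flagged: separation]" else ""))
  cat("  model:", x$model_spec, "\n")
  invisible(x)
}

#' Logistic odds ratio with cluster-robust Wald inference
#'
#' Maximum-likelihood logistic regression of a binary outcome on a binary
#' exposure and optional covariates, with the exposure coefficient
#' exponentiated to an odds ratio. Variance is estimated by the
#' cluster-aggregated sandwich estimator on `cluster_ids` (falling back to
#' heteroscedasticity-robust with a warning when all observations share one
#' cluster); the confidence interval and p-value are Wald-type. Perfect
#' separation is flagged in the result rather than failing silently.
#'
#' @param outcome,exposure Binary (0/1 or logical) vectors.
#' @param covariates Optional numeric matrix of adjustment covariates.
#' @param cluster_ids Optional cluster labels for the sandwich estimator.
#' @param weights Optional case weights (e.g. aggregated 2x2 counts).
#' @param conf_level Confidence level.
#' @return An `or_result` (estimate, log_se, ci_low, ci_high, p_value,
#'   n_pairs, n_clusters, model_spec, separation flag, fitted model).
#' @examples
#' # crude odds ratio from an aggregated 2x2 table
#' d <- expand.grid(y = 0:1, x = 0:1)
#' fit_logistic_or(d$y, d$x, weights = c(4850279, 209019, 113350, 5577))
#' @export
fit_logistic_or <- function(outcome, exposure, covariates = NULL,
                            cluster_ids = NULL, weights = NULL,
                            conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  stopifnot(length(outcome) == length(exposure))
  if (length(unique(outcome[!is.na(outcome)])) < 2L) {
    stop("outcome needs at least one case and one non-case", call. = FALSE)
  }
  dat <- data.frame(.y = outcome, .x = exposure)
  form <- .y ~ .x
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    dat$.cv <- covariates
    form <- .y ~ .x + .cv
  }
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  res <- .glm_binomial(form, dat, dat$.w)
  vc <- .robust_vcov(res$fit, cluster_ids)
  n_cl <- if (is.null(cluster_ids)) NA_integer_ else
    length(unique(cluster_ids))
  .or_from_fit(res$fit, vc, ".x", sum(dat$.w), n_cl,
               model_spec = paste0("logit(outcome) ~ exposure",
                                   if (!is.null(covariates))
                                     sprintf(" + %d covariate column(s)",
                                             ncol(covariates)) else ""),
               separation = res$separation, conf_level = conf_level)
}

#' Exposure-by-modifier interaction on the odds-ratio scale
#'
#' Fits `outcome ~ exposure * modifier + covariates` and reports the
#' exponentiated interaction coefficient -- the ratio of the exposure odds
#' ratio in the modifier stratum to that in the reference stratum -- with
#' cluster-robust Wald confidence interval and p-value, alongside
#' stratum-specific odds ratios from stratified refits.
#'
#' @inheritParams fit_logistic_or
#' @param modifier Binary stratum indicator.
#' @return An `interaction_result` with elements `ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `strata` (list of `or_result`).
#' @export
fit_or_with_interaction <- function(outcome, exposure, modifier,
                                    covariates = NULL, cluster_ids = NULL,
                                    weights = NULL, conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  exposure <- as.numeric(exposure)
  modifier <- as.numeric(modifier)
  for (lev in 0:1) {
    if (!any(modifier == lev)) {
      stop("modifier stratum ", lev, " is empty", call. = FALSE)
    }
  }
  dat <- data.frame(.y = outcome, .x = exposure, .m = modifier)
  form <- .y ~ .x * .m
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    dat$.cv <- covariates
    form <- .y ~ .x * .m + .cv
  }
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  res <- .glm_binomial(form, dat, dat$.w)
  vc <- .robust_vcov(res$fit, cluster_ids)
  term <- ".x:.m"
  b <- coef(res$fit)[[term]]
  se <- sqrt(vc[term, term])
  z <- qnorm(1 - (1 - conf_level) / 2)
  strata <- lapply(0:1, function(lev) {
    sel <- modifier == lev
    fit_logistic_or(outcome[sel], exposure[sel],
                    covariates = if (is.null(covariates)) NULL else
                      covariates[sel, , drop = FALSE],
                    cluster_ids = cluster_ids[sel],
                    weights = if (is.null(weights)) NULL else weights[sel],
                    conf_level = conf_level)
  })
  names(strata) <- c("modifier0", "modifier1")
  structure(
    list(ratio = exp(b), log_se = se,
         ci_low = exp(b - z * se), ci_high = exp(b + z * se),
         p_value = 2 * pnorm(-abs(b / se)),
         strata = strata, separation = res$separation, fit = res$fit,
         vcov = vc, conf_level = conf_level),
    class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("interaction ratio %.4f (%.0f%% CI %.4f-%.4f), p = %.3g\n",
              x$ratio, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

# assemble the analysis frame for one pair cohort: exposure of the index
# person, outcome of the relative, spline bases of both birth years
.pair_analysis_frame <- function(pairs, phenotypes, persons,
                                 exposure_phenotype, outcome_phenotype,
                                 n_knots = 5L) {
  ph_lookup <- function(ids, phen) {
    sub <- phenotypes[phenotypes$phenotype == phen, , drop = FALSE]
    if (!nrow(sub)) stop("phenotype '", phen, "' not found", call. = FALSE)
    v <- sub$is_case[match(ids, sub$person_id)]
    if (anyNA(v)) {
      stop("phenotype '", phen, "' does not cover all persons in the pairs",
           call. = FALSE)
    }
    as.numeric(v)
  }
  by_i <- persons$birth_year[match(pairs$index_id, persons$person_id)]
  by_r <- persons$birth_year[match(pairs$relative_id, persons$person_id)]
  list(exposure = ph_lookup(pairs$index_id, exposure_phenotype),
       outcome = ph_lookup(pairs$relative_id, outcome_phenotype),
       covariates = cbind(natural_cubic_spline_basis(by_i, n_knots),
                          natural_cubic_spline_basis(by_r, n_knots)),
       cluster_ids = pairs$family_cluster_id)
}

#' Familial co-aggregation odds ratio for one pair cohort
#'
#' Unit of analysis is the index-relative pair: the outcome is the
#' relative's lifetime outcome phenotype, the exposure the index person's
#' lifetime exposure phenotype, adjusted for natural cubic splines of both
#' members' birth years, with sandwich variance clustered on the family
#' component.
#'
#' @param pairs A `relative_pair_cohort`.
#' @param phenotypes A `phenotype_table` covering all persons in the pairs.
#' @param persons Person table (for birth years).
#' @param exposure_phenotype,outcome_phenotype Phenotype names.
#' @param n_knots Spline knots per birth-year term.
#' @param conf_level Confidence level.
#' @return An `or_result` with the relation recorded in `model_spec`.
#' @export
run_pair_association <- function(pairs, phenotypes, persons,
                                 exposure_phenotype, outcome_phenotype,
                                 n_knots = 5L, conf_level = 0.95) {
  fr <- .pair_analysis_frame(pairs, phenotypes, persons, exposure_phenotype,
                             outcome_phenotype, n_knots)
  out <- fit_logistic_or(fr$outcome, fr$exposure, fr$covariates,
                         fr$cluster_ids, conf_level = conf_level)
  out$model_spec <- sprintf(
    "relative %s ~ index %s + ns(index birth year) + ns(relative birth year), cluster = family [%s]",
    outcome_phenotype, exposure_phenotype, attr(pairs, "relation"))
  out
}

#' Within-individual association between two lifetime phenotypes
#'
#' Logistic regression of one phenotype on the other within the index
#' cohort, adjusted for sex and a natural cubic spline of birth year, with
#' family-clustered sandwich variance. Sex can instead be handled by
#' stratification via [fit_or_with_interaction()].
#'
#' @param index An `index_cohort` (person_id, sex, birth_year).
#' @param phenotypes A `phenotype_table`.
#' @param exposure_phenotype,outcome_phenotype Phenotype names.
#' @param cluster_ids Optional person-level cluster labels (family ids).
#' @param n_knots Spline knots for birth year.
#' @param sex_adjust Include sex as a covariate (default) or not.
#' @param conf_level Confidence level.
#' @return An `or_result`.
#' @export
run_within_association <- function(index, phenotypes, exposure_phenotype,
                                   outcome_phenotype, cluster_ids = NULL,
                                   n_knots = 5L, sex_adjust = TRUE,
                                   conf_level = 0.95) {
  get_ph <- function(phen) {
    sub <- phenotypes[phenotypes$phenotype == phen, , drop = FALSE]
    v <- sub$is_case[match(index$person_id, sub$person_id)]
    if (anyNA(v)) {
      stop("phenotype '", phen, "' does not cover the index cohort",
           call. = FALSE)
    }
    as.numeric(v)
  }
  cv <- natural_cubic_spline_basis(index$birth_year, n_knots)
  if (sex_adjust) cv <- cbind(cv, female = as.numeric(index$sex == "female"))
  out <- fit_logistic_or(get_ph(outcome_phenotype), get_ph(exposure_phenotype),
                         cv, cluster_ids, conf_level = conf_level)
  out$model_spec <- sprintf(
    "%s ~ %s + ns(birth year)%s [within individual]",
    outcome_phenotype, exposure_phenotype,
    if (sex_adjust) " + sex" else "")
  out
}
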