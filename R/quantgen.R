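#' Bivariate liability-threshold ACE modelling on relative pairs
#'
#' Decomposes the variance of two binary lifetime traits, and their
#' covariance, into additive-genetic (A), shared-environment (C) and
#' unique-environment (E) parts by maximum likelihood on the 16-cell joint
#' outcome patterns of relative pairs. Identification comes from contrasting
#' relative classes with different sharing coefficients: full siblings share
#' 50% of A and 100% of C, full cousins 12.5% of A and 0% of C. Each pair's
#' pattern probability is a rectangle probability of a 4-variate standard
#' normal liability vector, so the log-likelihood is a multinomial over the
#' 16 patterns per relative class.
#'
#' @name quantgen
NULL

#' Variance components of a bivariate liability model
#'
#' @param a2,c2,e2 Length-2 standardized variance proportions (trait 1,
#'   trait 2); each trait must sum to 1. A structurally absent component has
#'   proportion exactly 0.
#' @param rA,rC,rE Cross-trait correlations of the A, C, E factors; `NA`
#'   marks a correlation that is structurally absent because the component is
#'   missing from at least one trait (it enters all formulas as 0).
#' @param thresholds Length-2 baseline liability thresholds.
#' @param threshold_covariates Optional per-trait coefficient list for
#'   additive threshold shifts (sex, linear and cubic birth year).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(a2, c2, e2, rA = NA_real_, rC = NA_real_,
                                rE = NA_real_,
                                thresholds = c(NA_real_, NA_real_),
                                threshold_covariates = NULL) {
  stopifnot(length(a2) == 2, length(c2) == 2, length(e2) == 2)
  if (any(abs(a2 + c2 + e2 - 1) > 1e-12)) {
    stop("a2 + c2 + e2 must equal 1 per trait", call. = FALSE)
  }
  for (r in c(rA = rA, rC = rC, rE = rE)) {
    if (!is.na(r) && (r < -1 || r > 1)) {
      stop("correlations must lie in [-1, 1]", call. = FALSE)
    }
  }
  structure(list(a2 = a2, c2 = c2, e2 = e2, rA = rA, rC = rC, rE = rE,
                 thresholds = thresholds,
                 threshold_covariates = threshold_covariates),
            class = "variance_components")
}

#' Relative-class sharing specification
#'
#' @param label Class label.
#' @param a_share Expected shared fraction of additive-genetic variance.
#' @param c_share Shared fraction of the sibship environment (0 or 1).
#' @return An object of class `relative_class_spec`.
#' @export
relative_class_spec <- function(label, a_share, c_share) {
  stopifnot(a_share >= 0, a_share <= 1, c_share %in% c(0, 1))
  structure(list(label = label, a_share = a_share, c_share = c_share),
            class = "relative_class_spec")
}

#' @rdname relative_class_spec
#' @export
sibling_class <- function() relative_class_spec("full_sibling", 0.5, 1.0)

#' @rdname relative_class_spec
#' @export
cousin_class <- function() relative_class_spec("cousin", 0.125, 0.0)

.r0 <- function(r) if (is.na(r)) 0 else r

# cross-trait liability covariance contributed by one component
.cross_cov <- function(vc) {
  c(A = .r0(vc$rA) * sqrt(vc$a2[1] * vc$a2[2]),
    C = .r0(vc$rC) * sqrt(vc$c2[1] * vc$c2[2]),
    E = .r0(vc$rE) * sqrt(vc$e2[1] * vc$e2[2]))
}

#' Liability correlation matrix of a relative pair
#'
#' The 4x4 correlation matrix of (member1 trait1, member1 trait2,
#' member2 trait1, member2 trait2) liabilities. Within-person cross-trait
#' correlation is `rA*sqrt(a2_1*a2_2) + rC*sqrt(c2_1*c2_2) +
#' rE*sqrt(e2_1*e2_2)`; cross-person same-trait correlation for trait k is
#' `a_share*a2_k + c_share*c2_k`; cross-person cross-trait correlation is
#' `a_share*rA*sqrt(a2_1*a2_2) + c_share*rC*sqrt(c2_1*c2_2)`.
#'
#' @param vc A [variance_components()] object.
#' @param spec A [relative_class_spec()].
#' @return A symmetric positive semi-definite 4x4 matrix with unit diagonal.
#' @export
pair_correlation_matrix <- function(vc, spec) {
  stopifnot(inherits(vc, "variance_components"),
            inherits(spec, "relative_class_spec"))
  cc <- .cross_cov(vc)
  w <- sum(cc)
  x <- spec$a_share * cc["A"] + spec$c_share * cc["C"]
  s1 <- spec$a_share * vc$a2[1] + spec$c_share * vc$c2[1]
  s2 <- spec$a_share * vc$a2[2] + spec$c_share * vc$c2[2]
  M <- diag(4)
  M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- w
  M[1, 3] <- M[3, 1] <- s1
  M[2, 4] <- M[4, 2] <- s2
  M[1, 4] <- M[4, 1] <- M[2, 3] <- M[3, 2] <- x
  dimnames(M) <- list(c("m1t1", "m1t2", "m2t1", "m2t2"),
                      c("m1t1", "m1t2", "m2t1", "m2t2"))
  ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) {
    stop("implied pair correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  M
}

#' Simulate relative-pair liabilities component-wise
#'
#' Draws A, C and E components for both members of `n` pairs of one relative
#' class: A from a 4-variate normal with cross-member correlation `a_share`,
#' C fully shared or independent according to `c_share`, E independent. The
#' sum reproduces [pair_correlation_matrix()].
#'
#' @param vc A [variance_components()] object.
#' @param spec A [relative_class_spec()].
#' @param n Number of pairs.
#' @return List with n x 4 matrices `total`, `A`, `C`, `E`, columns ordered
#'   (m1t1, m1t2, m2t1, m2t2).
#' @export
simulate_pair_liabilities <- function(vc, spec, n) {
  draw4 <- function(v, r, share) {
    s <- sqrt(v)
    W <- matrix(c(v[1], r * s[1] * s[2], r * s[1] * s[2], v[2]), 2)
    S <- rbind(cbind(W, share * W), cbind(share * W, W))
    if (all(S == 0)) return(matrix(0, n, 4))
    ev <- eigen(S, symmetric = TRUE)
    rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    matrix(rnorm(4 * n), n, 4) %*% rt
  }
  A <- draw4(vc$a2, .r0(vc$rA), spec$a_share)
  C <- draw4(vc$c2, .r0(vc$rC), spec$c_share)
  E <- draw4(vc$e2, .r0(vc$rE), 0)
  tot <- A + C + E
  colnames(tot) <- c("m1t1", "m1t2", "m2t1", "m2t2")
  list(total = tot, A = A, C = C, E = E)
}

.pattern_labels <- function() rownames(.pattern_grid())

#' Tabulate joint outcome patterns of relative pairs
#'
#' @param cases n x 4 logical/0-1 matrix of case indicators, columns
#'   (m1t1, m1t2, m2t1, m2t2).
#' @param label Relative-class label for the resulting rows.
#' @return Data frame (relative_class, pattern, count) over all 16 patterns.
#' @export
tabulate_pair_patterns <- function(cases, label) {
  stopifnot(ncol(cases) == 4)
  key <- cases[, 1] + 2 * cases[, 2] + 4 * cases[, 3] + 8 * cases[, 4]
  cnt <- tabulate(key + 1L, nbins = 16L)
  data.frame(relative_class = label, pattern = .pattern_labels(),
             count = cnt, stringsAsFactors = FALSE)
}

#' Simulate collapsed pattern counts for sibling and cousin pairs
#'
#' Convenience generator for variance-component fitting: simulates pair
#' liabilities at the given generating values, dichotomizes at the
#' thresholds, and collapses to 16-cell counts per relative class.
#'
#' @param vc Generating [variance_components()] (thresholds must be set).
#' @param n_pairs Named vector of pair counts per class label.
#' @param classes List of [relative_class_spec()] objects matching
#'   `names(n_pairs)`.
#' @param seed Optional seed.
#' @return A `pattern_counts` data frame with the class specs attached as
#'   attribute `"specs"`.
#' @export
simulate_pattern_counts <- function(vc,
                                    n_pairs = c(full_sibling = 4e5,
                                                cousin = 1e5),
                                    classes = list(sibling_class(),
                                                   cousin_class()),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(is.finite(vc$thresholds)))
  names(classes) <- vapply(classes, `[[`, "", "label")
  out <- lapply(names(n_pairs), function(lb) {
    sim <- simulate_pair_liabilities(vc, classes[[lb]], n_pairs[[lb]])
    th <- rep(vc$thresholds, 2)
    tabulate_pair_patterns(sweep(sim$total, 2, th) > 0, lb)
  })
  res <- do.call(rbind, out)
  attr(res, "specs") <- classes[names(n_pairs)]
  class(res) <- c("pattern_counts", "data.frame")
  res
}

# pattern probabilities for one class at given vc (collapsed, no covariates)
.class_pattern_probs <- function(vc, spec, n_qmc, n_shifts) {
  corr <- pair_correlation_matrix(vc, spec)
  th <- rep(vc$thresholds, 2)
  mvn_pattern_probs(corr, th, n_qmc = n_qmc, n_shifts = n_shifts)
}

#' Log-likelihood of pattern data under a liability model
#'
#' Collapsed mode (`data` is a `pattern_counts` frame): multinomial
#' log-likelihood `sum over classes and patterns of n * log p`. Per-pair mode
#' (`data` has one row per pair with columns `relative_class`, `pattern` and
#' optional threshold-shift columns `shift_m1_t1`, `shift_m1_t2`,
#' `shift_m2_t1`, `shift_m2_t2`): pairs are grouped by identical shifts, and
#' both modes agree exactly when all shifts are zero.
#'
#' @param data Pattern data, see above; relative-class specs are taken from
#'   `attr(data, "specs")` unless given in `classes`.
#' @param vc A [variance_components()] with finite thresholds.
#' @param classes Optional list of [relative_class_spec()] keyed by label.
#' @param n_qmc,n_shifts Accuracy of the orthant evaluations.
#' @return The log-likelihood (pattern probabilities floored at 1e-300).
#' @export
pair_loglikelihood <- function(data, vc, classes = attr(data, "specs"),
                               n_qmc = 1021L, n_shifts = 1L) {
  stopifnot(!is.null(classes), all(is.finite(vc$thresholds)))
  shift_cols <- c("shift_m1_t1", "shift_m1_t2", "shift_m2_t1", "shift_m2_t2")
  per_pair <- all(shift_cols %in% names(data))
  ll <- 0
  for (lb in unique(data$relative_class)) {
    spec <- classes[[lb]]
    if (is.null(spec)) stop("no class spec for '", lb, "'", call. = FALSE)
    rows <- data[data$relative_class == lb, , drop = FALSE]
    if (!per_pair) {
      p <- .class_pattern_probs(vc, spec, n_qmc, n_shifts)
      cnt <- rows$count[match(names(p), rows$pattern)]
      cnt[is.na(cnt)] <- 0
      ll <- ll + sum(cnt * log(pmax(p, 1e-300)))
    } else {
      corr <- pair_correlation_matrix(vc, spec)
      grp <- interaction(rows$shift_m1_t1, rows$shift_m1_t2,
                         rows$shift_m2_t1, rows$shift_m2_t2, drop = TRUE)
      for (g in levels(grp)) {
        sel <- rows[grp == g, , drop = FALSE]
        th <- rep(vc$thresholds, 2) +
          as.numeric(sel[1, shift_cols])
        p <- mvn_pattern_probs(corr, th, n_qmc = n_qmc, n_shifts = n_shifts)
        cnt <- tabulate(match(sel$pattern, names(p)), nbins = 16L)
        ll <- ll + sum(cnt * log(pmax(p, 1e-300)))
      }
    }
  }
  ll
}

## ---- parameterization ------------------------------------------------

# model_spec: list(trait1 = subset of c("A","C","E"), trait2 = ...); E is
# always retained (a binary trait without unique variation is degenerate).
.check_model_spec <- function(model_spec) {
  stopifnot(is.list(model_spec), length(model_spec) == 2)
  for (cs in model_spec) {
    if (!"E" %in% cs || !all(cs %in% c("A", "C", "E"))) {
      stop("each trait's component set must be a subset of A, C, E and ",
           "include E", call. = FALSE)
    }
  }
  model_spec
}

.theta_names <- function(model_spec) {
  nm <- c()
  for (k in 1:2) {
    cs <- model_spec[[k]]
    if ("A" %in% cs) nm <- c(nm, paste0("log_a2_e2_", k))
    if ("C" %in% cs) nm <- c(nm, paste0("log_c2_e2_", k))
  }
  shared <- function(x) x %in% model_spec[[1]] && x %in% model_spec[[2]]
  if (shared("A")) nm <- c(nm, "atanh_rA")
  if (shared("C")) nm <- c(nm, "atanh_rC")
  nm <- c(nm, "atanh_rE", "t1", "t2")
  nm
}

.theta_to_vc <- function(theta, model_spec) {
  g <- function(nm) if (nm %in% names(theta)) theta[[nm]] else NULL
  a2 <- c2 <- e2 <- numeric(2)
  for (k in 1:2) {
    la <- g(paste0("log_a2_e2_", k))
    lc <- g(paste0("log_c2_e2_", k))
    den <- 1 + (if (is.null(la)) 0 else exp(la)) +
      (if (is.null(lc)) 0 else exp(lc))
    e2[k] <- 1 / den
    a2[k] <- if (is.null(la)) 0 else exp(la) / den
    c2[k] <- if (is.null(lc)) 0 else exp(lc) / den
  }
  r <- function(nm) {
    v <- g(nm)
    if (is.null(v)) NA_real_ else tanh(v)
  }
  variance_components(a2, c2, e2,
                      rA = r("atanh_rA"), rC = r("atanh_rC"),
                      rE = tanh(theta[["atanh_rE"]]),
                      thresholds = c(theta[["t1"]], theta[["t2"]]))
}

.vc_to_theta <- function(vc, model_spec) {
  nm <- .theta_names(model_spec)
  th <- setNames(numeric(length(nm)), nm)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  for (k in 1:2) {
    e2 <- max(vc$e2[k], 1e-4)
    if (paste0("log_a2_e2_", k) %in% nm) {
      th[paste0("log_a2_e2_", k)] <- log(max(vc$a2[k], 1e-4) / e2)
    }
    if (paste0("log_c2_e2_", k) %in% nm) {
      th[paste0("log_c2_e2_", k)] <- log(max(vc$c2[k], 1e-4) / e2)
    }
  }
  if ("atanh_rA" %in% nm) th["atanh_rA"] <- atanh(clamp(.r0(vc$rA), -0.99, 0.99))
  if ("atanh_rC" %in% nm) th["atanh_rC"] <- atanh(clamp(.r0(vc$rC), -0.99, 0.99))
  th["atanh_rE"] <- atanh(clamp(.r0(vc$rE), -0.99, 0.99))
  th["t1"] <- vc$thresholds[1]
  th["t2"] <- vc$thresholds[2]
  th
}

## ---- moment-based starting values ------------------------------------

# margins and pairwise 2x2 tables from a 16-cell count vector (pattern bit
# order m1t1, m1t2, m2t1, m2t2)
.pattern_margins <- function(counts) {
  g <- .pattern_grid()
  n <- sum(counts)
  list(p = vapply(1:4, function(j) sum(counts[g[, j] == 1]) / n, numeric(1)),
       table2 = function(i, j) {
         vapply(0:3, function(b) {
           sum(counts[g[, i] == b %% 2 & g[, j] == b %/% 2])
         }, numeric(1)) # order (0,0),(1,0),(0,1),(1,1)
       },
       n = n)
}

# tetrachoric correlation from a 2x2 table given both thresholds
.tetrachoric <- function(tab, t1, t2) {
  n <- sum(tab)
  if (any(tab == 0)) tab <- tab + 0.5
  obj <- function(r) {
    p11 <- .genz_batch(matrix(c(t1, t2), 1), matrix(c(Inf, Inf), 1),
                       t(chol(matrix(c(1, r, r, 1), 2))),
                       .qmc_lattice(521L, 1L, 1L)[[1]])
    p1 <- pnorm(t1, lower.tail = FALSE)
    p2 <- pnorm(t2, lower.tail = FALSE)
    p <- pmax(c(1 - p1 - p2 + p11, p1 - p11, p2 - p11, p11), 1e-12)
    -sum(tab * log(p))
  }
  optimize(obj, c(-0.98, 0.98))$minimum
}

# method-of-moments start: thresholds from margins, variance shares from the
# linear system in the cross-member same-trait correlations, cross-trait
# correlations from the within/cross tetrachorics
.moment_start <- function(data, model_spec, classes) {
  labs <- names(classes)
  m <- lapply(labs, function(lb) {
    rows <- data[data$relative_class == lb, , drop = FALSE]
    cnt <- rows$count[match(.pattern_labels(), rows$pattern)]
    cnt[is.na(cnt)] <- 0
    .pattern_margins(cnt)
  })
  names(m) <- labs
  wt <- vapply(m, `[[`, numeric(1), "n")
  p1 <- sum(vapply(m, function(x) mean(x$p[c(1, 3)]) * x$n, numeric(1))) / sum(wt)
  p2 <- sum(vapply(m, function(x) mean(x$p[c(2, 4)]) * x$n, numeric(1))) / sum(wt)
  t1 <- threshold_from_prevalence(min(max(p1, 1e-4), 0.9))
  t2 <- threshold_from_prevalence(min(max(p2, 1e-4), 0.9))

  same1 <- vapply(labs, function(lb) .tetrachoric(m[[lb]]$table2(1, 3), t1, t1),
                  numeric(1))
  same2 <- vapply(labs, function(lb) .tetrachoric(m[[lb]]$table2(2, 4), t2, t2),
                  numeric(1))
  cross <- vapply(labs, function(lb) {
    (.tetrachoric(m[[lb]]$table2(1, 4), t1, t2) +
       .tetrachoric(m[[lb]]$table2(2, 3), t2, t1)) / 2
  }, numeric(1))
  within <- sum(vapply(labs, function(lb) {
    x <- (.tetrachoric(m[[lb]]$table2(1, 2), t1, t2) +
            .tetrachoric(m[[lb]]$table2(3, 4), t1, t2)) / 2
    x * m[[lb]]$n
  }, numeric(1))) / sum(wt)

  S <- t(vapply(classes, function(s) c(s$a_share, s$c_share), numeric(2)))
  solve2 <- function(y) {
    fit <- tryCatch(qr.solve(S, y), error = function(e) c(0.3, 0.1))
    fit
  }
  ac1 <- solve2(same1)
  ac2 <- solve2(same2)
  shares <- function(ac, has_a, has_c) {
    a <- if (has_a) min(max(ac[1], 0.02), 0.95) else 0
    c <- if (has_c) min(max(ac[2], 0.02), 0.6) else 0
    if (a + c > 0.95) {
      f <- 0.95 / (a + c)
      a <- a * f; c <- c * f
    }
    c(a, c, 1 - a - c)
  }
  s1 <- shares(ac1, "A" %in% model_spec[[1]], "C" %in% model_spec[[1]])
  s2 <- shares(ac2, "A" %in% model_spec[[2]], "C" %in% model_spec[[2]])

  # cross-trait solves: x_class = a_share*covA + c_share*covC
  covAC <- solve2(cross)
  sA <- sqrt(s1[1] * s2[1])
  sC <- sqrt(s1[2] * s2[2])
  sE <- sqrt(s1[3] * s2[3])
  rA <- if (sA > 0) min(max(covAC[1] / sA, -0.9), 0.9) else NA_real_
  rC <- if (sC > 0) min(max(covAC[2] / sC, -0.9), 0.9) else NA_real_
  covW <- within - (if (is.na(rA)) 0 else rA * sA) -
    (if (is.na(rC)) 0 else rC * sC)
  rE <- if (sE > 0) min(max(covW / sE, -0.9), 0.9) else 0
  variance_components(c(s1[1], s2[1]), c(s1[2], s2[2]), c(s1[3], s2[3]),
                      rA = if ("A" %in% model_spec[[1]] &&
                               "A" %in% model_spec[[2]]) .r0(rA) else NA,
                      rC = if ("C" %in% model_spec[[1]] &&
                               "C" %in% model_spec[[2]]) .r0(rC) else NA,
                      rE = rE, thresholds = c(t1, t2))
}

## ---- fitting -----------------------------------------------------------

.check_identifiable <- function(model_spec, classes) {
  both_ac <- vapply(model_spec, function(cs) {
    all(c("A", "C") %in% cs)
  }, logical(1))
  if (any(both_ac)) {
    S <- t(vapply(classes, function(s) c(s$a_share, s$c_share), numeric(2)))
    if (qr(S)$rank < 2) {
      stop("A and C are jointly unidentified for trait ",
           paste(which(both_ac), collapse = " and "),
           ": need at least two relative classes with linearly independent ",
           "(a_share, c_share)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Control settings for the ACE fitter
#'
#' @param n_starts Number of optimizer starts (one moment-based, the rest
#'   dispersed around it).
#' @param n_qmc,n_shifts Lattice accuracy used inside the optimization.
#' @param n_qmc_final,n_shifts_final Accuracy used for the reported
#'   log-likelihood, AIC and Hessian.
#' @param maxit,reltol Passed to [stats::optim()] (BFGS).
#' @param hessian Compute the observed information (needed for Wald
#'   confidence intervals); disable for replicate studies that only use
#'   point estimates and AIC.
#' @param seed Seed for the dispersed starts.
#' @return List of control values.
#' @export
ace_control <- function(n_starts = 5L, n_qmc = 1021L, n_shifts = 1L,
                        n_qmc_final = 4093L, n_shifts_final = 2L,
                        maxit = 300L, reltol = 1e-9, hessian = TRUE,
                        seed = 1L) {
  list(n_starts = n_starts, n_qmc = n_qmc, n_shifts = n_shifts,
       n_qmc_final = n_qmc_final, n_shifts_final = n_shifts_final,
       maxit = maxit, reltol = reltol, hessian = hessian, seed = seed)
}

#' Fit a bivariate liability-threshold variance-component model
#'
#' Maximum-likelihood fit of the bivariate liability model to collapsed
#' 16-cell pattern counts (or per-pair rows with fixed threshold shifts)
#' from two or more relative classes. Variance proportions live on the
#' simplex via log-ratio coordinates with E as reference; cross-trait
#' correlations on the inverse-hyperbolic-tangent scale; thresholds are
#' free. Multi-start quasi-Newton optimization; confidence intervals by the
#' delta method on the observed information (profile likelihood available
#' via [profile_ci()]).
#'
#' @param data A `pattern_counts` frame (see [simulate_pattern_counts()] or
#'   [tabulate_pair_patterns()] with specs attached).
#' @param model_spec Per-trait component sets, e.g.
#'   `list(trait1 = c("A","E"), trait2 = c("A","C","E"))`.
#' @param classes List of [relative_class_spec()] keyed by label; defaults to
#'   `attr(data, "specs")`.
#' @param control See [ace_control()].
#' @return An object of class `ace_fit` with elements `estimates`
#'   ([variance_components()]), `loglik`, `aic`, `n_params`, `ci` (data
#'   frame), `shares` (cross-trait covariance decomposition), `convergence`.
#' @export
fit_bivariate_ace <- function(data,
                              model_spec = list(trait1 = c("A", "C", "E"),
                                                trait2 = c("A", "C", "E")),
                              classes = attr(data, "specs"),
                              control = ace_control()) {
  model_spec <- .check_model_spec(model_spec)
  stopifnot(!is.null(classes))
  .check_identifiable(model_spec, classes)
  nm <- .theta_names(model_spec)

  negll <- function(theta, n_qmc, n_shifts) {
    names(theta) <- nm
    vc <- tryCatch(.theta_to_vc(theta, model_spec), error = function(e) NULL)
    if (is.null(vc)) return(1e10)
    ll <- tryCatch(
      pair_loglikelihood(data, vc, classes, n_qmc = n_qmc,
                         n_shifts = n_shifts),
      error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start_vc <- .moment_start(data, model_spec, classes)
  theta0 <- .vc_to_theta(start_vc, model_spec)
  starts <- list(theta0)
  if (control$n_starts > 1L) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    set.seed(control$seed)
    for (i in seq_len(control$n_starts - 1L)) {
      starts[[i + 1L]] <- theta0 + rnorm(length(theta0), 0, 0.4)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  best <- NULL
  restarts <- 0L
  for (th0 in starts) {
    opt <- tryCatch(
      optim(th0, negll, n_qmc = control$n_qmc, n_shifts = control$n_shifts,
            method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
      restarts <- restarts + 1L
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("optimization failed from all starts", call. = FALSE)
  }
  theta_hat <- setNames(best$par, nm)
  vc_hat <- .theta_to_vc(theta_hat, model_spec)

  ll <- pair_loglikelihood(data, vc_hat, classes,
                           n_qmc = control$n_qmc_final,
                           n_shifts = control$n_shifts_final)
  k <- length(nm)
  aic <- 2 * k - 2 * ll

  Vtheta <- NULL
  if (isTRUE(control$hessian)) {
    H <- tryCatch(
      optimHess(theta_hat, negll, n_qmc = control$n_qmc_final,
                n_shifts = control$n_shifts_final),
      error = function(e) NULL)
    Vtheta <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  }
  ci <- .ace_wald_ci(theta_hat, Vtheta, model_spec)
  grad_norm <- {
    eps <- 1e-5
    g <- vapply(seq_along(theta_hat), function(j) {
      tp <- theta_hat; tm <- theta_hat
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      (negll(tp, control$n_qmc, control$n_shifts) -
         negll(tm, control$n_qmc, control$n_shifts)) / (2 * eps)
    }, numeric(1))
    sqrt(sum(g^2))
  }

  structure(
    list(estimates = vc_hat, model_spec = model_spec, classes = classes,
         theta = theta_hat, vcov_theta = Vtheta, loglik = ll, aic = aic,
         n_params = k, ci = ci,
         shares = decompose_correlation(vc_hat),
         convergence = list(code = best$convergence,
                            gradient_norm = grad_norm,
                            failed_starts = restarts,
                            n_starts = control$n_starts),
         control = control),
    class = "ace_fit")
}

# natural-scale parameter functions for delta-method intervals
.natural_params <- function(theta, model_spec) {
  vc <- .theta_to_vc(setNames(theta, .theta_names(model_spec)), model_spec)
  out <- c(a2_1 = vc$a2[1], c2_1 = vc$c2[1], e2_1 = vc$e2[1],
           a2_2 = vc$a2[2], c2_2 = vc$c2[2], e2_2 = vc$e2[2],
           rA = .r0(vc$rA), rC = .r0(vc$rC), rE = .r0(vc$rE),
           t1 = vc$thresholds[1], t2 = vc$thresholds[2])
  out
}

.ace_wald_ci <- function(theta_hat, Vtheta, model_spec, level = 0.95) {
  est <- .natural_params(theta_hat, model_spec)
  keep <- names(est)
  vc <- .theta_to_vc(setNames(theta_hat, .theta_names(model_spec)), model_spec)
  absent <- c(if (!"A" %in% model_spec[[1]]) c("a2_1"),
              if (!"C" %in% model_spec[[1]]) c("c2_1"),
              if (!"A" %in% model_spec[[2]]) c("a2_2"),
              if (!"C" %in% model_spec[[2]]) c("c2_2"),
              if (is.na(vc$rA)) "rA", if (is.na(vc$rC)) "rC")
  se <- rep(NA_real_, length(est))
  names(se) <- keep
  if (!is.null(Vtheta)) {
    eps <- 1e-6
    J <- vapply(seq_along(theta_hat), function(j) {
      tp <- theta_hat; tm <- theta_hat
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      (.natural_params(tp, model_spec) - .natural_params(tm, model_spec)) /
        (2 * eps)
    }, numeric(length(est)))
    V <- J %*% Vtheta %*% t(J)
    se <- sqrt(pmax(diag(V), 0))
    names(se) <- keep
  }
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(parameter = keep, estimate = unname(est),
                    se = unname(se),
                    ci_low = unname(est - z * se),
                    ci_high = unname(est + z * se),
                    stringsAsFactors = FALSE)
  out[out$parameter %in% absent, c("estimate", "se", "ci_low", "ci_high")] <-
    NA_real_
  out
}

#' Profile-likelihood confidence interval for one fitted parameter
#'
#' Re-optimizes all other parameters while a quadratic penalty pins the
#' chosen natural-scale parameter at candidate values, and locates the
#' likelihood-ratio crossing by bisection.
#'
#' @param fit An `ace_fit`.
#' @param parameter One of the natural-parameter names in `fit$ci$parameter`.
#' @param level Confidence level.
#' @param data,classes The data used for the fit.
#' @return Length-2 vector of interval bounds.
#' @export
profile_ci <- function(fit, parameter, data, classes = fit$classes,
                       level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"),
            parameter %in% fit$ci$parameter)
  nm <- .theta_names(fit$model_spec)
  target_ll <- fit$loglik - qchisq(level, 1) / 2
  ctrl <- fit$control
  prof_ll <- function(value) {
    obj <- function(theta) {
      names(theta) <- nm
      vc <- tryCatch(.theta_to_vc(theta, fit$model_spec),
                     error = function(e) NULL)
      if (is.null(vc)) return(1e10)
      np <- .natural_params(theta, fit$model_spec)
      pen <- 1e6 * (np[[parameter]] - value)^2
      ll <- tryCatch(pair_loglikelihood(data, vc, classes,
                                        n_qmc = ctrl$n_qmc,
                                        n_shifts = ctrl$n_shifts),
                     error = function(e) NA_real_)
      if (!is.finite(ll)) return(1e10)
      -ll + pen
    }
    opt <- optim(fit$theta, obj, method = "BFGS",
                 control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    -opt$value
  }
  est <- fit$ci$estimate[fit$ci$parameter == parameter]
  se <- fit$ci$se[fit$ci$parameter == parameter]
  if (!is.finite(se) || se <= 0) se <- 0.1
  bound <- function(dir) {
    f <- function(v) prof_ll(v) - target_ll
    lo <- est
    hi <- est + dir * 4 * se
    val <- f(hi)
    tries <- 0L
    while (val > 0 && tries < 4L) {
      hi <- hi + dir * 2 * se
      val <- f(hi)
      tries <- tries + 1L
    }
    if (val > 0) return(NA_real_)
    uniroot(f, sort(c(lo, hi)), tol = 1e-4)$root
  }
  c(lower = bound(-1), upper = bound(1))
}

#' Rank candidate component structures by AIC
#'
#' Fits each candidate model specification and ranks by Akaike information
#' criterion (2 * parameters - 2 * log-likelihood), breaking AIC ties in
#' favour of fewer parameters. Failed fits are excluded with a warning.
#'
#' @param data A `pattern_counts` frame.
#' @param candidates Named list of model specifications (each as in
#'   [fit_bivariate_ace()]).
#' @param classes,control Passed to [fit_bivariate_ace()].
#' @return A list with `table` (candidate, n_params, loglik, aic, delta_aic,
#'   ranked) and `fits` (the fitted objects, best first).
#' @export
select_model <- function(data, candidates, classes = attr(data, "specs"),
                         control = ace_control()) {
  stopifnot(length(candidates) >= 2, !is.null(names(candidates)))
  fits <- list()
  for (nm in names(candidates)) {
    fits[[nm]] <- tryCatch(
      fit_bivariate_ace(data, candidates[[nm]], classes, control),
      error = function(e) {
        warning("candidate '", nm, "' failed to fit: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("no candidate model could be fitted", call. = FALSE)
  tab <- data.frame(
    candidate = names(fits),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE)
  ord <- order(tab$aic, tab$n_params)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  list(table = tab, fits = fits[ord], best = fits[[ord[1]]])
}

#' Decompose the cross-trait liability covariance
#'
#' Splits the model-implied cross-trait covariance into its A, C and E parts
#' (`rA*sqrt(a2_1*a2_2)` and so on) and reports each as a share of the
#' total. Structurally absent components are reported as `NA`; if the total
#' covariance is (numerically) zero the shares are undefined.
#'
#' @param x A [variance_components()] object or an `ace_fit`.
#' @return Data frame (component, covariance, share).
#' @export
decompose_correlation <- function(x) {
  vc <- if (inherits(x, "ace_fit")) x$estimates else x
  stopifnot(inherits(vc, "variance_components"))
  cc <- .cross_cov(vc)
  absent <- c(A = is.na(vc$rA) || vc$a2[1] == 0 || vc$a2[2] == 0,
              C = is.na(vc$rC) || vc$c2[1] == 0 || vc$c2[2] == 0,
              E = is.na(vc$rE) || vc$e2[1] == 0 || vc$e2[2] == 0)
  total <- sum(cc[!absent])
  share <- if (abs(total) < 1e-12) rep(NA_real_, 3) else cc / total
  out <- data.frame(component = c("A", "C", "E"),
                    covariance = unname(cc), share = unname(share),
                    stringsAsFactors = FALSE)
  out$covariance[absent] <- NA_real_
  out$share[absent] <- NA_real_
  attr(out, "total_covariance") <- total
  out
}

#' @export
print.ace_fit <- function(x, digits = 3, ...) {
  vc <- x$estimates
  cat("Bivariate liability-threshold variance components",
      "(maximum likelihood)\n")
  spec_lab <- vapply(x$model_spec, paste, "", collapse = "")
  cat(sprintf("  model: trait1 %s / trait2 %s;  logLik %.2f;  AIC %.2f\n",
              spec_lab[1], spec_lab[2], x$loglik, x$aic))
  fmt <- function(v) ifelse(is.na(v), "  NA ", formatC(v, digits = digits,
                                                       format = "f"))
  cat("             A      C      E   threshold\n")
  for (k in 1:2) {
    cat(sprintf("  trait%d  %s %s %s   %s\n", k,
                fmt(if (vc$a2[k] == 0 && !("A" %in% x$model_spec[[k]]))
                  NA else vc$a2[k]),
                fmt(if (vc$c2[k] == 0 && !("C" %in% x$model_spec[[k]]))
                  NA else vc$c2[k]),
                fmt(vc$e2[k]), fmt(vc$thresholds[k])))
  }
  cat(sprintf("  correlations: rA %s  rC %s  rE %s\n",
              fmt(vc$rA), fmt(vc$rC), fmt(vc$rE)))
  sh <- x$shares
  cat(sprintf("  covariance shares: A %s  C %s  E %s\n",
              fmt(sh$share[1]), fmt(sh$share[2]), fmt(sh$share[3])))
  invisible(x)
}
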