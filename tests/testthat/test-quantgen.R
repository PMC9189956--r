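test_that("pair correlation matrices implement the sharing algebra", {
  vc <- table3_vc()
  # cousin class: within-person cross 0.0637, same-trait-1 0.105,
  # cross-person cross 0.00714 (arithmetic from the component formulas)
  M <- pair_correlation_matrix(vc, cousin_class())
  expect_equal(M[1, 2], 0.13 * sqrt(0.84 * 0.23) + 0.02 * sqrt(0.16 * 0.68),
               tolerance = 1e-12)
  expect_equal(M[1, 2], 0.0637, tolerance = 1e-3)
  expect_equal(M[1, 3], 0.125 * 0.84, tolerance = 1e-12)
  expect_equal(M[1, 4], 0.125 * 0.13 * sqrt(0.84 * 0.23), tolerance = 1e-12)
  expect_equal(M[1, 4], 0.00714, tolerance = 1e-3)
  expect_identical(M, t(M))
  expect_true(all(eigen(M, only.values = TRUE)$values > 0))

  # sibling class with a pure additive trait: cross-person correlation 1/2
  vc2 <- variance_components(c(1, 0), c(0, 0), c(0, 1),
                             thresholds = c(1, 1))
  M2 <- pair_correlation_matrix(vc2, sibling_class())
  expect_identical(M2[1, 3], 0.5)
  expect_identical(M2[1, 2], 0)
  expect_identical(M2[2, 4], 0)

  # zero sharing and zero correlations: identity off the diagonal
  M3 <- pair_correlation_matrix(vc2, relative_class_spec("none", 0, 0))
  expect_identical(M3[lower.tri(M3)], rep(0, 6))
})

test_that("the pair log-likelihood factorizes for independent liabilities", {
  vc <- variance_components(c(0, 0), c(0, 0), c(1, 1), rE = 0,
                            thresholds = c(1.2, 0.8))
  counts <- data.frame(relative_class = "none", pattern = "1010",
                       count = 1)
  attr(counts, "specs") <- list(none = relative_class_spec("none", 0, 0))
  ll <- pair_loglikelihood(counts, vc)
  # oracle: log of the product of four univariate probabilities
  want <- 2 * log(pnorm(1.2, lower.tail = FALSE)) + 2 * log(pnorm(0.8))
  expect_equal(ll, want, tolerance = 1e-6)
})

test_that("collapsed and per-pair likelihood modes agree at zero shifts", {
  vc <- table3_vc()
  set.seed(71)
  pc <- simulate_pattern_counts(vc, n_pairs = c(full_sibling = 3000,
                                                cousin = 1000))
  ll_collapsed <- pair_loglikelihood(pc, vc)
  per_pair <- pc[rep(seq_len(nrow(pc)), pc$count), c("relative_class",
                                                     "pattern")]
  per_pair$shift_m1_t1 <- 0
  per_pair$shift_m1_t2 <- 0
  per_pair$shift_m2_t1 <- 0
  per_pair$shift_m2_t2 <- 0
  ll_pairs <- pair_loglikelihood(per_pair, vc,
                                 classes = attr(pc, "specs"))
  expect_equal(ll_collapsed, ll_pairs, tolerance = 1e-9)
})

test_that("the likelihood is invariant to swapping pair members", {
  vc <- table3_vc()
  set.seed(72)
  pc <- simulate_pattern_counts(vc, n_pairs = c(full_sibling = 5000,
                                                cousin = 2000))
  swapped <- pc
  swapped$pattern <- paste0(substr(pc$pattern, 3, 4),
                            substr(pc$pattern, 1, 2))
  attr(swapped, "specs") <- attr(pc, "specs")
  # equality up to the accuracy of the lattice integration
  expect_equal(pair_loglikelihood(pc, vc),
               pair_loglikelihood(swapped, vc), tolerance = 1e-6)
})

test_that("the generating parameters beat perturbed ones on large counts", {
  vc <- table3_vc()
  set.seed(73)
  pc <- simulate_pattern_counts(vc, n_pairs = c(full_sibling = 2e5,
                                                cousin = 5e4))
  ll0 <- pair_loglikelihood(pc, vc)
  for (delta in list(c(0.06, 0), c(-0.06, 0), c(0, 0.2), c(0, -0.2))) {
    vcp <- variance_components(
      a2 = pmin(pmax(vc$a2 + delta[1], 0.01), 0.97),
      c2 = vc$c2, e2 = 1 - pmin(pmax(vc$a2 + delta[1], 0.01), 0.97) - vc$c2,
      rA = vc$rA, rC = vc$rC, rE = min(max(vc$rE + delta[2], -0.9), 0.9),
      thresholds = vc$thresholds)
    expect_lt(pair_loglikelihood(pc, vcp), ll0)
  }
})

test_that("identifiability of A and C requires contrasting relative classes", {
  vc <- table3_vc()
  set.seed(74)
  pc <- simulate_pattern_counts(vc, n_pairs = c(full_sibling = 2000))
  expect_error(
    fit_bivariate_ace(pc, list(trait1 = c("A", "C", "E"),
                               trait2 = c("A", "C", "E")),
                      classes = attr(pc, "specs")),
    "unidentified")
  expect_error(
    fit_bivariate_ace(pc, list(trait1 = c("A", "B"), trait2 = c("E"))),
    "subset")
})

test_that("maximum likelihood recovers generating parameters at reduced n", {
  # at this problem size the trait-2 decomposition has a flat ridge
  # (a2_2, c2_2 and rA trade off through the cousin cells), so the sharply
  # identified quantities carry tight bounds and the ridge parameters wide
  # ones
  vc <- table3_vc()
  pc <- simulate_pattern_counts(vc, n_pairs = c(full_sibling = 2e5,
                                                cousin = 5e4), seed = 76)
  fit <- fit_bivariate_ace(pc, list(trait1 = c("A", "E"),
                                    trait2 = c("A", "C", "E")),
                           control = ace_control(n_starts = 1))
  est <- fit$estimates
  # threshold/prevalence duality and trait-1 heritability: well identified
  expect_lt(abs(est$thresholds[1] - threshold_from_prevalence(0.023)), 0.03)
  expect_lt(abs(est$thresholds[2] - threshold_from_prevalence(0.0414)), 0.03)
  expect_lt(abs(est$a2[1] - 0.84), 0.08)
  # within-person cross-trait covariance: well identified
  w <- est$rA * sqrt(est$a2[1] * est$a2[2]) +
    est$rE * sqrt(est$e2[1] * est$e2[2])
  expect_lt(abs(w - 0.0637), 0.02)
  # sibling same-trait-2 liability correlation: well identified
  expect_lt(abs((0.5 * est$a2[2] + est$c2[2]) - 0.205), 0.03)
  # ridge parameters: wide sampling bounds
  expect_lt(abs(est$a2[2] - 0.23), 0.20)
  expect_lt(abs(est$c2[2] - 0.09), 0.12)
  expect_lt(abs(est$rA - 0.13), 0.20)
  expect_lt(abs(est$rE - 0.02), 0.12)
  # structurally absent parameters are reported absent
  ci <- fit$ci
  expect_true(is.na(ci$estimate[ci$parameter == "c2_1"]))
  expect_true(is.na(ci$estimate[ci$parameter == "rC"]))
  # interval geometry for reported parameters
  ok <- !is.na(ci$se) & ci$se > 0
  expect_true(all(ci$ci_low[ok] <= ci$estimate[ok] + 1e-12))
  expect_true(all(ci$estimate[ok] <= ci$ci_high[ok] + 1e-12))
})

test_that("a null genetic correlation is recovered with covering interval", {
  vc0 <- variance_components(c(0.84, 0.23), c(0, 0.09), c(0.16, 0.68),
                             rA = 0, rC = NA, rE = 0.02,
                             thresholds = threshold_from_prevalence(
                               c(0.023, 0.0414)))
  set.seed(76)
  pc <- simulate_pattern_counts(vc0, n_pairs = c(full_sibling = 2e5,
                                                 cousin = 5e4))
  fit <- fit_bivariate_ace(pc, list(trait1 = c("A", "E"),
                                    trait2 = c("A", "C", "E")),
                           control = ace_control(n_starts = 1))
  ci <- fit$ci
  r <- ci[ci$parameter == "rA", ]
  # the identified quantity is the genetic cross-trait covariance
  est <- fit$estimates
  expect_lt(abs(est$rA * sqrt(est$a2[1] * est$a2[2])), 0.05)
  expect_lt(abs(r$estimate), 0.25)
  expect_true(r$ci_low <= 0 && 0 <= r$ci_high)
})

test_that("AIC ranking follows the definition and penalizes rigidity", {
  vc <- table3_vc()
  set.seed(77)
  pc <- simulate_pattern_counts(vc, n_pairs = c(full_sibling = 5e4,
                                                cousin = 1.5e4))
  sel <- select_model(
    pc,
    candidates = list(
      AE_ACE = list(trait1 = c("A", "E"), trait2 = c("A", "C", "E")),
      AE_AE = list(trait1 = c("A", "E"), trait2 = c("A", "E")),
      E_E = list(trait1 = "E", trait2 = "E")),
    control = ace_control(n_starts = 1, hessian = FALSE))
  tab <- sel$table
  # nested models: AIC difference = 2 dparams - 2 dloglik exactly
  i <- match("AE_ACE", tab$candidate)
  j <- match("AE_AE", tab$candidate)
  expect_equal(tab$aic[i] - tab$aic[j],
               2 * (tab$n_params[i] - tab$n_params[j]) -
                 2 * (tab$loglik[i] - tab$loglik[j]), tolerance = 1e-9)
  # a no-familial-resemblance model is ranked last on familial data
  expect_identical(tab$candidate[nrow(tab)], "E_E")
  expect_identical(tab$delta_aic[1], 0)
})

test_that("cross-trait covariance decomposition normalizes and handles absences", {
  vc <- table3_vc()
  sh <- decompose_correlation(vc)
  expect_equal(sum(sh$share, na.rm = TRUE), 1, tolerance = 1e-12)
  # arithmetic from the fitted values: A share 0.0571/0.0637 = 0.897
  expect_equal(sh$share[sh$component == "A"],
               (0.13 * sqrt(0.84 * 0.23)) /
                 (0.13 * sqrt(0.84 * 0.23) + 0.02 * sqrt(0.16 * 0.68)),
               tolerance = 1e-12)
  expect_equal(sh$share[sh$component == "A"], 0.897, tolerance = 1e-3)
  expect_true(is.na(sh$share[sh$component == "C"]))

  # pure-A covariance: A share is 1
  vcA <- variance_components(c(0.84, 0.23), c(0, 0.09), c(0.16, 0.68),
                             rA = 0.13, rC = NA, rE = 0,
                             thresholds = c(2, 1.7))
  shA <- decompose_correlation(vcA)
  expect_equal(shA$share[shA$component == "A"], 1, tolerance = 1e-12)

  # no shared component at all: undefined shares
  vc0 <- variance_components(c(0.84, 0.23), c(0, 0.09), c(0.16, 0.68),
                             rA = 0, rC = NA, rE = 0,
                             thresholds = c(2, 1.7))
  expect_true(all(is.na(decompose_correlation(vc0)$share)))
})

test_that("simulated pair liabilities match the implied correlation matrix", {
  vc <- table3_vc()
  set.seed(78)
  sim <- simulate_pair_liabilities(vc, sibling_class(), 6e4)
  emp <- cor(sim$total)
  want <- pair_correlation_matrix(vc, sibling_class())
  expect_lt(max(abs(emp - want)), 0.02)
  # component sharing: C identical across members (up to the numerical
  # symmetrization of the rank-deficient square root), E uncorrelated
  expect_equal(sim$C[, 2], sim$C[, 4], tolerance = 1e-6)
  expect_lt(abs(cor(sim$E[, 1], sim$E[, 3])), 0.02)
})
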