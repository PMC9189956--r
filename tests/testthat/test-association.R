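# independent natural-cubic-spline construction via the truncated power
# basis with natural constraints: for knots k_1 < ... < k_K,
# d_j(x) = ((x - k_j)_+^3 - (x - k_K)_+^3) / (k_K - k_j), basis functions
# x and d_j - d_{K-1} for j = 1..K-2 (plus intercept in the model)
tpb_natural_spline <- function(x, knots) {
  K <- length(knots)
  d <- function(j) {
    (pmax(x - knots[j], 0)^3 - pmax(x - knots[K], 0)^3) / (knots[K] - knots[j])
  }
  cols <- lapply(seq_len(K - 2), function(j) d(j) - d(K - 1))
  cbind(x, do.call(cbind, cols))
}

test_that("the spline basis is natural and matches the power-basis fit", {
  set.seed(3)
  x <- c(seq(1960, 2010, by = 0.5), runif(200, 1960, 2010))
  basis <- natural_cubic_spline_basis(x, 5)
  expect_identical(ncol(basis), 4L) # 5 knots -> dimension 4
  knots <- attr(basis, "knots")

  # linearity beyond the boundary knots: second differences vanish
  grid_out <- seq(knots[5] + 1, knots[5] + 20, by = 1)
  vals <- predict_spline_basis(basis, grid_out)
  second_diff <- diff(vals, differences = 2)
  expect_lt(max(abs(second_diff)), 1e-8)
  grid_in <- seq(knots[2], knots[4], by = 0.5)
  vals_in <- predict_spline_basis(basis, grid_in)
  expect_gt(max(abs(diff(vals_in, differences = 2))), 1e-6)

  # same fitted values as the truncated-power-basis construction
  y <- sin((x - 1960) / 8) + rnorm(length(x), 0, 0.1)
  f1 <- lm.fit(cbind(1, basis), y)$fitted.values
  f2 <- lm.fit(cbind(1, tpb_natural_spline(x, knots)), y)$fitted.values
  expect_equal(f1, f2, tolerance = 1e-8)

  expect_error(natural_cubic_spline_basis(rep(5, 10)), "distinct")
  expect_error(natural_cubic_spline_basis(x, knots = c(1980, 1980, 1990)),
               "oincident")
})

test_that("a covariate-free fit reproduces the 2x2 cross-product ratio", {
  # counts laid out as (unexposed no-case, unexposed case, exposed no-case,
  # exposed case); cross-product ratio 5577*4850279/(113350*209019)
  d <- expand.grid(y = 0:1, x = 0:1)
  w <- c(4850279, 209019, 113350, 5577)
  res <- fit_logistic_or(d$y, d$x, weights = w)
  oracle <- (5577 * 4850279) / (113350 * 209019)
  expect_equal(res$estimate, oracle, tolerance = 1e-6)
  expect_equal(res$estimate, 1.141721, tolerance = 1e-6)
  expect_identical(res$n_pairs, sum(w))
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
  # Wald geometry: bounds are exp(log-estimate -/+ 1.96 log-se)
  z <- qnorm(0.975)
  expect_equal(res$ci_low, exp(res$log_or - z * res$log_se), tolerance = 1e-12)
  expect_equal(res$ci_high, exp(res$log_or + z * res$log_se), tolerance = 1e-12)
})

test_that("the null is calibrated: permuted exposures reject at the nominal rate", {
  set.seed(61)
  n <- 400
  reps <- 400
  pvals <- replicate(reps, {
    y <- rbinom(n, 1, 0.2)
    x <- sample(rbinom(n, 1, 0.3)) # independent of y by permutation
    fit_logistic_or(y, x)$p_value
  })
  rate <- mean(pvals < 0.05)
  bound <- 2.58 * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), bound)
})

test_that("sandwich variance collapses to HC0 for singleton clusters and is label-invariant", {
  set.seed(8)
  n <- 300
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  singleton <- fit_logistic_or(y, x, cluster_ids = seq_len(n))
  hc0 <- fit_logistic_or(y, x, cluster_ids = NULL)
  # n/(n-1) small-sample factors differ at most negligibly
  expect_equal(singleton$log_se, hc0$log_se, tolerance = 0.01)

  cl <- rep(1:30, each = 10)
  a <- fit_logistic_or(y, x, cluster_ids = cl)
  b <- fit_logistic_or(y, x, cluster_ids = sample(1000, 30)[cl])
  expect_equal(a$log_se, b$log_se, tolerance = 1e-12)
  expect_identical(a$n_clusters, 30L)

  expect_warning(fit_logistic_or(y, x, cluster_ids = rep(1, n)),
                 "fewer than two clusters")
})

test_that("clustered outcomes inflate the sandwich variance over the model-based one", {
  set.seed(12)
  hits <- 0
  for (r in 1:20) {
    cl <- rep(1:60, each = 8)
    u <- rnorm(60)[cl] # strong shared cluster effect
    x <- rbinom(60, 1, 0.5)[cl] # cluster-level exposure
    y <- rbinom(480, 1, plogis(-0.5 + x + 1.5 * u))
    res <- fit_logistic_or(y, x, cluster_ids = cl)
    naive_se <- sqrt(vcov(res$fit)[".x", ".x"])
    hits <- hits + (res$log_se > naive_se)
  }
  expect_gte(hits, 16) # robust SE larger in the clear majority of replicates
})

test_that("interaction models recover the ratio of stratum odds ratios", {
  # two hand-built 2x2 tables: OR 2.0 in stratum 1, OR 1.0 in stratum 0
  d <- expand.grid(y = 0:1, x = 0:1, m = 0:1)
  w <- c(1000, 250, 1000, 250,   # stratum 0: OR = 1
         1000, 200, 1000, 400)   # stratum 1: OR = (400/1000)/(200/1000) = 2
  res <- fit_or_with_interaction(d$y, d$x, d$m, weights = w)
  expect_equal(res$ratio, 2.0, tolerance = 1e-6)
  expect_equal(res$strata$modifier0$estimate, 1.0, tolerance = 1e-6)
  expect_equal(res$strata$modifier1$estimate, 2.0, tolerance = 1e-6)
  # saturation identity: stratified ORs equal the interaction-model
  # combinations exp(b_x) and exp(b_x + b_xm)
  bx <- coef(res$fit)[".x"]
  bxm <- coef(res$fit)[".x:.m"]
  expect_equal(unname(exp(bx)), res$strata$modifier0$estimate,
               tolerance = 1e-8)
  expect_equal(unname(exp(bx + bxm)), res$strata$modifier1$estimate,
               tolerance = 1e-8)
  expect_error(fit_or_with_interaction(d$y, d$x, rep(1, 8), weights = w),
               "stratum 0 is empty")
})

test_that("identical strata give an interaction ratio of one", {
  d <- expand.grid(y = 0:1, x = 0:1, m = 0:1)
  w <- rep(c(800, 150, 700, 300), 2)
  res <- fit_or_with_interaction(d$y, d$x, d$m, weights = w)
  expect_equal(res$ratio, 1.0, tolerance = 1e-8)
})

test_that("perfect separation is flagged rather than silent", {
  y <- c(rep(0, 20), rep(1, 20))
  x <- y
  res <- suppressWarnings(fit_logistic_or(y, c(x[-1], 0)))
  expect_false(res$separation)
  res2 <- fit_logistic_or(y, x)
  expect_true(res2$separation)
})

test_that("no cross-trait correlation means no cross-trait co-aggregation", {
  # with rA = rC = rE = 0 the two traits are independent within and across
  # persons, so every cross-relative odds ratio is null
  p <- simulation_params(n_families = 2500, rA = 0, rC = 0, rE = 0,
                         seed = 55)
  b <- simulate_register_bundle(p)
  idx <- build_index_cohort(b, c(1960L, 2010L))
  defs <- default_case_definitions()
  ph <- build_phenotypes(b, defs)
  ph <- build_any_ad(ph, setdiff(names(defs), "adhd"))
  for (rel in c("full_sibling", "cousin")) {
    pr <- build_relative_pairs(b, idx, rel)
    res <- run_pair_association(pr, ph, b$persons, "adhd", "anyAD")
    expect_true(res$ci_low <= 1 && 1 <= res$ci_high, info = rel)
    expect_lt(abs(log(res$estimate)), 3 * res$log_se)
  }
})

test_that("pair association wires exposure, outcome, splines and clusters", {
  b <- demo_bundle(400, 11)
  idx <- build_index_cohort(b, c(1960L, 2010L))
  defs <- default_case_definitions()
  ph <- build_phenotypes(b, defs)
  ph <- build_any_ad(ph, setdiff(names(defs), "adhd"))
  sib <- build_relative_pairs(b, idx, "full_sibling")
  res <- run_pair_association(sib, ph, b$persons, "adhd", "anyAD")
  expect_s3_class(res, "or_result")
  expect_equal(res$n_pairs, nrow(sib))
  expect_identical(res$n_clusters, length(unique(sib$family_cluster_id)))
  expect_match(res$model_spec, "full_sibling")
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)

  wi <- run_within_association(idx, ph, "adhd", "anyAD")
  expect_s3_class(wi, "or_result")
  expect_match(wi$model_spec, "within individual")
  expect_error(run_pair_association(sib, ph, b$persons, "nope", "anyAD"),
               "nope")
})
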