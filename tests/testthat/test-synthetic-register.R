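test_that("liability thresholds invert the standard normal upper tail", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  # oracle: inverse standard-normal CDF
  expect_equal(threshold_from_prevalence(0.023), qnorm(1 - 0.023))
  expect_equal(threshold_from_prevalence(0.023), 1.9954, tolerance = 1e-4)
  expect_equal(threshold_from_prevalence(0.0414), 1.7347, tolerance = 1e-4)
  expect_error(threshold_from_prevalence(0), "inside")
  expect_error(threshold_from_prevalence(1), "inside")
})

test_that("parameter validation rejects impossible settings", {
  expect_error(simulation_params(a2 = c(0.9, 0.23)), "equal 1")
  expect_error(simulation_params(rA = 1.5), "-1, 1")
  expect_error(simulation_params(prevalence = c(0, 0.04)), "inside")
  expect_error(
    simulate_pedigree_structure(
      simulation_params(birth_year_range = c(1990L, 2010L))),
    "too narrow")
})

test_that("degenerate sibship distributions yield the expected structure", {
  # all sibships of size 1: no siblings, no aunts/uncles, no cousins
  set.seed(104)
  p1 <- simulation_params(n_families = 1, sibship_probs = 1, seed = 4,
                          censor_before_10_prob = 0)
  ped <- simulate_pedigree_structure(p1)
  expect_identical(sum(ped$persons$role == "index"), 1L)
  expect_identical(sum(ped$persons$role %in% c("aunt", "uncle")), 0L)
  expect_identical(sum(ped$persons$role == "cousin"), 0L)
  idx <- ped$persons$person_id[ped$persons$role == "index"]
  lk <- ped$links[ped$links$child_id == idx, ]
  expect_false(is.na(lk$mother_id))
  expect_false(is.na(lk$father_id))

  # all sibships of size 2: every index person has at least one cousin
  p2 <- simulation_params(n_families = 1, sibship_probs = c(0, 1), seed = 4,
                          censor_before_10_prob = 0)
  ped2 <- simulate_pedigree_structure(p2)
  expect_identical(sum(ped2$persons$role %in% c("aunt", "uncle")), 2L)
  expect_gte(sum(ped2$persons$role == "cousin"), 2L)
})

test_that("pedigree composition matches branching expectations", {
  # uniform sibships on {1,2,3}: per family E[index-sibship sibling pairs]
  # = E[choose(s,2)] = 4/3 and E[index-cousin links] = E[s] * 2 * E[s-1]
  # * E[s] = 8; compare within 3 SD of the replicate mean
  nf <- 1500
  set.seed(121)
  p <- simulation_params(n_families = nf, seed = 21,
                         censor_before_10_prob = 0)
  ped <- simulate_pedigree_structure(p)
  roles <- ped$persons$role
  fam <- ped$persons$family
  sib_pairs_per_family <- tapply(roles == "index", fam, function(x) {
    choose(sum(x), 2)
  })
  expect_lt(abs(mean(sib_pairs_per_family) - 4 / 3),
            3 * sd(sib_pairs_per_family) / sqrt(nf))
  cousins_per_family <- tapply(seq_along(roles), fam, function(ix) {
    sum(roles[ix] == "index") * sum(roles[ix] == "cousin")
  })
  expect_lt(abs(mean(cousins_per_family) - 8),
            3 * sd(cousins_per_family) / sqrt(nf))
})

test_that("pedigree liabilities reproduce kinship sharing fractions", {
  # pure additive trait 1: sibling correlation 1/2, cousin correlation 1/8
  set.seed(131)
  p <- simulation_params(n_families = 4000, a2 = c(1, 0.23),
                        c2 = c(0, 0.09), e2 = c(0, 0.68), seed = 31,
                        censor_before_10_prob = 0)
  ped <- simulate_pedigree_structure(p)
  liab <- simulate_liabilities(ped, p)
  stopifnot(identical(liab$person_id, ped$persons$person_id))
  l1 <- liab$total[, 1]
  mo <- ped$links$mother_id[match(ped$persons$person_id,
                                  ped$links$child_id)]
  fa <- ped$links$father_id[match(ped$persons$person_id,
                                  ped$links$child_id)]
  sib_key <- paste(mo, fa)
  idx <- which(ped$persons$role == "index")
  sp <- split(idx, sib_key[idx])
  pairs <- do.call(rbind, lapply(sp[lengths(sp) >= 2], function(ix) {
    cbind(ix[1], ix[2])
  }))
  r_sib <- cor(l1[pairs[, 1]], l1[pairs[, 2]])
  expect_lt(abs(r_sib - 0.5), 3 / sqrt(nrow(pairs)))

  cz <- which(ped$persons$role == "cousin")
  fam <- ped$persons$family
  cpairs <- do.call(rbind, lapply(split(idx, fam[idx]), function(ix) {
    cc <- cz[fam[cz] == fam[ix[1]]]
    if (!length(cc)) return(NULL)
    cbind(ix[1], cc[1])
  }))
  r_cous <- cor(l1[cpairs[, 1]], l1[cpairs[, 2]])
  expect_lt(abs(r_cous - 0.125), 3 / sqrt(nrow(cpairs)))

  # study values: within-person cross-trait correlation of totals
  set.seed(132)
  p2 <- simulation_params(n_families = 4000, seed = 32,
                          censor_before_10_prob = 0)
  liab2 <- simulate_liabilities(simulate_pedigree_structure(p2), p2)
  # oracle: rA*sqrt(a2_1*a2_2) + rE*sqrt(e2_1*e2_2) = 0.0637
  r_within <- cor(liab2$total[, 1], liab2$total[, 2])
  expect_lt(abs(r_within - 0.0637), 3 / sqrt(nrow(liab2$total)))
  # and unit total variance
  expect_equal(var(liab2$total[, 1]), 1, tolerance = 0.05)
  expect_equal(var(liab2$total[, 2]), 1, tolerance = 0.05)
})

test_that("thresholding hits the target prevalence and sex ordering", {
  set.seed(141)
  p <- simulation_params(n_families = 4000, seed = 41)
  ped <- simulate_pedigree_structure(p)
  liab <- simulate_liabilities(ped, p)
  phen <- liabilities_to_phenotypes(liab, ped$persons, p)
  n <- nrow(ped$persons)
  fam <- ped$persons$family
  for (k in 1:2) {
    cases <- phen$is_case[phen$trait == paste0("trait", k)]
    pk <- mean(cases)
    # family-clustered sampling: 3 SE from the family-total residuals
    s_f <- tapply(cases, fam, sum)
    n_f <- tabulate(fam)
    se <- sqrt(sum((s_f - pk * n_f)^2)) / n
    expect_lt(abs(pk - p$prevalence[k]), 3 * se)
  }
  # positive female threshold shift for trait 1 depresses female prevalence
  sex <- ped$persons$sex
  t1 <- phen[phen$trait == "trait1", ]
  expect_lt(mean(t1$is_case[sex == "female"]), mean(t1$is_case[sex == "male"]))

  # truth is retained for persons censored in childhood
  cens <- !is.na(ped$persons$death_year) | !is.na(ped$persons$emigration_year)
  expect_gt(sum(t1$is_case[cens]), 0)
})

test_that("event emission respects the coding eras", {
  p <- simulation_params(n_families = 2, seed = 5)
  persons <- data.frame(person_id = c("a", "b", "c"), sex = "male",
                        birth_year = c(1950L, 1980L, 1995L),
                        death_year = NA_integer_,
                        emigration_year = NA_integer_)
  phen <- data.frame(
    person_id = c("a", "b", "c"), trait = "trait1",
    liability = 3, is_case = TRUE,
    diagnosis_year = c(1970L, 1999L, 2004L))
  phen <- rbind(phen, within(phen, {
    trait <- "trait2"; is_case <- FALSE; diagnosis_year <- NA_integer_
  }))
  links <- data.frame(child_id = character(0), mother_id = character(0),
                      father_id = character(0))

  cfg <- default_coding_config(drug_only_fraction = c(0, 0))
  set.seed(1)
  b <- emit_register(phen, persons, links, p, cfg)
  cs <- setNames(b$diagnoses$code_system, b$diagnoses$person_id)
  expect_identical(unname(cs["a"]), "ICD8")   # 1970
  expect_identical(unname(cs["b"]), "ICD10")  # 1999

  # drug-only case diagnosed 2004: before the drug-register era, invisible
  cfg2 <- default_coding_config(drug_only_fraction = c(1, 0))
  set.seed(1)
  b2 <- emit_register(phen[phen$person_id == "c" | phen$trait == "trait2", ],
                      persons, links, p, cfg2)
  expect_identical(nrow(b2$dispensations), 0L)
  expect_identical(nrow(b2$diagnoses), 0L)
})

test_that("generation is bit-reproducible under a fixed seed", {
  p <- simulation_params(n_families = 40, seed = 77)
  b1 <- simulate_register_bundle(p)
  b2 <- simulate_register_bundle(p)
  expect_identical(b1$persons, b2$persons)
  expect_identical(b1$diagnoses, b2$diagnoses)
  expect_identical(b1$dispensations, b2$dispensations)
  expect_identical(b1$truth, b2$truth)
})
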