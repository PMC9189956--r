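# 20-person fixture with hand-listed events; expected case sets enumerated
# by hand in the comments
manual_bundle <- function() {
  ids <- sprintf("p%02d", 1:20)
  persons <- data.frame(person_id = ids, sex = "male", birth_year = 1960L,
                        death_year = NA_integer_,
                        emigration_year = NA_integer_)
  diagnoses <- data.frame(
    person_id = c("p01", "p02", "p03", "p04", "p05", "p05", "p06"),
    code = c("F900", "F919", "31401", "M459", "K509", "F901", "714"),
    code_system = c("ICD10", "ICD10", "ICD9", "ICD10", "ICD10", "ICD10",
                    "ICD9"),
    event_year = c(2001L, 2002L, 1990L, 2003L, 2001L, 2005L, 1995L))
  dispensations <- data.frame(
    person_id = c("p07", "p08", "p05"),
    atc_code = c("N06BA04", "A10AB01", "N06BA09"),
    event_year = c(2006L, 2008L, 2010L))
  register_bundle(persons, links = NULL, diagnoses, dispensations)
}

test_that("case definitions match prefix rules against the hand enumeration", {
  b <- manual_bundle()
  adhd <- case_definition(
    "adhd",
    data.frame(code_system = c("ICD10", "ICD9"),
               code_prefix = c("F90", "314")),
    atc_prefixes = "N06BA")
  ph <- apply_case_definition(b, adhd)
  # by hand: p01 (F900), p03 (31401), p05 (F901 dx + N06BA09), p07 (N06BA04)
  expect_setequal(ph$person_id[ph$is_case], c("p01", "p03", "p05", "p07"))
  # p02 has F919 (not F90*), p08 has A10A (different stem)
  expect_identical(ph$first_event_year[ph$person_id == "p05"], 2005L)
  expect_identical(ph$first_event_year[ph$person_id == "p07"], 2006L)
  expect_true(all(is.na(ph$first_event_year[!ph$is_case])))
  # is_case and first_event_year are jointly present or absent
  expect_identical(ph$is_case, !is.na(ph$first_event_year))
})

test_that("dispensations before the drug-register era never ascertain", {
  b <- manual_bundle()
  dp <- b$dispensations
  dp$event_year[dp$person_id == "p07"] <- 2004L
  b2 <- register_bundle(b$persons, NULL, b$diagnoses, dp)
  drug_only <- case_definition("med_only", atc_prefixes = "N06BA")
  ph <- apply_case_definition(b2, drug_only)
  expect_false(ph$is_case[ph$person_id == "p07"])
  expect_true(ph$is_case[ph$person_id == "p05"])
})

test_that("the any-of composite equals the brute-force union", {
  b <- manual_bundle()
  defs <- list(
    as = case_definition("as", data.frame(code_system = "ICD10",
                                          code_prefix = "M45")),
    crohns = case_definition("crohns",
                             data.frame(code_system = "ICD10",
                                        code_prefix = "K50")),
    ra = case_definition("ra", data.frame(code_system = "ICD9",
                                          code_prefix = "714")),
    t1dm = case_definition("t1dm", atc_prefixes = "A10A"))
  ph <- build_phenotypes(b, defs)
  comp <- build_any_ad(ph, names(defs), name = "anyAD")
  got <- comp[comp$phenotype == "anyAD", ]
  # brute-force union over the member phenotype columns
  want <- Reduce(`|`, lapply(defs, function(d) {
    apply_case_definition(b, d)$is_case
  }))
  expect_identical(got$is_case, want)
  # by hand: p04 (M459), p05 (K509), p06 (714), p08 (A10AB01)
  expect_setequal(got$person_id[got$is_case], c("p04", "p05", "p06", "p08"))
  # first event year is the member minimum
  expect_identical(got$first_event_year[got$person_id == "p05"], 2001L)
  # composite prevalence at least the largest member prevalence
  member_prev <- vapply(names(defs), function(nm) {
    mean(ph$is_case[ph$phenotype == nm])
  }, numeric(1))
  expect_gte(mean(got$is_case), max(member_prev))
  # a person with two member diseases counts once
  expect_identical(sum(got$person_id == "p05"), 1L)
  expect_error(build_any_ad(ph, c("as", "nope")), "unknown")
})

test_that("the minimum-case filter is strict and index-scoped", {
  ids <- sprintf("q%04d", 1:3000)
  persons <- data.frame(person_id = ids, sex = "female", birth_year = 1990L,
                        death_year = NA_integer_,
                        emigration_year = NA_integer_)
  # exactly 2000 cases of 'a', 2001 cases of 'b'
  diagnoses <- rbind(
    data.frame(person_id = ids[1:2000], code = "M45", code_system = "ICD10",
               event_year = 2005L),
    data.frame(person_id = ids[1:2001], code = "K50", code_system = "ICD10",
               event_year = 2005L))
  b <- register_bundle(persons, NULL, diagnoses)
  idx <- build_index_cohort(b, c(1960L, 2010L))
  # all persons lack mother links -> empty index cohort drops everything
  expect_identical(nrow(idx), 0L)
  ph <- build_phenotypes(b, list(
    a = case_definition("a", data.frame(code_system = "ICD10",
                                        code_prefix = "M45")),
    b = case_definition("b", data.frame(code_system = "ICD10",
                                        code_prefix = "K50"))))
  expect_identical(length(apply_min_case_filter(ph, idx, 2000L)), 0L)

  links <- data.frame(child_id = ids, mother_id = "ext", father_id = "ext")
  persons2 <- rbind(persons,
                    data.frame(person_id = "ext", sex = "female",
                               birth_year = 1940L, death_year = NA_integer_,
                               emigration_year = NA_integer_))
  b2 <- register_bundle(persons2, links, diagnoses)
  idx2 <- build_index_cohort(b2, c(1960L, 2010L))
  keep <- apply_min_case_filter(ph, idx2, 2000L)
  expect_identical(as.character(keep), "b") # 2000 is dropped, 2001 retained
  counts <- attr(keep, "counts")
  expect_setequal(counts$index_cases, c(2000L, 2001L))
})

test_that("phenotyping recovers generator truth exactly when every case is observable", {
  p <- simulation_params(n_families = 250, seed = 19,
                         censor_before_10_prob = 0,
                         birth_year_range = c(1945L, 2008L))
  cfg <- default_coding_config(drug_only_fraction = c(0, 0))
  b <- simulate_register_bundle(p, cfg)
  defs <- default_case_definitions(cfg)
  ph <- build_phenotypes(b, defs)
  ph <- build_any_ad(ph, setdiff(names(defs), "adhd"), name = "anyAD")

  truth1 <- b$truth[b$truth$trait == "trait1", ]
  got1 <- ph[ph$phenotype == "adhd", ]
  expect_identical(
    got1$is_case[match(truth1$person_id, got1$person_id)],
    truth1$is_case)
  truth2 <- b$truth[b$truth$trait == "trait2", ]
  got2 <- ph[ph$phenotype == "anyAD", ]
  expect_identical(
    got2$is_case[match(truth2$person_id, got2$person_id)],
    truth2$is_case)
})

test_that("case definitions from YAML configuration round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "adhd:",
    "  icd:",
    "    ICD10: [F90]",
    "    ICD9: ['314']",
    "  atc: [N06BA]",
    "psoriasis:",
    "  icd:",
    "    ICD10: [L40]"), path)
  defs <- load_case_definitions(path)
  expect_named(defs, c("adhd", "psoriasis"))
  expect_identical(defs$adhd$atc_prefixes, "N06BA")
  expect_identical(nrow(defs$adhd$diagnosis_rules), 2L)
  expect_error(case_definition("empty"), "no rules")
})
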