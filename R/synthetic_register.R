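#' Synthetic register generation under a bivariate liability ACE model
#'
#' Generates register bundles from a known generative model so that every
#' downstream stage is testable without external data and parameter recovery
#' has known truth. Families are three-generation pedigrees: two grandparental
#' couples, a maternal and a paternal sibship (supplying the mother, father,
#' aunts and uncles), and a grandchild generation supplying index persons,
#' full siblings and full cousins. Each person carries a bivariate liability
#' L = A + C + E with additive-genetic (A), sibship-shared (C) and unique (E)
#' components; full siblings share the sibship C and half the parental A,
#' cousins share 12.5% of A and no C. Binary lifetime phenotypes arise when a
#' liability exceeds a threshold shifted by sex and a smooth birth-year trend,
#' and cases are emitted as era-coded diagnosis events and/or ATC-coded
#' dispensations.
#'
#' @name synthetic-register
NULL

#' Liability threshold from a lifetime prevalence
#'
#' The threshold t with upper-tail standard-normal probability p:
#' `P(Z > t) = p`.
#'
#' @param p Prevalence in (0, 1).
#' @return Threshold in liability standard-deviation units.
#' @examples
#' threshold_from_prevalence(0.5)    # 0
#' threshold_from_prevalence(0.023)  # about 1.995
#' @export
threshold_from_prevalence <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  qnorm(p, lower.tail = FALSE)
}

#' Simulation parameters for the synthetic register generator
#'
#' Defaults encode the study conditions the generator emulates: trait 1 is an
#' ADHD-like neurodevelopmental phenotype (lifetime prevalence 2.30%,
#' heritability 0.84, no shared environment), trait 2 an any-autoimmune-like
#' composite (prevalence 4.14%, A 0.23, C 0.09, E 0.68), genetic correlation
#' 0.13 and unique-environment correlation 0.02 between the two.
#'
#' @param n_families Number of independent three-generation families.
#' @param sibship_probs Probability vector over sibship sizes 1, 2, ...; used
#'   for the parental sibships, the index sibship and cousin sibships.
#' @param a2,c2,e2 Length-2 standardized variance proportions per trait; each
#'   trait's proportions must sum to 1.
#' @param rA,rC,rE Cross-trait correlations of the A, C and E factors.
#' @param prevalence Length-2 target lifetime prevalences.
#' @param sex_threshold_shift Length-2 additive threshold offset for females
#'   relative to males, in liability SD units.
#' @param birth_year_coeffs 2x2 matrix (rows = traits, columns = linear and
#'   cubic) of threshold coefficients on birth year standardized to
#'   `[-1, 1]` by midrange and half-range.
#' @param birth_year_range First and last calendar birth year of the pedigree.
#' @param censor_before_10_prob Probability that a (childless) person dies or
#'   emigrates before age 10.
#' @param female_prob Probability of female sex where sex is not forced by
#'   pedigree role.
#' @param last_register_year Final year covered by the registers.
#' @param seed RNG seed used by [simulate_register_bundle()].
#' @return A validated object of class `simulation_params`.
#' @export
simulation_params <- function(n_families = 1000L,
                              sibship_probs = c(1, 1, 1) / 3,
                              a2 = c(0.84, 0.23),
                              c2 = c(0.00, 0.09),
                              e2 = c(0.16, 0.68),
                              rA = 0.13, rC = 0, rE = 0.02,
                              prevalence = c(0.0230, 0.0414),
                              sex_threshold_shift = c(0.22, -0.14),
                              birth_year_coeffs =
                                matrix(c(-0.5, -0.3, -0.15, 0), nrow = 2,
                                       byrow = TRUE),
                              birth_year_range = c(1920L, 2010L),
                              censor_before_10_prob = 0.039,
                              female_prob = 0.486,
                              last_register_year = 2013L,
                              seed = 1L) {
  stopifnot(n_families >= 0, length(a2) == 2, length(c2) == 2,
            length(e2) == 2, length(prevalence) == 2,
            all(dim(birth_year_coeffs) == c(2, 2)),
            length(birth_year_range) == 2)
  if (any(abs(a2 + c2 + e2 - 1) > 1e-12)) {
    stop("a2 + c2 + e2 must equal 1 for each trait", call. = FALSE)
  }
  if (any(c(rA, rC, rE) < -1 | c(rA, rC, rE) > 1)) {
    stop("cross-trait correlations must lie in [-1, 1]", call. = FALSE)
  }
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalences must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(sibship_probs < 0) || sum(sibship_probs) <= 0) {
    stop("sibship_probs must be a non-negative probability vector",
         call. = FALSE)
  }
  p <- structure(
    list(n_families = as.integer(n_families),
         sibship_probs = sibship_probs / sum(sibship_probs),
         a2 = a2, c2 = c2, e2 = e2, rA = rA, rC = rC, rE = rE,
         prevalence = prevalence,
         sex_threshold_shift = sex_threshold_shift,
         birth_year_coeffs = birth_year_coeffs,
         birth_year_range = as.integer(birth_year_range),
         censor_before_10_prob = censor_before_10_prob,
         female_prob = female_prob,
         last_register_year = as.integer(last_register_year),
         seed = as.integer(seed)),
    class = "simulation_params")
  # the implied 4x4 pair correlation matrices must be positive semi-definite
  vc <- .params_to_vc(p)
  for (spec in list(sibling_class(), cousin_class())) {
    pair_correlation_matrix(vc, spec)
  }
  p
}

.params_to_vc <- function(params) {
  variance_components(
    a2 = params$a2, c2 = params$c2, e2 = params$e2,
    rA = params$rA, rC = params$rC, rE = params$rE,
    thresholds = threshold_from_prevalence(params$prevalence))
}

.rcat <- function(n, probs) {
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

.runif_year <- function(lo, hi) {
  lo + floor(runif(length(lo)) * (hi - lo + 1L))
}

# draw n bivariate normal rows with covariance built from per-trait variances
# v (length 2) and cross correlation r
.rbvn <- function(n, v, r) {
  s <- sqrt(v)
  cv <- r * s[1] * s[2]
  sig <- matrix(c(v[1], cv, cv, v[2]), 2)
  if (all(sig == 0)) return(matrix(0, n, 2))
  ev <- eigen(sig, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(rnorm(2 * n), n, 2) %*% rt
}

#' Simulate the pedigree structure of a synthetic register
#'
#' Builds persons and parent links (no phenotypes) for `n_families`
#' independent three-generation families. Each family has two grandparental
#' couples, a maternal and a paternal sibship (the first member of each being
#' the mother or father of the grandchild generation, the remaining members
#' aunts and uncles who, unless censored in childhood, get an external spouse
#' and a cousin sibship), and the index sibship. Birth years respect a
#' minimum parent-child gap of 15 years within `birth_year_range`; death or
#' emigration before age 10 is applied with `censor_before_10_prob` to
#' persons without descendants.
#'
#' @param params A [simulation_params()] object.
#' @return A list with data frames `persons` (with extra columns `family`,
#'   `generation`, `role`) and `links`.
#' @export
simulate_pedigree_structure <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  fr <- params$birth_year_range
  gp_span <- 15L
  if (fr[2] - fr[1] < 2L * 15L + gp_span + 1L) {
    stop("birth_year_range too narrow for three generations with ",
         "15-year parent-child gaps", call. = FALSE)
  }
  nf <- params$n_families
  if (nf == 0L) {
    return(list(persons = cbind(.empty_table(.persons_cols),
                                family = integer(0),
                                generation = integer(0),
                                role = character(0)),
                links = .empty_table(.links_cols)))
  }
  fam <- seq_len(nf)
  probs <- params$sibship_probs
  cens_p <- params$censor_before_10_prob
  fp <- params$female_prob

  person <- function(id, sex, by, family, generation, role, censorable) {
    n <- length(id)
    cens <- censorable & (runif(n) < cens_p)
    kind <- runif(n) < 0.5
    dy <- ifelse(cens & kind, .runif_year(by, by + 9L), NA_integer_)
    ey <- ifelse(cens & !kind, .runif_year(by, by + 9L), NA_integer_)
    data.frame(person_id = id, sex = sex, birth_year = as.integer(by),
               death_year = as.integer(dy), emigration_year = as.integer(ey),
               family = family, generation = generation, role = role,
               stringsAsFactors = FALSE)
  }

  # grandparents: two couples per family
  gp_id <- paste0("F", rep(fam, each = 4L),
                  rep(c("_GMm", "_GFm", "_GMp", "_GFp"), nf))
  gp_sex <- rep(c("female", "male", "female", "male"), nf)
  gp_by <- .runif_year(rep(fr[1], 4L * nf), rep(fr[1] + gp_span, 4L * nf))
  gp <- person(gp_id, gp_sex, gp_by, rep(fam, each = 4L), 1L, "grandparent",
               censorable = FALSE)
  gp_mat <- matrix(gp_by, nrow = nf, byrow = TRUE) # cols: GMm GFm GMp GFp

  # parental sibships; member 1 is the mother (maternal) / father (paternal)
  build_sibship <- function(side) {
    sizes <- .rcat(nf, probs)
    famr <- rep(fam, sizes)
    idx <- sequence(sizes)
    cols <- if (side == "m") 1:2 else 3:4
    gmax <- pmax(gp_mat[, cols[1]], gp_mat[, cols[2]])
    by <- .runif_year(rep(gmax + 15L, sizes), rep(fr[2] - 15L, sum(sizes)))
    forced <- idx == 1L
    sex <- ifelse(forced, if (side == "m") "female" else "male",
                  ifelse(runif(length(idx)) < fp, "female", "male"))
    role <- ifelse(forced, if (side == "m") "mother" else "father",
                   ifelse(sex == "female", "aunt", "uncle"))
    id <- paste0("F", famr, "_", toupper(side), idx)
    df <- person(id, sex, by, famr, 2L, role, censorable = !forced)
    df$mother_id <- paste0("F", famr, if (side == "m") "_GMm" else "_GMp")
    df$father_id <- paste0("F", famr, if (side == "m") "_GFm" else "_GFp")
    df
  }
  mat <- build_sibship("m")
  pat <- build_sibship("p")
  parents <- rbind(mat, pat)
  censored <- !is.na(parents$death_year) | !is.na(parents$emigration_year)

  # spouses and cousin sibships for uncensored aunts/uncles
  au <- parents[parents$role %in% c("aunt", "uncle") & !censored, ,
                drop = FALSE]
  spouses <- children <- NULL
  if (nrow(au)) {
    sp_by <- pmin(pmax(au$birth_year + sample(-5:5, nrow(au), replace = TRUE),
                       fr[1]), fr[2] - 15L)
    sp <- person(paste0(au$person_id, "s"),
                 ifelse(au$sex == "female", "male", "female"),
                 sp_by, au$family, 2L, "spouse", censorable = FALSE)
    csize <- .rcat(nrow(au), probs)
    famr <- rep(au$family, csize)
    par_i <- rep(seq_len(nrow(au)), csize)
    cby <- .runif_year(pmax(au$birth_year, sp_by)[par_i] + 15L, rep(fr[2],
                                                                    length(par_i)))
    kid <- person(paste0(au$person_id[par_i], "c", sequence(csize)),
                  ifelse(runif(length(par_i)) < fp, "female", "male"),
                  cby, famr, 3L, "cousin", censorable = TRUE)
    kid$mother_id <- ifelse(au$sex[par_i] == "female", au$person_id[par_i],
                            sp$person_id[par_i])
    kid$father_id <- ifelse(au$sex[par_i] == "male", au$person_id[par_i],
                            sp$person_id[par_i])
    spouses <- sp
    children <- kid
  }

  # index sibship: children of the mother and father
  mo <- mat[mat$role == "mother", , drop = FALSE]
  fa <- pat[pat$role == "father", , drop = FALSE]
  isz <- .rcat(nf, probs)
  famr <- rep(fam, isz)
  iby <- .runif_year(rep(pmax(mo$birth_year, fa$birth_year) + 15L, isz),
                     rep(fr[2], length(famr)))
  idx_kids <- person(paste0("F", famr, "_C", sequence(isz)),
                     ifelse(runif(length(famr)) < fp, "female", "male"),
                     iby, famr, 3L, "index", censorable = TRUE)
  idx_kids$mother_id <- mo$person_id[famr]
  idx_kids$father_id <- fa$person_id[famr]

  linked <- rbind(parents[, c(.persons_cols, "family", "generation", "role",
                              "mother_id", "father_id")],
                  if (!is.null(children))
                    children[, c(.persons_cols, "family", "generation",
                                 "role", "mother_id", "father_id")],
                  idx_kids[, c(.persons_cols, "family", "generation", "role",
                               "mother_id", "father_id")])
  links <- data.frame(child_id = linked$person_id,
                      mother_id = linked$mother_id,
                      father_id = linked$father_id, stringsAsFactors = FALSE)
  persons <- rbind(gp, if (!is.null(spouses)) spouses,
                   linked[, c(.persons_cols, "family", "generation", "role")])
  rownames(persons) <- NULL
  list(persons = persons, links = links)
}

#' Simulate A, C and E liabilities over a pedigree
#'
#' Founders draw additive-genetic (A) deviations from a zero-mean bivariate
#' normal with per-trait variance `a2` and cross-trait covariance
#' `rA * sqrt(a2[1] * a2[2])`; each child's A is the parental midpoint plus a
#' segregation deviate with half the founder covariance (a parent absent from
#' the pedigree contributes an unobserved founder draw, adding a quarter of
#' the founder covariance). The shared-environment component C is drawn once
#' per nuclear sibship (children sharing both listed parents) and is
#' independent across sibships; E is independent per person. Total liability
#' per trait then has unit variance in expectation, with full siblings
#' sharing 50% of A and all of C, and cousins 12.5% of A and none of C.
#'
#' @param pedigree A list with `persons` and `links` as produced by
#'   [simulate_pedigree_structure()] (any valid pedigree works).
#' @param params A [simulation_params()] object.
#' @return A list of class `liability_state` with `person_id` and n x 2
#'   matrices `A`, `C`, `E` and `total`.
#' @export
simulate_liabilities <- function(pedigree, params) {
  persons <- pedigree$persons
  links <- pedigree$links
  n <- nrow(persons)
  ids <- persons$person_id
  mo <- links$mother_id[match(ids, links$child_id)]
  fa <- links$father_id[match(ids, links$child_id)]
  mo[!(mo %in% ids)] <- NA
  fa[!(fa %in% ids)] <- NA

  A <- matrix(NA_real_, n, 2)
  done <- is.na(mo) & is.na(fa)
  A[done, ] <- .rbvn(sum(done), params$a2, params$rA)
  while (!all(done)) {
    mi <- match(mo, ids)
    fi <- match(fa, ids)
    ready <- !done &
      (is.na(mo) | done[ifelse(is.na(mi), 1L, mi)]) &
      (is.na(fa) | done[ifelse(is.na(fi), 1L, fi)])
    if (!any(ready)) {
      stop("pedigree contains a cycle; liabilities undefined", call. = FALSE)
    }
    w <- which(ready)
    mid <- matrix(0, length(w), 2)
    segvar_extra <- numeric(length(w)) # phantom-founder quarters
    hm <- !is.na(mo[w]); hf <- !is.na(fa[w])
    mid[hm, ] <- mid[hm, , drop = FALSE] + 0.5 * A[mi[w][hm], , drop = FALSE]
    mid[hf, ] <- mid[hf, , drop = FALSE] + 0.5 * A[fi[w][hf], , drop = FALSE]
    n_phantom <- (!hm) + (!hf)
    seg <- .rbvn(length(w), params$a2 / 2, params$rA) # segregation
    ph <- .rbvn(length(w), params$a2 / 4, params$rA) # per phantom parent
    ph2 <- .rbvn(length(w), params$a2 / 4, params$rA)
    A[w, ] <- mid + seg + ph * (n_phantom >= 1L) + ph2 * (n_phantom == 2L)
    done[w] <- TRUE
  }

  sib_key <- ifelse(is.na(mo) & is.na(fa), paste0("self:", ids),
                    paste(mo, fa, sep = "|"))
  uk <- unique(sib_key)
  Cu <- .rbvn(length(uk), params$c2, params$rC)
  C <- Cu[match(sib_key, uk), , drop = FALSE]
  E <- .rbvn(n, params$e2, params$rE)
  structure(list(person_id = ids, A = A, C = C, E = E, total = A + C + E),
            class = "liability_state")
}

# mean-zero standardized birth year and the per-person threshold shift
.threshold_shifts <- function(persons, params) {
  fr <- params$birth_year_range
  z <- (persons$birth_year - mean(fr)) / (diff(fr) / 2)
  female <- persons$sex == "female"
  b <- params$birth_year_coeffs
  vapply(1:2, function(k) {
    params$sex_threshold_shift[k] * female + b[k, 1] * z + b[k, 2] * z^3
  }, numeric(nrow(persons)))
}

# base threshold such that the population-average case probability over the
# realized covariate shifts equals the target prevalence
.calibrate_threshold <- function(shifts, p) {
  uniroot(function(t) mean(pnorm(t + shifts, lower.tail = FALSE)) - p,
          interval = c(-10, 10), tol = 1e-10)$root
}

#' Dichotomize liabilities into lifetime phenotypes
#'
#' A person is a case for trait k when total liability exceeds the trait
#' threshold shifted additively by sex and by a linear-plus-cubic trend in
#' standardized birth year. The baseline threshold is calibrated so that the
#' expected prevalence over the realized covariates matches the target. Cases
#' receive a first-diagnosis year drawn uniformly over the years in which the
#' person is alive, present, at least age 3 and inside the register period;
#' cases with an empty window keep `NA` (truth without observation).
#'
#' @param liabilities A `liability_state` from [simulate_liabilities()].
#' @param persons The person table matching the liabilities.
#' @param params A [simulation_params()] object.
#' @param register_start First year of the diagnosis registers.
#' @return Data frame (person_id, trait, liability, is_case, diagnosis_year)
#'   with the calibrated thresholds in attribute `"thresholds"`.
#' @export
liabilities_to_phenotypes <- function(liabilities, persons, params,
                                      register_start = 1964L) {
  stopifnot(inherits(liabilities, "liability_state"),
            identical(liabilities$person_id, persons$person_id))
  if (nrow(persons) == 0L) {
    out <- data.frame(person_id = character(0), trait = character(0),
                      liability = numeric(0), is_case = logical(0),
                      diagnosis_year = integer(0), stringsAsFactors = FALSE)
    attr(out, "thresholds") <- threshold_from_prevalence(params$prevalence)
    return(out)
  }
  shifts <- .threshold_shifts(persons, params)
  thr <- vapply(1:2, function(k) {
    .calibrate_threshold(shifts[, k], params$prevalence[k])
  }, numeric(1))
  end_year <- pmin(ifelse(is.na(persons$death_year), Inf, persons$death_year),
                   ifelse(is.na(persons$emigration_year), Inf,
                          persons$emigration_year),
                   params$last_register_year)
  lo <- pmax(persons$birth_year + 3L, register_start)
  out <- lapply(1:2, function(k) {
    is_case <- liabilities$total[, k] > thr[k] + shifts[, k]
    dy <- rep(NA_integer_, nrow(persons))
    ok <- is_case & lo <= end_year
    dy[ok] <- .runif_year(lo[ok], as.integer(end_year[ok]))
    data.frame(person_id = persons$person_id,
               trait = paste0("trait", k),
               liability = liabilities$total[, k],
               is_case = is_case, diagnosis_year = dy,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "thresholds") <- thr
  res
}

#' Default illustrative coding configuration
#'
#' Maps each generator trait to era-specific diagnosis code stems and
#' optional ATC stems. Trait 1 mimics an ADHD-style definition (diagnosis or
#' ADHD-medication dispensation); trait 2 draws one of 13 illustrative
#' autoimmune-disease code groups per case. The code lists are illustrative
#' placeholders in the shape of Swedish-adapted ICD revisions, not a
#' reconstruction of any study's operational definitions.
#'
#' @param drug_only_fraction Fraction of trait cases ascertained only through
#'   a dispensation (given the trait has an ATC stem).
#' @param drug_extra_fraction Fraction additionally emitting a dispensation.
#' @return A nested list, one element per trait.
#' @export
default_coding_config <- function(drug_only_fraction = c(0.15, 0),
                                  drug_extra_fraction = c(0.3, 0.1)) {
  ad <- function(label, icd10, icd9, icd8, icd7, atc = NA_character_) {
    list(label = label, ICD10 = icd10, ICD9 = icd9, ICD8 = icd8, ICD7 = icd7,
         atc = atc)
  }
  list(
    trait1 = list(
      label = "adhd",
      drug_only_fraction = drug_only_fraction[1],
      drug_extra_fraction = drug_extra_fraction[1],
      groups = list(ad("adhd", "F90", "314", "308", "306", atc = "N06BA"))),
    trait2 = list(
      label = "autoimmune",
      drug_only_fraction = drug_only_fraction[2],
      drug_extra_fraction = drug_extra_fraction[2],
      groups = list(
        ad("ankylosing_spondylitis", "M45", "720", "712", "722"),
        ad("celiac_disease", "K900", "579", "269", "286"),
        ad("crohns_disease", "K50", "555", "563", "572"),
        ad("graves_disease", "E050", "242", "242", "252"),
        ad("hashimotos_disease", "E063", "245", "245", "253"),
        ad("multiple_sclerosis", "G35", "340", "340", "345"),
        ad("psoriasis", "L40", "696", "696", "706"),
        ad("rheumatoid_arthritis", "M05", "714", "712", "722"),
        ad("sarcoidosis", "D86", "135", "135", "138"),
        ad("sjogrens_syndrome", "M350", "710", "734", "744"),
        ad("systemic_lupus", "M32", "710", "734", "744"),
        ad("type1_diabetes", "E10", "250", "250", "260", atc = "A10A"),
        ad("ulcerative_colitis", "K51", "556", "563", "572"))))
}

.era_for_year <- function(year, eras = register_eras()) {
  icd <- eras$icd
  idx <- vapply(year, function(y) {
    w <- which(y >= icd$first & y <= icd$last)
    if (!length(w)) NA_integer_ else w[1]
  }, integer(1))
  icd$code_system[idx]
}

#' Emit a register bundle from phenotype truth
#'
#' Every observable case emits at least one event whose code system matches
#' its first-diagnosis year under the era map. A configurable fraction of
#' cases with an ATC stem are drug-only: they emit a dispensation at the
#' drawn year if it falls in the drug-register era (2005 or later) and are
#' otherwise invisible to phenotyping. The full truth table and parameters
#' are retained in the bundle for testing.
#'
#' @param phenotypes Output of [liabilities_to_phenotypes()].
#' @param persons Person table (may carry generator bookkeeping columns,
#'   which are dropped).
#' @param links Parent-link table.
#' @param params A [simulation_params()] object.
#' @param coding_config See [default_coding_config()].
#' @param eras Era configuration, see [register_eras()].
#' @return A [register_bundle()].
#' @export
emit_register <- function(phenotypes, persons, links, params,
                          coding_config = default_coding_config(),
                          eras = register_eras()) {
  diagnoses <- list()
  dispensations <- list()
  for (k in 1:2) {
    cfg <- coding_config[[paste0("trait", k)]]
    ph <- phenotypes[phenotypes$trait == paste0("trait", k) &
                       phenotypes$is_case & !is.na(phenotypes$diagnosis_year), ,
                     drop = FALSE]
    if (!nrow(ph)) next
    gi <- sample.int(length(cfg$groups), nrow(ph), replace = TRUE)
    era <- .era_for_year(ph$diagnosis_year, eras)
    if (anyNA(era)) {
      stop("diagnosis year outside all configured eras: ",
           paste(unique(ph$diagnosis_year[is.na(era)]), collapse = ", "),
           call. = FALSE)
    }
    has_atc <- !vapply(cfg$groups, function(g) is.na(g$atc), logical(1))[gi]
    u <- runif(nrow(ph))
    drug_only <- has_atc & u < cfg$drug_only_fraction
    drug_extra <- has_atc & !drug_only &
      u < cfg$drug_only_fraction + cfg$drug_extra_fraction
    code <- vapply(seq_len(nrow(ph)), function(i) {
      cfg$groups[[gi[i]]][[era[i]]]
    }, character(1))
    keep <- !drug_only
    if (any(keep)) {
      diagnoses[[length(diagnoses) + 1L]] <- data.frame(
        person_id = ph$person_id[keep], code = code[keep],
        code_system = era[keep], event_year = ph$diagnosis_year[keep],
        stringsAsFactors = FALSE)
    }
    demit <- (drug_only & ph$diagnosis_year >= eras$drug_register_start) |
      (drug_extra & ph$diagnosis_year >= eras$drug_register_start)
    if (any(demit)) {
      atc <- vapply(which(demit), function(i) cfg$groups[[gi[i]]]$atc,
                    character(1))
      dispensations[[length(dispensations) + 1L]] <- data.frame(
        person_id = ph$person_id[demit], atc_code = atc,
        event_year = ph$diagnosis_year[demit], stringsAsFactors = FALSE)
    }
  }
  diagnoses <- if (length(diagnoses)) do.call(rbind, diagnoses) else NULL
  dispensations <- if (length(dispensations)) {
    do.call(rbind, dispensations)
  } else NULL
  truth <- phenotypes[, c("person_id", "trait", "liability", "is_case")]
  meta <- list(
    generator = "famcoag synthetic_register",
    seed = params$seed,
    n_families = params$n_families,
    params = unclass(params)[c("a2", "c2", "e2", "rA", "rC", "rE",
                               "prevalence", "sex_threshold_shift",
                               "birth_year_range", "censor_before_10_prob",
                               "sibship_probs")],
    thresholds = attr(phenotypes, "thresholds"))
  register_bundle(persons[, .persons_cols], links, diagnoses, dispensations,
                  metadata = meta, truth = truth)
}

#' Generate a complete synthetic register bundle
#'
#' Runs pedigree construction, liability simulation, phenotype thresholding
#' and event emission under one seed. Output is bit-reproducible for a fixed
#' parameter set and seed.
#'
#' @param params A [simulation_params()] object.
#' @param coding_config See [default_coding_config()].
#' @return A [register_bundle()] whose `truth` table holds the generating
#'   phenotypes and whose persons keep generator roles in the bundle
#'   metadata-free person table; the pedigree with roles is attached as
#'   attribute `"pedigree"`.
#' @export
simulate_register_bundle <- function(params,
                                     coding_config = default_coding_config()) {
  set.seed(params$seed)
  ped <- simulate_pedigree_structure(params)
  liab <- simulate_liabilities(ped, params)
  phen <- liabilities_to_phenotypes(liab, ped$persons, params)
  bundle <- emit_register(phen, ped$persons, ped$links, params, coding_config)
  attr(bundle, "pedigree") <- ped
  bundle
}
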