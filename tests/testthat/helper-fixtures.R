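# Shared fixtures, built in code. The demo bundle is cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# variance components at the study's fitted point values (AE trait 1,
# ACE trait 2), thresholds at prevalences 2.30% and 4.14%
table3_vc <- function() {
  variance_components(
    a2 = c(0.84, 0.23), c2 = c(0, 0.09), e2 = c(0.16, 0.68),
    rA = 0.13, rC = NA, rE = 0.02,
    thresholds = threshold_from_prevalence(c(0.0230, 0.0414)))
}

# small generator bundle shared across tests
demo_bundle <- function(n_families = 400, seed = 11) {
  key <- paste0("bundle_", n_families, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_register_bundle(
      simulation_params(n_families = n_families, seed = seed))
  }
  .fixture_cache[[key]]
}

# hand-built three-generation bundle:
#   gm/gf -> mother(m), aunt(a, one child c1), half-aunt(h: shares only gm)
#   pgm/pgf -> father(f)
#   m+f -> index i1 (1985), sibling s1 (1990, died age 9), sibling s2 (2000)
#   a+as -> c1 (1988)
#   h+hs -> hc1 (1989): child of a parent's half-sibling, not a cousin
toy_bundle <- function() {
  persons <- data.frame(
    person_id = c("gm", "gf", "gm2", "pgm", "pgf", "m", "a", "h", "f",
                  "as", "hs", "i1", "s1", "s2", "c1", "hc1"),
    sex = c("female", "male", "female", "female", "male", "female",
            "female", "female", "male", "male", "male", "male", "female",
            "male", "female", "male"),
    birth_year = c(1930L, 1930L, 1935L, 1932L, 1931L, 1958L, 1960L, 1962L,
                   1957L, 1959L, 1961L, 1985L, 1990L, 2000L, 1988L, 1989L),
    death_year = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 1999L,
                   NA, NA, NA),
    emigration_year = rep(NA_integer_, 16),
    stringsAsFactors = FALSE)
  links <- data.frame(
    child_id = c("m", "a", "h", "f", "i1", "s1", "s2", "c1", "hc1"),
    mother_id = c("gm", "gm", "gm2", "pgm", "m", "m", "m", "a", "h"),
    father_id = c("gf", "gf", "gf", "pgf", "f", "f", "f", "as", "hs"),
    stringsAsFactors = FALSE)
  register_bundle(persons, links)
}

# independent brute-force pedigree walker: enumerates relative pairs by
# nested person-level loops over parent maps (no merges, no vectorization)
brute_force_pairs <- function(bundle, index_ids, relation,
                              min_survival_age = 10) {
  p <- bundle$persons
  mo <- setNames(bundle$links$mother_id, bundle$links$child_id)
  fa <- setNames(bundle$links$father_id, bundle$links$child_id)
  sexof <- setNames(p$sex, p$person_id)
  surv <- setNames(
    !((!is.na(p$death_year) & p$death_year - p$birth_year <
         min_survival_age) |
        (!is.na(p$emigration_year) & p$emigration_year - p$birth_year <
           min_survival_age)),
    p$person_id)
  parents <- function(id) c(mo[id], fa[id])
  # sibship lookup built once: children grouped by their (mother, father)
  both <- !is.na(mo) & !is.na(fa)
  sib_groups <- split(names(mo)[both], paste(mo[both], fa[both]))
  kid_groups <- split(rep(names(mo), 2), c(mo, fa))
  full_sibs <- function(id) {
    pr <- parents(id)
    if (anyNA(pr)) return(character(0))
    setdiff(sib_groups[[paste(pr[1], pr[2])]], id)
  }
  children_of <- function(id) {
    unique(kid_groups[[id]])
  }
  res <- list()
  add <- function(i, r, side = NA_character_) {
    res[[length(res) + 1L]] <<- c(i, r, side)
  }
  for (i in index_ids) {
    if (relation == "mother") {
      if (!is.na(mo[i])) add(i, unname(mo[i]))
    } else if (relation == "father") {
      if (!is.na(fa[i])) add(i, unname(fa[i]))
    } else if (relation == "full_sibling") {
      for (s in full_sibs(i)) if (surv[s]) add(i, s)
    } else if (relation %in% c("aunt", "uncle")) {
      want <- if (relation == "aunt") "female" else "male"
      for (side in c("maternal", "paternal")) {
        par <- if (side == "maternal") mo[i] else fa[i]
        if (is.na(par)) next
        for (s in full_sibs(unname(par))) {
          if (sexof[s] == want && surv[s]) add(i, s, side)
        }
      }
    } else if (relation == "cousin") {
      for (side in c("maternal", "paternal")) {
        par <- if (side == "maternal") mo[i] else fa[i]
        if (is.na(par)) next
        for (s in full_sibs(unname(par))) {
          for (ch in children_of(s)) {
            if (ch != i && surv[ch]) add(i, ch, side)
          }
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(index_id = character(0), relative_id = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, res)
  out <- data.frame(index_id = m[, 1], relative_id = m[, 2], side = m[, 3],
                    stringsAsFactors = FALSE)
  if (relation %in% c("full_sibling", "cousin")) {
    lo <- pmin(out$index_id, out$relative_id)
    hi <- pmax(out$index_id, out$relative_id)
    out <- out[!duplicated(paste(lo, hi)), , drop = FALSE]
  } else {
    out <- out[!duplicated(paste(out$index_id, out$relative_id)), ,
               drop = FALSE]
  }
  out
}

# unordered pair key sets for comparisons
pair_key <- function(df, ordered = FALSE) {
  if (ordered) {
    sort(paste(df$index_id, df$relative_id))
  } else {
    sort(paste(pmin(df$index_id, df$relative_id),
               pmax(df$index_id, df$relative_id)))
  }
}
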