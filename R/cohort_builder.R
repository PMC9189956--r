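#' Cohort construction
#'
#' Reproduces the study-design steps between raw registers and analysis
#' data: the index birth cohort with its exclusion cascade, six
#' index-relative pair cohorts (mother, father, full sibling, aunt, uncle,
#' cousin) with maternal/paternal side labels and family-cluster
#' identifiers, and one-pair-per-family sampling for variance-component
#' modelling.
#'
#' @name cohort-builder
NULL

.relations <- c("mother", "father", "full_sibling", "aunt", "uncle", "cousin")

# did the person remain alive and present at least to `age` (year
# granularity: death/emigration year minus birth year below `age` excludes)
.survived_to <- function(persons, age) {
  d <- persons$death_year - persons$birth_year
  e <- persons$emigration_year - persons$birth_year
  !((!is.na(d) & d < age) | (!is.na(e) & e < age))
}

#' Family cluster identifiers
#'
#' Assigns every person the connected component of the parent-link graph
#' (edges child-mother and child-father), the most conservative clustering
#' unit for family-robust variance estimation: any two relative pairs that
#' share a person necessarily share a cluster.
#'
#' @param bundle A [register_bundle()].
#' @return Named integer vector mapping person_id to cluster id.
#' @export
family_clusters <- function(bundle) {
  l <- bundle$links
  edges <- rbind(
    cbind(l$child_id, l$mother_id),
    cbind(l$child_id, l$father_id))
  edges <- edges[!is.na(edges[, 2]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = bundle$persons$person_id,
                          stringsAsFactors = FALSE))
  igraph::components(g)$membership
}

#' Build the index birth cohort
#'
#' Members are persons born inside `birth_window` whose biological mother is
#' known and who did not die or emigrate before `min_survival_age` (at year
#' granularity: an event in the year the person turns `min_survival_age` or
#' later does not exclude). The exclusion cascade is reported in register
#' order: outside window, unknown mother, then early death/emigration.
#'
#' @param bundle A [register_bundle()].
#' @param birth_window First and last birth year (inclusive).
#' @param min_survival_age Minimum attained age in years.
#' @return Data frame of members (person_id, sex, birth_year) with class
#'   `index_cohort`; attributes `exclusions` (named counts) and
#'   `birth_window`.
#' @export
build_index_cohort <- function(bundle, birth_window = c(1960L, 2010L),
                               min_survival_age = 10L) {
  p <- bundle$persons
  mo <- bundle$links$mother_id[match(p$person_id, bundle$links$child_id)]
  in_window <- p$birth_year >= birth_window[1] & p$birth_year <= birth_window[2]
  known_mother <- !is.na(mo)
  survived <- .survived_to(p, min_survival_age)
  keep <- in_window & known_mother & survived
  excl <- c(
    total = nrow(p),
    outside_birth_window = sum(!in_window),
    unknown_mother = sum(in_window & !known_mother),
    died_or_emigrated_early = sum(in_window & known_mother & !survived),
    members = sum(keep))
  out <- p[keep, c("person_id", "sex", "birth_year"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, exclusions = excl, birth_window = birth_window,
            min_survival_age = min_survival_age,
            class = c("index_cohort", "data.frame"))
}

# ordered full-sibling pairs (a, b): children sharing both (known) parents
.sibling_pairs_table <- function(links) {
  l <- links[!is.na(links$mother_id) & !is.na(links$father_id), , drop = FALSE]
  if (!nrow(l)) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(l$mother_id, l$father_id, sep = "\r")
  df <- data.frame(id = l$child_id, key = key, stringsAsFactors = FALSE)
  m <- merge(df, df, by = "key")
  m <- m[m$id.x != m$id.y, , drop = FALSE]
  data.frame(a = m$id.x, b = m$id.y, stringsAsFactors = FALSE)
}

# long (child, parent) table: each child once per known parent
.child_parent_table <- function(links) {
  rbind(
    data.frame(child = links$child_id, parent = links$mother_id,
               stringsAsFactors = FALSE),
    data.frame(child = links$child_id, parent = links$father_id,
               stringsAsFactors = FALSE))
}

#' Build an index-relative pair cohort
#'
#' Mother/father pairs come from the direct parent links; full siblings
#' share both parents; aunts and uncles are full siblings of the linked
#' parent (side records which parent); cousins are children of a parent's
#' full siblings (side records the linking parent). For symmetric relations
#' (full sibling, cousin) unordered duplicates are removed. Relatives that
#' died or emigrated before the survival age are dropped for the sibling,
#' aunt, uncle and cousin cohorts, with counts reported; for parent-type
#' relations (`mother`, `father`, `aunt`, `uncle`) the index side is further
#' restricted to `late_window` birth years.
#'
#' @param bundle A [register_bundle()].
#' @param index An [build_index_cohort()] result.
#' @param relation One of `"mother"`, `"father"`, `"full_sibling"`,
#'   `"aunt"`, `"uncle"`, `"cousin"`.
#' @param late_window Index birth window for the parent-generation cohorts;
#'   required for mother/father/aunt/uncle.
#' @param min_survival_age Survival rule applied to relatives.
#' @return Data frame (index_id, relative_id, relation, side,
#'   family_cluster_id) with class `relative_pair_cohort`; attribute
#'   `dropped` reports exclusion counts.
#' @export
build_relative_pairs <- function(bundle, index, relation,
                                 late_window = NULL,
                                 min_survival_age = attr(index,
                                                         "min_survival_age")) {
  if (!relation %in% .relations) {
    stop("unknown relation '", relation, "'; must be one of ",
         paste(.relations, collapse = ", "), call. = FALSE)
  }
  parent_type <- relation %in% c("mother", "father", "aunt", "uncle")
  if (parent_type && is.null(late_window)) {
    stop("late_window is required for relation '", relation, "'",
         call. = FALSE)
  }
  p <- bundle$persons
  l <- bundle$links
  idx_ids <- index$person_id
  if (parent_type) {
    by <- index$birth_year
    idx_ids <- idx_ids[by >= late_window[1] & by <= late_window[2]]
  }
  mo <- l$mother_id[match(idx_ids, l$child_id)]
  fa <- l$father_id[match(idx_ids, l$child_id)]

  pairs <- switch(
    relation,
    mother = data.frame(index_id = idx_ids, relative_id = mo,
                        side = NA_character_, stringsAsFactors = FALSE),
    father = data.frame(index_id = idx_ids, relative_id = fa,
                        side = NA_character_, stringsAsFactors = FALSE),
    full_sibling = {
      st <- .sibling_pairs_table(l)
      st <- st[st$a %in% idx_ids, , drop = FALSE]
      data.frame(index_id = st$a, relative_id = st$b, side = NA_character_,
                 stringsAsFactors = FALSE)
    },
    aunt = ,
    uncle = {
      st <- .sibling_pairs_table(l)
      want_sex <- if (relation == "aunt") "female" else "male"
      out <- lapply(c(maternal = "maternal", paternal = "paternal"),
                    function(side) {
        par <- if (side == "maternal") mo else fa
        d <- data.frame(index_id = idx_ids, a = par, stringsAsFactors = FALSE)
        d <- d[!is.na(d$a), , drop = FALSE]
        m <- merge(d, st, by = "a")
        sex <- p$sex[match(m$b, p$person_id)]
        m <- m[!is.na(sex) & sex == want_sex, , drop = FALSE]
        if (!nrow(m)) return(NULL)
        data.frame(index_id = m$index_id, relative_id = m$b, side = side,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, Filter(Negate(is.null), out))
    },
    cousin = {
      st <- .sibling_pairs_table(l)
      cp <- .child_parent_table(l)
      cp <- cp[!is.na(cp$parent), , drop = FALSE]
      out <- lapply(c(maternal = "maternal", paternal = "paternal"),
                    function(side) {
        par <- if (side == "maternal") mo else fa
        d <- data.frame(index_id = idx_ids, a = par, stringsAsFactors = FALSE)
        d <- d[!is.na(d$a), , drop = FALSE]
        m <- merge(d, st, by = "a")           # index -> parent's sibling b
        if (!nrow(m)) return(NULL)
        m <- merge(m, cp, by.x = "b", by.y = "parent") # -> b's children
        if (!nrow(m)) return(NULL)
        data.frame(index_id = m$index_id, relative_id = m$child, side = side,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, Filter(Negate(is.null), out))
    })
  if (is.null(pairs)) {
    pairs <- data.frame(index_id = character(0), relative_id = character(0),
                        side = NA_character_, stringsAsFactors = FALSE)
  }
  pairs <- pairs[!is.na(pairs$relative_id) &
                   pairs$relative_id != pairs$index_id, , drop = FALSE]

  n_raw <- nrow(pairs)
  # symmetric relations: drop unordered duplicates deterministically
  if (relation %in% c("full_sibling", "cousin")) {
    lo <- pmin(pairs$index_id, pairs$relative_id)
    hi <- pmax(pairs$index_id, pairs$relative_id)
    pairs <- pairs[!duplicated(paste(lo, hi, sep = "\r")), , drop = FALSE]
  } else {
    pairs <- pairs[!duplicated(paste(pairs$index_id, pairs$relative_id,
                                     sep = "\r")), , drop = FALSE]
  }
  n_dedup <- n_raw - nrow(pairs)

  n_surv <- 0L
  if (relation %in% c("full_sibling", "aunt", "uncle", "cousin")) {
    rel_rows <- p[match(pairs$relative_id, p$person_id), , drop = FALSE]
    ok <- .survived_to(rel_rows, min_survival_age)
    n_surv <- sum(!ok)
    pairs <- pairs[ok, , drop = FALSE]
  }

  clusters <- family_clusters(bundle)
  pairs$relation <- relation
  pairs$family_cluster_id <- unname(clusters[pairs$index_id])
  pairs <- pairs[order(pairs$index_id, pairs$relative_id),
                 c("index_id", "relative_id", "relation", "side",
                   "family_cluster_id")]
  rownames(pairs) <- NULL
  structure(pairs, relation = relation,
            restriction = if (parent_type) late_window else
              attr(index, "birth_window"),
            dropped = c(deduplicated = n_dedup,
                        relative_died_or_emigrated_early = n_surv),
            class = c("relative_pair_cohort", "data.frame"))
}

#' Sample one pair per family for variance-component modelling
#'
#' For full siblings the family unit is the nuclear sibship (the shared
#' parent couple); for cousins it is the grandparental lineage (the parent
#' couple of the two linking full-sibling parents). Families are visited in
#' seeded random order; within each family one pair is drawn uniformly among
#' the pairs whose members have not already been selected for an earlier
#' family, so every person enters at most one sampled pair (a family whose
#' pairs are exhausted by earlier selections contributes none -- this can
#' only happen for cousins, where one person belongs to both a maternal and
#' a paternal lineage).
#'
#' @param bundle A [register_bundle()] (for the link table).
#' @param pairs A `relative_pair_cohort` with relation `full_sibling` or
#'   `cousin`.
#' @param seed RNG seed.
#' @return The sampled subset of `pairs`, at most one row per family unit.
#' @export
select_quantgen_pairs <- function(bundle, pairs, seed = 1L) {
  relation <- attr(pairs, "relation")
  if (!relation %in% c("full_sibling", "cousin")) {
    stop("quantgen pair sampling is defined for full_sibling and cousin ",
         "cohorts", call. = FALSE)
  }
  l <- bundle$links
  mo <- l$mother_id[match(pairs$index_id, l$child_id)]
  fa <- l$father_id[match(pairs$index_id, l$child_id)]
  if (relation == "full_sibling") {
    key <- paste(mo, fa, sep = "\r")
  } else {
    lp <- ifelse(pairs$side == "maternal", mo, fa) # linking parent
    gmo <- l$mother_id[match(lp, l$child_id)]
    gfa <- l$father_id[match(lp, l$child_id)]
    key <- paste(gmo, gfa, sep = "\r")
  }
  set.seed(seed)
  groups <- split(seq_len(nrow(pairs)), key)
  groups <- groups[sample.int(length(groups))]
  used <- new.env(parent = emptyenv())
  pick <- integer(0)
  for (ix in groups) {
    free <- ix[vapply(ix, function(i) {
      is.null(used[[pairs$index_id[i]]]) &&
        is.null(used[[pairs$relative_id[i]]])
    }, logical(1))]
    if (!length(free)) next
    sel <- free[sample.int(length(free), 1L)]
    used[[pairs$index_id[sel]]] <- TRUE
    used[[pairs$relative_id[sel]]] <- TRUE
    pick <- c(pick, sel)
  }
  out <- pairs[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "relation") <- relation
  class(out) <- class(pairs)
  out
}

#' Filter a cohort by predicates
#'
#' Applies a conjunction of named predicates (each a function of the cohort
#' data frame returning a keep-indicator) and reports how many rows each
#' clause alone would remove. Because the clauses combine by logical AND,
#' the final membership does not depend on their order.
#'
#' @param cohort A data frame cohort (index or pair cohort).
#' @param predicates Named list of functions `data.frame -> logical`.
#' @return List with `cohort` (filtered, class preserved) and `report`
#'   (clause, removed).
#' @export
apply_cohort_filter <- function(cohort, predicates) {
  stopifnot(is.list(predicates), length(predicates) >= 1,
            !is.null(names(predicates)))
  keeps <- lapply(names(predicates), function(nm) {
    k <- predicates[[nm]](cohort)
    if (!is.logical(k) || length(k) != nrow(cohort) || anyNA(k)) {
      stop("predicate '", nm, "' must return a complete logical vector ",
           "over the cohort rows", call. = FALSE)
    }
    k
  })
  keep <- Reduce(`&`, keeps)
  report <- data.frame(clause = names(predicates),
                       removed = vapply(keeps, function(k) sum(!k), 0L),
                       stringsAsFactors = FALSE)
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("relation", "restriction", "exclusions", "birth_window",
              "min_survival_age")) {
    attr(out, a) <- attr(cohort, a)
  }
  class(out) <- class(cohort)
  list(cohort = out, report = report)
}
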