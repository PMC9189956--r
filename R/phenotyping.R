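#' Lifetime phenotyping from register events
#'
#' Turns diagnosis and dispensation events into lifetime binary phenotypes
#' through configurable case definitions (code-system-qualified diagnosis
#' code prefixes and ATC prefixes, any-of logic), builds composite
#' phenotypes as unions, and applies the minimum-case inclusion filter used
#' to screen outcome diseases.
#'
#' @name phenotyping
NULL

#' Define a lifetime phenotype
#'
#' A person is a case when any diagnosis event matches one of the
#' `(code_system, code_prefix)` rules or any dispensation matches an ATC
#' prefix; the first event year is the earliest matching year. Prefix
#' matching mirrors how ICD hierarchies are conventionally queried: a
#' three-character stem matches all its subcodes.
#'
#' @param name Phenotype label.
#' @param diagnosis_rules Data frame with columns `code_system` and
#'   `code_prefix` (may be empty).
#' @param atc_prefixes Character vector of ATC code prefixes (may be empty).
#' @return An object of class `case_definition`.
#' @export
case_definition <- function(name, diagnosis_rules = NULL,
                            atc_prefixes = character(0)) {
  if (is.null(diagnosis_rules)) {
    diagnosis_rules <- data.frame(code_system = character(0),
                                  code_prefix = character(0),
                                  stringsAsFactors = FALSE)
  }
  if (!nrow(diagnosis_rules) && !length(atc_prefixes)) {
    stop("case definition '", name, "' has no rules", call. = FALSE)
  }
  if (nrow(diagnosis_rules) &&
      any(is.na(diagnosis_rules$code_prefix) |
            diagnosis_rules$code_prefix == "")) {
    stop("diagnosis code prefixes must be non-empty", call. = FALSE)
  }
  if (length(atc_prefixes) && any(is.na(atc_prefixes) | atc_prefixes == "")) {
    stop("ATC prefixes must be non-empty", call. = FALSE)
  }
  structure(list(name = name, diagnosis_rules = diagnosis_rules,
                 atc_prefixes = atc_prefixes),
            class = "case_definition")
}

#' Read case definitions from a YAML configuration
#'
#' The file maps phenotype names to lists with optional `icd` (mapping of
#' code system to one or more prefixes) and `atc` (one or more prefixes).
#'
#' @param path YAML file path.
#' @return Named list of [case_definition()] objects.
#' @export
load_case_definitions <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    spec <- raw[[nm]]
    rules <- NULL
    if (!is.null(spec$icd)) {
      rules <- do.call(rbind, lapply(names(spec$icd), function(cs) {
        data.frame(code_system = cs,
                   code_prefix = as.character(unlist(spec$icd[[cs]])),
                   stringsAsFactors = FALSE)
      }))
    }
    case_definition(nm, rules, as.character(unlist(spec$atc)))
  })
  names(out) <- names(raw)
  out
}

#' Apply a case definition to a register bundle
#'
#' Dispensations before the drug-register era never contribute (the
#' register did not exist), so a drug-only case with all events before 2005
#' is not ascertainable.
#'
#' @param bundle A [register_bundle()].
#' @param definition A [case_definition()].
#' @param eras Era configuration, see [register_eras()].
#' @return Data frame (person_id, phenotype, is_case, first_event_year) with
#'   one row per person in the bundle.
#' @export
apply_case_definition <- function(bundle, definition,
                                  eras = register_eras()) {
  stopifnot(inherits(definition, "case_definition"))
  dg <- bundle$diagnoses
  dp <- bundle$dispensations
  dp <- dp[dp$event_year >= eras$drug_register_start, , drop = FALSE]
  hits <- list()
  dr <- definition$diagnosis_rules
  if (nrow(dr)) {
    for (i in seq_len(nrow(dr))) {
      sel <- dg$code_system == dr$code_system[i] &
        startsWith(dg$code, dr$code_prefix[i])
      if (any(sel)) {
        hits[[length(hits) + 1L]] <- dg[sel, c("person_id", "event_year")]
      }
    }
  }
  for (pre in definition$atc_prefixes) {
    sel <- startsWith(dp$atc_code, pre)
    if (any(sel)) {
      hits[[length(hits) + 1L]] <- dp[sel, c("person_id", "event_year")]
    }
  }
  out <- data.frame(person_id = bundle$persons$person_id,
                    phenotype = definition$name,
                    is_case = FALSE,
                    first_event_year = NA_integer_,
                    stringsAsFactors = FALSE)
  if (length(hits)) {
    h <- do.call(rbind, hits)
    first <- tapply(h$event_year, h$person_id, min)
    m <- match(names(first), out$person_id)
    ok <- !is.na(m)
    out$is_case[m[ok]] <- TRUE
    out$first_event_year[m[ok]] <- as.integer(first[ok])
  }
  out
}

#' Phenotype every person against a set of case definitions
#'
#' @param bundle A [register_bundle()].
#' @param definitions Named list of [case_definition()] objects.
#' @return Long data frame (person_id, phenotype, is_case, first_event_year)
#'   of class `phenotype_table`.
#' @export
build_phenotypes <- function(bundle, definitions) {
  out <- do.call(rbind, lapply(definitions, function(d) {
    apply_case_definition(bundle, d)
  }))
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Composite any-of phenotype
#'
#' A person is a case of the composite when a case of at least one member
#' phenotype; the first event year is the minimum across members.
#'
#' @param phenotypes A `phenotype_table`.
#' @param member_names Phenotype names entering the union.
#' @param name Label for the composite column.
#' @return The `phenotypes` table with the composite rows appended.
#' @export
build_any_ad <- function(phenotypes, member_names, name = "anyAD") {
  present <- unique(phenotypes$phenotype)
  missing <- setdiff(member_names, present)
  if (length(missing)) {
    stop("unknown phenotype(s) in composite: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- phenotypes[phenotypes$phenotype %in% member_names, , drop = FALSE]
  ids <- unique(phenotypes$person_id)
  agg_case <- tapply(sub$is_case, sub$person_id, any)
  agg_year <- suppressWarnings(
    tapply(sub$first_event_year, sub$person_id,
           function(x) if (all(is.na(x))) NA_integer_ else
             min(x, na.rm = TRUE)))
  comp <- data.frame(person_id = ids, phenotype = name,
                     is_case = unname(agg_case[match(ids, names(agg_case))]),
                     first_event_year =
                       as.integer(unname(agg_year[match(ids,
                                                        names(agg_year))])),
                     stringsAsFactors = FALSE)
  comp$is_case[is.na(comp$is_case)] <- FALSE
  out <- rbind(phenotypes, comp)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Minimum-case inclusion filter
#'
#' Retains a phenotype only when its case count within the index cohort is
#' strictly greater than `min_cases` (a phenotype with exactly `min_cases`
#' index cases is dropped).
#'
#' @param phenotypes A `phenotype_table`.
#' @param index An [build_index_cohort()] result.
#' @param min_cases Threshold count.
#' @param protect Phenotype names never dropped (e.g. the exposure trait).
#' @return Character vector of retained phenotype names, with the full count
#'   table in attribute `"counts"`.
#' @export
apply_min_case_filter <- function(phenotypes, index, min_cases = 2000L,
                                  protect = character(0)) {
  sub <- phenotypes[phenotypes$person_id %in% index$person_id &
                      phenotypes$is_case, , drop = FALSE]
  all_ph <- unique(phenotypes$phenotype)
  counts <- table(factor(sub$phenotype, levels = all_ph))
  keep <- names(counts)[counts > min_cases | names(counts) %in% protect]
  structure(keep, counts = as.data.frame(counts,
                                         responseName = "index_cases",
                                         stringsAsFactors = FALSE))
}
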