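#' Register-shaped data model
#'
#' The analysis operates on four logical tables mirroring the structure of
#' Nordic national registers: a total-population table (person, sex, birth
#' year, death/emigration year), a multi-generation parent-link table, a
#' patient-register diagnosis event table (ICD-coded, era-dependent) and a
#' prescribed-drug dispensation table (ATC-coded, register era from 2005).
#' A `register_bundle` holds the four tables plus provenance metadata and,
#' for synthetic data, an optional truth table of generating phenotypes.
#'
#' @name register-model
NULL

.persons_cols <- c("person_id", "sex", "birth_year", "death_year",
                   "emigration_year")
.links_cols <- c("child_id", "mother_id", "father_id")
.diagnoses_cols <- c("person_id", "code", "code_system", "event_year")
.dispensations_cols <- c("person_id", "atc_code", "event_year")

#' Era map of diagnosis code systems
#'
#' Calendar eras of the ICD revisions used in the patient register, and the
#' first year of the dispensation register.
#'
#' @return A list with a data frame `icd` (code_system, first, last) and the
#'   scalar `drug_register_start`.
#' @export
register_eras <- function() {
  list(
    icd = data.frame(
      code_system = c("ICD7", "ICD8", "ICD9", "ICD10"),
      first = c(1964L, 1968L, 1987L, 1997L),
      last = c(1967L, 1986L, 1996L, 9999L),
      stringsAsFactors = FALSE),
    drug_register_start = 2005L)
}

.empty_table <- function(cols) {
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

.coerce_int <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x[x == ""] <- NA_character_
  as.integer(x)
}

#' Construct a register bundle
#'
#' @param persons Data frame with columns person_id, sex ("female"/"male"),
#'   birth_year, death_year, emigration_year (the last two may be `NA`).
#' @param links Data frame with columns child_id, mother_id, father_id
#'   (parent ids may be `NA`).
#' @param diagnoses Data frame with columns person_id, code, code_system,
#'   event_year.
#' @param dispensations Data frame with columns person_id, atc_code,
#'   event_year.
#' @param metadata Named list of provenance values (seed, generator version,
#'   configuration echo, ...).
#' @param truth Optional data frame of generating-truth phenotypes
#'   (person_id, trait, liability, is_case), carried for testing.
#' @return An object of class `register_bundle`.
#' @export
register_bundle <- function(persons = NULL, links = NULL, diagnoses = NULL,
                            dispensations = NULL, metadata = list(),
                            truth = NULL) {
  if (is.null(persons)) persons <- .empty_table(.persons_cols)
  if (is.null(links)) links <- .empty_table(.links_cols)
  if (is.null(diagnoses)) diagnoses <- .empty_table(.diagnoses_cols)
  if (is.null(dispensations)) dispensations <- .empty_table(.dispensations_cols)
  for (nm in c("birth_year", "death_year", "emigration_year")) {
    persons[[nm]] <- .coerce_int(persons[[nm]])
  }
  persons$person_id <- as.character(persons$person_id)
  persons$sex <- as.character(persons$sex)
  for (nm in .links_cols) {
    links[[nm]] <- as.character(links[[nm]])
    links[[nm]][links[[nm]] == ""] <- NA_character_
  }
  diagnoses$person_id <- as.character(diagnoses$person_id)
  diagnoses$code <- as.character(diagnoses$code)
  diagnoses$code_system <- as.character(diagnoses$code_system)
  diagnoses$event_year <- .coerce_int(diagnoses$event_year)
  dispensations$person_id <- as.character(dispensations$person_id)
  dispensations$atc_code <- as.character(dispensations$atc_code)
  dispensations$event_year <- .coerce_int(dispensations$event_year)
  stopifnot(identical(names(persons)[seq_along(.persons_cols)], .persons_cols),
            identical(names(links)[seq_along(.links_cols)], .links_cols))
  structure(
    list(persons = persons, links = links, diagnoses = diagnoses,
         dispensations = dispensations, metadata = metadata, truth = truth),
    class = "register_bundle")
}

#' @export
print.register_bundle <- function(x, ...) {
  cat("<register_bundle>\n")
  cat(sprintf("  persons:       %d\n", nrow(x$persons)))
  cat(sprintf("  links:         %d\n", nrow(x$links)))
  cat(sprintf("  diagnoses:     %d\n", nrow(x$diagnoses)))
  cat(sprintf("  dispensations: %d\n", nrow(x$dispensations)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

.finding <- function(rule, table, key, message) {
  data.frame(rule = rule, table = table, key = as.character(key),
             message = message, stringsAsFactors = FALSE)
}

# Kahn-style peeling of the child->parent graph; vertices never peeled lie on
# a directed cycle (a person who is their own ancestor).
.pedigree_cycle_members <- function(links) {
  edges <- rbind(
    data.frame(from = links$child_id, to = links$mother_id,
               stringsAsFactors = FALSE),
    data.frame(from = links$child_id, to = links$father_id,
               stringsAsFactors = FALSE))
  edges <- edges[!is.na(edges$to), , drop = FALSE]
  if (!nrow(edges)) return(character(0))
  repeat {
    sinks <- setdiff(edges$to, edges$from)
    keep <- !(edges$to %in% sinks)
    if (all(keep)) break
    edges <- edges[keep, , drop = FALSE]
    if (!nrow(edges)) break
  }
  unique(c(edges$from, edges$to))
}

#' Validate a register bundle
#'
#' Checks every structural invariant of the data model: identifier
#' uniqueness, resolvable person references, chronology (death/emigration and
#' events not before birth, events within the lifespan), era consistency of
#' diagnosis coding, the dispensation-register era, and absence of pedigree
#' cycles. Violations are data, not exceptions: the result is a report table,
#' empty if and only if the bundle is valid.
#'
#' @param bundle A [register_bundle()].
#' @param eras Era configuration, see [register_eras()].
#' @return A data frame of findings (rule, table, key, message) with class
#'   `register_validation`.
#' @export
validate_registers <- function(bundle, eras = register_eras()) {
  stopifnot(inherits(bundle, "register_bundle"))
  p <- bundle$persons; l <- bundle$links
  dg <- bundle$diagnoses; dp <- bundle$dispensations
  out <- list()

  dup <- unique(p$person_id[duplicated(p$person_id)])
  if (length(dup)) {
    out[[length(out) + 1L]] <- .finding(
      "duplicate_person_id", "persons", dup,
      sprintf("person_id '%s' occurs more than once", dup))
  }
  bad_sex <- p$person_id[!p$sex %in% c("female", "male")]
  if (length(bad_sex)) {
    out[[length(out) + 1L]] <- .finding(
      "invalid_sex", "persons", bad_sex, "sex must be 'female' or 'male'")
  }
  for (nm in c("death_year", "emigration_year")) {
    bad <- which(!is.na(p[[nm]]) & p[[nm]] < p$birth_year)
    if (length(bad)) {
      out[[length(out) + 1L]] <- .finding(
        "event_before_birth", "persons", p$person_id[bad],
        sprintf("%s precedes birth_year", nm))
    }
  }

  dupc <- unique(l$child_id[duplicated(l$child_id)])
  if (length(dupc)) {
    out[[length(out) + 1L]] <- .finding(
      "duplicate_child_id", "links", dupc,
      sprintf("child_id '%s' occurs more than once", dupc))
  }
  ids <- p$person_id
  for (nm in .links_cols) {
    ref <- l[[nm]]
    bad <- unique(ref[!is.na(ref) & !(ref %in% ids)])
    if (length(bad)) {
      out[[length(out) + 1L]] <- .finding(
        "unresolved_reference", "links", bad,
        sprintf("%s '%s' not found in persons", nm, bad))
    }
  }
  cyc <- .pedigree_cycle_members(l)
  if (length(cyc)) {
    out[[length(out) + 1L]] <- .finding(
      "pedigree_cycle", "links", cyc, "person lies on an ancestry cycle")
  }

  birth <- p$birth_year[match(dg$person_id, ids)]
  death <- p$death_year[match(dg$person_id, ids)]
  bad <- unique(dg$person_id[!(dg$person_id %in% ids)])
  if (length(bad)) {
    out[[length(out) + 1L]] <- .finding(
      "unresolved_reference", "diagnoses", bad,
      sprintf("person_id '%s' not found in persons", bad))
  }
  empty <- which(is.na(dg$code) | dg$code == "")
  if (length(empty)) {
    out[[length(out) + 1L]] <- .finding(
      "empty_code", "diagnoses", dg$person_id[empty], "diagnosis code is empty")
  }
  era <- eras$icd[match(dg$code_system, eras$icd$code_system), ]
  bad <- which(is.na(era$first))
  if (length(bad)) {
    out[[length(out) + 1L]] <- .finding(
      "unknown_code_system", "diagnoses", dg$person_id[bad],
      sprintf("unknown code_system '%s'", dg$code_system[bad]))
  }
  off <- which(!is.na(era$first) &
                 (dg$event_year < era$first | dg$event_year > era$last))
  if (length(off)) {
    out[[length(out) + 1L]] <- .finding(
      "era_mismatch", "diagnoses", dg$person_id[off],
      sprintf("%s event in %d is outside the %s era",
              dg$code_system[off], dg$event_year[off], dg$code_system[off]))
  }
  early <- which(!is.na(birth) & dg$event_year < birth)
  late <- which(!is.na(death) & dg$event_year > death)
  if (length(early) || length(late)) {
    idx <- c(early, late)
    out[[length(out) + 1L]] <- .finding(
      "event_outside_lifespan", "diagnoses", dg$person_id[idx],
      "diagnosis event outside the person's lifespan")
  }

  bad <- unique(dp$person_id[!(dp$person_id %in% ids)])
  if (length(bad)) {
    out[[length(out) + 1L]] <- .finding(
      "unresolved_reference", "dispensations", bad,
      sprintf("person_id '%s' not found in persons", bad))
  }
  empty <- which(is.na(dp$atc_code) | dp$atc_code == "")
  if (length(empty)) {
    out[[length(out) + 1L]] <- .finding(
      "empty_code", "dispensations", dp$person_id[empty], "ATC code is empty")
  }
  pre <- which(dp$event_year < eras$drug_register_start)
  if (length(pre)) {
    out[[length(out) + 1L]] <- .finding(
      "pre_register_era_event", "dispensations", dp$person_id[pre],
      sprintf("dispensation in %d precedes the drug register era (%d)",
              dp$event_year[pre], eras$drug_register_start))
  }

  report <- if (length(out)) do.call(rbind, out) else
    .finding(character(0), character(0), character(0), character(0))
  class(report) <- c("register_validation", "data.frame")
  report
}

#' @export
print.register_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("register bundle valid: no findings\n")
  } else {
    cat(sprintf("register bundle INVALID: %d finding(s)\n", nrow(x)))
    print.data.frame(utils::head(x, 20))
    if (nrow(x) > 20) cat("...\n")
  }
  invisible(x)
}

.sort_table <- function(df, keys) {
  df[do.call(order, df[keys]), , drop = FALSE]
}

#' Write a register bundle to a directory
#'
#' One tab-separated UTF-8 file per table with a single header row, absent
#' values encoded as empty strings, deterministic column and row order
#' (sorted by primary key), plus a JSON metadata sidecar and, when present,
#' the generating-truth phenotype table.
#'
#' @param bundle A [register_bundle()].
#' @param directory Target directory (created if needed).
#' @return Invisibly, a named character vector of written file paths.
#' @export
write_registers <- function(bundle, directory) {
  stopifnot(inherits(bundle, "register_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2L) != 0L) {
    stop("directory not writable: ", directory, call. = FALSE)
  }
  tabs <- list(
    persons = .sort_table(bundle$persons, "person_id"),
    links = .sort_table(bundle$links, "child_id"),
    diagnoses = .sort_table(bundle$diagnoses,
                            c("person_id", "event_year", "code")),
    dispensations = .sort_table(bundle$dispensations,
                                c("person_id", "event_year", "atc_code")))
  manifest <- c()
  for (nm in names(tabs)) {
    path <- file.path(directory, paste0(nm, ".tsv"))
    utils::write.table(tabs[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    manifest[nm] <- path
  }
  meta_path <- file.path(directory, "metadata.json")
  jsonlite::write_json(bundle$metadata, meta_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  manifest["metadata"] <- meta_path
  if (!is.null(bundle$truth)) {
    tp <- file.path(directory, "truth_phenotypes.tsv")
    utils::write.table(.sort_table(bundle$truth, c("person_id", "trait")), tp,
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "",
                       fileEncoding = "UTF-8")
    manifest["truth_phenotypes"] <- tp
  }
  invisible(manifest)
}

.read_register_table <- function(path, cols, int_cols) {
  if (!file.exists(path)) {
    stop("register file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, colClasses = "character", sep = "\t",
                           quote = "", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (!identical(names(raw), cols)) {
    stop(sprintf("header of '%s' is (%s); expected (%s)", path,
                 paste(names(raw), collapse = ", "),
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  for (nm in int_cols) {
    val <- suppressWarnings(as.integer(raw[[nm]]))
    bad <- which(!is.na(raw[[nm]]) & raw[[nm]] != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' in file '%s', line %d, column '%s'",
                   raw[[nm]][bad[1]], path, bad[1] + 1L, nm), call. = FALSE)
    }
    raw[[nm]] <- val
  }
  raw
}

#' Load a register bundle from files
#'
#' @param paths Either a directory written by [write_registers()] or a named
#'   list/vector with elements `persons`, `links`, `diagnoses`,
#'   `dispensations` and optionally `metadata` and `truth_phenotypes`.
#' @param validate Validate after loading (default `TRUE`); a bundle with
#'   findings raises an error naming the first violations.
#' @return A [register_bundle()].
#' @export
load_registers <- function(paths, validate = TRUE) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- list(
      persons = file.path(paths, "persons.tsv"),
      links = file.path(paths, "links.tsv"),
      diagnoses = file.path(paths, "diagnoses.tsv"),
      dispensations = file.path(paths, "dispensations.tsv"),
      metadata = file.path(paths, "metadata.json"),
      truth_phenotypes = file.path(paths, "truth_phenotypes.tsv"))
  }
  persons <- .read_register_table(paths$persons, .persons_cols,
                                  c("birth_year", "death_year",
                                    "emigration_year"))
  links <- .read_register_table(paths$links, .links_cols, character(0))
  diagnoses <- .read_register_table(paths$diagnoses, .diagnoses_cols,
                                    "event_year")
  dispensations <- .read_register_table(paths$dispensations,
                                        .dispensations_cols, "event_year")
  metadata <- list()
  if (!is.null(paths$metadata) && file.exists(paths$metadata)) {
    metadata <- jsonlite::read_json(paths$metadata, simplifyVector = TRUE)
  }
  truth <- NULL
  if (!is.null(paths$truth_phenotypes) && file.exists(paths$truth_phenotypes)) {
    truth <- utils::read.delim(paths$truth_phenotypes, sep = "\t", quote = "",
                               stringsAsFactors = FALSE)
    truth$person_id <- as.character(truth$person_id)
  }
  bundle <- register_bundle(persons, links, diagnoses, dispensations,
                            metadata = metadata, truth = truth)
  if (validate) {
    rep <- validate_registers(bundle)
    if (nrow(rep)) {
      stop("loaded bundle fails validation: ",
           paste(utils::head(unique(
             sprintf("[%s] %s", rep$rule, rep$message)), 5L), collapse = "; "),
           call. = FALSE)
    }
  }
  bundle
}
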