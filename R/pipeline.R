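#' Reproducible analysis pipeline
#'
#' Config-driven end-to-end runs: synthetic register generation, cohort
#' construction, phenotyping, within-individual and familial co-aggregation
#' odds ratios, standardized risks, ratio-of-odds-ratio contrasts, and
#' variance-component modelling, with deterministic per-stage seeds derived
#' from one master seed and tabular outputs mirroring the result structures
#' of a register-based co-aggregation study (pair-count table, case-count
#' table, odds-ratio forest table, ROR table, variance-component table).
#'
#' @name pipeline
NULL

# per-stage seed derivation from the master seed (documented scheme: master
# seed times 1009 plus a fixed stage offset, folded into the integer range)
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, quantgen_select = 2L, bootstrap = 3L)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Pipeline configuration
#'
#' Returns the default configuration, optionally overridden from a YAML file
#' and/or a named list. Settings: `seed`, `n_families`, `birth_window`,
#' `late_window`, `min_survival_age`, `min_cases`, `exposure`, `outcome`,
#' `relations`, `contrasts`, `spline_knots`, `n_boot`, `quantgen` (list with
#' `n_starts`, `candidates`).
#'
#' @param path Optional YAML file with overrides.
#' @param overrides Optional named list of overrides (applied last).
#' @return Configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    n_families = 5000L,
    birth_window = c(1960L, 2010L),
    late_window = c(1980L, 2010L),
    min_survival_age = 10L,
    min_cases = 20L,
    exposure = "adhd",
    outcome = "anyAD",
    relations = c("mother", "father", "full_sibling", "aunt", "uncle",
                  "cousin"),
    contrasts = c("mother_vs_father", "aunt_vs_uncle",
                  "maternal_side_vs_paternal_side"),
    spline_knots = 5L,
    n_boot = 200L,
    quantgen = list(n_starts = 2L, run = TRUE))
  apply_over <- function(cfg, ov) {
    for (nm in names(ov)) {
      cfg[[nm]] <- if (is.list(ov[[nm]]) && is.list(cfg[[nm]])) {
        utils::modifyList(cfg[[nm]], ov[[nm]])
      } else ov[[nm]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path))
  cfg <- apply_over(cfg, overrides)
  structure(cfg, class = c("pipeline_config", "list"))
}

.write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Simulate a register bundle from a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, the bundle is written there
#'   via [write_registers()].
#' @param verbose Log stage summaries.
#' @return The [register_bundle()] (invisibly when written to disk).
#' @export
pipeline_simulate <- function(config = pipeline_config(), outdir = NULL,
                              verbose = TRUE) {
  params <- simulation_params(n_families = config$n_families,
                              birth_year_range = c(1920L, 2010L),
                              seed = .stage_seed(config$seed, "simulate"))
  bundle <- simulate_register_bundle(params)
  .log_stage(verbose, "simulated %d persons in %d families (%d diagnoses, %d dispensations)",
             nrow(bundle$persons), config$n_families, nrow(bundle$diagnoses),
             nrow(bundle$dispensations))
  if (!is.null(outdir)) {
    write_registers(bundle, file.path(outdir, "bundle"))
    .log_stage(verbose, "bundle written to %s", file.path(outdir, "bundle"))
    return(invisible(bundle))
  }
  bundle
}

# default phenotype definitions matched to the generator's coding config
#' Case definitions mirroring the default coding configuration
#'
#' Builds one [case_definition()] per code group of
#' [default_coding_config()] (the exposure trait plus 13 illustrative
#' autoimmune diseases), suitable for phenotyping generator output.
#'
#' @param coding_config See [default_coding_config()].
#' @return Named list of [case_definition()] objects.
#' @export
default_case_definitions <- function(coding_config = default_coding_config()) {
  defs <- list()
  for (tr in coding_config) {
    for (g in tr$groups) {
      rules <- do.call(rbind, lapply(c("ICD10", "ICD9", "ICD8", "ICD7"),
                                     function(cs) {
        data.frame(code_system = cs, code_prefix = g[[cs]],
                   stringsAsFactors = FALSE)
      }))
      defs[[g$label]] <- case_definition(
        g$label, rules,
        if (is.na(g$atc)) character(0) else g$atc)
    }
  }
  defs
}

#' Run the full co-aggregation analysis pipeline
#'
#' Executes cohorts, phenotypes, the within-individual association, one
#' odds-ratio analysis per configured relation, standardized risks for the
#' within-individual and parent analyses, the configured ratio-of-odds-ratio
#' contrasts, and bivariate variance-component modelling on one
#' sibling/cousin pair per family. All outputs are written as tab-separated
#' tables (plus a JSON variance-component report) into `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param bundle Optional pre-simulated [register_bundle()]; simulated from
#'   the config when `NULL`.
#' @param verbose Log stage summaries.
#' @return Invisibly, a named list of result objects.
#' @export
pipeline_run_all <- function(config = pipeline_config(), outdir = "results",
                             bundle = NULL, verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(bundle)) {
    bdir <- file.path(outdir, "bundle")
    bundle <- if (dir.exists(bdir)) load_registers(bdir) else
      pipeline_simulate(config, verbose = verbose)
  }
  persons <- bundle$persons

  idx <- build_index_cohort(bundle, config$birth_window,
                            config$min_survival_age)
  .log_stage(verbose, "index cohort: %d members", nrow(idx))

  defs <- default_case_definitions()
  phen <- build_phenotypes(bundle, defs)
  ad_names <- setdiff(names(defs), config$exposure)
  phen <- build_any_ad(phen, ad_names, name = config$outcome)
  retained <- apply_min_case_filter(phen, idx, config$min_cases,
                                    protect = c(config$exposure,
                                                config$outcome))
  .write_tsv(attr(retained, "counts"), outdir, "case_filter.tsv")

  # Table 2 analogue: case counts, sex distribution, overlap with exposure
  exp_cases <- phen$person_id[phen$phenotype == config$exposure & phen$is_case]
  idx_ids <- idx$person_id
  case_tab <- do.call(rbind, lapply(unique(phen$phenotype), function(ph) {
    sub <- phen[phen$phenotype == ph & phen$is_case &
                  phen$person_id %in% idx_ids, , drop = FALSE]
    sex <- persons$sex[match(sub$person_id, persons$person_id)]
    data.frame(phenotype = ph, n_index_cases = nrow(sub),
               prevalence_per_10000 = round(1e4 * nrow(sub) /
                                              length(idx_ids), 1),
               female_pct = round(100 * mean(sex == "female"), 1),
               n_with_exposure = sum(sub$person_id %in% exp_cases),
               retained = ph %in% retained,
               stringsAsFactors = FALSE)
  }))
  .write_tsv(case_tab, outdir, "case_counts.tsv")

  clusters <- family_clusters(bundle)
  or_rows <- list()
  pair_rows <- list(data.frame(
    cohort = "within_individual", n_index = nrow(idx),
    n_relatives = NA_integer_, n_pairs = nrow(idx),
    stringsAsFactors = FALSE))

  within <- run_within_association(
    idx, phen, config$exposure, config$outcome,
    cluster_ids = unname(clusters[idx$person_id]),
    n_knots = config$spline_knots)
  or_rows[["within_individual"]] <- within
  .log_stage(verbose, "within-individual OR %.3f (%.3f-%.3f)",
             within$estimate, within$ci_low, within$ci_high)

  pair_cohorts <- list()
  for (rel in config$relations) {
    pr <- build_relative_pairs(bundle, idx, rel,
                               late_window = config$late_window,
                               min_survival_age = config$min_survival_age)
    pair_cohorts[[rel]] <- pr
    pair_rows[[rel]] <- data.frame(
      cohort = rel, n_index = length(unique(pr$index_id)),
      n_relatives = length(unique(pr$relative_id)), n_pairs = nrow(pr),
      stringsAsFactors = FALSE)
    or_rows[[rel]] <- run_pair_association(pr, phen, persons,
                                           config$exposure, config$outcome,
                                           n_knots = config$spline_knots)
    .log_stage(verbose, "%s: %d pairs, OR %.3f", rel, nrow(pr),
               or_rows[[rel]]$estimate)
  }
  .write_tsv(do.call(rbind, pair_rows), outdir, "pair_counts.tsv")

  or_tab <- do.call(rbind, lapply(names(or_rows), function(nm) {
    r <- or_rows[[nm]]
    data.frame(analysis_id = nm, relation = nm, outcome = config$outcome,
               exposure = config$exposure, n_pairs = r$n_pairs,
               n_clusters = r$n_clusters, or = r$estimate,
               ci_low = r$ci_low, ci_high = r$ci_high, p = r$p_value,
               model_spec = r$model_spec, stringsAsFactors = FALSE)
  }))
  .write_tsv(or_tab, outdir, "or_results.tsv")

  # standardized risks for the within-individual analysis
  sr_frame <- {
    sub <- phen[phen$phenotype %in% c(config$exposure, config$outcome), ]
    list(y = as.numeric(sub$is_case[sub$phenotype == config$outcome][
           match(idx$person_id,
                 sub$person_id[sub$phenotype == config$outcome])]),
         x = as.numeric(sub$is_case[sub$phenotype == config$exposure][
           match(idx$person_id,
                 sub$person_id[sub$phenotype == config$exposure])]))
  }
  sr <- standardized_risks(
    sr_frame$y, sr_frame$x,
    covariates = cbind(natural_cubic_spline_basis(idx$birth_year,
                                                  config$spline_knots),
                       as.numeric(idx$sex == "female")),
    cluster_ids = unname(clusters[idx$person_id]),
    n_boot = config$n_boot, seed = .stage_seed(config$seed, "bootstrap"))
  sr_tab <- data.frame(
    analysis_id = "within_individual",
    ar_exposed = sr$ar_exposed, ar_unexposed = sr$ar_unexposed, rd = sr$rd,
    ar_exposed_low = sr$ar_exposed_ci[1], ar_exposed_high = sr$ar_exposed_ci[2],
    ar_unexposed_low = sr$ar_unexposed_ci[1],
    ar_unexposed_high = sr$ar_unexposed_ci[2],
    rd_low = sr$rd_ci[1], rd_high = sr$rd_ci[2],
    n_boot = sr$n_boot, seed = sr$seed, stringsAsFactors = FALSE)
  .write_tsv(sr_tab, outdir, "standardized_risks.tsv")

  # ROR contrasts
  ror_rows <- list()
  side_split <- function(rel_pairs, side) {
    out <- rel_pairs[!is.na(rel_pairs$side) & rel_pairs$side == side, ,
                     drop = FALSE]
    attr(out, "relation") <- attr(rel_pairs, "relation")
    class(out) <- class(rel_pairs)
    out
  }
  for (ct in config$contrasts) {
    groups <- switch(ct,
      mother_vs_father = list(pair_cohorts$mother, pair_cohorts$father),
      aunt_vs_uncle = list(pair_cohorts$aunt, pair_cohorts$uncle),
      maternal_side_vs_paternal_side = {
        au <- rbind(as.data.frame(pair_cohorts$aunt),
                    as.data.frame(pair_cohorts$uncle))
        list(au[au$side == "maternal", ], au[au$side == "paternal", ])
      },
      stop("unknown contrast '", ct, "'", call. = FALSE))
    if (is.null(groups[[1]]) || is.null(groups[[2]])) next
    ror_rows[[ct]] <- ror_contrast(groups[[1]], groups[[2]], phen, persons,
                                   config$exposure, config$outcome,
                                   contrast = ct,
                                   n_knots = config$spline_knots)
    .log_stage(verbose, "%s: ROR %.3f", ct, ror_rows[[ct]]$ror)
  }
  if (length(ror_rows)) {
    ror_tab <- do.call(rbind, lapply(ror_rows, function(r) {
      data.frame(contrast = r$contrast, ror = r$ror, ci_low = r$ci_low,
                 ci_high = r$ci_high, p = r$p_value,
                 or_group_a = r$component_ors$group_a$estimate,
                 or_group_b = r$component_ors$group_b$estimate,
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(ror_tab, outdir, "ror_results.tsv")
  }

  # quantitative genetic modelling on one pair per family
  qg <- NULL
  if (isTRUE(config$quantgen$run) &&
      all(c("full_sibling", "cousin") %in% names(pair_cohorts))) {
    qseed <- .stage_seed(config$seed, "quantgen_select")
    sib <- select_quantgen_pairs(bundle, pair_cohorts$full_sibling, qseed)
    cou <- select_quantgen_pairs(bundle, pair_cohorts$cousin, qseed + 1L)
    get_case <- function(ids, ph) {
      sub <- phen[phen$phenotype == ph, ]
      sub$is_case[match(ids, sub$person_id)]
    }
    mk_cases <- function(pr) {
      cbind(get_case(pr$index_id, config$exposure),
            get_case(pr$index_id, config$outcome),
            get_case(pr$relative_id, config$exposure),
            get_case(pr$relative_id, config$outcome))
    }
    counts <- rbind(tabulate_pair_patterns(mk_cases(sib), "full_sibling"),
                    tabulate_pair_patterns(mk_cases(cou), "cousin"))
    attr(counts, "specs") <- list(full_sibling = sibling_class(),
                                  cousin = cousin_class())
    class(counts) <- c("pattern_counts", "data.frame")
    .write_tsv(counts, outdir, "pattern_counts.tsv")
    qg <- tryCatch({
      sel <- select_model(
        counts,
        candidates = list(
          ACE_ACE = list(trait1 = c("A", "C", "E"),
                         trait2 = c("A", "C", "E")),
          AE_ACE = list(trait1 = c("A", "E"), trait2 = c("A", "C", "E"))),
        control = ace_control(n_starts = config$quantgen$n_starts))
      fit <- sel$best
      report <- list(
        selection = sel$table,
        estimates = fit$ci,
        variance_components = unclass(fit$estimates)[
          c("a2", "c2", "e2", "rA", "rC", "rE", "thresholds")],
        covariance_shares = fit$shares,
        loglik = fit$loglik, aic = fit$aic,
        n_pairs = c(full_sibling = nrow(sib), cousin = nrow(cou)),
        convergence = fit$convergence)
      jsonlite::write_json(report, file.path(outdir, "quantgen_fit.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           dataframe = "rows")
      .log_stage(verbose, "quantgen best model: %s (AIC %.1f)",
                 sel$table$candidate[1], sel$table$aic[1])
      sel
    }, error = function(e) {
      warning("quantgen stage failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  }

  invisible(list(index = idx, phenotypes = phen, pair_cohorts = pair_cohorts,
                 or_results = or_rows, standardized_risks = sr,
                 ror_results = ror_rows, quantgen = qg))
}

#' Render a human-readable summary of pipeline results
#'
#' Reads the result tables written by [pipeline_run_all()] and prints
#' forest-style text summaries. Every number shown is read from a results
#' table; nothing is recomputed. Corrupted tables (e.g. inverted interval
#' bounds) are refused.
#'
#' @param outdir Results directory.
#' @return Invisibly, the list of tables read.
#' @export
pipeline_report <- function(outdir = "results") {
  need <- c("or_results.tsv", "pair_counts.tsv")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing)) {
    stop("results directory '", outdir, "' is missing expected file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tabs <- list()
  rd <- function(nm) utils::read.delim(file.path(outdir, nm), sep = "\t",
                                       stringsAsFactors = FALSE)
  tabs$pair_counts <- rd("pair_counts.tsv")
  tabs$or <- rd("or_results.tsv")
  if (any(tabs$or$ci_low > tabs$or$ci_high, na.rm = TRUE)) {
    stop("or_results.tsv is corrupted: ci_low exceeds ci_high", call. = FALSE)
  }
  cat("== pair cohorts ==\n")
  print(tabs$pair_counts, row.names = FALSE)
  cat("\n== odds ratios (95% CI) ==\n")
  bar <- function(or) {
    pos <- max(0L, min(40L, round(20 + 40 * log(or))))
    paste0(strrep(" ", pos), "*")
  }
  for (i in seq_len(nrow(tabs$or))) {
    r <- tabs$or[i, ]
    cat(sprintf("  %-18s OR %6.3f (%5.3f-%5.3f)  p=%-8.2g |%s\n",
                r$relation, r$or, r$ci_low, r$ci_high, r$p, bar(r$or)))
  }
  if (file.exists(file.path(outdir, "ror_results.tsv"))) {
    tabs$ror <- rd("ror_results.tsv")
    cat("\n== ratio-of-odds-ratio contrasts ==\n")
    for (i in seq_len(nrow(tabs$ror))) {
      r <- tabs$ror[i, ]
      cat(sprintf("  %-32s ROR %6.3f (%5.3f-%5.3f)  p=%-8.2g\n",
                  r$contrast, r$ror, r$ci_low, r$ci_high, r$p))
    }
  }
  if (file.exists(file.path(outdir, "standardized_risks.tsv"))) {
    tabs$sr <- rd("standardized_risks.tsv")
    cat("\n== standardized absolute risks ==\n")
    for (i in seq_len(nrow(tabs$sr))) {
      r <- tabs$sr[i, ]
      cat(sprintf("  %s: AR exposed %.4f (%.4f-%.4f), unexposed %.4f (%.4f-%.4f), RD %.4f (%.4f-%.4f)\n",
                  r$analysis_id, r$ar_exposed, r$ar_exposed_low,
                  r$ar_exposed_high, r$ar_unexposed, r$ar_unexposed_low,
                  r$ar_unexposed_high, r$rd, r$rd_low, r$rd_high))
    }
  }
  qfile <- file.path(outdir, "quantgen_fit.json")
  if (file.exists(qfile)) {
    q <- jsonlite::read_json(qfile, simplifyVector = TRUE)
    tabs$quantgen <- q
    cat("\n== variance components (best model by AIC) ==\n")
    est <- q$estimates
    for (i in seq_len(nrow(est))) {
      if (is.na(est$estimate[i])) next
      cat(sprintf("  %-6s %6.3f (%6.3f-%6.3f)\n", est$parameter[i],
                  est$estimate[i], est$ci_low[i], est$ci_high[i]))
    }
  }
  invisible(tabs)
}
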