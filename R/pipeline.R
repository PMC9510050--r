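#' Build the per-child cohort table
#'
#' One row per trio child: final DNM count, scaled phased counts, parental
#' ages at conception, family size, population, phenotype, and the parents'
#' estimated kinship with its relatedness class.
#'
#' @param dnms Final (phased) DNM tibble.
#' @param pedigree Pedigree tibble.
#' @param kinship Optional per-family kinship tibble from
#'   [parent_kinship()].
#' @return Cohort tibble with columns `child_id`, `family_id`, `dnm_count`,
#'   `scaled_paternal`, `scaled_maternal`, `father_age`, `mother_age`,
#'   `n_offspring`, `population`, `phenotype`, and (when kinship is given)
#'   `phi`, `relatedness`.
#' @export
build_cohort_table <- function(dnms, pedigree, kinship = NULL) {
  kids <- dplyr::filter(pedigree, .data$role == "child")
  counts <- dplyr::count(dnms, .data$child_id, name = "dnm_count")
  ph <- if ("phase" %in% names(dnms)) {
    dplyr::select(summarize_phasing(dnms), "child_id", "n_phased",
                  "scaled_paternal", "scaled_maternal")
  } else {
    tibble::tibble(child_id = character(), n_phased = integer(),
                   scaled_paternal = numeric(), scaled_maternal = numeric())
  }
  out <- dplyr::left_join(
    dplyr::select(kids, child_id = "individual_id", "family_id",
                  "father_age", "mother_age", "n_offspring", "population",
                  "phenotype", "consanguinity_class"),
    counts, by = "child_id"
  )
  out$dnm_count[is.na(out$dnm_count)] <- 0L
  out <- dplyr::left_join(out, ph, by = "child_id")
  if (!is.null(kinship)) {
    out <- dplyr::left_join(out, kinship, by = "family_id")
  }
  out
}

#' Run the full DNM discovery and characterization pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort: candidate
#' generation, per-tool base filtration, two-of-three consensus merge with
#' single-tool rescue, population-frequency filter, sibling-sharing filter,
#' read-backed phasing, cohort-table assembly, kinship estimation, spectra,
#' methylation enrichment, and the parental-age and family-size regressions.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed (fully determines the run).
#' @param thresholds A [dnm_thresholds()] object.
#' @param meth_subset Which DNM CpGs enter the methylation enrichment:
#'   `"paternal"` (paternally phased, the gonadal-tissue analysis) or
#'   `"all"`.
#' @param verbose Log per-stage funnel counts.
#' @return A list of class `dnmtrio_run`: the simulated `cohort`, the
#'   filtered/merged/final `dnms`, the per-child `cohort_table`, `phasing`
#'   summaries, `spectrum`, `coverage`, `rates`, `methylation`, and the
#'   regression `fits`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(sim_config(n_families = 8), seed = 1)
#' run$rates
#' }
run_pipeline <- function(config = sim_config(), seed = 1,
                         thresholds = dnm_thresholds(),
                         meth_subset = c("paternal", "all"),
                         verbose = FALSE) {
  meth_subset <- match.arg(meth_subset)
  sim <- simulate_cohort(config, seed)
  log_n <- function(stage, n) {
    if (verbose) inform(sprintf("%s: %d", stage, n))
  }
  log_n("candidates", nrow(sim$calls))

  filtered <- filter_tool_candidates(sim$calls, thresholds, verbose = verbose)
  merged <- merge_consensus(filtered, thresholds)
  log_n("consensus", nrow(merged))

  merged <- filter_population_af(merged,
                                 af_max = thresholds$population_af_max)
  member_geno <- family_genotype_table(merged, sim$genotypes, sim$pedigree,
                                       attr(sim$calls, "artifacts"))
  dnms <- filter_family_sharing(merged, member_geno)
  log_n("family-filtered", nrow(dnms))

  dnms <- annotate_cpg(dnms, sim$reference, sim$meth_track)
  dnms <- phase_dnms(dnms, sim$genotypes, sim$pedigree, sim$coobs,
                     window = config$read_length)
  phasing_by_child <- summarize_phasing(dnms)
  phasing_cohort <- summarize_phasing(sum(dnms$phase == "paternal"),
                                      sum(dnms$phase == "maternal"))

  kinship <- parent_kinship(sim$genotypes, sim$pedigree)
  cohort_table <- build_cohort_table(dnms, sim$pedigree, kinship)

  L <- nchar(sim$reference)
  coverage <- effective_coverage(rep(TRUE, L),
                                 cpg_covered_positions(sim$reference))
  counts <- summarize_dnm_counts(dnms, children = cohort_table$child_id)
  rates <- dplyr::mutate(counts,
                         rate = purrr::map_dbl(.data$median, dnm_rate,
                                               coverage = coverage))

  spectrum <- mutation_spectrum(dnms, sim$reference)

  cpg_units <- if (meth_subset == "paternal") {
    dnm_cpg_units(dnms[dnms$phase == "paternal", ], sim$reference)
  } else {
    dnm_cpg_units(dnms, sim$reference)
  }
  methylation <- if (nrow(cpg_units) > 0) {
    enrich_tissues(cpg_units, list(gonadal = sim$meth_track))
  } else {
    NULL
  }

  fits <- list(
    paternal_age = try_fit(fit_age_trend(cohort_table, "father")),
    maternal_age = try_fit(fit_age_trend(cohort_table, "mother")),
    family_size = try_fit(family_size_effect(cohort_table)),
    poisson_age = try_fit(fit_poisson_identity(cohort_table)),
    poisson_by_family = try_fit(fit_poisson_identity(cohort_table,
                                                     interaction = TRUE))
  )

  structure(
    list(config = config, seed = seed, sim = sim, merged = merged,
         dnms = dnms, cohort_table = cohort_table,
         phasing_by_child = phasing_by_child,
         phasing_cohort = phasing_cohort, kinship = kinship,
         coverage = coverage, counts = counts, rates = rates,
         spectrum = spectrum, methylation = methylation, fits = fits),
    class = "dnmtrio_run"
  )
}

try_fit <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}

#' @export
print.dnmtrio_run <- function(x, ...) {
  cat("<dnmtrio_run> seed", x$seed, "\n")
  cat("  children:", nrow(x$cohort_table),
      " final DNMs:", nrow(x$dnms), "\n")
  cat(sprintf("  phased: %d (%.0f%% paternal)\n",
              x$phasing_cohort$n_phased,
              100 * x$phasing_cohort$paternal_fraction))
  invisible(x)
}

#' Cohort report
#'
#' Assembles the summary tables of a pipeline run — cohort description
#' (sizes, medians, rates), methylation enrichment, phasing, and regression
#' summaries. Every number is recomputed from the run's outputs.
#'
#' @param run A `dnmtrio_run` object.
#' @return List of tibbles: `cohort`, `counts`, `methylation`, `phasing`,
#'   `regressions`.
#' @export
cohort_report <- function(run) {
  ct <- run$cohort_table
  cohort <- tibble::tibble(
    description = c("Families", "Trios", "Consanguineous families",
                    "Median father age", "Median mother age",
                    "Total DNMs", "Effective coverage (bases)"),
    value = c(length(unique(ct$family_id)), nrow(ct),
              length(unique(ct$family_id[ct$consanguinity_class !=
                                           "unrelated"])),
              median(ct$father_age), median(ct$mother_age),
              nrow(run$dnms), run$coverage$total)
  )
  regressions <- dplyr::bind_rows(
    purrr::map(purrr::compact(run$fits), glance)
  )
  list(
    cohort = cohort,
    counts = run$rates,
    methylation = run$methylation,
    phasing = run$phasing_cohort,
    regressions = regressions
  )
}
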