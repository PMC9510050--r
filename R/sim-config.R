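#' Simulation configuration for a synthetic multiplex-family cohort
#'
#' Bundles every tunable of the cohort generator. The defaults reproduce the
#' structure of a large consanguineous multiplex-family WGS cohort: 146
#' families yielding roughly 353 trios, paternal ages centred on a median of
#' 34 years (range 21-50), maternal ages on 29, family sizes of 1-10 offspring
#' with median 2, about one third of families consanguineous, a mean of 70 de
#' novo SNVs and 6 de novo indels per child at the reference parental ages, a
#' paternal-age effect of 1.36 additional DNMs per year, a maternal effect of
#' 0.33, 80% of DNMs paternal in origin, and a two-fold elevated mutability at
#' methylated CpG sites.
#'
#' Parental-age effects are planted on the parental components separately:
#' the paternal DNM count of a child is Poisson with mean
#' `paternal_fraction * dnm_base_count + paternal_age_slope * (father_age - father_ref_age)`
#' and the maternal count Poisson with mean
#' `(1 - paternal_fraction) * dnm_base_count + maternal_age_slope * (mother_age - mother_ref_age)`,
#' so at the reference ages the expected total is `dnm_base_count` and the
#' expected paternal fraction is `paternal_fraction`, while each parent's age
#' slope is recoverable from that parent's phased counts.
#'
#' @param n_families Number of families.
#' @param offspring_probs Probability weights over family sizes 1..10.
#' @param dnm_base_count Expected de novo SNVs per child at the reference
#'   parental ages.
#' @param indel_base_count Expected de novo indels per child (no age effect).
#' @param paternal_age_slope Additional DNMs per year of father's age.
#' @param maternal_age_slope Additional DNMs per year of mother's age.
#' @param father_ref_age,mother_ref_age Ages (years) at which the base count
#'   is anchored (cohort medians).
#' @param paternal_fraction Fraction of DNMs of paternal origin at the
#'   reference ages.
#' @param cpg_mutability_multiplier Relative per-base mutability at CpG sites
#'   methylated above 50%.
#' @param consanguinity_fraction Fraction of families with related parents.
#' @param spectrum Named probability vector over the six pyrimidine-oriented
#'   substitution classes.
#' @param reference_length Length in bases of the synthetic reference.
#' @param gc_fraction Target GC fraction of the reference.
#' @param cpg_enrichment Multiplier on the independence-expected CpG
#'   dinucleotide count.
#' @param high_meth_fraction Fraction of CpG units methylated above 50%.
#' @param n_markers Number of inherited polymorphic markers to simulate.
#' @param tool_error_profile Per-tool error rates: `fn` named vector of
#'   false-negative rates for freebayes/varscan/rufus, `fp_mean` expected
#'   false-positive candidates per child per tool, and `artifact_mean`
#'   expected missed-parental-heterozygote sites planted per family.
#' @param read_length Sequencing read length in bases.
#' @param depth Mean sequencing depth.
#' @param seq_error_rate Per-base sequencing error rate in co-observed reads.
#'
#' @return A list of class `dnmtrio_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_families = 10)
#' cfg$paternal_fraction
sim_config <- function(n_families = 146,
                       offspring_probs = c(0.28, 0.30, 0.17, 0.10, 0.06,
                                           0.04, 0.02, 0.015, 0.01, 0.005),
                       dnm_base_count = 70,
                       indel_base_count = 6,
                       paternal_age_slope = 1.36,
                       maternal_age_slope = 0.33,
                       father_ref_age = 34,
                       mother_ref_age = 29,
                       paternal_fraction = 0.8,
                       cpg_mutability_multiplier = 2,
                       consanguinity_fraction = 47 / 146,
                       spectrum = c("C>A" = 0.09, "C>G" = 0.08, "C>T" = 0.42,
                                    "T>A" = 0.07, "T>C" = 0.25, "T>G" = 0.09),
                       reference_length = 1e6,
                       gc_fraction = 0.41,
                       cpg_enrichment = 1,
                       high_meth_fraction = 0.69,
                       n_markers = 8000,
                       tool_error_profile = list(
                         fn = c(freebayes = 0.05, varscan = 0.08, rufus = 0.10),
                         fp_mean = c(freebayes = 3, varscan = 4, rufus = 5),
                         artifact_mean = 2
                       ),
                       read_length = 150,
                       depth = 30,
                       seq_error_rate = 0.002) {
  cfg <- list(
    n_families = n_families,
    offspring_probs = offspring_probs / sum(offspring_probs),
    dnm_base_count = dnm_base_count,
    indel_base_count = indel_base_count,
    paternal_age_slope = paternal_age_slope,
    maternal_age_slope = maternal_age_slope,
    father_ref_age = father_ref_age,
    mother_ref_age = mother_ref_age,
    paternal_fraction = paternal_fraction,
    cpg_mutability_multiplier = cpg_mutability_multiplier,
    consanguinity_fraction = consanguinity_fraction,
    spectrum = spectrum / sum(spectrum),
    reference_length = reference_length,
    gc_fraction = gc_fraction,
    cpg_enrichment = cpg_enrichment,
    high_meth_fraction = high_meth_fraction,
    n_markers = n_markers,
    tool_error_profile = tool_error_profile,
    read_length = read_length,
    depth = depth,
    seq_error_rate = seq_error_rate
  )
  validate_config(cfg)
  structure(cfg, class = "dnmtrio_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_families >= 0,
    length(cfg$offspring_probs) == 10,
    all(cfg$offspring_probs >= 0)
  )
  fracs <- c(cfg$paternal_fraction, cfg$consanguinity_fraction,
             cfg$gc_fraction, cfg$high_meth_fraction, cfg$seq_error_rate)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all fractions must lie in [0, 1]", class = "dnmtrio_config_error")
  }
  rates <- c(cfg$dnm_base_count, cfg$indel_base_count,
             cfg$cpg_mutability_multiplier, cfg$cpg_enrichment,
             cfg$tool_error_profile$fp_mean, cfg$tool_error_profile$fn,
             cfg$tool_error_profile$artifact_mean)
  if (any(rates < 0)) {
    abort("all rates must be non-negative", class = "dnmtrio_config_error")
  }
  if (cfg$cpg_mutability_multiplier < 1) {
    abort("cpg_mutability_multiplier must be >= 1",
          class = "dnmtrio_config_error")
  }
  invisible(cfg)
}

#' @export
print.dnmtrio_config <- function(x, ...) {
  cat("<dnmtrio_config>\n")
  cat("  families:", x$n_families,
      " base DNMs:", x$dnm_base_count, "SNV +", x$indel_base_count, "indel\n")
  cat("  age slopes: paternal", x$paternal_age_slope,
      "/ maternal", x$maternal_age_slope, "DNMs per year\n")
  cat("  paternal fraction:", x$paternal_fraction,
      " CpG multiplier:", x$cpg_mutability_multiplier, "\n")
  cat("  reference:", x$reference_length, "bp, GC", x$gc_fraction,
      ",", x$n_markers, "markers\n")
  invisible(x)
}
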