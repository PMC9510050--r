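#' Generative parameter-recovery experiment
#'
#' Runs the full discovery pipeline on one synthetic cohort and extracts the
#' estimates of the four planted generative parameters together with their
#' 95% intervals: the paternal and maternal age slopes (from the OLS age
#' trends on scaled phased counts), the paternal origin fraction (from the
#' cohort phasing summary, with an exact binomial interval), and the CpG
#' mutability multiplier (from the methylation enrichment fold, with a
#' log-normal interval on the count ratio).
#'
#' @param config A [sim_config()] object; its slopes/fractions are the
#'   planted truths being recovered.
#' @param seed Integer seed.
#' @return Tibble with one row per parameter: `parameter`, `planted`,
#'   `estimate`, `conf_low`, `conf_high`, `n`.
#' @export
recovery_experiment <- function(config = sim_config(), seed = 1) {
  run <- run_pipeline(config, seed = seed)
  pat <- run$fits$paternal_age
  mat <- run$fits$maternal_age

  ph <- run$phasing_cohort
  bt <- stats::binom.test(ph$n_paternal, ph$n_phased)

  me <- run$methylation
  fold_row <- if (!is.null(me) && is.finite(me$fold_difference)) {
    # given the total DNM-CpG count, the high-bin count is binomial; an
    # exact interval on that proportion maps to the fold through
    # odds(q) * genome_low / genome_high
    n_cpg <- me$dnm_low + me$dnm_high
    ci_q <- stats::binom.test(me$dnm_high, n_cpg)$conf.int
    g_ratio <- me$genome_low / me$genome_high
    tibble::tibble(
      parameter = "cpg_mutability_multiplier",
      planted = config$cpg_mutability_multiplier,
      estimate = me$fold_difference,
      conf_low = ci_q[1] / (1 - ci_q[1]) * g_ratio,
      conf_high = ci_q[2] / (1 - ci_q[2]) * g_ratio,
      n = n_cpg
    )
  } else {
    tibble::tibble()
  }

  dplyr::bind_rows(
    tibble::tibble(
      parameter = "paternal_age_slope",
      planted = config$paternal_age_slope,
      estimate = pat$slope, conf_low = pat$conf_low,
      conf_high = pat$conf_high, n = pat$n
    ),
    tibble::tibble(
      parameter = "maternal_age_slope",
      planted = config$maternal_age_slope,
      estimate = mat$slope, conf_low = mat$conf_low,
      conf_high = mat$conf_high, n = mat$n
    ),
    tibble::tibble(
      parameter = "paternal_fraction",
      planted = config$paternal_fraction,
      estimate = ph$paternal_fraction,
      conf_low = bt$conf.int[1], conf_high = bt$conf.int[2],
      n = ph$n_phased
    ),
    fold_row
  )
}

#' Desk-scale configuration for recovery experiments
#'
#' The cohort structure (146 families, about 353 trios, the published age
#' distributions, slopes 1.36/0.33, origin fraction 0.8, CpG multiplier 2)
#' is kept at full size; only the genomic substrate is scaled down (a 500 kb
#' reference with 5,000 markers) so that a multi-seed experiment runs in
#' minutes while leaving per-child DNM counts and phasing yields untouched.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()] object.
#' @export
recovery_config <- function(...) {
  args <- utils::modifyList(
    list(reference_length = 5e5, n_markers = 5000),
    list(...)
  )
  do.call(sim_config, args)
}
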