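#' Bin CpG methylation values into high/low compartments
#'
#' High methylation means strictly above the threshold (default 50% — a value
#' of exactly 0.5 is low), applied identically to the DNM CpG list and the
#' genome-wide CpG list.
#'
#' @param dnm_meth Methylation fractions of CpG units carrying a DNM.
#' @param genome_meth Methylation fractions of all CpG units under the track.
#' @param threshold Binning threshold in `[0, 1]`.
#' @return One-row tibble of class counts: `dnm_low`, `dnm_high`,
#'   `genome_low`, `genome_high`.
#' @export
#' @examples
#' bin_cpgs(c(0.2, 0.8), c(0.5, 0.6, 0.9, 0.1))
bin_cpgs <- function(dnm_meth, genome_meth, threshold = 0.5) {
  vals <- c(dnm_meth, genome_meth)
  if (any(vals < 0 | vals > 1, na.rm = TRUE) || any(is.na(vals))) {
    abort("methylation values must lie in [0, 1]",
          class = "dnmtrio_input_error")
  }
  tibble::tibble(
    dnm_low = sum(dnm_meth <= threshold),
    dnm_high = sum(dnm_meth > threshold),
    genome_low = sum(genome_meth <= threshold),
    genome_high = sum(genome_meth > threshold)
  )
}

#' Methylation enrichment of DNMs at CpG sites
#'
#' Computes, per methylation bin, the fraction of genome CpGs that carry a
#' DNM, the fold difference between the high and low bins, and an exact
#' binomial p-value for the excess of DNM CpGs in the high bin
#' ([binom_enrichment_test()]).
#'
#' @param counts Bin counts from [bin_cpgs()] (columns `dnm_low`, `dnm_high`,
#'   `genome_low`, `genome_high`).
#' @return One-row tibble: `fraction_low`, `fraction_high`,
#'   `fold_difference` (`NA` when the low fraction is zero), `binomial_p`.
#' @export
#' @examples
#' methylation_enrichment(tibble::tibble(
#'   dnm_low = 86, dnm_high = 389,
#'   genome_low = 8804182, genome_high = 19617481
#' )) # fold ~2.03
methylation_enrichment <- function(counts) {
  stopifnot(all(c("dnm_low", "dnm_high", "genome_low", "genome_high") %in%
                  names(counts)))
  if (counts$genome_low <= 0 || counts$genome_high <= 0) {
    abort("genome CpG counts must be positive in both bins",
          class = "dnmtrio_input_error")
  }
  f_low <- counts$dnm_low / counts$genome_low
  f_high <- counts$dnm_high / counts$genome_high
  p0 <- counts$genome_high / (counts$genome_high + counts$genome_low)
  n <- counts$dnm_low + counts$dnm_high
  tibble::tibble(
    fraction_low = f_low,
    fraction_high = f_high,
    fold_difference = ifelse(f_low > 0, f_high / f_low, NA_real_),
    binomial_p = if (n > 0) binom_enrichment_test(counts$dnm_high, n, p0)
                 else NA_real_
  )
}

#' Exact binomial upper-tail test
#'
#' Exact one-sided tail probability `P(X >= k)` for `X ~ Binomial(n, p0)` —
#' the probability of seeing at least the observed number of DNM CpGs in the
#' high-methylation bin if DNMs fell on CpGs in proportion to the genome-wide
#' bin sizes. Computed exactly (no normal approximation).
#'
#' @param k Observed successes (DNM CpGs in the high bin).
#' @param n Number of trials (all DNM CpGs under the track).
#' @param p0 Null success probability (genome-wide high-bin proportion).
#' @return The exact tail probability, in `(0, 1]`.
#' @export
#' @examples
#' binom_enrichment_test(10, 10, 0.5) # 2^-10
binom_enrichment_test <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) abort("p0 must lie in (0, 1)",
                                class = "dnmtrio_input_error")
  if (k < 0 || k > n) abort("k must lie in [0, n]",
                            class = "dnmtrio_input_error")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Methylation enrichment across tissues
#'
#' Joins a set of DNM CpG units against one methylation track per tissue and
#' computes the enrichment statistics for each; the same DNM subset is used
#' for every track (the gonadal-tissue comparison uses paternally phased DNM
#' CpGs, with somatic tissues as controls). CpG units missing from a track
#' are excluded from both numerator and denominator for that tissue. A DNM at
#' the G of a CpG unit inherits the unit value at the C.
#'
#' @param dnm_cpg Tibble of DNM CpG units with column `pos` (position of the
#'   unit's C).
#' @param tracks Named list of methylation tibbles (`pos`, `meth`).
#' @return Tibble with one row per tissue: the bin counts and enrichment
#'   columns.
#' @export
enrich_tissues <- function(dnm_cpg, tracks) {
  if (length(tracks) == 0) abort("no methylation tracks supplied",
                                 class = "dnmtrio_input_error")
  if (is.null(names(tracks))) names(tracks) <- paste0("tissue", seq_along(tracks))
  rows <- purrr::imap(tracks, function(track, tissue) {
    hit <- dnm_cpg$pos %in% track$pos
    if (!any(hit)) {
      abort(paste0("track '", tissue, "' shares no CpG with the DNM set"),
            class = "dnmtrio_input_error")
    }
    dnm_meth <- track$meth[match(dnm_cpg$pos[hit], track$pos)]
    counts <- bin_cpgs(dnm_meth, track$meth)
    dplyr::bind_cols(tibble::tibble(tissue = tissue), counts,
                     methylation_enrichment(counts))
  })
  dplyr::bind_rows(rows)
}

#' Annotate DNMs with CpG membership and methylation
#'
#' Flags each DNM lying on a CpG unit (C or G of a forward-strand CG
#' dinucleotide) and attaches the unit's methylation value when a track is
#' supplied.
#'
#' @param dnms DNM tibble with `pos`.
#' @param reference Reference string.
#' @param meth_track Optional methylation tibble (`pos`, `meth`).
#' @return `dnms` with logical `cpg` and numeric `meth` columns.
#' @export
annotate_cpg <- function(dnms, reference, meth_track = NULL) {
  covered <- cpg_covered_positions(reference)
  dnms$cpg <- dnms$pos %in% covered
  if (!is.null(meth_track)) {
    cp <- cpg_positions(reference)
    unit <- ifelse(dnms$pos %in% cp, dnms$pos, dnms$pos - 1L)
    dnms$meth <- ifelse(dnms$cpg,
                        meth_track$meth[match(unit, meth_track$pos)],
                        NA_real_)
  }
  dnms
}

#' Reduce DNM positions to CpG units
#'
#' Maps each CpG-flagged DNM to the position of the C of its covering unit
#' (a DNM at the G maps to the preceding C). Only SNVs are considered: an
#' indel has no single-base CpG semantics.
#'
#' @param dnms DNM tibble with `pos` and `cpg`.
#' @param reference Reference string.
#' @return Tibble with column `pos`, one row per DNM at a CpG.
#' @export
dnm_cpg_units <- function(dnms, reference) {
  if ("variant_class" %in% names(dnms)) {
    dnms <- dnms[dnms$variant_class == "SNV", , drop = FALSE]
  }
  at <- dnms[dnms$cpg %in% TRUE, , drop = FALSE]
  cp <- cpg_positions(reference)
  unit <- ifelse(at$pos %in% cp, at$pos, at$pos - 1L)
  tibble::tibble(pos = unit)
}
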