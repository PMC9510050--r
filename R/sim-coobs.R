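#' Simulate read-level co-observations for phasing
#'
#' For every true DNM that has an inherited heterozygous marker within read
#' length, emits simulated read records carrying the alleles observed at both
#' positions. Each read is drawn from one of the child's two haplotypes at
#' random; the DNM alternate allele rides on the haplotype of the true
#' parental origin, and the marker allele is the one the child inherited on
#' that haplotype, so the read-level co-occurrence structure encodes the true
#' parent-of-origin. Per-base sequencing errors flip observed alleles
#' independently.
#'
#' @param truth Truth tibble from [sim_dnms()].
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param pedigree Pedigree tibble.
#' @param read_length Read length in bases; a read can co-observe two
#'   positions at most `read_length - 1` apart.
#' @param depth Mean sequencing depth (reads are split between haplotypes).
#' @param error_rate Per-base probability of observing the wrong allele.
#' @param seed Optional integer seed.
#'
#' @return Long tibble of read observations: `read_id`, `child_id`, `pos`,
#'   `allele`; two rows per read (one at the DNM, one at the marker).
#' @export
sim_coobservations <- function(truth, genotypes, pedigree, read_length = 150,
                               depth = 30, error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- genotypes$markers
  dosage <- geno_dosage(genotypes)
  tr_split <- split(truth, truth$child_id)
  out <- vector("list", length(tr_split))
  i <- 0
  for (cid in names(tr_split)) {
    i <- i + 1
    tg <- trio_genotypes(genotypes, pedigree, cid, dosage = dosage)
    hets <- tg[tg$child_dos == 1, ]
    dn <- tr_split[[cid]]
    if (nrow(hets) == 0 || nrow(dn) == 0) next
    # nearest heterozygous marker to each DNM
    ix <- findInterval(dn$pos, hets$pos)
    lo <- pmax(ix, 1L)
    hi <- pmin(ix + 1L, nrow(hets))
    d_lo <- abs(dn$pos - hets$pos[lo])
    d_hi <- abs(dn$pos - hets$pos[hi])
    nearest <- ifelse(d_lo <= d_hi, lo, hi)
    dist <- pmin(d_lo, d_hi)
    ok <- dist >= 1 & dist <= (read_length - 1)
    if (!any(ok)) next
    dn <- dn[ok, ]
    site <- hets[nearest[ok], ]
    frac <- 1 - dist[ok] / read_length
    n_reads <- rpois(nrow(dn), depth * frac)
    keep <- n_reads > 0
    if (!any(keep)) next
    dn <- dn[keep, ]; site <- site[keep, ]; n_reads <- n_reads[keep]

    j <- rep(seq_len(nrow(dn)), n_reads)
    hap <- sample(c("f", "m"), length(j), replace = TRUE)
    origin_hap <- ifelse(dn$origin[j] == "paternal", "f", "m")
    dnm_has_alt <- hap == origin_hap
    site_hap_allele <- ifelse(hap == "f", site$child_hap_f[j],
                              site$child_hap_m[j])
    if (error_rate > 0) {
      dnm_has_alt <- xor(dnm_has_alt, runif(length(j)) < error_rate)
      site_hap_allele <- abs(site_hap_allele -
                               (runif(length(j)) < error_rate))
    }
    read_id <- sprintf("%s_r%d_%d", cid, dn$pos[j],
                       sequence(rle(j)$lengths))
    out[[i]] <- tibble::tibble(
      read_id = rep(read_id, 2),
      child_id = cid,
      pos = c(dn$pos[j], site$pos[j]),
      allele = c(ifelse(dnm_has_alt, dn$alt[j], dn$ref[j]),
                 ifelse(site_hap_allele == 1, site$alt[j], site$ref[j]))
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(read_id = character(), child_id = character(),
                          pos = integer(), allele = character()))
  }
  res
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: reference, methylation track, pedigree, marker
#' genotypes, planted DNMs, three noisy tool call sets, and read-level
#' co-observations, all from a single seed.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; fully determines the output.
#'
#' @return A list of class `dnmtrio_cohort` with elements `config`,
#'   `reference`, `meth_track`, `pedigree`, `genotypes`, `truth`, `calls`,
#'   `coobs`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_families = 3), seed = 1)
#' nrow(cohort$truth)
simulate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  reference <- sim_reference(config$reference_length, config$gc_fraction,
                             config$cpg_enrichment)
  meth_track <- sim_methylation_track(reference, config$high_meth_fraction)
  pedigree <- sim_pedigree(config)
  genotypes <- sim_genotypes(pedigree, reference, config$n_markers)
  truth <- sim_dnms(pedigree, reference, meth_track, config,
                    exclude_pos = genotypes$markers$pos)
  calls <- sim_tool_calls(truth, genotypes, pedigree, reference,
                          config$tool_error_profile)
  coobs <- sim_coobservations(truth, genotypes, pedigree,
                              config$read_length, config$depth,
                              config$seq_error_rate)
  structure(
    list(config = config, reference = reference, meth_track = meth_track,
         pedigree = pedigree, genotypes = genotypes, truth = truth,
         calls = calls, coobs = coobs),
    class = "dnmtrio_cohort"
  )
}

#' @export
print.dnmtrio_cohort <- function(x, ...) {
  cat("<dnmtrio_cohort>\n")
  cat("  families:", length(unique(x$pedigree$family_id)),
      " children:", sum(x$pedigree$role == "child"), "\n")
  cat("  reference:", nchar(x$reference), "bp;",
      length(cpg_positions(x$reference)), "CpG units\n")
  cat("  true DNMs:", nrow(x$truth),
      " candidate calls:", nrow(x$calls), "\n")
  invisible(x)
}
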