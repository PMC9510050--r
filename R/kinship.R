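#' KING robust kinship coefficient
#'
#' Within-family robust estimator of the kinship coefficient PHI from
#' biallelic dosages:
#' `PHI = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa,i + N_Aa,j)`,
#' where `N_Aa,Aa` counts sites at which both individuals are heterozygous,
#' `N_AA,aa` sites with opposite homozygotes, and `N_Aa,.` each individual's
#' heterozygous-site count. PHI is 0.5 for self-comparison, about 0.25 for
#' parent-offspring, and near 0 for unrelated pairs.
#'
#' @param geno_i,geno_j Integer dosage vectors (0/1/2) over the same markers;
#'   entries with a missing value in either individual are dropped.
#' @param min_sites Minimum overlapping genotyped sites (default 100).
#' @return The PHI estimate.
#' @export
#' @examples
#' g <- sample(0:2, 1000, TRUE, prob = c(.25, .5, .25))
#' king_kinship(g, g) # 0.5
king_kinship <- function(geno_i, geno_j, min_sites = 100) {
  stopifnot(length(geno_i) == length(geno_j))
  ok <- !is.na(geno_i) & !is.na(geno_j)
  gi <- geno_i[ok]; gj <- geno_j[ok]
  if (length(gi) < min_sites) {
    abort(paste0("fewer than ", min_sites, " overlapping genotyped sites"),
          class = "dnmtrio_input_error")
  }
  n_hh <- sum(gi == 1 & gj == 1)
  n_opp <- sum(abs(gi - gj) == 2)
  het_i <- sum(gi == 1)
  het_j <- sum(gj == 1)
  if (het_i + het_j == 0) {
    abort("no heterozygous sites in either individual",
          class = "dnmtrio_input_error")
  }
  (n_hh - 2 * n_opp) / (het_i + het_j)
}

#' Classify parental relatedness from PHI
#'
#' Applies the published cutoffs: first-degree cousins `[0.0884, 0.177)`,
#' second-degree cousins `[0.0442, 0.0884)`, unrelated `< 0.0442`. PHI of
#' 0.177 or more is flagged as closer than first-degree cousins.
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return Factor with levels `unrelated`, `second_degree_cousins`,
#'   `first_degree_cousins`, `closer_than_first_degree`.
#' @export
#' @examples
#' classify_relatedness(c(0.01, 0.05, 0.1, 0.3))
classify_relatedness <- function(phi) {
  stopifnot(all(is.finite(phi)))
  lab <- dplyr::case_when(
    phi >= 0.177 ~ "closer_than_first_degree",
    phi >= 0.0884 ~ "first_degree_cousins",
    phi >= 0.0442 ~ "second_degree_cousins",
    .default = "unrelated"
  )
  factor(lab, levels = c("unrelated", "second_degree_cousins",
                         "first_degree_cousins", "closer_than_first_degree"))
}

#' Parental kinship per family
#'
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param pedigree Pedigree tibble.
#' @return Tibble: `family_id`, `phi`, `relatedness`.
#' @export
parent_kinship <- function(genotypes, pedigree) {
  d <- geno_dosage(genotypes)
  fams <- dplyr::distinct(pedigree, .data$family_id)
  phi <- purrr::map_dbl(fams$family_id, function(f) {
    fa <- pedigree$individual_id[pedigree$family_id == f &
                                   pedigree$role == "father"]
    mo <- pedigree$individual_id[pedigree$family_id == f &
                                   pedigree$role == "mother"]
    king_kinship(d[, fa], d[, mo])
  })
  tibble::tibble(family_id = fams$family_id, phi = phi,
                 relatedness = classify_relatedness(phi))
}

#' Per-sample genotype quality control
#'
#' Per-sample heterozygosity fraction, missingness fraction, and the maximum
#' genotype-sharing fraction with any other sample (near 1 indicates a
#' duplicate or contamination). Samples beyond `z_cutoff` standard deviations
#' from the cohort mean on any metric are flagged.
#'
#' @param geno Dosage matrix (markers x samples), `NA` for missing calls.
#' @param z_cutoff Robust z-score cutoff for flagging.
#' @return Tibble: `individual_id`, `het_fraction`, `missing_fraction`,
#'   `max_sharing`, `flagged`.
#' @export
qc_samples <- function(geno, z_cutoff = 4) {
  if (ncol(geno) < 2) {
    abort("pairwise sharing undefined for a single-sample cohort",
          class = "dnmtrio_input_error")
  }
  n_called <- colSums(!is.na(geno))
  het <- colSums(geno == 1, na.rm = TRUE) / pmax(n_called, 1)
  miss <- 1 - n_called / nrow(geno)
  # sharing via one-hot crossproducts over the three genotype classes
  share <- matrix(0, ncol(geno), ncol(geno))
  both <- crossprod(!is.na(geno) + 0)
  for (g in 0:2) {
    m <- (!is.na(geno) & geno == g) + 0
    share <- share + crossprod(m)
  }
  share <- share / pmax(both, 1)
  diag(share) <- NA
  max_share <- apply(share, 2, max, na.rm = TRUE)
  z <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else abs(x - mean(x)) / s
  }
  tibble::tibble(
    individual_id = colnames(geno) %||% paste0("s", seq_len(ncol(geno))),
    het_fraction = unname(het),
    missing_fraction = unname(miss),
    max_sharing = unname(max_share),
    flagged = z(het) > z_cutoff | z(miss) > z_cutoff |
      z(max_share) > z_cutoff | max_share > 0.99
  )
}
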