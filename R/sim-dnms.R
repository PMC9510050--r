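#' Plant true de novo mutations in a synthetic cohort
#'
#' For each child, draws a paternal DNM count from
#' `Poisson(paternal_fraction * base + paternal_slope * (father_age - father_ref_age))`
#' and a maternal count from
#' `Poisson((1 - paternal_fraction) * base + maternal_slope * (mother_age - mother_ref_age))`,
#' mirroring the biology that the paternal-age effect acts on paternally
#' derived mutations (replication errors in spermatogonia). Expected means
#' that become negative at extreme ages are clamped to a small positive floor
#' with a warning. Sites are placed uniformly along the reference except that
#' positions inside CpG units methylated above 50% receive
#' `cpg_mutability_multiplier` times the baseline placement weight.
#' Substitution types are drawn from the configured six-class spectrum,
#' oriented to the actual reference base. A small number of 1-3 bp insertions
#' and deletions is planted in addition (no age effect).
#'
#' @param pedigree Pedigree tibble from [sim_pedigree()].
#' @param reference Reference string from [sim_reference()].
#' @param meth_track Methylation tibble from [sim_methylation_track()].
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed.
#' @param exclude_pos Positions to exclude from placement (e.g. segregating
#'   marker sites, where a coinciding call would be indistinguishable from an
#'   inherited variant).
#'
#' @return Truth tibble: `child_id`, `family_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_class` ("SNV"/"INDEL"), `origin` ("paternal"/"maternal"),
#'   `cpg` (logical), `meth` (methylation of the covering CpG unit, `NA`
#'   off-CpG).
#' @export
sim_dnms <- function(pedigree, reference, meth_track, config, seed = NULL,
                     exclude_pos = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kids <- pedigree[pedigree$role == "child", ]
  if (nrow(kids) == 0) return(empty_truth())
  L <- nchar(reference)
  ref_chars <- strsplit(as.character(reference), "")[[1]]

  pf <- config$paternal_fraction
  # an all-paternal (or all-maternal) configuration zeroes the other
  # component entirely, age slope included
  mu_pat <- if (pf == 0) rep(0, nrow(kids)) else {
    pf * config$dnm_base_count +
      config$paternal_age_slope * (kids$father_age - config$father_ref_age)
  }
  mu_mat <- if (pf == 1) rep(0, nrow(kids)) else {
    (1 - pf) * config$dnm_base_count +
      config$maternal_age_slope * (kids$mother_age - config$mother_ref_age)
  }
  if (any(mu_pat < 0) || any(mu_mat < 0)) {
    warn("expected DNM count negative after age adjustment; clamped to 0.1")
    mu_pat[mu_pat < 0] <- 0.1
    mu_mat[mu_mat < 0] <- 0.1
  }
  n_pat <- rpois(nrow(kids), mu_pat)
  n_mat <- rpois(nrow(kids), mu_mat)
  n_ipat <- rpois(nrow(kids), pf * config$indel_base_count)
  n_imat <- rpois(nrow(kids), (1 - pf) * config$indel_base_count)

  # placement compartments: CpG-unit bases with methylation > 0.5 get the
  # multiplier, everything else weight 1
  high_units <- meth_track$pos[meth_track$meth > 0.5]
  high_pos <- sort(unique(c(high_units, high_units + 1L)))
  high_pos <- high_pos[high_pos >= 2 & high_pos <= L - 1]
  excluded <- logical(L)
  if (!is.null(exclude_pos)) {
    excluded[exclude_pos] <- TRUE
    high_pos <- high_pos[!excluded[high_pos]]
  }
  n_high <- length(high_pos)
  w_high <- config$cpg_mutability_multiplier * n_high
  p_high <- w_high / (w_high + (L - 2 - n_high))
  is_high <- logical(L)
  is_high[high_pos] <- TRUE

  cpg_pos <- cpg_covered_positions(reference)
  is_cpg <- logical(L)
  is_cpg[cpg_pos] <- TRUE
  meth_by_unit <- setNames(meth_track$meth, meth_track$pos)

  sample_rest <- function(n) {
    rp <- integer(0)
    while (length(rp) < n) {
      cand <- sample(2:(L - 1L), n - length(rp) + 10, replace = TRUE)
      rp <- c(rp, cand[!is_high[cand] & !excluded[cand]])
    }
    rp[seq_len(n)]
  }

  spectrum <- config$spectrum
  # substitution class conditional on reference base (pyrimidine-oriented)
  draw_alt <- function(ref_base) {
    if (length(ref_base) == 0) return(character(0))
    pyr <- ifelse(ref_base %in% c("C", "G"), "C", "T")
    n <- length(ref_base)
    cls <- character(n)
    for (p in c("C", "T")) {
      idx <- which(pyr == p)
      if (length(idx) == 0) next
      sub <- spectrum[startsWith(names(spectrum), p)]
      cls[idx] <- sample(names(sub), length(idx), replace = TRUE,
                         prob = sub / sum(sub))
    }
    to <- substr(cls, 3, 3)
    ifelse(ref_base %in% c("C", "T"), to, comp_base(to))
  }

  # --- SNVs, vectorized across children ---
  n_kids <- nrow(kids)
  n_s <- n_pat + n_mat
  k_high <- rbinom(n_kids, n_s, p_high)
  high_draws <- if (sum(k_high) > 0) {
    high_pos[sample.int(n_high, sum(k_high), replace = TRUE)]
  } else integer(0)
  rest_draws <- sample_rest(sum(n_s - k_high))
  idc <- c(rep(seq_len(n_kids), k_high), rep(seq_len(n_kids), n_s - k_high))
  pos <- c(high_draws, rest_draws)
  # group by child and shuffle within, so placement compartment is
  # independent of the parental-origin labelling below
  ord <- order(idc, runif(length(idc)))
  idc <- idc[ord]; pos <- pos[ord]
  origin <- rep(rep(c("paternal", "maternal"), n_kids),
                times = as.vector(rbind(n_pat, n_mat)))
  keep <- !duplicated(paste0(idc, "_", pos))
  idc <- idc[keep]; pos <- pos[keep]; origin <- origin[keep]
  ref_b <- ref_chars[pos]
  truth <- tibble::tibble(
    child_id = kids$individual_id[idc], family_id = kids$family_id[idc],
    chrom = "chr1", pos = pos, ref = ref_b, alt = draw_alt(ref_b),
    variant_class = "SNV", origin = origin
  )

  # --- indels, vectorized across children ---
  n_i <- n_ipat + n_imat
  if (sum(n_i) > 0) {
    idi <- rep(seq_len(n_kids), n_i)
    ipos <- integer(0)
    while (length(ipos) < sum(n_i)) {
      cand <- sample(2:(L - 5L), sum(n_i) - length(ipos) + 10,
                     replace = TRUE)
      ipos <- c(ipos, cand[!excluded[cand]])
    }
    ipos <- ipos[seq_len(sum(n_i))]
    ins <- runif(sum(n_i)) < 0.5
    k <- sample(1:3, sum(n_i), replace = TRUE)
    iref <- ifelse(ins, ref_chars[ipos],
                   substring(reference, ipos, ipos + k))
    ialt <- ifelse(ins,
                   paste0(ref_chars[ipos],
                          vapply(k, function(kk)
                            paste(sample(BASES, kk, replace = TRUE),
                                  collapse = ""), character(1))),
                   ref_chars[ipos])
    indels <- tibble::tibble(
      child_id = kids$individual_id[idi], family_id = kids$family_id[idi],
      chrom = "chr1", pos = ipos, ref = iref, alt = ialt,
      variant_class = "INDEL",
      origin = rep(rep(c("paternal", "maternal"), n_kids),
                   times = as.vector(rbind(n_ipat, n_imat)))
    )
    keep_i <- !duplicated(paste0(indels$child_id, "_", indels$pos))
    truth <- dplyr::bind_rows(truth, indels[keep_i, ])
  }
  truth <- dplyr::arrange(truth, .data$child_id, .data$pos)
  truth$cpg <- is_cpg[truth$pos]
  unit_c <- ifelse(truth$pos %in% meth_track$pos, truth$pos, truth$pos - 1L)
  truth$meth <- ifelse(truth$cpg, unname(meth_by_unit[as.character(unit_c)]),
                       NA_real_)
  truth
}

empty_truth <- function() {
  tibble::tibble(
    child_id = character(), family_id = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    variant_class = character(), origin = character(), cpg = logical(),
    meth = numeric()
  )
}
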