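#' Simulate cohort genotypes at inherited polymorphic markers
#'
#' Draws biallelic marker genotypes for every pedigree member. Unrelated
#' parents are sampled under Hardy-Weinberg equilibrium at per-marker allele
#' frequencies drawn uniformly from `maf_range`. For consanguineous families
#' the parents are constructed with shared recent ancestry (half-siblings for
#' the `first_degree_cousins` class, expected kinship 1/8; first cousins for
#' `second_degree_cousins`, expected kinship 1/16), so that estimated kinship
#' falls in the corresponding classification windows. Children inherit one
#' allele from each parent, independently per marker, and the transmitted
#' haplotype of origin is recorded, which is what makes read-backed phasing
#' simulable.
#'
#' @param pedigree A pedigree tibble from [sim_pedigree()].
#' @param reference Reference sequence string (marker positions and ref
#'   alleles are taken from it).
#' @param n_markers Number of markers (>= 100 recommended).
#' @param maf_range Range of minor-allele frequencies.
#' @param seed Optional integer seed.
#'
#' @return A list of class `dnmtrio_genotypes` with elements `markers`
#'   (tibble: `marker_id`, `pos`, `ref`, `alt`, `maf`), `samples` (character),
#'   and integer 0/1 haplotype matrices `hap_f`, `hap_m` (markers x samples;
#'   for children `hap_f` is the paternally transmitted haplotype).
#' @export
sim_genotypes <- function(pedigree, reference, n_markers = 8000,
                          maf_range = c(0.1, 0.5), seed = NULL) {
  if (nrow(pedigree) == 0) {
    abort("empty pedigree", class = "dnmtrio_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  ref_len <- nchar(reference)
  stopifnot(n_markers >= 1, ref_len >= n_markers + 2)
  pos <- sort(sample(2:(ref_len - 1L), n_markers))
  ref_allele <- strsplit(substring(reference, 1, ref_len), "")[[1]][pos]
  alt_allele <- vapply(ref_allele,
                       function(b) sample(setdiff(BASES, b), 1), character(1),
                       USE.NAMES = FALSE)
  maf <- runif(n_markers, maf_range[1], maf_range[2])
  markers <- tibble::tibble(
    marker_id = sprintf("m%05d", seq_len(n_markers)),
    pos = pos, ref = ref_allele, alt = alt_allele, maf = maf
  )

  founder_hap <- function() as.integer(runif(n_markers) < maf)
  gamete <- function(hapA, hapB) {
    pick <- runif(n_markers) < 0.5
    ifelse(pick, hapA, hapB)
  }

  fams <- split(pedigree, pedigree$family_id)
  cols <- list()
  for (fam in fams) {
    class <- fam$consanguinity_class[1]
    if (class == "first_degree_cousins") {
      # half-sibling parents: one shared grandparent
      sh1 <- founder_hap(); sh2 <- founder_hap()
      fa_f <- gamete(sh1, sh2); fa_m <- founder_hap()
      mo_f <- gamete(sh1, sh2); mo_m <- founder_hap()
    } else if (class == "second_degree_cousins") {
      # first-cousin parents: their mothers are full siblings
      g1a <- founder_hap(); g1b <- founder_hap()
      g2a <- founder_hap(); g2b <- founder_hap()
      sibA_f <- gamete(g1a, g1b); sibA_m <- gamete(g2a, g2b)
      sibB_f <- gamete(g1a, g1b); sibB_m <- gamete(g2a, g2b)
      fa_f <- gamete(sibA_f, sibA_m); fa_m <- founder_hap()
      mo_f <- gamete(sibB_f, sibB_m); mo_m <- founder_hap()
    } else {
      fa_f <- founder_hap(); fa_m <- founder_hap()
      mo_f <- founder_hap(); mo_m <- founder_hap()
    }
    fa_id <- fam$individual_id[fam$role == "father"]
    mo_id <- fam$individual_id[fam$role == "mother"]
    cols[[fa_id]] <- list(f = fa_f, m = fa_m)
    cols[[mo_id]] <- list(f = mo_f, m = mo_m)
    for (cid in fam$individual_id[fam$role == "child"]) {
      cols[[cid]] <- list(f = gamete(fa_f, fa_m), m = gamete(mo_f, mo_m))
    }
  }
  samples <- names(cols)
  hap_f <- vapply(cols, `[[`, integer(n_markers), "f")
  hap_m <- vapply(cols, `[[`, integer(n_markers), "m")
  structure(
    list(markers = markers, samples = samples, hap_f = hap_f, hap_m = hap_m),
    class = "dnmtrio_genotypes"
  )
}

#' Allele-dosage matrix
#'
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param ids Optional subset of sample ids.
#' @return Integer matrix of alternate-allele dosages (0/1/2), markers x
#'   samples.
#' @export
geno_dosage <- function(genotypes, ids = NULL) {
  d <- genotypes$hap_f + genotypes$hap_m
  if (!is.null(ids)) d <- d[, ids, drop = FALSE]
  d
}

#' Trio genotype table for one child
#'
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param pedigree The pedigree tibble.
#' @param child_id Child individual id.
#' @return Tibble with marker info and `child_dos`, `father_dos`,
#'   `mother_dos` plus the child's transmitted haplotype alleles
#'   `child_hap_f`, `child_hap_m`.
#' @param dosage Optional precomputed [geno_dosage()] matrix (avoids
#'   recomputation in per-child loops).
#' @export
trio_genotypes <- function(genotypes, pedigree, child_id, dosage = NULL) {
  row <- pedigree[pedigree$individual_id == child_id, ]
  if (nrow(row) != 1 || row$role != "child") {
    abort(paste0("unknown child id: ", child_id),
          class = "dnmtrio_input_error")
  }
  d <- dosage %||% geno_dosage(genotypes)
  dplyr::mutate(
    genotypes$markers,
    child_dos = d[, child_id],
    father_dos = d[, row$father_id],
    mother_dos = d[, row$mother_id],
    child_hap_f = genotypes$hap_f[, child_id],
    child_hap_m = genotypes$hap_m[, child_id]
  )
}
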