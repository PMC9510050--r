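#' Simulate noisy per-tool candidate call sets
#'
#' Emulates the discordant outputs of three complementary de novo callers
#' (a FreeBayes-like, a VarScan-like, and a RUFUS-like dialect) on a cohort
#' with known truth. Each tool's set contains the true DNMs minus tool-specific
#' false negatives, plus tool-unique false positives, plus missed
#' parental-heterozygote artifacts: marker sites where one carrier parent is
#' wrongly genotyped homozygous-reference, so every carrier child presents the
#' variant as an apparent DNM to all three tools. True and artifact calls draw
#' metrics that satisfy the base filtration thresholds (depth around 30X,
#' allele fraction centred at 0.5, quality above the per-tool cutoffs), while
#' false positives draw low allele fractions, lower quality and occasional
#' parental alternate reads, so the thresholds are discriminative.
#'
#' @param truth Truth tibble from [sim_dnms()].
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param pedigree Pedigree tibble.
#' @param reference Reference string (for false-positive ref alleles).
#' @param profile Tool error profile (see [sim_config()]).
#' @param seed Optional integer seed.
#'
#' @return A candidate-call tibble (one row per call per tool) with columns
#'   `tool`, `child_id`, `family_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`, `child_alt_fraction`, `child_depth`,
#'   `parent_alt_depth_father`, `parent_alt_depth_mother`, `qual`, `tags`
#'   (comma-separated), `tool_p`, and the ground-truth label `truth_tag`
#'   ("true" / "artifact" / "false_positive"). The planted artifact sites are
#'   attached as attribute `"artifacts"`.
#' @export
sim_tool_calls <- function(truth, genotypes, pedigree, reference,
                           profile = sim_config()$tool_error_profile,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tools <- c("freebayes", "varscan", "rufus")
  kids <- pedigree[pedigree$role == "child", ]
  L <- nchar(reference)
  ref_chars <- strsplit(as.character(reference), "")[[1]]

  # --- artifacts: missed parental heterozygotes, shared across siblings ---
  artifacts <- sim_artifacts(genotypes, pedigree, profile$artifact_mean)

  # child-level artifact candidate rows (carrier children only)
  art_calls <- artifact_child_calls(artifacts, genotypes, pedigree)

  # --- assemble per tool ---
  per_tool <- purrr::map(tools, function(tl) {
    fn <- profile$fn[[tl]]
    tc <- dplyr::bind_rows(
      dplyr::mutate(truth[, c("child_id", "family_id", "chrom", "pos",
                              "ref", "alt", "variant_class")],
                    truth_tag = "true"),
      art_calls
    )
    tc <- tc[runif(nrow(tc)) >= fn, , drop = FALSE]
    tc <- dplyr::bind_cols(tc, passing_metrics(nrow(tc), tl, tc$variant_class))

    n_fp <- rpois(nrow(kids), profile$fp_mean[[tl]])
    if (sum(n_fp) > 0) {
      idx <- rep(seq_len(nrow(kids)), n_fp)
      pos <- sample(2:(L - 1L), sum(n_fp), replace = TRUE)
      rb <- ref_chars[pos]
      fp <- tibble::tibble(
        child_id = kids$individual_id[idx], family_id = kids$family_id[idx],
        chrom = "chr1", pos = pos, ref = rb,
        alt = vapply(rb, function(b) sample(setdiff(BASES, b), 1),
                     character(1), USE.NAMES = FALSE),
        variant_class = "SNV", truth_tag = "false_positive"
      )
      fp <- dplyr::anti_join(fp, truth, by = c("child_id", "pos"))
      fp <- dplyr::bind_cols(fp, noisy_metrics(nrow(fp), tl))
      tc <- dplyr::bind_rows(tc, fp)
    }
    dplyr::mutate(tc, tool = tl, .before = 1)
  })
  calls <- dplyr::bind_rows(per_tool)
  calls <- dplyr::arrange(calls, .data$child_id, .data$pos, .data$tool)
  attr(calls, "artifacts") <- artifacts
  calls
}

# Marker sites where one carrier parent will be miscalled hom-ref.
sim_artifacts <- function(genotypes, pedigree, artifact_mean) {
  fams <- unique(pedigree$family_id)
  d <- geno_dosage(genotypes)
  out <- purrr::map(fams, function(f) {
    n_art <- rpois(1, artifact_mean)
    if (n_art == 0) return(NULL)
    fa <- pedigree$individual_id[pedigree$family_id == f &
                                   pedigree$role == "father"]
    mo <- pedigree$individual_id[pedigree$family_id == f &
                                   pedigree$role == "mother"]
    het_fa <- d[, fa] == 1 & d[, mo] == 0
    het_mo <- d[, mo] == 1 & d[, fa] == 0
    cand <- which(het_fa | het_mo)
    if (length(cand) == 0) return(NULL)
    sites <- sample(cand, min(n_art, length(cand)))
    tibble::tibble(
      family_id = f,
      marker_idx = sites,
      pos = genotypes$markers$pos[sites],
      ref = genotypes$markers$ref[sites],
      alt = genotypes$markers$alt[sites],
      miscalled_parent = ifelse(het_fa[sites], fa, mo)
    )
  })
  dplyr::bind_rows(out)
}

artifact_child_calls <- function(artifacts, genotypes, pedigree) {
  if (is.null(artifacts) || nrow(artifacts) == 0) {
    return(tibble::tibble(
      child_id = character(), family_id = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      variant_class = character(), truth_tag = character()
    ))
  }
  d <- geno_dosage(genotypes)
  rows <- purrr::map(seq_len(nrow(artifacts)), function(i) {
    a <- artifacts[i, ]
    kids <- pedigree$individual_id[pedigree$family_id == a$family_id &
                                     pedigree$role == "child"]
    carriers <- kids[d[a$marker_idx, kids] >= 1]
    if (length(carriers) == 0) return(NULL)
    tibble::tibble(
      child_id = carriers, family_id = a$family_id, chrom = "chr1",
      pos = a$pos, ref = a$ref, alt = a$alt, variant_class = "SNV",
      truth_tag = "artifact"
    )
  })
  dplyr::bind_rows(rows)
}

# Metric draws for calls that should clear the base thresholds.
passing_metrics <- function(n, tool, variant_class) {
  indel <- variant_class == "INDEL"
  af <- ifelse(indel, 0.30 + 0.45 * rbeta(n, 8, 8), 0.25 + 0.5 * rbeta(n, 8, 8))
  depth <- 12L + rpois(n, 18)
  qual <- switch(tool,
    freebayes = ifelse(indel, 80, 30) + rgamma(n, 2, scale = 20),
    varscan = 30 + rgamma(n, 2, scale = 10),
    rufus = 17 + rgamma(n, 2, scale = 12)
  )
  tibble::tibble(
    child_alt_fraction = af,
    child_depth = depth,
    parent_alt_depth_father = 0L,
    parent_alt_depth_mother = 0L,
    qual = qual,
    tags = switch(tool, freebayes = "PASS", varscan = "DENOVO,PASS",
                  rufus = "DeNovo"),
    tool_p = if (tool == "varscan") 0.005 * rbeta(n, 1, 9) else NA_real_
  )
}

# Metric draws for false positives: low allele fraction, weak quality,
# occasional parental alternate reads.
noisy_metrics <- function(n, tool) {
  parent_alt <- function() ifelse(runif(n) < 0.3, sample(1:3, n, TRUE), 0L)
  tibble::tibble(
    child_alt_fraction = 0.75 * rbeta(n, 2, 6),
    child_depth = rpois(n, 25),
    parent_alt_depth_father = parent_alt(),
    parent_alt_depth_mother = parent_alt(),
    qual = switch(tool,
      freebayes = rexp(n, 1 / 25),
      varscan = rexp(n, 1 / 15),
      rufus = rexp(n, 1 / 12)
    ),
    tags = switch(tool,
      freebayes = "PASS",
      varscan = paste0(ifelse(runif(n) < 0.5, "DENOVO", ""), ",",
                       ifelse(runif(n) < 0.6, "PASS", "")),
      rufus = "DeNovo"
    ),
    tool_p = if (tool == "varscan") 10^runif(n, -4, -0.3) else NA_real_
  )
}
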