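#' Filtration thresholds for three-tool consensus DNM calling
#'
#' Default values are the published manual-inspection-optimized cutoffs:
#' FreeBayes-like calls need a proband alternate-allele fraction in
#' \[0.25, 0.75\], zero parental alternate reads, depth >= 12, and quality
#' >= 30 (SNV) / >= 80 (indel); VarScan-like calls need the DENOVO and PASS
#' tags, p <= 0.005, zero parental alternate reads, and allele fraction
#' >= 0.25 (SNV) / >= 0.30 (indel); RUFUS-like calls need the DeNovo tag.
#' Variants seen by only one tool are rescued only at stricter thresholds
#' (FreeBayes depth >= 14; RUFUS quality >= 16 SNV / >= 17 indel; VarScan
#' fraction >= 0.30 SNV / >= 0.35 indel). Candidates above 0.1% population
#' allele frequency are removed.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `dnm_thresholds`.
#' @export
#' @examples
#' th <- dnm_thresholds(fb_depth = 15)
#' th$fb_depth
dnm_thresholds <- function(...) {
  th <- list(
    fb_af_range = c(0.25, 0.75),
    fb_depth = 12,
    fb_qual_snv = 30,
    fb_qual_indel = 80,
    vs_p = 0.005,
    vs_freq_snv = 0.25,
    vs_freq_indel = 0.30,
    rescue_fb_depth = 14,
    rescue_rufus_qual_snv = 16,
    rescue_rufus_qual_indel = 17,
    rescue_vs_freq_snv = 0.30,
    rescue_vs_freq_indel = 0.35,
    population_af_max = 0.001
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) {
    abort(paste("unknown threshold:", paste(unknown, collapse = ", ")),
          class = "dnmtrio_config_error")
  }
  th[names(dots)] <- dots
  if (th$rescue_fb_depth < th$fb_depth ||
      th$rescue_vs_freq_snv < th$vs_freq_snv ||
      th$rescue_vs_freq_indel < th$vs_freq_indel ||
      th$fb_af_range[1] > th$fb_af_range[2]) {
    abort("rescue thresholds must be at least as strict as base thresholds",
          class = "dnmtrio_config_error")
  }
  structure(th, class = "dnm_thresholds")
}

has_tag <- function(tags, tag) {
  if (length(tags) == 0) return(logical(0))
  vapply(strsplit(ifelse(is.na(tags), "", tags), ",", fixed = TRUE),
         function(x) tag %in% trimws(x), logical(1))
}

#' Apply per-tool base filtration to candidate calls
#'
#' Keeps candidates that satisfy the calling tool's published thresholds (see
#' [dnm_thresholds()]). A missing metric required by a tool's rule counts as a
#' filter failure. Calls from unknown tools are an error.
#'
#' @param calls Candidate-call tibble with a `tool` column
#'   ("freebayes"/"varscan"/"rufus") and the per-tool metric columns produced
#'   by [sim_tool_calls()] or [read_tool_vcf()].
#' @param thresholds A [dnm_thresholds()] object.
#' @return The retained rows, invisibly logging the funnel counts via a
#'   message when `verbose = TRUE`.
#' @param verbose Emit input/output counts per tool.
#' @export
filter_tool_candidates <- function(calls, thresholds = dnm_thresholds(),
                                   verbose = FALSE) {
  known <- c("freebayes", "varscan", "rufus")
  bad <- setdiff(unique(calls$tool), known)
  if (length(bad)) {
    abort(paste("unknown tool label:", paste(bad, collapse = ", ")),
          class = "dnmtrio_input_error")
  }
  th <- thresholds
  indel <- calls$variant_class == "INDEL"
  parents0 <- dplyr::coalesce(calls$parent_alt_depth_father, 1L) == 0 &
    dplyr::coalesce(calls$parent_alt_depth_mother, 1L) == 0
  af <- calls$child_alt_fraction
  keep <- rep(FALSE, nrow(calls))

  fb <- calls$tool == "freebayes"
  keep[fb] <- (!is.na(af[fb]) & af[fb] >= th$fb_af_range[1] &
                 af[fb] <= th$fb_af_range[2]) &
    parents0[fb] &
    dplyr::coalesce(calls$child_depth[fb] >= th$fb_depth, FALSE) &
    dplyr::coalesce(calls$qual[fb] >=
                      ifelse(indel[fb], th$fb_qual_indel, th$fb_qual_snv),
                    FALSE)

  vs <- calls$tool == "varscan"
  keep[vs] <- has_tag(calls$tags[vs], "DENOVO") &
    has_tag(calls$tags[vs], "PASS") &
    dplyr::coalesce(calls$tool_p[vs] <= th$vs_p, FALSE) &
    parents0[vs] &
    dplyr::coalesce(af[vs] >=
                      ifelse(indel[vs], th$vs_freq_indel, th$vs_freq_snv),
                    FALSE)

  rf <- calls$tool == "rufus"
  keep[rf] <- has_tag(calls$tags[rf], "DeNovo")

  out <- calls[keep, , drop = FALSE]
  if (verbose) {
    counts <- table(factor(calls$tool, known))
    kept <- table(factor(out$tool, known))
    inform(paste0("base filtration: ",
                  paste(sprintf("%s %d -> %d", known, counts, kept),
                        collapse = "; ")))
  }
  out
}

#' Normalize variant identity
#'
#' Trims shared allele suffixes then shared prefixes (adjusting the position),
#' the usual left-alignment convention, so that differently written records of
#' the same event merge on (`chrom`, `pos`, `ref`, `alt`). Records where ref
#' and alt differ in length but share no anchor are left untouched.
#'
#' @param calls Tibble with `pos`, `ref`, `alt` columns.
#' @return The tibble with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variants <- function(calls) {
  ref <- calls$ref; alt <- calls$alt; pos <- calls$pos
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    # trim common suffix, keeping at least one base each
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim common prefix, keeping at least one base each
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  calls$ref <- ref; calls$alt <- alt; calls$pos <- pos
  calls
}

#' Merge per-tool filtered candidates into a consensus DNM set
#'
#' Variants supported by two or three tools pass as route `"consensus"`.
#' Variants unique to one tool pass as route `"rescued"` only if they clear
#' that tool's stricter rescue threshold, otherwise they are excluded. The
#' merge key is (`child_id`, `chrom`, `pos`, `ref`, `alt`) after
#' normalization, so the result is independent of input order.
#'
#' @param filtered Output of [filter_tool_candidates()] (all tools combined,
#'   or a list of per-tool tibbles).
#' @param thresholds A [dnm_thresholds()] object.
#' @return One row per passed variant per child: identity columns,
#'   `variant_class`, `supporting_tools` (comma-separated, alphabetical),
#'   `n_tools`, `pass_route`, plus `truth_tag` when present in the input.
#' @export
merge_consensus <- function(filtered, thresholds = dnm_thresholds()) {
  if (is.list(filtered) && !is.data.frame(filtered)) {
    filtered <- dplyr::bind_rows(filtered)
  }
  if (nrow(filtered) == 0) {
    return(tibble::tibble(
      child_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), variant_class = character(),
      supporting_tools = character(), n_tools = integer(),
      pass_route = character()
    ))
  }
  th <- thresholds
  filtered <- normalize_variants(filtered)
  key <- c("child_id", "chrom", "pos", "ref", "alt")

  # vectorized per-row rescue eligibility (only consulted for singletons)
  indel <- filtered$variant_class == "INDEL"
  rescue_ok <- rep(FALSE, nrow(filtered))
  fb <- filtered$tool == "freebayes"
  rescue_ok[fb] <- dplyr::coalesce(
    filtered$child_depth[fb] >= th$rescue_fb_depth, FALSE)
  rf <- filtered$tool == "rufus"
  rescue_ok[rf] <- dplyr::coalesce(
    filtered$qual[rf] >= ifelse(indel[rf], th$rescue_rufus_qual_indel,
                                th$rescue_rufus_qual_snv), FALSE)
  vs <- filtered$tool == "varscan"
  rescue_ok[vs] <- dplyr::coalesce(
    filtered$child_alt_fraction[vs] >=
      ifelse(indel[vs], th$rescue_vs_freq_indel, th$rescue_vs_freq_snv),
    FALSE)
  filtered$.rescue_ok <- rescue_ok
  if (!"truth_tag" %in% names(filtered)) filtered$truth_tag <- NA_character_
  if (!"family_id" %in% names(filtered)) filtered$family_id <- NA_character_
  filtered <- dplyr::arrange(filtered, .data$tool)

  kv <- paste(filtered$child_id, filtered$chrom, filtered$pos,
              filtered$ref, filtered$alt, sep = "\r")
  kf <- factor(kv)
  # distinct (variant, tool) rows, tool-sorted, for the support summary
  dd <- !duplicated(paste0(kv, "\r", filtered$tool))
  tool_by_key <- split(filtered$tool[dd], kf[dd])
  support <- vapply(tool_by_key, paste, character(1), collapse = ",")
  n_tools <- lengths(tool_by_key)
  rescue <- as.vector(rowsum((filtered$.rescue_ok) + 0, kf)) > 0

  first <- !duplicated(kv)
  merged <- filtered[first, c(key, "variant_class", "truth_tag",
                              "family_id")]
  mi <- match(kv[first], levels(kf))
  merged$supporting_tools <- unname(support[mi])
  merged$n_tools <- unname(n_tools[mi])
  merged$.rescue <- rescue[mi]

  merged <- dplyr::filter(merged, .data$n_tools >= 2 | .data$.rescue)
  merged <- dplyr::mutate(
    merged,
    pass_route = ifelse(.data$n_tools >= 2, "consensus", "rescued"),
    .rescue = NULL
  )
  merged <- merged[, c(key, "variant_class", "supporting_tools", "n_tools",
                       "truth_tag", "family_id", "pass_route")]
  dplyr::arrange(merged, .data$child_id, .data$chrom, .data$pos)
}

#' Remove candidates common in population databases
#'
#' Drops candidates whose allele frequency exceeds `af_max` (default 0.1%,
#' strict inequality) in any annotation database column. Absent annotations
#' mean the variant was never seen and count as frequency 0.
#'
#' @param dnms DNM tibble.
#' @param af_columns Character vector of AF column names; defaults to every
#'   column starting with `"af_"`.
#' @param af_max Maximum tolerated allele frequency.
#' @return The retained rows.
#' @export
filter_population_af <- function(dnms, af_columns = NULL, af_max = 0.001) {
  if (is.null(af_columns)) {
    af_columns <- grep("^af_", names(dnms), value = TRUE)
  }
  if (length(af_columns) == 0) return(dnms)
  af <- as.matrix(dnms[, af_columns, drop = FALSE])
  af[is.na(af)] <- 0
  if (any(af < 0 | af > 1)) {
    abort("allele frequencies must lie in [0, 1]",
          class = "dnmtrio_input_error")
  }
  dnms[apply(af, 1, max) <= af_max, , drop = FALSE]
}

#' Long genotype table of non-proband family members at candidate sites
#'
#' Builds the table [filter_family_sharing()] consumes: for each candidate
#' variant, the *called* alternate-allele dosage of every other member of the
#' proband's family. True marker genotypes are used, except that parents
#' miscalled homozygous-reference at planted artifact sites report dosage 0 —
#' exactly the error mode that makes missed parental heterozygotes
#' indistinguishable from DNMs in a single trio.
#'
#' @param candidates Candidate tibble with `child_id`, `family_id`, `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param pedigree Pedigree tibble.
#' @param artifacts Artifact tibble (attribute of [sim_tool_calls()] output),
#'   or `NULL`.
#' @return Tibble: `child_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `individual_id`, `alt_dosage`.
#' @export
family_genotype_table <- function(candidates, genotypes, pedigree,
                                  artifacts = NULL) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(child_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), individual_id = character(),
                          alt_dosage = integer()))
  }
  d <- geno_dosage(genotypes)
  mk <- genotypes$markers
  marker_row <- match(paste(candidates$pos, candidates$ref, candidates$alt),
                      paste(mk$pos, mk$ref, mk$alt))
  members <- dplyr::select(pedigree, "family_id", "individual_id")
  tab <- dplyr::inner_join(
    dplyr::mutate(candidates[, c("child_id", "family_id", "chrom", "pos",
                                 "ref", "alt")],
                  .marker = marker_row),
    members, by = "family_id", relationship = "many-to-many"
  )
  tab <- dplyr::filter(tab, .data$individual_id != .data$child_id)
  dos <- integer(nrow(tab))
  hit <- !is.na(tab$.marker)
  if (any(hit)) {
    dos[hit] <- d[cbind(tab$.marker[hit],
                        match(tab$individual_id[hit], genotypes$samples))]
  }
  tab$alt_dosage <- dos
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    mis <- match(paste(tab$pos, tab$individual_id),
                 paste(artifacts$pos, artifacts$miscalled_parent))
    tab$alt_dosage[!is.na(mis)] <- 0L
  }
  dplyr::select(tab, -".marker", -"family_id")
}

#' Remove candidates shared with other family members
#'
#' A true single-gamete DNM is private to one child; any candidate whose
#' alternate allele is also observed in a parent or sibling is either an
#' inherited variant or a missed parental heterozygote and is removed. A
#' family member missing from the genotype table is treated as a non-carrier.
#'
#' @param candidates Candidate tibble keyed by `child_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param member_genotypes Long genotype table from
#'   [family_genotype_table()] (or equivalent).
#' @return The retained rows.
#' @export
filter_family_sharing <- function(candidates, member_genotypes) {
  if (nrow(candidates) == 0 || nrow(member_genotypes) == 0) return(candidates)
  shared <- dplyr::filter(member_genotypes, .data$alt_dosage >= 1)
  dplyr::anti_join(candidates, shared,
                   by = c("child_id", "chrom", "pos", "ref", "alt"))
}
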