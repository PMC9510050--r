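#' Read and write cohort files
#'
#' Readers and writers for the standard formats the pipeline exchanges:
#' FASTA (reference), 6-column PED plus a TSV sidecar (pedigree and ages),
#' 4-column bedGraph (methylation, 0-based half-open), VCF 4.2 (per-tool
#' candidate calls and the consensus DNM set), and TSV (truth table,
#' co-observations). Internally all coordinates are 1-based fully closed;
#' conversion happens at these boundaries.
#'
#' @name dnmtrio-io
NULL

#' @describeIn dnmtrio-io Write a reference sequence as FASTA.
#' @param reference Reference string.
#' @param path File path.
#' @param name Sequence name.
#' @export
write_fasta <- function(reference, path, name = "chr1") {
  rlang::check_installed("Biostrings")
  x <- Biostrings::DNAStringSet(as.character(reference))
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @describeIn dnmtrio-io Read a single-sequence FASTA into a string with
#'   CpG sites attached.
#' @export
read_fasta <- function(path) {
  rlang::check_installed("Biostrings")
  x <- Biostrings::readDNAStringSet(path)
  seq <- as.character(x[[1]])
  structure(seq, cpg_sites = cpg_positions(seq))
}

#' @describeIn dnmtrio-io Write the pedigree as 6-column PED plus a metadata
#'   sidecar TSV (ages, population, phenotype, consanguinity).
#' @param pedigree Pedigree tibble.
#' @export
write_ped <- function(pedigree, path) {
  ped6 <- tibble::tibble(
    family_id = pedigree$family_id,
    individual_id = pedigree$individual_id,
    father_id = ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
    mother_id = ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    sex = ifelse(pedigree$sex == "male", 1L, 2L),
    phenotype = dplyr::case_when(
      is.na(pedigree$phenotype) ~ 0L,
      pedigree$phenotype == "Healthy" ~ 1L,
      .default = 2L
    )
  )
  readr::write_tsv(ped6, path, col_names = FALSE)
  sidecar <- sub("\\.ped$", "", path)
  readr::write_tsv(pedigree, paste0(sidecar, ".meta.tsv"))
  invisible(path)
}

#' @describeIn dnmtrio-io Read a pedigree written by [write_ped()] (the
#'   sidecar carries the full metadata).
#' @export
read_ped <- function(path) {
  sidecar <- paste0(sub("\\.ped$", "", path), ".meta.tsv")
  readr::read_tsv(sidecar, show_col_types = FALSE)
}

#' @describeIn dnmtrio-io Write a methylation track as 4-column bedGraph
#'   (0-based half-open single-base intervals at each CpG unit's C).
#' @param track Methylation tibble (`pos`, `meth`).
#' @param chrom Chromosome name.
#' @export
write_bedgraph <- function(track, path, chrom = "chr1") {
  out <- tibble::tibble(chrom = chrom, start = track$pos - 1L,
                        end = track$pos, value = track$meth)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @describeIn dnmtrio-io Read a bedGraph methylation track. Values on a
#'   0-100 percent scale are auto-detected by range and rescaled to
#'   fractions with a message. CRLF endings and `track`/`#` header lines are
#'   tolerated.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(trimws(lines))]
  d <- readr::read_tsv(I(lines),
                       col_names = c("chrom", "start", "end", "value"),
                       col_types = "ciid")
  if (any(d$value > 1)) {
    inform("bedGraph values exceed 1; interpreting as percent and rescaling")
    d$value <- d$value / 100
  }
  tibble::tibble(pos = d$start + 1L, meth = d$value)
}

#' @describeIn dnmtrio-io Write per-tool candidate calls for one trio as VCF
#'   4.2 (child, father, mother sample columns in that order; tool metrics in
#'   INFO).
#' @param calls Candidate-call tibble for a single tool and trio.
#' @param trio_ids Character vector of child, father, mother ids.
#' @export
write_tool_vcf <- function(calls, path, trio_ids) {
  info <- sprintf(
    "DP=%d;AF=%.4f;PAF=%d;PAM=%d;TAGS=%s%s",
    calls$child_depth, calls$child_alt_fraction,
    calls$parent_alt_depth_father, calls$parent_alt_depth_mother,
    gsub(",", "|", calls$tags),
    ifelse(is.na(calls$tool_p), "", sprintf(";TP=%.3g", calls$tool_p))
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\t.\t%s\tGT\t0/1\t0/0\t0/0",
                  calls$chrom, calls$pos, calls$ref, calls$alt, calls$qual,
                  info)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Child depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Child alt fraction\">",
    "##INFO=<ID=PAF,Number=1,Type=Integer,Description=\"Father alt depth\">",
    "##INFO=<ID=PAM,Number=1,Type=Integer,Description=\"Mother alt depth\">",
    "##INFO=<ID=TAGS,Number=1,Type=String,Description=\"Caller tags\">",
    "##INFO=<ID=TP,Number=1,Type=Float,Description=\"Caller p-value\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", trio_ids), collapse = "\t")
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Default INFO-field mapping for the three emulated caller dialects
#'
#' Real callers name their metrics differently; the mapping decouples VCF
#' parsing from filtering logic. Each entry maps the internal metric name to
#' the INFO key that carries it.
#'
#' @return Named list of per-tool field maps.
#' @export
default_field_map <- function() {
  base <- list(depth = "DP", af = "AF", parent_alt_father = "PAF",
               parent_alt_mother = "PAM", tags = "TAGS", p = "TP")
  list(freebayes = base, varscan = base, rufus = base)
}

#' @describeIn dnmtrio-io Read a per-tool candidate VCF into the
#'   candidate-call tibble consumed by [filter_tool_candidates()]. The
#'   chromosome name is normalized to carry a `chr` prefix.
#' @param tool Tool label ("freebayes"/"varscan"/"rufus").
#' @param field_map Field mapping, see [default_field_map()].
#' @export
read_tool_vcf <- function(path, tool, field_map = default_field_map()) {
  rlang::check_installed("vcfR")
  fm <- field_map[[tool]]
  if (is.null(fm)) abort(paste("no field map for tool", tool),
                         class = "dnmtrio_config_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  child <- colnames(v@gt)[2]
  chrom <- ifelse(startsWith(fix$CHROM, "chr"), fix$CHROM,
                  paste0("chr", fix$CHROM))
  getinfo <- function(key, as = "numeric") {
    vcfR::extract.info(v, element = key, as.numeric = as == "numeric")
  }
  tibble::tibble(
    tool = tool,
    child_id = child,
    chrom = chrom,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    variant_class = ifelse(nchar(fix$REF) == nchar(fix$ALT), "SNV", "INDEL"),
    child_alt_fraction = getinfo(fm$af),
    child_depth = getinfo(fm$depth),
    parent_alt_depth_father = getinfo(fm$parent_alt_father),
    parent_alt_depth_mother = getinfo(fm$parent_alt_mother),
    qual = as.numeric(fix$QUAL),
    tags = gsub("|", ",", getinfo(fm$tags, as = "character"), fixed = TRUE),
    tool_p = suppressWarnings(getinfo(fm$p))
  )
}

#' @describeIn dnmtrio-io Write the consensus DNM set as VCF with INFO keys
#'   TOOLS, ROUTE, PHASE, plus a flat TSV sidecar.
#' @param dnms Consensus DNM tibble.
#' @export
write_dnm_vcf <- function(dnms, path) {
  phase <- if ("phase" %in% names(dnms)) dnms$phase else "unphased"
  info <- sprintf("TOOLS=%s;ROUTE=%s;PHASE=%s;CHILD=%s",
                  gsub(",", "|", dnms$supporting_tools), dnms$pass_route,
                  phase, dnms$child_id)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  dnms$chrom, dnms$pos, dnms$ref, dnms$alt, info)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TOOLS,Number=1,Type=String,Description=\"Supporting tools\">",
    "##INFO=<ID=ROUTE,Number=1,Type=String,Description=\"consensus or rescued\">",
    "##INFO=<ID=PHASE,Number=1,Type=String,Description=\"Parent of origin\">",
    "##INFO=<ID=CHILD,Number=1,Type=String,Description=\"Child id\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  readr::write_lines(c(header, body), path)
  readr::write_tsv(dnms, paste0(path, ".tsv"))
  invisible(path)
}

#' @describeIn dnmtrio-io Write/read the co-observation table as TSV.
#' @param coobs Co-observation tibble.
#' @export
write_coobs <- function(coobs, path) {
  readr::write_tsv(coobs, path)
  invisible(path)
}

#' @describeIn dnmtrio-io Read a co-observation TSV.
#' @export
read_coobs <- function(path) {
  readr::read_tsv(path, col_types = "ccic")
}
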