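#' Collapse a substitution onto the six pyrimidine-oriented classes
#'
#' Substitutions representing the same event on complementary strands are
#' merged (G>A is the same event as C>T): when the reference base is a purine
#' both alleles are complemented, so every SNV maps to one of C>A, C>G, C>T,
#' T>A, T>C, T>G.
#'
#' @param ref,alt Single-base reference and alternate alleles (vectorized).
#' @return Factor over the six classes.
#' @export
#' @examples
#' collapse_substitution(c("G", "A"), c("A", "C")) # C>T, T>G
collapse_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% BASES & alt %in% BASES & ref != alt &
    nchar(ref) == 1 & nchar(alt) == 1
  if (!all(ok)) {
    abort("collapse_substitution expects single-base SNVs",
          class = "dnmtrio_input_error")
  }
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp_base(ref), ref)
  a <- ifelse(purine, comp_base(alt), alt)
  factor(paste0(r, ">", a), levels = SUB_CLASSES)
}

#' Pyrimidine-oriented trinucleotide context of a position
#'
#' Extracts the reference triplet centred on the position; when the centre
#' base is a purine the triplet is reverse-complemented so that the centre is
#' always a pyrimidine (the standard 96-context orientation).
#'
#' @param reference Reference string.
#' @param pos 1-based positions (vectorized); must be strictly inside the
#'   sequence.
#' @return Character vector of oriented triplets; `NA` (with a warning) when
#'   the triplet contains an ambiguous base.
#' @export
#' @examples
#' extract_context("AACGT", 3) # "ACG"
extract_context <- function(reference, pos) {
  L <- nchar(reference)
  if (any(pos <= 1 | pos >= L)) {
    abort("position at sequence edge has no full trinucleotide context",
          class = "dnmtrio_input_error")
  }
  trip <- toupper(substring(reference, pos - 1, pos + 1))
  centre <- substr(trip, 2, 2)
  out <- ifelse(centre %in% c("A", "G"), revcomp(trip), trip)
  bad <- grepl("[^ACGT]", trip)
  if (any(bad)) {
    warn(paste(sum(bad), "contexts contain ambiguous bases; set to NA"))
    out[bad] <- NA_character_
  }
  out
}

all_96_contexts <- function() {
  grid <- expand.grid(five = BASES, centre = c("C", "T"), three = BASES,
                      stringsAsFactors = FALSE)
  paste0(grid$five, grid$centre, grid$three)
}

#' Mutational spectrum and 96-context signature
#'
#' Computes the strand-collapsed six-class substitution fractions and the
#' 96-trinucleotide signature (fraction of SNVs per pyrimidine-centred
#' substitution class and flanking-base combination) of a DNM set. When a
#' `phase` column is present, per-parent stratified tables are attached.
#'
#' @param dnms DNM tibble with `pos`, `ref`, `alt`, `variant_class`
#'   (non-SNVs are ignored).
#' @param reference Reference string.
#' @return An object of class `dnm_spectrum`: list with `classes` (tibble
#'   `class`, `n`, `fraction`), `contexts` (tibble `context`, `class`,
#'   `label`, `n`, `fraction`, all 96 rows), `n_snvs`, and optionally
#'   `by_phase`, a list of spectra for paternal/maternal subsets.
#' @export
mutation_spectrum <- function(dnms, reference) {
  snvs <- dnms[dnms$variant_class == "SNV", , drop = FALSE]
  if (nrow(snvs) == 0) {
    abort("no SNVs in DNM set", class = "dnmtrio_input_error")
  }
  cls <- collapse_substitution(snvs$ref, snvs$alt)
  ctx <- extract_context(reference, snvs$pos)
  keep <- !is.na(ctx)
  cls_tab <- tibble::tibble(class = factor(SUB_CLASSES, SUB_CLASSES)) |>
    dplyr::left_join(dplyr::count(tibble::tibble(class = cls), .data$class),
                     by = "class")
  cls_tab$n[is.na(cls_tab$n)] <- 0L
  cls_tab$fraction <- cls_tab$n / sum(cls_tab$n)

  ctx_grid <- tidyr::expand_grid(context = all_96_contexts(),
                                 class = SUB_CLASSES)
  ctx_grid <- ctx_grid[substr(ctx_grid$context, 2, 2) ==
                         substr(ctx_grid$class, 1, 1), ]
  obs <- dplyr::count(
    tibble::tibble(context = ctx[keep], class = as.character(cls[keep])),
    .data$context, .data$class
  )
  ctx_tab <- dplyr::left_join(ctx_grid, obs, by = c("context", "class"))
  ctx_tab$n[is.na(ctx_tab$n)] <- 0L
  ctx_tab$fraction <- ctx_tab$n / sum(ctx_tab$n)
  ctx_tab$label <- paste0(substr(ctx_tab$context, 1, 1), "[",
                          ctx_tab$class, "]", substr(ctx_tab$context, 3, 3))

  out <- structure(
    list(classes = cls_tab,
         contexts = ctx_tab[, c("context", "class", "label", "n", "fraction")],
         n_snvs = nrow(snvs)),
    class = "dnm_spectrum"
  )
  if ("phase" %in% names(snvs)) {
    out$by_phase <- lapply(c(paternal = "paternal", maternal = "maternal"),
                           function(p) {
                             sub <- snvs[snvs$phase == p, , drop = FALSE]
                             sub$phase <- NULL
                             if (nrow(sub) == 0) NULL
                             else mutation_spectrum(sub, reference)
                           })
  }
  out
}

#' @export
print.dnm_spectrum <- function(x, ...) {
  cat("<dnm_spectrum>", x$n_snvs, "SNVs\n")
  print(x$classes, n = 6)
  invisible(x)
}

#' Transition:transversion ratio of a spectrum
#'
#' @param spectrum A `dnm_spectrum` object.
#' @return Ratio of transition (C>T, T>C) to transversion fractions.
#' @export
titv_ratio <- function(spectrum) {
  ts <- sum(spectrum$classes$fraction[spectrum$classes$class %in%
                                        c("C>T", "T>C")])
  ts / (1 - ts)
}

#' GC content in windows around DNMs
#'
#' For each window size `w`, computes the mean GC fraction of the `w`-base
#' region centred on each variant (`floor(w/2)` bases each side, variant base
#' included; windows are clipped at the reference edges), separately for SNVs
#' and indels.
#'
#' @param dnms DNM tibble with `pos` and `variant_class`.
#' @param reference Reference string.
#' @param windows Window sizes in bases, strictly increasing, each in
#'   `[10, 1000]` by convention.
#' @return Tibble: `window`, `variant_class`, `mean_gc`, `n`.
#' @export
gc_profile <- function(dnms, reference, windows = c(10, 50, 100, 250, 500,
                                                    1000)) {
  if (nrow(dnms) == 0) abort("empty DNM set", class = "dnmtrio_input_error")
  if (is.unsorted(windows, strictly = TRUE)) {
    abort("window sizes must be strictly increasing",
          class = "dnmtrio_input_error")
  }
  L <- nchar(reference)
  is_gc <- strsplit(as.character(reference), "")[[1]] %in% c("C", "G")
  cum <- c(0L, cumsum(is_gc))
  rows <- purrr::map(windows, function(w) {
    half <- floor(w / 2)
    lo <- pmax(dnms$pos - half, 1L)
    hi <- pmin(dnms$pos + half, L)
    gc <- (cum[hi + 1L] - cum[lo]) / (hi - lo + 1L)
    dplyr::summarise(
      dplyr::group_by(tibble::tibble(variant_class = dnms$variant_class,
                                     gc = gc),
                      .data$variant_class),
      window = w, mean_gc = mean(.data$gc), n = dplyr::n(), .groups = "drop"
    )
  })
  dplyr::bind_rows(rows)[, c("window", "variant_class", "mean_gc", "n")]
}

#' Mutation rates by CpG context
#'
#' Rates per base per generation at CpG versus non-CpG sites, overall and per
#' transition/transversion class, over the compartmental effective coverage.
#'
#' @param dnms DNM tibble with `cpg` (logical), `ref`, `alt`,
#'   `variant_class`.
#' @param coverage An [effective_coverage()] object.
#' @param n_children Number of genomes the DNM set was drawn from (rates are
#'   per genome per generation; default 1 treats the set as one genome's
#'   counts).
#' @return Tibble: `compartment`, `type` ("all"/"transition"/"transversion"),
#'   `n`, `bases`, `rate`.
#' @export
context_rates <- function(dnms, coverage, n_children = 1) {
  if (coverage$cpg_bases <= 0 || coverage$non_cpg_bases <= 0) {
    abort("zero coverage in a compartment", class = "dnmtrio_input_error")
  }
  snvs <- dnms[dnms$variant_class == "SNV", , drop = FALSE]
  cls <- collapse_substitution(snvs$ref, snvs$alt)
  ts <- cls %in% c("C>T", "T>C")
  tab <- tidyr::expand_grid(
    compartment = c("cpg", "non_cpg"),
    type = c("all", "transition", "transversion")
  )
  tab$n <- purrr::map2_int(tab$compartment, tab$type, function(cp, ty) {
    sel <- if (cp == "cpg") snvs$cpg else !snvs$cpg
    sel <- sel & switch(ty, all = TRUE, transition = ts, transversion = !ts)
    sum(sel)
  })
  tab$bases <- ifelse(tab$compartment == "cpg", coverage$cpg_bases,
                      coverage$non_cpg_bases)
  tab$rate <- tab$n / (2 * tab$bases * n_children)
  tab
}
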