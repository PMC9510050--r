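#' Effective genome coverage of a trio
#'
#' Counts the reference bases at which a de novo call could have been made —
#' here, bases flagged callable in the child and both parents — split into
#' CpG and non-CpG compartments. This count (times two for diploidy) is the
#' denominator of the per-generation mutation rate.
#'
#' @param callable Logical vector, one entry per reference base.
#' @param is_cpg Logical vector of the same length marking CpG-unit bases,
#'   or an integer vector of CpG-covered positions.
#' @return A list of class `effective_coverage` with `non_cpg_bases`,
#'   `cpg_bases`, `total`.
#' @export
#' @examples
#' effective_coverage(rep(TRUE, 100), c(10, 11, 50, 51))
effective_coverage <- function(callable, is_cpg) {
  if (!is.logical(is_cpg)) {
    v <- logical(length(callable))
    v[is_cpg] <- TRUE
    is_cpg <- v
  }
  if (length(callable) != length(is_cpg)) {
    abort("coverage track length differs from reference length",
          class = "dnmtrio_input_error")
  }
  cpg <- sum(callable & is_cpg)
  non <- sum(callable & !is_cpg)
  structure(list(non_cpg_bases = non, cpg_bases = cpg, total = non + cpg),
            class = "effective_coverage")
}

#' @export
print.effective_coverage <- function(x, ...) {
  cat("<effective_coverage> total", format(x$total, big.mark = ","),
      "=", format(x$non_cpg_bases, big.mark = ","), "non-CpG +",
      format(x$cpg_bases, big.mark = ","), "CpG bases\n")
  invisible(x)
}

#' Trio callability from per-member depth
#'
#' A base is callable when all three trio members reach the calling depth
#' filter and carry a genotype call.
#'
#' @param depths Numeric matrix or data frame, bases x members (child,
#'   father, mother).
#' @param min_depth Depth cutoff (default 12, the calling depth filter).
#' @param called Optional logical matrix of the same shape marking a present
#'   genotype call.
#' @return Logical callability vector.
#' @export
callable_from_depth <- function(depths, min_depth = 12, called = NULL) {
  depths <- as.matrix(depths)
  ok <- rowSums(depths >= min_depth) == ncol(depths)
  if (!is.null(called)) ok <- ok & rowSums(as.matrix(called)) == ncol(depths)
  ok
}

#' Per-generation mutation rate over effective coverage
#'
#' `rate = count / (2 * total effective bases)` — the factor two accounts for
#' genomic diploidy.
#'
#' @param dnm_count Number of DNMs (a median or mean per-genome count).
#' @param coverage An [effective_coverage()] object or a base count.
#' @return Rate per base per generation.
#' @export
#' @examples
#' dnm_rate(70, 2796691061) # ~1.25e-8
dnm_rate <- function(dnm_count, coverage) {
  total <- if (inherits(coverage, "effective_coverage")) coverage$total
           else coverage
  if (total <= 0) abort("zero effective coverage",
                        class = "dnmtrio_input_error")
  if (dnm_count < 0) abort("negative DNM count",
                           class = "dnmtrio_input_error")
  dnm_count / (2 * total)
}

#' Cohort DNM count summaries
#'
#' Medians, means and totals of per-child DNM counts by variant class.
#' Children listed in `children` but absent from a class contribute zero
#' counts (a child with no indel call still has an indel count of 0).
#'
#' @param dnms DNM tibble with `child_id` and `variant_class`.
#' @param children Character vector of child ids in the cohort; defaults to
#'   the children present in `dnms`.
#' @return Tibble: `variant_class`, `total`, `median`, `mean`.
#' @export
summarize_dnm_counts <- function(dnms, children = unique(dnms$child_id)) {
  if (length(children) == 0) {
    abort("no children to summarize", class = "dnmtrio_input_error")
  }
  counts <- dplyr::count(dnms, .data$child_id, .data$variant_class)
  grid <- tidyr::expand_grid(child_id = children,
                             variant_class = unique(dnms$variant_class))
  counts <- dplyr::left_join(grid, counts,
                             by = c("child_id", "variant_class"))
  counts$n[is.na(counts$n)] <- 0L
  dplyr::summarise(
    dplyr::group_by(counts, .data$variant_class),
    total = sum(.data$n), median = stats::median(.data$n),
    mean = mean(.data$n), .groups = "drop"
  )
}

#' Functional-impact grouping
#'
#' Maps annotation impact categories to the protein-disrupting /
#' non-disrupting dichotomy: MODIFIER and LOW are non-disrupting, MODERATE
#' and HIGH are disrupting. Labels are whitespace-trimmed and
#' case-normalized; anything else is an error.
#'
#' @param impact Character vector of impact categories.
#' @return Factor with levels `non_disrupting`, `disrupting`.
#' @export
#' @examples
#' classify_impact(c("MODERATE", "modifier", "HIGH "))
classify_impact <- function(impact) {
  x <- toupper(trimws(impact))
  known <- c(MODIFIER = "non_disrupting", LOW = "non_disrupting",
             MODERATE = "disrupting", HIGH = "disrupting")
  bad <- setdiff(unique(x[!is.na(x)]), names(known))
  if (length(bad)) {
    abort(paste("unknown impact category:", paste(bad, collapse = ", ")),
          class = "dnmtrio_input_error")
  }
  factor(unname(known[x]), levels = c("non_disrupting", "disrupting"))
}

#' Coding fraction and loss-of-function tallies
#'
#' Fractions are reported as percentages to two significant figures, rounding
#' half away from zero.
#'
#' @param dnms DNM tibble with logical columns `coding` and, optionally,
#'   `lof` and `nmd`.
#' @return One-row tibble: `n_total`, `n_coding`, `coding_pct`, `n_lof`,
#'   `n_nmd`, `nmd_of_lof_pct`.
#' @export
coding_fraction <- function(dnms) {
  n <- nrow(dnms)
  if (n == 0) abort("empty DNM set", class = "dnmtrio_input_error")
  n_coding <- sum(dnms$coding, na.rm = TRUE)
  n_lof <- if ("lof" %in% names(dnms)) sum(dnms$lof, na.rm = TRUE) else NA_integer_
  n_nmd <- if ("nmd" %in% names(dnms)) sum(dnms$nmd, na.rm = TRUE) else NA_integer_
  tibble::tibble(
    n_total = n, n_coding = n_coding,
    coding_pct = pct_2sf(n_coding, n),
    n_lof = n_lof, n_nmd = n_nmd,
    nmd_of_lof_pct = if (!is.na(n_lof) && n_lof > 0) pct_2sf(n_nmd, n_lof)
                     else NA_real_
  )
}

# percentage to two significant figures, half away from zero
pct_2sf <- function(num, den) {
  p <- 100 * num / den
  if (p == 0) return(0)
  digits <- 2 - 1 - floor(log10(abs(p)))
  sign(p) * floor(abs(p) * 10^digits + 0.5) / 10^digits
}
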