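#' Generate a synthetic reference sequence
#'
#' Draws an i.i.d. base sequence at the requested GC content, then optionally
#' plants additional CG dinucleotides so that the CpG count is a chosen
#' multiple of the independence expectation (`gc/2 * gc/2` per dinucleotide
#' start).
#'
#' @param length Sequence length in bases (>= 10,000 for realistic use; any
#'   positive length is accepted, zero or negative is an error).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param cpg_enrichment Multiplier (>= 0) on the independence-expected CpG
#'   dinucleotide count; 1 leaves the i.i.d. draw untouched.
#' @param seed Optional integer seed.
#'
#' @return A single uppercase string over `ACGT` with attribute `cpg_sites`,
#'   the 1-based positions of the C of every CG dinucleotide.
#' @export
#' @examples
#' ref <- sim_reference(10000, gc_fraction = 0.41, seed = 1)
#' length(attr(ref, "cpg_sites"))
sim_reference <- function(length, gc_fraction = 0.41, cpg_enrichment = 1,
                          seed = NULL) {
  if (length <= 0) abort("reference length must be positive",
                         class = "dnmtrio_input_error")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1, cpg_enrichment >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(BASES, length, replace = TRUE, prob = p)
  if (cpg_enrichment > 1 && length >= 2) {
    expected <- (gc_fraction / 2)^2 * (length - 1)
    extra <- round((cpg_enrichment - 1) * expected)
    if (extra > 0) {
      at <- sample.int(length - 1L, min(extra, length - 1L))
      bases[at] <- "C"
      bases[at + 1L] <- "G"
    }
  }
  seq <- paste(bases, collapse = "")
  structure(seq, cpg_sites = cpg_positions(seq))
}

#' Positions of CpG dinucleotides
#'
#' @param reference A reference sequence string.
#' @return Integer vector of 1-based positions of the C of each forward-strand
#'   CG dinucleotide ("CpG units").
#' @export
cpg_positions <- function(reference) {
  sites <- attr(reference, "cpg_sites")
  if (!is.null(sites)) return(sites)
  m <- gregexpr("(?=CG)", as.character(reference), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Reference positions covered by a CpG unit
#'
#' A DNM at either the C or the G of a CG dinucleotide counts as "at a CpG".
#'
#' @inheritParams cpg_positions
#' @return Integer vector of positions (C and G of every unit), sorted.
#' @export
cpg_covered_positions <- function(reference) {
  cp <- cpg_positions(reference)
  sort(unique(c(cp, cp + 1L)))
}

#' Simulate a CpG methylation track
#'
#' Assigns every CpG unit of the reference a methylation fraction. A fraction
#' `high_meth_fraction` of units is drawn from a high-methylation component
#' (strictly above 0.5) and the remainder from a low component (at most 0.5),
#' emulating the bimodal methylation landscape of bisulfite profiles.
#'
#' @param reference Reference string (must contain at least one CpG).
#' @param high_meth_fraction Fraction of units methylated above 50%.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `pos` (1-based position of the unit's C) and
#'   `meth` (methylation fraction in `[0, 1]`).
#' @export
sim_methylation_track <- function(reference, high_meth_fraction = 0.69,
                                  seed = NULL) {
  stopifnot(high_meth_fraction >= 0, high_meth_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  cp <- cpg_positions(reference)
  if (length(cp) == 0) {
    abort("reference contains no CpG site", class = "dnmtrio_input_error")
  }
  high <- runif(length(cp)) < high_meth_fraction
  meth <- numeric(length(cp))
  # high component: (0.5, 1]; low component: [0, 0.5]
  meth[high] <- 0.5 + 0.5 * rbeta(sum(high), 4, 1.3)
  meth[!high] <- 0.5 * rbeta(sum(!high), 1.3, 4)
  meth[high] <- pmax(meth[high], 0.5 + 1e-9)
  tibble::tibble(pos = cp, meth = meth)
}
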