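---
title: "De novo mutation discovery in multiplex families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo mutation discovery in multiplex families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmtrio)
library(dplyr)
```

`dnmtrio` analyzes germline de novo mutations (DNMs) in parent-offspring
trios drawn from multiplex families. This vignette is the package's account
of the science it implements: the models, their assumptions, the tunable
parameters, the numerical choices, and the limits of what the synthetic
validation shows.

## The discovery problem

A single-gamete DNM is a variant created during replication of a parental
gamete: it is heterozygous in one child and absent from both parents and
all siblings. Two error modes dominate trio-based discovery:

* **caller false positives**, which are largely tool-specific — different
  callers err on different sites; and
* **missed parental heterozygotes**: a real parental variant genotyped as
  absent in the parent. To a single trio this is exactly what a DNM looks
  like. Its signature is *sharing*: transmitted to several children, it
  appears as an impossible "recurrent DNM" across siblings.

The package's consensus stage attacks the first mode (variants seen by two
or three callers pass; singletons must clear stricter rescue thresholds:
FreeBayes-like depth ≥ 14, RUFUS-like QUAL ≥ 16 SNV / 17 indel,
VarScan-like Freq ≥ 0.30 SNV / 0.35 indel). The sibling-sharing filter
attacks the second: any candidate whose alternate allele is observed in a
parent or sibling is removed. A direct corollary, which the synthetic
cohort reproduces, is that per-child DNM counts *decrease* with the number
of sequenced siblings — each extra sibling is another chance to expose a
shared artifact. All base and rescue thresholds are inclusive (≥/≤) as
printed above, and candidates above 0.1% population allele frequency
(strict inequality; an absent annotation counts as frequency zero) are
removed as population-specific variants missed in the parents.

Variant identity for the three-way merge is (`chrom`, `pos`, `ref`, `alt`)
after suffix-then-prefix trimming (left alignment), since callers emit
differently normalized records. Records mixing equal-length multi-base
alleles (MNVs) are outside the analyzed classes; `variant_class` is INDEL
whenever `nchar(ref) != nchar(alt)`, SNV otherwise.

## Mutation rate

The per-generation rate divides a per-genome DNM count by twice the
*effective genome coverage*: the number of reference bases at which a de
novo call could have been made in that trio. Callability here is depth ≥ 12
with a genotype call in child and both parents — the same depth cutoff as
the calling filter. The factor two is diploidy. The coverage object carries
its CpG/non-CpG split so that context-specific rates use compartmental
denominators, and a published total (e.g. 2,796,691,061 bases) can be
passed directly as the denominator when reproducing reported rates.

## Parent-of-origin phasing

A DNM can be assigned to the paternal or maternal haplotype when a
sequencing read covers both the DNM and an *informative site*: an inherited
variant at which the child is heterozygous and Mendelian logic attributes
each allele to exactly one parent (e.g. mother carries no alternate and
father at least one, or father is homozygous alternate). Reads carrying the
DNM alternate vote for the parent whose allele they also carry; reads
without the DNM alternate are silent. Because read length bounds the
DNM-site distance (two positions co-occur on a 150 bp read only if under
150 bp apart), phasing yield is set by informative-site density and read
length, and both relationships are verified to be monotone on synthetic
data.

**Conflict rule.** Published pipelines rarely state how conflicting reads
are resolved; this package phases only on *unanimous* votes — any
disagreement leaves the DNM unphased. This is deliberately conservative:
mis-phasing biases parental fractions, whereas unphased DNMs only lose
power. Mate pairs sharing a read id count as one observation unit.

Per child, the paternal fraction among phased DNMs is scaled to the total
DNM count (`scaled_paternal = fraction × total`), kept real-valued, and
used as the regression response; children with zero phased DNMs have an
undefined fraction and are excluded rather than imputed.

## Parental-age models

Two regression views are provided:

* **OLS age trends** of scaled phased counts on the matching parent's age
  at conception, with Wald 95% intervals and the Pearson correlation
  p-value — the cross-family view.
* **Identity-link Poisson regression** of total DNM count on father's age,
  where the coefficient reads directly as *additional DNMs per year*. The
  identity link is not variance-stabilized and can walk the mean negative;
  the fitter starts from an OLS pre-fit, falls back to damped-slope
  restarts, and reports non-convergence explicitly rather than silently.
  The within-family model adds family intercepts and family × age
  interactions on families with four or more children, reports per-family
  slopes with Wald intervals, and compares against the no-interaction model
  with a likelihood-ratio chi-square (df = parameter difference).

## Kinship and the consanguinity confounder

Parental relatedness is estimated with the within-family robust KING
estimator,
$\phi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa,i} + N_{Aa,j})$,
which is 0.5 for self, ≈ 0.25 for parent-offspring, and ≈ 0 for unrelated
pairs; classification uses the standard cutoffs (≥ 0.177 flagged closer
than first-degree cousins; [0.0884, 0.177) first-degree cousins;
[0.0442, 0.0884) second-degree; below, unrelated). Because the cited
kinship tool's exact implementation is not restated anywhere, equivalence
is checked against Mendelian-simulation expectations (0.5 self, 0.25
parent-child, planted cousin classes), not against the tool.

Single-gamete DNMs arise before fertilization, so consanguinity cannot
causally change their count. An apparent association appears whenever
relatedness correlates with father's age or family size. The package's
"corrected" analyses residualize the count on the named covariate by OLS
and run the group comparisons on residuals; the synthetic confounder
experiment (consanguineous families given younger fathers) reproduces the
pattern of a raw group difference that vanishes after correction.
Group tests are pairwise two-sample Student t-tests, Bonferroni-corrected
by the number of pairs (capped at 1).

## Spectra and methylation

Substitutions are strand-collapsed onto the six pyrimidine-reference
classes (G>A ≡ C>T); trinucleotide contexts are reverse-complemented
whenever the centre base is a purine, giving the standard 96-context
signature. The orientation is pinned by an exhaustive 64-triplet oracle in
the tests. GC content is averaged in windows of 10–1000 bases; a window of
size `w` means `w` bases centred on the variant, variant base *included*
(the inclusive convention is this package's documented choice; at `w ≥ 10`
the difference from an exclusive flank is under one part in ten). Indels
are anchored at their left-aligned start.

A CpG site is a forward-strand CG dinucleotide; a DNM at either base is
"at a CpG", and its methylation value is the track value at the unit's C.
CpGs are binned at 50% methylation (strictly above = high). Enrichment
compares the fraction of genome CpGs carrying a DNM between bins; the fold
difference is their ratio. Significance uses the exact binomial upper tail:
under the null that DNM CpGs fall into bins in proportion to genome-wide
bin sizes, the high-bin DNM count is Binomial(n, p₀) with p₀ the
genome-wide high-bin proportion, and the reported p is P(X ≥ k), computed
exactly. The one-sided upper-tail construction is this package's stated
choice — it tests the direction of interest (elevated mutability at
methylated CpGs, the expected consequence of spontaneous deamination of
5-methylcytosine). Units absent from a tissue's track are excluded from
numerator and denominator for that tissue; the enrichment defaults to
paternally phased DNM CpGs (the gonadal comparison), with all-DNM CpGs as
an option, and only SNVs are counted (an indel has no single-base CpG
semantics).

## The synthetic cohort generator

The generator exists so that every stage can be validated against known
truth. Its defaults are the cohort conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `n_families` | 146 | multiplex families (~350–400 trios) |
| `offspring_probs` | median 2, range 1–10 | >70% multi-offspring |
| father/mother ages | medians 34 / 29 years | age at first conception ~N(30.5, 5) / −5 years; 2–3-year birth spacing |
| `dnm_base_count` | 70 SNVs | expected per child at reference ages 34/29 |
| `indel_base_count` | 6 | no age effect |
| `paternal_age_slope` | 1.36 /year | planted on the paternal component |
| `maternal_age_slope` | 0.33 /year | planted on the maternal component |
| `paternal_fraction` | 0.8 | origin fraction at reference ages |
| `cpg_mutability_multiplier` | 2 | placement weight at CpGs methylated >50% |
| `consanguinity_fraction` | 47/146 | half half-sib-parent class, half cousin-parent class |
| `high_meth_fraction` | 0.69 | CpG units methylated >50% |
| spectrum | C>T 0.42, T>C 0.25, … | transition:transversion 2:1 |
| `read_length`, `depth` | 150 bp, 30× | phasing geometry |

Counts are generated as independent paternal and maternal Poisson
components,
$K_{pat} \sim Pois(0.8 \cdot 70 + 1.36\,(a_f - 34))$ and
$K_{mat} \sim Pois(0.2 \cdot 70 + 0.33\,(a_m - 29))$,
so that the paternal-age effect lives on paternally derived mutations
(replication errors accumulating in spermatogonia) and each parent's slope
is recoverable from that parent's phased counts — a single total count
with i.i.d. origin labels would attenuate the paternal slope by the origin
fraction and make the planted parameters mutually inconsistent. At the
reference ages the expected total is 70 and the expected paternal fraction
0.8. Negative means at extreme ages are clamped to a small floor with a
warning.

Placement weights CpG-unit bases with >50% methylation by the multiplier;
the expected enrichment fold therefore *equals* the multiplier, which is
what the recovery experiment checks. Marker (segregating-site) positions
are excluded from placement: a de novo call coinciding in position and
allele with a segregating family variant is inherently indistinguishable
from inheritance, and including such sites would make exact truth recovery
impossible by construction rather than by pipeline error.

Tool emulation gives true calls metrics that clear the base thresholds
(depth 12 + Pois(18) at the 30× design depth, allele fraction centred on
0.5, qualities above the cutoffs) and false positives discriminable
metrics (allele fraction centred near 0.2, exponential qualities,
occasional parental alternate reads), with per-tool false-negative and
unique false-positive rates. True caller error rates are not knowable from
published summaries; these defaults are tunable knobs, not inferences.
Missed parental heterozygotes are planted at marker sites where exactly
one parent is heterozygous; that parent's called genotype is zeroed, and
every carrier child presents the variant to all three tools — the
mechanism behind the family-size effect. Read co-observations are emitted
per DNM from the nearest child-heterozygous marker within read length,
with reads drawn from the two haplotypes at equal probability and the DNM
alternate riding the haplotype of true origin; per-base errors flip
observed alleles. All randomness flows from one `set.seed` at cohort
entry, so a config plus seed determines the output byte-for-byte (a
single stream rather than per-family substreams; sub-setting a cohort
therefore changes downstream draws, which the determinism tests account
for by always regenerating whole cohorts).

### What the synthetic validation does and does not show

The generator emulates family structure, Mendelian transmission,
age-dependent counts, methylation-dependent placement, caller discordance,
artifact sharing, and read-level phasing geometry. It does **not** emulate
alignment error, mappability structure, GC-coverage bias, LD between
markers, mosaicism, sex chromosomes, or multi-nucleotide events. Passing
tests therefore establish that the *statistical machinery* is correct and
unbiased under the stated generative model — not that real-data error
modes outside that model are handled. Cohort-specific published values
that depend on real sequence data (e.g. a particular cohort's exact median
counts or phasing yield) are reproduced only where they are pure functions
of printed inputs.

## Numerical choices

* Rounding of reported percentages: two significant figures, half away
  from zero.
* Identity-link Poisson: OLS starting values, damped restarts, explicit
  convergence failure; per-family Wald intervals from the observed
  information.
* Exact binomial tails via the cumulative distribution (no normal
  approximation); the small-n oracle in the tests enumerates outcomes from
  factorials directly.
* The fold-difference interval in the recovery experiment is an exact
  Clopper-Pearson interval on the high-bin proportion, mapped to the fold
  scale through the odds times the genome bin ratio.
* Coordinates are 1-based closed internally; BED/bedGraph conversion
  happens only at IO boundaries. bedGraph values in 0–100 are
  auto-detected as percentages and rescaled.
* Desk-scale problem sizes: validation cohorts use a 200 kb–1 Mb synthetic
  reference with 2,500–8,000 markers. These sizes keep a 20-seed,
  353-trio recovery experiment within minutes while leaving per-child DNM
  counts, phasing yield, and all per-variant statistics at full scale;
  only quantities proportional to genome length (absolute rates) scale
  with the reference.

## Worked recovery check

```{r recovery, eval = FALSE}
# one seed of the cohort-scale experiment (seconds at reduced size)
recovery_experiment(recovery_config(n_families = 30), seed = 1)
```

The four rows report the estimate and 95% interval for the paternal and
maternal age slopes, the paternal origin fraction, and the CpG mutability
multiplier; across 20 seeds at full cohort size each interval covers its
planted value in at least 18 runs (the acceptance suite's check).

## Known limitations

* The KING estimator is validated by simulation expectations, not against
  the original implementation.
* Phasing ignores chromosome X and uses single reads as observation units
  unless mate ids are shared.
* The identity-link interaction model can fail to converge on
  pathological family configurations; it reports failure rather than
  switching link functions silently.
* The sibling-sharing filter treats a missing sibling genotype as
  non-carrier; systematically missing sibling data therefore weakens the
  artifact removal rather than biasing retained counts.
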