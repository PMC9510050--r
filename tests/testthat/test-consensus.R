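test_that("per-tool base filtration applies the published thresholds", {
  keep <- candidate_row() # af 0.5, depth 20, qual 45, parents 0
  expect_equal(nrow(filter_tool_candidates(keep)), 1)

  expect_equal(nrow(filter_tool_candidates(candidate_row(depth = 11))), 0)
  expect_equal(nrow(filter_tool_candidates(candidate_row(af = 0.2))), 0)
  expect_equal(nrow(filter_tool_candidates(candidate_row(af = 0.76))), 0)
  expect_equal(nrow(filter_tool_candidates(candidate_row(qual = 29))), 0)
  expect_equal(nrow(filter_tool_candidates(candidate_row(paf = 1))), 0)
  # indels need quality 80
  expect_equal(nrow(filter_tool_candidates(
    candidate_row(variant_class = "INDEL", ref = "A", alt = "AT",
                  qual = 79))), 0)
  expect_equal(nrow(filter_tool_candidates(
    candidate_row(variant_class = "INDEL", ref = "A", alt = "AT",
                  qual = 80))), 1)

  vs <- candidate_row(tool = "varscan", tags = "DENOVO,PASS", p = 0.001)
  expect_equal(nrow(filter_tool_candidates(vs)), 1)
  expect_equal(nrow(filter_tool_candidates(
    candidate_row(tool = "varscan", tags = "DENOVO,PASS", p = 0.01))), 0)
  expect_equal(nrow(filter_tool_candidates(
    candidate_row(tool = "varscan", tags = "PASS", p = 0.001))), 0)
  expect_equal(nrow(filter_tool_candidates(
    candidate_row(tool = "varscan", tags = "DENOVO,PASS", p = 0.001,
                  af = 0.2))), 0)

  expect_equal(nrow(filter_tool_candidates(
    candidate_row(tool = "rufus", tags = "DeNovo", qual = 1))), 1)
  expect_equal(nrow(filter_tool_candidates(
    candidate_row(tool = "rufus", tags = "PASS"))), 0)

  expect_error(filter_tool_candidates(candidate_row(tool = "gatk")),
               class = "dnmtrio_input_error")
  # missing required metric counts as failure
  expect_equal(nrow(filter_tool_candidates(candidate_row(depth = NA))), 0)
})

test_that("threshold container validates rescue strictness", {
  expect_error(dnm_thresholds(rescue_fb_depth = 10),
               class = "dnmtrio_config_error")
  expect_error(dnm_thresholds(no_such = 1), class = "dnmtrio_config_error")
})

test_that("consensus merge passes multi-tool variants and rescues singletons", {
  two <- dplyr::bind_rows(candidate_row(tool = "freebayes"),
                          candidate_row(tool = "varscan", tags = "DENOVO,PASS",
                                        p = 0.001))
  m <- merge_consensus(two)
  expect_equal(m$pass_route, "consensus")
  expect_equal(m$supporting_tools, "freebayes,varscan")

  expect_equal(nrow(merge_consensus(candidate_row(depth = 13))), 0)
  r <- merge_consensus(candidate_row(depth = 14))
  expect_equal(r$pass_route, "rescued")

  rq <- merge_consensus(candidate_row(tool = "rufus", tags = "DeNovo",
                                      qual = 16))
  expect_equal(rq$pass_route, "rescued")
  expect_equal(nrow(merge_consensus(candidate_row(tool = "rufus",
                                                  tags = "DeNovo",
                                                  qual = 15.9))), 0)
  # indel rescue needs 17
  expect_equal(nrow(merge_consensus(
    candidate_row(tool = "rufus", tags = "DeNovo", qual = 16.5,
                  variant_class = "INDEL", ref = "A", alt = "AT"))), 0)

  vsr <- merge_consensus(candidate_row(tool = "varscan",
                                       tags = "DENOVO,PASS", p = 0.001,
                                       af = 0.30))
  expect_equal(vsr$pass_route, "rescued")
  expect_equal(nrow(merge_consensus(
    candidate_row(tool = "varscan", tags = "DENOVO,PASS", p = 0.001,
                  af = 0.29))), 0)
})

test_that("merge is independent of input order", {
  co <- small_cohort()
  f <- filter_tool_candidates(co$calls)
  a <- merge_consensus(f)
  set.seed(1)
  b <- merge_consensus(f[sample.int(nrow(f)), ])
  expect_identical(a, b)
})

test_that("merge agrees with a literal set-algebra oracle", {
  # oracle: union of per-tool keys; >=2 tools -> pass; singletons checked
  # against that tool's quoted rescue rule, written out independently
  merge_oracle <- function(f, th = dnm_thresholds()) {
    key <- paste(f$child_id, f$chrom, f$pos, f$ref, f$alt, sep = "|")
    out <- character(0)
    for (k in unique(key)) {
      rows <- f[key == k, ]
      tools <- unique(rows$tool)
      if (length(tools) >= 2) {
        out <- c(out, k)
      } else {
        r <- rows[1, ]
        ok <- switch(r$tool,
          freebayes = isTRUE(r$child_depth >= 14),
          rufus = isTRUE(r$qual >= ifelse(r$variant_class == "INDEL", 17, 16)),
          varscan = isTRUE(r$child_alt_fraction >=
                             ifelse(r$variant_class == "INDEL", 0.35, 0.30))
        )
        if (ok) out <- c(out, k)
      }
    }
    sort(out)
  }
  set.seed(33)
  n <- 1000
  f <- tibble::tibble(
    tool = sample(c("freebayes", "varscan", "rufus"), n, TRUE),
    child_id = sample(c("c1", "c2", "c3"), n, TRUE),
    family_id = "F1", chrom = "chr1",
    pos = sample(1:400, n, TRUE),
    ref = sample(c("A", "C"), n, TRUE), alt = "G",
    variant_class = sample(c("SNV", "INDEL"), n, TRUE, prob = c(.9, .1)),
    child_alt_fraction = runif(n, 0.2, 0.6),
    child_depth = sample(10:20, n, TRUE),
    parent_alt_depth_father = 0L, parent_alt_depth_mother = 0L,
    qual = runif(n, 10, 40), tags = "x", tool_p = NA_real_
  )
  f <- dplyr::distinct(f, tool, child_id, pos, ref, alt, .keep_all = TRUE)
  got <- merge_consensus(f)
  got_keys <- sort(paste(got$child_id, got$chrom, got$pos, got$ref, got$alt,
                         sep = "|"))
  expect_identical(got_keys, merge_oracle(f))
})

test_that("rescued singletons always satisfy their base thresholds too", {
  co <- small_cohort()
  f <- filter_tool_candidates(co$calls)
  m <- merge_consensus(f)
  rescued <- m[m$pass_route == "rescued", ]
  # every rescued variant came through the base filter by construction;
  # re-filtering the matching raw calls must keep them
  raw <- dplyr::semi_join(
    co$calls,
    dplyr::mutate(rescued, tool = rescued$supporting_tools),
    by = c("tool", "child_id", "pos")
  )
  expect_equal(nrow(filter_tool_candidates(raw)), nrow(raw))
})

test_that("variant normalization left-aligns shared affixes", {
  x <- tibble::tibble(pos = c(10L, 5L, 7L), ref = c("CA", "TAG", "A"),
                      alt = c("CT", "TG", "AT"))
  n <- normalize_variants(x)
  expect_equal(n$pos, c(11L, 5L, 7L))
  expect_equal(n$ref, c("A", "TA", "A"))
  expect_equal(n$alt, c("T", "T", "AT"))
})

test_that("population-frequency filter removes only common variants", {
  d <- tibble::tibble(id = 1:3, af_gnomad = c(0.002, 0.001, NA),
                      af_topmed = c(0, 0, NA))
  kept <- filter_population_af(d)
  expect_equal(kept$id, c(2L, 3L)) # 0.001 retained (strict >), NA retained
  expect_error(filter_population_af(
    tibble::tibble(af_x = -0.1)), class = "dnmtrio_input_error")
})

test_that("family-sharing filter removes shared candidates only", {
  cand <- tibble::tibble(child_id = c("c1", "c2"), chrom = "chr1",
                         pos = c(100L, 200L), ref = "A", alt = "G")
  members <- tibble::tibble(
    child_id = c("c1", "c1", "c2"),
    chrom = "chr1", pos = c(100L, 100L, 200L), ref = "A", alt = "G",
    individual_id = c("sib1", "fa", "sib2"),
    alt_dosage = c(1L, 0L, 0L)
  )
  kept <- filter_family_sharing(cand, members)
  expect_equal(kept$child_id, "c2")

  # property: never removes a variant absent from all non-proband members
  set.seed(4)
  for (i in 1:20) {
    cand_i <- tibble::tibble(child_id = "c1", chrom = "chr1",
                             pos = sample(1000, 5), ref = "A", alt = "G")
    mem_i <- tidyr::expand_grid(cand_i[, c("child_id", "chrom", "pos",
                                           "ref", "alt")],
                                individual_id = c("m1", "m2"))
    mem_i$alt_dosage <- 0L
    expect_equal(nrow(filter_family_sharing(cand_i, mem_i)), 5)
  }
})

test_that("sibling sharing removes artifacts but not private DNMs", {
  co <- small_cohort()
  f <- filter_tool_candidates(co$calls)
  m <- merge_consensus(f)
  mg <- family_genotype_table(m, co$genotypes, co$pedigree,
                              attr(co$calls, "artifacts"))
  kept <- filter_family_sharing(m, mg)
  removed <- dplyr::anti_join(m, kept,
                              by = c("child_id", "pos", "ref", "alt"))
  # nothing true is removed, and some shared artifacts are
  expect_false(any(removed$truth_tag == "true"))
  art_in_multi <- dplyr::count(
    m[m$truth_tag == "artifact", ], family_id, pos)
  if (any(art_in_multi$n > 1)) {
    expect_gt(sum(removed$truth_tag == "artifact"), 0)
  }
})

test_that("effective coverage counts match a per-base oracle", {
  cov <- effective_coverage(rep(TRUE, 10000), c(11:110, 501:600))
  expect_equal(cov$total, 10000)
  expect_equal(cov$cpg_bases, 200)
  expect_equal(cov$non_cpg_bases, 9800)

  zero <- effective_coverage(rep(FALSE, 100), c(1, 2))
  expect_equal(zero$total, 0)

  set.seed(5)
  callable <- runif(5000) < 0.8
  cpg <- sort(sample(5000, 300))
  cov2 <- effective_coverage(callable, cpg)
  # brute force per-base loop
  brute_cpg <- 0; brute_non <- 0
  for (i in 1:5000) {
    if (callable[i]) {
      if (i %in% cpg) brute_cpg <- brute_cpg + 1 else brute_non <- brute_non + 1
    }
  }
  expect_equal(cov2$cpg_bases, brute_cpg)
  expect_equal(cov2$non_cpg_bases, brute_non)

  expect_error(effective_coverage(rep(TRUE, 10), rep(TRUE, 9)),
               class = "dnmtrio_input_error")
})

test_that("callability requires depth in all trio members", {
  depths <- cbind(child = c(15, 15, 5), father = c(15, 11, 15),
                  mother = c(15, 15, 15))
  expect_equal(callable_from_depth(depths), c(TRUE, FALSE, FALSE))
})

test_that("mutation rate divides by twice the effective coverage", {
  expect_equal(dnm_rate(0, 1000), 0)
  expect_equal(dnm_rate(10, 1e6), 5e-6)
  expect_error(dnm_rate(5, 0), class = "dnmtrio_input_error")
})

test_that("cohort count summaries include zero-count children", {
  d <- tibble::tibble(child_id = c("a", "a", "b"),
                      variant_class = c("SNV", "INDEL", "SNV"))
  s <- summarize_dnm_counts(d, children = c("a", "b", "c"))
  snv <- s[s$variant_class == "SNV", ]
  expect_equal(snv$total, 2)
  expect_equal(snv$median, 1)
  indel <- s[s$variant_class == "INDEL", ]
  expect_equal(indel$median, 0)
  expect_error(summarize_dnm_counts(d, children = character(0)),
               class = "dnmtrio_input_error")

  one <- summarize_dnm_counts(
    tibble::tibble(child_id = rep("a", 70), variant_class = "SNV"))
  expect_equal(one$median, 70)
})

test_that("impact grouping follows the disrupting dichotomy", {
  g <- classify_impact(c("MODERATE", "MODIFIER", "HIGH ", "low"))
  expect_equal(as.character(g),
               c("disrupting", "non_disrupting", "disrupting",
                 "non_disrupting"))
  expect_error(classify_impact("WEIRD"), class = "dnmtrio_input_error")
})

test_that("coding fractions round to the printed precision", {
  d <- tibble::tibble(coding = rep(c(TRUE, FALSE), c(459, 27168 - 459)))
  expect_equal(coding_fraction(d)$coding_pct, 1.7)

  d2 <- tibble::tibble(coding = rep(TRUE, 43),
                       lof = TRUE,
                       nmd = rep(c(TRUE, FALSE), c(13, 30)))
  expect_equal(coding_fraction(d2)$nmd_of_lof_pct, 30)

  d3 <- tibble::tibble(coding = rep(FALSE, 10))
  expect_equal(coding_fraction(d3)$coding_pct, 0)
  expect_error(coding_fraction(d3[0, ]), class = "dnmtrio_input_error")
})
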