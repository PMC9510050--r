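test_that("reference generation respects composition targets", {
  all_gc <- sim_reference(10000, gc_fraction = 1, seed = 1)
  expect_false(grepl("[AT]", all_gc))

  ref <- sim_reference(10000, gc_fraction = 0.41, seed = 1)
  gc <- sum(strsplit(as.character(ref), "")[[1]] %in% c("C", "G")) / 10000
  expect_lt(abs(gc - 0.41), 0.02)

  expect_error(sim_reference(0), class = "dnmtrio_input_error")

  # CpG enrichment multiplies the independence-expected dinucleotide count
  plain <- sim_reference(50000, 0.4, cpg_enrichment = 1, seed = 2)
  boosted <- sim_reference(50000, 0.4, cpg_enrichment = 3, seed = 2)
  expect_gt(length(cpg_positions(boosted)),
            2 * length(cpg_positions(plain)))
})

test_that("reference generation is deterministic under a seed", {
  expect_identical(as.character(sim_reference(5000, 0.41, seed = 11)),
                   as.character(sim_reference(5000, 0.41, seed = 11)))
})

test_that("methylation track covers every CpG with calibrated high fraction", {
  ref <- sim_reference(100000, 0.41, seed = 3)
  low <- sim_methylation_track(ref, high_meth_fraction = 0, seed = 1)
  expect_true(all(low$meth <= 0.5))
  expect_identical(low$pos, cpg_positions(ref))

  trk <- sim_methylation_track(ref, high_meth_fraction = 0.69, seed = 1)
  expect_true(all(trk$meth >= 0 & trk$meth <= 1))
  expect_lt(abs(mean(trk$meth > 0.5) - 0.69), 0.03)

  # querying a non-CpG position yields no value
  non_cpg <- setdiff(1:100, trk$pos)[1]
  expect_false(non_cpg %in% trk$pos)

  expect_error(sim_methylation_track("ATATAT"),
               class = "dnmtrio_input_error")
})

test_that("pedigree generation matches the configured cohort structure", {
  expect_equal(nrow(sim_pedigree(sim_config(n_families = 0))), 0)

  cfg2 <- sim_config(n_families = 20,
                     offspring_probs = c(0, 1, rep(0, 8)))
  ped2 <- sim_pedigree(cfg2, seed = 1)
  expect_true(all(ped2$n_offspring == 2))
  expect_equal(sum(ped2$role == "child"), 40)

  cfg <- sim_config(n_families = 146, consanguinity_fraction = 47 / 146)
  ped <- sim_pedigree(cfg, seed = 5)
  n_consang <- dplyr::n_distinct(
    ped$family_id[ped$consanguinity_class != "unrelated"])
  # binomial sampling bound around the expected 47
  expect_lt(abs(n_consang - 47), 3 * sqrt(146 * 0.32 * 0.68) + 1)

  # parental ages nondecreasing in birth order within each family
  kids <- dplyr::arrange(ped[ped$role == "child", ],
                         family_id, birth_order)
  by_fam <- split(kids$father_age, kids$family_id)
  expect_true(all(vapply(by_fam, function(a) !is.unsorted(a), logical(1))))
})

test_that("cohort-level parental age medians sit at 34 and 29", {
  ped <- sim_pedigree(sim_config(n_families = 146), seed = 8)
  kids <- ped[ped$role == "child", ]
  expect_lt(abs(median(kids$father_age) - 34), 1.5)
  expect_lt(abs(median(kids$mother_age) - 29), 1.5)
})

test_that("genotypes are Mendelian-consistent and HWE-plausible", {
  co <- small_cohort()
  g <- co$genotypes
  ped <- co$pedigree
  d <- geno_dosage(g)
  kids <- ped[ped$role == "child", ]
  for (i in seq_len(nrow(kids))) {
    fa <- d[, kids$father_id[i]]
    mo <- d[, kids$mother_id[i]]
    hf <- g$hap_f[, kids$individual_id[i]]
    hm <- g$hap_m[, kids$individual_id[i]]
    # an allele transmitted by a parent must exist in that parent
    expect_true(all(hf[fa == 0] == 0))
    expect_true(all(hf[fa == 2] == 1))
    expect_true(all(hm[mo == 0] == 0))
    expect_true(all(hm[mo == 2] == 1))
  }
  expect_error(sim_genotypes(empty_ped <- sim_pedigree(sim_config(0)),
                             co$reference),
               class = "dnmtrio_input_error")
})

test_that("planted DNM counts follow the configured generative model", {
  set.seed(21)
  ref <- sim_reference(2e5, 0.41)
  trk <- sim_methylation_track(ref, 0.69)
  cfg <- sim_config(n_families = 40,
                    offspring_probs = c(0, 0, 1, rep(0, 7)))
  ped <- sim_pedigree(cfg)
  # fix every conception at the reference ages
  ped$father_age[ped$role == "child"] <- 34
  ped$mother_age[ped$role == "child"] <- 29
  truth <- sim_dnms(ped, ref, trk, cfg)
  counts <- table(factor(truth$child_id[truth$variant_class == "SNV"],
                         ped$individual_id[ped$role == "child"]))
  n <- length(counts)
  # mean SNV count ~ dnm_base_count at reference ages
  expect_lt(abs(mean(counts) - 70), 4 * sqrt(70 / n))
  # ~80% paternal
  pf <- mean(truth$origin == "paternal")
  expect_lt(abs(pf - 0.8), 0.03)
})

test_that("degenerate plant settings behave as stated", {
  ref <- sim_reference(5e4, 0.41, seed = 2)
  trk <- sim_methylation_track(ref, 0.69, seed = 2)
  cfg <- sim_config(n_families = 4, paternal_fraction = 1)
  ped <- sim_pedigree(cfg, seed = 3)
  truth <- sim_dnms(ped, ref, trk, cfg, seed = 3)
  snvs <- truth[truth$variant_class == "SNV", ]
  expect_true(all(snvs$origin == "paternal"))
  # CpG flags agree with the reference CpG map
  expect_identical(truth$cpg, truth$pos %in% cpg_covered_positions(ref))

  # negative expected count is clamped with a warning
  cfg2 <- sim_config(n_families = 2, dnm_base_count = 1,
                     paternal_age_slope = 5)
  ped2 <- sim_pedigree(cfg2, seed = 4)
  ped2$father_age[ped2$role == "child"] <- 21
  expect_warning(sim_dnms(ped2, ref, trk, cfg2, seed = 4), "clamped")
})

test_that("zero-error tool simulation reproduces the truth in every tool", {
  co <- clean_cohort()
  for (tl in c("freebayes", "varscan", "rufus")) {
    calls <- co$calls[co$calls$tool == tl, ]
    expect_equal(nrow(calls), nrow(co$truth))
    expect_setequal(paste(calls$child_id, calls$pos, calls$ref, calls$alt),
                    paste(co$truth$child_id, co$truth$pos, co$truth$ref,
                          co$truth$alt))
    expect_true(all(calls$truth_tag == "true"))
  }
})

test_that("truth tags partition noisy call sets and FPs are tool-unique", {
  co <- small_cohort()
  calls <- co$calls
  expect_true(all(calls$truth_tag %in%
                    c("true", "artifact", "false_positive")))
  fp <- calls[calls$truth_tag == "false_positive", ]
  per_variant <- dplyr::count(fp, child_id, pos, ref, alt)
  expect_true(all(per_variant$n == 1))
  # artifacts originate from a parental variant
  art <- attr(calls, "artifacts")
  expect_gt(nrow(art), 0)
  d <- geno_dosage(co$genotypes)
  expect_true(all(d[cbind(art$marker_idx,
                          match(art$miscalled_parent,
                                co$genotypes$samples))] >= 1))
})

test_that("artifact calls are shared across carrier siblings", {
  co <- small_cohort()
  art_calls <- co$calls[co$calls$truth_tag == "artifact" &
                          co$calls$tool == "freebayes", ]
  skip_if(nrow(art_calls) == 0, "no artifacts drawn in fixture")
  carriers <- dplyr::count(art_calls, family_id, pos)
  # with multi-offspring families, at least some artifacts hit >= 2 siblings
  expect_gt(max(carriers$n), 1)
})

test_that("co-observations are absent without a nearby informative site", {
  co <- clean_cohort()
  few <- sim_coobservations(co$truth, co$genotypes, co$pedigree,
                            read_length = 1, depth = 30, seed = 1)
  expect_equal(nrow(few), 0)
})

test_that("the full cohort simulation is deterministic", {
  a <- simulate_cohort(small_config(), seed = 99)
  b <- simulate_cohort(small_config(), seed = 99)
  expect_identical(a$truth, b$truth)
  expect_identical(a$calls, b$calls)
  expect_identical(a$coobs, b$coobs)
  expect_identical(as.character(a$reference), as.character(b$reference))
})
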