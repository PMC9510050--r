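# one-marker trio: father het, mother hom-ref, child het (alt from father)
one_marker_setup <- function(father = c(f = 1, m = 0), mother = c(f = 0, m = 0),
                             child = c(f = 1, m = 0), marker_pos = 150L) {
  markers <- tibble::tibble(marker_id = "m1", pos = marker_pos, ref = "T",
                            alt = "C", maf = 0.3)
  geno <- make_genotypes(markers, list(
    F1_fa = list(f = father[["f"]], m = father[["m"]]),
    F1_mo = list(f = mother[["f"]], m = mother[["m"]]),
    F1_c1 = list(f = child[["f"]], m = child[["m"]])
  ))
  list(geno = geno, ped = make_trio_pedigree())
}

test_that("informative sites follow Mendelian attribution", {
  s <- one_marker_setup()
  trio <- trio_genotypes(s$geno, s$ped, "F1_c1")
  info <- find_informative_sites(trio, dnm_pos = 100, window = 150)
  expect_equal(nrow(info), 1)
  expect_equal(info$alt_parent, "father")
  expect_equal(info$distance, 50L)

  # both parents het: ambiguous
  amb <- one_marker_setup(father = c(f = 1, m = 0), mother = c(f = 1, m = 0))
  trio2 <- trio_genotypes(amb$geno, amb$ped, "F1_c1")
  expect_equal(nrow(find_informative_sites(trio2, 100, 150)), 0)

  # homozygous-alternate father is informative even with a carrier mother
  hom <- one_marker_setup(father = c(f = 1, m = 1), mother = c(f = 1, m = 0),
                          child = c(f = 1, m = 0))
  trio3 <- trio_genotypes(hom$geno, hom$ped, "F1_c1")
  expect_equal(find_informative_sites(trio3, 100, 150)$alt_parent, "father")

  # outside the read window
  far <- one_marker_setup(marker_pos = 300L)
  trio4 <- trio_genotypes(far$geno, far$ped, "F1_c1")
  expect_equal(nrow(find_informative_sites(trio4, 100, 150)), 0)
})

test_that("phasing votes follow the read alleles and require unanimity", {
  s <- one_marker_setup()
  dnm <- tibble::tibble(child_id = "F1_c1", chrom = "chr1", pos = 100L,
                        ref = "A", alt = "G")
  reads <- function(alleles_at_marker, alleles_at_dnm) {
    n <- length(alleles_at_marker)
    tibble::tibble(
      read_id = rep(paste0("r", seq_len(n)), 2),
      child_id = "F1_c1",
      pos = c(rep(100L, n), rep(150L, n)),
      allele = c(alleles_at_dnm, alleles_at_marker)
    )
  }
  # three reads all carrying DNM alt + the father-attributed marker alt
  p <- phase_dnms(dnm, s$geno, s$ped, reads(c("C", "C", "C"),
                                            c("G", "G", "G")))
  expect_equal(p$phase, "paternal")
  expect_equal(p$n_votes, 3L)

  # DNM alt co-occurring with the marker ref votes for the other parent
  m <- phase_dnms(dnm, s$geno, s$ped, reads(c("T", "T"), c("G", "G")))
  expect_equal(m$phase, "maternal")

  # 2 votes father vs 1 mother: conflict -> unphased
  c1 <- phase_dnms(dnm, s$geno, s$ped, reads(c("C", "C", "T"),
                                             c("G", "G", "G")))
  expect_equal(c1$phase, "unphased")

  # reads without the DNM alternate cast no vote
  novote <- phase_dnms(dnm, s$geno, s$ped, reads(c("C", "C"), c("A", "A")))
  expect_equal(novote$phase, "unphased")
  expect_equal(novote$n_votes, 0L)

  # no co-observations at all
  empty <- phase_dnms(dnm, s$geno, s$ped,
                      tibble::tibble(read_id = character(),
                                     child_id = character(),
                                     pos = integer(), allele = character()))
  expect_equal(empty$phase, "unphased")
})

test_that("phasing never assigns an origin without supporting reads", {
  co <- small_cohort()
  f <- filter_tool_candidates(co$calls)
  dnms <- filter_family_sharing(
    m <- merge_consensus(f),
    family_genotype_table(m, co$genotypes, co$pedigree,
                          attr(co$calls, "artifacts")))
  ph <- phase_dnms(dnms, co$genotypes, co$pedigree, co$coobs)
  expect_true(all(ph$n_votes[ph$phase != "unphased"] >= 1))
})

test_that("swapping parental labels swaps every phased call", {
  s <- one_marker_setup()
  dnm <- tibble::tibble(child_id = "F1_c1", chrom = "chr1", pos = 100L,
                        ref = "A", alt = "G")
  co <- tibble::tibble(read_id = c("r1", "r1"), child_id = "F1_c1",
                       pos = c(100L, 150L), allele = c("G", "C"))
  p1 <- phase_dnms(dnm, s$geno, s$ped, co)

  # same genotypes, but the marker carrier is now the mother
  sw <- one_marker_setup(father = c(f = 0, m = 0), mother = c(f = 1, m = 0),
                         child = c(f = 0, m = 1))
  p2 <- phase_dnms(dnm, sw$geno, sw$ped, co)
  expect_equal(p1$phase, "paternal")
  expect_equal(p2$phase, "maternal")
})

test_that("noiseless phasing recovers the true origin exhaustively", {
  co <- clean_cohort()
  ph <- phase_dnms(co$truth, co$genotypes, co$pedigree, co$coobs)
  phased <- ph[ph$phase != "unphased", ]
  expect_gt(nrow(phased), 100)
  expect_identical(phased$phase, phased$origin)
})

test_that("phasing yield grows with marker density and read length", {
  yield <- function(n_markers, read_length) {
    cfg <- clean_config(n_markers = n_markers, read_length = read_length)
    co <- simulate_cohort(cfg, seed = 13)
    ph <- phase_dnms(co$truth, co$genotypes, co$pedigree, co$coobs,
                     window = read_length)
    mean(ph$phase != "unphased")
  }
  sparse <- yield(300, 150)
  dense <- yield(3000, 150)
  expect_gt(dense, sparse)
  short <- yield(1000, 75)
  long <- yield(1000, 300)
  expect_gt(long, short)
})

test_that("phasing summaries scale fractions to total DNM counts", {
  s <- summarize_phasing(2817, 720)
  expect_equal(round(s$ratio, 2), 3.91)
  expect_equal(s$n_phased, 3537)

  z <- summarize_phasing(0, 0)
  expect_true(is.na(z$paternal_fraction))
  expect_true(is.na(z$ratio))

  even <- summarize_phasing(10, 10, total = 40)
  expect_equal(even$ratio, 1)
  expect_equal(even$paternal_fraction, 0.5)
  expect_equal(even$scaled_paternal, 20)
  expect_equal(even$scaled_paternal + even$scaled_maternal, 40)

  # data-frame form: per-child rows with scaled counts
  d <- tibble::tibble(
    child_id = rep(c("a", "b"), c(4, 3)),
    phase = c("paternal", "paternal", "maternal", "unphased",
              "unphased", "unphased", "unphased")
  )
  ps <- summarize_phasing(d)
  a <- ps[ps$child_id == "a", ]
  expect_equal(a$paternal_fraction, 2 / 3)
  expect_equal(a$scaled_paternal, 4 * 2 / 3)
  b <- ps[ps$child_id == "b", ]
  expect_true(is.na(b$scaled_paternal)) # no phased DNMs
})
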