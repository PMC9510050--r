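# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# small noisy cohort used across modules
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_families = 12, reference_length = 2e5, n_markers = 2500),
    list(...)
  )
  do.call(sim_config, args)
}

small_cohort <- function() {
  fixture("small_cohort", function() simulate_cohort(small_config(), seed = 42))
}

# noiseless cohort: no false negatives/positives, no artifacts
clean_config <- function(...) {
  small_config(
    tool_error_profile = list(
      fn = c(freebayes = 0, varscan = 0, rufus = 0),
      fp_mean = c(freebayes = 0, varscan = 0, rufus = 0),
      artifact_mean = 0
    ),
    seq_error_rate = 0,
    ...
  )
}

clean_cohort <- function() {
  fixture("clean_cohort", function() simulate_cohort(clean_config(), seed = 7))
}

# hand-built genotypes container for phasing unit tests
make_genotypes <- function(markers, haps) {
  # haps: named list id -> list(f = vector, m = vector)
  as_mat <- function(field) {
    matrix(unlist(lapply(haps, `[[`, field)), nrow = nrow(markers),
           dimnames = list(NULL, names(haps)))
  }
  structure(
    list(markers = markers, samples = names(haps),
         hap_f = as_mat("f"), hap_m = as_mat("m")),
    class = "dnmtrio_genotypes"
  )
}

make_trio_pedigree <- function() {
  tibble::tibble(
    family_id = "F1",
    individual_id = c("F1_fa", "F1_mo", "F1_c1"),
    role = c("father", "mother", "child"),
    sex = c("male", "female", "male"),
    father_id = c(NA, NA, "F1_fa"),
    mother_id = c(NA, NA, "F1_mo"),
    birth_order = c(NA, NA, 1L),
    father_age = c(NA, NA, 34),
    mother_age = c(NA, NA, 29),
    population = "Middle-Eastern",
    consanguinity_class = "unrelated",
    n_offspring = 1L,
    phenotype = c(NA, NA, "Healthy")
  )
}

# candidate-call row with passing freebayes metrics; override as needed
candidate_row <- function(tool = "freebayes", pos = 100, ref = "A",
                          alt = "G", variant_class = "SNV", af = 0.5,
                          depth = 20, paf = 0, pam = 0, qual = 45,
                          tags = "PASS", p = NA_real_,
                          child_id = "c1") {
  tibble::tibble(
    tool = tool, child_id = child_id, family_id = "F1", chrom = "chr1",
    pos = pos, ref = ref, alt = alt, variant_class = variant_class,
    child_alt_fraction = af, child_depth = depth,
    parent_alt_depth_father = paf, parent_alt_depth_mother = pam,
    qual = qual, tags = tags, tool_p = p
  )
}
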