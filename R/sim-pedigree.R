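#' Simulate a multiplex-family pedigree
#'
#' Generates families of 1-10 offspring with parental ages at each child's
#' conception. Fathers' ages at first conception are drawn around 30.5 years
#' and mothers' around 25.5, and successive births are spaced 2-3 years apart,
#' so that across all resulting trios the median father's age is close to 34
#' and the median mother's age close to 29. A configurable fraction of
#' families is planted as consanguineous, split evenly between a closer class
#' (half-sibling parents, expected kinship 1/8, falling in the 0.0884-0.177
#' window) and a more distant class (first-cousin parents, expected kinship
#' 1/16, falling in the 0.0442-0.0884 window). Population and phenotype labels
#' are drawn from realistic cohort proportions.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per individual: `family_id`,
#'   `individual_id`, `role` (father/mother/child), `sex`, `father_id`,
#'   `mother_id`, `birth_order`, `father_age`, `mother_age` (years at this
#'   child's conception; `NA` for parents), `phenotype`, `population`,
#'   `consanguinity_class`, `n_offspring`.
#' @export
#' @examples
#' ped <- sim_pedigree(sim_config(n_families = 5), seed = 1)
#' dplyr::count(ped, role)
sim_pedigree <- function(config, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_families
  if (n == 0) return(empty_pedigree())

  fam_id <- sprintf("F%03d", seq_len(n))
  n_off <- sample(1:10, n, replace = TRUE, prob = config$offspring_probs)
  consang <- runif(n) < config$consanguinity_fraction
  consang_class <- ifelse(
    !consang, "unrelated",
    ifelse(runif(n) < 0.5, "first_degree_cousins", "second_degree_cousins")
  )
  population <- sample(
    c("Middle-Eastern", "South-Asian", "African", "Caucasian", "Other"),
    n, replace = TRUE, prob = c(207, 67, 33, 21, 25)
  )
  father_age1 <- pmin(pmax(round(rnorm(n, 30.5, 5)), 21), 46)
  mother_age1 <- pmin(pmax(father_age1 - 5 + round(rnorm(n, 0, 2.5)), 16), 40)

  fams <- purrr::map(seq_len(n), function(i) {
    k <- n_off[i]
    gaps <- c(0, cumsum(sample(2:3, max(k - 1, 0), replace = TRUE)))
    parents <- tibble::tibble(
      family_id = fam_id[i],
      individual_id = paste0(fam_id[i], c("_fa", "_mo")),
      role = c("father", "mother"),
      sex = c("male", "female"),
      father_id = NA_character_, mother_id = NA_character_,
      birth_order = NA_integer_,
      father_age = NA_real_, mother_age = NA_real_
    )
    children <- tibble::tibble(
      family_id = fam_id[i],
      individual_id = sprintf("%s_c%d", fam_id[i], seq_len(k)),
      role = "child",
      sex = sample(c("male", "female"), k, replace = TRUE, prob = c(190, 163)),
      father_id = paste0(fam_id[i], "_fa"),
      mother_id = paste0(fam_id[i], "_mo"),
      birth_order = seq_len(k),
      father_age = father_age1[i] + gaps,
      mother_age = mother_age1[i] + gaps
    )
    dplyr::bind_rows(parents, children)
  })
  ped <- dplyr::bind_rows(fams)
  fam_meta <- tibble::tibble(
    family_id = fam_id,
    population = population,
    consanguinity_class = consang_class,
    n_offspring = n_off
  )
  ped <- dplyr::left_join(ped, fam_meta, by = "family_id")
  n_children <- sum(ped$role == "child")
  ped$phenotype <- NA_character_
  ped$phenotype[ped$role == "child"] <- sample(
    c("Neurogenetic", "Craniofacial", "Endocrine", "Multi-system",
      "Other", "Healthy"),
    n_children, replace = TRUE, prob = c(92, 17, 9, 17, 25, 193)
  )
  ped
}

empty_pedigree <- function() {
  tibble::tibble(
    family_id = character(), individual_id = character(), role = character(),
    sex = character(), father_id = character(), mother_id = character(),
    birth_order = integer(), father_age = numeric(), mother_age = numeric(),
    population = character(), consanguinity_class = character(),
    n_offspring = integer(), phenotype = character()
  )
}
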