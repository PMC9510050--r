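#' Informative inherited heterozygous sites near a DNM
#'
#' An informative site is one where the child is heterozygous and Mendelian
#' rules attribute each of its alleles to exactly one parent: the alternate
#' allele comes from the father when the mother carries no copy (and the
#' father at least one), or when the father is homozygous alternate (and the
#' mother is not); symmetrically for the mother. Sites where both parents
#' could have donated either allele are ambiguous and skipped.
#'
#' @param trio A trio genotype tibble ([trio_genotypes()]): columns `pos`,
#'   `ref`, `alt`, `child_dos`, `father_dos`, `mother_dos`.
#' @param dnm_pos DNM position (1-based).
#' @param window Maximum distance in bases (read length; co-observation on
#'   one read requires distance < read length).
#' @return Tibble of qualifying sites: `pos`, `ref`, `alt`, `alt_parent`
#'   ("father"/"mother"), `distance`; empty when none qualify.
#' @export
find_informative_sites <- function(trio, dnm_pos, window = 150) {
  near <- dplyr::filter(trio,
                        abs(.data$pos - dnm_pos) <= (window - 1),
                        .data$pos != dnm_pos,
                        .data$child_dos == 1)
  if (nrow(near) == 0) return(informative_empty())
  alt_parent <- attribute_alt(near$father_dos, near$mother_dos)
  out <- dplyr::mutate(near, alt_parent = alt_parent,
                       distance = abs(.data$pos - dnm_pos))
  out <- dplyr::filter(out, !is.na(.data$alt_parent))
  dplyr::select(out, "pos", "ref", "alt", "alt_parent", "distance")
}

informative_empty <- function() {
  tibble::tibble(pos = integer(), ref = character(), alt = character(),
                 alt_parent = character(), distance = integer())
}

# Mendelian attribution of the child's alternate allele at a het site.
attribute_alt <- function(father_dos, mother_dos) {
  dplyr::case_when(
    mother_dos == 0 & father_dos >= 1 ~ "father",
    father_dos == 0 & mother_dos >= 1 ~ "mother",
    father_dos == 2 & mother_dos < 2 ~ "father",
    mother_dos == 2 & father_dos < 2 ~ "mother",
    .default = NA_character_
  )
}

#' Phase DNMs from read-level co-observations
#'
#' For each read covering both a DNM and an informative site: a read carrying
#' the DNM alternate allele together with the informative allele attributed
#' to parent P votes for P; carrying the DNM alternate with the site's other
#' allele votes for the other parent. Reads not carrying the DNM alternate
#' cast no vote. A DNM is phased only on unanimous votes; any conflict, or no
#' votes at all, leaves it unphased. Co-observations at positions that are
#' not informative sites of that child are skipped.
#'
#' @param dnms DNM tibble (`child_id`, `pos`, `ref`, `alt`).
#' @param genotypes A `dnmtrio_genotypes` object.
#' @param pedigree Pedigree tibble.
#' @param coobs Co-observation tibble (`read_id`, `child_id`, `pos`,
#'   `allele`).
#' @param window Read length in bases.
#' @return `dnms` with added columns `phase`
#'   ("paternal"/"maternal"/"unphased") and `n_votes`.
#' @export
phase_dnms <- function(dnms, genotypes, pedigree, coobs, window = 150) {
  dnms$phase <- "unphased"
  dnms$n_votes <- 0L
  if (nrow(dnms) == 0 || nrow(coobs) == 0) return(dnms)

  dosage <- geno_dosage(genotypes)
  dn_split <- split(dnms[, c("child_id", "pos", "ref", "alt")],
                    dnms$child_id)
  co_split <- split(coobs, coobs$child_id)
  votes_all <- vector("list", length(dn_split))
  k <- 0
  for (cid in names(dn_split)) {
    dn <- dn_split[[cid]]
    co <- co_split[[cid]]
    if (is.null(co) || nrow(co) == 0) next
    trio <- trio_genotypes(genotypes, pedigree, cid, dosage = dosage)
    info <- dplyr::mutate(
      trio[trio$child_dos == 1, ],
      alt_parent = attribute_alt(.data$father_dos, .data$mother_dos)
    )
    info <- info[!is.na(info$alt_parent),
                 c("pos", "ref", "alt", "alt_parent")]
    if (nrow(info) == 0) next

    # reads carrying the DNM alternate allele (base match: a read covers at
    # most one DNM of a child in practice; duplicates handled by read pairing)
    di <- match(co$pos, dn$pos)
    sel_d <- !is.na(di) & co$allele == dn$alt[di]
    if (!any(sel_d)) next
    dn_read <- co$read_id[sel_d]
    dn_pos_by_read <- dn$pos[di[sel_d]]

    # observations on the same reads at informative sites
    si <- match(co$pos, info$pos)
    sel_s <- !is.na(si)
    if (!any(sel_s)) next
    ri <- match(co$read_id[sel_s], dn_read)
    hit <- !is.na(ri)
    if (!any(hit)) next
    s_idx <- which(sel_s)[hit]
    site_row <- si[s_idx]
    dnm_pos <- dn_pos_by_read[ri[hit]]
    site_pos <- co$pos[s_idx]
    ok <- abs(site_pos - dnm_pos) <= (window - 1) & site_pos != dnm_pos
    if (!any(ok)) next
    allele <- co$allele[s_idx][ok]
    sref <- info$ref[site_row][ok]
    salt <- info$alt[site_row][ok]
    aparent <- info$alt_parent[site_row][ok]
    vote <- ifelse(allele == salt, aparent,
                   ifelse(allele == sref,
                          ifelse(aparent == "father", "mother", "father"),
                          NA_character_))
    keep <- !is.na(vote)
    if (!any(keep)) next
    k <- k + 1
    votes_all[[k]] <- tibble::tibble(
      child_id = cid,
      dnm_pos = dnm_pos[ok][keep],
      vote = vote[keep]
    )
  }
  votes_all <- dplyr::bind_rows(votes_all)
  if (nrow(votes_all) == 0) return(dnms)
  votes_all <- dplyr::summarise(
    dplyr::group_by(votes_all, .data$child_id, .data$dnm_pos),
    n_votes = dplyr::n(),
    n_father = sum(.data$vote == "father"),
    .groups = "drop"
  )
  votes_all$phase_new <- dplyr::case_when(
    votes_all$n_father == votes_all$n_votes ~ "paternal",
    votes_all$n_father == 0 ~ "maternal",
    .default = "unphased"
  )
  m <- match(paste(dnms$child_id, dnms$pos),
             paste(votes_all$child_id, votes_all$dnm_pos))
  hit <- !is.na(m)
  dnms$phase[hit] <- votes_all$phase_new[m[hit]]
  dnms$n_votes[hit] <- votes_all$n_votes[m[hit]]
  dnms
}

#' Summarize parent-of-origin phasing
#'
#' Given a phased DNM table, computes per-child counts of paternally and
#' maternally phased DNMs, the paternal fraction among phased DNMs, the
#' paternal:maternal ratio, and the phased fractions scaled to the child's
#' total DNM count (`scaled = fraction x total`, kept real-valued for
#' regression input). Called with two counts instead, it returns the single
#' cohort-level summary row.
#'
#' @param x A phased DNM tibble (with `child_id` and `phase`), or the number
#'   of paternally phased DNMs.
#' @param n_maternal Number of maternally phased DNMs (count form only).
#' @param total Total DNM count(s) for scaling; optional in the count form.
#' @return Tibble with `n_phased`, `n_paternal`, `n_maternal`,
#'   `paternal_fraction`, `ratio` (`NA` when no maternal DNMs), and scaled
#'   counts when `total` is available (per child in the data-frame form).
#' @export
#' @examples
#' summarize_phasing(2817, 720) # ratio ~3.91
summarize_phasing <- function(x, n_maternal = NULL, total = NULL) {
  if (is.data.frame(x)) {
    tot <- dplyr::count(x, .data$child_id, name = "total_dnms")
    ph <- dplyr::summarise(
      dplyr::group_by(x, .data$child_id),
      n_paternal = sum(.data$phase == "paternal"),
      n_maternal = sum(.data$phase == "maternal"),
      .groups = "drop"
    )
    ph <- dplyr::left_join(ph, tot, by = "child_id")
    return(dplyr::bind_cols(
      ph["child_id"],
      phasing_row(ph$n_paternal, ph$n_maternal, ph$total_dnms)
    ))
  }
  if (is.null(n_maternal)) {
    abort("supply a phased DNM table or two counts",
          class = "dnmtrio_input_error")
  }
  phasing_row(x, n_maternal, total)
}

phasing_row <- function(n_paternal, n_maternal, total = NULL) {
  stopifnot(all(n_paternal >= 0), all(n_maternal >= 0))
  n_phased <- n_paternal + n_maternal
  out <- tibble::tibble(
    n_phased = n_phased,
    n_paternal = n_paternal,
    n_maternal = n_maternal,
    paternal_fraction = ifelse(n_phased > 0, n_paternal / n_phased, NA_real_),
    ratio = ifelse(n_maternal > 0, n_paternal / n_maternal, NA_real_)
  )
  if (!is.null(total)) {
    out$total_dnms <- total
    out$scaled_paternal <- out$paternal_fraction * total
    out$scaled_maternal <- (1 - out$paternal_fraction) * total
  }
  out
}
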