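# Species-level aggregation of architecture calls: does a species carry a
# CZB-regulated chemoreceptor, a CZB-regulated diguanylate cyclase, both,
# or neither?  EAL-CZB, CheW-CZB and CZB-only proteins count toward
# neither class (they transduce or degrade, not sense or synthesize).

#' Aggregate architecture calls to species summaries
#'
#' Joins calls to taxonomy by `protein_id`; proteins lacking a species
#' mapping are excluded and counted in the `unmapped` attribute.  The
#' species category derives from the union of its proteins' subgroups.
#'
#' @param arch_calls an architecture table (protein_id, subgroup, ...).
#' @param taxonomy data.frame with protein_id, species, phylum and
#'   optionally candidate_phylum_flag.
#' @param normalize_species case-fold species names before grouping.
#' @param strip_strain drop strain codes after a `sp.` token
#'   (`"Genus sp. ABC123"` -> `"Genus sp."`).
#' @return data.frame (class `"species_summary"`): species, phylum,
#'   candidate_phylum, subgroups_present (comma-joined), category in
#'   chemoreceptor_only / dgc_only / both / neither.
#' @export
aggregate_species <- function(arch_calls, taxonomy,
                              normalize_species = FALSE,
                              strip_strain = FALSE) {
  tax <- taxonomy
  if (is.null(tax$candidate_phylum_flag)) tax$candidate_phylum_flag <- FALSE
  sp <- tax$species[match(arch_calls$protein_id, tax$protein_id)]
  unmapped <- sum(is.na(sp) | !nzchar(sp))
  keep <- !is.na(sp) & nzchar(sp)
  calls <- arch_calls[keep, , drop = FALSE]
  sp <- sp[keep]
  if (strip_strain) sp <- sub("(sp\\.)\\s+\\S+.*$", "\\1", sp)
  if (normalize_species) sp <- tolower(sp)
  key <- match(sp, tax$species)
  if (normalize_species) key <- match(sp, tolower(tax$species))
  if (strip_strain) {
    tax_sp <- sub("(sp\\.)\\s+\\S+.*$", "\\1", tax$species)
    if (normalize_species) tax_sp <- tolower(tax_sp)
    key <- match(sp, tax_sp)
  }
  phylum <- tax$phylum[key]
  candidate <- tax$candidate_phylum_flag[key]
  rows <- lapply(split(seq_along(sp), sp), function(idx) {
    subs <- sort(unique(calls$subgroup[idx]))
    chem <- any(subs %in% CHEMO_SUBGROUPS)
    dgc <- any(subs %in% DGC_SUBGROUPS)
    category <- if (chem && dgc) "both" else if (chem) "chemoreceptor_only"
      else if (dgc) "dgc_only" else "neither"
    data.frame(species = sp[idx[1]],
               phylum = if (is.na(phylum[idx[1]]) ||
                            !nzchar(phylum[idx[1]])) "unclassified"
                        else phylum[idx[1]],
               candidate_phylum = isTRUE(candidate[idx[1]]),
               subgroups_present = paste(subs, collapse = ","),
               category = category, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), phylum = character(),
               candidate_phylum = logical(),
               subgroups_present = character(), category = character())
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Count species co-occurrence categories
#'
#' @param summaries an [aggregate_species()] table.
#' @return named integer vector: chemoreceptor_only, dgc_only, both,
#'   neither (sums to the number of species).
#' @export
category_counts <- function(summaries) {
  lev <- c("chemoreceptor_only", "dgc_only", "both", "neither")
  cnt <- table(factor(summaries$category, levels = lev))
  stats::setNames(as.integer(cnt), lev)
}

#' Phylum distribution of CZB-containing species
#'
#' @param summaries an [aggregate_species()] table.
#' @return list with `per_phylum` (named species counts),
#'   `n_phyla` (distinct non-candidate phyla) and `n_candidate_phyla`
#'   (distinct candidate phyla).
#' @export
phylum_distribution <- function(summaries) {
  per <- table(summaries$phylum)
  cand_by_phylum <- tapply(summaries$candidate_phylum, summaries$phylum,
                           any)
  list(per_phylum = stats::setNames(as.integer(per), names(per)),
       n_phyla = sum(!unlist(cand_by_phylum)),
       n_candidate_phyla = sum(unlist(cand_by_phylum)))
}
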