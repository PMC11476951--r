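# Orthologue-conservation summaries across target species.

#' Read an orthologue pairing table
#'
#' Tab-separated with header `gene_id`, `target_species`, `orthologue_id`
#' (BioMart-style export).  An empty `orthologue_id` means no match in that
#' species; one-to-many orthologies appear as repeated rows.
#'
#' @param path path to the TSV file.
#' @return data.frame with the three columns as character.
#' @export
read_orthologues <- function(path) {
  if (!file.exists(path)) stop_arg("orthologue file not found: ", path)
  orth <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = NULL)
  assert_df_cols(orth, c("gene_id", "target_species", "orthologue_id"),
                 "orthologue table")
  orth
}

matched_genes <- function(orth, species) {
  unique(orth$gene_id[orth$target_species == species &
                        !is.na(orth$orthologue_id) &
                        nzchar(orth$orthologue_id)])
}

#' Per-group orthologue conservation
#'
#' A gene counts as matched in `species` iff it has at least one non-empty
#' orthologue entry for that species (one-to-many rows and duplicates
#' collapse to presence/absence).  Genes absent from the table count as
#' unmatched.
#'
#' @param catalogue catalogue data.frame with `gene_id` and `group`.
#' @param orth orthologue table (see [read_orthologues()]).
#' @param species target species name; must occur in `orth$target_species`.
#' @param total also append an `"(all)"` row for the whole catalogue.
#' @return data.frame with `group`, `n_total`, `n_matched`, `percent`
#'   (half-up, one decimal).  Groups with zero genes are omitted.
#' @export
conservation_by_group <- function(catalogue, orth, species, total = FALSE) {
  assert_df_cols(catalogue, c("gene_id", "group"), "catalogue")
  avail <- unique(orth$target_species)
  if (!species %in% avail) {
    stop_arg("species '", species, "' not present in orthologue table; ",
             "available: ", paste(sort(avail), collapse = ", "))
  }
  n_absent <- sum(!catalogue$gene_id %in% unique(orth$gene_id))
  if (n_absent > 0) {
    message(n_absent, " catalogue gene(s) absent from the orthologue table; counted as unmatched")
  }
  hit <- catalogue$gene_id %in% matched_genes(orth, species)
  tab <- function(sel, label) {
    data.frame(group = label, n_total = sum(sel),
               n_matched = sum(sel & hit), stringsAsFactors = FALSE)
  }
  groups <- sort(unique(catalogue$group))
  out <- do.call(rbind, lapply(groups, function(g) tab(catalogue$group == g, g)))
  if (total) out <- rbind(out, tab(rep(TRUE, nrow(catalogue)), "(all)"))
  out$percent <- round_half_up(100 * out$n_matched / out$n_total, 1)
  rownames(out) <- NULL
  out
}

#' Genes without orthologues in every listed species
#'
#' Returns the gene ids that lack an orthologue in *each* of the listed
#' species — candidate lineage-specific genes.  An empty `species_list`
#' yields no calls (no evidence of absence has been examined).
#'
#' @param catalogue catalogue data.frame with `gene_id`.
#' @param orth orthologue table.
#' @param species_list character vector of target species.
#' @return character vector of gene ids, in catalogue order.
#' @export
lineage_specific_genes <- function(catalogue, orth, species_list) {
  if (!length(species_list)) return(character())
  matched_any <- unique(unlist(lapply(species_list, matched_genes, orth = orth)))
  catalogue$gene_id[!catalogue$gene_id %in% matched_any]
}
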