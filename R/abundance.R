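#' Remove plant-organelle OTUs
#'
#' Drops OTUs whose lineage contains a chloroplast or mitochondrial token at
#' any rank (case-insensitive substring match; reference taxonomies place
#' chloroplasts at class and mitochondria at family level). OTUs absent from
#' the taxonomy are kept.
#'
#' @param counts OTU table tibble.
#' @param taxonomy Taxonomy tibble (see [read_taxonomy]).
#' @param quiet Suppress the message reporting how many OTUs were removed.
#' @return The filtered OTU table.
#' @export
filter_organelles <- function(counts, taxonomy, quiet = FALSE) {
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  rank_cols <- intersect(taxonomy_ranks, names(taxonomy))
  hit <- purrr::map(rank_cols, function(rk) {
    v <- tolower(as.character(taxonomy[[rk]]))
    grepl("chloroplast|mitochondri", v)
  })
  organelle <- Reduce(`|`, hit)
  bad_ids <- taxonomy$otu_id[organelle]
  keep <- !(counts$otu_id %in% bad_ids)
  n_rm <- sum(!keep)
  if (!quiet) inform(paste0("filter_organelles: removed ", n_rm, " OTU(s)."))
  out <- counts[keep, , drop = FALSE]
  if (nrow(out) == 0L) warn("All OTUs were removed as organellar.")
  out
}

#' Per-sample relative abundance
#'
#' Divides every sample column by its total so that each sample sums to one.
#'
#' @param counts OTU table tibble (counts or any non-negative values).
#' @return Tibble with the same shape, entries in \[0, 1\].
#' @export
relative_abundance <- function(counts) {
  counts <- validate_otu_table(counts, integer_counts = FALSE)
  samp <- setdiff(names(counts), "otu_id")
  totals <- vapply(counts[samp], sum, numeric(1))
  zero <- samp[totals == 0]
  if (length(zero)) {
    abort(paste0("Zero-total sample(s): ", paste(zero, collapse = ", ")))
  }
  for (s in samp) counts[[s]] <- counts[[s]] / totals[[s]]
  counts
}

#' Aggregate relative abundances to a taxonomic rank
#'
#' Sums proportions within each taxon at the requested rank. OTUs lacking the
#' rank (or missing from the taxonomy) are pooled into `"Unclassified"`, so
#' per-sample totals are conserved. With `split_proteobacteria = TRUE` and
#' `level = "phylum"`, OTUs of phylum Proteobacteria are reported by class
#' instead (Alphaproteobacteria, Betaproteobacteria, ...; those without a
#' class become `"unclassified Proteobacteria"`), the convention used when
#' summarising amplicon surveys at phylum level.
#'
#' @param rel Relative abundance table (from [relative_abundance]).
#' @param taxonomy Taxonomy tibble.
#' @param level Rank to aggregate at: one of domain, phylum, class, order,
#'   family, genus.
#' @param split_proteobacteria Report Proteobacteria by class when aggregating
#'   at phylum level.
#' @return Tibble `taxon` x sample columns; columns sum as in `rel`.
#' @export
aggregate_taxa <- function(rel, taxonomy, level = "phylum",
                           split_proteobacteria = FALSE) {
  level <- match.arg(level, taxonomy_ranks)
  rel <- validate_otu_table(rel, integer_counts = FALSE)
  samp <- setdiff(names(rel), "otu_id")
  tax <- as_tibble(taxonomy)
  lab <- tax[[level]][match(rel$otu_id, tax$otu_id)]
  lab[is.na(lab)] <- "Unclassified"
  if (split_proteobacteria && level == "phylum") {
    idx <- match(rel$otu_id, tax$otu_id)
    phy <- tax$phylum[idx]
    cls <- tax$class[idx]
    is_proteo <- !is.na(phy) & phy == "Proteobacteria"
    lab[is_proteo] <- ifelse(is.na(cls[is_proteo]),
                             "unclassified Proteobacteria", cls[is_proteo])
  }
  rel |>
    mutate(taxon = lab) |>
    group_by(.data$taxon) |>
    summarise(across(all_of(samp), sum), .groups = "drop") |>
    arrange(desc(rowSums(across(all_of(samp)))))
}
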