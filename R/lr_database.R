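## Ligand-receptor database assembly: reference pairs (established) plus
## candidate pairs from differentially expressed genes gated by subcellular
## localization and experimentally validated PPI partners.

#' Is a gene eligible to seed candidate ligand-receptor pairs?
#'
#' Eligible classes are `plasma_membrane`, `secreted` and
#' `extracellular_matrix`. A gene absent from the annotation is ineligible
#' (positive evidence of localization is required); a warning is logged.
#' Annotation lookup is case-insensitive, but gene symbols keep their
#' original case everywhere else (case encodes pair provenance in display
#' names).
#'
#' @param gene Gene symbol(s).
#' @param genes Gene annotation tibble (see [read_gene_annotation()]).
#' @return Logical vector.
#' @export
eligible_for_candidacy <- function(gene, genes) {
  idx <- match(tolower(gene), tolower(genes$gene))
  absent <- is.na(idx)
  if (any(absent)) {
    warn(sprintf(
      "%d gene(s) absent from the annotation treated as ineligible (e.g. %s)",
      sum(absent), dQuote(gene[which(absent)[1]])
    ))
  }
  out <- rep(FALSE, length(gene))
  out[!absent] <- genes$localization_class[idx[!absent]] %in% ELIGIBLE_CLASSES
  out
}

#' Experimentally validated interaction partners of a gene
#'
#' Neighbors of `gene` in the PPI network whose edge carries the
#' experimental-evidence flag. Edges are undirected, so
#' `r %in% validated_partners(l, ppi)` iff `l %in% validated_partners(r, ppi)`.
#'
#' @param gene A single gene symbol.
#' @param ppi PPI edge tibble (see [read_ppi()]).
#' @return Character vector of partner genes (possibly empty).
#' @export
validated_partners <- function(gene, ppi) {
  hit <- ppi$experimental & (ppi$gene_a == gene | ppi$gene_b == gene)
  unique(c(ppi$gene_b[hit & ppi$gene_a == gene], ppi$gene_a[hit & ppi$gene_b == gene]))
}

lr_display_name <- function(ligand, receptor, provenance) {
  ifelse(provenance == "established",
    paste0(toupper(ligand), "\u2013", toupper(receptor)),
    paste0(ligand, "\u2013", receptor)
  )
}

#' Assemble the ligand-receptor database
#'
#' The database contains every reference pair (provenance `established`,
#' displayed in uppercase, e.g. "PDGFB-PDGFRB") plus, for each
#' differentially expressed gene that passes the localization gate, the
#' ordered pairs `(gene, partner)` and `(partner, gene)` for each
#' experimentally validated PPI partner (provenance `candidate`, displayed
#' in the original symbol case, e.g. "Bsg-Itga6"). Candidate pairs are added
#' in both directions because differential expression does not reveal which
#' member acts as the ligand; direction is resolved empirically by which
#' orientation scores significantly. Duplicates resolve in favor of
#' `established`. Order is deterministic: reference pairs first (input
#' order), then candidates sorted lexicographically.
#'
#' @param reference Reference pair tibble (see [read_reference_pairs()]).
#' @param de_tables A single DE tibble from [wilcoxon_de()] or a list of
#'   them (e.g. capillary ECs and astrocytes).
#' @param genes Gene annotation tibble.
#' @param ppi PPI edge tibble.
#' @param max_p_adjusted DE genes must have `p_adjusted` below this to seed
#'   candidates.
#' @return A tibble: `ligand`, `receptor`, `provenance`, `display_name`.
#' @export
build_database <- function(reference, de_tables, genes, ppi, max_p_adjusted = 0.05) {
  if (inherits(de_tables, "data.frame")) de_tables <- list(de_tables)
  de_genes <- unique(unlist(lapply(de_tables, function(d) d$gene[d$p_adjusted < max_p_adjusted])))
  if (nrow(reference) == 0L && length(de_genes) == 0L) {
    abort("empty database: no reference pairs and no differentially expressed genes")
  }
  db <- tibble::tibble(
    ligand = reference$ligand, receptor = reference$receptor,
    provenance = rep("established", nrow(reference))
  )
  seeds <- de_genes[eligible_for_candidacy(de_genes, genes)]
  if (length(seeds) > 0L) {
    cand <- dplyr::bind_rows(lapply(sort(seeds), function(g) {
      partners <- sort(validated_partners(g, ppi))
      if (length(partners) == 0L) return(NULL)
      tibble::tibble(
        ligand = c(rep(g, length(partners)), partners),
        receptor = c(partners, rep(g, length(partners))),
        provenance = "candidate"
      )
    }))
    if (!is.null(cand) && nrow(cand) > 0L) {
      cand <- dplyr::arrange(dplyr::distinct(cand), .data$ligand, .data$receptor)
      db <- rbind(db, cand)
    }
  }
  db <- db[!duplicated(paste(db$ligand, db$receptor)), ] # established listed first, so it wins
  if (nrow(db) == 0L) abort("empty database")
  db$display_name <- lr_display_name(db$ligand, db$receptor, db$provenance)
  validate_lr_database(db)
  db
}
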