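# Bundled reference count tables from a published genome-wide survey of
# duplicate genes in the bovine genome (Ensembl release 67 annotation). These
# are inputs to the summarization arithmetic, not outputs of this package:
# feeding them through the chromosome-summary and class-proportion operations
# reconstructs the published percentages.

#' Published bovine per-chromosome duplicate-gene counts
#'
#' Per chromosome: the number of annotated genes and the numbers of genes
#' participating in at least one intrachromosomal / interchromosomal duplicate
#' pair, overall and for the cattle-specific subset (genes whose duplicates
#' are observed only in the bovine genome). Gene counts, not pair counts; a
#' gene duplicated both ways is counted in both columns.
#'
#' @return A tibble in the [chromosome_summary_from_counts()] input layout.
#' @export
bovine_chromosome_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "bovine_duplicate_gene_counts.tsv",
      package = "dupdiverge", mustWork = TRUE
    ),
    col_types = readr::cols(
      chromosome = readr::col_character(), .default = readr::col_integer()
    )
  )
}

#' Published bovine structural-class counts of duplicate pairs
#'
#' Counts of duplicate gene pairs with different exon numbers (Class 1) and
#' with equal numbers but differing exon lengths (Class 2), for all pairs and
#' the cattle-specific subset.
#'
#' @return A tibble with columns `stratum`, `n_class1`, `n_class2`, `n_total`.
#' @export
bovine_structure_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "bovine_structure_class_counts.tsv",
      package = "dupdiverge", mustWork = TRUE
    ),
    col_types = readr::cols(
      stratum = readr::col_character(), .default = readr::col_integer()
    )
  )
}
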