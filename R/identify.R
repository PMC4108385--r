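# Duplicate-pair identification: reciprocal best hits from an all-vs-all
# protein alignment table, coverage and length-dependent identity criteria,
# pseudogene removal, locality/lineage classification and per-chromosome
# summaries.

#' Length-dependent identity threshold for duplicate calling
#'
#' The minimum alignment identity (fraction) required of a candidate duplicate
#' pair: a flat `constant` for alignments longer than `long_cutoff` amino
#' acids, and the homology-search curve
#' `0.01 n + 4.8 L^(-0.32 (1 + exp(-L/1000)))` for shorter alignments.
#'
#' @param aligned_length Alignment length(s) in amino acids.
#' @param constant Identity floor for long alignments (default 0.30).
#' @param long_cutoff Length above which `constant` applies (default 150 aa).
#' @param n_param Offset parameter `n` of the short-alignment curve (default 6).
#' @return Numeric vector of identity thresholds in `[0, 1]`.
#' @export
identity_threshold <- function(aligned_length, constant = 0.30,
                               long_cutoff = 150, n_param = 6) {
  L <- aligned_length
  short <- 0.01 * n_param + 4.8 * L^(-0.32 * (1 + exp(-L / 1000)))
  ifelse(L > long_cutoff, constant, short)
}

#' Reciprocal best hits from an all-vs-all alignment table
#'
#' For every ordered (query, subject) pair only the top-scoring HSP is kept
#' (bit score, then identity, then subject id as deterministic tie-breaks).
#' Each query's best subject is found with the same ordering, and a gene pair
#' is retained iff the choice is mutual. Pair metadata (identity, aligned
#' length, bit score) is taken from the higher-scoring direction.
#'
#' @param hits Alignment-hit tibble from [read_alignment_table()].
#' @return Tibble of candidate pairs: `gene_a` < `gene_b` lexicographically,
#'   `identity`, `aligned_length`, `bit_score`.
#' @export
reciprocal_best_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(
      gene_a = character(), gene_b = character(),
      identity = numeric(), aligned_length = numeric(), bit_score = numeric()
    ))
  }
  top_hsp <- hits |>
    dplyr::arrange(
      .data$query_id, .data$subject_id,
      dplyr::desc(.data$bit_score), dplyr::desc(.data$percent_identity)
    ) |>
    dplyr::distinct(.data$query_id, .data$subject_id, .keep_all = TRUE)
  best <- top_hsp |>
    dplyr::arrange(
      .data$query_id,
      dplyr::desc(.data$bit_score), dplyr::desc(.data$percent_identity),
      .data$subject_id
    ) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
  partner <- setNames(best$subject_id, best$query_id)
  mutual <- best[
    !is.na(partner[best$subject_id]) &
      partner[best$subject_id] == best$query_id, ,
    drop = FALSE
  ]
  if (nrow(mutual) == 0L) {
    return(tibble(
      gene_a = character(), gene_b = character(),
      identity = numeric(), aligned_length = numeric(), bit_score = numeric()
    ))
  }
  mutual |>
    dplyr::mutate(
      gene_a = pmin(.data$query_id, .data$subject_id),
      gene_b = pmax(.data$query_id, .data$subject_id)
    ) |>
    dplyr::arrange(
      .data$gene_a, .data$gene_b,
      dplyr::desc(.data$bit_score), dplyr::desc(.data$percent_identity),
      .data$query_id
    ) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    dplyr::transmute(
      gene_a = .data$gene_a, gene_b = .data$gene_b,
      identity = .data$percent_identity,
      aligned_length = .data$aligned_length,
      bit_score = .data$bit_score
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Apply the duplicate-pair coverage and identity criteria
#'
#' A candidate pair is kept iff its aligned region covers at least
#' `min_coverage` of the longer protein and its identity is at least
#' [identity_threshold()] of the aligned length.
#'
#' @param candidates Candidate pairs from [reciprocal_best_hits()].
#' @param proteins Protein tibble from [read_fasta()]; lengths are taken from
#'   it, and a gene missing from it is an error.
#' @param min_coverage Minimum fraction of the longer protein aligned.
#' @inheritParams identity_threshold
#' @return The surviving pairs with a `coverage` column added.
#' @export
apply_duplicate_criteria <- function(candidates, proteins, min_coverage = 0.8,
                                     constant = 0.30, long_cutoff = 150,
                                     n_param = 6) {
  lens <- setNames(nchar(proteins$residues), proteins$id)
  missing <- setdiff(unique(c(candidates$gene_a, candidates$gene_b)), names(lens))
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) missing from protein FASTA: %s",
      paste(missing, collapse = ", ")
    ))
  }
  candidates |>
    dplyr::mutate(
      # a global alignment with gaps in both sequences can span more columns
      # than the longer protein; coverage is capped at 1
      coverage = pmin(
        1,
        .data$aligned_length /
          pmax(unname(lens[.data$gene_a]), unname(lens[.data$gene_b]))
      ),
      .after = "aligned_length"
    ) |>
    dplyr::filter(
      .data$coverage >= min_coverage,
      .data$identity >= identity_threshold(
        .data$aligned_length, constant, long_cutoff, n_param
      )
    )
}

#' Remove pairs involving pseudogenes
#'
#' Any pair touching a gene whose biotype contains "pseudogene" is dropped.
#'
#' @param pairs Pair tibble with `gene_a`, `gene_b`.
#' @param gene_models Gene-model tibble; every pair member must be present.
#' @return The filtered pair tibble.
#' @export
filter_pseudogenes <- function(pairs, gene_models) {
  biotype <- setNames(gene_models$biotype, gene_models$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(biotype))
  if (length(missing) > 0L) {
    abort(sprintf(
      "gene(s) missing from gene models: %s",
      paste(missing, collapse = ", ")
    ))
  }
  is_pseudo <- grepl("pseudogene", biotype, fixed = TRUE)
  names(is_pseudo) <- names(biotype)
  pairs[!(is_pseudo[pairs$gene_a] | is_pseudo[pairs$gene_b]), , drop = FALSE]
}

#' Classify pairs by chromosomal locality and lineage
#'
#' Locality is `intra` iff both genes lie on the same chromosome. Lineage is
#' `species_specific` iff *both* genes are flagged lineage-specific (no
#' recorded homolog outside the focal species), else `shared`.
#'
#' @param pairs Pair tibble with `gene_a`, `gene_b`.
#' @param gene_models Gene-model tibble with `chromosome` and
#'   `lineage_specific` filled in.
#' @return The pairs with `locality` and `lineage` columns added.
#' @export
classify_pairs <- function(pairs, gene_models) {
  chrom <- setNames(gene_models$chromosome, gene_models$gene_id)
  ls <- setNames(gene_models$lineage_specific, gene_models$gene_id)
  pairs |>
    dplyr::mutate(
      locality = unname(ifelse(
        chrom[.data$gene_a] == chrom[.data$gene_b], "intra", "inter"
      )),
      lineage = unname(ifelse(
        ls[.data$gene_a] & ls[.data$gene_b], "species_specific", "shared"
      ))
    )
}

#' Per-chromosome duplicate-gene summary
#'
#' A gene is counted once per chromosome and locality class if it participates
#' in at least one pair of that class; a gene duplicated both intra- and
#' interchromosomally is therefore counted in both columns. Duplicate content
#' is `100 (intra + inter) / n_genes`.
#'
#' @param pairs Classified pairs from [classify_pairs()].
#' @param gene_models Gene-model tibble; supplies the per-chromosome gene
#'   totals.
#' @return A summary tibble (see [chromosome_summary_from_counts()]) with a
#'   final `All` genome row.
#' @export
summarize_by_chromosome <- function(pairs, gene_models) {
  chroms <- unique(gene_models$chromosome)
  chrom_of <- setNames(gene_models$chromosome, gene_models$gene_id)

  count_genes <- function(p, chr) {
    genes <- unique(c(p$gene_a, p$gene_b))
    sum(chrom_of[genes] == chr)
  }
  counts <- purrr::map_dfr(chroms, function(chr) {
    ss <- pairs[pairs$lineage == "species_specific", , drop = FALSE]
    tibble(
      chromosome = chr,
      n_genes = sum(gene_models$chromosome == chr),
      n_dup_intra = count_genes(pairs[pairs$locality == "intra", ], chr),
      n_dup_inter = count_genes(pairs[pairs$locality == "inter", ], chr),
      n_ss_intra = count_genes(ss[ss$locality == "intra", ], chr),
      n_ss_inter = count_genes(ss[ss$locality == "inter", ], chr)
    )
  })
  chromosome_summary_from_counts(counts)
}

#' Chromosome summary from raw per-chromosome counts
#'
#' The arithmetic core behind [summarize_by_chromosome()], usable directly on
#' published per-chromosome count tables: computes duplicate content
#' percentages, the genome (`All`) row, fold enrichment over the genome
#' average, and flags chromosomes exceeding twice the genome-average content,
#' overall and for the species-specific subset.
#'
#' @param counts Tibble with columns `chromosome`, `n_genes`, `n_dup_intra`,
#'   `n_dup_inter`, `n_ss_intra`, `n_ss_inter` (gene counts, not pair counts).
#' @return `counts` plus `n_dup`, `duplicate_content` (percent), `n_ss`,
#'   `ss_content`, `fold_enrichment`, `ss_fold_enrichment`, `enriched_2fold`,
#'   `ss_enriched_2fold`, with an `All` row appended.
#' @export
chromosome_summary_from_counts <- function(counts) {
  stopifnot(all(c(
    "chromosome", "n_genes", "n_dup_intra", "n_dup_inter",
    "n_ss_intra", "n_ss_inter"
  ) %in% names(counts)))
  counts <- counts[counts$chromosome != "All", , drop = FALSE]
  genome <- tibble(
    chromosome = "All",
    n_genes = sum(counts$n_genes),
    n_dup_intra = sum(counts$n_dup_intra),
    n_dup_inter = sum(counts$n_dup_inter),
    n_ss_intra = sum(counts$n_ss_intra),
    n_ss_inter = sum(counts$n_ss_inter)
  )
  out <- dplyr::bind_rows(counts, genome) |>
    dplyr::mutate(
      n_dup = .data$n_dup_intra + .data$n_dup_inter,
      duplicate_content = 100 * .data$n_dup / .data$n_genes,
      n_ss = .data$n_ss_intra + .data$n_ss_inter,
      ss_content = 100 * .data$n_ss / .data$n_genes
    )
  genome_content <- out$duplicate_content[out$chromosome == "All"]
  genome_ss <- out$ss_content[out$chromosome == "All"]
  out |>
    dplyr::mutate(
      fold_enrichment = .data$duplicate_content / genome_content,
      ss_fold_enrichment = .data$ss_content / genome_ss,
      enriched_2fold = .data$chromosome != "All" & .data$fold_enrichment > 2,
      ss_enriched_2fold = .data$chromosome != "All" & .data$ss_fold_enrichment > 2
    )
}

#' Identify duplicate gene pairs end to end
#'
#' Convenience wrapper chaining [reciprocal_best_hits()],
#' [apply_duplicate_criteria()], [filter_pseudogenes()] and
#' [classify_pairs()].
#'
#' @param hits Alignment-hit tibble.
#' @param proteins Protein tibble.
#' @param gene_models Gene-model tibble (with lineage flags filled in).
#' @inheritParams apply_duplicate_criteria
#' @return Classified duplicate-pair tibble.
#' @export
identify_duplicates <- function(hits, proteins, gene_models,
                                min_coverage = 0.8, constant = 0.30,
                                long_cutoff = 150, n_param = 6) {
  reciprocal_best_hits(hits) |>
    apply_duplicate_criteria(proteins, min_coverage, constant, long_cutoff, n_param) |>
    filter_pseudogenes(gene_models) |>
    classify_pairs(gene_models)
}
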