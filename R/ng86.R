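# Synonymous/nonsynonymous divergence by Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, on protein-guided codon alignments. Counting
# replaces likelihood estimation deliberately: downstream analyses use dS and
# dN ordinally (ranking, binning, regression), a regime in which counting and
# ML agree closely at moderate divergence, and counting is dependency-free and
# exactly testable against enumeration.

#' Estimate dN and dS for one codon alignment
#'
#' Site counts follow NG86 with stop-codon exclusion: each codon position
#' contributes the fraction of its single-nucleotide changes that are
#' synonymous, changes to stop codons removed from the denominator; sites are
#' averaged over the two sequences, so `S_sites + N_sites` equals three times
#' the number of ungapped codon columns. Differences are averaged over all
#' minimal mutational pathways between each codon pair, pathways through stop
#' codons excluded, all pathways weighted equally. Proportions are corrected
#' with the Jukes-Cantor formula `d = -(3/4) log(1 - (4/3) p)`; a proportion
#' at or beyond 3/4 saturates and the corresponding divergence is reported as
#' `NA` with `saturated = TRUE`.
#'
#' @param ca A `dd_codon_alignment` from [project_to_codons()].
#' @return A one-row tibble: `pair_id`, `dS`, `dN`, `S_sites`, `N_sites`,
#'   `S_diffs`, `N_diffs`, `n_codons` (ungapped columns), `saturated`.
#' @export
estimate_dn_ds <- function(ca) {
  ct <- codon_tables()
  keep <- !is.na(ca$codon_a) & !is.na(ca$codon_b)
  if (!any(keep)) {
    abort("codon alignment has no ungapped columns")
  }
  ia <- codon_to_index(ca$codon_a[keep])
  ib <- codon_to_index(ca$codon_b[keep])
  S_sites <- (sum(ct$syn_sites[ia]) + sum(ct$syn_sites[ib])) / 2
  n <- sum(keep)
  N_sites <- 3 * n - S_sites
  S_diffs <- sum(ct$syn_diff[cbind(ia, ib)])
  N_diffs <- sum(ct$nonsyn_diff[cbind(ia, ib)])
  pS <- S_diffs / S_sites
  pN <- N_diffs / N_sites
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  tibble(
    pair_id = attr(ca, "pair_id") %||% NA_character_,
    dS = dS, dN = dN,
    S_sites = S_sites, N_sites = N_sites,
    S_diffs = S_diffs, N_diffs = N_diffs,
    n_codons = n,
    saturated = is.na(dS) || is.na(dN)
  )
}

jukes_cantor <- function(p) {
  if (p >= 0.75 - 1e-9) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Divergence estimates for a table of duplicate pairs
#'
#' Aligns the two proteins of each pair, projects the alignment onto the
#' coding sequences, and estimates dN/dS. Per-pair failures (e.g. a length
#' mismatch between CDS and protein) are recorded in the `error` column rather
#' than aborting the whole table.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_b` (e.g. from
#'   [classify_pairs()]).
#' @param proteins,cds Sequence tibbles from [read_fasta()].
#' @return A tibble with one row per pair: the [estimate_dn_ds()] columns plus
#'   `gene_a`, `gene_b` and `error` (`NA` when estimation succeeded).
#' @export
divergence_table <- function(pairs, proteins, cds) {
  prot_map <- setNames(proteins$residues, proteins$id)
  cds_map <- setNames(cds$residues, cds$id)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    pid <- paste(ga, gb, sep = "|")
    base <- tibble(pair_id = pid, gene_a = ga, gene_b = gb)
    est <- tryCatch(
      {
        for (g in c(ga, gb)) {
          if (!g %in% names(prot_map)) abort(sprintf("protein '%s' missing", g))
          if (!g %in% names(cds_map)) abort(sprintf("CDS '%s' missing", g))
        }
        aln <- align_proteins_global(prot_map[[ga]], prot_map[[gb]])
        ca <- project_to_codons(aln, cds_map[[ga]], cds_map[[gb]], pair_id = pid)
        estimate_dn_ds(ca)
      },
      error = function(e) {
        tibble(
          pair_id = pid, dS = NA_real_, dN = NA_real_,
          S_sites = NA_real_, N_sites = NA_real_,
          S_diffs = NA_real_, N_diffs = NA_real_,
          n_codons = NA_integer_, saturated = NA,
          error = conditionMessage(e)
        )
      }
    )
    if (!"error" %in% names(est)) est$error <- NA_character_
    dplyr::left_join(base, est, by = "pair_id")
  })
}
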