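# Small in-code fixture builders shared across test files.

gene_model_row <- function(gene_id, chromosome = "chr1", strand = "+",
                           exons = list(c(1, 300)),
                           biotype = "protein_coding",
                           lineage_specific = FALSE) {
  tibble::tibble(
    gene_id = gene_id, chromosome = chromosome, strand = strand,
    biotype = biotype, lineage_specific = lineage_specific,
    n_exons = length(exons),
    coding_exons = list(tibble::tibble(
      start = vapply(exons, `[`, numeric(1), 1),
      end = vapply(exons, `[`, numeric(1), 2)
    ))
  )
}

hit_row <- function(q, s, pident = 0.9, len = 200, bit = 100) {
  tibble::tibble(
    query_id = q, subject_id = s, percent_identity = pident,
    aligned_length = len, mismatches = round(len * (1 - pident)),
    gap_openings = 0, query_start = 1, query_end = len,
    subject_start = 1, subject_end = len, evalue = 0, bit_score = bit
  )
}

protein_row <- function(id, len = 200) {
  tibble::tibble(
    id = id, kind = "protein",
    residues = paste(rep("A", len), collapse = "")
  )
}

# wide expression tibble from a named list of per-gene FPKM vectors
expression_fixture <- function(profiles, tissues = NULL) {
  n <- length(profiles[[1]])
  tissues <- tissues %||% sprintf("t%d", seq_len(n))
  out <- tibble::tibble(gene_id = names(profiles))
  for (i in seq_len(n)) {
    out[[tissues[i]]] <- unname(vapply(profiles, `[`, numeric(1), i))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small simulated bundle, cached per session to keep the suite fast
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(simulation_config(seed = 424L, n_pairs = 50L))
    }
    cache
  }
})
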