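# Global protein alignment and protein-guided codon projection. The aligner is
# the package's own Needleman-Wunsch with BLOSUM62 scoring and affine gaps
# (opening a gap costs 10, each gapped position a further 0.5), used both to
# align duplicate-pair proteins before dN/dS estimation and to build the
# synthetic all-vs-all hit tables.

blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62
  }
  the$blosum62
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch with BLOSUM62 scoring and affine gap penalties (gap open
#' 10, gap extend 0.5; a gap of length L costs `10 + 0.5 L`). Ties are broken
#' deterministically, preferring a match/mismatch column over a gap in the
#' second sequence over a gap in the first.
#'
#' @param prot_a,prot_b Protein sequences (single strings).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return A `dd_alignment` list: `a_aligned`/`b_aligned` (gapped strings with
#'   `-`), `a_pos`/`b_pos` (1-based residue index per column, `NA` at gaps),
#'   `score`, `n_columns`, `n_identical`, `identity` (identical columns over
#'   all alignment columns, gaps included in the denominator).
#' @export
align_proteins_global <- function(prot_a, prot_b, gap_open = 10, gap_extend = 0.5) {
  if (nchar(prot_a) == 0L || nchar(prot_b) == 0L) {
    abort("cannot align empty protein sequences")
  }
  sm <- blosum62()
  alphabet <- setdiff(rownames(sm), "*")
  av <- strsplit(toupper(prot_a), "")[[1]]
  bv <- strsplit(toupper(prot_b), "")[[1]]
  bad <- setdiff(unique(c(av, bv)), alphabet)
  if (length(bad) > 0L) {
    abort(sprintf("non-amino-acid character(s): %s", paste(bad, collapse = ", ")))
  }
  ai <- match(av, rownames(sm)) - 1L
  bi <- match(bv, rownames(sm)) - 1L
  res <- .nw_align_cpp(ai, bi, sm, gap_open, gap_extend)
  a_chr <- ifelse(is.na(res$a_pos), "-", av[res$a_pos])
  b_chr <- ifelse(is.na(res$b_pos), "-", bv[res$b_pos])
  n_ident <- sum(a_chr != "-" & b_chr != "-" & a_chr == b_chr)
  structure(
    list(
      a_aligned = paste(a_chr, collapse = ""),
      b_aligned = paste(b_chr, collapse = ""),
      a_pos = res$a_pos, b_pos = res$b_pos,
      score = res$score,
      n_columns = length(a_chr),
      n_identical = n_ident,
      identity = n_ident / length(a_chr)
    ),
    class = "dd_alignment"
  )
}

#' @export
print.dd_alignment <- function(x, ...) {
  cat(sprintf(
    "Global protein alignment: %d columns, %.1f%% identity, score %.1f\n",
    x$n_columns, 100 * x$identity, x$score
  ))
  invisible(x)
}

#' Project a protein alignment onto the coding sequences
#'
#' Each aligned residue column becomes the source codon of each sequence; a gap
#' residue becomes a codon gap (`NA`). Terminal stop codons are trimmed before
#' the length check; a CDS whose trimmed length is not three times its protein
#' length, or which contains an internal stop, is an error.
#'
#' @param alignment A `dd_alignment` from [align_proteins_global()].
#' @param cds_a,cds_b Coding sequences of the two proteins.
#' @param pair_id Optional label carried through to downstream tables.
#' @return A `dd_codon_alignment` tibble with columns `codon_a`, `codon_b`
#'   (codon strings or `NA` at gaps), and attributes `pair_id` and
#'   `n_ungapped`.
#' @export
project_to_codons <- function(alignment, cds_a, cds_b, pair_id = NA_character_) {
  ct <- codon_tables()
  prep <- function(cds, pos, label) {
    core <- trim_terminal_stop(gsub("U", "T", toupper(cds)))
    n_res <- sum(!is.na(pos))
    if (nchar(core) != 3L * n_res) {
      abort(sprintf(
        "%s: CDS length %d does not match protein length %d (expected %d nt)",
        label, nchar(core), n_res, 3L * n_res
      ))
    }
    codons <- split_codons(core)
    if (any(ct$is_stop[codon_to_index(codons)])) {
      abort(sprintf("%s: internal stop codon in CDS", label))
    }
    codons
  }
  lab_a <- if (is.na(pair_id)) "sequence a" else paste0(pair_id, " (a)")
  lab_b <- if (is.na(pair_id)) "sequence b" else paste0(pair_id, " (b)")
  codons_a <- prep(cds_a, alignment$a_pos, lab_a)
  codons_b <- prep(cds_b, alignment$b_pos, lab_b)
  out <- tibble(
    codon_a = ifelse(is.na(alignment$a_pos), NA_character_, codons_a[alignment$a_pos]),
    codon_b = ifelse(is.na(alignment$b_pos), NA_character_, codons_b[alignment$b_pos])
  )
  structure(out,
    class = c("dd_codon_alignment", class(out)),
    pair_id = pair_id,
    n_ungapped = sum(!is.na(out$codon_a) & !is.na(out$codon_b))
  )
}
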